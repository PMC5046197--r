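#' Construct a single read fragment
#'
#' A fragment is one row of the weighted fragment matrix: the set of allele
#' calls one read (or read pair) makes at the SNP columns it covers. Columns
#' are 0-based internally; a call carries the allele (0 or 1) and a positive
#' weight, the cost of flipping that call when correcting errors.
#'
#' @param read_id Character scalar naming the read.
#' @param columns Integer vector of 0-based SNP column indices, strictly
#'   increasing.
#' @param alleles Integer vector of alleles in \{0, 1\}, parallel to `columns`.
#' @param weights Numeric vector of positive flip costs, parallel to `columns`.
#' @return An object of class `"fragment"`.
#' @examples
#' fragment("f2", columns = c(0L, 1L), alleles = c(0L, 1L), weights = c(3, 8))
#' @export
fragment <- function(read_id, columns, alleles, weights) {
  columns <- as.integer(columns)
  alleles <- as.integer(alleles)
  weights <- as.numeric(weights)
  if (length(read_id) != 1L || !is.character(read_id) || is.na(read_id) ||
      !nzchar(read_id)) {
    stop("read_id must be a non-empty character scalar")
  }
  k <- length(columns)
  if (k < 1L) stop("a fragment must carry at least one call")
  if (length(alleles) != k || length(weights) != k) {
    stop("columns, alleles and weights must have equal length")
  }
  if (any(is.na(columns)) || any(columns < 0L)) {
    stop("columns must be non-negative integers")
  }
  if (k > 1L && any(diff(columns) <= 0L)) {
    stop("columns must be strictly increasing (duplicates forbidden)")
  }
  if (any(is.na(alleles)) || any(!alleles %in% c(0L, 1L))) {
    stop("alleles must lie in {0, 1}")
  }
  if (any(is.na(weights)) || any(weights <= 0)) {
    stop("call weights must be positive")
  }
  structure(
    list(read_id = read_id, columns = columns, alleles = alleles,
         weights = weights),
    class = "fragment"
  )
}

#' Construct a weighted fragment matrix
#'
#' The fragment matrix is the solver's input: n reads by m SNP columns with
#' entries in \{0, 1, -\}, where '-' means the read does not call that column,
#' and a positive confidence weight attached to every active call. Optionally
#' carries the 1-based genomic coordinate of each column for VCF export.
#'
#' @param fragments List of [fragment()] objects.
#' @param num_columns Number of SNP columns m; must exceed every call's
#'   column index.
#' @param positions Optional integer vector of m strictly increasing 1-based
#'   genomic positions.
#' @return An object of class `"fragment_matrix"` with elements `fragments`,
#'   `num_columns` and `positions`.
#' @examples
#' # the three-read, two-SNP matrix used throughout the documentation
#' fm <- fragment_matrix(
#'   list(
#'     fragment("f1", c(0, 1), c(1, 1), c(9, 9)),
#'     fragment("f2", c(0, 1), c(0, 1), c(3, 8)),
#'     fragment("f3", 1, 0, 8)
#'   ),
#'   num_columns = 2
#' )
#' @export
fragment_matrix <- function(fragments, num_columns, positions = NULL) {
  num_columns <- as.integer(num_columns)
  if (is.na(num_columns) || num_columns < 0L) {
    stop("num_columns must be a non-negative integer")
  }
  if (!is.list(fragments)) stop("fragments must be a list")
  for (fr in fragments) {
    if (!inherits(fr, "fragment")) stop("fragments must be fragment objects")
    if (max(fr$columns) >= num_columns) {
      stop("fragment '", fr$read_id, "' calls column ", max(fr$columns),
           " outside the declared ", num_columns, " columns")
    }
  }
  ids <- vapply(fragments, function(fr) fr$read_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate read_id in fragment list")
  if (!is.null(positions)) {
    positions <- as.integer(positions)
    if (length(positions) != num_columns) {
      stop("positions must have length num_columns")
    }
    if (any(is.na(positions)) || any(positions < 1L)) {
      stop("positions must be positive integers")
    }
    if (num_columns > 1L && any(diff(positions) <= 0L)) {
      stop("positions must be strictly increasing")
    }
  }
  structure(
    list(fragments = fragments, num_columns = num_columns,
         positions = positions),
    class = "fragment_matrix"
  )
}

#' @export
print.fragment_matrix <- function(x, ...) {
  cat(sprintf("fragment_matrix: %d reads x %d SNP columns\n",
              length(x$fragments), x$num_columns))
  if (!is.null(x$positions)) cat("  with genomic positions\n")
  invisible(x)
}

#' Number of reads in a fragment matrix
#' @param fm A [fragment_matrix()].
#' @return Integer count of fragments (rows).
#' @export
n_fragments <- function(fm) length(fm$fragments)

#' Read a weighted fragment matrix from its text format
#'
#' Parses the package's fragment dialect: a header line
#' `#FRAGMAT v1 columns=<m>`, an optional `#POSITIONS p1 p2 ...` line with m
#' strictly increasing 1-based genomic coordinates, then one line per read of
#' the form `read_id<TAB>col:allele:weight[,col:allele:weight]...` with
#' 1-based column indices. Columns are converted to 0-based indices
#' internally.
#'
#' @param con A file path or text; anything accepted by [readLines()], or a
#'   character vector of lines when `text = TRUE`.
#' @param text If `TRUE`, treat `con` as the lines themselves.
#' @return A [fragment_matrix()].
#' @seealso [write_fragments()]
#' @export
read_fragments <- function(con, text = FALSE) {
  lines <- if (text) unlist(strsplit(con, "\n", fixed = TRUE)) else readLines(con)
  if (length(lines) == 0L) stop("empty input: missing #FRAGMAT header")
  hdr <- lines[[1L]]
  hm <- regmatches(hdr, regexec("^#FRAGMAT v1 columns=([0-9]+)\\s*$", hdr))[[1L]]
  if (length(hm) != 2L) {
    stop("line 1: expected header '#FRAGMAT v1 columns=<m>', got: ", hdr)
  }
  m <- as.integer(hm[[2L]])
  positions <- NULL
  body_start <- 2L
  if (length(lines) >= 2L && startsWith(lines[[2L]], "#POSITIONS")) {
    toks <- strsplit(trimws(sub("^#POSITIONS", "", lines[[2L]])), "\\s+")[[1L]]
    toks <- toks[nzchar(toks)]
    positions <- suppressWarnings(as.integer(toks))
    if (anyNA(positions)) stop("line 2: non-integer value in #POSITIONS")
    if (length(positions) != m) {
      stop("line 2: #POSITIONS lists ", length(positions),
           " coordinates; header declares ", m, " columns")
    }
    body_start <- 3L
  }
  frags <- list()
  if (length(lines) >= body_start) {
    for (i in seq(body_start, length(lines))) {
      ln <- lines[[i]]
      if (!nzchar(trimws(ln))) next
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(parts) != 2L) {
        stop("line ", i, ": expected 'read_id<TAB>calls', got: ", ln)
      }
      read_id <- parts[[1L]]
      call_toks <- strsplit(parts[[2L]], ",", fixed = TRUE)[[1L]]
      fields <- strsplit(call_toks, ":", fixed = TRUE)
      if (any(lengths(fields) != 3L)) {
        stop("line ", i, ": each call must be col:allele:weight")
      }
      cols <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 1L)))
      alls <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
      wts <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
      if (anyNA(cols) || any(cols < 1L)) {
        stop("line ", i, ": columns must be 1-based positive integers")
      }
      if (anyDuplicated(cols)) {
        stop("line ", i, ": duplicate column within read '", read_id, "'")
      }
      if (anyNA(alls) || any(!alls %in% c(0L, 1L))) {
        stop("line ", i, ": allele outside {0,1}")
      }
      if (anyNA(wts) || any(wts <= 0)) {
        stop("line ", i, ": non-positive or malformed weight")
      }
      o <- order(cols)
      fr <- tryCatch(
        fragment(read_id, cols[o] - 1L, alls[o], wts[o]),
        error = function(e) stop("line ", i, ": ", conditionMessage(e),
                                 call. = FALSE)
      )
      if (max(fr$columns) >= m) {
        stop("line ", i, ": column ", max(fr$columns) + 1L,
             " exceeds declared column count ", m)
      }
      frags[[length(frags) + 1L]] <- fr
    }
  }
  fragment_matrix(frags, m, positions)
}

#' Write a fragment matrix in its text format
#'
#' Inverse of [read_fragments()]: emits the `#FRAGMAT v1` header, the
#' `#POSITIONS` line when coordinates are present, and one tab-separated line
#' per read with 1-based columns. `read_fragments(write_fragments(fm))`
#' reproduces `fm` exactly.
#'
#' @param fm A [fragment_matrix()].
#' @param path Optional file path; when `NULL` the lines are returned
#'   invisibly as a character vector.
#' @return Character vector of lines, invisibly.
#' @export
write_fragments <- function(fm, path = NULL) {
  stopifnot(inherits(fm, "fragment_matrix"))
  lines <- sprintf("#FRAGMAT v1 columns=%d", fm$num_columns)
  if (!is.null(fm$positions)) {
    lines <- c(lines, paste("#POSITIONS", paste(fm$positions, collapse = " ")))
  }
  for (fr in fm$fragments) {
    calls <- paste(sprintf("%d:%d:%s", fr$columns + 1L, fr$alleles,
                           format(fr$weights, scientific = FALSE, trim = TRUE)),
                   collapse = ",")
    lines <- c(lines, paste(fr$read_id, calls, sep = "\t"))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Write a phasing as VCF 4.2 text
#'
#' Emits one VCF record per SNP column with `GT` and `PS` FORMAT fields.
#' Sites phased on both haplotypes get a pipe-separated genotype whose two
#' alleles are the haplotype pair at that column, and a `PS` (phase set) tag
#' equal to the 1-based genomic position of the first column of the record's
#' phasing block. Columns where a haplotype carries '-' (no call on that
#' part) are emitted unphased, as `./.` by default or as `0/1` when
#' `unphased_genotype = "het"`.
#'
#' Alleles in the fragment matrix are abstract relabellings, so REF/ALT are
#' written as the placeholder bases A/C.
#'
#' @param result A phasing result from [phase_matrix()].
#' @param fm The phased [fragment_matrix()]; must carry `positions`.
#' @param sample_name Sample column name.
#' @param chrom CHROM field value for every record.
#' @param unphased_genotype `"missing"` (`./.`) or `"het"` (`0/1`).
#' @param path Optional output path.
#' @return Character vector of VCF lines, invisibly.
#' @export
write_phased_vcf <- function(result, fm, sample_name = "SAMPLE",
                             chrom = "1", unphased_genotype = c("missing", "het"),
                             path = NULL) {
  stopifnot(inherits(fm, "fragment_matrix"))
  unphased_genotype <- match.arg(unphased_genotype)
  if (is.null(fm$positions)) {
    stop("fragment matrix has no positions; cannot emit VCF")
  }
  if (length(result$haplotypes[[1L]]) != fm$num_columns) {
    stop("phasing result covers ", length(result$haplotypes[[1L]]),
         " columns but the matrix declares ", fm$num_columns)
  }
  h1 <- result$haplotypes[[1L]]
  h2 <- result$haplotypes[[2L]]
  # phase-set anchor: first column of the block containing each column
  ps_of_col <- rep(NA_integer_, fm$num_columns)
  for (b in result$blocks) {
    cols <- seq(b$col_start, b$col_end)
    ps_of_col[cols + 1L] <- fm$positions[b$col_start + 1L]
  }
  unphased_gt <- if (unphased_genotype == "missing") "./." else "0/1"
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set identifier\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  for (j in seq_len(fm$num_columns)) {
    a1 <- h1[[j]]
    a2 <- h2[[j]]
    phased <- a1 %in% c("0", "1") && a2 %in% c("0", "1")
    if (phased) {
      gt <- paste0(a1, "|", a2)
      fmt <- "GT:PS"
      val <- paste0(gt, ":", ps_of_col[[j]])
    } else {
      fmt <- "GT"
      val <- unphased_gt
    }
    lines <- c(lines, paste(chrom, fm$positions[[j]], ".", "A", "C", ".",
                            "PASS", ".", fmt, val, sep = "\t"))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
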