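#' Simulation parameters for the diploid read generator
#'
#' Defaults mirror the synthetic benchmark design the solver targets:
#' heterozygous-only sites, long reads spanning around ten SNP columns,
#' target coverage 15x and a 1 % per-call substitution rate (5 % being the
#' pessimistic variant), with phred-scaled call weights. Read lengths are
#' measured in covered SNP columns, not bases: the dynamic program only
#' ever sees SNP columns.
#'
#' @param m Number of SNP columns, >= 1.
#' @param coverage Target mean physical coverage (span-active reads per
#'   column), > 0.
#' @param read_len Mean calls per read (mean per end when `paired`).
#' @param paired Simulate read pairs as one fragment with an internal
#'   call-free gap, exercising the span-active convention.
#' @param mean_gap Mean internal gap in columns (paired mode only).
#' @param error_rate Per-call allele flip probability, in [0, 0.5).
#' @param weight_mode `"phred"` (weight = round(-10 log10 error_rate),
#'   capped at 60 when the error rate is 0) or `"fixed"`.
#' @param fixed_weight Weight used in `"fixed"` mode.
#' @param seed Integer seed driving all sampling.
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(m = 1000L, coverage = 15, read_len = 10,
                       paired = FALSE, mean_gap = 2, error_rate = 0.01,
                       weight_mode = c("phred", "fixed"), fixed_weight = 10,
                       seed = 1L) {
  weight_mode <- match.arg(weight_mode)
  m <- as.integer(m)
  stopifnot(m >= 1L, coverage > 0, read_len >= 1,
            error_rate >= 0, error_rate < 0.5, fixed_weight > 0,
            mean_gap >= 1)
  structure(
    list(m = m, coverage = coverage, read_len = read_len,
         paired = isTRUE(paired), mean_gap = mean_gap,
         error_rate = error_rate, weight_mode = weight_mode,
         fixed_weight = fixed_weight, seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Simulate a heterozygous haplotype pair
#'
#' Every site is heterozygous: haplotype 1 is uniform random bits and
#' haplotype 2 its bitwise complement, matching the all-heterozygous site
#' selection of read-based phasing benchmarks.
#'
#' @param m Number of SNP columns.
#' @param seed Optional seed; when `NULL` the current RNG state is used
#'   (so a caller can seed once for a whole pipeline).
#' @return List with integer vectors `h1` and `h2` (`h2 = 1 - h1`).
#' @export
simulate_haplotypes <- function(m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h1 <- sample(0:1, m, replace = TRUE)
  list(h1 = h1, h2 = 1L - h1)
}

# one read's covered columns: geometric-ish length around the mean
sample_len <- function(mean_len) {
  if (mean_len <= 1) return(1L)
  1L + stats::rgeom(1L, 1 / mean_len)
}

#' Simulate error-bearing reads from a haplotype pair
#'
#' Reads get a uniform random start column, a geometric-ish number of
#' consecutive calls around `read_len` (two call runs separated by a
#' call-free gap in paired mode), a fair-coin source haplotype, and each
#' call is flipped independently with probability `error_rate`. Weights
#' follow `weight_mode`. Sampling order per read is fixed (start, lengths,
#' gap, source, error flags), so identical parameters and seed reproduce
#' the matrix and truth exactly.
#'
#' @param haps Haplotype pair from [simulate_haplotypes()].
#' @param params A [sim_params()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return List with `matrix` (a [fragment_matrix()] with positions
#'   1000, 2000, ...) and `truth`: `h1`, `h2`, `source` (source haplotype
#'   per read, 0/1) and `errors` (list of per-call flip indicators).
#' @export
simulate_reads <- function(haps, params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  m <- params$m
  stopifnot(length(haps$h1) == m)
  mean_span <- if (params$paired) params$read_len + params$mean_gap
               else params$read_len
  n_reads <- max(1L, as.integer(round(m * params$coverage / mean_span)))
  weight_of <- function(k) {
    if (params$weight_mode == "fixed") rep(params$fixed_weight, k)
    else rep(min(60, round(-10 * log10(max(params$error_rate, 1e-6)))), k)
  }
  frags <- vector("list", n_reads)
  source <- integer(n_reads)
  errors <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    start <- sample(0:(m - 1L), 1L)
    if (params$paired) {
      len1 <- sample_len(params$read_len / 2)
      len2 <- sample_len(params$read_len / 2)
      gap <- sample_len(params$mean_gap)
      cols <- c(seq(start, start + len1 - 1L),
                seq(start + len1 + gap, start + len1 + gap + len2 - 1L))
    } else {
      len <- sample_len(params$read_len)
      cols <- seq(start, start + len - 1L)
    }
    cols <- cols[cols < m]
    src <- sample(0:1, 1L)
    err <- stats::runif(length(cols)) < params$error_rate
    hap <- if (src == 0L) haps$h1 else haps$h2
    alleles <- ifelse(err, 1L - hap[cols + 1L], hap[cols + 1L])
    frags[[i]] <- fragment(sprintf("r%05d", i), cols, alleles,
                           weight_of(length(cols)))
    source[[i]] <- src
    errors[[i]] <- err
  }
  fm <- fragment_matrix(frags, m, positions = seq_len(m) * 1000L)
  list(matrix = fm,
       truth = list(h1 = haps$h1, h2 = haps$h2, source = source,
                    errors = errors))
}

#' Simulate a complete phasing dataset
#'
#' Seeds the RNG once from `params$seed`, draws the haplotype pair, then
#' the reads. The single seed is the only source of randomness.
#'
#' @param params A [sim_params()].
#' @return As [simulate_reads()].
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  haps <- simulate_haplotypes(params$m)
  simulate_reads(haps, params)
}

#' Write / read the simulation truth file
#'
#' A small TSV carrying the true haplotype strings and each read's source
#' haplotype, for scoring phasings with [phasing_accuracy()].
#'
#' @param truth Truth list from [simulate_reads()].
#' @param fm The matching [fragment_matrix()] (for read ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, fm, path) {
  lines <- c(paste0("#H1\t", paste(truth$h1, collapse = "")),
             paste0("#H2\t", paste(truth$h2, collapse = "")))
  ids <- vapply(fm$fragments, function(fr) fr$read_id, character(1))
  lines <- c(lines, paste(ids, truth$source, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_truth
#' @return `read_truth()`: a truth list with `h1`, `h2` and `source`.
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  h1 <- as.integer(strsplit(sub("^#H1\t", "", lines[[1L]]), "")[[1L]])
  h2 <- as.integer(strsplit(sub("^#H2\t", "", lines[[2L]]), "")[[1L]])
  source <- integer(0)
  if (length(lines) > 2L) {
    parts <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
    source <- as.integer(vapply(parts, `[[`, "", 2L))
    names(source) <- vapply(parts, `[[`, "", 1L)
  }
  list(h1 = h1, h2 = h2, source = source)
}
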