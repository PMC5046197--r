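#' Per-column active-read sets
#'
#' A read is span-active at column j if its first call column <= j <= its
#' last call column; paired-end fragments therefore stay active across their
#' internal call-free gap, which keeps them consistently assigned to one
#' haplotype by the dynamic program (their cost contribution at gap columns
#' is zero). Coverage at a column is the number of span-active reads.
#'
#' @param fm A [fragment_matrix()].
#' @return A list with one entry per column `j = 0..m-1`: a list with
#'   `column` (0-based index), `active` (ascending 1-based fragment indices)
#'   and `coverage`.
#' @export
activity_profile <- function(fm) {
  stopifnot(inherits(fm, "fragment_matrix"))
  m <- fm$num_columns
  active <- vector("list", m)
  for (j in seq_len(m)) active[[j]] <- integer(0)
  for (i in seq_along(fm$fragments)) {
    fr <- fm$fragments[[i]]
    span <- seq(fr$columns[[1L]], fr$columns[[length(fr$columns)]]) + 1L
    for (j in span) active[[j]] <- c(active[[j]], i)
  }
  lapply(seq_len(m), function(j) {
    list(column = j - 1L, active = active[[j]],
         coverage = length(active[[j]]))
  })
}

#' Decompose a fragment matrix into independent phasing blocks
#'
#' Two adjacent columns belong to the same block when at least one read is
#' span-active at both; columns covered by no read separate blocks and belong
#' to none. Blocks share no reads, so each can be phased independently and
#' the per-block optimal costs sum to the global optimum.
#'
#' @param fm A [fragment_matrix()].
#' @return List of blocks; each has `col_start`, `col_end` (0-based,
#'   inclusive) and `fragments` (ascending 1-based fragment indices whose
#'   span lies inside the range).
#' @export
connected_blocks <- function(fm) {
  stopifnot(inherits(fm, "fragment_matrix"))
  m <- fm$num_columns
  if (m == 0L || length(fm$fragments) == 0L) return(list())
  firsts <- vapply(fm$fragments, function(fr) fr$columns[[1L]], integer(1))
  lasts <- vapply(fm$fragments,
                  function(fr) fr$columns[[length(fr$columns)]], integer(1))
  cov <- integer(m)
  for (i in seq_along(firsts)) {
    idx <- seq(firsts[[i]], lasts[[i]]) + 1L
    cov[idx] <- cov[idx] + 1L
  }
  # boundary j-1|j is linked when some read spans it
  linked <- logical(m)  # linked[j+1]: column j-1 and j joined (j >= 1)
  if (m > 1L) {
    for (j in seq_len(m - 1L)) {
      linked[j + 1L] <- any(firsts <= j - 1L & lasts >= j)
    }
  }
  blocks <- list()
  j <- 0L
  while (j < m) {
    if (cov[j + 1L] == 0L) { j <- j + 1L; next }
    start <- j
    while (j + 1L < m && cov[j + 2L] > 0L && linked[j + 2L]) j <- j + 1L
    frs <- which(firsts >= start & lasts <= j)
    blocks[[length(blocks) + 1L]] <-
      list(col_start = start, col_end = j, fragments = frs)
    j <- j + 1L
  }
  blocks
}

#' Prune reads to a maximum per-column coverage
#'
#' Greedy left-to-right heuristic: scan columns in order; at any column whose
#' coverage (among surviving reads) exceeds `max_cov`, drop active reads
#' until the cap holds. Reads are dropped in increasing order of total call
#' weight; ties prefer the read with fewer calls, then the higher fragment
#' index. Surviving fragments are an unmodified subset of the input, so the
#' pruned optimum can only be at most the original wMEC optimum. The rule is
#' deterministic.
#'
#' @param fm A [fragment_matrix()].
#' @param max_cov Coverage cap, >= 1.
#' @return A [fragment_matrix()] with every column's coverage <= `max_cov`.
#' @export
prune_to_max_coverage <- function(fm, max_cov) {
  stopifnot(inherits(fm, "fragment_matrix"))
  max_cov <- as.integer(max_cov)
  if (is.na(max_cov) || max_cov < 1L) stop("max_cov must be >= 1")
  n <- length(fm$fragments)
  if (n == 0L) return(fm)
  firsts <- vapply(fm$fragments, function(fr) fr$columns[[1L]], integer(1))
  lasts <- vapply(fm$fragments,
                  function(fr) fr$columns[[length(fr$columns)]], integer(1))
  tot_w <- vapply(fm$fragments, function(fr) sum(fr$weights), numeric(1))
  n_calls <- vapply(fm$fragments, function(fr) length(fr$columns), integer(1))
  keep <- rep(TRUE, n)
  for (j in seq_len(fm$num_columns) - 1L) {
    act <- which(keep & firsts <= j & lasts >= j)
    excess <- length(act) - max_cov
    if (excess <= 0L) next
    # drop order: smallest total weight, then fewest calls, then highest index
    o <- order(tot_w[act], n_calls[act], -act)
    keep[act[o[seq_len(excess)]]] <- FALSE
  }
  fragment_matrix(fm$fragments[keep], fm$num_columns, fm$positions)
}
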