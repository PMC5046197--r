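#' wMEC cost of a fixed read bipartition
#'
#' Independent scoring path: given an assignment of every read to part 0 or
#' 1, sums over columns the minimum correction cost of making both parts
#' conflict-free (each part taking its cheaper target allele, or the parts
#' forced to complementary alleles under `all_het`). The dynamic program's
#' optimum equals the minimum of this function over all 2^n assignments.
#'
#' @param fm A [fragment_matrix()].
#' @param read_part Integer vector of parts (0/1), one per fragment.
#' @param all_het Enforce complementary part alleles per column.
#' @return Total correction cost.
#' @export
wmec_of_assignment <- function(fm, read_part, all_het = FALSE) {
  stopifnot(inherits(fm, "fragment_matrix"),
            length(read_part) == length(fm$fragments))
  m <- fm$num_columns
  if (m == 0L) return(0)
  # w_to0[j, p+1]: cost of making part p all-0 at column j (sum of weights
  # of allele-1 calls); w_to1 likewise for all-1
  w_to0 <- matrix(0, nrow = m, ncol = 2L)
  w_to1 <- matrix(0, nrow = m, ncol = 2L)
  for (i in seq_along(fm$fragments)) {
    fr <- fm$fragments[[i]]
    p <- read_part[[i]] + 1L
    a1 <- fr$alleles == 1L
    if (any(a1)) {
      idx <- fr$columns[a1] + 1L
      w_to0[idx, p] <- w_to0[idx, p] + fr$weights[a1]
    }
    if (any(!a1)) {
      idx <- fr$columns[!a1] + 1L
      w_to1[idx, p] <- w_to1[idx, p] + fr$weights[!a1]
    }
  }
  if (all_het) {
    sum(pmin(w_to1[, 1L] + w_to0[, 2L], w_to0[, 1L] + w_to1[, 2L]))
  } else {
    sum(pmin(w_to0[, 1L], w_to1[, 1L]) + pmin(w_to0[, 2L], w_to1[, 2L]))
  }
}

#' Exhaustive wMEC optimum (oracle)
#'
#' Brute-force enumeration of all 2^n read bipartitions, scoring each with
#' [wmec_of_assignment()]. Intended as an independent check of the dynamic
#' program on small instances; refuses more than `n_limit` reads. Ties are
#' broken by the smallest assignment mask (bit i = part of read i).
#'
#' @inheritParams wmec_of_assignment
#' @param n_limit Maximum number of reads (default 15).
#' @return List with `cost`, `read_part` and the winning `mask`.
#' @export
brute_force_optimum <- function(fm, all_het = FALSE, n_limit = 15L) {
  stopifnot(inherits(fm, "fragment_matrix"))
  n <- length(fm$fragments)
  if (n > n_limit) {
    stop("refusing exhaustive enumeration of 2^", n, " assignments (limit ",
         n_limit, " reads)")
  }
  if (n == 0L) return(list(cost = 0, read_part = integer(0), mask = 0L))
  best_cost <- Inf
  best_mask <- NA_integer_
  bits <- seq_len(n) - 1L
  for (mask in 0:(2^n - 1)) {
    part <- bitwAnd(bitwShiftR(as.integer(mask), bits), 1L)
    cost <- wmec_of_assignment(fm, part, all_het)
    if (cost < best_cost) {
      best_cost <- cost
      best_mask <- as.integer(mask)
    }
  }
  list(cost = best_cost,
       read_part = bitwAnd(bitwShiftR(best_mask, bits), 1L),
       mask = best_mask)
}

#' Phasing accuracy against known haplotypes
#'
#' Scores a phasing per block against the true haplotype pair, then pools
#' counts across blocks:
#' \describe{
#'   \item{switch_error_rate}{fraction of adjacent phased heterozygous site
#'     pairs within a block whose relative phase disagrees with the truth.}
#'   \item{site_error_rate}{fraction of phased sites whose allele pair
#'     mismatches the truth under the better of the two per-block pair
#'     orientations.}
#'   \item{phased_fraction}{phased columns over phasable columns (columns
#'     inside some block, i.e. coverage >= 1). A column is phased when both
#'     emitted haplotype alleles are 0/1.}
#' }
#' Both error metrics are invariant under swapping the predicted pair.
#'
#' @param result A `"phasing_result"` from [phase_matrix()] (or any list
#'   with `haplotypes` and `blocks`).
#' @param truth List with integer vectors `h1`, `h2` of length m.
#' @return List of the three rates plus the pooled counts
#'   (`n_switch_errors`, `n_adjacent_pairs`, `n_site_errors`, `n_phased`,
#'   `n_phasable`).
#' @export
phasing_accuracy <- function(result, truth) {
  h1 <- result$haplotypes[[1L]]
  h2 <- result$haplotypes[[2L]]
  if (length(truth$h1) != length(h1)) {
    stop("truth haplotypes have length ", length(truth$h1),
         " but the phasing covers ", length(h1), " columns")
  }
  n_sw <- 0L; n_pairs <- 0L; n_site <- 0L; n_phased <- 0L; n_phasable <- 0L
  for (b in result$blocks) {
    cols <- seq(b$col_start, b$col_end) + 1L
    n_phasable <- n_phasable + length(cols)
    p1 <- h1[cols]; p2 <- h2[cols]
    t1 <- truth$h1[cols]; t2 <- truth$h2[cols]
    phased <- p1 %in% c("0", "1") & p2 %in% c("0", "1")
    n_phased <- n_phased + sum(phased)
    if (!any(phased)) next
    a1 <- suppressWarnings(as.integer(p1))
    a2 <- suppressWarnings(as.integer(p2))
    # site errors under the better per-block orientation
    mis_id <- sum(phased & (a1 != t1 | a2 != t2))
    mis_sw <- sum(phased & (a1 != t2 | a2 != t1))
    n_site <- n_site + min(mis_id, mis_sw)
    # switch errors over adjacent phased heterozygous sites
    het <- phased & a1 != a2
    if (sum(het) >= 2L) {
      ori <- as.integer(a1[het] != t1[het])
      n_sw <- n_sw + sum(diff(ori) != 0L)
      n_pairs <- n_pairs + sum(het) - 1L
    }
  }
  rate <- function(num, den) if (den > 0L) num / den else 0
  list(switch_error_rate = rate(n_sw, n_pairs),
       site_error_rate = rate(n_site, n_phased),
       phased_fraction = rate(n_phased, n_phasable),
       n_switch_errors = n_sw, n_adjacent_pairs = n_pairs,
       n_site_errors = n_site, n_phased = n_phased,
       n_phasable = n_phasable)
}
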