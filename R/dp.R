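#' Solver options for the wMEC dynamic program
#'
#' @param all_het Enforce the all-heterozygous assumption: at every column
#'   the two parts are corrected to complementary alleles. Off by default,
#'   in which case each part independently takes its cheaper allele (a
#'   column may then come out homozygous).
#' @param halve_symmetry Exploit the R/S swap symmetry by pinning the first
#'   active read of every column to part 0, enumerating 2^(c-1) masks per
#'   column instead of 2^c. Emitted tables and results are identical to full
#'   enumeration.
#' @param hard_coverage_limit Refuse columns whose coverage would need a
#'   cost table of more than 2^limit entries (default 25, roughly the memory
#'   ceiling of a desktop machine).
#' @param workers Number of parallel workers for chunk evaluation (forked
#'   via the parallel package when > 1). Results are independent of this
#'   setting.
#' @param chunksize Gray ranks per map task (default 4096).
#' @param parallel_threshold Minimum column coverage at which the chunked
#'   map-reduce path is used (default 20); columns below it are evaluated as
#'   a single range.
#' @return A list of class `"phase_options"`.
#' @export
phase_options <- function(all_het = FALSE, halve_symmetry = FALSE,
                          hard_coverage_limit = 25L, workers = 1L,
                          chunksize = 4096L, parallel_threshold = 20L) {
  stopifnot(hard_coverage_limit >= 1, workers >= 1, chunksize >= 1,
            parallel_threshold >= 1)
  structure(
    list(all_het = isTRUE(all_het), halve_symmetry = isTRUE(halve_symmetry),
         hard_coverage_limit = as.integer(hard_coverage_limit),
         workers = as.integer(workers), chunksize = as.integer(chunksize),
         parallel_threshold = as.integer(parallel_threshold)),
    class = "phase_options"
  )
}

#' Binary-reflected Gray code of a rank
#'
#' Maps an enumeration rank to the bipartition mask processed at that rank:
#' `mask = rank XOR (rank >> 1)`. Consecutive ranks yield masks differing in
#' exactly one bit, so a single read moves between parts and the column part
#' costs update in constant time. The mapping also fixes chunk entry points:
#' the chunk starting at rank r begins at Gray mask g(r), e.g. rank 4 of a
#' 3-bit space starts at mask 110 (6), not 100.
#'
#' @param rank Non-negative integer rank(s), below 2^31.
#' @return Integer mask(s) of the same length.
#' @examples
#' gray_rank_to_mask(4)  # 6, i.e. binary 110
#' @export
gray_rank_to_mask <- function(rank) {
  rank <- as.integer(rank)
  if (any(is.na(rank)) || any(rank < 0L)) stop("rank must be >= 0")
  bitwXor(rank, bitwShiftR(rank, 1L))
}

# calls made at column j by its active reads: slot (0-based position within
# activity_j$active), allele, weight. Span-active reads in a gap have no
# entry and contribute zero cost.
column_calls <- function(fm, activity_j) {
  j <- activity_j$column
  slot <- integer(0); allele <- integer(0); weight <- numeric(0)
  for (k in seq_along(activity_j$active)) {
    fr <- fm$fragments[[activity_j$active[[k]]]]
    hit <- match(j, fr$columns)
    if (!is.na(hit)) {
      slot <- c(slot, k - 1L)
      allele <- c(allele, fr$alleles[[hit]])
      weight <- c(weight, fr$weights[[hit]])
    }
  }
  list(slot = slot, allele = allele, weight = weight)
}

#' Four part costs of one bipartition at one column
#'
#' For bipartition `mask` (bit k = part of the k-th active read) returns the
#' cost of making each part all-0 or all-1 at this column: the sum of
#' weights of that part's calls carrying the opposite allele. Part R is the
#' mask-bit-0 part, S the mask-bit-1 part.
#'
#' @param fm A [fragment_matrix()].
#' @param activity_j One entry of [activity_profile()].
#' @param mask Bipartition mask, `0 <= mask < 2^coverage`.
#' @return Named list `w0_r`, `w1_r`, `w0_s`, `w1_s`.
#' @export
column_part_costs <- function(fm, activity_j, mask) {
  cc <- column_calls(fm, activity_j)
  part <- bitwAnd(bitwShiftR(as.integer(mask), cc$slot), 1L)
  w <- function(p, a) sum(cc$weight[part == p & cc$allele == a])
  list(w0_r = w(0L, 1L), w1_r = w(0L, 0L),
       w0_s = w(1L, 1L), w1_s = w(1L, 0L))
}

#' Local correction cost of a bipartition at one column
#'
#' Reference (per-mask) computation of the column-local wMEC cost: each part
#' is made conflict-free by flipping its minority-choice calls. In default
#' mode each part independently picks its cheaper target allele,
#' `min(w0_r, w1_r) + min(w0_s, w1_s)`; under the all-heterozygous
#' assumption the parts are forced to complementary alleles,
#' `min(w1_r + w0_s, w0_r + w1_s)`.
#'
#' @inheritParams column_part_costs
#' @param all_het Enforce complementary part alleles.
#' @return The local correction cost (non-negative number).
#' @export
column_local_cost <- function(fm, activity_j, mask, all_het = FALSE) {
  pc <- column_part_costs(fm, activity_j, mask)
  if (all_het) min(pc$w1_r + pc$w0_s, pc$w0_r + pc$w1_s)
  else min(pc$w0_r, pc$w1_r) + min(pc$w0_s, pc$w1_s)
}

#' Gray-incremental local costs over a rank range
#'
#' Evaluates the column-local cost for every bipartition whose Gray rank
#' lies in `rank_range = c(lo, hi)` (half-open), initialising the part costs
#' from scratch at the first rank and updating them in constant time per
#' step. Bit-exact equal to calling [column_local_cost()] per mask.
#'
#' @inheritParams column_local_cost
#' @param rank_range Integer pair `c(lo, hi)`, `0 <= lo <= hi <= 2^coverage`.
#' @return List with `masks`, `costs` (aligned, in rank order) and
#'   `evaluations` (the number of ranks processed).
#' @export
incremental_column_costs <- function(fm, activity_j, rank_range,
                                     all_het = FALSE) {
  cc <- column_calls(fm, activity_j)
  res <- eval_chunk_kernel(activity_j$coverage, rank_range[[1L]],
                           rank_range[[2L]], cc$slot, cc$allele, cc$weight,
                           integer(0), 0, integer(0), all_het, FALSE)
  list(masks = res$masks, costs = res$costs, evaluations = res$evaluations)
}

#' Project a column cost table onto the reads shared with the next column
#'
#' Two bipartitions of consecutive columns are compatible when every read
#' active in both columns sits in the same part. This reference
#' implementation reduces the full 2^c table of column j-1 to one minimum
#' per assignment of the shared reads, recording the smallest mask attaining
#' each minimum as the backtracking pointer. With no shared reads the table
#' collapses to a single key holding the global column minimum.
#'
#' @param cost_table List with `column` and `costs` (length 2^c, indexed by
#'   mask + 1) as produced by the forward pass.
#' @param activity_prev,activity_cur [activity_profile()] entries of columns
#'   j-1 and j.
#' @return A projection table: list with `shared` (fragment indices),
#'   `min_cost` and `argmin_mask` (each of length 2^|shared|, indexed by
#'   shared-assignment key + 1).
#' @export
project_costs <- function(cost_table, activity_prev, activity_cur) {
  shared <- intersect(activity_prev$active, activity_cur$active)
  masks <- seq_along(cost_table$costs) - 1L
  s <- length(shared)
  if (s == 0L) {
    best <- which.min(cost_table$costs)  # first index = smallest mask
    return(list(shared = integer(0),
                min_cost = cost_table$costs[[best]],
                argmin_mask = masks[[best]]))
  }
  prev_slots <- match(shared, activity_prev$active) - 1L
  key <- integer(length(masks))
  for (b in seq_len(s)) {
    key <- key + bitwAnd(bitwShiftR(masks, prev_slots[[b]]), 1L) *
      as.integer(2^(b - 1L))
  }
  o <- order(key, cost_table$costs, masks)
  first <- o[!duplicated(key[o])]
  ord <- order(key[first])
  list(shared = shared,
       min_cost = cost_table$costs[first][ord],
       argmin_mask = masks[first][ord])
}

# shared-assignment key of a full mask of the current column
shared_key <- function(mask, shared, activity_cur) {
  s <- length(shared)
  if (s == 0L) return(0L)
  slots <- match(shared, activity_cur$active) - 1L
  key <- 0L
  for (b in seq_len(s)) {
    key <- key + bitwAnd(bitwShiftR(as.integer(mask), slots[[b]]), 1L) *
      as.integer(2^(b - 1L))
  }
  key
}

#' Forward pass of the wMEC dynamic program over one block
#'
#' Builds, column by column, the table of minimum cumulative correction
#' costs per bipartition of the column's active reads: the column-local cost
#' plus the cheapest compatible history, read off the projection of the
#' previous column's table onto the shared reads. Columns at or above
#' `options$parallel_threshold` are evaluated through the chunked map-reduce
#' path ([chunk_ranks()], [evaluate_chunk()], [reduce_locals()]); the result
#' is independent of that delegation and of the worker count.
#'
#' @param fm A [fragment_matrix()].
#' @param block One block from [connected_blocks()].
#' @param options A [phase_options()].
#' @param activities Optional precomputed [activity_profile()] of `fm`.
#' @return List with `columns` (0-based), `tables` (per column: `column`,
#'   `costs` indexed by mask + 1), `projections` (per column: the projection
#'   onto the reads shared with the next column; the last one, over an empty
#'   shared set, anchors the optimum), `activities`, `evaluations` (total
#'   bipartition evaluations) and `tasks` (map tasks spawned).
#' @export
dp_forward <- function(fm, block, options = phase_options(),
                       activities = NULL) {
  stopifnot(inherits(fm, "fragment_matrix"))
  if (is.null(activities)) activities <- activity_profile(fm)
  cols <- seq(block$col_start, block$col_end)
  acts <- activities[cols + 1L]
  ncol <- length(cols)
  tables <- vector("list", ncol)
  projections <- vector("list", ncol)
  evaluations <- 0
  tasks <- 0L
  inherited <- NULL
  for (t in seq_len(ncol)) {
    act <- acts[[t]]
    cvg <- act$coverage
    if (cvg > options$hard_coverage_limit) {
      stop("column ", act$column, " has coverage ", cvg,
           ": its cost table would need 2^", cvg,
           " entries, above the hard limit 2^", options$hard_coverage_limit)
    }
    next_shared <- if (t < ncol) {
      intersect(act$active, acts[[t + 1L]]$active)
    } else integer(0)
    step <- parallel_column(fm, act, inherited, next_shared, options)
    tables[[t]] <- list(column = act$column, costs = step$costs)
    projections[[t]] <- step$projection
    evaluations <- evaluations + step$evaluations
    tasks <- tasks + step$tasks
    inherited <- step$projection
  }
  list(block = block, columns = cols, tables = tables,
       projections = projections, activities = acts,
       evaluations = evaluations, tasks = tasks)
}

# per-column target alleles of the chosen bipartition, with deterministic
# tie-breaks: default mode prefers allele 0 per part; all-het mode prefers
# the (R=0, S=1) orientation
column_targets <- function(fm, activity_j, mask, all_het) {
  cc <- column_calls(fm, activity_j)
  part <- bitwAnd(bitwShiftR(as.integer(mask), cc$slot), 1L)
  w <- function(p, a) sum(cc$weight[part == p & cc$allele != a])
  has <- c(any(part == 0L), any(part == 1L))
  if (all_het) {
    if (!any(has)) return(c(NA_integer_, NA_integer_))
    cost10 <- w(0L, 1L) + w(1L, 0L)   # R -> 1, S -> 0
    cost01 <- w(0L, 0L) + w(1L, 1L)   # R -> 0, S -> 1
    if (cost01 <= cost10) c(0L, 1L) else c(1L, 0L)
  } else {
    tgt <- function(p) {
      if (!has[[p + 1L]]) return(NA_integer_)
      if (w(p, 0L) <= w(p, 1L)) 0L else 1L
    }
    c(tgt(0L), tgt(1L))
  }
}

#' Backtrack an optimal phasing from the forward tables
#'
#' Starts from the smallest final-column mask attaining the block optimum
#' and walks backwards through the stored per-boundary argmin masks, which
#' agree with the chosen mask on every shared read. Each read takes the part
#' it holds at its active columns (consistent across columns because reads
#' are span-active over every boundary they cross). Corrections are the
#' calls disagreeing with their part's target allele at each column; their
#' weights sum to the block optimum.
#'
#' @param forward Output of [dp_forward()].
#' @param fm The [fragment_matrix()] that was phased.
#' @param options The [phase_options()] used in the forward pass.
#' @return List with `total_cost`, `read_part` (named integer vector over
#'   the block's fragments), `masks` (chosen mask per column), `targets`
#'   (2 x ncol matrix of per-part target alleles, NA where a part has no
#'   call) and `corrections` (data frame: fragment, read_id, column,
#'   old_allele, weight).
#' @export
backtrack <- function(forward, fm, options = phase_options()) {
  acts <- forward$activities
  ncol <- length(forward$columns)
  final <- forward$projections[[ncol]]
  total <- final$min_cost[[1L]]
  masks <- integer(ncol)
  masks[[ncol]] <- final$argmin_mask[[1L]]
  if (ncol > 1L) {
    for (t in seq(ncol, 2L)) {
      proj <- forward$projections[[t - 1L]]
      key <- shared_key(masks[[t]], proj$shared, acts[[t]])
      masks[[t - 1L]] <- proj$argmin_mask[[key + 1L]]
    }
  }
  # read parts from the chosen masks (consistent across columns)
  read_part <- integer(0)
  for (t in seq_len(ncol)) {
    act <- acts[[t]]
    p <- bitwAnd(bitwShiftR(masks[[t]], seq_along(act$active) - 1L), 1L)
    read_part[as.character(act$active)] <- p
  }
  # corrections and per-column targets
  targets <- matrix(NA_integer_, nrow = 2L, ncol = ncol)
  corr <- list()
  cost_check <- 0
  for (t in seq_len(ncol)) {
    act <- acts[[t]]
    tg <- column_targets(fm, act, masks[[t]], options$all_het)
    targets[, t] <- tg
    cc <- column_calls(fm, act)
    part <- bitwAnd(bitwShiftR(masks[[t]], cc$slot), 1L)
    for (i in seq_along(cc$slot)) {
      tgt <- tg[[part[[i]] + 1L]]
      if (!is.na(tgt) && cc$allele[[i]] != tgt) {
        fi <- act$active[[cc$slot[[i]] + 1L]]
        corr[[length(corr) + 1L]] <- data.frame(
          fragment = fi, read_id = fm$fragments[[fi]]$read_id,
          column = act$column, old_allele = cc$allele[[i]],
          weight = cc$weight[[i]], stringsAsFactors = FALSE)
        cost_check <- cost_check + cc$weight[[i]]
      }
    }
  }
  corrections <- if (length(corr)) do.call(rbind, corr) else
    data.frame(fragment = integer(0), read_id = character(0),
               column = integer(0), old_allele = integer(0),
               weight = numeric(0), stringsAsFactors = FALSE)
  list(total_cost = total, read_part = read_part, masks = masks,
       targets = targets, corrections = corrections,
       correction_weight = cost_check)
}

#' Phase a fragment matrix by weighted minimum error correction
#'
#' The main entry point: decomposes the matrix into independent blocks,
#' runs the fixed-parameter dynamic program over the bipartitions of each
#' block's active reads, and backtracks an optimal phasing. The reported
#' total cost is the exact wMEC optimum (per mode); tie-breaking is
#' deterministic (smallest mask wins everywhere), so repeated runs and any
#' worker count give identical results.
#'
#' @param fm A [fragment_matrix()].
#' @param options A [phase_options()].
#' @return An object of class `"phasing_result"`: `total_cost`; `read_part`
#'   (integer 0/1 per fragment); `haplotypes` (two character vectors over
#'   "0"/"1"/"-" of length m; haplotype 1 is the part-0 consensus);
#'   `corrections` (data frame with 0-based `column`); `blocks`;
#'   `evaluations` and `tasks` counters; `all_het` flag.
#' @examples
#' fm <- fragment_matrix(list(
#'   fragment("f1", c(0, 1), c(1, 1), c(9, 9)),
#'   fragment("f2", c(0, 1), c(0, 1), c(3, 8)),
#'   fragment("f3", 1, 0, 8)), num_columns = 2)
#' res <- phase_matrix(fm)
#' res$total_cost        # 3: flip f2's first call (weight 3)
#' @export
phase_matrix <- function(fm, options = phase_options()) {
  stopifnot(inherits(fm, "fragment_matrix"))
  m <- fm$num_columns
  n <- length(fm$fragments)
  blocks <- connected_blocks(fm)
  activities <- activity_profile(fm)
  h1 <- rep("-", m); h2 <- rep("-", m)
  read_part <- rep(NA_integer_, n)
  total <- 0
  evaluations <- 0
  tasks <- 0L
  corr_list <- list()
  for (b in blocks) {
    fw <- dp_forward(fm, b, options, activities)
    bt <- backtrack(fw, fm, options)
    total <- total + bt$total_cost
    evaluations <- evaluations + fw$evaluations
    tasks <- tasks + fw$tasks
    read_part[as.integer(names(bt$read_part))] <- bt$read_part
    corr_list[[length(corr_list) + 1L]] <- bt$corrections
    for (t in seq_along(fw$columns)) {
      j <- fw$columns[[t]]
      tg <- bt$targets[, t]
      if (options$all_het) {
        # a part with no call takes the complement of the other part
        if (is.na(tg[[1L]]) && !is.na(tg[[2L]])) tg[[1L]] <- 1L - tg[[2L]]
        if (is.na(tg[[2L]]) && !is.na(tg[[1L]])) tg[[2L]] <- 1L - tg[[1L]]
      }
      h1[[j + 1L]] <- if (is.na(tg[[1L]])) "-" else as.character(tg[[1L]])
      h2[[j + 1L]] <- if (is.na(tg[[2L]])) "-" else as.character(tg[[2L]])
    }
  }
  corrections <- if (length(corr_list)) do.call(rbind, corr_list) else
    data.frame(fragment = integer(0), read_id = character(0),
               column = integer(0), old_allele = integer(0),
               weight = numeric(0), stringsAsFactors = FALSE)
  rownames(corrections) <- NULL
  structure(
    list(total_cost = total, read_part = read_part,
         haplotypes = list(h1, h2), corrections = corrections,
         blocks = blocks, evaluations = evaluations, tasks = tasks,
         all_het = options$all_het),
    class = "phasing_result"
  )
}

#' @export
print.phasing_result <- function(x, ...) {
  cat(sprintf("phasing_result: wMEC cost %s over %d block(s), %d correction(s)\n",
              format(x$total_cost), length(x$blocks), nrow(x$corrections)))
  cat(sprintf("  haplotype 1: %s\n", paste(x$haplotypes[[1L]], collapse = "")))
  cat(sprintf("  haplotype 2: %s\n", paste(x$haplotypes[[2L]], collapse = "")))
  invisible(x)
}
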