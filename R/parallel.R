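#' Split a column's Gray-rank space into chunks
#'
#' Partitions the rank space `[0, 2^c)` into contiguous, disjoint ranges of
#' `chunksize` ranks (the last possibly shorter), in order. Each range is an
#' independent map task; its entry mask is the Gray code of its first rank,
#' not the plain binary of that rank (rank 4 of a 3-bit space enters at mask
#' 110).
#'
#' @param c Number of enumerated bits (the column coverage, or coverage - 1
#'   under symmetry halving).
#' @param chunksize Ranks per chunk, >= 1.
#' @return List of integer pairs `c(lo, hi)`, half-open.
#' @examples
#' chunk_ranks(3, 4)                      # [0,4) and [4,8)
#' gray_rank_to_mask(chunk_ranks(3, 4)[[2]][1])  # 6 = binary 110
#' @export
chunk_ranks <- function(c, chunksize) {
  c <- as.integer(c); chunksize <- as.integer(chunksize)
  stopifnot(c >= 0L, chunksize >= 1L)
  space <- 2^c
  starts <- seq(0, space - 1, by = chunksize)
  lapply(starts, function(lo) c(lo, min(lo + chunksize, space)))
}

#' Evaluate one chunk of a column's bipartition space
#'
#' Map phase of the column evaluation: computes the cumulative cost (local
#' correction cost plus cheapest compatible inherited cost) for every
#' bipartition mask in the Gray-rank range, and accumulates this chunk's
#' local minima per assignment of the reads shared with the next column. A
#' pure function of its inputs: no shared state, so any execution schedule
#' of chunks gives the same reduced result.
#'
#' @param fm A [fragment_matrix()].
#' @param activity_j One entry of [activity_profile()].
#' @param rank_range Integer pair `c(lo, hi)`, half-open, within the
#'   enumerated rank space.
#' @param inherited Projection table from the previous column boundary
#'   (see [project_costs()]), or `NULL` for the first column of a block.
#' @param next_shared Fragment indices shared with the next column
#'   (empty for the last column of a block).
#' @param options A [phase_options()]; `all_het` and `halve_symmetry` are
#'   honoured.
#' @return A local-minimum table: list with `rank_range`, `masks`, `costs`
#'   (the cost slice), `shared` (= `next_shared`) and the sparse per-key
#'   minima `local_keys`, `local_min`, `local_argmin` (only keys this chunk
#'   touched), plus `evaluations`.
#' @export
evaluate_chunk <- function(fm, activity_j, rank_range, inherited = NULL,
                           next_shared = integer(0),
                           options = phase_options()) {
  cc <- column_calls(fm, activity_j)
  if (is.null(inherited)) {
    inh_slots <- integer(0); inh_min <- 0
  } else {
    inh_slots <- match(inherited$shared, activity_j$active) - 1L
    if (anyNA(inh_slots)) {
      stop("inherited projection names reads not active at column ",
           activity_j$column)
    }
    inh_min <- inherited$min_cost
  }
  out_slots <- match(next_shared, activity_j$active) - 1L
  if (anyNA(out_slots)) {
    stop("next_shared names reads not active at column ", activity_j$column)
  }
  res <- eval_chunk_kernel(activity_j$coverage, rank_range[[1L]],
                           rank_range[[2L]], cc$slot, cc$allele, cc$weight,
                           inh_slots, inh_min, out_slots,
                           options$all_het, options$halve_symmetry)
  list(rank_range = rank_range, masks = res$masks, costs = res$costs,
       shared = next_shared, local_keys = res$local_keys,
       local_min = res$local_min, local_argmin = res$local_argmin,
       evaluations = res$evaluations)
}

#' Reduce chunk-local minima into a projection table
#'
#' Reduce phase: merges the per-key local minima of disjoint chunks of one
#' column into the global projection table for the next boundary. Ties are
#' broken by the smallest argmin mask, never by arrival order, which makes
#' the result independent of chunking and scheduling.
#'
#' @param locals List of tables from [evaluate_chunk()], covering disjoint
#'   rank ranges of one column.
#' @return A projection table (`shared`, `min_cost`, `argmin_mask`) as in
#'   [project_costs()].
#' @export
reduce_locals <- function(locals) {
  stopifnot(length(locals) >= 1L)
  los <- vapply(locals, function(l) l$rank_range[[1L]], numeric(1))
  his <- vapply(locals, function(l) l$rank_range[[2L]], numeric(1))
  o <- order(los)
  if (any(his[o][-length(o)] > los[o][-1L])) {
    stop("chunk rank ranges overlap; refusing to reduce")
  }
  shared <- locals[[1L]]$shared
  nk <- 2^length(shared)
  min_cost <- rep(Inf, nk)
  argmin <- rep(NA_integer_, nk)
  for (l in locals) {
    if (!identical(l$shared, shared)) {
      stop("chunk tables disagree on the shared-read key space")
    }
    idx <- l$local_keys + 1L
    cur_m <- min_cost[idx]
    cur_a <- argmin[idx]
    take <- l$local_min < cur_m |
      (l$local_min == cur_m & (is.na(cur_a) | l$local_argmin < cur_a))
    min_cost[idx[take]] <- l$local_min[take]
    argmin[idx[take]] <- l$local_argmin[take]
  }
  list(shared = shared, min_cost = min_cost, argmin_mask = argmin)
}

#' Evaluate one column, sequentially or by chunked map-reduce
#'
#' Columns with coverage below `options$parallel_threshold` are evaluated
#' as a single rank range; columns at or above it are split into
#' `options$chunksize`-rank map tasks whose local tables are then reduced.
#' Both paths emit byte-identical cost tables and projections; with
#' `workers > 1` the map tasks run in forked processes (the reduce is
#' order-free, so scheduling cannot change the result).
#'
#' @inheritParams evaluate_chunk
#' @return List with `costs` (full cost table, indexed by mask + 1),
#'   `projection` (for the next boundary), `evaluations` and `tasks` (map
#'   tasks spawned; 0 when the sequential path is taken).
#' @export
parallel_column <- function(fm, activity_j, inherited = NULL,
                            next_shared = integer(0),
                            options = phase_options()) {
  cvg <- activity_j$coverage
  nb <- if (options$halve_symmetry) max(cvg - 1L, 0L) else cvg
  parallelise <- cvg >= options$parallel_threshold
  ranges <- if (parallelise) chunk_ranks(nb, options$chunksize)
            else list(c(0, 2^nb))
  run_one <- function(rng) {
    evaluate_chunk(fm, activity_j, rng, inherited, next_shared, options)
  }
  locals <- if (parallelise && options$workers > 1L && length(ranges) > 1L &&
                .Platform$OS.type == "unix") {
    parallel::mclapply(ranges, run_one, mc.cores = options$workers)
  } else {
    lapply(ranges, run_one)
  }
  costs <- numeric(2^cvg)
  for (l in locals) costs[l$masks + 1L] <- l$costs
  list(costs = costs,
       projection = reduce_locals(locals),
       evaluations = sum(vapply(locals, function(l) l$evaluations,
                                numeric(1))),
       tasks = if (parallelise) length(ranges) else 0L)
}
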