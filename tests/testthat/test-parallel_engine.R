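test_that("chunking partitions the rank space in order", {
  r <- chunk_ranks(3L, 4L)
  expect_equal(r, list(c(0, 4), c(4, 8)))
  # the second chunk enters the Gray sequence at 110, not 100
  expect_identical(gray_rank_to_mask(r[[2L]][[1L]]), 6L)
  expect_equal(chunk_ranks(0L, 4L), list(c(0, 1)))

  set.seed(13)
  for (i in 1:30) {
    c_bits <- pick1(0:16)
    cs <- pick1(c(1L, 3L, 7L, 64L, 4096L))
    rr <- chunk_ranks(c_bits, cs)
    los <- vapply(rr, `[[`, numeric(1), 1L)
    his <- vapply(rr, `[[`, numeric(1), 2L)
    expect_equal(los[[1L]], 0)
    expect_equal(his[[length(his)]], 2^c_bits)
    if (length(rr) > 1L) {
      expect_equal(los[-1L], his[-length(his)])  # contiguous and disjoint
      expect_true(all(his[-length(his)] - los[-length(los)] == cs))
    }
  }
})

test_that("chunked evaluation of a column equals the sequential evaluation", {
  fm <- paper_matrix()
  acts <- activity_profile(fm)
  opts <- phase_options()
  inh <- project_costs(
    list(column = 0L,
         costs = vapply(0:3, function(mk) column_local_cost(fm, acts[[1L]], mk),
                        numeric(1))),
    acts[[1L]], acts[[2L]])
  seq_chunk <- evaluate_chunk(fm, acts[[2L]], c(0L, 8L), inh,
                              options = opts)
  two <- list(evaluate_chunk(fm, acts[[2L]], c(0L, 4L), inh, options = opts),
              evaluate_chunk(fm, acts[[2L]], c(4L, 8L), inh, options = opts))
  merged_masks <- c(two[[1L]]$masks, two[[2L]]$masks)
  merged_costs <- c(two[[1L]]$costs, two[[2L]]$costs)
  expect_equal(merged_masks, seq_chunk$masks)
  expect_identical(merged_costs, seq_chunk$costs)
  expect_equal(reduce_locals(two), reduce_locals(list(seq_chunk)))
  expect_equal(min(seq_chunk$costs), 3)

  # a chunk of length one is the single-mask evaluation
  one <- evaluate_chunk(fm, acts[[1L]], c(2L, 3L), options = opts)
  expect_identical(one$costs,
                   column_local_cost(fm, acts[[1L]], gray_rank_to_mask(2L)))
})

test_that("merged chunk-local tables equal the reference projection", {
  set.seed(17)
  for (i in 1:30) {
    fm <- random_matrix(n_max = 9L, m_max = 5L)
    acts <- activity_profile(fm)
    js <- which(vapply(acts, function(a) a$coverage, integer(1)) > 0L)
    if (length(js) < 2L) next
    a1 <- acts[[js[[1L]]]]; a2 <- acts[[js[[2L]]]]
    cs <- pick1(c(1L, 2L, 3L, 5L))
    opts <- phase_options(chunksize = cs)
    locals <- lapply(chunk_ranks(a1$coverage, cs), function(rng) {
      evaluate_chunk(fm, a1, rng, NULL, intersect(a1$active, a2$active),
                     opts)
    })
    table <- list(column = a1$column,
                  costs = vapply(0:(2^a1$coverage - 1L), function(mk) {
                    column_local_cost(fm, a1, mk)
                  }, numeric(1)))
    expect_equal(reduce_locals(locals), project_costs(table, a1, a2))
  }
})

test_that("the reduce is order-free with smallest-mask tie-breaking", {
  mk <- function(lo, hi, keys, mins, args) {
    list(rank_range = c(lo, hi), shared = c(1L, 2L), local_keys = keys,
         local_min = mins, local_argmin = args)
  }
  a <- mk(0, 4, 0:3, c(5, 2, 7, 1), c(3L, 5L, 6L, 0L))
  b <- mk(4, 8, 0:3, c(5, 3, 6, 1), c(12L, 9L, 8L, 10L))
  r1 <- reduce_locals(list(a, b))
  r2 <- reduce_locals(list(b, a))
  expect_equal(r1, r2)
  expect_equal(r1$min_cost, c(5, 2, 6, 1))
  # equal minima at keys 0 and 3: the smaller mask wins
  expect_equal(r1$argmin_mask, c(3L, 5L, 8L, 0L))
  expect_error(reduce_locals(list(a, mk(2, 6, 0:3, 1:4, 1:4))), "overlap")
})

test_that("the parallel path is byte-identical to the sequential path", {
  fm <- paper_matrix()
  seq_res <- phase_matrix(fm)
  par_res <- phase_matrix(fm, phase_options(parallel_threshold = 1L,
                                            chunksize = 2L, workers = 2L))
  expect_equal(par_res$total_cost, 3)
  expect_identical(serialize(unclass(seq_res[setdiff(names(seq_res), "tasks")]),
                             NULL),
                   serialize(unclass(par_res[setdiff(names(par_res), "tasks")]),
                             NULL))

  set.seed(29)
  for (i in 1:10) {
    fm <- random_matrix()
    base <- phase_matrix(fm, phase_options(parallel_threshold = 1L,
                                           chunksize = 3L, workers = 1L))
    for (w in c(2L, 4L)) {
      alt <- phase_matrix(fm, phase_options(parallel_threshold = 1L,
                                            chunksize = 3L, workers = w))
      expect_identical(serialize(alt, NULL), serialize(base, NULL))
    }
  }
})

test_that("columns below the threshold never spawn map tasks", {
  fm <- paper_matrix()
  quiet <- phase_matrix(fm, phase_options(parallel_threshold = 10L))
  expect_equal(quiet$tasks, 0L)
  loud <- phase_matrix(fm, phase_options(parallel_threshold = 3L,
                                         chunksize = 4L))
  # only the coverage-3 column is chunked: 8 ranks / 4 = 2 tasks
  expect_equal(loud$tasks, 2L)
  expect_equal(loud$total_cost, quiet$total_cost)
})
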