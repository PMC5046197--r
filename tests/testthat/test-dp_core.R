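# direct four-sum recomputation of the part costs, independent of the
# package's column_part_costs
naive_column_cost <- function(fm, act, mask, all_het) {
  w <- matrix(0, 2, 2)  # [part+1, target+1]: cost of flipping to target
  for (k in seq_along(act$active)) {
    fr <- fm$fragments[[act$active[[k]]]]
    hit <- which(fr$columns == act$column)
    if (!length(hit)) next
    p <- bitwAnd(bitwShiftR(mask, k - 1L), 1L)
    for (tgt in 0:1) {
      if (fr$alleles[[hit]] != tgt) {
        w[p + 1L, tgt + 1L] <- w[p + 1L, tgt + 1L] + fr$weights[[hit]]
      }
    }
  }
  if (all_het) min(w[1L, 2L] + w[2L, 1L], w[1L, 1L] + w[2L, 2L])
  else min(w[1L, ]) + min(w[2L, ])
}

test_that("column-local cost matches the worked example and the naive oracle", {
  fm <- paper_matrix()
  acts <- activity_profile(fm)
  # f1 and f2 in one part at column 0: flip f2's 0 (weight 3), not f1's 1
  expect_equal(column_local_cost(fm, acts[[1L]], 0L), 3)
  expect_equal(column_local_cost(fm, acts[[1L]], 3L), 3)
  # splitting the conflicting reads is free
  expect_equal(column_local_cost(fm, acts[[1L]], 1L), 0)
  expect_equal(column_local_cost(fm, acts[[1L]], 2L), 0)

  set.seed(5)
  done <- 0L
  while (done < 200L) {
    fm <- random_matrix()
    acts <- activity_profile(fm)
    act <- acts[[pick1(seq_along(acts))]]
    if (act$coverage == 0L) next
    mask <- pick1(0:(2^act$coverage - 1L))
    ah <- sample(c(TRUE, FALSE), 1L)
    expect_identical(column_local_cost(fm, act, mask, all_het = ah),
                     naive_column_cost(fm, act, mask, ah))
    done <- done + 1L
  }
})

test_that("gray ranks map to masks differing by one bit per step", {
  expect_identical(gray_rank_to_mask(4L), 6L)  # binary 110
  expect_identical(gray_rank_to_mask(0L), 0L)
  g <- gray_rank_to_mask(0:(2^10 - 1L))
  flips <- bitwXor(g[-1L], g[-length(g)])
  popcount <- vapply(flips, function(x) sum(bitwAnd(bitwShiftR(x, 0:10), 1L)),
                     integer(1))
  expect_true(all(popcount == 1L))
  expect_error(gray_rank_to_mask(-1L), ">= 0")
})

test_that("Gray-incremental costs equal per-mask recomputation bit-exactly", {
  fm <- paper_matrix()
  acts <- activity_profile(fm)
  full <- incremental_column_costs(fm, acts[[2L]], c(0L, 8L))
  expect_length(full$costs, 8L)
  expect_equal(full$masks, gray_rank_to_mask(0:7))
  direct <- vapply(full$masks, function(mk) {
    column_local_cost(fm, acts[[2L]], mk)
  }, numeric(1))
  expect_identical(full$costs, direct)
  expect_equal(full$evaluations, 8)

  # a length-1 range is the single-mask evaluation at its Gray entry point
  one <- incremental_column_costs(fm, acts[[2L]], c(5L, 6L))
  expect_identical(one$costs, column_local_cost(fm, acts[[2L]],
                                                gray_rank_to_mask(5L)))

  set.seed(19)
  for (i in 1:25) {
    fm <- random_matrix(n_max = 12L, m_max = 4L)
    acts <- activity_profile(fm)
    cov <- vapply(acts, function(a) a$coverage, integer(1))
    act <- acts[[which.max(cov)]]
    space <- 2^act$coverage
    lo <- pick1(0:(space - 1L))
    hi <- pick1(lo:space)
    if (hi == lo) hi <- lo + 1L
    ah <- i %% 2L == 0L
    inc <- incremental_column_costs(fm, act, c(lo, hi), all_het = ah)
    direct <- vapply(inc$masks, function(mk) {
      column_local_cost(fm, act, mk, all_het = ah)
    }, numeric(1))
    expect_identical(inc$costs, direct)
  }
})

test_that("projection keeps the cheapest compatible history per shared key", {
  fm <- paper_matrix()
  acts <- activity_profile(fm)
  tab <- list(column = 0L,
              costs = vapply(0:3, function(mk) {
                column_local_cost(fm, acts[[1L]], mk)
              }, numeric(1)))
  proj <- project_costs(tab, acts[[1L]], acts[[2L]])
  expect_equal(proj$shared, c(1L, 2L))
  # keys with f1, f2 in the same part inherit the cost-3 correction
  expect_equal(proj$min_cost, c(3, 0, 0, 3))
  expect_equal(proj$argmin_mask, c(0L, 1L, 2L, 3L))

  # identical active sets: the projection is the identity on the table
  fm2 <- fragment_matrix(list(
    fragment("a", c(0L, 1L), c(1L, 0L), c(2, 2)),
    fragment("b", c(0L, 1L), c(0L, 1L), c(3, 3))), 2L)
  acts2 <- activity_profile(fm2)
  tab2 <- list(column = 0L, costs = c(4, 0, 0, 4))
  proj2 <- project_costs(tab2, acts2[[1L]], acts2[[2L]])
  expect_equal(proj2$min_cost, tab2$costs)
  expect_equal(proj2$argmin_mask, 0:3)

  # brute-force oracle: min over all masks projecting to each key
  set.seed(23)
  for (i in 1:30) {
    fm3 <- random_matrix()
    acts3 <- activity_profile(fm3)
    js <- which(vapply(acts3, function(a) a$coverage, integer(1)) > 0L)
    if (length(js) < 2L) next
    j <- js[[1L]]; j2 <- js[[2L]]
    a1 <- acts3[[j]]; a2 <- acts3[[j2]]
    costs <- vapply(0:(2^a1$coverage - 1L), function(mk) {
      column_local_cost(fm3, a1, mk)
    }, numeric(1))
    proj3 <- project_costs(list(column = a1$column, costs = costs), a1, a2)
    shared <- intersect(a1$active, a2$active)
    slots <- match(shared, a1$active) - 1L
    for (key in seq_along(proj3$min_cost) - 1L) {
      if (length(shared) == 0L) {
        projecting <- seq_along(costs) - 1L
      } else {
        masks <- seq_along(costs) - 1L
        keys <- rep(0L, length(masks))
        for (b in seq_along(slots)) {
          keys <- keys + bitwAnd(bitwShiftR(masks, slots[[b]]), 1L) * 2^(b - 1L)
        }
        projecting <- masks[keys == key]
      }
      expect_equal(proj3$min_cost[[key + 1L]], min(costs[projecting + 1L]))
      expect_true(proj3$argmin_mask[[key + 1L]] %in% projecting)
      expect_equal(costs[[proj3$argmin_mask[[key + 1L]] + 1L]],
                   proj3$min_cost[[key + 1L]])
    }
  }
})

test_that("the forward pass reproduces the worked example optimum", {
  fm <- paper_matrix()
  fw <- dp_forward(fm, connected_blocks(fm)[[1L]])
  expect_equal(min(fw$tables[[2L]]$costs), 3)
  expect_equal(fw$projections[[2L]]$min_cost, 3)
  expect_equal(fw$evaluations, 4 + 8)

  # an error-free conflict-free matrix costs nothing
  clean <- fragment_matrix(list(
    fragment("a", c(0L, 1L, 2L), c(1L, 0L, 1L), c(5, 5, 5)),
    fragment("b", c(0L, 1L, 2L), c(0L, 1L, 0L), c(5, 5, 5)),
    fragment("c", c(1L, 2L), c(0L, 1L), c(5, 5))), 3L)
  expect_equal(phase_matrix(clean)$total_cost, 0)
  expect_error(
    dp_forward(fm, connected_blocks(fm)[[1L]],
               phase_options(hard_coverage_limit = 2L)),
    "coverage 3")
})

test_that("backtracking recovers the bipartition, corrections and cost", {
  fm <- paper_matrix()
  res <- phase_matrix(fm)
  expect_equal(res$total_cost, 3)
  expect_equal(res$read_part[[1L]], res$read_part[[2L]])
  expect_false(res$read_part[[3L]] == res$read_part[[1L]])
  expect_equal(nrow(res$corrections), 1L)
  expect_equal(res$corrections$read_id, "f2")
  expect_equal(res$corrections$column, 0L)
  expect_equal(res$corrections$old_allele, 0L)
  expect_equal(res$corrections$weight, 3)

  single <- fragment_matrix(list(fragment("a", c(0L, 1L), c(1L, 0L),
                                          c(2, 2))), 2L)
  rs <- phase_matrix(single)
  expect_equal(rs$total_cost, 0)
  expect_equal(nrow(rs$corrections), 0L)
})

test_that("dp invariants hold on random instances", {
  set.seed(31)
  for (i in 1:40) {
    fm <- random_matrix()
    ah <- i %% 2L == 0L
    opts <- phase_options(all_het = ah)
    res <- phase_matrix(fm, opts)
    # self-consistency: rescoring the returned assignment gives the optimum
    expect_equal(wmec_of_assignment(fm, res$read_part, all_het = ah),
                 res$total_cost)
    # conservation: total cost is the summed correction weight, and the
    # corrected matrix is conflict-free under the returned bipartition
    expect_equal(sum(res$corrections$weight), res$total_cost)
    corrected <- fm
    if (nrow(res$corrections)) {
      for (r in seq_len(nrow(res$corrections))) {
        fi <- res$corrections$fragment[[r]]
        fr <- corrected$fragments[[fi]]
        hit <- which(fr$columns == res$corrections$column[[r]])
        fr$alleles[[hit]] <- 1L - fr$alleles[[hit]]
        corrected$fragments[[fi]] <- fr
      }
    }
    expect_equal(wmec_of_assignment(corrected, res$read_part, all_het = ah), 0)
    # the constrained all-het optimum can never beat the default optimum
    if (ah) {
      expect_gte(res$total_cost, phase_matrix(fm)$total_cost)
    }
    # symmetry: complementing every mask leaves each cost table invariant
    if (i <= 10L) {
      b <- connected_blocks(fm)[[1L]]
      fw <- dp_forward(fm, b, opts)
      for (tb in fw$tables) {
        comp <- bitwXor(seq_along(tb$costs) - 1L, length(tb$costs) - 1L)
        expect_equal(tb$costs, tb$costs[comp + 1L])
      }
    }
  }
})
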