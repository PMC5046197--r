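# fixtures built in code; all randomness flows from set.seed() in the tests

# the three-read, two-SNP matrix used as the worked example everywhere:
# f1 = (1_9, 1_9), f2 = (0_3, 1_8), f3 = (-, 0_8)
paper_matrix <- function(positions = NULL) {
  fragment_matrix(list(
    fragment("f1", c(0L, 1L), c(1L, 1L), c(9, 9)),
    fragment("f2", c(0L, 1L), c(0L, 1L), c(3, 8)),
    fragment("f3", 1L, 0L, 8)
  ), num_columns = 2L, positions = positions)
}

pick1 <- function(x) x[sample.int(length(x), 1L)]

# random small matrix with integer weights and occasional internal gaps
# (paired-end-like reads); uses the current RNG stream
random_matrix <- function(n_max = 8L, m_max = 6L, w_max = 10L) {
  n <- pick1(2:n_max)
  m <- pick1(2:m_max)
  frags <- vector("list", n)
  for (i in seq_len(n)) {
    first <- pick1(0:(m - 1L))
    last <- pick1(first:(m - 1L))
    span <- first:last
    cols <- if (length(span) > 2L) {
      mid <- span[-c(1L, length(span))]
      sort(c(first, last, mid[stats::runif(length(mid)) < 0.7]))
    } else span
    frags[[i]] <- fragment(paste0("r", i), cols,
                           sample(0:1, length(cols), replace = TRUE),
                           sample(seq_len(w_max), length(cols),
                                  replace = TRUE))
  }
  fragment_matrix(frags, m)
}

# the block-restricted submatrix (same column indexing)
block_submatrix <- function(fm, block) {
  fragment_matrix(fm$fragments[block$fragments], fm$num_columns)
}
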