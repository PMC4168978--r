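# Independent oracles used across test files. These deliberately avoid the
# package's internal algorithms (neighbor tables, Walsh transforms) so that
# agreement is a genuine cross-check.

# adjacency matrix built from pairwise Hamming distances
oracle_adjacency <- function(L) {
  n <- 2^L
  A <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      A[a, b] <- as.integer(hamming_distance(a - 1L, b - 1L, L) == 1L)
    }
  }
  A
}

# recombination map by direct enumeration of (parent a, parent b, mask m):
# offspring = (a AND m) OR (b AND NOT m), each mask with weight 2^-L
oracle_recombination <- function(p, L) {
  n <- 2^L
  q <- numeric(n)
  for (a in seq_len(n) - 1L) {
    for (b in seq_len(n) - 1L) {
      w <- p[a + 1L] * p[b + 1L] / n
      if (w == 0) next
      for (m in seq_len(n) - 1L) {
        g <- bitwOr(bitwAnd(a, m), bitwAnd(b, bitwAnd(bitwNot(m), n - 1L)))
        q[g + 1L] <- q[g + 1L] + w
      }
    }
  }
  q
}

# random point on the simplex
random_simplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}

# per-locus mutant-allele frequencies of a counts/frequency vector
allele_freqs <- function(x, L) {
  g <- seq_along(x) - 1L
  vapply(seq_len(L) - 1L, function(i) {
    sum(x[bitwAnd(bitwShiftR(g, i), 1L) == 1L]) / sum(x)
  }, numeric(1))
}

# plain data.frame copy of a trajectory (drops class and engine attributes,
# keeping only the recorded columns)
bare_df <- function(x) as.data.frame(unclass(x)[names(x)])

# synthetic evo_trajectory with a given frequency matrix (t x 2^L)
synthetic_trajectory <- function(freq, land, N = 1000) {
  n_t <- nrow(freq)
  modal <- apply(freq, 1, which.max) - 1L
  modal_f <- apply(freq, 1, max)
  df <- data.frame(
    t = seq_len(n_t) - 1L,
    mean_fitness = as.numeric(freq %*% land$F),
    max_fitness = apply(freq, 1, function(p) max(land$F[p > 0])),
    entropy = apply(freq, 1, entropy),
    additive_variance = NA_real_,
    modal_genotype = modal,
    modal_frequency = modal_f,
    trapped = FALSE,
    reset_flag = FALSE
  )
  structure(df, class = c("evo_trajectory", "data.frame"),
            landscape_params = land$params,
            dynamics_params = list(N = N), engine = "finite",
            frequencies = freq)
}
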