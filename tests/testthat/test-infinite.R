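test_that("adjacency matrix: examples and the path-counting identity", {
  expect_identical(adjacency_matrix(1), matrix(c(0, 1, 1, 0), 2))
  A2 <- adjacency_matrix(2)
  expect_true(all(rowSums(A2) == 2))
  expect_identical(A2, t(A2))
  for (L in 2:5) {
    A <- adjacency_matrix(L)
    expect_identical(A, oracle_adjacency(L))
    expect_true(all(diag(A %*% A) == L))  # d(a,b)=1 paths out and back
  }
})

test_that("mutation operators are column-stochastic with the right limits", {
  # L = 1 closed form: M_inf = 1/(1+mu) [[1, mu], [mu, 1]]
  mu <- 0.37
  Minf <- mutation_operator(1, mu, Inf)$matrix
  expect_equal(Minf, matrix(c(1, mu, mu, 1), 2) / (1 + mu), tolerance = 1e-14)
  expect_equal(mutation_operator(3, 0, Inf)$matrix, diag(8))
  expect_equal(mutation_operator(3, 0, 1)$matrix, diag(8))
  for (ord in list(1, 2, 5, Inf)) {
    M <- mutation_operator(4, 0.2, ord)$matrix
    expect_true(all(abs(colSums(M) - 1) < 1e-12))
    expect_true(all(M >= 0))
  }
  expect_error(mutation_operator(3, 1, Inf), "mu must be")
  # matrix-free application agrees with the explicit matrices
  p <- random_simplex(16)
  nidx <- getFromNamespace("neighbor_idx", "recombdyn")(4)
  am <- getFromNamespace("apply_mutation", "recombdyn")
  bk <- getFromNamespace("backend_double", "recombdyn")
  for (ord in list(1, 3, Inf)) {
    M <- mutation_operator(4, 0.15, ord)$matrix
    expect_equal(am(p, 4, 0.15, ord, nidx, bk), as.numeric(M %*% p),
                 tolerance = 1e-13)
  }
})

test_that("M_inf equals the summed geometric series", {
  L <- 6; mu <- 0.1
  A <- adjacency_matrix(L)
  S <- diag(2^L)
  term <- diag(2^L)
  for (m in 1:50) {
    term <- (mu / L) * (term %*% A)
    S <- S + term
  }
  expect_lt(max(abs(mutation_operator(L, mu, Inf)$matrix - (1 - mu) * S)),
            1e-12)
})

test_that("recombination map: fixed points, worked example, marginals", {
  # point masses are fixed
  for (g in c(0L, 5L)) {
    p <- replace(numeric(8), g + 1, 1)
    expect_equal(recombination_map(p, 3), p, tolerance = 1e-14)
  }
  # L = 2 with p(00) = p(11) = 1/2: brute-force sum over the 4 parent pairs
  expect_equal(recombination_map(c(.5, 0, 0, .5), 2),
               c(3, 1, 1, 3) / 8, tolerance = 1e-14)
  # uniform distribution (linkage equilibrium at allele frequency 1/2)
  u <- rep(1 / 32, 32)
  expect_equal(recombination_map(u, 5), u, tolerance = 1e-14)
  # any product (linkage-equilibrium) distribution is fixed
  f <- c(0.2, 0.55, 0.9)
  pprod <- apply(expand.grid(a = 0:1, b = 0:1, cc = 0:1), 1, function(g) {
    prod(ifelse(g == 1, f, 1 - f))
  })
  expect_equal(recombination_map(pprod, 3), pprod, tolerance = 1e-14)
  # single-locus marginals preserved for random p at L = 8
  set.seed(18)
  p <- random_simplex(256)
  q <- recombination_map(p, 8)
  expect_equal(allele_freqs(q, 8), allele_freqs(p, 8), tolerance = 1e-13)
  expect_lt(abs(sum(q) - 1), 1e-13)
})

test_that("walsh and brute-force recombination agree with an independent
           enumeration oracle for L <= 3", {
  set.seed(19)
  for (L in 1:3) {
    for (i in 1:3) {
      p <- random_simplex(2^L)
      qo <- oracle_recombination(p, L)
      expect_lt(max(abs(recombination_map(p, L, "walsh") - qo)), 1e-14)
      expect_lt(max(abs(recombination_map(p, L, "brute") - qo)), 1e-14)
    }
  }
})

test_that("one infinite step: neutral identity and mass conservation", {
  land <- make_fixture("two_peak_L3")$landscape
  neutral <- land; neutral$F <- rep(1, 8)
  p <- replace(numeric(8), 1, 1)
  st <- step_infinite(p, neutral, mu = 0, r = 0)
  expect_identical(st$p, p)
  set.seed(20)
  for (i in 1:10) {
    p <- random_simplex(8)
    st <- step_infinite(p, land, mu = 0.1, r = 0.5)
    expect_lt(st$simplex_dev, 1e-12)
    expect_lt(abs(sum(st$p) - 1), 1e-12)
  }
})

test_that("infinite trajectories: determinism, positivity, distance decay", {
  land <- generate_landscape(landscape_params(6, "rmf", c = 1, lambda = 1,
                                              seed = 33))
  tr1 <- run_infinite(land, 0.05, 0.5, 30)
  tr2 <- run_infinite(land, 0.05, 0.5, 30)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  tr0 <- run_infinite(land, 0.05, 0.5, 0, start = 9L)
  expect_equal(tr0$entropy, 0)
  expect_equal(tr0$mean_fitness, land$F[10])
  # after one step every genotype is populated, shell means decaying with
  # Hamming distance from the start (strictly positive fitness everywhere,
  # so selection removes no genotype)
  addl <- generate_landscape(landscape_params(6, "rmf", c = 1, lambda = 0.5,
                                              seed = 34))
  tra <- run_infinite(addl, 0.01, 0, 1, keep_frequencies = TRUE)
  p1 <- attr(tra, "frequencies")[2, ]
  expect_true(all(p1 > 0))
  d <- hamming_distance(0:63, rep(0L, 64), 6)
  shell_means <- tapply(p1, d, mean)
  expect_true(all(diff(shell_means) < 0))
})

test_that("with r = 0 and small mu the population concentrates near the
           global additive optimum (mutation-selection balance)", {
  land <- generate_landscape(landscape_params(6, "additive", c = 1))
  tr <- run_infinite(land, 0.005, 0, 400, keep_frequencies = TRUE)
  pfin <- attr(tr, "frequencies")[401, ]
  expect_gt(pfin[64], 0.9)  # all-mutant genotype dominates
  expect_gt(tr$mean_fitness[401], 5.8)
  # mean fitness eventually non-decreasing after the initial transient
  v <- diff(tr$mean_fitness[50:401])
  expect_true(all(v > -1e-10))
})

test_that("high-precision mode keeps sub-1e-30 mass and tiny frequencies", {
  land <- generate_landscape(landscape_params(5, "rmf", c = 1, lambda = 1,
                                              seed = 66))
  trd <- run_infinite(land, 0.02, 0.3, 40)
  trq <- run_infinite(land, 0.02, 0.3, 40, precision = "dd",
                      keep_frequencies = TRUE)
  expect_lt(attr(trq, "max_simplex_dev"), 1e-30)
  expect_lt(max(abs(trd$mean_fitness - trq$mean_fitness)), 1e-10)
  expect_true(all(attr(trq, "frequencies")[41, ] > 0))
  expect_error(run_infinite(land, 0.02, 0.3, 2, precision = "dd", L_cap = 4),
               "exceeds the high-precision cap")
})
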