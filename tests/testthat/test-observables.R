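test_that("entropy: bounds and worked values", {
  expect_equal(entropy(c(0, 1, 0, 0)), 0)
  expect_equal(entropy(rep(1 / 16, 16)), 4 * log(2))
  expect_equal(entropy(c(0.5, 0.5)), log(2))
  expect_error(entropy(c(-0.1, 1.1)), "negative")
  set.seed(24)
  for (i in 1:20) {
    p <- random_simplex(32)
    s <- entropy(p)
    expect_gte(s, 0)
    expect_lte(s, 5 * log(2) + 1e-12)
  }
})

test_that("additive variance scales distance variance by c^2", {
  fx <- make_fixture("two_locus_valley")
  land <- fx$landscape  # c = 0.5
  expect_equal(as.numeric(additive_variance(c(0, 1, 0, 0), land)), 0)
  v <- additive_variance(fx$expected$p_example, land)
  expect_equal(as.numeric(v), fx$expected$additive_variance)
  expect_equal(attr(v, "distance_variance"), 1)
  hoc <- make_fixture("two_peak_L3")$landscape  # c = 0
  expect_equal(as.numeric(additive_variance(random_simplex(8), hoc)), 0)
  nk <- generate_landscape(landscape_params(3, "nk", nk_K = 1, seed = 4))
  expect_error(additive_variance(rep(1 / 8, 8), nk), "reference sequence")
})

test_that("velocity: differences, smoothing, and the crossing duality", {
  expect_equal(velocity(rep(2, 10)), rep(0, 9))
  expect_equal(velocity(c(0, 1, 3)), c(1, 2))
  expect_error(velocity(3), "shorter than 2")
  sm <- velocity(c(0, 1, 3, 6, 10), window = 3)
  expect_true(is.na(sm[1]) && is.na(sm[4]))
  expect_equal(sm[2:3], c(2, 3))
  # duality: for paired fitness series, sign changes of v_r - v_nr coincide
  # with local extrema of their difference
  set.seed(25)
  fr <- cumsum(runif(60, -1, 1.2))
  fnr <- cumsum(runif(60, -1, 1.2))
  dv <- velocity(fr) - velocity(fnr)
  dF <- fr - fnr
  expect_equal(dv, diff(dF))
  interior_extrema <- which(diff(sign(diff(dF))) != 0) + 1L
  crossings <- which(sign(dv[-1]) != sign(dv[-length(dv)])) + 1L
  expect_identical(interior_extrema, crossings)
})

test_that("trap events open on local maxima and close on escape", {
  fx <- make_fixture("two_locus_valley")
  land <- fx$landscape  # maxima at 00 and 11
  n_t <- 61
  freq <- matrix(0.01, n_t, 4)
  freq[, 2] <- 1 - 3 * 0.01
  freq[11:50, ] <- 0.002
  freq[11:50, 1] <- 0.99  # genotype 00 (a local maximum) near fixation
  freq[51:61, ] <- 0.2
  freq[51:61, 4] <- 0.4   # 00 drops to 0.2 < theta_escape
  freq <- freq / rowSums(freq)
  traj <- synthetic_trajectory(freq, land)
  ev <- detect_trap_escape(traj, land, theta_trap = 0.95, theta_escape = 0.5)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$genotype, 0L)
  expect_identical(ev$t_start, 10L)
  expect_identical(ev$t_end, 50L)
  expect_identical(ev$distance_from_start, 1L)

  # never reaching theta_trap: no events
  low <- matrix(1 / 4, 8, 4)
  ev2 <- detect_trap_escape(synthetic_trajectory(low, land), land)
  expect_identical(nrow(ev2), 0L)

  # near-fixation on a genotype that is not a local maximum: no event
  freq3 <- matrix(0.005, 20, 4)
  freq3[, 2] <- 1 - 3 * 0.005  # genotype 01, a valley genotype
  ev3 <- detect_trap_escape(synthetic_trajectory(freq3 / rowSums(freq3), land),
                            land)
  expect_identical(nrow(ev3), 0L)
  expect_error(detect_trap_escape(traj, land, 0.5, 0.9), "theta")
})

test_that("escape fraction counts closures within the horizon", {
  ev <- data.frame(genotype = rep(0L, 10),
                   t_start = seq(10, 100, by = 10),
                   t_end = c(15, 25, 35, 45, NA, NA, NA, NA, NA, NA),
                   distance_from_start = 1L)
  expect_equal(escape_fraction(ev), 0.4)
  expect_equal(escape_fraction(ev, horizon = 50), 4 / 5)
  all_closed <- transform(ev, t_end = t_start + 1)
  expect_equal(escape_fraction(all_closed), 1)
  expect_equal(escape_fraction(ev, baseline = escape_fraction(ev)), 1)
  none <- ev[0, ]
  expect_true(is.na(escape_fraction(none)))
})

test_that("first trap distance", {
  ev <- data.frame(genotype = c(15L, 3L), t_start = c(40L, 7L),
                   t_end = c(NA, 20L), distance_from_start = c(4L, 2L))
  expect_identical(first_trap_distance(ev, 0L, 4), 2L)   # earliest event
  expect_identical(first_trap_distance(ev[1, ], 0L, 4), 4L)  # antipode
  trapped_at_start <- data.frame(genotype = 5L, t_start = 0L, t_end = NA,
                                 distance_from_start = 0L)
  expect_identical(first_trap_distance(trapped_at_start, 5L, 4), 0L)
  expect_true(is.na(first_trap_distance(ev[0, ], 0L, 4)))
})

test_that("delta series: tie convention, fractions, linearity", {
  land <- make_fixture("two_peak_L3")$landscape
  freq <- matrix(1 / 8, 5, 8)
  base <- synthetic_trajectory(freq, land)
  d0 <- delta_series(list(base, base), list(base, base))
  expect_true(all(d0$delta_F == 0))
  expect_true(all(d0$P_plus == 0.5))
  expect_true(all(d0$delta_S == 0))
  # 4 pairs, recombining fitter in 3
  up <- base; up$mean_fitness <- base$mean_fitness + 1
  down <- base; down$mean_fitness <- base$mean_fitness - 1
  d <- delta_series(list(up, up, up, down), list(base, base, base, base))
  expect_true(all(d$P_plus == 0.75))
  expect_true(all(abs(d$delta_F - 0.5) < 1e-12))
  # difference of means equals mean of differences
  m <- attr(d, "delta_F_runs")
  expect_equal(rowMeans(m), d$delta_F)
  expect_error(delta_series(list(base), list(base[1:3, ])), "length mismatch")
})

test_that("advantage summary: maxima, ties, crossing time", {
  s <- advantage_summary(c(0, 0.1, 0.3, 0.2, -0.05))
  expect_identical(s$t_max, 2L)
  expect_equal(s$delta_max, 0.3)
  expect_identical(s$t_zero, 4L)
  s2 <- advantage_summary(c(-0.1, -0.2, -0.5))
  expect_identical(s2$t_max, 0L)
  expect_equal(s2$delta_max, -0.1)
  s3 <- advantage_summary(c(0.1, 0.4, 0.2))
  expect_true(is.na(s3$t_zero))
  # earliest argmax on ties
  s4 <- advantage_summary(c(0, 1, 1, 0))
  expect_identical(s4$t_max, 1L)
})

test_that("off-peak coefficient of variation", {
  land <- make_fixture("two_locus_valley")$landscape
  N <- 100
  freq <- rbind(c(0.95, 0.05, 0, 0),
                c(0.90, 0.10, 0, 0),
                c(0.85, 0.15, 0, 0))
  traj <- synthetic_trajectory(freq, land, N = N)
  expect_equal(offpeak_cv(list(traj), land), 0.5)  # sd(5,10,15)/mean = 0.5
  const <- synthetic_trajectory(rbind(c(0.9, 0.1, 0, 0), c(0.9, 0.1, 0, 0)),
                                land, N = N)
  expect_equal(offpeak_cv(list(const), land), 0)
  # on a rugged ensemble the statistic is a well-defined positive number
  rland <- generate_landscape(landscape_params(4, "rmf", c = 1, lambda = 3,
                                               seed = 26))
  trs <- lapply(1:6, function(i) {
    run_finite(rland, dynamics_params(500, 0.02, 1, seed = 300 + i), 200)
  })
  cv <- offpeak_cv(trs, rland)
  expect_true(is.finite(cv) && cv > 0)
})
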