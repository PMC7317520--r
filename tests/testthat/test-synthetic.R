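test_that("simulator reduces to closed forms in degenerate cases", {
  E <- demo_em_matrix()
  # zero kinetics, zero feed: constant concentrations
  sc0 <- simulation_scenario(
    kinetics = function(c) c(EM1 = 0, EM2 = 0, EM3 = 0, EM4 = 0),
    feed = NULL, t_end = 50, sample_times = seq(0, 50, by = 10))
  sim0 <- simulate_scenario(sc0)
  expect_lt(max(abs(sweep(sim0$conc, 2L, sim0$conc[1, ]))), 1e-8)

  # single mode, constant specific rate, constant Xv: linear decrease
  E1 <- matrix(c(-1, 1, 0) / sqrt(2), 3, 1,
               dimnames = list(c("A", "B", "Xv"), "m"))
  E1["Xv", ] <- 0
  sc1 <- simulation_scenario(
    E = E1, kinetics = function(c) c(m = 0.2),
    c0 = c(A = 10, B = 0, Xv = 2), t_end = 10, feed = NULL,
    noise = noise_model(a = c(A = 0, B = 0, Xv = 0),
                        b = c(A = 0.01, B = 0.01, Xv = 0.01)),
    sample_times = seq(0, 10, by = 1))
  sim1 <- simulate_scenario(sc1)
  slope <- -1 / sqrt(2) * 0.2 * 2          # e_A * r * Xv
  expect_equal(sim1$conc[, "A"], 10 + slope * sim1$times,
               tolerance = 1e-7)

  # conserved moiety: left-null-space weights of E stay constant
  sc <- simulation_scenario(feed = NULL)
  sim <- simulate_scenario(sc)
  w <- svd(t(sc$E), nv = nrow(sc$E))$v[, nrow(sc$E)]  # left null vector
  m0 <- sum(w * sim$conc[1, ])
  drift <- apply(sim$conc, 1L, function(cc) sum(w * cc)) - m0
  expect_lt(max(abs(drift)) / max(1, abs(m0)), 1e-6)
})

test_that("measurement sampling obeys the noise convention and seed", {
  sc <- simulation_scenario()
  sim <- simulate_scenario(sc)
  # zero noise model: measurements equal truth at the sample times
  m0 <- noise_model(a = setNames(rep(0, 7), rownames(sc$E)),
                    b = setNames(rep(0, 7), rownames(sc$E)))
  d0 <- sample_measurements(sim, model = m0, rng = 1)
  truth <- sim$conc_fun(sc$sample_times)
  for (s in rownames(sc$E))
    expect_equal(d0$value[d0$species == s], unname(truth[, s]),
                 tolerance = 1e-9)
  # default convention: 1.96 sigma = 5% of magnitude
  d <- sample_measurements(sim, rng = 2)
  glc <- d[d$species == "Glc", ]
  expect_equal(1.96 * glc$sigma[glc$value > 1],
               0.05 * truth[glc$value > 1, "Glc"], tolerance = 0.02)
  expect_identical(sample_measurements(sim, rng = 5)$value,
                   sample_measurements(sim, rng = 5)$value)
})

test_that("pseudo-batch shift inverts feed dilution and gas transfer", {
  sc <- simulation_scenario()
  sim <- simulate_scenario(sc)
  st <- sc$sample_times
  m0 <- noise_model(a = setNames(rep(0, 7), rownames(sc$E)),
                    b = setNames(rep(0, 7), rownames(sc$E)))
  d <- sample_measurements(sim, model = m0, rng = 1)

  # zero feed, zero gas: identity
  d_id <- pseudo_batch_shift(d, feed_rate = function(t) 0, V0 = 1)
  expect_equal(d_id$value, d$value, tolerance = 1e-9)

  # pure water feed: shifted values equal c * V / V_ref
  sc_w <- simulation_scenario(feed = list(rate = function(t) 0.004,
                                          conc = c(Glc = 0)))
  sim_w <- simulate_scenario(sc_w)
  d_w <- sample_measurements(sim_w, model = m0, rng = 1)
  shifted <- pseudo_batch_shift(d_w, feed_rate = function(t) 0.004,
                                V0 = 1)
  Vt <- sim_w$V_fun(st)
  for (s in c("Glc", "Xv")) {
    raw <- d_w$value[d_w$species == s]
    expect_equal(shifted$value[shifted$species == s], raw * Vt / 1,
                 tolerance = 1e-6)
  }

  # round trip: shifted fed-batch equals a batch integration of the
  # fed-batch's own volumetric rates rescaled to the reference volume
  # (agreement limited by the dense-output interpolation of the rates)
  sim_f <- simulate_scenario(sc, times = seq(0, 120, length.out = 4801))
  d_fb <- sample_measurements(sim_f, st, model = m0, rng = 1)
  shifted_fb <- pseudo_batch_shift(
    d_fb, feed_rate = sc$feed$rate, feed_conc = sc$feed$conc, V0 = 1)
  batch_rhs <- function(t, y, p) {
    R <- sim_f$R_fun(t)[1, ]
    list(as.numeric(sc$E %*% R) * sim_f$V_fun(t) / 1)
  }
  y0 <- sc$c0
  sol <- deSolve::lsoda(y0, st, batch_rhs, parms = NULL,
                        rtol = 1e-9, atol = 1e-11)
  for (s in rownames(sc$E)) {
    got <- shifted_fb$value[shifted_fb$species == s]
    want <- sol[, s]
    expect_lt(max(abs(got - want)) / max(1, max(abs(want))), 1e-4)
  }

  expect_error(
    pseudo_batch_shift(d, feed_rate = function(t) 1,
                       feed_conc = c(Unknown = 5), V0 = 1),
    "unmeasured")
})

test_that("flux estimation from derivatives matches analytic slopes", {
  # linear concentrations, constant Xv: q = slope / Xv for every method
  times <- seq(0, 20, by = 2)
  rows <- rbind(
    data.frame(time = times, species = "A", value = 10 - 0.3 * times,
               sigma = 0.1),
    data.frame(time = times, species = "Xv", value = 2, sigma = 0.1))
  d <- measurement_set(rows)
  xv <- function(t) rep(2, length(t))
  for (m in c("splines", "smoothing_splines", "ma_filter", "raw")) {
    qe <- estimate_specific_fluxes(d, xv, method = m)
    expect_equal(unname(qe$q["A", ]), rep(-0.15, length(times)),
                 tolerance = 1e-6, info = m)
  }

  # smooth nonlinear data: spline derivative ~ central differences
  y <- 5 * exp(-0.1 * times)
  d2 <- measurement_set(rbind(
    data.frame(time = times, species = "A", value = y, sigma = 0.1),
    data.frame(time = times, species = "Xv", value = 2, sigma = 0.1)))
  qs <- estimate_specific_fluxes(d2, xv, method = "splines")
  fd <- (y[3:11] - y[1:9]) / 4
  expect_equal(unname(qs$q["A", 2:10]), fd / 2, tolerance = 2e-2)

  # on noisy data the raw spline rate is far noisier than the smoother
  set.seed(33)
  tfine <- seq(0, 20, by = 0.5)
  yfine <- 5 * exp(-0.1 * tfine)
  q_ref <- -0.5 * exp(-0.1 * tfine) / 2
  reps <- vapply(1:20, function(i) {
    yn <- yfine + rnorm(length(yfine), 0, 0.2)
    dn <- measurement_set(rbind(
      data.frame(time = tfine, species = "A", value = yn, sigma = 0.1),
      data.frame(time = tfine, species = "Xv", value = 2, sigma = 0.1)))
    c(mean((estimate_specific_fluxes(dn, xv, "splines")$q["A", ] -
              q_ref)^2),
      mean((estimate_specific_fluxes(dn, xv,
                                     "smoothing_splines")$q["A", ] -
              q_ref)^2))
  }, numeric(2))
  expect_gt(mean(reps[1, ]), 2 * mean(reps[2, ]))
  expect_error(estimate_specific_fluxes(
    measurement_set(data.frame(time = c(0, 1, 2), species = "A",
                               value = 1, sigma = 1)), xv), "< 4")
})

test_that("per-timepoint NNLS matches the support-pattern oracle", {
  E <- demo_em_matrix()
  # consistent system: exact recovery
  r_true <- matrix(c(0.3, 0.1, 0.4, 0.2), 4, 3)
  q <- E %*% r_true
  r_hat <- em_rates_from_fluxes(q, E)
  expect_lt(max(abs(r_hat - r_true)), 1e-8)

  # sign-infeasible single mode: boundary optimum r = 0
  E1 <- E[, 1, drop = FALSE]
  q_neg <- -E1
  expect_lt(max(abs(em_rates_from_fluxes(q_neg, E1))), 1e-12)

  # random 4x6 instances vs combinatorial oracle
  set.seed(55)
  for (i in 1:12) {
    A <- matrix(rnorm(24), 4, 6,
                dimnames = list(c("a", "b", "c", "d"), NULL))
    b <- rnorm(4)
    r <- em_rates_from_fluxes(matrix(b, 4, 1,
                                     dimnames = list(rownames(A), NULL)),
                              A)
    obj <- sum((A %*% r - b)^2)
    expect_equal(obj, nnls_brute_force(A, b), tolerance = 1e-8)
  }
})

test_that("benchmark table is seeded and orders methods sensibly", {
  sc <- simulation_scenario()
  bm1 <- run_benchmark(sc, noise_levels = c(0, 0.05), n_replicates = 3,
                       seed = 31)
  bm2 <- run_benchmark(sc, noise_levels = c(0, 0.05), n_replicates = 3,
                       seed = 31)
  expect_identical(bm1$replicates, bm2$replicates)  # bitwise under seed
  expect_true(all(c("dmfa_reg", "poolman_splines") %in% bm1$table$method))
  # errors are finite and positive
  expect_true(all(is.finite(as.matrix(bm1$table[, -1]))))
  # noise hurts the raw-spline rate estimator
  ps <- bm1$table[bm1$table$method == "poolman_splines", ]
  expect_gt(ps$noise_0.05, ps$noise_0)
})
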