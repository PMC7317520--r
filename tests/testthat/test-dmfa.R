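test_that("design operator integrates piecewise-linear fluxes exactly", {
  D <- matrix(c(1.3, -0.4), 2, 1, dimnames = list(c("s1", "s2"), "u"))
  grid <- inflection_grid(span = c(0, 10), n_nodes = 3)

  # constant flux: linear concentration growth
  A <- design_matrix(D, grid, c(0, 4, 10))
  pred <- t(matrix(A %*% rep(2, 3), nrow = 2))  # U = 2 at every node
  expect_equal(pred[, 1], 1.3 * 2 * c(0, 4, 10), tolerance = 1e-12)

  # ramp 0 -> u: triangle area
  U <- c(0, 1, 2)                             # linear ramp over [0,10]
  A2 <- design_matrix(D[1, , drop = FALSE], grid, 10)
  expect_equal(as.numeric(A2 %*% U), 1.3 * 10 * 1, tolerance = 1e-12)

  # random node values vs adaptive quadrature oracle
  set.seed(4)
  g3 <- inflection_grid(nodes = c(0, 2.7, 6.1, 9))
  U3 <- rnorm(4)
  Ufun <- approxfun(as.numeric(g3), U3)
  tt <- c(0.3, 2.7, 5, 8.8)
  A3 <- design_matrix(D, g3, tt)
  pred3 <- t(matrix(A3 %*% U3, nrow = 2))
  for (i in seq_along(tt)) {
    oracle <- integrate(Ufun, 0, tt[i], rel.tol = 1e-12)$value
    expect_equal(pred3[i, ], as.numeric(D) * oracle, tolerance = 1e-10)
  }
  expect_error(design_matrix(D, grid, 11), "outside")
})

test_that("SSR is the sigma-standardized residual sum over unmasked points", {
  d <- measurement_set(data.frame(
    time = rep(c(0, 1, 2), 2), species = rep(c("x", "y"), each = 3),
    value = c(1, 2, 3, 4, 5, 6), sigma = c(1, 1, 2, 2, 1, 1)))
  perfect <- function(species, time)
    ifelse(species == "x", time + 1, time + 4)
  expect_equal(compute_ssr(d, perfect), 0)
  # residual exactly sigma at every point -> SSR = n points
  off_by_sigma <- function(species, time)
    perfect(species, time) + ifelse(species == "x", c(1, 1, 2), c(2, 1, 1))[time + 1]
  # hand-computed: residual/sigma = 1 everywhere -> 6
  expect_equal(compute_ssr(d, function(s, t)
    perfect(s, t) - (if (s == "x") c(1, 1, 2) else c(2, 1, 1))[t + 1]), 6)
  # hand-listed residuals
  fitv <- function(s, t) perfect(s, t) + (if (s == "x") 0.5 else -1)
  expect_equal(compute_ssr(d, fitv),
               sum((0.5 / c(1, 1, 2))^2) + sum((1 / c(2, 1, 1))^2))
  # masked values are excluded
  d2 <- d; d2$value[2] <- NA
  d2 <- measurement_set(as.data.frame(d2))
  expect_equal(compute_ssr(d2, fitv),
               sum((0.5 / c(1, 2))^2) + sum((1 / c(2, 1, 1))^2))
})

test_that("unbounded DMFA equals the weighted normal-equations oracle", {
  net <- chain_network()
  grid <- inflection_grid(span = c(0, 8), n_nodes = 3)
  times <- seq(0, 8, by = 1)
  K <- null_space_basis(net$N)$K
  D <- net$P %*% K
  rownames(D) <- net$external_ids
  set.seed(21)
  d <- pwl_dataset(D, grid, matrix(c(0.4, 0.9, 0.2), 1), c(A = 10, B = 0),
                   times, noise = 1, seed = 21)
  fit <- solve_unbounded(d, net, grid)

  # oracle: explicit weighted normal equations on the stacked system
  W <- dmfa:::hat_integrals(grid, times)
  rows <- list(); y <- c()
  sp <- c("A", "B")
  for (i in 1:2) for (j in seq_along(times)) {
    obs <- d[d$species == sp[i] & d$time == times[j], ]
    a_c0 <- c(i == 1, i == 2)
    a_u <- W[j, ] * D[i, 1]
    rows[[length(rows) + 1L]] <- c(a_c0, a_u) / obs$sigma
    y <- c(y, obs$value / obs$sigma)
  }
  Amat <- do.call(rbind, rows)
  x_oracle <- solve(crossprod(Amat), crossprod(Amat, y))
  expect_lt(max(abs(c(fit$c0, as.vector(fit$node_values)) -
                    as.numeric(x_oracle))), 1e-9)
  # gradient of the normal equations is ~0 at the solution
  x_fit <- c(fit$c0, as.vector(fit$node_values))
  expect_lt(max(abs(crossprod(Amat, Amat %*% x_fit - y))), 1e-8)
})

test_that("noise-free data in the model class are recovered by all modes", {
  net <- toy_network()
  ems <- enumerate_ems(net)
  grid <- inflection_grid(span = c(0, 40), n_nodes = 4)
  times <- seq(0, 40, by = 2.5)
  R_nodes <- toy_R_nodes(4, 4)
  d0 <- pwl_dataset(ems$E, grid, R_nodes, toy_c0, times, noise = 0)

  fe <- solve_em(d0, ems$E, grid)
  expect_lt(max(abs(fe$node_values - R_nodes) / abs(R_nodes)), 1e-6)
  expect_lt(fe$SSR, 1e-8)

  fb <- solve_bounded(d0, net, grid)
  fu <- solve_unbounded(d0, net, grid)
  En <- normalize_columns(net$P %*% ems$flux_patterns)
  for (fit in list(fb, fu)) {
    Vfit <- fit$K %*% fit$node_values
    Vtrue <- ems$flux_patterns %*%
      diag(1 / sqrt(colSums((net$P %*% ems$flux_patterns)^2))) %*% R_nodes
    expect_lt(max(abs(Vfit - Vtrue) / pmax(abs(Vtrue), 1e-8)), 1e-6)
  }
})

test_that("bounded DMFA clamps at zero and matches a grid-search oracle", {
  # 1 irreversible exchange, no internal species: 2 unknowns U(T1), U(T2)
  net <- metabolic_network(
    data.frame(id = c("A", "B"), role = c("external", "external")),
    list(list(id = "v1", stoichiometry = c(A = -1, B = 1),
              reversible = FALSE)))
  grid <- inflection_grid(span = c(0, 4), n_nodes = 2)
  times <- seq(0, 4, by = 0.5)
  # data drawn so the unconstrained optimum would need U(T2) < 0:
  # B first rises then falls back
  bvals <- c(0, 0.4, 0.8, 1.0, 1.05, 1.0, 0.9, 0.75, 0.6)
  rows <- rbind(
    data.frame(time = times, species = "A", value = 5 - bvals, sigma = 0.1),
    data.frame(time = times, species = "B", value = bvals, sigma = 0.1))
  d <- measurement_set(rows)
  fit <- solve_bounded(d, net, grid, estimate_c0 = FALSE)
  expect_gte(min(fit$node_values), -1e-9)
  expect_equal(min(fit$node_values), 0, tolerance = 1e-7)

  # two-stage dense grid search over the feasible quadrant
  ssr_of <- function(u1, u2) {
    f <- structure(list(grid = grid, D = matrix(c(-1, 1), 2, 1,
                          dimnames = list(c("A", "B"), "u")),
                        node_values = matrix(c(u1, u2), 1),
                        c0 = c(A = 5, B = 0), species = c("A", "B")),
                   class = "dmfa_fit")
    compute_ssr(d, f)
  }
  search <- function(r1, r2, n) {
    best <- Inf; arg <- c(NA, NA)
    for (u1 in seq(r1[1], r1[2], length.out = n))
      for (u2 in seq(r2[1], r2[2], length.out = n)) {
        v <- ssr_of(u1, u2)
        if (v < best) { best <- v; arg <- c(u1, u2) }
      }
    list(best = best, arg = arg)
  }
  coarse <- search(c(0, 1), c(0, 1), 101L)
  h <- 0.01
  fine <- search(pmax(0, coarse$arg[1] + c(-h, h)),
                 pmax(0, coarse$arg[2] + c(-h, h)), 81L)
  expect_equal(fit$SSR, fine$best, tolerance = 1e-4)
  expect_lt(max(abs(as.vector(fit$node_values) - fine$arg)), 0.01)

  # inactive constraints: bounded == unbounded
  d_pos <- pwl_dataset(matrix(c(-1, 1), 2, 1,
                              dimnames = list(c("A", "B"), "u")),
                       grid, matrix(c(0.5, 0.7), 1), c(A = 5, B = 0),
                       times, noise = 0)
  fb <- solve_bounded(d_pos, net, grid)
  fu <- solve_unbounded(d_pos, net, grid)
  expect_lt(max(abs(fb$node_values - fu$node_values)), 1e-9)

  # all-zero data: U = 0 is optimal, SSR = sum((c/sigma)^2) with c = 0
  rows0 <- rbind(
    data.frame(time = times, species = "A", value = 0, sigma = 0.1),
    data.frame(time = times, species = "B", value = 0, sigma = 0.1))
  f0 <- solve_bounded(measurement_set(rows0), net, grid,
                      estimate_c0 = FALSE)
  expect_lt(max(abs(f0$node_values)), 1e-9)
})

test_that("fits are invariant to the choice of null-space basis", {
  net <- toy_network()
  grid <- inflection_grid(span = c(0, 40), n_nodes = 3)
  times <- seq(0, 40, by = 4)
  ems <- enumerate_ems(net)
  d <- pwl_dataset(ems$E, grid, toy_R_nodes(4, 3, seed = 8), toy_c0,
                   times, noise = 1, seed = 8)
  fit1 <- solve_bounded(d, net, grid)

  # rotate the basis by solving with a permuted reaction order
  perm <- c(3, 1, 5, 2, 6, 4)
  net2 <- metabolic_network(net$species, net$reactions[perm])
  fit2 <- solve_bounded(d, net2, grid)
  expect_equal(fit2$SSR, fit1$SSR, tolerance = 1e-8)
  V1 <- fit1$K %*% fit1$node_values
  V2 <- fit2$K %*% fit2$node_values
  ids <- net$reaction_ids
  expect_equal(V2[ids, ], V1[ids, ], tolerance = 1e-6, ignore_attr = TRUE)
  ts <- seq(0, 40, by = 5)
  expect_equal(fitted_concentrations(fit2, ts)[, fit1$species],
               fitted_concentrations(fit1, ts)[, fit1$species],
               tolerance = 1e-7)
})

test_that("SSR obeys the nesting hierarchy across solver modes and grids", {
  net <- toy_network()
  ems <- enumerate_ems(net)
  grid <- inflection_grid(span = c(0, 40), n_nodes = 3)
  times <- seq(0, 40, by = 2.5)
  d <- pwl_dataset(ems$E, grid, toy_R_nodes(4, 3, seed = 13), toy_c0,
                   times, noise = 2, seed = 13)
  xv <- xv_interpolant(d)

  s_unb <- solve_unbounded(d, net, grid)$SSR
  s_bnd <- solve_bounded(d, net, grid)$SSR
  s_em <- solve_em(d, ems$E, grid)$SSR
  s_sub <- solve_em(d, ems$E[, -2, drop = FALSE], grid)$SSR
  s_reg <- solve_em(d, ems$E[, -2, drop = FALSE], grid, alpha = 1,
                    xv = xv)$SSR
  tol <- 1e-6
  expect_lte(s_unb, s_bnd * (1 + tol))
  expect_equal(s_bnd, s_em, tolerance = tol)
  expect_lte(s_em, s_sub * (1 + tol))
  expect_lte(s_sub, s_reg * (1 + tol))

  # refining the grid (superset of nodes) cannot worsen the fit
  grid_fine <- inflection_grid(nodes = sort(c(as.numeric(grid), 10, 30)))
  expect_lte(solve_em(d, ems$E, grid_fine)$SSR, s_em + 1e-9)

  # KKT certificates of the constrained solves
  fb <- solve_bounded(d, net, grid)
  expect_lt(fb$kkt$stationarity, 1e-8)
  expect_gt(fb$kkt$feasibility, -1e-9)
  expect_lt(fb$kkt$complementarity, 1e-8)
})

test_that("regularization path behaves like ridge on cell-specific rates", {
  E <- demo_em_matrix()
  grid <- inflection_grid(span = c(0, 48), n_nodes = 3)
  times <- seq(0, 48, by = 4)
  d <- pwl_dataset(E, grid, toy_R_nodes(4, 3, seed = 3, lo = 0.1, hi = 0.6),
                   demo_c0, times, noise = 1, seed = 3)
  xv <- xv_interpolant(d)
  f0 <- solve_em(d, E, grid, alpha = 0)
  alphas <- c(0, 1e-3, 1, 1e3, 1e12)
  ssrs <- vapply(alphas, function(a)
    solve_em(d, E, grid, alpha = a, xv = xv)$SSR, numeric(1))
  expect_equal(ssrs[1], f0$SSR, tolerance = 1e-10)
  expect_true(all(diff(ssrs) >= -1e-7 * ssrs[-1]))
  fbig <- solve_em(d, E, grid, alpha = 1e12, xv = xv)
  expect_lt(max(abs(fbig$node_values)), 1e-4)
  # R -> 0 means the fit degenerates to constant concentrations
  ssr_zero_R <- compute_ssr(d, function(s, t) fbig$c0[[s]])
  expect_equal(fbig$SSR, ssr_zero_R, tolerance = 1e-4)
  expect_error(solve_em(d, E, grid, alpha = 1), "requires")
})

test_that("cross-validation picks larger alpha for collinear mode sets", {
  E <- demo_em_matrix()
  grid <- inflection_grid(span = c(0, 48), n_nodes = 3)
  times <- seq(0, 48, by = 3)
  d <- pwl_dataset(E, grid, toy_R_nodes(4, 3, seed = 31, lo = 0.1, hi = 0.5),
                   demo_c0, times, noise = 1, seed = 31)
  alphas <- 10^seq(-6, 2, by = 2)

  # duplicated columns -> ill-conditioned -> some alpha > 0 wins
  Edup <- cbind(E, E[, 1], E[, 2], E[, 3])
  colnames(Edup) <- paste0("m", 1:7)
  cv_dup <- cross_validate_alpha(d, Edup, grid, alphas, folds = 4,
                                 seed = 2)
  expect_gt(cv_dup$alpha, 0)
  ssr_tab <- cv_dup$table
  expect_lt(min(ssr_tab$cv_ssr[ssr_tab$alpha > min(alphas)]),
            ssr_tab$cv_ssr[1] + 1e-9)

  # well-conditioned single mode, tiny noise -> smallest alpha wins
  E1 <- E[, 1, drop = FALSE]
  d1 <- pwl_dataset(E1, grid, matrix(c(0.2, 0.5, 0.3), 1), demo_c0,
                    times, noise = 0.01, seed = 5)
  cv1 <- cross_validate_alpha(d1, E1, grid, alphas, folds = 4, seed = 2)
  expect_equal(cv1$alpha, min(alphas))

  # determinism: same seed, bitwise identical table
  cv_rep <- cross_validate_alpha(d, Edup, grid, alphas, folds = 4,
                                 seed = 2)
  expect_identical(cv_rep$table, cv_dup$table)
  expect_error(cross_validate_alpha(d, E, grid, alphas, folds = 50),
               "fewer folds")
  # a fold that would leave a species with < 2 training points errors
  tiny <- pwl_dataset(E[, 1, drop = FALSE],
                      inflection_grid(span = c(0, 48), n_nodes = 2),
                      matrix(c(0.2, 0.4), 1), demo_c0, c(0, 24, 48))
  expect_error(cross_validate_alpha(tiny, E[, 1, drop = FALSE],
                                    inflection_grid(span = c(0, 48),
                                                    n_nodes = 2),
                                    alphas, folds = 2),
               "fewer folds|< 2 points")
})

test_that("specific rates divide volumetric rates by cell density", {
  E <- demo_em_matrix()
  grid <- inflection_grid(span = c(0, 10), n_nodes = 2)
  fit <- structure(list(grid = grid, D = E,
                        node_values = matrix(2, 4, 2), c0 = demo_c0,
                        species = rownames(E), mode = "em", alpha = 0),
                   class = "dmfa_fit")
  xv4 <- function(t) rep(4, length(t))
  r <- specific_rates(fit, xv4, c(2, 7), scale = 1)
  expect_equal(unname(r), matrix(0.5, 4, 2))
  # default scale applies the ml <-> l conversion once
  expect_equal(unname(specific_rates(fit, xv4, 5)), matrix(5e-4, 4, 1))
  # zero rates stay zero; division oracle on varying profiles
  fit$node_values <- matrix(c(0, 3), 1)[rep(1, 4), , drop = FALSE]
  ts <- seq(0, 10, by = 0.5)
  xvm <- function(t) 1 + 0.3 * t
  r2 <- specific_rates(fit, xvm, ts, scale = 1)
  Rt <- approx(c(0, 10), c(0, 3), xout = ts)$y
  expect_equal(r2[2, ], Rt / xvm(ts), tolerance = 1e-12)
  expect_error(specific_rates(fit, function(t) t - 5, c(2, 7)), "<= 0")
})

test_that("kinetic fitting recovers parameters and honors weights", {
  ts <- seq(0, 20, by = 1)
  # linear-in-parameters law: exact recovery
  lin <- function(t, th) th[1] + th[2] * t
  out <- fit_kinetics(lin, c(0, 0), ts, lin(ts, c(1.5, -0.2)))
  expect_true(out$converged)
  expect_equal(out$theta, c(1.5, -0.2), tolerance = 1e-8)

  # Monod law on synthetic substrate decay
  conc <- 10 * exp(-0.15 * ts)
  monod <- function(t, th) th[1] * (10 * exp(-0.15 * t)) /
    (th[2] + 10 * exp(-0.15 * t))
  r_true <- monod(ts, c(0.8, 2.5))
  out2 <- fit_kinetics(monod, c(0.5, 1), ts, r_true,
                       lower = c(0, 0), upper = c(10, 50))
  expect_lt(max(abs(out2$theta - c(0.8, 2.5)) / c(0.8, 2.5)), 1e-4)

  # strong down-weighting of early points pulls the fit to late times
  y <- lin(ts, c(1, 0)) + c(rep(1, 10), rep(0, 11))
  w_flat <- fit_kinetics(function(t, th) rep(th, length(t)), 1, ts, y)
  w_late <- fit_kinetics(function(t, th) rep(th, length(t)), 1, ts, y,
                         sigmas = c(rep(100, 10), rep(0.01, 11)))
  expect_gt(w_flat$theta, w_late$theta)
  expect_equal(w_late$theta, 1, tolerance = 1e-4)
})
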