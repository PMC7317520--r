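# Core DMFA estimators.  The volumetric free fluxes U(t) (or elementary-
# mode rates R(t)) are piecewise linear between inflection points T_j, so
# concentrations are piecewise quadratic and every fitted concentration
# is a linear function of the node values: the estimation problems are
# (inequality-constrained) weighted linear least squares.

#' Inflection-point grid
#'
#' Node times of the piecewise-linear parameterization of the volumetric
#' fluxes.  By default `n_nodes` equally spaced nodes spanning the data.
#'
#' @param data optional `measurement_set` supplying the span.
#' @param n_nodes number of nodes (>= 2).
#' @param nodes explicit strictly increasing node times (overrides
#'   `n_nodes`/`span`).
#' @param span numeric length-2 time span, used when `data` is absent.
#' @return numeric vector of class `inflection_grid`.
#' @export
inflection_grid <- function(data = NULL, n_nodes = 5L, nodes = NULL,
                            span = NULL) {
  if (is.null(nodes)) {
    if (!is.null(data)) span <- ms_span(data)
    if (is.null(span)) stop("need data, span, or explicit nodes")
    nodes <- seq(span[1], span[2], length.out = max(2L, n_nodes))
  }
  nodes <- as.numeric(nodes)
  if (length(nodes) < 2L || any(diff(nodes) <= 0))
    stop("grid nodes must be >= 2 and strictly increasing")
  if (!is.null(data)) {
    sp <- ms_span(data)
    if (nodes[1] > sp[1] + 1e-9 || nodes[length(nodes)] < sp[2] - 1e-9)
      stop("grid must span the data range")
  }
  structure(nodes, class = "inflection_grid")
}

# W[t, j] = integral from T_1 to t of the j-th hat basis function of the
# grid; exact closed form (piecewise quadratic in t).
hat_integrals <- function(grid, times) {
  Tn <- as.numeric(grid); m <- length(Tn)
  if (any(times < Tn[1] - 1e-9) || any(times > Tn[m] + 1e-9))
    stop("time(s) outside the inflection grid span")
  times <- pmin(pmax(times, Tn[1]), Tn[m])
  dT <- diff(Tn)
  # cumulative full-segment integrals at the nodes
  Cn <- matrix(0, m, m)
  for (l in 2:m) {
    Cn[l, ] <- Cn[l - 1L, ]
    Cn[l, l - 1L] <- Cn[l, l - 1L] + dT[l - 1L] / 2
    Cn[l, l] <- Cn[l, l] + dT[l - 1L] / 2
  }
  seg <- pmin(findInterval(times, Tn), m - 1L)
  W <- Cn[seg, , drop = FALSE]
  s <- (times - Tn[seg]) / dT[seg]
  W[cbind(seq_along(times), seg)] <-
    W[cbind(seq_along(times), seg)] + dT[seg] * (s - s^2 / 2)
  W[cbind(seq_along(times), seg + 1L)] <-
    W[cbind(seq_along(times), seg + 1L)] + dT[seg] * s^2 / 2
  W
}

#' Linear operator from flux node values to concentration increments
#'
#' Returns the matrix `A` such that for direction matrix `D` (rows:
#' external species, columns: flux directions, i.e. `P %*% K` for DMFA or
#' the macro-reaction matrix `E` for the elementary-mode variant) and
#' node values `U` (n_dir x n_nodes, piecewise linear in between),
#' `c(t) = c(T_1) + A %*% as.vector(U)` at the requested `times`, by
#' exact integration of the piecewise-linear volumetric flux.
#'
#' @param D direction matrix (n_species x n_dir).
#' @param grid an `inflection_grid` covering `times`.
#' @param times evaluation times.
#' @return matrix of dimension `(length(times) * nrow(D)) x
#'   (ncol(D) * length(grid))`; rows ordered time-major (all species at
#'   the first time, then the second, ...), columns node-major.
#' @export
design_matrix <- function(D, grid, times) {
  D <- as.matrix(D)
  W <- hat_integrals(grid, times)          # n_t x n_T
  # kron: row block for time t is [W[t,1]*D, W[t,2]*D, ...]
  out <- kronecker(W, D)
  # kronecker(W, D) stacks: rows = (t, species) time-major; cols node-major
  out
}

# Evaluate piecewise-linear node values at arbitrary times.
pwl_eval <- function(grid, values, times) {
  Tn <- as.numeric(grid)
  tq <- pmin(pmax(times, Tn[1]), Tn[length(Tn)])
  out <- matrix(NA_real_, nrow(values), length(times))
  for (i in seq_len(nrow(values)))
    out[i, ] <- stats::approx(Tn, values[i, ], xout = tq)$y
  rownames(out) <- rownames(values)
  out
}

#' Weighted sum of squared residuals of a fit
#'
#' `SSR = sum over non-masked observations of
#' ((c_measured - c_fitted) / sigma)^2`.
#'
#' @param data a `measurement_set`.
#' @param fit a `dmfa_fit`, or a function `f(species, times)` returning
#'   fitted concentrations.
#' @return the SSR (non-negative scalar).
#' @export
compute_ssr <- function(data, fit) {
  used <- !is.na(data$value)
  d <- data[used, , drop = FALSE]
  if (any(d$sigma <= 0)) stop("sigma must be > 0 at every used point")
  chat <- if (inherits(fit, "dmfa_fit")) {
    predict_species(fit, d$species, d$time)
  } else {
    mapply(fit, d$species, d$time)
  }
  sum(((d$value - chat) / d$sigma)^2)
}

# Assemble the weighted least-squares system for given data, direction
# matrix and grid.  Unknowns: [c0 for each fitted species; node values
# column by column].  Returns A, b, index bookkeeping.
build_system <- function(data, D, grid, estimate_c0 = TRUE) {
  used <- !is.na(data$value)
  d <- data[used, , drop = FALSE]
  sp <- intersect(rownames(D), unique(d$species))
  extra <- setdiff(unique(d$species), rownames(D))
  if (length(extra))
    stop("measured species not in the model: ", paste(extra, collapse = ", "))
  n_dir <- ncol(D); m <- length(grid); n_sp <- length(sp)
  irow <- match(d$species, sp)
  W <- hat_integrals(grid, d$time)                   # n_obs x m
  # A_flux[obs, (j-1)*n_dir + k] = W[obs, j] * D[species(obs), k]
  Dm <- D[sp, , drop = FALSE]
  A_flux <- matrix(0, nrow(d), n_dir * m)
  for (j in seq_len(m)) {
    cols <- (j - 1L) * n_dir + seq_len(n_dir)
    A_flux[, cols] <- W[, j] * Dm[irow, , drop = FALSE]
  }
  w <- 1 / d$sigma
  if (estimate_c0) {
    A_c0 <- matrix(0, nrow(d), n_sp)
    A_c0[cbind(seq_len(nrow(d)), irow)] <- 1
    A <- cbind(A_c0, A_flux) * w
    b <- d$value * w
    c0_fixed <- NULL
  } else {
    c0_fixed <- vapply(sp, function(s) {
      v <- d$value[d$species == s]; v[1]
    }, numeric(1))
    A <- A_flux * w
    b <- (d$value - c0_fixed[irow]) * w
  }
  list(A = A, b = b, species = sp, n_dir = n_dir, n_nodes = m,
       n_c0 = if (estimate_c0) n_sp else 0L, c0_fixed = c0_fixed,
       obs = d)
}

make_fit <- function(sol, sys, D, grid, mode, alpha, network = NULL,
                     K = NULL) {
  n_c0 <- sys$n_c0
  c0 <- if (n_c0 > 0L) stats::setNames(sol$x[seq_len(n_c0)], sys$species)
        else sys$c0_fixed
  U <- matrix(sol$x[(n_c0 + 1L):length(sol$x)], sys$n_dir, sys$n_nodes)
  rownames(U) <- colnames(D)
  colnames(U) <- sprintf("T%d", seq_len(sys$n_nodes))
  fit <- structure(list(
    grid = grid, mode = mode, D = D, species = sys$species,
    node_values = U, c0 = c0, SSR = NA_real_, alpha = alpha,
    kkt = sol$kkt, network = network, K = K
  ), class = "dmfa_fit")
  # SSR from data residuals only (excludes any regularization rows)
  fit$SSR <- compute_ssr(sys$obs_full, fit)
  fit
}

predict_species <- function(fit, species, times) {
  W <- hat_integrals(fit$grid, times)
  n_dir <- ncol(fit$D)
  inc <- numeric(length(times))
  DU <- fit$D %*% fit$node_values            # n_sp_all x n_nodes
  for (i in seq_along(times))
    inc[i] <- sum(W[i, ] * DU[species[i], ])
  fit$c0[species] + inc
}

#' Fitted concentration trajectories of a DMFA fit
#'
#' @param object a `dmfa_fit`.
#' @param times evaluation times (within the grid span).
#' @param species species ids (default: all fitted species).
#' @param ... unused.
#' @return matrix `length(times) x length(species)` of fitted
#'   concentrations.
#' @export
fitted_concentrations <- function(object, times, species = object$species,
                                  ...) {
  W <- hat_integrals(object$grid, times)
  DU <- object$D[species, , drop = FALSE] %*% object$node_values
  out <- matrix(rep(object$c0[species], each = length(times)),
                length(times), length(species))
  out <- out + W %*% t(DU)
  dimnames(out) <- list(NULL, species)
  out
}

#' @export
predict.dmfa_fit <- function(object, times, species = object$species, ...) {
  fitted_concentrations(object, times, species)
}

#' @export
print.dmfa_fit <- function(x, ...) {
  cat("DMFA fit (", x$mode, "): ", ncol(x$D), " flux directions, ",
      length(x$grid), " inflection nodes, SSR = ", format(x$SSR),
      if (x$alpha > 0) paste0(", alpha = ", format(x$alpha)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Node-value trajectories of a fit
#'
#' Evaluates the piecewise-linear free-flux (or elementary-mode rate)
#' profiles at arbitrary times.
#'
#' @param fit a `dmfa_fit`.
#' @param times evaluation times.
#' @return matrix n_dir x length(times).
#' @export
node_trajectories <- function(fit, times) {
  pwl_eval(fit$grid, fit$node_values, times)
}

#' Reaction-flux trajectories `V(t) = K U(t)` of a (un)bounded fit
#' @param fit a `dmfa_fit` of mode `unbounded` or `bounded`.
#' @param times evaluation times.
#' @return matrix n_reactions x length(times).
#' @export
flux_trajectories <- function(fit, times) {
  if (is.null(fit$K)) stop("fit carries no null-space basis")
  V <- fit$K %*% node_trajectories(fit, times)
  rownames(V) <- rownames(fit$K)
  V
}

#' Unbounded DMFA: weighted least-squares flux estimation
#'
#' Estimates free-flux node values `U_k(T_j)` (and, by default, the
#' initial concentrations) by minimizing the weighted SSR between
#' measured and fitted concentrations, with no sign constraints.
#'
#' @param data a `measurement_set`.
#' @param network a `metabolic_network`.
#' @param grid an `inflection_grid` (default 5 equally spaced nodes).
#' @param estimate_c0 estimate initial concentrations jointly (default);
#'   if `FALSE`, pin them to the first non-missing measurement.
#' @param minimum_norm return the minimum-norm solution instead of
#'   erroring when the design is rank-deficient.
#' @return a `dmfa_fit` (mode `"unbounded"`).
#' @export
solve_unbounded <- function(data, network, grid = inflection_grid(data),
                            estimate_c0 = TRUE, minimum_norm = FALSE) {
  nsb <- null_space_basis(network$N)
  D <- network$P %*% nsb$K
  rownames(D) <- network$external_ids
  colnames(D) <- sprintf("U%d", seq_len(ncol(D)))
  sys <- build_system(data, D, grid, estimate_c0)
  sys$obs_full <- data
  sol <- lsq_solve(sys$A, sys$b, minimum_norm = minimum_norm)
  make_fit(sol, sys, D, grid, "unbounded", 0, network, nsb$K)
}

#' Bounded DMFA: flux estimation with irreversibility constraints
#'
#' As [solve_unbounded()], but subject to `K_irr %*% U(T_j) >= 0` at
#' every inflection node, where `K_irr` collects the null-space rows of
#' the irreversible reactions.  Because fluxes are piecewise linear,
#' node-wise feasibility implies feasibility at all times.  With no
#' irreversible reactions this reduces to the unbounded problem.
#'
#' @inheritParams solve_unbounded
#' @return a `dmfa_fit` (mode `"bounded"`).
#' @export
solve_bounded <- function(data, network, grid = inflection_grid(data),
                          estimate_c0 = TRUE) {
  irr <- names(network$reversible)[!network$reversible]
  if (length(irr) == 0L) {
    fit <- solve_unbounded(data, network, grid, estimate_c0)
    fit$mode <- "bounded"
    return(fit)
  }
  nsb <- null_space_basis(network$N)
  D <- network$P %*% nsb$K
  rownames(D) <- network$external_ids
  colnames(D) <- sprintf("U%d", seq_len(ncol(D)))
  Kirr <- irreversibility_rows(nsb$K, irr, network)
  sys <- build_system(data, D, grid, estimate_c0)
  sys$obs_full <- data
  n_unk <- sys$n_c0 + sys$n_dir * sys$n_nodes
  G <- matrix(0, nrow(Kirr) * sys$n_nodes, n_unk)
  for (j in seq_len(sys$n_nodes)) {
    rows <- (j - 1L) * nrow(Kirr) + seq_len(nrow(Kirr))
    cols <- sys$n_c0 + (j - 1L) * sys$n_dir + seq_len(sys$n_dir)
    G[rows, cols] <- Kirr
  }
  sol <- lsq_solve(sys$A, sys$b, G = G)
  make_fit(sol, sys, D, grid, "bounded", 0, network, nsb$K)
}

#' DMFA for elementary modes, optionally regularized
#'
#' Estimates non-negative volumetric elementary-mode rates `R_k(T_j)` so
#' that `V(t) = E R(t)`.  With `alpha > 0` a ridge penalty
#' `alpha * sum_k sum_j (R_k(T_j) / Xv(T_j))^2` on the cell-specific
#' rates is added (the viable-cell density at the nodes is taken from a
#' linear interpolant of the measured series, keeping the problem a
#' convex quadratic program); `alpha = 0` gives the plain
#' elementary-mode problem, whose optimal SSR for the complete mode set
#' equals the bounded-DMFA SSR.
#'
#' @param data a `measurement_set`.
#' @param E macro-reaction matrix (rows: external species ids, columns:
#'   elementary modes), columns L2-normalized.
#' @param grid an `inflection_grid`.
#' @param alpha regularization weight (>= 0).
#' @param xv function of time returning viable-cell density (see
#'   [xv_interpolant()]); required when `alpha > 0`.
#' @param estimate_c0 see [solve_unbounded()].
#' @return a `dmfa_fit` (mode `"em"` or `"em_regularized"`); the
#'   `node_values` are the `R_k(T_j)`.
#' @export
solve_em <- function(data, E, grid = inflection_grid(data), alpha = 0,
                     xv = NULL, estimate_c0 = TRUE) {
  E <- as.matrix(E)
  if (is.null(rownames(E))) stop("E needs external species row names")
  if (alpha < 0) stop("alpha must be >= 0")
  sys <- build_system(data, E, grid, estimate_c0)
  sys$obs_full <- data
  n_R <- sys$n_dir * sys$n_nodes
  n_unk <- sys$n_c0 + n_R
  A <- sys$A; b <- sys$b
  if (alpha > 0) {
    if (is.null(xv)) stop("alpha > 0 requires a viable-cell interpolant")
    xv_nodes <- xv(as.numeric(grid))
    if (any(xv_nodes <= 0))
      stop("viable-cell density must be > 0 at all inflection nodes")
    ridge <- matrix(0, n_R, n_unk)
    w <- sqrt(alpha) / rep(xv_nodes, each = sys$n_dir)
    ridge[cbind(seq_len(n_R), sys$n_c0 + seq_len(n_R))] <- w
    A <- rbind(A, ridge)
    b <- c(b, rep(0, n_R))
  }
  G <- matrix(0, n_R, n_unk)
  G[cbind(seq_len(n_R), sys$n_c0 + seq_len(n_R))] <- 1
  sol <- lsq_solve(A, b, G = G)
  mode <- if (alpha > 0) "em_regularized" else "em"
  make_fit(sol, sys, E, grid, mode, alpha)
}

#' Cell-specific rates from a DMFA fit
#'
#' Converts volumetric rate trajectories to cell-specific rates,
#' `r_k(t) = scale * R_k(t) / Xv(t)`.  With volumetric rates in mM/h
#' (mmol/l/h) and viable-cell density in 1e6 cells/ml, the millilitre/
#' litre conversion gives `scale = 1e-3` for rates in
#' mmol/(1e6 cells)/h; set `scale = 1` to obtain the bare ratio.
#'
#' @param fit a `dmfa_fit`.
#' @param xv viable-cell interpolant (function of time, > 0 on the
#'   window).
#' @param times evaluation times.
#' @param scale unit conversion factor (default 1e-3, see above).
#' @return matrix n_dir x length(times) of cell-specific rates.
#' @export
specific_rates <- function(fit, xv, times, scale = 1e-3) {
  xvv <- xv(times)
  if (any(xvv <= 0))
    stop("viable-cell density <= 0 at time(s): ",
         paste(format(times[xvv <= 0]), collapse = ", "))
  R <- node_trajectories(fit, times)
  sweep(R, 2L, xvv, "/") * scale
}

#' Cross-validation of the regularization weight
#'
#' K-fold cross-validation over measurement time points: the unique
#' times are shuffled (seeded) and assigned to folds round-robin; for
#' each candidate `alpha` the elementary-mode problem is solved on the
#' training folds and scored by the weighted SSR on the held-out points.
#' Ties in mean held-out SSR are broken toward the larger `alpha`.
#'
#' @param data a `measurement_set`.
#' @param E macro-reaction matrix.
#' @param grid an `inflection_grid`.
#' @param alphas non-empty vector of candidate weights (>= 0).
#' @param folds number of folds (>= 2).
#' @param seed integer seed for the fold shuffle.
#' @param xv viable-cell interpolant (default from `data`).
#' @return list with `alpha` (selected), `table` (data.frame of alpha
#'   and mean held-out SSR), and `fold_assignment`.
#' @export
cross_validate_alpha <- function(data, E, grid, alphas, folds = 5L,
                                 seed = 1L, xv = xv_interpolant(data)) {
  if (length(alphas) < 1L || any(alphas < 0))
    stop("alphas must be non-empty and >= 0")
  if (folds < 2L) stop("need >= 2 folds")
  n_times_all <- length(unique(data$time[!is.na(data$value)]))
  if (folds > n_times_all)
    stop("more folds than measurement time points; use fewer folds")
  ord <- order(alphas)
  alphas <- alphas[ord]
  times <- sort(unique(data$time[!is.na(data$value)]))
  rng <- new_rng(seed)
  perm <- rng_sample(rng, length(times))   # shuffled order of time indices
  fold_id <- integer(length(times))
  fold_id[perm] <- rep(seq_len(folds), length.out = length(times))
  assignment <- stats::setNames(fold_id, times)

  held_out <- matrix(NA_real_, length(alphas), folds)
  for (f in seq_len(folds)) {
    test_times <- times[fold_id == f]
    train <- data
    mask <- train$time %in% test_times
    train$value[mask] <- NA
    # every species needs >= 2 training points
    cnt <- tapply(!is.na(train$value), train$species, sum)
    if (any(cnt < 2L))
      stop("fold ", f, " leaves species with < 2 points (",
           paste(names(cnt)[cnt < 2L], collapse = ", "),
           "); use fewer folds")
    test <- data[mask & !is.na(data$value), , drop = FALSE]
    test <- measurement_set(as.data.frame(test),
                            xv_species = attr(data, "xv_species"))
    for (a in seq_along(alphas)) {
      fit <- solve_em(train, E, grid, alpha = alphas[a], xv = xv)
      held_out[a, f] <- compute_ssr(test, fit)
    }
  }
  mean_ssr <- rowMeans(held_out)
  best <- max(which(mean_ssr <= min(mean_ssr)))  # ties -> larger alpha
  list(alpha = alphas[best],
       table = data.frame(alpha = alphas, cv_ssr = mean_ssr),
       fold_assignment = assignment)
}

#' Weighted nonlinear kinetic fit to estimated rates
#'
#' Fits a user-supplied rate law `rate_fn(times, theta)` to estimated
#' cell-specific rates by weighted least squares,
#' `min_theta sum_i ((rhat(t_i, theta) - r(t_i)) / sigma(t_i))^2`,
#' using the Levenberg-Marquardt algorithm.  The weights are typically
#' the bootstrap standard deviations of the rate estimates.
#'
#' @param rate_fn function `(times, theta) -> predicted rates`.
#' @param theta0 initial parameter vector (within bounds).
#' @param times observation times.
#' @param rates estimated rates at `times`.
#' @param sigmas positive weights (same length), default 1.
#' @param lower,upper parameter bounds.
#' @return list with `theta`, `objective`, `converged` (logical) and
#'   `message`; non-convergence is flagged, not an error.
#' @export
fit_kinetics <- function(rate_fn, theta0, times, rates,
                         sigmas = rep(1, length(rates)),
                         lower = rep(-Inf, length(theta0)),
                         upper = rep(Inf, length(theta0))) {
  stopifnot(length(times) == length(rates), all(is.finite(sigmas)),
            all(sigmas > 0))
  if (length(rates) < length(theta0))
    stop("need at least as many time points as parameters")
  resid <- function(theta) (rate_fn(times, theta) - rates) / sigmas
  out <- minpack.lm::nls.lm(par = theta0, fn = resid, lower = lower,
                            upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  list(theta = out$par, objective = sum(resid(out$par)^2),
       converged = out$info %in% 1:4, message = out$message)
}
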