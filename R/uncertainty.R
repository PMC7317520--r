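# Bootstrap confidence bounds for DMFA estimates: measurements are
# resampled from their assumed Gaussian error model and the inflection
# points are randomized, so that the bands reflect both measurement
# noise and the arbitrariness of the node placement.

#' Resample a measurement set from its noise model
#'
#' Each non-missing value is replaced by a Gaussian draw centered at the
#' original value with standard deviation `sigma_of(value, model,
#' species)`; negative draws are clipped at 0 (the number of clipped
#' values is recorded in attribute `"n_clipped"`).  The sigma column is
#' set to the model value at the original magnitude, so that all
#' resamples share the same weighting; to keep the weights finite for
#' species passing through zero, the recorded sigma is floored at
#' `sigma_floor_rel` times the species' largest observed value (the
#' same detection-limit convention as [sample_measurements()]).  The
#' floor never affects the noise draws themselves.
#'
#' @param data a `measurement_set`.
#' @param model a `noise_model` covering all measured species.
#' @param rng an RNG stream (internal) or integer seed.
#' @param sigma_floor_rel relative floor for the recorded sigma
#'   (default 1e-3).
#' @return a resampled `measurement_set`.
#' @export
resample_measurements <- function(data, model, rng,
                                  sigma_floor_rel = 1e-3) {
  if (!inherits(rng, "environment")) rng <- new_rng(rng)
  out <- data
  used <- which(!is.na(out$value))
  # the affine noise model is defined on magnitudes; stray negative
  # inputs (already-noisy fixtures) are treated as zero concentration
  sd <- mapply(function(v, s) sigma_of(max(v, 0), model, s),
               out$value[used], out$species[used])
  draws <- rng_norm(rng, length(used), mean = out$value[used], sd = sd)
  n_clip <- sum(draws < 0)
  out$value[used] <- pmax(draws, 0)
  peak <- tapply(abs(out$value[used]), out$species[used], max)
  out$sigma[used] <- pmax(sd, sigma_floor_rel * peak[out$species[used]])
  attr(out, "n_clipped") <- n_clip
  out
}

#' Randomize the interior inflection points
#'
#' Interior nodes are perturbed by independent uniform draws within
#' plus/minus `jitter_fraction` of half the minimum adjacent node
#' spacing; the endpoints stay fixed and strict ordering is preserved by
#' construction.
#'
#' @param grid an `inflection_grid`.
#' @param rng an RNG stream or integer seed.
#' @param jitter_fraction in `[0, 0.5]` (default 0.5).
#' @return a jittered `inflection_grid`.
#' @export
randomize_grid <- function(grid, rng, jitter_fraction = 0.5) {
  if (jitter_fraction < 0 || jitter_fraction > 0.5)
    stop("jitter_fraction must be in [0, 0.5]")
  if (!inherits(rng, "environment")) rng <- new_rng(rng)
  Tn <- as.numeric(grid); m <- length(Tn)
  if (m <= 2L || jitter_fraction == 0) return(grid)
  gaps <- diff(Tn)
  for (j in 2:(m - 1L)) {
    d <- min(gaps[j - 1L], gaps[j]) / 2
    Tn[j] <- Tn[j] + rng_unif(rng, 1L, -jitter_fraction * d,
                              jitter_fraction * d)
  }
  inflection_grid(nodes = Tn)
}

#' Bootstrap ensemble of DMFA fits
#'
#' Repeats resampling + grid randomization + solving `n_samples` times
#' with per-sample seeded substreams (reproducible regardless of
#' execution order) and summarizes the volumetric rate, fitted
#' concentration and (when `xv` is supplied) cell-specific rate
#' trajectories by their empirical median, 68% and 95% percentile bands
#' on `eval_times`.  For an unbiased ensemble the regularization weight
#' should be zero or tiny.
#'
#' @param data a `measurement_set`.
#' @param model a `noise_model`.
#' @param grid an `inflection_grid` (jittered per sample).
#' @param E macro-reaction matrix for modes `"em"` (ignored otherwise).
#' @param network a `metabolic_network` for modes
#'   `"unbounded"`/`"bounded"`.
#' @param mode one of `"unbounded"`, `"bounded"`, `"em"`.
#' @param n_samples number of bootstrap samples (>= 2; 500 is a typical
#'   production value).
#' @param alpha_boot regularization during bootstrap (default 0).
#' @param jitter_fraction see [randomize_grid()].
#' @param seed integer master seed.
#' @param eval_times trajectory evaluation grid (default 50 points over
#'   the data span).
#' @param xv optional viable-cell interpolant for cell-specific rates.
#' @param scale unit factor for [specific_rates()] (default 1e-3).
#' @return object of class `dmfa_ensemble` with elements `n_samples`,
#'   `n_failed`, `n_clipped`, `eval_times`, sample arrays `rates`,
#'   `conc`, `specific` (n_kept x n_quantity x n_times), and `bands`
#'   (list of long data.frames with columns quantity, time, median,
#'   lo68, hi68, lo95, hi95).
#' @export
dmfa_bootstrap <- function(data, model, grid, E = NULL, network = NULL,
                           mode = c("em", "bounded", "unbounded"),
                           n_samples = 500L, alpha_boot = 0,
                           jitter_fraction = 0.5, seed = 1L,
                           eval_times = NULL, xv = NULL, scale = 1e-3) {
  mode <- match.arg(mode)
  if (n_samples < 2L) stop("n_samples must be >= 2")
  if (mode == "em" && is.null(E)) stop("mode 'em' requires E")
  if (mode != "em" && is.null(network)) stop("this mode requires a network")
  if (is.null(eval_times)) {
    sp <- ms_span(data)
    eval_times <- seq(sp[1], sp[2], length.out = 50L)
  }
  solve_one <- function(d, g) {
    switch(mode,
      em = solve_em(d, E, g, alpha = alpha_boot, xv = xv),
      bounded = solve_bounded(d, network, g),
      unbounded = solve_unbounded(d, network, g))
  }
  rates <- list(); conc <- list(); spec <- list()
  n_failed <- 0L; n_clipped <- 0L
  for (i in seq_len(n_samples)) {
    rng <- new_rng(rng_subseed(seed, i))
    d <- resample_measurements(data, model, rng)
    n_clipped <- n_clipped + attr(d, "n_clipped")
    g <- randomize_grid(grid, rng, jitter_fraction)
    fit <- tryCatch(solve_one(d, g), error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    rates[[length(rates) + 1L]] <- node_trajectories(fit, eval_times)
    conc[[length(conc) + 1L]] <- t(fitted_concentrations(fit, eval_times))
    if (!is.null(xv))
      spec[[length(spec) + 1L]] <-
        specific_rates(fit, xv, eval_times, scale = scale)
  }
  if (n_failed > 0.2 * n_samples)
    stop("more than 20% of bootstrap solves failed (", n_failed, "/",
         n_samples, "); model and data are inconsistent")
  to_array <- function(lst) {
    if (!length(lst)) return(NULL)
    a <- array(unlist(lst), dim = c(dim(lst[[1]]), length(lst)),
               dimnames = c(dimnames(lst[[1]]), list(NULL)))
    aperm(a, c(3L, 1L, 2L))       # sample x quantity x time
  }
  arr <- list(rates = to_array(rates), conc = to_array(conc),
              specific = to_array(spec))
  bands <- lapply(arr[!vapply(arr, is.null, logical(1))],
                  ensemble_bands, eval_times = eval_times)
  structure(list(n_samples = n_samples, n_failed = n_failed,
                 n_clipped = n_clipped, eval_times = eval_times,
                 rates = arr$rates, conc = arr$conc,
                 specific = arr$specific, bands = bands, seed = seed,
                 mode = mode, alpha_boot = alpha_boot),
            class = "dmfa_ensemble")
}

# empirical percentile bands from a sample x quantity x time array
ensemble_bands <- function(a, eval_times) {
  qn <- dimnames(a)[[2]]
  if (is.null(qn)) qn <- sprintf("q%d", seq_len(dim(a)[2]))
  out <- expand.grid(quantity = qn, time = eval_times,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  qs <- c(0.025, 0.16, 0.5, 0.84, 0.975)
  vals <- apply(a, c(2L, 3L), stats::quantile, probs = qs, names = FALSE)
  # vals: 5 x n_q x n_t
  out$median <- as.vector(vals[3, , ])
  out$lo68 <- as.vector(vals[2, , ]); out$hi68 <- as.vector(vals[4, , ])
  out$lo95 <- as.vector(vals[1, , ]); out$hi95 <- as.vector(vals[5, , ])
  out
}

#' @export
print.dmfa_ensemble <- function(x, ...) {
  cat("DMFA bootstrap ensemble (", x$mode, "): ",
      x$n_samples - x$n_failed, "/", x$n_samples, " successful samples, ",
      length(x$eval_times), " evaluation times\n", sep = "")
  invisible(x)
}
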