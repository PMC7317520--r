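# Reports, configuration and the command-line entry point.  All
# artifacts are plain delimited text or JSON and can be re-read by the
# package's own readers.

#' Write a DMFA fit report
#'
#' Writes `nodes.tsv` (node values with the grid times), `curves.tsv`
#' (fitted concentrations on an evaluation grid) and `summary.json`
#' (mode, SSR, alpha, grid, initial concentrations, solver
#' diagnostics).
#'
#' @param fit a `dmfa_fit`.
#' @param outdir output directory (created if missing).
#' @param eval_times curve evaluation times (default 101 points over
#'   the grid span).
#' @return named vector of written file paths, invisibly.
#' @export
write_fit_report <- function(fit, outdir, eval_times = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(eval_times))
    eval_times <- seq(fit$grid[1], fit$grid[length(fit$grid)],
                      length.out = 101L)
  nodes <- data.frame(direction = rownames(fit$node_values),
                      fit$node_values, check.names = FALSE)
  names(nodes) <- c("direction", formatC(as.numeric(fit$grid),
                                         digits = 17, format = "g"))
  f_nodes <- file.path(outdir, "nodes.tsv")
  utils::write.table(format_num_df(nodes), f_nodes, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  curves <- data.frame(time = eval_times,
                       fitted_concentrations(fit, eval_times),
                       check.names = FALSE)
  f_curves <- file.path(outdir, "curves.tsv")
  utils::write.table(format_num_df(curves), f_curves, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  f_sum <- file.path(outdir, "summary.json")
  jsonlite::write_json(list(
    mode = fit$mode, SSR = fit$SSR, alpha = fit$alpha,
    grid = as.numeric(fit$grid), species = fit$species,
    c0 = as.list(fit$c0),
    kkt = fit$kkt[c("stationarity", "feasibility", "complementarity")],
    package_version = as.character(utils::packageVersion("dmfa"))),
    f_sum, auto_unbox = TRUE, digits = NA)
  invisible(c(nodes = f_nodes, curves = f_curves, summary = f_sum))
}

format_num_df <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 17, format = "g")
  df
}

#' Write bootstrap band tables
#'
#' One file per quantity class (`rates`, `conc`, `specific` when
#' present): columns quantity, time, median, lo68, hi68, lo95, hi95.
#'
#' @param ensemble a `dmfa_ensemble`.
#' @param outdir output directory.
#' @return named vector of file paths, invisibly.
#' @export
write_ensemble_report <- function(ensemble, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (nm in names(ensemble$bands)) {
    f <- file.path(outdir, paste0("bands_", nm, ".tsv"))
    utils::write.table(format_num_df(ensemble$bands[[nm]]), f,
                       sep = "\t", row.names = FALSE, quote = FALSE)
    out[nm] <- f
  }
  invisible(out)
}

#' Read a run configuration (YAML)
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

cli_usage <- function() {
  paste(
    "usage: dmfa <command> [--config FILE] [--out DIR] [--seed N] [--key value ...]",
    "commands:",
    "  simulate   simulate the demo fed-batch scenario and write noisy measurements",
    "  enumerate  enumerate elementary modes of a network file",
    "  reduce     geometrical reduction of an elementary-mode matrix",
    "  fit        DMFA fit (mode: unbounded|bounded|em|em_regularized, alpha: number|cv)",
    "  bootstrap  bootstrap confidence bands",
    "  select     NSGA-II selection of mode subsets",
    "  benchmark  reconstruction-error benchmark on the demo scenario",
    "  report     print the summary of a fit report directory",
    sep = "\n")
}

parse_flags <- function(argv) {
  flags <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (i == length(argv) || startsWith(argv[i + 1L], "--"))
      stop("flag --", key, " needs a value")
    flags[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  flags
}

cfg_get <- function(cfg, flags, key, default = NULL) {
  if (!is.null(flags[[key]])) return(flags[[key]])
  v <- cfg
  for (k in strsplit(key, ".", fixed = TRUE)[[1]]) {
    v <- v[[k]]
    if (is.null(v)) return(default)
  }
  v
}

#' Command-line dispatcher
#'
#' Thin shell over the package functions; see `cli_dispatch(character(0))`
#' for usage.  Flag values override config-file values.  Returns an
#' exit code (0 success, 1 validation/run error, 2 usage error) instead
#' of quitting, so it can be tested in-process; the installed
#' `exec/dmfa` script forwards `commandArgs()` and quits with the
#' returned status.
#'
#' @param argv character vector of arguments (subcommand first).
#' @return integer exit code, invisibly.
#' @export
cli_dispatch <- function(argv = commandArgs(trailingOnly = TRUE)) {
  cmds <- c("simulate", "enumerate", "reduce", "fit", "bootstrap",
            "select", "benchmark", "report")
  if (length(argv) == 0L || !argv[1] %in% cmds) {
    message(cli_usage())
    return(invisible(2L))
  }
  cmd <- argv[1]
  code <- tryCatch({
    flags <- parse_flags(argv[-1])
    cfg <- if (!is.null(flags$config)) read_config(flags$config) else list()
    do.call(paste0("cli_", cmd), list(cfg = cfg, flags = flags))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("unexpected argument|needs a value", conditionMessage(e))) {
      message(cli_usage()); 2L
    } else 1L
  })
  invisible(code)
}

cli_out <- function(cfg, flags) {
  out <- cfg_get(cfg, flags, "out", "dmfa_out")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  out
}

cli_simulate <- function(cfg, flags) {
  seed <- as.integer(cfg_get(cfg, flags, "seed", 1L))
  sc <- simulation_scenario()
  sim <- simulate_scenario(sc)
  d <- sample_measurements(sim, rng = seed)
  out <- cli_out(cfg, flags)
  write_measurements(d, file.path(out, "measurements.tsv"))
  write_em_matrix(em_set(sc$E, normalize = FALSE),
                  file.path(out, "em_matrix.tsv"))
  message("wrote ", file.path(out, "measurements.tsv"))
}

cli_enumerate <- function(cfg, flags) {
  net <- read_network(cfg_get(cfg, flags, "network"))
  ems <- enumerate_ems(net)
  out <- cli_out(cfg, flags)
  write_em_matrix(ems, file.path(out, "em_matrix.tsv"))
  message("wrote ", ncol(ems$E), " modes")
}

cli_load_data <- function(cfg, flags) {
  path <- cfg_get(cfg, flags, "measurements")
  if (is.null(path)) stop("measurements path required")
  read_measurements(path, schema = cfg_get(cfg, flags, "schema", "long"),
                    xv_species = cfg_get(cfg, flags, "xv_species", "Xv"))
}

cli_load_em <- function(cfg, flags, data) {
  path <- cfg_get(cfg, flags, "em_matrix")
  if (is.null(path)) stop("em_matrix path required")
  sp <- unique(data$species)
  read_em_matrix(path, species = sp)
}

cli_grid <- function(cfg, flags, data) {
  inflection_grid(data,
                  n_nodes = as.integer(cfg_get(cfg, flags,
                                               "grid.n_nodes", 5L)))
}

cli_fit <- function(cfg, flags) {
  data <- cli_load_data(cfg, flags)
  grid <- cli_grid(cfg, flags, data)
  mode <- cfg_get(cfg, flags, "mode", "em")
  fit <- if (mode %in% c("unbounded", "bounded")) {
    net <- read_network(cfg_get(cfg, flags, "network"))
    if (mode == "unbounded") solve_unbounded(data, net, grid)
    else solve_bounded(data, net, grid)
  } else {
    ems <- cli_load_em(cfg, flags, data)
    alpha <- cfg_get(cfg, flags, "alpha", "0")
    xv <- xv_interpolant(data)
    if (identical(alpha, "cv")) {
      alphas <- as.numeric(cfg_get(cfg, flags, "cv.alphas",
                                   10^seq(-4, 2)))
      cv <- cross_validate_alpha(
        data, ems$E, grid, alphas,
        folds = as.integer(cfg_get(cfg, flags, "cv.folds", 4L)),
        seed = as.integer(cfg_get(cfg, flags, "cv.seed", 1L)), xv = xv)
      message("cross-validated alpha = ", cv$alpha)
      solve_em(data, ems$E, grid, alpha = cv$alpha, xv = xv)
    } else {
      solve_em(data, ems$E, grid, alpha = as.numeric(alpha), xv = xv)
    }
  }
  files <- write_fit_report(fit, cli_out(cfg, flags))
  message("SSR = ", format(fit$SSR), "; wrote ", files[["summary"]])
}

cli_reduce <- function(cfg, flags) {
  data <- cli_load_data(cfg, flags)
  ems <- cli_load_em(cfg, flags, data)
  grid <- cli_grid(cfg, flags, data)
  red <- geometric_reduction(
    ems, data, grid,
    tol_fraction = as.numeric(cfg_get(cfg, flags, "tol_fraction", 0.01)))
  out <- cli_out(cfg, flags)
  write_em_matrix(red, file.path(out, "em_reduced.tsv"))
  utils::write.table(attr(red, "trace"),
                     file.path(out, "reduction_trace.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  message("reduced ", ncol(ems$E), " -> ", ncol(red$E), " modes")
}

cli_bootstrap <- function(cfg, flags) {
  data <- cli_load_data(cfg, flags)
  ems <- cli_load_em(cfg, flags, data)
  grid <- cli_grid(cfg, flags, data)
  sp <- unique(data$species)
  nm <- noise_model(
    a = stats::setNames(as.numeric(cfg_get(cfg, flags, "noise.a", 0)),
                        sp)[sp],
    b = stats::setNames(as.numeric(cfg_get(cfg, flags, "noise.b",
                                           0.05 / 1.96)), sp)[sp])
  ens <- dmfa_bootstrap(
    data, nm, grid, E = ems$E, mode = "em",
    n_samples = as.integer(cfg_get(cfg, flags, "n", 500L)),
    seed = as.integer(cfg_get(cfg, flags, "seed", 1L)),
    xv = xv_interpolant(data))
  files <- write_ensemble_report(ens, cli_out(cfg, flags))
  message("wrote ", paste(files, collapse = ", "))
}

cli_select <- function(cfg, flags) {
  data <- cli_load_data(cfg, flags)
  ems <- cli_load_em(cfg, flags, data)
  grid <- cli_grid(cfg, flags, data)
  always <- cfg_get(cfg, flags, "ga.always_include", NULL)
  if (!is.null(always) && is.character(always))
    always <- match(strsplit(always, ",")[[1]], ems$em_ids)
  front <- nsga2_select(
    data, ems$E, grid,
    pop = as.integer(cfg_get(cfg, flags, "ga.pop", 40L)),
    generations = as.integer(cfg_get(cfg, flags, "ga.generations", 60L)),
    seed = as.integer(cfg_get(cfg, flags, "seed", 1L)),
    always_include = always)
  write_front(front, file.path(cli_out(cfg, flags), "pareto_front.tsv"))
  message("front sizes: ", paste(front$size, collapse = ", "))
}

cli_benchmark <- function(cfg, flags) {
  bm <- run_benchmark(
    simulation_scenario(),
    n_replicates = as.integer(cfg_get(cfg, flags, "replicates", 5L)),
    seed = as.integer(cfg_get(cfg, flags, "seed", 1L)))
  out <- cli_out(cfg, flags)
  utils::write.table(bm$table, file.path(out, "benchmark.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  message("wrote ", file.path(out, "benchmark.tsv"))
}

cli_report <- function(cfg, flags) {
  dir <- cfg_get(cfg, flags, "dir")
  if (is.null(dir)) stop("report directory required (--dir)")
  s <- jsonlite::read_json(file.path(dir, "summary.json"))
  message("mode: ", s$mode, ", SSR: ", s$SSR, ", alpha: ", s$alpha)
}
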