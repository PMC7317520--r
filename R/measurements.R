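#' Construct a measurement set
#'
#' Holds time-stamped concentration measurements (medium components and
#' viable cell density) with per-point standard deviations.  Stored in
#' long format: one row per (time, species) observation.  Missing values
#' (`NA` in `value`) are kept but masked out of all fitting objectives.
#'
#' @param data data.frame with columns `time` (h), `species` (character),
#'   `value` (mM, or 1e6 cells/ml for the viable-cell series) and `sigma`
#'   (same units, > 0 wherever `value` is not `NA`).
#' @param xv_species id of the viable-cell density series (default
#'   `"Xv"`); may be absent from the data.
#' @return object of class `measurement_set` (a data.frame with
#'   attributes `xv_species`).
#' @export
measurement_set <- function(data, xv_species = "Xv") {
  stopifnot(is.data.frame(data),
            all(c("time", "species", "value", "sigma") %in% names(data)))
  data$species <- as.character(data$species)
  data <- data[order(data$species, data$time), , drop = FALSE]
  used <- !is.na(data$value)
  if (any(used & (is.na(data$sigma) | data$sigma <= 0)))
    stop("sigma must be > 0 for every non-missing measurement")
  rownames(data) <- NULL
  structure(data, class = c("measurement_set", "data.frame"),
            xv_species = xv_species)
}

#' @export
print.measurement_set <- function(x, ...) {
  cat("Measurement set:", length(unique(x$species)), "species,",
      length(unique(x$time)), "time points,",
      sum(!is.na(x$value)), "observations\n")
  invisible(x)
}

ms_span <- function(data) range(data$time[!is.na(data$value)])

#' Linear interpolant of the viable-cell density series
#'
#' Used for the cell-specific regularization penalty and for converting
#' volumetric to cell-specific rates; by convention the measured series
#' is interpolated linearly (never the fitted curve), which keeps the
#' regularized objective quadratic in the node values.
#'
#' @param data a `measurement_set` containing the viable-cell series.
#' @return function of time returning interpolated cell density
#'   (constant extrapolation beyond the data span).
#' @export
xv_interpolant <- function(data) {
  id <- attr(data, "xv_species")
  sub <- data[data$species == id & !is.na(data$value), , drop = FALSE]
  if (nrow(sub) < 2L)
    stop("viable-cell series '", id, "' needs at least two points")
  stats::approxfun(sub$time, sub$value, rule = 2)
}

#' Per-species linear noise model
#'
#' The standard deviation of a measurement is modeled as an affine
#' function of its magnitude, `sigma_i(c) = a_i + b_i * c`.  The common
#' benchmark convention "95% confidence interval equals p% of the
#' magnitude" corresponds to `a = 0`, `b = p / 100 / 1.96`.
#'
#' @param a named numeric vector of intercepts (concentration units),
#'   all >= 0.
#' @param b named numeric vector of slopes (dimensionless), all >= 0;
#'   names must match `a`.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b),
            !is.null(names(a)), identical(sort(names(a)), sort(names(b))))
  b <- b[names(a)]
  if (any(a < 0) || any(b < 0)) stop("noise parameters must be >= 0")
  # a + b == 0 (an exact, noise-free channel) is permitted here; such a
  # species cannot be used in a weighted fit and errors there instead.
  structure(list(a = a, b = b), class = "noise_model")
}

#' Evaluate the noise model
#' @param c concentration value(s), >= 0.
#' @param model a `noise_model`.
#' @param species species id.
#' @return standard deviation(s) `a + b * c`.
#' @export
sigma_of <- function(c, model, species) {
  stopifnot(inherits(model, "noise_model"))
  if (any(c < 0, na.rm = TRUE)) stop("negative concentration passed to sigma_of")
  if (!species %in% names(model$a))
    stop("noise model undefined for species '", species, "'")
  model$a[[species]] + model$b[[species]] * c
}

#' Read measurements from a delimited file
#'
#' Accepts long format (columns `time, species, value, sigma`) or wide
#' format (column `time`, one column per species, optional matching
#' `<species>_sigma` columns).  Blank cells become masked (`NA`)
#' observations.
#'
#' @param path file path (tab- or comma-separated, autodetected).
#' @param schema `"long"` or `"wide"`.
#' @param model optional `noise_model` used to fill sigmas when the file
#'   carries none.
#' @param xv_species viable-cell series id.
#' @return a `measurement_set`.
#' @export
read_measurements <- function(path, schema = c("long", "wide"),
                              model = NULL, xv_species = "Xv") {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("measurement file not found: ", path)
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (schema == "wide") {
    sig_cols <- grep("_sigma$", names(df), value = TRUE)
    sp_cols <- setdiff(names(df), c("time", sig_cols))
    long <- do.call(rbind, lapply(sp_cols, function(s) {
      sg <- paste0(s, "_sigma")
      data.frame(time = df$time, species = s, value = df[[s]],
                 sigma = if (sg %in% names(df)) df[[sg]] else NA_real_)
    }))
    df <- long
  }
  if (is.unsorted(tapply(df$time, df$species, function(t) !is.unsorted(t))))
    stop("times must be non-decreasing within each species")
  if (!is.null(model)) {
    fill <- is.na(df$sigma) & !is.na(df$value)
    df$sigma[fill] <- mapply(function(v, s) sigma_of(v, model, s),
                             df$value[fill], df$species[fill])
  }
  measurement_set(df, xv_species = xv_species)
}

#' Write measurements to a long-format delimited file
#' @param data a `measurement_set`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(data, path) {
  df <- as.data.frame(data)
  df$value <- formatC(df$value, digits = 17, format = "g")
  df$sigma <- formatC(df$sigma, digits = 17, format = "g")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
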