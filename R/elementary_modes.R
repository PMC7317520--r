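#' Elementary-mode set
#'
#' Container for a set of elementary modes: the external macro-reaction
#' matrix `E` (rows: external species, columns: modes, L2-normalized
#' unless flagged raw) and optionally the full flux patterns in reaction
#' space.
#'
#' @param E macro-reaction matrix with external species row names.
#' @param flux_patterns optional matrix (n_reactions x n_modes) of flux
#'   vectors in the network's reaction order.
#' @param em_ids mode labels (default `EM1..`).
#' @param normalize L2-normalize the columns of `E` (default TRUE).
#' @return object of class `em_set`.
#' @export
em_set <- function(E, flux_patterns = NULL, em_ids = NULL,
                   normalize = TRUE) {
  E <- as.matrix(E)
  if (is.null(rownames(E))) stop("E needs external species row names")
  if (is.null(em_ids)) em_ids <- sprintf("EM%d", seq_len(ncol(E)))
  colnames(E) <- em_ids
  if (normalize) E <- normalize_columns(E)
  if (!is.null(flux_patterns)) {
    flux_patterns <- as.matrix(flux_patterns)
    colnames(flux_patterns) <- em_ids
  }
  structure(list(E = E, flux_patterns = flux_patterns, em_ids = em_ids,
                 raw = !normalize),
            class = "em_set")
}

#' @export
print.em_set <- function(x, ...) {
  cat("Elementary-mode set:", ncol(x$E), "modes over", nrow(x$E),
      "external species",
      if (x$raw) "(raw columns)" else "(unit-norm columns)", "\n")
  invisible(x)
}

#' L2-normalize macro-reaction columns
#'
#' Scales every column to unit Euclidean norm, preserving consumption /
#' production signs.  Idempotent and invariant to positive column
#' scaling.
#'
#' @param E matrix with no zero column.
#' @return matrix of the same shape with unit-norm columns.
#' @export
normalize_columns <- function(E) {
  E <- as.matrix(E)
  nrm <- sqrt(colSums(E^2))
  if (any(nrm == 0)) {
    bad <- colnames(E)[nrm == 0]
    if (is.null(bad)) bad <- which(nrm == 0)
    stop("zero macro-reaction column(s): ", paste(bad, collapse = ", "))
  }
  sweep(E, 2L, nrm, "/")
}

#' Cosine similarity of two macro-reaction vectors
#' @param e_a,e_b nonzero numeric vectors of equal length.
#' @return `sum(e_a * e_b) / (||e_a|| ||e_b||)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(e_a, e_b) {
  na <- sqrt(sum(e_a^2)); nb <- sqrt(sum(e_b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vector")
  max(-1, min(1, sum(e_a * e_b) / (na * nb)))
}

#' Enumerate elementary modes of a small network
#'
#' Double-description enumeration of the extreme rays of the flux cone
#' `{v : N v = 0, v_irr >= 0}`: reversible reactions are split into
#' forward/backward non-negative pairs, the internal balances are
#' imposed one at a time with support-minimality filtering, split
#' artifacts (forward+backward two-cycles) are removed, and the modes
#' are mapped back to signed fluxes on the original reactions.  Intended
#' for small networks; enumeration stops with an error when the working
#' set exceeds `max_modes`.
#'
#' @param network a `metabolic_network`.
#' @param max_modes cap on the intermediate/final number of modes
#'   (default 5000); exceeded -> error advising external enumeration and
#'   [read_em_matrix()].
#' @param drop_internal_only drop modes with zero net external
#'   conversion (default TRUE; they cannot be observed in concentration
#'   data).
#' @return an `em_set` with normalized macro-reactions `E = P v / ||P v||`
#'   and the flux patterns.
#' @export
enumerate_ems <- function(network, max_modes = 5000L,
                          drop_internal_only = TRUE) {
  rev <- network$reversible
  n_rx <- length(rev)
  # split reversible columns into +/- pairs
  split_idx <- integer(0); split_sign <- numeric(0)
  for (k in seq_len(n_rx)) {
    split_idx <- c(split_idx, k); split_sign <- c(split_sign, 1)
    if (rev[k]) { split_idx <- c(split_idx, k); split_sign <- c(split_sign, -1) }
  }
  Ns <- network$N[, split_idx, drop = FALSE] *
    rep(split_sign, each = max(1L, nrow(network$N)))
  if (nrow(network$N) == 0L)
    Ns <- matrix(0, 0L, length(split_idx))
  n_split <- length(split_idx)

  rays <- diag(n_split)                       # columns are rays
  supports <- function(M) abs(M) > 1e-12
  for (i in seq_len(nrow(Ns))) {
    s <- as.numeric(Ns[i, ] %*% rays)
    zero <- abs(s) <= 1e-12
    pos <- which(s > 1e-12); neg <- which(s < -1e-12)
    new_rays <- rays[, zero, drop = FALSE]
    if (length(pos) && length(neg)) {
      for (p in pos) for (q in neg) {
        r_new <- s[p] * rays[, q] - s[q] * rays[, p]
        m <- max(abs(r_new))
        if (m > 0) new_rays <- cbind(new_rays, r_new / m)
      }
    }
    if (ncol(new_rays) == 0L) { rays <- new_rays; break }
    # support-minimality filter
    sup <- supports(new_rays)
    keep <- rep(TRUE, ncol(new_rays))
    card <- colSums(sup)
    ord <- order(card)
    for (a_i in seq_along(ord)) {
      a <- ord[a_i]
      if (!keep[a]) next
      for (b_i in seq_along(ord)) {
        b <- ord[b_i]
        if (a == b || !keep[b]) next
        if (card[b] > card[a] && all(sup[, a] <= sup[, b]))
          keep[b] <- FALSE
        }
    }
    rays <- new_rays[, keep, drop = FALSE]
    if (ncol(rays) > max_modes)
      stop("mode count exceeded cap (", max_modes,
           "); enumerate externally and import with read_em_matrix()")
  }
  if (ncol(rays) == 0L)
    stop("network admits no nontrivial steady-state flux")

  # map back to signed fluxes on the original reactions
  V <- matrix(0, n_rx, ncol(rays), dimnames = list(network$reaction_ids, NULL))
  for (j in seq_len(n_split))
    V[split_idx[j], ] <- V[split_idx[j], ] + split_sign[j] * rays[j, ]
  nz <- apply(abs(V), 2L, max) > 1e-12      # drop forward+backward cycles
  V <- V[, nz, drop = FALSE]
  # dedupe collinear columns (same direction)
  if (ncol(V) > 1L) {
    Vn <- sweep(V, 2L, sqrt(colSums(V^2)), "/")
    keep <- rep(TRUE, ncol(V))
    for (a in seq_len(ncol(V) - 1L)) {
      if (!keep[a]) next
      for (b in (a + 1L):ncol(V))
        if (keep[b] && sum(Vn[, a] * Vn[, b]) >= 1 - 1e-10) keep[b] <- FALSE
    }
    V <- V[, keep, drop = FALSE]
  }
  E_raw <- network$P %*% V
  if (drop_internal_only) {
    obs <- sqrt(colSums(E_raw^2)) > 1e-12
    V <- V[, obs, drop = FALSE]
    E_raw <- E_raw[, obs, drop = FALSE]
  }
  if (ncol(E_raw) == 0L) stop("no externally observable elementary modes")
  rownames(E_raw) <- network$external_ids
  em_set(E_raw, flux_patterns = V)
}

#' Geometrical reduction of an elementary-mode set
#'
#' Discards geometrically similar modes: columns are grouped by
#' single-linkage at a decreasing cosine-similarity threshold and each
#' group is replaced by its medoid (the member with the highest mean
#' similarity to the group).  After each threshold step the
#' elementary-mode DMFA problem is re-solved on the reduced set; the
#' reduction stops before the summed SSR over the supplied datasets
#' exceeds the full-set SSR by more than `tol_fraction` of the full-set
#' SSR.
#'
#' @param ems an `em_set`.
#' @param datasets a `measurement_set` or list of them.
#' @param grid an `inflection_grid` (or list, one per dataset).
#' @param tol_fraction allowed relative SSR increase (default 0.01);
#'   `0` removes only exactly collinear columns.
#' @param thresholds decreasing similarity schedule.
#' @return an `em_set` (subset of the input columns) with attribute
#'   `"trace"`: data.frame of threshold, n_modes and SSR at each step.
#' @export
geometric_reduction <- function(ems, datasets, grid, tol_fraction = 0.01,
                                thresholds = c(1 - 1e-10, 0.9999, 0.999,
                                               0.995, 0.99, 0.98, 0.95,
                                               0.90, 0.80, 0.70)) {
  if (tol_fraction < 0) stop("tol_fraction must be >= 0")
  if (inherits(datasets, "measurement_set")) datasets <- list(datasets)
  grids <- if (inherits(grid, "inflection_grid"))
    rep(list(grid), length(datasets)) else grid
  total_ssr <- function(E) {
    sum(vapply(seq_along(datasets), function(i)
      solve_em(datasets[[i]], E, grids[[i]], alpha = 0)$SSR, numeric(1)))
  }
  E <- normalize_columns(ems$E)
  ssr0 <- total_ssr(E)
  if (tol_fraction == 0) thresholds <- 1 - 1e-10
  trace <- data.frame(threshold = NA_real_, n_modes = ncol(E), ssr = ssr0)
  keep_idx <- seq_len(ncol(E))
  for (s in sort(thresholds, decreasing = TRUE)) {
    cur <- E[, keep_idx, drop = FALSE]
    if (ncol(cur) <= 1L) break
    grp <- single_linkage_groups(cur, s)
    if (max(grp) == length(keep_idx)) {   # no grouping at this threshold
      trace <- rbind(trace, data.frame(threshold = s,
                                       n_modes = length(keep_idx),
                                       ssr = NA_real_))
      next
    }
    med <- vapply(seq_len(max(grp)), function(g) {
      members <- which(grp == g)
      if (length(members) == 1L) return(members)
      S <- crossprod(cur[, members, drop = FALSE])
      members[which.max(colMeans(S))]
    }, integer(1))
    cand <- keep_idx[sort(med)]
    ssr <- total_ssr(E[, cand, drop = FALSE])
    trace <- rbind(trace, data.frame(threshold = s, n_modes = length(cand),
                                     ssr = ssr))
    if (ssr - ssr0 > tol_fraction * ssr0) break   # do not accept this step
    keep_idx <- cand
  }
  if (length(keep_idx) == ncol(E))
    warning("no reduction possible within the SSR tolerance")
  out <- em_set(ems$E[, keep_idx, drop = FALSE],
                flux_patterns = if (!is.null(ems$flux_patterns))
                  ems$flux_patterns[, keep_idx, drop = FALSE],
                em_ids = ems$em_ids[keep_idx])
  attr(out, "trace") <- trace
  out
}

# union-find single-linkage grouping at cosine-similarity threshold s
single_linkage_groups <- function(E_unit, s) {
  n <- ncol(E_unit)
  S <- crossprod(E_unit)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n)
    if (S[a, b] >= s) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[rb] <- ra
    }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Read an elementary-mode matrix from delimited text
#'
#' @param path file (tab- or comma-separated); first column species ids
#'   (orientation `"species_rows"`, default) or mode ids
#'   (`"modes_rows"`), header row with the other dimension's ids.
#' @param species external species ids of the target network, in order;
#'   the rows are realigned to this order (unmatched ids -> error).
#' @param orientation see above.
#' @param normalize normalize columns that are not unit norm (with a
#'   message).
#' @return an `em_set`.
#' @export
read_em_matrix <- function(path, species,
                           orientation = c("species_rows", "modes_rows"),
                           normalize = TRUE) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE)
  M <- as.matrix(df)
  if (orientation == "modes_rows") M <- t(M)
  missing_sp <- setdiff(species, rownames(M))
  if (length(missing_sp))
    stop("species missing from file: ", paste(missing_sp, collapse = ", "))
  extra <- setdiff(rownames(M), species)
  if (length(extra))
    stop("file species not in network: ", paste(extra, collapse = ", "))
  M <- M[species, , drop = FALSE]
  nrm <- sqrt(colSums(M^2))
  was_raw <- any(abs(nrm - 1) > 1e-6)
  if (was_raw && normalize)
    message("input columns were not unit norm; normalized on read")
  em_set(M, em_ids = colnames(M), normalize = normalize)
}

#' Write an elementary-mode matrix (species as rows) to delimited text
#' @param ems an `em_set`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_em_matrix <- function(ems, path) {
  df <- data.frame(species = rownames(ems$E),
                   apply(ems$E, 2L, formatC, digits = 17, format = "g"),
                   check.names = FALSE)
  names(df) <- c("species", ems$em_ids)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
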