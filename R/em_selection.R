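# Multiobjective selection of elementary-mode subsets: NSGA-II over
# binary inclusion chromosomes, minimizing jointly the summed DMFA SSR
# over all experiments and the subset cardinality.  The inner solve for
# each distinct chromosome is cached, since it dominates the runtime.

#' SSR of an elementary-mode subset
#'
#' Deletes the inactive columns of `E`, solves the (unregularized)
#' elementary-mode DMFA problem for every dataset and returns the summed
#' SSR.  Solver failures yield `Inf`.
#'
#' @param xi binary inclusion vector (length = ncol(E), at least one 1).
#' @param datasets a `measurement_set` or list of them.
#' @param E macro-reaction matrix.
#' @param grid an `inflection_grid` (or list, one per dataset).
#' @param cache optional environment used as a chromosome -> SSR cache.
#' @return summed SSR (scalar, possibly `Inf`).
#' @export
evaluate_subset <- function(xi, datasets, E, grid, cache = NULL) {
  xi <- as.integer(xi != 0)
  if (sum(xi) < 1L) stop("subset must contain at least one mode")
  key <- paste(xi, collapse = "")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  if (inherits(datasets, "measurement_set")) datasets <- list(datasets)
  grids <- if (inherits(grid, "inflection_grid"))
    rep(list(grid), length(datasets)) else grid
  Esub <- E[, xi == 1L, drop = FALSE]
  ssr <- tryCatch(
    sum(vapply(seq_along(datasets), function(i)
      solve_em(datasets[[i]], Esub, grids[[i]], alpha = 0)$SSR,
      numeric(1))),
    error = function(e) Inf)
  if (!is.null(cache)) cache[[key]] <- ssr
  ssr
}

# fast non-dominated sorting; objectives in rows of `obj` (n x 2), both
# minimized.  Returns integer front index per point (1 = best).
nds_rank <- function(obj) {
  n <- nrow(obj)
  rank <- integer(n)
  dominates <- function(a, b)
    all(obj[a, ] <= obj[b, ]) && any(obj[a, ] < obj[b, ])
  S <- vector("list", n); cnt <- integer(n)
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      if (p == q) next
      if (dominates(p, q)) S[[p]] <- c(S[[p]], q)
      else if (dominates(q, p)) cnt[p] <- cnt[p] + 1L
    }
    if (cnt[p] == 0L) rank[p] <- 1L
  }
  f <- 1L
  repeat {
    cur <- which(rank == f)
    if (!length(cur)) break
    for (p in cur) for (q in S[[p]]) {
      cnt[q] <- cnt[q] - 1L
      if (cnt[q] == 0L) rank[q] <- f + 1L
    }
    f <- f + 1L
  }
  rank
}

crowding_distance <- function(obj) {
  n <- nrow(obj)
  d <- rep(0, n)
  for (m in seq_len(ncol(obj))) {
    o <- order(obj[, m])
    rng <- obj[o[n], m] - obj[o[1], m]
    d[o[c(1, n)]] <- Inf
    if (n > 2L && rng > 0)
      d[o[2:(n - 1L)]] <- d[o[2:(n - 1L)]] +
        (obj[o[3:n], m] - obj[o[1:(n - 2L)], m]) / rng
  }
  d
}

#' NSGA-II selection of minimal elementary-mode subsets
#'
#' Searches binary inclusion chromosomes for the Pareto front of
#' `{summed SSR, subset size}` with the NSGA-II algorithm: binary
#' tournament selection on (front rank, crowding distance), uniform
#' crossover, per-bit flip mutation, and a repair step enforcing at
#' least one active mode plus an optional always-include mask.
#' Deterministic for a given seed.
#'
#' @param datasets a `measurement_set` or list of them.
#' @param E macro-reaction matrix (columns = candidate modes).
#' @param grid an `inflection_grid` (or list per dataset).
#' @param pop population size (even, >= 8; default 100).
#' @param generations number of generations (default 200).
#' @param p_cross uniform-crossover probability (default 0.9).
#' @param p_mut per-bit mutation rate (default `1/ncol(E)`).
#' @param seed integer seed.
#' @param always_include indices (or logical mask) of modes forced into
#'   every subset, e.g. a biomass death mode.
#' @return object of class `pareto_front`: data.frame with columns
#'   `size`, `SSR`, `chromosome` (bitstring) and `modes` (comma-joined
#'   ids), sorted by size, mutually non-dominated; attributes carry the
#'   GA provenance and the evaluation cache.
#' @export
nsga2_select <- function(datasets, E, grid, pop = 100L,
                         generations = 200L, p_cross = 0.9,
                         p_mut = NULL, seed = 1L, always_include = NULL) {
  n <- ncol(E)
  if (pop < 8L || pop %% 2L != 0L) stop("pop must be even and >= 8")
  if (generations < 1L) stop("generations must be >= 1")
  if (is.null(p_mut)) p_mut <- 1 / n
  mask <- rep(FALSE, n)
  if (!is.null(always_include)) {
    if (is.logical(always_include)) mask <- always_include else
      mask[always_include] <- TRUE
  }
  if (length(mask) != n) stop("always_include mask length mismatch")
  rng <- new_rng(seed)
  cache <- new.env(parent = emptyenv())
  repair <- function(xi) {
    xi[mask] <- 1L
    if (sum(xi) == 0L) xi[rng_sample(rng, n, 1L)] <- 1L
    xi
  }
  evalf <- function(xi) evaluate_subset(xi, datasets, E, grid, cache)

  # initial population: full set, singletons-ish random densities
  P <- matrix(0L, pop, n)
  P[1, ] <- 1L
  for (i in 2:pop) {
    dens <- rng_unif(rng, 1L, 0.05, 0.95)
    P[i, ] <- as.integer(rng_unif(rng, n) < dens)
    P[i, ] <- repair(P[i, ])
  }
  obj <- t(apply(P, 1L, function(xi) c(evalf(xi), sum(xi))))

  for (gen in seq_len(generations)) {
    rank <- nds_rank(obj)
    crowd <- numeric(pop)
    for (f in unique(rank)) {
      idx <- which(rank == f)
      crowd[idx] <- crowding_distance(obj[idx, , drop = FALSE])
    }
    tournament <- function() {
      ij <- rng_sample(rng, pop, 2L, replace = TRUE)
      a <- ij[1]; b <- ij[2]
      if (rank[a] < rank[b]) a
      else if (rank[b] < rank[a]) b
      else if (crowd[a] >= crowd[b]) a else b
    }
    Q <- matrix(0L, pop, n)
    for (i in seq(1L, pop, by = 2L)) {
      pa <- P[tournament(), ]; pb <- P[tournament(), ]
      if (rng_unif(rng, 1L) < p_cross) {
        swap <- rng_unif(rng, n) < 0.5
        tmp <- pa[swap]; pa[swap] <- pb[swap]; pb[swap] <- tmp
      }
      flip_a <- rng_unif(rng, n) < p_mut
      flip_b <- rng_unif(rng, n) < p_mut
      pa[flip_a] <- 1L - pa[flip_a]
      pb[flip_b] <- 1L - pb[flip_b]
      Q[i, ] <- repair(pa)
      Q[i + 1L, ] <- repair(pb)
    }
    obj_q <- t(apply(Q, 1L, function(xi) c(evalf(xi), sum(xi))))
    R <- rbind(P, Q); obj_r <- rbind(obj, obj_q)
    # dedupe identical chromosomes to keep diversity
    keys <- apply(R, 1L, paste, collapse = "")
    first <- !duplicated(keys)
    R <- R[first, , drop = FALSE]; obj_r <- obj_r[first, , drop = FALSE]
    rank_r <- nds_rank(obj_r)
    sel <- integer(0); f <- 1L
    while (length(sel) < pop && any(rank_r == f)) {
      idx <- which(rank_r == f)
      if (length(sel) + length(idx) <= pop) sel <- c(sel, idx)
      else {
        cd <- crowding_distance(obj_r[idx, , drop = FALSE])
        sel <- c(sel, idx[order(cd, decreasing = TRUE)][
          seq_len(pop - length(sel))])
      }
      f <- f + 1L
    }
    if (length(sel) < pop)      # refill after dedupe shrinkage
      sel <- c(sel, rep(sel[1], pop - length(sel)))
    P <- R[sel, , drop = FALSE]; obj <- obj_r[sel, , drop = FALSE]
  }

  nd <- which(nds_rank(obj) == 1L)
  # one representative (lowest SSR) per cardinality
  sizes <- obj[nd, 2L]; ssrs <- obj[nd, 1L]
  keep <- nd[order(sizes, ssrs)]
  keep <- keep[!duplicated(obj[keep, 2L])]
  ids <- colnames(E); if (is.null(ids)) ids <- sprintf("EM%d", seq_len(n))
  front <- data.frame(
    size = obj[keep, 2L], SSR = obj[keep, 1L],
    chromosome = apply(P[keep, , drop = FALSE], 1L, paste, collapse = ""),
    modes = apply(P[keep, , drop = FALSE], 1L, function(xi)
      paste(ids[xi == 1L], collapse = ",")),
    stringsAsFactors = FALSE)
  front <- front[order(front$size), , drop = FALSE]
  rownames(front) <- NULL
  structure(front, class = c("pareto_front", "data.frame"),
            pop = pop, generations = generations, seed = seed,
            n_evaluations = length(ls(cache)), cache = cache)
}

#' Smallest adequate subset size from a Pareto front
#'
#' Reports the SSR of each front entry relative to the bounded-DMFA
#' lower bound and flags the smallest cardinality whose SSR stays within
#' `(1 + tol)` of that bound.
#'
#' @param front a `pareto_front`.
#' @param ssr_bound the bounded-DMFA SSR on the same data/grid.
#' @param tol relative tolerance (default 0.05).
#' @return list with `table` (size, SSR, ratio to the bound, adequate
#'   flag) and `selected_size` (NA if no entry is adequate).
#' @export
knee_report <- function(front, ssr_bound, tol = 0.05) {
  stopifnot(nrow(front) >= 1L, ssr_bound >= 0)
  tab <- data.frame(size = front$size, SSR = front$SSR,
                    ratio = front$SSR / ssr_bound)
  tab$adequate <- tab$SSR <= (1 + tol) * ssr_bound
  sel <- if (any(tab$adequate)) min(tab$size[tab$adequate]) else NA_integer_
  list(table = tab, selected_size = sel)
}

#' Audit mutual non-domination of a Pareto front
#' @param front a `pareto_front` (or data.frame with `size` and `SSR`).
#' @return TRUE invisibly; error describing a violating pair otherwise.
#' @export
audit_front <- function(front) {
  n <- nrow(front)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    if (front$size[a] <= front$size[b] && front$SSR[a] <= front$SSR[b] &&
        (front$size[a] < front$size[b] || front$SSR[a] < front$SSR[b]))
      stop("entry ", b, " is dominated by entry ", a)
  }
  invisible(TRUE)
}

#' Export a Pareto front as delimited text
#' @param front a `pareto_front`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_front <- function(front, path) {
  utils::write.table(as.data.frame(front), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
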