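# Fixtures are built in code; oracles here are deliberately independent
# of the implementation paths they check.

chain_network <- function() {
  metabolic_network(
    data.frame(id = c("A", "M", "B"),
               role = c("external", "internal", "external")),
    list(list(id = "v1", stoichiometry = c(A = -1, M = 1), reversible = FALSE),
         list(id = "v2", stoichiometry = c(M = -1, B = 1), reversible = FALSE)))
}

branched_network <- function() {
  metabolic_network(
    data.frame(id = c("A", "M", "B", "C"),
               role = c("external", "internal", "external", "external")),
    list(list(id = "v1", stoichiometry = c(A = -1, M = 1), reversible = FALSE),
         list(id = "v2", stoichiometry = c(M = -1, B = 1), reversible = FALSE),
         list(id = "v3", stoichiometry = c(M = -1, C = 1), reversible = FALSE)))
}

reversible_exchange_network <- function() {
  metabolic_network(
    data.frame(id = c("A", "B"), role = c("external", "external")),
    list(list(id = "v1", stoichiometry = c(A = -1, B = 1), reversible = TRUE)))
}

toy_network <- function() {
  read_network(system.file("extdata", "toy_network.txt", package = "dmfa"))
}

# data whose truth is exactly in the DMFA model class: piecewise-linear
# volumetric mode rates R(t) on `grid`, concentrations from the tested
# design operator (itself validated against numerical quadrature in
# test-dmfa.R)
pwl_dataset <- function(E, grid, R_nodes, c0, times, noise = 0,
                        seed = 1, sigma = NULL) {
  A <- design_matrix(E, grid, times)
  # rows of A are time-major blocks of species; reshape to times x species
  inc <- t(matrix(A %*% as.vector(R_nodes), nrow = nrow(E)))
  truth <- sweep(inc, 2L, unlist(c0[rownames(E)]), "+")
  if (min(truth) < 0)
    stop("fixture error: true trajectory goes negative (",
         rownames(E)[which(truth == min(truth), arr.ind = TRUE)[1, 2]],
         " reaches ", round(min(truth), 3), ")")
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(nrow(E)), function(i) {
    s <- rownames(E)[i]
    v <- c0[[s]] + inc[, i]
    sig <- if (is.null(sigma)) pmax(0.02 * abs(v), 0.05) else rep(sigma, length(v))
    data.frame(time = times, species = s,
               value = v + if (noise > 0) rnorm(length(v), 0, noise * sig) else 0,
               sigma = sig)
  }))
  measurement_set(rows)
}

toy_R_nodes <- function(n_em, n_nodes, seed = 11, lo = 0.05, hi = 0.5) {
  set.seed(seed)
  matrix(runif(n_em * n_nodes, lo, hi), n_em, n_nodes)
}

# brute-force elementary-mode oracle: tests every support subset for a
# one-dimensional null space with feasible signs (subset-support
# enumeration; exponential, for <= 8 reactions)
brute_force_ems <- function(network) {
  n <- length(network$reaction_ids)
  irr <- !network$reversible
  found <- list()
  for (mask in 1:(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    NS <- network$N[, S, drop = FALSE]
    if (nrow(NS) == 0L) {
      if (length(S) != 1L) next
      v_s <- 1
    } else {
      dec <- svd(NS, nu = 0, nv = length(S))
      d <- c(dec$d, rep(0, length(S) - length(dec$d)))
      nullity <- sum(d <= 1e-10 * max(d, 1))
      if (nullity != 1L) next
      v_s <- dec$v[, length(S)]
    }
    if (any(abs(v_s) < 1e-10)) next          # support must be exactly S
    v <- numeric(n); v[S] <- v_s
    # orient: irreversible components must be non-negative
    for (sgn in c(1, -1)) {
      w <- sgn * v
      if (all(w[irr] >= -1e-12)) {
        found[[length(found) + 1L]] <- w / max(abs(w))
        }
    }
  }
  if (!length(found)) return(matrix(0, n, 0))
  V <- do.call(cbind, found)
  # minimality: drop supports that strictly contain another support
  sup <- abs(V) > 1e-9
  card <- colSums(sup)
  keep <- rep(TRUE, ncol(V))
  for (a in seq_len(ncol(V))) for (b in seq_len(ncol(V))) {
    if (a == b || !keep[b]) next
    if (card[a] < card[b] && all(sup[, a] <= sup[, b])) keep[b] <- FALSE
  }
  V <- V[, keep, drop = FALSE]
  # dedupe collinear same-direction columns
  Vn <- sweep(V, 2L, sqrt(colSums(V^2)), "/")
  keep <- rep(TRUE, ncol(V))
  for (a in seq_len(ncol(V))) for (b in seq_len(ncol(V))) {
    if (a >= b || !keep[b] || !keep[a]) next
    if (sum(Vn[, a] * Vn[, b]) >= 1 - 1e-9) keep[b] <- FALSE
  }
  V[, keep, drop = FALSE]
}

# same mode set up to column order and positive scaling?
same_mode_set <- function(V1, V2, tol = 1e-8) {
  if (ncol(V1) != ncol(V2)) return(FALSE)
  n1 <- sweep(V1, 2L, sqrt(colSums(V1^2)), "/")
  n2 <- sweep(V2, 2L, sqrt(colSums(V2^2)), "/")
  used <- rep(FALSE, ncol(V2))
  for (a in seq_len(ncol(n1))) {
    hit <- FALSE
    for (b in seq_len(ncol(n2))) {
      if (!used[b] && max(abs(n1[, a] - n2[, b])) < tol) {
        used[b] <- TRUE; hit <- TRUE; break
      }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

# combinatorial non-negative least squares oracle: best objective over
# all support patterns whose unconstrained solution is feasible
nnls_brute_force <- function(A, b) {
  n <- ncol(A)
  best <- sum(b^2)                   # empty support
  for (mask in 1:(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    AS <- A[, S, drop = FALSE]
    if (qr(AS)$rank < length(S)) next
    x <- qr.solve(AS, b)
    if (all(x >= -1e-12)) best <- min(best, sum((AS %*% x - b)^2))
  }
  best
}

demo_c0 <- c(Glc = 60, Gln = 15, Lac = 15, Amm = 1, Glu = 1, mAb = 0.5,
             Xv = 1)

toy_c0 <- c(Glc = 25, Lac = 1, Gln = 12, Amm = 0.5, CO2 = 0.5, mAb = 0,
            Xv = 1)
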