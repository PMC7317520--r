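# Inequality-constrained weighted least squares:
#   min ||A x - b||^2  s.t.  G x >= h
# solved by the classical least-squares-with-inequalities (LSI) reduction:
# SVD of A maps the problem to least distance programming (LDP), which is
# solved through a single non-negative least squares (NNLS) problem
# (Lawson & Hanson).  Sizes here are small (tens to a few hundred
# unknowns), so dense SVD is appropriate.

#' Solve a linearly inequality-constrained least-squares problem
#'
#' Minimizes `||A x - b||^2` subject to `G x >= h`.  With no constraints
#' this is ordinary least squares via QR.  `A` must have full column rank
#' (rank-deficient designs signal an error naming the deficient
#' directions unless `minimum_norm = TRUE`, in which case the
#' unconstrained minimum-norm solution is returned and constraints must
#' be absent).
#'
#' @param A design matrix (m x n, m >= n).
#' @param b response vector (length m).
#' @param G constraint matrix (p x n) or NULL.
#' @param h constraint right-hand side (length p), default zeros.
#' @param minimum_norm allow rank-deficient unconstrained solves.
#' @param tol relative singular-value tolerance for rank decisions.
#' @return list with `x`, `objective` (residual sum of squares), `kkt`
#'   (list: `stationarity`, `feasibility`, `complementarity`, `lambda`),
#'   and `rank`.
#' @keywords internal
lsq_solve <- function(A, b, G = NULL, h = NULL, minimum_norm = FALSE,
                      tol = 1e-10) {
  A <- as.matrix(A); b <- as.numeric(b)
  stopifnot(nrow(A) == length(b))
  n <- ncol(A)
  constrained <- !is.null(G) && nrow(G) > 0L
  if (constrained) {
    G <- as.matrix(G)
    stopifnot(ncol(G) == n)
    if (is.null(h)) h <- rep(0, nrow(G))
  }

  sv <- svd(A)
  r <- sum(sv$d > tol * max(sv$d))
  if (r < n && constrained) {
    # A constrained problem with collinear directions (e.g. an
    # elementary-mode set larger than the rank of its external cone)
    # still has a unique SSR minimum but non-unique coordinates; a tiny
    # conditioning ridge (1e-12 of the data scale) selects the
    # minimum-norm representative without affecting the SSR beyond
    # solver precision.
    lam <- 1e-6 * max(sv$d)            # sqrt of 1e-12 * sigma_max^2
    A <- rbind(A, diag(lam, n))
    b <- c(b, rep(0, n))
    sv <- svd(A)
    r <- n
  }
  if (r < n) {
    if (!minimum_norm) {
      defic <- sv$v[, (r + 1L):n, drop = FALSE]
      lead <- apply(abs(defic), 2L, which.max)
      nm <- colnames(A)
      stop("design matrix is rank deficient (rank ", r, " < ", n,
           "); unidentifiable directions involve column(s): ",
           paste(unique(if (is.null(nm)) lead else nm[lead]), collapse = ", "))
    }
    x <- sv$v[, 1:r, drop = FALSE] %*%
      ((crossprod(sv$u[, 1:r, drop = FALSE], b)) / sv$d[1:r])
    x <- as.numeric(x)
    res <- A %*% x - b
    return(list(x = x, objective = sum(res^2),
                kkt = list(stationarity = 0, feasibility = Inf,
                           complementarity = 0, lambda = numeric(0)),
                rank = r))
  }

  g <- crossprod(sv$u[, 1:n, drop = FALSE], b)   # U1' b
  if (!constrained) {
    x <- as.numeric(sv$v %*% (g / sv$d[1:n]))
  } else {
    # LSI -> LDP: x = V D^{-1} (z + g), minimize ||z|| s.t. Gt z >= ht
    VDinv <- sweep(sv$v, 2L, sv$d[1:n], "/")
    Gt <- G %*% VDinv
    ht <- h - as.numeric(Gt %*% g)
    z <- ldp_solve(Gt, ht)
    x <- as.numeric(VDinv %*% (z + g))
  }
  res <- as.numeric(A %*% x - b)
  obj <- sum(res^2)

  kkt <- list(stationarity = 0, feasibility = Inf,
              complementarity = 0, lambda = numeric(0))
  grad <- 2 * as.numeric(crossprod(A, res))
  scale <- max(1, sqrt(sum(grad^2)), 2 * max(sv$d)^2 * max(1, sqrt(sum(x^2))))
  if (!constrained) {
    kkt$stationarity <- sqrt(sum(grad^2)) / scale
  } else {
    slack <- as.numeric(G %*% x - h)
    kkt$feasibility <- min(slack)
    act <- which(slack <= 1e-8 * max(1, abs(h)))
    lambda <- rep(0, nrow(G))
    if (length(act)) {
      Ga <- t(G[act, , drop = FALSE])
      fit <- pracma::lsqnonneg(Ga, grad)
      lambda[act] <- fit$x
    }
    kkt$lambda <- lambda
    kkt$stationarity <- sqrt(sum((grad - as.numeric(t(G) %*% lambda))^2)) / scale
    kkt$complementarity <- max(abs(lambda * slack)) / scale
  }
  list(x = x, objective = obj, kkt = kkt, rank = r)
}

# Least distance programming: min ||z|| s.t. E z >= f (Lawson & Hanson).
# Constraint rows are normalized first: the feasible set is unchanged
# and the reduction becomes scale-invariant.
ldp_solve <- function(E, f) {
  n <- ncol(E)
  if (all(f <= 0)) return(rep(0, n))          # z = 0 already feasible
  nr <- sqrt(rowSums(E^2) + f^2)
  keep <- nr > 0
  E <- E[keep, , drop = FALSE] / nr[keep]
  f <- f[keep] / nr[keep]
  M <- rbind(t(E), matrix(f, nrow = 1L))      # (n+1) x p
  d <- c(rep(0, n), 1)
  fit <- pracma::lsqnonneg(M, d)
  r <- as.numeric(M %*% fit$x - d)
  rn1 <- r[n + 1L]
  if (abs(rn1) < 1e-12)
    stop("constraint set infeasible or numerically degenerate in LDP")
  -r[seq_len(n)] / rn1
}
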