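#' Define a metabolic network
#'
#' Builds a metabolic network object from a species table and a reaction
#' list, and assembles the internal and external stoichiometric matrices.
#' Species are tagged `internal` (balanced at pseudo steady state) or
#' `external` (medium components whose concentrations evolve in time,
#' including viable cells).  The sign convention is consumption negative,
#' production positive, in both matrices.
#'
#' @param species data.frame with columns `id` (unique short string),
#'   `role` (`"internal"` or `"external"`) and optionally `name`.
#' @param reactions list of reactions; each a list with elements `id`
#'   (string), `stoichiometry` (named numeric vector, names are species
#'   ids, values signed coefficients) and `reversible` (logical).
#' @return An object of class `metabolic_network` with elements
#'   `species`, `reactions`, `N` (internal stoichiometric matrix,
#'   n_internal x n_reactions), `P` (external stoichiometric matrix,
#'   n_external x n_reactions), `reaction_ids`, `internal_ids`,
#'   `external_ids`, `reversible` (named logical).
#' @examples
#' sp <- data.frame(id = c("A", "M", "B"),
#'                  role = c("external", "internal", "external"))
#' rx <- list(
#'   list(id = "v1", stoichiometry = c(A = -1, M = 1), reversible = FALSE),
#'   list(id = "v2", stoichiometry = c(M = -1, B = 1), reversible = FALSE))
#' net <- metabolic_network(sp, rx)
#' net$N   # [1, -1]
#' @export
metabolic_network <- function(species, reactions) {
  stopifnot(is.data.frame(species), all(c("id", "role") %in% names(species)))
  species$id <- as.character(species$id)
  if (anyDuplicated(species$id))
    stop("duplicate species id(s): ",
         paste(unique(species$id[duplicated(species$id)]), collapse = ", "))
  if (!all(species$role %in% c("internal", "external")))
    stop("species role must be 'internal' or 'external'")
  if (length(reactions) < 1L) stop("at least one reaction required")

  rids <- vapply(reactions, function(r) as.character(r$id), character(1))
  if (anyDuplicated(rids))
    stop("duplicate reaction id(s): ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  for (r in reactions) {
    s <- r$stoichiometry
    if (length(s) == 0L || all(s == 0))
      stop("reaction '", r$id, "' has no nonzero coefficient")
    if (!all(is.finite(s)))
      stop("reaction '", r$id, "' has non-finite coefficients")
    unknown <- setdiff(names(s), species$id)
    if (length(unknown))
      stop("reaction '", r$id, "' references unknown species: ",
           paste(unknown, collapse = ", "))
  }

  internal_ids <- species$id[species$role == "internal"]
  external_ids <- species$id[species$role == "external"]
  if (length(external_ids) == 0L)
    stop("at least one external species is required")

  full <- matrix(0, nrow(species), length(reactions),
                 dimnames = list(species$id, rids))
  for (k in seq_along(reactions)) {
    s <- reactions[[k]]$stoichiometry
    full[names(s), k] <- as.numeric(s)
  }
  rev <- vapply(reactions, function(r) isTRUE(r$reversible), logical(1))
  names(rev) <- rids

  structure(list(
    species = species,
    reactions = reactions,
    N = full[internal_ids, , drop = FALSE],
    P = full[external_ids, , drop = FALSE],
    reaction_ids = rids,
    internal_ids = internal_ids,
    external_ids = external_ids,
    reversible = rev
  ), class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("Metabolic network:", length(x$reaction_ids), "reactions,",
      length(x$internal_ids), "internal /", length(x$external_ids),
      "external species\n")
  cat("  irreversible:", sum(!x$reversible), "reactions\n")
  invisible(x)
}

#' Orthonormal null-space basis of the internal stoichiometric matrix
#'
#' Computes `K` with `N %*% K = 0`; every steady-state flux vector can be
#' written `V = K %*% U` in terms of free fluxes `U`.  The basis is taken
#' from the SVD right singular vectors with singular values below
#' `tol * sigma_max`, giving an orthonormal basis with a deterministic
#' sign convention (the largest-magnitude entry of each column is made
#' positive; ties broken by the first such entry).
#'
#' @param N internal stoichiometric matrix (possibly with 0 rows).
#' @param tol relative rank tolerance; singular values below
#'   `tol * max(singular values)` are treated as zero.
#' @return list with `K` (n_reactions x n_free, orthonormal columns),
#'   `rank` of `N`, and `n_free`.
#' @export
null_space_basis <- function(N, tol = 1e-10) {
  if (!is.matrix(N)) N <- matrix(N, nrow = NROW(N))
  n_rx <- ncol(N)
  if (n_rx < 1L) stop("need at least one reaction")
  if (!all(is.finite(N))) stop("N must be finite")
  if (nrow(N) == 0L) {
    K <- diag(n_rx)
    return(list(K = K, rank = 0L, n_free = n_rx))
  }
  sv <- svd(N, nu = 0, nv = n_rx)
  d <- c(sv$d, rep(0, n_rx - length(sv$d)))
  r <- sum(d > tol * max(d, 0))
  if (r >= n_rx)
    stop("no free fluxes; steady state over-determined (rank(N) = n_reactions)")
  K <- sv$v[, (r + 1L):n_rx, drop = FALSE]
  # deterministic sign: largest-magnitude entry of each column positive
  for (j in seq_len(ncol(K))) {
    i <- which.max(abs(K[, j]))
    if (K[i, j] < 0) K[, j] <- -K[, j]
  }
  rownames(K) <- colnames(N)
  list(K = K, rank = r, n_free = n_rx - r)
}

#' Rows of the null-space basis belonging to irreversible reactions
#'
#' Returns the matrix `K_irr` such that the irreversibility constraints of
#' bounded DMFA read `K_irr %*% U >= 0`.
#'
#' @param K null-space basis matrix (n_reactions x n_free).
#' @param irreversible_ids character vector of reaction ids; the returned
#'   rows follow this order.
#' @param network a `metabolic_network` (supplies the reaction order of
#'   the rows of `K`).
#' @return matrix with `length(irreversible_ids)` rows (possibly 0 rows).
#' @export
irreversibility_rows <- function(K, irreversible_ids, network) {
  if (length(irreversible_ids) == 0L)
    return(matrix(0, 0L, ncol(K)))
  idx <- match(irreversible_ids, network$reaction_ids)
  if (anyNA(idx))
    stop("unknown reaction id(s): ",
         paste(irreversible_ids[is.na(idx)], collapse = ", "))
  m <- K[idx, , drop = FALSE]
  rownames(m) <- irreversible_ids
  m
}

#' Read a metabolic network from a plain-text file
#'
#' The format has a `[species]` block (`id role [name]`, whitespace
#' separated, role `internal`/`external`) followed by a `[reactions]`
#' block with one reaction per line: `id : a A + b B -> c C` where
#' omitted coefficients default to 1 and `<->` marks reversibility.
#' Lines starting with `#` and blank lines are ignored.
#'
#' @param path file path.
#' @return a `metabolic_network`.
#' @seealso [write_network()]
#' @export
read_network <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sec <- ""
  sp <- list(); rx <- list()
  for (ln in lines) {
    if (ln %in% c("[species]", "[reactions]")) { sec <- ln; next }
    if (sec == "[species]") {
      tok <- strsplit(ln, "[[:space:]]+")[[1]]
      if (length(tok) < 2L) stop("bad species line: ", ln)
      sp[[length(sp) + 1L]] <- data.frame(
        id = tok[1], role = tok[2],
        name = if (length(tok) >= 3) paste(tok[-(1:2)], collapse = " ") else tok[1])
    } else if (sec == "[reactions]") {
      rx[[length(rx) + 1L]] <- parse_reaction_line(ln)
    } else stop("content before any section header: ", ln)
  }
  if (!length(sp)) stop("no [species] block found")
  if (!length(rx)) stop("no [reactions] block found")
  metabolic_network(do.call(rbind, sp), rx)
}

# "id : a A + b B -> c C"; "<->" means reversible; empty side allowed
parse_reaction_line <- function(ln) {
  parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("bad reaction line (need 'id : equation'): ", ln)
  id <- trimws(parts[1]); eq <- trimws(parts[2])
  reversible <- grepl("<->", eq, fixed = TRUE)
  sides <- strsplit(eq, if (reversible) "<->" else "->", fixed = TRUE)[[1]]
  if (length(sides) > 2L) stop("bad equation: ", eq)
  if (length(sides) == 1L) sides <- c(sides, "")
  stoich <- c(parse_side(sides[1], -1), parse_side(sides[2], +1))
  # merge duplicated species across sides
  stoich <- tapply(stoich, names(stoich), sum)
  stoich <- stoich[stoich != 0]
  list(id = id, stoichiometry = unlist(as.list(stoich)), reversible = reversible)
}

parse_side <- function(s, sign) {
  s <- trimws(s)
  if (!nzchar(s)) return(numeric(0))
  terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
  out <- numeric(0)
  for (tm in terms) {
    tok <- strsplit(tm, "[[:space:]]+")[[1]]
    if (length(tok) == 1L) { coef <- 1; spid <- tok[1] }
    else if (length(tok) == 2L) {
      coef <- suppressWarnings(as.numeric(tok[1]))
      if (is.na(coef)) stop("bad coefficient in term: ", tm)
      spid <- tok[2]
    } else stop("bad term: ", tm)
    out[spid] <- sign * coef
  }
  out
}

#' Write a metabolic network to the plain-text format of [read_network()]
#' @param network a `metabolic_network`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("[species]", con)
  nm <- if ("name" %in% names(network$species)) network$species$name
        else network$species$id
  writeLines(paste(network$species$id, network$species$role, nm), con)
  writeLines("[reactions]", con)
  for (r in network$reactions) {
    s <- r$stoichiometry
    fmt_side <- function(v) {
      if (!length(v)) return("")
      paste(sprintf("%.17g %s", abs(v), names(v)), collapse = " + ")
    }
    arrow <- if (isTRUE(r$reversible)) "<->" else "->"
    writeLines(paste(r$id, ":", fmt_side(s[s < 0]), arrow, fmt_side(s[s > 0])), con)
  }
  invisible(path)
}

#' Export a stoichiometric matrix as delimited text
#' @param M matrix with species row names and reaction column names.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(M, path) {
  df <- data.frame(species = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
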