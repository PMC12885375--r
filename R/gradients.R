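#' Microstructural profile covariance (MPC) matrix
#'
#' Vertex profiles are rank-transformed over depths (Spearman), the
#' cortex-wide average profile is formed in rank space (mean of the
#' rank-transformed profiles, so the matrix is invariant to monotone
#' transforms of any single vertex profile) and residualized out of every
#' vertex profile, pairwise Pearson correlations of the rank residuals
#' give partial Spearman correlations, and a Fisher z log-transform
#' `0.5 log((1 + r) / (1 - r))` with `|r|` clipped to `1 - 1e-7` yields
#' the MPC. Diagonal is 0. Vertices with constant profiles — or profiles
#' whose ranks coincide with the average profile, leaving no residual —
#' are flagged: their row/column is NaN.
#'
#' @param profiles a `profile_matrix` (>= 3 depths, >= 3 vertices),
#'   smoothed upstream per surface.
#' @param clip correlation clipping bound.
#' @return object of class `mpc_matrix`: `values` (V x V), `mean_profile`
#'   (raw units), `clip`, `flagged` (logical vector of degenerate
#'   vertices).
#' @export
compute_mpc <- function(profiles, clip = 1 - 1e-7) {
  vals <- profiles$values
  D <- nrow(vals); V <- ncol(vals)
  if (D < 3 || V < 3) stop("need at least 3 depths and 3 vertices")
  ok_vertex <- colSums(profiles$valid) == D & apply(vals, 2, function(x)
    all(is.finite(x)))
  mean_profile <- rowMeans(vals[, ok_vertex, drop = FALSE])
  ranks <- apply(vals, 2, rank)
  mr <- rowMeans(ranks[, ok_vertex, drop = FALSE])  # rank-space average
  flagged <- apply(vals, 2, function(x) !all(is.finite(x)) || var(x) < 1e-24)
  X <- cbind(1, mr)
  qr_ <- qr(X)
  resid <- ranks - X %*% qr.coef(qr_, ranks)
  rs <- sqrt(colSums(resid^2))
  # a profile whose ranks coincide with the mean profile's ranks leaves no
  # residual: its partial correlations are undefined, so it is flagged too
  degen <- rs < 1e-6 * sqrt(D)
  flagged <- flagged | degen
  resid[, degen] <- NA_real_
  r <- suppressWarnings(cor(resid))
  r[!is.finite(r)] <- NA_real_
  r <- pmin(pmax(r, -clip), clip)
  mpc <- 0.5 * log((1 + r) / (1 - r))
  diag(mpc) <- 0
  mpc[flagged, ] <- NaN
  mpc[, flagged] <- NaN
  diag(mpc)[!flagged] <- 0
  structure(list(values = mpc, mean_profile = mean_profile, clip = clip,
                 flagged = flagged),
            class = "mpc_matrix")
}

#' @export
print.mpc_matrix <- function(x, ...) {
  cat("<mpc_matrix> ", nrow(x$values), " x ", ncol(x$values),
      "; ", sum(x$flagged), " flagged vertices\n", sep = "")
  invisible(x)
}

#' Normalized-angle affinity of a (sparsified) MPC matrix
#'
#' Per row, the top `ceiling((1 - sparsity) * V)` entries are retained
#' (ties broken toward lower column index) and the rest zeroed; the
#' affinity between sparsified rows x_i, x_j is
#' `1 - acos(clip(cos(x_i, x_j), -1, 1)) / pi`, symmetric with unit
#' diagonal. Negative cosines are allowed (affinity < 0.5).
#'
#' @param mpc an `mpc_matrix` or plain square matrix.
#' @param sparsity fraction of entries dropped per row (default 0.9 keeps
#'   the top 10%).
#' @return V x V affinity matrix in `[0, 1]`.
#' @export
affinity_normalized_angle <- function(mpc, sparsity = 0.9) {
  M <- if (inherits(mpc, "mpc_matrix")) mpc$values else as.matrix(mpc)
  if (nrow(M) != ncol(M)) stop("MPC matrix must be square")
  if (!all(is.finite(M))) stop("MPC matrix must be finite (flagged vertices present?)")
  V <- ncol(M)
  k <- as.integer(ceiling((1 - sparsity) * V))
  S <- matrix(0, V, V)
  for (i in seq_len(V)) {
    ord <- order(M[i, ], seq_len(V), decreasing = c(TRUE, FALSE), method = "radix")
    keep <- ord[seq_len(k)]
    S[i, keep] <- M[i, keep]
  }
  nrm <- sqrt(rowSums(S^2))
  if (any(nrm == 0))
    stop("all-zero row after sparsification at vertex ", which(nrm == 0)[1])
  C <- tcrossprod(S) / outer(nrm, nrm)
  C <- pmin(pmax(C, -1), 1)
  A <- 1 - acos(C) / pi
  A <- (A + t(A)) / 2   # acos amplifies last-bit asymmetry near |cos| = 1
  diag(A) <- 1
  A
}

#' Diffusion map embedding of an affinity matrix
#'
#' Anisotropic normalization `W = D^-alpha A D^-alpha` with degrees
#' `d_i = sum_j a_ij`, Markov operator `P` = row-normalized `W`,
#' eigendecomposition (via the symmetric conjugate of `P`), trivial
#' stationary component (eigenvalue 1, constant loading) dropped, and
#' gradient k scaled as `psi_k lambda_k / (1 - lambda_k)` (diffusion time
#' 0). Component signs follow a fixed convention: first nonzero loading
#' positive.
#'
#' @param affinity symmetric nonnegative V x V matrix, connected graph.
#' @param alpha diffusion anisotropy parameter (0.5 default).
#' @param n_components retained non-trivial components.
#' @return object of class `gradient_set`: `gradients` (V x K),
#'   `eigenvalues` (nonincreasing, trivial dropped), `variance_explained`,
#'   `alpha`, `sparsity` attr if known.
#' @export
diffusion_embedding <- function(affinity, alpha = 0.5, n_components = 10) {
  A <- as.matrix(affinity)
  V <- nrow(A)
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-10)))
    stop("affinity must be symmetric")
  if (any(A < 0)) stop("affinity must be nonnegative")
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1)
    stop("disconnected affinity graph: ", comp$no, " components of sizes ",
         paste(comp$csize, collapse = ", "))
  d <- rowSums(A)
  W <- A / outer(d^alpha, d^alpha)
  d2 <- rowSums(W)
  # symmetric conjugate S = D2^-1/2 W D2^-1/2 shares eigenvalues with P
  S <- W / outer(sqrt(d2), sqrt(d2))
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  lam <- es$values
  psi <- es$vectors / sqrt(d2)   # right eigenvectors of P
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]; psi <- psi[, ord, drop = FALSE]
  # trivial component: eigenvalue closest to 1 with near-constant loadings
  cv <- apply(psi, 2, function(x) sd(x) / max(abs(mean(x)), 1e-300))
  triv <- which.min(abs(lam - 1) + (cv > 1e-6))
  lam <- lam[-triv]; psi <- psi[, -triv, drop = FALSE]
  K <- min(n_components, ncol(psi))
  lam <- lam[seq_len(K)]; psi <- psi[, seq_len(K), drop = FALSE]
  grads <- sweep(psi, 2, lam / (1 - lam), "*")
  for (k in seq_len(K)) {
    nz <- which(abs(grads[, k]) > 1e-12)[1]
    if (!is.na(nz) && grads[nz, k] < 0) grads[, k] <- -grads[, k]
  }
  structure(list(gradients = grads, eigenvalues = lam,
                 variance_explained = lam / sum(lam), alpha = alpha,
                 stationary = d2 / sum(d2)),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat("<gradient_set> ", nrow(x$gradients), " vertices x ",
      ncol(x$gradients), " gradients; G1 variance ",
      round(100 * x$variance_explained[1], 1), "%\n", sep = "")
  invisible(x)
}

#' MPC gradients with flagged-vertex handling
#'
#' Convenience wrapper chaining [affinity_normalized_angle()] and
#' [diffusion_embedding()] while excluding flagged (constant or
#' mean-degenerate) vertices, whose partial correlations are undefined.
#' Gradients are returned on the full vertex set with NA at flagged
#' vertices.
#'
#' @param mpc an `mpc_matrix`.
#' @inheritParams affinity_normalized_angle
#' @inheritParams diffusion_embedding
#' @return a `gradient_set` whose `gradients` have `length(mpc$flagged)`
#'   rows (NA rows at flagged vertices) plus a `kept` logical vector.
#' @export
mpc_gradients <- function(mpc, sparsity = 0.9, alpha = 0.5, n_components = 10) {
  stopifnot(inherits(mpc, "mpc_matrix"))
  keep <- !mpc$flagged
  if (sum(keep) < 3) stop("fewer than 3 unflagged vertices")
  aff <- affinity_normalized_angle(mpc$values[keep, keep, drop = FALSE],
                                   sparsity = sparsity)
  gs <- diffusion_embedding(aff, alpha = alpha, n_components = n_components)
  G <- matrix(NA_real_, length(keep), ncol(gs$gradients))
  G[keep, ] <- gs$gradients
  gs$gradients <- G
  gs$kept <- keep
  gs
}

#' Variance explained per retained gradient
#'
#' `fraction_k = lambda_k / sum(lambda)` over the retained non-trivial
#' components (scree-plot fractions).
#'
#' @param gset a `gradient_set`, or a numeric vector of eigenvalues.
#' @return numeric vector of fractions summing to 1.
#' @export
variance_explained <- function(gset) {
  lam <- if (inherits(gset, "gradient_set")) gset$eigenvalues else gset
  lam / sum(lam)
}

#' Sign-align one gradient map to a reference
#'
#' Eigenvector signs are arbitrary; the candidate is flipped when its
#' Pearson correlation with the reference is negative, and the
#' post-alignment correlation is returned (the inter-subject stability
#' statistic).
#'
#' @param g_ref,g_other equal-length numeric vectors (or `surface_map`s).
#' @return list with `aligned` (possibly flipped `g_other`), `flipped`,
#'   `pearson_r`.
#' @export
align_gradients <- function(g_ref, g_other) {
  a <- map_values(g_ref); b <- map_values(g_other)
  if (length(a) != length(b)) stop("gradient maps must have equal length")
  ok <- is.finite(a) & is.finite(b)
  if (var(a[ok]) < 1e-24 || var(b[ok]) < 1e-24)
    stop("zero-variance map cannot be aligned")
  r <- cor(a[ok], b[ok])
  flip <- r < 0
  if (flip) { b <- -b; r <- -r }
  list(aligned = b, flipped = flip, pearson_r = r)
}
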