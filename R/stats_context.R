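#' Vertex-by-vertex connectivity matrix
#'
#' @param values square symmetric matrix with zero diagonal; functional
#'   (`fc`) entries are correlations in (-1, 1), structural (`sc`) entries
#'   nonnegative streamline weights.
#' @param kind `"fc"` or `"sc"`.
#' @export
connectivity_matrix <- function(values, kind = c("fc", "sc")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectivity matrix must be square")
  if (max(abs(values - t(values))) > 1e-8) stop("connectivity matrix must be symmetric")
  if (any(diag(values) != 0)) stop("diagonal must be zero")
  if (kind == "fc" && any(abs(values[upper.tri(values)]) >= 1))
    stop("fc entries must lie in (-1, 1)")
  if (kind == "sc" && any(values < 0)) stop("data error: negative sc weight")
  structure(list(values = values, kind = kind), class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", x$kind, ", ", nrow(x$values), " nodes\n", sep = "")
  invisible(x)
}

#' Functional connectivity strength
#'
#' `strength_i = sum_{j != i} |atanh(r_ij)|` — the weighted row sum of
#' absolute Fisher r-to-z transformed correlations. Correlations at |r| = 1
#' are clipped to `1 - 1e-7` with a warning.
#'
#' @param fc a `connectivity_matrix` of kind `fc`.
#' @return length-V numeric strength vector.
#' @export
fc_strength <- function(fc) {
  if (!inherits(fc, "connectivity_matrix") || fc$kind != "fc")
    stop("fc_strength needs an fc connectivity_matrix")
  r <- fc$values
  if (any(abs(r[upper.tri(r)]) > 1 - 1e-7))
    warning("|r| at or above clipping bound: clipped to 1 - 1e-7")
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- abs(atanh(r))
  diag(z) <- 0
  rowSums(z)
}

#' Structural connectivity strength
#'
#' `strength_i = log(1 + sum_{j != i} w_ij)`; the +1 guards isolated nodes
#' (strength 0) and is monotone-equivalent to a plain log for rank-based
#' analyses.
#'
#' @param sc a `connectivity_matrix` of kind `sc`.
#' @return length-V numeric strength vector.
#' @export
sc_strength <- function(sc) {
  if (!inherits(sc, "connectivity_matrix") || sc$kind != "sc")
    stop("sc_strength needs an sc connectivity_matrix")
  w <- sc$values
  if (any(w < 0)) stop("data error: negative sc weight")
  log1p(rowSums(w))
}

#' Mask a connectome to short-range connections
#'
#' Zeroes entries whose geodesic distance is at or above the threshold;
#' strictly closer pairs (< threshold) are retained, isolating short
#' fibers such as the U-fiber system at the default 35 mm.
#'
#' @param sc a `connectivity_matrix`.
#' @param geodesic V x V distance matrix in mm.
#' @param threshold distance cutoff in mm.
#' @return a `connectivity_matrix` of the same kind.
#' @export
short_range_mask <- function(sc, geodesic, threshold = 35) {
  w <- sc$values
  if (!all(dim(geodesic) == dim(w))) stop("distance matrix dimension mismatch")
  w[geodesic >= threshold] <- 0
  diag(w) <- 0
  connectivity_matrix((w + t(w)) / 2, sc$kind)
}

spearman_rho <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) return(NA_real_)
  suppressWarnings(cor(a[ok], b[ok], method = "spearman"))
}

#' Spearman correlation of two surface maps, optionally per split class
#'
#' NaN-aware Spearman rho; with a `split` vector (e.g., the sign of
#' curvature for a gyral/sulcal contrast) a per-class rho is added.
#' Classes with fewer than 10 valid vertices give NA with a warning.
#'
#' @param map_a,map_b equal-length numeric vectors or `surface_map`s.
#' @param split optional class labels.
#' @return list with `rho` and, when split is given, `by_class`.
#' @export
correlate_maps <- function(map_a, map_b, split = NULL) {
  a <- map_values(map_a); b <- map_values(map_b)
  if (length(a) != length(b)) stop("maps must have equal length")
  out <- list(rho = spearman_rho(a, b))
  if (!is.null(split)) {
    split <- map_values(split)
    cls <- sort(unique(split[!is.na(split)]))
    out$by_class <- vapply(cls, function(cl) {
      sel <- !is.na(split) & split == cl
      if (sum(sel & is.finite(a) & is.finite(b)) < 10) {
        warning("fewer than 10 valid vertices in class ", cl)
        return(NA_real_)
      }
      spearman_rho(a[sel], b[sel])
    }, numeric(1))
    names(out$by_class) <- as.character(cls)
  }
  out
}

random_rotation <- function() {
  M <- matrix(rnorm(9), 3)
  qrd <- qr(M)
  Q <- qr.Q(qrd)
  d <- sign(diag(qr.R(qrd)))
  d[d == 0] <- 1
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

#' Spin permutation test for spatial maps on a sphere
#'
#' The observed statistic is the Spearman correlation of the two maps.
#' Each permutation applies a uniform random 3D rotation to the spherical
#' registration coordinates, reassigns `map_a` by nearest original vertex,
#' and recomputes rho; the two-sided p-value is
#' `(1 + #{|rho_null| >= |rho_obs|}) / (1 + n_perm)`, bounded below by
#' `1 / (n_perm + 1)`. The null preserves the spatial autocorrelation of
#' `map_a`, unlike a vertex-shuffling permutation.
#'
#' @param map_a,map_b equal-length vectors or `surface_map`s.
#' @param sphere `triangle_mesh` whose vertices lie on a sphere (radii may
#'   vary at most 1%), or a V x 3 matrix of spherical coordinates,
#'   vertex-corresponding to the maps.
#' @param n_perm number of rotations.
#' @param seed RNG seed (recorded in the result).
#' @return object of class `spin_result`: `r_observed`, `null` (length
#'   `n_perm`), `p_spin`, `n_perm`, `seed`.
#' @export
spin_test <- function(map_a, map_b, sphere, n_perm = 1000, seed = 1) {
  a <- map_values(map_a); b <- map_values(map_b)
  C <- if (inherits(sphere, "triangle_mesh")) sphere$vertices else as.matrix(sphere)
  ctr <- colMeans(C)
  C <- sweep(C, 2, ctr)
  rad <- sqrt(rowSums(C^2))
  if ((max(rad) - min(rad)) / mean(rad) > 0.01)
    stop("geometry error: vertex radii vary by more than 1% (not a sphere)")
  C <- C / rad
  if (length(a) != nrow(C) || length(b) != nrow(C))
    stop("maps must match sphere vertex count")
  robs <- spearman_rho(a, b)
  restore <- local_seed(seed)
  on.exit(restore())
  null <- numeric(n_perm)
  Ct <- t(C)
  for (p in seq_len(n_perm)) {
    Rt <- random_rotation()
    nn <- max.col((C %*% Rt) %*% Ct, ties.method = "first")
    null[p] <- spearman_rho(a[nn], b)
  }
  p_spin <- (1 + sum(abs(null) >= abs(robs), na.rm = TRUE)) / (1 + n_perm)
  structure(list(r_observed = robs, null = null, p_spin = p_spin,
                 n_perm = n_perm, seed = seed),
            class = "spin_result")
}

#' @export
print.spin_result <- function(x, ...) {
  cat("<spin_result> rho = ", signif(x$r_observed, 3), ", p_spin = ",
      signif(x$p_spin, 3), " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' LOWESS trend of y against x
#'
#' Locally weighted linear regression with tricube weights, evaluated at
#' sorted x (the group-trend curve drawn through gradient-vs-strength
#' scatters). One robustness iteration by default.
#'
#' @param x,y equal-length numeric vectors (>= 20 points).
#' @param span smoothing fraction (default 2/3).
#' @param iter robustness iterations.
#' @return list with sorted `x` and `fitted`.
#' @export
lowess_trend <- function(x, y, span = 2/3, iter = 1) {
  x <- map_values(x); y <- map_values(y)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 20) stop("need at least 20 points")
  fit <- lowess(x[ok], y[ok], f = span, iter = iter)
  list(x = fit$x, fitted = fit$y)
}
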