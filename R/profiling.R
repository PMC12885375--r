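#' Depth-by-vertex intensity profile matrix
#'
#' @param values D x V numeric matrix (feature units).
#' @param depths length-D depths in mm (negative = intracortical, 0 = GM/WM
#'   interface, positive = SWM), strictly increasing.
#' @param modality free-text modality name.
#' @param valid D x V logical matrix.
#' @export
profile_matrix <- function(values, depths, modality = "", valid = NULL) {
  values <- as.matrix(values)
  if (length(depths) != nrow(values)) stop("depths must match profile rows")
  if (any(diff(depths) <= 0)) stop("depths must be strictly increasing")
  if (is.null(valid)) valid <- is.finite(values)
  structure(list(values = values, depths = depths, modality = modality,
                 valid = valid),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("<profile_matrix> ", nrow(x$values), " depths x ", ncol(x$values),
      " vertices", if (nzchar(x$modality)) paste0(" [", x$modality, "]"),
      "; ", round(100 * mean(x$valid)), "% valid\n", sep = "")
  invisible(x)
}

#' Sample a feature volume onto a surface stack
#'
#' Each vertex position is mapped through the inverse affine and the volume
#' is interpolated trilinearly (exact for functions affine in voxel
#' coordinates). Positions outside the volume or invalid stack vertices
#' yield NaN with a false validity flag.
#'
#' @param stack a `surface_stack`.
#' @param volume a `scalar_volume` co-registered with the stack.
#' @param modality stored modality name.
#' @return a `profile_matrix` (rows follow `stack$depths`).
#' @export
sample_volume_to_stack <- function(stack, volume, modality = "") {
  D <- length(stack$meshes)
  V <- nrow(stack$meshes[[1]]$vertices)
  vals <- matrix(NA_real_, D, V)
  for (d in seq_len(D)) {
    vox <- world_to_voxel(volume, stack$meshes[[d]]$vertices)
    vals[d, ] <- trilinear_sample_cpp(as.numeric(volume$data),
                                      dim(volume$data), vox)
  }
  vals[t(!stack$valid)] <- NA_real_
  profile_matrix(vals, stack$depths, modality,
                 valid = is.finite(vals) & t(stack$valid))
}

#' Tukey fence outlier repair on a surface map
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` within the masked
#' region (type-7 quartiles) and replaces them by the mean of valid 1-ring
#' neighbors, iterated to closure; outliers with no valid neighbor get the
#' region median of non-flagged values. Non-flagged vertices are never
#' altered.
#'
#' @param map length-V numeric vector or `surface_map`.
#' @param mesh the `triangle_mesh` the map lives on.
#' @param region_mask logical length-V vector (default: all vertices).
#' @return list with `values` (repaired vector) and `outliers` (logical).
#' @export
repair_outliers_tukey <- function(map, mesh, region_mask = NULL) {
  x <- map_values(map)
  V <- length(x)
  if (is.null(region_mask)) region_mask <- rep(TRUE, V)
  region_mask <- region_mask & is.finite(x)
  if (!any(region_mask)) stop("region mask selects no finite values")
  q <- quantile(x[region_mask], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  out <- region_mask & (x < lo | x > hi)
  if (all(out[region_mask])) stop("all values in the region are outliers")
  if (!any(out)) return(list(values = x, outliers = out))
  adj <- mesh_adjacency(mesh)
  good <- is.finite(x) & !out
  vals <- x
  vals[out] <- NA_real_
  todo <- which(out)
  repeat {
    filled <- logical(length(todo))
    newvals <- vals
    for (i in seq_along(todo)) {
      nb <- adj[[todo[i]]]
      nbv <- vals[nb]
      nbv <- nbv[is.finite(nbv)]
      if (length(nbv)) { newvals[todo[i]] <- mean(nbv); filled[i] <- TRUE }
    }
    vals <- newvals
    if (!any(filled) || all(filled)) break
    todo <- todo[!filled]
  }
  still <- !is.finite(vals) & out
  if (any(still)) vals[still] <- median(x[good & region_mask])
  list(values = vals, outliers = out)
}

#' Per-depth statistical moments across vertices
#'
#' For each depth row, across valid vertices: mean, sample SD (n - 1),
#' Fisher-Pearson skewness `g1 = m3 / m2^1.5` and excess kurtosis
#' `g2 = m4 / m2^2 - 3` (central moments `m_k` about the mean, divided by
#' n). Rows with fewer than 4 valid vertices, or zero variance, yield NaN
#' for the shape moments (with a warning for zero variance).
#'
#' @param profiles a `profile_matrix`.
#' @return data.frame with columns `depth`, `n`, `mean`, `sd`, `skewness`,
#'   `kurtosis`.
#' @export
compute_moments <- function(profiles) {
  vals <- profiles$values
  vals[!profiles$valid] <- NA_real_
  warned <- FALSE
  rows <- lapply(seq_len(nrow(vals)), function(d) {
    x <- vals[d, ]
    x <- x[is.finite(x)]
    n <- length(x)
    if (n < 4) return(data.frame(depth = profiles$depths[d], n = n,
                                 mean = if (n) mean(x) else NaN, sd = NaN,
                                 skewness = NaN, kurtosis = NaN))
    mu <- mean(x)
    m2 <- mean((x - mu)^2)
    if (m2 <= 0) {
      if (!warned) { warning("zero variance: skewness/kurtosis undefined"); warned <<- TRUE }
      return(data.frame(depth = profiles$depths[d], n = n, mean = mu, sd = 0,
                        skewness = NaN, kurtosis = NaN))
    }
    m3 <- mean((x - mu)^3)
    m4 <- mean((x - mu)^4)
    data.frame(depth = profiles$depths[d], n = n, mean = mu,
               sd = sd(x), skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
  })
  do.call(rbind, rows)
}

#' Iterative uniform-kernel smoothing of a surface map
#'
#' Per iteration each vertex moves toward the mean of its 1-ring:
#' `v <- (1 - relaxation) v + relaxation mean(neighbors)`; NaN vertices are
#' excluded from neighbor means and keep their value; isolated vertices are
#' unchanged. Defaults follow the 5-iteration, relaxation-0.5 scheme used
#' before MPC construction.
#'
#' @param map length-V numeric vector or `surface_map`.
#' @param mesh the `triangle_mesh` (or a precomputed adjacency list).
#' @param iterations number of passes.
#' @param relaxation blending factor in (0, 1].
#' @return smoothed numeric vector.
#' @export
smooth_surface_map <- function(map, mesh, iterations = 5, relaxation = 0.5) {
  x <- map_values(map)
  adj <- if (inherits(mesh, "triangle_mesh")) mesh_adjacency(mesh) else mesh
  V <- length(x)
  ed_i <- rep(seq_len(V), lengths(adj))
  ed_j <- unlist(adj, use.names = FALSE)
  A <- Matrix::sparseMatrix(i = ed_i, j = ed_j, x = 1, dims = c(V, V))
  for (it in seq_len(iterations)) {
    fin <- is.finite(x)
    xs <- ifelse(fin, x, 0)
    num <- as.numeric(A %*% xs)
    den <- as.numeric(A %*% as.numeric(fin))
    nbmean <- ifelse(den > 0, num / den, x)
    xnew <- (1 - relaxation) * x + relaxation * nbmean
    x <- ifelse(fin, xnew, x)
  }
  x
}

#' Regress curvature out of an intensity profile matrix
#'
#' Per depth, ordinary least squares of intensity on curvature across valid
#' vertices; the output is residuals plus the fitted intercept, so the mean
#' level is preserved while the curvature-linked component is removed.
#' Constant curvature yields the identity transform with a warning.
#'
#' @param profiles a `profile_matrix`.
#' @param curvature length-V vector or `surface_map` on the seed mesh.
#' @return a `profile_matrix` with attribute-free corrected values;
#'   slopes/intercepts stored in `$provenance`.
#' @export
regress_out_curvature <- function(profiles, curvature) {
  cv <- map_values(curvature)
  vals <- profiles$values
  if (length(cv) != ncol(vals)) stop("curvature length must match vertex count")
  if (var(cv[is.finite(cv)]) < 1e-24) {
    warning("constant curvature: returning profiles unchanged")
    return(profiles)
  }
  D <- nrow(vals)
  coefs <- matrix(NA_real_, D, 2, dimnames = list(NULL, c("intercept", "slope")))
  out <- vals
  for (d in seq_len(D)) {
    y <- vals[d, ]
    ok <- profiles$valid[d, ] & is.finite(y) & is.finite(cv)
    if (sum(ok) < 3) next
    fit <- lm.fit(cbind(1, cv[ok]), y[ok])
    coefs[d, ] <- fit$coefficients
    out[d, ok] <- fit$residuals + fit$coefficients[1]
  }
  res <- profile_matrix(out, profiles$depths, profiles$modality, profiles$valid)
  res$provenance <- list(curvature_regression = coefs)
  res
}

#' Drop the outermost intracortical row of a profile matrix
#'
#' Mirrors the removal of the CSF/GM surface before analysis to limit
#' partial volume effects.
#'
#' @param profiles a `profile_matrix` whose first row is the outermost
#'   surface.
#' @return a `profile_matrix` without the first row.
#' @export
drop_outermost_row <- function(profiles) {
  if (nrow(profiles$values) < 2) stop("cannot drop the only row")
  profile_matrix(profiles$values[-1, , drop = FALSE], profiles$depths[-1],
                 profiles$modality, profiles$valid[-1, , drop = FALSE])
}
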