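#' Depth sampling specification
#'
#' Presets follow the published sampling schemes: `"histology"` = 50 depths
#' spaced 0.06 mm, `"invivo"` = 15 depths spaced 0.2 mm; both reach the
#' 3 mm maximum depth that captures the U-fiber system.
#'
#' @param preset `"histology"`, `"invivo"`, or `"custom"`.
#' @param n_surfaces,spacing surface count and spacing (mm); required for
#'   `"custom"`, override the preset otherwise.
#' @param step_size streamline integration step in mm (default set at solve
#'   time to 0.25 x min voxel size).
#' @return list of class `depth_spec` with `n_surfaces`, `spacing`,
#'   `max_depth`, `step_size`.
#' @export
depth_spec <- function(preset = c("invivo", "histology", "custom"),
                       n_surfaces = NULL, spacing = NULL, step_size = NULL) {
  preset <- match.arg(preset)
  if (preset == "histology") { n0 <- 50L; s0 <- 0.06 }
  else if (preset == "invivo") { n0 <- 15L; s0 <- 0.2 }
  else { n0 <- NULL; s0 <- NULL }
  n_surfaces <- if (is.null(n_surfaces)) n0 else as.integer(n_surfaces)
  spacing <- if (is.null(spacing)) s0 else spacing
  if (is.null(n_surfaces) || is.null(spacing))
    stop("custom depth_spec needs n_surfaces and spacing")
  if (spacing <= 0) stop("spacing must be positive")
  structure(list(preset = preset, n_surfaces = n_surfaces, spacing = spacing,
                 max_depth = n_surfaces * spacing, step_size = step_size),
            class = "depth_spec")
}

#' Solve the Laplace equation in the white-matter domain
#'
#' Dirichlet problem `lap u = 0` on WM voxels with u = 0 at the GM/WM
#' interface and u = 1 at the ventricular walls, discretized with a
#' 6-neighbor stencil whose boundary arms carry sub-voxel offsets
#' (Shortley-Weller). Offsets come from the segmentation's analytic
#' level-set fields when present (phantoms), otherwise they are estimated
#' by anti-aliasing the binary labels with a 3-voxel box filter; with
#' `subvoxel = FALSE` every boundary arm uses the half-voxel face offset.
#' Solved by SOR sweeps in fixed lexicographic order (deterministic).
#'
#' @param seg a `segmented_volume` with nonempty WM; GM supplies the low
#'   boundary. `high_role` names the label role used as the u = 1 boundary
#'   (default `"ventricle"`).
#' @param tolerance convergence threshold on the max absolute update.
#' @param max_iterations SOR sweep budget.
#' @param omega SOR over-relaxation factor.
#' @param subvoxel use sub-voxel boundary offsets (see above).
#' @param high_role label role serving as the high (u = 1) boundary.
#' @return object of class `potential_field`: `u` (3D array; solved values
#'   on WM, 0 on low-boundary voxels, 1 on high-boundary voxels, NaN
#'   elsewhere), `low_mask`/`high_mask`, `residual` (final max update),
#'   `iterations_run`, `converged`, `affine`, `voxel_size`.
#' @export
solve_laplace <- function(seg, tolerance = 1e-6, max_iterations = 20000L,
                          omega = 1.9, subvoxel = TRUE,
                          high_role = "ventricle") {
  wm <- label_mask(seg, "WM")
  gm <- label_mask(seg, "GM")
  hi <- label_mask(seg, high_role)
  if (!any(wm)) stop("boundary error: WM label is empty")
  if (!any(gm)) stop("boundary error: no GM (low boundary) voxels")
  if (!any(hi)) stop("boundary error: no '", high_role,
                     "' (high boundary) voxels and no fallback boundary")
  dims <- dim(seg$labels)
  if (subvoxel) {
    if (!is.null(seg$lev_low) && !is.null(seg$lev_high)) {
      lev_low <- seg$lev_low; lev_high <- seg$lev_high
    } else {
      lev_low <- array(box3_smooth_cpp(as.numeric(wm | hi), dims), dims) - 0.5
      lev_high <- array(box3_smooth_cpp(as.numeric(hi), dims), dims) - 0.5
    }
  } else {
    lev_low <- array(NA_real_, dims); lev_high <- lev_low
  }
  res <- solve_laplace_cpp(dims, as.integer(wm), as.integer(gm),
                           as.integer(hi), as.numeric(lev_low),
                           as.numeric(lev_high), seg$voxel_size,
                           tolerance, as.integer(max_iterations), omega,
                           0.05)
  u <- array(res$u, dims)
  adj6 <- function(mask) {
    out <- array(FALSE, dims)
    m <- array(as.numeric(mask), dims)
    for (ax in 1:3) for (d in c(1, -1)) {
      s <- array_shift(m, ax, d)
      out <- out | (!is.na(s) & s > 0)
    }
    out
  }
  wmadj <- adj6(wm)
  low_mask <- gm & wmadj
  high_mask <- hi & wmadj
  if (!any(low_mask) || !any(high_mask))
    stop("boundary error: a Dirichlet boundary is not adjacent to WM")
  u[low_mask] <- 0
  u[high_mask] <- 1
  if (!res$converged)
    warning("Laplace solver did not converge: residual ", signif(res$residual, 3),
            " after ", res$iterations, " iterations")
  structure(list(u = u, wm_mask = wm, low_mask = low_mask,
                 high_mask = high_mask, residual = res$residual,
                 iterations_run = res$iterations, converged = res$converged,
                 affine = seg$affine, voxel_size = seg$voxel_size),
            class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat("<potential_field> ", sum(x$wm_mask), " WM voxels; residual ",
      signif(x$residual, 3), " after ", x$iterations_run, " iterations",
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}

array_shift <- function(a, ax, d) {
  # values of a at index + d along ax; NA padded
  dims <- dim(a)
  n <- dims[ax]
  out <- array(NA_real_, dims)
  ix <- rep(list(quote(expr = )), 3)
  src <- ix; src[[ax]] <- if (d > 0) (1 + d):n else 1:(n + d)
  dst <- ix; dst[[ax]] <- if (d > 0) 1:(n - d) else (1 - d):n
  v <- do.call(`[`, c(list(a), src))
  eval(as.call(c(quote(`[<-`), list(out), dst, list(v))))
}

#' Unit gradient of a potential field
#'
#' Central differences on the extended field (boundary voxels carry their
#' Dirichlet values), one-sided at domain edges, mapped to world
#' coordinates through the affine and normalized to unit length. Voxels
#' with |grad u| < 1e-12 are flagged and get NaN direction.
#'
#' @param field a `potential_field`.
#' @return list with `gx`, `gy`, `gz` (3D arrays, world-mm unit components,
#'   defined on WM voxels) and `zero_flag` (logical array).
#' @export
potential_gradient <- function(field) {
  u <- field$u
  dims <- dim(u)
  gi <- vector("list", 3)
  for (ax in 1:3) {
    up <- array_shift(u, ax, 1)
    dn <- array_shift(u, ax, -1)
    g <- (up - dn) / 2
    one_up <- up - u
    one_dn <- u - dn
    g[is.na(g)] <- one_up[is.na(g)]
    g[is.na(g)] <- one_dn[is.na(g)]
    gi[[ax]] <- g / field$voxel_size[ax]
  }
  # world gradient: grad_w = A^-T grad_index(scaled by 1/h already via voxel_size
  # when affine is axis-aligned); general case via the affine direction cosines
  R <- field$affine[1:3, 1:3] %*% diag(1 / field$voxel_size)
  Minv <- t(solve(R))
  gx <- Minv[1, 1] * gi[[1]] + Minv[1, 2] * gi[[2]] + Minv[1, 3] * gi[[3]]
  gy <- Minv[2, 1] * gi[[1]] + Minv[2, 2] * gi[[2]] + Minv[2, 3] * gi[[3]]
  gz <- Minv[3, 1] * gi[[1]] + Minv[3, 2] * gi[[2]] + Minv[3, 3] * gi[[3]]
  nrm <- sqrt(gx^2 + gy^2 + gz^2)
  zero <- !is.na(nrm) & nrm < 1e-12
  keep <- field$wm_mask & !zero & !is.na(nrm)
  sel <- function(g) { g[!keep] <- NA_real_; g / pmax(nrm, 1e-300) }
  list(gx = sel(gx), gy = sel(gy), gz = sel(gz), zero_flag = zero)
}

#' Ordered stack of surfaces sharing topology
#'
#' @param meshes list of `triangle_mesh` sharing vertex count and faces.
#' @param depths numeric offsets per mesh (strictly increasing).
#' @param valid V x N logical matrix (vertex reached its depth inside WM).
#' @param provenance free-form list (depth spec, solver settings).
#' @export
surface_stack <- function(meshes, depths, valid = NULL, provenance = list()) {
  V <- nrow(meshes[[1]]$vertices)
  for (m in meshes) {
    if (nrow(m$vertices) != V || !identical(m$faces, meshes[[1]]$faces))
      stop("stack meshes must share vertex count and faces")
  }
  if (any(diff(depths) <= 0)) stop("depths must be strictly increasing")
  if (is.null(valid)) valid <- matrix(TRUE, V, length(meshes))
  structure(list(meshes = meshes, depths = depths, valid = valid,
                 provenance = provenance),
            class = "surface_stack")
}

#' @export
print.surface_stack <- function(x, ...) {
  cat("<surface_stack> ", length(x$meshes), " surfaces, ",
      nrow(x$meshes[[1]]$vertices), " vertices; depths [",
      signif(min(x$depths), 3), ", ", signif(max(x$depths), 3), "]; ",
      round(100 * mean(x$valid)), "% valid\n", sep = "")
  invisible(x)
}

#' Shift the GM/WM surface along the Laplace gradient
#'
#' Integrates a streamline per vertex along the unit potential gradient
#' (fixed step, trilinear interpolation) and emits the vertex position each
#' time the accumulated arc length — the distance traveled — crosses a
#' multiple of the depth spacing (linear interpolation between steps).
#' Topology is preserved across surfaces. Vertices leaving the WM mask or
#' hitting zero gradient keep their last position and are flagged invalid
#' from that depth on. The seed mesh is surface 0 at depth 0.
#'
#' @param seed_mesh `triangle_mesh` on/near the GM/WM interface.
#' @param field converged `potential_field`.
#' @param spec a `depth_spec`.
#' @return a `surface_stack` with `spec$n_surfaces + 1` meshes (the seed
#'   first).
#' @export
shift_surface <- function(seed_mesh, field, spec = depth_spec("invivo")) {
  step <- if (is.null(spec$step_size)) 0.25 * min(field$voxel_size) else spec$step_size
  g <- potential_gradient(field)
  depths <- spec$spacing * seq_len(spec$n_surfaces)
  ainv <- solve(field$affine)[1:3, , drop = FALSE]
  max_steps <- as.integer(ceiling(spec$max_depth / step) + 50L)
  tr <- trace_streamlines_cpp(as.numeric(g$gx), as.numeric(g$gy),
                              as.numeric(g$gz), dim(field$u), ainv,
                              seed_mesh$vertices, depths, step, max_steps)
  V <- nrow(seed_mesh$vertices)
  if (mean(tr$valid[, 1]) < 0.5)
    stop("geometry error: >50% of vertices invalid at the first depth; ",
         "is the seed mesh on the GM/WM interface?")
  meshes <- vector("list", length(depths) + 1L)
  meshes[[1]] <- seed_mesh
  for (d in seq_along(depths)) {
    vpos <- tr$positions[, , d]
    # invalid vertices carry the last valid position (tracer clamps); if a
    # vertex never moved, fall back to its seed position
    nas <- !is.finite(vpos[, 1])
    vpos[nas, ] <- seed_mesh$vertices[nas, ]
    meshes[[d + 1]] <- triangle_mesh(vpos, seed_mesh$faces)
  }
  valid <- cbind(TRUE, tr$valid)
  surface_stack(meshes, c(0, depths), valid,
                provenance = list(spec = unclass(spec), step_size = step,
                                  residual = field$residual,
                                  iterations = field$iterations_run))
}

#' Equivolumetric intracortical surfaces
#'
#' Places `n` surfaces between pial and white surfaces (shared topology) at
#' per-vertex equivolumetric fractions. With outer/inner vertex areas
#' `A_o`, `A_i` the fraction of the pial-to-white segment lying below the
#' surface bounding volume fraction `alpha` (counted from the white side)
#' is `rho(alpha) = (-A_i + sqrt(alpha A_o^2 + (1 - alpha) A_i^2)) /
#' (A_o - A_i)`, with the equidistant limit `rho = alpha` when
#' `A_o = A_i`. Positions are linear interpolations between corresponding
#' vertices; surface k uses `alpha = k / (n + 1)`.
#'
#' @param pial,white `triangle_mesh` objects with vertex correspondence.
#' @param n number of intermediate surfaces.
#' @return a `surface_stack` of `n` meshes ordered pial-to-white with
#'   pseudo-depths `-alpha` (fraction units; 0 = white surface).
#' @export
generate_equivolumetric_surfaces <- function(pial, white, n) {
  if (nrow(pial$vertices) != nrow(white$vertices) ||
      !identical(pial$faces, white$faces))
    stop("correspondence error: pial and white must share topology")
  Ao <- mesh_geometry(pial)$vertex_areas
  Ai <- mesh_geometry(white)$vertex_areas
  alphas <- seq_len(n) / (n + 1)
  meshes <- vector("list", n)
  for (k in seq_len(n)) {
    a <- alphas[k]
    rho <- ifelse(abs(Ao - Ai) < 1e-9 * pmax(Ao, Ai, 1e-12), a,
                  (-Ai + sqrt(pmax(a * Ao^2 + (1 - a) * Ai^2, 0))) / (Ao - Ai))
    rho <- pmin(pmax(rho, 0), 1)
    v <- white$vertices + (pial$vertices - white$vertices) * rho
    meshes[[k]] <- triangle_mesh(v, white$faces)
  }
  # order pial-to-white: alpha near 1 bounds the most volume below (toward
  # the white surface), so it lies closest to the pial surface
  ord <- order(alphas, decreasing = TRUE)
  surface_stack(meshes[ord], depths = -alphas[ord],
                provenance = list(kind = "equivolumetric", alphas = alphas))
}

#' Propagate cortical labels into the SWM along the Laplace correspondence
#'
#' The streamline correspondence is the identity over vertex index, so each
#' SWM surface inherits the seed vertex's label; vertices invalid at a depth
#' get the sentinel `NA` from that surface on.
#'
#' @param labels length-V vector (or `surface_map`) on the seed mesh.
#' @param stack a `surface_stack` from [shift_surface()].
#' @return list of per-surface label vectors (same order as `stack$meshes`).
#' @export
propagate_labels <- function(labels, stack) {
  lab <- map_values(labels)
  V <- nrow(stack$meshes[[1]]$vertices)
  if (length(lab) != V) stop("label length does not match stack vertex count")
  lapply(seq_along(stack$meshes), function(k) {
    out <- lab
    out[!stack$valid[, k]] <- NA
    out
  })
}
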