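## Synthetic phantoms with analytic Laplace solutions. They stand in for
## classified histology/MRI volumes so that surface placement, sampling,
## profiling, gradients and spin statistics can all be validated against
## known ground truth.

PHANTOM_LABELS <- c(background = 0L, CSF = 1L, GM = 2L, WM = 3L, ventricle = 4L)

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Slab phantom: parallel CSF | GM | WM | ventricle layers
#'
#' Layers are stacked along +z. The GM/WM interface and the ventricular
#' wall are voxel faces; the analytic Laplace potential between them is
#' linear in z (`u = depth / wm_thickness`), and the true depth below the
#' interface equals the z offset. The segmentation carries exact signed
#' level-set fields for both boundaries, so the solver's sub-voxel boundary
#' placement is exact on this phantom.
#'
#' @param voxel_size isotropic voxel size in mm (0.5 in-vivo-like,
#'   0.2 histology-like).
#' @param extent_xy lateral extent in mm.
#' @param csf,gm,wm,ventricle layer thicknesses in mm.
#' @param max_depth deepest surface to be supported (mm); `wm` must cover it.
#' @return list with `seg` (`segmented_volume`), `gm_wm_mesh`
#'   (`triangle_mesh` at the interface), `analytic_potential`
#'   (function of depth in mm), `depth_volume` (3D array of true depth below
#'   the interface, mm), `kind`, `params`.
#' @export
make_slab_phantom <- function(voxel_size = 0.5, extent_xy = 8,
                              csf = 1, gm = 2.5, wm = 6, ventricle = 2,
                              max_depth = 3) {
  h <- voxel_size
  if (any(c(csf, gm, wm, ventricle) <= 0)) stop("layer thicknesses must be positive")
  if (wm < max_depth)
    stop("config error: WM thickness (", wm, " mm) below requested max depth (",
         max_depth, " mm)")
  n_xy <- max(4L, round(extent_xy / h))
  n_csf <- max(1L, round(csf / h)); n_gm <- max(1L, round(gm / h))
  n_wm <- max(1L, round(wm / h)); n_vent <- max(1L, round(ventricle / h))
  nz <- n_csf + n_gm + n_wm + n_vent
  lab <- array(0L, c(n_xy, n_xy, nz))
  kz <- seq_len(nz) - 1L
  role <- rep(c(1L, 2L, 3L, 4L), c(n_csf, n_gm, n_wm, n_vent))
  for (k in seq_len(nz)) lab[, , k] <- role[k]
  # voxel k (0-based) center at world z = k*h; faces at (k - 1/2)*h
  z0 <- (n_csf + n_gm - 0.5) * h          # GM/WM interface plane
  z1 <- z0 + n_wm * h                     # ventricular wall plane
  L <- z1 - z0
  zc <- kz * h
  lev_low <- array(rep(zc - z0, each = n_xy * n_xy), c(n_xy, n_xy, nz))
  lev_high <- array(rep(z1 - zc, each = n_xy * n_xy), c(n_xy, n_xy, nz))
  seg <- segmented_volume(lab, PHANTOM_LABELS, diag(c(h, h, h, 1)),
                          lev_low = lev_low, lev_high = lev_high)
  # seed mesh on the interface plane, inset one voxel from the lateral walls
  xs <- seq(h, (n_xy - 2L) * h, by = h)
  mesh <- plane_mesh(xs, xs, z = z0)
  depth_volume <- lev_low
  list(seg = seg, gm_wm_mesh = mesh,
       analytic_potential = function(depth) depth / L,
       depth_volume = depth_volume, kind = "slab",
       params = list(voxel_size = h, wm_thickness = L, z_interface = z0,
                     z_wall = z1))
}

#' Spherical-shell phantom: concentric ventricle | WM | GM | CSF
#'
#' Ventricle radius `a`, WM outer radius `b` (the GM/WM interface), GM
#' outer radius `c_`. The analytic Laplace potential in the WM shell is
#' `u(r) = (1/r - 1/b) / (1/a - 1/b)` (0 at the interface, 1 at the
#' ventricular wall); field lines are radial, so streamline length equals
#' the radial offset `b - r`. Exact level sets are attached as in
#' [make_slab_phantom()].
#'
#' @param voxel_size isotropic voxel size (mm).
#' @param a,b,c_ ventricle / GM-WM / pial radii in mm, `a < b < c_`.
#' @param subdivisions icosphere subdivision level of the seed mesh.
#' @return list as in [make_slab_phantom()]; `analytic_potential` is a
#'   function of radius r.
#' @export
make_shell_phantom <- function(voxel_size = 0.5, a = 10, b = 20, c_ = 22,
                               subdivisions = 3) {
  h <- voxel_size
  if (!(a > 0 && a < b && b < c_)) stop("config error: radii must satisfy 0 < a < b < c")
  if (b - a < 3) stop("config error: WM shell thinner than the 3 mm default depth")
  ext <- c_ + 2 * h
  n <- as.integer(ceiling(2 * ext / h))
  cvec <- (seq_len(n) - 1) * h - (n - 1) * h / 2   # world coords, centered
  r <- sqrt(outer(outer(cvec^2, cvec^2, "+"), cvec^2, "+"))
  lab <- array(0L, c(n, n, n))
  lab[r <= c_] <- 2L
  lab[r <= b] <- 3L
  lab[r <= a] <- 4L
  lev_low <- b - r          # positive inside WM, negative in GM
  lev_high <- r - a         # positive inside WM, negative in ventricle
  aff <- diag(c(h, h, h, 1)); aff[1:3, 4] <- -(n - 1) * h / 2
  seg <- segmented_volume(lab, PHANTOM_LABELS, aff,
                          lev_low = lev_low, lev_high = lev_high)
  mesh <- icosphere(radius = b, subdivisions = subdivisions)
  upot <- function(r) (1 / r - 1 / b) / (1 / a - 1 / b)
  list(seg = seg, gm_wm_mesh = mesh, analytic_potential = upot,
       depth_volume = b - r, kind = "shell",
       params = list(voxel_size = h, a = a, b = b, c = c_))
}

#' Depth-dependent intensity volume on a phantom
#'
#' Voxel intensity = `profile_fn(depth below the GM/WM interface)` plus an
#' optional planted regional modulation `s_v * modulation_fn(depth)` (with
#' `s_v` the planted value of the nearest seed-mesh vertex) plus isotropic
#' Gaussian noise. Depth is negative above the interface (intracortical),
#' so one profile function covers cortex and SWM.
#'
#' @param phantom result of [make_slab_phantom()] / [make_shell_phantom()].
#' @param profile_fn vectorized function depth (mm) -> intensity.
#' @param planted_map optional length-V vector of regional scores on the
#'   phantom's seed mesh.
#' @param modulation_fn vectorized depth modulation (default one full sine
#'   period over the 3 mm SWM band, zero elsewhere; zero-mean over depth so
#'   the planted component is near-orthogonal to the mean profile).
#' @param noise_sd Gaussian noise SD (intensity units).
#' @param seed RNG seed (generation is bitwise reproducible).
#' @return a `scalar_volume`.
#' @export
make_depth_intensity_volume <- function(phantom, profile_fn = identity,
                                        planted_map = NULL,
                                        modulation_fn = function(d)
                                          ifelse(d > 0 & d < 3, sin(2 * pi * d / 3), 0),
                                        noise_sd = 0, seed = 1) {
  d <- phantom$depth_volume
  vol <- array(profile_fn(as.numeric(d)), dim(d))
  if (!is.null(planted_map)) {
    pm <- map_values(planted_map)
    svox <- phantom_region_scores(phantom, pm)
    vol <- vol + svox * array(modulation_fn(as.numeric(d)), dim(d))
  }
  if (noise_sd > 0) {
    restore <- local_seed(seed)
    on.exit(restore())
    vol <- vol + array(rnorm(length(vol), sd = noise_sd), dim(vol))
  }
  scalar_volume(vol, phantom$seg$affine)
}

# Map a per-vertex score onto voxels by phantom correspondence:
# slab -> nearest (x, y) grid vertex; shell -> nearest vertex by direction.
phantom_region_scores <- function(phantom, scores) {
  seg <- phantom$seg
  dims <- dim(seg$labels)
  V <- nrow(phantom$gm_wm_mesh$vertices)
  if (length(scores) != V) stop("planted map length does not match seed mesh")
  idx <- arrayInd(seq_len(prod(dims)), dims) - 1L
  xyz <- voxel_to_world(seg, idx)
  vert <- phantom$gm_wm_mesh$vertices
  out <- numeric(nrow(xyz))
  if (phantom$kind == "shell") {
    dirs <- xyz / pmax(sqrt(rowSums(xyz^2)), 1e-9)
    vdir <- vert / sqrt(rowSums(vert^2))
    chunk <- 20000L
    for (s in seq(1L, nrow(dirs), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(dirs))
      nn <- max.col(dirs[s:e, , drop = FALSE] %*% t(vdir), ties.method = "first")
      out[s:e] <- scores[nn]
    }
  } else {
    chunk <- 20000L
    for (s in seq(1L, nrow(xyz), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(xyz))
      d2 <- outer(xyz[s:e, 1], vert[, 1], "-")^2 + outer(xyz[s:e, 2], vert[, 2], "-")^2
      nn <- max.col(-d2, ties.method = "first")
      out[s:e] <- scores[nn]
    }
  }
  array(out, dims)
}

#' Planted-gradient profile set
#'
#' Constructs profiles `P(d, v) = baseline(depth_d) + s_v * modulation(depth_d)
#' + N(0, noise_sd)` with a centered regional score `s_v` (linear in vertex
#' index by default). The returned truth supports parameter-recovery tests
#' of the MPC-gradient pipeline.
#'
#' @param n_vertices number of vertices (>= 50).
#' @param depths vector of sampling depths in mm (>= 5 values).
#' @param noise_sd Gaussian noise SD; the spec'd recovery condition uses
#'   half the modulation amplitude.
#' @param seed RNG seed.
#' @param gradient_truth optional length-V score vector (default linear,
#'   centered, range 2).
#' @param baseline_fn,modulation_fn depth functions; defaults: baseline
#'   `10 - d` (intensity falling into the WM), modulation
#'   `sin(2 pi d / max(d))` with unit amplitude — a full period, so it is
#'   zero-mean over depth and near-orthogonal to the controlled mean
#'   profile.
#' @return list of class `planted_profile_set` with `profiles` (D x V),
#'   `gradient_truth`, `depths`, `noise_sd`, `seed`, and `adjacency` (the
#'   vertex-chain 1-ring of the planted spatial ordering, usable for the
#'   pre-MPC smoothing step).
#' @export
make_planted_gradient_profiles <- function(n_vertices, depths, noise_sd = 0.5,
                                           seed = 1, gradient_truth = NULL,
                                           baseline_fn = function(d) 10 - d,
                                           modulation_fn = NULL) {
  if (n_vertices < 50) stop("need at least 50 vertices")
  if (length(depths) < 5) stop("need at least 5 depths")
  if (is.null(modulation_fn)) {
    dmax <- max(depths)
    modulation_fn <- function(d) sin(2 * pi * d / dmax)
  }
  s <- if (is.null(gradient_truth))
    seq(-1, 1, length.out = n_vertices) else gradient_truth
  s <- s - mean(s)
  base <- baseline_fn(depths)
  mod <- modulation_fn(depths)
  profiles <- outer(base, rep(1, n_vertices)) + outer(mod, s)
  if (noise_sd > 0) {
    restore <- local_seed(seed)
    on.exit(restore())
    profiles <- profiles + matrix(rnorm(length(profiles), sd = noise_sd),
                                  nrow(profiles))
  }
  adjacency <- lapply(seq_len(n_vertices), function(i)
    c(if (i > 1) i - 1L, if (i < n_vertices) i + 1L))
  structure(list(profiles = profiles, gradient_truth = s, depths = depths,
                 baseline = base, modulation = mod, adjacency = adjacency,
                 noise_sd = noise_sd, seed = seed),
            class = "planted_profile_set")
}

#' Synthetic connectome with planted node strength
#'
#' Symmetric zero-diagonal matrix whose expected node strength is monotone
#' in `strength_truth`. The `fc` model draws correlations
#' `tanh(t_i t_j / scale + noise)` (entries in (-1, 1)); the `sc` model
#' draws Poisson streamline counts with rate proportional to `t_i t_j`.
#'
#' @param n number of nodes.
#' @param strength_truth nonnegative length-n target scores.
#' @param model `"fc"` or `"sc"`.
#' @param seed RNG seed.
#' @param noise_sd latent Gaussian noise for the fc model (0 = noiseless).
#' @param scale latent scale (fc) or mean count scale (sc).
#' @return a `connectivity_matrix` (see [connectivity_matrix()]).
#' @export
make_synthetic_connectome <- function(n, strength_truth, model = c("fc", "sc"),
                                      seed = 1, noise_sd = 0.05, scale = NULL) {
  model <- match.arg(model)
  t_ <- strength_truth
  if (length(t_) != n) stop("strength_truth must have length n")
  if (any(t_ < 0)) stop("strength_truth must be nonnegative")
  restore <- local_seed(seed)
  on.exit(restore())
  if (model == "fc") {
    if (is.null(scale)) scale <- max(mean(t_)^2, 1e-12) * 4
    lat <- outer(t_, t_) / scale
    if (noise_sd > 0) {
      eps <- matrix(rnorm(n * n, sd = noise_sd), n)
      lat <- lat + (eps + t(eps)) / sqrt(2)
    }
    w <- tanh(lat)
    diag(w) <- 0
    connectivity_matrix(w, kind = "fc")
  } else {
    if (is.null(scale)) scale <- 20 / max(mean(t_)^2, 1e-12)
    lam <- outer(t_, t_) * scale
    cnt <- matrix(0, n, n)
    up <- upper.tri(lam)
    cnt[up] <- stats::rpois(sum(up), lam[up])
    cnt <- cnt + t(cnt)
    diag(cnt) <- 0
    connectivity_matrix(cnt, kind = "sc")
  }
}
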