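test_that("slab solve matches the analytic linear solution", {
  ph <- slab_phantom()
  f <- slab_field()
  expect_true(f$converged)
  wm <- ph$seg$labels == 3L
  err <- abs(f$u[wm] - ph$analytic_potential(ph$depth_volume[wm]))
  expect_lt(max(err), 1e-3)
  # symmetry: u(d) + u(L - d) = 1 for voxel layers mirrored about the midplane
  L <- ph$params$wm_thickness
  d1 <- wm & abs(ph$depth_volume - 2.75) < 1e-9
  d2 <- wm & abs(ph$depth_volume - (L - 2.75)) < 1e-9
  expect_true(any(d1) && any(d2))
  expect_lt(abs(mean(f$u[d1]) + mean(f$u[d2]) - 1), 1e-3)
  # boundary values on the extended field
  expect_true(all(f$u[f$low_mask] == 0))
  expect_true(all(f$u[f$high_mask] == 1))
  expect_true(all(f$u[wm] >= 0 & f$u[wm] <= 1))
})

test_that("solver is deterministic and reports boundary errors", {
  f1 <- solve_laplace(slab_phantom()$seg)
  f2 <- solve_laplace(slab_phantom()$seg)
  expect_identical(f1$u, f2$u)

  ph <- slab_phantom()
  lab <- ph$seg$labels
  lab[lab == 4L] <- 0L  # remove ventricle
  seg <- segmented_volume(lab, ph$seg$label_map, ph$seg$affine)
  expect_error(solve_laplace(seg), "boundary error")
  expect_warning(solve_laplace(ph$seg, max_iterations = 3L), "not converge")
})

test_that("coarse shell solve approximates the spherical analytic solution", {
  ph <- shell_coarse()
  f <- shell_coarse_field()
  wm <- ph$seg$labels == 3L
  r <- ph$params$b - ph$depth_volume
  err <- abs(f$u[wm] - ph$analytic_potential(r[wm]))
  # 1 mm voxels: sub-voxel boundary scheme keeps the field within 1%
  expect_lt(max(err), 0.01)
  # label-only (anti-aliased estimate) mode still solves, less accurately
  seg2 <- ph$seg; seg2$lev_low <- NULL; seg2$lev_high <- NULL
  f2 <- solve_laplace(seg2)
  err2 <- abs(f2$u[wm] - ph$analytic_potential(r[wm]))
  expect_lt(max(err2), 0.06)
  expect_gt(max(err2), max(err))
})

test_that("potential gradient is unit length and matches analytic directions", {
  ph <- slab_phantom()
  g <- potential_gradient(slab_field())
  wm <- ph$seg$labels == 3L
  interior <- wm & ph$depth_volume > 0.6 & ph$depth_volume < ph$params$wm_thickness - 0.6
  expect_gt(min(g$gz[interior]), 0.999)   # +z into the slab
  nrm <- sqrt(g$gx^2 + g$gy^2 + g$gz^2)
  expect_equal(range(nrm[interior]), c(1, 1), tolerance = 1e-9)

  phs <- shell_coarse()
  gs <- potential_gradient(shell_coarse_field())
  wms <- phs$seg$labels == 3L
  rr <- phs$params$b - phs$depth_volume
  inner <- wms & rr > phs$params$a + 1.5 & rr < phs$params$b - 1.5
  idx <- which(inner, arr.ind = TRUE)
  xyz <- voxel_to_world(phs$seg, idx - 1L)
  rhat <- xyz / sqrt(rowSums(xyz^2))
  dots <- -(gs$gx[inner] * rhat[, 1] + gs$gy[inner] * rhat[, 2] +
            gs$gz[inner] * rhat[, 3])
  ang <- acos(pmin(pmax(dots, -1), 1)) * 180 / pi
  expect_lt(max(ang), 2)  # within 2 degrees of -r_hat
})

test_that("surface shifting places depths at the traveled arc length", {
  ph <- slab_phantom()
  st <- shift_surface(ph$gm_wm_mesh, slab_field(), depth_spec("invivo"))
  expect_equal(length(st$meshes), 16)
  expect_true(all(st$valid))
  for (k in c(2, 8, 16)) {
    zoff <- st$meshes[[k]]$vertices[, 3] - ph$params$z_interface
    expect_lt(abs(mean(zoff) - st$depths[k]), 0.125 + 1e-9)
  }
  # topology preserved
  expect_identical(st$meshes[[16]]$faces, ph$gm_wm_mesh$faces)

  # monotone ordering and monotone potential along streamlines
  zs <- sapply(st$meshes, function(m) m$vertices[, 3])
  expect_true(all(apply(zs, 1, function(x) all(diff(x) > 0))))

  # step halving changes positions by less than the coarser step
  st2 <- shift_surface(ph$gm_wm_mesh, slab_field(),
                       depth_spec("invivo", step_size = 0.0625))
  d <- sqrt(rowSums((st2$meshes[[16]]$vertices - st$meshes[[16]]$vertices)^2))
  expect_lt(max(d), 0.125)
})

test_that("shell placement: radial offsets track depth, ordering holds", {
  ph <- shell_coarse()
  st <- shift_surface(ph$gm_wm_mesh, shell_coarse_field(),
                      depth_spec("invivo"))
  b <- ph$params$b
  offs <- sapply(st$meshes, function(m) b - sqrt(rowSums(m$vertices^2)))
  fully <- rowSums(!st$valid) == 0
  expect_gt(mean(fully), 0.95)
  expect_true(all(apply(offs[fully, ], 1, function(x) all(diff(x) > 0))))
  expect_lt(abs(mean(offs[fully, 16]) - 3.0), 0.25 + 1e-9)  # one step (1 mm voxels)
  # streamline length equals radial offset here (radial field)
  expect_lt(mean(abs(offs[fully, 16] - 3.0)), 0.25)
})

test_that("misplaced seed mesh raises a geometry error", {
  ph <- slab_phantom()
  bad <- ph$gm_wm_mesh
  bad$vertices[, 3] <- -5  # far outside the volume
  expect_error(shift_surface(bad, slab_field(), depth_spec("invivo")),
               "geometry error")
})

test_that("equivolumetric fractions follow the closed-form area rule", {
  # parallel planes: equidistant limit
  pial <- plane_mesh(0:6, 0:6, z = 2)
  white <- plane_mesh(0:6, 0:6, z = 0)
  st <- generate_equivolumetric_surfaces(pial, white, 3)
  zs <- sort(sapply(st$meshes, function(m) mean(m$vertices[, 3])))
  expect_equal(zs, c(0.5, 1.0, 1.5), tolerance = 1e-9)

  # concentric spheres r = 10 / 11: matches the analytic equivolume radius
  w <- icosphere(10, 3); p <- icosphere(11, 3)
  st2 <- generate_equivolumetric_surfaces(p, w, 1)
  r_mid <- mean(sqrt(rowSums(st2$meshes[[1]]$vertices^2)))
  r_true <- ((10^3 + 11^3) / 2)^(1 / 3)
  expect_equal(r_mid, r_true, tolerance = 0.01)

  # single-surface fraction strictly inside (0, 1)
  frac <- (r_mid - 10) / (11 - 10)
  expect_gt(frac, 0); expect_lt(frac, 1)
  expect_error(generate_equivolumetric_surfaces(p, icosphere(10, 2), 1),
               "correspondence")
})

test_that("labels propagate identically along the vertex correspondence", {
  ph <- slab_phantom()
  st <- shift_surface(ph$gm_wm_mesh, slab_field(), depth_spec("invivo"))
  V <- nrow(ph$gm_wm_mesh$vertices)
  lab <- sample(1:4, V, replace = TRUE)
  out <- propagate_labels(lab, st)
  expect_length(out, length(st$meshes))
  for (k in seq_along(out)) expect_identical(out[[k]], lab)
  # class-wise counts preserved at every depth
  counts <- lapply(out, function(o) as.integer(table(o)))
  expect_identical(counts, rep(list(as.integer(table(lab))), length(out)))

  # invalid vertex gets the sentinel from its depth onward
  st$valid[3, 6:ncol(st$valid)] <- FALSE
  out2 <- propagate_labels(lab, st)
  expect_true(is.na(out2[[6]][3]) && is.na(out2[[16]][3]))
  expect_identical(out2[[5]][3], lab[3])
  expect_error(propagate_labels(lab[-1], st), "length")
})
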