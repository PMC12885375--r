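test_that("trilinear sampling is exact for affine functions of position", {
  # f(x, y, z) = 2x + 3y - z + 4 on an oblique-origin grid
  aff <- diag(c(0.5, 0.4, 0.8, 1)); aff[1:3, 4] <- c(-1, 2, 0.3)
  dims <- c(9, 11, 7)
  idx <- arrayInd(seq_len(prod(dims)), dims) - 1L
  xyz <- cbind(idx[, 1] * 0.5 - 1, idx[, 2] * 0.4 + 2, idx[, 3] * 0.8 + 0.3)
  f <- function(p) 2 * p[, 1] + 3 * p[, 2] - p[, 3] + 4
  vol <- scalar_volume(array(f(xyz), dims), aff)
  set.seed(2)
  pts <- cbind(runif(200, -0.9, 2.9), runif(200, 2.1, 5.9),
               runif(200, 0.4, 5.0))
  got <- swmtools:::trilinear_sample_cpp(as.numeric(vol$data), dims,
                                         world_to_voxel(vol, pts))
  expect_equal(got, f(pts), tolerance = 1e-12)
  # a vertex exactly at a voxel center returns that voxel's value
  expect_identical(
    swmtools:::trilinear_sample_cpp(as.numeric(vol$data), dims,
                                    matrix(c(3, 4, 2), 1)),
    vol$data[4, 5, 3])
  # outside the grid -> NA
  expect_true(is.na(swmtools:::trilinear_sample_cpp(
    as.numeric(vol$data), dims, matrix(c(-1, 0, 0), 1))))
})

test_that("stack sampling recovers the slab depth function row-wise", {
  ph <- slab_phantom()
  vol <- make_depth_intensity_volume(ph, profile_fn = identity, noise_sd = 0)
  st <- shift_surface(ph$gm_wm_mesh, slab_field(), depth_spec("invivo"))
  prof <- sample_volume_to_stack(st, vol)
  expect_equal(nrow(prof$values), 16)
  for (k in c(2, 8, 16))
    expect_lt(abs(mean(prof$values[k, ], na.rm = TRUE) - st$depths[k]), 0.13)
  # invalid stack vertices are NaN-masked
  st$valid[5, 10] <- FALSE
  prof2 <- sample_volume_to_stack(st, vol)
  expect_true(is.na(prof2$values[10, 5]))
  expect_false(prof2$valid[10, 5])
})

test_that("Tukey repair flags by type-7 fences and interpolates from rings", {
  cm <- chain_mesh(4)   # vertices 1..5 on a line + 4 apex vertices
  vals <- c(1, 2, 3, 4, 100, 2, 2, 3, 3)
  rep_ <- repair_outliers_tukey(vals, cm, region_mask = c(rep(TRUE, 5), rep(FALSE, 4)))
  # quartiles of {1,2,3,4,100} (type 7): Q1 = 2, Q3 = 4, fence 4 + 1.5*2 = 7
  expect_identical(which(rep_$outliers), 5L)
  # neighbors of vertex 5 in the chain mesh: vertex 4 (=4) and apex 9 (=3)
  expect_equal(rep_$values[5], mean(c(4, 3)))
  expect_identical(rep_$values[-5], vals[-5])  # untouched elsewhere

  # constant region: IQR 0, fences contain everything
  repc <- repair_outliers_tukey(rep(3, 9), cm)
  expect_false(any(repc$outliers))
  expect_error(repair_outliers_tukey(c(NA, NA, 1, 2, 3, 1, 2, 3, 1), cm,
                                     region_mask = c(TRUE, TRUE, rep(FALSE, 7))),
               "no finite values")
})

test_that("hand-checked fence: {1,2,3,4,100} against the stated convention", {
  # type-7 quartiles: Q1 = 2, Q3 = 4 -> upper fence 7; 100 flagged
  q <- quantile(c(1, 2, 3, 4, 100), c(.25, .75), type = 7, names = FALSE)
  expect_equal(q, c(2, 4))
  ic <- unit_icosphere()
  x <- rep(2, nrow(ic$vertices))
  x[1:5] <- c(1, 2, 3, 4, 100)
  region <- seq_along(x) <= 5
  r <- repair_outliers_tukey(x, ic, region_mask = region)
  expect_true(r$outliers[5])
  expect_false(any(r$outliers[-5]))
  expect_identical(r$values[-5], x[-5])
})

test_that("moments match a direct-summation oracle", {
  moments_oracle <- function(x) {
    x <- x[is.finite(x)]
    n <- length(x)
    mu <- sum(x) / n
    m2 <- sum((x - mu)^2) / n
    m3 <- sum((x - mu)^3) / n
    m4 <- sum((x - mu)^4) / n
    c(mean = mu, sd = sqrt(sum((x - mu)^2) / (n - 1)),
      skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
  }
  set.seed(4)
  vals <- rbind(rnorm(300), skewed_values(300), runif(300), rt(300, df = 5))
  pm <- profile_matrix(vals, 1:4)
  mt <- compute_moments(pm)
  for (d in 1:4) {
    o <- moments_oracle(vals[d, ])
    expect_equal(unlist(mt[d, c("mean", "sd", "skewness", "kurtosis")]),
                 o, tolerance = 1e-12, ignore_attr = TRUE)
  }
  # symmetric three-point row
  m3 <- compute_moments(profile_matrix(rbind(c(1, 2, 3, 2), c(1, 2, 3, 2)), 1:2))
  expect_equal(m3$mean[1], 2)
  expect_equal(m3$skewness[1], 0, tolerance = 1e-12)
  # large-sample excess kurtosis of a normal ~ 0
  mn <- compute_moments(profile_matrix(matrix(rnorm(1e5), 1), 1))
  expect_lt(abs(mn$kurtosis), 0.05)
  # degenerate rows
  expect_warning(mz <- compute_moments(profile_matrix(matrix(5, 1, 10), 1)),
                 "zero variance")
  expect_true(is.nan(mz$skewness))
  msm <- compute_moments(profile_matrix(matrix(c(1, 2, 3, NA), 1), 1))
  expect_true(is.nan(msm$kurtosis))  # < 4 valid vertices
})

test_that("smoothing: fixed point, impulse response, contraction, mean preservation", {
  ic <- unit_icosphere()
  adj <- swmtools:::mesh_adjacency(ic)
  V <- length(adj)
  # constant map unchanged
  expect_equal(smooth_surface_map(rep(2.5, V), adj), rep(2.5, V))
  # one-step impulse: center keeps (1 - relax) * 1, neighbors get relax / deg
  imp <- rep(0, V); imp[1] <- 1
  s1 <- smooth_surface_map(imp, adj, iterations = 1, relaxation = 0.5)
  expect_equal(s1[1], 0.5)
  for (j in adj[[1]]) expect_equal(s1[j], 0.5 / length(adj[[j]]))
  # variance strictly decreases each iteration; max-norm non-expansive
  set.seed(6)
  x <- rnorm(V)
  prev <- x
  for (it in 1:4) {
    cur <- smooth_surface_map(prev, adj, iterations = 1)
    expect_lt(var(cur), var(prev))
    expect_lte(max(abs(cur)), max(abs(prev)))
    prev <- cur
  }
  # NaN vertices are excluded and keep their value
  x2 <- x; x2[10] <- NaN
  s2 <- smooth_surface_map(x2, adj, iterations = 2)
  expect_true(is.nan(s2[10]))
  expect_true(all(is.finite(s2[-10])))
})

test_that("smoothing preserves the mean on a regular closed mesh", {
  # regular torus-like graph: every vertex same degree -> exact mean preservation
  ic <- icosphere(1, 2)
  adj <- swmtools:::mesh_adjacency(ic)
  deg <- lengths(adj)
  set.seed(7)
  x <- rnorm(length(adj))
  s <- smooth_surface_map(x, adj, iterations = 5)
  # icosphere is not perfectly regular (12 pentagons); weighted mean is the
  # exact invariant, plain mean holds to first order
  expect_lt(abs(mean(s) - mean(x)), 5e-3 * sd(x))
  w <- deg / sum(deg)
  expect_equal(sum(w * s), sum(w * x), tolerance = 1e-9)
})

test_that("curvature regression removes planted curvature effects", {
  ic <- unit_icosphere()
  V <- nrow(ic$vertices)
  curv <- mesh_geometry(ic)$mean_curvature + rnorm(V, sd = 0.05)
  # exact linear dependence -> constant residual level 5
  y <- 2 * curv + 5
  pm <- profile_matrix(rbind(y, y), c(0, 1))
  out <- regress_out_curvature(pm, curv)
  expect_equal(out$values[1, ], rep(5, V), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(out$provenance$curvature_regression[1, "slope"], 2,
               tolerance = 1e-9, ignore_attr = TRUE)
  # orthogonal covariate: output equals input
  set.seed(8)
  y2 <- rnorm(V)
  y2 <- y2 - curv * sum(y2 * (curv - mean(curv))) / sum((curv - mean(curv))^2)
  pm2 <- profile_matrix(matrix(y2, 1), 0)
  out2 <- regress_out_curvature(pm2, curv)
  expect_equal(out2$values[1, ], y2, tolerance = 1e-6)
  # planted mixture: post-correction Spearman with curvature ~ 0
  set.seed(9)
  y3 <- 3 + 0.8 * curv + rnorm(V, sd = 0.1)
  out3 <- regress_out_curvature(profile_matrix(matrix(y3, 1), 0), curv)
  expect_lt(abs(cor(out3$values[1, ], curv, method = "spearman")), 0.05)
  expect_warning(regress_out_curvature(pm2, rep(1, V)), "constant curvature")
})

test_that("dropping the outermost row mirrors CSF/GM exclusion", {
  pm <- profile_matrix(matrix(1:12, 3), c(-1, 0, 1))
  d <- drop_outermost_row(pm)
  expect_equal(d$depths, c(0, 1))
  expect_equal(nrow(d$values), 2)
})
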