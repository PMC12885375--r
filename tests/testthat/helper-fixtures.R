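# Shared fixtures, built lazily and cached for the test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

slab_phantom <- function() fixture("slab", function() make_slab_phantom())

slab_field <- function() fixture("slab_field", function()
  solve_laplace(slab_phantom()$seg))

# coarse shell for unit tests (fast); acceptance uses the 0.5 mm default
shell_coarse <- function() fixture("shell_coarse", function()
  make_shell_phantom(voxel_size = 1.0))

shell_coarse_field <- function() fixture("shell_coarse_field", function()
  solve_laplace(shell_coarse()$seg))

unit_icosphere <- function() fixture("icosphere", function() icosphere(1, 3))

# straight chain mesh: n + 1 vertices along x at unit spacing, degenerate-free
# triangles formed with an off-axis apex row
chain_mesh <- function(n = 5) {
  v <- cbind(0:n, 0, 0)
  apex <- cbind(0:(n - 1) + 0.5, 1, 0)
  verts <- rbind(v, apex)
  faces <- cbind(1:n, 2:(n + 1), n + 1 + 1:n)
  triangle_mesh(verts, faces)
}

# Brute-force partial correlation oracle: closed-form first-order partial
# correlation on the rank-space correlations (independent of the package's
# QR residualization route), then Fisher z with clipping. The controlled
# covariate is the mean of the rank-transformed profiles.
mpc_oracle <- function(vals, clip = 1 - 1e-7) {
  V <- ncol(vals)
  ranks <- apply(vals, 2, rank)
  mp <- rowMeans(ranks)
  out <- matrix(0, V, V)
  for (i in 1:V) for (j in 1:V) {
    if (i == j) next
    rij <- cor(ranks[, i], ranks[, j])
    rim <- cor(ranks[, i], mp)
    rjm <- cor(ranks[, j], mp)
    rp <- (rij - rim * rjm) / sqrt((1 - rim^2) * (1 - rjm^2))
    rp <- min(max(rp, -clip), clip)
    out[i, j] <- 0.5 * log((1 + rp) / (1 - rp))
  }
  out
}

skewed_values <- function(n, seed = 5) {
  restore <- swmtools:::local_seed(seed)
  on.exit(restore())
  exp(rnorm(n)) + rnorm(n, sd = 0.1)
}
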