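#' Pipeline run configuration
#'
#' Collects the fixed constants of the framework: the depth preset
#' (histology = 50 x 0.06 mm, invivo = 15 x 0.2 mm), solver tolerance,
#' profile smoothing (5 iterations, relaxation 0.5), MPC sparsity (top 10%
#' retained), diffusion alpha (0.5), spin permutations, and the master
#' seed. Unspecified fields take these published defaults.
#'
#' @param kind phantom kind, `"slab"` or `"shell"`.
#' @param preset depth preset name.
#' @param voxel_size phantom voxel size in mm.
#' @param noise_sd intensity noise SD.
#' @param smooth_iterations,smooth_relaxation per-surface smoothing.
#' @param tolerance,max_iterations Laplace solver settings.
#' @param sparsity,alpha,n_components gradient settings.
#' @param n_perm spin permutations.
#' @param seed master RNG seed.
#' @param ... extra fields stored verbatim.
#' @return list of class `run_config`.
#' @export
run_config <- function(kind = "slab", preset = "invivo", voxel_size = 0.5,
                       noise_sd = 0.1, smooth_iterations = 5,
                       smooth_relaxation = 0.5, tolerance = 1e-6,
                       max_iterations = 20000, sparsity = 0.9, alpha = 0.5,
                       n_components = 10, n_perm = 1000, seed = 1, ...) {
  cfg <- list(kind = kind, preset = preset, voxel_size = voxel_size,
              noise_sd = noise_sd, smooth_iterations = smooth_iterations,
              smooth_relaxation = smooth_relaxation, tolerance = tolerance,
              max_iterations = max_iterations, sparsity = sparsity,
              alpha = alpha, n_components = n_components, n_perm = n_perm,
              seed = seed, ...)
  if (!cfg$kind %in% c("slab", "shell")) stop("config error: kind must be slab or shell")
  if (!cfg$preset %in% c("invivo", "histology")) stop("config error: unknown preset")
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a JSON file
#' @param path JSON file with `run_config` fields.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config error: no such config file: ", path)
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the phantom-to-statistics pipeline
#'
#' Executes phantom generation, Laplace solve + surface shifting, intensity
#' profiling with per-surface smoothing, MPC + diffusion embedding, and
#' (for the shell phantom, which has a spherical registration) connectome
#' statistics with a spin test. All stage outputs land in `out_dir`
#' together with a provenance JSON (config, seed, package version, config
#' hash) sufficient to reproduce the run; identical config + seed gives
#' bitwise identical numeric outputs.
#'
#' @param config a `run_config`.
#' @param out_dir output directory (created; existing files overwritten).
#' @return invisible list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE, digits = NA)
  prov <- list(config_hash = unname(tools::md5sum(cfg_path)),
               package_version = as.character(utils::packageVersion("swmtools")),
               seed = config$seed)

  ## stage 1: phantom
  ph <- if (config$kind == "slab") {
    make_slab_phantom(voxel_size = config$voxel_size)
  } else make_shell_phantom(voxel_size = config$voxel_size)
  save_volume(ph$seg, file.path(out_dir, "seg.nii.gz"))
  save_mesh(ph$gm_wm_mesh, file.path(out_dir, "gmwm.surf.gii"))
  # planted regional score: spatially smooth pole-to-pole / end-to-end
  # coordinate gradient (per-surface smoothing must not destroy it)
  vtx <- ph$gm_wm_mesh$vertices
  ax <- if (config$kind == "shell") 3L else 1L
  truth <- vtx[, ax] / max(abs(vtx[, ax] - mean(vtx[, ax])))
  truth <- truth - mean(truth)
  vol <- make_depth_intensity_volume(
    ph, profile_fn = function(d) 10 - d, planted_map = truth,
    noise_sd = config$noise_sd, seed = config$seed)
  save_volume(vol, file.path(out_dir, "feature.nii.gz"))

  ## stage 2: Laplace + surface placement
  field <- solve_laplace(ph$seg, tolerance = config$tolerance,
                         max_iterations = config$max_iterations)
  spec <- depth_spec(config$preset)
  stack <- shift_surface(ph$gm_wm_mesh, field, spec)
  for (k in seq_along(stack$meshes))
    save_mesh(stack$meshes[[k]],
              file.path(out_dir, sprintf("swm_depth%02d.surf.gii", k - 1L)))
  write_tsv(as.data.frame(stack$valid * 1L), file.path(out_dir, "valid.tsv"))

  ## stage 3: profiling
  profiles <- sample_volume_to_stack(stack, vol, modality = "synthetic")
  ptab <- cbind(depth = profiles$depths, as.data.frame(profiles$values))
  write_tsv(ptab, file.path(out_dir, "profiles.tsv"))
  moments <- compute_moments(profiles)
  write_tsv(moments, file.path(out_dir, "moments.tsv"))

  ## stage 4: gradients
  adj <- mesh_adjacency(ph$gm_wm_mesh)
  sm <- profiles
  sm$values <- t(apply(profiles$values, 1, smooth_surface_map, mesh = adj,
                       iterations = config$smooth_iterations,
                       relaxation = config$smooth_relaxation))
  mpc <- compute_mpc(sm)
  gset <- mpc_gradients(mpc, sparsity = config$sparsity, alpha = config$alpha,
                        n_components = config$n_components)
  save_surface_data(gset$gradients[, 1], file.path(out_dir, "G1.func.gii"))
  write_tsv(data.frame(eigenvalue = gset$eigenvalues,
                       variance_explained = gset$variance_explained),
            file.path(out_dir, "eigenvalues.tsv"))

  ## stage 5: statistics (requires a spherical registration -> shell only)
  stats_out <- NULL
  if (config$kind == "shell") {
    # at the phantom's low effective noise the leading MPC axis organizes
    # vertices by the magnitude of their profile deviation from the mean
    # (see the methods vignette), so the planted strength follows |truth|
    fc <- make_synthetic_connectome(nrow(vtx), abs(truth) + 0.5, model = "fc",
                                    seed = config$seed + 1L)
    strength <- fc_strength(fc)
    spin <- spin_test(gset$gradients[, 1], strength, ph$gm_wm_mesh,
                      n_perm = config$n_perm, seed = config$seed + 2L)
    stats_out <- list(rho = spin$r_observed, p_spin = spin$p_spin,
                      n_perm = spin$n_perm)
    jsonlite::write_json(stats_out, file.path(out_dir, "association.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  prov$stages <- c("phantom", "laplace", "profile", "gradients",
                   if (config$kind == "shell") "stats")
  prov$solver <- list(residual = field$residual,
                      iterations = field$iterations_run)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(phantom = ph, field = field, stack = stack,
                 profiles = profiles, moments = moments, mpc = mpc,
                 gradients = gset, stats = stats_out))
}

#' Command-line entry point
#'
#' Subcommands: `phantom`, `sample-swm`, `profile`, `moments`, `gradients`,
#' `associate`, `run-all`. Arguments are `--key value` pairs; see the
#' README for examples. Returns (and, under `Rscript`, exits with) 0 on
#' success, 1 on user error, 2 on internal error.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return integer exit status, invisibly.
#' @export
swm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: swm <command> [--key value ...]",
    "commands: phantom sample-swm profile moments gradients associate run-all",
    sep = "\n")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list()
  kv <- args[-1]
  i <- 1L
  while (i <= length(kv)) {
    if (!startsWith(kv[i], "--")) { message("bad argument: ", kv[i]); return(invisible(1L)) }
    opts[[sub("^--", "", kv[i])]] <- if (i + 1 <= length(kv)) kv[i + 1] else ""
    i <- i + 2L
  }
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  chr <- function(x, d) if (is.null(x)) d else x
  status <- tryCatch({
    switch(cmd,
      "phantom" = {
        kind <- chr(opts$kind, "slab")
        out <- chr(opts$out, ".")
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        ph <- if (kind == "slab")
          make_slab_phantom(voxel_size = num(opts$voxel, 0.5))
        else make_shell_phantom(voxel_size = num(opts$voxel, 0.5))
        save_volume(ph$seg, file.path(out, "seg.nii.gz"))
        save_mesh(ph$gm_wm_mesh, file.path(out, "gmwm.surf.gii"))
        jsonlite::write_json(list(kind = kind, params = ph$params),
                             file.path(out, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
        0L
      },
      "sample-swm" = {
        seg <- load_volume(chr(opts$seg, stop("--seg required")))
        mesh <- load_mesh(chr(opts$surf, stop("--surf required")))
        spec <- depth_spec(chr(opts$preset, "invivo"),
                           n_surfaces = opts[["n-surfaces"]],
                           spacing = if (is.null(opts$spacing)) NULL
                                     else as.numeric(opts$spacing),
                           step_size = if (is.null(opts$step)) NULL
                                       else as.numeric(opts$step))
        field <- solve_laplace(seg, tolerance = num(opts$tol, 1e-6))
        stack <- shift_surface(mesh, field, spec)
        out <- chr(opts$out, "stack")
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        for (k in seq_along(stack$meshes))
          save_mesh(stack$meshes[[k]],
                    file.path(out, sprintf("depth%02d.surf.gii", k - 1L)))
        write_tsv(as.data.frame(stack$valid * 1L), file.path(out, "valid.tsv"))
        jsonlite::write_json(stack$provenance, file.path(out, "provenance.json"),
                             auto_unbox = TRUE, digits = NA)
        0L
      },
      "profile" = {
        stackdir <- chr(opts$stack, stop("--stack required"))
        vol <- load_volume(chr(opts$vol, stop("--vol required")))
        meshes <- lapply(sort(list.files(stackdir, "^depth.*surf\\.gii$",
                                         full.names = TRUE)), load_mesh)
        valid <- as.matrix(utils::read.delim(file.path(stackdir, "valid.tsv")))
        prov <- jsonlite::read_json(file.path(stackdir, "provenance.json"),
                                    simplifyVector = TRUE)
        depths <- c(0, prov$spec$spacing * seq_len(prov$spec$n_surfaces))
        stack <- surface_stack(meshes, depths, valid > 0)
        profiles <- sample_volume_to_stack(stack, vol)
        ptab <- cbind(depth = profiles$depths, as.data.frame(profiles$values))
        write_tsv(ptab, chr(opts$out, "profiles.tsv"))
        0L
      },
      "moments" = {
        tab <- utils::read.delim(chr(opts$profiles, stop("--profiles required")))
        pm <- profile_matrix(as.matrix(tab[, -1]), tab$depth)
        write_tsv(compute_moments(pm), chr(opts$out, "moments.tsv"))
        0L
      },
      "gradients" = {
        tab <- utils::read.delim(chr(opts$profiles, stop("--profiles required")))
        pm <- profile_matrix(as.matrix(tab[, -1]), tab$depth)
        mpc <- compute_mpc(pm)
        aff <- affinity_normalized_angle(mpc, sparsity = num(opts$sparsity, 0.9))
        gset <- diffusion_embedding(aff, alpha = num(opts$alpha, 0.5),
                                    n_components = num(opts[["n-components"]], 10))
        out <- chr(opts$out, "gset")
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        for (k in seq_len(ncol(gset$gradients)))
          save_surface_data(gset$gradients[, k],
                            file.path(out, sprintf("G%d.func.gii", k)))
        write_tsv(data.frame(eigenvalue = gset$eigenvalues,
                             variance_explained = gset$variance_explained),
                  file.path(out, "eigenvalues.tsv"))
        0L
      },
      "associate" = {
        g <- load_surface_data(chr(opts$gradient, stop("--gradient required")))
        f <- load_surface_data(chr(opts$feature, stop("--feature required")))
        sph <- load_mesh(chr(opts$sphere, stop("--sphere required")))
        res <- spin_test(g, f, sph, n_perm = num(opts[["n-perm"]], 1000),
                         seed = as.integer(num(opts$seed, 1)))
        jsonlite::write_json(list(rho = res$r_observed, p_spin = res$p_spin,
                                  n_perm = res$n_perm, seed = res$seed,
                                  null_mean = mean(res$null),
                                  null_sd = sd(res$null)),
                             chr(opts$out, "result.json"),
                             auto_unbox = TRUE, digits = NA)
        0L
      },
      "run-all" = {
        cfg <- if (!is.null(opts$config)) load_config(opts$config)
               else run_config(seed = as.integer(num(opts$seed, 1)))
        run_pipeline(cfg, chr(opts$out, "run"))
        0L
      },
      { message("unknown command: ", cmd, "\n", usage); 1L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("config error|required|no such", conditionMessage(e))) 1L else 2L
  })
  invisible(status)
}
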