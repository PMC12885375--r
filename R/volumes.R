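#' Scalar feature volume
#'
#' A 3D scalar array (e.g., staining intensity, T1 in ms, MTsat in p.u.)
#' together with a 4x4 voxel-index-to-world-mm affine. Voxel indices are
#' 0-based; world coordinates are millimetres.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to world mm.
#'   Defaults to `diag(4)` scaled by `voxel_size` if given.
#' @param voxel_size length-3 positive numeric, mm per axis. Derived from the
#'   affine when omitted.
#' @return An object of class `scalar_volume` with fields `data`, `affine`,
#'   `voxel_size`.
#' @export
scalar_volume <- function(data, affine = NULL, voxel_size = NULL) {
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  if (is.null(affine)) {
    vs <- if (is.null(voxel_size)) c(1, 1, 1) else rep_len(voxel_size, 3)
    affine <- diag(c(vs, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || !all(is.finite(affine)))
    stop("affine must be a finite 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < 1e-12) stop("affine is not invertible")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vs <= 0)) stop("voxel size must be strictly positive")
  structure(list(data = data, affine = affine, voxel_size = vs),
            class = "scalar_volume")
}

#' Labeled segmentation volume
#'
#' Integer label volume plus a role-to-label map covering
#' `background`, `CSF`, `GM`, `WM`, `ventricle`. Roles may be absent
#' (explicitly empty). Optional boundary level-set fields `lev_low` /
#' `lev_high` (positive inside WM, negative beyond the GM/WM interface or
#' ventricular wall respectively) enable sub-voxel boundary placement in
#' [solve_laplace()]; phantoms provide them analytically.
#'
#' @param labels 3D integer array.
#' @param label_map named integer vector, names from
#'   `c("background","CSF","GM","WM","ventricle")`.
#' @param affine 4x4 voxel-to-world affine (see [scalar_volume()]).
#' @param lev_low,lev_high optional 3D level-set arrays (mm or pseudo units).
#' @return An object of class `segmented_volume`.
#' @export
segmented_volume <- function(labels, label_map, affine = NULL,
                             lev_low = NULL, lev_high = NULL) {
  v <- scalar_volume(labels, affine)
  labels <- array(as.integer(labels), dim(labels))
  roles <- c("background", "CSF", "GM", "WM", "ventricle")
  if (is.null(names(label_map)) || !all(names(label_map) %in% roles))
    stop("label_map must be named with roles among: ",
         paste(roles, collapse = ", "))
  label_map <- vapply(label_map, as.integer, integer(1))
  if (!is.null(lev_low)) stopifnot(all(dim(lev_low) == dim(labels)))
  if (!is.null(lev_high)) stopifnot(all(dim(lev_high) == dim(labels)))
  structure(list(labels = labels, label_map = label_map, affine = v$affine,
                 voxel_size = v$voxel_size, lev_low = lev_low,
                 lev_high = lev_high),
            class = "segmented_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("<scalar_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, voxel size ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.segmented_volume <- function(x, ...) {
  cat("<segmented_volume> ", paste(dim(x$labels), collapse = " x "),
      " voxels; roles: ", paste(names(x$label_map), x$label_map,
                                sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

label_mask <- function(seg, role) {
  if (!role %in% names(seg$label_map)) return(array(FALSE, dim(seg$labels)))
  seg$labels == seg$label_map[[role]]
}

#' Convert world mm coordinates to 0-based voxel coordinates
#' @param vol a `scalar_volume` or `segmented_volume`.
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of continuous 0-based voxel coordinates.
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- rbind(t(xyz), 1)
  t(solve(vol$affine) %*% xyz)[, 1:3, drop = FALSE]
}

#' Convert 0-based voxel coordinates to world mm
#' @inheritParams world_to_voxel
#' @param ijk n x 3 matrix of 0-based voxel coordinates.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- rbind(t(ijk), 1)
  t(vol$affine %*% ijk)[, 1:3, drop = FALSE]
}

## ---- minimal NIfTI-1 I/O -------------------------------------------------
## No NIfTI reader ships with the supported R stack, so a minimal NIfTI-1
## codec is included: single-file .nii/.nii.gz, sform affine, datatypes
## uint8/int16/int32/uint16/float32/float64. Segmentations carry a JSON
## sidecar (<stem>.json) naming label roles and optional level-set files.

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

nifti_stem <- function(path) sub("\\.nii(\\.gz)?$", "", path)

#' Write a volume to a NIfTI-1 file
#'
#' Scalar volumes are stored as float64, segmentations as int32 with a JSON
#' sidecar holding the label map (and analytic level-set companion files if
#' present). Round trips preserve data bit-exactly and the affine to 1e-6.
#'
#' @param vol a `scalar_volume` or `segmented_volume`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) {
  seg <- inherits(vol, "segmented_volume")
  data <- if (seg) vol$labels else vol$data
  if (length(dim(data)) != 3L) stop("volume data must be 3D")
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  dims <- dim(data)
  writeBin(348L, con, size = 4)                      # sizeof_hdr
  writeBin(raw(36), con)                             # unused + dim_info
  writeBin(as.integer(c(3L, dims, 1L, 1L, 1L, 1L)), con, size = 2) # dim
  writeBin(raw(14), con)                             # intent_p1..3, intent_code
  dt <- if (seg) 8L else 64L
  bp <- if (seg) 32L else 64L
  writeBin(c(dt, bp, 0L), con, size = 2)             # datatype, bitpix, slice_start
  writeBin(c(0, vol$voxel_size, 1, 1, 1, 1), con, size = 4) # pixdim
  writeBin(c(352, 1, 0), con, size = 4)              # vox_offset, scl_slope, scl_inter
  writeBin(raw(3), con)                              # slice_end, slice_code
  writeBin(as.raw(2L), con)                          # xyzt_units = mm
  writeBin(c(0, 0, 0, 0), con, size = 4)             # cal_max/min, slice_dur, toffset
  writeBin(raw(8), con)                              # glmax, glmin
  writeBin(raw(80 + 24), con)                        # descrip, aux_file
  writeBin(c(0L, 1L), con, size = 2)                 # qform_code, sform_code
  writeBin(numeric(6), con, size = 4)                # quatern, qoffset
  writeBin(as.numeric(t(vol$affine[1:3, ])), con, size = 4) # srow_x/y/z
  writeBin(raw(16), con)                             # intent_name
  writeBin(c(as.raw(c(0x6e, 0x2b, 0x31)), raw(1)), con) # magic "n+1"
  writeBin(raw(4), con)                              # no extensions
  if (seg) writeBin(as.integer(data), con, size = 4)
  else writeBin(as.numeric(data), con, size = 8)
  sidecar <- list(label_map = if (seg) as.list(vol$label_map) else NULL)
  if (seg) {
    stem <- nifti_stem(path)
    if (!is.null(vol$lev_low)) {
      save_volume(scalar_volume(vol$lev_low, vol$affine),
                  paste0(stem, "_levlow.nii.gz"))
      sidecar$lev_low <- basename(paste0(stem, "_levlow.nii.gz"))
    }
    if (!is.null(vol$lev_high)) {
      save_volume(scalar_volume(vol$lev_high, vol$affine),
                  paste0(stem, "_levhigh.nii.gz"))
      sidecar$lev_high <- basename(paste0(stem, "_levhigh.nii.gz"))
    }
    jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a volume from a NIfTI-1 file
#'
#' If a `<stem>.json` sidecar with a `label_map` is present the result is a
#' `segmented_volume` (with level-set companions if named), otherwise a
#' `scalar_volume`.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return a `scalar_volume` or `segmented_volume`.
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  if (length(hdr) < 352) stop("truncated NIfTI header")
  rd <- function(off, what, n, size) readBin(hdr[(off + 1):352], what, n, size)
  if (rd(0, "integer", 1, 4) != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr)")
  dim0 <- rd(40, "integer", 8, 2)
  if (dim0[1] != 3L) stop("only 3D volumes are supported (ndim=", dim0[1], ")")
  dims <- dim0[2:4]
  datatype <- rd(70, "integer", 1, 2)
  pixdim <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  sform_code <- rd(254, "integer", 1, 2)
  srow <- rd(280, "double", 12, 4)
  affine <- if (sform_code > 0) {
    rbind(matrix(srow, 3, 4, byrow = TRUE), c(0, 0, 0, 1))
  } else diag(c(pixdim[2:4], 1))
  if (abs(det(affine[1:3, 1:3])) < 1e-12) stop("invalid affine in header")
  n <- prod(dims)
  skip <- vox_offset - 352
  if (skip > 0) readBin(con, "raw", skip)
  data <- switch(as.character(datatype),
    "2"   = readBin(con, "integer", n, size = 1, signed = FALSE),
    "4"   = readBin(con, "integer", n, size = 2, signed = TRUE),
    "8"   = readBin(con, "integer", n, size = 4),
    "16"  = readBin(con, "double", n, size = 4),
    "64"  = readBin(con, "double", n, size = 8),
    "512" = readBin(con, "integer", n, size = 2, signed = FALSE),
    stop("unsupported NIfTI datatype: ", datatype))
  if (length(data) < n) stop("truncated NIfTI data")
  arr <- array(data, dims)
  stem <- nifti_stem(path)
  sidecar_path <- paste0(stem, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path)
    if (!is.null(sc$label_map)) {
      lm <- unlist(sc$label_map)
      lev_low <- if (!is.null(sc$lev_low))
        load_volume(file.path(dirname(path), sc$lev_low))$data else NULL
      lev_high <- if (!is.null(sc$lev_high))
        load_volume(file.path(dirname(path), sc$lev_high))$data else NULL
      return(segmented_volume(arr, lm, affine, lev_low, lev_high))
    }
  }
  scalar_volume(arr, affine)
}
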