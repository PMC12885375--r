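#' Triangle surface mesh
#'
#' Vertices in world millimetres, 1-based face indices, and optional named
#' per-vertex maps. Closed phantom meshes use outward-pointing winding.
#'
#' @param vertices V x 3 numeric matrix (mm).
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @param maps named list of length-V per-vertex vectors.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, maps = list()) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (nrow(vertices) == 0L || ncol(vertices) != 3L) stop("empty or malformed vertex array")
  if (nrow(faces) == 0L) stop("mesh has no faces")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face index out of range (topology error)")
  keys <- apply(t(apply(faces, 1, sort)), 1, paste, collapse = "-")
  if (anyDuplicated(keys)) warning("mesh contains duplicated faces (preserved)")
  for (m in maps) if (length(m) != nrow(vertices))
    stop("per-vertex map length does not match vertex count")
  structure(list(vertices = vertices, faces = faces, maps = maps),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("<triangle_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces", if (length(x$maps)) paste0("; maps: ",
      paste(names(x$maps), collapse = ", ")), "\n", sep = "")
  invisible(x)
}

#' Per-vertex surface map
#'
#' @param values length-V numeric or integer vector (NaN/NA only where the
#'   accompanying validity flag is false).
#' @param mesh_id free-text reference to the mesh the map lives on.
#' @param units free-text units.
#' @export
surface_map <- function(values, mesh_id = "", units = "") {
  structure(list(values = values, mesh_id = mesh_id, units = units),
            class = "surface_map")
}

map_values <- function(x) if (inherits(x, "surface_map")) x$values else x

## ---- GIFTI-style XML I/O -------------------------------------------------

gii_array <- function(doc, intent, dtype, mat) {
  arr <- xml2::xml_add_child(doc, "DataArray",
    Intent = intent, DataType = dtype, ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = as.character(ifelse(is.matrix(mat), 2L, 1L)),
    Dim0 = as.character(NROW(mat)), Encoding = "ASCII",
    Endian = "LittleEndian")
  if (is.matrix(mat)) xml2::xml_set_attr(arr, "Dim1", as.character(ncol(mat)))
  txt <- if (dtype == "NIFTI_TYPE_INT32") {
    paste(as.integer(t(mat)), collapse = " ")
  } else paste(sprintf("%.17g", as.numeric(t(mat))), collapse = " ")
  xml2::xml_add_child(arr, "Data", txt)
  invisible(arr)
}

gii_read_array <- function(node) {
  dtype <- xml2::xml_attr(node, "DataType")
  d0 <- as.integer(xml2::xml_attr(node, "Dim0"))
  d1 <- xml2::xml_attr(node, "Dim1")
  txt <- xml2::xml_text(xml2::xml_find_first(node, ".//Data"))
  vals <- scan(text = txt, what = if (dtype == "NIFTI_TYPE_INT32") integer()
               else numeric(), quiet = TRUE)
  if (!is.na(d1)) matrix(vals, nrow = d0, ncol = as.integer(d1), byrow = TRUE)
  else vals
}

#' Write a triangle mesh as a GIFTI-style surface file
#'
#' Vertices and faces round-trip exactly (ASCII, full double precision;
#' faces stored 0-based per GIFTI convention). Per-vertex maps are written
#' as companion `<stem>_<name>.func.gii` files.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output path, conventionally ending in `.surf.gii` or `.gii`.
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "2")
  gii_array(doc, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT64", mesh$vertices)
  gii_array(doc, "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32", mesh$faces - 1L)
  xml2::write_xml(doc, path)
  if (length(mesh$maps)) {
    stem <- sub("(\\.surf)?\\.gii$", "", path)
    for (nm in names(mesh$maps))
      save_surface_data(mesh$maps[[nm]], paste0(stem, "_", nm, ".func.gii"))
  }
  invisible(path)
}

#' Read a triangle mesh from a GIFTI-style surface file
#' @param path path written by [save_mesh()] or a compatible ASCII GIFTI.
#' @return a `triangle_mesh`.
#' @export
load_mesh <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  intents <- xml2::xml_attr(arrays, "Intent")
  vi <- which(intents == "NIFTI_INTENT_POINTSET")[1]
  fi <- which(intents == "NIFTI_INTENT_TRIANGLE")[1]
  if (is.na(vi) || is.na(fi)) stop("not a surface GIFTI: missing pointset/triangle arrays")
  triangle_mesh(gii_read_array(arrays[[vi]]), gii_read_array(arrays[[fi]]) + 1L)
}

#' Write a per-vertex data vector as a GIFTI-style func file
#' @param values numeric vector.
#' @param path output path.
#' @export
save_surface_data <- function(values, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0", NumberOfDataArrays = "1")
  gii_array(doc, "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT64",
            as.numeric(map_values(values)))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a per-vertex data vector from a GIFTI-style func file
#' @param path path written by [save_surface_data()].
#' @return numeric vector.
#' @export
load_surface_data <- function(path) {
  doc <- xml2::read_xml(path)
  gii_read_array(xml2::xml_find_first(doc, ".//DataArray"))
}

## ---- mesh geometry -------------------------------------------------------

#' Mesh geometry: adjacency, areas, normals, mean curvature
#'
#' Vertex areas are one third of incident triangle areas (they sum to the
#' total surface area). Normals are area-weighted averages of face normals.
#' Mean curvature uses the umbrella estimator
#' `H_i = 2 (v_i - mean(neighbors)) . n_i / mean(|v_j - v_i|^2)`,
#' which is positive where the surface bulges along the outward normal
#' (sphere of radius r with outward normals: H = 1/r). On a GM/WM surface
#' with normals pointing out of the white matter this makes sulcal fundi
#' positive; the sign convention travels with the mesh winding.
#'
#' @param mesh a `triangle_mesh`.
#' @return list with `adjacency` (list of 1-ring neighbor indices),
#'   `vertex_areas` (mm^2), `normals` (V x 3 unit vectors),
#'   `mean_curvature` (1/mm).
#' @export
mesh_geometry <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  nv <- nrow(v)
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  fa <- 0.5 * sqrt(rowSums(cr^2))
  degen <- fa <= .Machine$double.eps
  if (any(degen)) warning(sum(degen), " zero-area face(s) excluded from area accumulation")
  va <- numeric(nv)
  for (c_ in 1:3) {
    acc <- tapply(fa[!degen], f[!degen, c_], sum)
    va[as.integer(names(acc))] <- va[as.integer(names(acc))] + acc / 3
  }
  nrm <- matrix(0, nv, 3)
  for (c_ in 1:3) for (d in 1:3) {
    acc <- tapply(cr[, d], f[, c_], sum)
    nrm[as.integer(names(acc)), d] <- nrm[as.integer(names(acc)), d] + acc
  }
  nlen <- sqrt(rowSums(nrm^2))
  nrm <- nrm / pmax(nlen, 1e-300)
  adj <- mesh_adjacency(mesh)
  H <- vapply(seq_len(nv), function(i) {
    nb <- adj[[i]]
    if (length(nb) < 3) return(NA_real_)
    d <- v[nb, , drop = FALSE] - matrix(v[i, ], length(nb), 3, byrow = TRUE)
    msq <- mean(rowSums(d^2))
    if (msq <= 0) return(NA_real_)
    2 * sum((v[i, ] - colMeans(v[nb, , drop = FALSE])) * nrm[i, ]) / msq
  }, numeric(1))
  list(adjacency = adj, vertex_areas = va, normals = nrm, mean_curvature = H)
}

mesh_adjacency <- function(mesh) {
  f <- mesh$faces
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ed <- unique(rbind(ed, ed[, 2:1]))
  split(ed[, 2], factor(ed[, 1], levels = seq_len(nrow(mesh$vertices))))
}

mesh_edges <- function(mesh) {
  f <- mesh$faces
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ed <- t(apply(ed, 1, sort))
  unique(ed)
}

#' Graph geodesic distances along mesh edges
#'
#' Shortest-path distance with Euclidean edge weights (Dijkstra via igraph).
#' An upper bound on — and for coarse thresholds a stand-in for — the exact
#' polyhedral geodesic. Disconnected vertices get `Inf`.
#'
#' @param mesh a `triangle_mesh`.
#' @param sources integer vertex indices (1-based).
#' @return length(sources) x V matrix of distances in mm.
#' @export
geodesic_distances <- function(mesh, sources) {
  ed <- mesh_edges(mesh)
  w <- sqrt(rowSums((mesh$vertices[ed[, 1], , drop = FALSE] -
                     mesh$vertices[ed[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$vertices) - igraph::vcount(g)))
  d <- igraph::distances(g, v = sources, weights = w, algorithm = "dijkstra")
  unname(as.matrix(d))
}

## ---- mesh constructors ---------------------------------------------------

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere; outward winding.
#'
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-to-1 subdivision passes.
#' @param center length-3 center (mm).
#' @return a `triangle_mesh` with `10 * 4^subdivisions + 2` vertices.
#' @export
icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(hash = TRUE)
    nf <- matrix(0L, nrow(f) * 4, 3)
    vlist <- list(v)
    nv <- nrow(v)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(m <- midcache[[key]])) return(m)
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- (v[a, ] + v[b, ]) / 2
      midcache[[key]] <- nv
      nv
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(c_, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, center, "+")
  triangle_mesh(v, f)
}

#' Quasi-uniform points on a sphere (Fibonacci lattice)
#'
#' Spherical registration coordinates for an arbitrary vertex count
#' (icospheres only come in counts `10 * 4^k + 2`). Points are ordered by
#' z, so an index-linear map is spatially smooth pole-to-pole.
#'
#' @param n number of points.
#' @param radius sphere radius.
#' @return n x 3 matrix of coordinates.
#' @export
fibonacci_sphere <- function(n, radius = 1) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  rho <- sqrt(pmax(1 - z^2, 0))
  radius * cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Regular grid mesh of a plane
#'
#' Rectangular grid in the xy-plane at height `z`, triangulated with
#' consistent winding so normals point along +z.
#'
#' @param xs,ys vertex coordinates along x and y (mm).
#' @param z plane height (mm).
#' @return a `triangle_mesh` with `length(xs) * length(ys)` vertices.
#' @export
plane_mesh <- function(xs, ys, z = 0) {
  nx <- length(xs); ny <- length(ys)
  g <- expand.grid(x = xs, y = ys)
  v <- cbind(g$x, g$y, z)
  idx <- function(i, j) (j - 1L) * nx + i
  fl <- vector("list", (nx - 1) * (ny - 1))
  k <- 0L
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    k <- k + 1L
    fl[[k]] <- rbind(c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                     c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  triangle_mesh(v, do.call(rbind, fl))
}
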