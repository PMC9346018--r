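# Tetrahedral cartilage meshes: prismatic extrusion of the articular surface
# toward the bone bed, split into conforming 4-node tetrahedra.

#' Scale a cartilage thickness map
#'
#' Sensitivity envelope of +/-40% around the nominal map.
#'
#' @param map per-vertex thickness vector (mm; `NA` outside cartilage).
#' @param factor multiplier in `[0.6, 1.4]`.
#' @return scaled map.
#' @export
scale_thickness <- function(map, factor) {
  check_range(factor, "factor", 0.6, 1.4)
  map * factor
}

#' Extrude the cartilage patch of a surface into a tetrahedral mesh
#'
#' The cartilage-labeled patch is offset along inward vertex normals by the
#' local thickness, in `layers` sheets; each prism is split into three
#' tetrahedra with globally consistent diagonals. Sheet 0 (the original
#' surface) becomes the `articular_surface` node set, the innermost sheet the
#' `bone_interface` set.
#'
#' @param surface a `surface_mesh` (closed shell with cartilage labels).
#' @param thickness per-vertex thickness map (mm).
#' @param layers number of element layers through the thickness (>= 1).
#' @param part part label (`"femoral"` or `"patellar"`).
#' @return object of class `tet_mesh`: `nodes`, `tets`, `part`, `node_sets`
#'   (`articular_surface`, `bone_interface`, `rim`), `surf_tris` (articular
#'   surface triangles, outward orientation), `n_surf` (vertices per sheet).
#' @export
extrude_cartilage <- function(surface, thickness, layers = 2, part = "femoral") {
  stopifnot(inherits(surface, "surface_mesh"))
  if (layers < 1) pf_stop("layers must be >= 1", class = "patellofem_config_error")
  keep_tri <- which(cartilage_triangles(surface))
  if (!length(keep_tri)) pf_stop("surface has no cartilage patch to extrude")
  tri_all <- surface$triangles[keep_tri, , drop = FALSE]
  vids <- sort(unique(as.vector(tri_all)))
  t_loc <- thickness[vids]
  if (anyNA(t_loc) || any(t_loc <= 0)) {
    pf_stop("thickness map must be positive on every cartilage vertex")
  }
  nv <- length(vids)
  tri <- matrix(match(as.vector(tri_all), vids), ncol = 3)
  vn <- vertex_normals(surface)[vids, , drop = FALSE]  # outward
  base <- surface$vertices[vids, , drop = FALSE]

  nodes <- matrix(0, nv * (layers + 1), 3)
  for (l in 0:layers) {
    nodes[l * nv + seq_len(nv), ] <- base - (l / layers) * t_loc * vn
  }
  tets <- matrix(0L, nrow(tri) * 3L * layers, 4L)
  row0 <- 0L
  for (l in seq_len(layers)) {
    bot <- (l - 1L) * nv
    top <- l * nv
    pr <- split_prisms(tri, bot, top)
    tets[row0 + seq_len(nrow(pr)), ] <- pr
    row0 <- row0 + nrow(pr)
  }
  vol <- tet_volumes(nodes, tets)
  neg <- vol < 0
  if (any(neg)) {  # enforce positive orientation
    tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
    vol <- abs(vol)
  }
  if (any(vol < 1e-9)) {
    bad <- which(vol < 1e-9)[1]
    pf_stop(sprintf(
      "degenerate/inverted extrusion near surface vertices %s (thickness exceeds local curvature radius?)",
      paste(vids[(tets[bad, ] - 1) %% nv + 1], collapse = ", ")))
  }
  bnd <- boundary_vertices(tri)
  rim <- as.integer(unlist(lapply(seq_len(layers - 1L),
                                  function(l) l * nv + bnd)))
  structure(list(
    nodes = nodes, tets = tets, part = part,
    node_sets = list(articular_surface = seq_len(nv),
                     bone_interface = layers * nv + seq_len(nv),
                     rim = rim),
    surf_tris = tri,                 # sheet-0 indices, original orientation
    surf_boundary = bnd,             # open boundary of the articular patch
    surf_vertex_ids = vids,          # map back into the shell mesh
    n_surf = nv, layers = layers,
    volumes = vol
  ), class = "tet_mesh")
}

# split the prism stack between sheet offsets bot/top into 3 tets per prism
# with consistent diagonals (lowest-global-index rule), so adjacent prisms
# share quad-face diagonals and the mesh is conforming
#' @noRd
split_prisms <- function(tri, bot, top) {
  n <- nrow(tri)
  out <- matrix(0L, 3L * n, 4L)
  for (e in seq_len(n)) {
    v <- tri[e, ]
    r <- which.min(v)                     # rotate so the smallest index leads
    ord <- ((r - 1L + 0:2) %% 3L) + 1L
    p <- c(v[ord] + bot, v[ord] + top)    # prism nodes 1-6 (bottom, top)
    if (min(p[2], p[6]) < min(p[3], p[5])) {
      t3 <- rbind(p[c(1, 2, 3, 6)], p[c(1, 2, 6, 5)], p[c(1, 5, 6, 4)])
    } else {
      t3 <- rbind(p[c(1, 2, 3, 5)], p[c(1, 5, 3, 6)], p[c(1, 5, 6, 4)])
    }
    out[(3 * e - 2):(3 * e), ] <- t3
  }
  out
}

#' Signed volumes of tetrahedra
#' @param nodes n x 3 node coordinates.
#' @param tets m x 4 connectivity.
#' @return numeric vector of signed volumes (mm^3).
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh (%s): %d nodes, %d tets, %d layers\n",
              x$part, nrow(x$nodes), nrow(x$tets), x$layers))
  invisible(x)
}

#' Write a tet mesh (with optional fields) as legacy-ASCII VTK
#'
#' @param mesh a `tet_mesh`.
#' @param path output `.vtk` path.
#' @param point_data named list of per-node scalar vectors.
#' @param cell_data named list of per-element scalar vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", "patellofem tet mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                     mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", point_data[[nm]]), con)
    }
  }
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", cell_data[[nm]]), con)
    }
  }
  invisible(path)
}
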