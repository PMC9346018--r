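# Triangulated surface shells with per-vertex region labels.

#' Construct a labeled triangle surface mesh
#'
#' @param vertices numeric n x 3 matrix (mm).
#' @param triangles integer m x 3 matrix of 1-based vertex indices with
#'   consistent (outward) orientation.
#' @param region character vector of length n, each `"cartilage"` or `"bone"`.
#' @param side `"left"` or `"right"`.
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, region = NULL, side = "right") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(triangles) <- NULL
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3)
  if (is.null(region)) region <- rep("bone", nrow(vertices))
  stopifnot(length(region) == nrow(vertices))
  if (!all(region %in% c("cartilage", "bone"))) {
    pf_stop("region labels must be 'cartilage' or 'bone'")
  }
  if (!side %in% c("left", "right")) pf_stop("side must be 'left' or 'right'")
  structure(list(vertices = vertices, triangles = triangles,
                 region = region, side = side),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles (%d cartilage vertices), %s side\n",
              nrow(x$vertices), nrow(x$triangles),
              sum(x$region == "cartilage"), x$side))
  invisible(x)
}

# per-triangle unnormalized normals (cross products); n x 3
#' @noRd
triangle_cross <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c_ <- v[tr[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Triangle areas of a surface mesh
#' @param mesh a `surface_mesh`.
#' @return numeric vector of areas (mm^2).
#' @export
triangle_areas <- function(mesh) 0.5 * row_norms(triangle_cross(mesh))

#' Unit triangle normals
#' @param mesh a `surface_mesh`.
#' @return m x 3 matrix of outward unit normals.
#' @export
triangle_normals <- function(mesh) {
  cr <- triangle_cross(mesh)
  n <- row_norms(cr)
  if (any(n < 1e-12)) pf_stop("mesh contains zero-area triangles")
  cr / n
}

#' Area-weighted outward vertex normals
#' @param mesh a `surface_mesh`.
#' @return n x 3 matrix of unit vertex normals.
#' @export
vertex_normals <- function(mesh) {
  cr <- triangle_cross(mesh)  # area-weighted facet normals (2A n)
  vn <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    idx <- mesh$triangles[, k]
    vn[, 1] <- vn[, 1] + tapply_add(cr[, 1], idx, nrow(vn))
    vn[, 2] <- vn[, 2] + tapply_add(cr[, 2], idx, nrow(vn))
    vn[, 3] <- vn[, 3] + tapply_add(cr[, 3], idx, nrow(vn))
  }
  n <- row_norms(vn)
  n[n < 1e-14] <- 1
  vn / n
}

# scatter-add x into a length-n accumulator by index
#' @noRd
tapply_add <- function(x, idx, n) {
  out <- numeric(n)
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# enclosed signed volume of a closed shell (divergence theorem); positive for
# outward-oriented triangles
#' @noRd
shell_signed_volume <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c_ <- vertices[triangles[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cr)) / 6
}

# flip a consistently-oriented closed shell to outward orientation if needed
#' @noRd
orient_outward <- function(vertices, triangles) {
  if (shell_signed_volume(vertices, triangles) < 0) triangles[, c(1, 3, 2)]
  else triangles
}

# sorted edge list (each row i<j), one row per half-edge
#' @noRd
mesh_edges <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Check that a surface mesh is a closed (watertight) shell
#'
#' Every undirected edge must be shared by exactly two triangles with opposite
#' orientation.
#'
#' @param mesh a `surface_mesh`.
#' @return `TRUE`/`FALSE`.
#' @export
is_watertight <- function(mesh) {
  e <- mesh_edges(mesh$triangles)
  key <- paste(e[, 1], e[, 2])
  all(table(key) == 2)
}

#' Boundary vertices of an open mesh region
#' @noRd
boundary_vertices <- function(triangles) {
  e <- mesh_edges(triangles)
  key <- paste(e[, 1], e[, 2])
  single <- names(table(key))[table(key) == 1]
  if (!length(single)) return(integer(0))
  parts <- do.call(rbind, strsplit(single, " "))
  sort(unique(as.integer(parts)))
}

#' Mirror a surface mesh across the sagittal (x = 0) plane
#'
#' Flips the x coordinate, reverses triangle orientation to keep outward
#' normals, and toggles the side flag.
#'
#' @param mesh a `surface_mesh`.
#' @return mirrored `surface_mesh`.
#' @export
mirror_mesh <- function(mesh) {
  v <- mesh$vertices
  v[, 1] <- -v[, 1]
  surface_mesh(v, mesh$triangles[, c(1, 3, 2)], mesh$region,
               side = if (mesh$side == "right") "left" else "right")
}

#' Total area of the cartilage-labeled patch
#' @param mesh a `surface_mesh`.
#' @return area (mm^2) of triangles whose three vertices are cartilage.
#' @export
cartilage_area <- function(mesh) {
  keep <- cartilage_triangles(mesh)
  sum(triangle_areas(mesh)[keep])
}

# logical mask of triangles fully inside the cartilage patch
#' @noRd
cartilage_triangles <- function(mesh) {
  lab <- mesh$region == "cartilage"
  lab[mesh$triangles[, 1]] & lab[mesh$triangles[, 2]] & lab[mesh$triangles[, 3]]
}

# connected components of the cartilage patch (by shared edges); returns count
#' @noRd
cartilage_patch_count <- function(mesh) {
  keep <- which(cartilage_triangles(mesh))
  if (!length(keep)) return(0L)
  tr <- mesh$triangles[keep, , drop = FALSE]
  verts <- sort(unique(as.vector(tr)))
  comp <- seq_along(verts)
  names(comp) <- verts
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  vi <- match(as.vector(tr), verts)
  dim(vi) <- dim(tr)
  for (r in seq_len(nrow(vi))) {
    a <- find(vi[r, 1]); b <- find(vi[r, 2]); c_ <- find(vi[r, 3])
    comp[b] <- a; comp[find(c_)] <- a
  }
  length(unique(vapply(seq_along(verts), find, integer(1))))
}
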