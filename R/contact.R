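# Node-to-surface contact detection: deterministic spatial-hash broadphase on
# the (x, z) plane (both articular surfaces are height fields over it in the
# contact zone) plus exact closest-point projection onto candidate triangles.

# grid index helpers
#' @noRd
grid_key <- function(ix, iz, nx) (iz - 1L) * nx + ix

#' Build a spatial hash of triangles over the (x, z) plane
#' @noRd
triangle_hash <- function(verts, tris, cell = NULL) {
  xs <- matrix(verts[tris, 1], ncol = 3)
  zs <- matrix(verts[tris, 3], ncol = 3)
  xmin <- pmin(xs[, 1], xs[, 2], xs[, 3]); xmax <- pmax(xs[, 1], xs[, 2], xs[, 3])
  zmin <- pmin(zs[, 1], zs[, 2], zs[, 3]); zmax <- pmax(zs[, 1], zs[, 2], zs[, 3])
  if (is.null(cell)) cell <- max(stats::quantile(xmax - xmin, 0.9),
                                 stats::quantile(zmax - zmin, 0.9), 0.5)
  x0 <- min(xmin) - cell; z0 <- min(zmin) - cell
  nx <- max(1L, ceiling((max(xmax) - x0) / cell) + 2L)
  nz <- max(1L, ceiling((max(zmax) - z0) / cell) + 2L)
  # register each triangle in every cell its (inflated) bbox overlaps
  ix1 <- pmax(1L, floor((xmin - x0) / cell) + 1L); ix2 <- pmin(nx, floor((xmax - x0) / cell) + 1L)
  iz1 <- pmax(1L, floor((zmin - z0) / cell) + 1L); iz2 <- pmin(nz, floor((zmax - z0) / cell) + 1L)
  keys <- integer(0); tids <- integer(0)
  for (t in seq_len(nrow(tris))) {
    gx <- ix1[t]:ix2[t]; gz <- iz1[t]:iz2[t]
    kk <- as.vector(outer(gx, gz, function(a, b) grid_key(a, b, nx)))
    keys <- c(keys, kk); tids <- c(tids, rep(t, length(kk)))
  }
  buckets <- split(tids, keys)
  list(buckets = buckets, cell = cell, x0 = x0, z0 = z0, nx = nx, nz = nz)
}

#' @noRd
hash_candidates <- function(hash, pts) {
  ix <- pmax(1L, pmin(hash$nx, floor((pts[, 1] - hash$x0) / hash$cell) + 1L))
  iz <- pmax(1L, pmin(hash$nz, floor((pts[, 3] - hash$z0) / hash$cell) + 1L))
  keys <- as.character(grid_key(ix, iz, hash$nx))
  hash$buckets[keys]
}

# exact closest point on triangles, vectorized over (point, triangle) pairs
# (Ericson, Real-Time Collision Detection); returns closest points and
# barycentric weights
#' @noRd
closest_point_pairs <- function(p, a, b, c_) {
  ab <- b - a; ac <- c_ - a
  ap <- p - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- p - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- p - c_
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  n <- nrow(p)
  u <- numeric(n); v <- numeric(n); w <- numeric(n)
  done <- logical(n)
  set_bary <- function(mask, uu, vv, ww) {
    m <- mask & !done
    u[m] <<- uu[m]; v[m] <<- vv[m]; w[m] <<- ww[m]
    done[m] <<- TRUE
  }
  one <- rep(1, n); zero <- numeric(n)
  set_bary(d1 <= 0 & d2 <= 0, one, zero, zero)                      # vertex a
  set_bary(d3 >= 0 & d4 <= d3, zero, one, zero)                     # vertex b
  t_ab <- d1 / (d1 - d3)
  set_bary(vc <= 0 & d1 >= 0 & d3 <= 0, 1 - t_ab, t_ab, zero)       # edge ab
  set_bary(d6 >= 0 & d5 <= d6, zero, zero, one)                     # vertex c
  t_ac <- d2 / (d2 - d6)
  set_bary(vb <= 0 & d2 >= 0 & d6 <= 0, 1 - t_ac, zero, t_ac)       # edge ac
  t_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set_bary(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0,
           zero, 1 - t_bc, t_bc)                                    # edge bc
  denom <- va + vb + vc
  vv <- vb / denom; ww <- vc / denom
  set_bary(!done, 1 - vv - ww, vv, ww)                              # interior
  list(point = a * u + b * v + c_ * w, bary = cbind(u, v, w))
}

#' Signed gaps from points to a triangulated surface
#'
#' For each query point: closest point on the surface (spatial-hash
#' candidates, exact projection) and the separation along the triangle's
#' outward normal. Positive `gap` = separated, negative = penetrating.
#'
#' @param points n x 3 query points.
#' @param verts,tris surface vertices and (outward-oriented) triangles.
#' @param hash optional precomputed hash (from repeated queries).
#' @param vnormals optional per-vertex outward normals; when given, the
#'   returned normal (and the gap sign) use the barycentric interpolation of
#'   the vertex normals, which is continuous across triangle edges — the
#'   smoothness the Newton solver needs.
#' @return list with `gap`, `tri` (triangle index, NA if no candidate),
#'   `bary` (n x 3), `normal` (n x 3), `point` (closest points).
#' @export
point_surface_gaps <- function(points, verts, tris, hash = NULL,
                               vnormals = NULL, boundary = NULL) {
  if (is.null(hash)) hash <- triangle_hash(verts, tris)
  cand <- hash_candidates(hash, points)
  n_cand <- vapply(cand, function(x) if (is.null(x)) 0L else length(x), integer(1))
  n <- nrow(points)
  out_gap <- rep(Inf, n); out_tri <- rep(NA_integer_, n)
  out_bary <- matrix(NA_real_, n, 3); out_norm <- matrix(NA_real_, n, 3)
  out_pt <- matrix(NA_real_, n, 3)
  has <- which(n_cand > 0L)
  if (!length(has)) {
    return(list(gap = out_gap, tri = out_tri, bary = out_bary,
                normal = out_norm, point = out_pt))
  }
  pid <- rep(has, n_cand[has])
  tid <- unlist(cand[has], use.names = FALSE)
  p <- points[pid, , drop = FALSE]
  a <- verts[tris[tid, 1], , drop = FALSE]
  b <- verts[tris[tid, 2], , drop = FALSE]
  c_ <- verts[tris[tid, 3], , drop = FALSE]
  cp <- closest_point_pairs(p, a, b, c_)
  if (!is.null(boundary)) {
    # reject projections clamped onto the open boundary of the master patch:
    # their pseudo-normals produce spurious deep "penetrations" for nodes
    # that have slid past the patch edge
    on_b <- logical(nrow(verts))
    on_b[boundary] <- TRUE
    vb <- cbind(on_b[tris[tid, 1]], on_b[tris[tid, 2]], on_b[tris[tid, 3]])
    clamped <- cp$bary < 1e-9
    bad <- rowSums(clamped) > 0 &
      rowSums((!clamped) & !vb) == 0  # all carrying vertices on the boundary
    if (any(bad)) {
      keep <- !bad
      pid <- pid[keep]; tid <- tid[keep]
      p <- p[keep, , drop = FALSE]; a <- a[keep, , drop = FALSE]
      b <- b[keep, , drop = FALSE]; c_ <- c_[keep, , drop = FALSE]
      cp$point <- cp$point[keep, , drop = FALSE]
      cp$bary <- cp$bary[keep, , drop = FALSE]
      if (!length(pid)) {
        return(list(gap = out_gap, tri = out_tri, bary = out_bary,
                    normal = out_norm, point = out_pt))
      }
    }
  }
  d <- p - cp$point
  dist <- row_norms(d)
  if (is.null(vnormals)) {
    # outward facet normal
    e1 <- b - a; e2 <- c_ - a
    nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  } else {
    nrm <- cp$bary[, 1] * vnormals[tris[tid, 1], , drop = FALSE] +
      cp$bary[, 2] * vnormals[tris[tid, 2], , drop = FALSE] +
      cp$bary[, 3] * vnormals[tris[tid, 3], , drop = FALSE]
  }
  nrm <- nrm / pmax(row_norms(nrm), 1e-14)
  if (is.null(vnormals)) {
    side <- sign(rowSums(d * nrm))
    sdist <- dist * ifelse(side == 0, 1, side)
  } else {
    # signed projection onto the smoothed normal field: continuous in the
    # query point even across the surface (unlike distance x side)
    sdist <- rowSums(d * nrm)
  }
  # per point: keep the pair with the smallest absolute distance
  ord <- order(pid, dist)
  first <- ord[!duplicated(pid[ord])]
  out_gap[pid[first]] <- sdist[first]
  out_tri[pid[first]] <- tid[first]
  out_bary[pid[first], ] <- cp$bary[first, , drop = FALSE]
  out_norm[pid[first], ] <- nrm[first, , drop = FALSE]
  out_pt[pid[first], ] <- cp$point[first, , drop = FALSE]
  list(gap = out_gap, tri = out_tri, bary = out_bary, normal = out_norm,
       point = out_pt)
}

#' Detect contact between a slave node set and a master surface
#'
#' Node-to-surface pairing via spatial hashing. The returned signed gap
#' follows the penetration convention: positive = penetration depth,
#' negative = open.
#'
#' @param slave_points n x 3 current (displaced) slave node positions.
#' @param master_verts,master_tris current master surface.
#' @param hash optional precomputed spatial hash of the master surface.
#' @param vnormals optional master vertex normals (see
#'   [point_surface_gaps()]).
#' @return data-frame-like list with `node`, `tri`, `penetration`, `bary`,
#'   `normal`; only candidate pairs (those with a located projection) are
#'   returned, and `active` flags penetration > 0.
#' @export
detect_contact <- function(slave_points, master_verts, master_tris,
                           hash = NULL, vnormals = NULL, boundary = NULL) {
  g <- point_surface_gaps(slave_points, master_verts, master_tris, hash,
                          vnormals, boundary)
  found <- which(is.finite(g$gap))
  list(node = found, tri = g$tri[found],
       penetration = -g$gap[found],
       bary = g$bary[found, , drop = FALSE],
       normal = g$normal[found, , drop = FALSE],
       active = -g$gap[found] > 0)
}
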