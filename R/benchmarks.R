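# Verification benchmarks with closed-form oracles: structured slab meshes,
# confined compression, linear patch test, and rigid-sphere indentation
# checked against the elastic-foundation and Hertz predictions.

#' Structured tetrahedral box mesh
#'
#' Nodes on a (optionally graded) grid over `[-Lx/2, Lx/2] x [-Ly/2, Ly/2] x
#' [0, Lz]`, each hex cell split into six tetrahedra with a consistent
#' (Kuhn) pattern, so the mesh is conforming.
#'
#' @param nx,ny,nz cells per direction.
#' @param Lx,Ly,Lz box dimensions (mm).
#' @param grade_xy radial grading exponent toward the (0, 0) axis (1 =
#'   uniform; > 1 refines the center of the top face).
#' @return a `tet_mesh`-classed list with `node_sets` `bottom`, `top` and
#'   `top_tris` (top-surface triangles for contact).
#' @export
box_tet_mesh <- function(nx, ny, nz, Lx, Ly, Lz, grade_xy = 1) {
  gr <- function(n, L) {
    s <- seq(-1, 1, length.out = n + 1)
    L / 2 * sign(s) * abs(s)^grade_xy
  }
  xs <- gr(nx, Lx); ys <- gr(ny, Ly)
  zs <- seq(0, Lz, length.out = nz + 1)
  nid <- function(i, j, k) {
    as.integer(i + (nx + 1L) * (j - 1L) + (nx + 1L) * (ny + 1L) * (k - 1L))
  }
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  # Kuhn subdivision of each hex into 6 tets sharing the main diagonal
  kuhn <- rbind(c(1, 2, 4, 8), c(1, 2, 8, 6), c(1, 6, 8, 5),
                c(1, 4, 3, 8), c(1, 3, 7, 8), c(1, 7, 5, 8))
  tets <- matrix(0L, 6L * nx * ny * nz, 4L)
  r <- 0L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    corners <- c(nid(i, j, k), nid(i + 1L, j, k), nid(i, j + 1L, k),
                 nid(i + 1L, j + 1L, k), nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
                 nid(i, j + 1L, k + 1L), nid(i + 1L, j + 1L, k + 1L))
    tets[r + 1:6, ] <- matrix(corners[t(kuhn)], 6, 4, byrow = TRUE)
    r <- r + 6L
  }
  vol <- tet_volumes(nodes, tets)
  flip <- vol < 0
  tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  top_k <- nz + 1L
  top_ids <- as.integer(vapply(seq_len(ny + 1L), function(j)
    vapply(seq_len(nx + 1L), function(i) nid(i, j, top_k), integer(1)),
    integer(nx + 1L)))
  bottom_ids <- as.integer(vapply(seq_len(ny + 1L), function(j)
    vapply(seq_len(nx + 1L), function(i) nid(i, j, 1L), integer(1)),
    integer(nx + 1L)))
  # top-surface triangulation consistent with the hex splits
  tt <- matrix(0L, 2L * nx * ny, 3L)
  r <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    a <- nid(i, j, top_k); b <- nid(i + 1L, j, top_k)
    c_ <- nid(i, j + 1L, top_k); d <- nid(i + 1L, j + 1L, top_k)
    tt[r + 1L, ] <- c(a, b, d); tt[r + 2L, ] <- c(a, d, c_)
    r <- r + 2L
  }
  structure(list(nodes = nodes, tets = tets, part = "slab",
                 node_sets = list(bottom = bottom_ids, top = top_ids),
                 top_tris = tt, volumes = abs(vol), layers = nz),
            class = "tet_mesh")
}

#' Linear patch test
#'
#' Imposes an affine displacement field on the boundary nodes of a mesh and
#' solves for the interior; a conforming constant-strain discretization must
#' reproduce the field exactly.
#'
#' @param mesh a `tet_mesh`.
#' @param m a `material_params`.
#' @param A 3 x 3 displacement gradient; default a mixed stretch/shear.
#' @param b translation.
#' @return max absolute nodal error, relative to the field magnitude.
#' @export
patch_test <- function(mesh, m, A = NULL, b = c(0.001, -0.002, 0.0005)) {
  if (is.null(A)) {
    A <- matrix(c(0.002, 0.001, 0, 0.0005, -0.001, 0.0003,
                  0, 0.0008, 0.0015), 3, 3, byrow = TRUE)
  }
  K <- assemble_stiffness(mesh, m)
  u_exact <- t(A %*% t(mesh$nodes) + b)
  nn <- nrow(mesh$nodes)
  on_bnd <- rep(FALSE, nn)
  rng <- apply(mesh$nodes, 2, range)
  for (d in 1:3) {
    on_bnd <- on_bnd | abs(mesh$nodes[, d] - rng[1, d]) < 1e-9 |
      abs(mesh$nodes[, d] - rng[2, d]) < 1e-9
  }
  fixed_dofs <- as.vector(outer(1:3, which(on_bnd), function(a, n) 3 * (n - 1) + a))
  free_dofs <- setdiff(seq_len(3 * nn), fixed_dofs)
  u <- as.vector(t(u_exact))
  rhs <- -K[free_dofs, fixed_dofs] %*% u[fixed_dofs]
  u_free <- Matrix::solve(K[free_dofs, free_dofs], rhs)
  err <- max(abs(as.numeric(u_free) - u[free_dofs]))
  err / max(abs(u))
}

#' Confined compression of a box
#'
#' Lateral and bottom faces constrained along their normals, a prescribed
#' axial strain on the top face: the axial stress must equal the constrained
#' modulus times the strain, and the equivalent stress obeys
#' `VMes = |sigma_axial| (1 - 2 nu) / (1 - nu)`.
#'
#' @param m a `material_params`.
#' @param strain applied compressive strain (positive number).
#' @param n cells per direction of the unit cube.
#' @return list with `sigma_axial` (MPa, compression negative), `vmes`,
#'   `expected_sigma`, `expected_vmes`.
#' @export
confined_compression <- function(m, strain = 0.01, n = 2) {
  mesh <- box_tet_mesh(n, n, n, 1, 1, 1)
  K <- assemble_stiffness(mesh, m)
  nn <- nrow(mesh$nodes)
  u <- numeric(3 * nn)
  fixed <- logical(3 * nn)
  at <- function(d, v) abs(mesh$nodes[, d] - v) < 1e-9
  for (cond in list(list(at(1, -0.5) | at(1, 0.5), 1L, 0),
                    list(at(2, -0.5) | at(2, 0.5), 2L, 0),
                    list(at(3, 0), 3L, 0),
                    list(at(3, 1), 3L, -strain))) {
    dofs <- 3L * (which(cond[[1]]) - 1L) + cond[[2]]
    u[dofs] <- cond[[3]]
    fixed[dofs] <- TRUE
  }
  free <- which(!fixed)
  if (length(free)) {
    u[free] <- as.numeric(Matrix::solve(K[free, free, drop = FALSE],
                                        -K[free, which(fixed), drop = FALSE] %*% u[fixed]))
  }
  es <- element_stress(mesh, m, u)
  M <- constrained_modulus(m)
  list(sigma_axial = mean(es$stress[, "zz"]), vmes = mean(es$vmes),
       expected_sigma = -strain * M,
       expected_vmes = strain * M * (1 - 2 * m$nu) / (1 - m$nu))
}

#' Press a rigid sphere into a bonded elastic slab
#'
#' Displacement-controlled penalty contact between an analytic sphere and the
#' slab's top surface, with an outer secant iteration on the indentation
#' depth when a target force is requested. Used for the elastic-foundation
#' oracle (thin bonded layer, `F = pi R k_f delta^2`, `p(0) = k_f delta`,
#' `k_f = E(1-nu)/((1+nu)(1-2nu) t)`) and, on a thick slab with
#' compressible material, the Hertz oracle
#' `p0 = (6 F E*^2 / (pi^3 R^2))^(1/3)`.
#'
#' @param mesh a slab mesh from [box_tet_mesh()].
#' @param m a `material_params`.
#' @param R sphere radius (mm).
#' @param force target total normal force (N); alternatively fix `depth`.
#' @param depth indentation depth (mm) if force is `NULL`.
#' @param penalty contact penalty stiffness (MPa/mm).
#' @param tol relative force tolerance of the outer iteration.
#' @return list with `depth`, `force`, `peak_pressure` (MPa), `pressures`
#'   (per top node), `contact_radius` (mm), `u` (displacements).
#' @export
indent_sphere <- function(mesh, m, R, force = NULL, depth = NULL,
                          penalty = 200, tol = 1e-3) {
  if (is.null(force) && is.null(depth)) pf_stop("give force or depth")
  K <- assemble_stiffness(mesh, m)
  nn <- nrow(mesh$nodes)
  fixed <- 3L * (rep(mesh$node_sets$bottom, each = 3) - 1L) + rep(1:3, length(mesh$node_sets$bottom))
  free <- setdiff(seq_len(3 * nn), fixed)
  Kff <- K[free, free]
  top <- mesh$node_sets$top
  Lz <- max(mesh$nodes[, 3])
  # tributary areas of the top nodes
  ar <- triangle_areas(surface_mesh(mesh$nodes, mesh$top_tris))
  trib <- numeric(nn)
  for (k in 1:3) trib <- trib + tapply_add(ar / 3, mesh$top_tris[, k], nn)
  trib <- trib[top]

  freepos <- integer(3 * nn)
  freepos[free] <- seq_along(free)
  solve_at_depth <- function(delta, u0 = NULL) {
    center <- c(0, 0, Lz + R - delta)
    u <- if (is.null(u0)) numeric(3 * nn) else u0
    act <- integer(0); nrm <- NULL; pen <- numeric(0)
    for (it in 1:30) {
      pos <- mesh$nodes[top, ] + matrix(u[as.vector(t(outer(3 * (top - 1), 1:3, `+`)))],
                                        ncol = 3, byrow = TRUE)
      d <- sweep(pos, 2, center)
      dist <- row_norms(d)
      pen <- R - dist
      act <- which(pen > 0)
      F_ext <- numeric(3 * nn)
      trips <- NULL
      if (length(act)) {
        nrm <- -d[act, , drop = FALSE] / dist[act]   # push outward from sphere
        coef <- penalty * trib[act] * pen[act]
        dofs <- 3L * (top[act] - 1L)
        for (a in 1:3) F_ext[dofs + a] <- F_ext[dofs + a] - coef * nrm[, a]
        ii <- jj <- vector("list", 9); xx <- vector("list", 9); s <- 0L
        for (a in 1:3) for (b in 1:3) {
          s <- s + 1L
          ii[[s]] <- freepos[dofs + a]; jj[[s]] <- freepos[dofs + b]
          xx[[s]] <- penalty * trib[act] * nrm[, a] * nrm[, b]
        }
        trips <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                      x = unlist(xx),
                                      dims = c(length(free), length(free)))
      }
      Rv <- as.numeric(K %*% u) - F_ext
      rn <- sqrt(sum(Rv[free]^2))
      fn <- max(sqrt(sum(F_ext^2)), 1e-10)
      if (rn < 1e-6 * fn || (it > 1 && rn < 1e-12)) break
      J <- if (is.null(trips)) Kff else Kff + trips
      du <- as.numeric(Matrix::solve(J, -Rv[free]))
      u[free] <- u[free] + du
    }
    pressures <- numeric(length(top))
    fz <- 0
    if (length(act)) {
      pressures[act] <- penalty * pen[act]
      fz <- sum(penalty * trib[act] * pen[act] * (-nrm[, 3]))
    }
    list(u = u, pressures = pressures, force = abs(fz), act = act)
  }

  if (is.null(force)) {
    res <- solve_at_depth(depth)
  } else {
    # secant iteration on depth, warm-started from the previous solution
    kf <- constrained_modulus(m) / Lz
    d0 <- sqrt(force / (pi * R * kf))
    res0 <- solve_at_depth(d0)
    d1 <- d0 * (force / max(res0$force, 1e-9))^(1 / 2)
    res <- solve_at_depth(d1, res0$u)
    for (it in 1:10) {
      if (abs(res$force - force) < tol * force) break
      slope <- (res$force - res0$force) / (d1 - d0)
      d_new <- d1 + (force - res$force) / slope
      d0 <- d1; res0 <- res; d1 <- max(d_new, 1e-4)
      res <- solve_at_depth(d1, res0$u)
    }
    depth <- d1
  }
  act_r <- if (length(res$act)) {
    max(sqrt(mesh$nodes[top[res$act], 1]^2 + mesh$nodes[top[res$act], 2]^2))
  } else 0
  list(depth = depth, force = res$force,
       peak_pressure = max(res$pressures), pressures = res$pressures,
       contact_radius = act_r, u = res$u)
}

#' Elastic-foundation prediction for sphere-on-bonded-layer
#' @param m a `material_params`.
#' @param R sphere radius (mm), `t` layer thickness (mm), `force` (N).
#' @param t layer thickness (mm).
#' @param force total force (N).
#' @return list with `depth` and `peak_pressure`.
#' @export
foundation_prediction <- function(m, R, t, force) {
  kf <- constrained_modulus(m) / t
  delta <- sqrt(force / (pi * R * kf))
  list(depth = delta, peak_pressure = kf * delta)
}

#' Hertz prediction for rigid sphere on elastic half-space
#' @param m a `material_params`.
#' @param R sphere radius (mm).
#' @param force total force (N).
#' @return list with `peak_pressure`, `contact_radius`, `depth`.
#' @export
hertz_prediction <- function(m, R, force) {
  Estar <- m$E / (1 - m$nu^2)
  a <- (3 * force * R / (4 * Estar))^(1 / 3)
  list(peak_pressure = (6 * force * Estar^2 / (pi^3 * R^2))^(1 / 3),
       contact_radius = a, depth = a^2 / R)
}
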