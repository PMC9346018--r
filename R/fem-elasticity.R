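# Small-strain isotropic linear elasticity on 4-node (constant strain)
# tetrahedra. Cartilage default: E = 5.0 MPa, nu = 0.47, friction mu = 0.02;
# bones are rigid and enter only through boundary constraints.

#' Cartilage material parameters
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio (`0 <= nu < 0.5`).
#' @param mu cartilage-cartilage friction coefficient.
#' @return list of class `material_params` with derived Lame constants.
#' @export
material_params <- function(E = 5.0, nu = 0.47, mu = 0.02) {
  check_range(E, "E", 1e-9, Inf)
  if (!(nu >= 0 && nu < 0.5)) {
    pf_stop("parameter 'nu' must satisfy 0 <= nu < 0.5",
            class = "patellofem_config_error")
  }
  check_range(mu, "mu", 0, 2)
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  G <- E / (2 * (1 + nu))
  structure(list(E = E, nu = nu, mu = mu, lambda = lambda, G = G),
            class = "material_params")
}

#' Constrained (oedometric) modulus of a material
#'
#' `E (1 - nu) / ((1 + nu)(1 - 2 nu))`; the stiffness probed by confined
#' compression and by the elastic-foundation contact model.
#'
#' @param m a `material_params` object.
#' @return modulus (MPa).
#' @export
constrained_modulus <- function(m) {
  m$E * (1 - m$nu) / ((1 + m$nu) * (1 - 2 * m$nu))
}

# shape-function gradients per element: list(gx, gy, gz) each m x 4, plus
# volumes; constant over each tet
#' @noRd
tet_gradients <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE]
  c_ <- nodes[tets[, 3], , drop = FALSE]
  d <- nodes[tets[, 4], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a; e3 <- d - a
  # inverse of the Jacobian [e1; e2; e3] (rows), times 6V
  cx <- cbind(e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2],
              e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3],
              e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])   # e2 x e3
  cy <- cbind(e3[, 2] * e1[, 3] - e3[, 3] * e1[, 2],
              e3[, 3] * e1[, 1] - e3[, 1] * e1[, 3],
              e3[, 1] * e1[, 2] - e3[, 2] * e1[, 1])   # e3 x e1
  cz <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])   # e1 x e2
  det <- rowSums(e1 * cx)
  if (any(abs(det) < 1e-12)) {
    pf_stop("inverted/degenerate element(s): ",
            paste(which(abs(det) < 1e-12)[1:min(3, sum(abs(det) < 1e-12))],
                  collapse = ", "))
  }
  # gradients of N2..N4 are rows of inv(J); N1 = -(N2+N3+N4)
  g2 <- cx / det; g3 <- cy / det; g4 <- cz / det
  g1 <- -(g2 + g3 + g4)
  list(gx = cbind(g1[, 1], g2[, 1], g3[, 1], g4[, 1]),
       gy = cbind(g1[, 2], g2[, 2], g3[, 2], g4[, 2]),
       gz = cbind(g1[, 3], g2[, 3], g3[, 3], g4[, 3]),
       vol = det / 6)
}

#' Element stiffness of a single linear tetrahedron
#'
#' Exact constant-strain integration; returns the 12 x 12 block in node-major
#' DOF order (x1, y1, z1, x2, ...).
#'
#' @param tet_nodes 4 x 3 matrix of node coordinates.
#' @param m a `material_params` object.
#' @return 12 x 12 stiffness matrix (N/mm).
#' @export
element_stiffness <- function(tet_nodes, m) {
  g <- tet_gradients(tet_nodes, matrix(1:4, 1))
  if (g$vol <= 0) pf_stop("inverted element (negative volume)")
  K <- matrix(0, 12, 12)
  grads <- rbind(c(g$gx[1, 1], g$gy[1, 1], g$gz[1, 1]),
                 c(g$gx[1, 2], g$gy[1, 2], g$gz[1, 2]),
                 c(g$gx[1, 3], g$gy[1, 3], g$gz[1, 3]),
                 c(g$gx[1, 4], g$gy[1, 4], g$gz[1, 4]))
  for (i in 1:4) for (j in 1:4) {
    gi <- grads[i, ]; gj <- grads[j, ]
    blk <- m$lambda * outer(gi, gj) + m$G * outer(gj, gi) +
      m$G * sum(gi * gj) * diag(3)
    K[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] <- g$vol * blk
  }
  K
}

#' Assemble the global sparse stiffness operator of a tet mesh
#'
#' Symmetric positive semi-definite with exactly six rigid-body zero-energy
#' modes before constraints.
#'
#' @param mesh a `tet_mesh`.
#' @param m a `material_params` object.
#' @return sparse `dgCMatrix` of size `3n x 3n` (DOF order x1, y1, z1, ...).
#' @export
assemble_stiffness <- function(mesh, m) {
  g <- tet_gradients(mesh$nodes, mesh$tets)
  ne <- nrow(mesh$tets)
  grads <- list(g$gx, g$gy, g$gz)
  iidx <- vector("list", 16 * 9)
  jidx <- vector("list", 16 * 9)
  xval <- vector("list", 16 * 9)
  slot <- 0L
  for (i in 1:4) for (j in 1:4) {
    for (a in 1:3) for (b in 1:3) {
      gi_a <- grads[[a]][, i]; gj_b <- grads[[b]][, j]
      gi_b <- grads[[b]][, i]; gj_a <- grads[[a]][, j]
      v <- m$lambda * gi_a * gj_b + m$G * gi_b * gj_a
      if (a == b) {
        v <- v + m$G * (grads[[1]][, i] * grads[[1]][, j] +
                        grads[[2]][, i] * grads[[2]][, j] +
                        grads[[3]][, i] * grads[[3]][, j])
      }
      slot <- slot + 1L
      iidx[[slot]] <- 3L * (mesh$tets[, i] - 1L) + a
      jidx[[slot]] <- 3L * (mesh$tets[, j] - 1L) + b
      xval[[slot]] <- g$vol * v
    }
  }
  Matrix::sparseMatrix(i = unlist(iidx), j = unlist(jidx), x = unlist(xval),
                       dims = c(3 * nrow(mesh$nodes), 3 * nrow(mesh$nodes)))
}

#' Per-element strain and stress from a displacement field
#'
#' @param mesh a `tet_mesh`.
#' @param m a `material_params` object.
#' @param u displacement vector (length `3n`, DOF order x1, y1, z1, ...).
#' @return list with `strain` and `stress`, each an m x 6 matrix in Voigt
#'   order (xx, yy, zz, xy, yz, xz; engineering shear strains), and `vmes`
#'   (Von Mises equivalent stress, MPa).
#' @export
element_stress <- function(mesh, m, u) {
  g <- tet_gradients(mesh$nodes, mesh$tets)
  ux <- matrix(u[3 * (mesh$tets - 1) + 1], ncol = 4)
  uy <- matrix(u[3 * (mesh$tets - 1) + 2], ncol = 4)
  uz <- matrix(u[3 * (mesh$tets - 1) + 3], ncol = 4)
  dux_dx <- rowSums(g$gx * ux); dux_dy <- rowSums(g$gy * ux); dux_dz <- rowSums(g$gz * ux)
  duy_dx <- rowSums(g$gx * uy); duy_dy <- rowSums(g$gy * uy); duy_dz <- rowSums(g$gz * uy)
  duz_dx <- rowSums(g$gx * uz); duz_dy <- rowSums(g$gy * uz); duz_dz <- rowSums(g$gz * uz)
  eps <- cbind(xx = dux_dx, yy = duy_dy, zz = duz_dz,
               xy = dux_dy + duy_dx, yz = duy_dz + duz_dy, xz = dux_dz + duz_dx)
  tr <- eps[, 1] + eps[, 2] + eps[, 3]
  sig <- cbind(m$lambda * tr + 2 * m$G * eps[, 1],
               m$lambda * tr + 2 * m$G * eps[, 2],
               m$lambda * tr + 2 * m$G * eps[, 3],
               m$G * eps[, 4], m$G * eps[, 5], m$G * eps[, 6])
  colnames(sig) <- colnames(eps)
  list(strain = eps, stress = sig, vmes = von_mises(sig))
}

#' Von Mises equivalent stress from Voigt stress rows
#'
#' `sqrt(3 J2)` of the deviatoric stress: a distortional (shear-dominated)
#' load measure, invariant to hydrostatic offsets.
#'
#' @param sig m x 6 stress matrix, Voigt order (xx, yy, zz, xy, yz, xz).
#' @return vector of equivalent stresses.
#' @export
von_mises <- function(sig) {
  sqrt(0.5 * ((sig[, 1] - sig[, 2])^2 + (sig[, 2] - sig[, 3])^2 +
              (sig[, 3] - sig[, 1])^2) +
       3 * (sig[, 4]^2 + sig[, 5]^2 + sig[, 6]^2))
}
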