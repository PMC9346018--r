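# Output measures: thresholded contact-pressure statistics, Von Mises
# equivalent stress at the articular and bone interfaces, contact area, and
# the clinical alignment indices (patellar tilt, bisect offset, TT-TG).

# The inclusion threshold for mean stress statistics: elements/faces below
# 271 kPa are excluded so that means are not diluted by the large
# low-stress periphery.
#' Default stress inclusion threshold (MPa)
#' @export
STRESS_TAU <- 0.271

# face pressures on the patellar articular surface from nodal values
#' @noRd
face_pressures <- function(sys, sol, side = c("patella", "trochlea")) {
  side <- match.arg(side)
  if (side == "patella") {
    mesh <- sys$patella
    pnod <- sol$contact$pressure
  } else {
    mesh <- sys$femur
    f <- sol$contact$f_fem_nodal
    # nodal traction = nodal force / tributary area, projected on the normal
    pnod <- row_norms(f) / pmax(sys$trib_fem, 1e-12)
  }
  tr <- mesh$surf_tris
  pf <- (pnod[tr[, 1]] + pnod[tr[, 2]] + pnod[tr[, 3]]) / 3
  areas <- triangle_areas(surface_mesh(mesh$nodes[seq_len(mesh$n_surf), , drop = FALSE], tr))
  list(pressure = pf, area = areas)
}

#' @noRd
require_converged <- function(sol) {
  if (!inherits(sol, "pf_solution") || !isTRUE(sol$converged)) {
    pf_stop("solution did not converge; metrics refused (status: ",
            if (inherits(sol, "pf_solution")) sol$status else "not a solution", ")")
  }
}

#' Thresholded contact pressure statistics
#'
#' Peak = maximum face pressure; mean = area-weighted mean over faces with
#' pressure above `tau`. If no face passes the threshold the mean is `NA`
#' (absent), not zero.
#'
#' @param sol a converged `pf_solution`.
#' @param sys its `fe_system`.
#' @param tau inclusion threshold (MPa).
#' @param side `"patella"` (default; the reported patellofemoral pressures)
#'   or `"trochlea"`.
#' @return list with `peak`, `mean` (MPa), `n_faces_included`.
#' @export
pressure_stats <- function(sol, sys, tau = STRESS_TAU, side = "patella") {
  require_converged(sol)
  fp <- face_pressures(sys, sol, side)
  pressure_stats_values(fp$pressure, fp$area, tau)
}

# pure kernel, also used directly on literature-style face tables
#' @noRd
pressure_stats_values <- function(pressure, area, tau) {
  peak <- if (length(pressure)) max(pressure) else NA_real_
  keep <- which(pressure > tau)
  mean_p <- if (length(keep)) {
    sum(pressure[keep] * area[keep]) / sum(area[keep])
  } else NA_real_
  list(peak = peak, mean = mean_p, n_faces_included = length(keep))
}

#' Contact area
#'
#' Sum of (undeformed) areas of patellar articular faces in contact. A face
#' is contacting when its pressure exceeds a numeric floor (default
#' 1e-6 MPa); the 271 kPa inclusion rule applies to mean-stress reporting,
#' not to area. Pass `tau` to compute the thresholded variant.
#'
#' @param sol a converged `pf_solution`.
#' @param sys its `fe_system`.
#' @param floor numeric contact floor (MPa).
#' @param tau optional threshold; if given, overrides `floor`.
#' @return contact area (mm^2).
#' @export
contact_area <- function(sol, sys, floor = 1e-6, tau = NULL) {
  require_converged(sol)
  fp <- face_pressures(sys, sol, "patella")
  thr <- if (is.null(tau)) floor else tau
  sum(fp$area[fp$pressure > thr])
}

#' Von Mises stress field and interface statistics
#'
#' `vmes_field()` returns the per-element equivalent stress of one cartilage
#' mesh; `vmes_stats()` restricts to elements adjacent to the articular or
#' bone interface of the requested part and applies the same 271 kPa
#' inclusion rule as the pressure statistics (volume-weighted mean).
#'
#' @param sol a converged `pf_solution`.
#' @param sys its `fe_system`.
#' @param region `"patella"` or `"trochlea"`.
#' @param surface `"articular"` (chondro-chondral) or `"bone_interface"`
#'   (chondro-osseous).
#' @param tau inclusion threshold (MPa).
#' @return `vmes_field`: numeric vector (MPa). `vmes_stats`: list with
#'   `peak`, `mean`, `n_elements_included`.
#' @export
vmes_field <- function(sol, sys, region = c("patella", "trochlea")) {
  region <- match.arg(region)
  if (region == "trochlea") {
    mesh <- sys$femur
    u <- sol$u_full[seq_len(3L * sys$n_f)]
  } else {
    mesh <- sys$patella
    u <- sol$u_full[3L * sys$n_f + seq_len(3L * sys$n_p)]
  }
  element_stress(mesh, sys$material, u)$vmes
}

#' @rdname vmes_field
#' @export
vmes_stats <- function(sol, sys, region = c("patella", "trochlea"),
                       surface = c("articular", "bone_interface"),
                       tau = STRESS_TAU) {
  require_converged(sol)
  region <- match.arg(region)
  surface <- match.arg(surface)
  mesh <- if (region == "trochlea") sys$femur else sys$patella
  field <- vmes_field(sol, sys, region)
  set <- if (surface == "articular") mesh$node_sets$articular_surface
         else mesh$node_sets$bone_interface
  inset <- logical(nrow(mesh$nodes))
  inset[set] <- TRUE
  adj <- inset[mesh$tets[, 1]] | inset[mesh$tets[, 2]] |
    inset[mesh$tets[, 3]] | inset[mesh$tets[, 4]]
  v <- field[adj]
  vol <- mesh$volumes[adj]
  keep <- v > tau
  list(peak = if (length(v)) max(v) else NA_real_,
       mean = if (any(keep)) sum(v[keep] * vol[keep]) / sum(vol[keep]) else NA_real_,
       n_elements_included = sum(keep))
}

#' Patellar tilt
#'
#' Axial-plane angle between the patellar transverse axis (medial edge
#' midpoint to most lateral point) and the posterior condylar baseline
#' (+x). Positive = lateral edge tilted posteriorly.
#'
#' @param model a `knee_model`.
#' @param pose patellar pose (e.g. `case$pose`); translation may include a
#'   solved displacement.
#' @param sol optional `pf_solution`; its rigid translation is added to the
#'   pose.
#' @return tilt (deg).
#' @export
patellar_tilt <- function(model, pose, sol = NULL) {
  pose <- pose_with_solution(pose, sol)
  pl <- model$patella_landmarks_local
  lat <- pose_points(pose, pl$most_lateral_patellar_point)
  med <- pose_points(pose, pl$medial_patellar_edge_midpoint)
  ax <- lat - med
  rad2deg(atan2(-ax[2], ax[1]))
}

#' Bisect offset
#'
#' Percentage of the patellar width lateral to the sagittal plane through the
#' deepest trochlear sulcus point, at the patellar equator. May exceed 100%
#' in subluxation.
#'
#' @inheritParams patellar_tilt
#' @return bisect offset (%).
#' @export
bisect_offset <- function(model, pose, sol = NULL) {
  pose <- pose_with_solution(pose, sol)
  pl <- model$patella_landmarks_local
  lat <- pose_points(pose, pl$most_lateral_patellar_point)
  med <- pose_points(pose, pl$medial_patellar_edge_midpoint)
  sx <- deepest_sulcus_point(model)[1]
  100 * (lat[1] - sx) / (lat[1] - med[1])
}

#' TT-TG distance
#'
#' Signed distance along the posterior condylar baseline (+x lateral)
#' between the tibial tuberosity reference and the deepest sulcus point of
#' the (possibly operated) trochlea.
#'
#' @param model a `knee_model`.
#' @return TT-TG (mm, positive = tuberosity lateral to the groove).
#' @export
tt_tg <- function(model) {
  lm <- model$landmarks
  if (is.null(lm$tibial_tuberosity_reference)) {
    pf_stop("missing landmark: tibial_tuberosity_reference")
  }
  lm$tibial_tuberosity_reference[1] - deepest_sulcus_point(model)[1]
}

#' @noRd
pose_with_solution <- function(pose, sol) {
  if (!is.null(sol)) {
    pose$translation <- pose$translation + sol$patella_translation
  }
  pose
}

#' All stress/area/alignment metrics of one solved configuration
#'
#' @param sol a converged `pf_solution`.
#' @param sys its `fe_system`.
#' @param model the `knee_model` solved.
#' @param tau inclusion threshold (MPa).
#' @return one-row data frame.
#' @export
solution_metrics <- function(sol, sys, model, tau = STRESS_TAU) {
  ps <- pressure_stats(sol, sys, tau)
  vp_a <- vmes_stats(sol, sys, "patella", "articular", tau)
  vt_a <- vmes_stats(sol, sys, "trochlea", "articular", tau)
  vp_b <- vmes_stats(sol, sys, "patella", "bone_interface", tau)
  vt_b <- vmes_stats(sol, sys, "trochlea", "bone_interface", tau)
  data.frame(
    theta = sys$case$theta,
    peak_pressure = ps$peak, mean_pressure = ps$mean,
    contact_area = contact_area(sol, sys),
    peak_vmes_patella = vp_a$peak, mean_vmes_patella = vp_a$mean,
    peak_vmes_trochlea = vt_a$peak, mean_vmes_trochlea = vt_a$mean,
    peak_vmes_patella_bone = vp_b$peak, mean_vmes_patella_bone = vp_b$mean,
    peak_vmes_trochlea_bone = vt_b$peak, mean_vmes_trochlea_bone = vt_b$mean,
    tilt = patellar_tilt(model, sys$case$pose, sol),
    bisect_offset = bisect_offset(model, sys$case$pose, sol),
    tt_tg = tt_tg(model),
    iterations = sol$iterations,
    converged = sol$converged
  )
}
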