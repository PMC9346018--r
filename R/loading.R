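# Flexion-angle-specific load cases: femur fixed, patella free in translation
# (rotations held at the configured tilt), three-spring patellar tendon,
# MPFL/LPFL springs with prestrain, and the three-component quadriceps force.

#' Split a total quadriceps force into functional groups
#'
#' Components proportional to RF/VI : VM : VL = 111 : 67 : 98 (cross-sectional
#' areas), summing exactly to `total`; 276 N yields (111, 67, 98).
#'
#' @param total total quadriceps force (N, >= 0).
#' @return named vector `c(RF_VI, VM, VL)` in N.
#' @export
muscle_components <- function(total = 276) {
  if (!is.numeric(total) || total < 0) pf_stop("total muscle force must be >= 0")
  w <- c(RF_VI = 111, VM = 67, VL = 98)
  total * w / sum(w)
}

#' Default quadriceps direction table
#'
#' Per-flexion-angle unit direction vectors (pull on the patella) for the
#' three functional groups, in the model frame (+x lateral, +y anterior,
#' +z proximal). The posterior (compressive) lean grows with flexion; VL is
#' directed slightly laterally and VM slightly medially. Values are an
#' editable stand-in for the experimentally derived directions the loading
#' protocol mimics; they are configuration, not measurement.
#'
#' @return data frame with columns `theta`, `sag_RF_VI`, `sag_VM`, `sag_VL`
#'   (posterior lean from the femoral shaft, deg) and `frontal_VM`,
#'   `frontal_VL` (medial/lateral lean, deg).
#' @export
quadriceps_direction_table <- function() {
  # sagittal wrap: at deeper flexion the extensor tendon bends over the
  # trochlea, so its pull on the patella leans increasingly posterior
  data.frame(
    theta = c(30, 45, 60, 75),
    sag_RF_VI = c(18, 26, 36, 46),
    sag_VM = c(20, 28, 38, 48),
    sag_VL = c(20, 28, 38, 48),
    frontal_VM = c(-28, -28, -28, -28),
    frontal_VL = c(22, 22, 22, 22)
  )
}

# per-theta start pose table: distal migration of the patella with flexion
#' @noRd
engagement_table <- function() {
  data.frame(theta = c(30, 45, 60, 75), z = c(8, 4, 0, -4))
}

#' Default loading configuration
#'
#' @param theta flexion angles (deg) the study solves.
#' @param muscle_total total quadriceps force (N).
#' @param tendon_stiffness total patellar tendon stiffness (N/mm), split
#'   equally across three fan springs.
#' @param mpfl_stiffness,lpfl_stiffness patellofemoral ligament stiffnesses
#'   (N/mm).
#' @param prestrain ligament prestrain (dimensionless).
#' @param clearance initial cartilage-cartilage clearance at placement (mm).
#' @param direction_table quadriceps direction table (see
#'   [quadriceps_direction_table()]).
#' @return named list.
#' @export
loading_config <- function(theta = c(30, 45, 60, 75), muscle_total = 276,
                           tendon_stiffness = 4334, mpfl_stiffness = 6.45,
                           lpfl_stiffness = 5.42, prestrain = 0.02,
                           clearance = 0.3,
                           direction_table = quadriceps_direction_table()) {
  list(theta = theta, muscle_total = muscle_total,
       tendon_stiffness = tendon_stiffness, mpfl_stiffness = mpfl_stiffness,
       lpfl_stiffness = lpfl_stiffness, prestrain = prestrain,
       clearance = clearance, direction_table = direction_table,
       engagement = engagement_table())
}

#' Uniaxial spring element
#'
#' @param origin,insertion endpoints (3D, mm); origin is on the fixed bone,
#'   insertion on the patella.
#' @param k stiffness (N/mm, > 0).
#' @param rest_length natural length (mm); alternatively give `prestrain` and
#'   the rest length is derived from the current endpoint distance `L` as
#'   `L / (1 + prestrain)`.
#' @param prestrain dimensionless prestrain at the build pose.
#' @param tension_only if `TRUE` the spring exerts no force when slack.
#' @param name label.
#' @return list of class `spring_element`.
#' @export
spring_element <- function(origin, insertion, k, rest_length = NULL,
                           prestrain = 0, tension_only = TRUE, name = "spring") {
  check_range(k, "k", 1e-12, Inf)
  L <- vnorm(insertion - origin)
  if (L < 1e-9) pf_stop("spring endpoints coincide")
  if (is.null(rest_length)) rest_length <- L / (1 + prestrain)
  structure(list(origin = origin, insertion = insertion, k = k,
                 rest_length = rest_length, tension_only = tension_only,
                 name = name),
            class = "spring_element")
}

#' Force exerted by a spring at given endpoint positions
#'
#' Hooke along the axis: magnitude `k (L - L0)`, equal and opposite at the
#' endpoints, clamped to zero for slack tension-only springs.
#'
#' @param s a `spring_element`.
#' @param origin,insertion current endpoint positions (default: as built).
#' @return list with `f_origin`, `f_insertion` (N, summing to zero), `length`,
#'   `tension` (N, positive in tension).
#' @export
spring_force <- function(s, origin = s$origin, insertion = s$insertion) {
  d <- insertion - origin
  L <- vnorm(d)
  if (L < 1e-9) pf_stop("spring endpoints coincide")
  axis <- d / L
  tension <- s$k * (L - s$rest_length)
  if (s$tension_only && tension < 0) tension <- 0
  list(f_origin = tension * axis, f_insertion = -tension * axis,
       length = L, tension = tension)
}

# 3x3 stiffness block d(-f_insertion)/d(insertion) of a spring
#' @noRd
spring_stiffness_block <- function(s, origin, insertion) {
  d <- insertion - origin
  L <- vnorm(d)
  axis <- d / L
  tension <- s$k * (L - s$rest_length)
  if (s$tension_only && tension <= 0) return(matrix(0, 3, 3))
  P <- outer(axis, axis)
  s$k * P + (tension / L) * (diag(3) - P)
}

# interpolate the quadriceps pull directions at theta; rows unit vectors
#' @noRd
muscle_directions <- function(theta, tab) {
  if (theta < min(tab$theta) || theta > max(tab$theta)) {
    pf_stop(sprintf("flexion angle %.1f outside the direction table range [%g, %g]; no extrapolation",
                    theta, min(tab$theta), max(tab$theta)))
  }
  g <- function(col) stats::approx(tab$theta, tab[[col]], xout = theta)$y
  dir1 <- function(sag, frontal) {
    s <- deg2rad(sag); f <- deg2rad(frontal)
    unit(c(sin(f), -sin(s) * cos(f), cos(s) * cos(f)))
  }
  rbind(RF_VI = dir1(g("sag_RF_VI"), 0),
        VM = dir1(g("sag_VM"), g("frontal_VM")),
        VL = dir1(g("sag_VL"), g("frontal_VL")))
}

# tibial tuberosity position at flexion theta: the tibia rotates about the
# posterior condylar axis; only the tendon origin it carries matters here
#' @noRd
tuberosity_at <- function(model, theta) {
  tt <- model$landmarks$tibial_tuberosity_reference
  axis_pt <- model$landmarks$posterior_condylar_axis[1, ]
  th <- deg2rad(theta)
  shaft <- 55; ant <- 24  # tibial shaft length / anterior offset (mm)
  c(tt[1],
    axis_pt[2] - shaft * sin(th) + ant * cos(th),
    axis_pt[3] - shaft * cos(th) - ant * sin(th))
}

#' Place the patella at its start pose for a flexion angle
#'
#' Translates the patellar local frame to the preset mediolateral alignment
#' (bisect-offset target), the flexion-dependent proximodistal engagement
#' station, and an anterior offset chosen so the unloaded minimal
#' cartilage-cartilage gap equals the configured clearance (no initial
#' overlap). Rotations are fixed at the preset tilt.
#'
#' @param model a `knee_model`.
#' @param theta flexion angle (deg).
#' @param config a [loading_config()].
#' @return pose list: `translation` (mm), `tilt_deg`.
#' @export
place_patella <- function(model, theta, config = loading_config()) {
  eng <- config$engagement
  if (theta < min(eng$theta) || theta > max(eng$theta)) {
    pf_stop(sprintf("flexion angle %.1f outside the configured range [%g, %g]",
                    theta, min(eng$theta), max(eng$theta)))
  }
  z_c <- stats::approx(eng$theta, eng$z, xout = theta)$y
  pl <- model$patella_landmarks_local
  # the preset tilt is the clinical measurement (transverse axis vs BL);
  # correct for the intrinsic axial angle of the asymmetric facet rim
  ax0 <- pl$most_lateral_patellar_point - pl$medial_patellar_edge_midpoint
  a0 <- rad2deg(atan2(-ax0[2], ax0[1]))
  tilt <- model$alignment$tilt_deg - a0
  R <- rot_z(-tilt)
  lat <- R %*% pl$most_lateral_patellar_point
  med <- R %*% pl$medial_patellar_edge_midpoint
  width <- lat[1] - med[1]
  # alignment is anchored to the knee's native (preoperative) sulcus plane:
  # surgery moves the groove, not the patellar soft-tissue alignment
  sulcus_x <- model$alignment$reference_x %||% deepest_sulcus_point(model)[1]
  # solve x so that (x_lat - sulcus_x) / width = bisect target
  x_c <- sulcus_x + width * model$alignment$bisect_target / 100 - lat[1]
  pose <- list(translation = c(x_c, 20, z_c), tilt_deg = tilt)
  # fixed-point passes: drop the patella until min gap = clearance (the gap
  # is measured along surface normals, so the y-step is slightly relaxed)
  for (pass in 1:5) {
    g <- patellar_surface_gap(model, pose)
    if (abs(g - config$clearance) < 0.01) break
    pose$translation[2] <- pose$translation[2] - (g - config$clearance) / 0.85
  }
  pose
}

#' Deepest sulcus point of the (possibly operated) trochlea
#' @param model a `knee_model`.
#' @return 3D point.
#' @export
deepest_sulcus_point <- function(model) {
  model$landmarks$sulcus_polyline[which.max(model$depths), ]
}

#' Transform patellar-local points into the joint frame
#' @param pose pose list from [place_patella()].
#' @param pts point (length 3) or n x 3 matrix in the patellar local frame.
#' @return transformed point(s).
#' @export
pose_points <- function(pose, pts) {
  R <- rot_z(-pose$tilt_deg)
  if (is.matrix(pts)) {
    sweep(pts %*% t(R), 2, -pose$translation)
  } else {
    as.numeric(R %*% pts + pose$translation)
  }
}

# unloaded minimal gap between posed patellar cartilage vertices and the
# femoral cartilage surface (along femoral normals)
#' @noRd
patellar_surface_gap <- function(model, pose) {
  pv <- pose_points(pose, model$patella_surface$vertices)
  cart <- model$patella_surface$region == "cartilage"
  fem_tris <- femoral_articular_triangles(model)
  g <- point_surface_gaps(pv[cart, , drop = FALSE],
                          model$femur_surface$vertices, fem_tris)
  min(g$gap)
}

# femoral cartilage triangles of the shell (outward orientation)
#' @noRd
femoral_articular_triangles <- function(model) {
  model$femur_surface$triangles[cartilage_triangles(model$femur_surface), ,
                                drop = FALSE]
}

#' Build the load case for one flexion angle
#'
#' Femur fixed; patella start pose from [place_patella()]; three patellar
#' tendon springs fanning from the (flexion-rotated) tibial tuberosity to the
#' inferior patellar pole, total stiffness split equally; MPFL and LPFL with
#' the configured prestrain; quadriceps components along the per-angle
#' direction table. Exactly five springs; three patellar rigid DOF.
#'
#' @param model a `knee_model`.
#' @param theta flexion angle (deg) within the configured range.
#' @param config a [loading_config()].
#' @return list of class `load_case`.
#' @export
build_load_case <- function(model, theta, config = loading_config()) {
  pose <- place_patella(model, theta, config)
  pl <- model$patella_landmarks_local
  inf_pole <- pose_points(pose, pl$inferior_pole)
  sup_pole <- pose_points(pose, pl$superior_pole)
  med_edge <- pose_points(pose, pl$medial_patellar_edge_midpoint)
  lat_edge <- pose_points(pose, pl$most_lateral_patellar_point)
  tub <- tuberosity_at(model, theta)
  k3 <- config$tendon_stiffness / 3
  fan <- c(-8, 0, 8)
  springs <- c(
    lapply(seq_along(fan), function(i) {
      spring_element(origin = tub + c(fan[i] * 0.6, 0, 0),
                     insertion = inf_pole + c(fan[i], 0, 0),
                     k = k3, prestrain = 0, tension_only = TRUE,
                     name = paste0("tendon_", i))
    }),
    list(
      spring_element(origin = model$landmarks$adductor_tubercle,
                     insertion = med_edge, k = config$mpfl_stiffness,
                     prestrain = config$prestrain, tension_only = TRUE,
                     name = "MPFL"),
      spring_element(origin = model$landmarks$lateral_epicondyle,
                     insertion = lat_edge, k = config$lpfl_stiffness,
                     prestrain = config$prestrain, tension_only = TRUE,
                     name = "LPFL")
    )
  )
  comp <- muscle_components(config$muscle_total)
  dirs <- muscle_directions(theta, config$direction_table)
  muscle_force <- colSums(dirs * comp)
  structure(list(
    theta = theta, pose = pose, springs = springs,
    muscle = list(components = comp, directions = dirs,
                  total = config$muscle_total, force = muscle_force,
                  application_point = sup_pole),
    config = config
  ), class = "load_case")
}

#' @export
print.load_case <- function(x, ...) {
  cat(sprintf("load_case: theta = %g deg, %d springs, |muscle| = %.0f N, pose t = (%.1f, %.1f, %.1f)\n",
              x$theta, length(x$springs), vnorm(x$muscle$force),
              x$pose$translation[1], x$pose$translation[2], x$pose$translation[3]))
  invisible(x)
}
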