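# Virtual sulcus-deepening trochleoplasty.
#
# The corrective geometry operator relocates the trochlear sulcus S to
# S1 = S + L x (lateral along BL) - D x (anterior normal), rebuilds the
# anterior subchondral contour through LC - S1 - MC at every axial station
# between two correction planes, and re-drapes the osteochondral flap
# (cartilage thickness is carried unchanged: the flap is moved, not thinned).

#' Surgery parameters for the virtual trochleoplasty
#'
#' @param L_mean mean sulcus lateralization (mm). The default 6.1 mm is the
#'   value implied by the reported TT-TG reductions (3.05 mm at half
#'   correction, 9.15 mm at 1.5x).
#' @param D_mean mean sulcus deepening (mm); the source series does not print
#'   it, 4.0 mm is a configurable default.
#' @param f correction factor scaling both (nominal set 0.5, 1.0, 1.5).
#' @param proximal_z,distal_z correction plane stations (mm); `NULL` = locate
#'   automatically via [locate_correction_planes()].
#' @param blend cosine transition width (mm) outside the correction band.
#' @param straight_segments if `TRUE`, use the literal two straight segments
#'   LC-S1 and S1-MC instead of the default smoothed monotone-cubic contour.
#' @return list of class `surgery_params`.
#' @export
surgery_params <- function(L_mean = 6.1, D_mean = 4.0, f = 1.0,
                           proximal_z = NULL, distal_z = NULL, blend = 3,
                           straight_segments = FALSE) {
  check_range(L_mean, "L_mean", 0, 20)
  check_range(D_mean, "D_mean", 0, 15)
  check_range(f, "f", 0, 3)
  check_range(blend, "blend", 0, 10)
  if (!is.null(proximal_z) && !is.null(distal_z) && proximal_z <= distal_z) {
    pf_stop("proximal_z must be proximal to (greater than) distal_z")
  }
  structure(list(L_mean = L_mean, D_mean = D_mean, f = f,
                 proximal_z = proximal_z, distal_z = distal_z, blend = blend,
                 straight_segments = straight_segments),
            class = "surgery_params")
}

#' TT-TG change produced by a correction
#'
#' The groove is lateralized toward the (fixed) tibial tuberosity, so the
#' TT-TG distance decreases by the applied lateralization `f * L_mean`:
#' 3.05 mm at f = 0.5 and 9.15 mm at f = 1.5 with the default mean.
#'
#' @param p a `surgery_params` object.
#' @return TT-TG reduction (mm, positive = reduction).
#' @export
tt_tg_change <- function(p) {
  stopifnot(inherits(p, "surgery_params"))
  p$f * p$L_mean
}

#' Locate the proximal and distal correction planes
#'
#' The proximal plane is the most proximal axial station whose articulating
#' arc (MC to LC) is fully covered by cartilage; the distal plane is the most
#' distal station before the sulcus polyline turns into the intercondylar
#' notch (tangent-to-axis angle exceeding `notch_angle`).
#'
#' @param model a `knee_model`.
#' @param notch_angle tangent threshold (deg, default 45).
#' @return list with `proximal_z`, `distal_z` (mm).
#' @export
locate_correction_planes <- function(model, notch_angle = 45) {
  stopifnot(inherits(model, "knee_model"))
  profs <- model$profiles
  region <- model$femur_surface$region
  covered <- vapply(profs, function(pr) {
    arc_span <- pr$u >= ARC_U[["mc"]] & pr$u <= ARC_U[["lc"]]
    all(region[pr$arc_ids[arc_span]] == "cartilage")
  }, logical(1))
  if (!any(covered)) {
    pf_stop("no station has a fully cartilage-covered articulating arc; ",
            "set the correction planes manually via surgery_params()")
  }
  proximal_z <- max(vapply(profs[covered], `[[`, numeric(1), "z"))
  sp <- model$landmarks$sulcus_polyline
  seg <- diff(sp)
  ang <- rad2deg(atan2(sqrt(seg[, 1]^2 + seg[, 2]^2), abs(seg[, 3])))
  ok <- which(ang <= notch_angle)
  if (!length(ok)) {
    pf_stop("the entire sulcus polyline exceeds the notch tangent threshold; ",
            "set the correction planes manually via surgery_params()")
  }
  distal_z <- sp[min(ok), 3]
  if (distal_z >= proximal_z) {
    pf_stop("located planes are degenerate (distal_z >= proximal_z); ",
            "set the correction planes manually via surgery_params()")
  }
  list(proximal_z = proximal_z, distal_z = distal_z)
}

#' Relocate the sulcus point of one axial profile
#'
#' `S1 = S + L * BL_lateral + D * posterior`, with BL the posterior condylar
#' baseline direction (+x lateral) and the posterior normal -y.
#'
#' @param profile a per-station profile (element of `model$profiles`), or any
#'   list with an `anchors` list carrying 2D points `s`, `mc`, `lc`, `em`,
#'   `el`.
#' @param L lateralization (mm, >= 0 toward lateral).
#' @param D deepening (mm, >= 0 toward posterior).
#' @param bone_margin minimal remaining bone stock (mm) between the new
#'   sulcus and the posterior cortex proxy.
#' @return the relocated 2D sulcus point `c(x, y)`.
#' @export
new_sulcus_point <- function(profile, L, D, bone_margin = 3) {
  a <- profile$anchors
  s1 <- c(a$s[1] + L, a$s[2] - D)
  if (s1[1] >= a$lc[1] || s1[1] <= a$mc[1]) {
    pf_stop(sprintf("lateralization %.2f mm moves the sulcus beyond the condylar peaks", L))
  }
  floor_y <- min(a$em[2], a$el[2]) - bone_margin
  if (s1[2] < floor_y) {
    pf_stop(sprintf(
      "deepening %.2f mm exceeds the local bone stock (new sulcus y %.2f < limit %.2f)",
      D, s1[2], floor_y))
  }
  s1
}

#' Apply the virtual sulcus-deepening trochleoplasty
#'
#' At every axial station inside the correction band the anterior subchondral
#' contour between MC and LC is replaced by a contour through MC - S1 - LC
#' (smoothed monotone cubic by default), where S1 applies the full corrected
#' lateralization/deepening `f * (L_mean, D_mean)` at both planes and in
#' between (the two planes carry the same nominal values), with a cosine
#' taper of width `blend` outside the band. Bone is only removed: the new
#' contour is clamped to never protrude anterior to the old one. The
#' cartilage flap (thickness map) rides along unchanged.
#'
#' @param model a `knee_model` (right-side; mirror afterwards if needed).
#' @param p a [surgery_params()] object.
#' @return list of class `osteotomy_result`: `model` (modified), `S1_polyline`,
#'   `wedge_volume` (mm^3), `displacement` (per femoral vertex, mm),
#'   `planes`, `params`.
#' @export
apply_trochleoplasty <- function(model, p) {
  stopifnot(inherits(model, "knee_model"), inherits(p, "surgery_params"))
  if (model$side != "right") {
    pf_stop("apply the surgery to the native right-side model and mirror afterwards")
  }
  planes <- if (is.null(p$proximal_z) || is.null(p$distal_z)) {
    locate_correction_planes(model)
  } else {
    list(proximal_z = p$proximal_z, distal_z = p$distal_z)
  }
  out <- model
  verts <- model$femur_surface$vertices
  disp <- numeric(nrow(verts))
  wedge_area <- numeric(length(model$profiles))
  zs <- vapply(model$profiles, `[[`, numeric(1), "z")

  for (k in seq_along(model$profiles)) {
    pr <- model$profiles[[k]]
    w <- cosine_band(pr$z, planes$distal_z, planes$proximal_z, p$blend)
    if (w <= 0 || p$f == 0) next
    L <- p$f * p$L_mean * w
    D <- p$f * p$D_mean * w
    s1 <- tryCatch(new_sulcus_point(pr, L, D), error = function(e) {
      pf_stop(sprintf("station z = %.1f mm: %s", pr$z, conditionMessage(e)))
    })
    anchors_new <- pr$anchors
    anchors_new$s <- s1
    arc_new <- if (p$straight_segments) {
      sample_anterior_arc_straight(anchors_new, pr$u)
    } else {
      sample_anterior_arc(anchors_new, pr$u)
    }
    # removal only: blend against the original contour (evaluated at new x)
    # with a smooth minimum, so the junction between the resected bed and
    # the untouched surface carries no convex crease (k ~ bone-file scale)
    old_fun <- arc_y_fun(pr$anchors)
    y_old_at <- old_fun(arc_new$x)
    dd <- arc_new$y - y_old_at
    k_sm <- 0.3
    y_new <- y_old_at - k_sm * log1p(exp(pmin(-dd / k_sm, 200)))
    mid <- pr$u > ARC_U[["mc"]] & pr$u < ARC_U[["lc"]]
    x_new <- arc_new$x
    x_new[!mid] <- pr$arc_x[!mid]
    y_new[!mid] <- pr$arc_y[!mid]
    dx <- x_new - pr$arc_x
    dy <- y_new - pr$arc_y
    rows <- pr$arc_ids
    verts[rows, 1] <- verts[rows, 1] + dx
    verts[rows, 2] <- verts[rows, 2] + dy
    disp[rows] <- sqrt(dx^2 + dy^2)
    wedge_area[k] <- contour_wedge_area(pr$arc_x, pr$arc_y, x_new, y_new, mid)
    pr$anchors <- anchors_new
    pr$arc_x <- x_new
    pr$arc_y <- y_new
    out$profiles[[k]] <- pr
  }
  out$femur_surface$vertices <- verts
  s1_poly <- t(vapply(seq_along(out$profiles), function(k) {
    c(out$profiles[[k]]$anchors$s, out$profiles[[k]]$z)
  }, numeric(3)))
  out$landmarks$sulcus_polyline <- s1_poly
  out$depths <- vapply(out$profiles, function(pr) chord_depth(pr$anchors),
                       numeric(1))
  k0 <- which.max(out$depths)
  out$landmarks$LC <- c(out$profiles[[k0]]$anchors$lc, out$profiles[[k0]]$z)
  out$landmarks$MC <- c(out$profiles[[k0]]$anchors$mc, out$profiles[[k0]]$z)
  wedge_volume <- sum(diff(zs) * (utils::head(wedge_area, -1) +
                                    utils::tail(wedge_area, -1)) / 2)
  structure(list(model = out, S1_polyline = s1_poly,
                 wedge_volume = wedge_volume, displacement = disp,
                 planes = planes, params = p),
            class = "osteotomy_result")
}

#' @export
print.osteotomy_result <- function(x, ...) {
  cat(sprintf(
    "osteotomy_result: f = %.2f, planes [%.1f, %.1f] mm, wedge %.0f mm^3, max displacement %.2f mm\n",
    x$params$f, x$planes$distal_z, x$planes$proximal_z, x$wedge_volume,
    max(x$displacement)))
  invisible(x)
}

# literal Fig-style contour: straight segments MC-S1 and S1-LC, outer
# segments unchanged (still monotone-cubic so the untouched part matches)
#' @noRd
sample_anterior_arc_straight <- function(anchors, u) {
  smooth <- sample_anterior_arc(anchors, u)
  ax <- vapply(anchors, `[`, numeric(1), 1)
  ay <- vapply(anchors, `[`, numeric(1), 2)
  mid <- smooth$x >= ax[2] & smooth$x <= ax[4]
  y <- smooth$y
  y[mid] <- stats::approx(ax[2:4], ay[2:4], xout = smooth$x[mid])$y
  list(x = smooth$x, y = y)
}

# area enclosed between the old and new contour over the corrected span
#' @noRd
contour_wedge_area <- function(x_old, y_old, x_new, y_new, mid) {
  xs <- c(x_old[mid], rev(x_new[mid]))
  ys <- c(y_old[mid], rev(y_new[mid]))
  n <- length(xs)
  j <- c(seq_len(n)[-1], 1L)
  abs(sum(xs * ys[j] - xs[j] * ys)) / 2
}
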