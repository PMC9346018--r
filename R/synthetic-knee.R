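# Parametric synthetic knee geometries.
#
# Coordinate frame (all modules): origin at the deepest mid-trochlear sulcus
# point; +x lateral along the posterior condylar baseline (BL), +y anterior,
# +z proximal. Models are generated as right knees; left knees by mirroring.
# Units mm.

#' Dysplasia shape parameters for the synthetic trochlea
#'
#' @param sulcus_depth groove depth (mm) at the deepest mid-trochlear station,
#'   measured from the LC-MC chord posteriorly to the sulcus floor. The
#'   dysplastic preset combines a small depth with a supratrochlear spur so
#'   that the proximal trochlea becomes flat or convex (depth <= 0 there).
#' @param sulcus_angle optional sulcus angle (deg). When given, overrides
#'   `sulcus_depth` via `depth = halfwidth / tan(angle/2)` with the condylar
#'   halfwidth of the template.
#' @param spur_height supratrochlear spur prominence (mm, >= 0); ramps in over
#'   the proximal third of the trochlea.
#' @param medial_facet_scale relative anterior prominence of the medial facet
#'   (1 = symmetric; < 1 = hypoplastic medial facet).
#' @param groove_lateral_offset proximal medial/lateral drift of the groove
#'   track (mm; negative = medial drift, as in dysplasia).
#' @param jitter vertex jitter amplitude (mm, default 0; only for robustness
#'   experiments, seeded).
#' @return list of class `dysplasia_params`.
#' @export
dysplasia_params <- function(sulcus_depth = 6.0, sulcus_angle = NULL,
                             spur_height = 0, medial_facet_scale = 1.0,
                             groove_lateral_offset = 0, jitter = 0) {
  check_range(sulcus_depth, "sulcus_depth", -3, 12)
  if (!is.null(sulcus_angle)) check_range(sulcus_angle, "sulcus_angle", 110, 220)
  check_range(spur_height, "spur_height", 0, 8)
  check_range(medial_facet_scale, "medial_facet_scale", 0.4, 1.2)
  check_range(groove_lateral_offset, "groove_lateral_offset", -8, 8)
  check_range(jitter, "jitter", 0, 1)
  structure(list(sulcus_depth = sulcus_depth, sulcus_angle = sulcus_angle,
                 spur_height = spur_height,
                 medial_facet_scale = medial_facet_scale,
                 groove_lateral_offset = groove_lateral_offset,
                 jitter = jitter),
            class = "dysplasia_params")
}

# Fixed template dimensions of the synthetic distal femur (mm). Sized so that
# the healthy knee articulates a ~38 mm patella with contact areas of order
# 600 mm^2 (a documented calibration, not patient geometry).
#' @noRd
femur_template <- function() {
  list(z_min = -22, z_max = 22,      # distal / proximal extent of the loft
       w_med = 22, w_lat = 22,       # axial half-widths at the anterior arc
       x_mc = -14, x_lc = 14,        # condylar peak abscissae
       prominence = 6.5,             # anterior condylar prominence (mm)
       edge_drop = 7,                # anterior arc drop at its free edges
       r_groove = 90,                # sagittal radius of the groove track
       r_notch = 7, z_notch = -14,   # distal dive into the intercondylar notch
       post_depth = 28,              # posterior semi-axis of the bone contour
       cart_u = c(0.12, 0.88),       # arc-parameter span of the cartilage
       cart_z_prox = 18,             # proximal cartilage margin at the groove
       cart_margin_slope = 10,       # margin recedes distally toward the edges
       thick_center = 3.3, thick_edge = 1.5)  # cartilage thickness map (mm)
}

# Anchor positions of each axial profile in normalized arc parameter u.
#' @noRd
ARC_U <- c(em = 0, mc = 0.3, s = 0.5, lc = 0.7, el = 1)

# Piecewise-linear x(u) between anchors; y(x) is an asymmetric parabolic
# channel between MC and LC (smooth groove of valley radius halfwidth^2 /
# (2 depth), tangent-continuous at the sulcus) and a monotone cubic over the
# non-articulating edge segments. The same construction is used by
# generation and by the virtual surgery so that a zero correction reproduces
# the contour exactly.
#' @noRd
sample_anterior_arc <- function(anchors, u) {
  ax <- vapply(anchors, `[`, numeric(1), 1)
  ay <- vapply(anchors, `[`, numeric(1), 2)
  if (any(diff(ax) <= 0)) {
    pf_stop("profile anchors are not monotone in x (medial to lateral)")
  }
  x <- stats::approx(ARC_U, ax, xout = u)$y
  y <- arc_y_fun(anchors)(x)
  list(x = x, y = y, ax = ax, ay = ay)
}

# contour height function of one profile (see sample_anterior_arc)
#' @noRd
arc_y_fun <- function(anchors) {
  mc <- anchors$mc; s <- anchors$s; lc <- anchors$lc
  em <- anchors$em; el <- anchors$el
  chord <- function(x) mc[2] + (lc[2] - mc[2]) * (x - mc[1]) / (lc[1] - mc[1])
  depth <- chord(s[1]) - s[2]
  outer_m <- shape_spline(c(em[1], mc[1]), c(em[2], mc[2]))
  outer_l <- shape_spline(c(lc[1], el[1]), c(lc[2], el[2]))
  function(x) {
    y <- numeric(length(x))
    med <- x < mc[1]
    lat <- x > lc[1]
    mid <- !med & !lat
    y[med] <- outer_m(x[med])
    y[lat] <- outer_l(x[lat])
    if (any(mid)) {
      xm <- x[mid]
      half <- ifelse(xm < s[1], s[1] - mc[1], lc[1] - s[1])
      uu <- (xm - s[1]) / half
      y[mid] <- chord(xm) - depth * (1 - uu^2)
    }
    y
  }
}

# Axial profile anchors at station z for given shape parameters.
#' @noRd
profile_anchors <- function(z, params, tpl) {
  zr <- z / tpl$z_max
  base <- -z^2 / (2 * tpl$r_groove) -
    (z < tpl$z_notch) * (tpl$z_notch - z)^2 / (2 * tpl$r_notch)
  prom <- tpl$prominence * (1 - 0.25 * zr^2)
  y_lc <- base + prom
  y_mc <- base + prom * params$medial_facet_scale
  depth0 <- if (!is.null(params$sulcus_angle)) {
    abs(tpl$x_lc - tpl$x_mc) / 2 / tan(deg2rad(params$sulcus_angle) / 2)
  } else params$sulcus_depth
  dshape <- 1 - 0.45 * zr^2
  spur <- params$spur_height * max(0, (z - 6) / (tpl$z_max - 6))^2
  depth <- depth0 * dshape - spur
  x_s <- params$groove_lateral_offset * max(0, zr)
  chord <- y_mc + (y_lc - y_mc) * (x_s - tpl$x_mc) / (tpl$x_lc - tpl$x_mc)
  y_s <- chord - depth
  list(
    anchors = list(em = c(-tpl$w_med, y_mc - tpl$edge_drop),
                   mc = c(tpl$x_mc, y_mc),
                   s = c(x_s, y_s),
                   lc = c(tpl$x_lc, y_lc),
                   el = c(tpl$w_lat, y_lc - tpl$edge_drop)),
    depth = depth, z = z
  )
}

# Posterior (bone) arc from the lateral to the medial free edge.
#' @noRd
posterior_arc <- function(anchors, n_post, tpl) {
  phi <- seq_len(n_post) * pi / (n_post + 1)
  y_el <- anchors$el[2]; y_em <- anchors$em[2]
  cx <- (anchors$el[1] + anchors$em[1]) / 2
  a <- (anchors$el[1] - anchors$em[1]) / 2
  x <- cx + a * cos(phi)
  y <- y_el + (y_em - y_el) * phi / pi - tpl$post_depth * sin(phi)
  cbind(x, y)
}

#' Generate the parametric femoral trochlea
#'
#' Lofts axial profiles (anterior articulating arc + posterior bone contour)
#' into a closed right-knee shell, labels the cartilage patch, and derives the
#' cartilage thickness map and femoral landmarks. The model is translated so
#' that the deepest mid-trochlear sulcus point sits at the origin.
#'
#' @param params a [dysplasia_params()] object.
#' @param n_stations number of axial stations (>= 4).
#' @param resolution linear mesh density multiplier (1 = reference density).
#' @param seed integer seed for the (optional, default-off) vertex jitter.
#' @param tpl template dimension overrides (named list into
#'   `femur_template()`).
#' @return list with `mesh` (a `surface_mesh`), `thickness` (per-vertex map,
#'   `NA` outside cartilage), `landmarks`, `profiles` (per-station contour
#'   data reused by the virtual surgery) and `loft` (index bookkeeping).
#' @export
generate_trochlea <- function(params = dysplasia_params(), n_stations = NULL,
                              resolution = 1, seed = 1L, tpl = list()) {
  stopifnot(inherits(params, "dysplasia_params"))
  template <- utils::modifyList(femur_template(), tpl)
  if (is.null(n_stations)) n_stations <- max(9L, round(33 * resolution))
  if (n_stations < 4) pf_stop("parameter 'n_stations' must be >= 4",
                              class = "patellofem_config_error")
  n_arc <- 2 * max(7L, round(30 * resolution)) + 1L
  n_post <- max(7L, round(21 * resolution))
  zs <- seq(template$z_min, template$z_max, length.out = n_stations)
  u <- seq(0, 1, length.out = n_arc)

  profs <- lapply(zs, profile_anchors, params = params, tpl = template)
  depths <- vapply(profs, `[[`, numeric(1), "depth")
  k_deep <- which.max(depths)
  s_deep <- profs[[k_deep]]$anchors$s
  shift <- c(s_deep[1], s_deep[2], zs[k_deep])

  n_ring <- n_arc + n_post
  verts <- matrix(0, n_stations * n_ring + 2, 3)
  region <- rep("bone", nrow(verts))
  thick <- rep(NA_real_, nrow(verts))
  idx <- matrix(0L, n_stations, n_ring)
  for (k in seq_len(n_stations)) {
    arc <- sample_anterior_arc(profs[[k]]$anchors, u)
    post <- posterior_arc(profs[[k]]$anchors, n_post, template)
    ring <- rbind(cbind(arc$x, arc$y), post)
    # ring order: medial edge -> anterior arc -> lateral edge -> posterior -> back
    rows <- (k - 1) * n_ring + seq_len(n_ring)
    idx[k, ] <- rows
    verts[rows, 1] <- ring[, 1] - shift[1]
    verts[rows, 2] <- ring[, 2] - shift[2]
    verts[rows, 3] <- zs[k] - shift[3]
    profs[[k]]$arc_ids <- rows[seq_len(n_arc)]
    profs[[k]]$u <- u
    profs[[k]]$arc_x <- arc$x
    profs[[k]]$arc_y <- arc$y
    # cartilage labeling on the anterior arc
    z <- zs[k]
    margin <- template$cart_z_prox - template$cart_margin_slope * abs(2 * u - 1)
    is_cart <- u >= template$cart_u[1] & u <= template$cart_u[2] &
      z <= margin & z >= template$z_min + 2
    region[rows[seq_len(n_arc)][is_cart]] <- "cartilage"
    x_s <- profs[[k]]$anchors$s[1]
    tk <- template$thick_edge + (template$thick_center - template$thick_edge) *
      exp(-((arc$x - x_s) / 10)^2)
    thick[rows[seq_len(n_arc)][is_cart]] <- tk[is_cart]
  }
  cap_d <- n_stations * n_ring + 1L
  cap_p <- n_stations * n_ring + 2L
  verts[cap_d, ] <- colMeans(verts[idx[1, ], ])
  verts[cap_p, ] <- colMeans(verts[idx[n_stations, ], ])

  tris <- orient_outward(verts, loft_triangles(idx, cap_d, cap_p))
  if (params$jitter > 0) {
    set.seed(as.integer(seed))
    verts <- verts + matrix(stats::rnorm(length(verts), 0, params$jitter),
                            ncol = 3)
  }
  mesh <- surface_mesh(verts, tris, region, side = "right")

  zs_sh <- zs - shift[3]
  sulcus <- t(vapply(seq_len(n_stations), function(k) {
    c(profs[[k]]$anchors$s - shift[1:2], zs_sh[k])
  }, numeric(3)))
  k0 <- k_deep
  landmarks <- list(
    LC = c(profs[[k0]]$anchors$lc - shift[1:2], zs_sh[k0]),
    MC = c(profs[[k0]]$anchors$mc - shift[1:2], zs_sh[k0]),
    sulcus_polyline = sulcus,
    adductor_tubercle = c(-template$w_med, -6, 12),
    lateral_epicondyle = c(template$w_lat, -8, 0),
    posterior_condylar_axis = rbind(c(0, -template$post_depth, 0),
                                    c(1, -template$post_depth, 0))
  )
  for (k in seq_len(n_stations)) {
    profs[[k]]$z <- zs_sh[k]
    profs[[k]]$shift <- shift[1:2]
  }
  list(mesh = mesh, thickness = thick, landmarks = landmarks,
       profiles = profs, depths = depths,
       loft = list(idx = idx, n_arc = n_arc, n_post = n_post,
                   n_stations = n_stations, caps = c(cap_d, cap_p)),
       params = params, template = template)
}

# closed-loft triangulation between station rings plus end-cap fans
#' @noRd
loft_triangles <- function(idx, cap_d, cap_p) {
  n_st <- nrow(idx); n_ring <- ncol(idx)
  nxt <- c(seq_len(n_ring)[-1], 1L)
  tris <- vector("list", n_st + 1)
  for (k in seq_len(n_st - 1)) {
    a <- idx[k, ]; b <- idx[k, nxt]
    c_ <- idx[k + 1, nxt]; d <- idx[k + 1, ]
    tris[[k]] <- rbind(cbind(a, b, c_), cbind(a, c_, d))
  }
  a <- idx[1, ]; b <- idx[1, nxt]
  tris[[n_st]] <- cbind(rep(cap_d, n_ring), b, a)
  a <- idx[n_st, ]; b <- idx[n_st, nxt]
  tris[[n_st + 1]] <- cbind(rep(cap_p, n_ring), a, b)
  do.call(rbind, tris)
}

#' Patellar shape parameters
#'
#' @param width_med,width_lat medial / lateral half-width (mm) of the patellar
#'   outline at the equator (Wiberg-type asymmetry: medial smaller).
#' @param half_height proximal-distal semi-axis (mm).
#' @param facet_radius transverse curvature radius (mm) of the articular
#'   surface at the median ridge. Slightly sharper than the trochlear groove
#'   radius (halfwidth^2 / 2 depth, about 16 mm for the healthy preset) so
#'   the two surfaces are congruent and contact is centered in the groove.
#' @param ridge_angle alternative specification: opening angle (deg) of the
#'   tangent facet V at the facet midpoints; when given it overrides
#'   `facet_radius` via `R = w tan(angle/2) / 2` with `w` the mean
#'   half-width.
#' @param medial_slope_scale extra steepness of the medial facet (Wiberg).
#' @param sagittal_radius convexity radius (mm) of the articular surface in
#'   the sagittal plane (trochlear groove track radius is 90 mm).
#' @param dome_height anterior (non-articular) dome height (mm).
#' @param ridge_x_offset lateral shift (mm) of the whole articular outline.
#' @param axis_tilt obliquity (deg) of the bony transverse axis relative to
#'   the articular groove axis. Clinical patellar tilt is measured on the
#'   bony axis; carrying the obliquity in the bone lets a tilted patella
#'   keep congruent facet contact (as real patellae do). Presets set it to
#'   their clinical tilt.
#' @return list of class `patella_params`.
#' @export
patella_params <- function(width_med = 17, width_lat = 21, half_height = 16,
                           facet_radius = 15.7, ridge_angle = NULL,
                           medial_slope_scale = 1.08, sagittal_radius = 88,
                           dome_height = 18, ridge_x_offset = 0,
                           axis_tilt = 12) {
  check_range(width_med, "width_med", 8, 30)
  check_range(width_lat, "width_lat", 8, 30)
  check_range(half_height, "half_height", 8, 30)
  if (!is.null(ridge_angle)) {
    check_range(ridge_angle, "ridge_angle", 100, 178)
    facet_radius <- (width_med + width_lat) / 4 * tan(deg2rad(ridge_angle) / 2) / 2
  }
  check_range(facet_radius, "facet_radius", 5, 60)
  check_range(sagittal_radius, "sagittal_radius", 15, 300)
  check_range(axis_tilt, "axis_tilt", -30, 30)
  structure(list(width_med = width_med, width_lat = width_lat,
                 half_height = half_height, facet_radius = facet_radius,
                 medial_slope_scale = medial_slope_scale,
                 sagittal_radius = sagittal_radius, dome_height = dome_height,
                 ridge_x_offset = ridge_x_offset, axis_tilt = axis_tilt),
            class = "patella_params")
}

# articular surface height field of the patella (local frame, y anterior):
# an elliptic paraboloid opening anteriorly, its vertex (the median ridge
# apex) pointing posteriorly (-y) toward the trochlea; the medial facet is
# steeper by medial_slope_scale
#' @noRd
patella_articular_y <- function(x, z, p) {
  xr <- x - p$ridge_x_offset
  s <- ifelse(xr < 0, p$medial_slope_scale, 1)
  s * xr^2 / (2 * p$facet_radius) + z^2 / (2 * p$sagittal_radius)
}

#' Generate a Wiberg-type patella matched to a trochlea
#'
#' Builds a closed shell from a posterior (articular, cartilage) disc and an
#' anterior bone dome sharing a rim, in a patellar local frame whose origin is
#' the median ridge apex. Placement into the joint happens per load case.
#'
#' @param params a [patella_params()] object.
#' @param trochlea result of [generate_trochlea()] (scale compatibility check).
#' @param resolution linear mesh density multiplier.
#' @return list with `mesh`, `thickness`, `landmarks` (local frame), `params`.
#' @export
generate_patella <- function(params = patella_params(), trochlea,
                             resolution = 1) {
  stopifnot(inherits(params, "patella_params"))
  tro_w <- diff(range(trochlea$mesh$vertices[, 1]))
  if (params$width_med + params$width_lat > tro_w) {
    pf_stop(sprintf(
      "patella width %.1f mm exceeds the trochlear bounding box width %.1f mm",
      params$width_med + params$width_lat, tro_w))
  }
  n_r <- max(5L, round(16 * resolution))
  n_phi <- 4L * max(4L, round(11 * resolution))
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[seq_len(n_phi)]
  w0 <- (params$width_lat + params$width_med) / 2
  w1 <- (params$width_lat - params$width_med) / 2
  a_phi <- w0 + w1 * cos(phi)
  r_b <- 1 / sqrt((cos(phi) / a_phi)^2 + (sin(phi) / params$half_height)^2)
  # interior (cartilage) rings reach a fixed 93% of the outline regardless of
  # resolution; the rim ring (bone, shared with the dome) sits at 100%
  rho <- c(seq_len(n_r - 1L) / (n_r - 1L) * 0.93, 1)

  n_disc <- 1L + n_r * n_phi
  verts <- matrix(0, n_disc + (n_r - 1L) * n_phi + 1L, 3)
  # articular disc: center + rings; dome shares the rim ring (rho = 1)
  verts[1, ] <- c(params$ridge_x_offset, patella_articular_y(params$ridge_x_offset, 0, params), 0)
  art_id <- function(i, j) as.integer(1L + (i - 1L) * n_phi + j)  # ring i, spoke j
  for (i in seq_len(n_r)) for (j in seq_len(n_phi)) {
    x <- rho[i] * r_b[j] * cos(phi[j]) + params$ridge_x_offset
    z <- rho[i] * r_b[j] * sin(phi[j])
    verts[art_id(i, j), ] <- c(x, patella_articular_y(x, z, params), z)
  }
  # dome interior: rings n_r-1 .. 0 (center last)
  dome_id <- function(i, j) n_disc + (n_r - 1L - i) * n_phi + j  # i in 1..n_r-1
  dome_center <- nrow(verts)
  for (i in seq_len(n_r - 1L)) for (j in seq_len(n_phi)) {
    x <- rho[i] * r_b[j] * cos(phi[j]) + params$ridge_x_offset
    z <- rho[i] * r_b[j] * sin(phi[j])
    y <- patella_articular_y(x, z, params) + params$dome_height * (1 - rho[i]^2)^0.8
    verts[dome_id(i, j), ] <- c(x, y, z)
  }
  verts[dome_center, ] <- c(params$ridge_x_offset,
                            patella_articular_y(params$ridge_x_offset, 0, params) +
                              params$dome_height, 0)

  nxt <- c(seq_len(n_phi)[-1], 1L)
  tris <- list()
  # articular disc faces -y: counter-clockwise in (x, z)
  tris[[1]] <- cbind(1L, art_id(1L, seq_len(n_phi)), art_id(1L, nxt))
  for (i in seq_len(n_r - 1L)) {
    a <- art_id(i, seq_len(n_phi)); b <- art_id(i, nxt)
    c_ <- art_id(i + 1L, nxt); d <- art_id(i + 1L, seq_len(n_phi))
    tris[[length(tris) + 1]] <- rbind(cbind(a, c_, b), cbind(a, d, c_))
  }
  # dome faces +y: reversed orientation; rim ring shared with articular disc
  ring_ids <- function(i) if (i == n_r) art_id(n_r, seq_len(n_phi)) else dome_id(i, seq_len(n_phi))
  for (i in rev(seq_len(n_r - 1L))) {
    outer <- ring_ids(i + 1L); inner <- ring_ids(i)
    a <- outer; b <- outer[nxt]; c_ <- inner[nxt]; d <- inner
    tris[[length(tris) + 1]] <- rbind(cbind(a, b, c_), cbind(a, c_, d))
  }
  in1 <- ring_ids(1L)
  tris[[length(tris) + 1]] <- cbind(dome_center, in1[nxt], in1)
  tris <- orient_outward(verts, do.call(rbind, tris))

  region <- rep("bone", nrow(verts))
  thick <- rep(NA_real_, nrow(verts))
  cart <- c(1L, as.vector(vapply(seq_len(n_r - 1L),
                                 function(i) art_id(i, seq_len(n_phi)),
                                 integer(n_phi))))
  region[cart] <- "cartilage"
  rr <- c(0, rep(rho[seq_len(n_r - 1L)], each = n_phi))
  thick[cart] <- 1.2 + 3.0 * (1 - rr^2)

  j_sup <- n_phi / 4L + 1L
  j_inf <- 3L * n_phi / 4L + 1L
  # the bony transverse axis carries the clinical tilt obliquity; its
  # endpoints sit at mid-substance height at the outline extremes
  y0 <- patella_articular_y(params$ridge_x_offset, 0, params) + 4
  slope <- tan(deg2rad(params$axis_tilt))
  x_lat <- params$ridge_x_offset + params$width_lat
  x_med <- params$ridge_x_offset - params$width_med
  landmarks <- list(
    most_lateral_patellar_point = c(x_lat, y0 - slope * x_lat, 0),
    medial_patellar_edge_midpoint = c(x_med, y0 - slope * x_med, 0),
    superior_pole = verts[art_id(n_r, j_sup), ],
    inferior_pole = verts[art_id(n_r, j_inf), ]
  )
  list(mesh = surface_mesh(verts, tris, region, side = "right"),
       thickness = thick, landmarks = landmarks, params = params)
}

#' Preset geometry and alignment parameters
#'
#' `"healthy"` reproduces a normally grooved trochlea with neutral patellar
#' tracking (tilt 12 deg, bisect offset 48.5%, TT-TG 9 mm). `"dysplastic_D"`
#' emulates a severe type-D dysplastic knee: shallow-to-convex proximal
#' trochlea with a supratrochlear spur, hypoplastic medial facet, and the
#' clinical indices of the dysplastic study knee (TT-TG 17 mm, tilt 18 deg,
#' bisect offset 76%). Only those clinical indices are targets; the remaining
#' shape parameters are design choices of the generator.
#'
#' @param preset `"healthy"` or `"dysplastic_D"`.
#' @return named list of preset parameters.
#' @export
knee_preset <- function(preset = c("healthy", "dysplastic_D")) {
  preset <- match.arg(preset)
  common <- list(jitter = 0, resolution = 1)
  geo <- if (preset == "healthy") {
    list(trochlea = dysplasia_params(sulcus_depth = 6.0),
         patella = patella_params(axis_tilt = 12),
         tt_tg = 9, tilt_deg = 12, bisect_target = 48.5)
  } else {
    list(trochlea = dysplasia_params(sulcus_depth = 1.2, spur_height = 3,
                                     medial_facet_scale = 0.75,
                                     groove_lateral_offset = -3),
         patella = patella_params(axis_tilt = 18),
         tt_tg = 17, tilt_deg = 18, bisect_target = 76)
  }
  c(list(preset = preset), common, geo)
}

#' Build a complete synthetic knee model
#'
#' @param preset `"healthy"` or `"dysplastic_D"`.
#' @param overrides named list of preset overrides (valid keys: those of
#'   [knee_preset()]); unknown keys raise an error listing the valid ones.
#' @param seed integer seed (only consumed by optional vertex jitter).
#' @param resolution linear mesh density multiplier; 1 is the reference
#'   density whose extruded cartilage meshes have a few tens of thousands of
#'   tetrahedra.
#' @param side `"right"` (native) or `"left"` (mirrored).
#' @return object of class `knee_model`: femoral and patellar surface meshes,
#'   thickness maps, landmarks, per-station profile data, alignment targets.
#' @export
build_knee <- function(preset = c("healthy", "dysplastic_D"), overrides = list(),
                       seed = 1L, resolution = 1, side = "right") {
  preset <- match.arg(preset)
  p <- knee_preset(preset)
  bad <- setdiff(names(overrides), names(p))
  if (length(bad)) {
    pf_stop("unknown override key(s) ", paste(bad, collapse = ", "),
            "; valid keys: ", paste(names(p), collapse = ", "))
  }
  p <- utils::modifyList(p, overrides)
  if (!missing(resolution)) p$resolution <- resolution
  tro_par <- p$trochlea
  tro_par$jitter <- p$jitter
  tro <- generate_trochlea(tro_par, resolution = p$resolution, seed = seed)
  pat <- generate_patella(p$patella, tro, resolution = p$resolution)
  landmarks <- c(tro$landmarks, list(
    tibial_tuberosity_reference = c(p$tt_tg, -15, -55)
  ), pat$landmarks[c("medial_patellar_edge_midpoint",
                     "most_lateral_patellar_point")])
  model <- structure(list(
    preset = preset,
    femur_surface = tro$mesh,
    patella_surface = pat$mesh,
    femur_thickness = tro$thickness,
    patella_thickness = pat$thickness,
    landmarks = landmarks,
    patella_landmarks_local = pat$landmarks,
    profiles = tro$profiles,
    loft = tro$loft,
    template = tro$template,
    depths = vapply(tro$profiles, function(pr) {
      chord_depth(pr$anchors)
    }, numeric(1)),
    alignment = list(tilt_deg = p$tilt_deg, bisect_target = p$bisect_target,
                     clearance = 0.3, reference_x = 0),
    params = p,
    side = "right"
  ), class = "knee_model")
  if (side == "left") mirror_knee(model) else model
}

# groove depth implied by a profile's anchors (chord at the sulcus abscissa)
#' @noRd
chord_depth <- function(a) {
  chord <- a$mc[2] + (a$lc[2] - a$mc[2]) * (a$s[1] - a$mc[1]) / (a$lc[1] - a$mc[1])
  chord - a$s[2]
}

#' @export
print.knee_model <- function(x, ...) {
  cat(sprintf("knee_model '%s' (%s): femur %d vtx / patella %d vtx, TT-TG target %.1f mm\n",
              x$preset, x$side, nrow(x$femur_surface$vertices),
              nrow(x$patella_surface$vertices), x$params$tt_tg))
  invisible(x)
}

#' Mirror a knee model across the sagittal plane
#'
#' Applying it twice is the identity.
#'
#' @param model a `knee_model`.
#' @return mirrored `knee_model`.
#' @export
mirror_knee <- function(model) {
  mirror_pt <- function(p) {
    if (is.matrix(p)) { p[, 1] <- -p[, 1]; p } else { p[1] <- -p[1]; p }
  }
  model$femur_surface <- mirror_mesh(model$femur_surface)
  model$patella_surface <- mirror_mesh(model$patella_surface)
  model$landmarks <- lapply(model$landmarks, mirror_pt)
  model$patella_landmarks_local <- lapply(model$patella_landmarks_local, mirror_pt)
  if (!is.null(model$alignment$reference_x)) {
    model$alignment$reference_x <- -model$alignment$reference_x
  }
  model$side <- if (model$side == "right") "left" else "right"
  model
}
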