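#' @keywords internal
"_PACKAGE"

# Consistent unit system: mm, N, MPa (N/mm^2).

#' Round half away from zero
#'
#' Fixed-point rounding where ties go away from zero (so 1.965 -> 1.97 at two
#' decimals), matching how the study tables print stress values. Base
#' `round()` rounds half to even and would print 1.96.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
deg2rad <- function(d) d * pi / 180

#' @noRd
rad2deg <- function(r) r * 180 / pi

# rotation about +z by angle (deg), 3x3
#' @noRd
rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' @noRd
vnorm <- function(v) sqrt(sum(v^2))

# row-wise norms of an n x 3 matrix
#' @noRd
row_norms <- function(m) sqrt(rowSums(m^2))

#' @noRd
unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

# stopifnot-style checked error with a consistent class so tests can target it
#' @noRd
pf_stop <- function(..., class = "patellofem_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' @noRd
check_range <- function(value, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
      value < lo || value > hi) {
    pf_stop(sprintf("parameter '%s' = %s outside allowed range [%g, %g]",
                    name, format(value), lo, hi),
            class = "patellofem_config_error")
  }
  invisible(value)
}

# monotone shape-preserving interpolator (Fritsch-Carlson) used for contours;
# returns a function of x
#' @noRd
shape_spline <- function(x, y) {
  stats::splinefun(x, y, method = "monoH.FC")
}

# linear interpolation with clamped ends
#' @noRd
lerp_fun <- function(x, y) {
  stats::approxfun(x, y, rule = 2)
}

# cosine taper: 1 inside [a, b], smooth fall to 0 over width w outside
#' @noRd
cosine_band <- function(z, a, b, w) {
  out <- numeric(length(z))
  inside <- z >= a & z <= b
  out[inside] <- 1
  if (w > 0) {
    lo <- z < a & z > a - w
    out[lo] <- 0.5 * (1 + cos(pi * (a - z[lo]) / w))
    hi <- z > b & z < b + w
    out[hi] <- 0.5 * (1 + cos(pi * (z[hi] - b) / w))
  }
  out
}
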