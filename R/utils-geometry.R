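# Small 3-vector helpers used by hydrogen placement and bond geometry.
# All coordinates are in Angstrom, angles in degrees unless noted.

vec_norm <- function(v) sqrt(sum(v * v))

vec_unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize zero vector")
  v / n
}

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle at vertex `b` formed by points `a`-`b`-`c`, in degrees.
#' @noRd
angle_deg <- function(a, b, c) {
  u <- vec_unit(a - b)
  v <- vec_unit(c - b)
  d <- sum(u * v)
  d <- max(-1, min(1, d))
  acos(d) * 180 / pi
}

#' Any unit vector perpendicular to `v`.
#' @noRd
perp_unit <- function(v) {
  v <- vec_unit(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  vec_unit(vec_cross(v, ref))
}

#' Rotate vector `v` about unit `axis` by `theta` degrees (Rodrigues).
#' @noRd
rotate_about <- function(v, axis, theta) {
  axis <- vec_unit(axis)
  th <- theta * pi / 180
  v * cos(th) + vec_cross(axis, v) * sin(th) +
    axis * sum(axis * v) * (1 - cos(th))
}

#' Direction making angle `ang` (deg) with `axis`, with azimuth chosen so the
#' direction is as close as possible to pointing toward `target` (a point
#' relative to the apex). Used for rotatable hydroxyl/amine hydrogens.
#' @noRd
cone_direction_toward <- function(axis, ang, target = NULL) {
  axis <- vec_unit(axis)
  if (is.null(target)) {
    ref <- perp_unit(axis)
  } else {
    t_perp <- target - axis * sum(target * axis)
    ref <- if (vec_norm(t_perp) < 1e-8) perp_unit(axis) else vec_unit(t_perp)
  }
  vec_unit(axis * cos(ang * pi / 180) + ref * sin(ang * pi / 180))
}
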