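#' Polar point on a constant-curvature surface
#'
#' A point given in intrinsic polar coordinates: `r` is the geodesic distance
#' from the origin (so the radial coordinate is a true arc length on the
#' surface, whatever the curvature), `theta` the angle in radians. The angle
#' is reduced to `[0, 2*pi)` at construction.
#'
#' @param r Geodesic radial distance from the origin; must be >= 0.
#' @param theta Angle in radians; any finite value, normalized modulo 2*pi.
#' @return An object of class `polar_point` with fields `r` and `theta`.
#' @examples
#' polar_point(1, pi / 2)
#' @export
polar_point <- function(r, theta) {
  stopifnot(is.numeric(r), is.numeric(theta), length(r) == length(theta))
  if (any(!is.finite(r)) || any(!is.finite(theta))) {
    stop("polar_point: coordinates must be finite")
  }
  if (any(r < 0)) stop("polar_point: radial coordinate must be >= 0")
  structure(list(r = as.numeric(r), theta = as.numeric(theta) %% (2 * pi)),
            class = "polar_point")
}

#' @export
print.polar_point <- function(x, ...) {
  cat(sprintf("<polar_point> r = %s, theta = %s rad\n",
              paste(signif(x$r, 6), collapse = ", "),
              paste(signif(x$theta, 6), collapse = ", ")))
  invisible(x)
}

#' Point in ambient Weierstrass (hyperboloid) coordinates
#'
#' Ambient coordinates `(x, y, z)` of a point on the upper sheet of the
#' hyperboloid `x^2 + y^2 - z^2 = 1/K` (K < 0), embedded in a space of
#' signature (+, +, -) with `z` the timelike coordinate.
#'
#' @param x,y,z Ambient coordinates.
#' @param K Gaussian curvature of the surface the point must lie on (< 0).
#'   When supplied, the surface equation is checked to tolerance 1e-9.
#' @return An object of class `hyperboloid_point`.
#' @export
hyperboloid_point <- function(x, y, z, K = NULL) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(z))
  if (any(z <= 0)) stop("hyperboloid_point: z must be > 0 (upper sheet)")
  if (!is.null(K)) {
    check_curvature(K, strict = TRUE)
    resid <- x^2 + y^2 - z^2 - 1 / K
    if (any(abs(resid) > 1e-9 * pmax(1, abs(1 / K)))) {
      stop("hyperboloid_point: point is off the surface x^2+y^2-z^2 = 1/K")
    }
  }
  structure(list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)),
            class = "hyperboloid_point")
}

#' @export
print.hyperboloid_point <- function(x, ...) {
  cat(sprintf("<hyperboloid_point> (%s, %s, %s)\n",
              paste(signif(x$x, 6), collapse = ","),
              paste(signif(x$y, 6), collapse = ","),
              paste(signif(x$z, 6), collapse = ",")))
  invisible(x)
}

# Validate a Gaussian curvature value. strict = TRUE requires K < 0.
check_curvature <- function(K, strict = FALSE) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K)) {
    stop("invalid curvature: K must be a single finite number")
  }
  if (strict && K >= 0) {
    stop("invalid curvature: K must be < 0 for the hyperboloid model")
  }
  if (!strict && K > 0) {
    stop("invalid curvature: K must be <= 0")
  }
  invisible(K)
}

#' Map polar coordinates onto the hyperboloid
#'
#' Weierstrass parameterization of the upper hyperboloid sheet: a point at
#' geodesic distance `r` from the apex, at angle `theta`, on the surface of
#' Gaussian curvature `K < 0`, has ambient coordinates
#' \deqn{x = \sinh(r\sqrt{-K})\cos\theta/\sqrt{-K},\quad
#'       y = \sinh(r\sqrt{-K})\sin\theta/\sqrt{-K},\quad
#'       z = \cosh(r\sqrt{-K})/\sqrt{-K}.}
#'
#' @param p A `polar_point` (vectors allowed).
#' @param K Gaussian curvature, strictly negative.
#' @return A `hyperboloid_point` on the surface `x^2+y^2-z^2 = 1/K`.
#' @examples
#' polar_to_weierstrass(polar_point(1, 0), K = -1)
#' @export
polar_to_weierstrass <- function(p, K) {
  stopifnot(inherits(p, "polar_point"))
  check_curvature(K, strict = TRUE)
  s <- sqrt(-K)
  hyperboloid_point(sinh(p$r * s) * cos(p$theta) / s,
                    sinh(p$r * s) * sin(p$theta) / s,
                    cosh(p$r * s) / s)
}

#' Minkowski inner product of two ambient points
#'
#' Bilinear form of signature (+, +, -):
#' `<p, q> = x_p x_q + y_p y_q - z_p z_q`. For any point on the hyperboloid of
#' curvature K, `<p, p> = 1/K`.
#'
#' @param p,q `hyperboloid_point` objects.
#' @return Numeric scalar (or vector, elementwise).
#' @export
minkowski_inner <- function(p, q) {
  stopifnot(inherits(p, "hyperboloid_point"), inherits(q, "hyperboloid_point"))
  p$x * q$x + p$y * q$y - p$z * q$z
}

# acosh with a round-off guard: arguments within tol below 1 are clamped to 1;
# anything lower is a genuine inconsistency (off-surface input), not round-off.
acosh_clamped <- function(a, tol = 1e-9) {
  if (any(a < 1 - tol)) {
    stop("numerical inconsistency: acosh argument < 1 beyond round-off")
  }
  acosh(pmax(a, 1))
}

#' Geodesic distance on the hyperboloid
#'
#' Distance between two points of a surface of constant Gaussian curvature
#' `K < 0`, computed through the Minkowski inner product of their Weierstrass
#' coordinates: `d = acosh(K <P, Q>) / sqrt(-K)`. The radial coordinate of
#' [polar_point()] is itself this distance from the origin.
#'
#' @param p,q `polar_point` objects (vectors allowed, recycled pairwise).
#' @param K Gaussian curvature, strictly negative.
#' @return Geodesic distance(s), >= 0.
#' @examples
#' hyperbolic_distance(polar_point(1, 0), polar_point(1, pi), K = -1) # == 2
#' @export
hyperbolic_distance <- function(p, q, K) {
  check_curvature(K, strict = TRUE)
  P <- polar_to_weierstrass(p, K)
  Q <- polar_to_weierstrass(q, K)
  acosh_clamped(K * minkowski_inner(P, Q)) / sqrt(-K)
}

#' Euclidean (flat-plane) distance between polar points
#'
#' Planar chord length
#' `sqrt(r_p^2 + r_q^2 - 2 r_p r_q cos(theta_p - theta_q))`; the `K = 0`
#' member of the constant-curvature family.
#'
#' @param p,q `polar_point` objects.
#' @return Distance(s), >= 0.
#' @export
euclidean_distance <- function(p, q) {
  stopifnot(inherits(p, "polar_point"), inherits(q, "polar_point"))
  d2 <- p$r^2 + q$r^2 - 2 * p$r * q$r * cos(p$theta - q$theta)
  sqrt(pmax(d2, 0))
}

# Pairwise distance matrix for a polar configuration under curvature K
# (K < 0 hyperbolic, K == 0 Euclidean). Used by the fitting and simulation
# layers; returns a full symmetric n x n matrix.
config_distances <- function(r, theta, K) {
  n <- length(r)
  stopifnot(length(theta) == n)
  if (K < 0) {
    s <- sqrt(-K)
    x <- sinh(r * s) * cos(theta) / s
    y <- sinh(r * s) * sin(theta) / s
    z <- cosh(r * s) / s
    inner <- outer(x, x) + outer(y, y) - outer(z, z)
    arg <- pmax(K * inner, 1)
    d <- acosh(arg) / s
  } else if (K == 0) {
    x <- r * cos(theta)
    y <- r * sin(theta)
    d2 <- outer(x, x, function(a, b) (a - b)^2) +
      outer(y, y, function(a, b) (a - b)^2)
    d <- sqrt(pmax(d2, 0))
  } else {
    stop("invalid curvature: K must be <= 0")
  }
  diag(d) <- 0
  d
}
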