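#' Perception functions for money and time
#'
#' How objective dollars and months are mapped into the decision space before
#' any geometry is applied. Both the money map `phi` and the time map `eta`
#' are strictly increasing with `phi(0) = eta(0) = 0`; each is either the
#' identity (`"linear"`) or a power function (Stevens-law form `m^alpha`,
#' `t^beta`).
#'
#' The default keeps both maps linear. In particular time is NOT log-compressed
#' up front: logarithmic-looking perception is a consequence the curved
#' geometry must produce on its own, so building it into `eta` would beg the
#' question the model answers.
#'
#' @param money_form `"linear"` or `"power"`.
#' @param alpha Exponent of the money power map (> 0); ignored when linear.
#' @param time_form `"linear"` or `"power"`.
#' @param beta Exponent of the time power map (> 0); ignored when linear.
#' @return An object of class `perception_spec`.
#' @examples
#' perception_spec()                          # phi(m)=m, eta(t)=t
#' perception_spec("power", alpha = 0.88)     # Stevens-law money perception
#' @export
perception_spec <- function(money_form = c("linear", "power"), alpha = 1,
                            time_form = c("linear", "power"), beta = 1) {
  money_form <- match.arg(money_form)
  time_form <- match.arg(time_form)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            is.numeric(beta), length(beta) == 1L, beta > 0)
  structure(list(money_form = money_form, alpha = alpha,
                 time_form = time_form, beta = beta),
            class = "perception_spec")
}

#' @export
print.perception_spec <- function(x, ...) {
  fm <- function(form, e, sym, arg) {
    if (form == "linear") sprintf("%s(%s) = %s", sym, arg, arg)
    else sprintf("%s(%s) = %s^%g", sym, arg, arg, e)
  }
  cat("<perception_spec>", fm(x$money_form, x$alpha, "phi", "m"), "|",
      fm(x$time_form, x$beta, "eta", "t"), "\n")
  invisible(x)
}

#' Perceived value of money
#'
#' `phi(m)`: identity or `m^alpha` according to the [perception_spec()].
#'
#' @param m Monetary amount(s) in dollars, >= 0.
#' @param spec A `perception_spec`.
#' @return Perceived value(s), same length as `m`.
#' @export
perceived_money <- function(m, spec = perception_spec()) {
  stopifnot(inherits(spec, "perception_spec"))
  if (any(m < 0)) stop("perceived_money: m must be >= 0")
  if (spec$money_form == "linear") m else m^spec$alpha
}

#' Perceived magnitude of a delay
#'
#' `eta(t)`: identity (default, t in months) or `t^beta`.
#'
#' @param t Delay(s) in months, >= 0.
#' @param spec A `perception_spec`.
#' @return Perceived magnitude(s).
#' @export
perceived_time <- function(t, spec = perception_spec()) {
  stopifnot(inherits(spec, "perception_spec"))
  if (any(t < 0)) stop("perceived_time: t must be >= 0")
  if (spec$time_form == "linear") t else t^spec$beta
}

# Derivatives of the perception maps, needed by the closed-form partials.
perceived_money_deriv <- function(m, spec) {
  if (spec$money_form == "linear") rep(1, length(m))
  else spec$alpha * m^(spec$alpha - 1)
}
perceived_time_deriv <- function(t, spec) {
  if (spec$time_form == "linear") rep(1, length(t))
  else spec$beta * t^(spec$beta - 1)
}

#' The Gamma factor of a money-time bundle
#'
#' `Gamma = sqrt(1 + phi(m)^2 + eta(t)^2)`, the quantity whose inverse
#' hyperbolic cosine is the bundle's distance from the origin when K = -1.
#' Always >= 1.
#'
#' @param m Amount(s) in dollars.
#' @param t Delay(s) in months.
#' @param spec A `perception_spec`.
#' @return `Gamma` value(s) >= 1.
#' @export
gamma_factor <- function(m, t, spec = perception_spec()) {
  sqrt(1 + perceived_money(m, spec)^2 + perceived_time(t, spec)^2)
}

#' Discounting spec: curvature and leak rate
#'
#' Bundles the two parameters of the leaking-bucket discount process: the
#' Gaussian curvature `K` of the decision space (1/length^2, < 0 for the
#' curved model) and `psi`, the fraction of value lost per unit of distance
#' travelled (1/length, >= 0). `psi = 1` is unit loss, the paperless default
#' of constant unit discounting per unit distance.
#'
#' @param K Gaussian curvature, <= 0 (0 only meaningful for control models).
#' @param psi Leak fraction per unit distance, >= 0.
#' @return An object of class `discount_spec`.
#' @export
discount_spec <- function(K = -1, psi = 1) {
  check_curvature(K)
  stopifnot(is.numeric(psi), length(psi) == 1L, psi >= 0)
  structure(list(K = K, psi = psi), class = "discount_spec")
}

#' @export
print.discount_spec <- function(x, ...) {
  cat(sprintf("<discount_spec> K = %g, psi = %g\n", x$K, x$psi))
  invisible(x)
}

#' Distance of a money-time bundle from the decision-space origin
#'
#' The geodesic distance between the origin (the present, nothing) and the
#' embedded bundle `(phi(m), eta(t))` on the surface of curvature `K < 0`:
#' \deqn{d_h = \mathrm{acosh}\!\left(\sqrt{1 - K(\phi^2 + \eta^2)}\right)
#'       / \sqrt{-K}.}
#' At `K = -1` this is `acosh(Gamma) = log(Gamma + sqrt(Gamma^2 - 1))`, and as
#' `K -> 0-` it tends to the Euclidean norm `sqrt(phi^2 + eta^2)`.
#'
#' @param m Amount(s) in dollars.
#' @param t Delay(s) in months.
#' @param spec A `perception_spec`.
#' @param K Gaussian curvature, strictly negative.
#' @return Distance(s) in model units, >= 0.
#' @examples
#' decision_distance(2, 2, perception_spec(), K = -1)  # acosh(3)
#' @export
decision_distance <- function(m, t, spec = perception_spec(), K = -1) {
  check_curvature(K, strict = TRUE)
  u <- perceived_money(m, spec)^2 + perceived_time(t, spec)^2
  acosh_clamped(sqrt(1 - K * u)) / sqrt(-K)
}

#' Discounted perceived value of a delayed amount
#'
#' The leaking-bucket solution: carrying `y0` a distance `d_h` across the
#' decision space leaves `phi(y0) * exp(-psi * d_h)`, where `d_h` is the
#' distance of the bundle `(y0, t)` from the origin. Non-increasing in `t`
#' and in `psi`.
#'
#' @param y0 Initial amount(s) in dollars, >= 0.
#' @param t Delay(s) in months.
#' @param disc A `discount_spec` (needs `K < 0`).
#' @param spec A `perception_spec`.
#' @return Discounted perceived value(s) in perceived-money units.
#' @export
discounted_value <- function(y0, t, disc = discount_spec(),
                             spec = perception_spec()) {
  stopifnot(inherits(disc, "discount_spec"))
  if (any(y0 < 0)) stop("discounted_value: y0 must be >= 0")
  phi0 <- perceived_money(y0, spec)
  if (disc$psi == 0) return(phi0)
  dh <- decision_distance(y0, t, spec, disc$K)
  phi0 * exp(-disc$psi * dh)
}

#' Closed-form partial derivatives of the bundle distance
#'
#' With `u = phi(m)^2 + eta(t)^2` and `A = sqrt(1 - K u)`,
#' \deqn{\partial d_h/\partial t = \eta(t)\,\eta'(t) / (A \sqrt{u}), \qquad
#'       \partial d_h/\partial m = \phi(m)\,\phi'(m) / (A \sqrt{u}).}
#' Both are positive away from the origin and vanish as their argument grows.
#' The second derivative in `t` (returned as `dt2`) is negative — the distance
#' is concave in the delay — whenever the perceived delay dominates the
#' perceived amount (exactly: `phi^2 (1 - K u) < -K eta^2 u`); with a large
#' amount and a short delay the distance is locally convex in `t`.
#' Subadditivity of the distance in the delay holds regardless of this local
#' regime, because the distance at zero delay is already positive.
#'
#' @param m Amount(s), dollars.
#' @param t Delay(s), months.
#' @param spec A `perception_spec`.
#' @param K Gaussian curvature, strictly negative.
#' @return A list with components `dt`, `dm` (first partials) and `dt2`
#'   (second partial in `t`).
#' @export
distance_partials <- function(m, t, spec = perception_spec(), K = -1) {
  check_curvature(K, strict = TRUE)
  phi <- perceived_money(m, spec)
  eta <- perceived_time(t, spec)
  u <- phi^2 + eta^2
  if (any(u == 0)) {
    stop("singular point: distance is not differentiable at the origin")
  }
  A <- sqrt(1 - K * u)
  dphi <- perceived_money_deriv(m, spec)
  deta <- perceived_time_deriv(t, spec)
  den <- A * sqrt(u)
  dt <- eta * deta / den
  dm <- phi * dphi / den
  # d/dt [eta eta' / (A sqrt(u))]; u' = 2 eta eta', A' = -K eta eta' / A
  deta2 <- if (spec$time_form == "linear") rep(0, length(t)) else
    spec$beta * (spec$beta - 1) * t^(spec$beta - 2)
  num_d <- deta^2 + eta * deta2
  den_d <- eta * deta * (1 - 2 * K * u) / den   # d(A sqrt u)/dt; A^2 - K u
  dt2 <- (num_d * den - eta * deta * den_d) / den^2
  list(dt = dt, dm = dm, dt2 = dt2)
}

#' Instantaneous discount rate
#'
#' The proportional decay of discounted value with delay,
#' `-(d/dt) exp(-psi d_h) / exp(-psi d_h) = psi * d(d_h)/dt`. Declines with
#' `t` (common-difference effect) and with `m` (magnitude effect), both to 0
#' in the limit — the geometry, not a fitted rate schedule, produces the
#' variable rate.
#'
#' @param m Amount(s), dollars (> 0 unless t > 0).
#' @param t Delay(s), months, > 0 recommended.
#' @param disc A `discount_spec` with `K < 0`.
#' @param spec A `perception_spec`.
#' @return Rate(s) in 1/months.
#' @export
discount_rate <- function(m, t, disc = discount_spec(),
                          spec = perception_spec()) {
  stopifnot(inherits(disc, "discount_spec"))
  disc$psi * distance_partials(m, t, spec, disc$K)$dt
}
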