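#' Phenomenon reports
#'
#' Each demonstration in this module returns a `phenomenon_report`: a named
#' verdict (`holds`/`fails`), the inputs that produced it, and a `witness`
#' list of the numeric evidence (crossover delay, subadditivity gap,
#' inequality margins). Verdicts are pure functions of the inputs — no RNG,
#' no hidden state.
#'
#' @param name Label of the phenomenon.
#' @param inputs Named list of the parameters used.
#' @param verdict Logical: does the phenomenon hold under these inputs?
#' @param witness Named list of numeric evidence.
#' @return An object of class `phenomenon_report`.
#' @keywords internal
phenomenon_report <- function(name, inputs, verdict, witness) {
  structure(list(name = name, inputs = inputs,
                 verdict = isTRUE(verdict), witness = witness),
            class = "phenomenon_report")
}

#' @export
print.phenomenon_report <- function(x, ...) {
  cat(sprintf("<phenomenon_report> %s: %s\n", x$name,
              if (x$verdict) "holds" else "fails"))
  w <- unlist(x$witness)
  if (length(w)) {
    cat(paste0("  ", names(w), " = ", signif(w, 6), collapse = "\n"), "\n")
  }
  invisible(x)
}

# Tolerance for calling two discounted values "indifferent".
.tie_tol <- 1e-12

# Discounted value under either the curved model or the exponential-on-t
# (discounted-utility) control, which discounts at a constant rate on raw
# delay and therefore can show none of the distance-driven phenomena.
.value_fn <- function(mode, disc, spec) {
  if (mode == "nc") {
    function(x, t) discounted_value(x, t, disc, spec)
  } else {
    function(x, t) perceived_money(x, spec) * exp(-disc$psi * t)
  }
}

#' Common-difference preference reversal
#'
#' Scans a common extra delay `n` added to both options of a smaller-sooner
#' `(x1, t1)` vs larger-later `(x2, t2)` choice. Under curved-space
#' discounting the smaller-sooner option wins at `n = 0` but the ranking
#' reverses at some finite `n` (the stationarity violation); under the
#' exponential control (`mode = "exponential"`, constant rate on raw delay)
#' the ranking can never reverse. Unit-month scan, then bisection refinement
#' of the crossover.
#'
#' @param x1,t1 Smaller-sooner amount and delay.
#' @param x2,t2 Larger-later amount and delay; requires `x2 > x1`, `t2 > t1`.
#' @param disc A `discount_spec`.
#' @param spec A `perception_spec`.
#' @param n_max Largest common delay scanned (months).
#' @param mode `"nc"` (curved model) or `"exponential"` (DU control).
#' @return A `phenomenon_report`; `witness$crossover` is the smallest common
#'   delay at which preference flips (NA if none).
#' @export
find_preference_reversal <- function(x1, t1, x2, t2,
                                     disc = discount_spec(),
                                     spec = perception_spec(),
                                     n_max = 1000, mode = c("nc", "exponential")) {
  mode <- match.arg(mode)
  if (!(x2 > x1 && x1 > 0)) stop("domain error: need x2 > x1 > 0")
  if (!(t2 > t1 && t1 >= 0)) stop("domain error: need t2 > t1 >= 0")
  v <- .value_fn(mode, disc, spec)
  gap <- function(n) v(x1, t1 + n) - v(x2, t2 + n)
  g0 <- gap(0)
  sooner_first <- g0 > .tie_tol
  crossover <- NA_real_
  if (sooner_first) {
    ns <- seq(0, n_max, by = 1)
    gs <- vapply(ns, gap, numeric(1))
    flip <- which(gs < -.tie_tol)
    if (length(flip)) {
      hi <- ns[flip[1]]
      lo <- if (flip[1] > 1) ns[flip[1] - 1] else 0
      crossover <- stats::uniroot(gap, c(lo, hi), tol = 1e-9)$root
    }
  }
  phenomenon_report(
    "common-difference preference reversal",
    list(x1 = x1, t1 = t1, x2 = x2, t2 = t2, K = disc$K, psi = disc$psi,
         n_max = n_max, mode = mode),
    verdict = sooner_first && is.finite(crossover),
    witness = list(gap_at_zero = g0, crossover = crossover)
  )
}

#' Subadditivity of the bundle distance
#'
#' Along one axis (delay or amount, the other held fixed), the distance of the
#' whole is at most the sum of the distances of its parts:
#' `d_h(a + b) <= d_h(a) + d_h(b)`. The discounting consequence — an amount
#' discounted over an undivided interval retains more value than when the
#' interval (or amount) is split — is reported alongside the gap.
#'
#' @param a,b Non-negative parts to be combined (months or dollars, per axis).
#' @param fixed Value of the axis held constant (dollars if `axis = "time"`,
#'   months if `axis = "money"`).
#' @param axis `"time"` or `"money"`.
#' @param spec A `perception_spec`.
#' @param K Gaussian curvature, < 0.
#' @param psi Leak rate for the discounting consequence.
#' @return A `phenomenon_report`; `witness$gap = d(a)+d(b)-d(a+b) >= 0`,
#'   `witness$whole_ratio` and `witness$divided_ratio` the retained fractions.
#' @export
subadditivity_gap <- function(a, b, fixed = 100, axis = c("time", "money"),
                              spec = perception_spec(), K = -1, psi = 1) {
  axis <- match.arg(axis)
  if (any(c(a, b) < 0)) stop("domain error: parts must be >= 0")
  d <- if (axis == "time") {
    function(x) decision_distance(fixed, x, spec, K)
  } else {
    function(x) decision_distance(x, fixed, spec, K)
  }
  gap <- d(a) + d(b) - d(a + b)
  whole <- exp(-psi * d(a + b))
  divided <- exp(-psi * (d(a) + d(b)))
  phenomenon_report(
    paste0(axis, " subadditivity"),
    list(a = a, b = b, fixed = fixed, axis = axis, K = K, psi = psi),
    verdict = gap >= -1e-12 && whole >= divided,
    witness = list(gap = gap, whole_ratio = whole, divided_ratio = divided)
  )
}

#' Absolute magnitude effect
#'
#' Evaluates the instantaneous discount rate along an increasing grid of
#' amounts at a fixed delay; the rate must be strictly decreasing (larger
#' amounts are discounted less steeply) and tend to zero.
#'
#' @param m_grid Strictly increasing positive amounts (dollars).
#' @param t Fixed delay (months).
#' @param disc A `discount_spec`.
#' @param spec A `perception_spec`.
#' @return A `phenomenon_report`; `witness` carries the rates.
#' @export
magnitude_effect_curve <- function(m_grid = c(100, 200, 3000, 4500), t = 6,
                                   disc = discount_spec(),
                                   spec = perception_spec()) {
  if (any(m_grid <= 0) || is.unsorted(m_grid, strictly = TRUE)) {
    stop("domain error: m_grid must be strictly increasing and positive")
  }
  rates <- vapply(m_grid, function(m) discount_rate(m, t, disc, spec),
                  numeric(1))
  phenomenon_report(
    "absolute magnitude effect",
    list(m_grid = m_grid, t = t, K = disc$K, psi = disc$psi),
    verdict = all(diff(rates) < 0),
    witness = as.list(stats::setNames(rates, paste0("rate_m", m_grid)))
  )
}

#' Preference for improving sequences
#'
#' Brute-forces all 6 assignments of three amounts to three dates and checks
#' that the improving assignment (smallest amount soonest, largest last)
#' maximizes total discounted value, and the declining assignment minimizes
#' it.
#'
#' @param amounts Three strictly increasing amounts (dollars).
#' @param times Three strictly increasing delays (months).
#' @param disc A `discount_spec`.
#' @param spec A `perception_spec`.
#' @return A `phenomenon_report`; `witness` holds all 6 totals, named by the
#'   amount ordering over the time slots.
#' @export
sequence_preference <- function(amounts = c(100, 200, 300),
                                times = c(1, 6, 12),
                                disc = discount_spec(),
                                spec = perception_spec()) {
  stopifnot(length(amounts) == 3, length(times) == 3)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("domain error: times must be strictly increasing")
  }
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  totals <- vapply(perms, function(p) {
    sum(discounted_value(amounts[p], times, disc, spec))
  }, numeric(1))
  names(totals) <- vapply(perms, function(p) {
    paste(amounts[p], collapse = "-")
  }, character(1))
  tied <- max(totals) - min(totals) <= .tie_tol * max(1, max(totals))
  improving_best <- tied || which.max(totals) == 1L
  declining_worst <- tied || which.min(totals) == 6L
  phenomenon_report(
    "preference for improving sequences",
    list(amounts = amounts, times = times, K = disc$K, psi = disc$psi),
    verdict = improving_best && declining_worst,
    witness = as.list(totals)
  )
}

#' Attenuation of subadditivity at distant times
#'
#' For a delay `t` pushed into the future by `g` and divided into `1/n` and
#' `(n-1)/n` parts, the excess marginal distance of the divided over the
#' undivided delay,
#' `Delta(g) = d'((t+g)/n) + d'((n-1)(t+g)/n) - d'(t+g)`
#' (derivatives of the bundle distance in its delay argument at fixed `m`),
#' is non-negative, non-increasing in `g`, and vanishes as `g` grows: the
#' subadditive pull of dividing an interval fades in the distant future.
#' `n = 1` (no division) gives `Delta == 0` identically.
#'
#' The default `m = 0` evaluates the pure-delay profile — the marginal
#' distance along the time axis alone, the regime the phenomenon concerns.
#' With a large fixed amount the short-delay end sits in the amount-dominant
#' (locally convex) regime, where the profile need not be monotone near
#' `g = 0`. The decay is of order `1/g`: at `K = -1`, `n = 2` the profile
#' behaves like `3/g` for large `g`.
#'
#' @param t Base delay (months), > 0.
#' @param n Number of parts the interval is (conceptually) divided into, >= 1.
#' @param g_grid Increasing non-negative grid of extra delays (months).
#' @param m Fixed amount (dollars), >= 0; 0 gives the pure-delay profile.
#' @param spec A `perception_spec`.
#' @param K Gaussian curvature, < 0.
#' @return A `phenomenon_report`; `witness` carries `Delta` along `g_grid`.
#' @export
distant_subadditivity_profile <- function(t = 12, n = 2,
                                          g_grid = c(0, 10, 100, 1e4),
                                          m = 0,
                                          spec = perception_spec(), K = -1) {
  if (n < 1) stop("domain error: n must be >= 1")
  if (t <= 0) stop("domain error: t must be > 0")
  if (any(g_grid < 0) || is.unsorted(g_grid)) {
    stop("domain error: g_grid must be increasing and >= 0")
  }
  dprime <- function(x) {
    vapply(x, function(xi) {
      if (xi == 0 && m == 0) return(NA_real_)
      if (xi == 0) return(0)  # eta = 0 kills the numerator away from origin
      distance_partials(m, xi, spec, K)$dt
    }, numeric(1))
  }
  delta <- vapply(g_grid, function(g) {
    x <- t + g
    if (n == 1) return(0)  # undivided: no second part, Delta vanishes exactly
    dprime(x / n) + dprime((n - 1) * x / n) - dprime(x)
  }, numeric(1))
  phenomenon_report(
    "distant-time subadditivity attenuation",
    list(t = t, n = n, g_grid = g_grid, m = m, K = K),
    verdict = all(delta >= -1e-12) && all(diff(delta) <= 1e-12),
    witness = as.list(stats::setNames(delta, paste0("Delta_g", g_grid)))
  )
}

#' Loss/gain discounting asymmetry via curvature
#'
#' Steeper discounting of delayed gains than accelerated gains requires the
#' gain-domain curvature to be more negative than the loss-domain curvature:
#' with `K_G < K_L < 0`, the discount rate under `K_L` exceeds the rate under
#' `K_G` at every point of a money-time grid, and swapping the two curvatures
#' reverses the inequality.
#'
#' @param m_grid Amounts grid (dollars).
#' @param t_grid Delays grid (months), > 0.
#' @param K_G,K_L Gain- and loss-domain curvatures, both < 0, `K_G < K_L`.
#' @param psi Leak rate.
#' @param spec A `perception_spec`.
#' @return A `phenomenon_report`; `witness` has the minimal rate margin and
#'   its value after swapping the curvatures.
#' @export
loss_gain_curvature_check <- function(m_grid = seq(50, 500, by = 50),
                                      t_grid = c(1, 6, 12, 24, 36),
                                      K_G = -2, K_L = -0.5, psi = 1,
                                      spec = perception_spec()) {
  check_curvature(K_G, strict = TRUE)
  check_curvature(K_L, strict = TRUE)
  grid <- expand.grid(m = m_grid, t = t_grid)
  rate_under <- function(K) {
    mapply(function(m, t) discount_rate(m, t, discount_spec(K, psi), spec),
           grid$m, grid$t)
  }
  margin <- rate_under(K_L) - rate_under(K_G)   # > 0 iff K_G < K_L
  phenomenon_report(
    "loss/gain curvature asymmetry",
    list(K_G = K_G, K_L = K_L, psi = psi),
    verdict = all(margin > 0),
    witness = list(min_margin = min(margin), max_margin = max(margin))
  )
}
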