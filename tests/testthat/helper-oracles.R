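# Independent numerical oracles used across the suite.

# Geodesic length by arc-length minimization over a discretized path in the
# intrinsic polar metric ds^2 = dr^2 + sinh^2(r s)/s^2 dtheta^2 (s = sqrt(-K)).
# Independent of the Minkowski/acosh route the package uses: only the metric
# line element enters. Midpoint-rule segments, free interior knots.
geodesic_length_numeric <- function(p, q, K, n_seg = 80) {
  s <- sqrt(-K)
  path_length <- function(r, theta) {
    rm <- (r[-1] + r[-length(r)]) / 2
    sum(sqrt(diff(r)^2 + (sinh(rm * s) / s)^2 * diff(theta)^2))
  }
  # unwrap the angular difference onto (-pi, pi]
  dth <- (q$theta - p$theta + pi) %% (2 * pi) - pi
  t_grid <- seq(0, 1, length.out = n_seg + 1)
  r0 <- p$r + (q$r - p$r) * t_grid
  th0 <- p$theta + dth * t_grid
  free <- 2:n_seg
  obj <- function(par) {
    r <- r0
    th <- th0
    r[free] <- par[seq_along(free)]
    th[free] <- par[length(free) + seq_along(free)]
    path_length(r, th)
  }
  fit <- stats::optim(c(r0[free], th0[free]), obj, method = "BFGS",
                      control = list(maxit = 400, reltol = 1e-12))
  fit$value
}

# Central finite difference of f at x.
central_diff <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# A deterministic 5-point polar configuration used by several fit tests.
fixture_config <- function() {
  list(r = c(0, 0.8, 1.5, 2.2, 3.0), theta = c(0, 0, 0.7, 1.5, 2.4))
}

fixture_distance_matrix <- function(K, labels = c(0, 1, 9, 18, 36)) {
  cfg <- fixture_config()
  distance_matrix(labels, riemdisc:::config_distances(cfg$r, cfg$theta, K))
}

# A clean 20-row participant on the 0/1/9/18/36 grid with $100/$200 bases,
# built from a strictly monotone distance profile (no violations).
fixture_participant <- function(id = "P1", ratio_fun = NULL) {
  grid <- c(0, 1, 9, 18, 36)
  pairs <- t(utils::combn(grid, 2))
  if (is.null(ratio_fun)) {
    ratio_fun <- function(ti, tj) 1 + 0.05 * (tj - ti)
  }
  rows <- do.call(rbind, lapply(c(100, 200), function(b) {
    data.frame(participant_id = id, base_amount = b,
               t_i = pairs[, 1], t_j = pairs[, 2],
               matched_amount = b * ratio_fun(pairs[, 1], pairs[, 2]),
               attention_failed = FALSE)
  }))
  rows
}
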