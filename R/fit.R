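#' Fit options for the embedding algorithms
#'
#' @param n_restarts Number of annealing restarts; the best objective wins.
#' @param sann_iter Simulated-annealing iterations per restart.
#' @param k_bounds Search interval for the curvature estimate (negative).
#' @param min_points Identifiability floor on the number of embedded points.
#' @return A list of options.
#' @export
fit_options <- function(n_restarts = 20, sann_iter = 150,
                        k_bounds = c(-25, -1e-4), min_points = 4) {
  stopifnot(n_restarts >= 1, sann_iter >= 1,
            k_bounds[1] < k_bounds[2], k_bounds[2] < 0)
  list(n_restarts = n_restarts, sann_iter = sann_iter,
       k_bounds = k_bounds, min_points = min_points)
}

# Can the observed distances be embedded on a single line (within tol)?
# Distances along one geodesic ray are additive and carry no curvature
# information, so a line-embeddable matrix leaves K unidentifiable.
line_embeddable <- function(D, tol = 1e-8) {
  d <- D$d
  n <- nrow(d)
  c1 <- d[1, ]                      # |coordinate| relative to point 1
  signs <- rep(1, n)
  for (k in seq_len(n)[-1]) {
    # choose the sign making the distance to point 2 consistent
    if (k == 2) next
    err_pos <- abs(abs(c1[k] - c1[2]) - d[2, k])
    err_neg <- abs(abs(-c1[k] - c1[2]) - d[2, k])
    signs[k] <- if (err_neg < err_pos) -1 else 1
  }
  coords <- signs * c1
  resid <- abs(abs(outer(coords, coords, "-")) - d)
  max(resid) <= tol * max(1, max(d))
}

# epsilon^2 objective for a parameter vector. Layout:
#   NC:        c(r[2..n], theta[3..n], log(-K))
#   Euclidean: c(r[2..n], theta[3..n])
# Gauge: point 1 at the origin (r = 0), point 2 on the theta = 0 ray.
# Radial coordinates are reflected through 0 so annealing can roam freely.
embed_objective <- function(par, dobs, n, nc, lk_bounds) {
  r <- c(0, abs(par[seq_len(n - 1)]))
  theta <- c(0, 0, par[n:(2 * n - 3)])
  if (nc) {
    lk <- min(max(par[2 * n - 2], lk_bounds[1]), lk_bounds[2])
    K <- -exp(lk)
  } else {
    K <- 0
  }
  dhat <- config_distances(r, theta, K)
  sum((dobs - dhat[lower.tri(dhat)])^2)
}

# Triangulation warm start: radial coordinates from distances to the gauge
# origin, angles from the planar law of cosines against point 2, each sign
# chosen greedily against the points already placed.
warm_start <- function(d) {
  n <- nrow(d)
  r <- d[1, ]
  theta <- numeric(n)
  for (k in seq_len(n)[-(1:2)]) {
    if (r[k] == 0 || r[2] == 0) { theta[k] <- 0; next }
    ca <- (r[2]^2 + r[k]^2 - d[2, k]^2) / (2 * r[2] * r[k])
    ang <- acos(min(max(ca, -1), 1))
    placed <- seq_len(k - 1)
    score <- function(th) {
      x <- r[placed] * cos(theta[placed]) - r[k] * cos(th)
      y <- r[placed] * sin(theta[placed]) - r[k] * sin(th)
      sum((sqrt(x^2 + y^2) - d[placed, k])^2)
    }
    theta[k] <- if (score(-ang) < score(ang)) -ang else ang
  }
  list(r = r, theta = theta)
}

# One annealing run + gradient polish from a given start.
anneal_once <- function(par0, dobs, n, nc, opts) {
  lkb <- sort(log(-opts$k_bounds))
  obj <- function(p) embed_objective(p, dobs, n, nc, lkb)
  scale0 <- max(stats::sd(dobs), 0.1)
  par <- stats::optim(par0, obj, method = "SANN",
                      control = list(maxit = opts$sann_iter, temp = scale0,
                                     tmax = 10))$par
  lower <- c(rep(0, n - 1), rep(-2 * pi, n - 2))
  upper <- c(rep(Inf, n - 1), rep(2 * pi, n - 2))
  if (nc) {
    lower <- c(lower, lkb[1])
    upper <- c(upper, lkb[2])
  }
  par[seq_len(n - 1)] <- abs(par[seq_len(n - 1)])
  fit <- stats::optim(pmin(pmax(par, lower), upper), obj,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(maxit = 500, factr = 1e4))
  fit
}

fit_geometry <- function(D, geometry, opts, seed) {
  stopifnot(inherits(D, "distance_matrix"))
  nc <- geometry == "nc"
  n <- length(D$labels)
  if (n < opts$min_points) {
    stop("under-identified: need at least ", opts$min_points,
         " points to fit a 2D embedding", if (nc) " plus a curvature" else "")
  }
  dobs <- upper_tri(D)
  if (stats::sd(dobs) == 0) {
    stop("degenerate matrix: observed distances have zero spread")
  }
  if (nc && line_embeddable(D)) {
    warning("curvature unidentifiable: distances embed on a single geodesic ",
            "ray; the objective is flat in K")
  }
  if (!is.null(seed)) set.seed(seed)
  ws <- warm_start(D$d)
  lkb <- sort(log(-opts$k_bounds))
  lk_grid <- seq(lkb[1], lkb[2], length.out = max(opts$n_restarts, 2))
  scale0 <- max(stats::sd(dobs), 0.1)

  best <- NULL
  for (i in seq_len(opts$n_restarts)) {
    if (i == 1) {
      r0 <- ws$r[-1]
      th0 <- ws$theta[-(1:2)]
    } else {
      r0 <- abs(ws$r[-1] + stats::rnorm(n - 1, 0, 0.3 * scale0))
      th0 <- ws$theta[-(1:2)] + stats::rnorm(n - 2, 0, 0.6)
    }
    par0 <- c(r0, th0)
    if (nc) par0 <- c(par0, if (i <= 2) 0 else sample(lk_grid, 1))
    fit <- anneal_once(par0, dobs, n, nc, opts)
    if (is.null(best) || fit$value < best$value) best <- fit
  }

  par <- best$par
  r <- c(0, abs(par[seq_len(n - 1)]))
  theta <- c(0, 0, par[n:(2 * n - 3)]) %% (2 * pi)
  K_hat <- if (nc) -exp(unname(par[2 * n - 2])) else 0
  eps2 <- best$value
  ratio <- sqrt(eps2 / length(dobs)) / stats::sd(dobs)
  structure(list(geometry = if (nc) "NC" else "Euclidean",
                 labels = D$labels, r = r, theta = theta,
                 K_hat = K_hat, epsilon2 = eps2, fit_ratio = ratio,
                 seed = seed, n_restarts = opts$n_restarts),
            class = "geometry_fit")
}

#' Fit a negative-curvature embedding to a distance matrix
#'
#' Embeds the n temporal points on a surface of constant negative Gaussian
#' curvature by minimizing
#' `epsilon^2 = sum_{i<j} (d_ij - dhat_h(i,j))^2` over the polar coordinates
#' and the curvature estimate `K_hat`, where `dhat_h` runs through the
#' Weierstrass parameterization and the hyperboloid geodesic distance. Gauge
#' freedoms are fixed (point 1 at the origin, point 2 on the zero-angle ray),
#' leaving `2n - 3` coordinates plus `K_hat`. Optimization is simulated
#' annealing followed by a bounded quasi-Newton polish, restarted from a
#' triangulation warm start plus random perturbations; the best restart wins.
#'
#' @param D A [distance_matrix()].
#' @param opts Options from [fit_options()].
#' @param seed RNG seed recorded in the fit (optional but recommended).
#' @return A `geometry_fit` with coordinates, `K_hat`, `epsilon2` and the
#'   RMSE/SD `fit_ratio`.
#' @export
fit_negative_curvature <- function(D, opts = fit_options(), seed = NULL) {
  fit_geometry(D, "nc", opts, seed)
}

#' Fit a flat (Euclidean) embedding to a distance matrix
#'
#' Same objective and gauge as [fit_negative_curvature()] but with planar
#' distances and `K_hat` pinned at 0.
#'
#' @inheritParams fit_negative_curvature
#' @return A `geometry_fit` with `K_hat = 0`.
#' @export
fit_euclidean <- function(D, opts = fit_options(), seed = NULL) {
  fit_geometry(D, "euclidean", opts, seed)
}

#' @export
print.geometry_fit <- function(x, ...) {
  cat(sprintf(
    "<geometry_fit> %s: epsilon^2 = %.4g, RMSE/SD = %.4g%s (%d restarts)\n",
    x$geometry, x$epsilon2, x$fit_ratio,
    if (x$geometry == "NC") sprintf(", K_hat = %.4g", x$K_hat) else "",
    x$n_restarts))
  invisible(x)
}

#' Fit quality: RMSE over the SD of the observed distances
#'
#' `sqrt(epsilon^2 / (n(n-1)/2)) / sd(d_ij)` — the dimensionless criterion on
#' which the two geometries are compared.
#'
#' @param fit A `geometry_fit`.
#' @param D The `distance_matrix` it was fitted to.
#' @return A non-negative scalar.
#' @export
fit_quality <- function(fit, D) {
  stopifnot(inherits(fit, "geometry_fit"), inherits(D, "distance_matrix"))
  dobs <- upper_tri(D)
  s <- stats::sd(dobs)
  if (s == 0) stop("degenerate matrix: observed distances have zero spread")
  sqrt(fit$epsilon2 / length(dobs)) / s
}

#' Classify one participant: curved, flat, or tie
#'
#' Compares the RMSE/SD fit ratios of the two geometries. With
#' `margin = (ratio_E - ratio_NC) / ratio_E`:
#' * `NC_better` if `margin >= tie_threshold` and `|K_hat| >= kappa0`;
#' * `tie` if `|margin| < tie_threshold`;
#' * `Euclidean_better` if `margin <= -tie_threshold`, or if the
#'   negative-curvature fit wins on margin but its estimated curvature is
#'   essentially zero (`|K_hat| < kappa0`) — a flat solution in disguise.
#'
#' @param fit_nc Negative-curvature `geometry_fit`.
#' @param fit_e Euclidean `geometry_fit` on the same matrix.
#' @param kappa0 Curvature magnitude below which an NC win is read as flat.
#' @param tie_threshold Relative improvement below which fits are tied.
#' @return An object of class `participant_classification` with `label`
#'   (`"NC_better"`, `"tie"`, `"Euclidean_better"`), `margin` and `K_hat`.
#' @export
classify_participant <- function(fit_nc, fit_e, kappa0 = 0.01,
                                 tie_threshold = 0.01) {
  stopifnot(inherits(fit_nc, "geometry_fit"), inherits(fit_e, "geometry_fit"))
  rn <- fit_nc$fit_ratio
  re <- fit_e$fit_ratio
  margin <- if (re <= .Machine$double.eps) 0 else (re - rn) / re
  label <- if (abs(margin) < tie_threshold) {
    "tie"
  } else if (margin >= tie_threshold && abs(fit_nc$K_hat) >= kappa0) {
    "NC_better"
  } else {
    "Euclidean_better"
  }
  structure(list(label = label, margin = margin, K_hat = fit_nc$K_hat,
                 ratio_NC = rn, ratio_E = re),
            class = "participant_classification")
}

#' @export
print.participant_classification <- function(x, ...) {
  cat(sprintf(
    "<classification> %s (margin %.3f, K_hat %.4g, RMSE/SD NC %.4g E %.4g)\n",
    x$label, x$margin, x$K_hat, x$ratio_NC, x$ratio_E))
  invisible(x)
}

#' Cohort chi-square on classification counts
#'
#' Tests the split of participants for whom the negative-curvature embedding
#' fits better against an even 50:50 split. In the conservative reading, ties
#' and flat-curvature wins all count AGAINST the curved decision space:
#' `a` = NC_better, `b = N - a`, and
#' `chi^2 = 2 (a - N/2)^2 / (N/2)` on 1 df (no continuity correction), with
#' the upper-tail p-value.
#'
#' @param classifications List of `participant_classification` objects, or a
#'   character vector of labels.
#' @param conservative Count ties/flat wins against the curved model
#'   (currently the only supported reading kept explicit for clarity).
#' @return An object of class `cohort_result` with `a`, `b`, `N`, `chi2`, `p`
#'   and the label table.
#' @export
aggregate_chi_square <- function(classifications, conservative = TRUE) {
  labels <- if (is.character(classifications)) classifications else
    vapply(classifications, function(x) x$label, character(1))
  N <- length(labels)
  if (N == 0) stop("empty cohort: no retained participants")
  a <- sum(labels == "NC_better")
  b <- N - a
  if (!conservative) {
    # non-conservative reading: ties split out, test NC_better vs E_better
    b <- sum(labels == "Euclidean_better")
    N2 <- a + b
    if (N2 == 0) stop("empty cohort: no decisive classifications")
    chi2 <- 2 * (a - N2 / 2)^2 / (N2 / 2)
    N <- N2
  } else {
    chi2 <- 2 * (a - N / 2)^2 / (N / 2)
  }
  structure(list(a = a, b = b, N = N, chi2 = chi2,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 labels = table(factor(labels, levels = c(
                   "NC_better", "tie", "Euclidean_better")))),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf(
    "<cohort_result> NC better for %d of %d: chi^2(1) = %.3f, p = %.4g\n",
    x$a, x$N, x$chi2, x$p))
  print(x$labels)
  invisible(x)
}
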