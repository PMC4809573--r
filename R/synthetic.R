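#' Ground truth for a synthetic participant
#'
#' Bundles everything needed to generate one participant's data: the true
#' curvature, a polar configuration of the temporal points in their decision
#' space, the SD of log-scale response noise, the seed, and the study design
#' (temporal grid in months and the base amounts in dollars).
#'
#' Defaults mirror the elicitation design this generator emulates: the
#' five-point grid 0/1/9/18/36 months crossed with $100 and $200 bases
#' (20 matching responses per participant) and multiplicative response noise
#' of 5% on the matched amounts.
#'
#' @param K_true True Gaussian curvature (<= 0; 0 = flat).
#' @param config List with `r` and `theta` (polar configuration), e.g. from
#'   [make_configuration()].
#' @param noise_sigma SD of additive noise on log-distances / log-ratios.
#' @param seed RNG seed making the participant reproducible.
#' @param time_grid Temporal design points (months).
#' @param base_amounts Matching-task base amounts (dollars).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(K_true = -1, config = NULL, noise_sigma = 0.05,
                         seed = 1, time_grid = c(0, 1, 9, 18, 36),
                         base_amounts = c(100, 200)) {
  check_curvature(K_true)
  stopifnot(noise_sigma >= 0)
  if (is.null(config)) {
    config <- make_configuration(length(time_grid), "spread", seed = seed)
  }
  stopifnot(length(config$r) == length(time_grid))
  structure(list(K_true = K_true, config = config,
                 noise_sigma = noise_sigma, seed = seed,
                 time_grid = time_grid, base_amounts = base_amounts),
            class = "ground_truth")
}

#' Generate a polar configuration of decision-space points
#'
#' Three layouts:
#' * `"spread"` — angles drawn uniformly on a half-turn, sorted, with a
#'   minimum separation of `pi / (2n)`; radii sorted increasing from
#'   `params$r_range` (default `c(1.5, 4)` model units), the first point (the
#'   "now" point) at the origin. The ordered arc makes latent distances grow
#'   with the temporal horizon, as monotone matching responses imply, and the
#'   radial span keeps curvature of magnitude ~1 resolvable against the
#'   design's response noise (curvature signal in a distance scales with
#'   r^2, noise only with r).
#' * `"collinear"` — all points on one ray (equal angles). Distances along a
#'   single geodesic are additive in any constant-curvature geometry, so this
#'   layout deliberately leaves the curvature unidentifiable (used to test
#'   that the fitter flags it).
#' * `"model_based"` — point k sits at radial coordinate
#'   `decision_distance(mean base, t_k)` under `params$K_true`, with spread
#'   angles: the configuration the discounting model itself implies for the
#'   temporal grid.
#'
#' @param n Number of points, >= 3.
#' @param layout `"spread"`, `"collinear"` or `"model_based"`.
#' @param params Layout parameters: `r_range` (spread/collinear),
#'   `K_true`, `time_grid`, `base_amount`, `spec` (model_based).
#' @param seed RNG seed.
#' @return List with numeric `r` and `theta` of length `n`.
#' @export
make_configuration <- function(n, layout = c("spread", "collinear",
                                             "model_based"),
                               params = list(), seed = 1) {
  layout <- match.arg(layout)
  if (n < 3) stop("domain error: need at least 3 points")
  set.seed(seed)
  spread_angles <- function(n) {
    min_sep <- pi / (2 * n)
    repeat {
      th <- sort(stats::runif(n, 0, pi))
      if (all(diff(th) >= min_sep)) return(th)
    }
  }
  if (layout == "model_based") {
    K_true <- params$K_true %||% -1
    grid <- params$time_grid %||% c(0, 1, 9, 18, 36)
    stopifnot(length(grid) == n)
    m_bar <- params$base_amount %||% 150
    spec <- params$spec %||% perception_spec()
    r <- if (K_true < 0) {
      decision_distance(m_bar, grid, spec, K_true)
    } else {
      sqrt(perceived_money(m_bar, spec)^2 + perceived_time(grid, spec)^2)
    }
    theta <- spread_angles(n)
  } else {
    r_range <- params$r_range %||% c(1.5, 4)
    r <- c(0, sort(stats::runif(n - 1, r_range[1], r_range[2])))
    theta <- if (layout == "collinear") rep(0, n) else spread_angles(n)
  }
  list(r = r, theta = theta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact or noisy distance matrix from a ground truth
#'
#' Pairwise distances of the configuration under `K_true` (hyperboloid
#' geodesics if negative, planar if 0). With `noise_sigma > 0` each distance
#' is multiplied by `exp(eps)`, `eps ~ N(0, noise_sigma^2)` — noise on the
#' log scale, matching the log-ratio transform the elicitation applies — and
#' stays non-negative by construction.
#'
#' @param gt A [ground_truth()].
#' @return A [distance_matrix()] labelled with the temporal grid.
#' @export
simulate_distance_matrix <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  d <- config_distances(gt$config$r, gt$config$theta, gt$K_true)
  if (gt$noise_sigma > 0) {
    set.seed(gt$seed)
    n <- nrow(d)
    eps <- matrix(0, n, n)
    eps[lower.tri(eps)] <- stats::rnorm(n * (n - 1) / 2, 0, gt$noise_sigma)
    d <- d * exp(eps + t(eps))
  }
  distance_matrix(gt$time_grid, d)
}

#' Simulate one participant's matching responses
#'
#' Inverts the elicitation transform: for every ordered temporal pair and
#' every base amount, the matched amount is
#' `y_j = y_i * exp(d_ij) * exp(eps)` with independent `eps ~
#' N(0, noise_sigma^2)` per response. At zero noise,
#' [distances_from_matching()] recovers `d_ij` exactly.
#'
#' @param gt A [ground_truth()].
#' @param participant_id Label for the participant column.
#' @param inject_violations Number of artificial smaller-later violations to
#'   plant (for exclusion-rule tests): the matched amount of the first
#'   `inject_violations` pairs at the first base is set below the base.
#' @param attention_failed Value of the attention flag.
#' @return A `matching_responses` data.frame (one participant).
#' @export
simulate_participant_responses <- function(gt, participant_id = "P1",
                                           inject_violations = 0,
                                           attention_failed = FALSE) {
  stopifnot(inherits(gt, "ground_truth"))
  if (length(gt$time_grid) < 4 || length(gt$base_amounts) < 1) {
    stop("design must include >= 4 temporal points and >= 1 base amount")
  }
  d <- config_distances(gt$config$r, gt$config$theta, gt$K_true)
  pairs <- t(utils::combn(seq_along(gt$time_grid), 2))
  set.seed(gt$seed)
  rows <- do.call(rbind, lapply(gt$base_amounts, function(b) {
    data.frame(participant_id = participant_id,
               base_amount = b,
               t_i = gt$time_grid[pairs[, 1]],
               t_j = gt$time_grid[pairs[, 2]],
               matched_amount = b * exp(d[pairs]) *
                 exp(stats::rnorm(nrow(pairs), 0, gt$noise_sigma)),
               attention_failed = attention_failed)
  }))
  if (inject_violations > 0) {
    idx <- seq_len(min(inject_violations, nrow(pairs)))
    rows$matched_amount[idx] <- rows$base_amount[idx] * 0.9
  }
  load_responses(rows)
}

#' Simulate a full cohort of matching responses
#'
#' Each participant gets an independent configuration (fresh seed) and
#' responses under the shared design. Default cohort size 35 with the
#' 0/1/9/18/36-month grid and sigma = 0.05, sized to a typical retained
#' sample.
#'
#' @param n_participants Cohort size.
#' @param K_true Shared true curvature.
#' @param noise_sigma Response noise SD (log scale).
#' @param layout Configuration layout (see [make_configuration()]);
#'   `"spread"` by default, whose latent distances are on the scale of the
#'   log amount ratios real matching data produce.
#' @param seed Master seed; per-participant seeds are derived from it.
#' @param time_grid,base_amounts Study design.
#' @return A `matching_responses` table for the whole cohort.
#' @export
simulate_cohort <- function(n_participants = 35, K_true = -1,
                            noise_sigma = 0.05, layout = "spread",
                            seed = 7, time_grid = c(0, 1, 9, 18, 36),
                            base_amounts = c(100, 200)) {
  set.seed(seed)
  seeds <- sample.int(2^31 - 1, n_participants)
  parts <- lapply(seq_len(n_participants), function(i) {
    cfg <- make_configuration(length(time_grid), layout,
                              params = list(K_true = K_true,
                                            time_grid = time_grid),
                              seed = seeds[i])
    gt <- ground_truth(K_true = K_true, config = cfg,
                       noise_sigma = noise_sigma, seed = seeds[i],
                       time_grid = time_grid, base_amounts = base_amounts)
    simulate_participant_responses(gt, participant_id = sprintf("P%03d", i))
  })
  load_responses(do.call(rbind, parts))
}

#' Parameter-recovery experiment over simulated conditions
#'
#' For each condition (a true curvature, a noise level, a layout), simulates
#' `reps` participants, runs the full pipeline — distance matrix, both
#' geometry fits, classification — and summarizes the curvature recovery and
#' the classification rates. Everything is reproducible from the seeds.
#'
#' @param conditions A data.frame with columns `K_true`, `noise_sigma` and
#'   optionally `layout`.
#' @param reps Participants per condition, >= 1.
#' @param seed Master seed.
#' @param opts [fit_options()] passed to the fitters.
#' @param kappa0 Near-zero curvature threshold for classification.
#' @param time_grid Temporal design.
#' @return A data.frame, one row per condition: median `K_hat`, the share of
#'   each classification label, and median fit ratios.
#' @export
recovery_experiment <- function(conditions, reps = 20, seed = 1,
                                opts = fit_options(n_restarts = 6),
                                kappa0 = 0.01,
                                time_grid = c(0, 1, 9, 18, 36)) {
  stopifnot(reps >= 1, is.data.frame(conditions))
  if (is.null(conditions$layout)) conditions$layout <- "spread"
  set.seed(seed)
  seeds <- matrix(sample.int(2^31 - 1, reps * nrow(conditions)),
                  nrow = nrow(conditions))
  out <- lapply(seq_len(nrow(conditions)), function(ci) {
    K_true <- conditions$K_true[ci]
    sig <- conditions$noise_sigma[ci]
    fits <- lapply(seq_len(reps), function(j) {
      s <- seeds[ci, j]
      cfg <- make_configuration(length(time_grid), conditions$layout[ci],
                                params = list(K_true = K_true,
                                              time_grid = time_grid),
                                seed = s)
      gt <- ground_truth(K_true = K_true, config = cfg, noise_sigma = sig,
                         seed = s, time_grid = time_grid)
      D <- simulate_distance_matrix(gt)
      f_nc <- fit_negative_curvature(D, opts, seed = s)
      f_e <- fit_euclidean(D, opts, seed = s)
      cl <- classify_participant(f_nc, f_e, kappa0 = kappa0)
      list(K_hat = f_nc$K_hat, label = cl$label,
           ratio_NC = f_nc$fit_ratio, ratio_E = f_e$fit_ratio)
    })
    labels <- vapply(fits, `[[`, character(1), "label")
    data.frame(
      K_true = K_true, noise_sigma = sig, layout = conditions$layout[ci],
      reps = reps,
      median_K_hat = stats::median(vapply(fits, `[[`, numeric(1), "K_hat")),
      prop_NC_better = mean(labels == "NC_better"),
      prop_tie = mean(labels == "tie"),
      prop_E_better = mean(labels == "Euclidean_better"),
      median_ratio_NC = stats::median(
        vapply(fits, `[[`, numeric(1), "ratio_NC")),
      median_ratio_E = stats::median(
        vapply(fits, `[[`, numeric(1), "ratio_E"))
    )
  })
  do.call(rbind, out)
}
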