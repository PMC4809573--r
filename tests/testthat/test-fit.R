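opts_fast <- fit_options(n_restarts = 8)

test_that("noiseless hyperbolic distances: configuration and curvature recovered", {
  D <- fixture_distance_matrix(-1)
  fit <- fit_negative_curvature(D, opts_fast, seed = 101)
  expect_lt(fit$epsilon2, 1e-6)
  expect_equal(fit$K_hat, -1, tolerance = 0.05)
  expect_equal(fit_quality(fit, D), fit$fit_ratio, tolerance = 1e-12)
})

test_that("noiseless Euclidean distances: flat recovery by both algorithms", {
  D <- fixture_distance_matrix(0)
  fit_e <- fit_euclidean(D, opts_fast, seed = 102)
  expect_lt(fit_e$epsilon2, 1e-6)
  expect_identical(fit_e$K_hat, 0)
  fit_nc <- fit_negative_curvature(D, opts_fast, seed = 102)
  expect_lt(abs(fit_nc$K_hat), 0.01)   # curvature recovered as (near) zero
  # nested model: the curved family contains the flat solution
  expect_lte(fit_nc$epsilon2, fit_e$epsilon2 + 1e-6)
})

test_that("a 3-4-5 triangle embeds exactly in the plane", {
  D <- distance_matrix(c(0, 1, 2), c(3, 4, 5))
  fit <- fit_euclidean(D, fit_options(n_restarts = 8, min_points = 3),
                       seed = 103)
  expect_lt(fit$epsilon2, 1e-10)
})

test_that("hyperbolic data penalize the flat embedding", {
  D <- fixture_distance_matrix(-1)
  fit_nc <- fit_negative_curvature(D, opts_fast, seed = 104)
  fit_e <- fit_euclidean(D, opts_fast, seed = 104)
  expect_lt(fit_nc$epsilon2, fit_e$epsilon2)
  cl <- classify_participant(fit_nc, fit_e)
  expect_equal(cl$label, "NC_better")
})

test_that("degenerate and under-identified inputs error; collinear warns", {
  D <- fixture_distance_matrix(-1)
  small <- distance_matrix(c(0, 1, 2), c(3, 4, 5))
  expect_error(fit_negative_curvature(small), "under-identified")
  zero <- distance_matrix(c(0, 1, 9, 18), rep(2, 6))
  expect_error(fit_negative_curvature(zero), "degenerate")
  # collinear configuration: additive distances identify no curvature
  cfg <- make_configuration(5, "collinear", seed = 9)
  dm <- riemdisc:::config_distances(cfg$r, cfg$theta, -1)
  Dcol <- distance_matrix(c(0, 1, 9, 18, 36), dm)
  expect_warning(fit_negative_curvature(Dcol, opts_fast, seed = 105),
                 "unidentifiable")
})

test_that("objective is gauge invariant under rotation of the configuration", {
  D <- fixture_distance_matrix(-1)
  fit <- fit_negative_curvature(D, opts_fast, seed = 106)
  rot <- runif(1, 0, 2 * pi)
  d_rot <- riemdisc:::config_distances(fit$r, (fit$theta + rot) %% (2 * pi),
                                       fit$K_hat)
  eps2_rot <- sum((riemdisc:::upper_tri(D) - d_rot[lower.tri(d_rot)])^2)
  expect_equal(eps2_rot, fit$epsilon2, tolerance = 1e-9)
  # reflection too
  d_ref <- riemdisc:::config_distances(fit$r, (-fit$theta) %% (2 * pi),
                                       fit$K_hat)
  eps2_ref <- sum((riemdisc:::upper_tri(D) - d_ref[lower.tri(d_ref)])^2)
  expect_equal(eps2_ref, fit$epsilon2, tolerance = 1e-9)
})

test_that("fit ratio is RMSE over the SD of observed distances", {
  D <- fixture_distance_matrix(-1)
  fit <- fit_negative_curvature(D, opts_fast, seed = 107)
  expect_equal(fit_quality(fit, D),
               sqrt(fit$epsilon2 / 10) / sd(riemdisc:::upper_tri(D)),
               tolerance = 1e-12)
  expect_lt(fit_quality(fit, D), 1e-3)   # perfect fit -> ratio ~ 0
})

test_that("classification rules: margin thresholds and the near-zero-curvature override", {
  mk <- function(ratio, K = -1, geom = "NC") {
    structure(list(geometry = geom, fit_ratio = ratio, K_hat = K,
                   epsilon2 = ratio^2),
              class = "geometry_fit")
  }
  # clear NC win
  cl <- classify_participant(mk(0.10), mk(0.20, 0, "Euclidean"))
  expect_equal(cl$label, "NC_better")
  expect_equal(cl$margin, 0.5)
  # sub-1% improvement is a tie
  cl2 <- classify_participant(mk(0.1000), mk(0.1005, 0, "Euclidean"))
  expect_equal(cl2$label, "tie")
  expect_lt(abs(cl2$margin), 0.01)
  # NC wins on margin but the estimated curvature is essentially flat
  cl3 <- classify_participant(mk(0.07, K = -0.001), mk(0.10, 0, "Euclidean"))
  expect_equal(cl3$label, "Euclidean_better")
  # Euclidean outright better
  cl4 <- classify_participant(mk(0.20), mk(0.10, 0, "Euclidean"))
  expect_equal(cl4$label, "Euclidean_better")
})

test_that("cohort chi-square matches the closed form and the base-R oracle", {
  labs1 <- c(rep("NC_better", 25), rep("tie", 6), rep("Euclidean_better", 4))
  res1 <- aggregate_chi_square(labs1)
  expect_equal(res1$N, 35)
  expect_equal(res1$a, 25)
  expect_equal(res1$chi2, 2 * (25 - 17.5)^2 / 17.5, tolerance = 1e-12)
  expect_equal(res1$chi2, 6.43, tolerance = 0.005)
  # independent oracle: goodness-of-fit chi-square against a 50:50 split
  expect_equal(res1$chi2,
               unname(chisq.test(c(25, 10), p = c(0.5, 0.5))$statistic),
               tolerance = 1e-12)
  expect_lt(res1$p, 0.05)

  labs2 <- c(rep("NC_better", 31), rep("tie", 4), rep("Euclidean_better", 3))
  res2 <- aggregate_chi_square(labs2)
  expect_equal(res2$chi2, 15.158, tolerance = 0.0005)
  expect_lt(res2$p, 1e-3)

  even <- c(rep("NC_better", 10), rep("Euclidean_better", 10))
  expect_equal(aggregate_chi_square(even)$chi2, 0)
  expect_error(aggregate_chi_square(character(0)), "empty cohort")
})
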