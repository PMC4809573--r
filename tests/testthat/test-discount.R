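test_that("perception maps: identity, power, domain checks", {
  lin <- perception_spec()
  expect_equal(perceived_money(100, lin), 100)
  expect_equal(perceived_money(0, lin), 0)
  pw <- perception_spec("power", alpha = 0.88)
  expect_equal(perceived_money(100, pw), 100^0.88, tolerance = 1e-12)
  expect_equal(perceived_time(18, lin), 18)
  expect_equal(perceived_time(4, perception_spec(time_form = "power",
                                                 beta = 0.5)), 2)
  expect_error(perceived_money(-1, lin), ">= 0")
  expect_error(perceived_time(-1, lin), ">= 0")
  # strictly increasing with phi(0) = 0
  m <- seq(0, 50, by = 0.5)
  expect_true(all(diff(perceived_money(m, pw)) > 0))
})

test_that("Gamma factor and the K = -1 distance agree with the log form", {
  spec <- perception_spec()
  expect_equal(gamma_factor(0, 0, spec), 1)
  expect_equal(gamma_factor(2, 2, spec), 3)
  expect_equal(gamma_factor(3, 4, spec), sqrt(26))

  # Gamma-form vs radical-form distance agree at K = -1; acosh/log identity
  set.seed(11)
  m <- runif(40, 0, 30)
  t <- runif(40, 0, 30)
  g <- gamma_factor(m, t, spec)
  d <- decision_distance(m, t, spec, K = -1)
  expect_equal(d, acosh(g), tolerance = 1e-14)
  expect_equal(acosh(g), log(g + sqrt(g^2 - 1)), tolerance = 1e-12)
})

test_that("decision distance: known values and the Euclidean limit", {
  spec <- perception_spec()
  expect_equal(decision_distance(0, 0, spec, -1), 0)
  expect_equal(decision_distance(2, 2, spec, -1), acosh(3), tolerance = 1e-12)
  expect_equal(decision_distance(3, 4, spec, -1e-6), 5, tolerance = 1e-3)
  expect_error(decision_distance(1, 1, spec, K = 0.1), "invalid curvature")
})

test_that("discounted value: no-leak identity, known value, monotonicity", {
  spec <- perception_spec()
  expect_equal(discounted_value(7, 12, discount_spec(-1, psi = 0), spec), 7)
  expect_equal(discounted_value(2, 2, discount_spec(-1, 1), spec),
               2 * exp(-acosh(3)), tolerance = 1e-12)
  expect_equal(discounted_value(0, 0, discount_spec(-1, 1), spec), 0)
  # strictly decreasing in t and in psi
  t <- seq(0, 60, by = 1)
  v <- discounted_value(100, t, discount_spec(-1, 1), spec)
  expect_true(all(diff(v) < 0))
  psis <- c(0.2, 0.5, 1, 2)
  vp <- vapply(psis, function(ps) {
    discounted_value(100, 12, discount_spec(-1, ps), spec)
  }, numeric(1))
  expect_true(all(diff(vp) < 0))
})

test_that("closed-form partials match central differences", {
  set.seed(12)
  for (i in 1:50) {
    m <- runif(1, 0.5, 200)
    t <- runif(1, 0.5, 60)
    K <- -runif(1, 0.05, 4)
    spec <- if (i %% 2 == 0) perception_spec() else
      perception_spec("power", alpha = 0.88, "power", beta = 0.8)
    p <- distance_partials(m, t, spec, K)
    num_t <- central_diff(function(x) decision_distance(m, x, spec, K), t,
                          h = 1e-4 * max(1, t))
    num_m <- central_diff(function(x) decision_distance(x, t, spec, K), m,
                          h = 1e-4 * max(1, m))
    expect_equal(p$dt, num_t, tolerance = 1e-6)
    expect_equal(p$dm, num_m, tolerance = 1e-6)
    expect_gt(p$dt, 0)
    expect_gt(p$dm, 0)
  }
  expect_error(distance_partials(0, 0), "singular point")
})

test_that("distance is concave in the delay once the delay term dominates", {
  # the concavity condition is phi^2 (1 - K u) < -K eta^2 u: it holds wherever
  # the perceived delay outweighs the perceived amount, the regime in which
  # subdividing an interval inflates its total perceived length
  set.seed(16)
  for (i in 1:50) {
    m <- runif(1, 0, 2)
    t <- runif(1, 5, 50)
    K <- -runif(1, 0.1, 3)
    expect_lt(distance_partials(m, t, perception_spec(), K)$dt2, 0)
  }
  # amount-dominant counter-regime: convex in t near the origin of the delay
  expect_gt(distance_partials(100, 1, perception_spec(), -1)$dt2, 0)
})

test_that("second partial in t matches a finite-difference Hessian", {
  set.seed(13)
  for (i in 1:10) {
    m <- runif(1, 1, 100)
    t <- runif(1, 1, 40)
    K <- -runif(1, 0.2, 2)
    spec <- perception_spec()
    d2 <- distance_partials(m, t, spec, K)$dt2
    f <- function(x) decision_distance(m, x, spec, K)
    h <- 1e-4 * max(1, t)
    num <- (f(t + h) - 2 * f(t) + f(t - h)) / h^2
    expect_equal(d2, num, tolerance = 1e-4)
  }
})

test_that("discount rate matches -D'/D of the discounted value and vanishes in both limits", {
  spec <- perception_spec()
  set.seed(14)
  for (i in 1:10) {
    m <- runif(1, 1, 300)
    t <- runif(1, 1, 48)
    disc <- discount_spec(K = -runif(1, 0.1, 3), psi = runif(1, 0.3, 2))
    rate <- discount_rate(m, t, disc, spec)
    Dv <- function(x) discounted_value(m, x, disc, spec)
    num <- -central_diff(Dv, t, h = 1e-4 * max(1, t)) / Dv(t)
    expect_equal(rate, num, tolerance = 1e-6)
  }
  disc <- discount_spec(-1, 1)
  expect_lt(discount_rate(100, 1e6, disc, spec), 1e-5)
  expect_lt(discount_rate(1e6, 12, disc, spec), 1e-5)
})

test_that("bundle distance is subadditive in each argument", {
  spec <- perception_spec()
  set.seed(15)
  for (i in 1:100) {
    a <- runif(1, 0, 30)
    b <- runif(1, 0, 30)
    fixed <- runif(1, 0, 100)
    K <- -runif(1, 0.1, 3)
    dt <- function(x) decision_distance(fixed, x, spec, K)
    dm <- function(x) decision_distance(x, fixed, spec, K)
    expect_lte(dt(a + b), dt(a) + dt(b) + 1e-12)
    expect_lte(dm(a + b), dm(a) + dm(b) + 1e-12)
  }
})
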