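test_that("loader accepts complete designs and rejects broken ones", {
  rows <- fixture_participant()
  resp <- load_responses(rows)
  expect_s3_class(resp, "matching_responses")
  expect_equal(nrow(resp), 20)                     # 10 pairs x 2 bases
  expect_equal(attr(resp, "time_grid"), c(0, 1, 9, 18, 36))
  expect_equal(attr(resp, "base_amounts"), c(100, 200))

  # a CSV round trip through disk behaves identically
  f <- tempfile(fileext = ".csv")
  write.csv(rows, f, row.names = FALSE)
  expect_equal(nrow(load_responses(f)), 20)

  expect_error(load_responses(rows[-1, ]), "incomplete design")
  bad <- rows; bad$matched_amount[3] <- 0
  expect_error(load_responses(bad), "positive")
  bad2 <- rows; bad2$t_j[1] <- bad2$t_i[1]
  expect_error(load_responses(bad2), "t_j must exceed t_i")
  expect_error(load_responses(rows[, -2]), "missing columns")
})

test_that("exclusion rules: attention check, and more than one violation", {
  clean <- fixture_participant("ok")
  att <- fixture_participant("inattentive")
  att$attention_failed <- TRUE

  # one violation only: matched amount drops once across horizons
  # (indifferent to $200 after 1 unit but only $150 after a longer one)
  one <- fixture_participant("one_slip")
  i18 <- which(one$base_amount == 100 & one$t_i == 0 & one$t_j == 18)
  i36 <- which(one$base_amount == 100 & one$t_i == 0 & one$t_j == 36)
  one$matched_amount[i18] <- 200
  one$matched_amount[i36] <- 150

  # two violations: excluded
  two <- fixture_participant("two_slips")
  j18 <- which(two$base_amount == 200 & two$t_i == 0 & two$t_j == 18)
  j36 <- which(two$base_amount == 200 & two$t_i == 0 & two$t_j == 36)
  two$matched_amount[i18] <- 400; two$matched_amount[i36] <- 300
  two$matched_amount[j18] <- 800; two$matched_amount[j36] <- 600

  resp <- load_responses(rbind(clean, att, one, two))
  res <- apply_exclusions(resp)
  expect_setequal(unique(res$retained$participant_id), c("ok", "one_slip"))
  expect_setequal(res$excluded$participant_id, c("inattentive", "two_slips"))
  expect_equal(
    res$excluded$reason[res$excluded$participant_id == "inattentive"],
    "attention_check")
  expect_equal(
    res$excluded$reason[res$excluded$participant_id == "two_slips"],
    "monotonicity_violations")
  # a smaller-later match (y_j <= y_i) also counts as a violation
  le <- fixture_participant("le_base")
  k <- which(le$base_amount == 100 & le$t_i == 0 & le$t_j == 1)
  le$matched_amount[k] <- 90
  expect_equal(riemdisc:::count_violations(load_responses(le)), 1)
})

test_that("distances: mean of ratios then log, alpha scaling, floor at zero", {
  # constant ratio 2 at both bases -> log(2) everywhere it applies
  resp <- load_responses(fixture_participant(
    "r2", ratio_fun = function(ti, tj) rep(2, length(ti))))
  D <- distances_from_matching(resp)
  expect_s3_class(D, "distance_matrix")
  expect_equal(unname(riemdisc:::upper_tri(D)), rep(log(2), 10),
               tolerance = 1e-12)
  D88 <- distances_from_matching(resp, alpha = 0.88)
  expect_equal(unname(riemdisc:::upper_tri(D88)), rep(0.88 * log(2), 10),
               tolerance = 1e-12)

  # mean of ratios then log (not mean of logs): bases disagree
  resp2 <- fixture_participant("mix")
  resp2$matched_amount <- ifelse(resp2$base_amount == 100,
                                 resp2$base_amount * 2,
                                 resp2$base_amount * 4)
  D2 <- distances_from_matching(load_responses(resp2))
  expect_equal(unname(riemdisc:::upper_tri(D2)), rep(log(3), 10),
               tolerance = 1e-12)

  # equal matched and base amounts -> zero distance, no warning
  resp3 <- load_responses(fixture_participant(
    "flat0", ratio_fun = function(ti, tj) rep(1, length(ti))))
  expect_equal(max(riemdisc:::upper_tri(distances_from_matching(resp3))), 0)

  # ratio < 1 floors at zero with a warning
  resp4 <- fixture_participant("neg")
  k <- which(resp4$t_i == 0 & resp4$t_j == 1)
  resp4$matched_amount[k] <- resp4$base_amount[k] * 0.8
  expect_warning(D4 <- distances_from_matching(load_responses(resp4)),
                 "floored")
  expect_gte(min(riemdisc:::upper_tri(D4)), 0)
})

test_that("distances are scale invariant in the base amount", {
  rows <- fixture_participant("base")
  doubled <- rows
  doubled$base_amount <- rows$base_amount * 2
  doubled$matched_amount <- rows$matched_amount * 2
  d1 <- riemdisc:::upper_tri(distances_from_matching(load_responses(rows)))
  d2 <- riemdisc:::upper_tri(distances_from_matching(load_responses(doubled)))
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("alpha sweep is exactly linear in the distances", {
  resp <- load_responses(fixture_participant("lin"))
  d1 <- riemdisc:::upper_tri(distances_from_matching(resp, alpha = 1))
  for (a in seq(0.2, 1.4, by = 0.2)) {
    da <- riemdisc:::upper_tri(distances_from_matching(resp, alpha = a))
    expect_equal(da, a * d1, tolerance = 1e-12)
  }
})

test_that("distance matrix JSON round trip preserves labels and values", {
  D <- fixture_distance_matrix(-1)
  f <- tempfile(fileext = ".json")
  write_distance_matrix(D, f)
  D2 <- read_distance_matrix(f)
  expect_equal(D2$labels, D$labels)
  expect_equal(D2$d, D$d, tolerance = 1e-12)
})
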