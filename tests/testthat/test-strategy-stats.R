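test_that("chi-squared matches hand computations and fills the effect class", {
  even <- chi_squared(matrix(c(5, 5, 5, 5), 2))
  expect_equal(even$chi2, 0)
  expect_equal(even$cramers_v, 0)
  expect_equal(even$effect_class, "weak")

  diag20 <- chi_squared(matrix(c(10, 0, 0, 10), 2))
  expect_equal(diag20$chi2, 20)
  expect_equal(diag20$df, 1L)
  expect_equal(diag20$cramers_v, 1)
  expect_equal(diag20$effect_class, "strong")

  # expected margins 5.5 / 4.5: chi2 = 20 * (8*7 - 2*3)^2 / (10*10*11*9)
  t22 <- chi_squared(matrix(c(8, 3, 2, 7), 2))
  expect_equal(t22$chi2, 20 * (8 * 7 - 2 * 3)^2 / (10 * 10 * 11 * 9),
               tolerance = 1e-12)
  expect_equal(t22$chi2, 5.050505, tolerance = 1e-6)

  expect_error(chi_squared(matrix(c(4, 6, 0, 0), 2)),
               class = "pp_degenerate_error")
})

test_that("chi-squared is permutation invariant and V stays in [0, 1]", {
  set.seed(31)
  for (rep in 1:25) {
    m <- matrix(rpois(6, 8) + 1, 2, 3)
    base <- chi_squared(m)
    perm <- chi_squared(m[2:1, c(2, 3, 1)])
    expect_equal(perm$chi2, base$chi2, tolerance = 1e-12)
    expect_gte(base$cramers_v, 0)
    expect_lte(base$cramers_v, 1)
  }
  # any diagonal 2x2 table has V = 1
  expect_equal(chi_squared(matrix(c(3, 0, 0, 17), 2))$cramers_v, 1)
})

test_that("Cramer's V formula reproduces the printed effect sizes", {
  # n = 39 back-derived from the run-up-speed row of the same table
  v <- cramers_v(26.542, 39, 2, 2)
  expect_equal(round(v$cramers_v, 3), 0.825)
  expect_equal(v$effect_class, "strong")
  expect_equal(cramers_v(0, 34, 2, 2)$cramers_v, 0)
  expect_equal(cramers_v(0, 34, 2, 2)$effect_class, "weak")
  expect_equal(cramers_v(20, 20, 2, 2)$cramers_v, 1)
})

test_that("point-biserial equals Pearson on 0/1 coding", {
  r <- point_biserial(c(0, 0, 1, 1), c(1, 2, 3, 4))
  expect_equal(r$r_pb, 2 / sqrt(5), tolerance = 1e-12)

  set.seed(32)
  for (rep in 1:20) {
    b <- rbinom(12, 1, 0.5)
    if (length(unique(b)) < 2) next
    x <- rnorm(12)
    expect_equal(point_biserial(b, x)$r_pb, pearson_by_hand(b, x),
                 tolerance = 1e-12)
  }

  grp_means_equal <- point_biserial(c(0, 0, 1, 1), c(1, 3, 3, 1))
  expect_equal(grp_means_equal$r_pb, 0, tolerance = 1e-12)
  expect_error(point_biserial(c(0, 1, 0, 1), c(2, 2, 2, 2)),
               class = "pp_degenerate_error")
})

test_that("retest reliability bands the Pearson coefficient of the two runs", {
  same <- retest_reliability(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$r, 1)
  expect_equal(same$band, "perfect")

  rr <- retest_reliability(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
  expect_equal(rr$r, pearson_by_hand(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8)),
               tolerance = 1e-12)
  expect_equal(rr$r, 4.7 / sqrt(5 * 4.5), tolerance = 1e-12)  # = 0.99085
  expect_equal(rr$band, "excellent")

  expect_error(retest_reliability(c(1, 1, 1), c(1, 2, 3)),
               class = "pp_degenerate_error")
})

test_that("band thresholds are exact step functions at their boundaries", {
  expect_equal(reliability_band(1), "perfect")
  expect_equal(reliability_band(0.9999), "excellent")
  expect_equal(reliability_band(0.9), "excellent")
  expect_equal(reliability_band(0.8999), "good")
  expect_equal(reliability_band(0.8), "good")
  expect_equal(reliability_band(0.7), "acceptable")
  expect_equal(reliability_band(0.6), "questionable")
  expect_equal(reliability_band(0.5), "poor")
  expect_equal(reliability_band(0.4999), "unacceptable")
  expect_equal(reliability_band(0), "none")
  expect_equal(reliability_band(0.924), "excellent")  # non-kick foot retest
  # effect-size class boundaries: <= on both cut points
  expect_equal(cramers_v(0.2^2 * 30, 30, 2, 2)$effect_class, "weak")
  expect_equal(cramers_v(0.2001^2 * 30, 30, 2, 2)$effect_class, "moderate")
  expect_equal(cramers_v(0.6^2 * 30, 30, 2, 2)$effect_class, "moderate")
  expect_equal(cramers_v(0.6001^2 * 30, 30, 2, 2)$effect_class, "strong")
})

test_that("confidence summary reports mean and sample SD to 2 decimals", {
  s <- summarize_confidence(c(0, 1))
  expect_equal(s$mean, 0.5)
  expect_equal(s$sd, 0.71)
  expect_equal(summarize_confidence(c(0.8, 0.8, 0.8))$sd, 0)
  expect_error(summarize_confidence(0.9), class = "pp_domain_error")
})

test_that("logistic fit reproduces the saturated 2x2 closed form", {
  # null model on balanced labels: no information, accuracy at chance
  null_fit <- logistic_fit(data.frame(row.names = 1:8)[, FALSE, drop = FALSE],
                           c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_equal(null_fit$model_chi2, 0, tolerance = 1e-10)
  expect_equal(null_fit$accuracy, 0.5)

  # 2x2 counts: x=1 -> 8 of 10 positive, x=0 -> 3 of 10 positive
  x <- rep(c(1, 0), each = 10)
  y <- c(rep(1, 8), rep(0, 2), rep(1, 3), rep(0, 7))
  fit <- logistic_fit(data.frame(x = x), y)
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(3 / 7),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["x"]), log(28 / 3), tolerance = 1e-6)
  expect_equal(fit$df, 1L)
  ll_null <- 11 * log(11 / 20) + 9 * log(9 / 20)
  ll_full <- 8 * log(0.8) + 2 * log(0.2) + 3 * log(0.3) + 7 * log(0.7)
  expect_equal(fit$model_chi2, 2 * (ll_full - ll_null), tolerance = 1e-6)
  expect_equal(fit$model_chi2, 5.299, tolerance = 1e-3)
  expect_equal(fit$accuracy, 0.75)

  expect_error(logistic_fit(data.frame(x = 1:4), c(1, 1, 1, 1)),
               class = "pp_fit_error")
})

test_that("separation is flagged and the log-likelihood never decreases with predictors", {
  x <- c(1, 2, 3, 4, 10, 11, 12, 13)
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  expect_warning(fit <- logistic_fit(data.frame(x = x), y), "separation")
  expect_true(fit$separation)
  expect_equal(fit$accuracy, 1)

  set.seed(33)
  for (rep in 1:10) {
    n <- 40
    d <- data.frame(a = rnorm(n), b = rnorm(n))
    yy <- rbinom(n, 1, plogis(0.5 * d$a))
    if (length(unique(yy)) < 2) next
    small <- logistic_fit(d["a"], yy)
    big <- logistic_fit(d, yy)
    expect_gte(big$model_chi2, small$model_chi2 - 1e-8)
  }
})

test_that("strategy report screens, retains and models the planted association", {
  sim <- simulate_ospaf_dataset(sim_study_config(n_penalties = 200L, seed = 5L))
  rep1 <- strategy_report(sim$features, "gk_strategy")
  retained <- rep1$screening$variable[rep1$screening$retained]
  expect_true("gk_tactical_action" %in% retained)
  expect_true("alpha_gk" %in% retained)
  expect_false(is.null(rep1$model_ospaf))
  expect_false(is.null(rep1$model_full))
  # the anticipation angle separates the strategies almost perfectly here,
  # so adding it can only improve in-sample accuracy
  expect_gte(rep1$model_full$accuracy, rep1$model_ospaf$accuracy)
  expect_gte(rep1$model_full$model_chi2, rep1$model_ospaf$model_chi2 - 1e-8)

  # a numeric column that encodes the label exactly yields perfect accuracy
  feats <- sim$features
  feats$oracle_metric <- as.numeric(feats$gk_strategy == "kicker_dependent")
  rep2 <- strategy_report(feats, "gk_strategy")
  expect_equal(rep2$model_full$accuracy, 1)

  # records coded unclear are excluded from the dichotomous analysis
  feats2 <- sim$features
  feats2$gk_strategy[1:10] <- "unclear"
  rep3 <- strategy_report(feats2, "gk_strategy")
  expect_equal(rep3$n, 190L)
})
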