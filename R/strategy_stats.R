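# Strategy association statistics: chi-squared with Cramer's V, point-
# biserial correlation, test-retest reliability bands, confidence summary,
# and enter-method logistic regression with classification accuracy.

#' Cramer's V and its effect-size class
#'
#' `V = sqrt(chi2 / (n * (min(rows, cols) - 1)))`, classed weak when
#' `V <= 0.2`, moderate when `0.2 < V <= 0.6`, strong when `V > 0.6`.
#'
#' @param chi2 Pearson chi-squared statistic (>= 0).
#' @param n Total count (>= 1).
#' @param rows,cols Contingency table dimensions (>= 2).
#' @return List with `cramers_v` and `effect_class`.
#' @export
cramers_v <- function(chi2, n, rows, cols) {
  if (chi2 < 0 || n < 1 || rows < 2 || cols < 2)
    pp_stop("cramers_v needs chi2 >= 0, n >= 1 and a table of at least 2x2",
            "pp_domain_error")
  v <- sqrt(chi2 / (n * (min(rows, cols) - 1)))
  class_ <- if (v <= 0.2) "weak" else if (v <= 0.6) "moderate" else "strong"
  list(cramers_v = v, effect_class = class_)
}

#' Pearson chi-squared test of association with effect size
#'
#' Pearson's chi-squared without continuity correction on an r x c
#' contingency table, plus Cramer's V and its weak / moderate / strong
#' class.
#'
#' @param table Matrix (or table) of non-negative counts with at least two
#'   non-empty rows and columns.
#' @return List of class `chi_square_result`: `chi2`, `df`, `p`, `n`,
#'   `cramers_v`, `effect_class`.
#' @export
chi_squared <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || sum(m) <= 0)
    pp_stop("contingency counts must be non-negative with positive total",
            "pp_domain_error")
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L)
    pp_stop("degenerate contingency table: fewer than 2 non-empty rows or columns",
            "pp_degenerate_error")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  v <- cramers_v(unname(ct$statistic), sum(m), nrow(m), ncol(m))
  structure(list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, n = sum(m),
                 cramers_v = v$cramers_v, effect_class = v$effect_class),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("chi2(%d) = %.3f, p = %.4g, n = %d, V = %.3f (%s)\n",
              x$df, x$chi2, x$p, x$n, x$cramers_v, x$effect_class))
  invisible(x)
}

#' Point-biserial correlation
#'
#' Correlation between a dichotomous (0/1-coded) variable and a continuous
#' one; identical to the Pearson coefficient on the 0/1 coding, with the p
#' value from the t transform on n - 2 degrees of freedom.
#'
#' @param binary 0/1 (or two-level) vector.
#' @param continuous Numeric vector of the same length (>= 3).
#' @return List with `r_pb` and `p`.
#' @export
point_biserial <- function(binary, continuous) {
  b <- as.numeric(factor(binary)) - 1
  if (length(b) != length(continuous) || length(b) < 3L)
    pp_stop("point_biserial needs equal-length inputs of at least 3",
            "pp_domain_error")
  if (length(unique(b)) < 2L)
    pp_stop("both groups of the binary variable must be non-empty",
            "pp_domain_error")
  if (stats::sd(continuous) == 0)
    pp_stop("continuous input is constant: correlation undefined",
            "pp_degenerate_error")
  ct <- stats::cor.test(b, continuous, method = "pearson")
  list(r_pb = unname(ct$estimate), p = ct$p.value)
}

#' Reliability band for a test-retest coefficient
#'
#' Bands: 1 perfect; >= 0.9 excellent; >= 0.8 good; >= 0.7 acceptable;
#' >= 0.6 questionable; >= 0.5 poor; < 0.5 unacceptable; exactly 0 none.
#'
#' @param r Pearson coefficient.
#' @return Band label.
#' @export
reliability_band <- function(r) {
  if (r == 1) "perfect"
  else if (r >= 0.9) "excellent"
  else if (r >= 0.8) "good"
  else if (r >= 0.7) "acceptable"
  else if (r >= 0.6) "questionable"
  else if (r >= 0.5) "poor"
  else if (r == 0) "none"
  else "unacceptable"
}

#' Test-retest reliability of repeated measurements
#'
#' Pearson correlation between two measurement runs of the same quantity,
#' with the stability band of [reliability_band()].
#'
#' @param run1,run2 Numeric vectors of equal length (>= 3), non-constant.
#' @return List of class `reliability_result`: `r`, `band`.
#' @export
retest_reliability <- function(run1, run2) {
  if (length(run1) != length(run2) || length(run1) < 3L)
    pp_stop("retest_reliability needs equal-length runs of at least 3",
            "pp_domain_error")
  if (stats::sd(run1) == 0 || stats::sd(run2) == 0)
    pp_stop("constant measurement run: reliability undefined",
            "pp_degenerate_error")
  r <- stats::cor(run1, run2)
  structure(list(r = r, band = reliability_band(r)),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("r = %.3f (%s reliability)\n", x$r, x$band))
  invisible(x)
}

# round half away from zero at the given decimals, with a one-ulp tolerance
# so that exact decimal halves stored just below .5 in binary still round up
round_half_up <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Summarize per-variable confidence scores
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of a
#' set of confidence scores, reported to 2 decimals (half-up rounding, the
#' usual reporting convention).
#'
#' @param scores Numeric vector (length >= 2).
#' @return List with `mean` and `sd`.
#' @export
summarize_confidence <- function(scores) {
  if (length(scores) < 2L)
    pp_stop("confidence summary needs at least 2 scores", "pp_domain_error")
  list(mean = round_half_up(mean(scores), 2),
       sd = round_half_up(stats::sd(scores), 2))
}

#' Enter-method logistic regression with classification accuracy
#'
#' Maximum-likelihood logistic fit with every predictor entered
#' simultaneously (no stepwise selection). Categorical predictors are
#' dummy-coded against their first (alphabetical) level. The model
#' chi-squared is the likelihood-ratio statistic `2 (LL_full - LL_null)` on
#' as many degrees of freedom as estimated predictor terms; accuracy is the
#' fraction of cases whose fitted probability, thresholded at 0.5, matches
#' the label (a fitted probability of exactly 0.5 predicts the positive
#' class). Quasi-complete separation is detected and reported as a warning;
#' iterations are capped.
#'
#' @param features Data frame of predictors (zero columns = null model);
#'   character columns are treated as factors.
#' @param labels Binary outcome: 0/1, logical, or two-level factor (second
#'   level = positive class).
#' @param maxit Iteration cap for the IRLS fit.
#' @return List of class `logistic_strategy_model`: `coefficients`,
#'   `model_chi2`, `df`, `p`, `accuracy`, `separation`, and the underlying
#'   `glm` fit.
#' @export
logistic_fit <- function(features, labels, maxit = 50L) {
  y <- if (is.factor(labels) || is.character(labels))
    as.numeric(factor(labels)) - 1 else as.numeric(labels)
  if (length(unique(y)) < 2L)
    pp_stop("labels contain a single class: logistic fit undefined",
            "pp_fit_error")
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  for (j in seq_along(features))
    if (is.character(features[[j]])) features[[j]] <- factor(features[[j]])
  df_fit <- cbind(data.frame(.y = y), features)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df_fit, family = stats::binomial(),
               control = stats::glm.control(maxit = maxit)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  model_chi2 <- fit$null.deviance - fit$deviance
  dof <- fit$df.null - fit$df.residual
  p <- if (dof > 0) stats::pchisq(model_chi2, dof, lower.tail = FALSE) else NA_real_
  acc <- mean((stats::fitted(fit) >= 0.5) == (y == 1))
  if (separation)
    warning("possible complete separation: fitted probabilities of 0 or 1; ",
            "coefficients are unstable (iterations capped at ", maxit, ")")
  structure(list(coefficients = stats::coef(fit), model_chi2 = model_chi2,
                 df = dof, p = p, accuracy = acc, separation = separation,
                 fit = fit),
            class = "logistic_strategy_model")
}

#' @export
print.logistic_strategy_model <- function(x, ...) {
  cat(sprintf("logistic model: chi2(%d) = %.3f, p = %.4g, accuracy = %.1f%%%s\n",
              x$df, x$model_chi2, x$p, 100 * x$accuracy,
              if (x$separation) " [separation warning]" else ""))
  invisible(x)
}

## ---- full screening + modelling workflow -----------------------------------

strategy_positive_level <- function(outcome) {
  switch(outcome,
         gk_strategy = "kicker_dependent",
         taker_strategy = "gk_dependent")
}

#' Strategy association report
#'
#' The full association workflow for one strategy outcome: dichotomize the
#' strategy (records coded `unclear` are excluded), screen every OSPAF
#' categorical variable with [chi_squared()] and every pose-derived or
#' speed numeric with [point_biserial()], retain variables with `p < alpha`,
#' fit an enter-method logistic model on the retained OSPAF variables, then
#' refit adding the retained numeric variables and report the accuracy
#' gain.
#'
#' @param data Per-penalty feature table ([merge_features()] output).
#' @param outcome `"gk_strategy"` or `"taker_strategy"`.
#' @param alpha Screening significance level.
#' @return List of class `strategy_report`: `screening` (one row per
#'   candidate variable: statistic, p, effect size, retained flag),
#'   `model_ospaf`, `model_full`, `accuracy_delta`, `n`.
#' @export
strategy_report <- function(data, outcome = c("gk_strategy", "taker_strategy"),
                            alpha = 0.05) {
  outcome <- match.arg(outcome)
  if (!(alpha > 0 && alpha < 1))
    pp_stop("alpha must be in (0, 1)", "pp_domain_error")
  pos <- strategy_positive_level(outcome)
  keep <- !is.na(data[[outcome]]) & data[[outcome]] != "unclear"
  data <- data[keep, , drop = FALSE]
  y <- factor(as.integer(data[[outcome]] == pos), levels = c(0, 1))
  if (length(unique(y)) < 2L)
    pp_stop("dichotomized strategy outcome has a single class", "pp_fit_error")

  schema <- ospaf_schema()
  cat_vars <- setdiff(intersect(names(schema), names(data)),
                      c("gk_strategy", "taker_strategy"))
  num_vars <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                      grep("^c_", names(data), value = TRUE))
  num_vars <- setdiff(num_vars, "penalty_id")

  rows <- list()
  for (v in cat_vars) {
    res <- tryCatch(chi_squared(table(y, data[[v]])),
                    penaltypose_error = function(e) NULL)
    rows[[v]] <- data.frame(
      variable = v, type = "ospaf",
      statistic = if (is.null(res)) NA_real_ else res$chi2,
      p = if (is.null(res)) NA_real_ else res$p,
      effect_size = if (is.null(res)) NA_real_ else res$cramers_v,
      stringsAsFactors = FALSE)
  }
  for (v in num_vars) {
    ok <- !is.na(data[[v]])
    res <- tryCatch(point_biserial(y[ok], data[[v]][ok]),
                    penaltypose_error = function(e) NULL)
    rows[[v]] <- data.frame(
      variable = v, type = "numeric",
      statistic = if (is.null(res)) NA_real_ else res$r_pb,
      p = if (is.null(res)) NA_real_ else res$p,
      effect_size = if (is.null(res)) NA_real_ else abs(res$r_pb),
      stringsAsFactors = FALSE)
  }
  screening <- do.call(rbind, rows)
  rownames(screening) <- NULL
  screening$retained <- !is.na(screening$p) & screening$p < alpha

  ret_cat <- screening$variable[screening$retained & screening$type == "ospaf"]
  ret_num <- screening$variable[screening$retained & screening$type == "numeric"]

  model_ospaf <- model_full <- NULL
  acc_delta <- NA_real_
  if (length(ret_cat) + length(ret_num) > 0L) {
    fit_on <- function(vars) {
      cc <- stats::complete.cases(data[, vars, drop = FALSE])
      suppressWarnings(logistic_fit(data[cc, vars, drop = FALSE], y[cc]))
    }
    if (length(ret_cat) > 0L) model_ospaf <- fit_on(ret_cat)
    model_full <- fit_on(c(ret_cat, ret_num))
    if (!is.null(model_ospaf))
      acc_delta <- model_full$accuracy - model_ospaf$accuracy
  }
  structure(list(outcome = outcome, positive_level = pos, alpha = alpha,
                 n = length(y), screening = screening,
                 model_ospaf = model_ospaf, model_full = model_full,
                 accuracy_delta = acc_delta),
            class = "strategy_report")
}

#' @export
print.strategy_report <- function(x, ...) {
  cat(sprintf("Strategy report: %s (positive = %s), n = %d, alpha = %g\n",
              x$outcome, x$positive_level, x$n, x$alpha))
  sc <- x$screening[x$screening$retained, , drop = FALSE]
  if (nrow(sc) == 0L) {
    cat("  no variable passed screening; no model fitted\n")
  } else {
    cat("  retained after screening:\n")
    for (i in seq_len(nrow(sc)))
      cat(sprintf("    %-24s %-7s stat = %8.3f  p = %.4g  ES = %.3f\n",
                  sc$variable[i], sc$type[i], sc$statistic[i], sc$p[i],
                  sc$effect_size[i]))
    if (!is.null(x$model_ospaf)) {
      cat("  OSPAF-only model:  "); print(x$model_ospaf)
    }
    if (!is.null(x$model_full)) {
      cat("  full model:        "); print(x$model_full)
      if (!is.na(x$accuracy_delta))
        cat(sprintf("  accuracy gain from pose/numeric variables: %+.1f%%\n",
                    100 * x$accuracy_delta))
    }
  }
  invisible(x)
}
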