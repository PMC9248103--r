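# Statistical layer: two-group ANOVA screens, univariate logistic models
# reported as odds ratios on per-feature reporting units (A1 per 1, A2 per
# 0.1, A3 per 10, A4 per 0.1) with Wald 95% CIs, sex stratification,
# odds-probability conversion, and descriptive (Table-1-style) output.

#' Reporting-scale units for the four acoustic features
#'
#' Odds ratios are reported per one unit of A1, per 0.1 of A2, per 10 Hz of
#' A3 and per 0.1 of A4.
#' @return Named numeric vector.
#' @export
feature_scale_units <- function() c(a1 = 1, a2 = 0.1, a3 = 10, a4 = 0.1)

#' One-way ANOVA of a feature across the frail grouping
#'
#' @param values Numeric feature values.
#' @param group Binary/factor grouping (frail vs robust/pre-frail).
#' @return `list(f, p, df1, df2)`; a degenerate fit with zero residual
#'   variance returns a large finite F and p = 0.
#' @export
anova_feature <- function(values, group) {
  group <- factor(group)
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]
  group <- droplevels(group[keep])
  if (nlevels(group) < 2 || any(table(group) < 2)) {
    stop("each group needs at least 2 observations")
  }
  tab <- anova(lm(values ~ group))
  f <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  if (!is.finite(f)) { # identical values within groups, different means
    f <- 1e12
    p <- 0
  }
  list(f = f, p = p, df1 = tab$Df[1], df2 = tab$Df[2])
}

#' Convert odds to probability
#'
#' `probability = odds / (1 + odds)`.
#' @param odds Non-negative odds.
#' @return Probability in \[0, 1).
#' @export
odds_to_probability <- function(odds) {
  if (any(odds < 0)) stop("odds must be non-negative")
  odds / (1 + odds)
}

#' Convert probability to odds
#' @param p Probability in \[0, 1).
#' @return Odds `p / (1 - p)`.
#' @export
probability_to_odds <- function(p) {
  if (any(p < 0 | p >= 1)) stop("probability must lie in [0, 1)")
  p / (1 - p)
}

# Firth-penalized univariate logistic fit (intercept + slope): Newton
# iterations on the modified score U*(b) = X'(y - p + h (1/2 - p)) with h
# the hat diagonal of the weighted design. Used when the ML fit fails to
# converge (e.g. complete separation).
firth_logistic <- function(x, y, max_iter = 100, tol = 1e-8) {
  X <- cbind(1, x)
  b <- c(qlogis(max(0.05, min(0.95, mean(y)))), 0)
  for (iter in seq_len(max_iter)) {
    eta <- as.numeric(X %*% b)
    p <- plogis(eta)
    w <- p * (1 - p)
    XtW <- t(X * w)
    info <- XtW %*% X
    inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(inv)) break
    h <- rowSums((X %*% inv) * (X * w))
    u <- as.numeric(t(X) %*% (y - p + h * (0.5 - p)))
    step <- as.numeric(inv %*% u)
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  eta <- as.numeric(X %*% b)
  w <- plogis(eta) * (1 - plogis(eta))
  se <- sqrt(diag(solve(t(X * w) %*% X)))
  list(coef = b, se = se)
}

#' Univariate logistic odds ratio on a reporting scale
#'
#' Fits `frail ~ feature / scale_unit` by maximum likelihood and reports
#' `OR = exp(coef)` with the Wald 95% CI `exp(coef +/- 1.96 SE)`. Complete
#' separation (or other non-convergence) falls back to a Firth-penalized
#' fit and is flagged `converged = FALSE`.
#'
#' @param values Numeric feature values.
#' @param frail Logical (or 0/1) outcome, frail vs robust/pre-frail.
#' @param scale_unit Reporting unit (e.g. 10 for A3's per-10-Hz OR).
#' @param feature,index,stratum Labels carried into the result.
#' @return One-row data.frame of class `association_result`: `feature`,
#'   `index`, `stratum`, `or_scaled`, `ci_lo`, `ci_hi`, `p_value`,
#'   `scale_unit`, `n`, `converged`, `b0`, `b1` (raw per-unit log-odds
#'   slope), `method`.
#' @export
fit_logistic_or <- function(values, frail, scale_unit = 1,
                            feature = NA_character_, index = NA_character_,
                            stratum = "all") {
  keep <- is.finite(values) & !is.na(frail)
  x <- values[keep]
  y <- as.numeric(frail[keep])
  n <- length(y)
  if (n < 20) stop("need at least 20 observations")
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  sx <- sd(x)
  if (sx == 0) stop("no variation in predictor")
  mx <- mean(x)
  u <- (x - mx) / sx # fit on the standardized predictor so separation
                     # detection is scale-free; coefficients mapped back

  fit <- suppressWarnings(glm(y ~ u, family = binomial()))
  separated <- !fit$converged || abs(coef(fit)[2]) > 12 ||
    summary(fit)$coefficients[2, 2] > 30
  if (separated) {
    fr <- firth_logistic(u, y)
    b <- fr$coef
    se <- fr$se
    converged <- FALSE
    method <- "firth"
  } else {
    b <- coef(fit)
    se <- summary(fit)$coefficients[, 2]
    converged <- TRUE
    method <- "ml-wald"
  }
  z <- b[2] / se[2]
  b_scaled <- b[2] * scale_unit / sx # log-odds per reporting unit
  se_scaled <- se[2] * scale_unit / sx
  res <- data.frame(
    feature = feature, index = index, stratum = stratum,
    or_scaled = exp(b_scaled), ci_lo = exp(b_scaled - 1.96 * se_scaled),
    ci_hi = exp(b_scaled + 1.96 * se_scaled),
    p_value = 2 * pnorm(-abs(z)), scale_unit = scale_unit, n = n,
    converged = converged, b0 = b[1] - b[2] * mx / sx,
    b1 = b[2] / sx, method = method, stringsAsFactors = FALSE
  )
  class(res) <- c("association_result", class(res))
  res
}

#' Predicted frailty probability along a feature grid
#'
#' Converts the fitted log-odds line to probabilities,
#' `probability = odds / (1 + odds)` with
#' `odds = exp(b0 + b1 * feature)`; monotone in the direction of the
#' slope.
#'
#' @param result An [fit_logistic_or()] result (must be converged).
#' @param grid Feature values (raw units) to evaluate.
#' @return Data.frame with `feature_value` and `probability`.
#' @export
probability_curve <- function(result, grid) {
  if (!isTRUE(result$converged)) stop("model did not converge")
  odds <- exp(result$b0 + result$b1 * grid)
  data.frame(feature_value = grid,
             probability = odds_to_probability(odds))
}

#' Feature-frailty odds ratios for all features, indices and sex strata
#'
#' Merges a feature table with a scored cohort and fits
#' [fit_logistic_or()] for each acoustic feature x frailty index x stratum
#' (all / male / female), each on its reporting scale. Strata in which a
#' model cannot be estimated (a missing outcome class, too few subjects)
#' are returned with `estimable = FALSE` instead of failing the batch.
#'
#' @param features Data.frame from [extract_features_batch()] (`id`,
#'   `a1`..`a4`).
#' @param assessments Data.frame from [score_all()] (`id`, `sex`, `index`,
#'   `frail`).
#' @return Data.frame with one row per combination (36 when all strata are
#'   estimable), an `estimable` flag, and a reference-only Bonferroni
#'   column (`p_bonferroni`) that no decision uses.
#' @export
stratified_associations <- function(features, assessments) {
  if (!"sex" %in% names(assessments)) stop("assessments need a sex column")
  merged <- merge(assessments, features, by = "id")
  units <- feature_scale_units()
  rows <- list()
  for (index in unique(merged$index)) {
    sub_i <- merged[merged$index == index, ]
    for (feature in names(units)) {
      for (stratum in c("all", "male", "female")) {
        sub <- if (stratum == "all") sub_i else sub_i[sub_i$sex == stratum, ]
        row <- tryCatch(
          fit_logistic_or(sub[[feature]], sub$frail, units[[feature]],
                          feature = feature, index = index,
                          stratum = stratum),
          error = function(e) {
            data.frame(feature = feature, index = index, stratum = stratum,
                       or_scaled = NA_real_, ci_lo = NA_real_,
                       ci_hi = NA_real_, p_value = NA_real_,
                       scale_unit = units[[feature]], n = nrow(sub),
                       converged = FALSE, b0 = NA_real_, b1 = NA_real_,
                       method = conditionMessage(e),
                       stringsAsFactors = FALSE)
          })
        row$estimable <- is.finite(row$or_scaled)
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # Bonferroni-adjusted p-values are reported for reference only; no
  # multiplicity correction enters any decision
  out$p_bonferroni <- NA_real_
  est <- out$estimable
  out$p_bonferroni[est] <- stats::p.adjust(out$p_value[est],
                                           method = "bonferroni")
  out
}

#' Percentage of a count within a group, as printed in descriptive tables
#' @param n Count.
#' @param total Group size.
#' @param digits Decimal places (default 1, the usual table precision).
#' @return Numeric percentage.
#' @export
count_pct <- function(n, total, digits = 1) round(100 * n / total, digits)

fmt_count_pct <- function(n, total) sprintf("%d (%.1f)", n,
                                            count_pct(n, total))
fmt_mean_sd <- function(x) sprintf("%.1f ± %.1f", mean(x), sd(x))

# chi-square unless any expected cell < 5, then Fisher
categorical_p <- function(flag, group) {
  tab <- table(flag, group)
  if (nrow(tab) < 2 || ncol(tab) < 2) return(list(p = NA_real_, test = "NA"))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    list(p = fisher.test(tab)$p.value, test = "Fisher")
  } else {
    list(p = suppressWarnings(chisq.test(tab, correct = FALSE)$p.value),
         test = "chi-square")
  }
}

#' Descriptive comparison of frail vs robust/pre-frail participants
#'
#' For each frailty index, builds the standard cohort-description rows -
#' women, age, body weight, BMI, and the prevalence of each criterion
#' field - as count (%) for categorical variables (chi-square, or Fisher
#' when an expected cell is below 5) and mean +/- SD for continuous ones
#' (one-way ANOVA).
#'
#' @param participants Participant table.
#' @param assessments Output of [score_all()].
#' @return Data.frame with `index`, `variable`, `robust_prefrail`,
#'   `frail`, `p_value`, `test_used`.
#' @export
descriptive_table <- function(participants, assessments) {
  cat_vars <- list(
    women = function(p) p$sex == "female",
    weight_loss = function(p) p$weight_loss_pct_year >= 5,
    exhaustion = function(p) as.logical(p$exhaustion_answer),
    low_grip_strength = function(p) {
      ifelse(p$sex == "male", p$grip_kg < 28, p$grip_kg < 18)
    },
    slow_gait_speed = function(p) {
      ifelse(is.na(p$gait_speed_m_s) & p$cannot_walk, TRUE,
             p$gait_speed_m_s < 1.0)
    },
    cannot_complete_chair_stand = function(p) as.logical(p$chair_stand_unable),
    adl_impairment = function(p) as.logical(p$adl_deterioration),
    polypharmacy = function(p) p$drug_count >= 8
  )
  num_vars <- list(age_years = "age_years", body_weight_kg = "weight_kg",
                   bmi = "bmi")
  rows <- list()
  for (index in unique(assessments$index)) {
    a <- assessments[assessments$index == index, c("id", "frail")]
    m <- merge(participants, a, by = "id")
    g_frail <- m[m$frail, ]
    g_rob <- m[!m$frail, ]
    if (nrow(g_frail) == 0 || nrow(g_rob) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        index = index, variable = "n", robust_prefrail = nrow(g_rob),
        frail = if (nrow(g_frail) == 0) "n=0" else nrow(g_frail),
        p_value = NA_real_, test_used = "NA", stringsAsFactors = FALSE)
      next
    }
    add <- function(variable, robust_prefrail, frail, p, test) {
      rows[[length(rows) + 1]] <<- data.frame(
        index = index, variable = variable,
        robust_prefrail = robust_prefrail, frail = frail,
        p_value = p, test_used = test, stringsAsFactors = FALSE)
    }
    for (v in names(cat_vars)) {
      flag <- cat_vars[[v]](m)
      keep <- !is.na(flag)
      ct <- categorical_p(flag[keep], m$frail[keep])
      add(v,
          fmt_count_pct(sum(flag[keep & !m$frail]), sum(keep & !m$frail)),
          fmt_count_pct(sum(flag[keep & m$frail]), sum(keep & m$frail)),
          ct$p, ct$test)
    }
    for (v in names(num_vars)) {
      x <- m[[num_vars[[v]]]]
      keep <- is.finite(x)
      if (!any(keep)) next
      p <- if (sd(x[keep]) == 0) {
        1 # no variation anywhere: no evidence of a difference
      } else {
        anova_feature(x[keep], m$frail[keep])$p
      }
      add(v, fmt_mean_sd(x[keep & !m$frail]), fmt_mean_sd(x[keep & m$frail]),
          p, "ANOVA")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-feature ANOVA screen by frailty index
#'
#' The screening table: one-way ANOVA of each acoustic feature across the
#' frail vs robust/pre-frail grouping, per index.
#'
#' @param features Feature table (`id`, `a1`..`a4`).
#' @param assessments Output of [score_all()].
#' @return Data.frame with `index`, `feature`, `f`, `p_value`.
#' @export
anova_table <- function(features, assessments) {
  merged <- merge(assessments, features, by = "id")
  rows <- list()
  for (index in unique(merged$index)) {
    sub <- merged[merged$index == index, ]
    for (feature in names(feature_scale_units())) {
      res <- anova_feature(sub[[feature]], sub$frail)
      rows[[length(rows) + 1]] <- data.frame(
        index = index, feature = feature, f = res$f, p_value = res$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
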