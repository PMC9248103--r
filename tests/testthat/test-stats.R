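test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(1)
  x <- c(rnorm(30, 0), rnorm(25, 0.7))
  g <- rep(c(0, 1), c(30, 25))
  res <- anova_feature(x, g)
  tt <- t.test(x[g == 0], x[g == 1], var.equal = TRUE)
  expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA type-I error sits near the nominal level", {
  set.seed(2)
  rejections <- vapply(seq_len(200), function(i) {
    x <- rnorm(400)
    g <- rep(c(0, 1), each = 200)
    anova_feature(x, g)$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.09)
})

test_that("degenerate within-group constancy yields a large finite F", {
  res <- suppressWarnings(
    anova_feature(rep(c(1, 2), each = 5), rep(c(0, 1), each = 5)))
  expect_true(is.finite(res$f))
  expect_gt(res$f, 1e10)
  expect_lt(res$p, 1e-10)
  expect_error(anova_feature(rnorm(5), rep(0, 5)), "group")
})

test_that("logistic OR on a binary predictor equals the cross-product", {
  # 2x2 counts: exposed-frail 34, exposed-nonfrail 24, unexposed-frail 15,
  # unexposed-nonfrail 204 -> OR = (34*204)/(24*15) = 19.2667
  x <- rep(c(1, 1, 0, 0), c(34, 24, 15, 204))
  y <- rep(c(1, 0, 1, 0), c(34, 24, 15, 204))
  res <- fit_logistic_or(x, y)
  expect_equal(res$or_scaled, (34 * 204) / (24 * 15), tolerance = 1e-6)
  expect_true(res$converged)
  expect_true(res$ci_lo <= res$or_scaled && res$or_scaled <= res$ci_hi)
})

test_that("logistic fit validates its inputs", {
  expect_error(fit_logistic_or(rep(1, 50), rbinom(50, 1, 0.5)),
               "no variation")
  expect_error(fit_logistic_or(rnorm(10), rbinom(10, 1, 0.5)),
               "at least 20")
  expect_error(fit_logistic_or(rnorm(50), rep(1, 50)), "both outcome")
})

test_that("Wald CIs reach nominal coverage", {
  set.seed(2)
  b <- log(1.4)
  covered <- vapply(seq_len(300), function(i) {
    x <- rnorm(1000)
    y <- rbinom(1000, 1, plogis(-1.5 + b * x))
    res <- fit_logistic_or(x, y)
    res$ci_lo <= 1.4 && 1.4 <= res$ci_hi
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("complete separation falls back to a penalized fit", {
  x <- c(rnorm(25, -3), rnorm(25, 3))
  y <- rep(c(0, 1), each = 25)
  res <- fit_logistic_or(x, y)
  expect_false(res$converged)
  expect_identical(res$method, "firth")
  expect_true(is.finite(res$or_scaled) && res$or_scaled > 1)
  expect_true(is.finite(res$ci_hi))
})

test_that("odds/probability conversions follow odds/(1+odds)", {
  expect_equal(odds_to_probability(1), 0.5)
  expect_equal(odds_to_probability(0), 0)
  expect_equal(odds_to_probability(3), 0.75)
  expect_error(odds_to_probability(-0.1), "non-negative")
  p <- seq(0.01, 0.97, by = 0.04)
  expect_equal(odds_to_probability(probability_to_odds(p)), p,
               tolerance = 1e-12)
})

test_that("probability curves match the definitional identity", {
  set.seed(4)
  x <- rnorm(200, 10, 2)
  y <- rbinom(200, 1, plogis(-4 + 0.3 * x))
  res <- fit_logistic_or(x, y)
  grid <- seq(5, 15, length.out = 30)
  cv <- probability_curve(res, grid)
  expect_equal(cv$probability,
               odds_to_probability(exp(res$b0 + res$b1 * grid)),
               tolerance = 1e-12)
  expect_true(all(diff(cv$probability) > 0)) # positive slope -> increasing
  expect_true(all(cv$probability > 0 & cv$probability < 1))

  flat <- res
  flat$b1 <- 0
  expect_equal(diff(range(probability_curve(flat, grid)$probability)), 0)

  bad <- res
  bad$converged <- FALSE
  expect_error(probability_curve(bad, grid), "converge")
})

# features/assessments pair with a configurable latent structure, no audio
make_tables <- function(n, b = c(a1 = 0, a2 = 0, a3 = 0, a4 = 0),
                        seed = 1, prev = 0.25) {
  set.seed(seed)
  frail <- runif(n) < prev
  sex <- sample(c("male", "female"), n, replace = TRUE)
  feats <- data.frame(
    id = sprintf("p%04d", seq_len(n)),
    a1 = rnorm(n, 0.1 + b["a1"] * frail, 0.02),
    a2 = rnorm(n, 0.05 + b["a2"] * frail, 0.015),
    a3 = rnorm(n, 30 + b["a3"] * frail, 10),
    a4 = rnorm(n, 0.1 + b["a4"] * frail, 0.03)
  )
  ass <- do.call(rbind, lapply(c("CHS", "SOF", "FRAIL"), function(ix) {
    data.frame(id = feats$id, sex = sex, index = ix, frail = frail,
               stringsAsFactors = FALSE)
  }))
  list(features = feats, assessments = ass)
}

test_that("stratified_associations covers 4 features x 3 indices x 3 strata", {
  tb <- make_tables(300)
  out <- stratified_associations(tb$features, tb$assessments)
  expect_equal(nrow(out), 36)
  expect_setequal(unique(out$stratum), c("all", "male", "female"))
  expect_true(all(out$scale_unit ==
                    feature_scale_units()[out$feature]))
})

test_that("null tables give ORs whose CIs usually cover 1", {
  tb <- make_tables(400, seed = 8)
  out <- stratified_associations(tb$features, tb$assessments)
  ok <- out$estimable
  cover <- mean(out$ci_lo[ok] <= 1 & out$ci_hi[ok] >= 1)
  expect_gte(cover, 0.85)
})

test_that("a stratum without both outcome classes is inestimable", {
  tb <- make_tables(200, seed = 3)
  males <- tb$assessments$sex == "male"
  tb$assessments$frail[males] <- FALSE
  tb$assessments$sex[which(males)[1]] <- "male"
  out <- stratified_associations(tb$features, tb$assessments)
  male_rows <- out[out$stratum == "male", ]
  expect_true(all(!male_rows$estimable))
  expect_true(all(out$estimable[out$stratum == "female"]))
})

test_that("descriptive percentages reproduce printed-table arithmetic", {
  expect_equal(count_pct(175, 277), 63.2)
  expect_equal(count_pct(43, 49), 87.8)
  expect_equal(count_pct(30, 49), 61.2)
  expect_equal(count_pct(145, 228), 63.6)
})

test_that("descriptive_table formats groups and chooses tests", {
  set.seed(10)
  n <- 277
  # 49 frail (30 women) and 228 robust/pre-frail (145 women): 175 women
  sex <- c(rep(c("female", "male"), c(30, 19)),
           rep(c("female", "male"), c(145, 83)))
  frail_sof <- rep(c(TRUE, FALSE), c(49, 228))
  parts <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- robust_participant(id = sprintf("p%03d", i), sex = sex[i])
    p$age_years <- rnorm(1, 74, 7)
    p$exhaustion_answer <- if (frail_sof[i]) i <= 43 else i <= 49 + 23
    p
  }))
  ass <- data.frame(id = parts$id, sex = parts$sex, index = "SOF",
                    frail = frail_sof, stringsAsFactors = FALSE)
  tab <- descriptive_table(parts, ass)
  women <- tab[tab$variable == "women", ]
  expect_match(women$frail, "^30 \\(61.2\\)$")
  exh <- tab[tab$variable == "exhaustion", ]
  expect_match(exh$frail, "^43 \\(87.8\\)$")
  expect_match(exh$robust_prefrail, "^23 \\(10.1\\)$")
  expect_true(all(tab$test_used[tab$variable == "age_years"] == "ANOVA"))
  expect_true(all(tab$test_used[tab$variable == "exhaustion"] %in%
                    c("chi-square", "Fisher")))
})

test_that("an all-identical continuous variable is handled gracefully", {
  parts <- do.call(rbind, lapply(1:40, function(i) {
    robust_participant(id = paste0("p", i))
  }))
  parts$age_years <- 70
  ass <- data.frame(id = parts$id, sex = parts$sex, index = "SOF",
                    frail = rep(c(TRUE, FALSE), 20), stringsAsFactors = FALSE)
  tab <- descriptive_table(parts, ass)
  age <- tab[tab$variable == "age_years", ]
  expect_equal(age$p_value, 1)
})

test_that("anova_table screens every feature-index pair", {
  tb <- make_tables(200, b = c(a1 = 0, a2 = 0.1, a3 = 0, a4 = 0), seed = 5)
  out <- anova_table(tb$features, tb$assessments)
  expect_equal(nrow(out), 12)
  # the configured a2 contrast is the strongest signal
  a2p <- out$p_value[out$feature == "a2"]
  expect_true(all(a2p < 0.01))
})

test_that("a configured sex interaction shows up in stratified fits", {
  wins <- 0L
  for (r in 1:20) {
    cc <- cohort_config(
      n_participants = 250, seed = 5000 + r, frailty_prevalence = 0.4,
      effect_ors = c(a4 = 1.35),
      feature_sds = c(a1 = 0.012, a2 = 0.013, a3 = 7, a4 = 0.04),
      sex_interaction = list(a4 = c(sex = "female", or_multiplier = 8)))
    co <- simulate_cohort(cc)
    ass <- score_all(co$participants)
    st <- stratified_associations(co$features, ass)
    sub <- st[st$index == "SOF" & st$feature == "a4", ]
    or_f <- sub$or_scaled[sub$stratum == "female"]
    or_m <- sub$or_scaled[sub$stratum == "male"]
    if (is.finite(or_f) && is.finite(or_m) && or_f > or_m) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})
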