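test_that("CHS scoring applies the published cutoffs and rule", {
  p <- robust_participant()
  p$grip_kg <- 27
  p$gait_speed_m_s <- 0.9
  p$exhaustion_answer <- TRUE
  a <- score_chs(p)
  expect_equal(a$score, 3L)
  expect_equal(a$category, "frail")

  expect_equal(score_chs(robust_participant())$category, "robust")

  # grip exactly at the cutoff is not weak (strict <)
  f <- robust_participant(sex = "female")
  f$grip_kg <- 18.0
  expect_false(score_chs(f)$criteria[["weakness"]])
  f$grip_kg <- 17.9
  expect_true(score_chs(f)$criteria[["weakness"]])

  # CHS weight loss requires the loss to be unintentional
  p2 <- robust_participant()
  p2$weight_loss_kg_year <- 5
  p2$weight_loss_pct_year <- 8
  p2$unintentional <- FALSE
  expect_false(score_chs(p2)$criteria[["weight_loss"]])
  p2$unintentional <- TRUE
  expect_true(score_chs(p2)$criteria[["weight_loss"]])
  # 4.5 kg is inclusive
  p2$weight_loss_kg_year <- 4.5
  p2$weight_loss_pct_year <- 3
  expect_true(score_chs(p2)$criteria[["weight_loss"]])
})

test_that("SOF scoring: two of three criteria make frail", {
  p <- robust_participant()
  p$chair_stand_unable <- TRUE
  p$energy_full_answer <- FALSE
  a <- score_sof(p)
  expect_equal(a$score, 2L)
  expect_equal(a$category, "frail")

  p2 <- robust_participant()
  p2$weight_loss_pct_year <- 6
  a2 <- score_sof(p2)
  expect_equal(a2$score, 1L)
  expect_equal(a2$category, "pre-frail")

  expect_equal(score_sof(robust_participant())$category, "robust")

  # SOF weight loss is strict > 5%
  p3 <- robust_participant()
  p3$weight_loss_pct_year <- 5.0
  expect_false(score_sof(p3)$criteria[["weight_loss"]])
})

test_that("FRAIL scoring: items, inclusive cutoffs, and categories", {
  p <- robust_participant()
  p$exhaustion_answer <- TRUE   # fatigue
  p$chair_stand_unable <- TRUE  # resistance
  p$gait_speed_m_s <- 0.8       # ambulation
  a <- score_frail(p)
  expect_equal(a$score, 3L)
  expect_equal(a$category, "frail")

  p2 <- robust_participant()
  p2$drug_count <- 8
  expect_true(score_frail(p2)$criteria[["illness"]])
  p2$drug_count <- 7
  expect_false(score_frail(p2)$criteria[["illness"]])

  # FRAIL weight loss is inclusive >= 5%
  p3 <- robust_participant()
  p3$weight_loss_pct_year <- 5.0
  expect_true(score_frail(p3)$criteria[["weight_loss"]])
})

test_that("wheelchair users count as slow/low mobility", {
  p <- robust_participant()
  p$gait_speed_m_s <- NA_real_
  p$cannot_walk <- TRUE
  expect_true(score_chs(p)$criteria[["slowness"]])
  expect_true(score_frail(p)$criteria[["ambulation"]])
})

test_that("missing criteria are reported and may flag incompleteness", {
  p <- robust_participant()
  p$grip_kg <- NA_real_
  a <- score_chs(p)
  expect_true("weakness" %in% a$missing_criteria)
  expect_false(a$incomplete) # score 0 + 1 missing cannot reach 3

  p2 <- robust_participant()
  p2$exhaustion_answer <- TRUE
  p2$gait_speed_m_s <- 0.8
  p2$grip_kg <- NA_real_
  a2 <- score_chs(p2) # score 2, threshold 3, one missing -> uncertain
  expect_true(a2$incomplete)

  empty <- participant(id = "void", sex = "male")
  expect_error(score_sof(empty), "missing")
})

test_that("turning a criterion positive never moves a score down", {
  toggles <- list(
    weight_loss_pct_year = c(0, 8), exhaustion_answer = c(FALSE, TRUE),
    grip_kg = c(35, 20), gait_speed_m_s = c(1.3, 0.7),
    adl_deterioration = c(FALSE, TRUE), chair_stand_unable = c(FALSE, TRUE),
    energy_full_answer = c(TRUE, FALSE), drug_count = c(2, 9)
  )
  cat_rank <- c(robust = 0, `pre-frail` = 1, frail = 2)
  set.seed(99)
  for (rep in 1:30) {
    p <- robust_participant(sex = sample(c("male", "female"), 1))
    # random baseline
    for (fld in names(toggles)) {
      p[[fld]] <- sample(toggles[[fld]], 1)
    }
    if (p$weight_loss_pct_year > 5) p$unintentional <- TRUE
    fld <- sample(names(toggles), 1)
    q <- p
    q[[fld]] <- toggles[[fld]][2] # force positive
    if (fld == "weight_loss_pct_year") q$unintentional <- TRUE
    for (scorer in list(score_chs, score_sof, score_frail)) {
      a <- scorer(p)
      b <- scorer(q)
      expect_gte(b$score, a$score)
      expect_gte(cat_rank[[b$category]], cat_rank[[a$category]])
    }
  }
})

test_that("categories are consistent with scores for random inputs", {
  set.seed(7)
  for (rep in 1:40) {
    p <- robust_participant()
    p$weight_loss_pct_year <- sample(c(NA, 0, 4, 5, 6, 9), 1)
    p$unintentional <- sample(c(NA, TRUE, FALSE), 1)
    p$exhaustion_answer <- sample(c(NA, TRUE, FALSE), 1)
    p$grip_kg <- sample(c(NA, 15, 27.9, 28, 40), 1)
    p$gait_speed_m_s <- sample(c(NA, 0.5, 0.99, 1, 1.4), 1)
    p$chair_stand_unable <- sample(c(NA, TRUE, FALSE), 1)
    p$energy_full_answer <- sample(c(NA, TRUE, FALSE), 1)
    p$drug_count <- sample(c(NA, 3, 7, 8, 12), 1)
    p$adl_deterioration <- sample(c(NA, TRUE, FALSE), 1)
    for (pair in list(list(score_chs, 3), list(score_sof, 2),
                      list(score_frail, 3))) {
      a <- tryCatch(pair[[1]](p), error = function(e) NULL)
      if (is.null(a)) next
      thr <- pair[[2]]
      expected <- if (a$score >= thr) "frail" else
        if (a$score >= 1) "pre-frail" else "robust"
      expect_equal(a$category, expected)
      expect_equal(a$score, sum(a$criteria, na.rm = TRUE))
    }
  }
})

test_that("indices depend only on their documented fields", {
  p <- robust_participant()
  p$weight_loss_pct_year <- 6
  q <- p
  q$grip_kg <- 10       # CHS-only field
  q$drug_count <- 12    # FRAIL-only field
  q$adl_deterioration <- TRUE
  expect_identical(score_sof(p)$criteria, score_sof(q)$criteria)

  r <- p
  r$energy_full_answer <- FALSE # SOF-only field
  expect_identical(score_chs(p)$criteria, score_chs(r)$criteria)
  expect_identical(score_frail(p)$criteria, score_frail(r)$criteria)
})

test_that("score_all produces 3 assessments per participant", {
  cohort <- do.call(rbind, lapply(1:277, function(i) {
    robust_participant(id = sprintf("p%03d", i),
                       sex = if (i %% 3 == 0) "female" else "male")
  }))
  out <- score_all(cohort)
  expect_equal(nrow(out), 831)
  expect_true(all(out$category == "robust"))

  dup <- rbind(cohort[1, ], cohort[1, ])
  expect_error(score_all(dup), "duplicate")
})

test_that("score_all agrees with the single-participant scorers", {
  set.seed(31)
  rows <- lapply(1:12, function(i) {
    p <- robust_participant(id = paste0("s", i),
                            sex = sample(c("male", "female"), 1))
    p$weight_loss_pct_year <- sample(c(NA, 0, 6), 1)
    p$unintentional <- TRUE
    p$exhaustion_answer <- sample(c(TRUE, FALSE), 1)
    p$grip_kg <- sample(c(NA, 20, 35), 1)
    p$chair_stand_unable <- sample(c(TRUE, FALSE), 1)
    p$drug_count <- sample(c(2, 9), 1)
    p
  })
  cohort <- do.call(rbind, rows)
  tab <- score_all(cohort)
  for (i in seq_along(rows)) {
    for (pair in list(c("CHS", "score_chs"), c("SOF", "score_sof"),
                      c("FRAIL", "score_frail"))) {
      single <- get(pair[2])(rows[[i]])
      row <- tab[tab$id == rows[[i]]$id & tab$index == pair[1], ]
      expect_equal(row$score, single$score)
      expect_equal(row$category, single$category)
    }
  }
})
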