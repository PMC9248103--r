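test_that("preprocess removes DC, trims, normalizes, and flags silence", {
  expect_error(preprocess(voice_recording(rep(0.3, FS), FS)), "silent")

  long <- make_sine(120, dur = 2)
  expect_equal(length(preprocess(long)$samples), FS)

  half <- make_sine(120, amp = 0.5)
  expect_equal(max(abs(preprocess(half)$samples)), 0.9, tolerance = 1e-6)

  hi <- make_sine(120, fs = 20000)
  pp <- preprocess(hi)
  expect_equal(pp$sample_rate_hz, 10000)
  expect_equal(length(pp$samples), 10000)
})

test_that("A1 matches the direct sign-change oracle for pure sines", {
  for (f0 in c(53, 97, 151, 249, 333, 487)) {
    rec <- make_sine(f0)
    expected <- 2 * f0 / FS
    a1 <- compute_a1(rec)
    expect_equal(a1, expected, tolerance = 0.025)
    expect_equal(a1, direct_zcr(rec$samples), tolerance = 0.01)
  }
})

test_that("A1 edge cases: positive signals, alternating samples, zeros", {
  pos <- voice_recording(2 + sin(2 * pi * 100 * seq(0, 1, by = 1 / FS)), FS)
  expect_equal(compute_a1(pos), 0)

  alt <- voice_recording(rep(c(1, -1), FS / 2), FS)
  frame_len <- 250
  expect_equal(compute_a1(alt), (frame_len - 1) / frame_len)

  # an exact zero between +1 and -1 is one crossing, not two
  with_zero <- voice_recording(rep(c(1, 1, 1, 1, 0, -1, -1, -1, -1, 0),
                                   FS / 10), FS)
  no_zero <- voice_recording(rep(c(1, 1, 1, 1, 1, -1, -1, -1, -1, -1),
                                 FS / 10), FS)
  expect_equal(compute_a1(with_zero), compute_a1(no_zero))
})

test_that("A2 is zero for a stable tone and 0.1 for the alternating fixture", {
  expect_lt(compute_a2(make_sine(100)), 1e-8)
  expect_equal(compute_a2(make_alternating_peak_fixture()), 0.1,
               tolerance = 1e-4)
  expect_error(compute_a2(voice_recording(seq(0, 1, length.out = FS), FS)),
               "extrema")
})

test_that("A2 increases with synthesized shimmer", {
  a2 <- vapply(c(0, 0.05, 0.10), function(sh) {
    sp <- clean_vowel_spec(seed = 11)
    sp$shimmer_rel <- sh
    compute_a2(preprocess(synthesize_vowel(sp)))
  }, numeric(1))
  expect_true(all(diff(a2) > 0))
})

test_that("LPC formant estimation recovers synthesis poles", {
  rec <- preprocess(synthesize_vowel(clean_vowel_spec(seed = 5)))
  frame <- rec$samples[2001:2250]
  est <- estimate_formants(frame, rec$sample_rate_hz)
  expect_true(est$valid)
  expect_equal(est$f1_hz, 700, tolerance = 50 / 700)
  expect_equal(est$f2_hz, 1200, tolerance = 50 / 1200)
})

test_that("formant estimation marks white noise and single poles invalid", {
  set.seed(42)
  flags <- vapply(seq_len(50), function(i) {
    estimate_formants(rnorm(250), FS)$valid
  }, logical(1))
  expect_gt(mean(!flags), 0.6)

  # a single resonator leaves fewer than two credible poles
  n <- 2500
  r <- exp(-pi * 60 / FS)
  x <- as.numeric(stats::filter(c(1, numeric(n - 1)) + rnorm(n, 0, 1e-4),
                                c(2 * r * cos(2 * pi * 500 / FS), -r^2),
                                method = "recursive"))
  est <- estimate_formants(x[501:750], FS)
  expect_false(est$valid)
})

test_that("formant recovery holds across a 3x3 (F1, F2) grid", {
  for (f1 in c(550, 700, 850)) {
    for (f2 in c(1100, 1300, 1500)) {
      sp <- clean_vowel_spec(formants = list(c(f1, 80), c(f2, 90),
                                             c(2600, 120)), seed = 7)
      tr <- formant_track(preprocess(synthesize_vowel(sp)))
      expect_gt(mean(tr$valid), 0.5)
      expect_lt(abs(median(tr$f1_hz[tr$valid]) - f1), 50)
      expect_lt(abs(median(tr$f2_hz[tr$valid]) - f2), 50)
    }
  }
})

test_that("A3 follows its mean-absolute-deviation definition", {
  const <- data.frame(frame = 1:10, f1_hz = 700, f2_hz = 1200, valid = TRUE)
  expect_equal(compute_a3(const), 0)

  alt <- data.frame(frame = 1:10, f1_hz = rep(c(690, 710), 5),
                    f2_hz = 1200, valid = TRUE)
  expect_equal(compute_a3(alt), 5)

  expect_error(compute_a3(const[1:3, ]), "too few")
})

test_that("A3 rises with synthesized formant drift", {
  a3 <- vapply(c(0, 40), function(d) {
    sp <- clean_vowel_spec(seed = 13)
    sp$formant_drift_hz <- d
    compute_a3(formant_track(preprocess(synthesize_vowel(sp))))
  }, numeric(1))
  expect_gt(a3[2], a3[1])
})

test_that("A4 splits spectral energy at the end frequency", {
  expect_lt(compute_a4(make_sine(1000)), 0.01)
  expect_gt(compute_a4(make_sine(4000)), 0.99)
  set.seed(7)
  wn <- voice_recording(rnorm(FS), FS)
  expect_equal(compute_a4(wn), 0.40, tolerance = 0.05)
  expect_error(compute_a4(voice_recording(rnorm(3000), 6000)),
               "sample rate")
})

test_that("A2 and A4 are invariant to input amplitude scaling", {
  sp <- vowel_spec(seed = 21)
  rec <- synthesize_vowel(sp)
  scaled <- voice_recording(rec$samples * 0.5, rec$sample_rate_hz)
  f1 <- extract_features(rec)
  f2 <- extract_features(scaled)
  expect_equal(f1$a2, f2$a2, tolerance = 1e-6)
  expect_equal(f1$a4, f2$a4, tolerance = 1e-6)
})

test_that("A3 is stable under silence-free repetition of the signal", {
  sp <- vowel_spec(formant_drift_hz = 8, seed = 17)
  rec <- preprocess(synthesize_vowel(sp))
  doubled <- voice_recording(rep(rec$samples, 2), rec$sample_rate_hz)
  a3_once <- compute_a3(formant_track(rec))
  a3_twice <- compute_a3(formant_track(doubled))
  expect_equal(a3_twice, a3_once, tolerance = 0.05)
})

test_that("extract_features returns one finite row for a clean vowel", {
  row <- extract_features(synthesize_vowel(vowel_spec(seed = 3)))
  expect_true(all(c(row$a1_ok, row$a2_ok, row$a3_ok, row$a4_ok)))
  expect_true(row$a1 >= 0 && row$a1 <= 1)
  expect_true(row$a4 >= 0 && row$a4 <= 1)
  expect_identical(row$reason, "")
})

test_that("a silent recording yields missing features with a reason", {
  silent <- voice_recording(numeric(FS), FS, id = "quiet")
  row <- extract_features(silent)
  expect_true(all(is.na(c(row$a1, row$a2, row$a3, row$a4))))
  expect_match(row$reason, "silent recording")
})

test_that("one corrupt recording does not abort a batch", {
  recs <- lapply(1:9, function(i) synthesize_vowel(vowel_spec(seed = i),
                                                   id = paste0("r", i)))
  recs[[10]] <- voice_recording(numeric(FS), FS, id = "bad")
  out <- extract_features_batch(recs)
  expect_equal(nrow(out), 10)
  expect_equal(sum(out$a1_ok), 9)
  expect_match(out$reason[out$id == "bad"], "silent")
})
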