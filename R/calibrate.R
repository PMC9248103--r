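# Mapping acoustic-feature targets to synthesis knobs.
#
# Each feature has a paired knob (A1 <- f0, A2 <- shimmer_rel,
# A3 <- formant_drift_hz, A4 <- noise_hf_rel). The map is built
# empirically once per session: synthesize a grid of knob values (a few
# fixed internal seeds each), extract the feature, fit a monotone
# (isotonic) curve, and invert it. On top of the univariate maps, a joint
# Monte-Carlo error model captures how the stochastic synthesis-extraction
# chain smears and cross-couples the four features; the cohort generator
# uses it to de-attenuate configured effect sizes.

.fv_cache <- new.env(parent = emptyenv())

CALIB_SEEDS <- c(101L, 202L, 303L)

knob_grids <- function() {
  list(a1 = seq(70, 300, length.out = 13),
       a2 = seq(0, 0.45, length.out = 13),
       a3 = seq(0, 60, length.out = 13),
       a4 = seq(0, 1.0, length.out = 13))
}

set_knob <- function(spec, feature, value) {
  switch(feature,
         a1 = { spec$f0_hz <- value },
         a2 = { spec$shimmer_rel <- value },
         a3 = { spec$formant_drift_hz <- value },
         a4 = { spec$noise_hf_rel <- value })
  spec
}

knob_name <- function(feature) {
  switch(feature, a1 = "f0_hz", a2 = "shimmer_rel",
         a3 = "formant_drift_hz", a4 = "noise_hf_rel")
}

extract_one_feature <- function(rec, feature, config = acoustic_config()) {
  pp <- preprocess(rec)
  switch(feature,
         a1 = compute_a1(pp, config),
         a2 = compute_a2(pp, config),
         a3 = compute_a3(formant_track(pp, config)),
         a4 = compute_a4(pp, config))
}

spec_cache_key <- function(base_spec) {
  paste(base_spec$duration_s, base_spec$f0_hz, base_spec$jitter_rel,
        base_spec$shimmer_rel,
        paste(unlist(base_spec$formants), collapse = ","),
        base_spec$formant_drift_hz, base_spec$noise_hf_rel,
        base_spec$sample_rate_hz, sep = "|")
}

# Monotone knob -> feature curve for one feature (cached per base spec).
calibration_curve <- function(feature, base_spec = vowel_spec()) {
  key <- paste0("curve|", feature, "|", spec_cache_key(base_spec))
  if (!is.null(.fv_cache[[key]])) return(.fv_cache[[key]])
  grid <- knob_grids()[[feature]]
  vals <- vapply(grid, function(k) {
    sp <- set_knob(base_spec, feature, k)
    mean(vapply(CALIB_SEEDS, function(s) {
      sp$seed <- s
      tryCatch(extract_one_feature(synthesize_vowel(sp), feature),
               error = function(e) NA_real_)
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(vals)
  if (sum(ok) < 4) stop("calibration failed for ", feature,
                        ": feature not extractable over the knob grid")
  grid <- grid[ok]
  vals <- vals[ok]
  iso <- stats::isoreg(grid, vals)
  yf <- iso$yf + seq_along(grid) * 1e-9 # break flats for inversion
  curve <- list(
    feature = feature, knob = knob_name(feature), grid = grid,
    feature_values = yf, range = range(yf),
    to_feature = approxfun(grid, yf, rule = 2),
    to_knob = approxfun(yf, grid, rule = 2)
  )
  .fv_cache[[key]] <- curve
  curve
}

#' Achievable interval of a feature under the synthesizer
#'
#' @param feature One of `"a1"`, `"a2"`, `"a3"`, `"a4"`.
#' @param base_spec Base [vowel_spec()] around which the paired knob is
#'   swept.
#' @return `c(lo, hi)` of attainable mean feature values.
#' @export
feature_achievable <- function(feature, base_spec = vowel_spec()) {
  calibration_curve(feature, base_spec)$range
}

#' Build a vowel spec whose extracted features approximate given targets
#'
#' Inverts the empirically calibrated monotone knob-to-feature maps:
#' higher target A1 raises the fundamental frequency, higher A2 raises
#' shimmer, higher A3 raises the formant drift, higher A4 raises the
#' high-pass noise level. Targets outside the achievable interval are an
#' error naming the interval.
#'
#' @param targets Named list/vector with any of `a1`, `a2`, `a3`, `a4`.
#' @param base_spec Base [vowel_spec()] supplying the remaining settings.
#' @param seed Seed for the returned spec.
#' @param clip Clamp out-of-range targets to the achievable interval
#'   instead of erroring (used when homing in on an operating point).
#' @return A [vowel_spec()].
#' @export
#' @examples
#' sp <- calibrate_spec_for_features(c(a2 = 0.05, a4 = 0.1), seed = 7)
calibrate_spec_for_features <- function(targets, base_spec = vowel_spec(),
                                        seed = base_spec$seed,
                                        clip = FALSE) {
  targets <- unlist(targets)
  bad <- setdiff(names(targets), c("a1", "a2", "a3", "a4"))
  if (length(bad)) stop("unknown feature target(s): ",
                        paste(bad, collapse = ", "))
  spec <- base_spec
  for (feature in names(targets)) {
    curve <- calibration_curve(feature, base_spec)
    t <- targets[[feature]]
    if (t < curve$range[1] - 1e-9 || t > curve$range[2] + 1e-9) {
      if (clip) {
        t <- clamp(t, curve$range)
      } else {
        stop(sprintf(
          "target %s = %.4g is unreachable; achievable interval is [%.4g, %.4g]",
          feature, t, curve$range[1], curve$range[2]))
      }
    }
    spec <- set_knob(spec, feature, curve$to_knob(t))
  }
  spec$seed <- as.integer(seed)
  validate_vowel_spec(spec)
  spec
}

# Reference model of the calibrate -> synthesize -> extract chain,
# estimated once per configuration (and cached): draw m target vectors
# from the configured marginals, push them through the chain, and keep
# (i) the pool of extracted features (used to place the logistic
# intercept of the frailty-status model at the configured prevalence) and
# (ii) a linear response summary (intercepts alpha, coupling matrix B)
# used to center and scale the target draws so the extracted features
# land on the configured means/SDs.
synthesis_reference <- function(means, sds, base_spec = vowel_spec(),
                                m = 200, seed = 424243L) {
  key <- paste0("ref|", paste(means, collapse = ","), "|",
                paste(sds, collapse = ","), "|", spec_cache_key(base_spec),
                "|", m)
  if (!is.null(.fv_cache[[key]])) return(.fv_cache[[key]])
  feats <- c("a1", "a2", "a3", "a4")
  ranges <- lapply(feats, feature_achievable, base_spec = base_spec)
  names(ranges) <- feats
  tmat <- with_seed(seed, {
    t(vapply(seq_len(m), function(i) {
      vapply(feats, function(f) {
        clamp(rnorm(1, means[[f]], sds[[f]]), ranges[[f]])
      }, numeric(1))
    }, numeric(4)))
  })
  xmat <- matrix(NA_real_, m, 4, dimnames = list(NULL, feats))
  for (i in seq_len(m)) {
    sp <- calibrate_spec_for_features(tmat[i, ], base_spec,
                                      seed = derive_seed(seed, i), clip = TRUE)
    row <- extract_features(synthesize_vowel(sp))
    xmat[i, ] <- unlist(row[feats])
  }
  ok <- stats::complete.cases(xmat)
  alpha <- numeric(4)
  B <- matrix(0, 4, 4, dimnames = list(feats, feats))
  sigma_e <- numeric(4)
  for (j in seq_along(feats)) {
    fit <- lm(xmat[ok, j] ~ tmat[ok, , drop = FALSE])
    alpha[j] <- coef(fit)[1]
    B[j, ] <- coef(fit)[-1]
    sigma_e[j] <- sd(fit$residuals)
  }
  names(alpha) <- names(sigma_e) <- feats
  out <- list(alpha = alpha, B = B, sigma_e = sigma_e,
              pool = xmat[ok, , drop = FALSE], ranges = ranges)
  .fv_cache[[key]] <- out
  out
}

# Logistic intercept placing the expected frail fraction of the reference
# pool at the configured prevalence, for per-unit slopes b (named by
# feature). Errors when the model is saturated.
solve_intercept <- function(pool, b, prevalence) {
  eta <- as.numeric(pool %*% b[colnames(pool)])
  f <- function(b0) mean(plogis(b0 + eta)) - prevalence
  lo <- -30
  hi <- 30
  if (f(lo) > 0 || f(hi) < 0) {
    stop("infeasible effect-OR / prevalence combination ",
         "(saturated probabilities)")
  }
  b0 <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  if (abs(b0) > 25) {
    stop("infeasible effect-OR / prevalence combination ",
         "(saturated probabilities)")
  }
  b0
}

clamp <- function(x, range) pmin(range[2], pmax(range[1], x))
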