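# Synthetic cohort generator: latent frailty status at a configured
# prevalence, criterion fields filled consistently with that status, and
# per-participant vowel recordings whose acoustic features carry
# configured odds ratios against the status.

#' Configure a synthetic cohort
#'
#' Defaults emulate a geriatric-outpatient study setting: n = 277, 63.2%
#' women, and a
#' latent frailty prevalence near the observed index prevalences; default
#' effect sizes are the headline all-participant odds ratios (A1 0.84 per
#' 1, A2 1.26 per 0.1, A3 1.04 per 10 Hz, A4 1.35 per 0.1).
#'
#' @param n_participants Cohort size (>= 2).
#' @param prop_female Proportion of women in \[0, 1\].
#' @param frailty_prevalence Latent frail proportion in (0, 1).
#' @param effect_ors Named vector of target odds ratios on the reporting
#'   scales of [feature_scale_units()]; features omitted default to 1.
#' @param feature_means_robust Mean extracted feature values in the
#'   robust/pre-frail group.
#' @param feature_sds Between-participant SDs of the extracted features.
#' @param sex_interaction Optional named list `feature = c(sex = "female",
#'   or_multiplier = 2)`: multiplies that feature's OR in one sex.
#' @param base_spec Base [vowel_spec()] for all participants.
#' @param seed Master seed; per-participant streams are derived by counter
#'   splitting, so earlier participants are unchanged when `n_participants`
#'   grows.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 277, prop_female = 0.632,
                          frailty_prevalence = 0.19,
                          effect_ors = c(a1 = 0.84, a2 = 1.26,
                                         a3 = 1.04, a4 = 1.35),
                          feature_means_robust = c(a1 = 0.115, a2 = 0.085,
                                                   a3 = 18, a4 = 0.04),
                          feature_sds = c(a1 = 0.012, a2 = 0.01,
                                          a3 = 6, a4 = 0.012),
                          sex_interaction = NULL,
                          base_spec = elderly_vowel_spec(), seed = 1L) {
  feats <- c("a1", "a2", "a3", "a4")
  ors <- setNames(rep(1, 4), feats)
  ors[names(effect_ors)] <- effect_ors
  cfg <- structure(
    list(n_participants = as.integer(n_participants),
         prop_female = prop_female,
         frailty_prevalence = frailty_prevalence,
         effect_ors = ors,
         feature_means_robust = feature_means_robust[feats],
         feature_sds = feature_sds[feats],
         sex_interaction = sex_interaction,
         base_spec = base_spec, seed = as.integer(seed)),
    class = "cohort_config"
  )
  if (cfg$n_participants < 2) stop("n_participants must be >= 2")
  if (any(cfg$effect_ors <= 0)) stop("all effect ORs must be > 0")
  if (cfg$frailty_prevalence <= 0 || cfg$frailty_prevalence >= 1)
    stop("frailty_prevalence must lie in (0, 1)")
  if (cfg$prop_female < 0 || cfg$prop_female > 1)
    stop("prop_female must lie in [0, 1]")
  cfg
}

# Index criterion sets over the underlying binary deficits and the scores
# at which each index calls a participant frail.
INDEX_SETS <- list(
  CHS = c("wl", "exhaustion", "weakness", "slowness", "adl"),
  SOF = c("wl", "chair", "energy_reduced"),
  FRAIL = c("exhaustion", "chair", "slowness", "drugs", "wl")
)
INDEX_FRAIL_AT <- c(CHS = 3, SOF = 2, FRAIL = 3)
DEFICIT_NAMES <- c("wl", "exhaustion", "weakness", "slowness", "adl",
                   "chair", "drugs", "energy_reduced")

# Deficit flags consistent with the latent status: background deficits at
# rate 0.15; frail participants get additional flags (sampled without
# replacement per index) until every index reaches its frail score; the
# non-frail get flags removed until every index is below it.
draw_deficits <- function(frail) {
  flags <- setNames(runif(length(DEFICIT_NAMES)) < 0.15, DEFICIT_NAMES)
  if (frail) {
    for (index in names(INDEX_SETS)) {
      set <- INDEX_SETS[[index]]
      deficit <- INDEX_FRAIL_AT[[index]] - sum(flags[set])
      if (deficit > 0) {
        off <- set[!flags[set]]
        flags[sample(off, deficit)] <- TRUE
      }
    }
  } else {
    repeat {
      over <- names(which(vapply(names(INDEX_SETS), function(index) {
        sum(flags[INDEX_SETS[[index]]]) >= INDEX_FRAIL_AT[[index]]
      }, logical(1))))
      if (length(over) == 0) break
      set <- INDEX_SETS[[over[1]]]
      on <- set[flags[set]]
      flags[sample(on, 1)] <- FALSE
    }
  }
  flags
}

# Raw criterion fields realizing a deficit-flag vector, away from the
# scoring cutoffs so the scorers reproduce the flags exactly.
fields_from_deficits <- function(flags, sex, frail) {
  age <- min(95, max(60, rnorm(1, 74 + 3 * frail, 7)))
  height <- rnorm(1, if (sex == "male") 1.68 else 1.55, 0.06)
  weight <- max(35, rnorm(1, (if (sex == "male") 64 else 56) - 5 * frail, 9))
  wl_pct <- if (flags[["wl"]]) runif(1, 5.5, 12) else runif(1, 0, 3)
  cannot_walk <- flags[["slowness"]] && runif(1) < 0.05
  grip_cut <- if (sex == "male") 28 else 18
  list(
    id = "tmp", sex = sex, age_years = age, weight_kg = weight,
    bmi = weight / height^2,
    weight_loss_pct_year = wl_pct,
    weight_loss_kg_year = wl_pct / 100 * weight,
    unintentional = if (flags[["wl"]]) TRUE else runif(1) < 0.3,
    exhaustion_answer = flags[["exhaustion"]],
    grip_kg = if (flags[["weakness"]]) runif(1, grip_cut - 12, grip_cut - 0.5)
              else runif(1, grip_cut + 0.5, grip_cut + 14),
    gait_speed_m_s = if (cannot_walk) NA_real_
                     else if (flags[["slowness"]]) runif(1, 0.4, 0.95)
                     else runif(1, 1.05, 1.6),
    cannot_walk = cannot_walk,
    adl_deterioration = flags[["adl"]],
    chair_stand_unable = flags[["chair"]],
    energy_full_answer = !flags[["energy_reduced"]],
    drug_count = if (flags[["drugs"]]) sample(8:15, 1)
                 else min(7L, rpois(1, 2.5))
  )
}

# columnwise assembly of a list of homogeneous named lists
bind_plain_rows <- function(rows) {
  cols <- names(rows[[1]])
  out <- lapply(setNames(cols, cols), function(cn) {
    unlist(lapply(rows, `[[`, cn), use.names = FALSE)
  })
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Simulate a cohort of participants with voice recordings
#'
#' The generator works forward through the measurement chain: per
#' participant it draws acoustic feature targets (no group structure),
#' synthesizes the vowel via [calibrate_spec_for_features()] and
#' [synthesize_vowel()], extracts the features, and then assigns the
#' latent frail status from a logistic model **on the extracted
#' features** whose slopes are the configured log odds ratios and whose
#' intercept is placed (on a cached reference pool) so the expected
#' frail fraction equals the configured prevalence. Criterion fields are
#' then filled consistently with the assigned status, so [score_all()]
#' reproduces it exactly. Deterministic given the master seed;
#' per-participant streams are split by counter so a larger cohort
#' extends, rather than reshuffles, a smaller one.
#'
#' @param config A [cohort_config()].
#' @param synthesize Set `FALSE` to skip audio: status is then drawn
#'   directly at the configured prevalence (fields-only cohort).
#' @return A list of class `cohort` with `participants` (including the
#'   `latent_frail` column), `recordings` (list of [voice_recording()],
#'   or `NULL`), `features` (the generator's own feature extraction),
#'   `truth` (drawn targets, knob values, status probability, stream
#'   seeds) and the `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), synthesize = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  feats <- c("a1", "a2", "a3", "a4")
  units <- feature_scale_units()
  prev <- config$frailty_prevalence

  b_all <- log(config$effect_ors) / units[feats]
  b_sex <- list(male = b_all, female = b_all)
  for (f in names(config$sex_interaction)) {
    si <- config$sex_interaction[[f]]
    sx <- si[["sex"]]
    b_sex[[sx]][f] <- log(config$effect_ors[[f]] *
                            as.numeric(si[["or_multiplier"]])) / units[[f]]
  }

  # with all slopes zero the status does not depend on the voice, so the
  # generator's own feature extraction pass can be skipped
  needs_features <- any(b_all != 0) || length(config$sex_interaction) > 0
  voice <- NULL
  if (synthesize) {
    ref <- synthesis_reference(config$feature_means_robust,
                               config$feature_sds, config$base_spec)
    # target means/SDs that land the extracted features on the configured
    # marginals, via the linear response summary
    t0 <- tryCatch(solve(ref$B, config$feature_means_robust - ref$alpha),
                   error = function(e) {
                     (config$feature_means_robust - ref$alpha) / diag(ref$B)
                   })
    t0 <- setNames(as.numeric(t0), feats)
    sigma_t <- config$feature_sds / pmax(abs(diag(ref$B)), 0.3)
    c_sex <- b0_sex <- NULL
    if (needs_features) {
      # configured ORs are *univariate* reporting-scale ORs; convert them
      # to conditional slopes via the reference pool's covariance so each
      # one-feature fit recovers its configured value despite the
      # features' cross-correlations
      S <- stats::cov(ref$pool)
      c_sex <- lapply(b_sex, function(b) {
        # restrict the solve to features with a configured effect: zero-b
        # features would otherwise demand exact cancellation of their
        # correlated neighbours, which is hopeless when the pool is
        # near-collinear (noise drives both A1 and A4)
        ct <- setNames(numeric(length(feats)), feats)
        J <- names(which(b[feats] != 0))
        if (length(J)) {
          SJ <- S[J, J, drop = FALSE]
          well_conditioned <- length(J) == 1 ||
            kappa(stats::cov2cor(SJ)) < 50
          ct[J] <- if (well_conditioned) {
            as.numeric(solve(SJ, b[J] * diag(S)[J]))
          } else {
            b[J]
          }
        }
        ct
      })
      b0_sex <- lapply(c_sex, solve_intercept, pool = ref$pool,
                       prevalence = prev)
    }
    voice <- list(ref = ref, t0 = t0, sigma_t = sigma_t,
                  c_sex = c_sex, b0_sex = b0_sex)
  }

  # pass 1: demographics, targets, synthesis, extraction
  sexes <- character(n)
  u_status <- numeric(n)
  targets <- matrix(NA_real_, n, 4, dimnames = list(NULL, feats))
  recordings <- if (synthesize) vector("list", n) else NULL
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    draw_seed <- derive_seed(config$seed, 3 * i)
    voice_seed <- derive_seed(config$seed, 3 * i + 1)
    d <- with_seed(draw_seed, {
      u <- runif(1)
      sex <- if (runif(1) < config$prop_female) "female" else "male"
      t_i <- if (synthesize) {
        vapply(feats, function(f) {
          clamp(rnorm(1, voice$t0[[f]], voice$sigma_t[[f]]),
                voice$ref$ranges[[f]])
        }, numeric(1))
      } else {
        rep(NA_real_, 4)
      }
      list(u = u, sex = sex, t = t_i)
    })
    u_status[i] <- d$u
    sexes[i] <- d$sex
    targets[i, ] <- d$t
    if (synthesize) {
      sp <- calibrate_spec_for_features(d$t, config$base_spec,
                                        seed = voice_seed, clip = TRUE)
      specs[[i]] <- sp
      recordings[[i]] <- synthesize_vowel(sp, id = sprintf("p%04d", i))
    }
  }

  # pass 2: status from the logistic model on the extracted features
  if (synthesize && needs_features) {
    features <- extract_features_batch(recordings)
    x <- as.matrix(features[, feats])
    eta <- vapply(seq_len(n), function(i) {
      b <- voice$c_sex[[sexes[i]]]
      xi <- x[i, ]
      ok <- is.finite(xi)
      voice$b0_sex[[sexes[i]]] + sum(b[ok] * xi[ok])
    }, numeric(1))
    p_frail <- plogis(eta)
  } else {
    features <- NULL
    p_frail <- rep(prev, n)
  }
  frail <- u_status < p_frail

  # pass 3: criterion fields consistent with the assigned status
  participants <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    field_seed <- derive_seed(config$seed, 3 * i + 2)
    p <- with_seed(field_seed, {
      flags <- draw_deficits(frail[i])
      fields_from_deficits(flags, sexes[i], frail[i])
    })
    p$id <- sprintf("p%04d", i)
    p$latent_frail <- frail[i]
    participants[[i]] <- p
    tr <- list(id = p$id, latent_frail = frail[i], p_frail = p_frail[i],
               draw_seed = derive_seed(config$seed, 3 * i),
               voice_seed = derive_seed(config$seed, 3 * i + 1),
               field_seed = field_seed)
    if (synthesize) {
      tr[paste0("target_", feats)] <- targets[i, ]
      sp <- specs[[i]]
      tr$f0_hz <- sp$f0_hz
      tr$shimmer_rel <- sp$shimmer_rel
      tr$formant_drift_hz <- sp$formant_drift_hz
      tr$noise_hf_rel <- sp$noise_hf_rel
    }
    truth[[i]] <- tr
  }
  structure(list(participants = bind_plain_rows(participants),
                 recordings = recordings,
                 features = features,
                 truth = bind_plain_rows(truth),
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort: %d participants (%.1f%% frail latent), %s recordings>\n",
    nrow(x$participants), 100 * mean(x$participants$latent_frail),
    if (is.null(x$recordings)) "no" else length(x$recordings)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes `cohort.csv` (participant fields + latent status), one 16-bit
#' PCM WAV per recording under `audio/`, and `manifest.json` mapping
#' participant ids to WAV paths, stream seeds and true synthesis
#' parameters.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$participants, file.path(dir, "cohort.csv"),
            row.names = FALSE)
  manifest <- cohort$truth
  if (!is.null(cohort$recordings)) {
    dir.create(file.path(dir, "audio"), showWarnings = FALSE)
    paths <- vapply(cohort$recordings, function(r) {
      p <- file.path("audio", paste0(r$id, ".wav"))
      write_wav(r, file.path(dir, p))
      p
    }, character(1))
    manifest$wav_path <- paths
  }
  jsonlite::write_json(
    list(seed = cohort$config$seed,
         n_participants = cohort$config$n_participants,
         effect_ors = as.list(cohort$config$effect_ors),
         participants = manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
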