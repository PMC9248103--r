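# Frailty scoring on three operational indices:
#   CHS (Fried phenotype): weight loss, exhaustion, weakness, slowness,
#     low activity; >= 3 frail, 1-2 pre-frail, 0 robust.
#   SOF: weight loss, chair stands, reduced energy; >= 2 frail, 1 pre-frail.
#   FRAIL: fatigue, resistance, ambulation, illness, loss of weight;
#     3-5 frail, 1-2 pre-frail, 0 robust.
# Flags are computed vectorized over whole participant tables; the
# per-participant scorers are thin wrappers around the same logic.

#' Frailty criterion cutoffs
#'
#' Every numeric threshold used by the scorers, with the boundary
#' conventions spelled out: grip weakness and slow gait are strict `<`;
#' SOF weight loss is strict `> 5` percent and FRAIL inclusive `>= 5`;
#' CHS weight loss is inclusive `>= 4.5` kg or strict `> 5` percent
#' (unintentional only); polypharmacy is inclusive `>= 8` drugs.
#'
#' @param grip_male_kg,grip_female_kg Grip-strength weakness cutoffs
#'   (Asian working-group values), strict `<`.
#' @param gait_slow_m_s Slow-gait cutoff in m/s, strict `<`.
#' @param weight_loss_chs_kg CHS unintentional weight-loss cutoff in kg,
#'   inclusive.
#' @param weight_loss_chs_pct CHS weight-loss percent cutoff, strict `>`.
#' @param weight_loss_sof_pct SOF percent weight-loss cutoff, strict `>`.
#' @param weight_loss_frail_pct FRAIL percent weight-loss cutoff,
#'   inclusive `>=`.
#' @param illness_drugs Drug-count cutoff for the FRAIL illness item,
#'   inclusive.
#' @return A list of cutoffs.
#' @export
frailty_config <- function(grip_male_kg = 28, grip_female_kg = 18,
                           gait_slow_m_s = 1.0, weight_loss_chs_kg = 4.5,
                           weight_loss_chs_pct = 5, weight_loss_sof_pct = 5,
                           weight_loss_frail_pct = 5, illness_drugs = 8) {
  list(grip_male_kg = grip_male_kg, grip_female_kg = grip_female_kg,
       gait_slow_m_s = gait_slow_m_s, weight_loss_chs_kg = weight_loss_chs_kg,
       weight_loss_chs_pct = weight_loss_chs_pct,
       weight_loss_sof_pct = weight_loss_sof_pct,
       weight_loss_frail_pct = weight_loss_frail_pct,
       illness_drugs = illness_drugs)
}

#' Construct a participant record
#'
#' One subject's raw criterion fields. `NA` marks a missing answer or
#' measurement; a missing gait speed together with `cannot_walk = TRUE`
#' encodes inability to perform the walking test (classified as low
#' mobility).
#'
#' @param id Identifier.
#' @param sex `"male"` or `"female"`.
#' @param age_years Age in years.
#' @param weight_kg,bmi Descriptive anthropometry (not used by scorers).
#' @param weight_loss_pct_year Weight change over the last year, percent of
#'   body weight.
#' @param weight_loss_kg_year Weight change over the last year, kg.
#' @param unintentional Was the weight loss unintentional?
#' @param exhaustion_answer "Less energy to do the things you want?"
#'   (`TRUE` = yes); feeds CHS exhaustion and FRAIL fatigue.
#' @param grip_kg Dominant-hand grip strength, kg.
#' @param gait_speed_m_s Usual gait speed over 4 m, m/s.
#' @param cannot_walk Unable to perform the walking test.
#' @param adl_deterioration Deterioration in activities of daily living
#'   over the last year (CHS low-activity proxy).
#' @param chair_stand_unable Unable to rise from a chair five times
#'   without using the arms.
#' @param energy_full_answer "Do you feel full of energy?" (`TRUE` = yes);
#'   a no feeds the SOF reduced-energy item.
#' @param drug_count Number of drugs in regular use.
#' @return One-row data.frame.
#' @export
participant <- function(id = "p1", sex = NA_character_, age_years = NA_real_,
                        weight_kg = NA_real_, bmi = NA_real_,
                        weight_loss_pct_year = NA_real_,
                        weight_loss_kg_year = NA_real_,
                        unintentional = NA,
                        exhaustion_answer = NA, grip_kg = NA_real_,
                        gait_speed_m_s = NA_real_, cannot_walk = FALSE,
                        adl_deterioration = NA, chair_stand_unable = NA,
                        energy_full_answer = NA, drug_count = NA_integer_) {
  data.frame(id = id, sex = sex, age_years = age_years,
             weight_kg = weight_kg, bmi = bmi,
             weight_loss_pct_year = weight_loss_pct_year,
             weight_loss_kg_year = weight_loss_kg_year,
             unintentional = unintentional,
             exhaustion_answer = exhaustion_answer, grip_kg = grip_kg,
             gait_speed_m_s = gait_speed_m_s, cannot_walk = cannot_walk,
             adl_deterioration = adl_deterioration,
             chair_stand_unable = chair_stand_unable,
             energy_full_answer = energy_full_answer,
             drug_count = drug_count, stringsAsFactors = FALSE)
}

# vectorized slowness/ambulation item: gait below cutoff (strict), or
# inability to walk when the gait test is missing
slowness_flags <- function(p, config) {
  ifelse(is.na(p$gait_speed_m_s),
         ifelse(!is.na(p$cannot_walk) & p$cannot_walk, TRUE, NA),
         p$gait_speed_m_s < config$gait_slow_m_s)
}

# flag matrices, one row per participant
chs_flag_matrix <- function(p, config) {
  above <- (!is.na(p$weight_loss_kg_year) &
              p$weight_loss_kg_year >= config$weight_loss_chs_kg) |
    (!is.na(p$weight_loss_pct_year) &
       p$weight_loss_pct_year > config$weight_loss_chs_pct)
  both_missing <- is.na(p$weight_loss_kg_year) & is.na(p$weight_loss_pct_year)
  weight_loss <- ifelse(both_missing, NA,
                        ifelse(!above, FALSE, # below cutoffs, intent moot
                               ifelse(is.na(p$unintentional), NA,
                                      p$unintentional)))
  cutoff <- ifelse(p$sex == "male", config$grip_male_kg,
                   config$grip_female_kg)
  weakness <- ifelse(is.na(p$grip_kg) | is.na(p$sex), NA, p$grip_kg < cutoff)
  cbind(weight_loss = weight_loss,
        exhaustion = as.logical(p$exhaustion_answer),
        weakness = weakness,
        slowness = slowness_flags(p, config),
        low_activity = as.logical(p$adl_deterioration))
}

sof_flag_matrix <- function(p, config) {
  energy <- as.logical(p$energy_full_answer)
  cbind(weight_loss = ifelse(is.na(p$weight_loss_pct_year), NA,
                             p$weight_loss_pct_year >
                               config$weight_loss_sof_pct),
        chair_stand = as.logical(p$chair_stand_unable),
        reduced_energy = ifelse(is.na(energy), NA, !energy))
}

frail_flag_matrix <- function(p, config) {
  cbind(fatigue = as.logical(p$exhaustion_answer),
        resistance = as.logical(p$chair_stand_unable),
        ambulation = slowness_flags(p, config),
        illness = ifelse(is.na(p$drug_count), NA,
                         p$drug_count >= config$illness_drugs),
        weight_loss = ifelse(is.na(p$weight_loss_pct_year), NA,
                             p$weight_loss_pct_year >=
                               config$weight_loss_frail_pct))
}

INDEX_FLAGS <- list(CHS = chs_flag_matrix, SOF = sof_flag_matrix,
                    FRAIL = frail_flag_matrix)
INDEX_THRESHOLD <- c(CHS = 3, SOF = 2, FRAIL = 3)

categorize <- function(score, frail_at) {
  ifelse(score >= frail_at, "frail",
         ifelse(score >= 1, "pre-frail", "robust"))
}

assessment_from_flags <- function(index, flags, frail_at) {
  missing <- names(flags)[is.na(flags)]
  score <- sum(flags, na.rm = TRUE)
  category <- categorize(score, frail_at)
  # missingness could push the score across the frailty threshold
  incomplete <- (score < frail_at) && (score + length(missing) >= frail_at)
  structure(
    list(index = index, criteria = flags, score = as.integer(score),
         category = category, missing_criteria = missing,
         incomplete = incomplete),
    class = "frailty_assessment"
  )
}

#' @export
print.frailty_assessment <- function(x, ...) {
  cat(sprintf("<%s assessment: score %d, %s%s>\n", x$index, x$score,
              x$category, if (x$incomplete) " (incomplete)" else ""))
  pos <- names(x$criteria)[!is.na(x$criteria) & x$criteria]
  if (length(pos)) cat("  positive:", paste(pos, collapse = ", "), "\n")
  if (length(x$missing_criteria))
    cat("  missing:", paste(x$missing_criteria, collapse = ", "), "\n")
  invisible(x)
}

score_one <- function(p, index, config) {
  stopifnot(nrow(p) == 1)
  flags <- INDEX_FLAGS[[index]](p, config)[1, ]
  if (all(is.na(flags))) stop("all ", index, " criteria missing for ", p$id)
  assessment_from_flags(index, flags, INDEX_THRESHOLD[[index]])
}

#' Score the CHS (Fried phenotype) frailty index
#'
#' Five criteria: unintentional weight loss (>= 4.5 kg or > 5%/year),
#' exhaustion (less-energy answer yes), weakness (grip below the
#' sex-specific cutoff, strict), slowness (gait < 1.0 m/s or unable to
#' walk), and low physical activity (ADL deterioration). Frail at >= 3
#' criteria, pre-frail at 1-2, robust at 0. Missing criteria count zero
#' but are listed, and the assessment is flagged incomplete when the
#' missing items could change the category.
#'
#' @param p One-row [participant()] data.frame.
#' @param config [frailty_config()].
#' @return A `frailty_assessment`.
#' @export
score_chs <- function(p, config = frailty_config()) {
  score_one(p, "CHS", config)
}

#' Score the SOF frailty index
#'
#' Three criteria: weight loss > 5% in the past year (intentional or not),
#' inability to rise from a chair five times without arms, and a negative
#' answer to "do you feel full of energy?". Frail at >= 2, pre-frail at 1.
#'
#' @inheritParams score_chs
#' @return A `frailty_assessment`.
#' @export
score_sof <- function(p, config = frailty_config()) {
  score_one(p, "SOF", config)
}

#' Score the FRAIL index
#'
#' Five items: Fatigue (less-energy answer yes), Resistance (chair-stand
#' unable), Ambulation (gait < 1.0 m/s or unable to walk), Illness (>= 8
#' drugs), and Loss of weight (self-reported >= 5%/year). Frail at 3-5,
#' pre-frail at 1-2, robust at 0.
#'
#' @inheritParams score_chs
#' @return A `frailty_assessment`.
#' @export
score_frail <- function(p, config = frailty_config()) {
  score_one(p, "FRAIL", config)
}

#' Score a cohort on all three indices
#'
#' @param participants Data.frame of [participant()] rows (unique ids).
#' @param config [frailty_config()].
#' @return Long data.frame: one row per participant per index with `id`,
#'   `sex`, `index`, `score`, `category`, `frail` (the binary frail vs
#'   robust/pre-frail grouping used throughout the analyses),
#'   `incomplete`, `n_missing`, `missing_criteria` and one `crit_*` column
#'   per criterion (NA where an index does not use it).
#' @export
score_all <- function(participants, config = frailty_config()) {
  if (nrow(participants) == 0) stop("empty participant table")
  if (anyDuplicated(participants$id)) stop("duplicate participant ids")
  crit_names <- c("weight_loss", "exhaustion", "weakness", "slowness",
                  "low_activity", "chair_stand", "reduced_energy",
                  "fatigue", "resistance", "ambulation", "illness")
  out <- vector("list", 3L)
  for (index in names(INDEX_FLAGS)) {
    flags <- INDEX_FLAGS[[index]](participants, config)
    if (any(all_na <- rowSums(!is.na(flags)) == 0)) {
      stop("all ", index, " criteria missing for ",
           paste(participants$id[all_na], collapse = ", "))
    }
    thr <- INDEX_THRESHOLD[[index]]
    score <- rowSums(flags, na.rm = TRUE)
    n_missing <- rowSums(is.na(flags))
    category <- categorize(score, thr)
    missing_str <- apply(is.na(flags), 1, function(m) {
      paste(colnames(flags)[m], collapse = ";")
    })
    row <- data.frame(id = participants$id, sex = participants$sex,
                      index = index, score = as.integer(score),
                      category = category, frail = category == "frail",
                      incomplete = score < thr & score + n_missing >= thr,
                      n_missing = n_missing, missing_criteria = missing_str,
                      stringsAsFactors = FALSE)
    for (cn in crit_names) {
      row[[paste0("crit_", cn)]] <- if (cn %in% colnames(flags)) {
        flags[, cn]
      } else {
        NA
      }
    }
    out[[index]] <- row
  }
  res <- do.call(rbind, out)
  # interleave so each participant's three assessments are adjacent
  res <- res[order(match(res$id, participants$id),
                   match(res$index, names(INDEX_FLAGS))), ]
  rownames(res) <- NULL
  res
}
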