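# End-to-end orchestration: simulate -> extract -> score -> associate,
# with a JSON run manifest for reproducibility.

#' Configure a pipeline run
#'
#' Collects every stage's settings in one validated, serializable list.
#' All clinical constants (3 kHz end frequency, 1.0 m/s gait cutoff,
#' 28/18 kg grip cutoffs, 8 drugs, 5% / 4.5 kg weight loss) sit in the
#' nested [acoustic_config()] and [frailty_config()] entries.
#'
#' @param cohort A [cohort_config()].
#' @param acoustic An [acoustic_config()].
#' @param frailty A [frailty_config()].
#' @param write_audio Write per-participant WAV files?
#' @param curve_points Grid size for the probability curves.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), acoustic = acoustic_config(),
                       frailty = frailty_config(), write_audio = FALSE,
                       curve_points = 50) {
  structure(list(cohort = cohort, acoustic = acoustic, frailty = frailty,
                 write_audio = write_audio, curve_points = curve_points),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [run_config()], [cohort_config()], [acoustic_config()] and
#' [frailty_config()]; unspecified keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cc <- y$cohort %||% list()
  if (!is.null(cc$effect_ors)) cc$effect_ors <- unlist(cc$effect_ors)
  if (!is.null(cc$feature_means_robust))
    cc$feature_means_robust <- unlist(cc$feature_means_robust)
  if (!is.null(cc$feature_sds)) cc$feature_sds <- unlist(cc$feature_sds)
  run_config(
    cohort = do.call(cohort_config, cc),
    acoustic = do.call(acoustic_config, y$acoustic %||% list()),
    frailty = do.call(frailty_config, y$frailty %||% list()),
    write_audio = y$write_audio %||% FALSE,
    curve_points = y$curve_points %||% 50
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full simulate-extract-score-associate pipeline
#'
#' Executes all stages, writes `cohort.csv`, `features.csv`,
#' `assessments.csv`, `associations.csv`, `anova.csv`,
#' `descriptives.csv`, `curves.csv` and a `manifest.json` (config echo,
#' seed, package version, per-stage row counts, output checksums) under
#' `out_dir`. Identical config and seed give byte-identical CSV outputs.
#' On any stage failure a `FAILED` marker naming the stage is left in
#' `out_dir` and the error is re-raised.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory stage outputs and the
#'   manifest.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  result <- tryCatch({
    message("[simulate] n = ", config$cohort$n_participants,
            ", seed = ", config$cohort$seed)
    cohort <- simulate_cohort(config$cohort)
    write.csv(cohort$participants, file.path(out_dir, "cohort.csv"),
              row.names = FALSE)
    if (config$write_audio) write_cohort(cohort, file.path(out_dir, "sim"))

    stage <- "extract"
    message("[extract] ", length(cohort$recordings), " recordings")
    features <- extract_features_batch(cohort$recordings, config$acoustic)
    n_bad <- sum(nchar(features$reason) > 0)
    if (n_bad > 0) message("[extract] ", n_bad, " recording(s) with warnings")
    write.csv(features, file.path(out_dir, "features.csv"),
              row.names = FALSE)

    stage <- "score"
    assessments <- score_all(cohort$participants, config$frailty)
    message("[score] ", nrow(assessments), " assessments")
    write.csv(assessments, file.path(out_dir, "assessments.csv"),
              row.names = FALSE)

    stage <- "associate"
    associations <- stratified_associations(features, assessments)
    write.csv(associations, file.path(out_dir, "associations.csv"),
              row.names = FALSE)
    anova_tab <- anova_table(features, assessments)
    write.csv(anova_tab, file.path(out_dir, "anova.csv"), row.names = FALSE)
    descriptives <- descriptive_table(cohort$participants, assessments)
    write.csv(descriptives, file.path(out_dir, "descriptives.csv"),
              row.names = FALSE)
    curves <- probability_curves_for(associations, features,
                                     config$curve_points)
    write.csv(curves, file.path(out_dir, "curves.csv"), row.names = FALSE)
    message("[associate] ", nrow(associations), " association rows")

    list(cohort = cohort, features = features, assessments = assessments,
         associations = associations, anova = anova_tab,
         descriptives = descriptives, curves = curves)
  }, error = function(e) {
    writeLines(paste0("stage ", stage, ": ", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(e)
  })

  csvs <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(packageVersion("frailvoice")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$cohort$seed,
    n_participants = config$cohort$n_participants,
    effect_ors = as.list(config$cohort$effect_ors),
    row_counts = list(
      cohort = nrow(result$cohort$participants),
      features = nrow(result$features),
      assessments = nrow(result$assessments),
      associations = nrow(result$associations)
    ),
    checksums = as.list(tools::md5sum(csvs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(result, list(manifest = manifest)))
}

#' Probability curves for every converged all-participants model
#'
#' @param associations Output of [stratified_associations()].
#' @param features Feature table supplying each feature's observed range.
#' @param points Grid size per curve.
#' @return Long data.frame: `feature`, `index`, `feature_value`,
#'   `probability`.
#' @export
probability_curves_for <- function(associations, features, points = 50) {
  rows <- list()
  sub <- associations[associations$stratum == "all" & associations$converged, ]
  for (i in seq_len(nrow(sub))) {
    a <- sub[i, ]
    x <- features[[a$feature]]
    x <- x[is.finite(x)]
    grid <- seq(min(x), max(x), length.out = points)
    cv <- probability_curve(a, grid)
    rows[[i]] <- data.frame(feature = a$feature, index = a$index,
                            feature_value = cv$feature_value,
                            probability = cv$probability,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
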