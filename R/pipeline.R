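#' Stage-stratified sensitivity
#'
#' Sensitivity of the classifier among cancer cases of each stage, with
#' Clopper-Pearson intervals. Stages with no cases are reported as `NA`
#' (undefined), not 0.
#'
#' @param truth Logical vector, `TRUE` = lung cancer.
#' @param calls Logical classifier calls.
#' @param stage Stage label per observation (`NA` for non-cancer).
#' @param stages Stage levels to report.
#' @return A tibble: `stage`, `n_cases`, `detected`, `sensitivity`,
#'   `lower`, `upper`.
#' @export
stage_stratified_metrics <- function(truth, calls, stage,
                                     stages = c("I", "II", "III", "IV", "Unknown")) {
  stopifnot(length(truth) == length(calls), length(stage) == length(truth))
  rows <- lapply(stages, function(s) {
    idx <- which(truth & !is.na(stage) & stage == s)
    n <- length(idx)
    if (n == 0)
      return(tibble::tibble(stage = s, n_cases = 0L, detected = 0L,
                            sensitivity = NA_real_, lower = NA_real_,
                            upper = NA_real_))
    x <- sum(calls[idx])
    ci <- clopper_pearson(x, n)
    tibble::tibble(stage = s, n_cases = n, detected = as.integer(x),
                   sensitivity = ci$estimate, lower = ci$lower,
                   upper = ci$upper)
  })
  dplyr::bind_rows(rows)
}

## Five-operating-point metrics table for one labelled subset.
operating_point_metrics <- function(ensemble, features) {
  truth <- features$label == "LC"
  votes <- ensemble_votes(ensemble, features)
  rows <- lapply(names(ensemble$thresholds), function(op) {
    m <- classification_metrics(truth, votes >= ensemble$thresholds[[op]])
    m$operating_point <- op
    m
  })
  dplyr::bind_rows(rows)[, c("operating_point", "metric", "estimate",
                             "lower", "upper", "successes", "trials")]
}

#' Run the complete analysis pipeline
#'
#' Chains every stage on synthetic data: cohort generation, plate-read
#' simulation, per-plate standard curves and quantitation, cohort
#' statistics, the stratified Training/Selection/Test split, evolutionary
#' training, evaluation of all five operating points on the entire set and
#' the held-out Test set, stage-stratified Test sensitivity, Test-set
#' triplicate precision, sensor relative impact, and the screening-triage
#' projection. All randomness flows from `seed` via named child streams
#' (`cohort`, `plates`, `split`, `evolve`), so any stage can be reproduced
#' independently; identical seed and configuration give an identical
#' report.
#'
#' @param cohort A [cohort_config()].
#' @param signal A [signal_model()].
#' @param evolution An [evolution_config()].
#' @param triage A [triage_params()].
#' @param seed Integer root seed.
#' @param strata Stratification fields for [split_data()].
#' @param ensemble_size Ensemble committee size.
#' @param out_dir Optional directory; when given, intermediate tables
#'   (`donors.csv`, `reads.csv`, `features.csv`) and the report
#'   (`report.json`) are written there.
#' @return A `leap_report` list: `cohort`, `quantitation`, `stats`,
#'   `split_sizes`, `metrics` (per subset and operating point),
#'   `stage_sensitivity`, `precision_pct`, `impact`, `triage`, `provenance`.
#' @export
run_pipeline <- function(cohort = cohort_config(), signal = signal_model(),
                         evolution = evolution_config(),
                         triage = triage_params(), seed = 1,
                         strata = c("label", "site", "stage"),
                         ensemble_size = 95, out_dir = NULL) {
  donors <- generate_cohort(cohort, child_seed(seed, "cohort"))
  reads <- generate_plate_reads(donors, signal, child_seed(seed, "plates"))
  curves <- fit_standard_curves(reads, lloq = signal$lloq)
  features <- build_feature_matrix(reads, curves, donors, lloq = signal$lloq)
  fcols <- feature_columns(features)

  tests <- timepoint_tests(features)
  designated <- intersect(c("BM01_40", "BM10_40", "BM13_50", "BM14_50",
                            "BM17_20", "BM18_30", "BM19_20"), fcols)
  ht <- hotelling_t2(as.matrix(features[features$label == "LC", designated]),
                     as.matrix(features[features$label != "LC", designated]))
  stats_block <- list(
    mean_percent_difference = mean(tests$percent_difference, na.rm = TRUE),
    designated_features = designated,
    designated_percent_difference =
      mean(tests$percent_difference[tests$feature %in% designated]),
    fraction_p01 = fraction_significant(tests),
    hotelling = ht, tests = tests
  )

  split <- split_data(features, strata, child_seed(seed, "split"))
  trained <- train_leap(features, split, evolution, child_seed(seed, "evolve"),
                        ensemble_size = ensemble_size)
  ens <- trained$ensemble

  test_rows <- subset_features(features, split, "Test")
  metrics <- list(entire = operating_point_metrics(ens, features),
                  test = operating_point_metrics(ens, test_rows))

  test_truth <- test_rows$label == "LC"
  test_calls <- ensemble_predict(ens, test_rows, "ensemble")
  stage_sens <- stage_stratified_metrics(test_truth, test_calls,
                                         test_rows$stage)
  trip <- test_rows[test_rows$n_assays == 3, ]
  precision_pct <- if (nrow(trip) > 0)
    precision_from_replicates(trip$donor_id,
                              ensemble_predict(ens, trip, "ensemble"))
  else NA_real_

  impact <- relative_impact(ens, subset_features(features, split, "Selection"))
  triage_block <- list(ldct_only = simulate_ldct_only(triage),
                       leap_triage = simulate_leap_triage(triage))
  triage_block$fold_increase <- fold_increase(triage_block$ldct_only,
                                              triage_block$leap_triage)

  report <- list(
    cohort = list(n_donors = nrow(donors),
                  n_cancer = sum(donors$diagnosis == "lung cancer"),
                  n_assays = sum(donors$n_assays),
                  n_triplicate = sum(donors$n_assays == 3)),
    quantitation = list(n_plates = length(curves),
                        r_squared_min = min(vapply(curves, `[[`, numeric(1), "r_squared")),
                        n_features = length(fcols),
                        intra_assay_cv_pct = intra_assay_cv(features)),
    stats = stats_block,
    split_sizes = table(split$subset),
    metrics = metrics,
    stage_sensitivity = stage_sens,
    precision_pct = precision_pct,
    impact = impact,
    triage = triage_block,
    provenance = list(seed = seed,
                      config_hash = rlang::hash(list(cohort, signal, evolution,
                                                     triage, strata,
                                                     ensemble_size)),
                      package_version = as.character(utils::packageVersion("leap")))
  )
  class(report) <- "leap_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_donors_csv(donors, file.path(out_dir, "donors.csv"))
    write_reads_csv(reads, file.path(out_dir, "reads.csv"))
    readr::write_csv(features, file.path(out_dir, "features.csv"), na = "")
    save_ensemble(ens, file.path(out_dir, "model.json"))
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

## Flatten a report into JSON-friendly structures.
report_to_json <- function(report) {
  r <- unclass(report)
  r$split_sizes <- as.list(r$split_sizes)
  r$stats$hotelling <- unclass(r$stats$hotelling)
  r$triage$ldct_only <- unclass(r$triage$ldct_only)
  r$triage$leap_triage <- unclass(r$triage$leap_triage)
  r
}

#' @export
print.leap_report <- function(x, ...) {
  cat("LEAP pipeline report\n")
  cat(sprintf("  cohort: %d donors (%d lung cancer), %d assays\n",
              x$cohort$n_donors, x$cohort$n_cancer, x$cohort$n_assays))
  cat(sprintf("  features: %d; intra-assay CV %.1f%%\n",
              x$quantitation$n_features, x$quantitation$intra_assay_cv_pct))
  cat(sprintf("  mean percent decrease %.1f%% (designated sensors %.1f%%); %d%% of features p<=0.01\n",
              x$stats$mean_percent_difference,
              x$stats$designated_percent_difference,
              round(100 * x$stats$fraction_p01)))
  tm <- x$metrics$test
  for (op in unique(tm$operating_point)) {
    sens <- tm$estimate[tm$operating_point == op & tm$metric == "sensitivity"]
    spec <- tm$estimate[tm$operating_point == op & tm$metric == "specificity"]
    cat(sprintf("  Test %-9s sensitivity %3.0f%%  specificity %3.0f%%\n",
                op, 100 * sens, 100 * spec))
  }
  cat(sprintf("  Test triplicate precision: %.0f%%\n", x$precision_pct))
  cat(sprintf("  triage: %d vs %d detected (%d-fold)\n",
              x$triage$ldct_only$detected, x$triage$leap_triage$detected,
              x$triage$fold_increase))
  invisible(x)
}
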