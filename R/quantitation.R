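#' Fit a per-plate standard curve
#'
#' Ordinary least-squares regression of fluorescence on the nominal
#' concentration of the plate's standard dilution series. `r_squared` is
#' the squared Pearson correlation. Curves whose `r_squared` falls below
#' `qc_threshold` are flagged (`qc_pass = FALSE`) with a warning rather than
#' an error.
#'
#' @param reads Read tibble containing the `role == "standard"` wells of one
#'   plate (extra sample rows are ignored).
#' @param lloq Lower limit of quantitation carried on the curve, ng/ml.
#' @param qc_threshold Minimum acceptable `r_squared`.
#' @return A `standard_curve` list: `plate_id`, `slope`, `intercept`,
#'   `r_squared`, `lloq`, `qc_pass`.
#' @export
fit_standard_curve <- function(reads, lloq = 2.98, qc_threshold = 0.999) {
  std <- reads[reads$role == "standard", , drop = FALSE]
  if (nrow(std) == 0) stop("no standard wells to fit", call. = FALSE)
  plate <- unique(std$plate_id)
  if (length(plate) != 1)
    stop("fit_standard_curve expects standards from a single plate", call. = FALSE)
  conc <- standard_concentration(std$assay_id)
  if (length(unique(conc)) < 3)
    stop("standard curve needs >= 3 distinct concentration levels", call. = FALSE)
  if (var(conc) == 0) stop("zero concentration variance", call. = FALSE)
  fit <- lm(std$fluorescence ~ conc)
  r2 <- if (var(std$fluorescence) == 0) 0 else cor(conc, std$fluorescence)^2
  qc <- is.finite(r2) && r2 >= qc_threshold
  if (!qc)
    warning(sprintf("standard curve QC failure on plate %s (r^2 = %.6f)",
                    plate, r2), call. = FALSE)
  structure(list(plate_id = plate,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, lloq = lloq, qc_pass = qc),
            class = "standard_curve")
}

#' Fit standard curves for every plate of a read table
#'
#' @inheritParams fit_standard_curve
#' @return A named list of `standard_curve` objects, one per plate.
#' @export
fit_standard_curves <- function(reads, lloq = 2.98, qc_threshold = 0.999) {
  std <- reads[reads$role == "standard", , drop = FALSE]
  plates <- unique(std$plate_id)
  out <- lapply(plates, function(p)
    fit_standard_curve(std[std$plate_id == p, ], lloq, qc_threshold))
  stats::setNames(out, plates)
}

#' Convert fluorescence to concentration
#'
#' Inverts the standard curve: `(fluorescence - intercept) / slope`, floored
#' at 0. Non-decreasing in fluorescence.
#'
#' @param curve A `standard_curve`.
#' @param fluorescence Numeric RFU.
#' @return Concentration in ng/ml.
#' @export
fluor_to_conc <- function(curve, fluorescence) {
  if (!is.finite(curve$slope) || curve$slope <= 0)
    stop("invalid standard curve: slope must be positive", call. = FALSE)
  pmax((fluorescence - curve$intercept) / curve$slope, 0)
}

#' Censor concentrations below the lower limit of quantitation
#'
#' Values strictly below `lloq` are recorded as 0; a value exactly at the
#' limit is kept. Idempotent.
#'
#' @param conc Non-negative concentrations, ng/ml.
#' @param lloq Lower limit of quantitation, ng/ml (default 2.98).
#' @return Censored concentrations.
#' @examples
#' apply_lloq(c(2, 2.98, 50))
#' @export
apply_lloq <- function(conc, lloq = 2.98) {
  stopifnot(all(conc >= 0))
  ifelse(conc < lloq, 0, conc)
}

#' Build the sensor-by-timepoint feature matrix
#'
#' Converts sample-well fluorescence to concentration through each plate's
#' standard curve, averages duplicate wells of the same sensor within an
#' assay on the concentration scale, then censors below-LLOQ values to zero
#' (averaging before censoring avoids the asymmetric downward bias that
#' censor-then-average would introduce near the limit). One row per assay;
#' replicate assays of a donor are separate rows. Feature columns are named
#' `<sensor>_<time>` (e.g. `BM01_40`) and ordered sensor-major then time:
#' 18 sensors x 6 timepoints = 108 columns under the defaults.
#'
#' @param reads Read tibble (see [generate_plate_reads()] /
#'   [read_reads_csv()]).
#' @param curves Named list of per-plate curves from [fit_standard_curves()];
#'   fitted from `reads` when `NULL`.
#' @param donors Donor tibble supplying labels and stratification metadata.
#' @param lloq Lower limit of quantitation, ng/ml.
#' @return A tibble: `assay_id`, `donor_id`, `label` (`"LC"`/`"non-LC"`),
#'   `site`, `sex`, `age_band`, `smoking`, `stage`, `histology`, `n_assays`,
#'   then the feature columns. No missing values; all features >= 0.
#' @export
build_feature_matrix <- function(reads, curves = NULL, donors, lloq = 2.98) {
  smp <- reads[reads$role == "sample", , drop = FALSE]
  if (nrow(smp) == 0) stop("no sample reads", call. = FALSE)
  if (is.null(curves)) curves <- fit_standard_curves(reads, lloq = lloq)
  missing_plates <- setdiff(unique(smp$plate_id), names(curves))
  if (length(missing_plates) > 0)
    stop(sprintf("no fitted standard curve for plate(s): %s",
                 paste(missing_plates, collapse = ", ")), call. = FALSE)
  slope <- vapply(curves, `[[`, numeric(1), "slope")[smp$plate_id]
  intercept <- vapply(curves, `[[`, numeric(1), "intercept")[smp$plate_id]
  smp$conc <- pmax((smp$fluorescence - intercept) / slope, 0)

  agg <- dplyr::summarise(
    dplyr::group_by(smp, .data$assay_id, .data$donor_id, .data$sensor_id,
                    .data$time_min),
    conc = mean(.data$conc), .groups = "drop")
  agg$conc <- apply_lloq(agg$conc, lloq)
  agg$feature <- sprintf("%s_%d", agg$sensor_id, as.integer(agg$time_min))

  timepoints <- sort(unique(agg$time_min))
  feat_order <- as.vector(t(outer(sort(unique(agg$sensor_id)),
                                  as.integer(timepoints), paste, sep = "_")))
  ## Completeness: every assay must carry every sensor x timepoint.
  n_feat <- length(feat_order)
  cnt <- dplyr::count(agg, .data$assay_id)
  short <- cnt$assay_id[cnt$n < n_feat]
  if (length(short) > 0) {
    gaps <- vapply(utils::head(short, 3), function(a) {
      miss <- setdiff(feat_order, agg$feature[agg$assay_id == a])
      sprintf("%s missing %s", a, paste(utils::head(miss, 4), collapse = ", "))
    }, character(1))
    stop(sprintf("incomplete assays (%d): %s", length(short),
                 paste(gaps, collapse = "; ")), call. = FALSE)
  }

  wide <- tidyr::pivot_wider(agg[, c("assay_id", "donor_id", "feature", "conc")],
                             names_from = "feature", values_from = "conc")
  wide <- wide[, c("assay_id", "donor_id", feat_order)]
  meta <- donors[, c("donor_id", "site", "sex", "age_band", "smoking",
                     "diagnosis", "stage", "histology", "n_assays")]
  out <- dplyr::inner_join(wide, meta, by = "donor_id")
  out$label <- ifelse(out$diagnosis == "lung cancer", "LC", "non-LC")
  cols <- c("assay_id", "donor_id", "label", "site", "sex", "age_band",
            "smoking", "stage", "histology", "n_assays")
  dplyr::arrange(out[, c(cols, feat_order)], .data$assay_id)
}

#' Intra-assay coefficient of variation from replicate assays
#'
#' For each donor with replicate rows, computes the per-feature CV
#' (SD / mean, over features whose replicate mean is positive), averages
#' over features, then averages over donors. Reported in percent.
#'
#' With only 2--3 replicates the sample SD is a noticeably biased estimator
#' of the true SD (`E[s] = c4(n) * sigma`, `c4(3) = 0.886`), so by default
#' the SD is divided by `c4(n)` to make the reported CV unbiased for the
#' underlying assay CV; `correct = FALSE` gives the plain sample-SD
#' version.
#'
#' @param features Feature matrix from [build_feature_matrix()].
#' @param correct Apply the `c4` small-sample bias correction.
#' @return Mean intra-assay CV in percent.
#' @export
intra_assay_cv <- function(features, correct = TRUE) {
  fcols <- feature_columns(features)
  reps <- split(features[, fcols], features$donor_id)
  reps <- reps[vapply(reps, nrow, integer(1)) >= 2]
  if (length(reps) == 0)
    stop("no donors with >= 2 replicate assays", call. = FALSE)
  c4 <- function(n) sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)
  donor_cv <- vapply(reps, function(m) {
    mu <- colMeans(m)
    s <- apply(m, 2, sd)
    if (correct) s <- s / c4(nrow(m))
    keep <- mu > 0
    if (!any(keep)) return(NA_real_)
    mean(s[keep] / mu[keep])
  }, numeric(1))
  100 * mean(donor_cv, na.rm = TRUE)
}
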