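## Seven sensors carry the large planted decreases. Their defaults average
## 9.5% with range 7.7--12.3%; the remaining 11 sensors share a small
## decrease chosen so the panel-wide mean is 5.4%.
HIGH_SENSORS <- c("BM01", "BM10", "BM13", "BM14", "BM17", "BM18", "BM19")
HIGH_DELTAS <- c(0.077, 0.080, 0.086, 0.092, 0.098, 0.109, 0.123)

default_deltas <- function(mean_delta = 0.054) {
  low <- (mean_delta * 18 - sum(HIGH_DELTAS)) / 11
  d <- stats::setNames(rep(low, 18), LEAP_SENSORS)
  d[HIGH_SENSORS] <- HIGH_DELTAS
  d
}

#' Fluorescence signal model
#'
#' Parametrises the kinetics and noise of the biosensor assay. Released
#' peptide-TCPP concentration follows a saturating curve
#' `A * t / (t + K)` per sensor, scaled down in lung cancer by the planted
#' percent decrease `delta` (the cancer mean is `control / (1 + delta)`, so
#' the percent-difference statistic recovers `100 * delta` directly) and
#' multiplied by a donor-level lognormal effect shared across sensors, which
#' induces the correlated panel behaviour seen in real sera. Fluorescence is
#' linear in concentration through the plate-reader response (`slope`,
#' `intercept`) with multiplicative assay noise (`cv`) and additive read
#' noise.
#'
#' @param amplitude Named vector of per-sensor saturating amplitudes
#'   (ng/ml). Absolute ranges are free parameters of the simulator.
#' @param half_time Named vector of per-sensor half-times (minutes).
#' @param delta Named vector of per-sensor fractional activity decreases in
#'   cancer. The default plants a 9.5% average decrease (range 7.7--12.3%)
#'   on seven sensors and a panel-wide mean of 5.4%.
#' @param donor_sd SD of the shared donor random effect on the log scale.
#' @param cv Intra-assay coefficient of variation of sample wells.
#' @param slope,intercept Standard-curve response, RFU per ng/ml and RFU.
#' @param read_noise_sd Additive instrument noise SD, RFU.
#' @param lloq Lower limit of quantitation, ng/ml.
#' @param timepoints Read times in minutes, strictly increasing.
#' @return A `signal_model` list.
#' @export
signal_model <- function(amplitude = stats::setNames(seq(150, 600, length.out = 18), LEAP_SENSORS),
                         half_time = stats::setNames(seq(8, 35, length.out = 18), LEAP_SENSORS),
                         delta = default_deltas(),
                         donor_sd = 0.2,
                         cv = 0.06,
                         slope = 12.5,
                         intercept = 50,
                         read_noise_sd = 1,
                         lloq = 2.98,
                         timepoints = seq(10, 60, by = 10)) {
  stopifnot(all(amplitude > 0), all(half_time > 0),
            all(delta >= 0), all(delta < 1),
            donor_sd >= 0, cv >= 0, slope > 0, read_noise_sd >= 0, lloq > 0)
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("`timepoints` must be strictly increasing", call. = FALSE)
  for (v in c("amplitude", "half_time", "delta")) {
    x <- get(v)
    if (!setequal(names(x), LEAP_SENSORS))
      stop(sprintf("`%s` must be named by the 18 panel sensors", v), call. = FALSE)
  }
  structure(list(amplitude = amplitude[LEAP_SENSORS],
                 half_time = half_time[LEAP_SENSORS],
                 delta = delta[LEAP_SENSORS],
                 donor_sd = donor_sd, cv = cv, slope = slope,
                 intercept = intercept, read_noise_sd = read_noise_sd,
                 lloq = lloq, timepoints = timepoints),
            class = "signal_model")
}

#' Noise-free released-TCPP concentration
#'
#' The deterministic kinetic core of the simulator:
#' `A_s * t / (t + K_s) / (1 + delta_s * [cancer]) * exp(donor_effect)`.
#' Strictly increasing in time and saturating at
#' `A_s / (1 + delta_s * [cancer]) * exp(donor_effect)`.
#'
#' @param diagnosis Character vector; `"lung cancer"` activates the planted
#'   decrease.
#' @param sensor Sensor id(s), e.g. `"BM01"`.
#' @param time Time(s) in minutes, > 0.
#' @param model A [signal_model()].
#' @param donor_effect Donor-level log-scale random effect(s); default 0.
#' @return Concentration(s) in ng/ml.
#' @export
true_concentration <- function(diagnosis, sensor, time, model = signal_model(),
                               donor_effect = 0) {
  stopifnot(all(time > 0))
  if (!all(sensor %in% LEAP_SENSORS))
    stop("unknown sensor id", call. = FALSE)
  A <- model$amplitude[sensor]
  K <- model$half_time[sensor]
  d <- model$delta[sensor]
  cancer <- as.numeric(diagnosis == "lung cancer")
  unname(A * time / (time + K) / (1 + d * cancer) * exp(donor_effect))
}

## 384-well coordinates A1..P24, row-major (A1, A2, ..., A24, B1, ...).
well_name <- function(idx) {
  paste0(LETTERS[(idx - 1) %/% 24 + 1], (idx - 1) %% 24 + 1)
}

#' Simulate plate reads for a cohort
#'
#' Lays assays onto 384-well plates (18 sensor wells per assay, 21 assays
#' per plate) and simulates every fluorescence read:
#' `intercept + slope * conc * (1 + cv * z) + read noise`, floored at 0.
#' Each plate carries a six-point two-fold BM19 peptide-TCPP standard
#' dilution series (800, 400, 200, 100, 50, 25 ng/ml) in its last six
#' wells. Standard wells are purified dye-peptide dilutions, not enzymatic
#' assays, so they receive read noise only. Standards are read once, at the
#' final timepoint.
#'
#' @param donors Donor tibble from [generate_cohort()].
#' @param model A [signal_model()].
#' @param seed Integer seed.
#' @return A tibble of reads with columns `plate_id`, `well`, `role`
#'   (`sample`/`standard`), `assay_id`, `donor_id`, `sensor_id`, `time_min`,
#'   `fluorescence`. Sample reads number `sum(n_assays) * 18 * length(timepoints)`.
#' @examples
#' donors <- generate_cohort(cohort_config(n_donors = 4, cancer_count = 2,
#'                                         triplicate_count = 1), seed = 1)
#' reads <- generate_plate_reads(donors, seed = 2)
#' @export
generate_plate_reads <- function(donors, model = signal_model(), seed = 1) {
  if (nrow(donors) == 0) stop("empty donor list", call. = FALSE)
  with_seed(seed, {
    donors$donor_effect <- rnorm(nrow(donors), 0, model$donor_sd)
    assays <- donors[rep(seq_len(nrow(donors)), donors$n_assays),
                     c("donor_id", "diagnosis", "donor_effect")]
    assays$replicate <- unlist(lapply(donors$n_assays, seq_len))
    assays$assay_id <- sprintf("%s_r%d", assays$donor_id, assays$replicate)
    per_plate <- 21L  # 21 * 18 sensor wells + 6 standards = 384
    assays$plate_id <- sprintf("P%03d", (seq_len(nrow(assays)) - 1L) %/% per_plate + 1L)
    assays$slot <- (seq_len(nrow(assays)) - 1L) %% per_plate

    reads <- tidyr::crossing(assays, sensor_id = LEAP_SENSORS,
                             time_min = model$timepoints)
    reads <- dplyr::arrange(reads, .data$assay_id, .data$sensor_id, .data$time_min)
    sensor_pos <- match(reads$sensor_id, LEAP_SENSORS)
    reads$well <- well_name(reads$slot * 18L + sensor_pos)
    conc <- true_concentration(reads$diagnosis, reads$sensor_id, reads$time_min,
                               model, reads$donor_effect)
    fl <- model$intercept +
      model$slope * conc * (1 + model$cv * rnorm(nrow(reads))) +
      rnorm(nrow(reads), 0, model$read_noise_sd)
    reads$fluorescence <- pmax(fl, 0)
    reads$role <- "sample"

    std_conc <- c(800, 400, 200, 100, 50, 25)
    std <- tidyr::crossing(plate_id = unique(assays$plate_id), conc = std_conc)
    std <- dplyr::arrange(std, .data$plate_id, dplyr::desc(.data$conc))
    std$well <- well_name(378L + rep(seq_along(std_conc), length(unique(assays$plate_id))))
    std$fluorescence <- pmax(model$intercept + model$slope * std$conc +
                               rnorm(nrow(std), 0, model$read_noise_sd), 0)
    std_reads <- tibble::tibble(
      plate_id = std$plate_id, well = std$well, role = "standard",
      assay_id = sprintf("STD_%g", std$conc), donor_id = NA_character_,
      sensor_id = "STD", time_min = max(model$timepoints),
      fluorescence = std$fluorescence
    )
    out <- dplyr::bind_rows(
      reads[, c("plate_id", "well", "role", "assay_id", "donor_id",
                "sensor_id", "time_min", "fluorescence")],
      std_reads
    )
    dplyr::arrange(out, .data$plate_id, .data$role, .data$assay_id,
                   .data$sensor_id, .data$time_min)
  })
}

#' Nominal concentration of a standard well
#'
#' Standard wells encode their nominal concentration in the assay id
#' (`"STD_800"` etc.); this parses it back.
#'
#' @param assay_id Character vector of standard assay ids.
#' @return Numeric ng/ml.
#' @export
standard_concentration <- function(assay_id) {
  out <- suppressWarnings(as.numeric(sub("^STD_", "", assay_id)))
  if (anyNA(out)) stop("malformed standard assay_id", call. = FALSE)
  out
}
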