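#' Cohort design configuration
#'
#' Describes the donor cohort to simulate. The defaults reproduce the study
#' design: 450 donors at three clinical sites, 132 with pathologically
#' confirmed lung cancer, and a 150-donor subset assayed in triplicate with
#' the same site and diagnosis distribution as the full cohort. Default
#' probabilities are the exact cohort fractions (e.g. 84/450 for KUMC), so
#' quota sampling at the default size reproduces the demographic table
#' exactly.
#'
#' @param n_donors Total number of donors.
#' @param cancer_count Number of donors with lung cancer.
#' @param site_probs,sex_probs,age_band_probs,smoking_probs Named probability
#'   vectors over demographic categories (each sums to 1).
#' @param stage_probs,histology_probs Named probability vectors over cancer
#'   stage and histology; apply to cancer donors only.
#' @param triplicate_count Number of donors assayed three times (the rest are
#'   assayed once).
#' @return A `cohort_config` list.
#' @examples
#' cfg <- cohort_config()
#' cfg$n_donors
#' @export
cohort_config <- function(n_donors = 450,
                          cancer_count = 132,
                          site_probs = c(KUMC = 84, Marmara = 235, Vejle = 131) / 450,
                          sex_probs = c(Male = 282, Female = 168) / 450,
                          age_band_probs = c(`0-49` = 14, `50-59` = 170, `60-69` = 153,
                                             `70-79` = 97, `>=80` = 16) / 450,
                          smoking_probs = c(Current = 238, Former = 172, Never = 40) / 450,
                          stage_probs = c(I = 53, II = 23, III = 27, IV = 25, Unknown = 4) / 132,
                          histology_probs = c(Adenocarcinoma = 78, `Squamous Cell` = 41,
                                              Other = 6, `Small Cell` = 1, `Large Cell` = 1,
                                              `Large Cell Neuro` = 1, `Typical Carcinoid` = 2,
                                              `Poorly Differentiated` = 1, Unknown = 1) / 132,
                          triplicate_count = 150) {
  stopifnot(n_donors >= 1, cancer_count >= 0, triplicate_count >= 0)
  if (cancer_count > n_donors)
    stop("`cancer_count` cannot exceed `n_donors`", call. = FALSE)
  if (triplicate_count > n_donors)
    stop("`triplicate_count` cannot exceed `n_donors`", call. = FALSE)
  check_simplex(site_probs, "site_probs")
  check_simplex(sex_probs, "sex_probs")
  check_simplex(age_band_probs, "age_band_probs")
  check_simplex(smoking_probs, "smoking_probs")
  check_simplex(stage_probs, "stage_probs")
  check_simplex(histology_probs, "histology_probs")
  structure(list(n_donors = as.integer(n_donors),
                 cancer_count = as.integer(cancer_count),
                 site_probs = site_probs, sex_probs = sex_probs,
                 age_band_probs = age_band_probs, smoking_probs = smoking_probs,
                 stage_probs = stage_probs, histology_probs = histology_probs,
                 triplicate_count = as.integer(triplicate_count)),
            class = "cohort_config")
}

#' Generate a donor cohort
#'
#' Quota-samples donor demographics so that category counts hit their integer
#' targets exactly (largest-remainder rounding), rather than drawing each
#' donor independently: the generated cohort *is* the design, not a noisy
#' realisation of it. Stage and histology are assigned only to cancer
#' donors. The triplicate subset is drawn per site-by-diagnosis cell so its
#' site and cancer composition mirrors the full cohort.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the same seed reproduces the same cohort.
#' @return A tibble with one row per donor: `donor_id`, `site`, `sex`,
#'   `age_band`, `smoking`, `diagnosis` (`"lung cancer"` /
#'   `"non-lung cancer"`), `stage`, `histology` (both `NA` for non-cancer),
#'   and `n_assays` (1 or 3).
#' @examples
#' donors <- generate_cohort(cohort_config(), seed = 1)
#' table(donors$diagnosis)
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    n <- config$n_donors
    nc <- config$cancer_count
    donors <- tibble::tibble(
      donor_id = sprintf("D%04d", seq_len(n)),
      site = quota_labels(config$site_probs, n),
      sex = quota_labels(config$sex_probs, n),
      age_band = quota_labels(config$age_band_probs, n),
      smoking = quota_labels(config$smoking_probs, n),
      diagnosis = sample(rep(c("lung cancer", "non-lung cancer"), c(nc, n - nc))),
      stage = NA_character_,
      histology = NA_character_,
      n_assays = 1L
    )
    idx_cancer <- which(donors$diagnosis == "lung cancer")
    if (nc > 0) {
      donors$stage[idx_cancer] <- quota_labels(config$stage_probs, nc)
      donors$histology[idx_cancer] <- quota_labels(config$histology_probs, nc)
    }
    ## Triplicate subset mirrors the site x diagnosis distribution.
    if (config$triplicate_count > 0) {
      cell <- interaction(donors$site, donors$diagnosis, drop = TRUE)
      cell_n <- table(cell)
      quotas <- quota_counts(as.numeric(cell_n) / n, config$triplicate_count)
      names(quotas) <- names(cell_n)
      trip <- unlist(lapply(names(quotas), function(cl) {
        pool <- which(cell == cl)
        pool[sample.int(length(pool), min(quotas[[cl]], length(pool)))]
      }), use.names = FALSE)
      donors$n_assays[trip] <- 3L
    }
    donors
  })
}

#' Write or read a donor table
#'
#' @param donors Donor tibble from [generate_cohort()].
#' @param path File path of a `donors.csv`.
#' @return `read_donors_csv` returns the donor tibble.
#' @export
write_donors_csv <- function(donors, path) {
  readr::write_csv(donors, path, na = "")
  invisible(path)
}

#' @rdname write_donors_csv
#' @export
read_donors_csv <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    donor_id = "c", site = "c", sex = "c", age_band = "c", smoking = "c",
    diagnosis = "c", stage = "c", histology = "c", n_assays = "i"
  ), na = "")
  bad <- which(!out$diagnosis %in% c("lung cancer", "non-lung cancer"))
  if (length(bad) > 0)
    stop(sprintf("invalid diagnosis at line %d of %s", bad[1] + 1L, path),
         call. = FALSE)
  out
}
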