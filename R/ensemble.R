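#' Default operating-point thresholds
#'
#' Vote-fraction thresholds for the five operating points, strictly
#' decreasing from specificity-maximising to sensitivity-maximising.
#'
#' @return Named numeric vector.
#' @export
operating_points <- function() {
  c(spec_max = 0.7, spec_bias = 0.6, ensemble = 0.5,
    sens_bias = 0.4, sens_max = 0.3)
}

#' Build a voting ensemble from ranked programs
#'
#' Takes the top `size` programs of a [select_final()] ranking as a voting
#' committee. A feature row is called positive at an operating point when
#' the fraction of members voting positive reaches that point's threshold;
#' lower thresholds bias the committee towards sensitivity, higher ones
#' towards specificity.
#'
#' @param selection A `leap_selection` from [select_final()].
#' @param size Number of member programs.
#' @param dedupe Drop byte-identical duplicate programs (clones produced by
#'   survival copying) before taking the top `size`, so the committee
#'   members are distinct and their voting errors can decorrelate.
#' @param per_island Spread the committee across islands: members are the
#'   best-scoring distinct programs of each island in turn, so the
#'   committee mixes independently evolved lineages instead of clones of
#'   the single best one. Set `FALSE` to take the overall top `size`.
#' @param thresholds Named, strictly decreasing vote-fraction thresholds.
#' @param center,scale Optional feature standardisation (training-set means
#'   and SDs) applied before member execution.
#' @param feature_names Optional feature column names (required for
#'   [relative_impact()] and data-frame prediction).
#' @return A `leap_ensemble`.
#' @export
build_ensemble <- function(selection, size = 95, thresholds = operating_points(),
                           center = NULL, scale = NULL, feature_names = NULL,
                           dedupe = TRUE, per_island = TRUE) {
  stopifnot(inherits(selection, "leap_selection"), size >= 1)
  if (is.unsorted(rev(thresholds), strictly = TRUE))
    stop("`thresholds` must be strictly decreasing from spec_max to sens_max",
         call. = FALSE)
  keep <- if (dedupe) {
    !duplicated(vapply(selection$programs, rlang::hash, character(1)))
  } else rep(TRUE, length(selection$programs))
  programs <- selection$programs[keep]
  table <- selection$table[keep, ]
  size <- min(size, length(programs))
  pick <- if (per_island && !is.null(table$island) &&
              length(unique(table$island)) > 1) {
    ## Round-robin over islands in rank order within each island.
    by_island <- split(seq_len(nrow(table)), table$island)
    rr <- unlist(lapply(seq_len(max(lengths(by_island))), function(r)
      vapply(by_island[lengths(by_island) >= r], `[[`, integer(1), r)),
      use.names = FALSE)
    rr[seq_len(size)]
  } else seq_len(size)
  structure(list(members = programs[pick],
                 member_table = table[pick, ],
                 thresholds = thresholds,
                 center = center, scale = scale,
                 feature_names = feature_names),
            class = "leap_ensemble")
}

## Raw input -> standardized numeric matrix in the ensemble's feature space.
ensemble_matrix <- function(ensemble, newdata) {
  x <- if (is.data.frame(newdata)) {
    if (is.null(ensemble$feature_names))
      stop("ensemble has no stored feature names; pass a numeric matrix",
           call. = FALSE)
    as.matrix(newdata[, ensemble$feature_names])
  } else as.matrix(newdata)
  if (!is.null(ensemble$center))
    x <- sweep(sweep(x, 2, ensemble$center), 2, ensemble$scale, "/")
  x
}

#' Ensemble vote fractions and operating-point calls
#'
#' `ensemble_votes` returns, per row, the fraction of member programs voting
#' positive. `ensemble_predict` thresholds that fraction at the chosen
#' operating point. By construction, moving from `spec_max` to `sens_max`
#' can only add positives: sensitivity is non-decreasing and specificity
#' non-increasing along the ladder.
#'
#' @param ensemble A `leap_ensemble`.
#' @param newdata Feature tibble (with the ensemble's feature columns) or
#'   numeric matrix.
#' @param operating_point One of `names(operating_points())`.
#' @return `ensemble_votes`: numeric vote fractions in \[0, 1\];
#'   `ensemble_predict`: logical calls.
#' @export
ensemble_votes <- function(ensemble, newdata) {
  x <- ensemble_matrix(ensemble, newdata)
  votes <- vapply(ensemble$members,
                  function(p) as.numeric(execute(p, x) > 0),
                  numeric(nrow(x)))
  if (nrow(x) == 1) votes <- matrix(votes, nrow = 1)
  rowMeans(votes)
}

#' @rdname ensemble_votes
#' @export
ensemble_predict <- function(ensemble, newdata, operating_point = "ensemble") {
  if (!operating_point %in% names(ensemble$thresholds))
    stop(sprintf("unknown operating point '%s' (expected one of %s)",
                 operating_point,
                 paste(names(ensemble$thresholds), collapse = ", ")),
         call. = FALSE)
  ensemble_votes(ensemble, newdata) >= ensemble$thresholds[[operating_point]]
}

#' Relative impact of each biosensor
#'
#' Ranks sensors by combining how often the ensemble picked them with their
#' contribution to accuracy. For sensor *i*, `f_i` is the fraction of
#' members referencing any of its features, and `a_i` is the drop in
#' ensemble balanced accuracy (floored at 0) when the sensor's features are
#' replaced by their training means (ablation). Each term is normalised to
#' its panel average and the impact is `100 * (f_i/mean(f) + a_i/mean(a)) / 2`,
#' so 100% marks a sensor contributing exactly the panel average and the
#' panel mean impact is 100% by construction. Sensors are binned into
#' `>200%`, `100-200%` and `<100%` tiers. If no sensor's ablation moves the
#' accuracy, the ablation term is dropped with a warning.
#'
#' @param ensemble A `leap_ensemble` with stored feature names.
#' @param features Labelled evaluation rows (typically the Selection
#'   subset).
#' @param operating_point Operating point used for the ablation accuracy.
#' @return A tibble: `sensor`, `usage_fraction`, `ablation_drop`, `impact`,
#'   `tier`.
#' @export
relative_impact <- function(ensemble, features, operating_point = "ensemble") {
  if (is.null(ensemble$feature_names))
    stop("ensemble has no stored feature names", call. = FALSE)
  fnames <- ensemble$feature_names
  sensors <- unique(sub("_[0-9]+$", "", fnames))
  y <- features$label == "LC"
  x <- ensemble_matrix(ensemble, features)
  thr <- ensemble$thresholds[[operating_point]]
  balacc <- function(xm) {
    votes <- vapply(ensemble$members, function(p) as.numeric(execute(p, xm) > 0),
                    numeric(nrow(xm)))
    calls <- rowMeans(votes) >= thr
    (mean(calls[y]) + mean(!calls[!y])) / 2
  }
  base <- balacc(x)
  ## Ablation: in standardized space the training mean is 0; otherwise use
  ## the evaluation-column means.
  fill <- if (is.null(ensemble$center)) colMeans(x) else rep(0, ncol(x))
  usage <- vapply(sensors, function(s) {
    cols <- which(sub("_[0-9]+$", "", fnames) == s)
    mean(vapply(ensemble$members,
                function(p) any(program_features(p) %in% cols), logical(1)))
  }, numeric(1))
  drop <- vapply(sensors, function(s) {
    cols <- which(sub("_[0-9]+$", "", fnames) == s)
    xa <- x
    xa[, cols] <- rep(fill[cols], each = nrow(x))
    max(0, base - balacc(xa))
  }, numeric(1))

  terms <- list()
  if (mean(usage) > 0) terms$f <- usage / mean(usage)
  if (mean(drop) > 0) terms$a <- drop / mean(drop)
  else warning("no sensor ablation changes ensemble accuracy; impact uses selection frequency only",
               call. = FALSE)
  if (length(terms) == 0)
    impact <- rep(100, length(sensors))
  else
    impact <- 100 * Reduce(`+`, terms) / length(terms)
  tibble::tibble(sensor = sensors, usage_fraction = unname(usage),
                 ablation_drop = unname(drop), impact = unname(impact),
                 tier = cut(impact, c(-Inf, 100, 200, Inf),
                            labels = c("<100%", "100-200%", ">200%"),
                            right = FALSE))
}

#' Train the full classifier on a feature matrix
#'
#' High-level wrapper chaining the evolutionary stages: standardises the
#' feature columns on Training-set statistics, evolves a program pool on
#' the Training subset, ranks it on the Selection subset by accuracy and
#' reliability, and returns the top programs as a voting ensemble carrying
#' the standardisation and feature names.
#'
#' @param features Feature matrix from [build_feature_matrix()].
#' @param split Donor split from [split_data()].
#' @param config An [evolution_config()].
#' @param seed Integer seed.
#' @param ensemble_size Number of ensemble members.
#' @return A list: `ensemble` (`leap_ensemble`), `selection`
#'   (`leap_selection`), `history` (evolution trace).
#' @export
train_leap <- function(features, split, config = evolution_config(), seed = 1,
                       ensemble_size = 95) {
  fcols <- feature_columns(features)
  train <- subset_features(features, split, "Training")
  sel <- subset_features(features, split, "Selection")
  center <- colMeans(train[, fcols])
  scale <- vapply(train[, fcols], sd, numeric(1))
  scale[scale == 0] <- 1
  std <- function(df) sweep(sweep(as.matrix(df[, fcols]), 2, center), 2, scale, "/")
  x_train <- std(train); y_train <- train$label == "LC"
  x_sel <- std(sel); y_sel <- sel$label == "LC"
  pool <- evolve(x_train, y_train, config, seed)
  selection <- select_final(pool, x_train, y_train, x_sel, y_sel)
  ensemble <- build_ensemble(selection, size = ensemble_size,
                             center = center, scale = scale,
                             feature_names = fcols)
  list(ensemble = ensemble, selection = selection, history = pool$history)
}

#' Serialize / restore an ensemble as JSON
#'
#' Stores the palette version, member instruction lists and constant pools,
#' thresholds, and feature standardisation.
#'
#' @param ensemble A `leap_ensemble`.
#' @param path JSON file path.
#' @return `load_ensemble` returns the restored `leap_ensemble`.
#' @export
save_ensemble <- function(ensemble, path) {
  payload <- list(
    format = "leap_ensemble", palette_version = 1L,
    thresholds = as.list(ensemble$thresholds),
    center = ensemble$center, scale = ensemble$scale,
    feature_names = ensemble$feature_names,
    members = lapply(ensemble$members, program_to_list)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "leap_ensemble"))
    stop("not a serialized ensemble", call. = FALSE)
  members <- lapply(payload$members, program_from_list)
  unlist1 <- function(x) if (is.null(x)) NULL else unlist(x)
  thresholds <- unlist(payload$thresholds)
  structure(list(members = members, member_table = NULL,
                 thresholds = thresholds,
                 center = unlist1(payload$center),
                 scale = unlist1(payload$scale),
                 feature_names = unlist1(payload$feature_names)),
            class = "leap_ensemble")
}
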