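## A hand-built ensemble of constant-voting members: n_pos members always
## vote positive, the rest always negative, so every row's vote fraction is
## n_pos / n.
constant_ensemble <- function(n_pos, n_neg, feature_names = NULL) {
  mk <- function(sign) manual_program("add", list(list(type = "const", idx = 1),
                                                  list(type = "reg", idx = 2)),
                                      consts = c(sign, 0, 0, 0), n_features = 8)
  sel <- structure(list(programs = c(replicate(n_pos, mk(1), simplify = FALSE),
                                     replicate(n_neg, mk(-1), simplify = FALSE)),
                        table = tibble::tibble(rank = seq_len(n_pos + n_neg),
                                               island = 1L)),
                   class = "leap_selection")
  build_ensemble(sel, size = n_pos + n_neg, feature_names = feature_names,
                 dedupe = FALSE, per_island = FALSE)
}

test_that("vote fractions and the operating-point ladder behave as designed", {
  x <- matrix(rnorm(24), 3)
  unanimous <- constant_ensemble(10, 0)
  for (op in names(operating_points()))
    expect_true(all(ensemble_predict(unanimous, x, op)))
  ## v = 0.55: negative at spec_max/spec_bias, positive from ensemble down.
  e55 <- constant_ensemble(11, 9)
  expect_equal(ensemble_votes(e55, x), rep(0.55, 3))
  expect_false(any(ensemble_predict(e55, x, "spec_max")))
  expect_false(any(ensemble_predict(e55, x, "spec_bias")))
  expect_true(all(ensemble_predict(e55, x, "ensemble")))
  expect_true(all(ensemble_predict(e55, x, "sens_bias")))
  expect_true(all(ensemble_predict(e55, x, "sens_max")))
  expect_error(ensemble_predict(e55, x, "middle"), "unknown operating point")
  expect_error(build_ensemble(structure(list(programs = list(), table = NULL),
                                        class = "leap_selection"),
                              thresholds = c(a = 0.5, b = 0.5)),
               "decreasing")
})

test_that("sensitivity rises and specificity falls along the ladder", {
  set.seed(101)
  n <- 80
  y <- rep(c(TRUE, FALSE), n / 2)
  x <- matrix(rnorm(n * 6), n)
  x[, 2] <- x[, 2] + ifelse(y, 1, 0)
  cfg <- tiny_evolution_config()
  pool <- evolve(x, y, cfg, seed = 4)
  sel <- select_final(pool, x, y, x, y)
  ens <- build_ensemble(sel, size = 11)
  sens <- spec <- numeric(0)
  for (op in names(operating_points())) {
    calls <- ensemble_predict(ens, x, op)
    sens <- c(sens, mean(calls[y])); spec <- c(spec, mean(!calls[!y]))
  }
  expect_true(all(diff(sens) >= 0))
  expect_true(all(diff(spec) <= 0))
})

test_that("relative impact normalises to a 100% panel mean", {
  sensors <- leap_sensors()
  fnames <- paste0(sensors, "_10")
  ## Members each reference one sensor but vote by a large constant, so
  ## ablation changes nothing: impact falls back to selection frequency.
  mk <- function(j) {
    p <- manual_program("add", list(list(type = "feat", idx = j),
                                    list(type = "const", idx = 1)),
                        consts = c(1000, 0, 0, 0), n_features = 18)
    p
  }
  sel <- structure(list(programs = lapply(1:18, mk),
                        table = tibble::tibble(rank = 1:18, island = 1L)),
                   class = "leap_selection")
  ens <- build_ensemble(sel, size = 18, feature_names = fnames,
                        dedupe = FALSE, per_island = FALSE)
  feats <- tibble::as_tibble(matrix(rnorm(40 * 18), 40,
                                    dimnames = list(NULL, fnames)))
  feats$label <- rep(c("LC", "non-LC"), 20)
  expect_warning(imp <- relative_impact(ens, feats), "selection frequency")
  expect_equal(imp$impact, rep(100, 18))
  expect_equal(mean(imp$impact), 100, tolerance = 1e-9)
})

test_that("a planted single informative sensor dominates the impact ranking", {
  set.seed(111)
  sensors <- leap_sensors()
  fnames <- paste0(sensors, "_10")
  n <- 120
  y <- rep(c(TRUE, FALSE), n / 2)
  x <- matrix(rnorm(n * 18), n, dimnames = list(NULL, fnames))
  x[, "BM05_10"] <- x[, "BM05_10"] + ifelse(y, 3, 0)
  feats <- tibble::as_tibble(x)
  feats$label <- ifelse(y, "LC", "non-LC")
  cfg <- evolution_config(n_islands = 2, island_size = 30, warmup = 5,
                          migration_interval = 5, total_generations = 30,
                          min_len = 2, max_len = 10, n_registers = 4)
  pool <- evolve(x, y, cfg, seed = 6)
  sel <- select_final(pool, x, y, x, y)
  ens <- build_ensemble(sel, size = 15, feature_names = fnames)
  imp <- relative_impact(ens, feats)
  expect_equal(mean(imp$impact), 100, tolerance = 1e-9)
  expect_equal(imp$sensor[which.max(imp$impact)], "BM05")
  expect_gt(max(imp$impact), 200)
  expect_equal(as.character(imp$tier[which.max(imp$impact)]), ">200%")
})

test_that("ensembles serialize to JSON and back without changing predictions", {
  set.seed(121)
  x <- matrix(rnorm(40 * 6), 40)
  y <- rep(c(TRUE, FALSE), 20)
  pool <- evolve(x, y, tiny_evolution_config(), seed = 8)
  sel <- select_final(pool, x, y, x, y)
  ens <- build_ensemble(sel, size = 5,
                        center = rep(0, 6), scale = rep(1, 6),
                        feature_names = paste0("BM0", 1:6, "_10"))
  path <- tempfile(fileext = ".json")
  save_ensemble(ens, path)
  back <- load_ensemble(path)
  expect_equal(ensemble_votes(back, x), ensemble_votes(ens, x))
  expect_equal(back$thresholds, ens$thresholds)
  expect_equal(back$feature_names, ens$feature_names)
})
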