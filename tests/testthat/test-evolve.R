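test_that("the stratified split is exact thirds without donor leakage", {
  dat <- small_dataset(seed = 30, config = cohort_config())
  split <- suppressWarnings(split_data(dat$features, seed = 1))
  expect_equal(as.vector(table(split$subset)), c(150, 150, 150))
  ## Balanced for disease status: 132 cancer donors -> 44 per subset.
  merged <- dplyr::inner_join(dat$donors, split, by = "donor_id")
  cancer_per <- table(merged$subset[merged$diagnosis == "lung cancer"])
  expect_true(all(abs(cancer_per - 44) <= 2))
  ## Disjoint and exhaustive at donor level.
  expect_setequal(split$donor_id, dat$donors$donor_id)
  expect_equal(anyDuplicated(split$donor_id), 0L)
  ## Replicate assays of one donor always share a subset.
  feats_sub <- lapply(levels(split$subset), function(s)
    subset_features(dat$features, split, s))
  donor_sets <- lapply(feats_sub, function(f) unique(f$donor_id))
  expect_equal(length(Reduce(intersect, donor_sets)), 0L)
  expect_equal(sum(vapply(feats_sub, nrow, integer(1))), nrow(dat$features))
  ## Deterministic given the seed.
  expect_identical(split, suppressWarnings(split_data(dat$features, seed = 1)))
  expect_error(split_data(dat$features, strata = c("label", "nope")), "nope")
})

test_that("tournament generations conserve size and retain winners", {
  set.seed(41)
  cfg <- tiny_evolution_config()
  x <- matrix(rnorm(40 * 6), 40)
  y <- rep(c(TRUE, FALSE), 20)
  pop <- lapply(1:4, function(i) random_program(6, cfg))
  fit <- fitness_programs(pop, x, y)
  nxt <- tournament_generation(pop, fit, x, y, cfg)
  ## n_i = 4: exactly 2 pairs, 2 survivors, size back to 4.
  expect_equal(length(nxt$population), 4)
  expect_equal(length(nxt$fitness), 4)
  ## The fittest program wins its pair and is retained: max never drops.
  expect_gte(max(nxt$fitness), max(fit))
  ## A population of identical programs changes only by variation.
  pop2 <- rep(list(pop[[1]]), 4)
  fit2 <- fitness_programs(pop2, x, y)
  nxt2 <- tournament_generation(pop2, fit2, x, y, cfg)
  expect_identical(nxt2$population[[1]]$instr, pop[[1]]$instr)
  expect_equal(length(nxt2$population), 4)
})

test_that("migration moves each island's best to its ring neighbour", {
  cfg <- evolution_config(n_islands = 4, island_size = 100,
                          warmup = 10, migration_interval = 5,
                          migration_percent = 10, total_generations = 50)
  set.seed(51)
  mk <- function() {
    pop <- lapply(1:100, function(i) random_program(5, cfg))
    list(population = pop, fitness = runif(100))
  }
  islands <- lapply(1:4, function(i) mk())
  ## No-op before/off the migration schedule.
  expect_identical(migrate(islands, 10, cfg), islands)  # gen <= warmup
  expect_identical(migrate(islands, 13, cfg), islands)  # off the interval
  out <- migrate(islands, 15, cfg)
  sizes <- vapply(out, function(i) length(i$population), integer(1))
  expect_equal(sizes, rep(100L, 4))
  expect_equal(sum(sizes), 400L)
  for (i in 1:4) {
    src <- if (i == 1) 4 else i - 1
    ## Oracle: an independent ranking of the source island.
    top10 <- order(islands[[src]]$fitness, decreasing = TRUE)[1:10]
    incoming <- tail(out[[i]]$fitness, 10)
    expect_equal(incoming, islands[[src]]$fitness[top10])
    ## Migrants left their source (without replacement).
    expect_false(any(islands[[src]]$fitness[top10] %in%
                       out[[src]]$fitness[1:90]))
  }
})

test_that("evolution conserves population and best fitness is monotone", {
  set.seed(61)
  x <- matrix(rnorm(60 * 8), 60)
  x[, 3] <- x[, 3] + ifelse(rep(c(TRUE, FALSE), 30), 1.5, 0)
  y <- rep(c(TRUE, FALSE), 30)
  cfg <- evolution_config(n_islands = 4, island_size = 20, warmup = 10,
                          migration_interval = 5, total_generations = 100,
                          min_len = 2, max_len = 10, n_registers = 4)
  pool <- evolve(x, y, cfg, seed = 7)
  expect_equal(unique(pool$history$total_size), 80L)
  expect_true(all(diff(pool$history$best_fitness) >= 0))
  expect_equal(nrow(pool$history), 101)
  expect_equal(length(pool$programs), 80)
  ## Bit-exact reproducibility: identical pool fingerprint.
  pool2 <- evolve(x, y, cfg, seed = 7)
  fp <- function(p) rlang::hash(lapply(p$programs, leap:::program_to_list))
  expect_identical(fp(pool), fp(pool2))
  expect_identical(pool$history, pool2$history)
})

test_that("a linearly separable planted rule is learned quickly", {
  set.seed(71)
  n <- 120
  y <- rep(c(TRUE, FALSE), n / 2)
  x <- matrix(rnorm(n * 10), n)
  x[, 4] <- x[, 4] + ifelse(y, 3, 0)  # one feature shifted by 3 SD
  cfg <- evolution_config(n_islands = 4, island_size = 100, warmup = 20,
                          migration_interval = 10, total_generations = 60,
                          min_len = 2, max_len = 12, n_registers = 4)
  pool <- evolve(x, y, cfg, seed = 3)
  expect_gte(max(pool$fitness), 0.95)
})

test_that("zero-signal data yields chance-level selection accuracy", {
  set.seed(81)
  x <- matrix(rnorm(200 * 10), 200)
  y <- rep(c(TRUE, FALSE), 100)
  x_sel <- matrix(rnorm(200 * 10), 200)
  y_sel <- rep(c(TRUE, FALSE), 100)
  cfg <- evolution_config(n_islands = 2, island_size = 20, warmup = 5,
                          migration_interval = 5, total_generations = 20,
                          min_len = 2, max_len = 8, n_registers = 4)
  pool <- evolve(x, y, cfg, seed = 5)
  sel <- select_final(pool, x, y, x_sel, y_sel)
  ## Max over the pool of a chance-level statistic stays near 0.5.
  expect_lt(max(sel$table$acc_sel), 0.75)
})

test_that("selection ranks by accuracy times reliability", {
  set.seed(91)
  cfg <- evolution_config(n_islands = 2, island_size = 20, warmup = 2,
                          migration_interval = 2, total_generations = 4,
                          min_len = 2, max_len = 8, n_registers = 4)
  x <- matrix(rnorm(80 * 6), 80); y <- rep(c(TRUE, FALSE), 40)
  xs <- matrix(rnorm(80 * 6), 80); ys <- rep(c(TRUE, FALSE), 40)
  pool <- evolve(x, y, cfg, seed = 2)
  sel <- select_final(pool, x, y, xs, ys)
  ## Oracle: exhaustive per-program scoring.
  sc <- vapply(pool$programs, function(p) {
    at <- program_fitness(p, x, y); as_ <- program_fitness(p, xs, ys)
    as_ * (1 - abs(at - as_))
  }, numeric(1))
  expect_equal(sel$table$score, sort(sc, decreasing = TRUE), tolerance = 1e-12)
  expect_true(all(diff(sel$table$score) <= 0))
  ## Reliability penalises the overfit program at equal selection accuracy.
  t1 <- tibble::tibble(rank = 1:2, island = 1L,
                       acc_train = c(0.7, 1.0), acc_sel = c(0.7, 0.7))
  r <- 1 - abs(t1$acc_train - t1$acc_sel)
  expect_gt(t1$acc_sel[1] * r[1], t1$acc_sel[2] * r[2])
})
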