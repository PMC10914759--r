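#' Stratified Training / Selection / Test split
#'
#' Partitions *donors* (never individual assays, so replicate assays of a
#' donor can never straddle subsets) into three equal thirds, balanced over
#' the requested stratification fields. Within each stratum cell donors are
#' shuffled and allocated by balanced quota: every cell's counts differ by
#' at most 1 across subsets, and overall subset sizes differ by at most 1
#' (exact thirds when divisible). Cells smaller than 3 donors are noted with
#' a warning; their members are still allocated to the currently smallest
#' subsets (effectively round-robin).
#'
#' @param features Feature matrix from [build_feature_matrix()] (or any
#'   tibble with `donor_id` and the strata fields).
#' @param strata Character vector of metadata columns to balance on.
#' @param seed Integer seed.
#' @return A tibble `donor_id`, `subset` (factor Training/Selection/Test).
#' @export
split_data <- function(features, strata = c("label", "site", "stage"),
                       seed = 1) {
  missing_cols <- setdiff(c("donor_id", strata), names(features))
  if (length(missing_cols) > 0)
    stop(sprintf("missing strata fields: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  donors <- dplyr::distinct(features[, c("donor_id", strata)])
  cells <- donors[strata]
  cells[] <- lapply(cells, function(v) ifelse(is.na(v), "(none)", as.character(v)))
  cell <- interaction(cells, drop = TRUE, sep = "/")
  subsets <- c("Training", "Selection", "Test")
  with_seed(seed, {
    totals <- stats::setNames(rep(0L, 3), subsets)
    assignment <- character(nrow(donors))
    small <- 0L
    for (cl in levels(cell)) {
      idx <- which(cell == cl)
      idx <- idx[sample.int(length(idx))]  # not sample(): length-1 gotcha
      if (length(idx) < 3) small <- small + 1L
      base <- length(idx) %/% 3L
      labels <- rep(subsets, base)
      for (r in seq_len(length(idx) - 3L * base)) {
        pick <- sample(subsets[totals == min(totals)], 1)
        labels <- c(labels, pick)
        totals[pick] <- totals[pick] + 1L
      }
      totals <- totals + base
      assignment[idx] <- labels[sample.int(length(labels))]
    }
    if (small > 0)
      warning(sprintf("%d stratum cell(s) smaller than 3 donors were allocated round-robin",
                      small), call. = FALSE)
    tibble::tibble(donor_id = donors$donor_id,
                   subset = factor(assignment, levels = subsets))
  })
}

#' Rows of a feature matrix belonging to one subset
#'
#' @param features Feature matrix.
#' @param split Split tibble from [split_data()].
#' @param subset `"Training"`, `"Selection"` or `"Test"`.
#' @return The matching feature rows.
#' @export
subset_features <- function(features, split, subset) {
  ids <- split$donor_id[split$subset == subset]
  features[features$donor_id %in% ids, , drop = FALSE]
}

#' One tournament generation on a single island
#'
#' `n_i/2` random disjoint pairs are drawn; from each pair the fitter
#' program survives (ties broken by shorter program, then at random). Each
#' survivor then reproduces: with probability `crossover_prob` it recombines
#' with another survivor producing two offspring, otherwise it produces one
#' mutated copy; parents are retained, and reproduction continues until the
#' island is back to exactly `n_i` programs.
#'
#' @param population List of `lgp_program`s of even size.
#' @param fitness Cached fitness of `population`.
#' @param x,y Training features and logical labels (used to score new
#'   offspring).
#' @param config An [evolution_config()].
#' @param features_allowed Optional feature subset (the island's random
#'   subspace) passed to the variation operators.
#' @return A list `population`, `fitness` of the same size.
#' @export
tournament_generation <- function(population, fitness, x, y, config,
                                  features_allowed = NULL) {
  n <- length(population)
  stopifnot(n %% 2 == 0, length(fitness) == n)
  ord <- sample.int(n)
  a <- ord[seq(1, n, by = 2)]
  b <- ord[seq(2, n, by = 2)]
  fa <- fitness[a]; fb <- fitness[b]
  la <- vapply(population[a], function(p) nrow(p$instr), integer(1))
  lb <- vapply(population[b], function(p) nrow(p$instr), integer(1))
  pick_a <- fa > fb | (fa == fb & (la < lb | (la == lb & runif(length(a)) < 0.5)))
  winners <- ifelse(pick_a, a, b)
  surv <- population[winners]
  surv_fit <- fitness[winners]

  m <- n %/% 2L
  offspring <- vector("list", m)
  count <- 0L
  order_s <- sample.int(m)
  i <- 0L
  while (count < m) {
    i <- i + 1L
    parent <- surv[[order_s[(i - 1L) %% m + 1L]]]
    if (m - count >= 2L && m >= 2L && runif(1) < config$crossover_prob) {
      partner <- surv[[sample.int(m, 1)]]
      kids <- crossover_programs(parent, partner, config, features_allowed)
      offspring[[count + 1L]] <- kids[[1]]
      offspring[[count + 2L]] <- kids[[2]]
      count <- count + 2L
    } else {
      offspring[[count + 1L]] <- mutate_program(parent, config,
                                                features_allowed)
      count <- count + 1L
    }
  }
  off_fit <- fitness_programs(offspring, x, y, config$fitness == "balanced")
  list(population = c(surv, offspring), fitness = c(surv_fit, off_fit))
}

#' Toroidal migration between islands
#'
#' After `warmup` generations, every `migration_interval` generations the
#' top `migration_percent` of each island migrate (without replacement:
#' they leave their source) to the next island on the ring, unidirectional.
#' Because every island simultaneously emits and receives the same number
#' of migrants, all island sizes are preserved.
#'
#' @param islands List of islands, each a list `population`, `fitness`.
#' @param generation Current generation index (1-based).
#' @param config An [evolution_config()].
#' @return The islands after any migration due this generation.
#' @export
migrate <- function(islands, generation, config) {
  w <- config$warmup; g <- config$migration_interval
  if (generation <= w || (generation - w) %% g != 0) return(islands)
  S <- length(islands)
  m <- max(1L, as.integer(round(config$migration_percent / 100 *
                                  length(islands[[1]]$population))))
  top_idx <- lapply(islands, function(isl)
    order(isl$fitness, decreasing = TRUE)[seq_len(m)])
  out <- islands
  for (i in seq_len(S)) {
    src <- if (i == 1) S else i - 1L
    keep <- setdiff(seq_along(islands[[i]]$population), top_idx[[i]])
    out[[i]]$population <- c(islands[[i]]$population[keep],
                             islands[[src]]$population[top_idx[[src]]])
    out[[i]]$fitness <- c(islands[[i]]$fitness[keep],
                          islands[[src]]$fitness[top_idx[[src]]])
  }
  out
}

#' Evolve a pool of candidate programs
#'
#' Runs the island model: random initial populations, tournament selection
#' with mutation and recombination each generation, and periodic toroidal
#' migration, for `total_generations` generations. The global best training
#' fitness is non-decreasing (winners are retained and migrants merely
#' change island).
#'
#' @param x Training feature matrix (numeric).
#' @param y Logical labels.
#' @param config An [evolution_config()].
#' @param seed Integer seed; the full run is reproducible bit-exact.
#' @return A `leap_pool`: list with `programs`, `fitness` (training),
#'   `history` (per-generation tibble of global best fitness and population
#'   size), `config`, `n_features`, `seed`.
#' @export
evolve <- function(x, y, config = evolution_config(), seed = 1) {
  x <- as.matrix(x)
  stopifnot(is.logical(y), nrow(x) == length(y))
  balanced <- config$fitness == "balanced"
  ## Heterogeneous islands: length-bound profiles recycle over islands.
  island_cfg <- lapply(seq_len(config$n_islands), function(i) {
    k <- (i - 1L) %% length(config$min_len) + 1L
    cfg <- config
    cfg$min_len <- config$min_len[k]
    cfg$max_len <- config$max_len[k]
    cfg
  })
  with_seed(seed, {
    ## Random-subspace decorrelation: each island draws the feature subset
    ## its variation operators may reference.
    n_sub <- max(1L, ceiling(config$feature_subspace * ncol(x)))
    subspaces <- lapply(seq_len(config$n_islands), function(i) {
      if (n_sub >= ncol(x)) NULL else sort(sample.int(ncol(x), n_sub))
    })
    ## Island bagging: each island scores programs on its own bootstrap of
    ## the training rows (fixed for the whole run, so within-island fitness
    ## stays comparable and cached).
    bags <- lapply(seq_len(config$n_islands), function(i) {
      if (!config$bagging) return(seq_len(nrow(x)))
      repeat {
        idx <- sample.int(nrow(x), replace = TRUE)
        if (sum(y[idx]) >= 2 && sum(!y[idx]) >= 2) return(idx)
      }
    })
    islands <- lapply(seq_len(config$n_islands), function(i) {
      pop <- lapply(seq_len(config$island_size), function(j)
        random_program(ncol(x), island_cfg[[i]], subspaces[[i]]))
      list(population = pop,
           fitness = fitness_programs(pop, x[bags[[i]], , drop = FALSE],
                                      y[bags[[i]]], balanced))
    })
    history <- vector("list", config$total_generations + 1L)
    snap <- function(gen) tibble::tibble(
      generation = gen,
      best_fitness = max(vapply(islands, function(i) max(i$fitness), numeric(1))),
      total_size = sum(vapply(islands, function(i) length(i$population), integer(1))))
    history[[1]] <- snap(0L)
    for (gen in seq_len(config$total_generations)) {
      islands <- lapply(seq_along(islands), function(i)
        tournament_generation(islands[[i]]$population, islands[[i]]$fitness,
                              x[bags[[i]], , drop = FALSE], y[bags[[i]]],
                              island_cfg[[i]], subspaces[[i]]))
      islands <- migrate(islands, gen, config)
      history[[gen + 1L]] <- snap(gen)
    }
    structure(list(programs = unlist(lapply(islands, `[[`, "population"),
                                     recursive = FALSE),
                   fitness = unlist(lapply(islands, `[[`, "fitness")),
                   island = rep(seq_len(config$n_islands),
                                vapply(islands, function(i)
                                  length(i$population), integer(1))),
                   history = dplyr::bind_rows(history),
                   config = config, n_features = ncol(x), seed = seed),
              class = "leap_pool")
  })
}

#' Rank evolved programs by Selection-set accuracy and reliability
#'
#' Every program in the pool is scored on the held-out Selection subset:
#' accuracy is balanced accuracy `(sensitivity + specificity) / 2`;
#' reliability is `1 - |accuracy_train - accuracy_selection|`, penalising
#' programs whose training performance does not carry over; the combined
#' score is their product. Programs are ranked by descending score: the
#' top-ranked program is the single selected algorithm, and the top `k`
#' form the ensemble.
#'
#' @param pool A `leap_pool` from [evolve()].
#' @param x_train,y_train Training data (for the reliability term).
#' @param x_sel,y_sel Selection data.
#' @return A `leap_selection`: list with `table` (tibble: `rank`,
#'   `acc_train`, `acc_sel`, `reliability`, `score`) and `programs` ordered
#'   by rank.
#' @export
select_final <- function(pool, x_train, y_train, x_sel, y_sel) {
  balanced <- pool$config$fitness == "balanced"
  acc_train <- fitness_programs(pool$programs, x_train, y_train, balanced)
  acc_sel <- fitness_programs(pool$programs, x_sel, y_sel, balanced)
  reliability <- 1 - abs(acc_train - acc_sel)
  score <- acc_sel * reliability
  ord <- order(score, decreasing = TRUE)
  island <- if (is.null(pool$island)) rep(1L, length(score)) else pool$island
  structure(list(
    table = tibble::tibble(rank = seq_along(ord), island = island[ord],
                           acc_train = acc_train[ord], acc_sel = acc_sel[ord],
                           reliability = reliability[ord], score = score[ord]),
    programs = pool$programs[ord]),
    class = "leap_selection")
}
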