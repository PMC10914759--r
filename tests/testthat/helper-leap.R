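# Shared fixtures, built in code.

## A small cohort + plate reads + feature matrix, cheap enough for unit
## tests. 36 donors (12 cancer), 6 triplicates -> 48 assays.
small_cohort_config <- function(n_donors = 36, cancer_count = 12,
                                triplicate_count = 6) {
  cohort_config(n_donors = n_donors, cancer_count = cancer_count,
                triplicate_count = triplicate_count)
}

small_dataset <- function(seed = 42, model = signal_model(),
                          config = small_cohort_config()) {
  donors <- generate_cohort(config, seed = seed)
  reads <- generate_plate_reads(donors, model, seed = seed + 1)
  features <- build_feature_matrix(reads, NULL, donors, lloq = model$lloq)
  list(donors = donors, reads = reads, features = features, model = model)
}

## A tiny evolution configuration for structural tests.
tiny_evolution_config <- function(...) {
  evolution_config(n_islands = 2, island_size = 12, warmup = 2,
                   migration_interval = 2, total_generations = 6,
                   min_len = 2, max_len = 8, n_registers = 4, ...)
}

## Hand-assemble a one-instruction program: dst <- fn(operands).
## Each operand is list(type = "reg"|"feat"|"const", idx = i).
manual_program <- function(fn_name, operands, consts = numeric(0),
                           n_registers = 4, n_features = 8, dst = 1) {
  fn <- match(fn_name, palette_functions()$name)
  stopifnot(!is.na(fn))
  row <- c(fn, dst, rep(c(1L, 1L), 3))
  type_code <- c(reg = 1L, feat = 2L, const = 3L)
  for (slot in seq_along(operands)) {
    row[2 + 2 * slot - 1] <- type_code[[operands[[slot]]$type]]
    row[2 + 2 * slot] <- operands[[slot]]$idx
  }
  instr <- matrix(as.integer(row), nrow = 1)
  colnames(instr) <- c("fn", "dst", "t1", "i1", "t2", "i2", "t3", "i3")
  structure(list(instr = instr,
                 consts = if (length(consts)) consts else rep(0, 4),
                 n_registers = as.integer(n_registers),
                 n_features = as.integer(n_features)),
            class = "lgp_program")
}

balanced_accuracy <- function(truth, calls) {
  (mean(calls[truth]) + mean(!calls[!truth])) / 2
}
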