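## Operand type codes used in instruction matrices.
OPD_REG <- 1L
OPD_FEAT <- 2L
OPD_CONST <- 3L

#' Evolution configuration
#'
#' Parameters of the island-model evolutionary run. Defaults are
#' desk-scale: 16 islands of 124 programs for 250 generations, with a long
#' 240-generation warm-up before the top 5% migrate every 10 generations.
#' The long warm-up keeps the islands evolving as independent lineages for
#' most of the run; committee selection then draws members across islands
#' ([build_ensemble()]), which decorrelates their voting errors far better
#' than early mixing, where one lineage quickly takes over every island.
#' Offspring receive only a few edits on average (low per-instruction
#' mutation rate), which preserves hill-climbing on accumulated feature
#' contrasts.
#'
#' @param n_islands Number of islands `S` (>= 2).
#' @param island_size Programs per island `n_i` (even; tournament pairing).
#' @param warmup Generations `w` before migration starts.
#' @param migration_interval Generations `g` between migrations.
#' @param migration_percent Percent `p` of each island that migrates
#'   (0 < p < 50).
#' @param total_generations Total generations (default 250).
#' @param mutation_rate Per-instruction mutation probability for copied
#'   survivors.
#' @param crossover_prob Probability a survivor reproduces by recombination
#'   rather than mutated copy.
#' @param min_len,max_len Program length bounds (instructions). Vectors are
#'   recycled across islands, giving a heterogeneous portfolio (e.g. half
#'   the islands evolve short programs, half long ones); the cross-island
#'   committee then draws on whichever program class suits the data.
#' @param n_registers Memory registers per program; register 1 is the
#'   output.
#' @param n_constants Size of each program's constant pool.
#' @param operand_probs Sampling probabilities of operand kinds
#'   (register, feature, constant) when instructions are generated or
#'   mutated.
#' @param chain_bias Probability that a newly generated instruction is
#'   forced to be *effective*: it writes the output register and reads it
#'   as its first operand, extending the output computation chain rather
#'   than (likely) becoming an intron. Random register-machine code is
#'   dominated by structural introns; biasing generation towards effective
#'   instructions is the standard linear-GP remedy.
#' @param feature_subspace Fraction of the features each island may
#'   reference when instructions are generated or mutated (random-subspace
#'   decorrelation of the islands' lineages; 1 gives every island the full
#'   feature set).
#' @param bagging Evaluate each island's fitness on its own bootstrap
#'   resample of the training rows instead of the full training set.
#'   Programs on different islands then overfit different resamples, so
#'   their errors decorrelate and the cross-island committee generalises
#'   markedly better; the Selection-set ranking always uses the real data.
#' @param fitness `"balanced"` accuracy (default) or raw `"accuracy"`.
#' @return An `evolution_config` list.
#' @export
evolution_config <- function(n_islands = 16, island_size = 124, warmup = 240,
                             migration_interval = 10, migration_percent = 5,
                             total_generations = 250,
                             mutation_rate = 0.05, crossover_prob = 0.7,
                             min_len = c(16, 32), max_len = c(48, 80),
                             n_registers = 4, n_constants = 8,
                             operand_probs = c(register = 0.15, feature = 0.65,
                                               constant = 0.20),
                             chain_bias = 0.6,
                             feature_subspace = 1,
                             bagging = TRUE,
                             fitness = c("balanced", "accuracy")) {
  fitness <- match.arg(fitness)
  stopifnot(length(operand_probs) == 3, all(operand_probs >= 0),
            sum(operand_probs) > 0, chain_bias >= 0, chain_bias <= 1,
            feature_subspace > 0, feature_subspace <= 1)
  stopifnot(n_islands >= 2, island_size >= 2, island_size %% 2 == 0,
            warmup >= 0, migration_interval >= 1,
            migration_percent > 0, migration_percent < 50,
            total_generations >= 1, mutation_rate >= 0, mutation_rate <= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            length(min_len) == length(max_len),
            all(min_len >= 1), all(max_len >= min_len), n_registers >= 1,
            n_constants >= 1)
  structure(list(n_islands = as.integer(n_islands),
                 island_size = as.integer(island_size),
                 warmup = as.integer(warmup),
                 migration_interval = as.integer(migration_interval),
                 migration_percent = migration_percent,
                 total_generations = as.integer(total_generations),
                 mutation_rate = mutation_rate, crossover_prob = crossover_prob,
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 n_registers = as.integer(n_registers),
                 n_constants = as.integer(n_constants),
                 operand_probs = operand_probs / sum(operand_probs),
                 chain_bias = chain_bias,
                 feature_subspace = feature_subspace,
                 bagging = isTRUE(bagging),
                 fitness = fitness),
            class = "evolution_config")
}

## One random instruction row: c(fn, dst, t1, i1, t2, i2, t3, i3).
## Operands favour features so random programs engage the data; with
## probability `chain_bias` the instruction extends the output-register
## chain (dst = R1, first operand = R1) instead of likely being an intron.
random_instruction <- function(n_features, config, features_allowed = NULL) {
  if (is.null(features_allowed)) features_allowed <- seq_len(n_features)
  fn <- sample.int(48L, 1, prob = PALETTE$weight)
  arity <- PALETTE$arity[fn]
  chain <- runif(1) < config$chain_bias
  dst <- if (chain) 1L else sample.int(config$n_registers, 1)
  row <- c(fn, dst, rep(c(OPD_REG, 1L), 3))
  for (slot in seq_len(arity)) {
    if (chain && slot == 1L && arity >= 2L) next  # reads R1
    type <- sample(c(OPD_REG, OPD_FEAT, OPD_CONST), 1,
                   prob = config$operand_probs)
    idx <- switch(type,
                  sample.int(config$n_registers, 1),
                  features_allowed[sample.int(length(features_allowed), 1)],
                  sample.int(config$n_constants, 1))
    row[2 + 2 * slot - 1] <- type
    row[2 + 2 * slot] <- idx
  }
  row
}

#' Generate a random linear genetic program
#'
#' A program is an ordered list of register-machine instructions plus a
#' private constant pool. Length is uniform on `[min_len, max_len]`;
#' operands are drawn over registers, features and constants; constants are
#' uniform on \[-5, 5\]. All registers start at 0 and the classification
#' score is register 1 after the last instruction.
#'
#' @param n_features Number of input features the program may reference.
#' @param config An [evolution_config()].
#' @param features_allowed Optional integer subset of features instructions
#'   may reference (the island's random subspace); all features by default.
#' @return An `lgp_program`: list with `instr` (integer matrix), `consts`,
#'   `n_registers`, `n_features`.
#' @export
random_program <- function(n_features, config = evolution_config(),
                           features_allowed = NULL) {
  len <- sample(seq(config$min_len[1], config$max_len[1]), 1)
  instr <- t(vapply(seq_len(len),
                    function(i) random_instruction(n_features, config,
                                                   features_allowed),
                    integer(8)))
  new_program(instr, runif(config$n_constants, -5, 5), config$n_registers,
              n_features)
}

new_program <- function(instr, consts, n_registers, n_features) {
  colnames(instr) <- c("fn", "dst", "t1", "i1", "t2", "i2", "t3", "i3")
  structure(list(instr = instr, consts = consts,
                 n_registers = as.integer(n_registers),
                 n_features = as.integer(n_features)),
            class = "lgp_program")
}

#' Execute a program on feature rows
#'
#' Runs the register machine over each row: registers start at 0,
#' instructions execute in order with protected arithmetic, and the score is
#' the final value of register 1. Execution is a total function: any finite
#' input yields a finite score.
#'
#' @param program An `lgp_program`.
#' @param x A numeric feature vector or a matrix with rows as observations.
#' @return Numeric score(s), one per row.
#' @seealso [classify_program()]
#' @export
execute <- function(program, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != program$n_features)
    stop(sprintf("feature row has %d values; program expects %d",
                 ncol(x), program$n_features), call. = FALSE)
  cpp_execute_program(program$instr, program$consts, x, program$n_registers)
}

#' @rdname execute
#' @return `classify_program` returns logical calls (`score > 0` is
#'   positive).
#' @export
classify_program <- function(program, x) execute(program, x) > 0

#' Program fitness on a labelled dataset
#'
#' Classification fitness of `score > 0` against the labels: balanced
#' accuracy `(sensitivity + specificity) / 2` by default, or raw accuracy.
#'
#' @param program An `lgp_program` (or list of programs for
#'   `fitness_programs`).
#' @param x Feature matrix.
#' @param y Logical labels (`TRUE` = positive class).
#' @param balanced Use balanced accuracy.
#' @return Fitness in \[0, 1\].
#' @export
program_fitness <- function(program, x, y, balanced = TRUE) {
  fitness_programs(list(program), x, y, balanced)
}

#' @rdname program_fitness
#' @export
fitness_programs <- function(program, x, y, balanced = TRUE) {
  x <- as.matrix(x)
  stopifnot(is.logical(y), nrow(x) == length(y))
  if (!any(y) || all(y))
    stop("fitness needs both classes present", call. = FALSE)
  cpp_fitness_batch(lapply(program, `[[`, "instr"),
                    lapply(program, `[[`, "consts"),
                    x, as.integer(y), program[[1]]$n_registers, balanced)
}

## --- variation operators ---------------------------------------------------

## Point-mutate a copied survivor: each instruction is rewritten with
## probability `rate` (resampled function + operands, an operand tweak, or a
## destination tweak); with probability `rate` an instruction is inserted
## and/or deleted within the length bounds; each constant is perturbed with
## probability `rate`.
mutate_program <- function(program, config, features_allowed = NULL) {
  instr <- program$instr
  n_feat <- program$n_features
  if (is.null(features_allowed)) features_allowed <- seq_len(n_feat)
  rate <- config$mutation_rate
  for (k in seq_len(nrow(instr))) {
    if (runif(1) < rate) {
      kind <- sample.int(4L, 1)
      if (kind == 1L) {
        instr[k, ] <- random_instruction(n_feat, config, features_allowed)
      } else if (kind == 4L) {
        ## Swap the function for another of the same arity, operands kept:
        ## the smallest semantic step (e.g. add <-> sub).
        arity <- PALETTE$arity[instr[k, 1]]
        same <- which(PALETTE$arity == arity)
        instr[k, 1] <- sample(same, 1, prob = PALETTE$weight[same])
      } else if (kind == 2L) {
        arity <- PALETTE$arity[instr[k, 1]]
        slot <- sample.int(arity, 1)
        type <- sample(c(OPD_REG, OPD_FEAT, OPD_CONST), 1,
                       prob = config$operand_probs)
        idx <- switch(type,
                      sample.int(config$n_registers, 1),
                      features_allowed[sample.int(length(features_allowed), 1)],
                      sample.int(config$n_constants, 1))
        instr[k, 2 + 2 * slot - 1] <- type
        instr[k, 2 + 2 * slot] <- idx
      } else {
        instr[k, 2] <- sample.int(config$n_registers, 1)
      }
    }
  }
  if (runif(1) < rate && nrow(instr) < config$max_len[1]) {
    at <- sample.int(nrow(instr) + 1L, 1)  # insert before position `at`
    tail_rows <- if (at <= nrow(instr))
      instr[at:nrow(instr), , drop = FALSE]
    else instr[0, , drop = FALSE]
    instr <- rbind(instr[seq_len(at - 1), , drop = FALSE],
                   random_instruction(n_feat, config, features_allowed),
                   tail_rows)
  }
  if (runif(1) < rate && nrow(instr) > config$min_len[1]) {
    instr <- instr[-sample.int(nrow(instr), 1), , drop = FALSE]
  }
  consts <- program$consts
  hit <- runif(length(consts)) < rate
  consts[hit] <- consts[hit] + rnorm(sum(hit), 0, 0.1 + 0.1 * abs(consts[hit]))
  new_program(instr, consts, program$n_registers, n_feat)
}

## One-point tail crossover between two parents; offspring lengths are
## resampled until within bounds (falling back to mutated copies). Each
## offspring inherits the constant pool of its head parent.
crossover_programs <- function(p1, p2, config, features_allowed = NULL) {
  n1 <- nrow(p1$instr); n2 <- nrow(p2$instr)
  for (try in 1:10) {
    c1 <- sample.int(n1, 1)  # head length kept from parent 1
    c2 <- sample.int(n2, 1)
    l1 <- c1 + (n2 - c2)
    l2 <- c2 + (n1 - c1)
    if (l1 >= config$min_len[1] && l1 <= config$max_len[1] &&
        l2 >= config$min_len[1] && l2 <= config$max_len[1]) {
      i1 <- rbind(p1$instr[seq_len(c1), , drop = FALSE],
                  p2$instr[seq_len(n2) > c2, , drop = FALSE])
      i2 <- rbind(p2$instr[seq_len(c2), , drop = FALSE],
                  p1$instr[seq_len(n1) > c1, , drop = FALSE])
      return(list(new_program(i1, p1$consts, p1$n_registers, p1$n_features),
                  new_program(i2, p2$consts, p2$n_registers, p2$n_features)))
    }
  }
  list(mutate_program(p1, config, features_allowed),
       mutate_program(p2, config, features_allowed))
}

## Feature indices a program references (static scan of feature operands).
program_features <- function(program) {
  instr <- program$instr
  idx <- integer(0)
  for (slot in 1:3) {
    t_col <- instr[, 2 + 2 * slot - 1]
    keep <- t_col == OPD_FEAT & PALETTE$arity[instr[, 1]] >= slot
    idx <- c(idx, instr[keep, 2 + 2 * slot])
  }
  sort(unique(idx))
}

## --- serialization ---------------------------------------------------------

program_to_list <- function(program) {
  list(instr = unname(apply(program$instr, 1, as.integer, simplify = FALSE)),
       consts = program$consts,
       n_registers = program$n_registers,
       n_features = program$n_features)
}

program_from_list <- function(x) {
  instr <- do.call(rbind, lapply(x$instr, as.integer))
  new_program(instr, as.numeric(x$consts), x$n_registers, x$n_features)
}
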