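#' Breeding-program configuration
#'
#' Defaults reproduce the full-scale recurrent scheme: 50 initial parents
#' drawn from the founder panel, 30 biparental crosses, 10 F1 per cross, a
#' 200-plant F2 bulk per cross, 100 F4 individuals per cross by single-seed
#' descent (3000 candidates), selection of 50 new parents from the 3000 F4
#' plus the current 50 parents, over 5 cycles and 50 replicates.
#'
#' @param n_cycles selection cycles per replicate.
#' @param n_replicates independent replicates.
#' @param n_initial_parents parents drawn at cycle 0.
#' @param n_crosses biparental crosses per cycle.
#' @param n_f1_per_cross F1 individuals kept per cross.
#' @param n_f2_bulk F2 bulk size per cross.
#' @param n_f4_per_cross F4 individuals per cross entering selection.
#' @param strategy a [strategy_config()].
#' @param bayesr a [bayesr_config()] for marker-effect training.
#' @param retrain_each_cycle refit marker effects on the founder panel each
#'   cycle (default `FALSE`: one fit per replicate, reused across cycles).
#' @param seed master seed; replicate seeds are derived from it.
#' @return an object of class `program_config`.
#' @export
program_config <- function(n_cycles = 5, n_replicates = 50,
                           n_initial_parents = 50, n_crosses = 30,
                           n_f1_per_cross = 10, n_f2_bulk = 200,
                           n_f4_per_cross = 100,
                           strategy = strategy_config("GY_plus_OL"),
                           bayesr = bayesr_config(),
                           retrain_each_cycle = FALSE, seed = 1) {
  counts <- c(n_cycles, n_replicates, n_initial_parents, n_crosses,
              n_f1_per_cross, n_f2_bulk, n_f4_per_cross)
  if (any(counts < 1)) stop("all counts must be >= 1")
  stopifnot(inherits(strategy, "strategy_config"),
            inherits(bayesr, "bayesr_config"))
  structure(list(n_cycles = n_cycles, n_replicates = n_replicates,
                 n_initial_parents = n_initial_parents, n_crosses = n_crosses,
                 n_f1_per_cross = n_f1_per_cross, n_f2_bulk = n_f2_bulk,
                 n_f4_per_cross = n_f4_per_cross, strategy = strategy,
                 bayesr = bayesr, retrain_each_cycle = retrain_each_cycle,
                 seed = seed),
            class = "program_config")
}

# GEBV summary + inbreeding record for one parent set
cycle_record <- function(parents, effects, base_freqs, cycle, replicate,
                         strategy, n_candidates = NA_integer_) {
  g <- predict_gebv(dosages(parents), effects)
  Fcoef <- inbreeding_coefficient(compute_grm(dosages(parents), base_freqs))
  data.frame(replicate = replicate, cycle = cycle, strategy = strategy,
             mean_gebv_GY = mean(g[, "GY"]), sd_gebv_GY = sd(g[, "GY"]),
             mean_gebv_OL = mean(g[, "OL"]), sd_gebv_OL = sd(g[, "OL"]),
             F = Fcoef, n_candidates = n_candidates,
             selected_ids = I(list(parents$id)))
}

#' Run one breeding cycle
#'
#' Executes crossing under `plan`, advances the families to F4 by
#' single-seed descent, predicts GEBVs on the candidate pool (all F4 plus
#' the current parents), applies the selection strategy, and records the
#' GEBV means/SDs and inbreeding coefficient of the newly selected parents.
#'
#' @param parents `saf_pop` of the current crossing parents.
#' @param plan a `cross_plan` over those parents.
#' @param effects named list of `marker_effects` (`GY`, `OL`).
#' @param config a [program_config()].
#' @param base_freqs fixed base allele frequencies for the GRM (founder
#'   frequencies, so inbreeding is tracked relative to initial diversity).
#' @param cycle,replicate indices recorded in the output.
#' @param id_prefix prefix for generated progeny ids (must be unique per
#'   cycle).
#' @return list with `parents` (new `saf_pop`), `plan` (next cycle's
#'   `cross_plan`) and `record` (one-row data.frame).
#' @export
run_cycle <- function(parents, plan, effects, config, base_freqs,
                      cycle = 1, replicate = 1, id_prefix = "") {
  if (n_ind(parents) < 2) stop("at least two parents are required")
  f1 <- make_crosses(parents, plan$crosses, config$n_f1_per_cross,
                     generation = "F1", id_prefix = paste0(id_prefix, "F1_"))
  f4 <- advance_ssd(f1, n_f2_bulk = config$n_f2_bulk,
                    n_f4_per_cross = config$n_f4_per_cross,
                    id_prefix = paste0(id_prefix, "F4_"))
  candidates <- combine_pops(f4, parents)
  dos <- dosages(candidates)
  g <- predict_gebv(dos, effects)
  gebv_table <- data.frame(id = candidates$id, GY = g[, "GY"], OL = g[, "OL"])
  grm <- if (config$strategy$strategy == "GY_plus_OL_Rel")
    compute_grm(dos, base_freqs) else NULL
  sel <- select_parents(config$strategy, gebv_table, grm)
  new_parents <- candidates[sel$ids]
  # non-Rel strategies cross the selected parents at random next cycle;
  # the Rel plan comes from the GA
  rec <- cycle_record(new_parents, effects, base_freqs, cycle, replicate,
                      config$strategy$strategy, n_ind(candidates))
  list(parents = new_parents, plan = sel$plan, record = rec)
}

#' Run the recurrent breeding program
#'
#' Per replicate: draw the initial parents uniformly from the founder
#' panel, fit BayesR marker effects per trait on the full panel's
#' phenotypes, then run `n_cycles` cycles of crossing, single-seed descent,
#' GEBV prediction and selection. Cycle 0 records the initial parents
#' (baseline for gains); replicate seeds are derived deterministically from
#' the master seed.
#'
#' @param founders founder `saf_pop` (the training panel).
#' @param arch trait architecture from [simulate_trait_architecture()].
#' @param config a [program_config()].
#' @param phenotypes optional BLUE-like phenotype data.frame for the panel;
#'   simulated from `arch` (seeded from the master seed) when `NULL`.
#' @return an object of class `sim_result`: list with `records` (data.frame
#'   with one row per replicate x cycle, cycle 0 = initial parents),
#'   `config`, `strategy`, `replicate_seeds` and `phenotypes`.
#' @export
run_program <- function(founders, arch, config = program_config(),
                        phenotypes = NULL) {
  stopifnot(inherits(founders, "saf_pop"), inherits(config, "program_config"))
  if (n_ind(founders) < config$n_initial_parents)
    stop("founder pool is smaller than the number of initial parents")
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, config$n_replicates)
  if (is.null(phenotypes))
    phenotypes <- simulate_phenotypes(founders, arch,
                                      seed = sample.int(.Machine$integer.max - 1, 1))
  dos_founders <- dosages(founders)
  base_freqs <- colMeans(dos_founders) / 2
  records <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    set.seed(rep_seeds[r])
    effects <- fit_marker_effects(dos_founders, phenotypes, config$bayesr)
    init <- founders[sample.int(n_ind(founders), config$n_initial_parents)]
    plan <- random_cross_plan(init$id, config$n_crosses)
    recs <- list(cycle_record(init, effects, base_freqs, 0, r,
                              config$strategy$strategy))
    parents <- init
    for (cyc in seq_len(config$n_cycles)) {
      if (config$retrain_each_cycle && cyc > 1)
        effects <- fit_marker_effects(dos_founders, phenotypes, config$bayesr)
      step <- run_cycle(parents, plan, effects, config, base_freqs,
                        cycle = cyc, replicate = r,
                        id_prefix = sprintf("r%d_c%d_", r, cyc))
      parents <- step$parents
      plan <- step$plan
      recs[[cyc + 1]] <- step$record
    }
    records[[r]] <- do.call(rbind, recs)
  }
  structure(list(records = do.call(rbind, records), config = config,
                 strategy = config$strategy$strategy,
                 replicate_seeds = rep_seeds, phenotypes = phenotypes),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulation result:", x$strategy, "strategy,",
      max(x$records$replicate), "replicate(s) x",
      max(x$records$cycle), "cycle(s)\n")
  invisible(x)
}

#' Desk-scale preset
#'
#' A reduced problem size for fast, single-machine strategy comparison:
#' a 349 x 1000 founder panel with 200 QTL at the study heritabilities
#' (0.54, 0.80) and genetic correlation 0.19, 30 crosses x 20 F4
#' candidates, 10 replicates, a shortened BayesR chain and a reduced GA
#' budget. See the methods vignette for the rationale.
#'
#' @param strategy strategy name (see [strategy_config()]).
#' @param n_replicates replicates (default 10).
#' @param seed master seed.
#' @return a [program_config()].
#' @export
desk_program_config <- function(strategy = "GY_plus_OL", n_replicates = 10,
                                seed = 1) {
  program_config(
    n_cycles = 5, n_replicates = n_replicates,
    n_initial_parents = 50, n_crosses = 30, n_f1_per_cross = 10,
    n_f2_bulk = 200, n_f4_per_cross = 20,
    strategy = strategy_config(strategy,
                               ga = ga_config(pop_size = 80,
                                              n_generations = 120)),
    bayesr = bayesr_config(n_iter = 1500, burn_in = 500, thin = 5),
    seed = seed)
}

#' @rdname desk_program_config
#' @export
desk_founder_config <- function(seed = NULL) {
  founder_config(n_individuals = 349, n_markers = 1000, seed = seed)
}

#' Run the four-strategy comparison
#'
#' Runs [run_program()] once per strategy on a shared founder panel, trait
#' architecture and phenotype set, with a common master seed so replicates
#' are matched across strategies (common random numbers).
#'
#' @param founders,arch,phenotypes shared inputs (see [run_program()]).
#' @param config_fn function(strategy) returning the [program_config()] for
#'   that strategy (default: the desk-scale preset).
#' @param strategies strategy names to run.
#' @param seed master seed shared by all strategies.
#' @return named list of `sim_result`, one per strategy.
#' @export
run_strategy_comparison <- function(founders, arch, phenotypes = NULL,
                                    config_fn = NULL,
                                    strategies = c("GY", "OL", "GY_plus_OL",
                                                   "GY_plus_OL_Rel"),
                                    seed = 1) {
  if (is.null(config_fn))
    config_fn <- function(s) desk_program_config(s, seed = seed)
  if (is.null(phenotypes)) {
    set.seed(seed)
    phenotypes <- simulate_phenotypes(founders, arch)
  }
  out <- lapply(strategies, function(s) {
    cfg <- config_fn(s)
    cfg$seed <- seed
    run_program(founders, arch, cfg, phenotypes = phenotypes)
  })
  names(out) <- strategies
  out
}
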