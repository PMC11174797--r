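# shared fixtures, all generated in code

tiny_founders <- function(n = 40, m = 120, seed = 1, ...) {
  simulate_founders(founder_config(n_individuals = n, n_markers = m,
                                   seed = seed, ...))
}

# population built from explicit haplotypes (rows 2i-1/2i per individual)
pop_from_haplo <- function(haplo, n_chromosomes = 1, lengths = 1) {
  new_population(haplo, genetic_map(ncol(haplo), n_chromosomes, lengths))
}

# a single fully heterozygous individual: hap1 all 1, hap2 all 0
het_individual <- function(m = 120, n_chromosomes = 12) {
  pop_from_haplo(rbind(rep(1L, m), rep(0L, m)), n_chromosomes)
}

# binomial-dosage population without map structure, for sampler tests
random_dosages <- function(n, m, p = NULL) {
  if (is.null(p)) p <- runif(m, 0.1, 0.9)
  matrix(stats::rbinom(n * m, 2, rep(p, each = n)), n, m,
         dimnames = list(paste0("I", seq_len(n)), paste0("M", seq_len(m))))
}

short_chain <- function(seed = NULL, n_iter = 800, burn_in = 300, thin = 2) {
  bayesr_config(n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed)
}

# minimal sim_result for metric arithmetic tests
fake_sim_result <- function(F_by_cycle, mean_gy = NULL, sd0 = 1,
                            strategy = "GY_plus_OL") {
  k <- length(F_by_cycle)
  if (is.null(mean_gy)) mean_gy <- seq_len(k)
  rec <- data.frame(replicate = 1, cycle = seq_len(k) - 1,
                    strategy = strategy,
                    mean_gebv_GY = mean_gy, sd_gebv_GY = sd0,
                    mean_gebv_OL = rev(mean_gy), sd_gebv_OL = sd0,
                    F = F_by_cycle)
  structure(list(records = rec, strategy = strategy), class = "sim_result")
}

# the desk-scale four-strategy comparison, computed once per test run
.desk_env <- new.env(parent = emptyenv())
desk_comparison <- function() {
  if (is.null(.desk_env$res)) {
    pop <- simulate_founders(desk_founder_config(seed = 1))
    arch <- simulate_trait_architecture(pop, n_qtl = 200, seed = 2)
    phen <- simulate_phenotypes(pop, arch, seed = 3)
    .desk_env$res <- run_strategy_comparison(pop, arch, phen, seed = 4)
  }
  .desk_env$res
}
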