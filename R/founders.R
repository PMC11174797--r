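#' Founder-panel configuration
#'
#' Defaults emulate the diverse safflower panel the simulation is built
#' around: 349 accessions, 6911 SNPs retained after filtering at minor
#' allele frequency >= 0.01, with mild subpopulation structure.
#'
#' @param n_individuals number of founders (>= 2).
#' @param n_markers number of biallelic SNPs (>= 10).
#' @param n_subpops number of subpopulations (>= 1).
#' @param maf_min minimum realized minor allele frequency, in (0, 0.5).
#' @param fst_like_divergence Balding-Nichols divergence of subpopulation
#'   allele frequencies around the ancestral frequency, in \[0, 1).
#' @param n_chromosomes,chrom_length genetic-map layout passed to
#'   [genetic_map()] (safflower: 12 chromosomes, 1 Morgan each).
#' @param seed optional integer seed applied before simulation.
#' @return an object of class `founder_config`.
#' @export
founder_config <- function(n_individuals = 349, n_markers = 6911,
                           n_subpops = 3, maf_min = 0.01,
                           fst_like_divergence = 0.05,
                           n_chromosomes = 12, chrom_length = 1,
                           seed = NULL) {
  if (n_individuals < 2) stop("n_individuals must be >= 2")
  if (n_markers < 10) stop("n_markers must be >= 10")
  if (n_subpops < 1) stop("n_subpops must be >= 1")
  if (maf_min <= 0 || maf_min >= 0.5)
    stop("maf_min must lie strictly between 0 and 0.5")
  if (fst_like_divergence < 0 || fst_like_divergence >= 1)
    stop("fst_like_divergence must lie in [0, 1)")
  structure(list(n_individuals = n_individuals, n_markers = n_markers,
                 n_subpops = n_subpops, maf_min = maf_min,
                 fst_like_divergence = fst_like_divergence,
                 n_chromosomes = n_chromosomes, chrom_length = chrom_length,
                 seed = seed),
            class = "founder_config")
}

# Balding-Nichols subpopulation frequencies around ancestral p:
# p_k ~ Beta(p (1-F)/F, (1-p)(1-F)/F), so Var(p_k) = F p (1-p).
bn_subpop_freqs <- function(p, fst) {
  if (fst <= 0) return(p)
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  stats::rbeta(length(p), a, b)
}

#' Simulate a founder panel
#'
#' Haplotypes are sampled independently per marker from subpopulation allele
#' frequencies drawn around a common ancestral frequency (Balding-Nichols
#' model); individuals are split evenly across subpopulations. Markers whose
#' realized minor allele frequency falls below `maf_min` are dropped and
#' replaced until the whole panel passes the filter, emulating a
#' MAF-filtered SNP panel.
#'
#' @param config a [founder_config()].
#' @return a `saf_pop` of phased diploid founders. The latent ancestral and
#'   per-subpopulation allele frequencies of the emitted markers are attached
#'   as attributes `ancestral_freqs` (length m) and `subpop_freqs`
#'   (n_subpops x m), and subpopulation membership as `subpop`.
#' @export
simulate_founders <- function(config = founder_config()) {
  stopifnot(inherits(config, "founder_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_markers
  K <- config$n_subpops
  subpop <- rep_len(seq_len(K), n)
  n_per <- tabulate(subpop, K)

  draw_block <- function(mm) {
    # returns list(p0, pk (K x mm), hap (2n x mm))
    p0 <- runif(mm, 0.05, 0.95)
    pk <- matrix(0, K, mm)
    for (k in seq_len(K)) pk[k, ] <- bn_subpop_freqs(p0, config$fst_like_divergence)
    hap <- matrix(0L, 2L * n, mm)
    for (k in seq_len(K)) {
      rows <- which(rep(subpop, each = 2) == k)
      hap[rows, ] <- matrix(
        as.integer(runif(length(rows) * mm) < rep(pk[k, ], each = length(rows))),
        length(rows), mm)
    }
    list(p0 = p0, pk = pk, hap = hap)
  }

  p0 <- numeric(m); pk <- matrix(0, K, m); hap <- matrix(0L, 2L * n, m)
  todo <- seq_len(m)
  for (attempt in 1:200) {
    blk <- draw_block(length(todo))
    p0[todo] <- blk$p0
    pk[, todo] <- blk$pk
    hap[, todo] <- blk$hap
    freq <- colMeans(hap[, todo, drop = FALSE])
    maf <- pmin(freq, 1 - freq)
    todo <- todo[maf < config$maf_min]
    if (!length(todo)) break
  }
  if (length(todo))
    stop("could not satisfy the MAF filter; maf_min may be too close to 0.5 ",
         "for this sample size")

  map <- genetic_map(m, config$n_chromosomes, config$chrom_length)
  pop <- new_population(hap, map, id = paste0("G", seq_len(n)),
                        generation = "founder")
  attr(pop, "ancestral_freqs") <- p0
  attr(pop, "subpop_freqs") <- pk
  attr(pop, "subpop") <- subpop
  pop
}

#' Trait architecture for two correlated traits
#'
#' QTL are a random subset of the marker panel. Per-QTL additive effects are
#' built from a shared and a trait-specific standard-normal component, then
#' the trait-2 loading on trait 1 is solved numerically so the realized
#' correlation of true breeding values (TBVs) in `pop` hits `rg` exactly,
#' and both effect vectors are rescaled so each trait's TBV variance in
#' `pop` equals 1 (the genetic-variance unit).
#'
#' @param pop founder `saf_pop` (the reference population for variances and
#'   correlation).
#' @param n_qtl number of QTL (<= number of markers).
#' @param h2 per-trait narrow-sense heritability targets, length 2
#'   (defaults: 0.54 for grain yield, 0.80 for oil content).
#' @param rg target genetic correlation between the two traits' TBVs
#'   (default 0.19).
#' @param seed optional integer seed.
#' @return an object of class `trait_architecture`: list with `qtl_indices`,
#'   `effects` (n_qtl x 2), `h2`, `rg`, and the founder TBV matrix `tbv`.
#' @export
simulate_trait_architecture <- function(pop, n_qtl = 200,
                                        h2 = c(GY = 0.54, OL = 0.80),
                                        rg = 0.19, seed = NULL) {
  stopifnot(inherits(pop, "saf_pop"), length(h2) == 2)
  if (any(h2 <= 0) || any(h2 > 1)) stop("h2 must lie in (0, 1]")
  if (rg < -1 || rg > 1) stop("rg must lie in [-1, 1]")
  m <- n_markers_map(pop$map)
  if (n_qtl > m) stop("n_qtl exceeds the number of markers")
  if (!is.null(seed)) set.seed(seed)
  qtl <- sort(sample.int(m, n_qtl))
  X <- dosages(pop)[, qtl, drop = FALSE]
  a1 <- rnorm(n_qtl)
  g1 <- drop(X %*% a1)
  if (n_qtl == 1 || abs(rg) == 1) {
    # a single locus forces |correlation| = 1 whatever the target
    if (n_qtl == 1 && abs(rg) != 1) rg <- sign(rg + (rg == 0))
    a2 <- sign(rg) * a1
    g2 <- drop(X %*% a2)
  } else {
    b <- rnorm(n_qtl)
    gb <- drop(X %*% b)
    # g2 = lambda g1 + gb; solve lambda for cor(g1, g2) = rg
    s1 <- stats::var(g1); sb <- stats::var(gb); c1b <- stats::cov(g1, gb)
    f <- function(lam) {
      (lam * s1 + c1b) / sqrt(s1 * (lam^2 * s1 + 2 * lam * c1b + sb)) - rg
    }
    lo <- -1e3; hi <- 1e3
    lam <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root,
                    error = function(e) stop("could not hit the target genetic correlation"))
    a2 <- lam * a1 + b
    g2 <- drop(X %*% a2)
  }
  # rescale each trait's effects so founder TBV variance = 1
  sc1 <- 1 / sd(g1)
  sc2 <- 1 / sd(g2)
  effects <- cbind(a1 * sc1, a2 * sc2)
  colnames(effects) <- names2_traits(h2)
  tbv <- cbind(g1 * sc1, g2 * sc2)
  colnames(tbv) <- colnames(effects)
  rownames(tbv) <- pop$id
  structure(list(qtl_indices = qtl, effects = effects,
                 h2 = setNames(as.numeric(h2), colnames(effects)),
                 rg = rg, tbv = tbv),
            class = "trait_architecture")
}

names2_traits <- function(h2) {
  nm <- names(h2)
  if (is.null(nm) || any(nm == "")) nm <- c("GY", "OL")
  nm
}

#' True breeding values under a trait architecture
#'
#' @param pop a `saf_pop` on the architecture's marker set.
#' @param arch a [simulate_trait_architecture()] result.
#' @return n x 2 matrix of TBVs.
#' @export
true_breeding_values <- function(pop, arch) {
  X <- dosages(pop)[, arch$qtl_indices, drop = FALSE]
  tbv <- X %*% arch$effects
  rownames(tbv) <- pop$id
  tbv
}

#' Simulate BLUE-like phenotypes
#'
#' One phenotypic value per individual and trait: TBV plus independent
#' normal noise with variance chosen so the realized (sample) heritability
#' matches the architecture's `h2`, emulating a best linear unbiased
#' estimate from field trials rather than replicated plot records.
#'
#' @param pop a `saf_pop`.
#' @param arch a `trait_architecture`.
#' @param seed optional integer seed.
#' @return data.frame with columns `id` and one column per trait.
#' @export
simulate_phenotypes <- function(pop, arch, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tbv <- true_breeding_values(pop, arch)
  n <- nrow(tbv)
  phen <- tbv
  for (t in seq_len(ncol(tbv))) {
    h2 <- arch$h2[t]
    ve <- stats::var(tbv[, t]) * (1 - h2) / h2
    phen[, t] <- tbv[, t] + rnorm(n, 0, sqrt(ve))
  }
  out <- data.frame(id = pop$id, phen, row.names = NULL,
                    check.names = FALSE)
  out
}
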