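---
title: "Simulating recurrent genomic selection for yield and oil content in safflower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating recurrent genomic selection for yield and oil content in safflower}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The breeding program being simulated

safsim models a recurrent genomic-selection (GS) program for safflower
(*Carthamus tinctorius* L., n = 12 chromosomes) improving two correlated
traits at once: grain yield (GY, t/ha) and seed oil content (OL, %). A
breeding cycle is:

1. 50 crossing parents (cycle 0: drawn uniformly at random from a diverse
   founder panel of 349 accessions);
2. 30 biparental crosses among them, 10 F1 kept per cross;
3. a 200-plant F2 bulk per cross, advanced F2 → F3 → F4 by single-seed
   descent (SSD), yielding 100 F4 individuals per cross at full scale
   (3000 candidates);
4. GEBV prediction for the candidate pool — all F4 plus the current 50
   parents — using marker effects trained once on the founder panel;
5. selection of the next 50 parents by one of four strategies, and so on
   for five cycles. Everything is replicated (50 replicates at full scale)
   and averaged.

The four strategies are single-trait truncation on GY or OL GEBVs
(independent culling), an equal-weight index of the two standardized GEBVs,
and the same index combined with genetic-algorithm (GA) parent selection
and mate allocation that penalizes genomic co-ancestry.

Records are indexed so that cycle 0 is the initial random parent set and
cycle k is the k-th *selected* parent set. Full-scale reports of this kind
of program often label the initial set "cycle 1"; under that convention our
cycle-k record corresponds to their cycle k+1, and the gain we label `ck`
(the transition into cycle k) corresponds to their k-th per-cycle gain row.

## Founder panel and trait architecture

Real founder data for such a panel are genotypes at ~7000 MAF-filtered GBS
SNPs plus one best linear unbiased estimate (BLUE) per trait and accession.
The synthetic founder module emulates that endpoint rather than the
pipeline that produced it:

* **Genotypes.** Each marker has an ancestral frequency
  `p0 ~ U(0.05, 0.95)`; subpopulation frequencies follow the
  Balding–Nichols model `p_k ~ Beta(p0(1-F)/F, (1-p0)(1-F)/F)` with
  divergence `F = fst_like_divergence`, so `Var(p_k) = F p0 (1-p0)` — the
  closed form the generator's tests check. Individuals are split evenly
  across `n_subpops = 3` subpopulations (defaults `F = 0.05`: the mild
  "few subgroups" structure a GRM heatmap of a genebank panel shows).
  Haplotypes are sampled independently per marker; markers whose realized
  minor allele frequency falls below `maf_min = 0.01` are redrawn, so the
  panel arrives pre-filtered like the real one. This model deliberately
  carries **no linkage disequilibrium** between founder markers: the
  downstream analyses depend on relationship structure and trait
  architecture, which it provides; LD realism is out of scope, so absolute
  prediction accuracies will differ from panels with long-range LD.
* **Traits.** `n_qtl = 200` QTL are a random subset of the markers (the
  number of causal loci is a free synthetic parameter; 200 gives a
  polygenic-but-trackable architecture for a 1000-marker desk panel).
  Trait-1 effects are standard normal; trait-2 effects are a linear
  combination `a2 = λ a1 + b` with λ solved numerically so the realized TBV
  correlation in the founder panel equals the target `rg = 0.19` exactly;
  both effect vectors are then rescaled so each trait's founder TBV
  variance is 1. A single-QTL architecture forces |correlation| = 1 and is
  handled as that special case.
* **Phenotypes.** One value per accession and trait — a BLUE surrogate, not
  replicated plots: `y = TBV + N(0, σ²e)` with σ²e set from the realized
  TBV variance so the sample heritability matches the targets 0.54 (GY)
  and 0.80 (OL).

## Meiosis, crossing, SSD

Gametes are simulated per chromosome with a crossover count drawn from
Poisson(length in Morgans), uniform crossover positions, no interference
and a fair coin for the starting haplotype. The default map is 12
chromosomes of 1 Morgan with evenly spaced markers — the species'
chromosome number; the map itself is a modeling choice, not an estimate.
The F2 bulk is produced by selfing the 10 kept F1s round-robin (20 F2
each at full scale); SSD lineage founders are sampled from the bulk
without replacement, and each lineage selfs twice more with a single seed
kept per generation. Three selfing generations separate F1 from F4, so
expected F4 heterozygosity is 0.5³ = 12.5% of the F1's — the brute-force
recursion the tests assert.

## Marker effects and GEBVs

Marker effects are estimated per trait with BayesR: a Gibbs sampler over a
four-component normal mixture for each marker effect with variances
(0, 1e-4, 1e-3, 1e-2) × σ²g. The mixture variances are interpreted as
*fractions of the current genetic-variance parameter*, rescaled every
iteration (the usual BayesR convention; the absolute-variance reading is
the other option, and the fractions make the sampler scale-free because
phenotypes are standardized internally anyway). Variance components use
weakly informative scaled-inverse-chi-square priors centred on half the
phenotypic variance (df 4); mixture proportions get a Dirichlet(1,1,1,1)
update. Defaults are 10 000 iterations, 2 000 burn-in, thinning 10; the
desk-scale preset shortens this to 1 500/500/5, which parameter-recovery
tests show is enough at n ≈ 350 training records.

GEBVs are the plain product `X'β` of candidate dosages with posterior-mean
effects — no intercept, since only differences between parent sets matter.
Marker effects are trained **once per replicate** on the founder panel and
reused across all cycles (`retrain_each_cycle` switches this), mirroring a
two-step program where the diversity panel is the permanent training set.

One identifiability caveat documented here because the tests rely on it:
with no genetic signal the non-null components' variances shrink toward
zero and become likelihood-equivalent to the null component, so per-marker
*class labels* are arbitrary under pure noise; what is identifiable — and
what the tests assert — is the absence of sizable effects and of phantom
genetic variance. A GBLUP REML utility (eigendecomposition plus a
one-dimensional profile-likelihood search) provides the independent
heritability check.

## Kinship and inbreeding

The genomic relationship matrix is VanRaden method 1,
`G = ZZ'/(2Σp(1-p))` with `Z = M - 2p`, markers monomorphic under the base
frequencies excluded. Base allele frequencies are **fixed at the founder
panel frequencies for all cycles**: inbreeding is tracked relative to the
initial diversity, which is what makes F rise as selection fixes alleles
(re-estimating frequencies each cycle would recentre F toward zero each
time); `base_freqs = "from-data"` remains available. F is the mean GRM
diagonal minus 1, and ΔF is its difference between consecutive cycles.
Because F4 candidates carry three generations of selfing, F jumps steeply
at the first selected parent set and grows slowly afterwards; F can exceed
1 late in the program when alleles rare in the founders reach fixation.

## Selection strategies and mate allocation

Truncation takes the top n by GEBV with ties broken by input order (a
documented, deterministic rule). The index is
`w1·z(GEBV_GY) + w2·z(GEBV_OL)` with equal weights by default,
standardized over the current candidate pool. For the
relationship-controlled strategy the pairwise fitness is
`(index_i + index_j)/2 − λ·G(i,j)` with λ = 0.5 — the mid-parent index
penalized by the mated pair's co-ancestry, taken as the off-diagonal GRM
entry itself (λ absorbs any scale constant). The GA encodes a plan as a
fixed-length list of 30 parent pairs; tournament selection (k = 3),
one-point crossover at pair boundaries (rate 0.8), per-pair mutation
(0.02), elitism 2, plus a repair operator that removes self-pairs and
duplicate pairs, enforces a per-parent usage cap of 2, and pushes the
distinct-parent count to the target. Two genuinely open choices were
settled as follows:

* **Exactly 50 distinct parents.** A 30-cross plan with usage cap 2 can
  span anywhere from 30 to 60 distinct parents; requiring "the set of 50
  parents" exactly (`exact_parents = TRUE`, configurable) matches how such
  programs describe their GA and spreads contributions, which is the point
  of relationship control. Without it the GA concentrates on ~30 elite
  (often related) parents and the strategy loses its inbreeding advantage.
* **Greedy seeding.** The initial GA population contains one greedily
  constructed plan, so the search starts from a strong incumbent; on
  6-candidate instances the GA then attains the exhaustively enumerated
  optimum in well over 90% of seeds with a small budget (population 40,
  40 generations).

For the non-controlled strategies the next cycle's plan is 30 distinct
random pairs among the 50 selected parents ("random crossing"), and the
cycle-0 plan is random for every strategy.

## Gains, reporting, and numerical conventions

Genetic gain between consecutive parent sets is
`ΔG = (mean_j − mean_i)/σ_cycle1`, where σ_cycle1 is the GEBV standard
deviation among that replicate's *initial* parents, held fixed so gains are
comparable across cycles and traits. Gains are averaged over replicates
*after* standardization (averaging gains, not means), which keeps the
per-replicate σ-normalization meaningful. The gain table lists transitions
`c1..cK` plus a `Sum` row that equals the column sums to float tolerance.
The reciprocal-recurrent expectation for a trait — the benchmark for
whether index selection beats crossing two independent-culling streams —
is the arithmetic mean of the two single-trait programs' cumulative gains
for that trait. `reference_gains()` ships the full-scale per-cycle gain
values for the four strategies so the aggregation and this comparison
arithmetic can be validated exactly.

Other numerical conventions: seeded runs are bit-reproducible (replicate
seeds are derived from the master seed; the C++ kernels draw from R's RNG);
degenerate inputs error early (zero-SD GEBVs for the index, monomorphic
GRMs, infeasible GA constraints); the GBLUP REML adds a logged 1e-6 ridge
when the GRM is numerically singular.

## Desk-scale preset and what the tests do (and do not) show

The package's strategy-comparison tests and the acceptance script run a
desk-scale preset chosen to finish in minutes on one core while keeping
the program's structure intact: 349 founders × 1000 markers, 200 QTL,
h² = 0.54/0.80, rG = 0.19, 30 crosses × 20 F4 (650 candidates per cycle),
10 replicates, BayesR chain 1500/500/5, GA budget 80 × 120. Replicates are
matched across strategies (common random numbers), which sharpens paired
strategy contrasts at small replicate counts.

At this scale the simulation reproduces the qualitative findings of the
full-scale program: positive gains for targeted traits in all strategies
with the largest gain in the first cycle; each single-trait strategy
winning its own trait and barely moving the other (rG = 0.19 gives only a
small favorable correlated response); index selection beating the
reciprocal-recurrent expectation for both traits; a sharp first-cycle rise
in F with the mate-allocation strategy entering selection with lower F
than the unconstrained index. It does **not** reproduce the full-scale
magnitudes: with no founder LD, a 1000-marker panel and 650-candidate
pools, per-cycle gains are larger and noisier than with 6911 SNPs and 3050
candidates, so numbers should be compared as orderings and trends, not
values. Selection intensity, candidate-pool composition and the fixed
training set are faithful to the full design.

## Known limitations

* No mutation, no crossover interference, no sex-specific maps.
* Founders carry no LD; prediction accuracy is driven by relationship
  capture and the QTL-on-marker architecture.
* Traits are strictly additive; BayesR is single-trait (the two traits are
  fitted independently, as in the two-step design).
* The GA explores a repair-constrained neighborhood; it is validated
  against exhaustive enumeration only on small instances, and against
  random-plan baselines at scale.
* Economic weights other than equal are configuration-only; no
  cost/budget modeling.
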