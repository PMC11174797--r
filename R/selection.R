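#' Truncation selection
#'
#' Returns the ids of the `n` candidates with the largest values; ties are
#' broken by input order (stable, documented for determinism).
#'
#' @param gebvs numeric vector of GEBVs (or index values).
#' @param candidate_ids ids aligned with `gebvs`.
#' @param n number of individuals to select.
#' @return character vector of selected ids, in decreasing value order.
#' @export
select_truncation <- function(gebvs, candidate_ids = names(gebvs), n) {
  if (is.null(candidate_ids)) candidate_ids <- as.character(seq_along(gebvs))
  stopifnot(length(gebvs) == length(candidate_ids))
  if (n > length(gebvs)) stop("cannot select more individuals than candidates")
  ord <- order(-gebvs, seq_along(gebvs))
  candidate_ids[ord[seq_len(n)]]
}

#' Equal-weight standardized selection index
#'
#' index = w1 z(gebv_gy) + w2 z(gebv_ol), where z standardizes to mean 0 and
#' SD 1 over the current candidate set.
#'
#' @param gebv_gy,gebv_ol per-candidate GEBVs for the two traits.
#' @param weights index weights (default equal).
#' @return numeric index vector.
#' @export
build_index <- function(gebv_gy, gebv_ol, weights = c(1, 1)) {
  stopifnot(length(gebv_gy) == length(gebv_ol), length(weights) == 2)
  s1 <- sd(gebv_gy); s2 <- sd(gebv_ol)
  if (s1 == 0 || s2 == 0)
    stop("degenerate candidate set: zero GEBV standard deviation")
  weights[1] * (gebv_gy - mean(gebv_gy)) / s1 +
    weights[2] * (gebv_ol - mean(gebv_ol)) / s2
}

#' Mate-allocation fitness matrix
#'
#' fitness(i, j) = (index_i + index_j)/2 - lambda * G(i, j): the mid-parent
#' index of each candidate pair penalized by their genomic co-ancestry (the
#' off-diagonal GRM entry). The diagonal is set to -Inf (no self-crosses).
#'
#' @param index per-candidate selection-index (or GEBV) values.
#' @param grm a `saf_grm` (or matrix) over the same candidates, same order.
#' @param lambda non-negative co-ancestry penalty weight (study value 0.5).
#' @return an object of class `fitness_matrix`: list with `values` and
#'   `candidate_ids`.
#' @export
build_fitness_matrix <- function(index, grm, lambda = 0.5) {
  G <- if (inherits(grm, "saf_grm")) grm$values else grm
  ids <- if (inherits(grm, "saf_grm")) grm$ids else rownames(G)
  n <- length(index)
  if (nrow(G) != n) stop("index and GRM dimensions do not match")
  if (lambda < 0) stop("lambda must be >= 0")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  V <- (outer(index, index, "+")) / 2 - lambda * G
  diag(V) <- -Inf
  structure(list(values = V, candidate_ids = ids, lambda = lambda),
            class = "fitness_matrix")
}

#' Genetic-algorithm configuration for mate allocation
#'
#' @param pop_size GA population size.
#' @param n_generations number of GA generations.
#' @param mutation_rate per-cross mutation probability.
#' @param crossover_rate probability of one-point recombination between two
#'   parent plans.
#' @param elitism number of best plans copied unchanged each generation.
#' @param tournament_k tournament size for plan selection.
#' @param seed optional integer seed.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 200, n_generations = 300,
                      mutation_rate = 0.02, crossover_rate = 0.8,
                      elitism = 2, tournament_k = 3, seed = NULL) {
  if (pop_size < 2) stop("pop_size must be >= 2")
  for (r in c(mutation_rate, crossover_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  structure(list(pop_size = as.integer(pop_size),
                 n_generations = as.integer(n_generations),
                 mutation_rate = mutation_rate, crossover_rate = crossover_rate,
                 elitism = as.integer(elitism),
                 tournament_k = as.integer(tournament_k), seed = seed),
            class = "ga_config")
}

# ---- GA internals -------------------------------------------------------
# A plan is an n_crosses x 2 integer matrix of candidate indices, pairs
# stored with p1 < p2. Constraints: no self-pairs, no duplicated pairs, at
# most `use_cap` crosses per parent, and a distinct-parent count of exactly
# `target` (exact_parents = TRUE, the "set of n_parents parents" reading)
# or at most `target`.

plan_objective <- function(plan, V) sum(V[cbind(plan[, 1], plan[, 2])])

plan_valid <- function(plan, target, use_cap, exact) {
  if (any(plan[, 1] == plan[, 2])) return(FALSE)
  key <- pmin(plan[, 1], plan[, 2]) * 1e6 + pmax(plan[, 1], plan[, 2])
  if (anyDuplicated(key)) return(FALSE)
  us <- tabulate(plan)
  if (max(us) > use_cap) return(FALSE)
  nd <- sum(us > 0)
  if (exact) nd == target else nd <= target
}

# pair up a fixed multiset of parent slots, removing self-pairs and
# duplicate pairs by count-preserving swaps
fix_pairing <- function(slots, n_crosses) {
  plan <- matrix(sample(slots), ncol = 2)
  for (it in 1:300) {
    key <- pmin(plan[, 1], plan[, 2]) * 1e6 + pmax(plan[, 1], plan[, 2])
    bad <- which(plan[, 1] == plan[, 2] | duplicated(key))
    if (!length(bad)) return(plan)
    i <- bad[1]
    j <- sample.int(n_crosses, 1)
    tmp <- plan[i, 1]
    plan[i, 1] <- plan[j, 2]
    plan[j, 2] <- tmp
  }
  NULL
}

random_plan <- function(n_cand, n_crosses, target, use_cap, exact) {
  n_slots <- 2L * n_crosses
  n_pool <- if (exact) target else min(target, n_slots)
  for (attempt in 1:200) {
    pool <- sample.int(n_cand, n_pool)
    extra <- n_slots - n_pool
    if (extra < 0) {             # more pool parents than slots (non-exact)
      slots <- sample(pool, n_slots)
    } else {
      # spread the extra usages nearly evenly so a conflict-free pairing
      # exists; randomness in which parents are reused
      alloc <- rep(extra %/% n_pool, n_pool)
      rem <- extra %% n_pool
      if (rem) alloc[sample.int(n_pool, rem)] <- alloc[1] + 1L
      if (is.finite(use_cap) && any(1L + alloc > use_cap)) break
      slots <- rep(pool, times = 1L + alloc)
    }
    plan <- fix_pairing(slots, n_crosses)
    if (!is.null(plan) && plan_valid(plan, target, use_cap, exact))
      return(plan)
  }
  stop("could not build a valid random crossing plan; constraints may be infeasible")
}

repair_plan <- function(plan, n_cand, target, use_cap, exact) {
  n_crosses <- nrow(plan)
  for (round in 1:80) {
    plan <- cbind(pmin(plan[, 1], plan[, 2]), pmax(plan[, 1], plan[, 2]))
    # self-pairs
    self <- which(plan[, 1] == plan[, 2])
    for (i in self) plan[i, 2] <- sample.int(n_cand, 1)
    plan <- cbind(pmin(plan[, 1], plan[, 2]), pmax(plan[, 1], plan[, 2]))
    # duplicated pairs: perturb one slot
    key <- plan[, 1] * 1e6 + plan[, 2]
    dup <- which(duplicated(key))
    for (i in dup) plan[i, sample(2, 1)] <- sample.int(n_cand, 1)
    if (length(self) || length(dup)) next
    usage <- tabulate(plan, n_cand)
    inset <- which(usage > 0)
    nd <- length(inset)
    # per-parent usage cap
    over <- which(usage > use_cap)
    if (length(over)) {
      p <- over[1]
      slots <- which(plan == p)
      s <- slots[sample.int(length(slots), 1)]
      repl_pool <- inset[usage[inset] < use_cap & inset != p]
      if (nd < target) repl_pool <- c(repl_pool, setdiff(seq_len(n_cand), inset))
      if (!length(repl_pool)) repl_pool <- setdiff(seq_len(n_cand), p)
      plan[s] <- repl_pool[sample.int(length(repl_pool), 1)]
      next
    }
    # too many distinct parents: merge a singleton into another parent
    if (nd > target) {
      singles <- which(usage == 1)
      if (length(singles) >= 2) {
        drop_p <- sample(singles, 1)
        into <- setdiff(singles, drop_p)
        into <- into[usage[into] < use_cap]
        if (!length(into)) into <- setdiff(inset[usage[inset] < use_cap], drop_p)
        s <- which(plan == drop_p)[1]
        plan[s] <- into[sample.int(length(into), 1)]
      } else {
        plan[cbind(sample(n_crosses, 1), sample(2, 1))] <-
          inset[sample.int(nd, 1)]
      }
      next
    }
    # too few distinct parents (exact mode): split a reused parent
    if (exact && nd < target) {
      multi <- which(usage >= 2)
      fresh <- setdiff(seq_len(n_cand), inset)
      if (length(multi) && length(fresh)) {
        p <- multi[sample.int(length(multi), 1)]
        s <- which(plan == p)[1]
        plan[s] <- fresh[sample.int(length(fresh), 1)]
        next
      }
    }
    return(plan)
  }
  random_plan(n_cand, n_crosses, target, use_cap, exact)
}

greedy_plan <- function(V, n_crosses, target, use_cap, exact) {
  n_cand <- nrow(V)
  # restrict to the most promising candidates to keep the pair sort small
  top <- order(-apply(V, 1, max))[seq_len(min(n_cand, max(3 * target, 12)))]
  prs <- t(utils::combn(sort(top), 2))
  prs <- prs[order(-V[prs]), , drop = FALSE]
  usage <- integer(n_cand)
  plan <- matrix(0L, 0, 2)
  for (i in seq_len(nrow(prs))) {
    a <- prs[i, 1]; b <- prs[i, 2]
    ndist <- sum(usage > 0) + (usage[a] == 0) + (usage[b] == 0)
    slots_left <- 2 * (n_crosses - nrow(plan) - 1)
    # with exactness, keep enough open slots to still reach `target` parents
    room_ok <- !exact || (ndist + slots_left >= target)
    if (usage[a] < use_cap && usage[b] < use_cap && ndist <= target && room_ok) {
      plan <- rbind(plan, prs[i, ])
      usage[a] <- usage[a] + 1L; usage[b] <- usage[b] + 1L
      if (nrow(plan) == n_crosses) break
    }
  }
  if (nrow(plan) < n_crosses) return(NULL)
  plan
}

#' Optimize a crossing plan with a genetic algorithm
#'
#' Searches for the set of `n_crosses` parent pairs maximizing the summed
#' pair fitness, subject to: no self-crosses, no duplicated pairs, at most
#' `use_cap` crosses per parent, and at most `n_parents` distinct parents.
#' Plans are fixed-length lists of pairs; offspring plans are repaired to
#' satisfy the constraints. Seeded and reproducible; the initial population
#' includes a greedy plan so the search starts from a strong incumbent.
#'
#' @param fitness a [build_fitness_matrix()] result.
#' @param n_crosses number of crosses in the plan.
#' @param n_parents number of distinct parents the plan may use. With
#'   `exact_parents = TRUE` (default) the plan uses exactly
#'   `min(n_parents, 2 n_crosses, n_candidates)` distinct parents (the
#'   "set of 50 parents" reading); otherwise at most `n_parents`.
#' @param ga a [ga_config()].
#' @param use_cap maximum crosses per parent (default 2, so 30 crosses can
#'   span 50 distinct parents; use `Inf` to disable).
#' @param exact_parents require the distinct-parent count to equal the
#'   target rather than merely not exceed it.
#' @return an object of class `cross_plan`: list with `crosses` (n_crosses
#'   x 2 id matrix), `parent_set`, `pair_fitness` and `objective`.
#' @export
ga_optimize_crosses <- function(fitness, n_crosses, n_parents,
                                ga = ga_config(), use_cap = 2,
                                exact_parents = TRUE) {
  stopifnot(inherits(fitness, "fitness_matrix"))
  V <- fitness$values
  n_cand <- nrow(V)
  target <- min(n_parents, 2 * n_crosses, n_cand)
  if (2 * n_crosses > use_cap * target || target < 2 ||
      n_crosses > choose(target, 2))
    stop("infeasible constraints: not enough candidates/parent slots for the requested crosses")
  if (!is.null(ga$seed)) set.seed(ga$seed)
  pop <- replicate(ga$pop_size,
                   random_plan(n_cand, n_crosses, target, use_cap, exact_parents),
                   simplify = FALSE)
  g0 <- greedy_plan(V, n_crosses, target, use_cap, exact_parents)
  if (!is.null(g0)) {
    if (!plan_valid(g0, target, use_cap, exact_parents))
      g0 <- repair_plan(g0, n_cand, target, use_cap, exact_parents)
    pop[[1]] <- g0
  }
  fit <- vapply(pop, plan_objective, numeric(1), V = V)
  for (gen in seq_len(ga$n_generations)) {
    ord <- order(-fit)
    newpop <- pop[ord[seq_len(ga$elitism)]]
    while (length(newpop) < ga$pop_size) {
      pick <- function() {
        k <- sample.int(ga$pop_size, ga$tournament_k)
        pop[[k[which.max(fit[k])]]]
      }
      a <- pick()
      if (runif(1) < ga$crossover_rate && n_crosses > 1) {
        b <- pick()
        cut <- sample.int(n_crosses - 1, 1)
        child <- rbind(a[seq_len(cut), , drop = FALSE],
                       b[(cut + 1):n_crosses, , drop = FALSE])
      } else child <- a
      mut <- runif(n_crosses) < ga$mutation_rate
      for (i in which(mut)) child[i, sample(2, 1)] <- sample.int(n_cand, 1)
      if (!plan_valid(child, target, use_cap, exact_parents))
        child <- repair_plan(child, n_cand, target, use_cap, exact_parents)
      newpop[[length(newpop) + 1]] <- child
    }
    pop <- newpop
    fit <- vapply(pop, plan_objective, numeric(1), V = V)
  }
  best <- pop[[which.max(fit)]]
  ids <- fitness$candidate_ids
  crosses <- cbind(ids[best[, 1]], ids[best[, 2]])
  structure(list(crosses = crosses,
                 parent_set = unique(as.vector(crosses)),
                 pair_fitness = V[best],
                 objective = max(fit)),
            class = "cross_plan")
}

#' @export
print.cross_plan <- function(x, ...) {
  cat("Crossing plan:", nrow(x$crosses), "crosses over",
      length(x$parent_set), "distinct parents")
  if (!is.null(x$objective)) cat("; objective", round(x$objective, 4))
  cat("\n")
  invisible(x)
}

#' Selection-strategy configuration
#'
#' The four strategies: `"GY"` and `"OL"` (single-trait truncation on one
#' trait's GEBVs), `"GY_plus_OL"` (equal-weight standardized index), and
#' `"GY_plus_OL_Rel"` (index selection with GA-based parent selection and
#' mate allocation penalizing genomic co-ancestry). `"random"` is a null
#' strategy (uniform parent choice) used for calibration checks.
#'
#' @param strategy one of `"GY"`, `"OL"`, `"GY_plus_OL"`,
#'   `"GY_plus_OL_Rel"`, `"random"`.
#' @param n_parents parents selected per cycle.
#' @param n_crosses crosses per cycle.
#' @param index_weights index weights for the two traits.
#' @param lambda co-ancestry penalty (study value 0.5).
#' @param use_cap per-parent usage cap in the GA plan.
#' @param exact_parents require the GA plan to span exactly `n_parents`
#'   distinct parents (see [ga_optimize_crosses()]).
#' @param ga a [ga_config()].
#' @return an object of class `strategy_config`.
#' @export
strategy_config <- function(strategy = c("GY", "OL", "GY_plus_OL",
                                         "GY_plus_OL_Rel", "random"),
                            n_parents = 50, n_crosses = 30,
                            index_weights = c(1, 1), lambda = 0.5,
                            use_cap = 2, exact_parents = TRUE,
                            ga = ga_config()) {
  strategy <- match.arg(strategy)
  if (n_parents < 2) stop("n_parents must be >= 2")
  if (n_crosses < 1) stop("n_crosses must be >= 1")
  if (lambda < 0) stop("lambda must be >= 0")
  structure(list(strategy = strategy, n_parents = as.integer(n_parents),
                 n_crosses = as.integer(n_crosses),
                 index_weights = index_weights, lambda = lambda,
                 use_cap = use_cap, exact_parents = exact_parents, ga = ga),
            class = "strategy_config")
}

# n random distinct unordered pairs among ids
random_cross_plan <- function(ids, n_crosses) {
  np <- length(ids)
  if (n_crosses > choose(np, 2)) stop("not enough distinct pairs available")
  pick <- sample.int(choose(np, 2), n_crosses)
  all_pairs <- t(utils::combn(np, 2))
  sel <- all_pairs[pick, , drop = FALSE]
  structure(list(crosses = cbind(ids[sel[, 1]], ids[sel[, 2]]),
                 parent_set = unique(ids[as.vector(sel)]),
                 pair_fitness = NULL, objective = NULL),
            class = "cross_plan")
}

#' Select parents and a crossing plan under a strategy
#'
#' Dispatches to the four strategies. For truncation/index strategies the
#' crossing plan is `n_crosses` random distinct pairs among the selected
#' parents (random crossing); for the relationship-controlled strategy,
#' parents and plan come jointly from the GA over the whole candidate pool.
#'
#' @param strategy a [strategy_config()].
#' @param gebv_table data.frame with columns `id`, `GY`, `OL` over the
#'   candidate pool.
#' @param grm `saf_grm` over the same candidates, same order (required for
#'   the `Rel` strategy only).
#' @return list with `ids` (selected parents) and `plan` (a `cross_plan`).
#' @export
select_parents <- function(strategy, gebv_table, grm = NULL) {
  stopifnot(inherits(strategy, "strategy_config"))
  ids <- gebv_table$id
  np <- strategy$n_parents
  sel <- switch(strategy$strategy,
    GY = select_truncation(gebv_table$GY, ids, np),
    OL = select_truncation(gebv_table$OL, ids, np),
    GY_plus_OL = {
      idx <- build_index(gebv_table$GY, gebv_table$OL, strategy$index_weights)
      select_truncation(idx, ids, np)
    },
    random = sample(ids, np),
    GY_plus_OL_Rel = NULL)
  if (strategy$strategy == "GY_plus_OL_Rel") {
    if (is.null(grm)) stop("the Rel strategy needs the candidate GRM")
    idx <- build_index(gebv_table$GY, gebv_table$OL, strategy$index_weights)
    fm <- build_fitness_matrix(idx, grm, strategy$lambda)
    plan <- ga_optimize_crosses(fm, strategy$n_crosses, np,
                                ga = strategy$ga, use_cap = strategy$use_cap,
                                exact_parents = strategy$exact_parents)
    return(list(ids = plan$parent_set, plan = plan))
  }
  list(ids = sel, plan = random_cross_plan(sel, strategy$n_crosses))
}
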