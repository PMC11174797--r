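# exhaustive enumeration of valid plans on small instances
enumerate_plans <- function(n_cand, n_crosses, n_parents, use_cap,
                            exact = TRUE) {
  prs <- t(utils::combn(n_cand, 2))
  combos <- utils::combn(nrow(prs), n_crosses)
  target <- min(n_parents, 2 * n_crosses, n_cand)
  keep <- list()
  for (i in seq_len(ncol(combos))) {
    plan <- prs[combos[, i], , drop = FALSE]
    us <- tabulate(plan, n_cand)
    nd <- sum(us > 0)
    ok <- max(us) <= use_cap && (if (exact) nd == target else nd <= n_parents)
    if (ok) keep[[length(keep) + 1]] <- plan
  }
  keep
}

best_plan_objective <- function(V, plans) {
  max(vapply(plans, function(p) sum(V[p]), numeric(1)))
}

test_that("truncation selects the top n with stable ties", {
  expect_equal(select_truncation(c(3, 1, 2), c("a", "b", "c"), 2), c("a", "c"))
  expect_equal(select_truncation(c(5, 5, 5), c("a", "b", "c"), 2), c("a", "b"))
  expect_error(select_truncation(1:3, letters[1:3], 4), "more")
  # brute-force sort oracle over random instances
  set.seed(81)
  for (i in 1:1000) {
    n <- sample(3:30, 1)
    v <- round(rnorm(n), 2)  # rounding forces frequent ties
    k <- sample.int(n, 1)
    got <- select_truncation(v, as.character(seq_len(n)), k)
    expect_equal(sort(v[as.integer(got)], decreasing = TRUE),
                 sort(v, decreasing = TRUE)[seq_len(k)])
  }
})

test_that("the standardized index reduces and composes correctly", {
  set.seed(82)
  gy <- rnorm(40); ol <- rnorm(40)
  idx <- build_index(gy, ol)
  expect_equal(mean(idx), 0, tolerance = 1e-12)
  # single-trait reduction: ranking equals the trait ranking
  expect_equal(order(build_index(gy, ol, c(1, 0))), order(gy))
  # identical traits: index = 2 z(gy)
  expect_equal(build_index(gy, gy), 2 * (gy - mean(gy)) / sd(gy))
  expect_error(build_index(gy, rep(1, 40)), "degenerate")
})

test_that("the fitness matrix implements mid-parent minus penalized co-ancestry", {
  idx <- c(1, 2, 0.5)
  G <- matrix(c(1, 0.5, 0.2, 0.5, 1.2, 0.1, 0.2, 0.1, 0.9), 3, 3)
  fm <- build_fitness_matrix(idx, G, lambda = 0.5)
  expect_equal(fm$values[1, 2], (1 + 2) / 2 - 0.5 * 0.5)  # = 1.25
  expect_true(all(is.infinite(diag(fm$values))))
  # lambda = 0: fitness is exactly the mid-parent value
  fm0 <- build_fitness_matrix(idx, G, lambda = 0)
  expect_equal(fm0$values[1, 3], 0.75)
  # fixed mid-parent: fitness strictly decreasing in co-ancestry
  set.seed(83)
  for (i in 1:50) {
    g1 <- runif(1, 0, 1); g2 <- g1 + runif(1, 0.01, 1)
    G2 <- matrix(c(1, g1, g1, 1), 2, 2)
    G3 <- matrix(c(1, g2, g2, 1), 2, 2)
    f_lo <- build_fitness_matrix(c(1, 1), G2, 0.5)$values[1, 2]
    f_hi <- build_fitness_matrix(c(1, 1), G3, 0.5)$values[1, 2]
    expect_gt(f_lo, f_hi)
  }
  expect_error(build_fitness_matrix(idx, G[1:2, 1:2], 0.5), "dimensions")
})

test_that("the GA attains the exhaustive optimum on a small instance", {
  hits <- vapply(1:50, function(s) {
    set.seed(3000 + s)
    idx <- rnorm(6)
    A <- matrix(rnorm(36), 6); G <- crossprod(A) / 6
    fm <- build_fitness_matrix(idx, G, lambda = 0.5)
    plans <- enumerate_plans(6, 3, 6, use_cap = 2, exact = TRUE)
    opt <- best_plan_objective(fm$values, plans)
    got <- ga_optimize_crosses(fm, 3, 6,
                               ga_config(pop_size = 40, n_generations = 40,
                                         seed = 4000 + s))
    as.numeric(abs(got$objective - opt) < 1e-9)
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("with no penalty and no caps the GA matches the greedy mid-parent oracle", {
  set.seed(85)
  for (s in 1:5) {
    idx <- rnorm(8)
    fm <- build_fitness_matrix(idx, matrix(0, 8, 8), lambda = 0)
    # greedy oracle: the n_crosses distinct pairs with the largest
    # mid-parent values
    prs <- t(utils::combn(8, 2))
    mid <- (idx[prs[, 1]] + idx[prs[, 2]]) / 2
    greedy <- sum(sort(mid, decreasing = TRUE)[1:4])
    got <- ga_optimize_crosses(fm, 4, 8,
                               ga_config(pop_size = 60, n_generations = 60,
                                         seed = 86 + s),
                               use_cap = Inf, exact_parents = FALSE)
    expect_equal(got$objective, greedy, tolerance = 1e-9)
  }
})

test_that("a strong co-ancestry penalty keeps identical twins unmated", {
  set.seed(87)
  for (s in 1:10) {
    idx <- c(3, 3, rnorm(4))      # twins have the highest index
    G <- diag(6) * 0
    G[1, 2] <- G[2, 1] <- 2       # genomically identical pair
    fm <- build_fitness_matrix(idx, G, lambda = 50)
    got <- ga_optimize_crosses(fm, 3, 6,
                               ga_config(pop_size = 40, n_generations = 40,
                                         seed = 88 + s))
    mated <- apply(got$crosses, 1, function(p) all(sort(p) == c("1", "2")))
    expect_false(any(mated))
  }
})

test_that("GA constraints are respected and infeasible requests rejected", {
  set.seed(89)
  idx <- rnorm(20)
  G <- diag(20)
  fm <- build_fitness_matrix(idx, G, 0.5)
  got <- ga_optimize_crosses(fm, 6, 10,
                             ga_config(pop_size = 30, n_generations = 20,
                                       seed = 90))
  expect_equal(nrow(got$crosses), 6)
  expect_equal(length(got$parent_set), 10)  # exact distinct-parent count
  usage <- table(as.vector(got$crosses))
  expect_lte(max(usage), 2)
  expect_false(any(got$crosses[, 1] == got$crosses[, 2]))
  expect_error(ga_optimize_crosses(fm, 30, 4, ga_config(pop_size = 10,
                                                        n_generations = 5)),
               "infeasible")
})

test_that("select_parents dispatches the four strategies on a candidate pool", {
  set.seed(91)
  n <- 60
  tab <- data.frame(id = paste0("c", 1:n), GY = rnorm(n), OL = rnorm(n))
  dos <- random_dosages(n, 120)
  rownames(dos) <- tab$id
  grm <- compute_grm(dos)
  # single-trait truncation
  cfgGY <- strategy_config("GY", n_parents = 10, n_crosses = 5)
  selGY <- select_parents(cfgGY, tab)
  expect_setequal(selGY$ids, tab$id[order(-tab$GY)][1:10])
  expect_equal(nrow(selGY$plan$crosses), 5)
  expect_true(all(selGY$plan$crosses %in% selGY$ids))
  # index strategy selects on the combined standardized index
  cfgIdx <- strategy_config("GY_plus_OL", n_parents = 10, n_crosses = 5)
  selIdx <- select_parents(cfgIdx, tab)
  idx <- build_index(tab$GY, tab$OL)
  expect_setequal(selIdx$ids, tab$id[order(-idx)][1:10])
  # Rel strategy: parents and plan from the GA
  cfgRel <- strategy_config("GY_plus_OL_Rel", n_parents = 10, n_crosses = 5,
                            ga = ga_config(pop_size = 30, n_generations = 20,
                                           seed = 92))
  selRel <- select_parents(cfgRel, tab, grm)
  expect_equal(length(selRel$ids), 10)
  expect_true(all(selRel$plan$crosses %in% selRel$ids))
  expect_error(select_parents(cfgRel, tab), "GRM")
  # selection differential is non-negative for the targeted criterion
  expect_gte(mean(tab$GY[tab$id %in% selGY$ids]), mean(tab$GY))
  expect_gte(mean(idx[tab$id %in% selIdx$ids]), mean(idx))
})

test_that("relationship control lowers mated-pair co-ancestry versus random index mating", {
  diffs <- vapply(1:20, function(s) {
    set.seed(5000 + s)
    pop <- tiny_founders(n = 80, m = 150, seed = 5100 + s)
    dos <- dosages(pop)
    grm <- compute_grm(dos)
    tab <- data.frame(id = pop$id, GY = rnorm(80), OL = rnorm(80))
    cfgRel <- strategy_config("GY_plus_OL_Rel", n_parents = 20, n_crosses = 10,
                              ga = ga_config(pop_size = 40, n_generations = 30))
    selRel <- select_parents(cfgRel, tab, grm)
    cfgIdx <- strategy_config("GY_plus_OL", n_parents = 20, n_crosses = 10)
    selIdx <- select_parents(cfgIdx, tab)
    pair_g <- function(plan) {
      mean(grm$values[cbind(match(plan$crosses[, 1], pop$id),
                            match(plan$crosses[, 2], pop$id))])
    }
    pair_g(selIdx$plan) - pair_g(selRel$plan)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("with lambda = 0 and saturated crossing the GA recovers the truncation parent set", {
  set.seed(93)
  for (s in 1:5) {
    n <- 12
    tab <- data.frame(id = paste0("c", 1:n), GY = rnorm(n), OL = rnorm(n))
    idx <- build_index(tab$GY, tab$OL)
    G0 <- matrix(0, n, n, dimnames = list(tab$id, tab$id))
    fm <- build_fitness_matrix(idx, G0, lambda = 0)
    # 6 crosses over exactly 4 parents with no usage cap: the optimum is
    # all pairs among the top 4 by index
    got <- ga_optimize_crosses(fm, 6, 4,
                               ga_config(pop_size = 60, n_generations = 60,
                                         seed = 94 + s),
                               use_cap = Inf, exact_parents = TRUE)
    top4 <- tab$id[order(-idx)][1:4]
    expect_setequal(got$parent_set, top4)
  }
})
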