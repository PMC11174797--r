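test_that("configuration contracts are enforced", {
  expect_error(bayesr_config(n_iter = 100, burn_in = 100), "burn_in")
  expect_error(bayesr_config(mixture_variance_fractions = c(0.1, 1e-4, 1e-3, 1e-2)),
               "fractions")
  expect_error(fit_bayesr(random_dosages(10, 5), c(1, 2, NA, 4:10),
                          short_chain()), "finite")
  expect_error(fit_bayesr(random_dosages(10, 5), 1:9, short_chain()),
               "length")
})

test_that("pure-noise phenotypes yield no confident marker effects", {
  # With no QTL the mixture components with variance ~0 are likelihood-
  # equivalent to the null, so class labels are not identifiable; what the
  # model must deliver is the absence of signal: shrunken effects, no
  # phantom genetic variance, and little mass in the large-effect class.
  stats <- t(vapply(1:20, function(s) {
    set.seed(600 + s)
    dos <- random_dosages(300, 500)
    y <- rnorm(300)
    fit <- fit_bayesr(dos, y, short_chain(seed = 700 + s))
    c(r2 = var(dos %*% fit$beta) / var(y),
      maxb = max(abs(fit$beta)) / sd(y),
      big = mean(fit$class_probs[, 4]))
  }, numeric(3)))
  expect_true(all(stats[, "r2"] < 0.10))   # fitted genetic variance ~ 0
  expect_true(all(stats[, "maxb"] < 0.2))  # no marker with a sizable effect
  expect_lt(mean(stats[, "big"]), 0.5)     # largest-variance class not favored
  # mixture memberships are a probability simplex
  set.seed(601)
  fit <- fit_bayesr(random_dosages(100, 80), rnorm(100), short_chain(seed = 1))
  expect_equal(unname(rowSums(fit$class_probs)), rep(1, 80))
  expect_equal(sum(fit$pi), 1, tolerance = 1e-9)
})

test_that("a large single QTL is recovered", {
  ests <- t(vapply(1:5, function(s) {
    set.seed(610 + s)
    n <- 500; m <- 300
    dos <- random_dosages(n, m)
    j <- 150
    beta_true <- 1
    g <- dos[, j] * beta_true
    # noise sized so the QTL explains 50% of phenotypic variance
    y <- g + rnorm(n, 0, sd(g))
    fit <- fit_bayesr(dos, y, short_chain(seed = 710 + s))
    bt <- numeric(m); bt[j] <- beta_true
    c(est = fit$beta[[j]], cor = cor(fit$beta, bt))
  }, numeric(2)))
  expect_equal(mean(ests[, "est"]), 1, tolerance = 0.25)
  expect_true(all(ests[, "cor"] > 0.5))
})

test_that("the noise-free limit assigns the causal marker to a non-null class", {
  set.seed(62)
  dos <- random_dosages(200, 100)
  y <- 2 * dos[, 40] + rnorm(200, 0, 1e-6)
  fit <- fit_bayesr(dos, y, short_chain(seed = 63))
  expect_gt(1 - fit$class_probs[40, 1], 0.9)
  expect_equal(fit$beta[[40]], 2, tolerance = 0.05)
})

test_that("GEBV prediction equals the dot-product oracle", {
  set.seed(64)
  dos <- random_dosages(10, 50)
  fit <- fit_bayesr(random_dosages(60, 50), rnorm(60), short_chain(seed = 65))
  g <- predict_gebv(dos, fit)
  oracle <- numeric(10)
  for (i in 1:10) for (j in 1:50)
    oracle[i] <- oracle[i] + dos[i, j] * fit$beta[j]
  expect_equal(unname(g), oracle, tolerance = 1e-12)
  # trivial cases
  fit0 <- fit; fit0$beta[] <- 0
  expect_equal(unname(predict_gebv(dos, fit0)), rep(0, 10))
  fit1 <- fit; fit1$beta[] <- 0; fit1$beta[3] <- 1
  expect_equal(unname(predict_gebv(dos, fit1)), unname(dos[, 3]))
  expect_error(predict_gebv(dos[, 1:10], fit), "align")
})

test_that("posterior variance components approximately partition the phenotypic variance", {
  set.seed(66)
  pop <- tiny_founders(n = 300, m = 200, seed = 67)
  arch <- simulate_trait_architecture(pop, n_qtl = 50, h2 = c(0.5, 0.5),
                                      seed = 68)
  phen <- simulate_phenotypes(pop, arch, seed = 69)
  fit <- fit_bayesr(dosages(pop), phen$GY, short_chain(seed = 70))
  total <- sum(fit$var_components)
  expect_equal(total, var(phen$GY), tolerance = 0.15)
})

test_that("prediction accuracy is positive and increases with heritability", {
  acc <- vapply(c(0.2, 0.5, 0.8), function(h2) {
    mean(vapply(1:20, function(s) {
      set.seed(800 + s)
      pop <- tiny_founders(n = 500, m = 150, seed = 900 + s)
      arch <- simulate_trait_architecture(pop, n_qtl = 40, h2 = c(h2, h2),
                                          seed = 950 + s)
      phen <- simulate_phenotypes(pop, arch, seed = 970 + s)
      train <- 1:300; test <- 301:500
      fit <- fit_bayesr(dosages(pop)[train, ], phen$GY[train],
                        short_chain(seed = 990 + s, n_iter = 600,
                                    burn_in = 200))
      cor(predict_gebv(dosages(pop)[test, ], fit), arch$tbv[test, 1])
    }, numeric(1)))
  }, numeric(1))
  expect_gt(acc[2], 0.3)            # clear signal at h2 = 0.5
  expect_true(all(diff(acc) > 0))   # monotone in h2
})

test_that("GBLUP heritability estimation behaves across signal regimes", {
  set.seed(71)
  pop <- tiny_founders(n = 349, m = 300, seed = 72)
  arch <- simulate_trait_architecture(pop, n_qtl = 100,
                                      h2 = c(0.54, 0.8), seed = 73)
  grm <- compute_grm(dosages(pop))
  # noise-free: h2 -> 1
  expect_gt(estimate_h2_gblup(arch$tbv[, 1], grm), 0.95)
  # recovery of the generating value over phenotype seeds
  h2s <- vapply(1:20, function(s) {
    ph <- simulate_phenotypes(pop, arch, seed = 1100 + s)
    estimate_h2_gblup(ph$GY, grm)
  }, numeric(1))
  expect_equal(mean(h2s), 0.54, tolerance = 0.28)
  # permutation null: no signal left
  set.seed(74)
  ph <- simulate_phenotypes(pop, arch, seed = 75)
  expect_lt(estimate_h2_gblup(sample(ph$GY), grm), 0.15)
})
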