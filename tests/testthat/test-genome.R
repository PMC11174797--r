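test_that("map construction validates positions and layout", {
  mp <- genetic_map(120, n_chromosomes = 12, lengths = 1)
  expect_equal(mp$n_chromosomes, 12)
  expect_true(all(mp$pos >= 0 & mp$pos <= 1))
  expect_error(genetic_map(chr = c(1, 1), pos = c(0.5, 0.2), lengths = 1),
               "non-decreasing")
  expect_error(genetic_map(chr = c(1, 1), pos = c(0.5, 1.2), lengths = 1),
               "within")
})

test_that("gametes follow the Poisson crossover model", {
  set.seed(41)
  # zero-length chromosome: no crossovers, gamete is one parental haplotype
  m <- 30
  p0 <- pop_from_haplo(rbind(rep(1L, m), rep(0L, m)), 1, lengths = 0)
  g <- replicate(200, make_gamete(p0, 1))
  expect_true(all(colSums(g) %in% c(0L, m)))
  # ... chosen with probability ~ 1/2
  expect_gt(mean(colSums(g) == m), 0.35)
  expect_lt(mean(colSums(g) == m), 0.65)
  # fully homozygous parent: gamete identical to either haplotype
  hom <- pop_from_haplo(rbind(rep(1L, 60), rep(1L, 60)), 4)
  expect_equal(make_gamete(hom, 1), rep(1L, 60))
  # 1-Morgan chromosome: mean crossover count ~ Poisson(1)
  het <- pop_from_haplo(rbind(rep(1L, 200), rep(0L, 200)), 1, lengths = 1)
  gams <- replicate(10000, make_gamete(het, 1))
  switches <- colSums(abs(apply(gams, 2, diff)))
  expect_gt(mean(switches), 0.94)
  expect_lt(mean(switches), 1.06)
})

test_that("crossing follows Mendelian expectations", {
  set.seed(42)
  m <- 20
  # identical fully homozygous parents: every F1 identical to them
  hap <- matrix(rep(c(0L, 1L), each = m / 2), 1)
  hom2 <- pop_from_haplo(rbind(hap, hap, hap, hap), 2)
  f1 <- cross(hom2, 1, 2, 10)
  expect_true(all(dosages(f1) == rep(2 * hap, each = 10)))
  expect_equal(unname(f1$parents[1, ]), c("I1", "I2"))
  # AA x aa: all F1 heterozygous
  pAAaa <- pop_from_haplo(rbind(rep(1L, m), rep(1L, m),
                                rep(0L, m), rep(0L, m)), 2)
  f1b <- cross(pAAaa, 1, 2, 15)
  expect_true(all(dosages(f1b) == 1L))
  # Aa x Aa at one locus: 1:2:1 within multinomial sampling error
  het1 <- pop_from_haplo(rbind(1L, 0L, 1L, 0L), 1)
  f1c <- cross(het1, 1, 2, 10000)
  counts <- tabulate(dosages(f1c) + 1L, 3)
  expect_gt(stats::chisq.test(counts, p = c(1, 2, 1) / 4)$p.value, 0.001)
  expect_error(cross(het1, 1, 2, 0), "n_progeny")
})

test_that("single-seed descent yields the expected counts and heterozygosity decay", {
  set.seed(43)
  founders <- tiny_founders(n = 12, m = 240, seed = 44)
  plan <- cbind(1:5, 6:10)
  f1 <- make_crosses(founders, plan, 4)
  f4 <- advance_ssd(f1, n_f2_bulk = 40, n_f4_per_cross = 10)
  expect_equal(n_ind(f4), 5 * 10)
  expect_equal(unique(f4$generation), "F4")
  expect_equal(attr(f4, "cross_id"), rep(1:5, each = 10))
  expect_error(advance_ssd(f1, n_f2_bulk = 10, n_f4_per_cross = 20), "bulk")
  # homozygous F1: all F4 genetically identical to it
  m <- 40
  hom <- pop_from_haplo(rbind(rep(1L, m), rep(1L, m)), 4)
  f1h <- hom
  attr(f1h, "cross_id") <- 1L
  f4h <- advance_ssd(f1h, n_f2_bulk = 10, n_f4_per_cross = 5)
  expect_true(all(dosages(f4h) == 2L))
  # fully heterozygous F1: three selfing meioses F1->F2->F3->F4, so
  # expected F4 heterozygosity is 0.5^3 (brute-force selfing recursion)
  g_self <- 3
  expected_het <- 0.5^g_self
  hetf1 <- het_individual(m = 480, n_chromosomes = 12)
  attr(hetf1, "cross_id") <- 1L
  f4het <- advance_ssd(hetf1, n_f2_bulk = 60, n_f4_per_cross = 60)
  obs <- mean(heterozygosity(f4het))
  se <- sd(heterozygosity(f4het)) / sqrt(n_ind(f4het))
  expect_lt(abs(obs - expected_het), 3 * se + 0.01)
  # heterozygosity halves per selfing generation: F2 from selfing ~ 0.5
  f2 <- cross(hetf1, 1, 1, 400, generation = "F2")
  expect_equal(mean(heterozygosity(f2)), 0.5, tolerance = 0.05)
})

test_that("no operation creates alleles absent from both parents", {
  set.seed(45)
  founders <- tiny_founders(n = 10, m = 150, seed = 46)
  d <- dosages(founders)
  f1 <- make_crosses(founders, cbind(1:3, 4:6), 5)
  f4 <- advance_ssd(f1, n_f2_bulk = 20, n_f4_per_cross = 8)
  for (pop in list(f1, f4)) {
    dp <- dosages(pop)
    # markers fixed in all founders must stay fixed
    fixed0 <- colSums(d) == 0
    fixed2 <- colSums(d) == 2 * nrow(d)
    expect_true(all(dp[, fixed0] == 0))
    expect_true(all(dp[, fixed2] == 2))
  }
})

test_that("populations subset and combine consistently", {
  pop <- tiny_founders(n = 8, m = 50, seed = 47)
  sub <- pop[c(2, 5)]
  expect_equal(sub$id, pop$id[c(2, 5)])
  expect_equal(dosages(sub), dosages(pop)[c(2, 5), ])
  two <- combine_pops(pop[1:3], pop[4:6])
  expect_equal(n_ind(two), 6)
  expect_equal(dosages(two), dosages(pop)[1:6, ])
  expect_error(pop["nope"], "unknown")
})
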