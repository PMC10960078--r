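test_that("biallelic base spectrum matches the Beta tail mass", {
  cfg <- sim_config(regime = "biallelic", n_loci = 4000, beta_shape1 = 0.3,
                    beta_shape2 = 3, seed = 5)
  base <- simulate_base_frequencies(cfg)
  maf <- vapply(base, min, 0)
  # P(min(X, 1-X) < 0.01) for X ~ Beta(0.3, 3)
  theory <- stats::pbeta(0.01, 0.3, 3) + (1 - stats::pbeta(0.99, 0.3, 3))
  mc_se <- sqrt(theory * (1 - theory) / 4000)
  expect_lt(abs(mean(maf < 0.01) - theory), 4 * mc_se)
})

test_that("k = 2 multiallelic regime is biallelic; frequencies sum to 1", {
  cfg <- sim_config(regime = "multiallelic", k_alleles = 2, n_loci = 50,
                    seed = 2)
  base <- simulate_base_frequencies(cfg)
  expect_true(all(lengths(base) == 2))
  expect_equal(unname(vapply(base, sum, 0)), rep(1, 50))
  pf <- simulate_population_frequencies(base, 0.2, 3, seed = 3)
  expect_equal(unname(vapply(pf[[2]], sum, 0)), rep(1, 50))
})

test_that("base frequency generation is seed-deterministic", {
  cfg <- sim_config(regime = "multiallelic", n_loci = 20, seed = 9)
  expect_identical(simulate_base_frequencies(cfg),
                   simulate_base_frequencies(cfg))
  cfg2 <- sim_config(regime = "multiallelic", n_loci = 20, seed = 10)
  expect_false(identical(simulate_base_frequencies(cfg),
                         simulate_base_frequencies(cfg2)))
})

test_that("min_base_freq floors the spectrum by rejection", {
  cfg <- sim_config(regime = "multiallelic", k_alleles = 4, n_loci = 100,
                    dirichlet_alpha = 1, min_base_freq = 0.05, seed = 4)
  base <- simulate_base_frequencies(cfg)
  expect_gte(min(vapply(base, min, 0)), 0.05)
})

test_that("population frequencies concentrate at base as F -> 0", {
  cfg <- sim_config(regime = "multiallelic", n_loci = 30, seed = 6)
  base <- simulate_base_frequencies(cfg)
  pf <- simulate_population_frequencies(base, 0.001, 2, seed = 7)
  dev <- unlist(Map(function(p, q) abs(p - q), base, pf[[1]]))
  expect_lt(max(dev), 0.08)
  expect_lt(mean(dev), 0.02)
})

test_that("Hardy-Weinberg genotype draws behave at the fixed points", {
  base <- list(L1 = c(A = 1), L2 = c(A = 0.5, B = 0.5))
  pf <- list(base)
  sim <- simulate_genotypes(pf, 200, seed = 8)
  expect_true(all(sim$gm$a1[, "L1"] == "A" & sim$gm$a2[, "L1"] == "A"))
  het <- mean(sim$gm$a1[, "L2"] != sim$gm$a2[, "L2"])
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 200))
  expect_identical(simulate_genotypes(pf, 50, seed = 1)$gm$a1,
                   simulate_genotypes(pf, 50, seed = 1)$gm$a1)
})

test_that("a garden equal to the whole wild set captures everything", {
  cfg <- sim_config(regime = "multiallelic", n_loci = 10, n_populations = 2,
                    n_per_pop = 10, seed = 12)
  base <- simulate_base_frequencies(cfg)
  pf <- simulate_population_frequencies(base, cfg$fst, 2, seed = 13)
  sim <- simulate_genotypes(pf, 10, seed = 14)
  gar <- sample_garden(sim$gm, sim$partition, scheme = "random",
                       size = 20, seed = 15)
  r <- exsitu_representation(gar$gm, gar$partition)
  expect_true(all(r$percent[!is.na(r$percent)] == 100))
  expect_error(sample_garden(sim$gm, sim$partition, scheme = "random",
                             size = 21, seed = 1), "exceeds")
})

test_that("stratified garden sampling splits evenly when divisible", {
  cfg <- sim_config(regime = "multiallelic", n_loci = 6, n_populations = 3,
                    n_per_pop = 10, seed = 16)
  base <- simulate_base_frequencies(cfg)
  pf <- simulate_population_frequencies(base, cfg$fst, 3, seed = 17)
  sim <- simulate_genotypes(pf, 10, seed = 18)
  gar <- sample_garden(sim$gm, sim$partition, scheme = "stratified",
                       size = 9, seed = 19)
  src_pop <- sim$partition$wild_population[gar$partition$founders]
  expect_equal(as.vector(table(src_pop)), rep(3L, 3))
})

test_that("skewing garden sampling away from a population hurts its private alleles", {
  cfg <- sim_config(regime = "multiallelic", n_loci = 20, n_populations = 3,
                    n_per_pop = 20, fst = 0.4, seed = 20)
  base <- simulate_base_frequencies(cfg)
  pf <- simulate_population_frequencies(base, 0.4, 3, seed = 21)
  sim <- simulate_genotypes(pf, 20, seed = 22)
  capture_rate_of_pop1_private <- function(gar) {
    fr <- wild_allele_frequencies(gar$gm, gar$partition)
    # alleles found only in pop1's wild samples
    w <- individuals(gar$gm)[gar$partition$origin[individuals(gar$gm)] ==
                               "wild"]
    pop <- gar$partition$wild_population[w]
    g1 <- gm_subset(gar$gm, individuals = w[pop == "pop1"])
    rest <- gm_subset(gar$gm, individuals = w[pop != "pop1"])
    k1 <- paste(rep(loci(g1), lengths(allele_labels(g1))),
                unlist(allele_labels(g1)))
    kr <- paste(rep(loci(rest), lengths(allele_labels(rest))),
                unlist(allele_labels(rest)))
    priv <- setdiff(k1, kr)
    gard <- gm_subset(gar$gm,
                      individuals = names(gar$partition$origin)[
                        gar$partition$origin == "garden"])
    kg <- paste(rep(loci(gard), lengths(allele_labels(gard))),
                unlist(allele_labels(gard)))
    mean(priv %in% kg)
  }
  strat <- sample_garden(sim$gm, sim$partition, scheme = "stratified",
                         size = 30, seed = 23)
  skew <- sample_garden(sim$gm, sim$partition, scheme = "skewed",
                        size = 30, weights = c(pop1 = 0, pop2 = 1,
                                               pop3 = 1), seed = 23)
  expect_lt(capture_rate_of_pop1_private(skew),
            capture_rate_of_pop1_private(strat))
  expect_equal(capture_rate_of_pop1_private(skew), 0) # no pop1 founders
})

test_that("missingness injection hits the target rate and R80 reacts", {
  gm <- random_gm(n = 50, L = 60, k = 3, miss = 0, seed = 24)
  expect_identical(inject_missingness(gm, 0), gm)
  gm3 <- inject_missingness(gm, 0.3, heterogeneity = 20, seed = 25)
  expect_lt(abs(mean(is.na(gm3$a1)) - 0.3), 0.05)
  expect_equal(n_loci(apply_missing_filter(gm3, 0)), 60)
  expect_lt(n_loci(apply_missing_filter(gm3, 0.8)), 60)
})

test_that("error alleles are sample-private singletons in the rare class", {
  cfg <- sim_config(regime = "biallelic", n_loci = 300, n_populations = 2,
                    n_per_pop = 50, garden_size = 30, seed = 26)
  sim <- simulate_dataset(cfg)
  gme <- inject_error_alleles(sim$gm, 0.01, seed = 27)
  truth <- attr(gme, "error_truth")
  expect_gt(nrow(truth), 0)
  expect_false(any(duplicated(truth$allele)))
  fr <- wild_allele_frequencies(gme, sim$partition)
  wild_err <- fr[fr$allele %in% truth$allele, ]
  # every wild-side artifact is a singleton: frequency 1/(2 * typed) < 1%
  expect_true(all(wild_err$count == 1))
  expect_true(all(wild_err$freq < 0.01))
  expect_identical(inject_error_alleles(sim$gm, 0.01, seed = 27)$a1, gme$a1)
  gm0 <- inject_error_alleles(sim$gm, 0)
  expect_identical(gm0$a1, sim$gm$a1)
})

test_that("artifact loci are unshared and pruned by any presence filter", {
  cfg <- sim_config(regime = "biallelic", n_loci = 200, n_populations = 2,
                    n_per_pop = 30, garden_size = 20, seed = 28)
  sim <- simulate_dataset(cfg)
  gma <- inject_artifact_loci(sim$gm, 0.02, seed = 29)
  truth <- attr(gma, "artifact_truth")
  expect_gt(nrow(truth), 0)
  pres <- colSums(!is.na(gma$a1[, truth$locus, drop = FALSE]))
  expect_true(all(pres == 1)) # typed only in the originating sample
  # R80 removes every artifact locus, R0 none
  expect_equal(n_loci(apply_missing_filter(gma, 0)), n_loci(gma))
  kept <- loci(apply_missing_filter(gma, 0.8))
  expect_false(any(truth$locus %in% kept))
  expect_true(all(loci(sim$gm) %in% kept))
})
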