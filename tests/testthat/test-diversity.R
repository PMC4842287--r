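test_that("forced heterozygosity gives Ho = 1 and the unbiased He", {
  n <- 8L
  g <- list(L1 = matrix(c(1L, 2L), n, 2, byrow = TRUE),
            L2 = rbind(matrix(c(5L, 6L), n - 1L, 2, byrow = TRUE),
                       c(5L, 5L)))  # second locus keeps the panel polymorphic
  pop <- adults_pop(g)
  s <- summarize_diversity(pop, "father")
  l1 <- s$per_locus[s$per_locus$locus == "L1", ]
  expect_equal(l1$Ho, 1)
  expect_equal(l1$He, 2 * n / (2 * n - 1) * 0.5)
  expect_lt(l1$F, 0)
})

test_that("monomorphic loci are excluded from the indices but reported", {
  g <- list(L1 = matrix(c(1L, 1L), 6, 2, byrow = TRUE),       # monomorphic
            L2 = matrix(c(1L, 2L), 6, 2, byrow = TRUE))
  pop <- adults_pop(g)
  s <- summarize_diversity(pop, "father")
  expect_equal(s$excluded_loci, "L1")
  expect_equal(s$k, 2L)     # only the polymorphic locus contributes alleles
  expect_equal(s$A, 2)
})

test_that("summary matches a brute-force per-locus tally on simulated data", {
  sim <- simulate_population(sim_config(rng_seed = 21, n_adults = 20L,
                                        n_mothers = 2L, offspring_per_mother = 2L))
  s <- summarize_diversity(sim$pop, "adult")
  mask <- cohort_mask(sim$pop, "adult")
  sHo <- 0; sHe <- 0
  for (l in seq_along(sim$pop$loci)) {
    a <- sim$pop$geno[mask, 2 * l - 1]; b <- sim$pop$geno[mask, 2 * l]
    ok <- !is.na(a)
    n <- sum(ok)
    p <- as.numeric(table(c(a[ok], b[ok]))) / (2 * n)
    Ho <- mean(a[ok] != b[ok])
    He <- 2 * n / (2 * n - 1) * (1 - sum(p^2))
    row <- s$per_locus[l, ]
    expect_equal(row$Ho, Ho, tolerance = 1e-12)
    expect_equal(row$He, He, tolerance = 1e-12)
    if (!(sim$pop$loci[l] %in% s$excluded_loci)) { sHo <- sHo + Ho; sHe <- sHe + He }
  }
  expect_equal(s$F, 1 - sHo / sHe, tolerance = 1e-12)
})

test_that("summaries are invariant to individual order and allele relabeling", {
  sim <- simulate_population(sim_config(rng_seed = 13, n_adults = 30L,
                                        n_mothers = 3L, offspring_per_mother = 2L))
  s1 <- summarize_diversity(sim$pop, "adult")
  perm <- sample(nrow(sim$pop$ind))
  pop2 <- pollen_pop(sim$pop$ind[perm, ], sim$pop$geno[perm, ], sim$pop$loci)
  s2 <- summarize_diversity(pop2, "adult")
  expect_equal(s2$He, s1$He)
  expect_equal(s2$F, s1$F)
  # relabel alleles at every locus (order-preserving shift keeps pairs sorted)
  pop3 <- sim$pop
  pop3$geno <- pop3$geno + 1000L
  s3 <- summarize_diversity(pop3, "adult")
  expect_equal(s3$He, s1$He)
  expect_equal(s3$Ho, s1$Ho)
})

test_that("private alleles are a set difference over cohort allele sets", {
  g <- list(L1 = rbind(c(1L, 2L), c(1L, 1L), c(1L, 2L), c(1L, 1L)))
  pop <- adults_pop(g)
  pop$ind$cohort <- c("father", "father", "mother", "mother")
  pop <- pollen_pop(pop$ind, pop$geno, pop$loci)
  expect_equal(unname(private_alleles(pop, "father", "mother")), c(0L, 0L))

  g2 <- list(L1 = rbind(c(1L, 211L), c(1L, 1L), c(1L, 2L), c(1L, 2L)))
  pop2 <- adults_pop(g2)
  pop2$ind$cohort <- c("father", "father", "mother", "mother")
  pop2 <- pollen_pop(pop2$ind, pop2$geno, pop2$loci)
  expect_equal(unname(private_alleles(pop2, "father", "mother")), c(1L, 1L))

  sim <- simulate_population(sim_config(rng_seed = 31))
  pr <- private_alleles(sim$pop, "adult", "offspring")
  am <- cohort_mask(sim$pop, "adult"); om <- cohort_mask(sim$pop, "offspring")
  expA <- 0L; expB <- 0L
  for (l in seq_along(sim$pop$loci)) {
    j <- 2 * l - 1
    sa <- unique(na.omit(c(sim$pop$geno[am, j], sim$pop$geno[am, j + 1])))
    sb <- unique(na.omit(c(sim$pop$geno[om, j], sim$pop$geno[om, j + 1])))
    expA <- expA + length(setdiff(sa, sb))
    expB <- expB + length(setdiff(sb, sa))
  }
  expect_equal(unname(pr), c(expA, expB))
})

test_that("fixation permutation test flags a forced heterozygote excess", {
  g <- list(L1 = matrix(c(1L, 2L), 6, 2, byrow = TRUE),
            L2 = matrix(c(3L, 4L), 6, 2, byrow = TRUE))
  pop <- adults_pop(g)
  res <- test_fixation(pop, "father", n_perm = 1000L, seed = 4)
  expect_lt(res$F_obs, 0)
  expect_lt(res$p_value, 0.05)
  expect_true(all(res$per_locus$p_bonferroni >= res$per_locus$p))
  expect_error(test_fixation(pop, "father", n_perm = 0), ">= 100")
})

test_that("cohort comparison takes the pooled branch on identical vectors", {
  sim <- simulate_population(sim_config(rng_seed = 19))
  sa <- summarize_diversity(sim$pop, "adult")
  cmp <- compare_cohorts(sa, sa)
  expect_true(all(cmp$t_stat == 0))
  expect_true(all(cmp$t_p == 1))
})

test_that("gross variance heterogeneity routes to the Welch branch", {
  sim <- simulate_population(sim_config(rng_seed = 23))
  sa <- summarize_diversity(sim$pop, "adult")
  sb <- summarize_diversity(sim$pop, "offspring")
  # inflate one cohort's per-locus spread 10-fold around its mean
  sb$per_locus$Ho <- mean(sb$per_locus$Ho) +
    10 * (sb$per_locus$Ho - mean(sb$per_locus$Ho)) + seq(-.2, .2, length.out = 10)
  cmp <- compare_cohorts(sa, sb)
  ho <- cmp[cmp$index == "Ho", ]
  expect_lt(ho$F_p, 0.05)
  expect_true(ho$welch)
})

test_that("adults and offspring of the default simulation do not differ", {
  # distributional check: across replicates the cohort contrasts reject at
  # roughly the nominal rate, i.e. the generations are exchangeable
  rej <- 0L; total <- 0L
  for (sd in c(29, 1, 7, 13, 101)) {
    sim <- simulate_population(sim_config(rng_seed = sd))
    cmp <- compare_cohorts(summarize_diversity(sim$pop, "adult"),
                           summarize_diversity(sim$pop, "offspring"))
    rej <- rej + sum(cmp$t_p < 0.05)
    total <- total + nrow(cmp)
  }
  expect_lte(rej / total, 0.15)
})
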