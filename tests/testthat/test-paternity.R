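test_that("Mendelian transition probabilities enumerate correctly", {
  expect_equal(transition_probability(c(1, 2), c(1, 1), c(2, 2)), 1)
  expect_equal(transition_probability(c(1, 1), c(1, 2), c(1, 2)), 0.25)
  expect_equal(transition_probability(c(1, 2), c(1, 2), c(1, 2)), 0.5)
  expect_equal(transition_probability(c(3, 4), c(1, 2), c(3, 4)), 0)
})

test_that("transition probabilities sum to one over offspring genotypes for every parental pair", {
  alleles <- 1:4
  genos <- list()
  for (i in alleles) for (j in alleles[alleles >= i]) genos <- c(genos, list(c(i, j)))
  for (gm in genos) for (gf in genos) {
    tot <- sum(vapply(genos, function(go)
      transition_probability(go, gm, gf), 0))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("LOD scores follow the paternal-allele-frequency formulation", {
  fr <- make_freqs(L1 = c(`1` = 0.5, `2` = 0.5))
  # off A/B, mother A/A, candidate B/B: T = 1, denominator = p_B = 0.5
  expect_equal(lod_score(c(1L, 2L), c(1L, 1L), c(2L, 2L), fr), log(2))
  # excluded candidate at one locus
  expect_identical(lod_score(c(1L, 1L), c(1L, 1L), c(2L, 2L), fr), -Inf)
  # candidate untyped: locus contributes zero
  expect_equal(lod_score(c(1L, 2L), c(1L, 1L), c(NA, NA), fr), 0)
})

test_that("the true father outscores a random non-father in most trios", {
  sim <- simulate_population(sim_config(rng_seed = 71, migration_mp = 0))
  fr <- allele_frequencies(sim$pop, "adult")
  off <- which(cohort_mask(sim$pop, "offspring"))
  wins <- 0L; total <- 0L
  set.seed(1)
  adults <- sim$pop$ind$id[cohort_mask(sim$pop, "adult")]
  for (i in off) {
    oid <- sim$pop$ind$id[i]
    tf <- sim$truth$true_father[sim$truth$offspring_id == oid]
    mrow <- match(sim$pop$ind$mother_id[i], sim$pop$ind$id)
    other <- sample(setdiff(adults, c(tf, sim$pop$ind$mother_id[i])), 1)
    l_t <- lod_score(sim$pop$geno[i, ], sim$pop$geno[mrow, ],
                     sim$pop$geno[match(tf, sim$pop$ind$id), ], fr)
    l_o <- lod_score(sim$pop$geno[i, ], sim$pop$geno[mrow, ],
                     sim$pop$geno[match(other, sim$pop$ind$id), ], fr)
    total <- total + 1L
    if (l_t > l_o) wins <- wins + 1L
  }
  expect_gte(wins / total, 0.95)
})

test_that("second-parent exclusion matches exhaustive trio enumeration", {
  cases <- list(c(0.5, 0.5), c(0.2, 0.8), c(0.3, 0.3, 0.4),
                c(0.1, 0.2, 0.3, 0.4))
  for (p in cases) {
    names(p) <- seq_along(p)
    fr <- make_freqs(L = p)
    q2 <- exclusion_probability(fr)$per_locus[["L"]]
    expect_equal(q2, q2_enumerate(unname(p)), tolerance = 1e-12)
  }
  # monomorphic locus can exclude nobody
  expect_equal(exclusion_probability(make_freqs(L = c(`1` = 1)))$per_locus[["L"]], 0)
})

test_that("combined exclusion is one minus the product of per-locus complements", {
  sim <- simulate_population(sim_config(rng_seed = 73))
  fr <- allele_frequencies(sim$pop, "adult")
  ex <- exclusion_probability(fr)
  expect_equal(ex$P2p, 1 - prod(1 - ex$per_locus), tolerance = 1e-12)
  expect_gte(ex$P2p, max(ex$per_locus))
  expect_true(all(ex$per_locus >= 0 & ex$per_locus <= 1))
})

test_that("the Delta critical value is monotone in confidence and can be unattainable", {
  sim <- simulate_population(sim_config(rng_seed = 79))
  fr <- allele_frequencies(sim$pop, "adult")
  ds <- vapply(c(0.6, 0.8, 0.95), function(cf)
    delta_criterion(fr, n_sim = 2000L, prop_sampled = 0.6,
                    n_candidates = 50L, confidence = cf,
                    seed = 123)$delta_star, 0)
  expect_true(all(diff(ds) >= 0))

  # three weak biallelic loci cannot support near-certain assignment
  weak <- make_freqs(L1 = c(`1` = .5, `2` = .5), L2 = c(`1` = .5, `2` = .5),
                     L3 = c(`1` = .5, `2` = .5))
  expect_warning(
    res <- delta_criterion(weak, n_sim = 1000L, prop_sampled = 0.6,
                           n_candidates = 100L, confidence = 0.9999,
                           seed = 5),
    "unattainable")
  expect_identical(res$delta_star, Inf)
})

test_that("fully sampled fathers with many informative loci need almost no Delta margin", {
  sim <- simulate_population(sim_config(rng_seed = 83))
  fr <- allele_frequencies(sim$pop, "adult")
  dc <- delta_criterion(fr, n_sim = 2000L, prop_sampled = 1,
                        n_candidates = 124L, confidence = 0.8, seed = 11)
  expect_lt(dc$delta_star, 1)
})

test_that("assignment never names a Mendelian-mismatched candidate at zero error", {
  sim <- simulate_population(sim_config(rng_seed = 89, migration_mp = 0.15))
  fr <- allele_frequencies(sim$pop, "adult")
  dc <- delta_criterion(fr, n_sim = 1000L, n_candidates = 124L, seed = 13)
  pat <- assign_paternity(sim$pop, dc$delta_star, freqs = fr)
  a <- pat$assignments
  assigned <- !is.na(a$father) & a$father != "MIGRANT"
  for (i in which(assigned)) {
    orow <- match(a$offspring_id[i], sim$pop$ind$id)
    mrow <- match(a$mother_id[i], sim$pop$ind$id)
    frow <- match(a$father[i], sim$pop$ind$id)
    lod <- lod_score(sim$pop$geno[orow, ], sim$pop$geno[mrow, ],
                     sim$pop$geno[frow, ], fr)
    expect_true(is.finite(lod))
  }
})

test_that("selfed offspring are detected and counted", {
  sim <- simulate_population(sim_config(rng_seed = 97, selfing_s = 0.3,
                                        migration_mp = 0))
  fr <- allele_frequencies(sim$pop, "adult")
  dc <- delta_criterion(fr, n_sim = 1000L, n_candidates = 124L, seed = 17)
  pat <- assign_paternity(sim$pop, dc$delta_star, freqs = fr)
  n_true_self <- sum(sim$truth$true_father == "SELF")
  expect_gt(pat$s_obs, 0)
  expect_lte(abs(pat$s_obs - n_true_self), 0.25 * n_true_self + 3)
})

test_that("pollen-flow count arithmetic aggregates per-mother rates", {
  pf <- pollen_flow_from_counts(Np = c(10L, 5L), Nm = c(1L, 0L))
  expect_equal(pf$per_mother$mp_pct, c(10, 0))
  expect_equal(pf$mp_total_pct, 100 / 15)
  expect_equal(pf$assignment_rate_pct, 100 * 14 / 15)
  expect_error(pollen_flow_from_counts(Np = 2L, Nm = 3L))
})
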