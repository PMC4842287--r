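test_that("the exponential-power kernel integrates to one over the plane", {
  for (par in list(c(20, 0.9), c(50, 2), c(5, 0.5))) {
    tot <- integrate(kernel_rdensity, 0, Inf, a = par[1], b = par[2],
                     rel.tol = 1e-10)$value
    expect_equal(tot, 1, tolerance = 1e-8)
  }
  expect_error(kernel_pdf(1, -2, 1), "positive")
})

test_that("kernel mean recovers the exponential and Gaussian special cases", {
  expect_equal(kernel_mean(20, 1), 40, tolerance = 1e-12)
  expect_equal(kernel_mean(30, 2), 30 * sqrt(pi) / 2, tolerance = 1e-12)
  # generic case agrees with numerical first moment of the distance density
  m <- integrate(function(r) r * kernel_rdensity(r, 20, 0.9), 0, Inf,
                 rel.tol = 1e-10)$value
  expect_equal(kernel_mean(20, 0.9), m, tolerance = 1e-8)
})

test_that("kernel distance sampler matches the analytic mean", {
  set.seed(1)
  d <- kernel_rdistance(20000, 20, 0.9)
  expect_lt(abs(mean(d) - kernel_mean(20, 0.9)) / kernel_mean(20, 0.9), 0.03)
})

test_that("effective neighborhood area follows Aep = 2 pi sigma^2", {
  en <- effective_neighborhood(49)
  expect_equal(en$aep_ha, 2 * pi * 49^2 / 1e4, tolerance = 1e-12)
  expect_equal(en$r_ep, 49 * sqrt(2), tolerance = 1e-12)
})

test_that("dispersal summary reduces the KS distance to zero on identical distributions", {
  # one mother; every other adult sires exactly one offspring, so realized
  # dispersal distances equal the mother-to-candidate reference distances
  n_f <- 12L
  ind <- data.frame(
    id = c(sprintf("F%02d", 1:n_f), "M01", sprintf("O%02d", 1:n_f)),
    cohort = c(rep("father", n_f), "mother", rep("offspring", n_f)),
    mother_id = c(rep(NA, n_f + 1L), rep("M01", n_f)),
    x = c(10 * (1:n_f), 0, rep(NA, n_f)),
    y = c(rep(0, n_f), 0, rep(NA, n_f)), stringsAsFactors = FALSE)
  geno <- matrix(1L, nrow(ind), 2, dimnames = list(NULL, c("L1_1", "L1_2")))
  pop <- pollen_pop(ind, geno)
  pat <- structure(list(assignments = data.frame(
    offspring_id = sprintf("O%02d", 1:n_f), mother_id = "M01",
    father = sprintf("F%02d", 1:n_f), selfing = FALSE,
    distance_m = 10 * (1:n_f), mother_compatible = TRUE,
    stringsAsFactors = FALSE)), class = "paternity_result")
  ds <- dispersal_summary(pat, pop)
  expect_equal(ds$ks_D, 0, tolerance = 1e-12)
  expect_equal(ds$ks_p, 1, tolerance = 1e-9)
  expect_equal(ds$mean, mean(10 * (1:n_f)))
  # axial convention halves the raw second moment
  ds2 <- dispersal_summary(pat, pop, sigma_convention = "axial")
  expect_equal(ds2$sigma_p2, sum((10 * (1:n_f))^2) / (2 * n_f))
})

test_that("simulated exponential matings have mean distance near 2a", {
  set.seed(2)
  d <- unlist(lapply(1:2, function(r) {
    sim <- simulate_population(sim_config(rng_seed = 400L + r, n_loci = 2L,
                                          migration_mp = 0, kernel_shape_b = 1,
                                          plot_width = 700, plot_height = 700,
                                          n_adults = 2500, n_mothers = 12,
                                          offspring_per_mother = 15))
    sim$truth$distance_m
  }))
  expect_lt(abs(mean(d) - 40) / 40, 0.2)
})

test_that("with s and m_p fixed at zero and one candidate the likelihood collapses", {
  # single candidate father: log-likelihood must equal the summed log
  # transition probabilities, independent of the kernel parameters
  set.seed(9)
  n_loci <- 5L
  loci <- sprintf("L%02d", 1:n_loci)
  gm <- matrix(sort(rep(1:2, n_loci))[1:(2 * n_loci)], 1)  # mother 1/1...
  gm <- matrix(rep(c(1L, 2L), n_loci), 1)
  gf <- matrix(rep(c(3L, 4L), n_loci), 1)
  n_off <- 6L
  og <- t(vapply(seq_len(n_off), function(i)
    mendelian_offspring(gm[1, ], gf[1, ]), integer(2 * n_loci)))
  ind <- data.frame(
    id = c("F1", "M1", sprintf("O%d", 1:n_off)),
    cohort = c("father", "mother", rep("offspring", n_off)),
    mother_id = c(NA, NA, rep("M1", n_off)),
    x = c(30, 0, rep(NA, n_off)), y = 0, stringsAsFactors = FALSE)
  geno <- rbind(gf, gm, og)
  colnames(geno) <- paste0(rep(loci, each = 2), c("_1", "_2"))
  pop <- pollen_pop(ind, geno, loci)
  km1 <- fit_neighborhood_model(pop, fix = c(s = 0, m_p = 0, a = 10, b = 1))
  km2 <- fit_neighborhood_model(pop, fix = c(s = 0, m_p = 0, a = 80, b = 0.4))
  expect_equal(km1$logL, km2$logL, tolerance = 1e-9)
  lT <- sum(vapply(seq_len(n_off), function(i) {
    sum(vapply(seq_len(n_loci), function(l) {
      j <- 2 * l - 1
      log(transition_probability(og[i, j:(j + 1)], gm[1, j:(j + 1)],
                                 gf[1, j:(j + 1)]))
    }, 0))
  }, 0))
  expect_equal(km1$logL, lT, tolerance = 1e-9)
})

test_that("the fitted model is at a likelihood optimum", {
  sim <- simulate_population(sim_config(rng_seed = 42, selfing_s = 0,
                                        migration_mp = 0.10, kernel_shape_b = 1,
                                        offspring_per_mother = 10))
  fr <- allele_frequencies(sim$pop, "adult")
  km <- fit_neighborhood_model(sim$pop, freqs = fr, starts = 3, seed = 3)
  at <- function(s, m_p, a, b)
    fit_neighborhood_model(sim$pop, freqs = fr,
                           fix = c(s = s, m_p = m_p, a = a, b = b))$logL
  expect_gte(km$logL + 1e-6, at(km$s, km$m_p, km$a * 1.3, km$b))
  expect_gte(km$logL + 1e-6, at(km$s, km$m_p, km$a, km$b * 1.4))
  expect_gte(km$logL + 1e-6, at(min(km$s + 0.05, 1), km$m_p, km$a, km$b))
  expect_gte(km$logL + 1e-6, at(km$s, min(km$m_p + 0.08, 1 - km$s), km$a, km$b))
})

test_that("increasing the true kernel scale increases the fitted mean dispersal", {
  fit_at <- function(a_true) {
    sim <- simulate_population(sim_config(rng_seed = 107, kernel_scale_a = a_true,
                                          kernel_shape_b = 1, migration_mp = 0.05))
    fit_neighborhood_model(sim$pop, starts = 3, seed = 5)$delta_mean
  }
  dm <- vapply(c(10, 30, 90), fit_at, 0)
  expect_true(all(diff(dm) > 0))
})

test_that("fat-tailed simulations are classified fat-tailed most of the time", {
  hits <- vapply(1:8, function(r) {
    sim <- simulate_population(sim_config(rng_seed = 500L + r,
                                          kernel_shape_b = 0.7,
                                          migration_mp = 0.05,
                                          offspring_per_mother = 15))
    fit_neighborhood_model(sim$pop, starts = 3, seed = r)$b < 1
  }, TRUE)
  expect_gte(mean(hits), 0.75)
})
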