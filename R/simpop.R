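#' Configuration for the synthetic-population simulator
#'
#' Defaults emulate a harvested Amazonian palm stand of roughly 8 ha:
#' 124 mapped reproductive adults (112 candidate fathers + 12 seed trees),
#' 10 offspring genotyped per seed tree, 10 polymorphic microsatellite loci
#' with 3-19 alleles each, no selfing (the species is protogynous), about 9%
#' migrant pollen, and insect pollination following a slightly fat-tailed
#' exponential-power kernel (scale 20 m, shape 0.9). Spatial genetic structure
#' from short seed dispersal can be induced by running `n_generations_sgs`
#' rounds of local recruitment (daughters placed a Gaussian step of sd
#' `seed_dispersal_sigma` from their mother).
#'
#' @param n_adults number of mapped reproductive adults.
#' @param plot_width,plot_height plot dimensions in meters (default 400 x 200
#'   = 8 ha).
#' @param n_loci number of microsatellite loci.
#' @param alleles_per_locus integer range (length 2) from which each locus's
#'   allele count is drawn uniformly.
#' @param n_mothers number of seed trees (sampled among the adults).
#' @param offspring_per_mother offspring genotyped per seed tree.
#' @param selfing_s probability an offspring is selfed.
#' @param migration_mp probability an offspring is sired by migrant pollen
#'   from outside the plot.
#' @param kernel_scale_a,kernel_shape_b exponential-power pollen kernel
#'   parameters (meters, dimensionless).
#' @param seed_dispersal_sigma sd (meters) of the Gaussian seed-dispersal step
#'   used when inducing spatial genetic structure.
#' @param n_generations_sgs number of local-recruitment rounds before sampling
#'   (0 = spatially random genotypes).
#' @param dirichlet_alpha symmetric Dirichlet concentration for founder
#'   allele frequencies. The default 0.3 gives the uneven spectra typical of
#'   microsatellite panels (a few common, many rare alleles); 1 gives a flat
#'   Dirichlet.
#' @param mistyping_rate per-allele uniform mistyping probability (default 0,
#'   the zero-genotyping-error regime).
#' @param rng_seed integer seed; the simulation is bit-reproducible given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_adults = 124L, plot_width = 400, plot_height = 200,
                       n_loci = 10L, alleles_per_locus = c(3L, 19L),
                       n_mothers = 12L, offspring_per_mother = 10L,
                       selfing_s = 0, migration_mp = 0.09,
                       kernel_scale_a = 20, kernel_shape_b = 0.9,
                       seed_dispersal_sigma = 20, n_generations_sgs = 0L,
                       dirichlet_alpha = 0.3, mistyping_rate = 0,
                       rng_seed = 1L) {
  cfg <- list(n_adults = as.integer(n_adults), plot_width = plot_width,
              plot_height = plot_height, n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              n_mothers = as.integer(n_mothers),
              offspring_per_mother = as.integer(offspring_per_mother),
              selfing_s = selfing_s, migration_mp = migration_mp,
              kernel_scale_a = kernel_scale_a,
              kernel_shape_b = kernel_shape_b,
              seed_dispersal_sigma = seed_dispersal_sigma,
              n_generations_sgs = as.integer(n_generations_sgs),
              dirichlet_alpha = dirichlet_alpha,
              mistyping_rate = mistyping_rate,
              rng_seed = as.integer(rng_seed))
  if (cfg$selfing_s + cfg$migration_mp > 1) stop("selfing_s + migration_mp must be <= 1")
  if (cfg$selfing_s < 0 || cfg$migration_mp < 0) stop("probabilities must be >= 0")
  if (cfg$plot_width <= 0 || cfg$plot_height <= 0) stop("degenerate plot")
  if (cfg$kernel_scale_a <= 0 || cfg$kernel_shape_b <= 0) stop("kernel parameters must be positive")
  if (cfg$n_adults < 2L || cfg$n_mothers < 1L || cfg$n_loci < 1L ||
      cfg$offspring_per_mother < 1L) stop("counts must be >= 1 (and n_adults >= 2)")
  if (cfg$n_mothers > cfg$n_adults) stop("n_mothers cannot exceed n_adults")
  if (length(cfg$alleles_per_locus) != 2L || any(cfg$alleles_per_locus < 2L)) {
    stop("alleles_per_locus must be a range with minimum >= 2")
  }
  if (cfg$dirichlet_alpha <= 0) stop("dirichlet_alpha must be positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulator configuration from YAML
#'
#' Fields mirror [sim_config()] arguments; absent fields keep their defaults.
#'
#' @param path YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(sim_config, y)
}

# one random gamete (allele index into geno columns for locus l) per parent row
.draw_gamete <- function(geno, rows, l) {
  pick <- sample(c(0L, 1L), length(rows), replace = TRUE)
  geno[cbind(rows, 2L * l - 1L + pick)]
}

#' Mendelian offspring genotype
#'
#' Each locus receives one allele from each parent, chosen uniformly.
#' Loci where a parent is missing come out missing (handled upstream for
#' migrant fathers, whose gametes are drawn from background frequencies).
#'
#' @param mother_g,father_g integer vectors of length `2 * n_loci`
#'   (`<locus>_1`,`<locus>_2` layout) as stored in a `pollen_pop`.
#' @return Offspring genotype vector in the same layout, pairs sorted.
#' @export
mendelian_offspring <- function(mother_g, father_g) {
  n_loci <- length(mother_g) %/% 2L
  out <- integer(2L * n_loci)
  for (l in seq_len(n_loci)) {
    j <- 2L * l - 1L
    ma <- mother_g[j:(j + 1L)][sample.int(2L, 1L)]
    pa <- father_g[j:(j + 1L)][sample.int(2L, 1L)]
    out[j] <- min(ma, pa); out[j + 1L] <- max(ma, pa)
  }
  out
}

#' Simulate a mapped, genotyped palm population with known parentage
#'
#' Adults are placed uniformly on the plot (or via local-recruitment rounds
#' inducing isolation by distance when `n_generations_sgs > 0`); founder
#' genotypes are drawn in Hardy-Weinberg proportions from Dirichlet(1) allele
#' frequencies. Each offspring's sire is drawn by the three-way mating
#' mixture: selfing with probability `selfing_s`, migrant pollen with
#' probability `migration_mp`, otherwise a within-plot male sampled with
#' probability proportional to the exponential-power kernel density at his
#' distance from the mother. Migrant paternal gametes are drawn from the
#' background (founder) allele frequencies.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{pop}{the simulated [pollen_pop()] (fathers, mothers, offspring)}
#'     \item{truth}{data.frame `offspring_id,true_father,distance_m` where
#'       `true_father` is an adult id, `"MIGRANT"` or `"SELF"`}
#'     \item{params}{the true parameter vector (s, m_p, a, b)}
#'     \item{background_freqs}{founder allele frequencies used for migrants}
#'     \item{config}{the configuration used}
#'   }
#' @export
simulate_population <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$rng_seed)
  n <- cfg$n_adults
  loci <- sprintf("L%02d", seq_len(cfg$n_loci))

  # founder allele frequencies: Dirichlet(1) over k ~ U{range} alleles,
  # labels spaced like microsatellite fragment sizes
  bg <- lapply(seq_len(cfg$n_loci), function(l) {
    k <- sample(seq(cfg$alleles_per_locus[1L], cfg$alleles_per_locus[2L]), 1L)
    w <- stats::rgamma(k, cfg$dirichlet_alpha)
    list(freq = stats::setNames(w / sum(w), 100L + 2L * seq_len(k)),
         alleles = 100L + 2L * seq_len(k), n_copies = NA_integer_)
  })
  names(bg) <- loci
  class(bg) <- "allele_freqs"

  draw_hwe <- function(m) {    # m individuals, HWE from background freqs
    g <- matrix(NA_integer_, m, 2L * cfg$n_loci)
    for (l in seq_len(cfg$n_loci)) {
      a <- sample(bg[[l]]$alleles, m, TRUE, prob = bg[[l]]$freq)
      b <- sample(bg[[l]]$alleles, m, TRUE, prob = bg[[l]]$freq)
      g[, 2L * l - 1L] <- pmin(a, b); g[, 2L * l] <- pmax(a, b)
    }
    g
  }

  xy <- cbind(stats::runif(n, 0, cfg$plot_width),
              stats::runif(n, 0, cfg$plot_height))
  geno <- draw_hwe(n)

  reflect <- function(v, lim) {   # keep recruits inside the plot
    v <- abs(v)
    v <- lim - abs(lim - v %% (2 * lim))
    v
  }
  if (cfg$n_generations_sgs > 0L) {
    for (gen in seq_len(cfg$n_generations_sgs)) {
      moms <- sample.int(n, n, replace = TRUE)
      # sire for each recruit: kernel-weighted among adults other than mother
      D <- as.matrix(stats::dist(xy))
      K <- kernel_pdf(D, cfg$kernel_scale_a, cfg$kernel_shape_b)
      diag(K) <- 0
      dads <- vapply(moms, function(i) sample.int(n, 1L, prob = K[i, ]), 1L)
      newxy <- cbind(reflect(xy[moms, 1L] + stats::rnorm(n, 0, cfg$seed_dispersal_sigma),
                             cfg$plot_width),
                     reflect(xy[moms, 2L] + stats::rnorm(n, 0, cfg$seed_dispersal_sigma),
                             cfg$plot_height))
      newg <- matrix(NA_integer_, n, 2L * cfg$n_loci)
      for (l in seq_len(cfg$n_loci)) {
        ma <- .draw_gamete(geno, moms, l)
        pa <- .draw_gamete(geno, dads, l)
        newg[, 2L * l - 1L] <- pmin(ma, pa); newg[, 2L * l] <- pmax(ma, pa)
      }
      xy <- newxy; geno <- newg
    }
  }

  mother_rows <- sort(sample.int(n, cfg$n_mothers))
  adult_ids <- sprintf("A%03d", seq_len(n))
  adult_ids[mother_rows] <- sprintf("M%03d", seq_len(cfg$n_mothers))
  cohort <- rep("father", n)
  cohort[mother_rows] <- "mother"

  n_off <- cfg$n_mothers * cfg$offspring_per_mother
  off_id <- character(n_off); off_mother <- character(n_off)
  off_geno <- matrix(NA_integer_, n_off, 2L * cfg$n_loci)
  true_father <- character(n_off); true_dist <- rep(NA_real_, n_off)

  D_all <- as.matrix(stats::dist(xy))
  k <- 0L
  for (mi in seq_len(cfg$n_mothers)) {
    mrow <- mother_rows[mi]
    w <- kernel_pdf(D_all[mrow, ], cfg$kernel_scale_a, cfg$kernel_shape_b)
    w[mrow] <- 0                      # selfing is its own mixture component
    for (o in seq_len(cfg$offspring_per_mother)) {
      k <- k + 1L
      off_id[k] <- sprintf("%s-O%02d", adult_ids[mrow], o)
      off_mother[k] <- adult_ids[mrow]
      u <- stats::runif(1)
      if (u < cfg$selfing_s) {
        frow <- mrow; true_father[k] <- "SELF"; true_dist[k] <- 0
        off_geno[k, ] <- mendelian_offspring(geno[mrow, ], geno[frow, ])
      } else if (u < cfg$selfing_s + cfg$migration_mp) {
        true_father[k] <- "MIGRANT"
        fg <- draw_hwe(1L)[1L, ]      # migrant gamete from background freqs
        off_geno[k, ] <- mendelian_offspring(geno[mrow, ], fg)
      } else {
        frow <- sample.int(n, 1L, prob = w)
        true_father[k] <- adult_ids[frow]
        true_dist[k] <- D_all[mrow, frow]
        off_geno[k, ] <- mendelian_offspring(geno[mrow, ], geno[frow, ])
      }
    }
  }

  if (cfg$mistyping_rate > 0) {
    flip <- which(stats::runif(length(off_geno)) < cfg$mistyping_rate)
    for (j in flip) {
      l <- (j - 1L) %/% nrow(off_geno)  # column index - 1
      l <- l %/% 2L + 1L
      off_geno[j] <- sample(bg[[l]]$alleles, 1L, prob = bg[[l]]$freq)
    }
  }

  ind <- data.frame(
    id = c(adult_ids, off_id),
    cohort = c(cohort, rep("offspring", n_off)),
    mother_id = c(rep(NA_character_, n), off_mother),
    x = c(xy[, 1L], rep(NA_real_, n_off)),
    y = c(xy[, 2L], rep(NA_real_, n_off)),
    stringsAsFactors = FALSE)
  pop <- pollen_pop(ind, rbind(geno, off_geno), loci)

  list(pop = pop,
       truth = data.frame(offspring_id = off_id, true_father = true_father,
                          distance_m = true_dist, stringsAsFactors = FALSE),
       params = c(s = cfg$selfing_s, m_p = cfg$migration_mp,
                  a = cfg$kernel_scale_a, b = cfg$kernel_shape_b),
       background_freqs = bg,
       config = cfg)
}

#' Write simulator outputs to disk
#'
#' Emits `genotypes.csv`, `coords.csv` and `truth.csv`
#' (`offspring_id,true_father,distance_m`) into a directory.
#'
#' @param sim result of [simulate_population()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_population(sim$pop, file.path(dir, "genotypes.csv"),
                   file.path(dir, "coords.csv"))
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
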