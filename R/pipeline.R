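#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed; each stochastic stage derives its own seed from
#'   it, so identical configurations give identical outputs.
#' @param genotype_file,coords_file input tables; when `NULL` a population is
#'   simulated from `sim` instead.
#' @param sim a [sim_config()] for the simulated-input case.
#' @param n_perm_fixation,n_perm_sgs permutation counts for the fixation
#'   test and the SGS correlogram.
#' @param n_classes SGS distance classes.
#' @param paternity_sims,prop_sampled,confidence Delta-criterion settings.
#' @param kernel_starts optimizer starts for the neighborhood model.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("polliflow_run_"), seed = 1L,
                       genotype_file = NULL, coords_file = NULL,
                       sim = sim_config(rng_seed = seed),
                       n_perm_fixation = 1000L, n_perm_sgs = 10000L,
                       n_classes = 10L, paternity_sims = 10000L,
                       prop_sampled = 0.60, confidence = 0.80,
                       kernel_starts = 5L) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              genotype_file = genotype_file, coords_file = coords_file,
              sim = sim, n_perm_fixation = as.integer(n_perm_fixation),
              n_perm_sgs = as.integer(n_perm_sgs),
              n_classes = as.integer(n_classes),
              paternity_sims = as.integer(paternity_sims),
              prop_sampled = prop_sampled, confidence = confidence,
              kernel_starts = as.integer(kernel_starts))
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; a `sim:` block is passed to [sim_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Stages: load or simulate the population, per-cohort diversity summaries
#' with the fixation-index permutation test and cohort comparison, the
#' adult SGS correlogram with Sp, group coancestry and effective size,
#' Delta-criterion paternity with pollen-flow summaries, the dispersal
#' summary, and the neighborhood-model kernel fit. Tabular outputs
#' (`diversity.tsv`, `correlogram.tsv`, `pollen_flow.tsv`, `kernel.tsv`)
#' and a `metrics.json` bundle are written to `cfg$out_dir`.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, the metrics list.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_seed <- function(k) (cfg$seed * 1000003L + k * 7919L) %% 2147483647L
  log_stage <- function(name, t0) {
    message(sprintf("[polliflow] %-10s seed=%d  %.1fs", name, cfg$seed,
                    as.numeric(proc.time()[3L] - t0)))
  }

  t0 <- proc.time()[3L]
  if (!is.null(cfg$genotype_file)) {
    for (f in c(cfg$genotype_file, cfg$coords_file)) {
      if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
    }
    pop <- read_population(cfg$genotype_file, cfg$coords_file)
    truth <- NULL
  } else {
    simres <- simulate_population(cfg$sim)
    pop <- simres$pop
    truth <- simres$truth
  }
  log_stage("input", t0)

  t0 <- proc.time()[3L]
  div_a <- summarize_diversity(pop, "adult")
  div_o <- summarize_diversity(pop, "offspring")
  fix_a <- test_fixation(pop, "adult", cfg$n_perm_fixation,
                         seed = stage_seed(1L))
  fix_o <- test_fixation(pop, "offspring", cfg$n_perm_fixation,
                         seed = stage_seed(2L))
  priv <- private_alleles(pop, "adult", "offspring")
  cmp <- compare_cohorts(div_a, div_o)
  freqs_ad <- allele_frequencies(pop, "adult")
  excl <- exclusion_probability(freqs_ad)
  div_tab <- data.frame(
    cohort = c("adults", "offspring"),
    n = c(div_a$n, div_o$n), k = c(div_a$k, div_o$k),
    Ap = c(priv[["a"]], priv[["b"]]), A = c(div_a$A, div_o$A),
    He = c(div_a$He, div_o$He), Ho = c(div_a$Ho, div_o$Ho),
    F = c(div_a$F, div_o$F),
    F_p_value = c(fix_a$p_value, fix_o$p_value),
    P2p = c(excl$P2p, NA))
  utils::write.table(div_tab, file.path(cfg$out_dir, "diversity.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log_stage("diversity", t0)

  t0 <- proc.time()[3L]
  kin <- loiselle_kinship(pop, "adult")
  cg <- build_correlogram(kin, n_classes = cfg$n_classes,
                          n_perm = cfg$n_perm_sgs, seed = stage_seed(3L))
  utils::write.table(cg$classes, file.path(cfg$out_dir, "correlogram.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log_stage("sgs", t0)

  t0 <- proc.time()[3L]
  eff <- effective_size_report(pop, "adult")
  log_stage("effsize", t0)

  t0 <- proc.time()[3L]
  n_cand <- sum(cohort_mask(pop, "adult"))
  dc <- delta_criterion(freqs_ad, n_sim = cfg$paternity_sims,
                        prop_sampled = cfg$prop_sampled,
                        n_candidates = n_cand, confidence = cfg$confidence,
                        seed = stage_seed(4L))
  pat <- assign_paternity(pop, dc$delta_star, freqs = freqs_ad)
  utils::write.table(pat$summary, file.path(cfg$out_dir, "pollen_flow.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log_stage("paternity", t0)

  t0 <- proc.time()[3L]
  disp <- dispersal_summary(pat, pop)
  km <- fit_neighborhood_model(pop, freqs = freqs_ad,
                               starts = cfg$kernel_starts,
                               seed = stage_seed(5L))
  kern_tab <- data.frame(s = km$s, m_p = km$m_p, a = km$a, b = km$b,
                         delta_mean = km$delta_mean, logL = km$logL)
  utils::write.table(kern_tab, file.path(cfg$out_dir, "kernel.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log_stage("kernel", t0)

  metrics <- list(
    seed = cfg$seed,
    diversity = list(
      adults = list(n = div_a$n, k = div_a$k, A = div_a$A, He = div_a$He,
                    Ho = div_a$Ho, F = div_a$F, F_p = fix_a$p_value),
      offspring = list(n = div_o$n, k = div_o$k, A = div_o$A, He = div_o$He,
                       Ho = div_o$Ho, F = div_o$F, F_p = fix_o$p_value),
      private_alleles = as.list(priv),
      P2p = excl$P2p),
    sgs = list(theta_1 = cg$theta_1, b_k = cg$b_k, b_k_p = cg$b_k_p,
               Sp = cg$Sp),
    effsize = as.list(eff),
    paternity = list(delta_star = dc$delta_star,
                     assignment_rate_pct = pat$assignment_rate_pct,
                     mp_pct = pat$mp_pct, s_obs = pat$s_obs,
                     n_distinct_fathers = pat$n_distinct_fathers),
    dispersal = list(mean = disp$mean, sd = disp$sd, median = disp$median,
                     aep_ha = disp$aep_ha, r_ep = disp$r_ep,
                     ks_D = disp$ks_D, ks_p = disp$ks_p),
    kernel = list(s = km$s, m_p = km$m_p, a = km$a, b = km$b,
                  delta_mean = km$delta_mean, logL = km$logL))
  jsonlite::write_json(metrics, file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(metrics)
}
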