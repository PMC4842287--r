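# Per-locus tallies for one cohort: n (individuals genotyped), allele counts,
# observed het, Nei (1978) unbiased expected het.
.locus_stats <- function(pop, mask) {
  res <- lapply(seq_along(pop$loci), function(l) {
    j <- 2L * l - 1L
    a <- pop$geno[mask, j]; b <- pop$geno[mask, j + 1L]
    ok <- !is.na(a)
    n <- sum(ok)
    if (n < 1L) return(list(n = 0L, A = 0L, Ho = NA_real_, He = NA_real_))
    p <- as.numeric(table(c(a[ok], b[ok]))) / (2 * n)
    Ho <- mean(a[ok] != b[ok])
    He <- if (n > 1L) 2 * n / (2 * n - 1) * (1 - sum(p^2)) else NA_real_
    list(n = n, A = length(p), Ho = Ho, He = He)
  })
  data.frame(locus = pop$loci,
             n = vapply(res, `[[`, 0L, "n"),
             A = vapply(res, `[[`, 0L, "A"),
             Ho = vapply(res, `[[`, 0, "Ho"),
             He = vapply(res, `[[`, 0, "He"),
             stringsAsFactors = FALSE)
}

# loci monomorphic over every genotyped individual (all cohorts pooled)
.monomorphic_loci <- function(pop) {
  all_stats <- .locus_stats(pop, rep(TRUE, nrow(pop$ind)))
  all_stats$locus[all_stats$A <= 1L]
}

#' Genetic-diversity summary for one cohort
#'
#' Reports sample size `n`, total alleles over loci `k`, mean alleles per
#' locus `A`, observed heterozygosity `Ho` (fraction heterozygous among
#' non-missing), Nei (1978) unbiased expected heterozygosity `He`, and the
#' multilocus fixation index `F = 1 - sum(Ho_l)/sum(He_l)` (ratio of sums
#' over polymorphic loci). Loci monomorphic across *all* genotyped
#' individuals are excluded from the indices but listed in the result;
#' per-locus values are returned alongside.
#'
#' @param pop a `pollen_pop`.
#' @param cohort cohort selector, see [cohort_mask()].
#' @return A `diversity_summary` list: `n`, `k`, `A`, `Ho`, `He`, `F`,
#'   `per_locus` (data.frame with per-locus n/A/Ho/He/F), and
#'   `excluded_loci`.
#' @export
summarize_diversity <- function(pop, cohort) {
  mask <- cohort_mask(pop, cohort)
  if (sum(mask) < 2L) stop("need at least two individuals in the cohort")
  mono <- .monomorphic_loci(pop)
  st <- .locus_stats(pop, mask)
  st$F <- ifelse(!is.na(st$He) & st$He > 0, 1 - st$Ho / st$He, NA_real_)
  keep <- !(st$locus %in% mono)
  if (!any(keep)) stop("all loci are monomorphic; diversity indices undefined")
  stk <- st[keep, , drop = FALSE]
  if (all(is.na(stk$He)) || sum(stk$He, na.rm = TRUE) == 0) {
    stop("no polymorphic locus with data in this cohort; F undefined")
  }
  structure(list(
    cohort = cohort,
    n = sum(mask),
    k = sum(stk$A),
    A = mean(stk$A),
    Ho = mean(stk$Ho, na.rm = TRUE),
    He = mean(stk$He, na.rm = TRUE),
    F = 1 - sum(stk$Ho, na.rm = TRUE) / sum(stk$He, na.rm = TRUE),
    per_locus = st,
    excluded_loci = mono), class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf(
    "<diversity_summary> cohort=%s n=%d k=%d A=%.2f Ho=%.3f He=%.3f F=%.3f\n",
    paste(x$cohort, collapse = "+"), x$n, x$k, x$A, x$Ho, x$He, x$F))
  if (length(x$excluded_loci))
    cat("  monomorphic loci excluded:", paste(x$excluded_loci, collapse = ", "), "\n")
  invisible(x)
}

#' Private alleles between two cohorts
#'
#' Counts alleles observed (non-missing copies) in one cohort and absent from
#' the other, over the shared locus panel.
#'
#' @param pop a `pollen_pop`.
#' @param cohort_a,cohort_b cohort selectors.
#' @return Named integer vector `c(a = ..., b = ...)`.
#' @export
private_alleles <- function(pop, cohort_a, cohort_b) {
  ma <- cohort_mask(pop, cohort_a); mb <- cohort_mask(pop, cohort_b)
  tot <- c(a = 0L, b = 0L)
  for (l in seq_along(pop$loci)) {
    j <- 2L * l - 1L
    seta <- unique(stats::na.omit(c(pop$geno[ma, j], pop$geno[ma, j + 1L])))
    setb <- unique(stats::na.omit(c(pop$geno[mb, j], pop$geno[mb, j + 1L])))
    tot["a"] <- tot["a"] + length(setdiff(seta, setb))
    tot["b"] <- tot["b"] + length(setdiff(setb, seta))
  }
  tot
}

# multilocus F (ratio of sums) from a genotype matrix restricted to given loci
.multilocus_f <- function(a_mat, b_mat) {
  sHo <- 0; sHe <- 0
  for (l in seq_len(ncol(a_mat))) {
    a <- a_mat[, l]; b <- b_mat[, l]
    ok <- !is.na(a)
    n <- sum(ok)
    if (n < 2L) next
    p <- as.numeric(table(c(a[ok], b[ok]))) / (2 * n)
    He <- 2 * n / (2 * n - 1) * (1 - sum(p^2))
    if (He <= 0) next
    sHo <- sHo + mean(a[ok] != b[ok])
    sHe <- sHe + He
  }
  if (sHe == 0) return(NA_real_)
  1 - sHo / sHe
}

#' Permutation test of the fixation index
#'
#' Permutes gene copies among individuals within each locus (preserving
#' allele counts), recomputes the multilocus `F` each time, and reports the
#' two-sided p-value `(#{|F*| >= |F|} + 1) / (n_perm + 1)`. Per-locus
#' p-values are Bonferroni-adjusted across loci.
#'
#' @param pop a `pollen_pop`.
#' @param cohort cohort selector.
#' @param n_perm number of permutations (>= 100).
#' @param seed optional RNG seed.
#' @return List with `F_obs`, `p_value`, `per_locus` (data.frame with
#'   per-locus F, raw and Bonferroni-adjusted p), `n_perm`.
#' @export
test_fixation <- function(pop, cohort, n_perm = 1000L, seed = NULL) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  mask <- cohort_mask(pop, cohort)
  mono <- .monomorphic_loci(pop)
  keep <- which(!(pop$loci %in% mono))
  if (!length(keep)) stop("all loci monomorphic; F undefined")
  a_mat <- pop$geno[mask, 2L * keep - 1L, drop = FALSE]
  b_mat <- pop$geno[mask, 2L * keep, drop = FALSE]
  nl <- length(keep)

  per_f <- function(am, bm) vapply(seq_len(nl), function(l)
    .multilocus_f(am[, l, drop = FALSE], bm[, l, drop = FALSE]), 0)
  F_obs <- .multilocus_f(a_mat, b_mat)
  Fl_obs <- per_f(a_mat, b_mat)

  Fstar <- matrix(NA_real_, n_perm, nl + 1L)
  n <- nrow(a_mat)
  for (p in seq_len(n_perm)) {
    am <- a_mat; bm <- b_mat
    for (l in seq_len(nl)) {
      ok <- !is.na(a_mat[, l])
      copies <- sample(c(a_mat[ok, l], b_mat[ok, l]))
      k <- sum(ok)
      am[ok, l] <- pmin(copies[seq_len(k)], copies[k + seq_len(k)])
      bm[ok, l] <- pmax(copies[seq_len(k)], copies[k + seq_len(k)])
    }
    Fstar[p, seq_len(nl)] <- per_f(am, bm)
    Fstar[p, nl + 1L] <- .multilocus_f(am, bm)
  }
  pval <- function(obs, null) {
    null <- null[!is.na(null)]
    (sum(abs(null) >= abs(obs)) + 1) / (length(null) + 1)
  }
  p_multi <- pval(F_obs, Fstar[, nl + 1L])
  p_loc <- vapply(seq_len(nl), function(l) pval(Fl_obs[l], Fstar[, l]), 0)
  list(F_obs = F_obs, p_value = p_multi,
       per_locus = data.frame(locus = pop$loci[keep], F = Fl_obs,
                              p = p_loc,
                              p_bonferroni = stats::p.adjust(p_loc, "bonferroni"),
                              stringsAsFactors = FALSE),
       n_perm = n_perm)
}

#' Compare diversity indices between two cohorts
#'
#' For each index (`A`, `Ho`, `He`, `F`), per-locus values of the two cohorts
#' are compared by a two-sample t-test, preceded by an F-test of variance
#' homogeneity that selects the pooled-variance or Welch variant
#' (Welch when the F-test rejects at `alpha`). Both branches use the
#' standard [stats::var.test()] / [stats::t.test()] machinery.
#'
#' @param summary_a,summary_b `diversity_summary` objects for the two cohorts.
#' @param alpha significance level for the variance F-test branch choice.
#' @return data.frame: index, per-cohort means, F statistic and p,
#'   chosen branch, t statistic, df, p.
#' @export
compare_cohorts <- function(summary_a, summary_b, alpha = 0.05) {
  pa <- summary_a$per_locus; pb <- summary_b$per_locus
  keep <- !(pa$locus %in% summary_a$excluded_loci)
  pa <- pa[keep, ]; pb <- pb[keep, ]
  if (nrow(pa) != nrow(pb) || !identical(pa$locus, pb$locus)) {
    stop("summaries must share the same locus panel")
  }
  if (nrow(pa) < 3L) stop("need at least 3 loci to compare cohorts")
  one <- function(va, vb, index) {
    ok <- stats::complete.cases(va, vb)
    va <- va[ok]; vb <- vb[ok]
    if (identical(va, vb) || (stats::var(va) == 0 && stats::var(vb) == 0)) {
      return(data.frame(index = index, mean_a = mean(va), mean_b = mean(vb),
                        F_stat = 1, F_p = 1, welch = FALSE, t_stat = 0,
                        df = 2 * length(va) - 2, t_p = 1))
    }
    vt <- stats::var.test(va, vb)
    welch <- vt$p.value < alpha
    tt <- stats::t.test(va, vb, var.equal = !welch)
    data.frame(index = index, mean_a = mean(va), mean_b = mean(vb),
               F_stat = unname(vt$statistic), F_p = vt$p.value, welch = welch,
               t_stat = unname(tt$statistic), df = unname(tt$parameter),
               t_p = tt$p.value)
  }
  rbind(one(pa$A, pb$A, "A"), one(pa$Ho, pb$Ho, "Ho"),
        one(pa$He, pb$He, "He"), one(pa$F, pb$F, "F"))
}
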