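# Small deterministic populations assembled in code.

# 1 father, 1 mother, 1 offspring, 2 loci
toy_pop <- function() {
  ind <- data.frame(
    id = c("F1", "M1", "O1"),
    cohort = c("father", "mother", "offspring"),
    mother_id = c(NA, NA, "M1"),
    x = c(0, 10, NA), y = c(0, 0, NA),
    stringsAsFactors = FALSE)
  geno <- rbind(c(101L, 103L, 202L, 202L),
                c(101L, 101L, 204L, 206L),
                c(101L, 103L, 202L, 204L))
  colnames(geno) <- c("La_1", "La_2", "Lb_1", "Lb_2")
  pollen_pop(ind, geno, c("La", "Lb"))
}

# n adults (2 cohorts split arbitrarily), genotypes supplied per locus as a
# list of n x 2 matrices
adults_pop <- function(geno_by_locus, xy = NULL) {
  n <- nrow(geno_by_locus[[1L]])
  if (is.null(xy)) xy <- cbind(seq_len(n) * 7.3, (seq_len(n) %% 5) * 11.1)
  loci <- names(geno_by_locus)
  if (is.null(loci)) loci <- sprintf("L%02d", seq_along(geno_by_locus))
  geno <- do.call(cbind, geno_by_locus)
  colnames(geno) <- paste0(rep(loci, each = 2L), c("_1", "_2"))
  ind <- data.frame(id = sprintf("A%03d", seq_len(n)), cohort = "father",
                    mother_id = NA_character_, x = xy[, 1L], y = xy[, 2L],
                    stringsAsFactors = FALSE)
  pollen_pop(ind, geno, loci)
}

# hand-built allele_frequencies object
make_freqs <- function(...) {
  loci <- list(...)
  out <- lapply(loci, function(p) {
    list(freq = p, alleles = as.integer(names(p)),
         n_copies = 1000L)  # large reference: negligible floor / correction
  })
  names(out) <- names(loci)
  class(out) <- "allele_freqs"
  out
}

# independent scalar-loop implementation of the Loiselle estimator, used as
# the brute-force oracle against the vectorized one
loiselle_brute <- function(pop, cohort = "adult") {
  fr <- allele_frequencies(pop, cohort)
  mask <- cohort_mask(pop, cohort)
  ids <- pop$ind$id[mask]
  g <- pop$geno[mask, , drop = FALSE]
  n <- length(ids)
  th <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    num <- 0; den <- 0
    for (l in seq_along(pop$loci)) {
      f <- fr[[l]]
      if (length(f$freq) < 2L) next
      jj <- 2L * l - 1L
      gi <- g[i, jj:(jj + 1L)]; gj <- g[j, jj:(jj + 1L)]
      if (anyNA(gi) || anyNA(gj)) next
      for (k in seq_along(f$alleles)) {
        al <- f$alleles[k]; p <- f$freq[k]
        pi <- mean(gi == al); pj <- mean(gj == al)
        num <- num + (pi - p) * (pj - p) + p * (1 - p) / (f$n_copies - 1L)
        den <- den + p * (1 - p)
      }
    }
    th[i, j] <- th[j, i] <- num / den
  }
  th
}

# exhaustive-enumeration oracle for the second-parent exclusion probability:
# mother and true father in HWE, offspring Mendelian, candidate male in HWE;
# probability the candidate is Mendelian-incompatible given mother+offspring
q2_enumerate <- function(p) {
  k <- length(p)
  tot <- 0
  for (m1 in 1:k) for (m2 in 1:k) for (f1 in 1:k) for (f2 in 1:k) {
    w_par <- p[m1] * p[m2] * p[f1] * p[f2]
    for (om in c(m1, m2)) for (op in c(f1, f2)) {
      po <- 0.25
      o <- sort(c(om, op))
      pex <- 0
      for (c1 in 1:k) for (c2 in 1:k) {
        tp <- transition_probability(o, c(m1, m2), c(c1, c2))
        if (tp == 0) pex <- pex + p[c1] * p[c2]
      }
      tot <- tot + w_par * po * pex
    }
  }
  tot
}
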