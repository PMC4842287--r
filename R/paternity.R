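#' Mendelian transition probability at one locus
#'
#' \eqn{P(g_{off} \mid g_{mother}, g_{father})} under Mendelian segregation:
#' each parent transmits one of its two alleles with probability 1/2.
#' Returns 0 for incompatible trios; summed over all possible offspring
#' genotypes it equals 1 for every parental pair.
#'
#' @param off,mother,father length-2 integer vectors (unordered allele
#'   pairs at one locus).
#' @return The transition probability.
#' @export
transition_probability <- function(off, mother, father) {
  if (anyNA(c(off, mother, father))) return(NA_real_)
  s <- 0
  for (ma in mother) for (fa in father) {
    s <- s + 0.25 * ((ma == off[1L] && fa == off[2L]) ||
                     (ma == off[2L] && fa == off[1L]))
  }
  s
}

# vectorized single-locus transition probability; all args equal-length
# vectors (or matrices of identical shape)
.trans_v <- function(o1, o2, m1, m2, f1, f2) {
  0.25 * (((m1 == o1) & (f1 == o2)) + ((m1 == o2) & (f1 == o1)) +
          ((m1 == o1) & (f2 == o2)) + ((m1 == o2) & (f2 == o1)) +
          ((m2 == o1) & (f1 == o2)) + ((m2 == o2) & (f1 == o1)) +
          ((m2 == o1) & (f2 == o2)) + ((m2 == o2) & (f2 == o1)))
}

# P(g_off | g_mother, random male from freqs) at one locus, vectorized.
# fr: named numeric frequency vector. Given maternal allele m, the paternal
# allele must complete the offspring pair. `floor` protects against alleles
# required of the father but unseen in the reference sample (e.g. carried in
# by migrant pollen): they get half a gene copy rather than probability 0.
.pbg_v <- function(o1, o2, m1, m2, fr, floor = 0) {
  p_of <- function(al) {
    out <- fr[as.character(al)]
    out[is.na(out) | out < floor] <- floor
    unname(out)
  }
  pat_given <- function(m) {
    # paternal-allele probability completing {o1,o2} given maternal allele m
    ifelse(o1 == o2,
           ifelse(m == o1, p_of(o1), 0),
           ifelse(m == o1, p_of(o2), ifelse(m == o2, p_of(o1), 0)))
  }
  0.5 * (pat_given(m1) + pat_given(m2))
}

# default frequency floor for a locus: half a gene copy
.freq_floor <- function(f) {
  if (is.na(f$n_copies)) 1e-4 else 0.5 / f$n_copies
}

# genuine Mendelian mother-offspring compatibility at one locus, vectorized
.mother_compat_v <- function(o1, o2, m1, m2) {
  (m1 == o1) | (m1 == o2) | (m2 == o1) | (m2 == o2)
}

#' Paternity LOD score of a candidate father
#'
#' \eqn{LOD = \sum_l \ln [P(g_o \mid g_m, g_c) / P(g_o \mid g_m, \mathrm{random\ male})]},
#' the random-male denominator being the paternal-allele-frequency
#' formulation under Hardy-Weinberg. Loci where the offspring or mother is
#' untyped are skipped; loci where only the candidate is untyped contribute
#' 0 (ratio 1). A Mendelian mismatch at any typed locus gives `-Inf`
#' (candidate excluded) under zero genotyping error.
#'
#' @param off_g,mother_g,cand_g multilocus genotype vectors
#'   (`<locus>_1`,`<locus>_2` layout, as stored in a `pollen_pop`).
#' @param freqs [allele_frequencies()] of the candidate population.
#' @param error per-locus genotyping-error rate; with `error > 0` the
#'   candidate likelihood becomes `(1-error) * T + error * P_bg`, so
#'   mismatches are down-weighted instead of excluded.
#' @return The LOD (natural log); `-Inf` if excluded.
#' @export
lod_score <- function(off_g, mother_g, cand_g, freqs, error = 0) {
  n_loci <- length(freqs)
  lod <- 0
  for (l in seq_len(n_loci)) {
    j <- 2L * l - 1L
    o <- off_g[j:(j + 1L)]; m <- mother_g[j:(j + 1L)]; f <- cand_g[j:(j + 1L)]
    if (anyNA(o) || anyNA(m)) next
    if (!.mother_compat_v(o[1L], o[2L], m[1L], m[2L])) {
      stop("offspring-mother pair Mendelian-incompatible at locus ",
           names(freqs)[l])
    }
    pd <- .pbg_v(o[1L], o[2L], m[1L], m[2L], freqs[[l]]$freq,
                 floor = .freq_floor(freqs[[l]]))
    if (anyNA(f)) next
    tp <- transition_probability(o, m, f)
    num <- (1 - error) * tp + error * pd
    lod <- lod + log(num) - log(pd)
  }
  lod
}

# Batched LOD computation.
# off: n x 2L matrix (offspring genotypes); mom: n x 2L (their mothers');
# cand: m x 2L (candidates). Returns list(lod = n x m matrix,
# mismatch = n x m mismatch counts, mother_ok = logical n).
.lod_matrix <- function(off, mom, cand, freqs, error = 0) {
  n <- nrow(off); m <- nrow(cand)
  lod <- matrix(0, n, m)
  mism <- matrix(0L, n, m)
  mother_ok <- rep(TRUE, n)
  for (l in seq_along(freqs)) {
    j <- 2L * l - 1L
    o1 <- off[, j]; o2 <- off[, j + 1L]
    m1 <- mom[, j]; m2 <- mom[, j + 1L]
    use <- !(is.na(o1) | is.na(m1))
    if (!any(use)) next
    pd <- rep(NA_real_, n)
    pd[use] <- .pbg_v(o1[use], o2[use], m1[use], m2[use], freqs[[l]]$freq,
                      floor = .freq_floor(freqs[[l]]))
    mother_ok[use] <- mother_ok[use] &
      .mother_compat_v(o1[use], o2[use], m1[use], m2[use])
    c1 <- cand[, j]; c2 <- cand[, j + 1L]
    cok <- !is.na(c1)
    O1 <- matrix(o1, n, m); O2 <- matrix(o2, n, m)
    M1 <- matrix(m1, n, m); M2 <- matrix(m2, n, m)
    C1 <- matrix(c1, n, m, byrow = TRUE); C2 <- matrix(c2, n, m, byrow = TRUE)
    tp <- .trans_v(O1, O2, M1, M2, C1, C2)
    active <- outer(use & pd > 0, cok, "&")
    num <- (1 - error) * tp + error * matrix(pd, n, m)
    contrib <- matrix(0, n, m)
    contrib[active] <- log(num[active]) - log(matrix(pd, n, m)[active])
    lod <- lod + contrib
    mism <- mism + (active & tp == 0)
  }
  list(lod = lod, mismatch = mism, mother_ok = mother_ok)
}

# draw m Hardy-Weinberg genotypes from allele frequencies
.rhwe <- function(m, freqs) {
  g <- matrix(NA_integer_, m, 2L * length(freqs))
  for (l in seq_along(freqs)) {
    al <- freqs[[l]]$alleles
    pr <- freqs[[l]]$freq
    a <- if (length(al) == 1L) rep(al, m) else sample(al, m, TRUE, prob = pr)
    b <- if (length(al) == 1L) rep(al, m) else sample(al, m, TRUE, prob = pr)
    g[, 2L * l - 1L] <- pmin(a, b); g[, 2L * l] <- pmax(a, b)
  }
  g
}

# best and second-best per row of a matrix that may contain -Inf
.top2 <- function(L) {
  n <- nrow(L)
  i1 <- max.col(L, ties.method = "first")
  best <- L[cbind(seq_len(n), i1)]
  L2 <- L
  L2[cbind(seq_len(n), i1)] <- -Inf
  i2 <- max.col(L2, ties.method = "first")
  second <- L2[cbind(seq_len(n), i2)]
  list(best = best, second = second, i1 = i1, i2 = i2)
}

#' Simulation-derived critical value of the Delta statistic
#'
#' Simulates offspring of random Hardy-Weinberg parents drawn from the
#' candidate-population allele frequencies; with probability `prop_sampled`
#' the true father is present among the `n_candidates` candidates. For each
#' simulated offspring the Delta statistic (gap between the top two
#' candidate LODs; the top LOD itself when only one candidate is
#' compatible) is computed, and the critical value `Delta*` is the smallest
#' threshold such that, among simulated offspring whose most-likely
#' candidate passes it, at least `confidence` are the true father.
#'
#' @param freqs [allele_frequencies()] of the candidate population.
#' @param n_sim number of simulated offspring.
#' @param prop_sampled proportion of the true fathers present in the
#'   candidate set.
#' @param n_candidates number of candidate fathers per offspring.
#' @param error genotyping-error rate passed to the likelihood.
#' @param confidence target assignment confidence (e.g. 0.80).
#' @param seed optional RNG seed.
#' @return List with `delta_star` (`+Inf` with a warning when the
#'   confidence is unattainable), `confidence`, `n_sim`, and the simulated
#'   `delta`/`success` vectors (for diagnostics).
#' @export
delta_criterion <- function(freqs, n_sim = 10000L, prop_sampled = 0.60,
                            n_candidates = 124L, error = 0,
                            confidence = 0.80, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_sim < 100L) stop("n_sim must be >= 100")
  mom <- .rhwe(n_sim, freqs)
  dad <- .rhwe(n_sim, freqs)
  off <- matrix(NA_integer_, n_sim, ncol(mom))
  for (l in seq_along(freqs)) {
    j <- 2L * l - 1L
    pick <- sample(c(0L, 1L), n_sim, TRUE)
    ma <- mom[cbind(seq_len(n_sim), j + pick)]
    pick <- sample(c(0L, 1L), n_sim, TRUE)
    pa <- dad[cbind(seq_len(n_sim), j + pick)]
    off[, j] <- pmin(ma, pa); off[, j + 1L] <- pmax(ma, pa)
  }
  sampled <- stats::runif(n_sim) < prop_sampled

  # candidate slot 1 holds the true father when he is sampled; LODs are
  # computed against one shared pool of unrelated males for efficiency
  res_td <- .lod_pairwise(off, mom, dad, freqs, error = error)
  # fresh pool of unrelated candidate males for each block of simulations
  L <- matrix(-Inf, n_sim, n_candidates)
  blocks <- split(seq_len(n_sim), (seq_len(n_sim) - 1L) %/% 1000L)
  for (ix in blocks) {
    pool <- .rhwe(n_candidates, freqs)
    rp <- .lod_matrix(off[ix, , drop = FALSE], mom[ix, , drop = FALSE],
                      pool, freqs, error = error)
    Lb <- rp$lod
    if (error == 0) Lb[rp$mismatch > 0L] <- -Inf
    L[ix, ] <- Lb
  }
  L[, 1L] <- ifelse(sampled, res_td, L[, 1L])

  finite <- is.finite(L)
  any_cand <- rowSums(finite) > 0L
  t2 <- .top2(L)
  delta <- ifelse(rowSums(finite) >= 2L & is.finite(t2$second),
                  t2$best - t2$second, t2$best)
  success <- sampled & t2$i1 == 1L
  keep <- any_cand & is.finite(delta)
  delta <- delta[keep]; success <- success[keep]

  ord <- order(delta, decreasing = TRUE)
  prec <- cumsum(success[ord]) / seq_along(ord)
  ok <- which(prec >= confidence)
  if (length(ok) == 0L) {
    warning("requested confidence unattainable; Delta* = +Inf")
    delta_star <- Inf
  } else {
    delta_star <- delta[ord][max(ok)]
  }
  list(delta_star = delta_star, confidence = confidence, n_sim = n_sim,
       prop_sampled = prop_sampled, n_candidates = n_candidates,
       delta = delta, success = success)
}

# LOD of each offspring against its own single paired candidate (rowwise)
.lod_pairwise <- function(off, mom, cand, freqs, error = 0) {
  n <- nrow(off)
  lod <- numeric(n)
  for (l in seq_along(freqs)) {
    j <- 2L * l - 1L
    o1 <- off[, j]; o2 <- off[, j + 1L]
    m1 <- mom[, j]; m2 <- mom[, j + 1L]
    c1 <- cand[, j]; c2 <- cand[, j + 1L]
    use <- !(is.na(o1) | is.na(m1) | is.na(c1))
    if (!any(use)) next
    pd <- .pbg_v(o1[use], o2[use], m1[use], m2[use], freqs[[l]]$freq,
                 floor = .freq_floor(freqs[[l]]))
    tp <- .trans_v(o1[use], o2[use], m1[use], m2[use], c1[use], c2[use])
    num <- (1 - error) * tp + error * pd
    contrib <- rep(0, n)
    contrib[use] <- log(num) - log(pd)
    lod <- lod + contrib
  }
  lod
}

#' Assign paternity to offspring by the Delta criterion
#'
#' Every reproductive adult (candidate fathers and mothers alike) is a
#' candidate. The most-likely non-excluded candidate is assigned when its
#' Delta (LOD gap to the runner-up) reaches `delta_star`; an assignment to
#' the offspring's own mother is counted as selfing; offspring with no
#' passing candidate are attributed to migrant pollen. LOD ties are broken
#' by geographic proximity to the mother, then id.
#'
#' @param pop a `pollen_pop` with mapped adults.
#' @param delta_star critical Delta from [delta_criterion()].
#' @param freqs candidate-population allele frequencies (default: adults).
#' @param error genotyping-error rate (default 0: mismatched candidates are
#'   excluded outright).
#' @return A `paternity_result`: list with `assignments` (one row per
#'   offspring: best/second candidate, LODs, delta, father id or
#'   `"MIGRANT"`, selfing flag, distance), `summary` (per-mother `Np`,
#'   `Nm`, `mp_pct` plus totals), `sires` (per-father sired counts), and
#'   `excluded_offspring` (mother-incompatible, dropped with a warning).
#' @export
assign_paternity <- function(pop, delta_star, freqs = NULL, error = 0) {
  if (is.null(freqs)) freqs <- allele_frequencies(pop, "adult")
  am <- cohort_mask(pop, "adult")
  om <- cohort_mask(pop, "offspring")
  if (!any(om)) stop("population has no offspring")
  cand_ids <- pop$ind$id[am]
  off_ids <- pop$ind$id[om]
  mom_ids <- pop$ind$mother_id[om]
  mrow <- match(mom_ids, pop$ind$id)
  off <- pop$geno[om, , drop = FALSE]
  mom <- pop$geno[mrow, , drop = FALSE]
  cand <- pop$geno[am, , drop = FALSE]

  res <- .lod_matrix(off, mom, cand, freqs, error = error)
  bad <- !res$mother_ok
  if (any(bad)) {
    warning(sum(bad), " offspring incompatible with their recorded mother; excluded")
  }
  L <- res$lod
  if (error == 0) L[res$mismatch > 0L] <- -Inf

  # distances mother -> candidate, for tie-breaks and dispersal
  D <- matrix(NA_real_, sum(om), sum(am))
  xs <- pop$ind$x; ys <- pop$ind$y
  for (i in seq_len(sum(om))) {
    D[i, ] <- sqrt((xs[am] - xs[mrow[i]])^2 + (ys[am] - ys[mrow[i]])^2)
  }

  n_off <- nrow(L)
  best_i <- integer(n_off)
  for (i in seq_len(n_off)) {
    mx <- max(L[i, ])
    if (!is.finite(mx)) { best_i[i] <- NA_integer_; next }
    tied <- which(L[i, ] >= mx - 1e-9)
    if (length(tied) > 1L) {
      tied <- tied[order(D[i, tied], cand_ids[tied])]
    }
    best_i[i] <- tied[1L]
  }
  best_lod <- ifelse(is.na(best_i), -Inf, L[cbind(seq_len(n_off), best_i)])
  second_lod <- vapply(seq_len(n_off), function(i) {
    if (is.na(best_i[i])) return(-Inf)
    v <- L[i, -best_i[i]]
    v <- v[is.finite(v)]
    if (length(v)) max(v) else NA_real_
  }, 0)
  delta <- ifelse(is.na(second_lod), best_lod,
                  ifelse(is.finite(second_lod), best_lod - second_lod, best_lod))
  n_compat <- rowSums(is.finite(L))

  assigned <- !bad & !is.na(best_i) & is.finite(best_lod) & delta >= delta_star
  father <- rep("MIGRANT", n_off)
  father[assigned] <- cand_ids[best_i[assigned]]
  selfing <- assigned & father == mom_ids
  dist_m <- rep(NA_real_, n_off)
  dist_m[assigned] <- D[cbind(which(assigned), best_i[assigned])]

  assignments <- data.frame(
    offspring_id = off_ids, mother_id = mom_ids,
    best_candidate = ifelse(is.na(best_i), NA_character_, cand_ids[best_i]),
    lod_best = best_lod, delta = delta, n_compatible = n_compat,
    father = ifelse(bad, NA_character_, father),
    selfing = selfing, distance_m = dist_m,
    mother_compatible = !bad, stringsAsFactors = FALSE)

  ok <- !bad
  mothers <- sort(unique(mom_ids[ok]))
  Np <- vapply(mothers, function(m) sum(mom_ids[ok] == m), 0L)
  Nm <- vapply(mothers, function(m) sum(mom_ids[ok] == m & father[ok] == "MIGRANT"), 0L)
  summary <- data.frame(mother = mothers, Np = Np, Nm = Nm,
                        mp_pct = 100 * Nm / Np, stringsAsFactors = FALSE)
  tot <- data.frame(mother = "Total", Np = sum(Np), Nm = sum(Nm),
                    mp_pct = 100 * sum(Nm) / sum(Np))
  summary <- rbind(summary, tot)

  sired <- table(father[ok & father != "MIGRANT" & !selfing])
  sires <- data.frame(father = names(sired), n_offspring = as.integer(sired),
                      stringsAsFactors = FALSE)

  structure(list(assignments = assignments, summary = summary, sires = sires,
                 delta_star = delta_star,
                 assignment_rate_pct = 100 * sum(father[ok] != "MIGRANT") / sum(ok),
                 mp_pct = 100 * sum(father[ok] == "MIGRANT") / sum(ok),
                 s_obs = sum(selfing[ok]),
                 n_distinct_fathers = nrow(sires),
                 excluded_offspring = off_ids[bad]),
            class = "paternity_result")
}

#' @export
print.paternity_result <- function(x, ...) {
  cat(sprintf(
    "<paternity_result> %d offspring | assignment rate %.1f%% | pollen immigration %.1f%% | selfed %d | distinct sires %d\n",
    nrow(x$assignments), x$assignment_rate_pct, x$mp_pct, x$s_obs,
    x$n_distinct_fathers))
  invisible(x)
}

#' Pollen-flow arithmetic from per-mother counts
#'
#' Given the number of genotyped offspring per mother (`Np`) and the number
#' attributed to outside pollen donors (`Nm`), returns per-mother and overall
#' immigration percentages and the within-population assignment rate.
#'
#' @param Np,Nm equal-length integer vectors of per-mother counts.
#' @param mothers optional mother labels.
#' @return List with `per_mother` (data.frame), `mp_total_pct` and
#'   `assignment_rate_pct`.
#' @export
pollen_flow_from_counts <- function(Np, Nm, mothers = NULL) {
  stopifnot(length(Np) == length(Nm), all(Nm <= Np), all(Np >= 0))
  if (is.null(mothers)) mothers <- sprintf("M%02d", seq_along(Np))
  list(per_mother = data.frame(mother = mothers, Np = Np, Nm = Nm,
                               mp_pct = 100 * Nm / Np),
       mp_total_pct = 100 * sum(Nm) / sum(Np),
       assignment_rate_pct = 100 * (sum(Np) - sum(Nm)) / sum(Np))
}

#' Second-parent exclusion probabilities
#'
#' Per-locus probability `Q2` that a random unrelated male is excluded by
#' Mendelian incompatibility as the father of a random offspring whose
#' mother is known, under Hardy-Weinberg genotype proportions
#' (Jamieson & Taylor): with \eqn{a_k = \sum_i p_i^k},
#' \deqn{Q_2 = 1 - 2a_2 + a_3 + 3 a_2 a_3 - 3 a_5 - 2 a_2^2 + 2 a_4.}
#' Combined over loci, \eqn{P_{2p} = 1 - \prod_l (1 - Q_{2l})}.
#'
#' @param freqs [allele_frequencies()].
#' @return List with `per_locus` (named `Q2` vector) and `P2p`.
#' @export
exclusion_probability <- function(freqs) {
  q2 <- vapply(freqs, function(f) {
    p <- f$freq
    if (length(p) < 2L) return(0)
    a2 <- sum(p^2); a3 <- sum(p^3); a4 <- sum(p^4); a5 <- sum(p^5)
    1 - 2 * a2 + a3 + 3 * a2 * a3 - 3 * a5 - 2 * a2^2 + 2 * a4
  }, 0)
  list(per_locus = q2, P2p = 1 - prod(1 - q2))
}
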