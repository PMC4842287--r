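#' Pairwise Loiselle coancestry coefficients
#'
#' The allele-frequency-covariance kinship estimator. For locus \eqn{l},
#' allele \eqn{a} with reference frequency \eqn{\bar p_{la}} estimated from
#' \eqn{n_l} gene copies, and individual allele "frequencies"
#' \eqn{p_{ila} \in \{0, 0.5, 1\}}:
#' \deqn{\theta_{ij} = \frac{\sum_l \sum_a [(p_{ila}-\bar p_{la})
#'   (p_{jla}-\bar p_{la}) + \bar p_{la}(1-\bar p_{la})/(n_l-1)]}
#'   {\sum_l \sum_a \bar p_{la}(1-\bar p_{la})}}
#' (ratio of sums over loci; loci where either member of a pair is missing
#' are dropped from that pair's sums). With reference frequencies taken from
#' the sample itself the all-pairs mean is slightly negative, of order
#' \eqn{-1/(n-1)}.
#'
#' @param pop a `pollen_pop`.
#' @param cohort cohort selector (default `"adult"`).
#' @param ref_freqs reference [allele_frequencies()]; defaults to frequencies
#'   of the same selection (the usual convention for within-population SGS).
#' @return A `kinship_matrix`: list with `theta` (symmetric matrix, `NA`
#'   diagonal), `dist` (meter distances, if mapped), `ids`, `ref_freqs`,
#'   and `dropped_pairs` (pairs sharing no typed locus, if any).
#' @export
loiselle_kinship <- function(pop, cohort = "adult", ref_freqs = NULL) {
  mask <- cohort_mask(pop, cohort)
  n <- sum(mask)
  if (n < 2L) stop("need at least two individuals")
  if (is.null(ref_freqs)) ref_freqs <- allele_frequencies(pop, cohort)
  poly <- vapply(ref_freqs, function(f) length(f$freq) > 1L, TRUE)
  if (sum(poly) < 1L) stop("no polymorphic locus in reference frequencies")

  NUM <- matrix(0, n, n); DEN <- matrix(0, n, n)
  for (l in which(poly)) {
    f <- ref_freqs[[l]]
    if (f$n_copies < 2L || is.na(f$n_copies)) {
      stop("locus ", names(ref_freqs)[l], " has fewer than 2 reference copies")
    }
    j <- 2L * l - 1L
    a <- pop$geno[mask, j]; b <- pop$geno[mask, j + 1L]
    ok <- !is.na(a)
    # individual allele-frequency matrix X: n x n_alleles with entries 0/.5/1
    A <- length(f$alleles)
    X <- matrix(0, n, A)
    ia <- match(a, f$alleles); ib <- match(b, f$alleles)
    if (any(ok & (is.na(ia) | is.na(ib)))) {
      stop("allele outside reference frequency set at locus ",
           names(ref_freqs)[l])
    }
    idx <- which(ok)
    for (i in idx) {
      X[i, ia[i]] <- X[i, ia[i]] + 0.5
      X[i, ib[i]] <- X[i, ib[i]] + 0.5
    }
    C <- sweep(X, 2L, f$freq)           # p_i - p_bar
    C[!ok, ] <- 0
    cross <- tcrossprod(C)              # sum_a (p_i - p)(p_j - p)
    het <- sum(f$freq * (1 - f$freq))
    both <- outer(ok, ok, "&")
    NUM <- NUM + (cross + het / (f$n_copies - 1)) * both
    DEN <- DEN + het * both
  }
  theta <- NUM / DEN
  theta[DEN == 0] <- NA
  diag(theta) <- NA
  ids <- pop$ind$id[mask]
  dimnames(theta) <- list(ids, ids)
  dropped <- which(DEN == 0 & upper.tri(DEN), arr.ind = TRUE)
  d <- NULL
  if (!anyNA(pop$ind$x[mask])) {
    d <- as.matrix(stats::dist(cbind(pop$ind$x[mask], pop$ind$y[mask])))
    dimnames(d) <- dimnames(theta)
  }
  structure(list(theta = theta, dist = d, ids = ids, ref_freqs = ref_freqs,
                 dropped_pairs = if (nrow(dropped))
                   data.frame(i = ids[dropped[, 1L]], j = ids[dropped[, 2L]])
                 else NULL),
            class = "kinship_matrix")
}

# equal-count distance classes; ties share the lower class
.distance_classes <- function(d, n_classes) {
  cls <- ceiling(n_classes * rank(d, ties.method = "min") / length(d))
  cls[cls < 1L] <- 1L
  cls
}

# OLS slope of theta on ln(distance)
.bk_slope <- function(theta, lnd) {
  ok <- !is.na(theta)
  stats::cov(theta[ok], lnd[ok]) / stats::var(lnd[ok])
}

#' Distance-class correlogram of pairwise coancestry
#'
#' Pairs are binned into `n_classes` distance classes holding (near-)equal
#' pair counts (empirical-quantile edges, ties to the lower class). The 95%
#' null envelope per class, and the p-value of the regression slope `b_k` of
#' \eqn{\theta_{ij}} on \eqn{\ln d_{ij}} (all pairs, natural log), are
#' obtained by permuting individuals among spatial locations while holding
#' genotypes fixed. `Sp` is computed via [sp_statistic()] from `b_k` and the
#' first-class mean \eqn{\theta_1}.
#'
#' @param kin a [loiselle_kinship()] result with distances.
#' @param n_classes number of distance classes.
#' @param n_perm number of location permutations.
#' @param seed optional RNG seed.
#' @param envelope_probs percentile pair for the null envelope.
#' @return A `correlogram`: list with `classes` (data.frame: class, d_min,
#'   d_max, d_mean, n_pairs, theta_mean, env_lo, env_hi, outside),
#'   `theta_1`, `b_k`, `b_k_p`, `Sp`, `n_perm`.
#' @export
build_correlogram <- function(kin, n_classes = 10L, n_perm = 10000L,
                              seed = NULL, envelope_probs = c(0.025, 0.975)) {
  if (is.null(kin$dist)) stop("kinship matrix has no distances; map the individuals")
  if (!is.null(seed)) set.seed(seed)
  n <- length(kin$ids)
  ut <- upper.tri(kin$dist)
  d <- kin$dist[ut]
  th <- kin$theta[ut]
  if (length(unique(d)) < n_classes) {
    stop("fewer distinct pair distances than classes")
  }
  if (any(d <= 0)) stop("coincident individuals: zero pair distance")
  cls <- .distance_classes(d, n_classes)
  lnd <- log(d)

  cls_mean <- function(th_v) {
    as.numeric(tapply(th_v, cls, mean, na.rm = TRUE))
  }
  obs_mean <- cls_mean(th)
  b_k <- .bk_slope(th, lnd)

  perm_means <- matrix(NA_real_, n_perm, n_classes)
  perm_bk <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    pm <- sample.int(n)
    thp <- kin$theta[pm, pm][ut]
    perm_means[p, ] <- cls_mean(thp)
    perm_bk[p] <- .bk_slope(thp, lnd)
  }
  env <- apply(perm_means, 2L, stats::quantile, probs = envelope_probs,
               na.rm = TRUE)
  b_k_p <- (sum(abs(perm_bk) >= abs(b_k)) + 1) / (n_perm + 1)

  classes <- data.frame(
    class = seq_len(n_classes),
    d_min = as.numeric(tapply(d, cls, min)),
    d_max = as.numeric(tapply(d, cls, max)),
    d_mean = as.numeric(tapply(d, cls, mean)),
    n_pairs = as.integer(table(factor(cls, seq_len(n_classes)))),
    theta_mean = obs_mean,
    env_lo = env[1L, ], env_hi = env[2L, ])
  classes$outside <- classes$theta_mean < classes$env_lo |
    classes$theta_mean > classes$env_hi
  theta_1 <- obs_mean[1L]
  structure(list(classes = classes, theta_1 = theta_1, b_k = b_k,
                 b_k_p = b_k_p, Sp = sp_statistic(b_k, theta_1),
                 n_perm = n_perm),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf(
    "<correlogram> %d classes | theta_1 = %.4f  b_k = %.5f (p = %.4g)  Sp = %.4f\n",
    nrow(x$classes), x$theta_1, x$b_k, x$b_k_p, x$Sp))
  print(x$classes, digits = 4)
  invisible(x)
}

#' Sp statistic of spatial genetic structure
#'
#' \eqn{Sp = -b_k / (1 - \theta_1)}: a scale-free intensity measure of
#' isolation by distance, comparable across studies.
#'
#' @param b_k regression slope of pairwise coancestry on ln(distance).
#' @param theta_1 mean coancestry in the first distance class (< 1).
#' @return The Sp value.
#' @export
sp_statistic <- function(b_k, theta_1) {
  if (theta_1 >= 1) stop("theta_1 must be < 1")
  -b_k / (1 - theta_1)
}
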