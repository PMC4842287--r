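#' Group coancestry of a sampled cohort
#'
#' \deqn{\Theta = \frac{0.5\,n\,(1+F_p) + \sum_{i \ne j} \theta_{ij}}{n^2},}
#' where \eqn{n} is the census of sampled adults, \eqn{F_p} the population
#' inbreeding coefficient (the fixation index truncated at zero: heterozygote
#' excess does not make individuals less than non-inbred), and the double sum
#' runs over all ordered pairs of distinct individuals. The
#' \eqn{0.5 n (1+F_p)} term is the diagonal (self-coancestry).
#'
#' @param kin a [loiselle_kinship()] result for the cohort.
#' @param F the cohort's fixation index.
#' @return List with `Theta`, `n`, `F_p` (the truncated value used) and
#'   `sum_theta` (the off-diagonal double sum).
#' @export
group_coancestry <- function(kin, F) {
  n <- length(kin$ids)
  if (n < 1L) stop("empty cohort")
  th <- kin$theta
  diag(th) <- 0
  if (anyNA(th)) stop("kinship matrix has missing pairs; cannot sum")
  F_p <- max(F, 0)
  S <- sum(th)
  list(Theta = (0.5 * n * (1 + F_p) + S) / n^2, n = n, F_p = F_p,
       sum_theta = S)
}

#' Variance effective population size
#'
#' Equates the drift variance of allele frequencies in the sampled group,
#' \eqn{\sigma_p^2 = [\Theta (n-1)/n + (1+F)/(2n)]\,p(1-p)}, with that of an
#' idealized population, \eqn{p(1-p)/(2 N_e)}, giving
#' \deqn{N_e = \frac{0.5}{\Theta \frac{n-1}{n} + \frac{1+F}{2n}}.}
#'
#' @param Theta group coancestry (see [group_coancestry()]).
#' @param F average inbreeding coefficient; negative values are truncated to
#'   zero by default (`truncate_f = FALSE` uses the raw value).
#' @param n census of sampled individuals.
#' @param truncate_f truncate negative `F` at zero (default `TRUE`).
#' @return List with `Ne`, `n`, `Theta`, `F_used`.
#' @export
effective_size <- function(Theta, F, n, truncate_f = TRUE) {
  F_used <- if (truncate_f) max(F, 0) else F
  denom <- Theta * (n - 1) / n + (1 + F_used) / (2 * n)
  if (denom <= 0) stop("non-positive denominator; Ne undefined")
  list(Ne = 0.5 / denom, n = n, Theta = Theta, F_used = F_used)
}

#' One-stop effective-size report for a cohort
#'
#' Computes the fixation index, pairwise Loiselle coancestry, group
#' coancestry and variance effective size for one cohort.
#'
#' @param pop a `pollen_pop`.
#' @param cohort cohort selector (default adults).
#' @param truncate_f see [effective_size()].
#' @return data.frame with one row: n, F, F_p, Theta, Ne.
#' @export
effective_size_report <- function(pop, cohort = "adult", truncate_f = TRUE) {
  div <- summarize_diversity(pop, cohort)
  kin <- loiselle_kinship(pop, cohort)
  gc <- group_coancestry(kin, div$F)
  ne <- effective_size(gc$Theta, div$F, gc$n, truncate_f = truncate_f)
  data.frame(n = gc$n, F = div$F, F_p = gc$F_p, Theta = gc$Theta, Ne = ne$Ne)
}
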