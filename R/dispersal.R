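#' Pollen-dispersal summary from paternity assignments
#'
#' Summarizes realized pollination distances (mother to assigned within-plot
#' sire, outcross events only): mean, SD, median, the axial variance
#' \eqn{\sigma_p^2}, the effective pollination neighborhood area
#' \eqn{A_{ep} = 2 \pi \sigma_p^2} (hectares) with its radius
#' \eqn{r_{ep} = \sqrt{A_{ep}/\pi}}, a two-sample Kolmogorov-Smirnov test of
#' the realized distances against the mother-to-candidate distance
#' distribution (does distance alone explain the mating pattern?), and an
#' approximate distance-dependence R-squared from regressing binned mating
#' counts on bin-center distance.
#'
#' Two conventions for \eqn{\sigma_p^2} are offered. `"radial"` (default)
#' takes \eqn{\sigma_p} as the standard deviation of the realized dispersal
#' distances. `"axial"` takes the variance of one Cartesian component of the
#' isotropic dispersal vector, \eqn{\sum_i d_i^2 / (2N)}.
#'
#' @param pat a [assign_paternity()] result.
#' @param pop the `pollen_pop` the assignments came from.
#' @param sigma_convention `"radial"` or `"axial"`, see Details.
#' @param n_bins bins for the distance-dependence regression.
#' @return A `dispersal_summary` list; see Details for fields.
#' @export
dispersal_summary <- function(pat, pop, sigma_convention = c("radial", "axial"),
                              n_bins = 10L) {
  sigma_convention <- match.arg(sigma_convention)
  a <- pat$assignments
  within <- a$mother_compatible & !is.na(a$father) & a$father != "MIGRANT" &
    !a$selfing
  if (!any(within)) stop("no within-plot outcross assignments to summarize")
  d <- a$distance_m[within]

  sigma2 <- switch(sigma_convention,
                   radial = stats::var(d),
                   axial = sum(d^2) / (2 * length(d)))
  aep_ha <- effective_neighborhood(sqrt(sigma2))

  # reference: every mother-to-candidate distance (candidate = any other adult)
  am <- cohort_mask(pop, "adult")
  mm <- cohort_mask(pop, "mother")
  xs <- pop$ind$x; ys <- pop$ind$y
  ref <- unlist(lapply(which(mm), function(i) {
    dd <- sqrt((xs[am] - xs[i])^2 + (ys[am] - ys[i])^2)
    dd[dd > 0]
  }))
  ks <- suppressWarnings(stats::ks.test(d, ref, exact = FALSE))

  # approximate distance dependence of mating counts (binned)
  edges <- seq(0, max(ref, d), length.out = n_bins + 1L)
  cnt <- as.integer(table(cut(d, edges, include.lowest = TRUE)))
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  fit <- stats::lm(cnt ~ mids)
  r2 <- summary(fit)$r.squared
  r2_p <- stats::coef(summary(fit))["mids", "Pr(>|t|)"]

  structure(list(
    distances = d, n = length(d),
    mean = mean(d), sd = stats::sd(d), median = stats::median(d),
    sigma_p2 = sigma2, sigma_convention = sigma_convention,
    aep_ha = aep_ha$aep_ha, r_ep = aep_ha$r_ep,
    ks_D = unname(ks$statistic), ks_p = ks$p.value,
    distance_r2 = r2, distance_r2_p = r2_p), class = "dispersal_summary")
}

#' @export
print.dispersal_summary <- function(x, ...) {
  cat(sprintf(
    "<dispersal_summary> n=%d | mean=%.1f m sd=%.1f m median=%.1f m | Aep=%.2f ha r_ep=%.1f m | KS D=%.3f (p=%.2g)\n",
    x$n, x$mean, x$sd, x$median, x$aep_ha, x$r_ep, x$ks_D, x$ks_p))
  invisible(x)
}

#' Effective pollination neighborhood area
#'
#' \eqn{A_{ep} = 2\pi\sigma_p^2} (a circle about the seed tree containing
#' the bulk of effective pollen movement) and its radius
#' \eqn{r_{ep} = \sqrt{A_{ep}/\pi} = \sigma_p \sqrt 2}.
#'
#' @param sigma_p axial SD of pollen dispersal, meters.
#' @return List with `aep_ha` (hectares) and `r_ep` (meters).
#' @export
effective_neighborhood <- function(sigma_p) {
  stopifnot(sigma_p >= 0)
  aep_m2 <- 2 * pi * sigma_p^2
  list(aep_ha = aep_m2 / 1e4, r_ep = sqrt(aep_m2 / pi))
}

#' Fit the neighborhood mating model by maximum likelihood
#'
#' Each offspring's paternity is modeled as a three-way mixture: selfing
#' with probability `s`, migrant pollen from outside the plot with
#' probability `m_p`, or outcrossing with a within-plot male sampled with
#' probability proportional to the exponential-power kernel density at his
#' distance from the mother (all mapped adults compete; no distance cutoff).
#' The log-likelihood
#' \deqn{\sum_o \ln\big[ s\,T(g_o|g_m,g_m) + m_p\,P_{bg}(g_o|g_m)
#'   + (1{-}s{-}m_p) \textstyle\sum_j w_j(a,b)\, T(g_o|g_m,g_j) \big]}
#' is maximized over `(s, m_p, a, b)`; the migrant-gamete background
#' `P_bg` uses the candidate-population allele frequencies, and the weights
#' `w_j` are normalized over the within-plot males (the mother excluded
#' from her own outcross set). Optimization runs on transformed parameters
#' (stick-breaking logits for `s`, `m_p`; logs for `a`, `b`) from several
#' starts; standard errors come from the numerical Hessian by the delta
#' method.
#'
#' @param pop a `pollen_pop` with mapped adults and offspring.
#' @param freqs background allele frequencies (default: within-plot adults).
#' @param fix optional named numeric fixing parameters, e.g.
#'   `c(s = 0)` or `c(s = 0, m_p = 0)`.
#' @param starts number of optimizer starts (the first from a neutral
#'   default, the rest drawn around it).
#' @param seed optional RNG seed for the extra starts.
#' @param error genotyping-error rate for the transition probabilities.
#' @return A `kernel_model`: list with `s`, `m_p`, `a`, `b`, `se` (named,
#'   `NA` where fixed or at a boundary), `logL`, `delta_mean` (mean
#'   dispersal distance of the fitted kernel), `boundary`, `convergence`.
#' @export
fit_neighborhood_model <- function(pop, freqs = NULL, fix = NULL,
                                   starts = 5L, seed = NULL, error = 0) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(freqs)) freqs <- allele_frequencies(pop, "adult")
  am <- cohort_mask(pop, "adult")
  om <- cohort_mask(pop, "offspring")
  if (!any(om)) stop("population has no offspring")
  cand_ids <- pop$ind$id[am]
  mom_ids <- pop$ind$mother_id[om]
  mrow <- match(mom_ids, pop$ind$id)
  off <- pop$geno[om, , drop = FALSE]
  mom <- pop$geno[mrow, , drop = FALSE]
  cand <- pop$geno[am, , drop = FALSE]
  n_off <- sum(om)

  # likelihood pieces that do not depend on (s, m_p, a, b)
  res <- .lod_matrix(off, mom, cand, freqs, error = error)
  if (any(!res$mother_ok)) {
    stop("offspring incompatible with recorded mother: ",
         paste(pop$ind$id[om][!res$mother_ok], collapse = ", "))
  }
  R <- exp(res$lod)                       # T_j / P_bg likelihood ratios
  self_col <- match(mom_ids, cand_ids)
  R_self <- R[cbind(seq_len(n_off), self_col)]
  logPbg <- .logpbg_total(off, mom, freqs) # per-offspring log P_bg constant

  # mother-to-candidate distances; weights per mother
  mothers <- unique(mom_ids)
  mi <- match(mom_ids, mothers)
  xs <- pop$ind$x; ys <- pop$ind$y
  Dm <- t(vapply(match(mothers, pop$ind$id), function(i)
    sqrt((xs[am] - xs[i])^2 + (ys[am] - ys[i])^2), numeric(sum(am))))
  self_of_mother <- match(mothers, cand_ids)

  free <- setdiff(c("s", "m_p", "a", "b"), names(fix))
  par0 <- c(s = -2, m_p = -2, a = log(30), b = log(1))  # transformed scale

  natural <- function(tp) {
    s <- if ("s" %in% names(fix)) fix[["s"]] else stats::plogis(tp[["s"]])
    mp_max <- 1 - s
    m_p <- if ("m_p" %in% names(fix)) fix[["m_p"]] else
      mp_max * stats::plogis(tp[["m_p"]])
    a <- if ("a" %in% names(fix)) fix[["a"]] else exp(tp[["a"]])
    b <- if ("b" %in% names(fix)) fix[["b"]] else exp(tp[["b"]])
    c(s = s, m_p = m_p, a = a, b = b)
  }
  nll <- function(tpfree) {
    tp <- par0
    tp[free] <- tpfree
    np <- natural(tp)
    s <- np[["s"]]; m_p <- np[["m_p"]]; a <- np[["a"]]; b <- np[["b"]]
    if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) return(1e10)
    W <- kernel_pdf(Dm, a, b)
    W[cbind(seq_along(mothers), self_of_mother)] <- 0
    sw <- rowSums(W)
    if (any(sw <= 0) || any(!is.finite(sw))) return(1e10)
    W <- W / sw
    outx <- rowSums(R * W[mi, , drop = FALSE])
    mix <- s * R_self + m_p + (1 - s - m_p) * outx
    if (any(mix <= 0) || any(!is.finite(mix))) return(1e10)
    -sum(log(mix))
  }

  if (length(free) == 0L) {     # all parameters fixed: evaluate, don't optimize
    best <- list(par = numeric(0), value = nll(numeric(0)), convergence = 0L)
    np <- natural(par0)
    return(structure(list(s = np[["s"]], m_p = np[["m_p"]], a = np[["a"]],
                          b = np[["b"]],
                          se = c(s = NA_real_, m_p = NA_real_,
                                 a = NA_real_, b = NA_real_),
                          logL = -best$value + sum(logPbg),
                          delta_mean = kernel_mean(np[["a"]], np[["b"]]),
                          boundary = character(0), convergence = 0L,
                          fixed = fix, n_offspring = n_off),
                     class = "kernel_model"))
  }

  best <- NULL
  start_list <- list(par0[free])
  if (starts > 1L) {
    for (k in seq_len(starts - 1L)) {
      jit <- par0[free] + stats::rnorm(length(free), 0, 1.2)
      start_list[[k + 1L]] <- jit
    }
  }
  for (st in start_list) {
    fit <- tryCatch(
      stats::optim(st, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("neighborhood-model optimization failed from all starts")

  tp <- par0; tp[free] <- best$par
  np <- natural(tp)
  boundary <- character(0)
  if (!("s" %in% names(fix)) && abs(tp[["s"]]) > 8) boundary <- c(boundary, "s")
  if (!("m_p" %in% names(fix)) && abs(tp[["m_p"]]) > 8) boundary <- c(boundary, "m_p")

  se <- c(s = NA_real_, m_p = NA_real_, a = NA_real_, b = NA_real_)
  if (length(free)) {
    H <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
    if (!is.null(V) && all(is.finite(diag(V))) && all(diag(V) > 0)) {
      # delta method: numerical jacobian of natural params wrt free transforms
      eps <- 1e-5
      J <- matrix(0, 4L, length(free),
                  dimnames = list(c("s", "m_p", "a", "b"), free))
      for (k in seq_along(free)) {
        tp_hi <- tp; tp_hi[free[k]] <- tp_hi[free[k]] + eps
        tp_lo <- tp; tp_lo[free[k]] <- tp_lo[free[k]] - eps
        J[, k] <- (natural(tp_hi) - natural(tp_lo)) / (2 * eps)
      }
      Vn <- J %*% V %*% t(J)
      se[] <- sqrt(pmax(diag(Vn), 0))
      se[names(fix)] <- NA_real_
      se[boundary] <- NA_real_
    }
  }

  logL <- -best$value + sum(logPbg)
  structure(list(s = np[["s"]], m_p = np[["m_p"]], a = np[["a"]], b = np[["b"]],
                 se = se, logL = logL,
                 delta_mean = kernel_mean(np[["a"]], np[["b"]]),
                 boundary = boundary, convergence = best$convergence,
                 fixed = fix, n_offspring = n_off),
            class = "kernel_model")
}

#' @export
print.kernel_model <- function(x, ...) {
  cat(sprintf(
    "<kernel_model> s=%.4f m_p=%.4f a=%.2f m b=%.3f | mean dispersal %.1f m | logL=%.2f\n",
    x$s, x$m_p, x$a, x$b, x$delta_mean, x$logL))
  if (length(x$boundary))
    cat("  boundary estimates:", paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

# per-offspring log P_bg(g_o | g_m) summed over typed loci
.logpbg_total <- function(off, mom, freqs) {
  n <- nrow(off)
  out <- numeric(n)
  for (l in seq_along(freqs)) {
    j <- 2L * l - 1L
    o1 <- off[, j]; o2 <- off[, j + 1L]
    m1 <- mom[, j]; m2 <- mom[, j + 1L]
    use <- !(is.na(o1) | is.na(m1))
    if (!any(use)) next
    pd <- .pbg_v(o1[use], o2[use], m1[use], m2[use], freqs[[l]]$freq,
                 floor = .freq_floor(freqs[[l]]))
    contrib <- rep(0, n)
    contrib[use] <- log(pd)
    out <- out + contrib
  }
  out
}
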