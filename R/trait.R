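## ---------------------------------------------------------------------------
## Trait model: QTL effects, TBV, variance standardization, phenotypes
## ---------------------------------------------------------------------------

#' Sample single-trait QTL effects
#'
#' Magnitudes are exponential with rate 1 (the scale is immaterial because
#' effects are later standardized to a target additive variance); signs are
#' negative with probability `p_negative`, mimicking mostly deleterious
#' mutant alleles. The wild-type allele effect is 0 by convention.
#'
#' @param n_qtl number of QTLs.
#' @param p_negative probability that a mutant-allele effect is negative
#'   (default 0.9).
#' @return numeric effect vector of length `n_qtl`.
#' @export
sample_qtl_effects <- function(n_qtl, p_negative = 0.9) {
  if (n_qtl < 1) stop("invalid configuration: n_qtl must be >= 1")
  if (p_negative < 0 || p_negative > 1)
    stop("invalid configuration: p_negative must be in [0, 1]")
  mag <- rexp(n_qtl, rate = 1)
  sgn <- ifelse(runif(n_qtl) < p_negative, -1, 1)
  mag * sgn
}

#' Sample multi-trait QTL effects
#'
#' Each QTL receives an effect vector drawn i.i.d. from a multivariate
#' normal distribution with the given genetic (co)variance matrix, so
#' correlated traits share the same set of QTLs with correlated effects.
#'
#' @param n_qtl number of QTLs.
#' @param genetic_covariance symmetric PSD matrix (traits x traits).
#' @return matrix of effects, `n_qtl` rows x traits columns.
#' @export
sample_qtl_effects_multitrait <- function(n_qtl, genetic_covariance) {
  S <- as.matrix(genetic_covariance)
  if (!isSymmetric(unname(S), tol = 1e-8))
    stop("invalid configuration: genetic covariance must be symmetric")
  ev <- eigen(S, symmetric = TRUE)
  if (any(ev$values < -1e-8 * max(abs(ev$values), 1)))
    stop("invalid configuration: genetic covariance must be positive semi-definite")
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  matrix(rnorm(n_qtl * ncol(S)), n_qtl) %*% rt
}

#' True breeding values from allele dosages
#'
#' `g = sum_j x_j a_j` with dosages `x_j` in 0/1/2 counting copies of the
#' mutant allele at each QTL.
#'
#' @param dosage numeric vector (one plant) or matrix (plants x QTLs).
#' @param effects effect vector or matrix (QTLs x traits).
#' @return TBV scalar, vector or matrix (plants x traits).
#' @export
compute_tbv <- function(dosage, effects) {
  effects <- as.matrix(effects)
  if (is.matrix(dosage)) {
    stopifnot(ncol(dosage) == nrow(effects))
    r <- dosage %*% effects
    if (ncol(r) == 1) as.vector(r) else r
  } else {
    stopifnot(length(dosage) == nrow(effects))
    r <- as.vector(dosage %*% effects)
    if (length(r) == 1) r[[1]] else r
  }
}

#' Allele-dosage matrix of a cohort
#'
#' Counts of the mutant allele (0/1/2) per plant at the requested loci —
#' QTLs by default; pass `map$marker_cols` for the marker panel used in
#' genomic prediction.
#'
#' @param cohort a cohort.
#' @param map the genome map.
#' @param cols locus columns (default: QTL columns).
#' @export
cohort_dosage <- function(cohort, map, cols = map$qtl_cols) {
  cohort$hap1[, cols, drop = FALSE] + cohort$hap2[, cols, drop = FALSE]
}

#' Standardize QTL effects to a target additive variance
#'
#' Multiplies each trait's effect vector by a single scalar so that the
#' realized variance (denominator n-1) of the base cohort's TBVs equals the
#' target genetic variance exactly. The base cohort should be an unselected,
#' non-inbred (Hardy-Weinberg) sample from the founder pool: the genetic
#' variance parameter of the package refers to this outbred base variance,
#' and fully inbred lines then carry twice that variance between lines.
#'
#' @param effects effect vector or matrix (QTLs x traits).
#' @param base_dosage dosage matrix of the base cohort (plants x QTLs).
#' @param sigma_g2 target variance(s), one per trait.
#' @return scaled effects with attribute `scalars`.
#' @export
standardize_effects <- function(effects, base_dosage, sigma_g2) {
  effects <- as.matrix(effects)
  if (nrow(base_dosage) < 2) stop("base cohort must contain at least 2 plants")
  sigma_g2 <- rep_len(sigma_g2, ncol(effects))
  tbv <- base_dosage %*% effects
  v <- apply(tbv, 2, var)
  if (any(v <= 0))
    stop("standardization error: no segregating QTL variance in the base cohort")
  s <- sqrt(sigma_g2 / v)
  out <- sweep(effects, 2, s, `*`)
  attr(out, "scalars") <- s
  out
}

#' Residual variance from plot heritability
#'
#' Closed form under Hardy-Weinberg assumptions:
#' `sigma_e2 = 2 Ns H sigma_g2 (1 - h2_plot)/h2_plot - (1 - H) sigma_g2`,
#' where `H` is the expected homozygosity frequency of the generation and
#' `Ns` the number of plants per plot. Between-line genetic variance
#' `2 H sigma_g2` is signal; within-line genetic variance `(1 - H) sigma_g2`
#' joins the residual. At `H = 1` this reduces to the fully-inbred form
#' `2 Ns sigma_g2 (1 - h2)/h2`.
#'
#' @param sigma_g2 additive genetic variance (outbred base scale).
#' @param h2_plot target plot heritability, in (0, 1].
#' @param Ns plants grown per plot.
#' @param H homozygosity frequency in the generation, in \[0, 1\].
#' @return residual variance per individual phenotype.
#' @export
calibrate_residual_variance <- function(sigma_g2, h2_plot, Ns, H) {
  if (h2_plot <= 0 || h2_plot > 1)
    stop("invalid configuration: h2_plot must be in (0, 1]")
  if (Ns < 1) stop("invalid configuration: Ns must be >= 1")
  if (H < 0 || H > 1) stop("invalid configuration: H must be in [0, 1]")
  se2 <- 2 * Ns * H * sigma_g2 * (1 - h2_plot) / h2_plot - (1 - H) * sigma_g2
  if (se2 < 0) {
    h2_max <- 2 * Ns * H / (2 * Ns * H + (1 - H))
    stop(sprintf(
      "infeasible h2_plot target: closed form gives negative residual variance (h2_plot must be <= %.4f)",
      h2_max))
  }
  se2
}

#' Empirical recalibration of residual variance
#'
#' Trial-and-error loop for use under selection, where the closed form is
#' only a starting value: simulate the stage with the current residual
#' variance, measure the realized plot heritability, and adjust the residual
#' variance multiplicatively (odds matching) until within tolerance.
#'
#' @param simulate_h2 function(sigma_e2) returning the realized plot
#'   heritability of the simulated stage.
#' @param target target plot heritability.
#' @param sigma_e2_init starting value (e.g. the closed form).
#' @param tol convergence tolerance on h2 (default 0.01).
#' @param max_iter maximum iterations (default 20).
#' @return list with `sigma_e2`, `h2_realized`, `iterations`, `converged`.
#' @export
calibrate_residual_variance_empirical <- function(simulate_h2, target,
                                                  sigma_e2_init,
                                                  tol = 0.01, max_iter = 20) {
  se2 <- sigma_e2_init
  h2 <- simulate_h2(se2)
  it <- 1
  while (abs(h2 - target) > tol && it < max_iter) {
    ## realized odds of noise vs signal scale linearly in sigma_e2
    se2 <- se2 * (h2 * (1 - target)) / (target * (1 - h2))
    h2 <- simulate_h2(se2)
    it <- it + 1
  }
  list(sigma_e2 = se2, h2_realized = h2, iterations = it,
       converged = abs(h2 - target) <= tol)
}

#' Realize phenotypes
#'
#' `y = g + e` with `e ~ N(0, sigma_e2)`, independent across plants, traits
#' and observations.
#'
#' @param tbv vector of true breeding values.
#' @param sigma_e2 residual variance.
#' @param n_obs number of independent observations per plant (default 1).
#' @return vector (n_obs = 1) or matrix (plants x observations).
#' @export
realize_phenotype <- function(tbv, sigma_e2, n_obs = 1) {
  n <- length(tbv)
  e <- matrix(rnorm(n * n_obs, 0, sqrt(sigma_e2)), n, n_obs)
  y <- tbv + e
  if (n_obs == 1) as.vector(y) else y
}

#' Plot-level phenotype
#'
#' A plot's value is the SUM of its member plants' phenotypes (with the
#' companion sum of member TBVs for diagnostics); plot heritability is the
#' squared correlation between the two sums.
#'
#' @param phenotypes member phenotypes.
#' @param tbv member TBVs (optional).
#' @return list with `phenotype` and (if given) `tbv` sums.
#' @export
plot_phenotype <- function(phenotypes, tbv = NULL) {
  if (length(phenotypes) == 0) stop("empty plot")
  out <- list(phenotype = sum(phenotypes))
  if (!is.null(tbv)) out$tbv <- sum(tbv)
  out
}

#' Aggregate breeding value
#'
#' Weighted sum of per-trait TBVs by their economic values; stage-specific
#' economic values override the global ones when provided.
#'
#' @param tbv vector (one plant) or matrix (plants x traits).
#' @param economic_values global weights, one per trait.
#' @param stage_values optional stage-specific weights.
#' @return scalar or vector of aggregate breeding values.
#' @export
aggregate_breeding_value <- function(tbv, economic_values,
                                     stage_values = NULL) {
  v <- if (!is.null(stage_values)) stage_values else economic_values
  if (is.matrix(tbv)) {
    stopifnot(ncol(tbv) == length(v))
    as.vector(tbv %*% v)
  } else {
    stopifnot(length(tbv) == length(v))
    sum(tbv * v)
  }
}

## ---------------------------------------------------------------------------
## Infinitesimal model
## ---------------------------------------------------------------------------

#' Base-population TBVs under the infinitesimal model
#'
#' @param n number of plants.
#' @param sigma_g2 additive genetic variance.
#' @export
infinitesimal_base_tbv <- function(n, sigma_g2) rnorm(n, 0, sqrt(sigma_g2))

#' Offspring TBV under the infinitesimal model
#'
#' Midparent plus a Mendelian-sampling deviation with variance
#' `0.5 sigma_g2 (1 - (F_sire + F_dam)/2)`; inbreeding of the parents
#' shrinks the within-family variance.
#'
#' @param sire_tbv,dam_tbv parental TBVs (vectorized).
#' @param sire_f,dam_f parental inbreeding coefficients in \[0, 1\].
#' @param sigma_g2 base additive genetic variance.
#' @param n number of offspring (default: length of the parent vectors).
#' @export
infinitesimal_offspring_tbv <- function(sire_tbv, dam_tbv, sire_f, dam_f,
                                        sigma_g2, n = max(length(sire_tbv),
                                                          length(dam_tbv))) {
  if (any(c(sire_f, dam_f) < 0) || any(c(sire_f, dam_f) > 1))
    stop("invalid configuration: inbreeding coefficients must be in [0, 1]")
  mid <- (rep_len(sire_tbv, n) + rep_len(dam_tbv, n)) / 2
  vm <- 0.5 * sigma_g2 * (1 - (rep_len(sire_f, n) + rep_len(dam_f, n)) / 2)
  mid + rnorm(n, 0, sqrt(vm))
}
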