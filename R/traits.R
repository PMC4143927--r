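#' Define the generative model for one protein trait
#'
#' A trait on the ddCq (log2) scale is built additively from covariate
#' effects, an optional cis-SNP dosage effect, a polygenic component with
#' covariance `sigma2g * K`, and independent residual noise, scaled so the
#' expected total variance is `sigma_total`. The narrow-sense heritability
#' target `h2` is the polygenic fraction of `sigma_total`; the fractions
#' explained by covariates and the cis SNP are checked at simulation time
#' so that all explained fractions together stay below 1.
#'
#' @param name Protein/trait name.
#' @param h2 Target narrow-sense heritability in [0, 1]; at 1 the trait is
#'   purely polygenic (no residual noise).
#' @param sigma_total Total trait variance in ddCq^2 units.
#' @param mean Trait mean (ddCq units).
#' @param covariate_effects Named numeric vector of linear coefficients on
#'   covariate columns (effects on the ddCq scale per covariate unit).
#' @param cis_snp Optional marker id (character) carrying a dosage effect.
#' @param beta_snp Effect size per dosage unit for `cis_snp`.
#' @param lod_censor_fraction Fraction in [0, 1) of lowest values rendered
#'   below the detection limit by the plate renderer.
#' @param batch_effect Additive ddCq shift applied to the "replication"
#'   cohort (a sample-round/storage-time style batch effect).
#' @return An object of class `trait_model`.
#' @export
trait_model <- function(name, h2, sigma_total = 1, mean = 5,
                        covariate_effects = NULL,
                        cis_snp = NULL, beta_snp = 0,
                        lod_censor_fraction = 0, batch_effect = 0) {
  if (h2 < 0 || h2 > 1) stop("'h2' must lie in [0, 1]", call. = FALSE)
  if (sigma_total <= 0) stop("'sigma_total' must be positive", call. = FALSE)
  if (lod_censor_fraction < 0 || lod_censor_fraction >= 1) {
    stop("'lod_censor_fraction' must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(name = name, h2 = h2, sigma_total = sigma_total, mean = mean,
         covariate_effects = covariate_effects, cis_snp = cis_snp,
         beta_snp = beta_snp, lod_censor_fraction = lod_censor_fraction,
         batch_effect = batch_effect),
    class = "trait_model"
  )
}

#' Simulate heritable protein traits on a family cohort
#'
#' Draws `y = mean + X beta + g beta_snp + batch + u + e` per trait, with
#' `u ~ MVN(0, sigma2g K)` (one Cholesky factor of `K` shared across
#' traits and replicates) and `e` iid normal. `sigma2g = h2 * sigma_total`;
#' the residual variance is `sigma_total` minus `sigma2g` minus the
#' empirical variance of all fixed parts, which must be non-negative.
#' Realized components are stored so recovery tests can compare against
#' truth.
#'
#' @param models List of [trait_model()] objects (or a single one).
#' @param ped A `pedigree`.
#' @param genotypes A `genotype_dosages`, required when any model has a
#'   cis SNP.
#' @param covariates A `covariate_table`, required when any model has
#'   covariate effects.
#' @param kinship Optional relationship matrix (expected value 2 * kinship);
#'   defaults to [kinship_from_pedigree()] of `ped`.
#' @param seed Optional integer seed.
#' @return A list of class `trait_panel`: `ddcq` (traits x individuals
#'   matrix), `models`, and `components` (per trait: list with `fixed`,
#'   `snp`, `polygenic`, `residual` vectors).
#' @export
simulate_traits <- function(models, ped, genotypes = NULL, covariates = NULL,
                            kinship = NULL, seed = NULL) {
  if (inherits(models, "trait_model")) models <- list(models)
  stopifnot(inherits(ped, "pedigree"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  if (is.null(kinship)) kinship <- kinship_from_pedigree(ped)
  stopifnot(nrow(kinship) == n)
  L <- t(chol(kinship + diag(1e-8, n)))

  ddcq <- matrix(NA_real_, length(models), n,
                 dimnames = list(vapply(models, `[[`, "", "name"), ped$id))
  comps <- vector("list", length(models))
  for (k in seq_along(models)) {
    m <- models[[k]]
    fixed <- rep(m$mean, n)
    if (!is.null(m$covariate_effects) && length(m$covariate_effects)) {
      if (is.null(covariates)) stop("covariate effects given but no covariate table", call. = FALSE)
      for (nm in names(m$covariate_effects)) {
        x <- covariates$data[[nm]]
        if (is.null(x)) stop(sprintf("unknown covariate '%s'", nm), call. = FALSE)
        fixed <- fixed + m$covariate_effects[[nm]] * as.numeric(x)
      }
    }
    snp_part <- rep(0, n)
    if (!is.null(m$cis_snp)) {
      if (is.null(genotypes)) stop("cis SNP given but no genotypes", call. = FALSE)
      g <- genotypes$dosage[, m$cis_snp]
      if (is.null(g)) stop(sprintf("marker '%s' not found", m$cis_snp), call. = FALSE)
      snp_part <- m$beta_snp * g
    }
    batch <- ifelse(ped$cohort == "replication", m$batch_effect, 0)

    sigma2g <- m$h2 * m$sigma_total
    var_fixed <- stats::var(fixed + snp_part + batch)
    sigma2e <- m$sigma_total - sigma2g - var_fixed
    if (sigma2e < 0) {
      stop(sprintf(
        "trait '%s': heritability plus fixed-effect variance fractions exceed 1 (fixed fraction %.2f)",
        m$name, var_fixed / m$sigma_total), call. = FALSE)
    }
    u <- sqrt(sigma2g) * as.numeric(L %*% stats::rnorm(n))
    e <- stats::rnorm(n, 0, sqrt(sigma2e))
    ddcq[k, ] <- fixed + snp_part + batch + u + e
    comps[[k]] <- list(fixed = fixed, snp = snp_part, batch = batch,
                       polygenic = u, residual = e,
                       sigma2g = sigma2g, sigma2e = sigma2e)
  }
  names(comps) <- rownames(ddcq)
  structure(list(ddcq = ddcq, models = models, components = comps),
            class = "trait_panel")
}
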