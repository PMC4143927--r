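#' Stratified personalized reference intervals for a biomarker
#'
#' Fits a normal distribution (mean, SD on the ddCq scale) within each
#' stratum of a genotype, covariate-bin or medication stratifier and
#' reports the normal-fit central interval (default 95%:
#' `mean +/- 1.96 SD`) and interquartile range (`mean +/- 0.6745 SD`).
#' Strata with fewer than `min_group_size` individuals are suppressed.
#' The central-interval percentile is a configurable convention, not an
#' empirically validated clinical threshold.
#'
#' @param values Named numeric vector of ddCq values (`NA` dropped).
#' @param strata Vector (same length/order) of stratum labels; `NA`
#'   individuals are dropped.
#' @param min_group_size Minimum stratum size to report (default 10).
#' @param level Central-interval coverage (default 0.95).
#' @return A data.frame of class `cutoff_profile`: `stratum`, `n`,
#'   `mean`, `sd`, `lower`, `upper` (central interval), `iqr_lower`,
#'   `iqr_upper`. Suppressed strata are listed in attribute
#'   `suppressed`. Empty (with a warning) if no stratum qualifies.
#' @export
stratified_reference <- function(values, strata, min_group_size = 10,
                                 level = 0.95) {
  stopifnot(length(values) == length(strata))
  keep <- is.finite(values) & !is.na(strata)
  values <- values[keep]
  strata <- as.character(strata[keep])
  z <- stats::qnorm((1 + level) / 2)
  zq <- stats::qnorm(0.75)
  rows <- lapply(sort(unique(strata)), function(s) {
    v <- values[strata == s]
    data.frame(stratum = s, n = length(v), mean = mean(v), sd = stats::sd(v),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  suppressed <- tab$stratum[tab$n < min_group_size]
  tab <- tab[tab$n >= min_group_size, , drop = FALSE]
  if (!nrow(tab)) {
    warning("no stratum reaches the minimum group size", call. = FALSE)
  } else {
    tab$lower <- tab$mean - z * tab$sd
    tab$upper <- tab$mean + z * tab$sd
    tab$iqr_lower <- tab$mean - zq * tab$sd
    tab$iqr_upper <- tab$mean + zq * tab$sd
  }
  rownames(tab) <- NULL
  attr(tab, "suppressed") <- suppressed
  attr(tab, "level") <- level
  class(tab) <- c("cutoff_profile", "data.frame")
  tab
}

#' Ratio of two ddCq means on the linear scale
#'
#' ddCq values live on a log2 abundance scale, so the linearized level of
#' stratum `a` relative to stratum `b` is `100 * 2^(mean_a - mean_b)`
#' percent.
#'
#' @param mean_a,mean_b Stratum means (ddCq).
#' @return Percentage.
#' @examples
#' linearized_ratio(6, 5)  # 200: one ddCq unit is a doubling
#' @export
linearized_ratio <- function(mean_a, mean_b) {
  if (any(!is.finite(c(mean_a, mean_b)))) stop("non-finite input", call. = FALSE)
  100 * 2^(mean_a - mean_b)
}

#' Ranked factor-contribution profile for a biomarker
#'
#' Combines the per-covariate sequential variance fractions with the
#' top-marker (and optionally conditional-marker) variance-explained
#' fractions into one ranked table, and computes the combined-model total
#' fraction: the R^2 of a single linear model containing all covariates
#' plus the top-ranking marker dosage(s).
#'
#' @param vd A `variance_decomposition` for the biomarker.
#' @param snp_varexpl Named numeric vector of per-marker variance
#'   explained fractions (e.g. top SNP and conditional top SNP); may be
#'   empty.
#' @param y Raw trait values (named) for the combined model, or `NULL`
#'   to skip the combined fit.
#' @param covariates The `covariate_table` used in `vd`.
#' @param dosages Named list (or matrix columns) of the marker dosages to
#'   include in the combined model.
#' @return A list of class `covariate_profile`: `ranked` (data.frame
#'   `factor`, `fraction`, `kind`), `combined_fraction` (or `NA` with a
#'   flag when inputs are missing).
#' @export
covariate_profile <- function(vd, snp_varexpl = numeric(0), y = NULL,
                              covariates = NULL, dosages = NULL) {
  tab <- rbind(
    data.frame(factor = vd$table$term, fraction = vd$table$fraction,
               kind = "covariate", stringsAsFactors = FALSE),
    if (length(snp_varexpl)) data.frame(factor = names(snp_varexpl),
                                        fraction = as.numeric(snp_varexpl),
                                        kind = "snp", stringsAsFactors = FALSE)
  )
  tab <- tab[order(-tab$fraction), , drop = FALSE]
  rownames(tab) <- NULL
  combined <- NA_real_
  partial <- TRUE
  if (!is.null(y) && !is.null(covariates)) {
    dat <- covariate_frame(covariates)
    if (!is.null(names(y))) dat <- dat[names(y), , drop = FALSE]
    if (!is.null(dosages)) {
      dos <- as.data.frame(dosages)
      if (!is.null(names(y))) dos <- dos[names(y), , drop = FALSE]
      dat <- cbind(dat, dos)
    }
    keep <- is.finite(y) & stats::complete.cases(dat)
    fit <- stats::lm(y[keep] ~ ., data = dat[keep, , drop = FALSE])
    combined <- summary(fit)$r.squared
    partial <- FALSE
  }
  structure(list(ranked = tab, combined_fraction = combined,
                 partial = partial),
            class = "covariate_profile")
}
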