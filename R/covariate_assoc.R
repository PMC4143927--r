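#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 158)       # 3.16e-4
#' bonferroni_threshold(0.05, 4840842)   # 1.03e-8
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)", call. = FALSE)
  if (m < 1) stop("'m' must be >= 1", call. = FALSE)
  alpha / m
}

# Build a model frame from a covariate table; categorical covariates are
# expanded by R's treatment contrasts with alphabetically first level as
# reference (factor levels are sorted at construction).
covariate_frame <- function(covariates, columns = NULL) {
  dat <- covariates$data
  if (!is.null(columns)) dat <- dat[, columns, drop = FALSE]
  dat
}

#' Fit the all-covariates linear model for one protein
#'
#' Ordinary least squares of the trait (ddCq, below-LOD cells excluded)
#' on every covariate simultaneously, on complete cases. Covariates that
#' are constant on the analysis sample or aliased with earlier terms are
#' dropped with a warning. Per-term significance comes from the
#' sequential (type-I) analysis-of-variance F tests, with terms entered
#' in covariate-table column order.
#'
#' @param y Named numeric vector of trait values (`NA` = missing or
#'   below LOD).
#' @param covariates A `covariate_table`; rows are matched to `names(y)`.
#' @return A list of class `trait_fit`: `fit` (the `lm`), `anova`
#'   (sequential ANOVA table), `n`, `dropped` (aliased/constant terms),
#'   `terms` (order used).
#' @export
fit_full_model <- function(y, covariates) {
  stopifnot(inherits(covariates, "covariate_table"))
  dat <- covariate_frame(covariates)
  if (!is.null(names(y))) dat <- dat[names(y), , drop = FALSE]
  keep <- is.finite(y)
  for (j in seq_along(dat)) keep <- keep & !is.na(dat[[j]])
  dat <- dat[keep, , drop = FALSE]
  yy <- y[keep]

  constant <- vapply(dat, function(x) length(unique(x)) < 2L, logical(1))
  dropped <- names(dat)[constant]
  if (length(dropped)) {
    warning("dropping constant covariate(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
    dat <- dat[, !constant, drop = FALSE]
  }
  if (length(yy) <= ncol(dat) + 1L) {
    stop("not enough complete observations for the model", call. = FALSE)
  }
  df <- cbind(.y = yy, dat)
  fit <- stats::lm(.y ~ ., data = df)
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased)) {
    warning("aliased term(s) dropped from decomposition: ",
            paste(aliased, collapse = ", "), call. = FALSE)
  }
  structure(list(fit = fit, anova = stats::anova(fit), n = length(yy),
                 dropped = dropped, terms = names(dat)),
            class = "trait_fit")
}

#' Sequential variance decomposition of a fitted trait model
#'
#' Attributes trait variance to covariates by incremental (type-I) sums
#' of squares: `fraction(term) = seqSS(term) / totalSS`. The combined
#' fraction is the model R^2 (sum of term fractions). Order-dependent by
#' construction; the order used is recorded.
#'
#' @param tf A `trait_fit` from [fit_full_model()].
#' @return A list of class `variance_decomposition`: `table` (data.frame
#'   `term`, `fraction`, `p`), `combined_fraction`, `residual_fraction`,
#'   `order`, `n`.
#' @export
variance_decomposition <- function(tf) {
  stopifnot(inherits(tf, "trait_fit"))
  a <- tf$anova
  ss <- a[["Sum Sq"]]
  total <- sum(ss)
  if (total <= 0) stop("zero total sum of squares", call. = FALSE)
  terms <- rownames(a)
  resid_row <- terms == "Residuals"
  tab <- data.frame(term = terms[!resid_row],
                    fraction = ss[!resid_row] / total,
                    p = a[["Pr(>F)"]][!resid_row],
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 combined_fraction = sum(tab$fraction),
                 residual_fraction = ss[resid_row] / total,
                 order = tab$term, n = tf$n),
            class = "variance_decomposition")
}

#' Select significant covariates by the Bonferroni screen
#'
#' @param vd A `variance_decomposition`.
#' @param alpha Family-wise rate (default 0.05).
#' @param m Number of covariates tested (defaults to the number of terms).
#' @return Character vector of significant covariate names.
#' @export
significant_covariates <- function(vd, alpha = 0.05, m = NULL) {
  if (is.null(m)) m <- nrow(vd$table)
  thr <- bonferroni_threshold(alpha, m)
  vd$table$term[!is.na(vd$table$p) & vd$table$p < thr]
}

#' Adjust a trait for covariates and rank-transform to normality
#'
#' Residualizes the trait on the given covariates (OLS on complete
#' cases; intercept only if none), then maps average-tie ranks through
#' the standard normal quantile at `(rank - 0.5) / n`. The result is
#' invariant to any strictly monotone transform that preserves residual
#' ranks, and to affine transforms of the trait when the covariate set is
#' unchanged.
#'
#' @param y Named trait vector (`NA` = missing/below LOD).
#' @param covariates A `covariate_table` (or `NULL` for no adjustment).
#' @param which_covariates Character vector of covariate columns to
#'   adjust for (possibly empty).
#' @return A list of class `adjusted_trait`: `values` (named, `NA` where
#'   missing), `adjusted_for`, `n`.
#' @export
adjust_and_rint <- function(y, covariates = NULL, which_covariates = character(0)) {
  ids <- names(y)
  keep <- is.finite(y)
  resid <- rep(NA_real_, length(y))
  if (length(which_covariates)) {
    dat <- covariate_frame(covariates, which_covariates)
    if (!is.null(ids)) dat <- dat[ids, , drop = FALSE]
    for (j in seq_along(dat)) keep <- keep & !is.na(dat[[j]])
    df <- cbind(.y = y, dat)[keep, , drop = FALSE]
    resid[keep] <- stats::resid(stats::lm(.y ~ ., data = df))
  } else {
    resid[keep] <- y[keep] - mean(y[keep])
  }
  r <- resid[keep]
  if (length(unique(r)) < 3L) stop("fewer than 3 distinct residual values", call. = FALSE)
  n <- length(r)
  z <- stats::qnorm((rank(r, ties.method = "average") - 0.5) / n)
  out <- rep(NA_real_, length(y))
  out[keep] <- z
  names(out) <- ids
  structure(list(values = out, adjusted_for = which_covariates, n = n),
            class = "adjusted_trait")
}

#' Pairwise Spearman correlations between adjusted biomarkers
#'
#' @param panel Numeric matrix, proteins x individuals (`NA` allowed);
#'   e.g. rows of [adjust_and_rint()] values.
#' @param r2_min Report pairs with squared Spearman correlation strictly
#'   greater than this (default 0.5).
#' @param min_overlap Minimum shared observations per pair (default 3);
#'   pairs below it are skipped with a warning.
#' @return A data.frame (`protein_a`, `protein_b`, `rho`, `r2`) sorted by
#'   decreasing `r2`, containing the reported pairs; the full correlation
#'   matrix is attached as attribute `rho`.
#' @export
correlate_pairs <- function(panel, r2_min = 0.5, min_overlap = 3) {
  if (nrow(panel) < 2) stop("need at least two proteins", call. = FALSE)
  rho <- stats::cor(t(panel), method = "spearman", use = "pairwise.complete.obs")
  obs <- !is.na(panel)
  n_shared <- obs %*% t(obs)
  few <- which(n_shared < min_overlap & upper.tri(n_shared), arr.ind = TRUE)
  if (nrow(few)) {
    warning(sprintf("%d pair(s) skipped: fewer than %d shared observations",
                    nrow(few), min_overlap), call. = FALSE)
    rho[n_shared < min_overlap] <- NA
  }
  idx <- which(upper.tri(rho) & !is.na(rho) & rho^2 > r2_min, arr.ind = TRUE)
  out <- data.frame(protein_a = rownames(panel)[idx[, 1]],
                    protein_b = rownames(panel)[idx[, 2]],
                    rho = rho[idx], r2 = rho[idx]^2,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$r2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rho") <- rho
  out
}
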