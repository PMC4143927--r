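#' Kinship-adjusted score test for one marker
#'
#' Score ("mmscore"-style) test using a fitted polygenic model's
#' residuals and inverse trait covariance. The dosage is centered by
#' projecting it off the fixed-effect design under the `Omega^-1` inner
#' product (for an intercept-only design this is the precision-weighted
#' mean), which makes the statistic algebraically identical to the Wald
#' test from a full generalized-least-squares refit with the marker as an
#' extra fixed effect, at fixed variance components:
#' `beta = (gc' Omega^-1 r) / (gc' Omega^-1 gc)`,
#' `se = (gc' Omega^-1 gc)^(-1/2)`, `chi2 = (beta/se)^2`, p from
#' `chi2_1`, and variance explained `chi2 / N`.
#'
#' @param fit A `polygenic_fit`.
#' @param g Dosage vector aligned to `fit$ids` (missing dosages are
#'   mean-imputed).
#' @return A list of class `score_result`: `beta`, `se`, `chi2`, `p`,
#'   `var_expl`, `n`, or `NULL` (with a warning) for a zero-variance
#'   marker.
#' @export
mmscore <- function(fit, g) {
  res <- mmscore_scan(fit, matrix(g, ncol = 1))
  if (!nrow(res)) {
    warning("marker skipped: zero dosage variance", call. = FALSE)
    return(NULL)
  }
  structure(c(as.list(res[1, c("beta", "se", "chi2", "p", "var_expl")]),
              n = fit$n),
            class = "score_result")
}

#' Vectorized kinship-adjusted score scan
#'
#' @param fit A `polygenic_fit`.
#' @param G Dosage matrix, individuals x markers, aligned to `fit$ids`.
#' @param min_mac Markers with minor-allele count below this are skipped
#'   (default 0 = keep all polymorphic markers).
#' @return A data.frame with one row per tested marker: `marker`, `beta`,
#'   `se`, `chi2`, `p`, `var_expl`. Monomorphic (or sub-MAC) markers are
#'   omitted; their ids are in attribute `skipped`.
#' @export
mmscore_scan <- function(fit, G, min_mac = 0) {
  stopifnot(inherits(fit, "polygenic_fit"))
  G <- as.matrix(G)
  if (is.null(colnames(G))) colnames(G) <- sprintf("g%d", seq_len(ncol(G)))
  if (nrow(G) != fit$n) stop("dosage rows must match the fitted sample", call. = FALSE)
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  mac <- pmin(colSums(G), 2 * nrow(G) - colSums(G))
  poly <- apply(G, 2, function(g) stats::var(g) > 0)
  ok <- poly & mac >= min_mac
  skipped <- colnames(G)[!ok]
  G <- G[, ok, drop = FALSE]
  if (!ncol(G)) {
    out <- data.frame(marker = character(), beta = numeric(), se = numeric(),
                      chi2 = numeric(), p = numeric(), var_expl = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "skipped") <- skipped
    return(out)
  }
  Oi <- fit$omega_inv
  X <- fit$X
  r <- fit$residuals
  Or <- Oi %*% r
  OX <- Oi %*% X
  XtOX <- crossprod(X, OX)
  # project each marker off X under the Omega^-1 metric
  A <- solve(XtOX, crossprod(OX, G))        # k x m coefficients
  num <- as.numeric(crossprod(G, Or)) - as.numeric(crossprod(A, crossprod(X, Or)))
  OG_diag <- colSums(G * (Oi %*% G))
  den <- OG_diag - colSums(A * (XtOX %*% A))
  # markers (near-)collinear with the fixed effects carry no score
  # information: their projected dosage is numerically zero
  degenerate <- den <= 1e-10 * pmax(OG_diag, 1e-300)
  beta <- ifelse(degenerate, 0, num / den)
  se <- ifelse(degenerate, Inf, 1 / sqrt(den))
  chi2 <- ifelse(degenerate, 0, num^2 / den)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  out <- data.frame(marker = colnames(G), beta = beta, se = se, chi2 = chi2,
                    p = p, var_expl = chi2 / fit$n,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "skipped") <- skipped
  out
}

#' Genomic inflation factor
#'
#' Median of the observed 1-df chi-square statistics divided by the null
#' median (`qchisq(0.5, 1)`, about 0.4549).
#'
#' @param chi2 Numeric vector of 1-df chi-square statistics.
#' @return Lambda.
#' @export
genomic_lambda <- function(chi2) {
  stats::median(chi2) / stats::qchisq(0.5, df = 1)
}

#' Invert a printed p-value to the variance-explained fraction
#'
#' The per-marker effect-size summary on the adjusted phenotype scale is
#' `chi2 / N`; given a reported two-sided 1-df p-value and the sample
#' size, the fraction is recovered as `qchisq(p, 1, lower = FALSE) / N`.
#'
#' @param p Two-sided p-value from a 1-df chi-square statistic.
#' @param n Number of samples used.
#' @param percent Return a percentage (default `TRUE`).
#' @return Variance explained (percent or fraction).
#' @export
varexpl_from_p <- function(p, n, percent = TRUE) {
  v <- stats::qchisq(p, df = 1, lower.tail = FALSE) / n
  if (percent) 100 * v else v
}

#' Discovery / replication / combined association scans
#'
#' For one adjusted trait: fits the polygenic model in the discovery
#' cohort and scans all markers at the Bonferroni discovery threshold
#' `alpha / n_markers`; re-tests the discovery hits in the replication
#' cohort at `alpha / n_hits`; and scans all markers in the pooled
#' sample (variance components refitted there) at the discovery
#' threshold. Markers below the minor-allele-count floor in a cohort are
#' skipped. Reports the genomic inflation factor per scan.
#'
#' @param y Named adjusted trait vector over the full sample (`NA`
#'   allowed).
#' @param genotypes A `genotype_dosages` covering the full sample.
#' @param cohort Character vector (aligned with `y`) of
#'   `"discovery"`/`"replication"` labels.
#' @param K Relationship matrix over the full sample.
#' @param alpha Family-wise rate (default 0.05).
#' @param min_mac Minimum minor-allele count per cohort (default 3).
#' @return A list of class `gwas_result`: per-phase score tables
#'   (`discovery`, `replication`, `combined`), `hits` per phase,
#'   `lambda` per phase, `thresholds`, `fits` (the three polygenic
#'   fits), `n` per phase.
#' @export
run_gwas <- function(y, genotypes, cohort, K, alpha = 0.05, min_mac = 3) {
  G <- genotypes$dosage
  ids <- names(y)
  stopifnot(!is.null(ids), all(ids %in% rownames(G)))
  if (!all(c("discovery", "replication") %in% cohort)) {
    stop("both cohorts must be non-empty", call. = FALSE)
  }
  phases <- list(discovery = ids[cohort == "discovery"],
                 replication = ids[cohort == "replication"],
                 combined = ids)
  m <- ncol(G)
  thr_disc <- bonferroni_threshold(alpha, m)

  fit_phase <- function(who) {
    yy <- y[who]
    fit_polygenic(yy, K[who, who, drop = FALSE])
  }
  scan_phase <- function(fit, markers = NULL) {
    Gp <- G[fit$ids, , drop = FALSE]
    if (!is.null(markers)) Gp <- Gp[, markers, drop = FALSE]
    mmscore_scan(fit, Gp, min_mac = min_mac)
  }

  fits <- lapply(phases, fit_phase)
  disc <- scan_phase(fits$discovery)
  disc_hits <- disc$marker[disc$p < thr_disc]
  thr_repl <- if (length(disc_hits)) bonferroni_threshold(alpha, length(disc_hits)) else NA_real_
  repl <- if (length(disc_hits)) scan_phase(fits$replication, disc_hits) else
    disc[0, , drop = FALSE]
  repl_hits <- repl$marker[repl$p < thr_repl]
  comb <- scan_phase(fits$combined)
  comb_hits <- comb$marker[comb$p < thr_disc]

  structure(
    list(discovery = disc, replication = repl, combined = comb,
         hits = list(discovery = disc_hits, replication = repl_hits,
                     combined = comb_hits),
         lambda = list(discovery = genomic_lambda(disc$chi2),
                       replication = if (nrow(repl)) genomic_lambda(repl$chi2) else NA_real_,
                       combined = genomic_lambda(comb$chi2)),
         thresholds = list(discovery = thr_disc, replication = thr_repl,
                           combined = thr_disc),
         fits = fits,
         n = vapply(fits, `[[`, 0, "n")),
    class = "gwas_result")
}

#' Conditional association scan on the top-ranking marker
#'
#' Refits the polygenic model on the pooled sample with the top marker's
#' dosage as an extra fixed effect, then repeats the score test for the
#' remaining markers on the chromosome(s) carrying hits. Signals in
#' linkage with the top marker collapse; independent loci survive the
#' conditioning.
#'
#' @param y Named adjusted trait vector (full sample).
#' @param genotypes A `genotype_dosages`.
#' @param K Relationship matrix.
#' @param top_marker Marker id to condition on.
#' @param chromosomes Chromosomes to rescan (default: the top marker's).
#' @param cutoff Genome-wide significance cutoff for conditional hits
#'   (default 5e-8).
#' @return A list of class `conditional_result`: `scores`, `hits`,
#'   `top_marker`, `fit`.
#' @export
conditional_scan <- function(y, genotypes, K, top_marker,
                             chromosomes = NULL, cutoff = 5e-8) {
  G <- genotypes$dosage
  if (!top_marker %in% colnames(G)) stop("top marker not found", call. = FALSE)
  ids <- names(y)[is.finite(y)]
  g_top <- G[ids, top_marker]
  if (stats::var(g_top) == 0) stop("top marker has zero variance", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, top = g_top)
  fit <- fit_polygenic(y[ids], K[ids, ids, drop = FALSE], X = X)
  mk <- genotypes$markers
  if (is.null(chromosomes)) chromosomes <- mk$chr[mk$id == top_marker]
  rescan <- setdiff(mk$id[mk$chr %in% chromosomes], top_marker)
  sc <- mmscore_scan(fit, G[ids, rescan, drop = FALSE])
  structure(list(scores = sc, hits = sc$marker[sc$p < cutoff],
                 top_marker = top_marker, fit = fit),
            class = "conditional_result")
}

#' Variance explained by a single marker in the unadjusted trait
#'
#' Coefficient of determination of the ordinary single-marker linear
#' model on raw ddCq values (complete cases).
#'
#' @param y Numeric trait vector (raw ddCq; `NA` allowed).
#' @param g Dosage vector.
#' @return R^2 fraction.
#' @export
variance_explained_raw <- function(y, g) {
  keep <- is.finite(y) & is.finite(g)
  if (sum(keep) < 10) stop("fewer than 10 complete cases", call. = FALSE)
  if (stats::var(y[keep]) == 0) stop("zero trait variance", call. = FALSE)
  summary(stats::lm(y[keep] ~ g[keep]))$r.squared
}
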