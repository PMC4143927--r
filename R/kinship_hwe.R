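#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on genotype counts: given the observed allele
#' counts, every possible heterozygote count (same parity as the minor
#' allele count) is assigned its conditional probability
#' `P(nAa | n, nA) = C(n; nAA, nAa, naa) * 2^nAa / C(2n, nA)`, and the
#' p-value is the sum of probabilities of configurations no more probable
#' than the observed one. Invariant to swapping allele labels; a
#' monomorphic marker has p = 1.
#'
#' @param nAA,nAa,naa Genotype counts (non-negative, total > 0).
#' @return A list of class `hwe_result`: `counts`, `p`.
#' @export
hwe_exact <- function(nAA, nAa, naa) {
  counts <- c(nAA, nAa, naa)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero", call. = FALSE)
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  nm <- min(nA, na)                      # minor allele count
  hets <- seq(nm %% 2, nm, by = 2)       # feasible heterozygote counts
  # log conditional probability for each feasible het count
  logp <- vapply(hets, function(h) {
    aa_min <- (nm - h) / 2               # homozygotes of the minor allele
    AA_maj <- n - h - aa_min
    lgamma(n + 1) - lgamma(AA_maj + 1) - lgamma(h + 1) - lgamma(aa_min + 1) +
      h * log(2) - (lgamma(2 * n + 1) - lgamma(nA + 1) - lgamma(na + 1))
  }, numeric(1))
  p_all <- exp(logp - max(logp))
  p_all <- p_all / sum(p_all)
  p_obs <- p_all[match(nAa, hets)]
  p <- sum(p_all[p_all <= p_obs * (1 + 1e-12)])
  structure(list(counts = c(nAA = nAA, nAa = nAa, naa = naa),
                 p = min(1, p)),
            class = "hwe_result")
}

#' Genotype-level quality control
#'
#' Applies, in order: marker call-rate filter, individual call-rate
#' filter, exact Hardy-Weinberg filter at a Bonferroni-corrected level
#' (hard-call markers only; dosage-only markers skip HWE with a note),
#' and a minor-allele-count filter ("at least one chromosome", i.e.
#' MAC >= `mac_min`). Thresholds are retained-if-at-boundary: a marker
#' with exactly 95% calls passes.
#'
#' @param genotypes A `genotype_dosages` (dosage matrix may contain `NA`).
#' @param marker_call_rate Minimum per-marker call rate (default 0.95).
#' @param individual_call_rate Minimum per-individual call rate
#'   (default 0.98).
#' @param hwe_alpha Family-wise level for the HWE filter, Bonferroni
#'   corrected over tested markers (default 0.05).
#' @param mac_min Minimum minor-allele count (default 1).
#' @return The filtered `genotype_dosages` with a `qc_report` element
#'   (data.frame of removals with reasons, plus counts).
#' @export
genotype_qc <- function(genotypes, marker_call_rate = 0.95,
                        individual_call_rate = 0.98,
                        hwe_alpha = 0.05, mac_min = 1) {
  for (thr in c(marker_call_rate, individual_call_rate)) {
    if (thr <= 0 || thr > 1) stop("call-rate thresholds must lie in (0, 1]", call. = FALSE)
  }
  G <- genotypes$dosage
  removals <- data.frame(type = character(), id = character(),
                         reason = character(), stringsAsFactors = FALSE)
  add <- function(type, id, reason) {
    if (length(id)) rbind(removals, data.frame(type = type, id = id, reason = reason,
                                               stringsAsFactors = FALSE)) else removals
  }

  cr_marker <- colMeans(!is.na(G))
  bad <- colnames(G)[cr_marker < marker_call_rate]
  removals <- add("marker", bad, "marker call rate")
  G <- G[, cr_marker >= marker_call_rate, drop = FALSE]

  cr_ind <- rowMeans(!is.na(G))
  bad_i <- rownames(G)[cr_ind < individual_call_rate]
  removals <- add("individual", bad_i, "individual call rate")
  G <- G[cr_ind >= individual_call_rate, , drop = FALSE]

  if (isTRUE(genotypes$hard_calls) && ncol(G) > 0) {
    thr <- bonferroni_threshold(hwe_alpha, ncol(G))
    hwe_p <- apply(G, 2, function(g) {
      g <- g[!is.na(g)]
      hwe_exact(sum(g == 2), sum(g == 1), sum(g == 0))$p
    })
    bad_h <- colnames(G)[hwe_p < thr]
    removals <- add("marker", bad_h, "Hardy-Weinberg")
    G <- G[, hwe_p >= thr, drop = FALSE]
  }

  if (ncol(G) > 0) {
    alt <- colSums(G, na.rm = TRUE)
    tot <- 2 * colSums(!is.na(G))
    mac <- pmin(alt, tot - alt)
    bad_m <- colnames(G)[mac < mac_min]
    removals <- add("marker", bad_m, "minor-allele count")
    G <- G[, mac >= mac_min, drop = FALSE]
  }

  out <- genotypes
  out$dosage <- G
  out$markers <- genotypes$markers[match(colnames(G), genotypes$markers$id), , drop = FALSE]
  out$qc_report <- list(removals = removals,
                        n_markers_in = ncol(genotypes$dosage),
                        n_markers_out = ncol(G),
                        n_individuals_in = nrow(genotypes$dosage),
                        n_individuals_out = nrow(G))
  out
}

#' Genomic relationship (kinship) matrix
#'
#' Allele-frequency-standardized relationship estimator:
#' `K_ij = (1/L_ij) * sum_l (g_il - 2 p_l) (g_jl - 2 p_l) / (2 p_l (1 - p_l))`
#' with `p_l` the sample allele frequency over complete cases of marker
#' `l` and `L_ij` the number of markers observed in both individuals.
#' Its expected value is twice the kinship coefficient (1 on the diagonal
#' for non-inbred individuals), and it is invariant to swapping the
#' ref/effect allele labels at any marker.
#'
#' @param genotypes A `genotype_dosages` (post-QC; all markers must be
#'   polymorphic) or a plain dosage matrix individuals x markers.
#' @return A symmetric matrix of class `kinship_matrix` with attributes
#'   `n_markers` and `estimator`.
#' @export
genomic_kinship <- function(genotypes) {
  G <- if (inherits(genotypes, "genotype_dosages")) genotypes$dosage else genotypes
  p <- colMeans(G, na.rm = TRUE) / 2
  if (any(p <= 0) || any(p >= 1)) {
    stop("monomorphic marker(s) present; filter with genotype_qc() first", call. = FALSE)
  }
  Z <- sweep(G, 2, 2 * p) / rep(sqrt(2 * p * (1 - p)), each = nrow(G))
  obs <- !is.na(Z)
  Z[!obs] <- 0
  K <- tcrossprod(Z) / tcrossprod(obs * 1)
  K <- (K + t(K)) / 2
  structure(K, n_markers = ncol(G), estimator = "allele-frequency standardized (2*kinship scale)",
            class = c("kinship_matrix", "matrix", "array"))
}
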