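#' Simulate genotype dosages on a pedigree by gene dropping
#'
#' Founder haplotypes are drawn as independent Bernoulli alleles at each
#' marker's population frequency; non-founder haplotypes are produced by
#' Mendelian transmission (each parent passes one of its two alleles,
#' chosen at random per marker). The result is a hard-call dosage matrix
#' (0/1/2 copies of the effect allele) whose empirical relationship matrix
#' converges to twice the pedigree kinship as markers accumulate.
#'
#' Markers are spread over autosomes 1..22 with strictly increasing
#' positions within a chromosome. No linkage disequilibrium is simulated
#' beyond the within-family correlation that transmission itself creates
#' (markers are dropped independently).
#'
#' @param ped A `pedigree` from [simulate_pedigree()].
#' @param n_markers Number of autosomal markers (> 0).
#' @param maf_sampler Function of one argument `n` returning `n` effect
#'   allele frequencies in (0, 1). Default: uniform on (0.05, 0.5).
#' @param seed Optional integer seed.
#' @param missing_rate Fraction of genotype calls set to missing at random
#'   (default 0, i.e. a post-QC-like complete matrix).
#' @return A list of class `genotype_dosages` with elements
#'   `dosage` (individuals x markers matrix, possibly with `NA`),
#'   `markers` (data.frame: `id`, `chr`, `pos`, `ref`, `alt`, `freq`),
#'   `hard_calls` (logical) and, internally for round-trip tests,
#'   attribute `haplotypes`.
#' @export
simulate_genotypes <- function(ped, n_markers,
                               maf_sampler = function(n) stats::runif(n, 0.05, 0.5),
                               seed = NULL, missing_rate = 0) {
  stopifnot(inherits(ped, "pedigree"))
  if (n_markers < 1) stop("'n_markers' must be positive", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("'missing_rate' must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  p <- maf_sampler(n_markers)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("allele frequencies must lie strictly in (0, 1)", call. = FALSE)
  }
  n <- nrow(ped)
  id <- ped$id
  fa <- match(ped$father, id)
  mo <- match(ped$mother, id)

  h1 <- matrix(0L, n, n_markers)  # paternal haplotype
  h2 <- matrix(0L, n, n_markers)  # maternal haplotype
  for (i in seq_len(n)) {
    if (is.na(fa[i]) || is.na(mo[i])) {
      h1[i, ] <- stats::rbinom(n_markers, 1L, p)
      h2[i, ] <- stats::rbinom(n_markers, 1L, p)
    } else {
      pick_f <- stats::runif(n_markers) < 0.5
      pick_m <- stats::runif(n_markers) < 0.5
      h1[i, ] <- ifelse(pick_f, h1[fa[i], ], h2[fa[i], ])
      h2[i, ] <- ifelse(pick_m, h1[mo[i], ], h2[mo[i], ])
    }
  }
  dosage <- h1 + h2
  storage.mode(dosage) <- "double"
  marker_ids <- sprintf("mk%06d", seq_len(n_markers))
  dimnames(dosage) <- list(id, marker_ids)
  if (missing_rate > 0) {
    miss <- stats::runif(length(dosage)) < missing_rate
    dosage[miss] <- NA_real_
  }

  chr <- sort(rep_len(1:22, n_markers))
  pos <- integer(n_markers)
  for (c_ in unique(chr)) {
    k <- sum(chr == c_)
    pos[chr == c_] <- sort(sample.int(2.4e8, k))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_markers, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  markers <- data.frame(id = marker_ids, chr = chr, pos = pos,
                        ref = ref, alt = unname(alt), freq = p,
                        stringsAsFactors = FALSE)
  structure(
    list(dosage = dosage, markers = markers, hard_calls = TRUE),
    haplotypes = list(h1 = h1, h2 = h2),
    class = "genotype_dosages"
  )
}
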