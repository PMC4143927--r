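#' Default tag-SNP table for ABO haplotype assignment
#'
#' Maps the five classical ABO haplotype lineages (A1, A2, B, O01, O02)
#' to counts of the tagging allele at four SNPs: the rs505922 minor
#' allele tags the O lineage, rs8176746 tags B, rs8176704 tags A2 and
#' rs574347 separates O02 from O01. The mapping is supplied as editable
#' data (rather than code) since tag orientations differ between
#' genotyping builds; every unordered pair of these haplotypes produces a
#' distinct 4-SNP genotype, so unphased resolution is unambiguous under
#' this table.
#'
#' @return A matrix, haplotypes x SNPs, of tag-allele counts (0/1).
#' @export
abo_tag_table <- function() {
  t(matrix(c(
    # rs505922, rs8176746, rs8176704, rs574347
    0, 0, 0, 0,   # A1
    0, 0, 1, 0,   # A2
    0, 1, 0, 0,   # B
    1, 0, 0, 0,   # O01
    1, 0, 0, 1),  # O02
    nrow = 4, dimnames = list(c("rs505922", "rs8176746", "rs8176704", "rs574347"),
                              c("A1", "A2", "B", "O01", "O02"))))
}

.abo_group <- function(h1, h2) {
  is_a <- c(h1, h2) %in% c("A1", "A2")
  is_b <- c(h1, h2) == "B"
  if (any(is_a) && any(is_b)) "AB"
  else if (any(is_a)) "A"
  else if (any(is_b)) "B"
  else "O"
}

#' Assign ABO blood groups from four tag-SNP genotypes
#'
#' Deterministic diplotype resolution from unphased hard-call genotypes:
#' the genotype vector at the four tag SNPs is compared against the sums
#' of all unordered haplotype pairs in the tag table; a unique match
#' yields the diplotype, group (A/B are codominant over O) and subtype
#' labels. Individuals with any missing genotype, or a genotype matching
#' no (or more than one) haplotype pair, are `unassigned`.
#'
#' @param genotypes Matrix or data.frame, individuals x 4 SNPs, counting
#'   tag alleles (0/1/2); column names must match the tag table's SNPs.
#' @param tag_table Haplotype x SNP tag-allele table
#'   (default [abo_tag_table()]).
#' @return A data.frame of class `abo_calls`: `id`, `diplotype` (e.g.
#'   `"A1/O01"`), `group` (`A`/`B`/`AB`/`O`/`unassigned`).
#' @export
assign_abo <- function(genotypes, tag_table = abo_tag_table()) {
  G <- as.matrix(genotypes)
  snps <- colnames(tag_table)
  if (!all(snps %in% colnames(G))) {
    stop("genotypes must contain columns: ", paste(snps, collapse = ", "),
         call. = FALSE)
  }
  G <- G[, snps, drop = FALSE]
  haps <- rownames(tag_table)
  pairs <- expand.grid(i = seq_along(haps), j = seq_along(haps))
  pairs <- pairs[pairs$i <= pairs$j, ]
  sums <- t(apply(pairs, 1, function(pr) tag_table[pr[1], ] + tag_table[pr[2], ]))
  key <- apply(sums, 1, paste, collapse = "/")
  if (anyDuplicated(key)) {
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    key[dup] <- NA  # ambiguous under a user-supplied table -> unassigned
  }
  labels <- sprintf("%s/%s", haps[pairs$i], haps[pairs$j])

  out <- data.frame(id = rownames(G) %||% as.character(seq_len(nrow(G))),
                    diplotype = NA_character_, group = "unassigned",
                    stringsAsFactors = FALSE)
  gk <- apply(G, 1, function(g) if (anyNA(g)) NA_character_ else paste(g, collapse = "/"))
  hit <- match(gk, key)
  ok <- !is.na(hit)
  out$diplotype[ok] <- labels[hit[ok]]
  out$group[ok] <- vapply(hit[ok], function(h)
    .abo_group(haps[pairs$i[h]], haps[pairs$j[h]]), character(1))
  class(out) <- c("abo_calls", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fraction of samples receiving an ABO assignment
#'
#' @param calls An `abo_calls` data.frame.
#' @return Fraction assigned in [0, 1].
#' @export
assignment_rate <- function(calls) {
  if (!nrow(calls)) stop("no calls", call. = FALSE)
  mean(calls$group != "unassigned")
}

#' Simulate ABO tag-SNP genotypes with known diplotypes
#'
#' Draws two haplotypes per individual at the given lineage frequencies
#' and renders the corresponding unphased tag-SNP genotypes, optionally
#' with per-genotype missingness (so assignment rates below 100% can be
#' emulated). The drawn diplotypes are returned for round-trip tests.
#'
#' @param n Number of individuals.
#' @param hap_freq Named haplotype frequencies (default roughly European:
#'   O01 0.53, O02 0.07, A1 0.26, A2 0.07, B 0.07).
#' @param snp_missing_rate Per-genotype missing probability (default
#'   0.0053, i.e. about 97.9% of individuals have all four calls).
#' @param seed Optional integer seed.
#' @param ids Optional individual ids.
#' @return A list: `genotypes` (n x 4), `diplotype` (true labels,
#'   unordered), `haplotypes`.
#' @export
simulate_abo_genotypes <- function(n, hap_freq = c(A1 = 0.26, A2 = 0.07, B = 0.07,
                                                   O01 = 0.53, O02 = 0.07),
                                   snp_missing_rate = 0.0053, seed = NULL,
                                   ids = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- abo_tag_table()
  stopifnot(all(names(hap_freq) %in% rownames(tab)))
  hap_freq <- hap_freq / sum(hap_freq)
  h1 <- sample(names(hap_freq), n, replace = TRUE, prob = hap_freq)
  h2 <- sample(names(hap_freq), n, replace = TRUE, prob = hap_freq)
  G <- tab[h1, , drop = FALSE] + tab[h2, , drop = FALSE]
  rownames(G) <- ids %||% sprintf("ind%04d", seq_len(n))
  if (snp_missing_rate > 0) {
    G[matrix(stats::runif(length(G)) < snp_missing_rate, nrow(G))] <- NA
  }
  ordered <- ifelse(h1 <= h2, paste(h1, h2, sep = "/"), paste(h2, h1, sep = "/"))
  list(genotypes = G, diplotype = ordered, haplotypes = cbind(h1, h2))
}
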