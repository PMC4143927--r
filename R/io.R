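# Delimited-text I/O helpers shared by the pipeline writers.

fmt_num <- function(x) {
  # full-precision text so artifacts round-trip exactly
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a numeric matrix as tab-delimited text with row/column ids
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param header Optional named list written as `# key: value` comment
#'   lines (seed, thresholds, ...).
#' @export
write_matrix_tsv <- function(m, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(sprintf("# %s: %s", names(header),
                       vapply(header, function(v) paste(format(v), collapse = ","), "")),
               con)
  }
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path Input path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

write_df_tsv <- function(d, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(sprintf("# %s: %s", names(header),
                       vapply(header, function(v) paste(format(v), collapse = ","), "")),
               con)
  }
  num <- vapply(d, is.numeric, logical(1))
  for (j in which(num)) d[[j]] <- fmt_num(d[[j]])
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotype dosages from a delimited matrix or a VCF
#'
#' Delimited input: the matrix layout written by [write_matrix_tsv()]
#' (individuals in rows, markers in columns), with marker metadata in a
#' sidecar `<path>.markers.tsv` if present. VCF input (requires the
#' `vcfR` package): dosages from the `DS` FORMAT field when present,
#' otherwise hard calls from `GT`.
#'
#' @param path Path to a `.tsv`/`.txt` dosage matrix or a `.vcf` file.
#' @return A `genotype_dosages` list.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF input requires the 'vcfR' package", call. = FALSE)
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    has_ds <- any(grepl("(^|:)DS(:|$)", v@gt[, "FORMAT"]))
    if (has_ds) {
      dos <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
      hard <- FALSE
    } else {
      gt <- vcfR::extract.gt(v, element = "GT")
      dos <- matrix(vapply(gt, function(g) {
        if (is.na(g)) return(NA_real_)
        sum(as.numeric(strsplit(g, "[/|]")[[1]]))
      }, numeric(1)), nrow = nrow(gt), dimnames = dimnames(gt))
      hard <- TRUE
    }
    dosage <- t(dos)  # individuals x markers
    markers <- data.frame(id = fix[, "ID"], chr = fix[, "CHROM"],
                          pos = as.integer(fix[, "POS"]),
                          ref = fix[, "REF"], alt = fix[, "ALT"],
                          freq = colMeans(t(dos), na.rm = TRUE) / 2,
                          stringsAsFactors = FALSE)
    colnames(dosage) <- markers$id
  } else {
    dosage <- read_matrix_tsv(path)
    side <- paste0(path, ".markers.tsv")
    markers <- if (file.exists(side)) {
      utils::read.delim(side, stringsAsFactors = FALSE)
    } else {
      data.frame(id = colnames(dosage), chr = NA_integer_, pos = NA_integer_,
                 ref = NA_character_, alt = NA_character_,
                 freq = colMeans(dosage, na.rm = TRUE) / 2,
                 stringsAsFactors = FALSE)
    }
    hard <- all(dosage == round(dosage), na.rm = TRUE)
  }
  structure(list(dosage = dosage, markers = markers, hard_calls = hard),
            class = "genotype_dosages")
}

#' Write a GWAS summary table as delimited text
#'
#' Fixed column order (`marker`, `chr`, `pos`, `effect_allele`,
#' `other_allele`, `n`, `beta`, `se`, `chi2`, `p`, `var_expl`, `phase`),
#' rows sorted by chromosome and 1-based position, p-values in
#' scientific notation, full precision so the file parses back to
#' identical values.
#'
#' @param results Data.frame with at least `marker`, `beta`, `se`,
#'   `chi2`, `p`, `var_expl` and `phase` columns (phase labels e.g.
#'   `discovery`/`replication`/`combined`/`conditional`).
#' @param markers Marker metadata (`id`, `chr`, `pos`, `ref`, `alt`).
#' @param path Output path.
#' @param n Sample size column or single value.
#' @param header Optional comment header (see [write_matrix_tsv()]).
#' @return The path, invisibly.
#' @export
write_gwas_summary <- function(results, markers, path, n = NA_integer_,
                               header = NULL) {
  if (!nrow(results)) stop("empty results", call. = FALSE)
  if (anyDuplicated(results[, c("marker", "phase")])) {
    stop("duplicate marker ids within a phase", call. = FALSE)
  }
  mi <- match(results$marker, markers$id)
  out <- data.frame(
    marker = results$marker,
    chr = markers$chr[mi],
    pos = markers$pos[mi],
    effect_allele = markers$alt[mi],
    other_allele = markers$ref[mi],
    n = if (length(n) == 1) rep(n, nrow(results)) else n,
    beta = results$beta, se = results$se, chi2 = results$chi2,
    p = results$p, var_expl = results$var_expl, phase = results$phase,
    stringsAsFactors = FALSE)
  out <- out[order(out$chr, out$pos, out$phase), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(sprintf("# %s: %s", names(header),
                       vapply(header, function(v) paste(format(v), collapse = ","), "")),
               con)
  }
  out$p <- ifelse(is.na(out$p), "NA", sprintf("%.10e", out$p))
  for (cc in c("beta", "se", "chi2", "var_expl")) out[[cc]] <- fmt_num(out[[cc]])
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GWAS summary written by [write_gwas_summary()]
#'
#' @param path Input path.
#' @return Data.frame with typed columns.
#' @export
read_gwas_summary <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
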