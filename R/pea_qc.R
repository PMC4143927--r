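#' Normalize one plate of Cq values into ddCq
#'
#' For every sample well, `dCq(sample, assay) = Cq(sample, assay) -
#' Cq(extension control of the same sample)` and `ddCq = correction(assay)
#' - dCq`, placing measurements on a positive log2 abundance scale (one
#' ddCq unit is roughly a doubling). ddCq is therefore invariant to any
#' additive Cq shift affecting a sample's analyte and extension control
#' equally, and monotone decreasing in raw Cq. Control wells are
#' normalized the same way (the negative control feeds the detection
#' limit).
#'
#' @param plate A `plate_run`.
#' @param assays Assay definitions (`assay`, `protein`, `correction`).
#' @return A list: `ddcq` (proteins x samples), `neg_ddcq` (per assay
#'   ddCq of the negative-control well), `controls` (samples x 4),
#'   `flagged` (sample ids with a missing extension control; their cells
#'   are `NA`, they are not silently dropped), `plate_id`.
#' @export
normalize_ddcq <- function(plate, assays) {
  stopifnot(inherits(plate, "plate_run"))
  if (sum(plate$well_type == "negative") != 1L) {
    stop("plate must contain exactly one negative-control well", call. = FALSE)
  }
  sw <- which(plate$well_type == "sample")
  ext <- plate$controls[, "ext"]
  flagged <- plate$sample_id[sw][!is.finite(ext[sw])]
  corr <- assays$correction

  dcq <- plate$cq - ext            # wells x assays, recycled by column? no:
  # plate$cq is wells x assays; ext is length wells -> recycles down columns,
  # which is the per-well subtraction we want
  ddcq_wells <- sweep(-dcq, 2, corr, `+`)
  ddcq <- t(ddcq_wells[sw, , drop = FALSE])
  rownames(ddcq) <- assays$protein
  colnames(ddcq) <- plate$sample_id[sw]
  neg <- ddcq_wells[plate$well_type == "negative", ]
  list(ddcq = ddcq, neg_ddcq = as.numeric(neg),
       controls = plate$controls[sw, , drop = FALSE],
       flagged = flagged, plate_id = plate$plate_id)
}

#' Estimate per-assay detection limits from negative controls
#'
#' The lower detection limit of an assay is the mean negative-control
#' ddCq across plates plus `k` standard deviations (sample SD across
#' plates; 0 when only one plate is available). Cells at or below the
#' LOD are treated as not detected.
#'
#' @param plates A `plate_run` or list of them.
#' @param assays Assay definitions.
#' @param k LOD multiplier on the across-plate SD (default 3).
#' @return Named numeric vector of per-assay LODs (names = proteins).
#' @export
estimate_lod <- function(plates, assays, k = 3) {
  if (inherits(plates, "plate_run")) plates <- list(plates)
  if (!length(plates)) stop("no plates supplied", call. = FALSE)
  neg <- vapply(plates, function(p) {
    if (sum(p$well_type == "negative") < 1L) {
      stop("plate without a negative control", call. = FALSE)
    }
    normalize_ddcq(p, assays)$neg_ddcq
  }, numeric(nrow(assays)))
  neg <- matrix(neg, nrow = nrow(assays))
  m <- rowMeans(neg)
  s <- if (ncol(neg) > 1) apply(neg, 1, stats::sd) else rep(0, nrow(neg))
  stats::setNames(m + k * s, assays$protein)
}

#' Normalize a set of plates into a panel with LOD mask
#'
#' Runs [normalize_ddcq()] on every plate, concatenates samples, estimates
#' per-assay detection limits with [estimate_lod()] and masks cells at or
#' below them.
#'
#' @inheritParams estimate_lod
#' @return A list of class `normalized_panel`: `ddcq` (proteins x
#'   individuals), `below_lod` (logical mask, `TRUE` = at/below LOD),
#'   `lod`, `controls` (individuals x 4), `plate` (plate id per
#'   individual), `flagged`, `exclusions` (empty data.frame before QC).
#' @export
normalize_panel <- function(plates, assays, k = 3) {
  if (inherits(plates, "plate_run")) plates <- list(plates)
  slices <- lapply(plates, normalize_ddcq, assays = assays)
  ddcq <- do.call(cbind, lapply(slices, `[[`, "ddcq"))
  controls <- do.call(rbind, lapply(slices, `[[`, "controls"))
  plate_of <- unlist(lapply(slices, function(s) rep(s$plate_id, ncol(s$ddcq))))
  rownames(controls) <- colnames(ddcq)
  lod <- estimate_lod(plates, assays, k = k)
  below <- sweep(ddcq, 1, lod, `<=`)
  below[is.na(below)] <- TRUE
  structure(
    list(ddcq = ddcq, below_lod = below, lod = lod, controls = controls,
         plate = stats::setNames(plate_of, colnames(ddcq)),
         flagged = unlist(lapply(slices, `[[`, "flagged")),
         exclusions = data.frame(type = character(), id = character(),
                                 reason = character(), stringsAsFactors = FALSE)),
    class = "normalized_panel")
}

#' Apply sample- and protein-level quality control
#'
#' Excludes samples with an outlying internal-control value (per control,
#' per plate: more than `control_outlier_k` robust SDs, i.e.
#' `1.4826 * MAD`, from the plate median) or with more than
#' `max_below_lod_fraction` of their cells below the detection limit; then
#' excludes proteins with fewer than `min_protein_obs` above-LOD
#' observations. Exclusion statistics are always derived from the
#' original, unfiltered panel, so re-applying QC to an already filtered
#' panel reproduces it unchanged.
#'
#' @param panel A `normalized_panel`.
#' @param min_protein_obs Minimum above-LOD observations per protein
#'   (default 200; proteins with at least this many are retained).
#' @param max_below_lod_fraction Samples with a strictly greater fraction
#'   of below-LOD cells are excluded (default 0.75).
#' @param control_outlier_k Robust-SD multiplier for the internal-control
#'   rule (default 3).
#' @return The filtered `normalized_panel`, with `exclusions` (type, id,
#'   reason) and a `qc_report` element used by [qc_summary()].
#' @export
apply_qc <- function(panel, min_protein_obs = 200,
                     max_below_lod_fraction = 0.75,
                     control_outlier_k = 3) {
  stopifnot(inherits(panel, "normalized_panel"))
  if (min_protein_obs < 1) stop("'min_protein_obs' must be >= 1", call. = FALSE)
  if (max_below_lod_fraction <= 0 || max_below_lod_fraction > 1) {
    stop("'max_below_lod_fraction' must lie in (0, 1]", call. = FALSE)
  }
  full <- if (is.null(panel$full)) panel else panel$full
  n_samp <- ncol(full$ddcq)
  n_prot <- nrow(full$ddcq)

  # internal-control outliers, per plate and per control channel
  bad_ctrl <- character(0)
  for (pl in unique(full$plate)) {
    idx <- which(full$plate == pl)
    for (cc in colnames(full$controls)) {
      v <- full$controls[idx, cc]
      med <- stats::median(v, na.rm = TRUE)
      s <- stats::mad(v, na.rm = TRUE)  # includes the 1.4826 consistency factor
      if (s > 0) {
        bad_ctrl <- c(bad_ctrl, colnames(full$ddcq)[idx][abs(v - med) > control_outlier_k * s])
      }
    }
  }
  bad_ctrl <- unique(c(bad_ctrl, full$flagged))

  frac_below <- colMeans(full$below_lod)
  bad_lod <- colnames(full$ddcq)[frac_below > max_below_lod_fraction]
  bad_samples <- union(bad_ctrl, bad_lod)
  keep_samp <- setdiff(colnames(full$ddcq), bad_samples)

  above <- rowSums(!full$below_lod[, keep_samp, drop = FALSE])
  keep_prot <- rownames(full$ddcq)[above >= min_protein_obs]
  drop_prot <- setdiff(rownames(full$ddcq), keep_prot)

  excl <- rbind(
    if (length(bad_ctrl)) data.frame(type = "sample", id = bad_ctrl,
                                     reason = "internal-control outlier",
                                     stringsAsFactors = FALSE),
    if (length(setdiff(bad_lod, bad_ctrl))) data.frame(
      type = "sample", id = setdiff(bad_lod, bad_ctrl),
      reason = sprintf(">%.0f%% cells below LOD", 100 * max_below_lod_fraction),
      stringsAsFactors = FALSE),
    if (length(drop_prot)) data.frame(
      type = "protein", id = drop_prot,
      reason = sprintf("<%d above-LOD observations", min_protein_obs),
      stringsAsFactors = FALSE)
  )
  if (is.null(excl)) excl <- data.frame(type = character(), id = character(),
                                        reason = character(), stringsAsFactors = FALSE)

  out <- full
  out$ddcq <- full$ddcq[keep_prot, keep_samp, drop = FALSE]
  out$below_lod <- full$below_lod[keep_prot, keep_samp, drop = FALSE]
  out$lod <- full$lod[keep_prot]
  out$controls <- full$controls[keep_samp, , drop = FALSE]
  out$plate <- full$plate[keep_samp]
  out$exclusions <- excl
  out$full <- full
  out$qc_report <- list(
    n_samples_total = n_samp,
    n_samples_pass = length(keep_samp),
    n_proteins_total = n_prot,
    n_proteins_pass = length(keep_prot),
    retained_reactions_total = length(keep_prot) * n_samp,
    retained_reactions_above_lod =
      sum(!full$below_lod[keep_prot, , drop = FALSE]),
    removed_reactions_total = length(drop_prot) * n_samp,
    removed_reactions_below_lod =
      sum(full$below_lod[drop_prot, , drop = FALSE]),
    thresholds = list(min_protein_obs = min_protein_obs,
                      max_below_lod_fraction = max_below_lod_fraction,
                      control_outlier_k = control_outlier_k))
  class(out) <- "normalized_panel"
  out
}

#' Percentage helper for QC reporting
#'
#' @param numerator,denominator Counts; the denominator must be positive.
#' @return `100 * numerator / denominator` (unrounded; round to one
#'   decimal for display).
#' @examples
#' round(qc_fraction(70651, 77385), 1)  # 91.3
#' @export
qc_fraction <- function(numerator, denominator) {
  if (any(denominator == 0)) stop("zero denominator", call. = FALSE)
  100 * numerator / denominator
}

#' Summarize a QC run as the familiar headline percentages
#'
#' @param panel A QC'd `normalized_panel` (from [apply_qc()]).
#' @return A list with raw fractions and display percentages (one
#'   decimal): `reaction_success_pct` (above-LOD reactions among retained
#'   proteins, over all samples), `below_lod_pct` (below-LOD reactions
#'   among removed proteins), `sample_pass_pct` and
#'   `sample_excluded_pct`.
#' @export
qc_summary <- function(panel) {
  r <- panel$qc_report
  if (is.null(r)) stop("panel has no QC report; run apply_qc() first", call. = FALSE)
  out <- list(
    reaction_success_pct =
      if (r$retained_reactions_total > 0)
        round(qc_fraction(r$retained_reactions_above_lod, r$retained_reactions_total), 1)
      else NA_real_,
    below_lod_pct =
      if (r$removed_reactions_total > 0)
        round(qc_fraction(r$removed_reactions_below_lod, r$removed_reactions_total), 1)
      else NA_real_,
    sample_pass_pct = round(qc_fraction(r$n_samples_pass, r$n_samples_total), 1),
    sample_excluded_pct = round(qc_fraction(
      r$n_samples_total - r$n_samples_pass, r$n_samples_total), 1))
  out$raw <- r
  out
}
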