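#' Assay definitions for a simulated PEA panel
#'
#' @param proteins Character vector of protein names.
#' @param correction Per-assay correction constants (log2 units), the
#'   manufacturer-style offsets that place ddCq values on a positive log2
#'   scale; recycled. Default 18.
#' @return A data.frame with columns `assay`, `protein`, `correction`.
#' @export
assay_definitions <- function(proteins, correction = 18) {
  if (any(!is.finite(correction))) stop("correction constants must be finite", call. = FALSE)
  data.frame(assay = sprintf("A%03d", seq_along(proteins)),
             protein = proteins,
             correction = rep_len(correction, length(proteins)),
             stringsAsFactors = FALSE)
}

#' Render ddCq traits into raw qPCR plates
#'
#' Inverse of the ddCq normalization: writes plate-level Cq values such
#' that `Cq(sample, assay) = correction(assay) + Cq(extension control) -
#' ddCq`, so normalization recovers the input exactly for cells above the
#' detection limit. Each 96-well plate carries 92 samples, one negative
#' control and three positive (spike-in) controls; each sample well also
#' carries four per-sample internal controls (two incubation, one
#' extension, one detection).
#'
#' The negative-control ddCq of every assay is placed at that assay's
#' `lod_censor_fraction` quantile of the trait values (or well below the
#' sample minimum when the fraction is 0), so downstream LOD masking
#' censors approximately the requested fraction of cells.
#'
#' @param traits A `trait_panel` from [simulate_traits()].
#' @param assays Assay definitions from [assay_definitions()]; rows must
#'   match the panel's proteins.
#' @param seed Optional integer seed.
#' @param control_outlier_rate Fraction of samples given a deviant
#'   internal-control value (emulating failed wells); default 0.
#' @return A list of `plate_run` objects. Each has `plate_id`, `cq`
#'   (wells x assays), `well_type` (`sample`/`negative`/`positive`),
#'   `sample_id` (NA for control wells) and `controls` (wells x 4 matrix:
#'   `inc1`, `inc2`, `ext`, `det`).
#' @export
render_plates <- function(traits, assays, seed = NULL,
                          control_outlier_rate = 0) {
  stopifnot(inherits(traits, "trait_panel"))
  if (!is.null(seed)) set.seed(seed)
  ddcq <- traits$ddcq
  if (nrow(assays) != nrow(ddcq) || !all(assays$protein == rownames(ddcq))) {
    stop("assay definitions must match the trait panel proteins", call. = FALSE)
  }
  n <- ncol(ddcq)
  if (n == 0) return(list())
  samples_per_plate <- 92L
  n_plates <- ceiling(n / samples_per_plate)

  # per-assay negative-control ddCq controlling the censored fraction
  neg_ddcq <- vapply(seq_len(nrow(ddcq)), function(k) {
    f <- traits$models[[k]]$lod_censor_fraction
    if (f > 0) stats::quantile(ddcq[k, ], f, type = 1, names = FALSE)
    else min(ddcq[k, ]) - 3
  }, numeric(1))

  plates <- vector("list", n_plates)
  idx_all <- split(seq_len(n), ceiling(seq_len(n) / samples_per_plate))
  for (pl in seq_len(n_plates)) {
    idx <- idx_all[[pl]]
    n_wells <- length(idx) + 4L
    well_type <- c(rep("sample", length(idx)), "negative", rep("positive", 3))
    sample_id <- c(colnames(ddcq)[idx], rep(NA_character_, 4))
    ext <- stats::rnorm(n_wells, 18, 0.3)
    controls <- cbind(inc1 = stats::rnorm(n_wells, 20, 0.1),
                      inc2 = stats::rnorm(n_wells, 21, 0.1),
                      ext = ext,
                      det = stats::rnorm(n_wells, 22, 0.1))
    if (control_outlier_rate > 0 && length(idx)) {
      hit <- which(stats::runif(length(idx)) < control_outlier_rate)
      if (length(hit)) {
        col <- sample(c(1L, 2L, 4L), length(hit), replace = TRUE)
        controls[cbind(hit, col)] <- controls[cbind(hit, col)] +
          sample(c(-4, 4), length(hit), replace = TRUE)
      }
    }
    cq <- matrix(NA_real_, n_wells, nrow(assays),
                 dimnames = list(NULL, assays$assay))
    for (k in seq_len(nrow(assays))) {
      corr <- assays$correction[k]
      cq[seq_along(idx), k] <- corr + ext[seq_along(idx)] - ddcq[k, idx]
      cq[length(idx) + 1L, k] <- corr + ext[length(idx) + 1L] - neg_ddcq[k]
      cq[length(idx) + 2:4, k] <- corr + ext[length(idx) + 2:4] - 10
    }
    plates[[pl]] <- structure(
      list(plate_id = sprintf("plate%02d", pl), cq = cq,
           well_type = well_type, sample_id = sample_id,
           controls = controls),
      class = "plate_run")
  }
  plates
}
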