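#' Specify the structure of a synthetic family cohort
#'
#' Describes a two-generation cohort made of nuclear families (two founder
#' parents plus a number of full-sib offspring) and unrelated singletons,
#' split into a "discovery" and a "replication" cohort the way a two-round
#' population survey would be.
#'
#' @param n_families Number of nuclear families.
#' @param offspring_per_family Number of offspring in each family.
#' @param n_singletons Number of unrelated founder individuals without
#'   family links.
#' @param cohort_split Fraction of individuals assigned the cohort label
#'   `"discovery"`; the remainder are labelled `"replication"`. Whole
#'   families are kept within one cohort (villages, not individuals, were
#'   recruited per round), so the realized fraction is the closest
#'   attainable by whole units.
#' @return An object of class `pedigree_spec`.
#' @examples
#' pedigree_spec(n_families = 3, offspring_per_family = 2, n_singletons = 4)
#' @export
pedigree_spec <- function(n_families, offspring_per_family, n_singletons,
                          cohort_split = 2 / 3) {
  for (v in c(n_families, offspring_per_family, n_singletons)) {
    if (length(v) != 1L || !is.finite(v) || v < 0 || v != round(v)) {
      stop("pedigree counts must be single non-negative integers", call. = FALSE)
    }
  }
  if (cohort_split < 0 || cohort_split > 1) {
    stop("'cohort_split' must lie in [0, 1]", call. = FALSE)
  }
  n_total <- n_families * (2L + offspring_per_family) + n_singletons
  if (n_total <= 0) stop("pedigree must contain at least one individual", call. = FALSE)
  structure(
    list(n_families = as.integer(n_families),
         parents_per_family = 2L,
         offspring_per_family = as.integer(offspring_per_family),
         n_singletons = as.integer(n_singletons),
         cohort_split = cohort_split,
         n_total = as.integer(n_total)),
    class = "pedigree_spec"
  )
}

#' Simulate a family-structured pedigree
#'
#' Builds the pedigree table for a [pedigree_spec()]: founders first, then
#' offspring with explicit parent links. Individual ids are stable strings
#' (`"F<family>_P1"`, `"F<family>_O3"`, `"S5"`), so downstream matrices can
#' be aligned by name.
#'
#' @param spec A [pedigree_spec()].
#' @param seed Optional integer seed (sets the RNG; only sex assignment is
#'   random here).
#' @return A `data.frame` of class `pedigree` with columns `id`, `father`,
#'   `mother` (`NA` for founders), `sex` (`"M"`/`"F"`), `family` (`NA` for
#'   singletons) and `cohort`.
#' @seealso [kinship_from_pedigree()] for the implied expected kinship.
#' @export
simulate_pedigree <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "pedigree_spec"))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  fam_sizes <- integer(0)
  if (spec$n_families > 0) {
    for (f in seq_len(spec$n_families)) {
      fid <- sprintf("F%d", f)
      fa <- sprintf("%s_P1", fid)
      mo <- sprintf("%s_P2", fid)
      rows[[length(rows) + 1L]] <- data.frame(
        id = c(fa, mo), father = NA_character_, mother = NA_character_,
        sex = c("M", "F"), family = fid, stringsAsFactors = FALSE)
      if (spec$offspring_per_family > 0) {
        kid_ids <- sprintf("%s_O%d", fid, seq_len(spec$offspring_per_family))
        rows[[length(rows) + 1L]] <- data.frame(
          id = kid_ids, father = fa, mother = mo,
          sex = sample(c("M", "F"), length(kid_ids), replace = TRUE),
          family = fid, stringsAsFactors = FALSE)
      }
      fam_sizes <- c(fam_sizes, 2L + spec$offspring_per_family)
    }
  }
  if (spec$n_singletons > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("S%d", seq_len(spec$n_singletons)),
      father = NA_character_, mother = NA_character_,
      sex = sample(c("M", "F"), spec$n_singletons, replace = TRUE),
      family = NA_character_, stringsAsFactors = FALSE)
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL

  # assign whole families (then singletons) to discovery until the target
  # individual fraction is reached
  target <- spec$cohort_split * nrow(ped)
  cohort <- rep("replication", nrow(ped))
  assigned <- 0L
  units <- c(if (spec$n_families > 0) sprintf("F%d", seq_len(spec$n_families)),
             if (spec$n_singletons > 0) sprintf("S%d", seq_len(spec$n_singletons)))
  for (u in units) {
    idx <- if (grepl("^F", u)) which(ped$family %in% u) else which(ped$id == u)
    if (assigned + length(idx) / 2 <= target) {
      cohort[idx] <- "discovery"
      assigned <- assigned + length(idx)
    }
    if (assigned >= target) break
  }
  ped$cohort <- cohort
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Expected kinship matrix from a pedigree
#'
#' Computes the expected kinship coefficients by the classical recursive
#' (path-counting) algorithm: founders are unrelated and non-inbred,
#' `phi(i,i) = 0.5 * (1 + phi(father_i, mother_i))` and
#' `phi(i,j) = 0.5 * (phi(i, father_j) + phi(i, mother_j))` for `j` not an
#' ancestor of `i`. Parents must precede offspring in the table (as
#' produced by [simulate_pedigree()]).
#'
#' @param ped A `pedigree` data.frame.
#' @param scale Either `"kinship"` (phi itself; self 0.5) or
#'   `"relationship"` (2 * phi, the expected genomic relationship scale used
#'   by the polygenic model; self 1 for non-inbred individuals).
#' @return A symmetric numeric matrix with individual ids as dimnames.
#' @export
kinship_from_pedigree <- function(ped, scale = c("relationship", "kinship")) {
  scale <- match.arg(scale)
  n <- nrow(ped)
  id <- ped$id
  fa <- match(ped$father, id)
  mo <- match(ped$mother, id)
  if (any(!is.na(fa) & fa >= seq_len(n)) || any(!is.na(mo) & mo >= seq_len(n))) {
    stop("parents must precede offspring in the pedigree table", call. = FALSE)
  }
  phi <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    phi[i, i] <- if (is.na(fa[i]) || is.na(mo[i])) 0.5 else
      0.5 * (1 + phi[fa[i], mo[i]])
    if (i > 1L) {
      js <- seq_len(i - 1L)
      val <- if (is.na(fa[i]) || is.na(mo[i])) rep(0, length(js)) else
        0.5 * (phi[js, fa[i]] + phi[js, mo[i]])
      phi[i, js] <- val
      phi[js, i] <- val
    }
  }
  if (scale == "relationship") 2 * phi else phi
}
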