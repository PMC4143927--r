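#' Simulate a clinical/lifestyle covariate table for a cohort
#'
#' Emulates the structure of a population-survey covariate set: age
#' (uniform 15-90 years), sex, anthropometrics (height, weight, waist;
#' weakly sex- and age-dependent), systolic blood pressure rising with
#' age, current smoking, a traditional-lifestyle flag, the cohort
#' (sample-round) indicator, and a configurable number of rare ATC-coded
#' medication indicators whose prevalence increases with age through a
#' logistic link, so that age, blood pressure and medication are
#' realistically collinear.
#'
#' @param ped A `pedigree` (supplies ids and the cohort label).
#' @param n_medications Number of binary medication indicator columns.
#' @param med_users Target number of users per medication per 1000
#'   individuals; recycled. Default spans rare (2) to common (54).
#' @param seed Optional integer seed.
#' @return A list of class `covariate_table` with elements `data`
#'   (individuals x covariates data.frame, rownames = ids) and `meta`
#'   (data.frame: `name`, `kind` in continuous/binary/categorical,
#'   `users` for indicators).
#' @export
simulate_covariates <- function(ped, n_medications = 8,
                                med_users = c(2, 3, 6, 13, 26, 54),
                                seed = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  age <- stats::runif(n, 15, 90)
  sex <- ifelse(ped$sex == "F", 1, 0)
  height <- stats::rnorm(n, 175 - 12 * sex, 7)
  weight <- stats::rnorm(n, 0.45 * height - 10 + 0.08 * (age - 50), 10)
  waist <- stats::rnorm(n, 55 + 0.4 * weight + 0.05 * age, 6)
  sbp <- stats::rnorm(n, 105 + 0.45 * age, 12)
  smoking <- as.integer(stats::runif(n) < 0.13)
  tls <- as.integer(stats::runif(n) < 0.15)
  cohort_disc <- as.integer(ped$cohort == "discovery")

  dat <- data.frame(age = age, sex = sex, height = height, weight = weight,
                    waist = waist, sbp = sbp, smoking = smoking, tls = tls,
                    cohort_discovery = cohort_disc)
  meta <- data.frame(
    name = names(dat),
    kind = c("continuous", "binary", "continuous", "continuous", "continuous",
             "continuous", "binary", "binary", "binary"),
    users = NA_integer_, stringsAsFactors = FALSE)

  if (n_medications > 0) {
    users_per_1000 <- rep_len(med_users, n_medications)
    for (j in seq_len(n_medications)) {
      target_p <- users_per_1000[j] / 1000
      # logistic link on age: older individuals more likely to be users,
      # intercept solved so the marginal prevalence matches the target
      slope <- 0.06
      f <- function(b0) mean(stats::plogis(b0 + slope * (age - 50))) - target_p
      b0 <- stats::uniroot(f, c(-25, 5))$root
      ind <- as.integer(stats::runif(n) < stats::plogis(b0 + slope * (age - 50)))
      nm <- sprintf("atc_med%02d", j)
      dat[[nm]] <- ind
      meta <- rbind(meta, data.frame(name = nm, kind = "binary",
                                     users = sum(ind), stringsAsFactors = FALSE))
    }
  }
  rownames(dat) <- ped$id
  structure(list(data = dat, meta = meta), class = "covariate_table")
}

#' Attach a categorical covariate (such as ABO blood group) to a table
#'
#' @param covs A `covariate_table`.
#' @param name Column name.
#' @param values Character/factor vector aligned with the table rows;
#'   `NA` allowed (e.g. unassigned blood groups).
#' @return The updated `covariate_table`.
#' @export
add_categorical_covariate <- function(covs, name, values) {
  stopifnot(inherits(covs, "covariate_table"))
  if (length(values) != nrow(covs$data)) {
    stop("'values' must match the number of individuals", call. = FALSE)
  }
  covs$data[[name]] <- factor(values, levels = sort(unique(stats::na.omit(as.character(values)))))
  covs$meta <- rbind(covs$meta,
                     data.frame(name = name, kind = "categorical",
                                users = NA_integer_, stringsAsFactors = FALSE))
  covs
}
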