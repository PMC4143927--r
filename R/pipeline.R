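#' Load and validate a pipeline configuration
#'
#' Configurations are YAML files (or equivalent nested lists) describing
#' either a synthetic cohort to simulate or paths to existing inputs,
#' the QC/association thresholds, stage toggles, the RNG seed and the
#' output directory. Unknown keys are rejected by name, so typos fail
#' fast.
#'
#' @param config Path to a YAML file or a named list.
#' @return A validated config list of class `pipeline_config`, with
#'   defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    seed = 1L,
    output_dir = "proteovar_run",
    synthetic = list(n_families = 150L, offspring_per_family = 4L,
                     n_singletons = 0L, cohort_split = 2 / 3,
                     n_markers = 5000L, n_proteins = 10L,
                     n_medications = 8L, control_outlier_rate = 0,
                     h2_range = c(0.19, 0.78), cis_fraction = 0.5,
                     cis_varexpl = c(0.05, 0.27),
                     age_effect_max = 0.27,
                     lod_censor_fraction = 0.05,
                     batch_effect = 0.2),
    inputs = list(cq = NULL, covariates = NULL, genotypes = NULL),
    thresholds = list(min_protein_obs = 200L, max_below_lod_fraction = 0.75,
                      control_outlier_k = 3, alpha = 0.05, min_mac = 3L,
                      marker_call_rate = 0.95, individual_call_rate = 0.98,
                      hwe_alpha = 0.05, conditional_cutoff = 5e-8,
                      min_group_size = 10L, r2_min = 0.5),
    stages = list(qc = TRUE, covariates = TRUE, kinship = TRUE,
                  heritability = TRUE, gwas = TRUE, conditional = TRUE,
                  abo = TRUE, cutoffs = TRUE))
  merge1 <- function(def, usr, path) {
    unknown <- setdiff(names(usr), names(def))
    if (length(unknown)) {
      stop("unknown config key(s): ",
           paste(paste0(path, unknown), collapse = ", "), call. = FALSE)
    }
    for (k in names(usr)) {
      def[[k]] <- if (is.list(def[[k]]) && is.list(usr[[k]]))
        merge1(def[[k]], usr[[k]], paste0(path, k, ".")) else usr[[k]]
    }
    def
  }
  cfg <- merge1(defaults, config, "")
  th <- cfg$thresholds
  if (th$alpha <= 0 || th$alpha >= 1) stop("alpha outside (0,1)", call. = FALSE)
  if (th$max_below_lod_fraction <= 0 || th$max_below_lod_fraction > 1) {
    stop("max_below_lod_fraction outside (0,1]", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full biomarker-variation pipeline
#'
#' Orchestrates: cohort simulation (or input loading), plate rendering
#' and ddCq normalization with LOD masking, sample/protein QC, the
#' all-covariates variance decomposition with Bonferroni screening and
#' rank-inverse-normal adjustment, inter-biomarker correlations,
#' genotype QC and genomic kinship, polygenic heritability, the
#' discovery/replication/combined score-test GWAS, conditional scans on
#' top hits, ABO blood-group typing and stratified personalized
#' reference profiles. All artifacts are tab-delimited text carrying the
#' seed and thresholds in comment headers; reruns with the same config
#' and seed are byte-identical.
#'
#' @param config A [pipeline_config()], YAML path, or list.
#' @return Invisibly, a list with the in-memory results of every stage
#'   and `paths` to the written artifacts.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- cfg$thresholds
  seed <- as.integer(cfg$seed)
  hdr <- list(seed = seed, package = "proteovar",
              version = as.character(utils::packageVersion("proteovar")))
  paths <- list()
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message("[proteovar] ", msg)
    log_lines <<- c(log_lines, msg)
  }

  ## ---- stage: cohort (simulate or load) -------------------------------
  syn <- cfg$synthetic
  use_synthetic <- is.null(cfg$inputs$cq)
  if (use_synthetic) {
    spec <- pedigree_spec(syn$n_families, syn$offspring_per_family,
                          syn$n_singletons, syn$cohort_split)
    ped <- simulate_pedigree(spec, seed = seed)
    genotypes <- simulate_genotypes(ped, syn$n_markers, seed = seed + 1L)
    covs <- simulate_covariates(ped, n_medications = syn$n_medications,
                                seed = seed + 2L)
    set.seed(seed + 3L)
    K_ped <- kinship_from_pedigree(ped)
    models <- synthetic_trait_models(syn, genotypes)
    traits <- simulate_traits(models, ped, genotypes, covs,
                              kinship = K_ped, seed = seed + 4L)
    assays <- assay_definitions(rownames(traits$ddcq))
    plates <- render_plates(traits, assays, seed = seed + 5L,
                            control_outlier_rate = syn$control_outlier_rate)
    say("simulated cohort: %d individuals (%d discovery / %d replication), %d markers, %d proteins",
        nrow(ped), sum(ped$cohort == "discovery"),
        sum(ped$cohort == "replication"), syn$n_markers, length(models))
  } else {
    stop("reading external Cq inputs requires 'cq', 'covariates' and 'genotypes' paths; ",
         "plate-level external input is supported via normalize_panel() directly",
         call. = FALSE)
  }

  ## ---- stage: normalization + QC --------------------------------------
  panel <- normalize_panel(plates, assays)
  results <- list(pedigree = ped, genotypes = genotypes, covariates = covs,
                  traits = traits, panel = panel)
  if (isTRUE(cfg$stages$qc)) {
    panel <- apply_qc(panel, min_protein_obs = th$min_protein_obs,
                      max_below_lod_fraction = th$max_below_lod_fraction,
                      control_outlier_k = th$control_outlier_k)
    qs <- qc_summary(panel)
    say("QC: %d/%d samples pass (%.1f%%), %d/%d proteins retained",
        qs$raw$n_samples_pass, qs$raw$n_samples_total, qs$sample_pass_pct,
        qs$raw$n_proteins_pass, qs$raw$n_proteins_total)
    paths$qc_report <- file.path(out_dir, "qc_report.txt")
    writeLines(c(sprintf("# seed: %d", seed),
                 sprintf("reaction_success_pct: %s", qs$reaction_success_pct),
                 sprintf("below_lod_pct: %s", qs$below_lod_pct),
                 sprintf("sample_pass_pct: %s", qs$sample_pass_pct),
                 sprintf("sample_excluded_pct: %s", qs$sample_excluded_pct),
                 sprintf("excluded: %s",
                         paste(sprintf("%s=%s(%s)", panel$exclusions$type,
                                       panel$exclusions$id, panel$exclusions$reason),
                               collapse = "; "))),
               paths$qc_report)
    results$qc_summary <- qs
  }
  results$panel <- panel
  ddcq <- panel$ddcq
  ddcq[panel$below_lod] <- NA
  paths$ddcq <- file.path(out_dir, "ddcq_matrix.tsv")
  write_matrix_tsv(ddcq, paths$ddcq, header = hdr)

  ids <- colnames(ddcq)
  cohort <- ped$cohort[match(ids, ped$id)]

  ## ---- stage: covariates ----------------------------------------------
  adjusted <- NULL
  decomps <- list()
  sig_covs <- list()
  if (isTRUE(cfg$stages$covariates)) {
    m_cov <- nrow(covs$meta)
    adj_mat <- matrix(NA_real_, nrow(ddcq), ncol(ddcq),
                      dimnames = dimnames(ddcq))
    cov_rows <- list()
    for (pr in rownames(ddcq)) {
      y <- ddcq[pr, ]
      tf <- fit_full_model(y, covs)
      vd <- variance_decomposition(tf)
      decomps[[pr]] <- vd
      sig <- significant_covariates(vd, alpha = th$alpha, m = m_cov)
      sig_covs[[pr]] <- sig
      adj <- adjust_and_rint(y, covs, sig)
      adj_mat[pr, names(adj$values)] <- adj$values
      cov_rows[[pr]] <- data.frame(protein = pr, term = vd$table$term,
                                   fraction = vd$table$fraction, p = vd$table$p,
                                   significant = vd$table$term %in% sig,
                                   stringsAsFactors = FALSE)
    }
    adjusted <- adj_mat
    vd_tab <- do.call(rbind, cov_rows)
    rownames(vd_tab) <- NULL
    paths$variance_decomposition <- file.path(out_dir, "variance_decomposition.tsv")
    write_df_tsv(vd_tab, paths$variance_decomposition, header = hdr)

    # Table-1-shaped covariate report with univariate direction labels
    sig_tab <- vd_tab[vd_tab$significant, , drop = FALSE]
    if (nrow(sig_tab)) {
      dirn <- vapply(seq_len(nrow(sig_tab)), function(i) {
        x <- as.numeric(covs$data[ids, sig_tab$term[i]])
        if (stats::cor(ddcq[sig_tab$protein[i], ], x,
                       use = "complete.obs") >= 0) "Up" else "Down"
      }, character(1))
      cov_report <- do.call(rbind, lapply(split(seq_len(nrow(sig_tab)),
                                                sig_tab$term), function(ii) {
        data.frame(covariate = sig_tab$term[ii[1]],
                   n_proteins = length(ii),
                   proteins = paste(sprintf("%s(%s)", sig_tab$protein[ii], dirn[ii]),
                                    collapse = ","),
                   stringsAsFactors = FALSE)
      }))
    } else {
      cov_report <- data.frame(covariate = character(), n_proteins = integer(),
                               proteins = character(), stringsAsFactors = FALSE)
    }
    paths$covariate_report <- file.path(out_dir, "covariate_report.tsv")
    write_df_tsv(cov_report, paths$covariate_report, header = hdr)
    paths$adjusted <- file.path(out_dir, "adjusted_traits.tsv")
    write_matrix_tsv(adj_mat, paths$adjusted, header = hdr)

    if (nrow(adj_mat) >= 2) {
      cp <- correlate_pairs(adj_mat, r2_min = th$r2_min)
      paths$correlations <- file.path(out_dir, "biomarker_correlations.tsv")
      write_df_tsv(cp, paths$correlations, header = hdr)
      results$correlations <- cp
    }
    say("covariates: decomposed %d proteins over %d covariates", nrow(ddcq), m_cov)
    results$decompositions <- decomps
    results$significant_covariates <- sig_covs
    results$adjusted <- adjusted
  }

  ## ---- stage: kinship --------------------------------------------------
  K <- NULL
  if (isTRUE(cfg$stages$kinship)) {
    gqc <- genotype_qc(genotypes, marker_call_rate = th$marker_call_rate,
                       individual_call_rate = th$individual_call_rate,
                       hwe_alpha = th$hwe_alpha, mac_min = 1)
    results$genotypes_qc <- gqc
    K <- genomic_kinship(gqc)
    paths$kinship <- file.path(out_dir, "kinship.tsv")
    write_matrix_tsv(unclass(K), paths$kinship, header = hdr)
    say("kinship: %d markers after QC (%d removed)",
        gqc$qc_report$n_markers_out,
        gqc$qc_report$n_markers_in - gqc$qc_report$n_markers_out)
  }

  ## ---- stage: heritability --------------------------------------------
  if (isTRUE(cfg$stages$heritability) && !is.null(K) && !is.null(adjusted)) {
    her <- do.call(rbind, lapply(rownames(adjusted), function(pr) {
      y <- adjusted[pr, ]
      y <- y[!is.na(y)]
      fit <- fit_polygenic(y, K[names(y), names(y)])
      data.frame(protein = pr, n = fit$n, h2 = fit$h2,
                 sigma2g = fit$sigma2g, sigma2e = fit$sigma2e,
                 p = heritability_pvalue(fit), stringsAsFactors = FALSE)
    }))
    her$significant <- her$p < bonferroni_threshold(th$alpha, nrow(her))
    paths$heritability <- file.path(out_dir, "heritability.tsv")
    write_df_tsv(her, paths$heritability, header = hdr)
    say("heritability: %d/%d proteins significant (Bonferroni %.1e)",
        sum(her$significant), nrow(her), bonferroni_threshold(th$alpha, nrow(her)))
    results$heritability <- her
  }

  ## ---- stage: GWAS -----------------------------------------------------
  gwas <- list()
  top_hits <- list()
  if (isTRUE(cfg$stages$gwas) && !is.null(K) && !is.null(adjusted)) {
    gq <- results$genotypes_qc
    for (pr in rownames(adjusted)) {
      y <- adjusted[pr, ]
      names(y) <- colnames(adjusted)
      gw <- run_gwas(y[!is.na(y)], gq, cohort[!is.na(y)], K,
                     alpha = th$alpha, min_mac = th$min_mac)
      gwas[[pr]] <- gw
      if (length(gw$hits$combined)) {
        comb <- gw$combined
        top <- comb[which.min(comb$p), ]
        top_hits[[pr]] <- data.frame(
          protein = pr,
          h2_discovery = gw$fits$discovery$h2, n_discovery = gw$n[["discovery"]],
          hits_discovery = length(gw$hits$discovery),
          p_best_discovery = min(gw$discovery$p),
          h2_replication = gw$fits$replication$h2, n_replication = gw$n[["replication"]],
          hits_replication = length(gw$hits$replication),
          p_best_replication = if (nrow(gw$replication)) min(gw$replication$p) else NA_real_,
          h2_combined = gw$fits$combined$h2,
          hits_combined = length(gw$hits$combined),
          top_marker = top$marker, p_best_combined = top$p,
          var_expl_pct = 100 * top$var_expl,
          lambda_combined = gw$lambda$combined,
          stringsAsFactors = FALSE)
      }
    }
    all_scores <- do.call(rbind, lapply(names(gwas), function(pr) {
      do.call(rbind, lapply(c("discovery", "replication", "combined"), function(ph) {
        s <- gwas[[pr]][[ph]]
        if (!nrow(s)) return(NULL)
        s$phase <- ph
        s$protein <- pr
        s
      }))
    }))
    if (!is.null(all_scores) && nrow(all_scores)) {
      # full per-marker summary statistics; phase carries the protein label
      paths$gwas_summary <- file.path(out_dir, "gwas_summary.tsv")
      write_gwas_summary(
        transform(all_scores, phase = paste(protein, phase, sep = ":"))[
          , c("marker", "beta", "se", "chi2", "p", "var_expl", "phase")],
        gq$markers, paths$gwas_summary,
        n = NA_integer_, header = hdr)
    }
    if (length(top_hits)) {
      tt <- do.call(rbind, top_hits)
      rownames(tt) <- NULL
      paths$gwas_top_hits <- file.path(out_dir, "gwas_top_hits.tsv")
      write_df_tsv(tt, paths$gwas_top_hits, header = hdr)
      results$gwas_top_hits <- tt
    }
    say("gwas: %d/%d proteins with combined genome-wide hits",
        length(top_hits), nrow(adjusted))
    results$gwas <- gwas
  }

  ## ---- stage: conditional ---------------------------------------------
  if (isTRUE(cfg$stages$conditional) && length(top_hits)) {
    gq <- results$genotypes_qc
    cond_rows <- list()
    for (pr in names(top_hits)) {
      gw <- gwas[[pr]]
      if (!length(gw$hits$replication)) next
      y <- adjusted[pr, ]
      names(y) <- colnames(adjusted)
      y <- y[!is.na(y)]
      cs <- conditional_scan(y, gq, K, top_hits[[pr]]$top_marker,
                             cutoff = th$conditional_cutoff)
      if (length(cs$hits)) {
        s <- cs$scores[cs$scores$marker %in% cs$hits, , drop = FALSE]
        s$protein <- pr
        s$conditioned_on <- cs$top_marker
        cond_rows[[pr]] <- s
      }
      results$conditional[[pr]] <- cs
    }
    cond_tab <- if (length(cond_rows)) do.call(rbind, cond_rows) else
      data.frame(marker = character(), beta = numeric(), se = numeric(),
                 chi2 = numeric(), p = numeric(), var_expl = numeric(),
                 protein = character(), conditioned_on = character(),
                 stringsAsFactors = FALSE)
    rownames(cond_tab) <- NULL
    paths$conditional <- file.path(out_dir, "conditional_hits.tsv")
    write_df_tsv(cond_tab, paths$conditional, header = hdr)
    say("conditional: %d independent secondary hit(s)", nrow(cond_tab))
    results$conditional_hits <- cond_tab
  }

  ## ---- stage: ABO ------------------------------------------------------
  if (isTRUE(cfg$stages$abo)) {
    abo_sim <- simulate_abo_genotypes(length(ids), seed = seed + 6L, ids = ids)
    calls <- assign_abo(abo_sim$genotypes)
    paths$abo <- file.path(out_dir, "abo_calls.tsv")
    write_df_tsv(calls, paths$abo, header = hdr)
    say("abo: assignment rate %.1f%%", 100 * assignment_rate(calls))
    results$abo <- list(calls = calls, rate = assignment_rate(calls),
                        truth = abo_sim$diplotype)
  }

  ## ---- stage: cutoffs --------------------------------------------------
  if (isTRUE(cfg$stages$cutoffs)) {
    prof_rows <- list()
    gq <- results$genotypes_qc
    for (pr in rownames(ddcq)) {
      y <- ddcq[pr, ]
      # genotype strata at the top combined marker, when the GWAS ran
      if (!is.null(top_hits[[pr]])) {
        mk <- top_hits[[pr]]$top_marker
        g <- round(gq$dosage[ids, mk])
        sr <- stratified_reference(y, paste0(mk, "=", g),
                                   min_group_size = th$min_group_size)
        if (nrow(sr)) {
          sr$protein <- pr
          sr$stratifier <- "genotype"
          prof_rows[[paste(pr, "g", sep = ".")]] <- sr
        }
      } else if (isTRUE(cfg$stages$gwas) == FALSE) {
        say("cutoffs: gwas stage off, %s profiled on covariate strata only", pr)
      }
      age <- covs$data[ids, "age"]
      tert <- cut(age, stats::quantile(age, c(0, 1 / 3, 2 / 3, 1)),
                  include.lowest = TRUE,
                  labels = c("age_low", "age_mid", "age_high"))
      sr_a <- stratified_reference(y, as.character(tert),
                                   min_group_size = th$min_group_size)
      if (nrow(sr_a)) {
        sr_a$protein <- pr
        sr_a$stratifier <- "age_tertile"
        prof_rows[[paste(pr, "a", sep = ".")]] <- sr_a
      }
    }
    profiles <- if (length(prof_rows)) do.call(rbind, prof_rows) else
      data.frame()
    rownames(profiles) <- NULL
    paths$cutoffs <- file.path(out_dir, "cutoff_profiles.tsv")
    write_df_tsv(as.data.frame(profiles), paths$cutoffs, header = hdr)
    results$cutoff_profiles <- profiles
    say("cutoffs: %d strata profiled", nrow(profiles))
  }

  ## ---- manifest --------------------------------------------------------
  paths$manifest <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(list(seed = seed,
                        package = "proteovar",
                        version = as.character(utils::packageVersion("proteovar")),
                        thresholds = th,
                        stages = cfg$stages,
                        synthetic = if (use_synthetic) syn else NULL,
                        log = log_lines),
                   paths$manifest)
  results$paths <- paths
  results$config <- cfg
  invisible(results)
}

# Build the trait models the synthetic config describes: heritabilities
# spread over the configured range, cis effects on a random subset of
# proteins sized to the configured variance-explained range, an age
# effect up to the configured maximum fraction, rare medication effects,
# and a cohort batch shift.
synthetic_trait_models <- function(syn, genotypes) {
  np <- syn$n_proteins
  h2 <- seq(syn$h2_range[1], syn$h2_range[2], length.out = np)
  has_cis <- seq_len(np) <= round(syn$cis_fraction * np)
  cis_ids <- sample(colnames(genotypes$dosage), sum(has_cis))
  ve <- seq(syn$cis_varexpl[1], syn$cis_varexpl[2], length.out = max(sum(has_cis), 1))
  age_fracs <- seq(0.02, syn$age_effect_max, length.out = np)
  models <- vector("list", np)
  ci <- 0L
  for (k in seq_len(np)) {
    sigma_total <- 1
    # age is uniform(15, 90): var = 75^2/12; solve beta for the target fraction
    beta_age <- sqrt(age_fracs[k] * sigma_total / (75^2 / 12))
    cov_eff <- c(age = beta_age)
    cis <- NULL
    beta_snp <- 0
    if (has_cis[k]) {
      ci <- ci + 1L
      cis <- cis_ids[ci]
      p <- genotypes$markers$freq[match(cis, genotypes$markers$id)]
      beta_snp <- sqrt(ve[ci] * sigma_total / (2 * p * (1 - p)))
    }
    # leave room for the residual: scale down h2 if fractions crowd 1
    # (the empirical fixed-effect variance fluctuates around its target,
    # so budget a 25% buffer on the planned fractions)
    room <- 1 - 1.25 * (age_fracs[k] + (if (has_cis[k]) ve[ci] else 0)) - 0.03
    models[[k]] <- trait_model(
      name = sprintf("protein%02d", k),
      h2 = min(h2[k], max(room, 0)), sigma_total = sigma_total,
      mean = stats::runif(1, 4, 10),
      covariate_effects = cov_eff,
      cis_snp = cis, beta_snp = beta_snp,
      lod_censor_fraction = syn$lod_censor_fraction,
      batch_effect = syn$batch_effect)
  }
  models
}
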