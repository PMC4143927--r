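test_that("polygenic model collapses to OLS when K = I", {
  set.seed(51)
  n <- 80
  y <- setNames(rnorm(n, 5), sprintf("i%d", 1:n))
  K <- diag(n)
  dimnames(K) <- list(names(y), names(y))
  fit <- fit_polygenic(y, K)
  expect_true(fit$boundary)
  expect_lt(fit$h2, 1e-3)
  expect_equal(unname(fit$beta["(Intercept)"]), mean(y), tolerance = 1e-6)
  expect_equal(heritability_pvalue(fit), 0.5, tolerance = 1e-3)
})

test_that("optimum beats a dense heritability grid", {
  cohort <- small_cohort(n_families = 25, offspring = 3, singletons = 0,
                         n_markers = 50, seed = 52)
  tr <- simulate_traits(trait_model("t", h2 = 0.5), cohort$ped,
                        kinship = cohort$K, seed = 53)
  y <- tr$ddcq[1, ]
  fit <- fit_polygenic(y, cohort$K)
  eig <- kinship_eigen(cohort$K)
  U <- eig$vectors
  ys <- as.numeric(crossprod(U, y))
  Xs <- crossprod(U, matrix(1, length(y), 1))
  grid_ll <- vapply(seq(1e-6, 1 - 1e-6, length.out = 101), function(h2)
    proteovar:::.profile_h2(h2, ys, Xs, eig$values)$loglik, numeric(1))
  expect_gte(fit$loglik + 1e-6, max(grid_ll))
})

test_that("heritability is invariant to rescaling the kinship matrix", {
  cohort <- small_cohort(n_families = 20, offspring = 3, singletons = 0,
                         n_markers = 50, seed = 54)
  tr <- simulate_traits(trait_model("t", h2 = 0.6), cohort$ped,
                        kinship = cohort$K, seed = 55)
  y <- tr$ddcq[1, ]
  f1 <- fit_polygenic(y, cohort$K)
  f2 <- fit_polygenic(y, 3 * cohort$K)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-4)
  expect_equal(f1$sigma2g, 3 * f2$sigma2g, tolerance = 1e-3)
})

test_that("heritability likelihood-ratio test has power on heritable traits", {
  cohort <- small_cohort(n_families = 80, offspring = 3, singletons = 0,
                         n_markers = 10, seed = 56)
  hits <- replicate(10, {
    tr <- simulate_traits(trait_model("t", h2 = 0.6), cohort$ped,
                          kinship = cohort$K)
    fit <- fit_polygenic(tr$ddcq[1, ], cohort$K)
    heritability_pvalue(fit) < 0.05 / 77
  })
  expect_gte(mean(hits), 0.9)
})

test_that("mmscore equals the GLS Wald refit at fixed variance components", {
  set.seed(57)
  cohort <- small_cohort(n_families = 12, offspring = 3, singletons = 0,
                         n_markers = 30, seed = 58)
  tr <- simulate_traits(trait_model("t", h2 = 0.5), cohort$ped,
                        kinship = cohort$K, seed = 59)
  y <- tr$ddcq[1, ]
  fit <- fit_polygenic(y, cohort$K)
  Oi <- fit$omega_inv
  for (j in 1:20) {
    g <- cohort$genotypes$dosage[, j]
    if (var(g) == 0) next
    sc <- mmscore(fit, g)
    X2 <- cbind(1, g)
    XtOX <- crossprod(X2, Oi %*% X2)
    b <- solve(XtOX, crossprod(X2, Oi %*% y))
    wald <- b[2]^2 / solve(XtOX)[2, 2]
    expect_equal(sc$chi2, as.numeric(wald), tolerance = 1e-6)
    expect_equal(sc$var_expl, sc$chi2 / fit$n)
  }
})

test_that("degenerate markers carry no score information", {
  cohort <- small_cohort(n_families = 12, offspring = 2, singletons = 10,
                         n_markers = 20, seed = 60)
  tr <- simulate_traits(trait_model("t", h2 = 0.4), cohort$ped,
                        kinship = cohort$K, seed = 61)
  y <- tr$ddcq[1, ]
  g <- cohort$genotypes$dosage[, 1]
  # conditioning on the marker itself: chi2 collapses to zero
  fit_c <- fit_polygenic(y, cohort$K, X = cbind(1, top = g))
  sc <- mmscore(fit_c, g)
  expect_equal(sc$chi2, 0)
  expect_equal(sc$p, 1)
  # a perfectly correlated proxy dies the same way
  expect_equal(mmscore(fit_c, 2 - g)$chi2, 0)
  # a monomorphic marker is skipped with a warning
  fit <- fit_polygenic(y, cohort$K)
  expect_warning(res <- mmscore(fit, rep(1, fit$n)), "zero dosage variance")
  expect_null(res)
})

test_that("lambda is the chi-square median over its null value", {
  expect_equal(genomic_lambda(rep(qchisq(0.5, 1), 7)), 1)
  expect_equal(genomic_lambda(2 * rep(qchisq(0.5, 1), 7)), 2)
})

test_that("single-marker variance explained on raw ddCq", {
  set.seed(62)
  n <- 500
  g <- rbinom(n, 2, 0.3)
  expect_equal(suppressWarnings(variance_explained_raw(0.7 * g, g)), 1)
  r2_null <- replicate(40, variance_explained_raw(rnorm(n), g))
  expect_lt(abs(mean(r2_null) - 1 / (n - 1)), 1.5e-3)
  y <- 0.5 * g + rnorm(n, 0, sqrt(1 - 0.25 * var(g)))
  f_target <- 0.25 * var(g) / (0.25 * var(g) + (1 - 0.25 * var(g)))
  expect_lt(abs(variance_explained_raw(y, g) - f_target), 0.05)
  expect_error(variance_explained_raw(rep(1, 50), g[1:50]), "zero trait variance")
  expect_error(variance_explained_raw(rnorm(5), g[1:5]), "complete cases")
})

test_that("planted cis signals are recovered through the phased GWAS", {
  cohort <- small_cohort(n_families = 100, offspring = 4, singletons = 0,
                         n_markers = 800, seed = 63)
  g <- cohort$genotypes
  mk <- g$markers$id[100]
  p <- g$markers$freq[100]
  ve <- 0.25
  tr <- simulate_traits(
    trait_model("t", h2 = 0.35, cis_snp = mk,
                beta_snp = sqrt(ve / (2 * p * (1 - p)))),
    cohort$ped, genotypes = g, kinship = cohort$K, seed = 64)
  y <- tr$ddcq[1, ]
  gw <- run_gwas(y, g, cohort$ped$cohort, cohort$K)
  expect_true(mk %in% gw$hits$discovery)
  expect_true(mk %in% gw$hits$replication)
  expect_true(mk %in% gw$hits$combined)
  comb <- gw$combined[gw$combined$marker == mk, ]
  expect_lt(abs(comb$var_expl - ve), 0.05)
  # a planted signal gains evidence when cohorts are pooled
  expect_lt(comb$p, max(gw$discovery$p[gw$discovery$marker == mk],
                        gw$replication$p[gw$replication$marker == mk]))
  expect_error(run_gwas(y, g, rep("discovery", length(y)), cohort$K),
               "cohorts")
})

test_that("conditional scans separate linked from independent loci", {
  cohort <- small_cohort(n_families = 100, offspring = 4, singletons = 0,
                         n_markers = 300, seed = 65)
  g <- cohort$genotypes
  # two causal markers on chromosome 1, plus a perfect proxy of the first
  m1 <- g$markers$id[5]
  m2 <- g$markers$id[10]
  g$dosage[, 6] <- g$dosage[, m1]          # proxy in perfect LD with m1
  p1 <- g$markers$freq[5]; p2 <- g$markers$freq[10]
  tr <- simulate_traits(
    trait_model("t", h2 = 0.2, cis_snp = m1,
                beta_snp = sqrt(0.2 / (2 * p1 * (1 - p1)))),
    cohort$ped, genotypes = g, kinship = cohort$K, seed = 66)
  y <- tr$ddcq[1, ] + sqrt(0.15 / (2 * p2 * (1 - p2))) * g$dosage[, m2]
  names(y) <- colnames(tr$ddcq)
  cs <- conditional_scan(y, g, cohort$K, top_marker = m1, cutoff = 5e-8)
  expect_true(m2 %in% cs$hits)                       # independent locus survives
  proxy <- cs$scores[cs$scores$marker == g$markers$id[6], ]
  expect_lt(proxy$chi2, 1e-6)                        # proxy collapses
  expect_false(m1 %in% cs$scores$marker)             # self excluded from rescan
})
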