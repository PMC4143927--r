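test_that("pedigree spec validates counts and partitions cohorts", {
  expect_error(pedigree_spec(1, -1, 0), "non-negative")
  expect_error(pedigree_spec(0, 0, 0), "at least one")
  spec <- pedigree_spec(3, 2, 4)
  expect_equal(spec$n_total, 3 * 4 + 4)
  ped <- simulate_pedigree(spec, seed = 1)
  expect_setequal(unique(ped$cohort), c("discovery", "replication"))
  expect_equal(nrow(ped), spec$n_total)
})

test_that("expected kinship: unrelated singletons and nuclear families", {
  ped0 <- simulate_pedigree(pedigree_spec(0, 0, 10), seed = 1)
  K0 <- kinship_from_pedigree(ped0, scale = "kinship")
  expect_equal(unname(diag(K0)), rep(0.5, 10))
  expect_equal(max(abs(K0[upper.tri(K0)])), 0)

  ped1 <- simulate_pedigree(pedigree_spec(1, 2, 0), seed = 1)
  Phi <- kinship_from_pedigree(ped1, scale = "kinship")
  expect_equal(Phi["F1_P1", "F1_O1"], 0.25)  # parent-offspring
  expect_equal(Phi["F1_O1", "F1_O2"], 0.25)  # full sibs
  expect_equal(Phi["F1_P1", "F1_P2"], 0)     # founders unrelated
  # relationship scale is exactly twice the kinship scale
  expect_equal(kinship_from_pedigree(ped1), 2 * Phi)
})

test_that("gene dropping obeys allele frequencies and Mendelian transmission", {
  ped <- simulate_pedigree(pedigree_spec(0, 0, 200), seed = 2)
  g <- simulate_genotypes(ped, 10000, maf_sampler = function(n) rep(0.5, n),
                          seed = 3)
  expect_true(abs(mean(g$dosage) - 1) < 0.02)

  expect_error(simulate_genotypes(ped, 0), "positive")
  expect_error(simulate_genotypes(ped, 10, maf_sampler = function(n) rep(0, n)),
               "strictly in")

  fam <- simulate_pedigree(pedigree_spec(30, 4, 0), seed = 4)
  gf <- simulate_genotypes(fam, 300, seed = 5)
  D <- gf$dosage
  kids <- which(!is.na(fam$father))
  for (i in kids) {
    pa <- D[fam$father[i], ]
    ma <- D[fam$mother[i], ]
    kid <- D[fam$id[i], ]
    # each parent transmits one allele: child within reach of both parents
    expect_true(all(kid >= (pa > 1) + (ma > 1)))
    expect_true(all(kid <= 2 - ((pa < 1) + (ma < 1))))
  }
  # positions strictly increasing within chromosome
  by_chr <- split(gf$markers$pos, gf$markers$chr)
  expect_true(all(vapply(by_chr, function(p) all(diff(p) > 0), logical(1))))
})

test_that("empirical genomic kinship converges to the pedigree expectation", {
  # n large enough that the -1/(n-1) sample-allele-frequency bias of the
  # GRM stays well inside the convergence bound
  spec <- pedigree_spec(30, 3, 50)
  ped <- simulate_pedigree(spec, seed = 6)
  g <- simulate_genotypes(ped, 20000, seed = 7)
  poly <- colMeans(g$dosage) > 0 & colMeans(g$dosage) < 2
  Kg <- genomic_kinship(g$dosage[, poly])
  Kp <- kinship_from_pedigree(ped)
  expect_lt(mean(abs(Kg - Kp)), 0.02)
})

test_that("trait simulation matches its variance budget", {
  ped <- simulate_pedigree(pedigree_spec(0, 0, 500), seed = 8)
  tr0 <- simulate_traits(trait_model("null", h2 = 0, sigma_total = 1),
                         ped, seed = 9)
  expect_true(abs(var(tr0$ddcq[1, ]) - 1) < 0.15)

  fam <- simulate_pedigree(pedigree_spec(20, 3, 0), seed = 10)
  tr1 <- simulate_traits(trait_model("pure", h2 = 1, mean = 3), fam, seed = 11)
  expect_equal(unname(tr1$ddcq[1, ]),
               3 + tr1$components$pure$polygenic)

  big <- simulate_pedigree(pedigree_spec(60, 3, 0), seed = 12)
  g <- simulate_genotypes(big, 100, seed = 12)
  phat <- mean(g$dosage[, 1]) / 2
  beta <- sqrt(0.25 / (2 * phat * (1 - phat)))
  tr2 <- simulate_traits(
    trait_model("cis", h2 = 0.3, cis_snp = g$markers$id[1], beta_snp = beta),
    big, genotypes = g, seed = 13)
  frac <- var(tr2$components$cis$snp) / var(tr2$ddcq[1, ])
  expect_lt(abs(frac - 0.25), 0.08)

  expect_error(
    simulate_traits(trait_model("over", h2 = 0.9, cis_snp = g$markers$id[1],
                                beta_snp = 2), big, genotypes = g, seed = 14),
    "exceed 1")
})

test_that("realized heritability tracks the target over replicates", {
  fam <- simulate_pedigree(pedigree_spec(40, 3, 0), seed = 15)
  K <- kinship_from_pedigree(fam)
  for (h2 in c(0.3, 0.7)) {
    real <- replicate(20, {
      tr <- simulate_traits(trait_model("t", h2 = h2), fam, kinship = K)
      var(tr$components$t$polygenic) / var(tr$ddcq[1, ])
    })
    expect_lt(abs(mean(real) - h2), 0.05)
  }
})

test_that("generators are seed-deterministic", {
  spec <- pedigree_spec(5, 2, 5)
  expect_identical(simulate_pedigree(spec, seed = 42),
                   simulate_pedigree(spec, seed = 42))
  ped <- simulate_pedigree(spec, seed = 42)
  expect_identical(simulate_genotypes(ped, 50, seed = 42),
                   simulate_genotypes(ped, 50, seed = 42))
  expect_identical(simulate_covariates(ped, seed = 42),
                   simulate_covariates(ped, seed = 42))
  tr <- function() simulate_traits(trait_model("t", h2 = 0.4), ped, seed = 42)
  expect_identical(tr(), tr())
})
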