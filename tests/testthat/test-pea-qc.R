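test_that("ddCq normalization follows the extension-control formula", {
  assays <- data.frame(assay = "A001", protein = "P1", correction = 10)
  pl <- manual_plate(cq_assay = matrix(c(20, 21), ncol = 1,
                                       dimnames = list(NULL, "A001")),
                     ext = c(18, 18), neg_cq = 25, neg_ext = 18,
                     assays = assays)
  nm <- normalize_ddcq(pl, assays)
  expect_equal(unname(nm$ddcq["P1", "s1"]), 10 - (20 - 18))  # = 8
  expect_equal(unname(nm$ddcq["P1", "s2"]), 7)

  # a uniform +1 Cq shift of a sample (analyte and extension control)
  pl2 <- pl
  pl2$cq[1, ] <- pl2$cq[1, ] + 1
  pl2$controls[1, "ext"] <- pl2$controls[1, "ext"] + 1
  nm2 <- normalize_ddcq(pl2, assays)
  expect_equal(nm2$ddcq["P1", "s1"], nm$ddcq["P1", "s1"])

  # ddCq is monotone decreasing in raw Cq
  expect_lt(nm$ddcq["P1", "s2"], nm$ddcq["P1", "s1"])
})

test_that("detection limits come from negative controls across plates", {
  assays <- data.frame(assay = "A001", protein = "P1", correction = 10)
  mk <- function(neg_ddcq) {
    manual_plate(cq_assay = matrix(15, 1, 1, dimnames = list(NULL, "A001")),
                 ext = 18, neg_cq = 10 + 18 - neg_ddcq, neg_ext = 18,
                 assays = assays)
  }
  # single plate: LOD equals the negative-control ddCq (SD term vanishes)
  expect_equal(unname(estimate_lod(mk(1.2), assays)), 1.2)
  # three plates: mean 1.2 + 3 * sample SD 0.2
  lod3 <- estimate_lod(list(mk(1.0), mk(1.2), mk(1.4)), assays)
  expect_equal(unname(lod3), 1.2 + 3 * sd(c(1.0, 1.2, 1.4)))
  # a cell exactly at the LOD is masked (<= convention)
  pan <- normalize_panel(mk(5), assays)   # sample ddCq = 10 - (15 - 18) = 13...
  expect_false(pan$below_lod["P1", "s1"])
  pan2 <- normalize_panel(mk(13), assays) # LOD equals the sample value
  expect_true(pan2$below_lod["P1", "s1"])
  expect_error(estimate_lod(list(), assays), "no plates")
})

test_that("plate rendering round-trips through normalization", {
  ped <- simulate_pedigree(pedigree_spec(0, 0, 150), seed = 21)
  models <- list(trait_model("P1", h2 = 0, mean = 6),
                 trait_model("P2", h2 = 0, mean = 8, lod_censor_fraction = 0.2))
  tr <- simulate_traits(models, ped, seed = 22)
  assays <- assay_definitions(rownames(tr$ddcq))
  plates <- render_plates(tr, assays, seed = 23)
  expect_equal(length(plates), ceiling(150 / 92))
  pan <- normalize_panel(plates, assays)
  expect_equal(pan$ddcq[, colnames(tr$ddcq)], tr$ddcq, tolerance = 1e-12)
  # uncensored assay fully above LOD; censored assay close to 20% below
  expect_equal(sum(pan$below_lod["P1", ]), 0)
  expect_equal(mean(pan$below_lod["P2", ]), 0.2, tolerance = 0.01)
  # empty input
  tr0 <- tr
  tr0$ddcq <- tr$ddcq[, 0, drop = FALSE]
  expect_identical(render_plates(tr0, assays), list())
})

test_that("QC thresholds act exactly at their boundaries", {
  # panel built directly: 2 proteins x 400 samples, constant controls
  n <- 400
  set.seed(24)
  ddcq <- matrix(rnorm(2 * n, 8), 2, n,
                 dimnames = list(c("P1", "P2"), sprintf("s%d", 1:n)))
  below <- matrix(FALSE, 2, n, dimnames = dimnames(ddcq))
  below["P1", 1:(n - 199)] <- TRUE   # 199 above-LOD observations -> excluded
  below["P2", 1:(n - 200)] <- TRUE   # exactly 200 -> retained
  panel <- structure(list(
    ddcq = ddcq, below_lod = below, lod = c(P1 = 0, P2 = 0),
    controls = matrix(20, n, 4, dimnames = list(colnames(ddcq),
                                                c("inc1", "inc2", "ext", "det"))),
    plate = setNames(rep("p1", n), colnames(ddcq)),
    flagged = character(0),
    exclusions = data.frame()), class = "normalized_panel")
  q <- apply_qc(panel, min_protein_obs = 200)
  expect_identical(rownames(q$ddcq), "P2")

  # sample boundary: > 75% below LOD excluded, exactly 75% retained
  m <- 8
  ddcq2 <- matrix(rnorm(m * 40, 8), m, 40,
                  dimnames = list(sprintf("P%d", 1:m), sprintf("s%d", 1:40)))
  below2 <- matrix(FALSE, m, 40, dimnames = dimnames(ddcq2))
  below2[1:6, "s1"] <- TRUE   # 6/8 = 75% -> retained
  below2[1:7, "s2"] <- TRUE   # 87.5% -> excluded
  panel2 <- structure(list(
    ddcq = ddcq2, below_lod = below2, lod = setNames(rep(0, m), rownames(ddcq2)),
    controls = matrix(20, 40, 4, dimnames = list(colnames(ddcq2),
                                                 c("inc1", "inc2", "ext", "det"))),
    plate = setNames(rep("p1", 40), colnames(ddcq2)),
    flagged = character(0),
    exclusions = data.frame()), class = "normalized_panel")
  q2 <- apply_qc(panel2, min_protein_obs = 10)
  expect_true("s1" %in% colnames(q2$ddcq))
  expect_false("s2" %in% colnames(q2$ddcq))

  # clean panel: no exclusions; QC is idempotent
  panel3 <- panel2
  panel3$below_lod[] <- FALSE
  q3 <- apply_qc(panel3, min_protein_obs = 10)
  expect_equal(nrow(q3$exclusions), 0)
  expect_equal(apply_qc(q3, min_protein_obs = 10), q3)
  expect_error(apply_qc(panel3, max_below_lod_fraction = 0), "0, 1")
})

test_that("internal-control outliers exclude the sample", {
  n <- 60
  set.seed(25)
  ddcq <- matrix(rnorm(3 * n, 8), 3, n,
                 dimnames = list(c("P1", "P2", "P3"), sprintf("s%d", 1:n)))
  controls <- matrix(rnorm(n * 4, 20, 0.1), n, 4,
                     dimnames = list(colnames(ddcq), c("inc1", "inc2", "ext", "det")))
  controls["s5", "inc1"] <- 25   # gross failure
  panel <- structure(list(
    ddcq = ddcq, below_lod = matrix(FALSE, 3, n, dimnames = dimnames(ddcq)),
    lod = setNames(rep(0, 3), rownames(ddcq)), controls = controls,
    plate = setNames(rep("p1", n), colnames(ddcq)), flagged = character(0),
    exclusions = data.frame()), class = "normalized_panel")
  q <- apply_qc(panel, min_protein_obs = 10)
  expect_true("s5" %in% q$exclusions$id[q$exclusions$reason == "internal-control outlier"])
})

test_that("QC summary percentages follow 100 * num / den at one decimal", {
  expect_equal(round(qc_fraction(70651, 77385), 1), 91.3)
  expect_equal(round(qc_fraction(14598, 15075), 1), 96.8)
  expect_equal(round(qc_fraction(970, 1005), 1), 96.5)
  expect_equal(round(qc_fraction(35, 1005), 1), 3.5)
  expect_error(qc_fraction(1, 0), "zero denominator")
})
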