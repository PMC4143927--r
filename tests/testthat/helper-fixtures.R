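# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small enough that each file runs in seconds.

# A small family cohort reused across association tests.
small_cohort <- function(n_families = 40, offspring = 3, singletons = 20,
                         n_markers = 400, seed = 101) {
  spec <- pedigree_spec(n_families, offspring, singletons)
  ped <- simulate_pedigree(spec, seed = seed)
  list(ped = ped,
       K = kinship_from_pedigree(ped),
       genotypes = simulate_genotypes(ped, n_markers, seed = seed + 1))
}

# A hand-built single plate with deterministic values: 3 samples, one
# negative control well, one positive control well slot kept minimal.
manual_plate <- function(cq_assay, ext, neg_cq, neg_ext, assays) {
  n_s <- nrow(cq_assay)
  cq <- rbind(cq_assay, neg = neg_cq)
  controls <- cbind(inc1 = rep(20, n_s + 1), inc2 = rep(21, n_s + 1),
                    ext = c(ext, neg_ext), det = rep(22, n_s + 1))
  structure(list(plate_id = "p1", cq = cq,
                 well_type = c(rep("sample", n_s), "negative"),
                 sample_id = c(sprintf("s%d", seq_len(n_s)), NA),
                 controls = controls),
            class = "plate_run")
}

# Independent enumeration oracle for the exact Hardy-Weinberg test,
# built on the recurrence between successive heterozygote probabilities
# rather than direct log-factorials.
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  nm <- min(nA, 2 * n - nA)
  hets <- seq(nm %% 2, nm, by = 2)
  probs <- numeric(length(hets))
  probs[1] <- 1
  if (length(hets) > 1) {
    for (k in seq_len(length(hets) - 1)) {
      h <- hets[k]
      # P(h+2) / P(h) from the conditional distribution
      aa <- (nm - h) / 2
      AA <- n - h - aa
      probs[k + 1] <- probs[k] * 4 * AA * aa / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(nAa, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}
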