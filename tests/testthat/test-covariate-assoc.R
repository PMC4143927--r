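test_that("Bonferroni thresholds", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
  expect_error(bonferroni_threshold(1.2, 10), "0, 1")
})

make_covs <- function(dat) {
  structure(list(
    data = dat,
    meta = data.frame(name = names(dat),
                      kind = ifelse(vapply(dat, is.factor, TRUE), "categorical",
                                    "continuous"),
                      users = NA_integer_, stringsAsFactors = FALSE)),
    class = "covariate_table")
}

test_that("full model recovers a planted covariate effect", {
  set.seed(31)
  n <- 300
  age <- runif(n, 15, 90)
  y <- setNames(2 * age + rnorm(n, 0, 0.5), sprintf("i%d", 1:n))
  covs <- make_covs(data.frame(age = age, row.names = names(y)))
  tf <- fit_full_model(y, covs)
  expect_equal(unname(coef(tf$fit)["age"]), 2, tolerance = 0.01)
  vd <- variance_decomposition(tf)
  expect_gt(vd$table$fraction[vd$table$term == "age"], 0.99)
  # single-covariate fraction is the squared Pearson correlation
  expect_equal(vd$table$fraction[1], cor(y, age)^2)
})

test_that("null covariates stay below the Bonferroni screen", {
  set.seed(32)
  n <- 500
  dat <- as.data.frame(matrix(rnorm(n * 10), n,
                              dimnames = list(sprintf("i%d", 1:n),
                                              sprintf("c%d", 1:10))))
  y <- setNames(rnorm(n), rownames(dat))
  vd <- variance_decomposition(fit_full_model(y, make_covs(dat)))
  expect_length(significant_covariates(vd, alpha = 0.05, m = 10), 0)
  # a pure-noise covariate explains about 1/(n-1) in expectation
  expect_lt(mean(vd$table$fraction), 3 / (n - 1))
  # sequential fractions plus the residual account for everything
  expect_equal(vd$combined_fraction + vd$residual_fraction, 1)
  expect_true(all(vd$table$fraction >= 0))
})

test_that("constant covariates are dropped with a warning", {
  set.seed(33)
  n <- 100
  dat <- data.frame(age = runif(n, 15, 90), fixedcov = rep(1, n),
                    row.names = sprintf("i%d", 1:n))
  y <- setNames(rnorm(n), rownames(dat))
  expect_warning(tf <- fit_full_model(y, make_covs(dat)), "fixedcov")
  expect_false("fixedcov" %in% tf$terms)
})

test_that("orthogonal designs decompose order-independently", {
  # orthogonal-projection oracle: with mutually orthogonal centered
  # covariates, fraction(j) = (x_j' y)^2 / (|x_j|^2 * total SS),
  # independent of entry order
  set.seed(34)
  n <- 64
  # orthonormal columns, all orthogonal to the constant (mean zero)
  X <- qr.Q(qr(cbind(1, matrix(rnorm(n * 4), n))))[, 2:5]
  y <- setNames(rnorm(n), sprintf("i%d", 1:n))
  yc <- y - mean(y)
  oracle <- as.numeric((crossprod(X, yc))^2 / sum(yc^2))
  dat <- as.data.frame(X)
  names(dat) <- sprintf("c%d", 1:4)
  rownames(dat) <- names(y)
  vd1 <- variance_decomposition(fit_full_model(y, make_covs(dat)))
  expect_equal(vd1$table$fraction, oracle, tolerance = 1e-10)
  # reversed entry order: same per-term fractions
  dat2 <- dat[, 4:1]
  vd2 <- variance_decomposition(fit_full_model(y, make_covs(dat2)))
  expect_equal(vd2$table$fraction[match(vd1$table$term, vd2$table$term)],
               vd1$table$fraction, tolerance = 1e-10)
  expect_equal(vd1$combined_fraction, vd2$combined_fraction)
})

test_that("rank-inverse-normal adjustment has the closed quantile form", {
  y <- setNames(c(3.2, -1.5, 0.4, 10), sprintf("i%d", 1:4))
  a <- adjust_and_rint(y)
  expect_equal(sort(unname(a$values)),
               qnorm(c(0.125, 0.375, 0.625, 0.875)))
  # invariance to strictly monotone transforms
  a2 <- adjust_and_rint(setNames(exp(y / 3), names(y)))
  expect_equal(a2$values[order(y)], a$values[order(y)])
  # affine invariance
  a3 <- adjust_and_rint(5 - 2 * y * -1)
  expect_equal(a3$values, a$values)
  expect_error(adjust_and_rint(setNames(rep(1, 10), 1:10)), "distinct")
})

test_that("adjustment removes covariates and normalizes moments", {
  set.seed(35)
  n <- 500
  age <- runif(n, 15, 90)
  y <- setNames(0.1 * age + rnorm(n), sprintf("i%d", 1:n))
  covs <- make_covs(data.frame(age = age, row.names = names(y)))
  a <- adjust_and_rint(y, covs, "age")
  expect_lt(abs(mean(a$values)), 1e-10)
  expect_lt(abs(var(a$values) - 1), 0.05)
  expect_lt(abs(cor(a$values, age)), 0.1)
})

test_that("pairwise Spearman screening reports only strong pairs", {
  set.seed(36)
  n <- 500
  z <- rnorm(n)
  lam <- 0.9
  panel <- rbind(
    a = z,
    b = z,                                     # identical: rho = 1
    c = lam * scale(z)[, 1] + sqrt(1 - lam^2) * rnorm(n),
    d = rnorm(n), e = rnorm(n))                # independent
  colnames(panel) <- sprintf("i%d", 1:n)
  cp <- correlate_pairs(panel, r2_min = 0.5)
  ab <- cp[cp$protein_a == "a" & cp$protein_b == "b", ]
  expect_equal(ab$rho, 1)
  expect_true(all(cp$r2 > 0.5))
  expect_false(any(cp$protein_a %in% c("d", "e") & cp$protein_b %in% c("d", "e")))
  # latent-factor pair recovered near loading^2 (Spearman slightly below Pearson)
  ac <- cp[cp$protein_a == "a" & cp$protein_b == "c", ]
  expect_equal(ac$r2, lam^2, tolerance = 0.08)
  # independent pairs average near zero squared correlation
  rho <- attr(cp, "rho")
  expect_lt(mean(rho[c("d", "e"), c("a", "b", "c")]^2), 0.02)
  # sparse overlap pairs are skipped with a warning
  panel2 <- panel
  panel2["d", 3:n] <- NA
  panel2["e", 1:(n - 2)] <- NA
  expect_warning(correlate_pairs(panel2), "shared observations")
})
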