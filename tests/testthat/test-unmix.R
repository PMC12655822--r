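test_that("ratio designs normalise to theoretical fractions", {
  expect_equal(ratios_to_fractions(c(1, 6, 1, 1, 1)),
               c(0.10, 0.60, 0.10, 0.10, 0.10))
  expect_equal(ratios_to_fractions(c(2, 2, 2, 2, 2)), rep(0.2, 5))
  expect_equal(ratios_to_fractions(c(0, 0, 5, 0, 0)), c(0, 0, 1, 0, 0))
  expect_error(ratios_to_fractions(c(0, 0, 0, 0, 0)), "all zero")
  expect_error(ratios_to_fractions(c(-1, 1, 1, 1, 1)), "non-negative")
  expect_error(ratios_to_fractions(c(1, 1, 1)), "length 5")
})

test_that("unmixing a pure reference returns a one-hot weight vector", {
  pure <- tibble::tibble(wavenumber = attr(ref_mat, "wavenumber"),
                         intensity = ref_mat[, "QSY21"])
  for (mode in c("ols", "nnls")) {
    fit <- cls_unmix(pure, ref_lib, mode)
    expect_equal(unname(fit$weights),
                 c(0, 0, 0, 1, 0), tolerance = 1e-9)
    expect_lt(fit$residual_norm, 1e-9)
  }
})

test_that("CLS matches the normal-equation oracle and recovers any mixture", {
  oracle <- function(y) drop(solve(t(ref_mat) %*% ref_mat,
                                   t(ref_mat) %*% y))
  two <- mix_spectra(ref_lib, c(0.3, 0.7, 0, 0, 0))
  for (mode in c("ols", "nnls")) {
    fit <- cls_unmix(two, ref_lib, mode)
    expect_equal(unname(fit$weights), c(0.3, 0.7, 0, 0, 0),
                 tolerance = 1e-9)
  }
  W <- random_weights(20, seed = 31)
  for (i in seq_len(nrow(W))) {
    sp <- mix_spectra(ref_lib, W[i, ])
    ols <- cls_unmix(sp, ref_lib, "ols")
    nnls <- cls_unmix(sp, ref_lib, "nnls")
    expect_equal(unname(ols$weights), unname(oracle(sp$intensity)),
                 tolerance = 1e-9)
    expect_equal(unname(nnls$weights), W[i, ], tolerance = 1e-9)
  }
})

test_that("NNLS agrees with OLS whenever the OLS solution is non-negative", {
  W <- random_weights(100, seed = 47)
  checked <- 0
  for (i in seq_len(nrow(W))) {
    sp <- mix_spectra(ref_lib, W[i, ], noise_sd = 0.01, seed = 100 + i)
    ols <- cls_unmix(sp, ref_lib, "ols")
    if (all(ols$weights >= 0)) {
      nnls <- cls_unmix(sp, ref_lib, "nnls")
      expect_equal(unname(nnls$weights), unname(ols$weights),
                   tolerance = 1e-9)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 50)
})

test_that("OLS weights are scale-covariant in the input spectrum", {
  sp <- mix_spectra(ref_lib, c(0.2, 0.1, 0.4, 0.05, 0.25), noise_sd = 0.01,
                    seed = 3)
  base <- cls_unmix(sp, ref_lib, "ols")
  scaled <- sp
  scaled$intensity <- 3.5 * scaled$intensity
  expect_equal(unname(cls_unmix(scaled, ref_lib, "ols")$weights),
               3.5 * unname(base$weights), tolerance = 1e-9)
})

test_that("unmixing rejects mismatched axes and collinear libraries", {
  sp <- mix_spectra(ref_lib, rep(0.2, 5))
  off <- sp
  off$wavenumber <- off$wavenumber + 1
  expect_error(cls_unmix(off, ref_lib), "resample")

  collinear <- ref_lib
  collinear$intensity[collinear$reporter == "BHQ3"] <-
    2 * collinear$intensity[collinear$reporter == "SiNC"]
  expect_error(cls_unmix(sp, collinear), "SiNC.*BHQ3|BHQ3.*SiNC")
})

test_that("pearson_with_slope_p reproduces the textbook formulas", {
  exact <- pearson_with_slope_p(c(1, 2, 3), c(2, 4, 6))
  expect_equal(exact$r, 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 0)

  hand <- pearson_with_slope_p(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(hand$r, 0.6)

  x <- c(1, 2, 3, 4, 5)
  y <- x + c(0.1, -0.1, 0.1, -0.1, 0.1)
  res <- pearson_with_slope_p(x, y)
  lmfit <- summary(lm(y ~ x))
  expect_equal(res$r, sqrt(lmfit$r.squared) * sign(res$slope))
  expect_equal(res$slope, unname(lmfit$coefficients["x", "Estimate"]))
  expect_equal(res$p, unname(lmfit$coefficients["x", "Pr(>|t|)"]))

  expect_error(pearson_with_slope_p(x, rep(1, 5)), "variance")
  expect_error(pearson_with_slope_p(1:2, 1:2), "3 pairs")
})

test_that("recovery correlation is exact for perfect recovery and affine-invariant", {
  res <- tibble::tibble(design = rep("d1", 5),
                        true_fraction = c(0.1, 0.6, 0.1, 0.1, 0.1),
                        recovered_fraction = c(0.1, 0.6, 0.1, 0.1, 0.1))
  expect_equal(recovery_correlation(res)$r, 1)

  x <- c(0.1, 0.2, 0.3, 0.25, 0.15)
  y <- c(0.12, 0.18, 0.33, 0.22, 0.15)
  r0 <- pearson_with_slope_p(x, y)$r
  expect_equal(pearson_with_slope_p(2 * x + 1, y)$r, r0)
  expect_equal(pearson_with_slope_p(x, 0.5 * y + 3)$r, r0)
})

test_that("recovered weights are renormalised within each design", {
  res <- tibble::tibble(design = rep(c("d1", "d2"), each = 5),
                        true_fraction = rep(c(0.1, 0.6, 0.1, 0.1, 0.1), 2),
                        recovered_weight = c(1, 6, 1, 1, 1, 2, 12, 2, 2, 2))
  expect_equal(recovery_correlation(res)$r, 1)
})
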