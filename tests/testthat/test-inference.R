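test_that("twin label assignment is deterministic, balanced, and validated", {
  at <- small_study_table()
  a1 <- assign_twin_labels(at, seed = 3)
  a2 <- assign_twin_labels(at, seed = 3)
  expect_identical(a1, a2)
  big <- tibble::tibble(family_id = rep(1:10000, each = 2),
                        twin_index = rep(1:2, 10000))
  asg <- assign_twin_labels(big, seed = 1)
  expect_equal(mean(asg$twin_a == 1), 0.5, tolerance = 0.02)
  lone <- tibble::tibble(family_id = c(1, 1, 2), twin_index = c(1, 2, 1))
  expect_error(assign_twin_labels(lone, seed = 1), "exactly two twins")
})

test_that("difference scores subtract B from A and exclude incomplete families", {
  d <- tibble::tibble(family_id = rep(1:3, each = 2), zygosity = "MZ",
                      twin_index = rep(1:2, 3),
                      x = c(3, 1, 2, 5, 1, NA), y = c(2, 0, 1, 1, 0, 4))
  asg <- tibble::tibble(family_id = 1:3, twin_a = c(1L, 2L, 1L))
  diffs <- compute_difference_scores(d, "x", "y", asg)
  expect_equal(nrow(diffs), 2)
  expect_equal(diffs$dx, c(2, 3))   # fam1: 3-1; fam2: 5-2 (twin 2 is A)
  expect_equal(diffs$dy, c(2, 0))
  expect_equal(attr(diffs, "n_excluded"), 1)
  expect_error(compute_difference_scores(d, "nope", "y", asg),
               "not found")
})

test_that("difference correlations match hand-computed values and the Fisher CI", {
  diffs <- tibble::tibble(family_id = 1:4, zygosity = "MZ",
                          dx = c(1, 2, 3, 4), dy = c(2, 4, 6, 8))
  est <- diff_correlation(diffs, "MZ")
  expect_equal(est$estimate, 1)
  # frozen Fisher-transform arithmetic: r = 0.5, n = 103
  # atanh(0.5) +/- 1.96/10, back-transformed -> (0.339, 0.632)
  z <- atanh(0.5)
  expect_lt(abs(tanh(z - 1.96 / sqrt(100)) - 0.339), 1e-3)
  expect_lt(abs(tanh(z + 1.96 / sqrt(100)) - 0.632), 1e-3)
  expect_error(diff_correlation(diffs[1:3, ], "MZ"), "at least 4")
  zero <- tibble::tibble(family_id = 1:5, zygosity = "DZ",
                         dx = rep(0, 5), dy = rnorm(5))
  flagged <- diff_correlation(zero, "DZ")
  expect_true(flagged$degenerate)
  expect_true(is.na(flagged$estimate))
})

test_that("difference correlations agree with brute-force sums on small tables", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    diffs <- tibble::tibble(family_id = 1:n, zygosity = "MZ",
                            dx = rnorm(n), dy = rnorm(n))
    est <- diff_correlation(diffs, "MZ")
    num <- 0; sxx <- 0; syy <- 0
    for (j in 1:n) {
      num <- num + diffs$dx[j] * diffs$dy[j]
      sxx <- sxx + diffs$dx[j]^2
      syy <- syy + diffs$dy[j]^2
    }
    expect_equal(est$estimate, num / sqrt(sxx * syy), tolerance = 1e-12)
  }
})

test_that("difference correlations are invariant to the A/B assignment seed", {
  at <- small_study_table()
  xcol <- nurt_column("mother")
  ycol <- asb_column("cbcl_aggression", "mother", "raw")
  e1 <- diff_correlation(
    compute_difference_scores(at, xcol, ycol,
                              assign_twin_labels(at, seed = 1)), "MZ")
  e2 <- diff_correlation(
    compute_difference_scores(at, xcol, ycol,
                              assign_twin_labels(at, seed = 999)), "MZ")
  expect_identical(e1$estimate, e2$estimate)
  expect_identical(e1$p, e2$p)
})

test_that("the multilevel model reduces to the pooled slope without family variance", {
  set.seed(22)
  fam <- rep(1:400, each = 2)
  x <- rnorm(800)
  y <- 0.3 * x + rnorm(800)
  y <- y - stats::ave(y, fam)   # family means exactly zero
  est <- mlm_phenotypic(x, y, fam)
  expect_equal(est$estimate, cor(x, y), tolerance = 1e-6)
  expect_equal(est$n, 800L)
})

test_that("the multilevel model is unbiased under the null and recovers a known slope", {
  set.seed(23)
  fam <- rep(1:10000, each = 2)
  x <- rnorm(20000)
  y <- rnorm(20000) + rep(rnorm(10000), each = 2)
  null_est <- mlm_phenotypic(x, y, fam)
  expect_equal(null_est$estimate, 0, tolerance = 0.02)
  expect_true(null_est$ci_low <= null_est$estimate &&
                null_est$estimate <= null_est$ci_high)

  # latent study-scale data generated with individual-level r = -0.10
  p <- scenario_preset("scenario3_genetic_shared", 0.10, -1)
  pairs <- simulate_biometric_pairs(p, 426, 604, seed = 24)
  est <- mlm_phenotypic(pairs$x, pairs$y, pairs$family_id)
  expect_lt(abs(est$estimate - (-0.10)), 0.04)
  expect_error(mlm_phenotypic(rep(1, 10), rnorm(10), rep(1:5, each = 2)),
               "zero-variance")
})

test_that("p-to-z conversion anchors at 1.96, handles edge cases, round-trips", {
  expect_equal(p_to_signed_z(0.05, -1), -1.96, tolerance = 5e-3)
  expect_identical(p_to_signed_z(1, 1), 0)
  expect_identical(p_to_signed_z(0.5, 0), 0)
  expect_equal(p_to_signed_z(0.3173, 1), 1.00, tolerance = 5e-3)
  expect_error(p_to_signed_z(0, 1), "p-values")
  expect_error(p_to_signed_z(1.2, 1), "p-values")
  expect_error(p_to_signed_z(0.05, 2), "effect_sign")
  p <- 10^seq(-12, 0, length.out = 40)
  z <- p_to_signed_z(p, 1)
  back <- 2 * stats::pnorm(-abs(z))
  expect_equal(back, p, tolerance = 1e-9)
})

test_that("the dependent-correlation test matches its formula and is antisymmetric", {
  st <- steiger_dependent_z(0.1, 0.4, 0.3, 200)
  rbar <- (0.1 + 0.4) / 2
  psi <- 0.3 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - 0.3^2)
  s <- psi / (1 - rbar^2)^2
  z_ref <- (atanh(0.1) - atanh(0.4)) * sqrt(197) / sqrt(2 - 2 * s)
  expect_equal(st$z, z_ref, tolerance = 1e-12)
  expect_equal(st$p, 2 * pnorm(-abs(z_ref)), tolerance = 1e-12)

  set.seed(25)
  for (i in 1:20) {
    m <- cor(matrix(rnorm(60), ncol = 3))
    sw <- steiger_dependent_z(m[1, 2], m[1, 3], m[2, 3], 50)
    ws <- steiger_dependent_z(m[1, 3], m[1, 2], m[2, 3], 50)
    expect_equal(sw$z, -ws$z, tolerance = 1e-12)
  }
})

test_that("the dependent-correlation test validates its inputs and degenerate cases", {
  expect_identical(steiger_dependent_z(0.3, 0.3, 0.5, 100)$z, 0)
  expect_identical(steiger_dependent_z(0.3, 0.3, 0.999, 100)$p, 1)
  expect_error(steiger_dependent_z(0.9, -0.9, 0.9, 100),
               "positive\\s+semi-definite")
  expect_error(steiger_dependent_z(0.1, 0.2, 0.3, 3), "at least 4")
  expect_error(steiger_dependent_z(1, 0.2, 0.3, 100), "correlations")
})
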