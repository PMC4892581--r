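test_that("implied correlations follow the shared-over-total variance ratio", {
  expect_equal(implied_correlation(0.030, c(0.030, 0.050)), 0.375)
  expect_equal(round(implied_correlation(0.015, c(0.015, 0.050)), 3), 0.231)
  expect_equal(round(implied_correlation(0.010, c(0.010, 0.050)), 3), 0.167)
  expect_equal(implied_correlation(numeric(0), 0.05), 0)
  expect_error(implied_correlation(0.1, numeric(0)), "positive")
  expect_error(implied_correlation(0.2, 0.1), "subset")
})

test_that("flat generator matches its implied correlation structure at large m", {
  x <- as.matrix(simulate_modules(c(4, 4), m = 50000, v_c = 0.030,
                                  v_e = 0.050, seed = 42))
  cm <- cor(x)
  within <- c(cm[1:4, 1:4][upper.tri(diag(4))],
              cm[5:8, 5:8][upper.tri(diag(4))])
  between <- cm[1:4, 5:8]
  expect_equal(mean(within), 0.375, tolerance = 0.01 / 0.375)
  expect_lt(abs(mean(between)), 0.01)
  # v_c = 0: no shared component, all correlations vanish
  x0 <- as.matrix(simulate_modules(c(4, 4), m = 20000, v_c = 0,
                                   v_e = 0.050, seed = 43))
  off <- cor(x0)[upper.tri(diag(8))]
  expect_lt(abs(mean(off)), 0.01)
})

test_that("beta and uniform components reproduce the target variances", {
  for (dist in c("beta", "uniform")) {
    x <- as.matrix(simulate_modules(c(4, 4), m = 50000, distribution = dist,
                                    seed = 7))
    cm <- cov(x)
    # within-module covariance estimates v(c); residual variance estimates v(e)
    v_c_hat <- mean(c(cm[1:4, 1:4][upper.tri(diag(4))],
                      cm[5:8, 5:8][upper.tri(diag(4))]))
    v_e_hat <- mean(diag(cm)) - v_c_hat
    expect_equal(v_c_hat, 0.030, tolerance = 0.05)
    expect_equal(v_e_hat, 0.050, tolerance = 0.05)
  }
  expect_error(simulate_modules(c(4, 4), v_c = 0.02, distribution = "beta"),
               "0.030")
})

test_that("hierarchical generator reproduces the nested correlation levels", {
  x <- as.matrix(simulate_hierarchy(list(list(2, 2), list(2, 2)), m = 50000,
                                    level_variances = c(0.03, 0.03),
                                    v_e = 0.05, seed = 11))
  cm <- cor(x)
  same_sub <- c(cm[1, 2], cm[3, 4], cm[5, 6], cm[7, 8])
  same_mod <- c(cm[1, 3], cm[1, 4], cm[2, 3], cm[2, 4],
                cm[5, 7], cm[5, 8], cm[6, 7], cm[6, 8])
  diff_mod <- cm[1:4, 5:8]
  expect_equal(mean(same_sub), 6 / 11, tolerance = 0.01 / 0.5)
  expect_equal(mean(same_mod), 3 / 11, tolerance = 0.01 / 0.27)
  expect_lt(abs(mean(diff_mod)), 0.01)
  # three levels: innermost pairs share three components
  x3 <- as.matrix(simulate_hierarchy(
    list(list(list(2, 2), list(2, 2)), list(list(2, 2), list(2, 2))),
    m = 50000, level_variances = c(0.03, 0.03, 0.03), v_e = 0.05, seed = 12))
  inner <- mean(vapply(seq(1, 15, 2), function(i) cor(x3[, i], x3[, i + 1]),
                       numeric(1)))
  expect_equal(inner, 9 / 14, tolerance = 0.01 / 0.64)
})

test_that("flat normal simulation is the one-level special case of the hierarchy", {
  a <- simulate_modules(c(4, 4), m = 200, v_c = 0.03, v_e = 0.05, seed = 99)
  b <- simulate_hierarchy(list(4, 4), m = 200, level_variances = 0.03,
                          v_e = 0.05, seed = 99)
  expect_equal(as.matrix(a), as.matrix(b), ignore_attr = TRUE)
})

test_that("generators are reproducible and validate their specs", {
  expect_identical(simulate_modules(c(3, 3), m = 50, seed = 5),
                   simulate_modules(c(3, 3), m = 50, seed = 5))
  expect_error(simulate_modules(c(0, 4)), "positive")
  expect_error(simulate_modules(c(4, 4), v_e = 0), "v_e")
  expect_error(simulate_hierarchy(list(list(2, 2)), level_variances = 0.03),
               "level")
  expect_error(simulate_hierarchy(list("x")), "structure|leaves")
})
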