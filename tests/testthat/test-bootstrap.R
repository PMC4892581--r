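test_that("bootstrap resampling is deterministic and preserves records", {
  x <- null_data(m = 12, n = 5, seed = 1)
  b1 <- bootstrap_resample(x, seed = 99)
  b2 <- bootstrap_resample(x, seed = 99)
  expect_identical(b1, b2)
  expect_equal(dim(b1), dim(x))
  # every resampled row is one of the original records, intact
  orig <- apply(as.matrix(x), 1, paste, collapse = "|")
  drawn <- apply(as.matrix(b1), 1, paste, collapse = "|")
  expect_true(all(drawn %in% orig))
})

test_that("resampling identical rows returns the same rows", {
  x <- tibble::as_tibble(matrix(rep(c(1, 2, 3, 4), each = 6), 6, 4,
                                dimnames = list(NULL, paste0("v", 1:4))))
  expect_equal(as.matrix(bootstrap_resample(x, seed = 5)), as.matrix(x),
               ignore_attr = TRUE)
})

test_that("row draw frequencies are uniform across 10,000 resamples of m = 5", {
  m <- 5L
  counts <- numeric(m)
  # child seeds exactly as a B = 10000 ensemble would derive them
  sb0 <- boclust:::fold_seed(1, 2)
  for (b in 1:10000) {
    idx <- boclust:::.boot_indices_cpp(m, boclust:::fold_seed(sb0, b))
    counts <- counts + tabulate(idx, m)
  }
  freq <- counts / (10000 * m)
  se <- sqrt(0.2 * 0.8 / (10000 * m))
  expect_true(all(abs(freq - 0.2) < 3 * se))
})

test_that("ensemble rows equal the composed resample-cluster-encode pipeline", {
  x <- null_data(m = 30, n = 6, seed = 7)
  seed <- 101
  ens <- ensemble_coincidences(x, p = 3, B = 10, seed = seed)
  for (b in c(1L, 4L, 10L)) {
    sb <- boclust:::fold_seed(boclust:::fold_seed(seed, 2), b)
    xb <- bootstrap_resample(x, sb)
    part <- cluster_variables(xb, 3, seed = sb)
    expect_equal(unname(ens$bits[b, ]), unname(coincidence_vector(part)))
  }
})

test_that("ensemble shape, determinism, and perfect-structure stability", {
  x <- null_data(m = 25, n = 5, seed = 9)
  ens <- ensemble_coincidences(x, p = 2, B = 2, seed = 3)
  expect_equal(dim(ens$bits), c(2L, pair_count(5)))
  e1 <- ensemble_coincidences(x, p = 3, B = 20, seed = 4)
  e2 <- ensemble_coincidences(x, p = 3, B = 20, seed = 4)
  expect_identical(e1$bits, e2$bits)
  # perfectly separated blocks: every bootstrap finds the same partition
  tb <- two_block_data(m = 40, block = 4, seed = 5)
  ens <- ensemble_coincidences(tb, p = 2, B = 50, seed = 6)
  expect_equal(nrow(unique(as.data.frame(ens$bits))), 1L)
  expect_equal(variance_sum(ens), 0)
})

test_that("medoid ensembles run and flag unrecoverable degenerate columns", {
  x <- null_data(m = 20, n = 5, seed = 11)
  ens <- ensemble_coincidences(x, p = 2, B = 5, method = "medoid", seed = 2)
  expect_equal(dim(ens$bits), c(5L, pair_count(5)))
  xz <- x
  xz$v2 <- 0  # constant in every resample: redraws cannot help
  expect_error(
    ensemble_coincidences(xz, p = 2, B = 3, method = "medoid", seed = 2),
    "constant|redraws")
})

test_that("variance_sum equals the brute-force per-position variance oracle", {
  expect_equal(variance_sum(matrix(c(1, 1, 0, 0), 4, 1)), 0.25)
  expect_equal(variance_sum(matrix(1L, 5, 10)), 0)
  set.seed(21)
  for (rep in 1:10) {
    bits <- matrix(rbinom(60, 1, runif(1)), 6, 10)
    expect_equal(variance_sum(bits), varsum_oracle(bits))
  }
})

test_that("raw scan has n-2 entries bounded by the Bernoulli maximum", {
  x <- null_data(m = 30, n = 4, seed = 13)
  scan <- stability_scan(x, B = 30, seed = 1)
  expect_equal(scan$p, 2:3)
  x8 <- null_data(m = 30, n = 8, seed = 14)
  scan8 <- stability_scan(x8, B = 50, seed = 2)
  expect_equal(nrow(scan8), 6L)
  expect_true(all(scan8$raw_sum >= 0))
  expect_true(all(scan8$raw_sum <= 0.25 * pair_count(8)))
  # perfect structure scores exactly zero at the true p
  tb <- two_block_data(m = 40, block = 4, seed = 15)
  scan_tb <- stability_scan(tb, B = 40, seed = 3)
  expect_equal(scan_tb$raw_sum[scan_tb$p == 2], 0)
})
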