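test_that("k-means recovers the partition minimizing within-cluster SS, verified exhaustively", {
  # 4 variables: columns 1,2 identical, columns 3,4 identical, blocks
  # independent -> {12}{34} is the unique WSS-optimal 2-cluster partition
  set.seed(42)
  a <- rnorm(30)
  b <- rnorm(30)
  x <- tibble::tibble(w = a, x = a, y = b, z = b)
  part <- cluster_variables(x, p = 2, seed = 3)
  xm <- as.matrix(x)
  two_cluster <- Filter(function(l) length(unique(l)) == 2, enum_partitions(4))
  expect_length(two_cluster, 7L)
  wss <- vapply(two_cluster, function(l) wss_oracle(xm, l), numeric(1))
  best <- two_cluster[[which.min(wss)]]
  expect_equal(coincidence_oracle(best), c(1L, 0L, 0L, 0L, 0L, 1L))
  expect_equal(unname(coincidence_vector(part)), coincidence_oracle(best))
})

test_that("compiled k-means matches stats::kmeans on separable data and in WSS", {
  x <- two_block_data(m = 60, block = 4, seed = 9)
  part <- cluster_variables(x, p = 2, seed = 1)
  ref <- stats::kmeans(t(as.matrix(x)), 2, nstart = 20)
  expect_equal(unname(coincidence_vector(part)),
               unname(coincidence_vector(ref$cluster)))
  # on unstructured data, given enough restarts the Lloyd machinery reaches
  # the same optimum as restarted Hartigan-Wong
  y <- null_data(m = 50, n = 6, seed = 4)
  for (p in 2:3) {
    ours <- boclust:::.kmeans_labels_cpp(as.matrix(y), p, 11, 100L, 200L)
    set.seed(1)
    theirs <- stats::kmeans(t(as.matrix(y)), p, nstart = 25, iter.max = 100)
    expect_equal(ours$wss, theirs$tot.withinss, tolerance = 1e-8)
  }
})

test_that("any valid p yields exactly p non-empty clusters", {
  x <- null_data(m = 30, n = 7, seed = 2)
  for (p in 2:6) {
    for (method in c("kmeans", "medoid")) {
      part <- cluster_variables(x, p, method = method, seed = 5)
      expect_equal(length(unique(part$cluster)), p)
      expect_equal(nrow(part), 7L)
    }
  }
})

test_that("p out of range and degenerate medoid columns error informatively", {
  x <- null_data(m = 20, n = 5, seed = 3)
  expect_error(cluster_variables(x, 1), "\\[2, n-1\\]|\\[2, 4\\]")
  expect_error(cluster_variables(x, 5), "\\[2, 4\\]")
  xz <- x
  xz$v3 <- 0
  expect_error(cluster_variables(xz, 2, method = "medoid"), "v3")
  # k-means tolerates constant columns
  expect_s3_class(cluster_variables(xz, 2, method = "kmeans"), "tbl_df")
})

test_that("medoid clustering co-clusters duplicated columns (distance 0)", {
  set.seed(8)
  base <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("v", 1:4)))
  x <- tibble::as_tibble(cbind(base, dup1 = base[, 1], dup2 = base[, 1]))
  for (p in 2:4) {
    part <- cluster_variables(x, p, method = "medoid")
    cl <- part$cluster[part$variable %in% c("v1", "dup1", "dup2")]
    expect_length(unique(cl), 1L)
  }
})

test_that("clustering is deterministic given the seed", {
  x <- null_data(m = 40, n = 8, seed = 6)
  p1 <- cluster_variables(x, 3, seed = 77)
  p2 <- cluster_variables(x, 3, seed = 77)
  expect_identical(p1, p2)
})

test_that("standardization flag changes the k-means feature space", {
  set.seed(10)
  x <- null_data(m = 50, n = 6, seed = 10)
  x$v1 <- x$v1 * 100  # dominant-scale variable
  raw <- cluster_variables(x, 2, seed = 1, standardize = FALSE)
  std <- cluster_variables(x, 2, seed = 1, standardize = TRUE)
  # with raw scaling v1 is isolated by magnitude alone
  expect_equal(sum(raw$cluster == raw$cluster[raw$variable == "v1"]), 1L)
  expect_s3_class(std, "variable_partition")
})
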