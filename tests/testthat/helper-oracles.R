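# Independent oracles and fixture builders used across the suite.

# all set partitions of n objects as label vectors (restricted growth
# strings), independent of any package code
enum_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_label) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(next_label)) {
      recurse(c(labels, lab), max(next_label, lab + 1L))
    }
  }
  recurse(integer(0), 1L)
  out
}

# brute-force double-loop coincidence encoding in the canonical pair order
coincidence_oracle <- function(labels) {
  n <- length(labels)
  bits <- integer(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      bits <- c(bits, as.integer(labels[i] == labels[j]))
    }
  }
  bits
}

# brute-force summed per-column population variance (mean squared deviation)
varsum_oracle <- function(bits) {
  total <- 0
  for (q in seq_len(ncol(bits))) {
    col <- bits[, q]
    total <- total + mean((col - mean(col))^2)
  }
  total
}

# within-cluster sum of squares of a partition of the columns of x
wss_oracle <- function(x, labels) {
  total <- 0
  for (k in unique(labels)) {
    block <- x[, labels == k, drop = FALSE]
    ctr <- rowMeans(block)
    total <- total + sum((block - ctr)^2)
  }
  total
}

# two blocks of duplicated columns: a dataset with perfect (correlation 1)
# within-block structure and independent blocks
two_block_data <- function(m = 40, block = 4, seed = 1) {
  set.seed(seed)
  a <- rnorm(m)
  b <- rnorm(m)
  x <- cbind(matrix(rep(a, block), m), matrix(rep(b, block), m))
  colnames(x) <- c(paste0("a", seq_len(block)), paste0("b", seq_len(block)))
  tibble::as_tibble(x)
}

# independent-column (no-structure) data
null_data <- function(m = 100, n = 8, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(m * n), m, n)
  colnames(x) <- paste0("v", seq_len(n))
  tibble::as_tibble(x)
}

# block membership of a partition as a canonical string, for comparing
# partitions up to relabeling
partition_signature <- function(partition) {
  labs <- partition$cluster
  groups <- split(partition$variable, labs)
  groups <- lapply(groups, sort)
  paste(sort(vapply(groups, paste, character(1), collapse = ",")),
        collapse = " | ")
}
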