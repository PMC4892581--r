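#' Cluster the variables of a data matrix into p groups
#'
#' Partitions the n variables (columns) of `data` into exactly `p` non-empty
#' clusters. With `method = "kmeans"` each variable is represented by its
#' m record values and clustered by multi-restart Lloyd k-means (10 seeded
#' restarts, 100 iterations each, best within-cluster sum of squares kept;
#' restarts that leave a cluster empty are repaired by moving in the point
#' farthest from its centre, and up to 100 extra restarts are spent if no
#' restart yields p non-empty clusters). With `method = "medoid"` the
#' variables are clustered by partitioning around medoids
#' ([cluster::pam()]) on the dissimilarity 1 - |Pearson correlation|.
#'
#' @param data data frame or numeric matrix, records x variables
#' @param p number of clusters, 2 <= p <= n - 1
#' @param method `"kmeans"` (record-profile k-means) or `"medoid"`
#'   (PAM on 1 - |r|)
#' @param seed integer seed; the result is deterministic given
#'   `(data, p, method, seed)`
#' @param standardize z-score each variable before k-means clustering
#'   (ignored for `"medoid"`, where correlation is scale-free)
#' @return a tibble with columns `variable` and `cluster` (integer labels
#'   1..p), of class `"variable_partition"`
#' @examples
#' x <- simulate_modules(c(4, 4), m = 50, seed = 1)
#' cluster_variables(x, p = 2)
#' @export
cluster_variables <- function(data, p, method = c("kmeans", "medoid"),
                              seed = 1L, standardize = FALSE) {
  method <- match.arg(method)
  x <- as_variable_matrix(data)
  n <- ncol(x)
  check_p(p, n)
  labels <- fit_partition(x, p, method, seed, standardize)
  new_variable_partition(colnames(x), labels, p)
}

check_p <- function(p, n) {
  if (!is.numeric(p) || length(p) != 1L || p != round(p) || p < 2 || p > n - 1) {
    stop("`p` must be an integer in [2, n-1] = [2, ", n - 1, "], got ", p,
         call. = FALSE)
  }
}

# shared by cluster_variables() and the medoid ensemble loop
fit_partition <- function(x, p, method, seed, standardize = FALSE) {
  if (method == "kmeans") {
    if (standardize) x <- scale(x)
    fit <- .kmeans_labels_cpp(x, as.integer(p), as.double(seed %% 2147483647),
                              10L, 100L)
    fit$labels
  } else {
    sds <- apply(x, 2L, sd)
    if (any(sds == 0)) {
      stop("zero-variance column(s), correlation undefined: ",
           paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
    }
    d <- stats::as.dist(1 - abs(cor(x)))
    cluster::pam(d, k = p, diss = TRUE, cluster.only = TRUE)
  }
}

new_variable_partition <- function(variable_names, labels, p) {
  out <- tibble::tibble(variable = variable_names,
                        cluster = as.integer(labels))
  class(out) <- c("variable_partition", class(out))
  attr(out, "p") <- as.integer(p)
  out
}

# accept a variable_partition tibble or a bare label vector
partition_labels <- function(partition) {
  if (is.data.frame(partition)) {
    if (!all(c("variable", "cluster") %in% names(partition))) {
      stop("partition data frame needs `variable` and `cluster` columns",
           call. = FALSE)
    }
    labs <- partition$cluster
    names(labs) <- partition$variable
    labs
  } else if (is.atomic(partition)) {
    partition
  } else {
    stop("`partition` must be a variable_partition or a label vector",
         call. = FALSE)
  }
}

#' Pairwise co-clustering indicators of a partition
#'
#' Encodes a partition of n variables as the (n^2 - n)/2 binary indicators of
#' whether each unordered pair of variables shares a cluster — the
#' non-redundant upper triangle of the coincidence matrix, in the canonical
#' pair order (i, j), i < j, lexicographic. The encoding is invariant under
#' any relabeling of the cluster ids.
#'
#' @param partition a `variable_partition` (from [cluster_variables()]) or a
#'   label vector (integer, character or factor), one label per variable
#' @return named integer vector of 0/1 indicators, one per variable pair
#' @examples
#' coincidence_vector(c(a = 1, b = 1, c = 2, d = 2))
#' @export
coincidence_vector <- function(partition) {
  labs <- partition_labels(partition)
  n <- length(labs)
  if (n < 2L) stop("need at least 2 variables", call. = FALSE)
  if (anyNA(labs)) stop("labels must not contain NA", call. = FALSE)
  eq <- outer(labs, labs, "==")
  bits <- as.integer(t(eq)[lower.tri(eq)])
  vn <- names(labs)
  if (is.null(vn)) vn <- paste0("V", seq_len(n))
  names(bits) <- pair_names(vn)
  bits
}

#' Bootstrap-resample the records of a data matrix
#'
#' Draws m rows with replacement from the m rows of `data` (rows are
#' resampled jointly, so within-record variable values stay together),
#' returning a full-size resampled dataset. Deterministic given `seed`, and
#' consistent with the resampling used inside [ensemble_coincidences()]:
#' bootstrap b of an ensemble with seed s uses the child seed obtained by
#' folding (s, stream 2, b).
#'
#' @inheritParams cluster_variables
#' @param seed integer seed
#' @return a tibble with the same columns as `data` and m rows
#' @export
bootstrap_resample <- function(data, seed = 1L) {
  x <- as_variable_matrix(data, min_n = 2L)
  idx <- .boot_indices_cpp(nrow(x), as.double(seed %% 2147483647))
  tibble::as_tibble(x[idx, , drop = FALSE])
}

#' Coincidence vectors across a bootstrap ensemble
#'
#' Runs B bootstrap resamples of the records; on each resample the variables
#' are clustered into p groups and the pairwise coincidence vector recorded.
#' Row b equals
#' `coincidence_vector(cluster_variables(bootstrap_resample(data, s_b), p,
#' method, s_b))` for child seeds s_b derived deterministically from `seed`.
#' For `method = "medoid"`, a resample that makes some column constant
#' (undefined correlation) is redrawn with a fresh child seed, up to 100
#' times, before erroring.
#'
#' @inheritParams cluster_variables
#' @param B number of bootstrap resamples (at least 2)
#' @return an object of class `"coincidence_ensemble"`: a list with `bits`
#'   (B x pair_count(n) binary matrix), `frequency` (per-pair co-clustering
#'   frequency across the B resamples), and the call parameters
#' @export
ensemble_coincidences <- function(data, p, B, method = c("kmeans", "medoid"),
                                  seed = 1L, standardize = FALSE) {
  method <- match.arg(method)
  x <- as_variable_matrix(data)
  n <- ncol(x)
  check_p(p, n)
  if (!is.numeric(B) || length(B) != 1L || B < 2) {
    stop("`B` must be an integer >= 2", call. = FALSE)
  }
  B <- as.integer(B)
  if (method == "kmeans") {
    xx <- if (standardize) scale(x) else x
    res <- .ensemble_cpp(xx, as.integer(p), B, as.double(seed %% 2147483647),
                         10L, 100L, TRUE)
    bits <- res$bits
    freq <- res$frequency
  } else {
    bits <- matrix(0L, B, pair_count(n))
    sb0 <- fold_seed(seed, 2)
    for (b in seq_len(B)) {
      sb <- fold_seed(sb0, b)
      xb <- resample_nondegenerate(x, sb)
      labs <- fit_partition(xb, p, "medoid", sb)
      bits[b, ] <- coincidence_vector(labs)
    }
    freq <- colMeans(bits)
  }
  colnames(bits) <- pair_names(colnames(x))
  names(freq) <- colnames(bits)
  structure(list(bits = bits, frequency = freq, p = as.integer(p), B = B,
                 method = method, seed = seed,
                 variable_names = colnames(x)),
            class = "coincidence_ensemble")
}

# medoid-mode resample: redraw (fresh child seeds) while any column is
# constant, up to 100 retries
resample_nondegenerate <- function(x, seed, max_retry = 100L) {
  m <- nrow(x)
  idx <- .boot_indices_cpp(m, as.double(seed))
  for (attempt in seq_len(max_retry + 1L)) {
    xb <- x[idx, , drop = FALSE]
    rng <- matrixStats_colrange(xb)
    if (all(rng > 0)) return(xb)
    if (attempt > max_retry) {
      stop("bootstrap resample has constant column(s) after ", max_retry,
           " redraws: ", paste(colnames(x)[rng == 0], collapse = ", "),
           call. = FALSE)
    }
    idx <- .boot_indices_cpp(m, as.double(fold_seed(seed, 1000 + attempt)))
  }
}

matrixStats_colrange <- function(x) {
  apply(x, 2L, function(col) max(col) - min(col))
}

#' @export
print.coincidence_ensemble <- function(x, ...) {
  cat("<coincidence_ensemble> p =", x$p, ", B =", x$B,
      ", method =", x$method, "\n")
  cat("  ", length(x$frequency), "variable pairs; variance sum =",
      format(variance_sum(x)), "\n")
  invisible(x)
}

#' Summed across-bootstrap variance of the coincidence indicators
#'
#' For each variable pair, the variance of its B binary co-clustering
#' indicators across the bootstrap resamples is computed with the population
#' denominator B (for a 0/1 variable with mean f this is f(1 - f)); the
#' variances are then summed over all pairs. Low values mean the partition
#' is stable under resampling; the maximum possible value is
#' 0.25 * pair_count(n).
#'
#' @param ensemble a `"coincidence_ensemble"` (from
#'   [ensemble_coincidences()]) or a binary matrix with one row per
#'   bootstrap and one column per pair
#' @return a non-negative number
#' @export
variance_sum <- function(ensemble) {
  bits <- if (inherits(ensemble, "coincidence_ensemble")) ensemble$bits
          else ensemble
  if (!is.matrix(bits) || nrow(bits) < 2L) {
    stop("need a matrix of at least 2 bootstrap rows", call. = FALSE)
  }
  f <- colMeans(bits)
  sum(f * (1 - f))
}

#' Raw stability profile over all candidate cluster counts
#'
#' Computes the raw (un-normalized) summed coincidence variance for every
#' candidate cluster count p = 2..n-1. One series of B bootstrap resamples
#' is drawn and each resample is clustered at every p, so the raw sums are
#' paired across cluster counts: resampling noise common to all p cancels
#' when the profile is compared across p.
#'
#' @inheritParams ensemble_coincidences
#' @return a tibble with columns `p` and `raw_sum` (n - 2 rows)
#' @export
stability_scan <- function(data, B = 500L, method = c("kmeans", "medoid"),
                           seed = 1L, standardize = FALSE) {
  method <- match.arg(method)
  scan_raw(data, B, method, seed, standardize)$profile
}

# internal scan that also keeps per-p pair frequencies (for diagnostics);
# the single ensemble seed makes the B resamples identical across p
scan_raw <- function(data, B, method, seed, standardize = FALSE) {
  x <- as_variable_matrix(data)
  n <- ncol(x)
  ps <- 2:(n - 1L)
  raw <- numeric(length(ps))
  freqs <- vector("list", length(ps))
  es <- fold_seed(seed, 1)
  for (k in seq_along(ps)) {
    if (method == "kmeans") {
      xx <- if (standardize) scale(x) else x
      res <- .ensemble_cpp(xx, ps[k], as.integer(B), as.double(es),
                           10L, 100L, FALSE)
      raw[k] <- res$variance_sum
      freqs[[k]] <- res$frequency
    } else {
      ens <- ensemble_coincidences(x, ps[k], B, method, es, standardize)
      raw[k] <- variance_sum(ens)
      freqs[[k]] <- ens$frequency
    }
  }
  px <- pair_index(n)
  vn <- colnames(x)
  freq_tbl <- tibble::tibble(
    p = rep(ps, each = nrow(px)),
    var1 = rep(vn[px[, 1]], length(ps)),
    var2 = rep(vn[px[, 2]], length(ps)),
    frequency = unlist(freqs, use.names = FALSE)
  )
  list(profile = tibble::tibble(p = ps, raw_sum = raw),
       pair_frequencies = freq_tbl)
}
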