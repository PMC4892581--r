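#' Destroy between-variable correlation by within-column permutation
#'
#' Independently permutes each variable's values across the records, so each
#' univariate (marginal) distribution is preserved exactly while every
#' between-variable correlation is destroyed. This is the null
#' randomization the stability criterion is calibrated against.
#'
#' @inheritParams cluster_variables
#' @param seed integer seed; permutations are deterministic given the seed
#'   and independent across columns
#' @return a tibble with the same columns as `data`
#' @export
randomize_columns <- function(data, seed = 1L) {
  x <- as_variable_matrix(data, min_n = 2L)
  m <- nrow(x)
  set.seed(as_r_seed(seed))
  for (j in seq_len(ncol(x))) {
    x[, j] <- x[sample.int(m), j]
  }
  tibble::as_tibble(x)
}

#' Null distribution of the raw stability score at one cluster count
#'
#' Repeats the full bootstrap-stability computation on R independently
#' column-randomized copies of the data, giving the distribution of the raw
#' summed coincidence variance at cluster count p when no module structure
#' exists. Its mean normalizes the observed score; its lower 2.5 percentile
#' is the significance threshold.
#'
#' The percentile uses linear interpolation between order statistics with
#' plotting positions h = (R + 1) * prob ([stats::quantile()] type 6), so
#' that under exchangeability a new null draw falls below the interpolated
#' 2.5-percentile with probability 2.5% — the test is calibrated at its
#' nominal level even at moderate R.
#'
#' @inheritParams ensemble_coincidences
#' @param R number of randomized null datasets (at least 2)
#' @return an object of class `"null_distribution"`: list with `p`,
#'   `raw_sums` (length R), `mean`, `lower_2_5`, `B`, `R`
#' @export
null_distribution <- function(data, p, B, R, method = c("kmeans", "medoid"),
                              seed = 1L, standardize = FALSE) {
  method <- match.arg(method)
  x <- as_variable_matrix(data)
  check_p(p, ncol(x))
  if (!is.numeric(R) || length(R) != 1L || R < 2) {
    stop("`R` must be an integer >= 2", call. = FALSE)
  }
  R <- as.integer(R)
  raw <- numeric(R)
  for (r in seq_len(R)) {
    sr <- fold_seed(fold_seed(seed, 4), r)
    xr <- randomize_columns(x, sr)
    ens_seed <- fold_seed(sr, 5)
    if (method == "kmeans") {
      xx <- as_variable_matrix(xr)
      if (standardize) xx <- scale(xx)
      raw[r] <- .ensemble_cpp(xx, as.integer(p), as.integer(B),
                              as.double(ens_seed), 10L, 100L,
                              FALSE)$variance_sum
    } else {
      raw[r] <- variance_sum(
        ensemble_coincidences(xr, p, B, method, ens_seed, standardize))
    }
  }
  new_null_distribution(p, raw, B)
}

new_null_distribution <- function(p, raw_sums, B) {
  structure(list(p = as.integer(p), raw_sums = raw_sums,
                 mean = mean(raw_sums),
                 lower_2_5 = quantile(raw_sums, 0.025, type = 6,
                                      names = FALSE),
                 B = as.integer(B), R = length(raw_sums)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> p =", x$p, ", R =", x$R, ", B =", x$B, "\n")
  cat("  mean =", format(x$mean), "; lower 2.5% =", format(x$lower_2_5), "\n")
  invisible(x)
}

#' Normalize a raw stability score by its null expectation
#'
#' The raw summed coincidence variance depends on the cluster count p even
#' without any module structure; dividing by the mean of the null
#' distribution at the same p makes scores comparable across p. The result
#' is the variance criterion: values well below 1 indicate partitions more
#' stable than chance.
#'
#' @param raw_sum observed raw summed variance (from [variance_sum()])
#' @param null a `"null_distribution"` at the same p
#' @return the normalized criterion, `raw_sum / mean(null raw sums)`
#' @export
normalize_criterion <- function(raw_sum, null) {
  stopifnot(inherits(null, "null_distribution"))
  if (null$mean == 0) {
    stop("degenerate null: all null runs perfectly stable (mean raw sum 0)",
         call. = FALSE)
  }
  raw_sum / null$mean
}

#' Test a stability score against the permutation null
#'
#' Flags a cluster count as significantly more stable than chance when its
#' observed raw summed variance falls strictly below the lower 2.5
#' percentile of the null distribution (equivalently, when the normalized
#' criterion falls below the identically-normalized percentile line).
#'
#' @inheritParams normalize_criterion
#' @return `TRUE` if `raw_sum` is below the null's lower 2.5 percentile
#' @export
significance_test <- function(raw_sum, null) {
  stopifnot(inherits(null, "null_distribution"))
  raw_sum < null$lower_2_5
}

#' Local minima of a criterion profile
#'
#' Returns every cluster count whose normalized criterion is strictly lower
#' than both neighbors (endpoints are compared to their single neighbor).
#' Multiple local minima hint at hierarchical module structure — modules
#' composed of sub-modules — but are reported as hints only: the procedure
#' has no formal test for hierarchy.
#'
#' @param profile a `module_stability` fit, a data frame with columns `p`
#'   and `criterion`, or a bare numeric vector of criterion values (then
#'   taken to correspond to p = 2, 3, ...)
#' @return integer vector of cluster counts at local minima
#' @examples
#' find_local_minima(c(0.3, 0.8, 0.2, 0.9, 1.0))  # p = 2 and 4
#' @export
find_local_minima <- function(profile) {
  if (inherits(profile, "module_stability")) profile <- profile$profile
  if (is.data.frame(profile)) {
    stopifnot(all(c("p", "criterion") %in% names(profile)))
    v <- profile$criterion[order(profile$p)]
    ps <- sort(profile$p)
  } else {
    v <- as.numeric(profile)
    ps <- seq_along(v) + 1L
  }
  k <- length(v)
  if (k == 1L) return(as.integer(ps))
  left_ok <- c(TRUE, v[-1] < v[-k])
  right_ok <- c(v[-k] < v[-1], TRUE)
  as.integer(ps[left_ok & right_ok])
}

#' Best partition according to the variance criterion
#'
#' Picks the cluster count with the lowest normalized criterion (ties broken
#' toward the smaller p, the more parsimonious solution) and reports the
#' partition obtained by clustering the original, un-resampled data at that
#' cluster count.
#'
#' @param profile a `module_stability` fit or a data frame with columns `p`
#'   and `criterion`
#' @inheritParams cluster_variables
#' @return a list with `selected_p` and `partition` (a `variable_partition`)
#' @export
select_best_partition <- function(profile, data,
                                  method = c("kmeans", "medoid"), seed = 1L,
                                  standardize = FALSE) {
  method <- match.arg(method)
  if (inherits(profile, "module_stability")) profile <- profile$profile
  stopifnot(all(c("p", "criterion") %in% names(profile)))
  ord <- order(profile$p)
  ps <- profile$p[ord]
  crit <- profile$criterion[ord]
  selected_p <- as.integer(ps[which.min(crit)])
  partition <- cluster_variables(data, selected_p, method,
                                 fold_seed(seed, 6), standardize)
  list(selected_p = selected_p, partition = partition)
}
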