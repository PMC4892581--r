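#' Bootstrap-stability module detection
#'
#' The main entry point. For every candidate cluster count p = 2..n-1 it
#' (1) clusters the variables on B bootstrap resamples of the records and
#' sums the across-resample variance of the pairwise co-clustering
#' indicators; (2) repeats the same computation on R column-randomized
#' (correlation-free) copies of the data to obtain a null distribution at
#' the same p; (3) normalizes the observed score by the null mean (the
#' variance criterion) and flags it significant when it falls below the
#' null's lower 2.5 percentile. The cluster count with the lowest criterion
#' is selected and the original data are clustered at that count to give the
#' reported module membership. Local minima of the criterion profile are
#' reported as hints of hierarchical (nested) module structure.
#'
#' @inheritParams ensemble_coincidences
#' @param B bootstrap resamples per dataset (default 500)
#' @param R randomized null datasets per cluster count (default 100)
#' @param verbose print per-p progress to standard error
#' @return an object of class `"module_stability"`, a list with
#'   \describe{
#'     \item{profile}{tibble: `p`, `raw_sum`, `null_mean`, `null_lower_2_5`,
#'       `criterion`, `significant`}
#'     \item{selected_p}{cluster count minimizing the criterion}
#'     \item{partition}{`variable_partition` of the original data at
#'       `selected_p`}
#'     \item{local_minima}{cluster counts at local criterion minima}
#'     \item{pair_frequencies}{tibble of per-pair bootstrap co-clustering
#'       frequencies at every p (diagnostic)}
#'     \item{params}{call parameters, including the seed}
#'   }
#'   with [tidy()], [glance()], [autoplot()] and `print()` methods.
#' @examples
#' x <- simulate_modules(c(4, 4), m = 100, v_c = 0.030, v_e = 0.050, seed = 7)
#' fit <- module_stability(x, B = 50, R = 10, seed = 7)
#' fit$selected_p
#' tidy(fit)
#' @export
module_stability <- function(data, B = 500L, R = 100L,
                             method = c("kmeans", "medoid"), seed = 1L,
                             standardize = FALSE, verbose = FALSE) {
  method <- match.arg(method)
  x <- as_variable_matrix(data)
  n <- ncol(x)
  scan <- scan_raw(x, B, method, seed, standardize)
  profile <- scan$profile
  # the whole scan is repeated on each of R randomized datasets, so the
  # null raw sums are paired across p exactly like the observed ones
  null_raw <- matrix(0, R, nrow(profile))
  for (r in seq_len(R)) {
    if (verbose) message("null dataset ", r, " of ", R)
    sr <- fold_seed(fold_seed(seed, 4), r)
    xr <- as_variable_matrix(randomize_columns(x, sr))
    null_raw[r, ] <- scan_raw(xr, B, method, fold_seed(sr, 5),
                              standardize)$profile$raw_sum
  }
  null_mean <- colMeans(null_raw)
  null_lower <- apply(null_raw, 2L, quantile, probs = 0.025, type = 6,
                      names = FALSE)
  if (any(null_mean == 0)) {
    stop("degenerate null at p = ",
         paste(profile$p[null_mean == 0], collapse = ", "),
         ": all null runs perfectly stable", call. = FALSE)
  }
  profile$null_mean <- null_mean
  profile$null_lower_2_5 <- null_lower
  profile$criterion <- profile$raw_sum / null_mean
  profile$significant <- profile$raw_sum < null_lower
  sel <- select_best_partition(profile, x, method, seed, standardize)
  structure(list(
    profile = profile,
    selected_p = sel$selected_p,
    partition = sel$partition,
    local_minima = find_local_minima(profile),
    pair_frequencies = scan$pair_frequencies,
    params = list(B = as.integer(B), R = as.integer(R), method = method,
                  seed = seed, standardize = standardize,
                  n = n, m = nrow(x), variable_names = colnames(x))
  ), class = "module_stability")
}

#' @export
print.module_stability <- function(x, ...) {
  cat("Bootstrap-stability module detection (", x$params$method,
      ", B = ", x$params$B, ", R = ", x$params$R, ")\n", sep = "")
  cat(x$params$n, "variables,", x$params$m, "records\n\n")
  print(as.data.frame(x$profile), row.names = FALSE, digits = 4)
  cat("\nselected p =", x$selected_p,
      if (x$profile$significant[x$profile$p == x$selected_p])
        "(significant at the lower 2.5 percentile)" else "(not significant)",
      "\n")
  cat("local minima at p =", paste(x$local_minima, collapse = ", "), "\n")
  memb <- split(x$partition$variable, x$partition$cluster)
  for (k in names(memb)) {
    cat("  module ", k, ": ", paste(memb[[k]], collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Tidy the per-cluster-count stability profile
#'
#' @param x a `module_stability` fit
#' @param ... unused
#' @return the profile tibble: one row per candidate cluster count with the
#'   raw score, null summaries, normalized criterion and significance flag
#' @export
tidy.module_stability <- function(x, ...) x$profile

#' One-row summary of a stability fit
#'
#' @inheritParams tidy.module_stability
#' @return a one-row tibble: selected p, its criterion and significance,
#'   number of significant cluster counts, local-minima count, and the
#'   run parameters
#' @export
glance.module_stability <- function(x, ...) {
  sel <- x$profile[x$profile$p == x$selected_p, ]
  tibble::tibble(
    selected_p = x$selected_p,
    criterion = sel$criterion,
    significant = sel$significant,
    n_significant = sum(x$profile$significant),
    n_local_minima = length(x$local_minima),
    n = x$params$n, m = x$params$m,
    B = x$params$B, R = x$params$R,
    method = x$params$method, seed = x$params$seed
  )
}

#' Plot the variance-criterion profile
#'
#' Normalized criterion against candidate cluster count, with the
#' identically-normalized lower 2.5 percentile of the permutation null as a
#' line; the selected cluster count is filled. Points below the line are
#' more stable than expected under no correlation between variables.
#'
#' @param object a `module_stability` fit
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.module_stability <- function(object, ...) {
  prof <- object$profile
  prof$selected <- prof$p == object$selected_p
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_lower_2_5 / .data$null_mean,
                                    linetype = "null lower 2.5%")) +
    ggplot2::geom_point(ggplot2::aes(y = .data$criterion,
                                     fill = .data$selected),
                        shape = 21, size = 3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey50",
                                          `FALSE` = "white"),
                               guide = "none") +
    ggplot2::scale_linetype_manual(values = c("null lower 2.5%" = "solid"),
                                   name = NULL) +
    ggplot2::scale_x_continuous(breaks = prof$p) +
    ggplot2::labs(x = "number of clusters p",
                  y = "variance criterion (normalized)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
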