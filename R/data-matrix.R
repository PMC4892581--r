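#' Validate a records-by-variables data frame
#'
#' All analysis functions accept a data frame (or matrix) whose rows are
#' records (individuals, samples) and whose columns are named numeric
#' variables. This internal validator enforces the contract: at least 2
#' records, at least `min_n` variables (the cluster-count scan over
#' p = 2..n-1 needs n >= 4), unique variable names, and finite numeric
#' entries throughout.
#'
#' @return a numeric matrix with column names
#' @noRd
as_variable_matrix <- function(data, min_n = 4L) {
  if (is.data.frame(data)) {
    bad <- !vapply(data, is.numeric, logical(1))
    if (any(bad)) {
      stop("non-numeric variable column(s): ",
           paste(names(data)[bad], collapse = ", "), call. = FALSE)
    }
    x <- as.matrix(data)
  } else if (is.matrix(data) && is.numeric(data)) {
    x <- data
    if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  } else {
    stop("`data` must be a data frame or numeric matrix (records x variables)",
         call. = FALSE)
  }
  if (nrow(x) < 2L) stop("need at least 2 records (rows)", call. = FALSE)
  if (ncol(x) < min_n) {
    stop("need at least ", min_n, " variables (columns), got ", ncol(x),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate variable names: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)
    bad <- head(bad, 5L)
    stop("missing or non-finite entries, e.g. ",
         paste(sprintf("[row %d, %s]", bad[, 1], colnames(x)[bad[, 2]]),
               collapse = ", "), call. = FALSE)
  }
  x
}

#' Number of unordered variable pairs
#'
#' The coincidence vector of an n-variable partition has one entry per
#' unordered pair, i.e. (n^2 - n) / 2 entries — also the number of pairwise
#' correlations among n variables.
#'
#' @param n number of variables (integer, at least 2)
#' @return integer pair count
#' @examples
#' pair_count(8)    # 28
#' pair_count(104)  # 5356
#' @export
pair_count <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 2) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  as.integer((n^2 - n) / 2)
}

# canonical pair order: (i, j), i < j, lexicographic, matching the compiled
# ensemble loop. Returns a 2-column integer matrix of 1-based indices.
pair_index <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i = i, j = j)
}

pair_names <- function(variable_names) {
  px <- pair_index(length(variable_names))
  paste(variable_names[px[, 1]], variable_names[px[, 2]], sep = ":")
}
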