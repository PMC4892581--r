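#' Read a delimited records-by-variables matrix
#'
#' Expects delimited text with a header row of variable names and one record
#' per subsequent row, all body cells numeric. Validation is strict: ragged
#' rows, duplicate variable names, fewer than 4 variables, and any blank or
#' non-numeric cell are hard errors that name the offending cells.
#'
#' @param path file path
#' @param delim field delimiter (default `","`; use `"\t"` for TSV)
#' @return a tibble of numeric variables
#' @export
read_variable_matrix <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) {
    stop("need a header row and at least 2 record rows", call. = FALSE)
  }
  cells <- strsplit(lines, delim, fixed = TRUE)
  header <- trimws(cells[[1]])
  n <- length(header)
  if (anyDuplicated(header)) {
    stop("duplicate variable names: ",
         paste(unique(header[duplicated(header)]), collapse = ", "),
         call. = FALSE)
  }
  if (n < 4L) stop("need at least 4 variables, got ", n, call. = FALSE)
  widths <- lengths(cells[-1])
  if (any(widths != n)) {
    bad <- which(widths != n)[1]
    stop("ragged row ", bad, ": ", widths[bad], " fields, expected ", n,
         call. = FALSE)
  }
  body <- matrix(trimws(unlist(cells[-1], use.names = FALSE)),
                 ncol = n, byrow = TRUE)
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) | body == "", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    bad <- head(bad, 5L)
    stop("non-numeric or blank cell(s): ",
         paste(sprintf("[record %d, %s] = \"%s\"", bad[, 1],
                       header[bad[, 2]], body[bad]), collapse = ", "),
         call. = FALSE)
  }
  colnames(num) <- header
  tibble::as_tibble(num)
}

#' Write a records-by-variables matrix as delimited text
#'
#' Full double precision (17 significant digits, always a `.` decimal
#' point), so a write/read round trip reproduces the numbers exactly.
#'
#' @param data data frame or numeric matrix
#' @param path output file path
#' @param delim field delimiter
#' @return `path`, invisibly
#' @export
write_variable_matrix <- function(data, path, delim = ",") {
  x <- as_variable_matrix(data, min_n = 2L)
  body <- apply(x, c(1, 2), function(v) sprintf("%.17g", v))
  lines <- c(paste(colnames(x), collapse = delim),
             apply(body, 1L, paste, collapse = delim))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full analysis and write its artifacts to disk
#'
#' Fits [module_stability()] on a data frame or a delimited input file and
#' writes to `output_dir`: `profile.tsv` (per-p raw score, null mean, null
#' lower 2.5 percentile, normalized criterion, significance flag),
#' `summary.json` (selected p, module membership by variable name, local
#' minima, all parameters including the seed), `pair_frequencies.tsv`
#' (per-pair bootstrap co-clustering frequency at every p), and optionally
#' `profile.png` (the criterion profile plot). Numeric output uses full
#' precision and locale-independent formatting; repeat runs with the same
#' configuration are byte-identical.
#'
#' @param input a data frame or a path to a delimited matrix
#' @param output_dir directory for outputs (created if absent)
#' @inheritParams module_stability
#' @param plot also write `profile.png`
#' @param delim input delimiter when `input` is a path
#' @return the `module_stability` fit, invisibly
#' @export
run_analysis <- function(input, output_dir, B = 500L, R = 100L,
                         method = c("kmeans", "medoid"), seed = 1L,
                         standardize = FALSE, plot = FALSE, delim = ",",
                         verbose = FALSE) {
  method <- match.arg(method)
  data <- if (is.character(input)) read_variable_matrix(input, delim)
          else input
  fit <- module_stability(data, B = B, R = R, method = method, seed = seed,
                          standardize = standardize, verbose = verbose)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_profile_tsv(fit$profile, file.path(output_dir, "profile.tsv"))
  write_pair_freq_tsv(fit$pair_frequencies,
                      file.path(output_dir, "pair_frequencies.tsv"))
  memb <- split(fit$partition$variable, fit$partition$cluster)
  names(memb) <- paste0("module_", names(memb))
  summary <- list(
    selected_p = fit$selected_p,
    significant = fit$profile$significant[fit$profile$p == fit$selected_p],
    modules = memb,
    local_minima = fit$local_minima,
    parameters = fit$params[c("B", "R", "method", "seed", "standardize",
                              "n", "m")]
  )
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (plot) {
    ggplot2::ggsave(file.path(output_dir, "profile.png"), autoplot(fit),
                    width = 6, height = 4, dpi = 150)
  }
  invisible(fit)
}

# full-precision, locale-independent TSV writers
fmt_num <- function(v) sprintf("%.17g", v)

write_profile_tsv <- function(profile, path) {
  lines <- c(
    paste(c("p", "raw_sum", "null_mean", "null_lower_2_5", "criterion",
            "significant"), collapse = "\t"),
    vapply(seq_len(nrow(profile)), function(i) {
      paste(c(profile$p[i], fmt_num(profile$raw_sum[i]),
              fmt_num(profile$null_mean[i]),
              fmt_num(profile$null_lower_2_5[i]),
              fmt_num(profile$criterion[i]),
              if (profile$significant[i]) "TRUE" else "FALSE"),
            collapse = "\t")
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

write_pair_freq_tsv <- function(freq, path) {
  lines <- c(
    "var1\tvar2\tp\tfrequency",
    sprintf("%s\t%s\t%d\t%s", freq$var1, freq$var2, freq$p,
            fmt_num(freq$frequency)))
  writeLines(lines, path)
  invisible(path)
}
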