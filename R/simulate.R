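#' Simulate variables with a flat module structure
#'
#' Generates m records of n variables grouped into modules under the
#' additive model x = c + e: the component c is drawn once per record per
#' module and shared by all of that module's variables, e is drawn
#' independently per record per variable. Two variables in the same module
#' then have correlation v_c / (v_c + v_e); variables in different modules
#' are uncorrelated.
#'
#' Component distributions:
#' \describe{
#'   \item{normal}{c ~ N(0, v_c), e ~ N(0, v_e); any non-negative `v_c` and
#'     positive `v_e`.}
#'   \item{beta}{c ~ Beta(0.246, 2), e ~ Beta(0.625, 2) — markedly
#'     asymmetric components whose variances are 0.030 and 0.050; only that
#'     variance pair is available.}
#'   \item{uniform}{c ~ U(0, 0.600), e ~ U(0, 0.775), again with variances
#'     0.030 and 0.050; only that variance pair is available.}
#' }
#'
#' @param module_sizes integer vector of module sizes; one module per entry,
#'   n = sum of sizes
#' @param m number of records (rows)
#' @param v_c variance of the shared (module) component
#' @param v_e variance of the variable-specific component
#' @param distribution component distribution family
#' @param seed integer seed; identical spec + seed give identical data
#' @return a tibble, m rows by n named variables (`m1_v1`, `m1_v2`, ...,
#'   prefix = module)
#' @examples
#' x <- simulate_modules(c(4, 4), m = 100, v_c = 0.030, v_e = 0.050, seed = 1)
#' implied_correlation(0.030, c(0.030, 0.050))  # expected within-module r
#' @export
simulate_modules <- function(module_sizes, m = 100L, v_c = 0.030,
                             v_e = 0.050,
                             distribution = c("normal", "beta", "uniform"),
                             seed = 1L) {
  distribution <- match.arg(distribution)
  check_sizes(module_sizes)
  if (!is.numeric(v_c) || v_c < 0) stop("`v_c` must be >= 0", call. = FALSE)
  if (!is.numeric(v_e) || v_e <= 0) stop("`v_e` must be > 0", call. = FALSE)
  if (!is.numeric(m) || m < 2) stop("`m` must be >= 2", call. = FALSE)
  m <- as.integer(m)
  if (distribution == "normal") {
    return(simulate_hierarchy(as.list(as.integer(module_sizes)), m = m,
                              level_variances = v_c, v_e = v_e, seed = seed,
                              .names = flat_names(module_sizes)))
  }
  # beta / uniform parameterizations encode v(c) = 0.030, v(e) = 0.050;
  # other variances are not representable without changing the shapes
  if (abs(v_c - 0.030) > 1e-12 || abs(v_e - 0.050) > 1e-12) {
    stop("`distribution = \"", distribution,
         "\"` is parameterized for v_c = 0.030, v_e = 0.050 only",
         call. = FALSE)
  }
  draw_c <- switch(distribution,
    beta = function() rbeta(m, 0.246, 2),
    uniform = function() runif(m, 0, 0.600))
  draw_e <- switch(distribution,
    beta = function() rbeta(m, 0.625, 2),
    uniform = function() runif(m, 0, 0.775))
  set.seed(as_r_seed(seed))
  cols <- vector("list", sum(module_sizes))
  k <- 0L
  for (size in module_sizes) {
    ci <- draw_c()
    for (j in seq_len(size)) {
      k <- k + 1L
      cols[[k]] <- ci + draw_e()
    }
  }
  names(cols) <- flat_names(module_sizes)
  tibble::as_tibble(cols)
}

check_sizes <- function(sizes) {
  if (!is.numeric(sizes) || length(sizes) < 1L || any(sizes != round(sizes)) ||
      any(sizes < 1)) {
    stop("module sizes must be positive integers", call. = FALSE)
  }
}

flat_names <- function(module_sizes) {
  unlist(lapply(seq_along(module_sizes), function(i) {
    sprintf("m%d_v%d", i, seq_len(module_sizes[i]))
  }))
}

#' Simulate variables with a hierarchical (nested) module structure
#'
#' Generates data under the nested additive model x = g + s + ... + e: each
#' level of the hierarchy contributes a normal component shared by all
#' variables below it, drawn once per record per group, plus a
#' variable-specific component e. The expected correlation between two
#' variables is the sum of their shared component variances divided by the
#' total component variance (see [implied_correlation()]).
#'
#' `structure` is a nested list whose leaves are integer variable counts:
#' `list(list(2, 2), list(2, 2))` is two modules of two sub-modules of two
#' variables each. `level_variances[d]` is the variance of the component
#' drawn at nesting depth d (depth 1 = top-level modules).
#'
#' @param structure nested list of group sizes (leaves = integers)
#' @param m number of records
#' @param level_variances numeric vector, one shared-component variance per
#'   nesting level (length = leaf depth)
#' @param v_e variance of the variable-specific component
#' @param seed integer seed
#' @param .names optional variable names (internal)
#' @return a tibble, m rows by n named variables; names encode the lineage
#'   (`m1.2_v1` = module 1, sub-module 2, variable 1)
#' @examples
#' x <- simulate_hierarchy(list(list(2, 2), list(2, 2)), m = 100,
#'                         level_variances = c(0.03, 0.03), v_e = 0.05)
#' @export
simulate_hierarchy <- function(structure, m = 100L,
                               level_variances = c(0.03, 0.03), v_e = 0.05,
                               seed = 1L, .names = NULL) {
  if (!is.list(structure) || length(structure) < 1L) {
    stop("`structure` must be a non-empty nested list of group sizes",
         call. = FALSE)
  }
  depth <- leaf_depth(structure)
  if (length(level_variances) < depth) {
    stop("`level_variances` has ", length(level_variances),
         " entries but the structure has ", depth, " nesting level(s)",
         call. = FALSE)
  }
  if (any(level_variances < 0)) {
    stop("level variances must be >= 0", call. = FALSE)
  }
  if (!is.numeric(v_e) || v_e <= 0) stop("`v_e` must be > 0", call. = FALSE)
  if (!is.numeric(m) || m < 2) stop("`m` must be >= 2", call. = FALSE)
  m <- as.integer(m)
  set.seed(as_r_seed(seed))
  cols <- list()
  walk <- function(node, inherited, d, path) {
    for (i in seq_along(node)) {
      child <- node[[i]]
      comp <- inherited + rnorm(m, 0, sqrt(level_variances[d]))
      pth <- c(path, i)
      if (is.list(child)) {
        walk(child, comp, d + 1L, pth)
      } else {
        if (!is.numeric(child) || length(child) != 1L ||
            child != round(child) || child < 1) {
          stop("structure leaves must be positive integer counts",
               call. = FALSE)
        }
        for (j in seq_len(child)) {
          nm <- sprintf("m%s_v%d", paste(pth, collapse = "."), j)
          cols[[nm]] <<- comp + rnorm(m, 0, sqrt(v_e))
        }
      }
    }
  }
  walk(structure, rep(0, m), 1L, integer(0))
  if (!is.null(.names)) names(cols) <- .names
  tibble::as_tibble(cols)
}

leaf_depth <- function(node, d = 1L) {
  depths <- vapply(node, function(child) {
    if (is.list(child)) leaf_depth(child, d + 1L) else d
  }, integer(1))
  max(depths)
}

#' Correlation implied by shared additive components
#'
#' Under the additive component models of [simulate_modules()] and
#' [simulate_hierarchy()], the Pearson correlation between two variables is
#' the summed variance of the components they share divided by the summed
#' variance of all components of one variable.
#'
#' @param shared_variances variances of the components shared by the pair
#'   (may be empty: no shared components, correlation 0)
#' @param total_variances variances of all components making up a variable
#'   (shared plus specific)
#' @return the implied correlation, `sum(shared) / sum(total)`
#' @examples
#' implied_correlation(0.030, c(0.030, 0.050))              # 0.375
#' implied_correlation(c(0.03, 0.03), c(0.03, 0.03, 0.05))  # 0.545...
#' @export
implied_correlation <- function(shared_variances, total_variances) {
  if (any(shared_variances < 0) || any(total_variances < 0)) {
    stop("variances must be >= 0", call. = FALSE)
  }
  tot <- sum(total_variances)
  if (length(total_variances) < 1L || tot <= 0) {
    stop("total component variance must be positive", call. = FALSE)
  }
  sh <- sum(shared_variances)
  if (sh > tot + 1e-12) {
    stop("shared variances must be a subset of the total", call. = FALSE)
  }
  sh / tot
}
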