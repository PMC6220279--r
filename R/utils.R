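#' Run code under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so that
#' seeded generators do not perturb the global stream. A `NULL` seed runs
#' `expr` against the current stream unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# log-normal parameterized by arithmetic mean and CV
rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# label lookup with a readable error naming the missing region
region_label <- function(vol, region) {
  lab <- vol$label_map[region]
  if (length(lab) != 1 || is.na(lab))
    stop(sprintf("region '%s' not present in label map", region), call. = FALSE)
  unname(lab)
}

stopifnot_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", what), call. = FALSE)
  invisible(x)
}
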