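#' Specify a sampling distribution for a Monte Carlo parameter
#'
#' Lightweight distribution specification used by the probabilistic
#' exposure engine. Supported families and parameters:
#' \describe{
#'   \item{point}{`value` (a degenerate, single-value distribution)}
#'   \item{uniform}{`min`, `max`}
#'   \item{triangular}{`min`, `mode`, `max`}
#'   \item{normal}{`mean`, `sd`}
#'   \item{lognormal}{`meanlog`, `sdlog` (mean and sd of the underlying
#'     natural-log scale)}
#'   \item{empirical}{`values` (resampled with replacement)}
#' }
#' An optional `truncation = c(low, high)` restricts the support; draws
#' outside the bounds are regenerated by rejection (see [sample_dist()]).
#'
#' @param family One of the family names above.
#' @param ... Family-specific parameters, named.
#' @param truncation Optional numeric length-2 vector `c(low, high)`.
#' @return An object of class `"dist_spec"`.
#' @examples
#' dist_spec("lognormal", meanlog = log(0.1), sdlog = 1)
#' dist_spec("normal", mean = 60.95, sd = 10, truncation = c(40, 120))
#' @export
dist_spec <- function(family = c("point", "uniform", "triangular", "normal",
                                 "lognormal", "empirical"),
                      ..., truncation = NULL) {
  family <- match.arg(family)
  params <- list(...)
  need <- switch(family,
                 point = "value",
                 uniform = c("min", "max"),
                 triangular = c("min", "mode", "max"),
                 normal = c("mean", "sd"),
                 lognormal = c("meanlog", "sdlog"),
                 empirical = "values")
  missing_p <- setdiff(need, names(params))
  if (length(missing_p))
    stop(family, " spec needs parameter(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(params), need)
  if (length(extra))
    warning(family, " spec: ignoring unknown parameter(s) ",
            paste(extra, collapse = ", "), call. = FALSE)
  params <- lapply(params[need], as.numeric)
  if (family == "point" && length(params$value) != 1L)
    stop("point spec takes exactly one value", call. = FALSE)
  if (family == "uniform" && params$min > params$max)
    stop("uniform spec needs min <= max", call. = FALSE)
  if (family == "triangular" &&
      !(params$min <= params$mode && params$mode <= params$max))
    stop("triangular spec needs min <= mode <= max", call. = FALSE)
  if (family %in% c("normal", "lognormal") && params[[2L]] < 0)
    stop(family, " spec needs a non-negative sd", call. = FALSE)
  if (family == "empirical" && !length(params$values))
    stop("empirical spec needs at least one value", call. = FALSE)
  if (!is.null(truncation)) {
    truncation <- as.numeric(truncation)
    if (length(truncation) != 2L || truncation[1L] >= truncation[2L])
      stop("truncation must be c(low, high) with low < high", call. = FALSE)
  }
  structure(list(family = family, params = params, truncation = truncation),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  ps <- paste(names(x$params),
              vapply(x$params, function(p)
                if (length(p) > 4L) paste0("<", length(p), " values>")
                else paste(format(p), collapse = ","), character(1)),
              sep = " = ", collapse = ", ")
  cat(sprintf("dist_spec: %s(%s)", x$family, ps))
  if (!is.null(x$truncation))
    cat(sprintf(" truncated to (%g, %g)", x$truncation[1L],
                x$truncation[2L]))
  cat("\n")
  invisible(x)
}

draw_raw <- function(spec, n) {
  p <- spec$params
  switch(spec$family,
         point = rep(p$value, n),
         uniform = stats::runif(n, p$min, p$max),
         triangular = rtriangular(n, p$min, p$mode, p$max),
         normal = stats::rnorm(n, p$mean, p$sd),
         lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
         empirical = sample(p$values, n, replace = TRUE))
}

# Inverse-CDF triangular sampler (no CRAN triangular distribution is
# assumed).
rtriangular <- function(n, min, mode, max) {
  u <- stats::runif(n)
  if (max == min) return(rep(min, n))
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

#' Draw reproducible samples from a distribution specification
#'
#' Truncation is enforced by rejection: out-of-bound draws are regenerated,
#' up to `max_rounds` passes; if the truncation region holds (almost) no
#' mass the sampler errors out rather than looping forever. Draws are
#' reproducible for a fixed `seed`; with `seed = NULL` the current RNG
#' stream is used (this is what the Monte Carlo engine does, after seeding
#' each parameter's own substream).
#'
#' @param spec A [dist_spec()] object.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @param max_rounds Rejection passes allowed before declaring the
#'   truncation infeasible.
#' @return Numeric vector of length `n`, all values within the truncation
#'   bounds.
#' @examples
#' sample_dist(dist_spec("point", value = 2.5), 4)
#' @export
sample_dist <- function(spec, n, seed = NULL, max_rounds = 1000L) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  x <- draw_raw(spec, n)
  if (is.null(spec$truncation)) return(x)
  lo <- spec$truncation[1L]; hi <- spec$truncation[2L]
  bad <- which(x < lo | x > hi)
  round <- 0L
  while (length(bad)) {
    round <- round + 1L
    if (round > max_rounds)
      stop("truncation to (", lo, ", ", hi, ") looks infeasible for the ",
           spec$family, " spec: no in-bound draw after ", max_rounds,
           " rejection rounds", call. = FALSE)
    repl <- draw_raw(spec, length(bad))
    ok <- repl >= lo & repl <= hi
    x[bad[ok]] <- repl[ok]
    bad <- bad[!ok]
  }
  x
}
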