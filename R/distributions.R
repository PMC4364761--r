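#' Sampling distribution specifications
#'
#' Light-weight constructors for the four distribution families used to
#' express second-order (parameter) uncertainty: beta, gamma (parameterised
#' by mean and standard deviation), triangular, and a degenerate point mass.
#' Each returns a `dist_spec` object that [dist_sample()] can draw from and
#' [dist_mean()] can summarise.
#'
#' The gamma is converted internally to shape/scale via
#' `shape = (mean/sd)^2`, `scale = sd^2/mean`. Triangular bounds must satisfy
#' `min <= mode <= max`; constructors reorder misordered bounds rather than
#' failing, because published tables occasionally print them reversed.
#'
#' @param alpha,beta Positive beta shape parameters.
#' @param mean,sd Positive gamma mean and standard deviation.
#' @param min,mode,max Triangular support and mode.
#' @param value Point value.
#' @return A `dist_spec` object.
#' @name dist_spec
NULL

#' @rdname dist_spec
#' @export
dist_beta <- function(alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  structure(list(family = "beta", alpha = alpha, beta = beta),
            class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_gamma_ms <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  structure(list(family = "gamma", mean = mean, sd = sd,
                 shape = (mean / sd)^2, scale = sd^2 / mean),
            class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_triangular <- function(min, mode, max) {
  b <- sort(c(min, mode, max))
  structure(list(family = "triangular", min = b[1], mode = b[2], max = b[3]),
            class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_point <- function(value) {
  structure(list(family = "point", value = value), class = "dist_spec")
}

#' Beta distribution from a mean and an effective sample size
#'
#' Used for event-rate parameters whose published description is
#' "approximated from the mean annual event rate" without an explicit
#' variance: `alpha = mean * ess`, `beta = (1 - mean) * ess`.
#'
#' @param mean Mean in (0,1).
#' @param ess Effective sample size (> 0); larger means tighter.
#' @export
dist_beta_mean_ess <- function(mean, ess) {
  stopifnot(mean > 0, mean < 1, ess > 0)
  dist_beta(mean * ess, (1 - mean) * ess)
}

#' Draw from a distribution specification
#'
#' @param spec A `dist_spec`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`, always within the family's support.
#' @export
dist_sample <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$family,
    point = rep(spec$value, n),
    beta = stats::rbeta(n, spec$alpha, spec$beta),
    gamma = stats::rgamma(n, shape = spec$shape, scale = spec$scale),
    triangular = qtriangular(stats::runif(n), spec$min, spec$mode, spec$max),
    stop("unknown distribution family: ", spec$family)
  )
}

#' @rdname dist_sample
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$family,
    point = spec$value,
    beta = spec$alpha / (spec$alpha + spec$beta),
    gamma = spec$mean,
    triangular = (spec$min + spec$mode + spec$max) / 3
  )
}

# Triangular quantile function (inverse CDF).
qtriangular <- function(p, min, mode, max) {
  stopifnot(min <= mode, mode <= max)
  if (min == max) return(rep(min, length(p)))
  fc <- (mode - min) / (max - min)
  ifelse(p < fc,
         min + sqrt(p * (max - min) * (mode - min)),
         max - sqrt((1 - p) * (max - min) * (max - mode)))
}

#' @export
print.dist_spec <- function(x, ...) {
  args <- x[setdiff(names(x), "family")]
  cat(sprintf("<dist_spec %s(%s)>\n", x$family,
              paste(sprintf("%s=%g", names(args), unlist(args)), collapse = ", ")))
  invisible(x)
}
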