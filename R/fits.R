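## Least-squares fits of named density shapes to tabulated distributions:
## lognormal for AFM length densities, Weibull for measured s densities.
## Fitting is on the tabulated density (the workflow used for classed
## microscopy/AUC data), with maximum likelihood on raw records available
## through stats::fitdistr-style moments only as starting values.

#' Fit a lognormal density to a tabulated distribution
#'
#' Least squares of `A * dlnorm(x, meanlog, sdlog)` against the tabulated
#' density (`A` absorbs normalization differences; it is ~1 for a normalized
#' distribution). Starting values come from the weighted log-moments.
#'
#' @param dist A [weighted_distribution()] (any axis).
#' @return An object of class `c("lognormal_fit", "density_fit")` with
#'   elements `meanlog`, `sdlog`, `scale`, `rss` (residual sum of squares),
#'   `fitted` and `median = exp(meanlog)`.
#' @export
fit_lognormal <- function(dist) {
  xy <- fit_xy(dist)
  w <- xy$y * node_weights(xy$x)
  w <- w / sum(w)
  lx <- log(xy$x)
  ml0 <- sum(w * lx)
  sl0 <- sqrt(max(sum(w * (lx - ml0)^2), 1e-4))
  fit <- minpack.lm::nlsLM(
    y ~ A * stats::dlnorm(x, meanlog, sdlog),
    data = xy,
    start = list(A = 1, meanlog = ml0, sdlog = sl0),
    lower = c(1e-12, -Inf, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  p <- as.list(stats::coef(fit))
  rss <- sum(stats::resid(fit)^2)
  check_convergence(fit, rss)
  structure(list(meanlog = p$meanlog, sdlog = p$sdlog, scale = p$A,
                 median = exp(p$meanlog),
                 mean = exp(p$meanlog + p$sdlog^2 / 2),
                 rss = rss, fitted = stats::fitted(fit), grid = xy$x,
                 family = "lognormal"),
            class = c("lognormal_fit", "density_fit"))
}

#' Fit a Weibull density to a tabulated distribution
#'
#' Least squares of `A * dweibull(x - location, shape, scale)` against the
#' tabulated density. The location offset is fixed at 0 unless
#' `location = TRUE`, in which case it is fitted (bounded below the smallest
#' grid point); measured s densities of stressed fibrils are tailing and
#' typically well described without an offset.
#'
#' @param dist A [weighted_distribution()].
#' @param location Fit a location offset? Default FALSE.
#' @return An object of class `c("weibull_fit", "density_fit")` with
#'   `shape`, `scale`, `location`, `scale_factor`, `rss`, `fitted`.
#' @export
fit_weibull <- function(dist, location = FALSE) {
  xy <- fit_xy(dist)
  w <- xy$y * node_weights(xy$x)
  w <- w / sum(w)
  mu <- sum(w * xy$x)
  sdv <- sqrt(max(sum(w * (xy$x - mu)^2), 1e-12))
  ## moment-matched start: cv -> shape (Weibull cv is monotone in 1/shape)
  cv <- sdv / mu
  k0 <- max(cv^(-1.086), 0.2)          # Justus' approximation
  sc0 <- mu / gamma(1 + 1 / k0)
  if (location) {
    fit <- minpack.lm::nlsLM(
      y ~ A * stats::dweibull(pmax(x - loc, 1e-12), shape, scale),
      data = xy,
      start = list(A = 1, shape = k0, scale = sc0, loc = 0),
      lower = c(1e-12, 1e-3, 1e-9, -Inf),
      upper = c(Inf, Inf, Inf, min(xy$x) - 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14))
  } else {
    fit <- minpack.lm::nlsLM(
      y ~ A * stats::dweibull(x, shape, scale),
      data = xy,
      start = list(A = 1, shape = k0, scale = sc0),
      lower = c(1e-12, 1e-3, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14))
  }
  p <- as.list(stats::coef(fit))
  rss <- sum(stats::resid(fit)^2)
  check_convergence(fit, rss)
  structure(list(shape = p$shape, scale = p$scale,
                 location = if (location) p$loc else 0,
                 scale_factor = p$A, rss = rss,
                 fitted = stats::fitted(fit), grid = xy$x,
                 family = "weibull"),
            class = c("weibull_fit", "density_fit"))
}

fit_xy <- function(dist) {
  stopifnot(inherits(dist, "weighted_distribution"))
  keep <- dist$density > 0
  if (sum(keep) < 5)
    stop("need at least 5 grid points with positive density to fit")
  data.frame(x = dist$grid, y = dist$density)
}

check_convergence <- function(fit, rss) {
  info <- fit$convInfo
  if (!is.null(info) && !isTRUE(info$isConv))
    stop(sprintf("density fit did not converge (final residual sum of squares %.3g)",
                 rss))
  invisible(TRUE)
}

#' @export
print.density_fit <- function(x, ...) {
  if (x$family == "lognormal") {
    cat(sprintf("lognormal density fit: meanlog %.5g, sdlog %.5g (median %.5g, mean %.5g), rss %.3g\n",
                x$meanlog, x$sdlog, x$median, x$mean, x$rss))
  } else {
    cat(sprintf("Weibull density fit: shape %.5g, scale %.5g, location %.4g, rss %.3g\n",
                x$shape, x$scale, x$location, x$rss))
  }
  invisible(x)
}

#' @export
coef.density_fit <- function(object, ...) {
  if (object$family == "lognormal")
    c(meanlog = object$meanlog, sdlog = object$sdlog)
  else
    c(shape = object$shape, scale = object$scale, location = object$location)
}
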