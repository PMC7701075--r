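## Weighted-distribution machinery: the common 1D container for length and
## sedimentation-coefficient distributions, weighting-basis conversions, and
## Jacobian-exact mapping between length space and s space.

## Trapezoid node weights: integral(density) == sum(density * node_weights).
## All conservation guarantees in the package rest on this identity.
node_weights <- function(grid) {
  n <- length(grid)
  if (n == 1) return(1)
  d <- diff(grid)
  c(d[1] / 2, (d[-(n - 1)] + d[-1]) / 2, d[n - 1] / 2)
}

#' Weighted 1D distribution
#'
#' A tabulated density over a strictly increasing grid of lengths (nm) or
#' sedimentation coefficients (Svedberg), with an explicit weighting basis:
#' `number` (per particle), `mass` (per unit fibril mass) or `extinction`
#' (per unit optical signal; identical to mass under the equal-extinction-
#' per-subunit assumption). The density is normalized so that its trapezoid
#' integral over the grid is 1.
#'
#' @param grid Strictly increasing positive values (nm or S).
#' @param density Non-negative weights per grid point.
#' @param axis `"length"` or `"s"`.
#' @param weighting `"number"`, `"mass"` or `"extinction"`.
#' @param metadata Optional named list of provenance notes.
#' @param normalize Normalize the density to unit integral (default TRUE).
#' @return An object of class `weighted_distribution`.
#' @export
weighted_distribution <- function(grid, density,
                                  axis = c("length", "s"),
                                  weighting = c("number", "mass", "extinction"),
                                  metadata = list(), normalize = TRUE) {
  axis <- match.arg(axis)
  weighting <- match.arg(weighting)
  stopifnot(is.numeric(grid), is.numeric(density),
            length(grid) == length(density), length(grid) >= 1)
  if (any(!is.finite(grid)) || any(grid <= 0))
    stop("grid must be finite and positive")
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing")
  if (any(!is.finite(density)) || any(density < 0))
    stop("density must be finite and non-negative")
  total <- sum(density * node_weights(grid))
  if (normalize) {
    if (total <= 0) stop("density has zero total weight")
    density <- density / total
  }
  structure(list(grid = grid, density = density, axis = axis,
                 weighting = weighting, metadata = metadata),
            class = "weighted_distribution")
}

#' @export
print.weighted_distribution <- function(x, ...) {
  unit <- if (x$axis == "length") "nm" else "S"
  cat(sprintf("weighted_distribution: %s-weighted %s density, %d grid points on [%.4g, %.4g] %s\n",
              x$weighting, x$axis, length(x$grid), min(x$grid), max(x$grid), unit))
  s <- summary(x)
  cat(sprintf("  mode %.4g %s, mean %.4g %s, Q10/Q50/Q90 = %.4g / %.4g / %.4g %s\n",
              s$mode, unit, s$mean, unit, s$q10, s$q50, s$q90, unit))
  invisible(x)
}

#' @export
plot.weighted_distribution <- function(x, ..., cumulative = FALSE) {
  unit <- if (x$axis == "length") "fibril length (nm)" else "sedimentation coefficient (S)"
  if (cumulative) {
    graphics::plot(x$grid, cumulative_weight(x), type = "l", xlab = unit,
                   ylab = sprintf("%s cumulative fraction", x$weighting), ...)
  } else {
    graphics::plot(x$grid, x$density, type = "l", xlab = unit,
                   ylab = sprintf("%s density", x$weighting), ...)
  }
  invisible(x)
}

#' Cumulative form of a weighted distribution
#'
#' Trapezoid cumulative integral of the density, non-decreasing from 0 to the
#' total weight (1 for a normalized distribution).
#'
#' @param dist A [weighted_distribution()].
#' @return Numeric vector of cumulative weights at the grid points.
#' @export
cumulative_weight <- function(dist) {
  stopifnot(inherits(dist, "weighted_distribution"))
  g <- dist$grid
  p <- dist$density
  n <- length(g)
  if (n == 1) return(1)
  cumsum(c(0, diff(g) * (p[-n] + p[-1]) / 2))
}

#' Total (trapezoid) weight of a distribution
#' @param dist A [weighted_distribution()].
#' @return The trapezoid integral of the density over the grid.
#' @export
total_weight <- function(dist) {
  sum(dist$density * node_weights(dist$grid))
}

#' Ingest an AFM fibril-length table
#'
#' Applies the minimum-length filter used in statistical AFM image analysis
#' (default 50 nm), reports the number of records removed, bins the surviving
#' lengths and returns a normalized number-weighted length density.
#'
#' @param lengths Measured fibril lengths in nm.
#' @param min_length Minimum length retained, nm (default 50).
#' @param bins Number of linear bins spanning the surviving records
#'   (default 64). If the survivors take fewer distinct values than `bins`,
#'   the distinct values themselves are used as the grid.
#' @return A number-weighted [weighted_distribution()] over length. The
#'   number of filtered records is stored in `metadata$n_removed`.
#' @export
#' @examples
#' d <- ingest_length_table(c(40, 100, 100, 300))
#' d$metadata$n_removed  # 1
ingest_length_table <- function(lengths, min_length = 50, bins = 64) {
  stopifnot(is.numeric(lengths))
  lengths <- lengths[is.finite(lengths)]
  keep <- lengths >= min_length
  n_removed <- sum(!keep)
  lengths <- lengths[keep]
  if (length(lengths) == 0)
    stop(sprintf("no records remain after the %g nm minimum-length filter",
                 min_length))
  message(sprintf("ingest_length_table: removed %d record(s) below %g nm (%d retained)",
                  n_removed, min_length, length(lengths)))
  ux <- sort(unique(lengths))
  if (length(ux) == 1) {
    dist <- weighted_distribution(ux, 1, axis = "length", weighting = "number",
                                  normalize = FALSE)
  } else if (length(ux) <= bins) {
    cnt <- as.numeric(table(factor(lengths, levels = ux)))
    dist <- weighted_distribution(ux, cnt / node_weights(ux), axis = "length",
                                  weighting = "number")
  } else {
    edges <- seq(min(lengths), max(lengths), length.out = bins + 1)
    centers <- (edges[-1] + edges[-(bins + 1)]) / 2
    idx <- pmin(pmax(findInterval(lengths, edges, rightmost.closed = TRUE), 1), bins)
    cnt <- tabulate(idx, nbins = bins)
    dist <- weighted_distribution(centers, cnt / node_weights(centers),
                                  axis = "length", weighting = "number")
  }
  dist$metadata$n_removed <- n_removed
  dist$metadata$n_retained <- length(lengths)
  dist$metadata$min_length_nm <- min_length
  dist
}

## Relative fibril mass at a grid point, used for weighting conversions.
## At constant height the mass of a cylinder is proportional to h^2 * l; on a
## length axis this is proportional to l, on an s axis the length is obtained
## through the inverse hydrodynamic model.
relative_mass <- function(dist, height, material, solvent) {
  if (dist$axis == "length") {
    dist$grid
  } else {
    if (is.null(height))
      stop("converting the weighting of an s-axis distribution requires `height`")
    length_from_s(dist$grid, height, material, solvent)
  }
}

#' Convert the weighting basis of a distribution
#'
#' Number <-> mass conversions multiply or divide the density by the relative
#' fibril mass (proportional to `h^2 l`; to `l` at constant height) and
#' renormalize. Extinction weighting is identical to mass weighting under the
#' assumption that every subunit of a fibril contributes equally to the
#' optical signal.
#'
#' @param dist A [weighted_distribution()].
#' @param target `"number"`, `"mass"` or `"extinction"`.
#' @param height Constant fibril height in nm; required only for
#'   distributions on the s axis (the inverse model recovers the length).
#' @inheritParams sedimentation_coefficient
#' @return A [weighted_distribution()] in the target weighting.
#' @export
#' @examples
#' d <- weighted_distribution(c(100, 300), c(0.5, 0.5))
#' convert_weighting(d, "mass")
convert_weighting <- function(dist, target, height = NULL,
                              material = fibril_material(),
                              solvent = solvent_conditions()) {
  stopifnot(inherits(dist, "weighted_distribution"))
  if (!target %in% c("number", "mass", "extinction"))
    stop("unknown weighting: ", target)
  from <- if (dist$weighting == "extinction") "mass" else dist$weighting
  to <- if (target == "extinction") "mass" else target
  out <- dist
  if (from != to) {
    m <- relative_mass(dist, height, material, solvent)
    dens <- if (to == "mass") dist$density * m else dist$density / m
    out <- weighted_distribution(dist$grid, dens, axis = dist$axis,
                                 weighting = "number", metadata = dist$metadata)
  }
  out$weighting <- target
  out
}

## Map a distribution through a monotone axis transform, conserving weight
## exactly under the trapezoid rule: point masses w_i = p_i * nodew(old grid)
## are carried to the new grid and divided by its node weights (a discrete
## Jacobian). `new_grid` must be the image of `grid`, strictly monotone.
map_through <- function(dist, new_grid, new_axis) {
  w <- dist$density * node_weights(dist$grid)
  decreasing <- is.unsorted(new_grid, strictly = TRUE)
  if (decreasing) {
    new_grid <- rev(new_grid)
    w <- rev(w)
  }
  if (is.unsorted(new_grid, strictly = TRUE))
    stop("axis transform is not monotone on this grid")
  weighted_distribution(new_grid, w / node_weights(new_grid), axis = new_axis,
                        weighting = dist$weighting, metadata = dist$metadata,
                        normalize = FALSE)
}

#' Map a length distribution to a sedimentation-coefficient distribution
#'
#' Each grid length is pushed through the forward cylinder model at constant
#' height; the density is transformed with the discrete Jacobian of the
#' change of variables so total weight is conserved exactly under the
#' trapezoid rule.
#'
#' @param dist A [weighted_distribution()] over length (nm).
#' @param height Constant fibril height in nm (4.7 nm = 4.0 nm AFM height
#'   plus two bound water layers is the conventional in-solution value).
#' @inheritParams sedimentation_coefficient
#' @return A [weighted_distribution()] over s (Svedberg), same weighting.
#' @export
length_dist_to_s_dist <- function(dist, height = 4.7,
                                  material = fibril_material(),
                                  solvent = solvent_conditions()) {
  stopifnot(inherits(dist, "weighted_distribution"), dist$axis == "length")
  s <- sedimentation_coefficient(dist$grid, height, material, solvent)
  out <- map_through(dist, s, "s")
  out$metadata$height_nm <- height
  out
}

#' Map a sedimentation-coefficient distribution to a length distribution
#'
#' Inverse of [length_dist_to_s_dist()]: each s maps through the inverse
#' cylinder model at constant height. Grid points below the q = 1 rod limit
#' `s(h, h)` cannot correspond to any rod; they are excluded and the excluded
#' weight fraction is reported in `metadata$excluded_weight`.
#'
#' @param dist A [weighted_distribution()] over s (Svedberg).
#' @inheritParams length_dist_to_s_dist
#' @return A [weighted_distribution()] over length (nm), same weighting.
#' @export
s_dist_to_length_dist <- function(dist, height = 4.7,
                                  material = fibril_material(),
                                  solvent = solvent_conditions()) {
  stopifnot(inherits(dist, "weighted_distribution"), dist$axis == "s")
  s_min <- sedimentation_coefficient(height, height, material, solvent)
  ok <- dist$grid >= s_min
  excluded <- 1 - sum((dist$density * node_weights(dist$grid))[ok])
  if (!any(ok))
    stop(sprintf("entire s grid lies below the q = 1 limit (%.3g S)", s_min))
  if (any(!ok)) {
    message(sprintf("s_dist_to_length_dist: excluded %.3g%% of weight below the q = 1 limit (%.3g S)",
                    100 * excluded, s_min))
    dist <- weighted_distribution(dist$grid[ok], dist$density[ok], axis = "s",
                                  weighting = dist$weighting,
                                  metadata = dist$metadata, normalize = FALSE)
  }
  l <- length_from_s(dist$grid, height, material, solvent)
  out <- map_through(dist, l, "length")
  out$metadata$height_nm <- height
  out$metadata$excluded_weight <- max(excluded, 0)
  out
}

#' Quantile summary of a weighted distribution
#'
#' Modal value (grid point of maximum density), weighted mean, and the Q10 /
#' Q50 / Q90 quantiles of the cumulative distribution by linear
#' interpolation. Two width conventions are reported: half the Q10-Q90 span,
#' and the weighted standard deviation; `width` is the former wherever a
#' single number is needed.
#'
#' @param object A [weighted_distribution()].
#' @param ... Unused.
#' @return A list of class `dist_summary` with fields `mode`, `mean`,
#'   `median`, `q10`, `q50`, `q90`, `width` (= `(q90 - q10)/2`), `width_sd`.
#'   `q50` is the weighted mean (the convention used for reporting central
#'   fibril lengths); the median is reported separately.
#' @export
summary.weighted_distribution <- function(object, ...) {
  g <- object$grid
  nw <- node_weights(g)
  w <- object$density * nw
  tot <- sum(w)
  w <- w / tot
  mu <- sum(w * g)
  sdv <- sqrt(max(sum(w * (g - mu)^2), 0))
  cum <- cumulative_weight(object) / tot
  qs <- if (length(g) == 1) rep(g, 3) else
    vapply(c(0.1, 0.5, 0.9), function(p) {
      if (p <= cum[1]) return(g[1])
      if (p >= cum[length(cum)]) return(g[length(g)])
      stats::approx(cum, g, xout = p, ties = "ordered")$y
    }, numeric(1))
  structure(list(mode = g[which.max(object$density)], mean = mu,
                 median = qs[2], q10 = qs[1], q50 = mu, q90 = qs[3],
                 width = (qs[3] - qs[1]) / 2, width_sd = sdv,
                 axis = object$axis, weighting = object$weighting),
            class = "dist_summary")
}

#' @export
print.dist_summary <- function(x, ...) {
  unit <- if (x$axis == "length") "nm" else "S"
  cat(sprintf("%s-weighted %s distribution summary:\n", x$weighting, x$axis))
  cat(sprintf("  mode   %10.4g %s\n  mean   %10.4g %s\n  median %10.4g %s\n",
              x$mode, unit, x$mean, unit, x$median, unit))
  cat(sprintf("  Q10    %10.4g %s\n  Q90    %10.4g %s\n", x$q10, unit, x$q90, unit))
  cat(sprintf("  width  %10.4g %s  [(Q90-Q10)/2]\n  sd     %10.4g %s\n",
              x$width, unit, x$width_sd, unit))
  invisible(x)
}
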