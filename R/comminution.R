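## Comminution (size-reduction) bookkeeping for rotor-stator stressing and
## the power-law fit of fibril length against stress intensity.
##
## The stress intensity of an Ultra-Turrax style rotor-stator run is indexed
## by its number of rotations n; in the turbulent regime the volume-specific
## energy input scales as E_V ~ n^3, so a size-reduction law x ~ E_V^(-b)
## appears as l ~ n^(-3b) and b is read off a log-log fit.

#' Number of rotor rotations of a stressing run
#'
#' `n = (rpm / 60) * t_stress`, the first-order stress-intensity index of a
#' rotor-stator experiment.
#'
#' @param rpm Rotor speed, revolutions per minute.
#' @param seconds Stressing time, s.
#' @return Rotation count (dimensionless).
#' @export
#' @examples
#' rotations(19000, 60)  # 19000
rotations <- function(rpm, seconds) {
  stopifnot(all(rpm >= 0), all(seconds >= 0))
  rpm / 60 * seconds
}

#' Rotor Reynolds number
#'
#' `Re = n d_R^2 rho_S / eta` with the revolution rate `n` in rev/s. Above
#' 1e4 the flow is turbulent and the Newton number is constant.
#'
#' @param n_rev_s Revolution rate, rev/s.
#' @param d_rotor Rotor diameter, m.
#' @param solvent A [solvent_conditions()].
#' @return Reynolds number, with attribute `turbulent` (`Re > 1e4`).
#' @export
reynolds <- function(n_rev_s, d_rotor, solvent = solvent_conditions()) {
  stopifnot(n_rev_s > 0, d_rotor > 0)
  re <- n_rev_s * d_rotor^2 * solvent$density / solvent$viscosity
  attr(re, "turbulent") <- re > 1e4
  re
}

#' Power draw from the Newton number
#'
#' `P = Ne n^3 d_R^5 rho_S`.
#'
#' @param newton Newton (power) number of the rotor-stator geometry.
#' @param n_rev_s Revolution rate, rev/s.
#' @param d_rotor Rotor diameter, m.
#' @param solvent A [solvent_conditions()].
#' @return Power in W.
#' @export
newton_power <- function(newton, n_rev_s, d_rotor,
                         solvent = solvent_conditions()) {
  stopifnot(newton > 0, n_rev_s > 0, d_rotor > 0)
  newton * n_rev_s^3 * d_rotor^5 * solvent$density
}

#' Volume-specific energy input
#'
#' `E_V = P t / V`.
#'
#' @param power Power in W.
#' @param seconds Stressing time, s.
#' @param volume Processed volume, m^3.
#' @return Energy per volume, J m^-3.
#' @export
energy_per_volume <- function(power, seconds, volume) {
  stopifnot(power >= 0, seconds >= 0, volume > 0)
  power * seconds / volume
}

#' Comminution data series
#'
#' Characteristic fibril lengths measured after stressing runs at given
#' rotor speed and time, tagged with which statistic they are (mean or
#' modal) and which technique produced them (AFM or AUC).
#'
#' @param rpm Rotor speeds, rev/min.
#' @param seconds Stressing times, s.
#' @param length_nm Characteristic fibril lengths, nm.
#' @param statistic `"mean"` or `"modal"` per point (recycled).
#' @param source `"AFM"` or `"AUC"` per point (recycled).
#' @return A data frame of class `comminution_series` with a derived
#'   `rotations` column.
#' @export
comminution_series <- function(rpm, seconds, length_nm,
                               statistic = "mean", source = "AFM") {
  stopifnot(length(rpm) == length(seconds),
            length(rpm) == length(length_nm),
            all(length_nm > 0))
  statistic <- match.arg(rep_len(as.character(statistic), length(rpm)),
                         c("mean", "modal"), several.ok = TRUE)
  source <- match.arg(rep_len(as.character(source), length(rpm)),
                      c("AFM", "AUC"), several.ok = TRUE)
  out <- data.frame(rpm = rpm, seconds = seconds,
                    rotations = rotations(rpm, seconds),
                    length_nm = length_nm,
                    statistic = rep_len(statistic, length(rpm)),
                    source = rep_len(source, length(rpm)))
  class(out) <- c("comminution_series", "data.frame")
  out
}

#' Fit the size-reduction exponent b
#'
#' Ordinary least squares of `ln(length)` on `ln(n)` (rotations); the
#' size-reduction exponent is `b = -slope / 3` because `E_V ~ n^3` in the
#' turbulent regime. By default the 11,000 rpm / 5 s condition is excluded:
#' within such a short run the flow pattern around the stirrer is not fully
#' developed, so its stress intensity is not comparable. Exclusions are
#' explicit and echoed in the result; there is no automatic outlier
#' rejection.
#'
#' @param series A [comminution_series()] (or data frame with `rpm`,
#'   `seconds`, `length_nm`).
#' @param exclude A list of `c(rpm, seconds)` pairs to exclude. Default
#'   `list(c(11000, 5))`. Use `list()` to keep every point.
#' @return An object of class `comminution_fit`: `a` (prefactor, nm), `b`,
#'   `slope`, `stderr_slope`, `stderr_b`, `residual_se`, `excluded`
#'   (data frame of excluded points), `n_points`, and the underlying `lm`
#'   fit.
#' @export
#' @examples
#' ser <- comminution_series(rep(c(11, 16, 22) * 1000, each = 2),
#'                           rep(c(30, 90), 3),
#'                           1000 * rotations(rep(c(11, 16, 22) * 1000,
#'                                                each = 2),
#'                                            rep(c(30, 90), 3))^-0.9)
#' fit_size_reduction(ser, exclude = list())  # b = 0.3
fit_size_reduction <- function(series, exclude = list(c(11000, 5))) {
  stopifnot(is.data.frame(series),
            all(c("rpm", "seconds", "length_nm") %in% names(series)))
  if (is.numeric(exclude)) exclude <- list(exclude)
  excl <- rep(FALSE, nrow(series))
  for (e in exclude) {
    stopifnot(length(e) == 2)
    excl <- excl | (series$rpm == e[1] & series$seconds == e[2])
  }
  kept <- series[!excl, , drop = FALSE]
  if (nrow(kept) < 3)
    stop("need at least 3 points after exclusion to fit the power law")
  n <- rotations(kept$rpm, kept$seconds)
  if (length(unique(n)) < 3)
    stop("need at least 3 distinct rotation counts to fit the power law")
  fit <- stats::lm(log(length_nm) ~ log(n),
                   data = data.frame(length_nm = kept$length_nm, n = n))
  cf <- stats::coef(fit)
  ## slope standard error from the residual scale directly (avoids the
  ## perfect-fit warning of summary.lm on noiseless synthetic series)
  x <- log(n)
  se_slope <- stats::sigma(fit) / sqrt(sum((x - mean(x))^2))
  structure(list(a = exp(cf[[1]]), b = -cf[[2]] / 3, slope = cf[[2]],
                 stderr_slope = se_slope, stderr_b = se_slope / 3,
                 residual_se = stats::sigma(fit),
                 excluded = series[excl, , drop = FALSE],
                 n_points = nrow(kept), lm = fit),
            class = "comminution_fit")
}

#' @export
print.comminution_fit <- function(x, ...) {
  cat(sprintf("comminution power law: l = a * n^(-3b)\n"))
  cat(sprintf("  a = %.4g nm, b = %.4g +/- %.2g (slope %.4g), %d points\n",
              x$a, x$b, x$stderr_b, x$slope, x$n_points))
  if (nrow(x$excluded) > 0)
    cat(sprintf("  excluded: %s\n",
                paste(sprintf("%g rpm / %g s", x$excluded$rpm,
                              x$excluded$seconds), collapse = ", ")))
  if (x$b < 0.1 || x$b > 0.8)
    cat("  note: b outside the 0.3-0.8 range typical of fluid-stress comminution\n")
  invisible(x)
}

#' @export
coef.comminution_fit <- function(object, ...) {
  c(a = object$a, b = object$b, slope = object$slope)
}

#' @export
predict.comminution_fit <- function(object, rpm, seconds, ...) {
  object$a * rotations(rpm, seconds)^(-3 * object$b)
}
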