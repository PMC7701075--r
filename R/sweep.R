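## Brownian-dynamics simulation of constant-speed gravitational-sweep AUC
## experiments and the back-transformation of detector time traces into
## sedimentation-coefficient distributions.

#' Gravitational-sweep experiment configuration
#'
#' Rotor and cell geometry, speed and timing for the Brownian-dynamics
#' sweep simulator. Defaults reproduce the published simulation study:
#' 30,000 rpm, meniscus 5.9 cm, cell bottom 7.2 cm, detector at 6.9 cm,
#' 7200 s duration.
#'
#' @param rotor_rpm Rotor speed in revolutions per minute (held constant).
#' @param meniscus_cm,bottom_cm,detector_cm Radial positions (cm from the
#'   rotor axis) of the solution meniscus, cell bottom and fixed detector.
#' @param duration_s Simulated experiment duration, s.
#' @param dt_s Integration time step, s.
#' @param n_particles Particles per species.
#' @param seed Integer seed; every random draw of a run derives from it.
#' @param detector_bin_um Radial width of the detector window, micrometres.
#' @param record_every_s Trace output interval, s (rounded to a multiple of
#'   `dt_s`).
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(rotor_rpm = 30000, meniscus_cm = 5.9,
                         bottom_cm = 7.2, detector_cm = 6.9,
                         duration_s = 7200, dt_s = 0.5,
                         n_particles = 1e5, seed = 1,
                         detector_bin_um = 1000, record_every_s = 5) {
  stopifnot(rotor_rpm > 0, duration_s > 0, dt_s > 0, n_particles >= 1)
  if (!(meniscus_cm < detector_cm && detector_cm < bottom_cm))
    stop("need meniscus < detector < bottom")
  structure(list(rotor_rpm = rotor_rpm,
                 omega = rotor_rpm / 60 * 2 * pi,
                 meniscus = meniscus_cm * 1e-2,
                 bottom = bottom_cm * 1e-2,
                 detector = detector_cm * 1e-2,
                 duration = duration_s, dt = dt_s,
                 n_particles = as.integer(n_particles),
                 seed = as.integer(seed),
                 detector_bin = detector_bin_um * 1e-6,
                 record_every = max(1L, as.integer(round(record_every_s / dt_s)))),
            class = "sweep_config")
}

#' Sedimenting species specification
#'
#' @param s Sedimentation coefficient in Svedberg.
#' @param ffo Frictional ratio f/f0 (>= 1).
#' @param density Effective particle density, kg m^-3.
#' @param abundance Relative signal (extinction) weight; abundances of a
#'   species list are renormalized to sum to 1.
#' @param label Optional species label.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(s, ffo = 1.5, density = 1.02 * 1331.6,
                         abundance = 1, label = NULL) {
  stopifnot(s > 0, ffo >= 1, density > 0, abundance > 0)
  structure(list(s = s, ffo = ffo, density = density, abundance = abundance,
                 label = if (is.null(label)) sprintf("%gS", s) else label),
            class = "species_spec")
}

#' The published three-species test mixture
#'
#' Non-aggregated material (NAM, the monomer/peptide pool) at 4 S with
#' f/f0 = 1.26 and the native density 1331.6 kg m^-3, plus two fibril-like
#' species at 50 S and 100 S with f/f0 = 1.5 and a 2 % densified density, in
#' equal signal thirds.
#'
#' @return A list of three [species_spec()] objects.
#' @export
nam_fibril_species <- function() {
  list(species_spec(4, ffo = 1.26, density = 1331.6, abundance = 1 / 3,
                    label = "NAM"),
       species_spec(50, ffo = 1.5, density = 1.02 * 1331.6, abundance = 1 / 3),
       species_spec(100, ffo = 1.5, density = 1.02 * 1331.6, abundance = 1 / 3))
}

#' Diffusion coefficient from sedimentation coefficient and frictional ratio
#'
#' The equivalent-sphere diameter follows from the Svedberg-type relation
#' `s = d_eq^2 (rho - rho_S) / (18 eta f/f0)`; Stokes drag
#' `f = 3 pi eta d_eq (f/f0)` then gives `D = kB T / f`. For fibril-scale
#' species (tens of Svedberg) D is small enough that sedimentation fronts
#' stay sharp over an experiment.
#'
#' @param s Sedimentation coefficient in Svedberg.
#' @param ffo Frictional ratio f/f0.
#' @param density Effective particle density, kg m^-3.
#' @param solvent A [solvent_conditions()]; its `temperature` (deg C) sets
#'   the thermal energy.
#' @return Diffusion coefficient in m^2 s^-1.
#' @export
#' @examples
#' # 10 nm equivalent sphere at f/f0 = 1: classic Stokes-Einstein value
#' s10 <- (10e-9)^2 * (1358.232 - 998.2) / (18 * 1.002e-3) / 1e-13
#' diffusion_from_s(s10, 1, 1358.232)
diffusion_from_s <- function(s, ffo, density, solvent = solvent_conditions()) {
  drho <- density - solvent$density
  stopifnot(s > 0, ffo >= 1, drho > 0)
  d_eq <- sqrt(18 * solvent$viscosity * ffo * (s * SVEDBERG) / drho)
  f <- 3 * pi * solvent$viscosity * d_eq * ffo
  BOLTZMANN * (solvent$temperature + 273.15) / f
}

#' Simulate a gravitational-sweep experiment
#'
#' Each particle follows the overdamped Langevin step
#' `dr = s w^2 r dt + sqrt(2 D dt) xi` with standard-normal `xi`, starting
#' from sector-geometry initial positions (density proportional to r on
#' `[meniscus, bottom]`), reflecting at the meniscus and accumulating at the
#' cell bottom. The detector signal is the abundance-weighted particle count
#' in a radial window at the detector radius, normalized per species by its
#' expected initial window count, so radial dilution emerges from the
#' dynamics rather than being imposed.
#'
#' @param config A [sweep_config()].
#' @param species A [species_spec()] or list of them.
#' @param solvent A [solvent_conditions()].
#' @param diffusion If FALSE, run with D = 0 (sharp-front reference).
#' @return An object of class `detector_trace`: `time` (s), `signal`
#'   (normalized total), `species_signal` (matrix, one column per species),
#'   `abundance`, `config`, `species`.
#' @export
simulate_sweep <- function(config, species, solvent = solvent_conditions(),
                           diffusion = TRUE) {
  stopifnot(inherits(config, "sweep_config"))
  if (inherits(species, "species_spec")) species <- list(species)
  stopifnot(length(species) >= 1,
            all(vapply(species, inherits, logical(1), "species_spec")))
  omega2 <- config$omega^2
  s_max <- max(vapply(species, `[[`, numeric(1), "s")) * SVEDBERG
  if (s_max * omega2 * config$bottom * config$dt > 1e-4)
    stop(paste("time step too large: the fastest species advances more than",
               "0.1 mm per step; reduce dt_s"))
  abundance <- vapply(species, `[[`, numeric(1), "abundance")
  abundance <- abundance / sum(abundance)
  n_steps <- as.integer(round(config$duration / config$dt))
  det_lo <- config$detector - config$detector_bin / 2
  det_hi <- config$detector + config$detector_bin / 2
  ## expected initial window count under the sector-geometry initial density
  ## (prop. to r); normalizing by the expectation rather than the realized
  ## count keeps the per-species traces free of a common scale error
  expected0 <- config$n_particles * (det_hi^2 - det_lo^2) /
    (config$bottom^2 - config$meniscus^2)
  if (expected0 < 1)
    stop("fewer than one particle expected in the detector window; increase n_particles or detector_bin_um")
  sig <- vapply(seq_along(species), function(j) {
    sp <- species[[j]]
    D <- if (diffusion) diffusion_from_s(sp$s, sp$ffo, sp$density, solvent) else 0
    counts <- bd_sweep_kernel(config$n_particles, sp$s * SVEDBERG, D, omega2,
                              config$dt, n_steps, config$record_every,
                              config$meniscus, config$bottom, det_lo, det_hi,
                              config$seed * 1000 + j)
    counts / expected0
  }, numeric(n_steps %/% config$record_every + 1))
  time <- seq(0, by = config$dt * config$record_every,
              length.out = nrow(sig))
  structure(list(time = time,
                 signal = as.numeric(sig %*% abundance),
                 species_signal = sig, abundance = abundance,
                 config = config, species = species),
            class = "detector_trace")
}

#' @export
print.detector_trace <- function(x, ...) {
  cat(sprintf("detector trace: %d species, %d time points over %g s at %g rpm\n",
              length(x$species), length(x$time), max(x$time),
              x$config$rotor_rpm))
  cat(sprintf("  final signal %.4f of initial\n", x$signal[length(x$signal)]))
  invisible(x)
}

#' @export
plot.detector_trace <- function(x, ...) {
  graphics::plot(x$time, x$signal, type = "l", xlab = "time (s)",
                 ylab = "normalized detector signal", ...)
  invisible(x)
}

#' Map an arrival time to a sedimentation coefficient
#'
#' The sweep back-transformation `s = ln(r_fix / r_m) / (w^2 t)`.
#'
#' @param t Time since the start of sedimentation, s.
#' @param config A [sweep_config()].
#' @return Sedimentation coefficient in Svedberg.
#' @export
#' @examples
#' s_from_time(1586.4, sweep_config())  # ~100 S
s_from_time <- function(t, config) {
  stopifnot(inherits(config, "sweep_config"), all(t > 0))
  log(config$detector / config$meniscus) / (config$omega^2 * t) / SVEDBERG
}

#' Recover the sedimentation-coefficient distribution from a detector trace
#'
#' The arrival time of a species' sedimentation front at the detector maps to
#' its sedimentation coefficient through [s_from_time()]. Because the plateau
#' concentration of a species in a sector cell decays as
#' `exp(-2 s w^2 t)` (radial dilution), the raw signal drop does not read off
#' the cumulative distribution directly. The default `method = "model"`
#' therefore fits the trace by non-negative least squares with single-species
#' model traces
#' `B_s(t) = exp(-2 s w^2 t) * Phi((r_fix - r_m exp(s w^2 t)) / sigma(t))`,
#' the radially diluted plateau times a diffusion- and window-broadened
#' boundary (`sigma^2 = 2 D(s) t + w_det^2 / 12`, with `D(s)` tied to s by a
#' fixed frictional ratio as in c(s)-style boundary modeling); the fitted
#' class weights are the extinction-weighted distribution.
#' `method = "naive"` reads the cumulative directly from the normalized
#' signal drop and is kept as a diagnostic of the size of the dilution
#' correction.
#'
#' The fibril-range recovery grid starts at the smallest sedimentation
#' coefficient whose boundary traverses meniscus-to-detector within the run
#' (`s_min = ln(r_fix/r_m) / (w^2 T)`): slower classes produce no front at
#' the detector, carry no recoverable information, and would only absorb
#' noise. Material slower than that but above `cutoff` is therefore outside
#' the experiment's window by design (the run duration is chosen so that all
#' fibril species sediment completely). A few slow catch-all components
#' below `cutoff` absorb the gradual dilution of non-sedimenting material
#' (NAM); classes below `cutoff` (default 10 S) are discarded and the
#' distribution renormalized.
#'
#' @param trace A [simulate_sweep()] result (or any list with `time`,
#'   `signal`).
#' @param config A [sweep_config()]; defaults to `trace$config`.
#' @param cutoff Smallest sedimentation coefficient retained, S.
#' @param s_grid Grid of s classes (class centers) for the recovery, S.
#'   Default: slow catch-alls at 1, 2, 4, 6, 8 S, then classes of width
#'   `class_width` from the resolvable minimum up to `s_max`.
#' @param class_width Width of the fibril-range s classes, S. The default
#'   10 S exceeds diffusional boundary spreading of fibril-scale species, so
#'   recovered discrete species stay in single classes.
#' @param s_max Largest class center, S.
#' @param ffo Frictional ratio assumed when tying the diffusion broadening
#'   of the model boundaries to s (default 1.5, the fibril-like value).
#' @param density Effective density assumed for the same purpose, kg m^-3.
#' @param solvent A [solvent_conditions()].
#' @param method `"model"` (dilution-corrected, default) or `"naive"`.
#' @return An object of class `s_recovery`: `s` (class centers retained),
#'   `mass` (renormalized extinction weights summing to 1), `cumulative`
#'   (a [stats::stepfun()] giving the fraction of material at or below s),
#'   `cutoff`, `method`, and `dist`, the same recovery as a
#'   [weighted_distribution()] over s.
#' @export
trace_to_s_distribution <- function(trace, config = trace$config, cutoff = 10,
                                    s_grid = NULL, class_width = 10,
                                    s_max = 300, ffo = 1.5,
                                    density = 1.02 * 1331.6,
                                    solvent = solvent_conditions(),
                                    method = c("model", "naive")) {
  method <- match.arg(method)
  stopifnot(inherits(config, "sweep_config"))
  time <- trace$time
  signal <- trace$signal
  stopifnot(length(time) == length(signal), !is.unsorted(time))
  omega2 <- config$omega^2
  A <- log(config$detector / config$meniscus)
  if (is.null(s_grid)) {
    s_resolvable <- A / (omega2 * config$duration) / SVEDBERG
    s_lo <- max(cutoff, class_width * ceiling(s_resolvable / class_width))
    s_grid <- c(c(1, 2, 4, 6, 8)[c(1, 2, 4, 6, 8) < cutoff],
                seq(s_lo, s_max, by = class_width))
  }
  s_grid <- sort(unique(s_grid))
  t_front <- A / (omega2 * s_grid * SVEDBERG)

  if (method == "model") {
    B <- vapply(seq_along(s_grid), function(j) {
      s_si <- s_grid[j] * SVEDBERG
      D <- diffusion_from_s(s_grid[j], ffo, density, solvent)
      g <- s_si * omega2
      ## boundary variance of the linear SDE dr = g r dt + sqrt(2D) dW:
      ## the r-proportional drift stretches the diffusive spread
      vr <- D / g * (exp(2 * g * time) - 1)
      sigma <- sqrt(vr + config$detector_bin^2 / 12)
      boundary <- config$meniscus * exp(g * time)
      exp(-2 * g * time) *
        stats::pnorm((config$detector - boundary) / sigma)
    }, numeric(length(time)))
    mass <- pracma::lsqnonneg(B, signal)$x
  } else {
    ## signal drop between successive samples, assigned to the s class of
    ## the mid-time of the interval
    drops <- -diff(signal)
    drops[drops < 0] <- 0
    t_mid <- (time[-1] + time[-length(time)]) / 2
    s_mid <- A / (omega2 * pmax(t_mid, config$dt) * SVEDBERG)
    edges <- c(-Inf, (s_grid[-1] + s_grid[-length(s_grid)]) / 2, Inf)
    idx <- findInterval(s_mid, edges)
    mass <- vapply(seq_along(s_grid), function(j) sum(drops[idx == j]),
                   numeric(1))
  }

  keep <- s_grid >= cutoff & mass > 0
  if (!any(keep))
    stop(sprintf("the %g S cutoff excludes all recovered material", cutoff))
  s_keep <- s_grid[keep]
  m_keep <- mass[keep] / sum(mass[keep])
  cum <- stats::stepfun(s_keep, c(0, cumsum(m_keep)), right = FALSE)
  dist <- if (length(s_keep) >= 2)
    weighted_distribution(s_keep, m_keep / node_weights(s_keep), axis = "s",
                          weighting = "extinction",
                          metadata = list(cutoff_svedberg = cutoff,
                                          method = method))
  else NULL
  structure(list(s = s_keep, mass = m_keep, cumulative = cum,
                 cutoff = cutoff, method = method, dist = dist),
            class = "s_recovery")
}

#' @export
print.s_recovery <- function(x, ...) {
  cat(sprintf("recovered s distribution (%s, cutoff %g S): %d classes\n",
              x$method, x$cutoff, length(x$s)))
  major <- x$mass >= 0.01
  cat(sprintf("  %6.1f S: %.3f\n", x$s[major], x$mass[major]), sep = "")
  invisible(x)
}
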