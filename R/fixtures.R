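## Seeded synthetic fixture generators: every input the analysis modules need
## can be produced in code, with parameter defaults anchored to the reported
## study conditions (lognormal lengths with mean 395 nm on [80, 810] nm;
## normal heights 4.0 +/- 1.0 nm; the three-species sweep mixture).

## Log-scale location of a lognormal truncated to [lo, hi] whose truncated
## mean equals `target`, at fixed log-sd. Solved by uniroot; the truncated
## mean is monotone in meanlog.
truncated_lognormal_meanlog <- function(target, lo, hi, sdlog) {
  tmean <- function(ml) {
    ## E[X | lo <= X <= hi] for X ~ lognormal(ml, sdlog)
    p <- stats::plnorm(c(lo, hi), ml, sdlog)
    ## partial expectation: E[X 1{X<=x}] = exp(ml+sd^2/2) Phi((ln x - ml - sd^2)/sd)
    pe <- exp(ml + sdlog^2 / 2) *
      stats::pnorm((log(c(lo, hi)) - ml - sdlog^2) / sdlog)
    (pe[2] - pe[1]) / (p[2] - p[1])
  }
  stats::uniroot(function(ml) tmean(ml) - target,
                 c(log(lo), log(hi)), extendInt = "yes", tol = 1e-10)$root
}

#' Generate a synthetic AFM length sample
#'
#' Lognormal fibril lengths truncated to `bounds` (rejection sampling). The
#' log-scale location is solved so the truncated mean equals `mean_nm`;
#' with the defaults (mean 395 nm, bounds 80-810 nm, n = 2000) the sample
#' mean lands within a few percent of 395 nm. Sampling uses R's RNG under
#' the given seed, so a fixed seed reproduces the sample exactly.
#'
#' @param n Number of fibrils (>= 10).
#' @param mean_nm Target mean length after truncation, nm.
#' @param bounds Truncation bounds `c(min, max)`, nm.
#' @param sdlog Lognormal shape (log-sd); 0.4 is a realistic polydispersity
#'   for fragmented fibrils.
#' @param seed Integer seed (mandatory).
#' @param heights If TRUE, add a `height_nm` column drawn from
#'   N(`height_mean`, `height_sd`) truncated at 0.5 nm.
#' @param height_mean,height_sd Height distribution parameters, nm.
#' @return Data frame with `length_nm` (and `height_nm` if requested).
#' @export
#' @examples
#' x <- generate_afm_fixture(seed = 42)
#' mean(x$length_nm)  # ~395
generate_afm_fixture <- function(n = 2000, mean_nm = 395,
                                 bounds = c(80, 810), sdlog = 0.4,
                                 seed, heights = FALSE,
                                 height_mean = 4.0, height_sd = 1.0) {
  stopifnot(n >= 10, !missing(seed))
  if (bounds[1] >= bounds[2])
    stop("infeasible truncation: bounds[1] >= bounds[2]")
  ml <- truncated_lognormal_meanlog(mean_nm, bounds[1], bounds[2], sdlog)
  out <- withr_seed(seed, {
    x <- numeric(0)
    while (length(x) < n) {
      draw <- stats::rlnorm(2 * n, ml, sdlog)
      x <- c(x, draw[draw >= bounds[1] & draw <= bounds[2]])
    }
    lengths <- x[seq_len(n)]
    df <- data.frame(length_nm = lengths)
    if (heights) {
      h <- stats::rnorm(4 * n, height_mean, height_sd)
      df$height_nm <- h[h >= 0.5][seq_len(n)]
    }
    df
  })
  out
}

## Evaluate `expr` under a local RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic sedimentation-coefficient density
#'
#' A Weibull-shaped s density on a linear grid, mimicking the tailing
#' densities measured for stressed fibril samples, with optional seeded
#' Gaussian noise (a fraction of the peak height).
#'
#' @param shape,scale Weibull parameters (scale in S).
#' @param s_max Grid upper end, S; grid is 200 points from ~0 to `s_max`.
#' @param noise Noise standard deviation as a fraction of the peak density.
#' @param seed Integer seed (needed when `noise > 0`).
#' @return An extinction-weighted [weighted_distribution()] over s.
#' @export
generate_s_density_fixture <- function(shape = 2.2, scale = 35, s_max = 120,
                                       noise = 0, seed = NULL) {
  s <- seq(s_max / 200, s_max, length.out = 200)
  dens <- stats::dweibull(s, shape, scale)
  if (noise > 0) {
    stopifnot(!is.null(seed))
    dens <- withr_seed(seed,
      pmax(dens + stats::rnorm(length(s), 0, noise * max(dens)), 0))
  }
  weighted_distribution(s, dens, axis = "s", weighting = "extinction",
                        metadata = list(shape = shape, scale = scale))
}

#' Emit the three-species sweep configuration
#'
#' Writes (or returns) the exact published simulation setup: NAM at 4 S
#' (f/f0 1.26, density 1331.6 kg m^-3) plus fibril-like species at 50 S and
#' 100 S (f/f0 1.5, density 2 % above native), equal signal thirds; 30,000
#' rpm, 7200 s, meniscus 5.9 cm, bottom 7.2 cm, detector 6.9 cm, 10 S
#' analysis cutoff.
#'
#' @param path Optional YAML output path; if NULL, nothing is written.
#' @param n_particles Particles per species.
#' @param seed Integer seed stored in the configuration.
#' @return A list with `config`, `species`, `cutoff` (as
#'   [read_sweep_config()] returns), invisibly if written to a file.
#' @export
generate_sweep_fixture <- function(path = NULL, n_particles = 1e5, seed = 1) {
  config <- sweep_config(n_particles = n_particles, seed = seed)
  out <- list(config = config, species = nam_fibril_species(), cutoff = 10)
  if (!is.null(path)) {
    write_sweep_config(config, out$species, path, cutoff = 10)
    return(invisible(out))
  }
  out
}

#' Generate a synthetic comminution series
#'
#' Lengths following `l = a n^(-3b)` over the study's stressing grid (11-24
#' krpm, 5-90 s) with optional multiplicative lognormal noise.
#'
#' @param b Size-reduction exponent of the generator.
#' @param a Prefactor, nm.
#' @param rpm,seconds Vectors of stressing conditions; the default crosses
#'   the studied speeds and times.
#' @param noise_sd Multiplicative noise standard deviation (e.g. 0.05).
#' @param seed Integer seed (needed when `noise_sd > 0`).
#' @param statistic,source Tags passed to [comminution_series()].
#' @return A [comminution_series()].
#' @export
generate_comminution_fixture <- function(b = 0.33, a = 5e4,
                                         rpm = rep(c(11, 13, 16, 19, 22, 24) * 1000,
                                                   each = 4),
                                         seconds = rep(c(5, 30, 60, 90), 6),
                                         noise_sd = 0, seed = NULL,
                                         statistic = "mean", source = "AFM") {
  n <- rotations(rpm, seconds)
  l <- a * n^(-3 * b)
  if (noise_sd > 0) {
    stopifnot(!is.null(seed))
    l <- withr_seed(seed, l * exp(stats::rnorm(length(l), 0, noise_sd)))
  }
  comminution_series(rpm, seconds, l, statistic = statistic, source = source)
}
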