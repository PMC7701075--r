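# Brownian-dynamics gravitational-sweep simulator and the time -> s
# back-transformation.

test_that("diffusion coefficient matches the Stokes-Einstein closed form", {
  solv <- solvent_conditions(temperature = 20)  # 293.15 K
  # choose s so that the equivalent sphere is exactly 10 nm at f/f0 = 1
  rho <- 1.02 * 1331.6
  s10 <- (10e-9)^2 * (rho - solv$density) / (18 * solv$viscosity) / 1e-13
  D <- diffusion_from_s(s10, 1, rho, solv)
  D_oracle <- 1.380649e-23 * 293.15 / (3 * pi * solv$viscosity * 10e-9)
  expect_equal(D, D_oracle, tolerance = 1e-12)
  expect_equal(D, 4.2858e-11, tolerance = 1e-4)
  # doubling f/f0 halves D at fixed s? no: d_eq grows as sqrt(ffo), so
  # D falls by ffo^(3/2); at fixed d_eq, doubling ffo halves D
  expect_equal(diffusion_from_s(s10, 2, rho, solv) / D, 2^(-3 / 2),
               tolerance = 1e-12)
  expect_gt(diffusion_from_s(4, 1.26, 1331.6), 0)
})

test_that("time -> s transformation matches the closed form", {
  cfg <- sweep_config()
  expect_equal(s_from_time(1586.376, cfg), 100, tolerance = 1e-4)
  # inverse: 100 S front arrives at ln(6.9/5.9)/(w^2 1e-11)
  t100 <- log(6.9 / 5.9) / (cfg$omega^2 * 100e-13)
  expect_equal(t100, 1586.376, tolerance = 1e-4)
})

test_that("with D = 0 the front arrival equals the analytic time", {
  # narrow detector window: the test reads the *front position*, so the
  # window transit (width / front speed) must stay below the time step
  cfg <- sweep_config(n_particles = 1e5, seed = 2, duration_s = 2000,
                      dt_s = 1, record_every_s = 1, detector_bin_um = 50)
  tr <- simulate_sweep(cfg, species_spec(100), diffusion = FALSE)
  plateau <- exp(-2 * 100e-13 * cfg$omega^2 * tr$time)
  ratio <- tr$signal / plateau
  # linear interpolation of the half-crossing of the plateau-corrected front
  i <- which(ratio < 0.5)[1]
  t_half <- approx(ratio[c(i - 1, i)], tr$time[c(i - 1, i)], xout = 0.5)$y
  t_analytic <- log(6.9 / 5.9) / (cfg$omega^2 * 100e-13)
  expect_lt(abs(t_half - t_analytic), cfg$dt + 1e-9)
})

test_that("no drift and no diffusion freezes the trace", {
  cfg <- sweep_config(n_particles = 5000, seed = 4, duration_s = 50,
                      dt_s = 0.5, detector_bin_um = 2000)
  tr <- simulate_sweep(cfg, species_spec(1e-6), diffusion = FALSE)
  expect_true(all(abs(tr$signal - tr$signal[1]) < 1e-12))
})

test_that("a perfect step trace recovers a step cumulative distribution", {
  cfg <- sweep_config()
  t_star <- log(6.9 / 5.9) / (cfg$omega^2 * 60e-13)  # 60 S front
  time <- seq(0, 7200, by = 5)
  signal <- exp(-2 * 60e-13 * cfg$omega^2 * time) * (time < t_star)
  rec <- trace_to_s_distribution(list(time = time, signal = signal),
                                 config = cfg)
  expect_equal(sum(rec$mass), 1, tolerance = 1e-9)
  expect_equal(rec$s[which.max(rec$mass)], 60)
  expect_gt(max(rec$mass), 0.99)
  # cumulative is a step from 0 to 1 at 60 S
  expect_equal(rec$cumulative(59), 0, tolerance = 1e-6)
  expect_equal(rec$cumulative(61), 1, tolerance = 1e-6)
})

test_that("the naive drop reading misstates the cumulative by the dilution
          factor while the model recovery does not", {
  cfg <- sweep_config()
  time <- seq(0, 7200, by = 5)
  t_front <- function(s) log(6.9 / 5.9) / (cfg$omega^2 * s * 1e-13)
  signal <- (exp(-2 * 50e-13 * cfg$omega^2 * time) * (time < t_front(50)) +
             exp(-2 * 100e-13 * cfg$omega^2 * time) * (time < t_front(100))) / 2
  rec <- trace_to_s_distribution(list(time = time, signal = signal),
                                 config = cfg)
  expect_equal(rec$cumulative(75), 0.5, tolerance = 0.01)
  naive <- trace_to_s_distribution(list(time = time, signal = signal),
                                   config = cfg, method = "naive")
  # radial dilution inflates the naive mid-plateau reading by >> 1%
  expect_gt(abs(naive$cumulative(75) - 0.5), 0.05)
})

test_that("monotone bounded cumulative and total-weight invariants hold", {
  cfg <- sweep_config(n_particles = 2e4, seed = 6, duration_s = 3600)
  tr <- simulate_sweep(cfg, list(species_spec(60, abundance = 0.4),
                                 species_spec(120, abundance = 0.6)))
  rec <- trace_to_s_distribution(tr)
  s_eval <- seq(5, 300, by = 1)
  cum <- rec$cumulative(s_eval)
  expect_true(all(diff(cum) >= 0))
  expect_true(all(cum >= 0 & cum <= 1 + 1e-12))
  expect_equal(sum(rec$mass), 1, tolerance = 1e-12)
})

test_that("Monte-Carlo error of the trace shrinks as sqrt(n) over doublings", {
  # D = 0: deviations from the analytic trace stem purely from the finite
  # particle sample, so doubling n three times should shrink the sup error
  # by about sqrt(8)
  cfg0 <- sweep_config(duration_s = 1200, dt_s = 1, record_every_s = 2,
                       seed = 8)
  analytic <- NULL
  err <- vapply(c(4e3, 8e3, 16e3, 32e3), function(n) {
    cfg <- sweep_config(duration_s = 1200, dt_s = 1, record_every_s = 2,
                        seed = 8, n_particles = n)
    tr <- simulate_sweep(cfg, species_spec(100), diffusion = FALSE)
    plateau <- exp(-2 * 100e-13 * cfg$omega^2 * tr$time)
    keep <- tr$time < 1400
    max(abs((tr$signal - plateau)[keep]))
  }, numeric(1))
  expect_lt(err[4], err[1])
  expect_gt(err[1] / err[4], sqrt(8) / 2)   # allow MC spread around sqrt(8)
  expect_lt(err[1] / err[4], 2 * sqrt(8))
})

test_that("too-large time steps are refused with guidance", {
  cfg <- sweep_config(dt_s = 30)
  expect_error(simulate_sweep(cfg, species_spec(500)), "reduce dt_s")
})

test_that("identical seeds reproduce traces bit for bit", {
  cfg <- sweep_config(n_particles = 3000, seed = 12, duration_s = 600)
  t1 <- simulate_sweep(cfg, species_spec(80))
  t2 <- simulate_sweep(cfg, species_spec(80))
  expect_identical(t1$signal, t2$signal)
  cfg2 <- sweep_config(n_particles = 3000, seed = 13, duration_s = 600)
  expect_false(identical(simulate_sweep(cfg2, species_spec(80))$signal,
                         t1$signal))
})
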