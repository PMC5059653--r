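# fixed-step RK4 integration of steady and transient scenarios

adler_set <- function(b) tanh_param_set(b, 0, 0, 0, 0.05, 0, C = 1, Tbar = 0)

test_that("steady run with A = 0 matches the Adler rotation period", {
  cfg <- simulation_config(dt = 0.01, t_end = 200)
  traj <- simulate_steady(adler_set(1.25), 20, cfg)
  sp <- detect_spikes(traj)
  expect_gt(length(sp), 10)
  period <- 2 * pi / sqrt(1.25^2 - 1)
  expect_equal(mean(diff(as.numeric(sp))), period, tolerance = 1e-3)
})

test_that("steady run with A = 0, b < 1 locks at a fixed point (no spikes)", {
  cfg <- simulation_config(dt = 0.01, t_end = 200)
  traj <- simulate_steady(adler_set(0.9), 20, cfg)
  expect_length(detect_spikes(traj), 0)
  # the phase settles near the stable root of b + cos(theta) = 0
  expect_equal(tail(traj$theta, 1), acos(-0.9), tolerance = 1e-3)
})

test_that("compiled stepper agrees with a pure-R RK4 oracle", {
  pv <- eval_params(default_set, 25)
  cfg <- simulation_config(dt = 0.02, t_end = 40)
  traj <- simulate_steady(default_set, 25, cfg)
  th <- rk4_steady_oracle(pv$b, pv$A, pv$Omega, 0, 0.02, nrow(traj) - 1)
  expect_equal(traj$theta, th, tolerance = 1e-12)
})

test_that("trajectory bookkeeping: uniform grid, recorded F, stride", {
  cfg <- simulation_config(dt = 0.01, t_end = 50, record_stride = 5L)
  traj <- simulate_steady(default_set, 30, cfg)
  expect_equal(unique(round(diff(traj$t), 10)), 0.05)
  pv <- eval_params(default_set, 30)
  m <- modulation_terms(pv, traj$phi)
  expect_equal(traj$F, phase_velocity(m$f1, m$f2, traj$theta))
  expect_equal(traj$Teff, rep(30, nrow(traj)))
  # theta is continuous at converged dt: no jumps above pi per sample
  expect_lt(max(abs(diff(traj$theta))), pi)
})

test_that("mean spikes per burst is larger cold than warm (steady tanh)", {
  cold <- steady_burst_stats(default_set, 15)
  warm <- steady_burst_stats(default_set, 40)
  expect_gt(cold$mean_SB, warm$mean_SB)
})

test_that("transient run couples temperature and phase correctly", {
  spec <- make_transition(40, 15)
  a <- 0.002
  cfg <- simulation_config(dt = 0.01)
  traj <- simulate_transition(default_set, spec, a, cfg)
  # Teff along the trajectory matches the closed form (constant a)
  expect_lt(max(abs(traj$Teff - morse_teff(spec, a, traj$t))), 1e-4)
  # minimum is T0_eff at dt resolution
  expect_equal(min(traj$Teff), spec$T0_eff, tolerance = 1e-6)
  expect_equal(traj$t[which.min(traj$Teff)], transition_tbar(spec, a),
               tolerance = 1e-4)
  # integrated modulation phase is increasing and continuous
  expect_true(all(diff(traj$phi) > 0))
})

test_that("the transient onset burst dominates all later bursts", {
  spec <- make_transition(40, 15)
  traj <- simulate_transition(default_set, spec, 0.002,
                              simulation_config(dt = 0.01))
  sp <- detect_spikes(traj)
  bursts <- segment_bursts(sp, overlap_windows(traj))
  b <- bursts$bursts
  onset <- which(b$onset >= transition_tbar(spec, 0.002) - log(2) / 0.002)[1]
  expect_false(is.na(onset))
  later <- b$spike_count[-seq_len(onset)]
  expect_gt(length(later), 2)
  expect_true(all(b$spike_count[onset] > later))
  # ... and exceeds the steady spikes-per-burst at the final temperature
  expect_gt(b$spike_count[onset],
            steady_burst_stats(default_set, 15)$mean_SB)
})

test_that("step halving leaves spike counts unchanged and times stable", {
  spec <- make_transition(40, 15)
  cfg1 <- simulation_config(dt = 0.01, t_end = 1500)
  cfg2 <- simulation_config(dt = 0.005, t_end = 1500)
  s1 <- detect_spikes(simulate_transition(default_set, spec, 0.002, cfg1))
  s2 <- detect_spikes(simulate_transition(default_set, spec, 0.002, cfg2))
  expect_equal(length(s1), length(s2))
  expect_lt(max(abs(as.numeric(s1) - as.numeric(s2))), 0.05)

  t1 <- detect_spikes(simulate_steady(default_set, 25, cfg1))
  t2 <- detect_spikes(simulate_steady(default_set, 25, cfg2))
  expect_equal(length(t1), length(t2))
  expect_lt(max(abs(as.numeric(t1) - as.numeric(t2))), 0.05)
})

test_that("literal and integrated modulation phases differ in transients", {
  spec <- make_transition(40, 15)
  cfg_i <- simulation_config(dt = 0.02, t_end = 1000)
  cfg_l <- simulation_config(dt = 0.02, t_end = 1000,
                             phase_mode = "literal")
  ti <- simulate_transition(default_set, spec, 0.002, cfg_i)
  tl <- simulate_transition(default_set, spec, 0.002, cfg_l)
  expect_equal(tl$phi, eval_params(default_set, tl$Teff)$Omega * tl$t)
  expect_gt(max(abs(ti$phi - tl$phi)), 0.1)
  # both still track the same temperature path
  expect_equal(ti$Teff, tl$Teff, tolerance = 1e-10)
})

test_that("state-dependent width a(w) accelerates warm transitions", {
  fit <- default_width_fit()
  spec <- make_transition(40, 35)
  cfg <- simulation_config(dt = 0.02, t_end = 800)
  tw <- simulate_transition(default_set, spec, fit, cfg)
  tc <- simulate_transition(default_set, spec, 5e-4, cfg)
  # fitted width at 35 degC final state is ~0.015/ms, far faster than 5e-4
  expect_lt(abs(tail(tw$Teff, 1) - 35), abs(tail(tc$Teff, 1) - 35))
})

test_that("trajectories round-trip through TSV byte-identically", {
  cfg <- simulation_config(dt = 0.05, t_end = 30)
  traj <- simulate_steady(default_set, 30, cfg)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(traj, p1)
  write_trajectory(simulate_steady(default_set, 30, cfg), p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_trajectory(p1)
  expect_equal(back$theta, traj$theta, tolerance = 1e-6)
  expect_equal(names(back), c("t", "theta", "F", "phi", "w", "Teff"))
})

test_that("simulation configs are validated", {
  expect_error(simulation_config(dt = 0), "dt")
  expect_error(simulation_config(t_end = 0.005), "t_end")
  expect_error(simulation_config(phase_mode = "banana"))
  expect_error(simulate_steady(roper_set, 10), "t_end")  # Omega <= 0 there
})
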