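#' Simulation configuration
#'
#' Bundles the numerical settings of a fixed-step run.  The integrator is
#' the classical 4th-order Runge-Kutta scheme with no adaptivity, so that
#' spike timing is exactly reproducible.
#'
#' `phase_mode` decides how the modulation phase enters a *transient* run
#' where the modulation frequency `Omega(T_eff(t))` changes in time:
#'
#' * `"integrated"` (default): the modulation phase is a state variable,
#'   `dphi/dt = Omega(T_eff(t))`.  The instantaneous modulation is then
#'   continuous and free of spurious frequency transients.
#' * `"literal"`: the modulation argument is the product
#'   `Omega(T_eff(t)) * t`.
#'
#' Steady runs are unaffected (`phi = Omega * t` either way).
#'
#' @param dt integration step, ms; default 0.01.
#' @param t_end run duration, ms.  `NULL` (default) lets the simulators
#'   choose: six modulation periods for a steady run, and
#'   `max(5/a, 8 periods at Tf_eff)` for a transient run.
#' @param theta0 initial membrane-potential phase, radians; default 0.
#' @param phase_mode `"integrated"` or `"literal"`, see Details.
#' @param record_stride record every `record_stride`-th step; default 1.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(dt = 0.01, t_end = NULL, theta0 = 0,
                              phase_mode = c("integrated", "literal"),
                              record_stride = 1L) {
  phase_mode <- match.arg(phase_mode)
  stopifnot(is.numeric(dt), length(dt) == 1L, is.finite(dt), dt > 0,
            is.numeric(theta0), length(theta0) == 1L, is.finite(theta0),
            is.numeric(record_stride), record_stride >= 1)
  if (!is.null(t_end)) {
    stopifnot(is.numeric(t_end), length(t_end) == 1L, is.finite(t_end))
    if (t_end <= dt)
      stop("simulation_config: t_end must exceed dt", call. = FALSE)
  }
  structure(list(dt = dt, t_end = t_end, theta0 = theta0,
                 phase_mode = phase_mode,
                 record_stride = as.integer(record_stride)),
            class = "simulation_config")
}

new_trajectory <- function(mat, kind, cfg, Teff = NULL, spec = NULL,
                           pset = NULL) {
  df <- as.data.frame(mat)
  if (kind == "steady") {
    df$w <- NA_real_
    df$Teff <- Teff
  }
  df <- df[, c("t", "theta", "F", "phi", "w", "Teff")]
  structure(df,
            class = c("trajectory", "data.frame"),
            kind = kind, dt = cfg$dt,
            record_stride = cfg$record_stride,
            phase_mode = cfg$phase_mode,
            spec = spec, pset = pset)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory: %s> %d samples, t in [0, %.4g] ms, dt = %g ms (stride %d)\n",
    attr(x, "kind"), nrow(x), max(x$t), attr(x, "dt"),
    attr(x, "record_stride")))
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("...\n")
  invisible(x)
}

#' Simulate the phase model at a steady temperature
#'
#' Integrates `dtheta/dt = f1(t) + f2(t) cos(theta)` with parameters
#' frozen at `eval_params(pset, Teff)` and modulation phase
#' `phi = Omega * t`.  The run starts at the quiescent point of the
#' modulation cycle (`phi = 0`, where `f1` is minimal).
#'
#' @param pset a `tanh_param_set` or `linear_param_set`.
#' @param Teff steady effective temperature, degC.
#' @param cfg a [simulation_config()]; when `cfg$t_end` is `NULL` the run
#'   lasts six modulation periods `6 * 2*pi/Omega` (an explicit `t_end`
#'   is required if `Omega <= 0`).
#' @return A `trajectory`: a data frame with columns `t` (ms), `theta`
#'   (radians, unwrapped), `F` (ms^-1), `phi` (radians), `w` (NA for
#'   steady runs) and `Teff` (degC).
#' @examples
#' traj <- simulate_steady(default_tanh_params(), 35,
#'                         simulation_config(t_end = 500))
#' @export
simulate_steady <- function(pset, Teff, cfg = simulation_config()) {
  stopifnot(inherits(pset, "param_set"), inherits(cfg, "simulation_config"))
  pv <- eval_params(pset, Teff)
  t_end <- cfg$t_end
  if (is.null(t_end)) {
    if (pv$Omega <= 0)
      stop("simulate_steady: Omega <= 0 at this temperature; ",
           "supply an explicit t_end", call. = FALSE)
    t_end <- 6 * 2 * pi / pv$Omega
  }
  nstep <- max(1L, as.integer(ceiling(t_end / cfg$dt)))
  mat <- .rk4_steady(pv$b, pv$A, pv$Omega, cfg$theta0, cfg$dt, nstep,
                     cfg$record_stride)
  new_trajectory(mat, "steady", cfg, Teff = Teff, pset = pset)
}

#' Simulate a high-to-low temperature transition
#'
#' Jointly integrates the phase `theta`, the half-width state `w`
#' (carrying `T_eff = T0_eff + w^2`) and, in `"integrated"` mode, the
#' modulation phase `phi`.  The drift parameters are re-evaluated from
#' the tanh forms at `T_eff(t)` every sub-step.  The run starts on the
#' *negative* branch, `w(0) = -sqrt(Ti_eff - T0_eff)`, which is what
#' produces the undershoot of the effective temperature.
#'
#' @param pset a `tanh_param_set` (the transient model is defined for the
#'   saturating forms).
#' @param spec a [make_transition()] object.
#' @param a either a positive constant width parameter (ms^-1) or a
#'   [width_fit()] for the state-dependent width `a(w)`.
#' @param cfg a [simulation_config()]; when `cfg$t_end` is `NULL` the run
#'   lasts `max(5/a_ref, 8 * 2*pi/Omega(Tf_eff))` ms, `a_ref` being the
#'   constant `a` or the fitted width at the final state.
#' @return A `trajectory` with columns `t`, `theta`, `F`, `phi`, `w`,
#'   `Teff`.
#' @examples
#' traj <- simulate_transition(default_tanh_params(), make_transition(40, 15),
#'                             a = 0.002,
#'                             simulation_config(dt = 0.05, t_end = 1000))
#' @export
simulate_transition <- function(pset, spec, a, cfg = simulation_config()) {
  stopifnot(inherits(pset, "tanh_param_set"),
            inherits(spec, "transition_spec"),
            inherits(cfg, "simulation_config"))
  const_a <- !inherits(a, "width_fit")
  if (const_a)
    stopifnot(is.numeric(a), length(a) == 1L, is.finite(a), a > 0)
  a_ref <- if (const_a) a else width_function(a, sqrt(spec$D), spec)
  t_end <- cfg$t_end
  if (is.null(t_end)) {
    Om_f <- eval_params(pset, spec$Tf_eff)$Omega
    t_end <- max(5 / a_ref, 8 * 2 * pi / Om_f)
  }
  nstep <- max(1L, as.integer(ceiling(t_end / cfg$dt)))
  w0 <- -sqrt(spec$Ti_eff - spec$T0_eff)
  mat <- .rk4_transition(unclass(pset), spec$D, spec$T0_eff,
                         const_a,
                         if (const_a) a else 0,
                         if (const_a) 0 else a$a0,
                         if (const_a) 0 else a$alpha,
                         cfg$theta0, w0, 0,
                         cfg$dt, nstep, cfg$record_stride,
                         cfg$phase_mode == "literal")
  spec$tbar <- transition_tbar(spec, a_ref)
  new_trajectory(mat, "transition", cfg, spec = spec, pset = pset)
}

#' Write or read a trajectory as TSV
#'
#' Columns `t_ms, theta_rad, F_per_ms, phi_rad, w_sqrtC, Teff_C`, written
#' with fixed six-decimal formatting so repeated runs produce
#' byte-identical files.
#'
#' @param traj a `trajectory`.
#' @param path output file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a data frame with the same columns named
#'   as in the trajectory object.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v))
  lines <- c(paste(c("t_ms", "theta_rad", "F_per_ms", "phi_rad",
                     "w_sqrtC", "Teff_C"), collapse = "\t"),
             paste(fmt(traj$t), fmt(traj$theta), fmt(traj$F),
                   fmt(traj$phi), fmt(traj$w), fmt(traj$Teff),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  names(df) <- c("t", "theta", "F", "phi", "w", "Teff")
  df
}
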