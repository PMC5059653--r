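#' Calibrate the saturating forms against the linear forms
#'
#' Determines the tanh constants so that the saturating forms agree with
#' the linear forms at the two endpoint temperatures.  For `b` and `A`
#' the exact 2x2 linear system in `(b0, b1)` / `(A0, A1)` is solved, so
#' the agreement at both endpoints is exact by construction.  For the
#' frequency the additional saturation condition `Omega -> 0` as
#' `T_eff -> -Inf` forces `Omega0 = Omega1`; the single remaining degree
#' of freedom is anchored at the high endpoint (the high-temperature
#' regime drives the beating/skipping behaviour), and the resulting
#' mismatch at the low endpoint is reported as a residual.
#'
#' @param linear a [linear_param_set()].
#' @param T_low,T_high endpoint temperatures, degC, `T_low < T_high`.
#' @param C sigmoid steepness, 1/degC (> 0); default 0.055.
#' @param Tbar sigmoid centre, degC; default 33.75.
#' @return An object of class `calibration_report`: list with `pset`
#'   (the fitted `tanh_param_set`) and `residuals` (named rates, ms^-1:
#'   endpoint mismatches, zero for `b` and `A`, the `T_low` mismatch for
#'   `Omega`).
#' @examples
#' calibrate_tanh_endpoints(roper_linear_params(), 15, 40)
#' @export
calibrate_tanh_endpoints <- function(linear, T_low, T_high,
                                     C = 0.055, Tbar = 33.75) {
  stopifnot(inherits(linear, "linear_param_set"),
            is.numeric(T_low), is.numeric(T_high), T_low < T_high,
            is.numeric(C), C > 0, is.numeric(Tbar))
  h_lo <- tanh(C * (T_low - Tbar))
  h_hi <- tanh(C * (T_high - Tbar))
  if (isTRUE(all.equal(h_lo, h_hi)))
    stop("calibrate_tanh_endpoints: endpoints give equal tanh values; ",
         "the 2x2 system is singular", call. = FALSE)
  lo <- eval_params(linear, T_low)
  hi <- eval_params(linear, T_high)
  # b = b0 - b1 * h : minus sign convention
  b1 <- (lo$b - hi$b) / (h_hi - h_lo)
  b0 <- lo$b + b1 * h_lo
  # A = A0 + A1 * h
  A1 <- (hi$A - lo$A) / (h_hi - h_lo)
  A0 <- lo$A - A1 * h_lo
  # Omega = Omega0 * (1 + h), anchored at T_high
  Om0 <- hi$Omega / (1 + h_hi)
  pset <- tanh_param_set(b0, b1, A0, A1, Om0, Om0, C, Tbar)
  fit_lo <- eval_params(pset, T_low)
  fit_hi <- eval_params(pset, T_high)
  residuals <- c(b_low = fit_lo$b - lo$b, b_high = fit_hi$b - hi$b,
                 A_low = fit_lo$A - lo$A, A_high = fit_hi$A - hi$A,
                 Omega_low = fit_lo$Omega - lo$Omega,
                 Omega_high = fit_hi$Omega - hi$Omega)
  structure(list(pset = pset, residuals = residuals,
                 T_low = T_low, T_high = T_high),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> endpoints %.4g / %.4g degC\n",
              x$T_low, x$T_high))
  print(x$pset)
  cat("endpoint residuals (ms^-1):\n")
  print(signif(x$residuals, 4))
  invisible(x)
}

# Mismatch between the centre of the matching overlap window and the
# time of the effective-temperature minimum, for a constant-a transient.
# The modulation phase is the integral of Omega(T_eff(t)) (trapezoid on
# a fine grid; no theta integration is needed because f1, f2 depend on
# time only).  The matching window is the first f1 > f2 window opening
# after T_eff has fallen below Tf_eff, i.e. the onset burst of the
# transient response; earlier windows belong to the residual
# high-temperature regime.
matching_mismatch <- function(a, pset, spec, dt = 0.1) {
  tbar <- transition_tbar(spec, a)
  t_below <- tbar - log(2) / a          # T_eff first drops below Tf_eff
  Om_min <- eval_params(pset, spec$T0_eff)$Omega
  t_end <- tbar + 3 * 2 * pi / Om_min
  t <- seq(0, t_end, by = dt)
  Te <- morse_teff(spec, a, t)
  pv <- eval_params(pset, Te)
  dphi <- (pv$Omega[-1] + pv$Omega[-length(t)]) / 2 * dt
  phi <- cumsum(c(0, dphi))
  g <- pv$b - 1 - 2 * pv$A * cos(phi)
  r <- rle(g > 0)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  iw <- which(r$values)
  if (!length(iw)) return(NA_real_)
  ws <- t[starts_i[iw]]
  we <- t[ends_i[iw]]
  k <- which(ws >= t_below)
  if (!length(k)) return(NA_real_)
  (ws[k[1]] + we[k[1]]) / 2 - tbar
}

#' Bisection search for the relaxation width parameter
#'
#' Finds the width parameter `a` of the constant-width transient at
#' which the onset burst of the response (the first `f1 > f2` overlap
#' window after the effective temperature has fallen below `Tf_eff`)
#' is centred on the time of the temperature minimum `tbar`.  The
#' mismatch (window centre minus `tbar`, ms) has in general several
#' sign-change roots because the burst grid is quantised by modulation
#' cycles; the search scans a log-spaced grid over `bounds`, refines
#' every bracketing pair by bisection, and returns the largest root --
#' the first-cycle alignment (smaller roots align the minimum with later
#' modulation cycles).
#'
#' @param pset a `tanh_param_set`.
#' @param spec a [make_transition()] object.
#' @param bounds length-2 numeric search interval for `a`, ms^-1;
#'   default `c(1e-5, 0.1)`.
#' @param tol convergence tolerance on the mismatch, ms; default 1.
#' @param n_scan grid points of the bracketing scan; default 40.
#' @param dt grid spacing used to evaluate the mismatch, ms; default 0.1.
#' @return An object of class `match_result`: list with `a` (ms^-1),
#'   `residual` (ms), `iterations` and `converged`.  When no bracketing
#'   sign change exists within `bounds`, `converged` is `FALSE` and `a` /
#'   `residual` report the grid point with the smallest mismatch.
#' @examples
#' \donttest{
#' find_matching_a(default_tanh_params(), make_transition(40, 15))
#' }
#' @export
find_matching_a <- function(pset, spec, bounds = c(1e-5, 0.1), tol = 1,
                            n_scan = 40L, dt = 0.1) {
  stopifnot(inherits(pset, "tanh_param_set"),
            inherits(spec, "transition_spec"),
            is.numeric(bounds), length(bounds) == 2L,
            all(bounds > 0), bounds[1] < bounds[2],
            is.numeric(tol), tol > 0)
  grid <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = n_scan))
  mm <- vapply(grid, matching_mismatch, numeric(1),
               pset = pset, spec = spec, dt = dt)
  iterations <- length(grid)
  ok <- !is.na(mm)
  sgn <- sign(mm)
  brackets <- which(ok[-length(ok)] & ok[-1] &
                    sgn[-length(sgn)] * sgn[-1] < 0)
  if (!length(brackets)) {
    if (!any(ok))
      return(structure(list(a = NA_real_, residual = NA_real_,
                            iterations = iterations, converged = FALSE),
                       class = "match_result"))
    best <- which.min(abs(mm))
    return(structure(list(a = grid[best], residual = mm[best],
                          iterations = iterations,
                          converged = abs(mm[best]) <= tol),
                     class = "match_result"))
  }
  i <- brackets[length(brackets)]       # largest-a bracket
  lo <- grid[i]; hi <- grid[i + 1]
  flo <- mm[i]
  a_best <- grid[i]; f_best <- flo
  for (iter in seq_len(60L)) {
    mid <- sqrt(lo * hi)
    fm <- matching_mismatch(mid, pset, spec, dt = dt)
    iterations <- iterations + 1L
    if (!is.na(fm) && abs(fm) < abs(f_best)) {
      a_best <- mid; f_best <- fm
    }
    if (is.na(fm) || abs(fm) <= tol) break
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  structure(list(a = a_best, residual = f_best, iterations = iterations,
                 converged = is.finite(f_best) && abs(f_best) <= tol),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> a = %.6g ms^-1  residual = %.3g ms  (%d evals, %s)\n",
    x$a, x$residual, x$iterations,
    if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit the exponential width function to matched transitions
#'
#' Least-squares fit of `log(a)` against the final-state abscissa
#' `w^2 + T0_eff = Tf_eff`, giving the exponential law
#' `a(w) = a0 * exp(alpha * (w^2 + T0_eff))`.
#'
#' @param samples either a data frame with columns `Tf_eff` and `a`, or a
#'   list of `list(spec = <transition_spec>, a = <rate>)` pairs (e.g.
#'   collected from [find_matching_a()] runs).  At least two samples with
#'   distinct `Tf_eff` are required.
#' @return A [width_fit()] with attribute `residuals` (log-scale fit
#'   residuals).
#' @examples
#' fit_width_function(data.frame(Tf_eff = c(15, 35),
#'                               a = 0.002 * exp(c(0, 2))))
#' @export
fit_width_function <- function(samples) {
  if (is.data.frame(samples)) {
    stopifnot(all(c("Tf_eff", "a") %in% names(samples)))
    x <- samples$Tf_eff
    a <- samples$a
  } else if (is.list(samples)) {
    x <- vapply(samples, function(s) s$spec$Tf_eff, numeric(1))
    a <- vapply(samples, function(s) s$a, numeric(1))
  } else {
    stop("fit_width_function: unsupported samples format", call. = FALSE)
  }
  if (length(x) < 2L || length(unique(x)) < 2L)
    stop("fit_width_function: need at least two distinct abscissae",
         call. = FALSE)
  if (any(!is.finite(a)) || any(a <= 0))
    stop("fit_width_function: width parameters must be positive",
         call. = FALSE)
  co <- stats::lm.fit(cbind(1, x), log(a))
  fit <- width_fit(a0 = exp(co$coefficients[[1]]),
                   alpha = co$coefficients[[2]])
  attr(fit, "residuals") <- as.numeric(co$residuals)
  fit
}

#' Serialise calibration results to key-value configs
#'
#' `write_calibration_report()` writes the fitted parameter set (plus
#' residuals as comments); `write_match_result()` writes the matched
#' width parameter.  Both formats round-trip through
#' [read_param_config()] / [read_keyvals] conventions.
#'
#' @param x the object to write.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(x, path) {
  stopifnot(inherits(x, "calibration_report"))
  res <- sprintf("# residual %s = %.6g", names(x$residuals), x$residuals)
  pset <- x$pset
  keys <- names(unclass(pset))
  lines <- c(res, vapply(keys, function(k)
    sprintf("%s = %s", k, format_config_number(pset[[k]])), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_calibration_report
#' @export
write_match_result <- function(x, path) {
  stopifnot(inherits(x, "match_result"))
  writeLines(c(sprintf("a = %.10g", x$a),
               sprintf("residual = %.10g", x$residual),
               sprintf("iterations = %d", x$iterations),
               sprintf("converged = %s", tolower(isTRUE(x$converged)))),
             path)
  invisible(path)
}
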