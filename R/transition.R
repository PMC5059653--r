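#' Specify a high-to-low effective-temperature transition
#'
#' During a sudden cooling step the effective temperature does not move
#' monotonically from `Ti_eff` to `Tf_eff`: it follows a Morse-like time
#' course that undershoots to a minimum `T0_eff` before relaxing up to
#' `Tf_eff`.  The well depth is fixed to `D = (Ti_eff - Tf_eff)/4` and the
#' minimum to `T0_eff = (5*Tf_eff - Ti_eff)/4`, so that `D + T0_eff =
#' Tf_eff` exactly.  Both can be overridden when a different undershoot is
#' wanted, subject to `D > 0`, `D + T0_eff = Tf_eff` and
#' `T0_eff < Tf_eff < Ti_eff`.
#'
#' @param Ti_eff initial effective temperature (degC).
#' @param Tf_eff final effective temperature (degC); must be `< Ti_eff`
#'   (the model describes high-to-low transitions only).
#' @param D optional override of the well depth (degC).
#' @param T0_eff optional override of the undershoot minimum (degC).  If
#'   only one of `D`, `T0_eff` is given the other is derived from
#'   `D + T0_eff = Tf_eff`.
#' @return An object of class `transition_spec` with fields `Ti_eff`,
#'   `Tf_eff`, `D`, `T0_eff` and (once a width parameter is known, see
#'   [transition_tbar()]) the minimum time `tbar`.
#' @examples
#' make_transition(40, 15)  # D = 6.25, T0_eff = 8.75
#' @export
make_transition <- function(Ti_eff, Tf_eff, D = NULL, T0_eff = NULL) {
  stopifnot(is.numeric(Ti_eff), is.numeric(Tf_eff),
            length(Ti_eff) == 1L, length(Tf_eff) == 1L,
            is.finite(Ti_eff), is.finite(Tf_eff))
  if (Tf_eff >= Ti_eff)
    stop("make_transition: need Tf_eff < Ti_eff (high-to-low transition)",
         call. = FALSE)
  if (is.null(D) && is.null(T0_eff)) {
    D <- (Ti_eff - Tf_eff) / 4
    T0_eff <- (5 * Tf_eff - Ti_eff) / 4
  } else if (is.null(T0_eff)) {
    T0_eff <- Tf_eff - D
  } else if (is.null(D)) {
    D <- Tf_eff - T0_eff
  }
  if (!isTRUE(all.equal(D + T0_eff, Tf_eff)))
    stop("make_transition: overrides must satisfy D + T0_eff = Tf_eff",
         call. = FALSE)
  if (D <= 0 || T0_eff >= Tf_eff)
    stop("make_transition: need D > 0 and T0_eff < Tf_eff", call. = FALSE)
  structure(list(Ti_eff = Ti_eff, Tf_eff = Tf_eff, D = D, T0_eff = T0_eff,
                 tbar = NA_real_),
            class = "transition_spec")
}

#' @export
print.transition_spec <- function(x, ...) {
  cat(sprintf(
    "<transition_spec> %.4g -> %.4g degC  (D = %.4g, T0_eff = %.4g%s)\n",
    x$Ti_eff, x$Tf_eff, x$D, x$T0_eff,
    if (is.finite(x$tbar)) sprintf(", tbar = %.4g ms", x$tbar) else ""))
  invisible(x)
}

#' Time of the effective-temperature minimum
#'
#' The Morse-like curve is anchored by the initial condition
#' `T_eff(0) = Ti_eff`, which forces
#' `tbar = log(1 + sqrt((Ti_eff - T0_eff)/D)) / a`
#' (equal to `log(1 + sqrt(5))/a` for the default depth).  `tbar` is the
#' time at which `T_eff` reaches its minimum `T0_eff`.
#'
#' @param spec a [make_transition()] object.
#' @param a width (inverse-time) parameter of the relaxation, ms^-1.
#' @return `tbar` in ms.
#' @export
transition_tbar <- function(spec, a) {
  stopifnot(inherits(spec, "transition_spec"), is.numeric(a), a > 0)
  log(1 + sqrt((spec$Ti_eff - spec$T0_eff) / spec$D)) / a
}

#' Morse-like effective-temperature time course
#'
#' Closed-form evaluation of
#' `T_eff(t) = D*(1 - exp(-a*(t - tbar)))^2 + T0_eff`,
#' with `tbar` fixed by `T_eff(0) = Ti_eff` (see [transition_tbar()]).
#' The curve starts at `Ti_eff`, dips to `T0_eff` at `t = tbar` and
#' relaxes towards `Tf_eff = D + T0_eff` from below.
#'
#' @inheritParams transition_tbar
#' @param t time(s), ms (vectorised).
#' @return Effective temperature(s), degC.
#' @export
morse_teff <- function(spec, a, t) {
  tbar <- transition_tbar(spec, a)
  spec$D * (1 - exp(-a * (t - tbar)))^2 + spec$T0_eff
}

#' Half-width variable and its dynamics
#'
#' The substitution `w^2 = T_eff - T0_eff` converts the Morse-like curve
#' into the first-order relaxation `dw/dt = a*(sqrt(D) - w)`.  Solving the
#' ODE from the *negative* root `w(0) = -sqrt(Ti_eff - T0_eff)` reproduces
#' the undershoot; the positive root would relax monotonically and skip
#' it.  When the width parameter is itself state dependent
#' (`a = a(w)`, see [width_function()]) the same right-hand side applies
#' with `a` evaluated at `w`.
#'
#' @param w half-width state, degC^(1/2) (vectorised).
#' @param spec a [make_transition()] object.
#' @param a either a positive constant rate (ms^-1) or a [width_fit()]
#'   object for the state-dependent width.
#' @return `width_rhs()`: dw/dt in degC^(1/2)/ms.  `teff_from_w()`: the
#'   effective temperature `T0_eff + w^2` in degC.
#' @export
width_rhs <- function(w, spec, a) {
  stopifnot(inherits(spec, "transition_spec"), is.numeric(w))
  rate <- if (inherits(a, "width_fit")) width_function(a, w, spec) else {
    stopifnot(is.numeric(a), length(a) == 1L, a > 0)
    a
  }
  rate * (sqrt(spec$D) - w)
}

#' @rdname width_rhs
#' @export
teff_from_w <- function(w, spec) {
  stopifnot(inherits(spec, "transition_spec"), is.numeric(w))
  spec$T0_eff + w^2
}

#' Exponential width function of the relaxation
#'
#' Across different cooling steps the matched width parameter grows
#' roughly exponentially with the final temperature.  The fitted law is
#' `a(w) = a0 * exp(alpha * (w^2 + T0_eff))`, i.e. `a0 * exp(alpha *
#' T_eff)` with `T_eff` recovered through [teff_from_w()].  Defaults
#' `a0 = 4.5e-4 ms^-1`, `alpha = 0.1/degC`.
#'
#' @param a0 prefactor, ms^-1; must be positive.
#' @param alpha temperature sensitivity, 1/degC.
#' @return `width_fit()` returns an object of class `width_fit`;
#'   `width_function()` evaluates it (ms^-1).
#' @examples
#' width_function(default_width_fit(), 0, make_transition(40, 15))
#' @export
width_fit <- function(a0, alpha) {
  stopifnot(is.numeric(a0), is.numeric(alpha),
            length(a0) == 1L, length(alpha) == 1L,
            is.finite(a0), is.finite(alpha))
  if (a0 <= 0) stop("width_fit: a0 must be positive", call. = FALSE)
  structure(list(a0 = a0, alpha = alpha), class = "width_fit")
}

#' @rdname width_fit
#' @export
default_width_fit <- function() width_fit(a0 = 4.5e-4, alpha = 0.1)

#' @rdname width_fit
#' @param fit a `width_fit` object.
#' @param w half-width state(s), degC^(1/2).
#' @param spec a [make_transition()] object supplying `T0_eff`.
#' @export
width_function <- function(fit, w, spec) {
  stopifnot(inherits(fit, "width_fit"), inherits(spec, "transition_spec"),
            is.numeric(w))
  fit$a0 * exp(fit$alpha * (w^2 + spec$T0_eff))
}

#' @export
print.width_fit <- function(x, ...) {
  cat(sprintf("<width_fit> a0 = %.4g ms^-1, alpha = %.4g /degC\n",
              x$a0, x$alpha))
  invisible(x)
}

#' Read a transition specification from a key-value config
#'
#' Recognised keys: `Ti_eff`, `Tf_eff` (required) and optional `D`,
#' `T0_eff` overrides, same semantics as [make_transition()].
#'
#' @param path file path.
#' @return A `transition_spec`.
#' @export
read_transition_config <- function(path) {
  kv <- read_keyvals(path)
  if (!all(c("Ti_eff", "Tf_eff") %in% names(kv)))
    stop("transition config needs keys Ti_eff and Tf_eff", call. = FALSE)
  num <- lapply(kv, parse_config_number)
  make_transition(num$Ti_eff, num$Tf_eff,
                  D = num$D, T0_eff = num$T0_eff)
}
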