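#' Modulation terms of the phase equation
#'
#' The phase model splits the drive into a slow modulation pair
#' `f1 = b - A*cos(phi)` and `f2 = 1 + A*cos(phi)`, where `phi` is the
#' modulation phase (radians; `Omega*t` in a steady run).  A burst is in
#' progress whenever `f1 > f2`.  The identity `f1 + f2 = 1 + b` holds for
#' every phase.
#'
#' @param pv a `param_values` object from [eval_params()], or a list with
#'   numeric `b` and `A`.
#' @param phi modulation phase, radians (vectorised; recycled against the
#'   parameter values).
#' @return A list with components `f1` and `f2` (ms^-1).
#' @examples
#' pv <- eval_params(default_tanh_params(), 35)
#' modulation_terms(pv, pi / 2)  # f1 = b, f2 = 1
#' @export
modulation_terms <- function(pv, phi) {
  stopifnot(is.numeric(pv$b), is.numeric(pv$A), is.numeric(phi))
  cp <- cos(phi)
  list(f1 = pv$b - pv$A * cp, f2 = 1 + pv$A * cp)
}

#' Phase velocity of the oscillator
#'
#' The right-hand side of the phase equation,
#' `dtheta/dt = F(t, theta) = f1 + f2*cos(theta)`.
#' One full 2*pi rotation of `theta` is one action potential.  When
#' `f2 >= |f1|` the flow has fixed points at
#' `theta = +/- acos(-f1/f2)` and the oscillator is excitable rather than
#' spiking.
#'
#' @param f1,f2 modulation terms (ms^-1), e.g. from [modulation_terms()].
#' @param theta membrane-potential phase, radians (vectorised).
#' @return The phase velocity `F` in ms^-1.
#' @export
phase_velocity <- function(f1, f2, theta) {
  stopifnot(is.numeric(f1), is.numeric(f2), is.numeric(theta))
  f1 + f2 * cos(theta)
}
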