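#' Temperature-dependent parameter sets for the cold-receptor phase model
#'
#' The phase model drifts with three rate parameters: the mean-drive `b`,
#' the modulation amplitude `A` and the modulation frequency `Omega`
#' (all in ms^-1).  Two functional forms map effective temperature (degC)
#' to these rates:
#'
#' * the classical *linear* form, `b = b0 - b1*T`, `A = A0 + A1*T`,
#'   `Omega = Omega0 + Omega1*T`, which is unbounded and therefore
#'   unrealistic at temperature extremes;
#' * the saturating *tanh* form,
#'   `b = b0 - b1*tanh(C*(Teff - Tbar))` (and analogously `A`, `Omega`
#'   with `+` signs), which plateaus at both ends of the temperature axis.
#'
#' `tanh_param_set()` and `linear_param_set()` construct validated sets;
#' [eval_params()] evaluates either at a temperature.
#'
#' @param b0,b1,A0,A1,Omega0,Omega1 numeric rates (ms^-1).  For the linear
#'   form the `*1` entries carry units ms^-1/degC.
#' @param C inverse temperature scale (1/degC), must be positive
#'   (tanh form only).
#' @param Tbar centre temperature of the sigmoid (degC, tanh form only).
#' @return An object of class `tanh_param_set` or `linear_param_set`.
#' @examples
#' ps <- default_tanh_params()
#' eval_params(ps, 15)
#' @export
tanh_param_set <- function(b0, b1, A0, A1, Omega0, Omega1, C, Tbar) {
  x <- list(b0 = b0, b1 = b1, A0 = A0, A1 = A1,
            Omega0 = Omega0, Omega1 = Omega1, C = C, Tbar = Tbar)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("tanh_param_set: field '", nm, "' must be a finite scalar",
           call. = FALSE)
  }
  if (x$C <= 0)
    stop("tanh_param_set: C must be positive", call. = FALSE)
  if (x$A0 - x$A1 < 0)
    stop("tanh_param_set: need A0 - A1 >= 0 so that A stays non-negative ",
         "over all temperatures", call. = FALSE)
  if (x$Omega0 - x$Omega1 < 0)
    stop("tanh_param_set: need Omega0 - Omega1 >= 0 so that Omega stays ",
         "non-negative over all temperatures", call. = FALSE)
  structure(x, class = c("tanh_param_set", "param_set"))
}

#' @rdname tanh_param_set
#' @export
linear_param_set <- function(b0, b1, A0, A1, Omega0, Omega1) {
  x <- list(b0 = b0, b1 = b1, A0 = A0, A1 = A1,
            Omega0 = Omega0, Omega1 = Omega1)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("linear_param_set: field '", nm, "' must be a finite scalar",
           call. = FALSE)
  }
  structure(x, class = c("linear_param_set", "param_set"))
}

#' Default saturating (tanh) parameter set
#'
#' The calibrated sigmoidal set: `b0 = 0.4475`, `b1 = 0.1575`,
#' `A0 = 0.3325`, `A1 = 0.0225`, `Omega0 = Omega1 = 3*pi/200` (all ms^-1),
#' `C = 0.055/degC`, `Tbar = 33.75 degC`.  With `Omega0 = Omega1` the
#' modulation frequency vanishes in the deep-cold limit.
#'
#' @return A `tanh_param_set`.
#' @export
default_tanh_params <- function() {
  tanh_param_set(b0 = 0.4475, b1 = 0.1575,
                 A0 = 0.3325, A1 = 0.0225,
                 Omega0 = 3 * pi / 200, Omega1 = 3 * pi / 200,
                 C = 0.055, Tbar = 33.75)
}

#' Classical linear parameter set
#'
#' The original linear temperature dependence: `b0 = 0.675`,
#' `b1 = 0.007`, `A0 = 0.3`, `A1 = 0.001`, `Omega0 = -pi/150`,
#' `Omega1 = pi/1500` (rates in ms^-1, slopes per degC).
#'
#' @return A `linear_param_set`.
#' @export
roper_linear_params <- function() {
  linear_param_set(b0 = 0.675, b1 = 0.007,
                   A0 = 0.3, A1 = 0.001,
                   Omega0 = -pi / 150, Omega1 = pi / 1500)
}

#' Evaluate a parameter set at a temperature
#'
#' Returns the instantaneous phase-model rates at effective temperature
#' `Teff`.  For the tanh form,
#' `b = b0 - b1*tanh(C*(Teff - Tbar))`,
#' `A = A0 + A1*tanh(C*(Teff - Tbar))`,
#' `Omega = Omega0 + Omega1*tanh(C*(Teff - Tbar))`;
#' for the linear form the straight-line expressions are used with no
#' clamping.  `Teff` may be a vector.
#'
#' @param pset a `tanh_param_set` or `linear_param_set`.
#' @param Teff effective temperature(s), degC; must be finite.
#' @return A list of class `param_values` with components `b`, `A`,
#'   `Omega` (ms^-1) and `Teff` (degC), each the length of `Teff`.
#' @examples
#' eval_params(default_tanh_params(), 33.75)  # returns the offsets
#' @export
eval_params <- function(pset, Teff) UseMethod("eval_params")

#' @export
eval_params.tanh_param_set <- function(pset, Teff) {
  if (!is.numeric(Teff) || length(Teff) < 1L || any(!is.finite(Teff)))
    stop("eval_params: Teff must be finite numeric (degC)", call. = FALSE)
  s <- tanh(pset$C * (Teff - pset$Tbar))
  new_param_values(b = pset$b0 - pset$b1 * s,
                   A = pset$A0 + pset$A1 * s,
                   Omega = pset$Omega0 + pset$Omega1 * s,
                   Teff = Teff)
}

#' @export
eval_params.linear_param_set <- function(pset, Teff) {
  if (!is.numeric(Teff) || length(Teff) < 1L || any(!is.finite(Teff)))
    stop("eval_params: Teff must be finite numeric (degC)", call. = FALSE)
  new_param_values(b = pset$b0 - pset$b1 * Teff,
                   A = pset$A0 + pset$A1 * Teff,
                   Omega = pset$Omega0 + pset$Omega1 * Teff,
                   Teff = Teff)
}

new_param_values <- function(b, A, Omega, Teff) {
  structure(list(b = b, A = A, Omega = Omega, Teff = Teff),
            class = "param_values")
}

#' @export
print.param_set <- function(x, ...) {
  kind <- if (inherits(x, "tanh_param_set")) "saturating (tanh)" else "linear"
  cat(sprintf("<%s parameter set>\n", kind))
  for (nm in names(x))
    cat(sprintf("  %-7s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.param_values <- function(x, ...) {
  cat("<param_values>\n")
  df <- data.frame(Teff = x$Teff, b = x$b, A = x$A, Omega = x$Omega)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.param_values <- function(x, ...) {
  data.frame(Teff = x$Teff, b = x$b, A = x$A, Omega = x$Omega)
}

# ---- plain-text key-value serialisation --------------------------------

# Values in config files may be decimal ("0.4475") or small pi-rational
# expressions ("3*pi/200", "-pi/150", "pi/60", "2*pi").  Parsed with a
# regex, never eval(), so config files stay data.
parse_config_number <- function(s) {
  s <- gsub("[[:space:]]", "", s)
  if (grepl("pi", s, fixed = TRUE)) {
    m <- regmatches(s, regexec(
      "^([+-]?)(?:([0-9.]+)\\*)?pi(?:/([0-9.]+))?$", s))[[1]]
    if (length(m) == 0L)
      stop("cannot parse pi-expression: '", s, "'", call. = FALSE)
    sgn <- if (m[2] == "-") -1 else 1
    num <- if (nzchar(m[3])) as.numeric(m[3]) else 1
    den <- if (nzchar(m[4])) as.numeric(m[4]) else 1
    sgn * num * pi / den
  } else {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop("cannot parse number: '", s, "'", call. = FALSE)
    v
  }
}

read_keyvals <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[=:]", perl = TRUE)
  bad <- vapply(kv, length, 1L) < 2L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = ":"), ""))
  stats::setNames(as.list(vals), keys)
}

#' Read or write a parameter set as a plain-text config
#'
#' The format is one `key = value` pair per line (`#` comments allowed).
#' Recognised keys: `b0, b1, A0, A1, Omega0, Omega1` and, for the tanh
#' form, `C` and `Tbar`.  Values may be decimal or pi-rational
#' expressions such as `3*pi/200`; frequencies are written back
#' symbolically when they are exact multiples of pi over an integer.
#'
#' @param path file path.
#' @param pset parameter set to write.
#' @return `read_param_config()` returns a `tanh_param_set` if `C`/`Tbar`
#'   are present, else a `linear_param_set`; `write_param_config()`
#'   returns `path` invisibly.
#' @export
read_param_config <- function(path) {
  kv <- read_keyvals(path)
  need <- c("b0", "b1", "A0", "A1", "Omega0", "Omega1")
  miss <- setdiff(need, names(kv))
  if (length(miss))
    stop("parameter config missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  num <- lapply(kv, parse_config_number)
  if (all(c("C", "Tbar") %in% names(kv))) {
    tanh_param_set(num$b0, num$b1, num$A0, num$A1,
                   num$Omega0, num$Omega1, num$C, num$Tbar)
  } else {
    linear_param_set(num$b0, num$b1, num$A0, num$A1,
                     num$Omega0, num$Omega1)
  }
}

format_config_number <- function(v) {
  # write k*pi/n when v is an exact small rational multiple of pi
  if (v == 0) return("0")
  for (den in c(1:2000)) {
    k <- v * den / pi
    if (abs(k - round(k)) < 1e-12 && abs(round(k)) >= 1) {
      k <- round(k)
      num <- if (abs(k) == 1) "" else paste0(abs(k), "*")
      s <- if (k < 0) "-" else ""
      d <- if (den == 1) "" else paste0("/", den)
      return(paste0(s, num, "pi", d))
    }
  }
  # shortest decimal that round-trips exactly
  for (d in 1:17) {
    s <- format(v, digits = d)
    if (suppressWarnings(identical(as.numeric(s), v))) return(s)
  }
  format(v, digits = 17)
}

#' @rdname read_param_config
#' @export
write_param_config <- function(pset, path) {
  stopifnot(inherits(pset, "param_set"))
  keys <- names(unclass(pset))
  lines <- vapply(keys, function(k)
    sprintf("%s = %s", k, format_config_number(pset[[k]])), "")
  writeLines(lines, path)
  invisible(path)
}
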