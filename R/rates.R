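# Voltage-dependent transition rates for Hodgkin-Huxley-style gating.
# Three functional forms cover all six Wang-Buzsaki rate functions.

#' Voltage-dependent transition-rate function
#'
#' Builds one of the three functional forms used by the Wang-Buzsaki (WB)
#' channel kinetics.  With `x = (V - Vref) / slope` the forms are
#'
#' * `"linear-over-expm1"`: `amplitude * (V - Vref) / (1 - exp(-x))`
#'   (used for the activation rates `alpha_m`, `alpha_n`),
#' * `"pure-exponential"`: `amplitude * exp(-x)`
#'   (used for `beta_m`, `alpha_h`, `beta_n`),
#' * `"sigmoid"`: `amplitude / (1 + exp(-x))` (used for `beta_h`).
#'
#' The linear-over-expm1 form has a removable singularity at `V == Vref`;
#' [eval_rate()] returns its analytic limit `amplitude * slope` there.
#'
#' @param amplitude Rate scale (ms^-1, or ms^-1 mV^-1 for the
#'   linear-over-expm1 form).
#' @param Vref Reference voltage (mV).
#' @param slope Slope factor (mV); must be non-zero.
#' @param form One of `"linear-over-expm1"`, `"pure-exponential"`,
#'   `"sigmoid"`.
#' @return An object of class `rate_function`.
#' @seealso [eval_rate()], [wb_rates()]
#' @examples
#' an <- rate_function(0.05, -34, 10, "linear-over-expm1")
#' eval_rate(an, -34)  # analytic limit: 0.05 * 10 = 0.5
#' @export
rate_function <- function(amplitude, Vref, slope,
                          form = c("linear-over-expm1", "pure-exponential",
                                   "sigmoid")) {
  form <- match.arg(form)
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude),
            is.numeric(Vref), length(Vref) == 1L, is.finite(Vref),
            is.numeric(slope), length(slope) == 1L, is.finite(slope))
  if (slope == 0) stop("'slope' must be non-zero")
  structure(list(amplitude = amplitude, Vref = Vref, slope = slope,
                 form = form),
            class = "rate_function")
}

# unvalidated numeric core, shared by eval_rate() and the chain stepper
.rate_eval <- function(a, v0, k, form, V) {
  x <- (V - v0) / k
  if (form == "linear-over-expm1") {
    out <- a * (V - v0) / (1 - exp(-x))
    sing <- abs(V - v0) < 1e-9
    if (any(sing)) out[sing] <- a * k
    out
  } else if (form == "pure-exponential") {
    a * exp(-x)
  } else {
    a / (1 + exp(-x))
  }
}

#' Evaluate a transition-rate function
#'
#' @param coeffs A [rate_function()] object.
#' @param V Membrane potential(s), mV; must be finite.
#' @return Rate(s) in ms^-1, same length as `V`.
#' @export
eval_rate <- function(coeffs, V) {
  stopifnot(inherits(coeffs, "rate_function"), is.numeric(V))
  if (!all(is.finite(V))) stop("'V' must be finite")
  .rate_eval(coeffs$amplitude, coeffs$Vref, coeffs$slope, coeffs$form, V)
}

#' Wang-Buzsaki rate-function set
#'
#' The six alpha/beta rate functions of the WB model (K activation `n`,
#' Na activation `m`, Na inactivation `h`), each with its amplitude,
#' reference voltage and slope factor.
#'
#' @return A named list of six [rate_function()] objects:
#'   `alpha_m`, `beta_m`, `alpha_h`, `beta_h`, `alpha_n`, `beta_n`.
#' @export
wb_rates <- function() {
  list(
    alpha_m = rate_function(0.50,  -35, 10, "linear-over-expm1"),
    beta_m  = rate_function(20.0,  -60, 18, "pure-exponential"),
    alpha_h = rate_function(0.35,  -58, 20, "pure-exponential"),
    beta_h  = rate_function(5.0,   -28, 10, "sigmoid"),
    alpha_n = rate_function(0.05,  -34, 10, "linear-over-expm1"),
    beta_n  = rate_function(0.625, -44, 80, "pure-exponential"))
}

#' @export
print.rate_function <- function(x, ...) {
  cat(sprintf("<rate_function> %s: amplitude %g, Vref %g mV, slope %g mV\n",
              x$form, x$amplitude, x$Vref, x$slope))
  invisible(x)
}
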