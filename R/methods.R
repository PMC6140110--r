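# print/summary/plot methods for the package's S3 classes.

#' @export
print.membrane_model <- function(x, ...) {
  kind <- switch(class(x)[1L],
                 wb_model = "Wang-Buzsaki (conductance-based)",
                 seif_model = "standard exponential integrate-and-fire",
                 beif_model = "bounded exponential integrate-and-fire",
                 passive_model = "passive leak membrane")
  cat(sprintf("<%s> %s, %d parameters\n", class(x)[1L], kind, n_parameters(x)))
  flat <- x[vapply(x, function(e) is.numeric(e) && length(e) == 1L, TRUE)]
  cat(" ", paste(sprintf("%s = %g", names(flat), unlist(flat)),
                 collapse = ", "), "\n")
  if (inherits(x, "beif_model")) cat("  mode:", x$mode, "\n")
  invisible(x)
}

#' @export
summary.membrane_model <- function(object, ...) print(object, ...)

#' @export
print.axon_chain <- function(x, ...) {
  cat(sprintf("<axon_chain> %s, %d compartments, %s membrane\n",
              x$type, x$n, class(x$membrane)[1L]))
  if (x$n > 1L)
    cat(sprintf("  spacing %g um, g_axon %.4g uS, cm %.4g nF, gl %.4g uS per compartment\n",
                x$positions[2] - x$positions[1], x$g_axon[1], x$cm[1], x$gl[1]))
  invisible(x)
}

#' @export
print.axon_trace <- function(x, ...) {
  cat(sprintf("<axon_trace> %s, %d compartments, %g ms at dt = %g ms (%s), %d spike events\n",
              x$model, x$n, x$duration_ms, x$dt_ms, x$scheme, nrow(x$spikes)))
  invisible(x)
}

#' Plot voltage traces of a simulation
#'
#' @param x An `axon_trace`.
#' @param comps Compartments to draw (default: up to 15, evenly spaced).
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.axon_trace <- function(x, comps = NULL, ...) {
  if (is.null(comps))
    comps <- unique(round(seq(1, x$n, length.out = min(15, x$n))))
  graphics::matplot(x$times, x$V[, comps, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (ms)",
                    ylab = "membrane potential (mV)", ...)
  invisible(x)
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf("<velocity_estimate> %.3g m/s (compartments %d -> %d, %.3g mm in %.4g ms)\n",
              x$velocity_m_s, x$node_a, x$node_b,
              x$distance_um * 1e-3, x$t_peak_b - x$t_peak_a))
  invisible(x)
}

#' @export
print.sqrt_fit <- function(x, ...) {
  cat(sprintf("<sqrt_fit> u = %.4g * sqrt(%s)  (%d points, residual norm %.3g)\n",
              x$coefficient, x$predictor, nrow(x$data), x$residual_norm))
  invisible(x)
}

#' @export
coef.sqrt_fit <- function(object, ...) {
  stats::setNames(object$coefficient, object$predictor)
}

#' @export
predict.sqrt_fit <- function(object, newdata = object$data$x, ...) {
  object$coefficient * sqrt(newdata)
}

#' Plot a square-root scaling fit
#'
#' @param x A `sqrt_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.sqrt_fit <- function(x, ...) {
  graphics::plot(x$data$x, x$data$u, xlab = x$predictor,
                 ylab = "conduction velocity (m/s)", ...)
  xs <- seq(min(x$data$x), max(x$data$x), length.out = 100)
  graphics::lines(xs, predict(x, xs), lty = 2)
  invisible(x)
}

#' Plot an f-I curve
#'
#' @param x An `fi_curve` from [f_i_curve()].
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fi_curve <- function(x, ...) {
  graphics::plot(x$amplitude, x$rate_hz, type = "b",
                 xlab = expression(paste("current density (", mu, "A/", cm^2, ")")),
                 ylab = "firing rate (spikes/s)", ...)
  invisible(x)
}

#' @export
print.axon_experiment <- function(x, ...) {
  cat(sprintf("<axon_experiment> %s: %d-compartment %s chain, dt = %g ms, %g ms\n",
              x$name, x$chain$n, x$chain$type, x$dt_ms, x$duration_ms))
  invisible(x)
}
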