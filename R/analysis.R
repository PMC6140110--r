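# Trace analysis: spike peaks, conduction velocity, f-I curves, square-root
# scaling fits, waveform metrics.

.no_spike <- function(msg) {
  stop(errorCondition(msg, class = c("axonsim_no_spike", "error", "condition")))
}

.window_idx <- function(trace, window) {
  if (is.null(window)) return(seq_along(trace$times))
  which(trace$times >= window[1] & trace$times <= window[2])
}

#' Time of the spike peak at one compartment
#'
#' Time of the global maximum of the recorded voltage in the search
#' window; ties are broken by the earliest sample.  If the maximum does
#' not exceed `min_peak_mV` the compartment is considered not to have
#' spiked and an error of condition class `axonsim_no_spike` is raised.
#'
#' @param trace An `axon_trace`.
#' @param comp Compartment index.
#' @param window Optional `c(from, to)` time window (ms).
#' @param min_peak_mV Suprathreshold criterion for "a spike happened"
#'   (mV).
#' @return Peak time (ms).
#' @export
spike_peak_time <- function(trace, comp, window = NULL, min_peak_mV = -20) {
  stopifnot(inherits(trace, "axon_trace"), comp >= 1, comp <= trace$n)
  idx <- .window_idx(trace, window)
  v <- trace$V[idx, comp]
  k <- which.max(v)
  if (v[k] < min_peak_mV)
    .no_spike(sprintf("no suprathreshold excursion at compartment %d (max %.1f mV)",
                      comp, v[k]))
  trace$times[idx[k]]
}

#' Conduction velocity between two compartments
#'
#' Distance between the compartment centers divided by the difference of
#' their spike-peak times.
#'
#' @param trace An `axon_trace`.
#' @param node_a,node_b Compartment indices (`node_b` downstream).
#' @param window Optional search window (ms) passed to
#'   [spike_peak_time()].
#' @param min_peak_mV Suprathreshold criterion (mV).
#' @return An object of class `velocity_estimate` with fields `node_a`,
#'   `node_b`, `t_peak_a`, `t_peak_b` (ms), `distance_um`,
#'   `velocity_m_s`.
#' @export
conduction_velocity <- function(trace, node_a, node_b, window = NULL,
                                min_peak_mV = -20) {
  stopifnot(inherits(trace, "axon_trace"))
  ta <- spike_peak_time(trace, node_a, window, min_peak_mV)
  tb <- spike_peak_time(trace, node_b, window, min_peak_mV)
  if (tb == ta)
    stop(errorCondition("equal peak times: velocity undefined",
                        class = c("axonsim_undefined_velocity", "error",
                                  "condition")))
  dist_um <- abs(trace$positions[node_b] - trace$positions[node_a])
  u <- dist_um / abs(tb - ta) * 1e-3   # um/ms -> m/s
  structure(list(node_a = node_a, node_b = node_b,
                 t_peak_a = ta, t_peak_b = tb,
                 distance_um = dist_um, velocity_m_s = u),
            class = "velocity_estimate")
}

#' Firing rate versus injected current (f-I curve)
#'
#' Injects a step current of each amplitude for `duration_ms` and counts
#' spikes; the rate is `count / duration` in spikes/s.
#'
#' @param model A `membrane_model`.
#' @param amplitudes Step-current densities (uA/cm^2).
#' @param duration_ms Step duration (ms); 1000 ms by default.
#' @param dt_ms Time step (ms).
#' @return A data.frame (class `fi_curve`) with columns `amplitude` and
#'   `rate_hz`.
#' @export
f_i_curve <- function(model, amplitudes, duration_ms = 1000, dt_ms = 0.004) {
  stopifnot(inherits(model, "membrane_model"), duration_ms > 0)
  rate <- vapply(amplitudes, function(a) {
    tr <- simulate_point(model, a, duration_ms = duration_ms, dt_ms = dt_ms,
                         record_stride = 64L)
    nrow(tr$spikes) / duration_ms * 1000
  }, numeric(1))
  structure(data.frame(amplitude = amplitudes, rate_hz = rate),
            class = c("fi_curve", "data.frame"))
}

#' Rheobase from an f-I curve
#'
#' The smallest tested amplitude that produced at least one spike (no
#' bisection refinement; grid resolution is the user's choice).
#'
#' @param fi An `fi_curve` from [f_i_curve()].
#' @return Amplitude (uA/cm^2), or `NA` if nothing spiked.
#' @export
rheobase <- function(fi) {
  stopifnot(inherits(fi, "fi_curve"))
  pos <- fi$amplitude[fi$rate_hz > 0]
  if (!length(pos)) return(NA_real_)
  min(pos)
}

#' Least-squares square-root fit
#'
#' Fits `u = c * sqrt(x)` by minimizing `sum((u - c sqrt(x))^2)`; the
#' closed-form solution is `c = sum(u sqrt(x)) / sum(x)`.  Used for the
#' square-root scaling of conduction velocity with axon diameter and with
#' internodal length.
#'
#' @param x Predictor values (> 0), at least 3.
#' @param u Velocities (same length).
#' @param predictor Label for the predictor (e.g. `"D"` or `"Li"`).
#' @return An object of class `sqrt_fit` with fields `coefficient`,
#'   `predictor`, `residual_norm`, `data`.
#' @examples
#' fit_sqrt(1:5, 2 * sqrt(1:5))  # coefficient 2, zero residual
#' @export
fit_sqrt <- function(x, u, predictor = "x") {
  stopifnot(is.numeric(x), is.numeric(u), length(x) == length(u))
  if (length(x) < 3) stop("need at least 3 points")
  if (any(x <= 0)) stop("all predictor values must be positive")
  cc <- sum(u * sqrt(x)) / sum(x)
  if (cc <= 0) stop("degenerate fit: non-positive coefficient")
  res <- u - cc * sqrt(x)
  structure(list(coefficient = cc, predictor = predictor,
                 residual_norm = sqrt(sum(res^2)),
                 data = data.frame(x = x, u = u)),
            class = "sqrt_fit")
}

#' Spike width at half height
#'
#' Full width of the spike at the midpoint between a baseline (the first
#' recorded sample of the compartment) and the peak, with linear
#' interpolation of the crossing times.
#'
#' @inheritParams spike_peak_time
#' @return Width (ms).
#' @export
spike_width <- function(trace, comp, window = NULL, min_peak_mV = -20) {
  stopifnot(inherits(trace, "axon_trace"))
  idx <- .window_idx(trace, window)
  v <- trace$V[idx, comp]; tt <- trace$times[idx]
  k <- which.max(v)
  if (v[k] < min_peak_mV) .no_spike("no spike at compartment")
  half <- (v[k] + v[1]) / 2
  cross <- function(i0, i1) {
    # linear interpolation of the half-height crossing between samples
    f <- (half - v[i0]) / (v[i1] - v[i0])
    tt[i0] + f * (tt[i1] - tt[i0])
  }
  lo <- max(which(v[seq_len(k)] < half))
  up_seq <- seq(k, length(v))
  hi <- k - 1L + min(which(v[up_seq] < half))
  cross(hi - 1L, hi) - cross(lo, lo + 1L)
}

#' Peak-aligned waveform deviation across compartments
#'
#' Extracts the voltage waveform around each compartment's spike peak,
#' aligns the waveforms at their peaks, interpolates them onto a common
#' relative-time grid, and returns the maximum absolute deviation of each
#' from the reference compartment.  For a uniformly conducting spike this
#' deviation is small (the waveform is translation invariant along the
#' chain); non-uniform conduction (e.g. the hard-reset bEIF variant or
#' the diverging sEIF chain) produces large values.
#'
#' @param trace An `axon_trace`.
#' @param comps Compartments to compare.
#' @param ref Reference compartment; defaults to the first of `comps`.
#' @param window_ms Relative window `c(before, after)` around each peak
#'   (ms).
#' @param min_peak_mV Suprathreshold criterion (mV); compartments that
#'   never spike are reported as `Inf` deviation.
#' @return Named numeric vector of max-abs deviations (mV), one per
#'   compartment in `comps`.
#' @export
waveform_uniformity <- function(trace, comps, ref = comps[1],
                                window_ms = c(-0.5, 1.5),
                                min_peak_mV = -20) {
  stopifnot(inherits(trace, "axon_trace"))
  grid <- seq(window_ms[1], window_ms[2], by = trace$dt_ms * trace$record_stride)
  shape <- function(comp) {
    tp <- tryCatch(spike_peak_time(trace, comp, min_peak_mV = min_peak_mV),
                   axonsim_no_spike = function(e) NA_real_)
    if (is.na(tp)) return(NULL)
    stats::approx(trace$times - tp, trace$V[, comp], xout = grid, rule = 2)$y
  }
  ref_w <- shape(ref)
  if (is.null(ref_w)) .no_spike("reference compartment did not spike")
  out <- vapply(comps, function(cp) {
    w <- shape(cp)
    if (is.null(w)) return(Inf)
    max(abs(w - ref_w))
  }, numeric(1))
  names(out) <- comps
  out
}
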