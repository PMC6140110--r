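# Stimulus protocols: intracellular step currents and extracellular
# point-source stimulation.

#' Intracellular step-current stimulus
#'
#' A rectangular current pulse injected into one compartment.
#'
#' @param site Compartment index (1-based).
#' @param amplitude_nA Amplitude in nA (100 pA = 0.1 nA).
#' @param onset_ms Pulse onset (ms).
#' @param duration_ms Pulse duration (ms), positive.
#' @return An object of class `step_current`.
#' @examples
#' step_current(site = 20, amplitude_nA = 0.1, duration_ms = 1)
#' @export
step_current <- function(site, amplitude_nA, onset_ms = 0, duration_ms = 1) {
  stopifnot(site >= 1, site == round(site), is.finite(amplitude_nA),
            onset_ms >= 0, duration_ms > 0)
  structure(list(site = as.integer(site), amplitude_nA = amplitude_nA,
                 onset_ms = onset_ms, duration_ms = duration_ms),
            class = "step_current")
}

#' Diameter-scaled stimulus amplitude
#'
#' Securely initiating a spike in a thicker axon needs a proportionally
#' larger current; the amplitude is scaled linearly with diameter,
#' `base * D / D_ref` (e.g. `(D/2) x 100 pA` for the myelinated default,
#' `(D/10) x 10 nA` for the unmyelinated default).
#'
#' @param D_um Axon diameter (um), positive.
#' @param base Base amplitude at the reference diameter (any current unit).
#' @param D_ref_um Reference diameter (um).
#' @return Scaled amplitude in the unit of `base`.
#' @export
diameter_scaled_amplitude <- function(D_um, base, D_ref_um) {
  stopifnot(D_um > 0, D_ref_um > 0)
  base * D_um / D_ref_um
}

#' Extracellular point-source stimulus
#'
#' A monophasic rectangular current pulse delivered by a dimensionless
#' point electrode in a resistive medium.  The electrode sits at
#' perpendicular distance `distance_mm` from the compartment
#' `electrode_node` of a straight axon, so the electrode-to-compartment
#' distance is `r_j = sqrt(distance^2 + (x_j - x_e)^2)`.
#'
#' @param I_ex_mA Injected current (mA); negative values are cathodic.
#' @param onset_ms Pulse onset (ms).
#' @param duration_ms Pulse duration (ms), positive.
#' @param electrode_node Compartment closest to the electrode (1-based).
#' @param distance_mm Perpendicular electrode-axon distance (mm), positive.
#' @param rho_ex_ohm_m Extracellular resistivity (Ohm m).
#' @return An object of class `extracellular_stimulus`.
#' @export
extracellular_stimulus <- function(I_ex_mA = -1, onset_ms = 0,
                                   duration_ms = 0.1, electrode_node = 20,
                                   distance_mm = 1.0, rho_ex_ohm_m = 3.0) {
  stopifnot(is.finite(I_ex_mA), onset_ms >= 0, duration_ms > 0,
            electrode_node >= 1, electrode_node == round(electrode_node),
            distance_mm > 0, rho_ex_ohm_m > 0)
  structure(list(I_ex_mA = I_ex_mA, onset_ms = onset_ms,
                 duration_ms = duration_ms,
                 electrode_node = as.integer(electrode_node),
                 distance_mm = distance_mm, rho_ex_ohm_m = rho_ex_ohm_m),
            class = "extracellular_stimulus")
}

#' Extracellular potential at every compartment
#'
#' Point-source potential `U_ex,j = rho_ex * I_ex / (4 pi r_j)` at each
#' compartment, zero outside the stimulus window.  The potential enters
#' the dynamics only through the axial term: the intracellular drive is
#' `U_in = V + U_ex` and axial currents follow its gradient, while the
#' membrane currents depend on `V` alone.
#'
#' @param source An [extracellular_stimulus()].
#' @param chain An `axon_chain` (supplies compartment positions).
#' @param t Time (ms) at which to evaluate; defaults to the pulse onset
#'   (i.e. the full-amplitude profile).
#' @return Per-compartment extracellular potential (mV).
#' @examples
#' ax <- myelinated_axon(beif_model())
#' src <- extracellular_stimulus()
#' max(abs(extracellular_potential(src, ax)))  # ~238.7 mV at node 20
#' @export
extracellular_potential <- function(source, chain, t = source$onset_ms) {
  stopifnot(inherits(source, "extracellular_stimulus"),
            inherits(chain, "axon_chain"),
            source$electrode_node <= chain$n)
  r_mm <- .electrode_distances_mm(source, chain)
  if (any(r_mm <= 0)) stop("electrode must not lie on the axon (all r_j > 0)")
  on <- t >= source$onset_ms & t < source$onset_ms + source$duration_ms
  # rho (Ohm m) * I (mA -> A) / (4 pi r (mm -> m)), in V -> mV
  amp <- source$rho_ex_ohm_m * source$I_ex_mA / (4 * pi * r_mm) * 1e3
  amp * as.numeric(on)
}

.electrode_distances_mm <- function(source, chain) {
  x_mm <- chain$positions * 1e-3
  dx <- x_mm - x_mm[source$electrode_node]
  sqrt(source$distance_mm^2 + dx^2)
}
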