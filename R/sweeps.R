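# Parameter sweeps: conduction velocity versus diameter, internodal length
# and depolarization ceiling.

.myelinated_velocity <- function(membrane, D_um, Ln_um, Li_um, n_nodes, Rax,
                                 amplitude_nA, stim_node, measure, dt_ms,
                                 duration_ms, scheme) {
  ax <- myelinated_axon(membrane, D_um = D_um, Ln_um = Ln_um, Li_um = Li_um,
                        n_nodes = n_nodes, Rax_ohm_cm = Rax)
  tr <- simulate_axon(ax, step_current(stim_node, amplitude_nA,
                                       duration_ms = 1),
                      duration_ms = duration_ms, dt_ms = dt_ms,
                      scheme = scheme)
  conduction_velocity(tr, measure[1], measure[2])$velocity_m_s
}

#' Conduction velocity versus axon diameter (myelinated)
#'
#' Simulates the default myelinated axon for each diameter, scaling the
#' stimulus amplitude linearly with the diameter
#' (`(D / D_ref) x base`), and measures the velocity between two nodes.
#'
#' @param D_um Diameters to test (um).
#' @param membrane Membrane model attached to every node.
#' @param Ln_um,Li_um,n_nodes,Rax_ohm_cm Chain geometry.
#' @param base_nA Stimulus amplitude at the reference diameter (nA).
#' @param D_ref_um Reference diameter for the amplitude scaling (um).
#' @param stim_node Injection node.
#' @param measure Two node indices for the velocity measurement.
#' @param dt_ms,duration_ms,scheme Solver settings.
#' @return data.frame with columns `D_um`, `velocity_m_s`.
#' @export
sweep_diameter <- function(D_um = c(1, 2, 3, 4, 5, 6, 8),
                           membrane = beif_model(),
                           Ln_um = 2, Li_um = 200, n_nodes = 141,
                           Rax_ohm_cm = 100,
                           base_nA = 0.1, D_ref_um = 2,
                           stim_node = 20, measure = c(40, 90),
                           dt_ms = 0.004, duration_ms = 12,
                           scheme = "euler-cn") {
  u <- vapply(D_um, function(D) {
    .myelinated_velocity(membrane, D, Ln_um, Li_um, n_nodes, Rax_ohm_cm,
                         diameter_scaled_amplitude(D, base_nA, D_ref_um),
                         stim_node, measure, dt_ms, duration_ms, scheme)
  }, numeric(1))
  data.frame(D_um = D_um, velocity_m_s = u)
}

#' Conduction velocity versus internodal length (myelinated)
#'
#' @param Li_um Internodal lengths to test (um).
#' @param amplitude_nA Stimulus amplitude (nA), fixed across the sweep.
#' @inheritParams sweep_diameter
#' @param D_um Axon diameter (um), fixed.
#' @return data.frame with columns `Li_um`, `velocity_m_s`.
#' @export
sweep_internode <- function(Li_um = c(50, 100, 150, 200, 300, 400, 500),
                            membrane = beif_model(),
                            D_um = 2, Ln_um = 2, n_nodes = 141,
                            Rax_ohm_cm = 100, amplitude_nA = 0.1,
                            stim_node = 20, measure = c(40, 90),
                            dt_ms = 0.004, duration_ms = 12,
                            scheme = "euler-cn") {
  u <- vapply(Li_um, function(Li) {
    .myelinated_velocity(membrane, D_um, Ln_um, Li, n_nodes, Rax_ohm_cm,
                         amplitude_nA, stim_node, measure, dt_ms,
                         duration_ms, scheme)
  }, numeric(1))
  data.frame(Li_um = Li_um, velocity_m_s = u)
}

#' Conduction velocity versus diameter (unmyelinated)
#'
#' @param D_um Diameters to test (um).
#' @param dx_um Compartment length (um).
#' @param n_comp Number of compartments.
#' @param base_nA Stimulus amplitude at the reference diameter (nA).
#' @inheritParams sweep_diameter
#' @param stim_comp Injection compartment.
#' @return data.frame with columns `D_um`, `velocity_m_s`.
#' @export
sweep_unmyelinated <- function(D_um = c(2, 5, 10, 15, 20),
                               membrane = beif_model(),
                               dx_um = 20, n_comp = 301, Rax_ohm_cm = 100,
                               base_nA = 10, D_ref_um = 10,
                               stim_comp = 50, measure = c(100, 200),
                               dt_ms = 0.004, duration_ms = 18,
                               scheme = "euler-cn") {
  u <- vapply(D_um, function(D) {
    ax <- unmyelinated_axon(membrane, D_um = D, dx_um = dx_um,
                            n_comp = n_comp, Rax_ohm_cm = Rax_ohm_cm)
    amp <- diameter_scaled_amplitude(D, base_nA, D_ref_um)
    tr <- simulate_axon(ax, step_current(stim_comp, amp, duration_ms = 1),
                        duration_ms = duration_ms, dt_ms = dt_ms,
                        scheme = scheme)
    conduction_velocity(tr, measure[1], measure[2])$velocity_m_s
  }, numeric(1))
  data.frame(D_um = D_um, velocity_m_s = u)
}

#' Conduction velocity versus the depolarization ceiling AT
#'
#' For each ceiling value `AT`, simulates the default myelinated bEIF
#' axon.  Extreme ceilings can leave the membrane stuck depolarized after
#' a spike; following the measurement protocol, the repolarization
#' trigger `Vrep` is then lowered in `vrep_step_mV` steps (from
#' `vrep_start_mV` down to at most `vrep_min_mV`) until the potential
#' returns to within `rest_tol_mV` of rest by the end of the trace.
#'
#' @param AT_values Ceiling factors to test (> 0).
#' @param membrane Template bEIF model supplying all other parameters.
#' @param vrep_start_mV,vrep_min_mV,vrep_step_mV The `Vrep` readjustment
#'   ladder (mV).
#' @param rest_tol_mV Return-to-rest tolerance (mV).
#' @inheritParams sweep_diameter
#' @return data.frame with columns `AT`, `Vrep_used`, `velocity_m_s`,
#'   `returned_to_rest`.  `velocity_m_s` is `NA` when no `Vrep` in the
#'   ladder restored rest or the spike failed to conduct.
#' @export
at_sweep <- function(AT_values, membrane = beif_model(),
                     vrep_start_mV = 15, vrep_min_mV = -20,
                     vrep_step_mV = 5, rest_tol_mV = 2,
                     Ln_um = 2, Li_um = 200, D_um = 2, n_nodes = 141,
                     Rax_ohm_cm = 100, stim_node = 20, measure = c(40, 90),
                     dt_ms = 0.004, duration_ms = 25, scheme = "euler-cn") {
  stopifnot(all(AT_values > 0), inherits(membrane, "beif_model"))
  rows <- lapply(AT_values, function(AT) {
    for (vrep in seq(vrep_start_mV, vrep_min_mV, by = -vrep_step_mV)) {
      mdl <- beif_model(Cm = membrane$Cm, GL = membrane$GL, EL = membrane$EL,
                        VT = membrane$VT, KT = membrane$KT, AT = AT,
                        Vrep = vrep, tau_rep = membrane$tau_rep,
                        Arep = membrane$Arep)
      ax <- myelinated_axon(mdl, D_um = D_um, Ln_um = Ln_um, Li_um = Li_um,
                            n_nodes = n_nodes, Rax_ohm_cm = Rax_ohm_cm)
      tr <- simulate_axon(ax, step_current(stim_node, 0.1, duration_ms = 1),
                          duration_ms = duration_ms, dt_ms = dt_ms,
                          scheme = scheme)
      rest_ok <- max(abs(tr$V[nrow(tr$V), ] - tr$V[1L, ])) <= rest_tol_mV
      if (rest_ok) {
        # low trigger voltages give low-amplitude conducted waves, so the
        # "a spike happened" criterion follows the trigger voltage down
        u <- tryCatch(conduction_velocity(tr, measure[1], measure[2],
                                          min_peak_mV = min(-20, vrep - 10))$velocity_m_s,
                      error = function(e) NA_real_)
        return(data.frame(AT = AT, Vrep_used = vrep, velocity_m_s = u,
                          returned_to_rest = TRUE))
      }
    }
    data.frame(AT = AT, Vrep_used = NA_real_, velocity_m_s = NA_real_,
               returned_to_rest = FALSE)
  })
  do.call(rbind, rows)
}
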