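# Point-membrane models: Wang-Buzsaki (WB), standard exponential
# integrate-and-fire (sEIF), bounded EIF (bEIF), and a passive leak membrane.
#
# All models share the membrane equation
#   Cm dV/dt = GL (EL - V) + psi(V) + Iinj
# and differ only in the spike-generating term psi(V).  Parameters are stored
# as densities (Cm in uF/cm^2, conductances in mS/cm^2, potentials in mV);
# compartment builders convert them to absolute values using membrane area.
# In density units uF/cm^2 * mV/ms = uA/cm^2 = mS/cm^2 * mV, so point-model
# computations are consistent without an explicit area.

.check_passive <- function(Cm, GL, EL) {
  stopifnot(is.numeric(Cm), length(Cm) == 1L, is.finite(Cm), Cm > 0,
            is.numeric(GL), length(GL) == 1L, is.finite(GL), GL > 0,
            is.numeric(EL), length(EL) == 1L, is.finite(EL))
}

new_membrane <- function(subclass, fields) {
  structure(fields, class = c(subclass, "membrane_model"))
}

#' Wang-Buzsaki conductance-based membrane model
#'
#' Hodgkin-Huxley-type model with a fast transient Na current
#' `INa = GNa m^3 h (ENa - V)` and a delayed-rectifier K current
#' `IK = GK n^4 (EK - V)`.  All three gating variables (including Na
#' activation `m`) follow first-order kinetics
#' `dy/dt = alpha_y(V)(1 - y) - beta_y(V) y`; sodium activation is
#' integrated, not instantaneous.  Defaults are the standard parameter set
#' (25 parameters in total: 7 membrane constants plus 3 per rate function).
#'
#' @param Cm Membrane capacitance density (uF/cm^2).
#' @param GL,GK,GNa Leak, K and Na conductance densities (mS/cm^2).
#' @param EL,EK,ENa Leak, K and Na reversal potentials (mV);
#'   must satisfy `EK < EL < ENa`.
#' @param rates List of six [rate_function()] objects as returned by
#'   [wb_rates()].
#' @param Vdetect Voltage whose upward crossing is recorded as a spike
#'   event (mV); a bookkeeping threshold only, it does not affect the
#'   dynamics.
#' @return A `membrane_model` of class `wb_model`.
#' @examples
#' wb <- wb_model()
#' wb_steady_gates(wb, -65)
#' @export
wb_model <- function(Cm = 1.0, GL = 0.1, GK = 15.0, GNa = 35.0,
                     EL = -65, EK = -90, ENa = 55,
                     rates = wb_rates(), Vdetect = -10) {
  .check_passive(Cm, GL, EL)
  stopifnot(GK > 0, GNa > 0, is.finite(EK), is.finite(ENa))
  if (!(EK < EL && EL < ENa)) stop("reversal potentials must satisfy EK < EL < ENa")
  need <- c("alpha_m", "beta_m", "alpha_h", "beta_h", "alpha_n", "beta_n")
  if (!all(need %in% names(rates)) ||
      !all(vapply(rates[need], inherits, TRUE, "rate_function")))
    stop("'rates' must contain the six rate_function objects ", paste(need, collapse = ", "))
  new_membrane("wb_model",
               list(Cm = Cm, GL = GL, GK = GK, GNa = GNa,
                    EL = EL, EK = EK, ENa = ENa,
                    rates = rates[need], Vdetect = Vdetect))
}

#' Standard exponential integrate-and-fire (sEIF) membrane model
#'
#' The spike-generating current grows exponentially with voltage,
#' `Idep = GL KT exp((V - VT)/KT)`, so the membrane potential diverges in
#' finite time once a spike starts.  When `V` reaches the detection
#' threshold `Vspike`, it is reset to and held at `Vreset` for the
#' refractory period `tau_ref`.  The exponent is capped at 700 to keep the
#' divergence finite in floating point; the `Vspike` test fires long before
#' the cap matters in single-compartment use.
#'
#' @inheritParams wb_model
#' @param VT Soft threshold of the spike-generating current (mV).
#' @param KT Slope factor (mV), positive.
#' @param Vspike Spike-detection threshold (mV).
#' @param Vreset Reset potential (mV); must satisfy `Vreset <= VT < Vspike`.
#' @param tau_ref Refractory period (ms).
#' @return A `membrane_model` of class `seif_model`.
#' @export
seif_model <- function(Cm = 1.0, GL = 0.1, EL = -65.3,
                       VT = -60.2, KT = 3.5, Vspike = 15, Vreset = -65.3,
                       tau_ref = 2.8) {
  .check_passive(Cm, GL, EL)
  stopifnot(KT > 0, tau_ref >= 0)
  if (!(Vreset <= VT && VT < Vspike))
    stop("sEIF thresholds must satisfy Vreset <= VT < Vspike")
  new_membrane("seif_model",
               list(Cm = Cm, GL = GL, EL = EL, VT = VT, KT = KT,
                    Vspike = Vspike, Vreset = Vreset, tau_ref = tau_ref))
}

#' Bounded exponential integrate-and-fire (bEIF) membrane model
#'
#' EIF variant whose spike-generating current saturates at a ceiling,
#' `Idep = GL KT AT / (1 + AT exp(-(V - VT)/KT))`, bounded above by
#' `GL KT AT`, and whose after-spike reset is replaced by an alpha-function
#' repolarizing conductance `Grep(t) = GL Arep s exp(1 - s)` with
#' `s = (t - Trep)/tau_rep`, driving the repolarizing current
#' `Irep = Grep (EL - V)`.  An episode starts (and a spike is recorded)
#' when `V` crosses `Vrep` from below while no episode is active.  The
#' bounded current and the smooth repolarization are what make the model
#' compatible with propagating spikes in a compartment chain.  Nine
#' parameters in default mode.
#'
#' @inheritParams seif_model
#' @param AT Ceiling factor of the spike-generating current (dimensionless,
#'   positive).
#' @param Vrep Voltage that triggers a repolarization episode (mV).
#' @param tau_rep Time constant of the repolarizing conductance (ms).
#' @param Arep Amplitude factor of the repolarizing conductance
#'   (dimensionless, positive); peak conductance is `GL * Arep`.
#' @param mode `"alpha-repolarization"` (default) or `"hard-reset"`, the
#'   latter replacing the repolarizing current by an instantaneous reset of
#'   `V` to `EL` on crossing `Vrep` (a deliberately unstable variant used
#'   to demonstrate why the smooth repolarization is needed).
#' @return A `membrane_model` of class `beif_model`.
#' @examples
#' b <- beif_model()
#' beif_dep_current(b, c(-70, -60.2, 40))
#' @export
beif_model <- function(Cm = 1.0, GL = 0.1, EL = -65.3,
                       VT = -60.2, KT = 3.5, AT = 520,
                       Vrep = 10, tau_rep = 0.60, Arep = 90,
                       mode = c("alpha-repolarization", "hard-reset")) {
  mode <- match.arg(mode)
  .check_passive(Cm, GL, EL)
  stopifnot(KT > 0, AT > 0, tau_rep > 0, Arep > 0, is.finite(Vrep))
  new_membrane("beif_model",
               list(Cm = Cm, GL = GL, EL = EL, VT = VT, KT = KT, AT = AT,
                    Vrep = Vrep, tau_rep = tau_rep, Arep = Arep, mode = mode))
}

#' Passive (leak-only) membrane
#'
#' A membrane with no spike-generating current; useful for testing the
#' cable discretization against linear theory.
#'
#' @inheritParams wb_model
#' @return A `membrane_model` of class `passive_model`.
#' @export
passive_model <- function(Cm = 1.0, GL = 0.1, EL = -65) {
  .check_passive(Cm, GL, EL)
  new_membrane("passive_model", list(Cm = Cm, GL = GL, EL = EL))
}

#' Number of free parameters of a membrane model
#'
#' WB: 7 membrane constants + 6 rate functions x 3 = 25.  sEIF: 8.
#' bEIF: 9 (mode is a structural switch, not a parameter).  Passive: 3.
#'
#' @param model A `membrane_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "membrane_model"))
  switch(class(model)[1L],
         wb_model = 25L, seif_model = 8L, beif_model = 9L,
         passive_model = 3L)
}

## ---- current equations -----------------------------------------------------

#' WB active current density
#'
#' `GNa m^3 h (ENa - V) + GK n^4 (EK - V)` in uA/cm^2.
#'
#' @param model A [wb_model()].
#' @param V Membrane potential (mV), vectorized.
#' @param m,h,n Gating variables in `[0, 1]`, recycled against `V`.
#' @return Current density (uA/cm^2).
#' @export
wb_active_current <- function(model, V, m, h, n) {
  stopifnot(inherits(model, "wb_model"))
  if (any(c(m, h, n) < 0) || any(c(m, h, n) > 1))
    stop("gating variables must lie in [0, 1]")
  model$GNa * m^3 * h * (model$ENa - V) + model$GK * n^4 * (model$EK - V)
}

#' WB gating-variable derivatives
#'
#' First-order kinetics `dy/dt = alpha_y(V)(1 - y) - beta_y(V) y` for
#' `y = m, h, n`.
#'
#' @inheritParams wb_active_current
#' @return List with components `dm`, `dh`, `dn` (ms^-1).
#' @export
wb_gating_derivatives <- function(model, V, m, h, n) {
  stopifnot(inherits(model, "wb_model"))
  r <- model$rates
  list(dm = eval_rate(r$alpha_m, V) * (1 - m) - eval_rate(r$beta_m, V) * m,
       dh = eval_rate(r$alpha_h, V) * (1 - h) - eval_rate(r$beta_h, V) * h,
       dn = eval_rate(r$alpha_n, V) * (1 - n) - eval_rate(r$beta_n, V) * n)
}

#' WB steady-state gating values at a fixed voltage
#'
#' `y_inf(V) = alpha_y / (alpha_y + beta_y)`.
#'
#' @inheritParams wb_active_current
#' @return List with components `m`, `h`, `n`.
#' @export
wb_steady_gates <- function(model, V) {
  stopifnot(inherits(model, "wb_model"))
  r <- model$rates
  inf <- function(a, b) {
    aa <- eval_rate(a, V); bb <- eval_rate(b, V)
    aa / (aa + bb)
  }
  list(m = inf(r$alpha_m, r$beta_m),
       h = inf(r$alpha_h, r$beta_h),
       n = inf(r$alpha_n, r$beta_n))
}

#' sEIF spike-generating current density
#'
#' `Idep = GL KT exp((V - VT)/KT)`, strictly positive and increasing in
#' `V`.  The exponent is capped at 700 so the divergence of the sEIF
#' potential stays representable in floating point.
#'
#' @param model A [seif_model()].
#' @param V Membrane potential (mV), vectorized.
#' @return Current density (uA/cm^2).
#' @export
seif_dep_current <- function(model, V) {
  stopifnot(inherits(model, "seif_model"), is.numeric(V))
  model$GL * model$KT * exp(pmin((V - model$VT) / model$KT, 700))
}

#' bEIF spike-generating current density
#'
#' `Idep = GL KT AT / (1 + AT exp(-(V - VT)/KT))`: strictly positive,
#' strictly increasing in `V`, and bounded above by its ceiling
#' `GL KT AT`.  For `V` well below `VT` it coincides with the sEIF
#' exponential to within a factor `1 + exp((V - VT)/KT)/AT`.
#'
#' @param model A [beif_model()].
#' @param V Membrane potential (mV), vectorized.
#' @return Current density (uA/cm^2).
#' @export
beif_dep_current <- function(model, V) {
  stopifnot(inherits(model, "beif_model"), is.numeric(V))
  model$GL * model$KT * model$AT /
    (1 + model$AT * exp(-(V - model$VT) / model$KT))
}

#' bEIF repolarizing conductance density
#'
#' Alpha function `Grep = GL Arep s exp(1 - s)` with
#' `s = t_since_onset / tau_rep`: zero at onset, peak `GL * Arep` at
#' `s = 1`, decaying to zero.  Computed in closed form from the time since
#' episode onset at every step (no auxiliary ODE).
#'
#' @param model A [beif_model()].
#' @param t_since_onset Time since the episode started (ms), non-negative.
#' @return Conductance density (mS/cm^2).
#' @export
beif_rep_conductance <- function(model, t_since_onset) {
  stopifnot(inherits(model, "beif_model"), is.numeric(t_since_onset))
  if (any(t_since_onset < 0)) stop("'t_since_onset' must be non-negative")
  s <- t_since_onset / model$tau_rep
  model$GL * model$Arep * s * exp(1 - s)
}

## ---- state -----------------------------------------------------------------

#' Initial state of a membrane model
#'
#' By default the membrane starts at `V = EL`; WB gates start at their
#' steady-state values for that voltage, the sEIF model outside its
#' refractory period, and the bEIF model with no repolarization episode.
#'
#' @param model A `membrane_model`.
#' @param V Optional starting potential (mV); default `EL`.
#' @return A named list: always `V`; `m`, `h`, `n` for WB;
#'   `refractory_remaining` for sEIF; `Trep` (episode onset time, `NA` if
#'   inactive) and `active` for bEIF.
#' @export
membrane_state <- function(model, V = NULL) {
  stopifnot(inherits(model, "membrane_model"))
  if (is.null(V)) V <- model$EL
  st <- list(V = V)
  if (inherits(model, "wb_model")) {
    st <- c(st, wb_steady_gates(model, V))
  } else if (inherits(model, "seif_model")) {
    st$refractory_remaining <- rep(0, length(V))
  } else if (inherits(model, "beif_model")) {
    st$Trep <- rep(NA_real_, length(V))
    st$active <- rep(FALSE, length(V))
  }
  st
}

#' Advance a single point membrane by one time step
#'
#' One forward-Euler step of the membrane equation in density units
#' (uA/cm^2), including the model's per-step event logic: sEIF reset and
#' refractory hold, bEIF repolarization-episode triggering.
#'
#' @param model A `membrane_model`.
#' @param state State list as from [membrane_state()].
#' @param dt Time step (ms), positive.
#' @param I_inj Injected current density (uA/cm^2).
#' @param t Current time (ms); the bEIF repolarizing conductance is a
#'   function of `t - Trep`.
#' @return List with components `state` (the new state) and `spiked`
#'   (logical).
#' @export
step_point_neuron <- function(model, state, dt, I_inj = 0, t = 0) {
  stopifnot(inherits(model, "membrane_model"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("'dt' must be positive")
  chain <- .point_chain(model)
  stepper <- .make_stepper(chain, dt, "euler")
  st <- .chain_state_from_point(model, state)
  st <- stepper(st, t, I_inj, 0)
  list(state = .point_state_from_chain(model, st),
       spiked = length(st$spiked) > 0L)
}

# A single-compartment pseudo-chain operating in density units
# (cm = Cm uF/cm^2, gl = GL mS/cm^2, currents in uA/cm^2).
.point_chain <- function(model) {
  structure(list(n = 1L, cm = model$Cm, gl = model$GL,
                 gna = if (inherits(model, "wb_model")) model$GNa,
                 gk = if (inherits(model, "wb_model")) model$GK,
                 g_axon = numeric(0), positions = 0,
                 membrane = model, type = "point",
                 Rax = NA_real_, area_cm2 = NA_real_),
            class = "axon_chain")
}

.chain_state_from_point <- function(model, state) {
  st <- state
  if (inherits(model, "seif_model")) {
    st$refr <- state$refractory_remaining
    st$refractory_remaining <- NULL
  }
  st$spiked <- integer(0)
  st
}

.point_state_from_chain <- function(model, st) {
  out <- list(V = st$V)
  if (inherits(model, "wb_model")) out[c("m", "h", "n")] <- st[c("m", "h", "n")]
  if (inherits(model, "seif_model")) out$refractory_remaining <- st$refr
  if (inherits(model, "beif_model")) out[c("Trep", "active")] <- st[c("Trep", "active")]
  out
}
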