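# Time integration of compartment chains.
#
# One semi-implicit ("euler-cn") step: all membrane currents (leak, active,
# repolarizing, injected) are evaluated explicitly at the old time, and the
# linear axial coupling is advanced with the trapezoidal (Crank-Nicolson)
# rule,
#   (C/dt - L/2) V_new = (C/dt + L/2) V_old + I_mem(V_old) + I_inj + I_ex ,
# where L is the tridiagonal axial operator and the extracellular drive is
# the CN average of L applied to U_ex at the old and new times.  Because the
# conductances are constant over a simulation, the left-hand matrix is
# factorized once (inverted) and applied as a matrix-vector product each
# step; this is the same linear solve as a per-step tridiagonal elimination,
# done once.  Event logic (sEIF reset/hold, bEIF episode bookkeeping) runs
# after the voltage update; a value exactly equal to a threshold counts as a
# crossing.

.make_stepper <- function(chain, dt, scheme = c("euler-cn", "euler")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("'dt' must be positive")
  n <- chain$n
  cm <- chain$cm; gl <- chain$gl; g <- chain$g_axon
  model <- chain$membrane
  kind <- class(model)[1L]
  EL <- model$EL
  use_cn <- scheme == "euler-cn" && n > 1L
  if (use_cn) {
    A <- matrix(0, n, n)
    idx <- seq_len(n - 1L)
    A[cbind(idx, idx + 1L)] <- -g / 2
    A[cbind(idx + 1L, idx)] <- -g / 2
    diag(A) <- cm / dt + (c(g, 0) + c(0, g)) / 2
    # strictly diagonally dominant with positive diagonal for g, cm > 0
    Ainv <- solve(A)
  }
  cm_over_dt <- cm / dt
  dt_over_cm <- dt / cm

  if (kind == "wb_model") {
    gna <- chain$gna; gk <- chain$gk
    ENa <- model$ENa; EK <- model$EK; Vdet <- model$Vdetect
    rr <- model$rates
    rc <- lapply(rr, function(r) list(a = r$amplitude, v0 = r$Vref,
                                      k = r$slope, f = r$form))
  } else if (kind == "seif_model") {
    VT <- model$VT; KT <- model$KT
    Vspike <- model$Vspike; Vreset <- model$Vreset; tau_ref <- model$tau_ref
  } else if (kind == "beif_model") {
    VT <- model$VT; KT <- model$KT; AT <- model$AT
    Vrep <- model$Vrep; tau_rep <- model$tau_rep; Arep <- model$Arep
    hard_reset <- model$mode == "hard-reset"
  }

  function(state, t, inj, lex) {
    V <- state$V
    Imem <- gl * (EL - V)
    if (kind == "wb_model") {
      m <- state$m; h <- state$h; nn <- state$n
      Imem <- Imem + gna * m * m * m * h * (ENa - V) + gk * nn^4 * (EK - V)
    } else if (kind == "beif_model") {
      Imem <- Imem + gl * KT * AT / (1 + AT * exp(-(V - VT) / KT))
      if (!hard_reset && any(state$active)) {
        act <- state$active
        s <- (t - state$Trep[act]) / tau_rep
        grep <- numeric(n)
        grep[act] <- gl[act] * Arep * s * exp(1 - s)
        Imem <- Imem + grep * (EL - V)
      }
    } else if (kind == "seif_model") {
      Imem <- Imem + gl * KT * exp(pmin((V - VT) / KT, 700))
    }

    if (use_cn) {
      rhs <- cm_over_dt * V + 0.5 * .lap_apply(g, V) + Imem + inj + lex
      Vn <- drop(Ainv %*% rhs)
    } else {
      Vn <- V + dt_over_cm * (Imem + .lap_apply(g, V) + inj + lex)
    }

    spiked <- integer(0)
    if (kind == "wb_model") {
      spiked <- which(V < Vdet & Vn >= Vdet)
      r <- rc
      am <- .rate_eval(r$alpha_m$a, r$alpha_m$v0, r$alpha_m$k, r$alpha_m$f, V)
      bm <- .rate_eval(r$beta_m$a,  r$beta_m$v0,  r$beta_m$k,  r$beta_m$f,  V)
      ah <- .rate_eval(r$alpha_h$a, r$alpha_h$v0, r$alpha_h$k, r$alpha_h$f, V)
      bh <- .rate_eval(r$beta_h$a,  r$beta_h$v0,  r$beta_h$k,  r$beta_h$f,  V)
      an <- .rate_eval(r$alpha_n$a, r$alpha_n$v0, r$alpha_n$k, r$alpha_n$f, V)
      bn <- .rate_eval(r$beta_n$a,  r$beta_n$v0,  r$beta_n$k,  r$beta_n$f,  V)
      state$m <- state$m + dt * (am * (1 - state$m) - bm * state$m)
      state$h <- state$h + dt * (ah * (1 - state$h) - bh * state$h)
      state$n <- state$n + dt * (an * (1 - state$n) - bn * state$n)
    } else if (kind == "seif_model") {
      refr <- state$refr
      held <- refr > 0
      if (any(held)) {
        Vn[held] <- Vreset
        refr[held] <- refr[held] - dt
      }
      fire <- !held & Vn >= Vspike
      if (any(fire)) {
        spiked <- which(fire)
        Vn[fire] <- Vreset
        refr[fire] <- tau_ref
      }
      state$refr <- refr
    } else if (kind == "beif_model") {
      if (hard_reset) {
        fire <- Vn >= Vrep
        if (any(fire)) {
          spiked <- which(fire)
          Vn[fire] <- EL
        }
      } else {
        act <- state$active
        if (any(act)) {
          s_new <- (t + dt - state$Trep) / tau_rep
          done <- act & s_new >= 1 & s_new * exp(1 - s_new) < 1e-6 & Vn < Vrep
          act[done] <- FALSE
        }
        fire <- !act & Vn >= Vrep
        if (any(fire)) {
          spiked <- which(fire)
          act[fire] <- TRUE
          state$Trep[fire] <- t + dt
        }
        state$active <- act
      }
    }
    state$V <- Vn
    state$spiked <- spiked
    state
  }
}

#' Initial state vectors for a compartment chain
#'
#' Every compartment starts at `V = EL` (or the supplied voltage); WB
#' gates at their steady-state values for that voltage, sEIF compartments
#' non-refractory, bEIF compartments with no active repolarization
#' episode.
#'
#' @param chain An `axon_chain`.
#' @param V Starting potential(s) (mV), recycled to `chain$n`; default
#'   `EL`.
#' @return A state list as consumed by [step_chain()] and
#'   [simulate_axon()].
#' @export
chain_state <- function(chain, V = NULL) {
  stopifnot(inherits(chain, "axon_chain"))
  model <- chain$membrane
  if (is.null(V)) V <- model$EL
  V <- rep_len(V, chain$n)
  st <- list(V = V)
  if (inherits(model, "wb_model")) {
    st <- c(st, wb_steady_gates(model, V))
  } else if (inherits(model, "seif_model")) {
    st$refr <- numeric(chain$n)
  } else if (inherits(model, "beif_model")) {
    st$Trep <- rep(NA_real_, chain$n)
    st$active <- rep(FALSE, chain$n)
  }
  st$spiked <- integer(0)
  st
}

#' Advance a compartment chain by one step
#'
#' Single semi-implicit (or fully explicit) step; see [simulate_axon()]
#' for the scheme.  Intended for inspection and testing; simulations
#' should use [simulate_axon()], which prepares the linear solve once.
#'
#' @param chain An `axon_chain`.
#' @param state State list from [chain_state()] (or a previous step).
#' @param t Current time (ms).
#' @param dt Time step (ms), positive.
#' @param injected Per-compartment injected current (nA), length
#'   `chain$n` (or `NULL` for none).
#' @param scheme `"euler-cn"` or `"euler"`.
#' @return The new state; `state$spiked` holds the indices of
#'   compartments that spiked during the step.
#' @export
step_chain <- function(chain, state, t = 0, dt = 0.004, injected = NULL,
                       scheme = c("euler-cn", "euler")) {
  stopifnot(inherits(chain, "axon_chain"))
  if (is.null(injected)) injected <- numeric(chain$n)
  if (length(injected) != chain$n)
    stop("'injected' must have one entry per compartment")
  stepper <- .make_stepper(chain, dt, match.arg(scheme))
  stepper(state, t, injected, 0)
}

#' Simulate a compartment chain
#'
#' Integrates the chain for `duration_ms` with fixed step `dt_ms`,
#' recording the per-compartment voltage (optionally strided) and all
#' spike events at full resolution.  `"euler-cn"` (default) treats the
#' stiff axial coupling with the unconditionally stable Crank-Nicolson
#' rule and everything else with forward Euler; `"euler"` is fully
#' explicit.
#'
#' Spike events are: for WB, upward crossings of the detection voltage;
#' for sEIF, resets; for bEIF, upward crossings of `Vrep` (episode
#' onsets).
#'
#' @param chain An `axon_chain`.
#' @param stimulus A [step_current()], an [extracellular_stimulus()], or
#'   `NULL`.
#' @param duration_ms Total simulated time (ms).
#' @param dt_ms Time step (ms); 0.004 ms (4 us) by default.
#' @param scheme `"euler-cn"` or `"euler"`.
#' @param record_stride Record every `record_stride`-th step (the initial
#'   state is always recorded).
#' @param init Optional initial state from [chain_state()].
#' @return An object of class `axon_trace`: `times` (ms), `V`
#'   (time-by-compartment matrix, mV), `spikes` (data.frame with columns
#'   `comp`, `time_ms`), `positions` (um), `dt_ms`, `scheme`.
#' @examples
#' \donttest{
#' ax <- myelinated_axon(beif_model(), n_nodes = 41)
#' tr <- simulate_axon(ax, step_current(5, 0.1), duration_ms = 5)
#' conduction_velocity(tr, 10, 30)
#' }
#' @export
simulate_axon <- function(chain, stimulus = NULL, duration_ms,
                          dt_ms = 0.004, scheme = c("euler-cn", "euler"),
                          record_stride = 1L, init = NULL) {
  stopifnot(inherits(chain, "axon_chain"), duration_ms > 0)
  scheme <- match.arg(scheme)
  n <- chain$n
  nt <- as.integer(round(duration_ms / dt_ms))
  stopifnot(nt >= 1L)
  stride <- as.integer(record_stride)
  stopifnot(stride >= 1L)

  zero <- numeric(n)
  inj_on <- zero; lex_on <- zero
  on_from <- Inf; on_to <- -Inf; is_ext <- FALSE
  if (!is.null(stimulus)) {
    if (inherits(stimulus, "step_current")) {
      if (stimulus$site > n) stop("stimulus site outside the chain")
      inj_on[stimulus$site] <- stimulus$amplitude_nA
    } else if (inherits(stimulus, "extracellular_stimulus")) {
      is_ext <- TRUE
      uex <- extracellular_potential(stimulus, chain,
                                     t = stimulus$onset_ms)
      lex_on <- .lap_apply(chain$g_axon, uex)
    } else stop("unsupported stimulus class: ", class(stimulus)[1L])
    on_from <- stimulus$onset_ms
    on_to <- stimulus$onset_ms + stimulus$duration_ms
    if (on_to > duration_ms + dt_ms)
      warning("stimulus extends beyond the simulated duration")
  }

  stepper <- .make_stepper(chain, dt_ms, scheme)
  state <- if (is.null(init)) chain_state(chain) else init
  stopifnot(length(state$V) == n)

  nrec <- nt %/% stride + 1L
  Vrec <- matrix(NA_real_, nrec, n)
  Vrec[1L, ] <- state$V
  ev_comp <- integer(0); ev_time <- numeric(0)
  cn <- scheme == "euler-cn"

  for (i in seq_len(nt)) {
    t0 <- (i - 1L) * dt_ms
    act0 <- t0 >= on_from && t0 < on_to
    inj <- if (!is_ext && act0) inj_on else zero
    if (is_ext) {
      if (cn) {
        t1 <- i * dt_ms
        act1 <- t1 >= on_from && t1 < on_to
        lex <- 0.5 * ((if (act0) lex_on else zero) +
                      (if (act1) lex_on else zero))
      } else {
        lex <- if (act0) lex_on else zero
      }
    } else lex <- zero
    state <- stepper(state, t0, inj, lex)
    sp <- state$spiked
    if (length(sp)) {
      ev_comp <- c(ev_comp, sp)
      ev_time <- c(ev_time, rep.int(i * dt_ms, length(sp)))
    }
    if (i %% stride == 0L) Vrec[i %/% stride + 1L, ] <- state$V
  }

  structure(list(times = seq(0, by = stride * dt_ms, length.out = nrec),
                 V = Vrec,
                 spikes = data.frame(comp = ev_comp, time_ms = ev_time),
                 positions = chain$positions,
                 dt_ms = dt_ms, scheme = scheme,
                 record_stride = stride,
                 duration_ms = duration_ms,
                 n = n,
                 model = class(chain$membrane)[1L],
                 final_state = state),
            class = "axon_trace")
}

#' Simulate a single point membrane
#'
#' Forward-Euler integration of one membrane compartment in density units
#' (injected current in uA/cm^2), with a rectangular step-current
#' protocol.
#'
#' @param model A `membrane_model`.
#' @param amplitude Step-current density (uA/cm^2).
#' @param duration_ms Total simulated time (ms).
#' @param dt_ms Time step (ms).
#' @param onset_ms Stimulus onset (ms).
#' @param stim_duration_ms Stimulus duration (ms); defaults to the
#'   remainder of the simulation.
#' @param record_stride Record every k-th sample.
#' @return An `axon_trace` with a single compartment.
#' @export
simulate_point <- function(model, amplitude = 0, duration_ms = 1000,
                           dt_ms = 0.004, onset_ms = 0,
                           stim_duration_ms = NULL, record_stride = 1L) {
  stopifnot(inherits(model, "membrane_model"))
  chain <- .point_chain(model)
  stim <- NULL
  if (amplitude != 0) {
    if (is.null(stim_duration_ms)) stim_duration_ms <- duration_ms - onset_ms
    stim <- step_current(1L, amplitude, onset_ms, stim_duration_ms)
  }
  simulate_axon(chain, stim, duration_ms = duration_ms, dt_ms = dt_ms,
                scheme = "euler", record_stride = record_stride)
}
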