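# Named presets.  Every parameter table ships as a human-readable YAML file
# under inst/extdata/presets/; the resolve functions read those files, so a
# resolved preset is byte-identical to what is on disk.

.preset_dir <- function() system.file("extdata", "presets", package = "axonsim")

.preset_path <- function(name) {
  path <- file.path(.preset_dir(), paste0(name, ".yaml"))
  if (!file.exists(path))
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(list_presets(), collapse = ", ")))
  path
}

#' List shipped preset names
#'
#' @return Character vector of preset names (YAML files under
#'   `inst/extdata/presets`).
#' @export
list_presets <- function() {
  sub("\\.yaml$", "", list.files(.preset_dir(), pattern = "\\.yaml$"))
}

#' Read a preset file as a plain list
#'
#' @param name Preset name (see [list_presets()]).
#' @return Named list of the YAML contents.
#' @export
read_preset <- function(name) yaml::read_yaml(.preset_path(name))

.model_from_config <- function(cfg) {
  type <- cfg$model
  take <- function(keys) cfg[intersect(keys, names(cfg))]
  switch(type,
    wb = do.call(wb_model, take(c("Cm", "GL", "GK", "GNa", "EL", "EK", "ENa"))),
    seif = do.call(seif_model, take(c("Cm", "GL", "EL", "VT", "KT",
                                      "Vspike", "Vreset", "tau_ref"))),
    beif = do.call(beif_model, take(c("Cm", "GL", "EL", "VT", "KT", "AT",
                                      "Vrep", "tau_rep", "Arep", "mode"))),
    stop("unknown model type '", type, "' (expected wb, seif or beif)"))
}

#' Resolve a single-compartment membrane preset
#'
#' `"wb-point"`, `"seif-point"` and `"beif-point"` are the reference
#' single-compartment parameter sets; `"an-low"` / `"an-high"` resolve to
#' the auditory-nerve bEIF membranes (leak density 0.2 / 0.4 mS/cm^2,
#' soft threshold -50 mV, everything else inherited from the bEIF
#' default).
#'
#' @param name Preset name.
#' @return A `membrane_model`.
#' @examples
#' neuron_preset("beif-point")
#' @export
neuron_preset <- function(name) {
  cfg <- read_preset(name)
  if (is.null(cfg$model)) stop(sprintf("preset '%s' is not a membrane preset", name))
  .model_from_config(cfg)
}

#' Resolve a full axon experiment preset
#'
#' Builds the chain, stimulus and measurement protocol for a named
#' experiment:
#' * `"myelinated-wb"`, `"myelinated-beif"`, `"myelinated-seif"` — the
#'   141-node myelinated axon (100 pA x 1 ms at node 20, velocity from
#'   nodes 40/90); the sEIF variant defaults to dt = 0.2 us because its
#'   diverging spikes are otherwise undersampled.
#' * `"unmyelinated-wb"`, `"unmyelinated-beif"` — the 301-compartment
#'   cable (10 nA x 1 ms at compartment 50, velocity from 100/200).
#' * `"an-low"`, `"an-high"` — 40-node auditory-nerve fibers
#'   (60 pA x 1 ms at node 1, velocity from nodes 10/30).
#'
#' @param name Experiment preset name.
#' @return An object of class `axon_experiment`: a list with `name`,
#'   `chain`, `stimulus`, `dt_ms`, `duration_ms`, `scheme`,
#'   `velocity_nodes`, `config` (the merged raw configuration).
#' @examples
#' \donttest{
#' exp <- axon_preset("an-high")
#' res <- run_experiment(exp)
#' res$velocity$velocity_m_s
#' }
#' @export
axon_preset <- function(name) {
  known <- c("myelinated-wb", "myelinated-beif", "myelinated-seif",
             "unmyelinated-wb", "unmyelinated-beif", "an-low", "an-high")
  if (!name %in% known)
    stop(sprintf("unknown experiment preset '%s'; available: %s",
                 name, paste(known, collapse = ", ")))
  if (name %in% c("an-low", "an-high")) {
    cfg <- read_preset(name)
    # AN presets inherit unlisted membrane parameters from the bEIF default
    base <- read_preset("beif-point")
    cfg <- utils::modifyList(base, cfg)
    dur <- 6
  } else {
    parts <- strsplit(name, "-", fixed = TRUE)[[1L]]
    geom_name <- paste0(parts[1L], "-default")
    model_name <- paste0(parts[2L], "-point")
    cfg <- c(read_preset(model_name), read_preset(geom_name))
    dur <- if (parts[1L] == "myelinated") 10 else 18
  }
  model <- .model_from_config(cfg)
  chain <- if (cfg$kind == "myelinated") {
    myelinated_axon(model, D_um = cfg$D_um, Ln_um = cfg$Ln_um,
                    Li_um = cfg$Li_um, n_nodes = cfg$n_nodes,
                    Rax_ohm_cm = cfg$Rax_ohm_cm)
  } else {
    unmyelinated_axon(model, D_um = cfg$D_um, dx_um = cfg$dx_um,
                      n_comp = cfg$n_comp, Rax_ohm_cm = cfg$Rax_ohm_cm)
  }
  stim <- step_current(cfg$stimulus$site, cfg$stimulus$amplitude_nA,
                       duration_ms = cfg$stimulus$duration_ms)
  dt <- 0.004
  if (identical(name, "myelinated-seif")) {
    dt <- 2e-4   # 0.2 us: resolve the diverging sEIF upstroke
    dur <- 4
  }
  structure(list(name = name, chain = chain, stimulus = stim,
                 dt_ms = dt, duration_ms = dur, scheme = "euler-cn",
                 velocity_nodes = unlist(cfg$velocity_nodes),
                 config = cfg),
            class = "axon_experiment")
}
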