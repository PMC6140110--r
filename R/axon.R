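# Compartment-chain builders.  Density parameters (per cm^2) are converted
# to absolute per-compartment values at construction:
#   mV, ms, nF, uS, nA  (uS * mV = nA; nF * mV / ms = nA)
# so the integrator never mixes unit systems.

.UM_TO_CM <- 1e-4

# membrane area of one compartment, cm^2, from diameter and length in um
.compartment_area_cm2 <- function(D_um, len_um) pi * D_um * len_um * 1e-8

#' Build a myelinated axon as a chain of nodes of Ranvier
#'
#' The axon is a series of excitable nodes joined by perfectly insulated
#' internodes: internodes contribute only axial resistance, no capacitance
#' and no transmembrane conductance.  Per node,
#' `cm = pi D Ln Cm` and `gl = pi D Ln GL`; between adjacent nodes the
#' axial conductance is `g_axon = pi D^2 / (4 Li Rax)`.  Node centers are
#' spaced `Ln + Li` apart.  Nodes are indexed from 1.
#'
#' All per-compartment vectors (`cm`, `gl`, `gna`, `gk`) are stored in the
#' returned object and may be edited directly to build heterogeneous
#' chains; the shipped experiments all use uniform chains.
#'
#' @param membrane A `membrane_model` attached to every node.
#' @param D_um Axon diameter (um).
#' @param Ln_um Nodal length (um).
#' @param Li_um Internodal length (um).
#' @param n_nodes Number of nodes (>= 2).
#' @param Rax_ohm_cm Axial resistivity (Ohm cm).
#' @return An object of class `axon_chain` with fields `n`, `cm` (nF),
#'   `gl` (uS), `gna`/`gk` (uS, WB only), `g_axon` (uS, length `n - 1`),
#'   `positions` (um), `membrane`, `Rax`, `geometry`.
#' @examples
#' ax <- myelinated_axon(beif_model())
#' ax$g_axon[1]  # ~1.571e-2 uS for the default geometry
#' @export
myelinated_axon <- function(membrane, D_um = 2, Ln_um = 2, Li_um = 200,
                            n_nodes = 141, Rax_ohm_cm = 100) {
  stopifnot(inherits(membrane, "membrane_model"),
            D_um > 0, Ln_um > 0, Li_um > 0, Rax_ohm_cm > 0,
            n_nodes >= 2, n_nodes == round(n_nodes))
  n <- as.integer(n_nodes)
  area <- .compartment_area_cm2(D_um, Ln_um)
  g_axon_uS <- pi * (D_um * .UM_TO_CM)^2 /
    (4 * Li_um * .UM_TO_CM * Rax_ohm_cm) * 1e6
  .new_chain(membrane, n, area, g_axon_uS,
             positions = (seq_len(n) - 1) * (Ln_um + Li_um),
             type = "myelinated", Rax = Rax_ohm_cm,
             geometry = list(D_um = D_um, Ln_um = Ln_um, Li_um = Li_um,
                             n_nodes = n, Rax_ohm_cm = Rax_ohm_cm))
}

#' Build an unmyelinated axon as a discretized cable
#'
#' Discretizes the cable equation
#' `Cm dV/dt = IL + Iactive + (D / 4 Rax) d2V/dx2 + Iinj`
#' into compartments of length `dx`: each compartment has membrane area
#' `pi D dx` and neighbouring compartments are coupled with
#' `g_axon = pi D^2 / (4 Rax dx)`, which reproduces the continuum axial
#' term as `dx -> 0`.  A warning is issued when `dx` exceeds a tenth of
#' the passive length constant.
#'
#' @inheritParams myelinated_axon
#' @param dx_um Compartment length (um).
#' @param n_comp Number of compartments (>= 2).
#' @return An `axon_chain`; see [myelinated_axon()].
#' @export
unmyelinated_axon <- function(membrane, D_um = 10, dx_um = 20,
                              n_comp = 301, Rax_ohm_cm = 100) {
  stopifnot(inherits(membrane, "membrane_model"),
            D_um > 0, dx_um > 0, Rax_ohm_cm > 0,
            n_comp >= 2, n_comp == round(n_comp))
  n <- as.integer(n_comp)
  lam_mm <- length_constant(D_um, membrane$GL, Rax_ohm_cm)
  if (dx_um * 1e-3 > lam_mm / 10)
    warning(sprintf("dx = %g um exceeds lambda/10 = %g um; discretization may be too coarse",
                    dx_um, lam_mm * 100))
  area <- .compartment_area_cm2(D_um, dx_um)
  g_axon_uS <- pi * (D_um * .UM_TO_CM)^2 /
    (4 * Rax_ohm_cm * dx_um * .UM_TO_CM) * 1e6
  .new_chain(membrane, n, area, g_axon_uS,
             positions = (seq_len(n) - 1) * dx_um,
             type = "unmyelinated", Rax = Rax_ohm_cm,
             geometry = list(D_um = D_um, dx_um = dx_um, n_comp = n,
                             Rax_ohm_cm = Rax_ohm_cm))
}

.new_chain <- function(membrane, n, area_cm2, g_axon_uS, positions, type,
                       Rax, geometry) {
  # density -> absolute: uF/cm^2 * cm^2 = uF = 1e3 nF; mS * 1e3 = uS
  to_abs <- function(density) density * area_cm2 * 1e3
  structure(list(n = n,
                 cm = rep(to_abs(membrane$Cm), n),
                 gl = rep(to_abs(membrane$GL), n),
                 gna = if (inherits(membrane, "wb_model")) rep(to_abs(membrane$GNa), n),
                 gk = if (inherits(membrane, "wb_model")) rep(to_abs(membrane$GK), n),
                 g_axon = rep(g_axon_uS, n - 1L),
                 positions = positions,
                 membrane = membrane, type = type, Rax = Rax,
                 area_cm2 = area_cm2, geometry = geometry),
            class = "axon_chain")
}

#' Passive length constant of an unmyelinated fiber
#'
#' `lambda = sqrt(D / (4 GL Rax))`, the distance over which a steady
#' subthreshold voltage decays by `1/e` in the passive cable; it sets the
#' compartment-size requirement for the discretization.
#'
#' @param D_um Diameter (um).
#' @param GL_mS_cm2 Leak conductance density (mS/cm^2).
#' @param Rax_ohm_cm Axial resistivity (Ohm cm).
#' @return Length constant in mm.
#' @export
length_constant <- function(D_um, GL_mS_cm2, Rax_ohm_cm) {
  stopifnot(D_um > 0, GL_mS_cm2 > 0, Rax_ohm_cm > 0)
  lam_cm <- sqrt(D_um * .UM_TO_CM / (4 * GL_mS_cm2 * 1e-3 * Rax_ohm_cm))
  lam_cm * 10
}

# net axial current into each compartment (nA) for potentials u (mV):
# lap(u)_j = g_{j-1}(u_{j-1} - u_j) + g_j(u_{j+1} - u_j), sealed ends.
.lap_apply <- function(g, u) {
  n <- length(u)
  if (n == 1L) return(0)
  d <- g * (u[-1L] - u[-n])
  c(d, 0) - c(0, d)
}

#' Axial currents along a chain
#'
#' For a vector of compartment potentials, returns the net axial current
#' entering each compartment and the per-link currents.  Link `j` carries
#' `g_axon[j] * (V[j+1] - V[j])` from compartment `j + 1` into
#' compartment `j`; the net currents therefore sum to zero over the chain
#' (sealed ends carry nothing beyond the terminal compartments).
#'
#' @param chain An `axon_chain`.
#' @param V Compartment potentials (mV), length `chain$n`.
#' @return List with `net` (nA, length `n`) and `link` (nA, length
#'   `n - 1`).
#' @export
axial_currents <- function(chain, V) {
  stopifnot(inherits(chain, "axon_chain"), length(V) == chain$n)
  list(net = .lap_apply(chain$g_axon, V),
       link = chain$g_axon * (V[-1L] - V[-chain$n]))
}
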