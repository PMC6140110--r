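---
title: "Simulating spike conduction with a bounded exponential integrate-and-fire membrane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating spike conduction with a bounded exponential integrate-and-fire membrane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Integrate-and-fire (IF) neurons are the workhorse of efficient spiking
simulations, but their defining trick — an instantaneous reset of the
membrane potential after a spike — is incompatible with spatially extended
membranes.  In a chain of electrically coupled compartments, a reset acts
like an enormous negative current delivered within one time step, and the
resulting discontinuity destroys the propagating waveform.  That is why
axonal conduction studies have traditionally required Hodgkin–Huxley (HH)
type conductance models, with many parameters that are hard to constrain
(particularly for human nerves, where intracellular data are scarce).

`axonsim` implements a membrane model that keeps the economy of the
exponential integrate-and-fire (EIF) family while remaining compatible
with conduction: the **bounded EIF (bEIF)** model.  Two modifications to
the standard EIF (sEIF) make this possible:

1. the exponentially growing spike current is given a *ceiling*, so the
   upstroke of the action potential slows near its peak instead of
   diverging in finite time;
2. the hard reset is replaced by a transient, smooth **repolarizing
   conductance**, so the downstroke is an ordinary membrane current that
   coupled compartments can follow.

The package also ships the Wang–Buzsáki (WB) conductance model as the
biophysical reference and the sEIF model to demonstrate *why* the
modifications are needed.

## The membrane models

All three models share the membrane equation

$$C_m \frac{dV}{dt} = G_L (E_L - V) + \psi(V) + I_{inj},$$

with capacitance density $C_m$ (µF/cm²), linear leak $G_L$ (mS/cm²)
reversing at $E_L$ (mV), and a spike-generating term $\psi(V)$:

* **WB**: $\psi = G_{Na} m^3 h (E_{Na} - V) + G_K n^4 (E_K - V)$, with
  first-order kinetics $\dot y = \alpha_y(V)(1-y) - \beta_y(V)\,y$ for
  $y = m, h, n$.  Sodium activation is integrated (voltage-dependent time
  constant), not instantaneous.  25 parameters.
* **sEIF**: $\psi = I_{dep} = G_L K_T \exp((V - V_T)/K_T)$, a soft
  threshold $V_T$ and slope factor $K_T$; after $V$ reaches $V_{spike}$
  it is reset to and held at $V_{reset}$ for $\tau_{ref}$.  8 parameters.
* **bEIF**: $\psi = I_{dep} + I_{rep}$ with the *bounded* spike current
  $$I_{dep} = \frac{G_L K_T A_T}{1 + A_T \exp(-(V - V_T)/K_T)},
    \qquad \max I_{dep} = G_L K_T A_T,$$
  and the repolarizing current $I_{rep} = G_{rep}(t)\,(E_L - V)$, where
  $G_{rep}$ is an alpha function
  $G_L A_{rep}\, s\, e^{1-s}$, $s = (t - T_{rep})/\tau_{rep}$, started
  when $V$ first crosses the trigger voltage $V_{rep}$ from below.
  9 parameters.

Defaults (mV, ms, mS/cm², µF/cm²): $C_m = 1$, $G_L = 0.1$,
$E_L = -65.3$, $V_T = -60.2$, $K_T = 3.5$, $A_T = 520$, $V_{rep} = +10$,
$\tau_{rep} = 0.6$, $A_{rep} = 90$.  Below threshold the bEIF current is
within a factor $1 + e^{(V-V_T)/K_T}/A_T$ of the sEIF exponential, so
subthreshold behaviour is essentially unchanged; the ceiling only
reshapes the spike.  The repolarizing conductance is evaluated in closed
form from $t - T_{rep}$ at every step (no auxiliary ODE), which is exact
and cheap.

Because $I_{rep}$ rapidly overwhelms $I_{dep}$ after each spike, the
model has no explicit refractory parameter: the episode's amplitude and
time scale set an effective dead time.  We end an episode — making the
membrane eligible to trigger a new one — only once $G_{rep}$ has passed
its peak and decayed below $10^{-6}$ of it *and* $V$ has fallen back
below $V_{rep}$; the alpha function is also small immediately after
onset, so a past-peak guard is required to avoid ending an episode the
moment it starts.

A `"hard-reset"` mode replaces $I_{rep}$ by an instantaneous reset to
$E_L$; it exists to demonstrate the instability that motivates the
repolarizing current.

## Axon models and units

Internally all chain computations use mV, ms, nF, µS and nA, which are
mutually consistent (µS·mV = nA, nF·mV/ms = nA); table densities are
converted once at construction using the compartment membrane area.
This removes every unit conversion from the integrator.  Single-point
simulations (`simulate_point()`, `f_i_curve()`) work directly in density
units (µA/cm²), which are equally self-consistent.

**Myelinated axons** are chains of nodes of Ranvier joined by perfectly
insulated internodes: per node $c_m = \pi D L_n C_m$,
$g_L = \pi D L_n G_L$, and between nodes
$g_{axon} = \pi D^2/(4 L_i R_{ax})$.  Node centers sit $L_n + L_i$
apart.  Defaults: $D = 2$ µm, $L_n = 2$ µm, $L_i = 200$ µm,
$R_{ax} = 100$ Ω·cm, 141 nodes.

**Unmyelinated axons** discretize the cable equation with compartments
of length $dx = 20$ µm (301 compartments, $D = 10$ µm by default);
$g_{axon} = \pi D^2/(4 R_{ax}\, dx)$ reproduces the continuum term
$(D/4R_{ax})\,\partial^2 V/\partial x^2$ as $dx \to 0$.  The builder
warns when $dx$ exceeds a tenth of the passive length constant
$\lambda = \sqrt{D/(4 G_L R_{ax})}$.  Note that direct evaluation of
this formula with the default unmyelinated parameters gives
$\lambda \approx 1.58$ mm; `length_constant()` always reports the
formula's value.

Both ends of every chain are sealed (no axial current beyond the
terminal compartments) — the standard compartmental convention; the
measurement nodes of all shipped protocols are far from the ends.
Compartments are indexed from 1.  The per-compartment vectors (`cm`,
`gl`, `gna`, `gk`) are plain numeric fields of the chain object and can
be edited directly to build heterogeneous axons; every shipped protocol
uses uniform chains.

## Numerical scheme

The scheme is the hybrid that is standard for nodal chains: all
membrane currents are evaluated
explicitly (forward Euler) at the old time, while the stiff linear axial
coupling is advanced with the trapezoidal (Crank–Nicolson) rule:

$$\Big(\tfrac{C}{\Delta t} - \tfrac{L}{2}\Big) V^{n+1} =
  \Big(\tfrac{C}{\Delta t} + \tfrac{L}{2}\Big) V^{n} + I_{mem}(V^n) + I_{inj},$$

where $L$ is the tridiagonal axial operator.  This matters: at the
default $\Delta t = 4$ µs the explicit stability limit of the axial
coupling in the default myelinated chain is exactly at its edge
($4 g_{axon} \Delta t / c_m \approx 2$), so a fully explicit scheme
is only usable at finer steps (`scheme = "euler"` is provided for
cross-checks).  Because all conductances are constant within a
simulation, the left-hand matrix is assembled and factorized (inverted)
once and applied as a matrix–vector product per step — the same linear
solve as a per-step tridiagonal elimination, performed once instead of
every step, which is substantially faster in R.

Event logic runs after the voltage update (voltage update, then
threshold tests, then bookkeeping); a value exactly at a threshold
counts as a crossing.  The default step is $\Delta t = 4$ µs; the sEIF
conduction-failure demonstration uses 0.2 µs so that the diverging
upstroke is resolved.  Everything is deterministic — there is no
randomness anywhere in the system.

Extracellular stimulation introduces the point-source potential
$U_{ex,j} = \rho_{ex} I_{ex} / (4 \pi r_j)$ at each node
($\rho_{ex} = 3$ Ω·m); axial currents are driven by the gradient of
$U_{in} = V + U_{ex}$ while membrane currents depend on $V$ alone.  The
default geometry is the electrode at 1 mm perpendicular distance from
node 20 of a straight axon, $r_j = \sqrt{1\,\text{mm}^2 + x_j^2}$, with
a monophasic rectangular pulse (instantaneous on/off edges).  The pulse
is applied with the same Crank–Nicolson weighting as the axial term, and
a zero-amplitude extracellular source reproduces the unstimulated
trajectory bit for bit.

## What the models do

* A 100 pA × 1 ms pulse at node 20 of the default WB chain produces a
  spike that travels at ≈ 5.7 m/s (nodes 40→90 peak-time measurement);
  the bEIF chain conducts at a comparable speed with a wider propagating
  waveform, since its repolarizing conductance is static rather than
  voltage-gated.
* The sEIF chain cannot conduct: its potential diverges essentially
  instantaneously once a spike starts (the package caps the exponential
  argument at 700 so the divergence stays finite in floating point), so
  almost no charge is transferred to the neighbours before the reset.
* The hard-reset bEIF variant conducts, but the waveforms are grossly
  non-uniform across nodes — the reset discontinuity again.
* Velocity scales approximately as the square root of diameter and of
  internodal length (myelinated), and of diameter (unmyelinated);
  `fit_sqrt()` provides the closed-form least-squares coefficient
  $c = \sum u\sqrt{x} / \sum x$.
* The auditory-nerve presets (`an-low`, `an-high`) differ only in leak
  density (0.2 vs 0.4 mS/cm²) and internodal length (350 vs 450 µm) on
  a 40-node, 2.5 µm bEIF axon with $V_T = -50$ mV; the high-frequency
  (basal) fiber conducts markedly faster — the package's tonotopic
  prediction.

## Design choices and numerical caveats

* **$V_{rep}$ default.**  The shipped single-compartment default is
  $V_{rep} = +10$ mV; the ceiling-sweep protocol (`at_sweep()`) starts
  its readjustment ladder at +15 mV.  Both values are plain arguments
  and can be overridden everywhere.
* **`at_sweep()` readjustment.**  Extreme ceilings can leave the chain
  stuck depolarized after a spike (for large $A_T$ the balance voltage
  of the repolarizing conductance sits above the voltage at which
  $I_{dep}$ collapses, so no $V_{rep}$ rescues it).  The sweep lowers
  $V_{rep}$ in 5 mV steps to −20 mV until the end-of-trace potential is
  within 2 mV of rest, and flags the ceiling as failed otherwise.  With
  low trigger voltages the conducted wave peaks just below $V_{rep}$,
  so the sweep's spike criterion follows the trigger voltage down.
* **Spike times and events.**  Conduction velocity always uses voltage
  *peak* times (no sub-sample interpolation: at 4 µs over a ≥ 0.7 ms
  travel time the quantization error is well below 1 %).  bEIF spike
  *events* are the $V_{rep}$ upward crossings that start episodes.  In
  a chain, the axial length constant spans ~35 nodes, so a fraction of
  nodes ride the wave passively and peak ~1 mV below the trigger
  without starting an episode of their own; conduction remains complete
  and single-spiked per node (verifiable from the recorded voltages).
  WB events are upward crossings of a detection voltage (default
  −10 mV; WB spikes in this parameterization peak only a few mV above
  0).
* **Translation invariance.**  The propagating bEIF upstroke and peak
  are translation invariant along the chain to ~0.15 mV; the
  repolarization tail is axially coupled over the same ~35-node range
  and therefore keeps relaxing along a finite axon, differing by a few
  mV between distant nodes (a dt-independent property of the finite
  chain, not a solver artifact).
* **Initialization.**  Chains start at $V = E_L$ with WB gates at their
  steady-state values for that voltage (the WB and bEIF resting points
  lie ~0.5–1 mV above $E_L$, giving a slow, harmless baseline drift).
* **Degenerate inputs.**  Missing spikes raise a typed condition
  (`axonsim_no_spike`), equal peak times a typed undefined-velocity
  error; geometry and threshold invariants are validated at
  construction.

## Problem sizes

The shipped protocols are the full-size ones: 141-node myelinated
chains (~2,500–5,000 steps at 4 µs), 301-compartment unmyelinated
cables (~4,500 steps), 40-node auditory-nerve fibers, diameter sweeps
over 7 × and 5 × geometries, and 0.2 µs resolution (20,000 steps) for
the sEIF demonstration.  Each chain simulation takes well under a
second; the complete velocity-scaling analysis runs in a few seconds.
f–I curves integrate 0.4–1 s of membrane time per amplitude.

## What passing tests do and do not show

The test suite verifies the current equations against hand-evaluated
values, the discretization against linear cable theory (matrix
exponential on a passive chain), conduction against the published
velocities and scaling laws, and the qualitative claims (sEIF failure,
hard-reset non-uniformity, extracellular activating pattern, Type I
excitability).  All of this concerns the *model*: idealized uniform
axons with perfectly insulating myelin, all channels at the nodes, no
channel noise, no temperature dependence, and somatic parameters
applied to axons.  Agreement with the model's published numbers is not
evidence about real nerves beyond what the original calibration
supports.

## Known limitations

* No after-spike hyperpolarization: $I_{rep}$ reverses at $E_L$, so the
  bEIF spike does not undershoot as the WB spike does.
* Branched axons, imperfect myelin, heterogeneous channel
  distributions, channel noise and biphasic/charge-balanced stimulation
  are out of scope.
* The fully explicit scheme is only conditionally stable; at the
  default 4 µs step on the default myelinated geometry it sits at the
  stability boundary and should not be used there.
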