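# axonsim

Compartmental simulation of action-potential conduction along axons with
a **bounded exponential integrate-and-fire (bEIF)** membrane.

## Why

Simulating spikes that *travel* — along myelinated or unmyelinated
axons, driven intracellularly or by an extracellular electrode — has
traditionally required Hodgkin–Huxley-type conductance models, because
the instantaneous voltage reset of ordinary integrate-and-fire (IF)
neurons destroys a propagating waveform.  That is a problem wherever
computational efficiency matters (thousands of fibers in a prosthetic
simulation) or data to constrain 25+ parameters do not exist (human
nerves).

The bEIF model keeps the 9-parameter economy of the exponential IF
family but is compatible with conduction, via two changes to the
standard EIF (sEIF) model:

* a **ceiling** on the spike-generating current,

  `Idep = GL·KT·AT / (1 + AT·exp(−(V − VT)/KT))`,  `max Idep = GL·KT·AT`,

  so the upstroke slows near the peak instead of diverging, and
* an **alpha-function repolarizing conductance**
  `Grep(t) = GL·Arep·s·e^(1−s)`, `s = (t − Trep)/τ_rep`, started when
  `V` crosses the trigger voltage `Vrep`, replacing the hard reset with
  a smooth membrane current.

The package ships the Wang–Buzsáki (WB) conductance model as the
biophysical reference, the sEIF model (whose conduction failure
motivates the design), chain builders for myelinated (nodes of Ranvier
+ perfectly insulated internodes) and unmyelinated (discretized cable)
axons, a hybrid forward-Euler/Crank–Nicolson integrator, intracellular
and point-source extracellular stimulation, and analysis tools
(conduction velocity, f–I curves, square-root scaling fits, waveform
metrics).  Parameter sets — including low-/high-frequency
auditory-nerve fiber presets — ship as YAML presets.

## Worked example

```r
library(axonsim)

## default myelinated axon: 141 bEIF nodes, D = 2 um, internodes 200 um
ax <- myelinated_axon(beif_model())
ax
#> <axon_chain> myelinated, 141 compartments, beif_model membrane
#>   spacing 202 um, g_axon 0.01571 uS, cm 0.0001257 nF, gl 1.257e-05 uS per compartment

## 100 pA x 1 ms at node 20, 10 ms at dt = 4 us
tr <- simulate_axon(ax, step_current(site = 20, amplitude_nA = 0.1,
                                     duration_ms = 1), duration_ms = 10)
conduction_velocity(tr, 40, 90)
#> <velocity_estimate> 5.65 m/s (compartments 40 -> 90, 10.1 mm in 1.788 ms)
```

The spike peaks at nodes 40 and 90 are 1.788 ms apart over 10.1 mm of
axon: 5.65 m/s, essentially the speed of the same axon built from WB
nodes (5.71 m/s) — the conduction velocity is insensitive to the details
of the spike-generating mechanism.

```r
## high-frequency auditory-nerve preset: 40 bEIF nodes, GL = 0.4 mS/cm2,
## Li = 450 um, 60 pA x 1 ms at node 1
run_experiment(axon_preset("an-high"))$velocity
#> <velocity_estimate> 14.4 m/s (compartments 10 -> 30, 9.04 mm in 0.628 ms)

## velocity scales as the square root of the diameter
sw <- sweep_diameter()           # D = 1..8 um, diameter-scaled stimulus
fit_sqrt(sw$D_um, sw$velocity_m_s, predictor = "D")
#> <sqrt_fit> u = 4.032 * sqrt(D)  (7 points, residual norm 0.219)
```

The low-frequency preset (`an-low`: GL = 0.2 mS/cm², Li = 350 µm)
conducts at 9.12 m/s — the model predicts that high-frequency (basal)
auditory-nerve fibers conduct faster than low-frequency (apical) ones.

`vignettes/axon-conduction.Rmd` describes the models, the unit system,
the numerical scheme and the design decisions in detail.  A thin
command-line wrapper lives at `inst/cli/axonsim.R`
(`Rscript inst/cli/axonsim.R list-presets`).

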