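# Shared fixtures for the test suite.  Everything is built in code; the
# system is fully deterministic, so no seeds are needed.

# default myelinated chains, built once per test run
default_beif_axon <- function(...) myelinated_axon(beif_model(), ...)
default_wb_axon <- function(...) myelinated_axon(wb_model(), ...)

# the standard intracellular velocity protocol: 100 pA x 1 ms at node 20
standard_stim <- function() step_current(20, 0.1, duration_ms = 1)

# upward crossings of a voltage level in the recorded trace of one
# compartment (an event count independent of the models' trigger logic)
count_crossings <- function(trace, comp, level = -10) {
  v <- trace$V[, comp]
  sum(v[-length(v)] < level & v[-1] >= level)
}

# peak-aligned waveform of one compartment on a relative time grid
aligned_waveform <- function(trace, comp, grid) {
  tp <- spike_peak_time(trace, comp)
  stats::approx(trace$times - tp, trace$V[, comp], xout = grid)$y
}

# caches traces that several test files reuse (each is ~0.2 s to produce,
# but the acceptance file reuses them repeatedly)
.trace_cache <- new.env(parent = emptyenv())
cached_trace <- function(key, build) {
  if (is.null(.trace_cache[[key]])) .trace_cache[[key]] <- build()
  .trace_cache[[key]]
}

beif_reference_trace <- function() {
  cached_trace("beif_myel", function()
    simulate_axon(default_beif_axon(), standard_stim(), duration_ms = 12))
}

wb_reference_trace <- function() {
  cached_trace("wb_myel", function()
    simulate_axon(default_wb_axon(), standard_stim(), duration_ms = 10))
}
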