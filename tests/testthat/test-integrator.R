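# The hybrid forward-Euler / Crank-Nicolson chain integrator.

test_that("a passive chain matches the matrix-exponential solution", {
  skip_if_not_installed("Matrix")
  pm <- passive_model()
  ax <- myelinated_axon(pm, n_nodes = 5)
  V0 <- rep(pm$EL, 5); V0[3] <- V0[3] + 1          # +1 mV displacement
  dt <- 0.001
  tr <- simulate_axon(ax, NULL, duration_ms = 0.5, dt_ms = dt,
                      init = chain_state(ax, V = V0))
  # exact linear solution: V(t) = EL + expm(M t) (V0 - EL),
  # M = C^-1 (L - diag(gl))
  L <- diag(-(c(ax$g_axon, 0) + c(0, ax$g_axon)))
  L[cbind(1:4, 2:5)] <- ax$g_axon
  L[cbind(2:5, 1:4)] <- ax$g_axon
  M <- (L - diag(ax$gl)) / ax$cm[1]
  for (tt in c(0.1, 0.25, 0.5)) {
    exact <- pm$EL + as.vector(Matrix::expm(M * tt) %*% (V0 - pm$EL))
    got <- tr$V[which.min(abs(tr$times - tt)), ]
    expect_equal(got, exact, tolerance = 1e-4)
  }
  # symmetric spread around the displaced compartment
  expect_equal(tr$V[, 2], tr$V[, 4], tolerance = 1e-12)
  expect_equal(tr$V[, 1], tr$V[, 5], tolerance = 1e-12)
})

test_that("a chain at its resting fixed point stays there", {
  b <- beif_model()
  fp <- uniroot(function(V) b$GL * (b$EL - V) + beif_dep_current(b, V),
                c(-66, -62), tol = 1e-12)$root
  ax <- myelinated_axon(b, n_nodes = 11)
  tr <- simulate_axon(ax, NULL, duration_ms = 5,
                      init = chain_state(ax, V = fp))
  expect_lt(max(abs(tr$V - fp)), 1e-6)
  expect_identical(nrow(tr$spikes), 0L)
})

test_that("Crank-Nicolson treatment of the axial coupling is stable at 10x dt", {
  pm <- passive_model()
  ax <- myelinated_axon(pm, n_nodes = 21)
  V0 <- rep(pm$EL, 21); V0[11] <- -35
  tr <- simulate_axon(ax, NULL, duration_ms = 2, dt_ms = 0.04,
                      init = chain_state(ax, V = V0))
  expect_true(all(is.finite(tr$V)))
  # no amplification beyond the initial 30 mV displacement
  expect_lte(max(abs(tr$V - pm$EL)), 30 + 1e-9)
  # the displacement has spread across the chain (30 mV over 21
  # compartments, with only ~20 % leak decay over 2 ms)
  expect_lt(max(abs(tr$V[nrow(tr$V), ] - pm$EL)), 2)
})

test_that("explicit and semi-implicit schemes agree where both resolve the chain", {
  # at dt = 1 us the axial step limit of the explicit scheme is respected
  ax <- myelinated_axon(beif_model())
  st <- step_current(20, 0.1, duration_ms = 1)
  dt <- 0.001
  cn <- simulate_axon(ax, st, duration_ms = 8, dt_ms = dt, scheme = "euler-cn")
  eu <- simulate_axon(ax, st, duration_ms = 8, dt_ms = dt, scheme = "euler")
  expect_lte(abs(spike_peak_time(cn, 90) - spike_peak_time(eu, 90)),
             2 * dt + 1e-9)
  expect_lte(abs(spike_peak_time(cn, 40) - spike_peak_time(eu, 40)),
             2 * dt + 1e-9)
})

test_that("step_chain advances one step and reports spikes", {
  ax <- myelinated_axon(beif_model(), n_nodes = 5)
  st <- chain_state(ax)
  st2 <- step_chain(ax, st, t = 0, dt = 0.004)
  expect_length(st2$V, 5L)
  expect_identical(st2$spiked, integer(0))
  # compartments lifted above Vrep trigger episodes in one step (uniform
  # displacement, so no axial current pulls them back down)
  st$V <- rep(20, 5)
  st3 <- step_chain(ax, st, t = 0, dt = 0.004)
  expect_identical(st3$spiked, 1:5)
  expect_true(all(st3$active))
  expect_equal(st3$Trep, rep(0.004, 5))
  expect_error(step_chain(ax, st, dt = 0.004, injected = 1:2), "per compartment")
})

test_that("spike conduction is stable and ordered for WB and bEIF chains", {
  for (tr in list(wb_reference_trace(), beif_reference_trace())) {
    # every node past the stimulated one carries exactly one action
    # potential (one suprathreshold excursion, no re-excitation)
    crossings <- vapply(21:141, function(nd) count_crossings(tr, nd),
                        numeric(1))
    expect_true(all(crossings == 1))
    peaks <- vapply(c(30, 50, 70, 90, 110), function(nd)
      spike_peak_time(tr, nd), numeric(1))
    expect_true(all(diff(peaks) > 0))   # monotone travel away from node 20
  }
  # WB spike events (detection-voltage crossings) agree with the trace
  trw <- wb_reference_trace()
  cnt <- table(factor(trw$spikes$comp[trw$spikes$comp >= 21], levels = 21:141))
  expect_true(all(cnt == 1))
})

test_that("the propagating bEIF waveform is translation invariant up the chain", {
  tr <- beif_reference_trace()
  # rising phase and peak: node 80 is node 60 shifted by 20 per-node delays
  g <- seq(-1, 0.1, by = 0.004)
  dev <- abs(aligned_waveform(tr, 60, g) - aligned_waveform(tr, 80, g))
  expect_lt(max(dev, na.rm = TRUE), 0.5)
  # whole waveform including the axially-coupled repolarization tail
  full <- waveform_uniformity(tr, c(60, 80), ref = 60,
                              window_ms = c(-0.5, 1.5))
  expect_lt(max(full), 5)
})

test_that("halving dt changes the node 40 -> 90 travel time by < 1 %", {
  travel <- function(dt) {
    tr <- simulate_axon(myelinated_axon(beif_model()),
                        step_current(20, 0.1, duration_ms = 1),
                        duration_ms = 10, dt_ms = dt)
    spike_peak_time(tr, 90) - spike_peak_time(tr, 40)
  }
  t4 <- travel(0.004); t2 <- travel(0.002)
  expect_lt(abs(t4 - t2) / t2, 0.01)
})

test_that("the hard-reset variant conducts but with non-uniform waveforms", {
  axh <- myelinated_axon(beif_model(mode = "hard-reset"))
  trh <- simulate_axon(axh, step_current(20, 0.1, duration_ms = 1),
                       duration_ms = 10)
  # activity still propagates to the far nodes
  expect_gt(max(trh$V[, 120]), -20)
  # but peak-aligned waveforms differ grossly, far above the uniform bound
  devh <- waveform_uniformity(trh, c(60, 80), ref = 60,
                              window_ms = c(-0.5, 1.5))
  expect_gt(max(devh), 5)
})

test_that("the sEIF chain fails to propagate spikes that the bEIF chain conducts", {
  e <- axon_preset("myelinated-seif")
  trs <- simulate_axon(e$chain, e$stimulus, duration_ms = e$duration_ms,
                       dt_ms = e$dt_ms)
  # the stimulated node diverges and resets, but the spike does not
  # travel: nodes past the stimulus never reach a suprathreshold peak
  expect_error(spike_peak_time(trs, 40), class = "axonsim_no_spike")
  expect_error(spike_peak_time(trs, 90), class = "axonsim_no_spike")
  expect_lt(length(unique(trs$spikes$comp)), 5)
  # the bEIF chain under the matched protocol reaches every node
  trb <- beif_reference_trace()
  expect_gt(spike_peak_time(trb, 90), spike_peak_time(trb, 40))
})
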