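# Membrane current equations and per-step event logic of the three models.

test_that("WB active current follows GNa m^3 h (ENa-V) + GK n^4 (EK-V)", {
  wb <- wb_model()
  # closed gates carry no current
  expect_equal(wb_active_current(wb, -30, 0, 0, 0), 0)
  # zero driving force for Na with K gates closed
  expect_equal(wb_active_current(wb, wb$ENa, 1, 1, 0), 0)
  # direct evaluation with the default densities
  expect_equal(wb_active_current(wb, -65, 0.5, 0.5, 0.5),
               35 * 0.125 * 0.5 * (55 + 65) + 15 * 0.0625 * (-90 + 65))
  expect_error(wb_active_current(wb, -65, 1.5, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("sEIF spike current is the exponential of Table-type parameters", {
  s <- seif_model()
  expect_equal(seif_dep_current(s, s$VT), s$GL * s$KT)
  expect_equal(seif_dep_current(s, s$VT + s$KT), s$GL * s$KT * exp(1))
  expect_equal(seif_dep_current(s, -65.3), 0.08151526451, tolerance = 1e-9)
  # strictly increasing and positive on a voltage grid
  v <- seq(-100, 40, by = 0.5)
  iv <- seif_dep_current(s, v)
  expect_true(all(iv > 0))
  expect_true(all(diff(iv) > 0))
  # the overflow guard keeps extreme voltages finite
  expect_true(is.finite(seif_dep_current(s, 1e7)))
})

test_that("bEIF spike current is bounded, monotone, and matches sEIF subthreshold", {
  b <- beif_model()
  s <- seif_model()
  ceiling_val <- b$GL * b$KT * b$AT
  expect_equal(beif_dep_current(b, b$VT), 0.349328215, tolerance = 1e-9)
  # strict bound and monotonicity over the physiological range
  v <- seq(-120, 40, by = 0.25)
  iv <- beif_dep_current(b, v)
  expect_true(all(iv > 0))
  expect_true(all(iv < ceiling_val))
  expect_true(all(diff(iv) > 0))
  # never exceeds the ceiling anywhere, and saturates at it when far above VT
  expect_true(all(beif_dep_current(b, seq(40, 500, by = 5)) <= ceiling_val))
  expect_equal(beif_dep_current(b, 500), ceiling_val, tolerance = 1e-12)
  # algebraic subthreshold bound: |Ib - Is|/Is <= e^((V-VT)/KT)/AT for V <= VT
  vsub <- seq(-100, b$VT, by = 0.25)
  rel <- abs(beif_dep_current(b, vsub) - seif_dep_current(s, vsub)) /
    seif_dep_current(s, vsub)
  expect_true(all(rel <= exp((vsub - b$VT) / b$KT) / b$AT + 1e-12))
  # at VT - 3 KT the two agree within e^3/AT (~3.9 %)
  v3 <- b$VT - 3 * b$KT
  expect_lt(abs(beif_dep_current(b, v3) - seif_dep_current(s, v3)) /
              seif_dep_current(s, v3), exp(3) / b$AT)
})

test_that("repolarizing conductance is an alpha function peaking at GL*Arep", {
  b <- beif_model()
  expect_equal(beif_rep_conductance(b, 0), 0)
  expect_equal(beif_rep_conductance(b, b$tau_rep), b$GL * b$Arep)  # 9.0 mS/cm^2
  expect_equal(beif_rep_conductance(b, 5 * b$tau_rep), 0.82420375,
               tolerance = 1e-9)
  # the peak at s = 1 is the global maximum
  ts <- seq(0, 10 * b$tau_rep, by = 0.01)
  expect_true(all(beif_rep_conductance(b, ts) <= b$GL * b$Arep + 1e-12))
  expect_error(beif_rep_conductance(b, -0.1), "non-negative")
})

test_that("model constructors enforce their invariants and parameter counts", {
  expect_error(seif_model(VT = -60, Vreset = -50), "Vreset <= VT")
  expect_error(beif_model(AT = -1))
  expect_error(wb_model(EK = -60), "EK < EL < ENa")
  expect_error(passive_model(GL = 0))
  expect_identical(n_parameters(wb_model()), 25L)
  expect_identical(n_parameters(seif_model()), 8L)
  expect_identical(n_parameters(beif_model()), 9L)
})

test_that("the bEIF resting fixed point sits where the current balance says", {
  b <- beif_model()
  # independent oracle: 1-D root find of GL (EL - V) + Idep(V) = 0
  fp <- uniroot(function(V) b$GL * (b$EL - V) + beif_dep_current(b, V),
                c(-66, -62), tol = 1e-10)$root
  expect_equal(fp, -64.18, tolerance = 1e-3)
  st <- membrane_state(b, V = fp)
  out <- step_point_neuron(b, st, dt = 0.004)
  # one Euler step from the fixed point moves by less than its truncation
  expect_lt(abs(out$state$V - fp), 1e-8)
  expect_false(out$spiked)
})

test_that("WB initialized at steady state barely moves without input", {
  wb <- wb_model()
  st <- membrane_state(wb)           # V = EL, gates at steady state
  out <- step_point_neuron(wb, st, dt = 0.004)
  # residual active current at EL is ~0.06 uA/cm^2 -> |dV| ~ 2.6e-4 mV
  expect_lt(abs(out$state$V - wb$EL), 1e-3)
  expect_true(all(unlist(out$state[c("m", "h", "n")]) >= 0 &
                  unlist(out$state[c("m", "h", "n")]) <= 1))
})

test_that("sEIF holds the potential at Vreset during the refractory period", {
  s <- seif_model()
  st <- membrane_state(s)
  st$refractory_remaining <- 1.0
  st$V <- s$Vreset
  out <- step_point_neuron(s, st, dt = 0.004, I_inj = 100)  # huge input
  expect_equal(out$state$V, s$Vreset)
  expect_equal(out$state$refractory_remaining, 1.0 - 0.004)
  expect_false(out$spiked)
})

test_that("step_point_neuron rejects a non-positive time step", {
  expect_error(step_point_neuron(beif_model(), membrane_state(beif_model()),
                                 dt = 0), "positive")
})
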