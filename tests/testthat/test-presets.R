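# Presets, configuration round-trips, and the experiment runner.

test_that("membrane presets resolve to the shipped parameter values", {
  wb <- neuron_preset("wb-point")
  expect_equal(wb[c("GNa", "GK", "EL", "EK", "ENa", "Cm", "GL")],
               list(GNa = 35.0, GK = 15.0, EL = -65, EK = -90, ENa = 55,
                    Cm = 1.0, GL = 0.1))
  be <- neuron_preset("beif-point")
  expect_equal(be[c("VT", "KT", "AT", "tau_rep", "Arep", "Vrep", "EL")],
               list(VT = -60.2, KT = 3.5, AT = 520, tau_rep = 0.60,
                    Arep = 90, Vrep = 10, EL = -65.3))
  se <- neuron_preset("seif-point")
  expect_equal(se[c("VT", "KT", "Vspike", "Vreset", "tau_ref")],
               list(VT = -60.2, KT = 3.5, Vspike = 15, Vreset = -65.3,
                    tau_ref = 2.8))
  expect_error(neuron_preset("nonsense"), "unknown preset")
})

test_that("auditory-nerve presets carry their tonotopic parameters exactly", {
  lo <- axon_preset("an-low"); hi <- axon_preset("an-high")
  expect_equal(lo$chain$membrane$GL, 0.2)
  expect_equal(hi$chain$membrane$GL, 0.4)
  expect_equal(lo$chain$membrane$VT, -50.0)
  expect_equal(hi$chain$membrane$VT, -50.0)
  expect_equal(lo$chain$geometry$Li_um, 350)
  expect_equal(hi$chain$geometry$Li_um, 450)
  expect_equal(lo$chain$geometry$D_um, 2.5)
  expect_identical(lo$chain$n, 40L)
  # everything else inherits the bEIF defaults
  expect_equal(lo$chain$membrane$AT, 520)
  expect_equal(lo$chain$membrane$tau_rep, 0.6)
  expect_equal(lo$chain$membrane$EL, -65.3)
  # 60 pA x 1 ms at node 1; velocity between nodes 10 and 30
  expect_equal(lo$stimulus$amplitude_nA, 0.06)
  expect_identical(lo$stimulus$site, 1L)
  expect_equal(lo$velocity_nodes, c(10, 30))
  expect_error(axon_preset("an-mid"), "unknown experiment preset")
})

test_that("preset serialization round-trips", {
  for (nm in c("wb-point", "beif-point", "an-low")) {
    cfg <- read_preset(nm)
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(cfg, tmp)
    expect_identical(yaml::read_yaml(tmp), cfg)
    unlink(tmp)
  }
})

test_that("re-running an experiment is bit-identical (the system is deterministic)", {
  e <- axon_preset("an-low")
  a <- simulate_axon(e$chain, e$stimulus, duration_ms = 3, dt_ms = e$dt_ms)
  b <- simulate_axon(e$chain, e$stimulus, duration_ms = 3, dt_ms = e$dt_ms)
  expect_identical(a$V, b$V)
  expect_identical(a$spikes, b$spikes)
})

test_that("run_experiment writes a complete, structurally valid bundle", {
  out <- tempfile("bundle")
  res <- run_experiment("myelinated-beif", out_dir = out)
  # 141 voltage columns plus time
  tab <- utils::read.delim(file.path(out, "trace.tsv"))
  expect_identical(ncol(tab), 142L)
  # the action potential reaches every node downstream of the stimulus;
  # episode-onset events fire at most once per node (spike times of nodes
  # whose own repolarization episode started; nodes between them ride the
  # wave passively and peak just below the trigger voltage)
  spk <- utils::read.delim(file.path(out, "spikes.tsv"))
  expect_true(all(table(spk$comp) <= 1))
  expect_gt(sum(spk$comp >= 21), 80)
  peaks <- vapply(21:141, function(nd) max(res$trace$V[, nd]), numeric(1))
  expect_true(all(peaks > 0))
  vel <- utils::read.delim(file.path(out, "velocity.tsv"))
  expect_identical(nrow(vel), 1L)
  expect_true(is.finite(vel$velocity_m_s))
  # resolved config and log sit next to the results
  expect_true(file.exists(file.path(out, "config.yaml")))
  expect_true(file.exists(file.path(out, "log.txt")))
  expect_false(is.null(res$velocity))
  unlink(out, recursive = TRUE)
})

test_that("malformed experiment configurations are rejected before simulation", {
  expect_error(resolve_experiment(list()), "empty")
  expect_error(resolve_experiment(list(model = "beif", kind = "myelinated")),
               "missing field")
  expect_error(resolve_experiment(list(model = "beif", kind = "spiral",
                                       stimulus = list(site = 1,
                                                       amplitude_nA = 0.1))),
               "myelinated")
  expect_error(resolve_experiment(list(model = "quadratic", kind = "myelinated",
                                       stimulus = list(site = 1,
                                                       amplitude_nA = 0.1))),
               "unknown model")
})

test_that("an explicit config runs end to end through the resolver", {
  cfg <- list(model = "beif", kind = "myelinated", n_nodes = 41,
              stimulus = list(site = 5, amplitude_nA = 0.1, duration_ms = 1),
              velocity_nodes = c(10, 30),
              solver = list(dt_us = 4, duration_ms = 6))
  res <- run_experiment(cfg)
  expect_equal(res$velocity$node_a, 10)
  expect_true(is.finite(res$velocity$velocity_m_s))
})
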