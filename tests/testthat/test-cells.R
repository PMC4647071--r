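test_that("density table encodes laminar channel structure", {
  tb <- granule_cell_table()
  expect_equal(tb$densities["na", "outer"], 0)        # no distal sodium
  expect_equal(tb$densities["ka", "soma"], 0.108)     # A-type is somatic
  expect_true(all(tb$densities["ka", -1] == 0))
  expect_true(all(tb$densities >= 0))
  expect_equal(mossy_cell_table()$area_cm2, 2.51e-3)
})

test_that("granule cell reproduces tabulated passive properties", {
  p <- memo("gc_passive", measure_passive(build_granule_cell()))
  expect_equal(p$rmp_mV, -75.01, tolerance = 1 / 75)  # +/- 1 mV
  expect_equal(p$rin_Mohm, 185.86, tolerance = 0.05)
  expect_equal(p$tau_m_ms, 31, tolerance = 0.15)
})

test_that("point cells rest at their tabulated potentials", {
  pm <- memo("mc_passive", measure_passive(build_point_cell("MC")))
  expect_lt(abs(pm$rmp_mV - -64.75), 1)
  pb <- measure_passive(build_point_cell("BC"))
  expect_lt(abs(pb$rmp_mV - -65), 1)
  expect_error(build_point_cell("XX"))
})

test_that("fully passive cell relaxes to the leak reversal with tau = Cm/g", {
  prm <- mossy_cell_table()
  prm$densities <- c(na = 0)
  prm$leak_S_cm2 <- 2.9e-4
  prm$cm_uF_cm2 <- 9.8
  prm$area_cm2 <- 1e-5
  cell <- build_point_cell("MC", prm)
  p <- measure_passive(cell)
  expect_equal(p$rmp_mV, prm$rmp_mV, tolerance = 1e-6)
  expect_equal(p$tau_m_ms, 9.8e-6 / 2.9e-4 * 1e3, tolerance = 0.01)
  expect_equal(p$rin_Mohm, 1 / (1e-5 * 2.9e-4) / 1e6, tolerance = 0.01)
})

test_that("a cell with all densities zeroed is passive at the leak reversal", {
  tb <- granule_cell_table()
  tb$densities[] <- 0
  cell <- build_granule_cell(tb)
  tr <- run_cell(cell, duration = 500)
  expect_equal(tr$v[nrow(tr$v), 1], tb$rmp_mV, tolerance = 1e-4)
  expect_length(tr$spikes, 0)
})

test_that("all cell types are quiescent for 4 s without synaptic input", {
  for (cell in list(build_granule_cell(), build_point_cell("BC"),
                    build_point_cell("MC"))) {
    tr <- run_cell(cell, duration = 4000, probe_every = 100L)
    expect_length(tr$spikes, 0)
    expect_true(all(tr$v > -120 & tr$v < 60))
  }
})

test_that("integration converges: halving dt barely changes the trace", {
  cell <- build_granule_cell()
  inj <- data.frame(amp = 0.03, t0 = 100, t1 = 1500)  # subthreshold
  tr1 <- run_cell(cell, duration = 2000, dt = 0.1, inj = inj,
                  probe_every = 10L)
  tr2 <- run_cell(cell, duration = 2000, dt = 0.05, inj = inj,
                  probe_every = 20L)
  n <- min(nrow(tr1$v), nrow(tr2$v))
  expect_lt(max(abs(tr1$v[1:n, 1] - tr2$v[1:n, 1])), 1)
})

test_that("integration is deterministic", {
  cell <- build_point_cell("BC")
  inj <- data.frame(amp = 0.1, t0 = 50, t1 = 500)
  a <- run_cell(cell, duration = 600, inj = inj)
  b <- run_cell(cell, duration = 600, inj = inj)
  expect_identical(a$v, b$v)
  expect_identical(a$spikes, b$spikes)
})

test_that("gating variables are well-formed over the voltage grid", {
  v <- seq(-120, 60, by = 0.5)
  for (ch in channel_kinetics()) {
    for (g in ch$gates) {
      x <- g$inf(v)
      expect_true(all(is.finite(x) & x >= 0 & x <= 1))
      expect_true(all(g$tau(v) > 0))
    }
  }
})

test_that("missing density regions raise a configuration error", {
  tb <- granule_cell_table()
  colnames(tb$densities)[5] <- "elsewhere"
  expect_error(build_granule_cell(tb), "outer")
})
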