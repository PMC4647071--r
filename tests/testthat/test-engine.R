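test_that("a fully decoupled network is silent", {
  net <- tiny_network()
  zero <- setNames(rep(0, length(net$base_weights)),
                   names(net$base_weights))
  sim <- dg_simulate(net, stimulus_spec(duration_ms = 1000),
                     weight_multipliers = zero, seed = 1)
  expect_equal(sum(sim$counts), 0)
  expect_equal(nrow(sim$raster), 0)
  expect_gt(sim$ec_spikes, 0)
})

test_that("identical seeds give bit-identical rasters", {
  net <- tiny_network()
  a <- dg_simulate(net, stimulus_spec(duration_ms = 1500), seed = 4)
  b <- dg_simulate(net, stimulus_spec(duration_ms = 1500), seed = 4)
  expect_identical(a$raster, b$raster)
  c2 <- dg_simulate(net, stimulus_spec(duration_ms = 1500), seed = 5)
  expect_false(identical(a$raster, c2$raster))
})

test_that("no granule spike precedes the first entorhinal spike plus delay", {
  net <- tiny_network()
  ff_only <- c(bc_gc = 0, gc_bc = 0, mec_bc = 0, lec_bc = 0)
  spec <- stimulus_spec(duration_ms = 2000)
  sim <- dg_simulate(net, spec, weight_multipliers = ff_only, seed = 8)
  ec <- net$ec
  first_ec <- min(vapply(seq_len(nrow(ec)), function(i) {
    t <- poisson_ramp_train(spec, ec$id[i], seed = 8,
                            population = as.character(ec$population[i]))
    if (length(t)) t[1] else Inf
  }, 0))
  gc_t <- sim$raster$t_ms[sim$raster$population == "GC"]
  if (length(gc_t)) expect_gte(min(gc_t), first_ec + 0.8)
})

test_that("every presynaptic spike schedules exactly out-degree deliveries", {
  lay <- tiny_layout(7)
  g <- suppressMessages(wire_network(lay, include_mc = TRUE, seed = 7))
  net <- dg_network(lay, g)
  spec <- stimulus_spec(duration_ms = 1200)
  sim <- dg_simulate(net, spec, seed = 2)

  outdeg <- function(pathway, pop) {
    e <- g$edges[[pathway]]
    tabulate(e$pre, nbins = max(lay$id[lay$population == pop]))
  }
  # out-degree per source, by population
  od <- list(
    GC = outdeg("gc_bc", "GC") + outdeg("gc_mc", "GC"),
    BC = outdeg("bc_gc", "BC"),
    MC = outdeg("mc_gc", "MC") + outdeg("mc_bc", "MC"),
    MEC = outdeg("mec_gc", "MEC") + outdeg("mec_bc", "MEC"),
    LEC = outdeg("lec_gc", "LEC") + outdeg("lec_bc", "LEC"))
  expected <- 0
  for (p in c("GC", "BC", "MC")) {
    r <- sim$raster[sim$raster$population == p, ]
    if (nrow(r)) expected <- expected + sum(od[[p]][r$cell_id])
  }
  ec <- net$ec
  for (i in seq_len(nrow(ec))) {
    t <- poisson_ramp_train(spec, ec$id[i], seed = 2,
                            population = as.character(ec$population[i]))
    expected <- expected +
      length(t) * od[[as.character(ec$population[i])]][ec$id[i]]
  }
  expect_equal(sim$deliveries, expected)
})

test_that("total_spikes is consistent and additive over windows", {
  net <- tiny_network()
  sim <- memo("tiny_sim", dg_simulate(net, stimulus_spec(), seed = 4))
  n_gc <- total_spikes(sim, "GC")
  expect_equal(n_gc, sim$counts[match("GC", sim$populations)])
  parts <- vapply(seq(0, 3500, by = 500), function(t0)
    total_spikes(sim, "GC", c(t0, t0 + 500)), 0)
  expect_equal(sum(parts), n_gc)
  empty <- make_raster(integer(0), numeric(0), numeric(0))
  expect_equal(total_spikes(empty, "GC"), 0)
})

test_that("raster files round-trip", {
  net <- tiny_network()
  sim <- memo("tiny_sim", dg_simulate(net, stimulus_spec(), seed = 4))
  f <- tempfile(fileext = ".tsv")
  write_raster(sim$raster, f)
  r2 <- read_raster(f)
  expect_equal(nrow(r2), nrow(sim$raster))
  expect_equal(r2$t_ms, sim$raster$t_ms, tolerance = 1e-9)
  expect_equal(as.character(r2$population), as.character(sim$raster$population))
  unlink(f)
})

test_that("spike times lie within the run and rasters are time-sorted", {
  net <- tiny_network()
  sim <- memo("tiny_sim", dg_simulate(net, stimulus_spec(), seed = 4))
  expect_true(all(sim$raster$t_ms >= 0 & sim$raster$t_ms <= 4000))
  expect_false(is.unsorted(sim$raster$t_ms))
  # positions match the layout
  gcl <- net$layout[net$layout$population == "GC", ]
  r <- sim$raster[sim$raster$population == "GC", ]
  expect_equal(r$position_mm, gcl$pos_st[match(r$cell_id, gcl$id)])
})
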