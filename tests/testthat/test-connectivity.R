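test_that("terminal field densities normalise and follow the extent rules", {
  x <- seq(0, 10, by = 0.01)
  for (ty in c("EC", "GC", "MC")) {
    d <- terminal_field_density(ty, 5, x)
    expect_equal(sum(d) * 0.01, 1, tolerance = 1e-3)
  }
  # mossy field extent: 2/3 of the axis at the septal pole, 1/3 at the
  # temporal pole; sigma = extent/4 so density(center)/density(center+sigma)
  # = exp(1/2)
  d0 <- terminal_field_density("MC", 0, c(0, 10 * 2 / 3 / 4))
  expect_equal(d0[1] / d0[2], exp(0.5), tolerance = 1e-6)
  dT <- terminal_field_density("MC", 10, c(10, 10 - 10 / 3 / 4))
  expect_equal(dT[1] / dT[2], exp(0.5), tolerance = 1e-6)
  expect_error(terminal_field_density("MC", 11, x), "outside")
  expect_error(terminal_field_density("ZZ", 5, x), "unknown")
})

test_that("conduction delays are latency plus distance over velocity", {
  expect_equal(conduction_delay(3, 3), 0.8)
  expect_equal(conduction_delay(0, 1, velocity_m_s = 0.25), 4.8)
  d <- conduction_delay(rep(0, 50), seq(0, 5, length.out = 50))
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= 0.8))
  # matrix form includes the transverse component
  a <- cbind(0, 0); b <- cbind(3, 4)
  expect_equal(conduction_delay(a, b, velocity_m_s = 1), 5 + 0.8)
})

test_that("realized in-degrees stay within the pathway ranges", {
  lay <- tiny_layout(3, gc = 150, bc = 60, mc = 20, ec = 40)
  pw <- dg_pathways()
  e <- wire_pathway(lay, pw$bc_gc, seed = 5)
  deg <- as.integer(in_degree(e))
  expect_true(all(deg >= 40 & deg <= 80))
  expect_equal(length(deg), 150)          # every GC innervated
  expect_true(all(e$region == "soma"))
  e2 <- suppressMessages(wire_pathway(lay, pw$mc_bc, seed = 5))
  expect_true(all(in_degree(e2) >= 950 & in_degree(e2) <= 1050))
})

test_that("laminar targeting assigns every synapse to the pathway region", {
  lay <- tiny_layout(4, gc = 50, ec = 30)
  pw <- dg_pathways()
  expect_true(all(suppressMessages(
    wire_pathway(lay, pw$mec_gc, seed = 1))$region == "middle"))
  expect_true(all(suppressMessages(
    wire_pathway(lay, pw$lec_gc, seed = 1))$region == "outer"))
  expect_true(all(suppressMessages(
    wire_pathway(lay, pw$mc_gc, seed = 1))$region == "inner"))
})

test_that("entorhinal connection distances respect the terminal extent", {
  lay <- build_layout(dg_scale(1), tiny_counts(gc = 300, ec = 400), seed = 9)
  pw <- dg_pathways(ec_extent_mm = 1.5)
  e <- wire_pathway(lay, pw$mec_bc, seed = 2)
  pre <- lay[lay$population == "MEC", ]
  post <- lay[lay$population == "BC", ]
  d <- abs(pre$pos_st[e$pre] - post$pos_st[match(e$post, post$id)])
  # sigma = extent/2 = 0.75 mm: ~2/3 of partners within one extent radius
  expect_lt(quantile(d, 0.95), 2 * 0.75 * 1.1)
  expect_gt(mean(d < 0.75), 0.6)
})

test_that("wiring is reproducible and seeds separate pathways", {
  lay <- tiny_layout(5)
  pw <- dg_pathways()
  a <- suppressMessages(wire_pathway(lay, pw$gc_bc, seed = 3))
  b <- suppressMessages(wire_pathway(lay, pw$gc_bc, seed = 3))
  expect_identical(a, b)
  c2 <- suppressMessages(wire_pathway(lay, pw$gc_bc, seed = 4))
  expect_false(identical(a$pre, c2$pre))
})

test_that("randomising topography preserves in-degrees and spreads partners", {
  lay <- build_layout(dg_scale(1), tiny_counts(gc = 400, mc = 60), seed = 2)
  pw <- dg_pathways()
  e <- suppressMessages(wire_pathway(lay, pw$mc_gc, seed = 6))
  r <- randomize_topography(e, lay, pw$mc_gc, seed = 6)
  expect_identical(in_degree(r), in_degree(e))
  r2 <- randomize_topography(e, lay, pw$mc_gc, seed = 6)
  expect_identical(r, r2)

  pre <- lay[lay$population == "MC", ]
  post <- lay[lay$population == "GC", ]
  dist_of <- function(ed) mean(abs(pre$pos_st[match(ed$pre, pre$id)] -
                                     post$pos_st[match(ed$post, post$id)]))
  expect_gt(dist_of(r), dist_of(e))
  # uniform resampling has mean |pre - post| distance near axis_length/3
  expect_equal(dist_of(r), 10 / 3, tolerance = 0.15)
})

test_that("wire_network excludes the mossy loop when asked", {
  lay <- tiny_layout(6)
  g <- suppressMessages(wire_network(lay, include_mc = FALSE, seed = 1))
  expect_false(any(c("gc_mc", "mc_gc", "mc_bc") %in% names(g$edges)))
  g2 <- suppressMessages(wire_network(lay, include_mc = TRUE, seed = 1))
  expect_true(all(c("gc_mc", "mc_gc", "mc_bc") %in% names(g2$edges)))
})
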