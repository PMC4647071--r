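scenario_scale <- 0.003  # 3000 GC; keeps scripted-scenario tests affordable

test_that("scenario presets encode the experimental conditions", {
  s <- dg_scenario("feedback")
  expect_false(s$include_mc)
  expect_equal(s$multipliers[["bc_gc"]], 4)
  s2 <- dg_scenario("mc-literature")
  expect_true(s2$include_mc)
  expect_gt(s2$multipliers[["mc_gc"]], 1)
  expect_lt(s2$multipliers[["bc_gc"]], 1)
  s3 <- dg_scenario("mc-random-topo")
  expect_equal(s3$mc_topography, "random")
  expect_error(dg_scenario("baseline", multipliers = c(bc_gc = -1)))
  # overrides merge with preset multipliers
  s4 <- dg_scenario("feedback", multipliers = c(mec_gc = 2))
  expect_equal(s4$multipliers[["bc_gc"]], 4)
  expect_equal(s4$multipliers[["mec_gc"]], 2)
})

test_that("identical scenarios reproduce identical results", {
  sc <- dg_scenario("baseline", scale_factor = scenario_scale,
                    stimulus = stimulus_spec(duration_ms = 1000), seed = 3)
  net <- memo("scenario_net", build_scenario_network(sc))
  a <- run_scenario(sc, network = net, stc = FALSE)
  b <- run_scenario(sc, network = net, stc = FALSE)
  expect_identical(a$totals, b$totals)
  expect_gt(a$totals[["GC"]], 0)
})

test_that("reports mirror engine totals and tabulate deltas", {
  sc <- dg_scenario("baseline", scale_factor = scenario_scale,
                    stimulus = stimulus_spec(duration_ms = 1000), seed = 3)
  net <- memo("scenario_net", build_scenario_network(sc))
  r1 <- run_scenario(sc, network = net, stc = FALSE)
  sc2 <- dg_scenario("pathway-perturb", multipliers = c(mec_gc = 2),
                     scale_factor = scenario_scale,
                     stimulus = stimulus_spec(duration_ms = 1000), seed = 3)
  r2 <- run_scenario(sc2, network = net, stc = FALSE)
  rep <- generate_report(list(r1, r2), reference = "baseline")
  expect_equal(rep$table$gc_spikes[1], unname(r1$totals[["GC"]]))
  expect_equal(nrow(rep$deltas), 1)
  expect_equal(rep$deltas$gc_change_pct,
               100 * (r2$totals[["GC"]] - r1$totals[["GC"]]) /
                 r1$totals[["GC"]])
  expect_true(jsonlite::validate(rep$json))
  # single result, no reference: still a well-formed report
  rep1 <- generate_report(r1)
  expect_null(rep1$deltas)
  expect_equal(nrow(rep1$table), 1)
})

test_that("raising perforant-path drive raises granule output", {
  sc <- dg_scenario("baseline", scale_factor = scenario_scale,
                    stimulus = stimulus_spec(duration_ms = 1000), seed = 3)
  net <- memo("scenario_net", build_scenario_network(sc))
  base <- run_scenario(sc, network = net, stc = FALSE)
  up <- run_scenario(dg_scenario("pathway-perturb",
                                 multipliers = c(mec_gc = 3, lec_gc = 3),
                                 scale_factor = scenario_scale,
                                 stimulus = stimulus_spec(duration_ms = 1000),
                                 seed = 3),
                     network = net, stc = FALSE)
  expect_gt(up$totals[["GC"]], base$totals[["GC"]])
})

test_that("paired activation approaches control at long delays", {
  # a scale/seed at which the conditioning volley does not ignite
  # self-sustaining network activity, so the no-interaction limit is clean
  sc <- dg_scenario("mc-rebalanced", scale_factor = 0.002, seed = 11)
  net <- memo("scenario_net_mc", build_scenario_network(sc))
  cur <- paired_activation_curve(net, delays = c(10, 150), seed = 11)
  expect_true(all(cur$percent_of_control >= 0))
  # at a delay far beyond every synaptic/membrane time constant the volley
  # cannot interact with the test response
  expect_equal(cur$percent_of_control[2], 100, tolerance = 0.12)
  # short-delay conditioning is the stronger modulation
  expect_lte(abs(cur$percent_of_control[2] - 100) - 1e-9,
             max(abs(cur$percent_of_control - 100)))
})

test_that("rebalancing against the initial curve returns immediately", {
  sc <- dg_scenario("mc-rebalanced", scale_factor = 0.002, seed = 11)
  net <- memo("scenario_net_mc", build_scenario_network(sc))
  target <- paired_activation_curve(net, delays = c(10, 40), seed = 11)
  fit <- rebalance(net, target, tolerance = 1, max_iter = 10, seed = 11)
  expect_equal(unname(fit$multipliers), c(1, 1))
  expect_true(fit$converged)
  expect_equal(fit$objective, 0)
  expect_equal(nrow(fit$trace), 1)
})

test_that("the synthetic rebalance target has the documented shape", {
  tg <- synthetic_rebalance_target()
  expect_true(all(diff(tg$percent_of_control) > 0))  # recovers with delay
  expect_lt(tg$percent_of_control[1], 50)            # strong early inhibition
  expect_lt(max(tg$percent_of_control), 100)
})
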