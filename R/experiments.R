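# Scripted network scenarios, the paired-activation protocol, and the
# excitation/inhibition rebalancing of the associational loop.

#' Define a simulation scenario
#'
#' A scenario bundles everything needed for one reproducible network run:
#' scale, pathway weight multipliers, whether the mossy-cell loop is
#' included, its topography mode, and the stimulus.
#'
#' Named presets:
#' \describe{
#'   \item{baseline}{no mossy cells, all multipliers 1}
#'   \item{feedback}{no MC, basket-to-granule weight multiplied (default 4)}
#'   \item{feedforward}{no MC, entorhinal-to-basket weight multiplied
#'     (default 5)}
#'   \item{ppdrive}{no MC, entorhinal-to-granule weight multiplied
#'     (default 10)}
#'   \item{mc-literature}{mossy cells at literature-strength excitation:
#'     the pre-rebalancing condition, with the mossy-to-granule weight an
#'     order of magnitude above the rebalanced base and basket-to-granule
#'     inhibition at half strength}
#'   \item{mc-rebalanced}{mossy cells at the rebalanced base weights
#'     (all multipliers 1)}
#'   \item{mc-random-topo}{as mc-rebalanced but with the mossy-to-granule
#'     projection randomised (topography removed)}
#' }
#'
#' @param name preset name or a free-form label
#' @param multipliers named per-pathway weight multipliers (override preset)
#' @param include_mc include the mossy-cell loop (presets set this)
#' @param mc_topography "topographic" or "random"
#' @param stimulus a [stimulus_spec()]
#' @param scale_factor network scale (default desk scale, 0.01)
#' @param seed master seed (placement, wiring, stimulus substreams)
#' @return a `dg_scenario` list
#' @export
dg_scenario <- function(name = "baseline", multipliers = NULL,
                        include_mc = NULL, mc_topography = NULL,
                        stimulus = stimulus_spec(), scale_factor = 0.01,
                        seed = 1) {
  preset <- switch(name,
    "baseline" = list(mult = NULL, mc = FALSE, topo = "topographic"),
    "feedback" = list(mult = c(bc_gc = 4), mc = FALSE, topo = "topographic"),
    "feedforward" = list(mult = c(mec_bc = 5, lec_bc = 5), mc = FALSE,
                         topo = "topographic"),
    "ppdrive" = list(mult = c(mec_gc = 10, lec_gc = 10), mc = FALSE,
                     topo = "topographic"),
    "mc-literature" = list(mult = c(mc_gc = 10, bc_gc = 0.5), mc = TRUE,
                           topo = "topographic"),
    "mc-rebalanced" = list(mult = NULL, mc = TRUE, topo = "topographic"),
    "mc-random-topo" = list(mult = NULL, mc = TRUE, topo = "random"),
    list(mult = NULL, mc = FALSE, topo = "topographic"))
  mult <- preset$mult
  if (!is.null(multipliers)) {
    mult <- c(multipliers, mult[setdiff(names(mult), names(multipliers))])
  }
  if (!is.null(mult) && any(mult <= 0)) stop("multipliers must be positive")
  structure(list(
    name = name,
    multipliers = mult,
    include_mc = if (is.null(include_mc)) preset$mc else include_mc,
    mc_topography = if (is.null(mc_topography)) preset$topo else mc_topography,
    stimulus = stimulus, scale_factor = scale_factor, seed = seed),
    class = "dg_scenario")
}

#' Build the network for a scenario
#'
#' Networks differing only in weight multipliers share identical wiring for
#' the same seed/scale, so a built network can be reused across conditions
#' via the `network` argument of [run_scenario()].
#'
#' @param scenario a [dg_scenario()]
#' @param dt integration step (ms)
#' @return a [dg_network()] object
#' @export
build_scenario_network <- function(scenario, dt = 0.1) {
  preset <- desk_scale_preset(scenario$scale_factor)
  layout <- build_layout(preset$scale, preset$counts, seed = scenario$seed)
  graph <- wire_network(layout, include_mc = scenario$include_mc,
                        mc_topography = scenario$mc_topography,
                        seed = scenario$seed)
  dg_network(layout, graph, dt = dt)
}

#' Run a scenario and its standard analyses
#'
#' Executes the simulation and computes total spikes, the mean
#' spike-density spectrum with its dominant peak, and (optionally) the
#' spatio-temporal correlation with its extents.
#'
#' @param scenario a [dg_scenario()]
#' @param network optionally a prebuilt [build_scenario_network()] network
#' @param stc also compute the STC (the slowest analysis)?
#' @param stc_sample STC neuron sample size
#' @return a `dg_result` list
#' @export
run_scenario <- function(scenario, network = NULL, stc = TRUE,
                         stc_sample = 10000) {
  if (is.null(network)) network <- build_scenario_network(scenario)
  sim <- dg_simulate(network, stimulus = scenario$stimulus,
                     seed = scenario$seed,
                     weight_multipliers = scenario$multipliers)
  totals <- sapply(c("GC", "BC", "MC"), function(p) total_spikes(sim, p))
  sdm <- if (totals[["GC"]] > 0)
    spike_density_matrix(sim$raster, "GC") else NULL
  spec <- if (!is.null(sdm)) mean_spectrum(sdm) else NULL
  peak <- if (!is.null(spec)) spectral_peak(spec) else
    list(found = FALSE, frequency_hz = NA_real_, magnitude = NA_real_,
         width_hz = NA_real_)
  stc_obj <- ext <- NULL
  if (stc && totals[["GC"]] > 1) {
    stc_obj <- compute_stc(sim$raster, "GC", n_sample = stc_sample,
                           seed = scenario$seed)
    ext <- tryCatch(stc_extent(stc_obj), error = function(e) NULL)
  }
  structure(list(
    scenario = scenario, sim = sim, totals = totals,
    spectrum = spec, peak = peak, stc = stc_obj, stc_extent = ext),
    class = "dg_result")
}

#' @export
print.dg_result <- function(x, ...) {
  cat("dg_result [", x$scenario$name, "]  GC:", x$totals[["GC"]],
      " BC:", x$totals[["BC"]], " MC:", x$totals[["MC"]], "spikes\n")
  if (isTRUE(x$peak$found)) {
    cat("  spectral peak:", round(x$peak$frequency_hz, 2), "Hz\n")
  } else cat("  no spectral peak in band\n")
  if (!is.null(x$stc_extent)) {
    cat("  STC extent:", round(x$stc_extent$spatial_mm, 2), "mm /",
        round(x$stc_extent$temporal_ms, 1), "ms\n")
  }
  invisible(x)
}

#' Paired mossy/perforant-path activation curve
#'
#' Reproduces the paired-stimulation protocol used to balance the
#' associational loop: a control run delivers a synchronous perforant-path
#' test volley alone; conditioned runs precede the test volley by a
#' synchronous mossy-cell population volley at increasing delays.  The
#' granule-cell response to the test volley is reported as a percentage of
#' the control response per delay.
#'
#' @param network a mossy-cell network from [build_scenario_network()]
#' @param delays inter-stimulus delays (ms), increasing
#' @param weight_multipliers per-pathway multipliers for all runs
#' @param seed master seed
#' @param ec_frac fraction of entorhinal cells recruited by the test volley
#' @param window response-counting window after the test volley (ms)
#' @return data.frame with `delay_ms` and `percent_of_control`
#' @export
paired_activation_curve <- function(network, delays = c(2, 5, 10, 20, 60),
                                    weight_multipliers = NULL, seed = 1,
                                    ec_frac = 0.1, window = 30) {
  stopifnot(length(delays) > 0, !is.unsorted(delays))
  t_test <- max(delays) + 20
  dur <- t_test + window + 20
  quiet <- stimulus_spec(rate_hz = 0, ramp_ms = 0, duration_ms = dur)
  count_gc <- function(with_test, mc_volley) {
    sim <- dg_simulate(network, stimulus = quiet, duration = dur,
                       seed = seed, weight_multipliers = weight_multipliers,
                       ec_volley = if (with_test)
                         list(t = t_test, frac = ec_frac),
                       mc_volley = mc_volley)
    total_spikes(sim, "GC", window = c(t_test, t_test + window))
  }
  control <- count_gc(TRUE, NULL)
  if (control == 0) {
    stop("zero granule-cell spikes in the control run; ",
         "percentage undefined")
  }
  # test-evoked response under conditioning, with the conditioning volley's
  # own contribution to the window subtracted (the volley also excites)
  pct <- vapply(delays, function(d) {
    paired <- count_gc(TRUE, t_test - d)
    volley_only <- count_gc(FALSE, t_test - d)
    100 * max(paired - volley_only, 0) / control
  }, 0)
  data.frame(delay_ms = delays, percent_of_control = pct)
}

#' Rebalance the associational loop against a target activation curve
#'
#' Searches over the basket-to-granule and mossy-to-granule weight
#' multipliers (the procedure raises perisomatic inhibition and lowers
#' direct mossy excitation) minimising the sum of squared deviations
#' between the simulated paired-activation curve and a target curve.  The
#' default optimiser is Nelder-Mead on the log-multipliers, which follows
#' the curved valley this objective typically has; a multiplicative
#' coordinate search is available as `method = "coordinate"`.  The search
#' stops at `tolerance` or after `max_iter` objective evaluations
#' (memoised), returning the best weights found (with a warning on
#' non-convergence).
#'
#' @param network a mossy-cell network
#' @param target data.frame with `delay_ms`, `percent_of_control`
#' @param initial named initial multipliers (bc_gc, mc_gc)
#' @param tolerance stop when the objective falls below this
#' @param max_iter evaluation cap
#' @param seed master seed (shared by every candidate evaluation)
#' @param method "nelder-mead" or "coordinate"
#' @param ... passed to [paired_activation_curve()]
#' @return list: `multipliers`, `objective`, `curve`, `converged`, `trace`
#' @export
rebalance <- function(network, target, initial = c(bc_gc = 1, mc_gc = 1),
                      tolerance = 25, max_iter = 60, seed = 1,
                      method = c("nelder-mead", "coordinate"), ...) {
  stopifnot(all(c("bc_gc", "mc_gc") %in% names(initial)))
  method <- match.arg(method)
  delays <- target$delay_ms
  evals <- 0
  cache <- new.env(parent = emptyenv())
  trace <- NULL
  objective <- function(mult) {
    mult <- c(bc_gc = min(10, max(0.05, mult[["bc_gc"]])),
              mc_gc = min(10, max(0.05, mult[["mc_gc"]])))
    key <- paste(signif(mult, 6), collapse = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    if (evals >= max_iter) return(Inf)
    evals <<- evals + 1
    cur <- paired_activation_curve(network, delays = delays,
                                   weight_multipliers = mult, seed = seed,
                                   ...)
    o <- sum((cur$percent_of_control - target$percent_of_control)^2)
    cache[[key]] <- o
    trace <<- rbind(trace, data.frame(eval = evals, bc_gc = mult[["bc_gc"]],
                                      mc_gc = mult[["mc_gc"]],
                                      objective = o))
    o
  }
  start <- initial[c("bc_gc", "mc_gc")]
  best_obj <- objective(start)
  cur <- start

  if (best_obj <= tolerance) {
    method <- "none"
  }
  if (method == "nelder-mead") {
    fn <- function(lp) {
      o <- objective(c(bc_gc = exp(lp[1]), mc_gc = exp(lp[2])))
      if (!is.finite(o)) 1e12 else o
    }
    opt <- stats::optim(log(unname(start)), fn, method = "Nelder-Mead",
                        control = list(maxit = max_iter, reltol = 1e-3,
                                       abstol = tolerance / 2))
    cand <- c(bc_gc = exp(opt$par[1]), mc_gc = exp(opt$par[2]))
    o <- objective(cand)
    best <- trace[which.min(trace$objective), ]
    cur <- c(bc_gc = best$bc_gc, mc_gc = best$mc_gc)
    best_obj <- best$objective
  } else if (method == "coordinate") {
    step <- 1.6
    while (best_obj > tolerance && evals < max_iter && step > 1.02) {
      improved <- FALSE
      for (par in c("bc_gc", "mc_gc")) {
        for (fac in c(step, 1 / step)) {
          if (best_obj <= tolerance || evals >= max_iter) break
          cand <- cur
          cand[par] <- min(10, max(0.05, cand[par] * fac))
          if (cand[par] == cur[par]) next
          o <- objective(cand)
          if (o < best_obj) {
            best_obj <- o
            cur <- cand
            improved <- TRUE
            break
          }
        }
      }
      if (!improved) step <- sqrt(step)
    }
  }
  converged <- best_obj <= tolerance
  if (!converged && evals >= max_iter) {
    warning("rebalance: iteration cap reached; returning best-so-far")
  }
  curve <- paired_activation_curve(network, delays = delays,
                                   weight_multipliers = cur, seed = seed,
                                   ...)
  list(multipliers = cur, objective = best_obj, curve = curve,
       converged = converged, trace = trace)
}

#' Default stand-in target curve for rebalancing
#'
#' The in-vivo paired-stimulation target (strong inhibition of the test
#' response at short commissural-to-test delays, recovering toward control
#' as the delay grows) is not tabulated in the modelling sources; this
#' SYNTHETIC stand-in encodes that documented shape and is meant to be
#' replaced by experimental values when available.
#'
#' @param delays delays (ms)
#' @return data.frame with `delay_ms`, `percent_of_control`
#' @export
synthetic_rebalance_target <- function(delays = c(5, 10, 20, 40, 80)) {
  data.frame(delay_ms = delays,
             percent_of_control = 100 * (1 - 0.8 * exp(-delays / 25)))
}

#' Summarise a set of scenario results
#'
#' Tabulates totals, spectral peaks and STC extents per scenario, plus the
#' per-pathway delta grid (percent change in granule-cell totals and regime
#' notes) relative to a named reference result when one is present.
#'
#' @param results list of `dg_result` objects (or a single one)
#' @param reference name of the scenario serving as the comparison base
#' @return a `dg_report`: list with `table` (data.frame) and `json` string
#' @export
generate_report <- function(results, reference = NULL) {
  if (inherits(results, "dg_result")) results <- list(results)
  stopifnot(length(results) >= 1)
  rows <- lapply(results, function(r) {
    data.frame(
      scenario = r$scenario$name,
      gc_spikes = unname(r$totals[["GC"]]),
      bc_spikes = unname(r$totals[["BC"]]),
      mc_spikes = unname(r$totals[["MC"]]),
      peak_hz = if (isTRUE(r$peak$found)) r$peak$frequency_hz else NA_real_,
      stc_spatial_mm = if (!is.null(r$stc_extent))
        r$stc_extent$spatial_mm else NA_real_,
      stc_temporal_ms = if (!is.null(r$stc_extent))
        r$stc_extent$temporal_ms else NA_real_)
  })
  tab <- do.call(rbind, rows)
  deltas <- NULL
  if (!is.null(reference) && reference %in% tab$scenario) {
    base <- tab[match(reference, tab$scenario), ]
    others <- tab[tab$scenario != reference, , drop = FALSE]
    if (nrow(others)) {
      deltas <- data.frame(
        scenario = others$scenario,
        gc_change_pct = 100 * (others$gc_spikes - base$gc_spikes) /
          base$gc_spikes)
    }
  }
  json <- jsonlite::toJSON(list(
    totals = tab[, c("scenario", "gc_spikes", "bc_spikes", "mc_spikes")],
    spectral_peaks = tab[, c("scenario", "peak_hz")],
    stc_extents = tab[, c("scenario", "stc_spatial_mm", "stc_temporal_ms")],
    deltas = deltas), dataframe = "rows", auto_unbox = TRUE, digits = NA,
    na = "null")
  structure(list(table = tab, deltas = deltas, json = json),
            class = "dg_report")
}

#' @export
print.dg_report <- function(x, ...) {
  print(x$table, row.names = FALSE)
  if (!is.null(x$deltas)) {
    cat("\nchanges vs reference:\n")
    print(x$deltas, row.names = FALSE)
  }
  invisible(x)
}
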