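#' Simulate the dentate network
#'
#' Clock-driven integration of all membranes with delayed synaptic event
#' delivery.  Entorhinal sources fire ramped Poisson trains generated from
#' per-cell substreams of `seed`; network cells spike when their somatic
#' voltage crosses 0 mV (1 ms refractory).  Deterministic given the seed.
#'
#' @param network a [dg_network()] object
#' @param stimulus a [stimulus_spec()]
#' @param duration simulated time (ms); defaults to the stimulus duration
#' @param seed master seed for the entorhinal drive
#' @param weight_multipliers named numeric vector of per-pathway multipliers
#'   applied to the base synaptic weights (e.g. `c(bc_gc = 4)`)
#' @param mc_volley optional numeric vector of times (ms) at which the whole
#'   mossy-cell population is driven to fire synchronously (suprathreshold
#'   2-ms somatic current pulses), used for paired-activation protocols
#' @param ec_volley optional list `list(t = , frac = )`: a synchronous
#'   volley from a random fraction of entorhinal cells at the given times
#' @param probe_cells optional internal cell indices whose somatic voltage
#'   is recorded
#' @return a `dg_sim` object: `raster` (population, cell_id, position_mm,
#'   t_ms, sorted by time), per-population `counts`, and run metadata
#' @export
dg_simulate <- function(network, stimulus = stimulus_spec(),
                        duration = NULL, seed = 1,
                        weight_multipliers = NULL, mc_volley = NULL,
                        ec_volley = NULL, probe_cells = NULL) {
  stopifnot(inherits(network, "dg_network"))
  if (is.null(duration)) duration <- stimulus$duration_ms
  w <- network$base_weights
  if (!is.null(weight_multipliers)) {
    bad <- setdiff(names(weight_multipliers), names(w))
    if (length(bad)) stop("unknown pathway(s): ", paste(bad, collapse = ", "))
    w[names(weight_multipliers)] <- w[names(weight_multipliers)] *
      weight_multipliers
  }
  # convert to absolute peak conductance (uS) at the target compartment
  if (network$weight_units == "density") {
    w <- w * network$path_area_cm2 * 1e6
  }

  trains <- ec_spike_trains(network$layout, stimulus, seed = seed)
  ncells <- nrow(network$cells)
  ext_src <- ncells + trains$row - 1L
  ext_t <- trains$t
  if (!is.null(ec_volley)) {
    nec <- nrow(network$ec)
    sel <- with_seed(substream_seed(seed, "ec_volley"),
                     sample.int(nec, max(1L, round(ec_volley$frac * nec))))
    ext_src <- c(ext_src, rep(ncells + sel - 1L, length(ec_volley$t)))
    ext_t <- c(ext_t, rep(ec_volley$t, each = length(sel)))
  }
  ord <- order(ext_t)
  run <- empty_run(network$dt, duration)
  run$pathway_weights <- unname(w)
  run$ext_src <- as.integer(ext_src[ord])
  run$ext_t <- ext_t[ord]

  if (!is.null(mc_volley)) {
    if (!network$graph_meta$include_mc) {
      stop("mc_volley requires a network that includes mossy cells")
    }
    mc_somas <- network$soma_comp[network$cells$population == "MC"]
    run$inj_comp <- rep(mc_somas, length(mc_volley))
    run$inj_amp <- rep(15, length(run$inj_comp))     # nA, suprathreshold
    run$inj_t0 <- rep(mc_volley, each = length(mc_somas))
    run$inj_t1 <- run$inj_t0 + 2
  }
  if (!is.null(probe_cells)) {
    run$probe_comp <- network$soma_comp[probe_cells]
    run$probe_every <- 10L
  }

  out <- .engine_run(network$engine, run)
  ci <- out$spike_cell + 1L
  raster <- data.frame(
    population = network$cells$population[ci],
    cell_id = network$cells$id[ci],
    position_mm = network$cells$pos_st[ci],
    t_ms = out$spike_t)
  raster <- raster[order(raster$t_ms), , drop = FALSE]
  rownames(raster) <- NULL
  class(raster) <- c("dg_raster", "data.frame")
  attr(raster, "duration_ms") <- duration

  counts <- table(factor(raster$population, levels = c("GC", "BC", "MC")))
  structure(list(
    raster = raster,
    counts = as.integer(counts),
    populations = names(counts),
    duration_ms = duration, dt = network$dt, seed = seed,
    weights = w, deliveries = out$deliveries,
    probes = if (!is.null(probe_cells)) out$probes,
    ec_spikes = length(trains$t)),
    class = "dg_sim")
}

#' @export
print.dg_sim <- function(x, ...) {
  cat("dg_sim:", x$duration_ms, "ms, dt", x$dt, "ms\n")
  cat("spike counts:",
      paste(x$populations, x$counts, sep = "=", collapse = ", "),
      "(EC input spikes:", x$ec_spikes, ")\n")
  invisible(x)
}

#' Total spike count of a population in a time window
#'
#' @param result a `dg_sim` or a raster data.frame
#' @param population population tag ("GC", "BC", "MC")
#' @param window `c(t0, t1)` in ms; default the full duration
#' @return integer count
#' @export
total_spikes <- function(result, population = "GC", window = NULL) {
  raster <- if (inherits(result, "dg_sim")) result$raster else result
  x <- raster[raster$population == population, "t_ms"]
  if (!is.null(window)) x <- x[x >= window[1] & x < window[2]]
  length(x)
}

#' Write / read a spike raster as tab-separated text
#'
#' Columns: population, cell_id, position_mm, t_ms (one row per spike,
#' sorted by time, header line included).
#'
#' @param raster a raster data.frame
#' @param path file path
#' @export
write_raster <- function(raster, path) {
  raster <- raster[order(raster$t_ms), , drop = FALSE]
  utils::write.table(raster, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  class(x) <- c("dg_raster", "data.frame")
  x
}
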