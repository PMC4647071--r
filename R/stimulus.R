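#' Entorhinal stimulus specification
#'
#' Poisson spiking at `rate_hz` with the rate ramped linearly from zero over
#' the first `ramp_ms` of the simulation, the standard drive used to avoid a
#' strong transient network response to step-onset input.
#'
#' @param rate_hz steady-state mean rate (Hz)
#' @param ramp_ms onset ramp duration (ms)
#' @param duration_ms total stimulus duration (ms)
#' @return a `stim_spec` list
#' @export
stimulus_spec <- function(rate_hz = 3, ramp_ms = 1000, duration_ms = 4000) {
  stopifnot(rate_hz >= 0, ramp_ms >= 0, ramp_ms <= duration_ms)
  structure(list(rate_hz = rate_hz, ramp_ms = ramp_ms,
                 duration_ms = duration_ms), class = "stim_spec")
}

#' Inhomogeneous Poisson spike train with linear onset ramp
#'
#' Thinning-based sampler for rate `lambda(t) = rate * min(t/ramp, 1)`.
#' Trains for distinct `(seed, population, cell_id)` keys are independent and
#' reproducible regardless of generation order.
#'
#' @param spec a [stimulus_spec()]
#' @param cell_id integer id keying the per-cell substream
#' @param seed master seed
#' @param population label keying the substream (default "EC")
#' @return numeric vector of spike times (ms), sorted
#' @export
poisson_ramp_train <- function(spec, cell_id, seed = 1, population = "EC") {
  if (spec$rate_hz == 0) return(numeric(0))
  lmax <- spec$rate_hz / 1000  # spikes per ms
  with_seed(substream_seed(seed, "stim", population, cell_id), {
    n <- stats::rpois(1, lmax * spec$duration_ms)
    t <- sort(runif(n, 0, spec$duration_ms))
    keep <- runif(n) < pmin(if (spec$ramp_ms > 0) t / spec$ramp_ms else 1, 1)
    t[keep]
  })
}

# Generate trains for every EC cell in a layout; returns a list with source
# row indices into the layout's MEC/LEC block and flat spike times.
ec_spike_trains <- function(layout, spec, seed = 1) {
  ec <- layout[layout$population %in% c("MEC", "LEC"), , drop = FALSE]
  trains <- lapply(seq_len(nrow(ec)), function(i) {
    poisson_ramp_train(spec, ec$id[i], seed = seed,
                       population = as.character(ec$population[i]))
  })
  n <- lengths(trains)
  list(row = rep(seq_len(nrow(ec)), n), t = unlist(trains), ec = ec)
}
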