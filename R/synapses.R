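#' Synapse parameter set
#'
#' @param weight peak conductance (uS)
#' @param tau_rise,tau_fall rise/fall time constants (ms), `tau_fall > tau_rise`
#' @param e_rev reversal potential (mV)
#' @return a `syn_params` list
#' @export
syn_params <- function(weight, tau_rise, tau_fall, e_rev) {
  if (tau_fall <= tau_rise) {
    stop("tau_fall (", tau_fall, ") must exceed tau_rise (", tau_rise, ")")
  }
  if (weight < 0) stop("weight must be nonnegative")
  structure(list(weight = weight, tau_rise = tau_rise, tau_fall = tau_fall,
                 e_rev = e_rev), class = "syn_params")
}

# peak-normalisation constant: max_t (e^{-t/tf} - e^{-t/tr}) = 1/N
syn_norm <- function(tau_rise, tau_fall) {
  tp <- tau_rise * tau_fall / (tau_fall - tau_rise) * log(tau_fall / tau_rise)
  1 / (exp(-tp / tau_fall) - exp(-tp / tau_rise))
}

#' Double-exponential synaptic conductance waveform
#'
#' `g(t) = w * N * (exp(-t/tau_fall) - exp(-t/tau_rise))`, with `N` chosen so
#' the peak equals the weight `w`.  Responses to multiple presynaptic events
#' sum linearly.
#'
#' @param t time since the presynaptic event (ms, vectorised, `t >= 0`)
#' @param p a [syn_params()] object
#' @return conductance in the units of `p$weight`
#' @export
conductance_waveform <- function(t, p) {
  stopifnot(all(t >= 0))
  n <- syn_norm(p$tau_rise, p$tau_fall)
  p$weight * n * (exp(-t / p$tau_fall) - exp(-t / p$tau_rise))
}

#' Time of peak of the double-exponential waveform (ms)
#' @param p a [syn_params()] object
#' @export
conductance_peak_time <- function(p) {
  p$tau_rise * p$tau_fall / (p$tau_fall - p$tau_rise) *
    log(p$tau_fall / p$tau_rise)
}

#' Synaptic current
#'
#' `I = g * (V_post - E_rev)`; positive current hyperpolarises.
#'
#' @param g conductance (uS)
#' @param v_post postsynaptic membrane potential (mV)
#' @param e_rev reversal potential (mV)
#' @return current (nA when `g` is uS and voltages are mV)
#' @export
synaptic_current <- function(g, v_post, e_rev) {
  g * (v_post - e_rev)
}

#' Pathway synaptic parameter defaults
#'
#' The nine pathway parameter sets of the model: weights (peak conductance,
#' uS), double-exponential rise/fall times (ms) and reversal potentials (mV).
#' Excitatory pathways reverse at 0 mV; basket-to-granule inhibition at
#' -75 mV.  Rise/fall kinetics that are not individually tabulated for the
#' mossy-cell pathways default to the perforant-path values (1.05/5.75 ms).
#'
#' @return named list of [syn_params()] keyed by pathway id
#' @export
pathway_defaults <- function() {
  list(
    mec_gc = syn_params(1.17e-5, 1.05, 5.75, 0),
    lec_gc = syn_params(1.50e-5, 1.05, 5.75, 0),
    bc_gc  = syn_params(1.09e-5, 1.05, 5.75, -75),
    gc_mc  = syn_params(2.00e-5, 1.05, 5.75, 0),
    gc_bc  = syn_params(1.13e-4, 0.1, 0.59, 0),
    mec_bc = syn_params(4.21e-6, 1.05, 18, 0),
    lec_bc = syn_params(4.21e-6, 1.05, 18, 0),
    mc_gc  = syn_params(1.17e-6, 1.05, 5.75, 0),
    mc_bc  = syn_params(2.27e-5, 1.05, 5.75, 0))
}
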