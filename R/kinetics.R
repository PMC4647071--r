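# Voltage-gated channel kinetics.
#
# The published model inherits its gating kinetics from earlier dentate
# models and prints only the maximal conductance densities; this file is the
# package's single, swappable definition of those kinetics.  Activation/
# inactivation follow standard Hodgkin-Huxley rate-function forms
# (Traub-lineage Na/K rates; sigmoidal steady states with fixed or
# voltage-dependent time constants for A-type K and the Ca channels).
# Calcium-dependent channels (SK, BK) are parameterised directly by the
# engine (see `ca_dependent_params`).
#
# All voltages mV, times ms.  The engine consumes these as lookup tables on
# a fixed grid, so alternative kinetics can be dropped in by editing the
# functions below only.

v_table_grid <- function() seq(-120, 60, by = 0.05)

vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2), x / (exp(x / y) - 1))

sigmoid <- function(v, mid, slope) 1 / (1 + exp(-(v - mid) / slope))

# Traub-style Na/K rate functions, shifted by a threshold parameter vt.
# h_slope sets how sharply inactivation closes with depolarisation: the
# principal cells use a steep 6 mV e-fold (prevents Na-window plateau block
# with the very large tabulated Na densities); fast-spiking basket cells
# use the shallower classical 18 mV tail and keep firing under strong
# sustained drive.
.na_rates <- function(v, vt, h_slope = 6) {
  u <- v - vt
  am <- 0.32 * vtrap(13 - u, 4)
  bm <- 0.28 * vtrap(u - 40, 5)
  ah <- 0.128 * exp((17 - u) / h_slope)
  bh <- 4 / (1 + exp((40 - u) / 5))
  list(m_inf = am / (am + bm), m_tau = 1 / (am + bm),
       h_inf = ah / (ah + bh), h_tau = 1 / (ah + bh))
}

.kdr_rates <- function(v, vt, rate_scale = 1) {
  u <- v - vt
  an <- 0.032 * vtrap(15 - u, 5) * rate_scale
  bn <- 0.5 * exp((10 - u) / 40) * rate_scale
  list(n_inf = an / (an + bn), n_tau = 1 / (an + bn))
}

#' Channel kinetics definitions
#'
#' Returns the kinetics set used to build gating tables: one entry per
#' voltage-gated mechanism with gate steady states `inf(v)`, time constants
#' `tau(v)` (ms), gate powers and the reversal potential.  `vt` shifts the
#' Na/K rate functions and thereby the spike threshold of a cell class.
#'
#' @param vt spike-threshold shift for the Na/KDR rate functions (mV)
#' @param na_h_slope e-fold voltage of Na inactivation closure (mV)
#' @return named list of channel kinetic descriptions
#' @export
channel_kinetics <- function(vt = -55, na_h_slope = 6) {
  list(
    na = list(
      erev = 55, is_ca = FALSE,
      gates = list(
        list(power = 3,
             inf = function(v) .na_rates(v, vt)$m_inf,
             tau = function(v) pmax(.na_rates(v, vt)$m_tau, 0.02)),
        list(power = 1,
             inf = function(v) .na_rates(v, vt, na_h_slope)$h_inf,
             tau = function(v) pmax(.na_rates(v, vt, na_h_slope)$h_tau, 0.2)))),
    kdr_fast = list(
      erev = -85, is_ca = FALSE,
      gates = list(
        list(power = 4,
             inf = function(v) .kdr_rates(v, vt)$n_inf,
             tau = function(v) pmax(.kdr_rates(v, vt)$n_tau, 0.2)))),
    kdr_slow = list(
      erev = -85, is_ca = FALSE,
      gates = list(
        list(power = 4,
             inf = function(v) .kdr_rates(v, vt, 0.2)$n_inf,
             tau = function(v) pmax(.kdr_rates(v, vt, 0.2)$n_tau, 1)))),
    ka = list(
      erev = -85, is_ca = FALSE,
      gates = list(
        list(power = 4,
             inf = function(v) sigmoid(v, -45, 12),
             tau = function(v) rep(2, length(v))),
        list(power = 1,
             inf = function(v) sigmoid(v, -70, -6),
             tau = function(v) rep(30, length(v))))),
    ca_l = list(
      erev = 80, is_ca = TRUE,
      gates = list(
        list(power = 2,
             inf = function(v) sigmoid(v, -5, 8),
             tau = function(v) rep(1.5, length(v))))),
    ca_n = list(
      erev = 80, is_ca = TRUE,
      gates = list(
        list(power = 2,
             inf = function(v) sigmoid(v, -15, 7),
             tau = function(v) rep(1.5, length(v))),
        list(power = 1,
             inf = function(v) sigmoid(v, -60, -10),
             tau = function(v) rep(80, length(v))))),
    ca_t = list(
      erev = 80, is_ca = TRUE,
      gates = list(
        list(power = 2,
             inf = function(v) sigmoid(v, -50, 6.5),
             tau = function(v) rep(3, length(v))),
        list(power = 1,
             inf = function(v) sigmoid(v, -78, -5),
             tau = function(v) rep(50, length(v)))))
  )
}

#' Calcium-dependent channel parameters (SK and BK)
#'
#' SK opens as a Hill function of intracellular Ca with half-activation `kd`;
#' BK open fraction is `Ca / (Ca + K(V))` with `K(V) = k0 * exp(-V / kslope)`
#' so that depolarisation and raised Ca are both required.  Units follow the
#' model's Ca pool variable ("mol", steady state 5e-06).
#'
#' @return list with `sk` and `bk` parameter sets
#' @export
ca_dependent_params <- function() {
  list(sk = list(erev = -85, kd = 3e-4, tau = 10),
       bk = list(erev = -85, k0 = 5e-4, kslope = 24, tau = 2))
}

# Build the engine's lookup tables for one kinetics set at a given dt.
build_gate_tables <- function(kin, dt) {
  v <- v_table_grid()
  lapply(kin, function(ch) {
    gates <- lapply(ch$gates, function(g) {
      inf <- g$inf(v)
      tau <- g$tau(v)
      list(power = as.integer(g$power), inf = inf, dec = exp(-dt / tau))
    })
    list(erev = ch$erev, is_ca = ch$is_ca, gates = gates)
  })
}

bk_kv_table <- function(bk) {
  v <- v_table_grid()
  bk$k0 * exp(-v / bk$kslope)
}
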