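#' Granule cell channel density table
#'
#' Per-region maximal conductance densities (S/cm2) and passive parameters
#' for the reduced granule cell scheme: soma, granule cell layer segment
#' (GCL), and the inner/middle/outer thirds of the molecular layer.  Absent
#' channels are encoded as 0 (sodium is absent from the outer third, A-type K
#' is somatic only, SK is absent from the two distal thirds).
#'
#' @return list with passive parameters and a `densities` matrix
#'   (channel x region)
#' @export
granule_cell_table <- function() {
  regions <- c("soma", "gcl", "inner", "middle", "outer")
  dens <- rbind(
    na       = c(0.84,    0.126,   0.091,   0.056,   0),
    kdr_slow = c(0.006,   0.006,   0.006,   0.006,   0.008),
    kdr_fast = c(0.036,   0.009,   0.009,   0.00225, 0.00225),
    ka       = c(0.108,   0,       0,       0,       0),
    ca_l     = c(0.0025,  0.00375, 0.00375, 0.00025, 0),
    ca_n     = c(1.47e-3, 7.35e-4, 7.35e-4, 7.35e-4, 7.35e-4),
    ca_t     = c(7.4e-5,  1.5e-4,  5e-4,    1e-3,    2e-3),
    sk       = c(0.001,   4e-4,    2e-4,    0,       0),
    bk       = c(1.2e-4,  1.2e-4,  2e-4,    4.8e-4,  4.8e-4))
  colnames(dens) <- regions
  list(
    regions = regions,
    densities = dens,
    cm_uF_cm2 = c(soma = 9.8, gcl = 9.8, inner = 15.68, middle = 15.68,
                  outer = 15.68),
    leak_S_cm2 = c(soma = 2.9e-4, gcl = 2.9e-4, inner = 4.57e-4,
                   middle = 4.57e-4, outer = 4.57e-4),
    ra_ohm_cm = 210,
    rmp_mV = -75.01,
    rin_Mohm = 185.86,
    tau_m_ms = 31,
    ca_tau_ms = 10,
    ca_ss = 5e-6)
}

#' Mossy cell parameter set (single compartment)
#' @return list of passive and channel parameters
#' @export
mossy_cell_table <- function() {
  list(
    area_cm2 = 2.51e-3,
    cm_uF_cm2 = 0.6,
    ra_ohm_cm = 100,
    leak_S_cm2 = 1.10e-5,
    rmp_mV = -64.75,
    densities = c(na = 0.12, kdr_fast = 5e-4, ka = 1e-5, ca_l = 6e-4,
                  ca_n = 5e-5, sk = 1.6e-3, bk = 1.65e-2),
    ca_tau_ms = 10,
    ca_ss = 5e-6,
    # Ca-pool gain per unit membrane area; sets spike-frequency adaptation.
    # The mossy cell's large Ca conductances need a lower gain than the
    # granule cell's for it to sustain the burst firing seen in vivo.
    ca_B_scale = 1e-9)
}

#' Basket cell parameter set (single compartment, fast spiking)
#'
#' The basket cell is a fast-spiking single-compartment model with transient
#' Na, fast delayed-rectifier K and passive leak; its parameters are not part
#' of the printed density table and follow standard fast-spiking interneuron
#' models (low capacitance, ~10 ms membrane time constant, low threshold).
#'
#' @return list of passive and channel parameters
#' @export
basket_cell_table <- function() {
  list(
    area_cm2 = 1.4e-5,
    cm_uF_cm2 = 1.0,
    ra_ohm_cm = 100,
    leak_S_cm2 = 5.0e-4,
    rmp_mV = -65,
    densities = c(na = 0.2, kdr_fast = 0.06),
    ca_tau_ms = 10,
    ca_ss = 5e-6,
    # spike threshold sits well above the entorhinal background noise so
    # basket firing is phasic (granule-burst-driven), not tonic; shallow
    # Na inactivation keeps the fast-spiking phenotype free of
    # depolarisation block under strong sustained drive
    vt = -52,
    na_h_slope = 18,
    # detection threshold for spike propagation: under storm-level drive a
    # partially Na-inactivated basket cell emits reduced-amplitude spikes
    # peaking below 0 mV, which must still deliver inhibition
    spike_threshold_mV = -10)
}

# Solve reduced granule-cell compartment areas so that the somatic DC input
# resistance of the 5-compartment ladder reproduces the target, given the
# region leak densities, a dendritic/somatic area ratio, and an electrotonic
# compactness factor (axial conductance between adjacent sections as a
# multiple of total membrane conductance).
granule_geometry <- function(table, area_ratio = 10, n_branches = 1,
                             rin_Mohm = table$rin_Mohm, axial_factor = 10) {
  lk <- table$leak_S_cm2
  per_region <- area_ratio / 4
  denom <- lk[["soma"]] + per_region *
    (lk[["gcl"]] + lk[["inner"]] + lk[["middle"]] + lk[["outer"]])
  a_soma <- 1 / (rin_Mohm * 1e6) / denom     # lumped-cell first guess, cm2
  regions <- c("soma", "gcl", "inner", "middle", "outer")
  areas <- c(a_soma, rep(a_soma * per_region, 4))
  names(areas) <- regions
  g_leak <- areas * lk[regions]              # S
  g_ax <- axial_factor * sum(g_leak)         # S, uniform along the chain
  # exact DC input resistance of the ladder, then rescale all conductances
  G <- diag(g_leak)
  for (i in 1:4) {
    G[i, i] <- G[i, i] + g_ax
    G[i + 1, i + 1] <- G[i + 1, i + 1] + g_ax
    G[i, i + 1] <- G[i, i + 1] - g_ax
    G[i + 1, i] <- G[i + 1, i] - g_ax
  }
  rin_dc <- solve(G)[1, 1]                   # ohm
  s <- rin_dc / (rin_Mohm * 1e6)
  areas <- areas * s
  g_ax <- g_ax * s
  lengths <- c(soma = 40, gcl = 50, inner = 80, middle = 80, outer = 80) # um
  list(areas_cm2 = areas, lengths_um = lengths, n_branches = n_branches,
       g_axial_uS = g_ax * 1e6)
}

#' Build the reduced granule cell model
#'
#' Assembles a cable-connected compartment chain soma -> GCL -> inner ->
#' middle -> outer third with the region-specific channel densities.  The
#' dendrite can be multiplied into `n_branches` parallel equivalent branches
#' (total dendritic area is conserved).  Compartment areas are solved from
#' the target input resistance (see vignette); the leak reversal of each
#' compartment is balanced so the model rests exactly at the tabulated
#' resting potential with all channels at steady state.
#'
#' @param table density table from [granule_cell_table()]
#' @param area_ratio dendritic/somatic membrane area ratio
#' @param n_branches number of parallel dendritic branches
#' @param vt Na/KDR rate-function shift controlling spike threshold (mV)
#' @param axial_factor electrotonic compactness: axial conductance between
#'   adjacent sections as a multiple of total membrane conductance
#' @return a `dg_cell` object
#' @export
build_granule_cell <- function(table = granule_cell_table(), area_ratio = 10,
                               n_branches = 1, vt = -57, axial_factor = 10) {
  need <- c("soma", "gcl", "inner", "middle", "outer")
  if (!all(need %in% colnames(table$densities))) {
    stop("density table must cover regions: ", paste(need, collapse = ", "))
  }
  geo <- granule_geometry(table, area_ratio, n_branches,
                          axial_factor = axial_factor)
  regions <- c("soma", rep(c("gcl", "inner", "middle", "outer"), n_branches))
  parent <- c(NA_integer_)
  for (b in seq_len(n_branches)) {
    base <- 1 + (b - 1) * 4
    parent <- c(parent, 1L, base + 1L, base + 2L, base + 3L)
  }
  area <- numeric(length(regions))
  area[1] <- geo$areas_cm2[["soma"]]
  for (i in seq_along(regions)[-1]) {
    area[i] <- geo$areas_cm2[[regions[i]]] / n_branches
  }
  len <- geo$lengths_um[regions]
  comp <- data.frame(region = regions, area_cm2 = area, length_um = len,
                     parent = parent)
  comp$cm <- table$cm_uF_cm2[regions]
  comp$g_leak_dens <- table$leak_S_cm2[regions]
  comp$g_axial_uS <- c(NA_real_,
                       rep(geo$g_axial_uS / n_branches, length(regions) - 1))
  dens <- table$densities[, regions, drop = FALSE]
  cell <- structure(list(
    type = "GC", comp = comp, densities = dens, vt = vt,
    kinetics = channel_kinetics(vt), ca_params = ca_dependent_params(),
    ca_tau_ms = table$ca_tau_ms, ca_ss = table$ca_ss,
    ca_B_scale = 1e-8, spike_threshold_mV = 0,
    rmp_mV = table$rmp_mV), class = "dg_cell")
  cell
}

#' Build a single-compartment basket or mossy cell model
#'
#' @param type `"BC"` or `"MC"`
#' @param params parameter list (defaults to the built-in tables)
#' @return a `dg_cell` object
#' @export
build_point_cell <- function(type = c("BC", "MC"), params = NULL) {
  type <- match.arg(type)
  if (is.null(params)) {
    params <- if (type == "BC") basket_cell_table() else mossy_cell_table()
  }
  vt <- if (!is.null(params$vt)) params$vt else -55
  hs <- if (!is.null(params$na_h_slope)) params$na_h_slope else 6
  comp <- data.frame(region = "soma", area_cm2 = params$area_cm2,
                     length_um = 20, parent = NA_integer_)
  comp$cm <- params$cm_uF_cm2
  comp$g_leak_dens <- params$leak_S_cm2
  comp$g_axial_uS <- NA_real_
  dens <- matrix(params$densities, ncol = 1,
                 dimnames = list(names(params$densities), "soma"))
  structure(list(
    type = type, comp = comp, densities = dens, vt = vt,
    kinetics = channel_kinetics(vt, na_h_slope = hs),
    ca_params = ca_dependent_params(),
    ca_tau_ms = params$ca_tau_ms, ca_ss = params$ca_ss,
    ca_B_scale = if (!is.null(params$ca_B_scale)) params$ca_B_scale else 1e-8,
    spike_threshold_mV = if (!is.null(params$spike_threshold_mV))
      params$spike_threshold_mV else 0,
    rmp_mV = params$rmp_mV), class = "dg_cell")
}

#' @export
print.dg_cell <- function(x, ...) {
  cat("dg_cell:", x$type, "-", nrow(x$comp), "compartment(s), rest",
      x$rmp_mV, "mV\n")
  invisible(x)
}

# Steady-state channel current density (nA/cm2-equivalent per uS..) --
# returns, for a compartment with given densities (S/cm2) held at v with Ca
# at steady state, the net channel current per cm2 (mA/cm2 scale is
# irrelevant: used only relative to leak density for rest balancing).
channel_rest_current_density <- function(cell, region, v) {
  kin <- cell$kinetics
  cap <- cell$ca_params
  total <- 0
  for (ch in rownames(cell$densities)) {
    g0 <- cell$densities[ch, region]
    if (g0 == 0 || is.na(g0)) next
    if (ch %in% names(kin)) {
      k <- kin[[ch]]
      open <- 1
      for (g in k$gates) open <- open * g$inf(v)^g$power
      total <- total + g0 * open * (v - k$erev)
    } else if (ch == "sk") {
      z <- cell$ca_ss^2 / (cell$ca_ss^2 + cap$sk$kd^2)
      total <- total + g0 * z * (v - cap$sk$erev)
    } else if (ch == "bk") {
      kv <- cap$bk$k0 * exp(-v / cap$bk$kslope)
      o <- cell$ca_ss / (cell$ca_ss + kv)
      total <- total + g0 * o * (v - cap$bk$erev)
    }
  }
  total
}

# Leak reversal per compartment such that the cell rests exactly at v_rest.
balanced_leak_reversal <- function(cell, v_rest = cell$rmp_mV) {
  vapply(seq_len(nrow(cell$comp)), function(i) {
    region <- cell$comp$region[i]
    ich <- channel_rest_current_density(cell, region, v_rest)
    v_rest + ich / cell$comp$g_leak_dens[i]
  }, 0)
}

#' Measure passive properties of a cell model
#'
#' Lets the model rest, verifies convergence (drift < 0.5 mV over the final
#' 100 ms of the rest period), then applies a small hyperpolarising somatic
#' current step.  Input resistance is the steady-state voltage deflection
#' over the injected current; the membrane time constant is a single
#' exponential fitted to the charging curve.
#'
#' @param cell a `dg_cell`
#' @param i_step step amplitude in nA (negative = hyperpolarising)
#' @param rest_ms settling time before the step
#' @param step_ms step duration
#' @param dt time step (ms)
#' @return list with `rmp_mV`, `rin_Mohm`, `tau_m_ms`
#' @export
measure_passive <- function(cell, i_step = -0.01, rest_ms = 600,
                            step_ms = 400, dt = 0.1) {
  tr <- run_cell(cell, duration = rest_ms + step_ms, dt = dt,
                 inj = data.frame(amp = i_step, t0 = rest_ms,
                                  t1 = rest_ms + step_ms))
  t <- tr$t
  v <- tr$v[, 1]
  pre <- v[t >= rest_ms - 100 & t < rest_ms]
  if (max(pre) - min(pre) > 0.5) {
    stop("cell did not reach rest: drift ",
         signif(max(pre) - min(pre), 3), " mV over final 100 ms")
  }
  rmp <- mean(pre)
  plateau <- mean(v[t >= rest_ms + step_ms - 50])
  rin <- (plateau - rmp) / i_step         # mV / nA == MOhm
  sel <- t >= rest_ms & t < rest_ms + 200
  tt <- t[sel] - rest_ms
  vv <- v[sel]
  frac <- (vv - rmp) / (plateau - rmp)
  keep <- frac > 0.05 & frac < 0.95 & tt > 1
  fit <- lm(log(1 - frac[keep]) ~ tt[keep])
  tau <- -1 / coef(fit)[[2]]
  list(rmp_mV = rmp, rin_Mohm = rin, tau_m_ms = tau)
}
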