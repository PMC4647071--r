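# Assembly of cell templates + wired graph into the flat arrays consumed by
# the C++ integration core.

# Engine arrays for n identical copies of one cell template.
# Compartment indices are 0-based and offset by `offset`.
template_engine_arrays <- function(cell, n, dt, offset) {
  cpg <- nrow(cell$comp)
  area <- cell$comp$area_cm2
  eleak <- balanced_leak_reversal(cell)
  parent0 <- ifelse(is.na(cell$comp$parent), -1L,
                    as.integer(cell$comp$parent) - 1L)
  idx_all <- rep((seq_len(n) - 1L) * cpg, each = cpg) + seq_len(cpg) - 1L
  parent <- ifelse(rep(parent0, n) < 0, -1L,
                   rep((seq_len(n) - 1L) * cpg, each = cpg) + rep(parent0, n))
  parent <- as.integer(ifelse(parent < 0, -1L, parent + offset))
  gax <- rep(ifelse(is.na(cell$comp$g_axial_uS), 0, cell$comp$g_axial_uS), n)

  tabs <- build_gate_tables(cell$kinetics, dt)
  cap <- cell$ca_params
  is_ca_comp <- rep(FALSE, cpg)
  channels <- list()
  rest <- cell$rmp_mV
  for (ch in rownames(cell$densities)) {
    dens <- cell$densities[ch, ]
    offs <- which(dens > 0 & !is.na(dens))
    if (!length(offs)) next
    comp <- rep((seq_len(n) - 1L) * cpg, each = length(offs)) +
      rep(offs - 1L, n) + offset
    gbar <- rep(dens[offs] * area[offs] * 1e6, n)  # uS
    if (ch %in% names(tabs)) {
      tb <- tabs[[ch]]
      gates <- lapply(tb$gates, function(g) {
        v <- v_table_grid()
        x0 <- g$inf[[which.min(abs(v - rest))]]
        list(power = g$power, inf = g$inf, dec = g$dec,
             state = rep(x0, length(comp)))
      })
      channels[[length(channels) + 1]] <-
        list(kind = "hh", comp = as.integer(comp), gbar = as.numeric(gbar),
             erev = tb$erev, is_ca = tb$is_ca, gates = gates)
      if (tb$is_ca) is_ca_comp[offs] <- TRUE
    } else if (ch == "sk") {
      z0 <- cell$ca_ss^2 / (cell$ca_ss^2 + cap$sk$kd^2)
      channels[[length(channels) + 1]] <-
        list(kind = "sk", comp = as.integer(comp), gbar = as.numeric(gbar),
             erev = cap$sk$erev, is_ca = FALSE, kd = cap$sk$kd,
             tau = cap$sk$tau, state = rep(z0, length(comp)))
    } else if (ch == "bk") {
      kv <- bk_kv_table(cap$bk)
      v <- v_table_grid()
      o0 <- cell$ca_ss / (cell$ca_ss + kv[[which.min(abs(v - rest))]])
      channels[[length(channels) + 1]] <-
        list(kind = "bk", comp = as.integer(comp), gbar = as.numeric(gbar),
             erev = cap$bk$erev, is_ca = FALSE, kv = kv, tau = cap$bk$tau,
             state = rep(o0, length(comp)))
    } else {
      stop("no kinetics defined for channel ", ch)
    }
  }
  ca_B <- ifelse(rep(is_ca_comp, n), cell$ca_B_scale / rep(area, n), 0)

  list(cpg = cpg,
       C_nF = rep(cell$comp$cm * area * 1e3, n),
       g_leak_uS = rep(cell$comp$g_leak_dens * area * 1e6, n),
       E_leak_mV = rep(eleak, n),
       parent = parent,
       g_axial_uS = gax,
       ca_B = ca_B,
       channels = channels,
       soma_comp = as.integer((seq_len(n) - 1L) * cpg + offset),
       spike_thresh = rep(cell$spike_threshold_mV, n),
       V_init = rep(rest, n * cpg))
}

# engine-net skeleton with no synapses (single template, n cells)
bare_engine_net <- function(cell, n = 1) {
  function(dt) {
    a <- template_engine_arrays(cell, n, dt, offset = 0L)
    list(C_nF = a$C_nF, g_leak_uS = a$g_leak_uS, E_leak_mV = a$E_leak_mV,
         parent = a$parent, g_axial_uS = a$g_axial_uS,
         soma_comp = a$soma_comp, spike_thresh = a$spike_thresh,
         ca_B = a$ca_B,
         ca_tau_ms = cell$ca_tau_ms, ca_ss = cell$ca_ss,
         channels = a$channels,
         slot_comp = integer(0), slot_decay_r = numeric(0),
         slot_decay_f = numeric(0), slot_norm = numeric(0),
         slot_erev = numeric(0),
         src_ptr = rep(0L, n + 1L),
         edge_slot = integer(0), edge_delay = integer(0),
         edge_path = integer(0),
         V_init = a$V_init)
  }
}

empty_run <- function(dt, duration) {
  list(dt = dt, duration = duration, pathway_weights = numeric(0),
       ext_src = integer(0), ext_t = numeric(0),
       refractory_ms = 1,
       inj_comp = integer(0), inj_amp = numeric(0),
       inj_t0 = numeric(0), inj_t1 = numeric(0),
       probe_comp = integer(0), probe_every = 1L)
}

#' Run a single cell model
#'
#' Integrates one isolated cell (no synaptic input) with optional current
#' injections, recording the somatic (or all-compartment) voltage trace.
#'
#' @param cell a `dg_cell`
#' @param duration duration (ms)
#' @param dt time step (ms)
#' @param inj data.frame with columns `amp` (nA), `t0`, `t1` (ms); injected
#'   at the soma
#' @param probe "soma" or "all"
#' @param probe_every record every k-th step
#' @return list with `t` (ms), `v` (matrix, one column per probed
#'   compartment) and `spikes` (somatic threshold-crossing times)
#' @export
run_cell <- function(cell, duration = 1000, dt = 0.1, inj = NULL,
                     probe = c("soma", "all"), probe_every = 1L) {
  probe <- match.arg(probe)
  net <- bare_engine_net(cell, 1)(dt)
  run <- empty_run(dt, duration)
  if (!is.null(inj)) {
    run$inj_comp <- rep(net$soma_comp[1], nrow(inj))
    run$inj_amp <- inj$amp
    run$inj_t0 <- inj$t0
    run$inj_t1 <- inj$t1
  }
  run$probe_comp <- if (probe == "soma") net$soma_comp[1] else
    seq_along(net$C_nF) - 1L
  run$probe_every <- as.integer(probe_every)
  out <- .engine_run(net, run)
  nrec <- nrow(out$probes)
  list(t = (seq_len(nrec) - 1) * dt * probe_every, v = out$probes,
       spikes = out$spike_t)
}

#' Assemble a simulatable dentate network
#'
#' Combines a cell placement, a wired connectivity graph and the three cell
#' templates into the flat state arrays used by the integration engine.
#' The time step is fixed at assembly (synaptic/gating decay factors and
#' delay quantisation are precomputed).
#'
#' @param layout a [build_layout()] result
#' @param graph a [wire_network()] result
#' @param gc_cell,bc_cell,mc_cell cell templates
#' @param dt integration time step (ms), must be <= 0.1
#' @param weight_units `"density"` (default): pathway weights are peak
#'   conductance densities in S/cm2 applied to the target compartment, the
#'   same convention as the channel-density tables; `"uS"`: weights are
#'   absolute peak conductances in microsiemens
#' @return a `dg_network` object
#' @export
dg_network <- function(layout, graph, gc_cell = build_granule_cell(),
                       bc_cell = build_point_cell("BC"),
                       mc_cell = build_point_cell("MC"), dt = 0.1,
                       weight_units = c("density", "uS")) {
  stopifnot(dt > 0, dt <= 0.1)
  weight_units <- match.arg(weight_units)
  counts <- attr(layout, "counts")
  nGC <- as.integer(counts[["GC"]])
  nBC <- as.integer(counts[["BC"]])
  nMC <- as.integer(counts[["MC"]])
  has_mc <- graph$include_mc
  if (!has_mc) nMC_eff <- 0L else nMC_eff <- nMC

  gc_arr <- template_engine_arrays(gc_cell, nGC, dt, 0L)
  off_bc <- nGC * gc_arr$cpg
  bc_arr <- template_engine_arrays(bc_cell, nBC, dt, off_bc)
  off_mc <- off_bc + nBC
  mc_arr <- if (has_mc) template_engine_arrays(mc_cell, nMC, dt, off_mc) else NULL

  parts <- Filter(Negate(is.null), list(gc_arr, bc_arr, mc_arr))
  cat_num <- function(f) do.call(c, lapply(parts, `[[`, f))
  net <- list(
    C_nF = cat_num("C_nF"), g_leak_uS = cat_num("g_leak_uS"),
    E_leak_mV = cat_num("E_leak_mV"),
    parent = as.integer(cat_num("parent")),
    g_axial_uS = cat_num("g_axial_uS"),
    soma_comp = as.integer(cat_num("soma_comp")),
    spike_thresh = cat_num("spike_thresh"),
    ca_B = cat_num("ca_B"),
    ca_tau_ms = gc_cell$ca_tau_ms, ca_ss = gc_cell$ca_ss,
    channels = do.call(c, lapply(parts, `[[`, "channels")),
    V_init = cat_num("V_init"))

  # ---- internal cell bookkeeping ----
  gcl <- layout[layout$population == "GC", ]
  bcl <- layout[layout$population == "BC", ]
  mcl <- layout[layout$population == "MC", ]
  ecl <- layout[layout$population %in% c("MEC", "LEC"), ]
  cells <- rbind(
    data.frame(population = "GC", id = gcl$id, pos_st = gcl$pos_st),
    data.frame(population = "BC", id = bcl$id, pos_st = bcl$pos_st),
    if (has_mc) data.frame(population = "MC", id = mcl$id,
                           pos_st = mcl$pos_st))
  ncells <- nrow(cells)
  nEC <- nrow(ecl)

  # source index (0-based) by population for presynaptic lookup
  src_base <- c(GC = 0L, BC = nGC, MC = nGC + nBC)
  cpg <- gc_arr$cpg
  nb <- (cpg - 1L) %/% 4L  # dendritic branches
  region_off <- c(gcl = 1L, inner = 2L, middle = 3L, outer = 4L)

  # ---- synapse slots and edges ----
  kin_tab <- unique(do.call(rbind, lapply(graph$pathways, function(p) {
    data.frame(tau_rise = p$tau_rise, tau_fall = p$tau_fall, e_rev = p$e_rev)
  })))
  nkin <- nrow(kin_tab)
  kin_id_of <- function(p) {
    which(kin_tab$tau_rise == p$tau_rise & kin_tab$tau_fall == p$tau_fall &
          kin_tab$e_rev == p$e_rev)
  }

  path_names <- names(graph$edges)
  all_src <- all_key <- all_path <- integer(0)
  all_delay <- numeric(0)
  eslices <- vector("list", length(path_names))
  for (pi in seq_along(path_names)) {
    nm <- path_names[pi]
    e <- graph$edges[[nm]]
    p <- graph$pathways[[nm]]
    ne <- nrow(e)
    # presynaptic source index
    ec_rows <- function(pop) {
      rows <- which(ecl$population == pop)
      m <- integer(max(ecl$id[rows]))
      m[ecl$id[rows]] <- rows
      m
    }
    src <- switch(p$pre,
      GC = e$pre - 1L + src_base[["GC"]],
      BC = e$pre - 1L + src_base[["BC"]],
      MC = e$pre - 1L + src_base[["MC"]],
      MEC = ncells + ec_rows("MEC")[e$pre] - 1L,
      LEC = ncells + ec_rows("LEC")[e$pre] - 1L)
    # postsynaptic compartment (0-based global)
    if (p$post == "GC") {
      if (p$region == "soma") {
        comp <- (e$post - 1L) * cpg
      } else {
        branch <- if (nb > 1L) {
          with_seed(substream_seed(graph$seed, "branch", nm),
                    sample.int(nb, ne, replace = TRUE))
        } else rep(1L, ne)
        comp <- (e$post - 1L) * cpg + (branch - 1L) * 4L +
          region_off[[p$region]]
      }
    } else if (p$post == "BC") {
      comp <- off_bc + (e$post - 1L)
    } else {
      comp <- off_mc + (e$post - 1L)
    }
    kid <- kin_id_of(p)
    eslices[[pi]] <- ne
    all_src <- c(all_src, as.integer(src))
    all_key <- c(all_key, as.integer(comp * nkin + (kid - 1L)))
    all_path <- c(all_path, rep(pi - 1L, ne))
    all_delay <- c(all_delay, e$delay_ms)
  }

  uq <- sort(unique(all_key))
  edge_slot <- findInterval(all_key, uq) - 1L
  slot_comp <- as.integer(uq %/% nkin)
  slot_kin <- as.integer(uq %% nkin) + 1L
  slot_decay_r <- exp(-dt / kin_tab$tau_rise[slot_kin])
  slot_decay_f <- exp(-dt / kin_tab$tau_fall[slot_kin])
  slot_norm <- vapply(seq_len(nkin), function(k)
    syn_norm(kin_tab$tau_rise[k], kin_tab$tau_fall[k]), 0)[slot_kin]
  slot_erev <- kin_tab$e_rev[slot_kin]

  edge_delay <- pmax(1L, as.integer(round(all_delay / dt)))
  nsrc <- ncells + nEC
  ord <- order(all_src)
  edge_slot <- edge_slot[ord]
  edge_delay <- edge_delay[ord]
  edge_path <- all_path[ord]
  src_counts <- tabulate(all_src[ord] + 1L, nbins = nsrc)
  src_ptr <- c(0L, cumsum(src_counts))

  net$slot_comp <- slot_comp
  net$slot_decay_r <- slot_decay_r
  net$slot_decay_f <- slot_decay_f
  net$slot_norm <- slot_norm
  net$slot_erev <- slot_erev
  net$src_ptr <- as.integer(src_ptr)
  net$edge_slot <- as.integer(edge_slot)
  net$edge_delay <- as.integer(edge_delay)
  net$edge_path <- as.integer(edge_path)

  # representative target-compartment area per pathway (identical across
  # cells of a template), used to convert density weights to conductance
  region_area <- function(p) {
    if (p$post == "GC") {
      i <- if (p$region == "soma") 1L else region_off[[p$region]] + 1L
      gc_cell$comp$area_cm2[i]
    } else if (p$post == "BC") bc_cell$comp$area_cm2[1]
    else mc_cell$comp$area_cm2[1]
  }
  path_area <- vapply(graph$pathways, region_area, 0)

  structure(list(
    engine = net, dt = dt, cells = cells, ec = ecl,
    layout = layout, graph_meta = list(
      pathways = path_names, include_mc = has_mc,
      mc_topography = graph$mc_topography, seed = graph$seed,
      n_edges = vapply(graph$edges, nrow, 0L)),
    base_weights = vapply(graph$pathways, function(p)
      p$weight * (if (!is.null(p$calib)) p$calib else 1), 0),
    path_area_cm2 = path_area,
    weight_units = weight_units,
    soma_comp = net$soma_comp,
    off = list(bc = off_bc, mc = off_mc, cpg = cpg)),
    class = "dg_network")
}

#' @export
print.dg_network <- function(x, ...) {
  cat("dg_network:", nrow(x$cells), "cells +", nrow(x$ec),
      "EC sources;", sum(x$graph_meta$n_edges), "synapses; dt =",
      x$dt, "ms\n")
  invisible(x)
}
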