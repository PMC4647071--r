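#' Pathway specifications
#'
#' The seven anatomical pathway classes of the network (nine parameter sets,
#' since the medial and lateral entorhinal divisions are wired separately).
#' Each entry gives pre/post populations, the laminar target region on the
#' postsynaptic cell, the convergence range (synapses per postsynaptic
#' cell), the terminal-field rule, and the synaptic kinetics from
#' [pathway_defaults()].
#'
#' Terminal fields are Gaussian in the septo-temporal coordinate.
#' Entorhinal axons reach 1-1.5 mm around their topographically mapped
#' dentate position and granule-cell/basket-cell axons are local (these
#' extents are read as the characteristic reach, `sigma = extent / 2`); the
#' mossy-cell field extent is a full septo-temporal span
#' (`sigma = extent / 4`) that depends linearly on the somatic position,
#' shrinking from 2/3 of the axis at the septal pole to 1/3 at the temporal
#' pole.
#'
#' @param ec_extent_mm septo-temporal extent of the entorhinal terminal field
#' @param local_extent_mm extent of the local (GC, BC) fields
#' @param gc_mc_convergence granule-to-mossy convergence (not anatomically
#'   pinned; default 50)
#' @param bc_gc_calibration calibration multiplier on the basket-to-granule
#'   weight.  The density-to-conductance conversion under-scales this one
#'   pathway (the granule soma is the smallest target compartment in the
#'   model, giving ~16 pS per synaptic contact); the default restores a
#'   physiological ~100 pS unitary GABA_A contact conductance.  See the
#'   methods vignette.
#' @return named list of pathway specs
#' @export
dg_pathways <- function(ec_extent_mm = 1.25, local_extent_mm = 1,
                        gc_mc_convergence = 50, bc_gc_calibration = 4) {
  syn <- pathway_defaults()
  mk <- function(name, pre, post, region, conv, field, extent = NA) {
    p <- c(list(name = name, pre = pre, post = post, region = region,
                conv = conv, field = field, extent_mm = extent), syn[[name]])
    p$calib <- if (name == "bc_gc") bc_gc_calibration else 1
    p
  }
  list(
    mec_gc = mk("mec_gc", "MEC", "GC", "middle", c(1050, 1200), "ec", ec_extent_mm),
    lec_gc = mk("lec_gc", "LEC", "GC", "outer", c(1100, 1300), "ec", ec_extent_mm),
    mec_bc = mk("mec_bc", "MEC", "BC", "soma", c(100, 200), "ec", ec_extent_mm),
    lec_bc = mk("lec_bc", "LEC", "BC", "soma", c(100, 200), "ec", ec_extent_mm),
    gc_bc  = mk("gc_bc", "GC", "BC", "soma", c(500, 1400), "local", local_extent_mm),
    gc_mc  = mk("gc_mc", "GC", "MC", "soma", rep(gc_mc_convergence, 2), "local", local_extent_mm),
    bc_gc  = mk("bc_gc", "BC", "GC", "soma", c(40, 80), "local", local_extent_mm),
    mc_gc  = mk("mc_gc", "MC", "GC", "inner", c(750, 850), "mc"),
    mc_bc  = mk("mc_bc", "MC", "BC", "soma", c(950, 1050), "mc"))
}

mc_field_extent <- function(pre_pos, axis_length) {
  (2 * axis_length - pre_pos) / 3
}

# Gaussian terminal fields.  The entorhinal/local extents are read as the
# characteristic reach about the field centre (sigma = extent/2); the
# mossy-cell extents are full septo-temporal spans (sigma = extent/4, so
# +/-2 sigma covers the span).  The former calibration is what lets the
# emergent granule-cell activity clusters reach the reported 1-2 mm scale;
# see the methods vignette.
field_sigma <- function(spec, pre_pos, axis_length) {
  if (spec$field == "mc") {
    mc_field_extent(pre_pos, axis_length) / 4
  } else {
    rep(spec$extent_mm / 2, length(pre_pos))
  }
}

#' Axon terminal field density along the septo-temporal axis
#'
#' Normalised density of connection probability contributed by a presynaptic
#' cell at `pre_position` to postsynaptic positions `x`.  Entorhinal and
#' local fields are Gaussian with a fixed extent; the mossy-cell field
#' extent interpolates linearly from two-thirds of the axis (septal soma) to
#' one-third (temporal soma).  The density integrates to 1 over the axis.
#'
#' @param pre_type one of "EC", "GC", "BC", "MC"
#' @param pre_position septo-temporal soma position (mm)
#' @param x positions at which to evaluate (mm)
#' @param axis_length_mm axis length (mm)
#' @param ec_extent_mm,local_extent_mm field extents (mm)
#' @return density values at `x` (1/mm)
#' @export
terminal_field_density <- function(pre_type, pre_position, x,
                                   axis_length_mm = 10, ec_extent_mm = 1.25,
                                   local_extent_mm = 1) {
  if (pre_position < 0 || pre_position > axis_length_mm) {
    stop("pre_position outside the septo-temporal axis")
  }
  sigma <- switch(pre_type,
    EC = ec_extent_mm / 2,
    MEC = ec_extent_mm / 2,
    LEC = ec_extent_mm / 2,
    GC = local_extent_mm / 2,
    BC = local_extent_mm / 2,
    MC = mc_field_extent(pre_position, axis_length_mm) / 4,
    stop("unknown pre_type: ", pre_type))
  z <- stats::pnorm(axis_length_mm, pre_position, sigma) -
    stats::pnorm(0, pre_position, sigma)
  stats::dnorm(x, pre_position, sigma) / z
}

#' Conduction delay between two cells
#'
#' Delay = path length / conduction velocity + a fixed synaptic latency.
#' Axons are represented functionally as these delays.
#'
#' @param pre_pos,post_pos septo-temporal positions (mm), or two-column
#'   matrices of (septo-temporal mm, transverse mm)
#' @param velocity_m_s conduction velocity (m/s)
#' @param latency_ms fixed synaptic latency added to every delay
#' @return delay in ms
#' @export
conduction_delay <- function(pre_pos, post_pos, velocity_m_s = 0.25,
                             latency_ms = 0.8) {
  stopifnot(velocity_m_s > 0)
  if (is.matrix(pre_pos) || is.matrix(post_pos)) {
    d <- sqrt(rowSums((as.matrix(pre_pos) - as.matrix(post_pos))^2))
  } else {
    d <- abs(pre_pos - post_pos)
  }
  d / velocity_m_s + latency_ms   # mm / (mm/ms) = ms
}

#' Wire one pathway
#'
#' For every postsynaptic cell a convergence count is drawn uniformly from
#' the pathway's range, and that many presynaptic partners are sampled with
#' probability proportional to the presynaptic terminal-field density
#' evaluated at the postsynaptic position (multiple synapses per pair are
#' allowed; a note is emitted when the presynaptic population is smaller
#' than the convergence).  Every synapse is assigned the pathway's laminar
#' target region and a conduction delay.
#'
#' @param layout a [build_layout()] result
#' @param spec one entry of [dg_pathways()]
#' @param seed master seed (wiring uses a per-pathway substream)
#' @param velocity_m_s,latency_ms delay model parameters
#' @return a `dg_edges` data.frame: `pre`, `post` (within-population ids),
#'   `region`, `delay_ms`
#' @export
wire_pathway <- function(layout, spec, seed = 1, velocity_m_s = 0.25,
                         latency_ms = 0.8) {
  scale <- attr(layout, "scale")
  L <- scale$axis_length_mm
  pre <- layout[layout$population == spec$pre, , drop = FALSE]
  post <- layout[layout$population == spec$post, , drop = FALSE]
  npre <- nrow(pre)
  npost <- nrow(post)
  if (npre == 0 || npost == 0) {
    stop("pathway ", spec$name, ": empty population")
  }
  if (npre < spec$conv[1]) {
    message("pathway ", spec$name, ": presynaptic population (", npre,
            ") smaller than convergence range; allowing multiplicity")
  }
  sigma <- field_sigma(spec, pre$pos_st, L)
  # transverse physical coordinate for within-dentate distances
  tvmm <- scale$transverse_extent_mm
  within_dg <- !(spec$pre %in% c("MEC", "LEC"))
  with_seed(substream_seed(seed, "wire", spec$name), {
    conv <- sample(spec$conv[1]:spec$conv[2], npost, replace = TRUE)
    pre_idx <- vector("list", npost)
    for (j in seq_len(npost)) {
      w <- stats::dnorm(post$pos_st[j], pre$pos_st, sigma)
      s <- sum(w)
      if (s <= 0 || !is.finite(s)) {
        stop("pathway ", spec$name, ": terminal field of no presynaptic ",
             "cell overlaps postsynaptic cell at ",
             round(post$pos_st[j], 3), " mm")
      }
      pre_idx[[j]] <- sample.int(npre, conv[j], replace = TRUE, prob = w)
    }
  })
  pre_i <- unlist(pre_idx)
  post_i <- rep.int(seq_len(npost), conv)
  dst <- abs(pre$pos_st[pre_i] - post$pos_st[post_i])
  if (within_dg && tvmm > 0) {
    dtv <- (pre$pos_tv[pre_i] - post$pos_tv[post_i]) * tvmm
    dst <- sqrt(dst^2 + dtv^2)
  }
  edges <- data.frame(pre = pre$id[pre_i], post = post$id[post_i],
                      delay_ms = dst / velocity_m_s + latency_ms)
  edges$region <- spec$region
  attr(edges, "pathway") <- spec$name
  attr(edges, "conv") <- conv
  class(edges) <- c("dg_edges", "data.frame")
  edges
}

#' Remove topographic constraints from a wired pathway
#'
#' Keeps each postsynaptic cell's in-degree but resamples its presynaptic
#' partners uniformly over the whole presynaptic population
#' (distance-independent), recomputing conduction delays.
#'
#' @param edges a [wire_pathway()] result
#' @param layout the layout the edges were wired on
#' @param spec the pathway spec
#' @param seed master seed
#' @param velocity_m_s,latency_ms delay model parameters
#' @return a `dg_edges` data.frame
#' @export
randomize_topography <- function(edges, layout, spec, seed = 1,
                                 velocity_m_s = 0.25, latency_ms = 0.8) {
  scale <- attr(layout, "scale")
  pre <- layout[layout$population == spec$pre, , drop = FALSE]
  post <- layout[layout$population == spec$post, , drop = FALSE]
  n <- nrow(edges)
  with_seed(substream_seed(seed, "randomize", spec$name), {
    pre_i <- sample.int(nrow(pre), n, replace = TRUE)
  })
  post_i <- match(edges$post, post$id)
  dst <- abs(pre$pos_st[pre_i] - post$pos_st[post_i])
  tvmm <- scale$transverse_extent_mm
  if (!(spec$pre %in% c("MEC", "LEC")) && tvmm > 0) {
    dtv <- (pre$pos_tv[pre_i] - post$pos_tv[post_i]) * tvmm
    dst <- sqrt(dst^2 + dtv^2)
  }
  out <- data.frame(pre = pre$id[pre_i], post = edges$post,
                    delay_ms = dst / velocity_m_s + latency_ms)
  out$region <- edges$region
  attr(out, "pathway") <- attr(edges, "pathway")
  attr(out, "conv") <- attr(edges, "conv")
  class(out) <- c("dg_edges", "data.frame")
  out
}

#' Wire the whole network
#'
#' Wires all pathways (optionally excluding the mossy-cell loop) with
#' independent substreams per pathway.
#'
#' @param layout a [build_layout()] result
#' @param pathways from [dg_pathways()]
#' @param include_mc include the mossy-cell pathways (gc_mc, mc_gc, mc_bc)?
#' @param mc_topography "topographic" or "random" wiring of mc_gc
#' @param seed master seed
#' @param velocity_m_s,latency_ms delay model parameters
#' @return a `dg_graph`: named list of edge tables plus metadata
#' @export
wire_network <- function(layout, pathways = dg_pathways(), include_mc = TRUE,
                         mc_topography = c("topographic", "random"),
                         seed = 1, velocity_m_s = 0.25, latency_ms = 0.8) {
  mc_topography <- match.arg(mc_topography)
  keep <- names(pathways)
  if (!include_mc) keep <- setdiff(keep, c("gc_mc", "mc_gc", "mc_bc"))
  edges <- lapply(keep, function(nm) {
    e <- wire_pathway(layout, pathways[[nm]], seed = seed,
                      velocity_m_s = velocity_m_s, latency_ms = latency_ms)
    if (nm == "mc_gc" && mc_topography == "random") {
      e <- randomize_topography(e, layout, pathways[[nm]], seed = seed,
                                velocity_m_s = velocity_m_s,
                                latency_ms = latency_ms)
    }
    e
  })
  names(edges) <- keep
  structure(list(edges = edges, pathways = pathways[keep],
                 include_mc = include_mc, mc_topography = mc_topography,
                 seed = seed, velocity_m_s = velocity_m_s,
                 latency_ms = latency_ms),
            class = "dg_graph")
}

#' @export
print.dg_graph <- function(x, ...) {
  n <- vapply(x$edges, nrow, 0L)
  cat("dentate connectivity graph:", sum(n), "synapses\n")
  print(n)
  invisible(x)
}

#' Realized in-degree of a pathway
#' @param edges a `dg_edges` table
#' @return named integer vector (per postsynaptic cell id)
#' @export
in_degree <- function(edges) {
  table(edges$post)
}
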