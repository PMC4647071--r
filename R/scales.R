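#' Model scale specification
#'
#' The full-scale model matches the anatomy of one adult rat hippocampal
#' hemisphere; reduced scales keep population ratios and all per-cell
#' convergence values and shrink only the cell counts.
#'
#' @param scale_factor fraction of full scale, in (0, 1]
#' @param axis_length_mm septo-temporal axis length (mm).  Default 10 mm,
#'   consistent with cluster and terminal-field extents of up to 7.5-8 mm in
#'   the rat dentate gyrus.
#' @param transverse_extent_mm physical span assigned to the normalised
#'   transverse coordinate, used only for within-dentate distances
#' @return a `dg_scale` object
#' @export
dg_scale <- function(scale_factor = 1, axis_length_mm = 10,
                     transverse_extent_mm = 1) {
  stopifnot(is.numeric(scale_factor), length(scale_factor) == 1,
            scale_factor > 0, scale_factor <= 1,
            axis_length_mm > 0, transverse_extent_mm >= 0)
  structure(list(scale_factor = scale_factor,
                 axis_length_mm = axis_length_mm,
                 transverse_extent_mm = transverse_extent_mm),
            class = "dg_scale")
}

#' Full-scale population counts
#'
#' One million granule cells, 112 k entorhinal layer-II axons (split evenly
#' between medial and lateral divisions) and 6 k basket cells, matching the
#' anatomical counts used at full scale.  The mossy-cell count is not pinned
#' by the transcribed sources; the default of 30,000 follows standard rat
#' anatomy and is configurable.
#'
#' @param mc_count full-scale mossy cell count
#' @return named integer vector with entries MEC, LEC, GC, BC, MC
#' @export
full_scale_counts <- function(mc_count = 30000) {
  c(MEC = 56000L, LEC = 56000L, GC = 1000000L, BC = 6000L,
    MC = as.integer(mc_count))
}

#' Place cell populations along the dentate axes
#'
#' Each population receives `round(full_count * scale_factor)` cells with
#' positions drawn i.i.d. uniformly: GC, BC and MC along the dentate
#' septo-temporal axis and transverse fraction; MEC and LEC along an
#' entorhinal band axis that is mapped 1:1 onto the septo-temporal axis
#' (the single-axis reduction of the tracer-derived entorhinal-dentate map).
#'
#' @param scale a [dg_scale()] object
#' @param counts named full-scale counts (default [full_scale_counts()])
#' @param seed integer master seed; placement uses a dedicated substream
#' @return a `dg_layout` data.frame with columns `population`, `id`
#'   (1-based within population), `pos_st` (mm) and `pos_tv` (fraction)
#' @export
build_layout <- function(scale, counts = full_scale_counts(), seed = 1) {
  stopifnot(inherits(scale, "dg_scale"))
  pops <- c("MEC", "LEC", "GC", "BC", "MC")
  if (!all(pops %in% names(counts))) {
    stop("counts must name all of: ", paste(pops, collapse = ", "))
  }
  n <- round(counts[pops] * scale$scale_factor)
  bad <- names(n)[n < 1]
  if (length(bad)) {
    stop("population(s) ", paste(bad, collapse = ", "),
         " scale to zero cells at scale_factor = ", scale$scale_factor)
  }
  out <- do.call(rbind, lapply(pops, function(p) {
    np <- as.integer(n[[p]])
    with_seed(substream_seed(seed, "layout", p), {
      data.frame(population = p,
                 id = seq_len(np),
                 pos_st = runif(np, 0, scale$axis_length_mm),
                 pos_tv = runif(np))
    })
  }))
  out$population <- factor(out$population, levels = pops)
  attr(out, "scale") <- scale
  attr(out, "counts") <- n
  attr(out, "seed") <- seed
  class(out) <- c("dg_layout", "data.frame")
  out
}

#' Desk-scale preset
#'
#' A ratio-preserving 1:100 reduction of the full-scale model (10,000 granule
#' cells, 1,120 entorhinal axons, 60 basket cells, 300 mossy cells), the
#' default scale for interactive runs, tests and the scripted experiments.
#'
#' @param scale_factor reduction factor (default 0.01)
#' @return list with elements `scale` (a [dg_scale()]) and `counts`
#' @export
desk_scale_preset <- function(scale_factor = 0.01) {
  list(scale = dg_scale(scale_factor = scale_factor),
       counts = full_scale_counts())
}

#' @export
print.dg_layout <- function(x, ...) {
  n <- attr(x, "counts")
  sc <- attr(x, "scale")
  cat("dentate layout: scale", sc$scale_factor, "on a",
      sc$axis_length_mm, "mm axis\n")
  print(n)
  invisible(x)
}

layout_positions <- function(layout, population) {
  layout[layout$population == population, , drop = FALSE]
}
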