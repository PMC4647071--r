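# Population analytics: distance-binned spatio-temporal spike correlations,
# spike-density spectra, inter-spike-interval histograms.

raster_duration <- function(raster, duration = NULL) {
  if (!is.null(duration)) return(duration)
  d <- attr(raster, "duration_ms")
  if (!is.null(d)) return(d)
  max(raster$t_ms)
}

bin_trains <- function(t_ms, cell, nb, time_bin) {
  i <- findInterval(t_ms, seq(0, nb * time_bin, by = time_bin),
                    rightmost.closed = TRUE)
  i[i > nb] <- nb
  cells <- sort(unique(cell))
  m <- matrix(0, nb, length(cells))
  ci <- match(cell, cells)
  for (k in seq_along(t_ms)) m[i[k], ci[k]] <- m[i[k], ci[k]] + 1
  list(counts = m, cells = cells)
}

#' Spatio-temporal correlation (STC) of a spike raster
#'
#' Computes every pairwise cross-correlation of discretised spike trains in
#' a random sample of up to `n_sample` active neurons, sorts the pairs by
#' septo-temporal distance, and averages within distance bins.  Trains are
#' binned at `time_bin` ms; distances at `dist_bin` mm.  The default
#' normalisation is the Pearson correlation of the binned counts (biased
#' estimator, divisor `n` at every lag); `normalization = "cov"` gives the
#' raw cross-covariance.
#'
#' The fast path aggregates z-scored trains per spatial bin and computes all
#' pairwise terms by FFT, which is algebraically identical to averaging the
#' individual pairwise correlations with distances measured between bin
#' centres; `method = "direct"` is the literal quadratic-time computation
#' used for validation.
#'
#' @param raster raster data.frame (columns population, cell_id,
#'   position_mm, t_ms)
#' @param population population to analyse
#' @param n_sample neuron sample size (all active neurons if fewer)
#' @param time_bin,dist_bin bin widths (ms, mm)
#' @param max_lag maximum lag (ms)
#' @param seed seed for the neuron subsample
#' @param duration raster duration override (ms)
#' @param method "fft" or "direct"
#' @param normalization "pearson" or "cov"
#' @return a `dg_stc`: list with `corr` (distance bin x lag matrix),
#'   `distance_mm`, `lag_ms`, `n_pairs`, `n_cells`, `n_excluded`
#' @export
compute_stc <- function(raster, population = "GC", n_sample = 10000,
                        time_bin = 5, dist_bin = 0.05, max_lag = 100,
                        seed = 1, duration = NULL,
                        method = c("fft", "direct"),
                        normalization = c("pearson", "cov")) {
  method <- match.arg(method)
  normalization <- match.arg(normalization)
  r <- raster[raster$population == population, , drop = FALSE]
  if (nrow(r) == 0) stop("no spikes for population ", population)
  dur <- raster_duration(raster, duration)
  nb <- ceiling(dur / time_bin)
  L <- floor(max_lag / time_bin)

  cells <- unique(r[, c("cell_id", "position_mm")])
  if (nrow(cells) > n_sample) {
    keep <- with_seed(substream_seed(seed, "stc_sample"),
                      sample.int(nrow(cells), n_sample))
    cells <- cells[keep, , drop = FALSE]
    r <- r[r$cell_id %in% cells$cell_id, , drop = FALSE]
  }
  bt <- bin_trains(r$t_ms, r$cell_id, nb, time_bin)
  pos <- cells$position_mm[match(bt$cells, cells$cell_id)]
  sdv <- apply(bt$counts, 2, sd)
  ok <- sdv > 0
  n_excluded <- sum(!ok)
  if (!any(ok)) stop("no neuron has a non-degenerate spike train")
  X <- bt$counts[, ok, drop = FALSE]
  pos <- pos[ok]
  if (normalization == "pearson") {
    X <- scale(X)  # per-train z-score
  } else {
    X <- scale(X, scale = FALSE)
  }
  sbin <- floor(pos / dist_bin)

  lags <- (-L):L
  if (method == "direct") {
    nc <- ncol(X)
    dmax <- max(sbin) - min(sbin)
    acc <- matrix(0, dmax + 1, length(lags))
    np <- integer(dmax + 1)
    xc <- function(a, b, l) {
      if (l >= 0) sum(a[1:(nb - l)] * b[(1 + l):nb]) else
        sum(a[(1 - l):nb] * b[1:(nb + l)])
    }
    for (i in seq_len(nc - 1)) {
      for (j in (i + 1):nc) {
        d <- abs(sbin[i] - sbin[j]) + 1
        v <- vapply(lags, function(l)
          xc(X[, i], X[, j], l) + xc(X[, j], X[, i], l), 0)
        acc[d, ] <- acc[d, ] + v
        np[d] <- np[d] + 2L
      }
    }
    corr <- acc / (np * nb)
  } else {
    b0 <- min(sbin)
    sb <- sbin - b0
    nbin <- max(sb) + 1
    # per-spatial-bin aggregated trains and cell counts
    Z <- matrix(0, nb, nbin)
    for (k in seq_len(ncol(X))) Z[, sb[k] + 1] <- Z[, sb[k] + 1] + X[, k]
    mcount <- tabulate(sb + 1, nbins = nbin)
    m <- stats::nextn(nb + L + 1, 2)
    FZ <- stats::mvfft(rbind(Z, matrix(0, m - nb, nbin)))
    FX <- stats::mvfft(rbind(X, matrix(0, m - nb, ncol(X))))
    self_power <- rowSums(Mod(FX)^2)    # sum over cells of |F_i|^2
    dmax <- nbin - 1
    corr <- matrix(NA_real_, dmax + 1, length(lags))
    np <- numeric(dmax + 1)
    pick <- c(m - (L:1) + 1, 1:(L + 1))  # lags -L..L from ifft layout
    for (d in 0:dmax) {
      if (d == 0) {
        cs <- rowSums(Mod(FZ)^2) - self_power
        npairs <- sum(mcount * (mcount - 1))
      } else {
        a <- seq_len(nbin - d)
        cs2 <- FZ[, a, drop = FALSE] * Conj(FZ[, a + d, drop = FALSE])
        cs <- rowSums(cs2) + Conj(rowSums(cs2))
        npairs <- 2 * sum(mcount[a] * mcount[a + d])
      }
      v <- Re(stats::fft(cs, inverse = TRUE)) / m
      np[d + 1] <- npairs
      if (npairs > 0) corr[d + 1, ] <- v[pick] / (npairs * nb)
    }
  }
  structure(list(corr = corr,
                 distance_mm = (seq_len(nrow(corr)) - 1) * dist_bin,
                 lag_ms = lags * time_bin,
                 n_pairs = np, n_cells = ncol(X), n_excluded = n_excluded,
                 time_bin = time_bin, dist_bin = dist_bin),
            class = "dg_stc")
}

#' @export
print.dg_stc <- function(x, ...) {
  cat("dg_stc:", nrow(x$corr), "distance bins x", length(x$lag_ms),
      "lags;", x$n_cells, "neurons\n")
  invisible(x)
}

#' Spatial and temporal extent of an STC
#'
#' The extents are read off the lag-0 distance profile and the distance-0
#' lag profile: the largest contiguous distance (lag) from the origin over
#' which the mean correlation stays at or above
#' `threshold_fraction * STC(0, 0)`.
#'
#' @param stc a [compute_stc()] result
#' @param threshold_fraction fraction of the zero-distance zero-lag value
#' @return list with `spatial_mm` and `temporal_ms`
#' @export
stc_extent <- function(stc, threshold_fraction = exp(-1)) {
  i0 <- which(stc$lag_ms == 0)
  z <- stc$corr[1, i0]
  if (!is.finite(z) || z <= 0) {
    stop("degenerate STC: nonpositive zero-distance zero-lag correlation")
  }
  thr <- threshold_fraction * z
  dprof <- stc$corr[, i0]
  below <- which(!is.finite(dprof) | dprof < thr)
  last_d <- if (length(below)) min(below) - 1 else length(dprof)
  tprof <- stc$corr[1, i0:length(stc$lag_ms)]
  belowt <- which(!is.finite(tprof) | tprof < thr)
  last_t <- if (length(belowt)) min(belowt) - 1 else length(tprof)
  list(spatial_mm = (last_d - 1) * stc$dist_bin + stc$dist_bin / 2,
       temporal_ms = (last_t - 1) * stc$time_bin + stc$time_bin / 2)
}

#' Spike density matrix
#'
#' Spike counts per (septo-temporal position bin, time bin).
#'
#' @param raster raster data.frame
#' @param population population to analyse
#' @param space_bin,time_bin bin widths (mm, ms)
#' @param axis_length_mm spatial extent covered by the rows
#' @param duration raster duration override (ms)
#' @return matrix (position bins x time bins) with attributes
#' @export
spike_density_matrix <- function(raster, population = "GC",
                                 space_bin = 0.05, time_bin = 8,
                                 axis_length_mm = 10, duration = NULL) {
  r <- raster[raster$population == population, , drop = FALSE]
  if (nrow(r) == 0) stop("no spikes for population ", population)
  dur <- raster_duration(raster, duration)
  ns <- ceiling(axis_length_mm / space_bin)
  nt <- ceiling(dur / time_bin)
  si <- pmin(pmax(floor(r$position_mm / space_bin), 0), ns - 1) + 1
  ti <- pmin(pmax(floor(r$t_ms / time_bin), 0), nt - 1) + 1
  m <- matrix(0L, ns, nt)
  for (k in seq_along(si)) m[si[k], ti[k]] <- m[si[k], ti[k]] + 1L
  attr(m, "space_bin") <- space_bin
  attr(m, "time_bin") <- time_bin
  m
}

#' Mean spike-density spectrum
#'
#' Magnitude DFT of each spatial row of a spike density matrix (row mean
#' removed first, so the DC component is zero), averaged across rows.
#'
#' @param matrix a [spike_density_matrix()] (or any rows-x-time matrix)
#' @param time_bin time bin width in ms (taken from the matrix attribute if
#'   present)
#' @param detrend remove each row's mean before the DFT
#' @return a `dg_spectrum` data.frame with `freq_hz` and `magnitude`
#' @export
mean_spectrum <- function(matrix, time_bin = NULL, detrend = TRUE) {
  if (is.null(time_bin)) time_bin <- attr(matrix, "time_bin")
  if (is.null(time_bin)) stop("time_bin must be given")
  nt <- ncol(matrix)
  if (nt < 2) stop("need at least 2 time bins")
  x <- t(matrix)
  if (detrend) x <- scale(x, scale = FALSE)
  Fm <- Mod(stats::mvfft(x))
  nf <- floor(nt / 2) + 1
  mag <- rowMeans(Fm[seq_len(nf), , drop = FALSE])
  out <- data.frame(freq_hz = (seq_len(nf) - 1) / (nt * time_bin / 1000),
                    magnitude = mag)
  class(out) <- c("dg_spectrum", "data.frame")
  out
}

#' Locate the dominant spectral peak in a frequency band
#'
#' Returns the argmax frequency within `band` provided it is a genuine
#' local maximum whose magnitude exceeds `prominence_ratio` times the
#' median in-band magnitude; otherwise a "no peak" result (`found = FALSE`)
#' is returned rather than an error.  Width is measured at half prominence.
#'
#' @param spectrum a [mean_spectrum()] result
#' @param band frequency band (Hz)
#' @param prominence_ratio peak / median magnitude required to call a peak
#' @return list: `found`, `frequency_hz`, `magnitude`, `width_hz`
#' @export
spectral_peak <- function(spectrum, band = c(2, 60), prominence_ratio = 2) {
  s <- spectrum[spectrum$freq_hz >= band[1] & spectrum$freq_hz <= band[2], ]
  if (nrow(s) == 0) stop("band outside spectrum range")
  i <- which.max(s$magnitude)
  medmag <- median(s$magnitude)
  # an argmax on the band edge is a monotone trend, not an oscillation peak
  is_local_max <- i > 1 && i < nrow(s) &&
    s$magnitude[i] >= s$magnitude[i - 1] &&
    s$magnitude[i] >= s$magnitude[i + 1]
  if (!is_local_max || medmag <= 0 ||
      s$magnitude[i] < prominence_ratio * medmag) {
    return(list(found = FALSE, frequency_hz = NA_real_,
                magnitude = NA_real_, width_hz = NA_real_))
  }
  half <- medmag + (s$magnitude[i] - medmag) / 2
  lo <- i
  while (lo > 1 && s$magnitude[lo] > half) lo <- lo - 1
  hi <- i
  while (hi < nrow(s) && s$magnitude[hi] > half) hi <- hi + 1
  list(found = TRUE, frequency_hz = s$freq_hz[i], magnitude = s$magnitude[i],
       width_hz = s$freq_hz[hi] - s$freq_hz[lo])
}

#' Inter-spike-interval histogram
#'
#' Consecutive intervals are collected per cell and pooled over the
#' population.
#'
#' @param raster raster data.frame
#' @param population population tag
#' @param breaks histogram bin edges (ms)
#' @return a `dg_isi`: list with `counts`, `breaks`, `isis_ms`
#' @export
isi_histogram <- function(raster, population = "GC",
                          breaks = seq(0, 4000, by = 50)) {
  r <- raster[raster$population == population, , drop = FALSE]
  isis <- unlist(lapply(split(r$t_ms, r$cell_id), function(t) {
    if (length(t) < 2) numeric(0) else diff(sort(t))
  }), use.names = FALSE)
  if (is.null(isis)) isis <- numeric(0)
  counts <- if (length(isis)) {
    tabulate(pmin(findInterval(isis, breaks, rightmost.closed = TRUE),
                  length(breaks) - 1), nbins = length(breaks) - 1)
  } else integer(length(breaks) - 1)
  structure(list(counts = counts, breaks = breaks, isis_ms = isis,
                 population = population),
            class = "dg_isi")
}

#' @export
print.dg_isi <- function(x, ...) {
  cat("dg_isi:", x$population, "-", length(x$isis_ms), "intervals",
      if (length(x$isis_ms))
        paste0("(range ", signif(min(x$isis_ms), 3), "-",
               signif(max(x$isis_ms), 4), " ms)"), "\n")
  invisible(x)
}
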