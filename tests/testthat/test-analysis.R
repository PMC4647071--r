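test_that("fast and direct STC computations agree", {
  r <- poisson_raster(runif(25, 0, 2), rate_hz = 6, duration = 1000, seed = 3)
  a <- compute_stc(r, time_bin = 5, dist_bin = 0.05, max_lag = 50,
                   method = "fft")
  b <- compute_stc(r, time_bin = 5, dist_bin = 0.05, max_lag = 50,
                   method = "direct")
  expect_equal(dim(a$corr), dim(b$corr))
  expect_equal(a$n_pairs, b$n_pairs)
  ok <- a$n_pairs > 0
  expect_equal(a$corr[ok, ], b$corr[ok, ], tolerance = 1e-10)
})

test_that("offset twin trains produce a peak at the offset lag", {
  set.seed(11)
  t1 <- sort(runif(160, 0, 3800))
  dt_off <- 20
  r <- make_raster(cell_id = c(rep(1, 160), rep(2, 160)),
                   position_mm = c(rep(1, 160), rep(1.6, 160)),
                   t_ms = c(t1, t1 + dt_off), duration = 4000)
  stc <- compute_stc(r, time_bin = 5, max_lag = 60)
  d_idx <- which.max(stc$n_pairs[-1]) + 1   # the occupied distance bin
  prof <- stc$corr[d_idx, ]
  expect_equal(abs(stc$lag_ms[which.max(prof)]), dt_off)
})

test_that("globally synchronous bursts correlate at all distances, lag 0", {
  bursts <- seq(200, 3800, by = 400)
  cells <- 40
  sp <- expand.grid(cell = 1:cells, b = bursts)
  set.seed(4)
  pos <- runif(cells, 0, 9)
  r <- make_raster(sp$cell, pos[sp$cell], sp$b + runif(nrow(sp), 0, 2),
                   duration = 4000)
  stc <- compute_stc(r, time_bin = 5, max_lag = 50)
  i0 <- which(stc$lag_ms == 0)
  occupied <- which(stc$n_pairs > 0)
  expect_true(all(stc$corr[occupied, i0] > 0.5))
})

test_that("single active neuron leaves distance bins empty and flagged", {
  r <- make_raster(rep(1, 30), rep(2, 30), sort(runif(30, 0, 1000)))
  expect_error(compute_stc(r), NA)
  stc <- compute_stc(r)
  expect_true(all(stc$n_pairs == 0))
  expect_true(all(!is.finite(stc$corr) | stc$corr == 0))
  expect_error(stc_extent(stc), "degenerate")
})

test_that("shuffling positions removes the distance structure", {
  # strongly distance-structured raster: nearby cells share event times
  set.seed(8)
  base <- sort(runif(250, 0, 4000))
  cells <- 80
  pos <- sort(runif(cells, 0, 8))
  sp <- do.call(rbind, lapply(1:cells, function(i) {
    # cells participate in events with probability decaying in position
    keep <- runif(250) < exp(-((pos[i] - 4) / 1.5)^2)
    if (!any(keep)) return(NULL)
    data.frame(cell = i, t = base[keep] + runif(sum(keep), 0, 3))
  }))
  r <- make_raster(sp$cell, pos[sp$cell], sp$t, duration = 4000)
  zero_lag_profile <- function(raster) {
    stc <- compute_stc(raster, max_lag = 25)
    i0 <- which(stc$lag_ms == 0)
    occ <- stc$n_pairs > 30
    list(d = stc$distance_mm[occ], r = stc$corr[occ, i0])
  }
  a <- zero_lag_profile(r)
  # structured raster: correlation declines systematically with distance
  expect_lt(cor(a$d, a$r, method = "spearman"), -0.8)

  shuf <- r
  perm <- sample(cells)
  shuf$position_mm <- pos[perm][match(shuf$cell_id, 1:cells)]
  b <- zero_lag_profile(shuf)
  # after shuffling positions the distance trend disappears
  expect_gt(cor(b$d, b$r, method = "spearman"),
            cor(a$d, a$r, method = "spearman") + 0.4)
})

test_that("delta-correlated rasters have one-bin extents", {
  # twin cells at the same position share identical trains; different
  # positions are independent: correlation lives only at (0 mm, 0 ms)
  set.seed(9)
  sites <- 30
  pos <- runif(sites, 0, 9)
  sp <- do.call(rbind, lapply(1:sites, function(i) {
    t <- sort(runif(90, 0, 4000))
    rbind(data.frame(cell = 2 * i - 1, pos = pos[i], t = t),
          data.frame(cell = 2 * i, pos = pos[i], t = t))
  }))
  r <- make_raster(sp$cell, sp$pos, sp$t, duration = 4000)
  stc <- compute_stc(r, time_bin = 5, dist_bin = 0.05)
  ex <- stc_extent(stc)
  expect_equal(ex$spatial_mm, 0.025)   # half a distance bin
  expect_equal(ex$temporal_ms, 2.5)    # half a time bin
})

test_that("spike-density matrix conserves spikes and localises them", {
  r <- make_raster(c(1, 2, 3), c(0.12, 3.33, 9.99), c(10, 500, 3999))
  m <- spike_density_matrix(r, duration = 4000)
  expect_equal(sum(m), 3)
  expect_equal(sum(m > 0), 3)
  expect_equal(m[floor(0.12 / 0.05) + 1, floor(10 / 8) + 1], 1)

  # equal cell counts per position bin: row sums are iid Poisson
  grid_pos <- rep(seq(0.025, 9.975, by = 0.05), each = 3)
  rp <- poisson_raster(grid_pos, 4, duration = 4000, seed = 5)
  mp <- spike_density_matrix(rp, duration = 4000)
  expect_equal(sum(mp), nrow(rp))
  chi <- suppressWarnings(chisq.test(rowSums(mp)))
  expect_gt(chi$p.value, 0.001)
})

test_that("uniform-rate rows give a flat spectrum and the right Nyquist", {
  m <- matrix(5, nrow = 20, ncol = 500)
  attr(m, "time_bin") <- 8
  sp <- mean_spectrum(m)
  expect_equal(max(sp$freq_hz), 62.5, tolerance = 0.01)  # 1/(2 * 8 ms)
  expect_true(all(sp$magnitude < 1e-9))                  # flat after DC removal
  expect_false(spectral_peak(sp)$found)
})

test_that("sinusoidal rate modulation is recovered at the right frequency", {
  tb <- 8
  tt <- (0:499) * tb / 1000
  m <- do.call(rbind, lapply(1:20, function(i)
    10 + 8 * sin(2 * pi * 20 * tt)))
  attr(m, "time_bin") <- tb
  pk <- spectral_peak(mean_spectrum(m))
  expect_true(pk$found)
  expect_equal(pk$frequency_hz, 20, tolerance = 0.26 / 20)  # one bin

  # injected 18 Hz modulation in actual spike trains
  r <- modulated_raster(f_hz = 18)
  pk2 <- spectral_peak(mean_spectrum(spike_density_matrix(r, duration = 4000)))
  expect_true(pk2$found)
  expect_lt(abs(pk2$frequency_hz - 18), 0.26)
})

test_that("a harmonic pair is seen as primary plus secondary peak", {
  tb <- 8
  tt <- (0:499) * tb / 1000
  m <- do.call(rbind, lapply(1:12, function(i)
    12 + 8 * sin(2 * pi * 17.5 * tt) + 3 * sin(2 * pi * 35 * tt)))
  attr(m, "time_bin") <- tb
  sp <- mean_spectrum(m)
  pk <- spectral_peak(sp)
  expect_equal(pk$frequency_hz, 17.5, tolerance = 0.3 / 17.5)
  # secondary: local maximum near 35 Hz
  near35 <- sp[abs(sp$freq_hz - 35) < 2, ]
  away <- sp[abs(sp$freq_hz - 35) > 3 & abs(sp$freq_hz - 17.5) > 3 &
               sp$freq_hz > 2 & sp$freq_hz < 60, ]
  expect_gt(max(near35$magnitude), 5 * median(away$magnitude))
})

test_that("spectrum is invariant to spatial row permutation", {
  set.seed(13)
  m <- matrix(rpois(40 * 250, 3), nrow = 40)
  attr(m, "time_bin") <- 8
  a <- mean_spectrum(m)
  m2 <- m[sample(40), ]
  attr(m2, "time_bin") <- 8
  expect_equal(a$magnitude, mean_spectrum(m2)$magnitude, tolerance = 1e-12)
})

test_that("ISI histograms pool per-cell consecutive intervals", {
  # single spike per cell: no intervals
  r1 <- make_raster(1:5, runif(5), c(10, 20, 30, 40, 50))
  h1 <- isi_histogram(r1)
  expect_equal(sum(h1$counts), 0)

  # periodic 100 ms train: one occupied bin
  r2 <- make_raster(rep(1, 30), rep(1, 30), seq(0, 2900, by = 100))
  h2 <- isi_histogram(r2, breaks = seq(0, 1000, by = 50))
  expect_equal(sum(h2$counts > 0), 1)
  expect_equal(sum(h2$counts), 29)

  # invariant: intervals = spikes - active cells
  r3 <- poisson_raster(runif(40, 0, 5), 5, duration = 4000, seed = 6)
  h3 <- isi_histogram(r3)
  active <- length(unique(r3$cell_id))
  expect_equal(length(h3$isis_ms), nrow(r3) - active)

  # Poisson input trains: approximately exponential intervals
  ks <- suppressWarnings(ks.test(h3$isis_ms, "pexp", 5 / 1000))
  expect_gt(ks$p.value, 0.01)
})

test_that("analysis operations are pure", {
  r <- poisson_raster(runif(30, 0, 5), 4, duration = 2000, seed = 7)
  expect_identical(compute_stc(r, seed = 2), compute_stc(r, seed = 2))
  m <- spike_density_matrix(r, duration = 2000)
  expect_identical(mean_spectrum(m), mean_spectrum(m))
})
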