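# Shared fixtures: tiny deterministic networks and synthetic rasters.
# Everything is generated in code; expensive objects are memoised per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_counts <- function(gc = 80, ec = 30, bc = 5, mc = 8) {
  c(MEC = ec, LEC = ec, GC = gc, BC = bc, MC = mc)
}

tiny_layout <- function(seed = 7, ...) {
  build_layout(dg_scale(1), tiny_counts(...), seed = seed)
}

tiny_network <- function(include_mc = FALSE, seed = 7) {
  key <- paste0("net_", include_mc, "_", seed)
  memo(key, {
    lay <- tiny_layout(seed)
    g <- suppressMessages(wire_network(lay, include_mc = include_mc,
                                       seed = seed))
    dg_network(lay, g)
  })
}

# raster constructor from explicit spike lists
make_raster <- function(cell_id, position_mm, t_ms, population = "GC",
                        duration = if (length(t_ms)) max(t_ms) + 1 else 1) {
  r <- data.frame(population = rep(population, length.out = length(cell_id)),
                  cell_id = cell_id,
                  position_mm = position_mm, t_ms = t_ms)
  r <- r[order(r$t_ms), ]
  attr(r, "duration_ms") <- duration
  r
}

# n cells at given positions firing homogeneous Poisson at rate_hz
poisson_raster <- function(positions, rate_hz, duration = 4000, seed = 1) {
  set.seed(seed)
  sp <- lapply(seq_along(positions), function(i) {
    n <- rpois(1, rate_hz * duration / 1000)
    if (n == 0) return(NULL)
    data.frame(cell_id = i, position_mm = positions[i],
               t_ms = sort(runif(n, 0, duration)))
  })
  sp <- do.call(rbind, sp)
  make_raster(sp$cell_id, sp$position_mm, sp$t_ms, duration = duration)
}

# population firing with sinusoidal rate modulation at f_hz
modulated_raster <- function(n_cells = 60, f_hz = 18, duration = 4000,
                             base_rate = 8, depth = 0.95, seed = 2) {
  set.seed(seed)
  pos <- runif(n_cells, 0, 10)
  sp <- lapply(seq_len(n_cells), function(i) {
    lmax <- base_rate * (1 + depth) / 1000
    t <- sort(runif(rpois(1, lmax * duration), 0, duration))
    lam <- base_rate * (1 + depth * sin(2 * pi * f_hz * t / 1000)) / 1000
    t <- t[runif(length(t)) < lam / lmax]
    if (!length(t)) return(NULL)
    data.frame(cell_id = i, position_mm = pos[i], t_ms = t)
  })
  sp <- do.call(rbind, sp)
  make_raster(sp$cell_id, sp$position_mm, sp$t_ms, duration = duration)
}
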