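# Independent brute-force oracles used to validate the vectorized
# implementations. These deliberately transcribe the defining formulas
# with explicit loops and share no code with the package internals.

# Local Moran's I: literal triple-loop transcription. x: values,
# wm: dense weights matrix.
oracle_local_moran <- function(x, wm) {
  n <- length(x)
  xbar <- mean(x)
  I <- numeric(n)
  for (i in seq_len(n)) {
    s2 <- 0
    for (j in seq_len(n)) if (j != i) s2 <- s2 + (x[j] - xbar)^2
    s2 <- s2 / (n - 1)
    acc <- 0
    for (j in seq_len(n)) if (j != i) acc <- acc + wm[i, j] * (x[j] - xbar)
    I[i] <- (x[i] - xbar) / s2 * acc
  }
  I
}

# Global Moran's I by the direct formula.
oracle_global_moran <- function(x, wm) {
  n <- length(x)
  z <- x - mean(x)
  (n / sum(wm)) * sum(wm * outer(z, z)) / sum(z^2)
}

# Lagged cross-correlation with window-local means, direct evaluation.
oracle_ccf <- function(x, y, max_lag) {
  n <- length(x)
  vapply(seq.int(-max_lag, max_lag), function(k) {
    tt <- seq.int(max(1, 1 - k), min(n, n - k))
    xs <- x[tt]
    ys <- y[tt + k]
    ok <- !is.na(xs) & !is.na(ys)
    xs <- xs[ok]; ys <- ys[ok]
    num <- sum((xs - mean(xs)) * (ys - mean(ys)))
    num / sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
  }, numeric(1))
}

# Two-loop group mean over (area, variable) or arbitrary keys.
oracle_group_mean <- function(keys, values) {
  uk <- unique(keys)
  out <- numeric(length(uk))
  for (i in seq_along(uk)) {
    acc <- 0; cnt <- 0
    for (j in seq_along(values)) {
      if (keys[j] == uk[i]) { acc <- acc + values[j]; cnt <- cnt + 1 }
    }
    out[i] <- acc / cnt
  }
  names(out) <- uk
  out
}

# Small irregular area set: two adjacent unit squares plus one square
# detached from everything (an island under any contiguity).
island_area_set <- function() {
  sq <- function(x0, y0) {
    cbind(x = c(x0, x0 + 1, x0 + 1, x0, x0), y = c(y0, y0, y0 + 1, y0 + 1, y0))
  }
  out <- tibble::tibble(
    id = c("L", "R", "FAR"),
    x = c(0.5, 1.5, 10.5), y = c(0.5, 0.5, 10.5),
    area_km2 = 1, population = c(100L, 200L, 50L),
    geometry = list(sq(0, 0), sq(1, 0), sq(10, 10))
  )
  class(out) <- c("area_set", class(out))
  out
}

# A cached default 20x20 synthetic study used by several spatial tests:
# generating it once keeps the suite fast without sharing state.
.study_cache <- new.env(parent = emptyenv())

default_study <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(.study_cache[[key]])) {
    cfg <- synthetic_config(seed = seed)
    areas <- make_lattice(cfg$nx, cfg$ny, seed = seed)
    .study_cache[[key]] <- list(
      cfg = cfg, areas = areas, panel = simulate_panel(cfg, areas)
    )
  }
  .study_cache[[key]]
}
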