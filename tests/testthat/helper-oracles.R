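# Independent reference implementations used to check the package against.
# These are deliberately written as plain, slow, obviously-correct code.

# Exhaustive Otsu maximizer: loops over every cut of the same 256-bin
# histogram and keeps the cut with the largest between-class variance
# (w0 * w1 * (mu0 - mu1)^2), breaking ties toward the lower threshold.
oracle_otsu <- function(v, levels = 256L) {
  v <- as.numeric(v)
  rng <- range(v)
  width <- diff(rng) / levels
  bin <- pmin(levels, floor((v - rng[1]) / width) + 1L)
  counts <- tabulate(bin, nbins = levels)
  mids <- rng[1] + (seq_len(levels) - 0.5) * width
  n <- sum(counts)
  best_k <- NA_integer_
  best_sb <- -Inf
  sb_all <- rep(-Inf, levels - 1L)
  for (k in seq_len(levels - 1L)) {
    n0 <- sum(counts[1:k]); n1 <- n - n0
    if (n0 == 0L || n1 == 0L) next
    w0 <- n0 / n; w1 <- n1 / n
    mu0 <- sum(counts[1:k] * mids[1:k]) / n0
    mu1 <- sum(counts[(k + 1L):levels] * mids[(k + 1L):levels]) / n1
    sb <- w0 * w1 * (mu0 - mu1)^2
    sb_all[k] <- sb
    if (sb > best_sb) { best_sb <- sb; best_k <- k }
  }
  list(threshold = rng[1] + best_k * width, k = best_k, sigma_b = sb_all)
}

# Pure-R flood-fill connected components of a logical 3D array.
# Returns a list of sorted linear-index vectors, ordered by first voxel.
oracle_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  man <- abs(offs$dz) + abs(offs$dy) + abs(offs$dx)
  offs <- switch(as.character(connectivity),
                 "6"  = offs[man == 1, ],
                 "18" = offs[man <= 2, ],
                 "26" = offs)
  visited <- array(FALSE, d)
  comps <- list()
  for (start in which(mask)) {
    if (visited[start]) next
    queue <- start
    visited[start] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cur)
      i0 <- cur - 1L
      z <- i0 %% nz + 1L
      y <- (i0 %/% nz) %% ny + 1L
      x <- i0 %/% (nz * ny) + 1L
      for (r in seq_len(nrow(offs))) {
        zz <- z + offs$dz[r]; yy <- y + offs$dy[r]; xx <- x + offs$dx[r]
        if (zz < 1L || zz > nz || yy < 1L || yy > ny || xx < 1L || xx > nx) next
        lin <- (xx - 1L) * nz * ny + (yy - 1L) * nz + zz
        if (mask[lin] && !visited[lin]) {
          visited[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, min, 1L))]
}

# Closed-form 20-80% rise time (ms) of the peak-normalized
# difference-of-exponentials transient, found by root bracketing on the
# analytic expression (independent of any sampled evaluation).
oracle_rise_ms <- function(tau_rise_ms, tau_decay_ms) {
  tr <- tau_rise_ms * 1e-3
  td <- tau_decay_ms * 1e-3
  tpk <- tr * td / (td - tr) * log(td / tr)
  k <- 1 / (exp(-tpk / td) - exp(-tpk / tr))
  f <- function(t) k * (exp(-t / td) - exp(-t / tr))
  t_at <- function(level)
    uniroot(function(t) f(t) - level, c(0, tpk), tol = 1e-14)$root
  (t_at(0.8) - t_at(0.2)) * 1000
}

# Analytic integral of the transient over [0, T_s].
oracle_auc_window <- function(amplitude_um, tau_rise_ms, tau_decay_ms, T_s) {
  tr <- tau_rise_ms * 1e-3
  td <- tau_decay_ms * 1e-3
  tpk <- tr * td / (td - tr) * log(td / tr)
  k <- 1 / (exp(-tpk / td) - exp(-tpk / tr))
  amplitude_um * k * (td * (1 - exp(-T_s / td)) - tr * (1 - exp(-T_s / tr)))
}

# Build a trace that ramps linearly from 0 to `peak` over `ramp_s` seconds
# starting at `onset_s`, then holds the peak; zero before onset.
ramp_trace <- function(onset_s, ramp_s, peak, duration_s = onset_s + ramp_s + 0.1,
                       fs = 10000) {
  t <- seq(0, duration_s, by = 1 / fs)
  v <- pmin(pmax((t - onset_s) / ramp_s, 0), 1) * peak
  trace(v, fs, units = "uM")
}
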