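# Independent reference implementations used to cross-check the package.
# All are deliberately naive (double loops, chain following, grid search):
# they share no code with the implementation under test.

# -- density-peak clustering, O(n^2) brute force ------------------------------

brute_density_peaks <- function(points, dc_percentile, min_share = 0.05) {
  n <- nrow(points)
  d <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      d[i, j] <- sqrt(sum((points[i, ] - points[j, ])^2))
  dvec <- numeric(n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) { k <- k + 1L; dvec[k] <- d[i, j] }
  dc <- unname(quantile(dvec, dc_percentile / 100, type = 7))
  rho <- integer(n)
  for (i in seq_len(n)) {
    cnt <- 0L
    for (j in seq_len(n)) if (j != i && d[i, j] < dc) cnt <- cnt + 1L
    rho[i] <- cnt
  }
  # strict order: higher rho first, index breaks ties
  beats <- function(j, i) rho[j] > rho[i] || (rho[j] == rho[i] && j < i)
  delta <- numeric(n); nh <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    best <- Inf; bj <- NA_integer_
    for (j in seq_len(n)) {
      if (j != i && beats(j, i) && d[i, j] < best) { best <- d[i, j]; bj <- j }
    }
    if (is.na(bj)) { delta[i] <- max(d) } else { delta[i] <- best; nh[i] <- bj }
  }
  list(d = d, dc = dc, rho = rho, delta = delta, nh = nh,
       gamma = rho * delta^2)
}

# chain-following label assignment: walk up nearest-denser links to a center
brute_assign <- function(nh, centers, d) {
  n <- length(nh)
  labels <- integer(n)
  for (i in seq_len(n)) {
    cur <- i
    while (!(cur %in% centers)) {
      if (is.na(nh[cur])) {
        cur <- centers[which.min(d[cur, centers])]
        break
      }
      cur <- nh[cur]
    }
    labels[i] <- match(cur, centers)
  }
  labels
}

# -- threshold-crossing detection, naive scan ---------------------------------

brute_detect <- function(x, thr) {
  runs <- list()
  inside <- FALSE
  for (i in seq_along(x)) {
    if (x[i] < thr && !inside) { start <- i; inside <- TRUE }
    if (x[i] >= thr && inside) {
      runs[[length(runs) + 1L]] <- c(start, i - 1L)
      inside <- FALSE
    }
  }
  if (inside) runs[[length(runs) + 1L]] <- c(start, length(x))
  peaks <- vapply(runs, function(r) {
    idx <- r[1]:r[2]
    idx[which.min(x[idx])]
  }, integer(1))
  list(onsets = vapply(runs, `[`, integer(1), 1),
       offsets = vapply(runs, `[`, integer(1), 2),
       peaks = peaks)
}

# -- grid-search + simplex event fitter ---------------------------------------

grid_fit_event <- function(snippet, fs) {
  n <- length(snippet)
  t_ms <- (seq_len(n) - 1) * 1000 / fs
  sse <- function(p) {
    if (p[1] <= 0 || p[2] <= 0 || p[4] <= 0) return(1e12)
    sum((mepsctools::model_waveform(
      list(amplitude = p[1], rise = p[2], t0 = p[3], decay = p[4]), t_ms) -
        snippet)^2)
  }
  ipk <- which.max(snippet)
  amp0 <- snippet[ipk]; tpk <- t_ms[ipk]
  grid <- expand.grid(a = amp0 * c(0.8, 1, 1.2),
                      r = c(0.2, 0.4, 0.6, 0.9, 1.4),
                      t0 = tpk + c(-0.15, 0, 0.15),
                      d = c(0.8, 1.5, 2.2, 3, 4.5))
  vals <- apply(grid, 1, sse)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- optim(best, sse, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  opt$par
}

# -- misc ---------------------------------------------------------------------

# event table from a ground-truth schedule, shaped like fit_events() output
schedule_to_events <- function(gt) {
  data.frame(event_time_s = gt$time_s,
             amplitude_pA = gt$amplitude_pA,
             rise_ms = gt$rise_ms,
             rise_10_90_ms = 0.8 * gt$rise_ms,
             decay_ms = gt$decay_ms,
             r2 = 0.99, fit_status = "ok",
             stringsAsFactors = FALSE)
}

# sinusoid probe trace
probe_trace <- function(freq, fs = 20000, duration = 2, amplitude = 10) {
  tt <- (0:(duration * fs - 1)) / fs
  trace(amplitude * sin(2 * pi * freq * tt), fs, cell_id = "probe")
}

rms <- function(x) sqrt(mean(x^2))

# magnitude of a designed digital filter at frequency f: polynomial-ratio
# evaluation, independent of the time-domain filtering path
filter_gain <- function(flt, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  b <- flt$b; a <- flt$a
  H <- sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1))
  Mod(H)
}
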