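# Independent brute-force oracles and small fixture builders used across tests.

# Smooth pseudo-random scene with enough texture for registration.
make_scene <- function(n, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * n), n, n)
  k <- outer(dnorm(-2:2), dnorm(-2:2))
  k <- k / sum(k)
  pad <- function(m) m
  out <- matrix(0, n, n)
  for (di in -2:2) for (dj in -2:2) {
    out <- out + k[di + 3, dj + 3] *
      x[((seq_len(n) + di - 1) %% n) + 1, ((seq_len(n) + dj - 1) %% n) + 1]
  }
  100 + 50 * out
}

# Naive per-window running standard deviation (direct sd call per window).
naive_running_std_mean <- function(x, w) {
  n <- length(x)
  mean(vapply(seq_len(n - w + 1), function(i) sd(x[i:(i + w - 1)]), numeric(1)))
}

# Naive per-pixel maximum projection by explicit loops.
naive_mip <- function(cube) {
  d <- dim(cube)
  out <- matrix(-Inf, d[2], d[3])
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    for (p in seq_len(d[1])) out[i, j] <- max(out[i, j], cube[p, i, j])
  }
  out
}

# Naive 8-connected component labeling by scalar BFS.
naive_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc); cur <- 0L
  for (j0 in seq_len(nc)) for (i0 in seq_len(nr)) {
    if (!mask[i0, j0] || lab[i0, j0] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i0, j0)); lab[i0, j0] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        i <- p[1] + di; j <- p[2] + dj
        if (i >= 1 && i <= nr && j >= 1 && j <= nc &&
            mask[i, j] && lab[i, j] == 0L) {
          lab[i, j] <- cur
          queue[[length(queue) + 1]] <- c(i, j)
        }
      }
    }
  }
  lab
}

# Unbiasing factor c4(n) of the sample standard deviation of a Gaussian.
c4_factor <- function(n) {
  sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
}

# Two-regime phantom used by several spectral tests.
two_regime_stack <- function(side = 24, n_frames = 512, seed = 11,
                             tau_fast = 0.02, tau_slow = 0.11) {
  lay <- phantom_layout(side, side, list(
    list(rows = c(1, side / 2), cols = c(1, side),
         params = pixel_dynamics("fast", phase_correlation_time_s = tau_fast)),
    list(rows = c(side / 2 + 1, side), cols = c(1, side),
         params = pixel_dynamics("slow", phase_correlation_time_s = tau_slow))))
  simulate_phantom_stack(lay, n_frames, 100, seed = seed)
}
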