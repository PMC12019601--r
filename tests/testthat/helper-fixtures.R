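# Shared fixtures, all generated in code.

# Sampled triangle transient: 0 -> 60 %DFF over 2 s, back to 0 over 4 s, 20 Hz
triangle_trace <- function() {
  t <- (0:120) / 20
  y <- ifelse(t <= 2, 30 * t, 60 - 15 * (t - 2))
  dff_trace("tri", t, y)
}

# Flat trace with rendered kernels injected at given on-grid onsets
kernel_trace <- function(onsets, amplitude = 50, duration = 200, fs = 20,
                         rise_tau = 0.5, decay_tau = 4, id = "k1") {
  spec <- kernel_spec("x", amplitude_mean = amplitude, amplitude_sd = 0,
                      rise_tau = rise_tau, decay_tau = decay_tau,
                      duration_mean = 30)
  n <- duration * fs
  t <- (0:(n - 1)) / fs
  y <- numeric(n)
  for (o in onsets) {
    i0 <- round(o * fs) + 1
    seg_t <- t[i0:min(n, i0 + 30 * fs)] - t[i0]
    y[i0:min(n, i0 + 30 * fs)] <- y[i0:min(n, i0 + 30 * fs)] +
      render_kernel(spec, amplitude, seg_t)
  }
  dff_trace(id, t, y)
}

# Transient table row for assignment tests (features are placeholders)
fake_transient <- function(neuron_id, t_onset, t_offset,
                           amplitude = 50, censored = FALSE) {
  dt <- t_offset - t_onset
  data.frame(neuron_id = neuron_id, t_onset = t_onset,
             t_peak = t_onset + dt / 3, t_offset = t_offset,
             amplitude = amplitude, duration = dt,
             rise_slope = amplitude / (dt / 3),
             decay_slope = -amplitude / (2 * dt / 3),
             integral = amplitude * dt / 2, n_peaks = 1L,
             censored = censored, stringsAsFactors = FALSE)
}

# Feature matrix with given amplitude values and constant other features,
# one group/condition cell (for fence tests)
fence_fm <- function(amplitudes, group = "TNF", condition = "control") {
  data.frame(amplitude = amplitudes, duration = 10, rise_slope = 5,
             decay_slope = -2, integral = 100, group = group,
             condition = condition, stringsAsFactors = FALSE)
}

# Random feature matrix over 3 groups x 2 conditions
random_fm <- function(seed, n_per = 12) {
  with_seed(seed, {
    rows <- lapply(c("control", "dss"), function(cond) {
      out <- lapply(seq_len(3), function(g) {
        data.frame(amplitude = rnorm(n_per, 20 * g, 4),
                   duration = rnorm(n_per, 10 * g, 2),
                   rise_slope = rnorm(n_per, 3 * g, 1),
                   decay_slope = rnorm(n_per, -2 * g, 0.5),
                   integral = rnorm(n_per, 300 * g, 60),
                   group = c("IL-1b", "TNF", "IL-10")[g],
                   condition = cond, stringsAsFactors = FALSE)
      })
      do.call(rbind, out)
    })
    do.call(rbind, rows)
  })
}

# Brute-force CH by literal evaluation of the definition (independent of the
# package implementation)
ch_bruteforce <- function(x, groups) {
  x <- as.matrix(x)
  g <- as.character(groups)
  lev <- unique(g)
  k <- length(lev)
  n <- nrow(x)
  mu <- colMeans(x)
  B <- 0
  W <- 0
  for (l in lev) {
    xi <- x[g == l, , drop = FALSE]
    mg <- colMeans(xi)
    B <- B + nrow(xi) * sum((mg - mu)^2)
    for (i in seq_len(nrow(xi))) W <- W + sum((xi[i, ] - mg)^2)
  }
  if (B == 0) return(0)
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

# Exact two-sided Mann-Whitney p-value by exhaustive enumeration of all
# rank arrangements (small samples, no ties)
mw_exact_enum <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  u_obs <- u_of(seq_len(nx))
  combos <- utils::combn(length(pooled), nx)
  us <- apply(combos, 2L, function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  mean_u <- nx * length(y) / 2
  mean(abs(us - mean_u) >= abs(u_obs - mean_u))
}
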