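# Independent finite-difference oracles used to cross-check the package's
# closed-form and simulation results. These deliberately share no code with
# the implementation under test.

# Crank-Nicolson solver for diffusion into a slab: domain x in [0, L]
# (half-slab by symmetry), no-flux at x = 0 (centre), c = 1 at x = L (face),
# c = 0 initially. Returns the time (ms) at which the centre first reaches
# `fraction`, by linear interpolation between steps.
oracle_slab_center_time <- function(travel_um, d_um2_s, fraction,
                                    n_nodes = 2000, n_steps = 4000,
                                    t_end_ms = NULL) {
  if (is.null(t_end_ms)) t_end_ms <- 3000 * travel_um^2 / d_um2_s
  dx <- travel_um / (n_nodes - 1)
  dt <- t_end_ms / n_steps / 1000            # seconds
  r <- d_um2_s * dt / dx^2
  # tridiagonal CN matrices for interior nodes 1..n-1 (node n fixed at 1)
  n <- n_nodes
  conc <- numeric(n)
  conc[n] <- 1
  a <- rep(-r / 2, n)                        # sub-diagonal
  b <- rep(1 + r, n)                         # diagonal
  cc <- rep(-r / 2, n)                       # super-diagonal
  # no-flux at node 1: ghost mirror doubles the neighbour coupling
  cc[1] <- -r
  # Dirichlet at node n
  a[n] <- 0; b[n] <- 1; cc[n] <- 0
  thomas <- function(a, b, cc, d) {
    n <- length(d)
    cp <- numeric(n); dp <- numeric(n)
    cp[1] <- cc[1] / b[1]; dp[1] <- d[1] / b[1]
    for (i in 2:n) {
      m <- b[i] - a[i] * cp[i - 1]
      cp[i] <- cc[i] / m
      dp[i] <- (d[i] - a[i] * dp[i - 1]) / m
    }
    x <- numeric(n)
    x[n] <- dp[n]
    for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
    x
  }
  prev <- conc[1]
  for (s in seq_len(n_steps)) {
    d <- numeric(n)
    d[1] <- conc[1] * (1 - r) + r * conc[2]
    i <- 2:(n - 1)
    d[i] <- conc[i] * (1 - r) + (r / 2) * (conc[i - 1] + conc[i + 1])
    d[n] <- 1
    conc <- thomas(a, b, cc, d)
    if (conc[1] >= fraction) {
      t2 <- s * dt * 1000; t1 <- t2 - dt * 1000
      return(t1 + (fraction - prev) / (conc[1] - prev) * (t2 - t1))
    }
    prev <- conc[1]
  }
  stop("oracle: centre never reached the target fraction within t_end")
}

# Plain FTCS diffusion on a disk with reflecting (no-flux) walls; returns
# the spatial CV (population sd / mean) of the field at the requested times.
# Grid geometry matches run_mixing_sim (n cells across the diameter) so the
# two solvers discretize the same domain, but the stepping code is separate.
oracle_disk_diffusion_cv <- function(conc0, mask, dx_um, d_um2_s, times_ms) {
  d_ms <- d_um2_s / 1000
  dt <- 0.2 * dx_um^2 / d_ms
  conc <- conc0
  n <- nrow(conc)
  shift <- function(m, dr, dc) {
    out <- matrix(0, n, n)
    rs <- seq_len(n) - dr; cs <- seq_len(n) - dc
    ok_r <- rs >= 1 & rs <= n; ok_c <- cs >= 1 & cs <= n
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  cv_of <- function(m) {
    v <- m[mask]
    stats::sd(v) * sqrt((length(v) - 1) / length(v)) / mean(v)
  }
  out <- numeric(length(times_ms))
  t_now <- 0
  maskn <- mask * 1
  for (k in seq_along(times_ms)) {
    while (t_now < times_ms[k] - 1e-12) {
      step <- min(dt, times_ms[k] - t_now)
      lap <- matrix(0, n, n)
      for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        nb_mask <- shift(maskn, sh[1], sh[2])
        nb_val <- shift(conc, sh[1], sh[2])
        lap <- lap + nb_mask * (nb_val - conc)
      }
      lap[!mask] <- 0
      conc <- conc + d_ms * step / dx_um^2 * lap
      t_now <- t_now + step
    }
    out[k] <- cv_of(conc)
  }
  out
}
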