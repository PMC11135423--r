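# Shared fixtures: random-walk test tracks and an O(N^2) brute-force MSD
# oracle kept deliberately independent of compute_msd().

random_track <- function(id, n, dt = 0.6) {
  trajectory(id,
             t = (seq_len(n) - 1L) * dt,
             x = cumsum(stats::rnorm(n)),
             y = cumsum(stats::rnorm(n)))
}

# brute force: explicit double loop over all (i, i+k) index pairs
msd_brute_force <- function(traj, k_max) {
  n <- length(traj$t)
  out <- numeric(k_max)
  for (k in seq_len(k_max)) {
    s <- 0
    for (i in seq_len(n - k)) {
      s <- s + (traj$x[i + k] - traj$x[i])^2 + (traj$y[i + k] - traj$y[i])^2
    }
    out[k] <- s / (n - k)
  }
  out
}

# straight-line trajectory along x covering `nd` micrometres in n frames
line_track <- function(id, nd, n = 30, dt = 0.6) {
  trajectory(id, t = (seq_len(n) - 1L) * dt,
             x = seq(0, nd, length.out = n), y = numeric(n))
}

# out-and-back trajectory: x rises to `peak` then returns to 0
out_and_back_track <- function(id, peak, n = 31, dt = 0.6) {
  half <- ceiling(n / 2)
  x <- c(seq(0, peak, length.out = half),
         seq(peak, 0, length.out = n - half + 1L)[-1L])
  trajectory(id, t = (seq_len(n) - 1L) * dt, x = x, y = numeric(n))
}

# msd_curve built directly from a closed-form generating function
curve_from_function <- function(f, tau = seq(0.6, 9, by = 0.6)) {
  structure(data.frame(lag_s = tau, msd_um2 = f(tau),
                       n_pairs = rep(10L, length(tau))),
            class = c("msd_curve", "data.frame"))
}
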