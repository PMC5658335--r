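# shared fixtures: schedules, truths, oracles, session-noise helpers

t1rho_sched <- protocol_schedule("T1rho")
t2_sched <- protocol_schedule("T2")

# in-vivo global estimates used as canonical truths
t1rho_truth <- decay_params(a_s = 0.25, T_s = 6.3, a_l = 0.75, T_l = 37)
t2_truth <- decay_params(a_s = 0.20, T_s = 6.1, a_l = 0.80, T_l = 35)

# Exhaustive grid-search oracle for the S0 = 1 biexponential fit:
# T_s in [1, 20] step 0.25, T_l in [10, 100] step 1, F_s in [0, 100]% step 1.
# Returns the grid point with the smallest residual sum of squares.
grid_search_oracle <- function(y, t) {
  Ts_g <- seq(1, 20, by = 0.25)
  Tl_g <- seq(10, 100, by = 1)
  Fs_g <- seq(0, 100, by = 1) / 100
  Es <- exp(-outer(Ts_g, t, function(T, tt) tt / T))  # |Ts| x |t|
  El <- exp(-outer(Tl_g, t, function(T, tt) tt / T))
  best <- c(rss = Inf, F_s = NA, T_s = NA, T_l = NA)
  for (f in Fs_g) {
    A <- f * Es                      # |Ts| x |t|
    C <- (1 - f) * El - matrix(y, nrow(El), length(y), byrow = TRUE)
    rss <- matrix(rowSums(A^2), nrow(A), nrow(C)) +
      2 * A %*% t(C) +
      matrix(rowSums(C^2), nrow(A), nrow(C), byrow = TRUE)
    i <- arrayInd(which.min(rss), dim(rss))
    if (rss[i] < best["rss"]) {
      best <- c(rss = rss[i], F_s = 100 * f, T_s = Ts_g[i[1]], T_l = Tl_g[i[2]])
    }
  }
  best
}

# add fresh Gaussian noise to a (noiseless) phantom series
with_session_noise <- function(phantom, sigma, seed) {
  set.seed(seed)
  phantom$series + array(stats::rnorm(length(phantom$series), 0, sigma),
                         dim(phantom$series))
}

# phantom spec whose ROI means are shifted by `s` between-subject SDs
shifted_t1rho_spec <- function(s, grid_shape) {
  base <- default_phantom_spec("T1rho", grid_shape, snr = Inf)
  rp <- dplyr::mutate(base$roi_params,
                      T_mono = .data$T_mono + s * .data$T_mono_sd,
                      T_s = .data$T_s + s * .data$T_s_sd,
                      T_l = .data$T_l + s * .data$T_l_sd,
                      F_s = .data$F_s + s * .data$F_s_sd)
  phantom_spec(base$grid_shape, rp, base$schedule, base$noise)
}
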