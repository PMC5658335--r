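test_that("mono fit recovers noiseless parameters and the two-point closed form", {
  y <- mono_signal(t1rho_sched$times, decay_params(S0 = 1.3, T_mono = 25))
  f <- fit_mono(y, t1rho_sched)
  expect_equal(f$params$T_mono, 25, tolerance = 1e-6)
  expect_equal(f$params$S0, 1.3, tolerance = 1e-6)
  expect_identical(f$status, "ok")
  expect_lt(f$rss, 1e-12)

  # two points determine the fit exactly: T = (t2 - t1) / log(y1 / y2)
  sch2 <- acq_schedule(c(2, 55), "T1rho")
  y2 <- exp(-c(2, 55) / 30)
  T_closed <- (55 - 2) / log(y2[1] / y2[2])
  expect_equal(T_closed, 30)  # analytic cross-check of the oracle itself
  expect_equal(fit_mono(y2, sch2)$params$T_mono, 30, tolerance = 1e-6)
})

test_that("degenerate and invalid signals are flagged", {
  expect_identical(fit_mono(rep(1, 10), t1rho_sched)$status, "degenerate")
  expect_identical(fit_mono(rep(0, 10), t1rho_sched)$status, "failed")
  expect_identical(fit_mono(c(rep(1, 9), NA), t1rho_sched)$status, "failed")
  expect_identical(fit_bi(rep(0, 10), t1rho_sched)$status, "failed")
  expect_error(fit_mono(1:5, t1rho_sched), "length")
  expect_error(fit_bi(exp(-c(1, 2, 3, 4) / 10), acq_schedule(1:4, "T2")),
               "at least 5")
})

test_that("bi fit recovers noiseless parameters with free and fixed S0", {
  p <- decay_params(a_s = 0.2, T_s = 5, a_l = 0.8, T_l = 35)
  y <- bi_signal(t1rho_sched$times, p)
  for (S0 in list(NULL, 1)) {
    f <- fit_bi(y, t1rho_sched, S0 = S0)
    expect_identical(f$status, "ok")
    expect_equal(f$params$T_s, 5, tolerance = 1e-3)
    expect_equal(f$params$T_l, 35, tolerance = 1e-3)
    expect_equal(f$fractions$F_s, 20, tolerance = 1e-3 * 20)
    expect_false(f$excluded)
  }
})

test_that("bi fit of mono data is degenerate and the verdict resolves to mono", {
  y <- mono_signal(t1rho_sched$times, decay_params(T_mono = 30))
  v <- fit_voxel(y, t1rho_sched)
  expect_identical(v$verdict, "mono")
  b <- v$bi
  # degenerate either through a vanishing amplitude or coincident constants
  expect_true(b$status == "degenerate" ||
                b$fractions$F_s < 1 || b$fractions$F_s > 99 ||
                b$params$T_s / b$params$T_l > 0.99)
})

test_that("model selection separates mono and bi noiseless decays", {
  vb <- fit_voxel(bi_signal(t1rho_sched$times, t1rho_truth), t1rho_sched)
  expect_identical(vb$verdict, "bi")
  vm <- fit_voxel(mono_signal(t1rho_sched$times, decay_params(T_mono = 27)),
                  t1rho_sched)
  expect_identical(vm$verdict, "mono")
})

test_that("F-test false-biexponential rate on noisy mono decays is near alpha", {
  set.seed(5)
  n <- 400
  y0 <- mono_signal(t1rho_sched$times, decay_params(T_mono = 30))
  verdicts <- replicate(n, {
    y <- pmax(y0 + rnorm(10, 0, 1 / 65), 0)
    fit_voxel(y, t1rho_sched)$verdict
  })
  rate <- mean(verdicts == "bi")
  # F-test at alpha = 0.05 plus degeneracy guards: rate at or below alpha,
  # but clearly non-zero
  expect_gte(rate, 0.002)
  expect_lte(rate, 0.12)
})

test_that("separation rule excludes insufficiently separated components", {
  retained <- decay_params(a_s = .25, T_s = 6.3, a_l = .75, T_l = 37)
  expect_false(apply_exclusion(retained))  # 4 * 6.3 = 25.2 < 37
  expect_true(apply_exclusion(
    decay_params(a_s = .5, T_s = 10, a_l = .5, T_l = 20)))
  # boundary: 4 * T_s == T_l is excluded (strict inequality required)
  expect_true(apply_exclusion(
    decay_params(a_s = .5, T_s = 5, a_l = .5, T_l = 20)))
})

test_that("fitting is invariant to the order of (time, sample) pairs", {
  y <- bi_signal(t1rho_sched$times, t1rho_truth)
  perm <- c(7, 1, 10, 3, 5, 2, 9, 4, 8, 6)
  sch_perm <- structure(list(times = t1rho_sched$times[perm],
                             modality = "T1rho", snr = 65),
                        class = "acq_schedule")
  v1 <- fit_voxel(y, t1rho_sched)
  v2 <- fit_voxel(y[perm], sch_perm)
  expect_equal(glance(v2), glance(v1))
})

test_that("fit_voxels matches fit_voxel row-wise on a long table", {
  d <- tidyr::expand_grid(voxel = 1:2, time = t1rho_sched$times)
  d$signal <- ifelse(d$voxel == 1,
                     bi_signal(d$time, t1rho_truth),
                     mono_signal(d$time, decay_params(T_mono = 27)))
  out <- fit_voxels(d[sample(nrow(d)), ], t1rho_sched)
  expect_identical(nrow(out), 2L)
  expect_identical(out$verdict, c("bi", "mono"))
  expect_equal(out$T_short[1], 6.3, tolerance = 1e-3)
  expect_equal(out$T_mono[2], 27, tolerance = 1e-6)
})

test_that("bi residual never exceeds mono residual on converged fits", {
  set.seed(7)
  for (i in 1:30) {
    y <- pmax(bi_signal(t1rho_sched$times,
                        decay_params(a_s = runif(1, .1, .5),
                                     T_s = runif(1, 2, 10),
                                     a_l = runif(1, .5, .9),
                                     T_l = runif(1, 25, 60))) +
                rnorm(10, 0, 1 / 65), 0)
    v <- fit_voxel(y, t1rho_sched)
    if (v$mono$status != "failed" && v$bi$status != "failed") {
      expect_lte(v$bi$rss, v$mono$rss + 1e-12)
    }
  }
})

test_that("fit_volume validates inputs and handles empty masks", {
  series <- array(1, c(3, 3, 1, 9))
  expect_error(fit_volume(series, t1rho_sched), "4th dimension")
  series <- array(1, c(3, 3, 1, 10))
  expect_error(fit_volume(series, t1rho_sched,
                          tissue_mask = array(TRUE, c(2, 2, 1))),
               "dimensions")
  maps <- fit_volume(series, t1rho_sched,
                     tissue_mask = array(FALSE, c(3, 3, 1)))
  expect_identical(maps$n_fitted, 0L)
  expect_true(all(is.na(maps$T_mono)))
})

test_that("volume fitting is deterministic and round-trips a noiseless phantom", {
  ph <- generate_phantom(
    default_phantom_spec("T1rho", c(14, 14, 2), bi_fraction = 0.5, snr = Inf),
    seed = 21)
  m1 <- fit_volume(ph$series, ph$spec$schedule, phantom_tissue_mask(ph))
  m2 <- fit_volume(ph$series, ph$spec$schedule, phantom_tissue_mask(ph))
  expect_identical(m1$T_short, m2$T_short)  # bit-identical replay
  expect_identical(m1$T_mono, m2$T_mono)

  j <- dplyr::inner_join(ph$truth, as_tibble(m1), by = c("x", "y", "z", "voxel"))
  # verdicts match generating labels exactly on noiseless data
  expect_identical(j$bi_detected == 1,
                   j$label == "bi" & !(4 * j$T_s >= j$T_l))
  det <- dplyr::filter(j, .data$bi_detected == 1)
  expect_gt(nrow(det), 20)
  expect_equal(det$T_short, det$T_s, tolerance = 1e-3)
  expect_equal(det$T_long, det$T_l, tolerance = 1e-3)
  expect_equal(det$F_short, det$F_s, tolerance = 1e-3)
  mono <- dplyr::filter(j, .data$label == "mono")
  expect_equal(mono$T_mono.y, mono$T_mono.x, tolerance = 1e-3)
})

test_that("SNR estimation inverts the generator noise level", {
  spec <- default_phantom_spec("T1rho", c(24, 24, 2))
  ph <- generate_phantom(spec, seed = 9)
  tissue <- phantom_tissue_mask(ph)
  bg <- ph$label_map == 1L
  snr <- estimate_snr(ph$series, tissue, bg)
  # generator SNR is 1/sigma with S0 = 1; tissue signal at t = 2 ms is
  # slightly below S0, so allow 10%
  expect_equal(snr, 65, tolerance = 0.10)

  ph0 <- generate_phantom(default_phantom_spec("T1rho", c(24, 24, 2),
                                               snr = Inf), seed = 9)
  expect_identical(estimate_snr(ph0$series, tissue, ph0$label_map == 1L), Inf)

  noise_only <- array(abs(rnorm(24 * 24 * 2 * 10, 0, 1 / 65)),
                      c(24, 24, 2, 10))
  expect_lt(estimate_snr(noise_only, tissue, bg), 3)
  expect_error(estimate_snr(ph$series, tissue, tissue), "disjoint")
  expect_error(estimate_snr(ph$series, array(FALSE, c(24, 24, 2)), bg),
               "non-empty")
})
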