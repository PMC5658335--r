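test_that("scan-rescan CV follows the sample-SD convention", {
  expect_equal(cv_scan_rescan(20, 20), 0)
  expect_equal(cv_scan_rescan(20, 30), (10 / sqrt(2)) / 25)
  # first-order behaviour: CV((x, x(1 + eps))) ~ eps / sqrt(2)
  eps <- 1e-4
  expect_equal(cv_scan_rescan(10, 10 * (1 + eps)), eps / sqrt(2),
               tolerance = 1e-3)
  expect_error(cv_scan_rescan(-5, 5), "undefined")
})

test_that("RMSCV pools subject spreads per the root-mean-square definition", {
  expect_equal(rmscv(c(10, 10, 10), c(0, 0, 0)), 0)
  expect_equal(rmscv(c(10, 10, 10), c(1, 1, 1)), 0.10)
  expect_equal(rmscv(c(10, 10, 10), c(3, 4, 0)), sqrt(25 / 3) / 10)
  # with identical subjects RMSCV equals each subject's CV
  expect_equal(rmscv(c(25, 25), c(10 / sqrt(2), 10 / sqrt(2))),
               cv_scan_rescan(20, 30))
  expect_error(rmscv(c(0, 0), c(1, 1)), "undefined")
})

test_that("one-way ICC matches the brute-force ANOVA decomposition", {
  # brute-force oracle: sums of squares computed from first principles
  brute_icc <- function(m) {
    n <- nrow(m); k <- ncol(m)
    grand <- mean(m)
    msb <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
    msw <- sum((m - rowMeans(m))^2) / (n * (k - 1))
    sb2 <- max((msb - msw) / k, 0)
    sb2 / (sb2 + msw)
  }
  m <- matrix(c(10, 20, 30, 12, 22, 32), ncol = 2)
  # hand decomposition: MSW = 2, MSB = 200, sigma_b2 = 99 -> 99/101
  res <- icc(m)
  expect_equal(res$icc, 99 / 101)
  expect_equal(res$sigma_w2, 2)
  expect_equal(res$sigma_b2, 99)
  expect_equal(res$icc, brute_icc(m))
  # independent cross-check through stats::aov mean squares
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(nrow(m)), ncol(m))))
  ms <- summary(stats::aov(y ~ subj, d))[[1]][["Mean Sq"]]
  expect_equal(res$sigma_w2, ms[2])
  expect_equal(res$sigma_b2, (ms[1] - ms[2]) / 2)

  # identical sessions, distinct subjects: all variance is between
  expect_equal(icc(matrix(c(1, 2, 3, 1, 2, 3), ncol = 2))$icc, 1)
  # constructed sigma_b2 == sigma_w2 gives exactly 1/2
  d_ <- sqrt(1.5)
  m2 <- rbind(c(d_ - 1, d_ + 1), c(-d_ - 1, -d_ + 1))
  expect_equal(icc(m2)$icc, 0.5)
  expect_equal(icc(m2)$icc, brute_icc(m2))
  # random matrices stay in [0, 1] after truncation
  set.seed(10)
  for (i in 1:50) {
    r <- icc(matrix(rnorm(12), 4, 3))$icc
    expect_gte(r, 0)
    expect_lte(r, 1)
  }
  expect_warning(res0 <- icc(matrix(5, 3, 2)), "constant")
  expect_true(is.na(res0$icc))
  expect_error(icc(matrix(1:3, 3, 1)), "at least 2")
})

test_that("CV, RMSCV and ICC are invariant under positive rescaling", {
  set.seed(11)
  m <- matrix(rnorm(8, 50, 5), 4, 2)
  for (c_ in c(0.1, 3)) {
    expect_equal(cv_scan_rescan(c_ * m[1, 1], c_ * m[1, 2]),
                 cv_scan_rescan(m[1, 1], m[1, 2]))
    expect_equal(rmscv(c_ * rowMeans(m), c_ * apply(m, 1, sd)),
                 rmscv(rowMeans(m), apply(m, 1, sd)))
    expect_equal(icc(c_ * m)$icc, icc(m)$icc)
  }
})

test_that("roi_means summarises maps per muscle with a valid-bi ratio", {
  ph <- generate_phantom(default_phantom_spec("T1rho", c(16, 16, 2),
                                              bi_fraction = 0.4, snr = Inf),
                         seed = 13)
  maps <- fit_volume(ph$series, ph$spec$schedule, phantom_tissue_mask(ph))
  rm_ <- roi_means(maps, ph$label_map)
  expect_setequal(unique(rm_$metric),
                  c("T_mono", "T_short", "T_long", "F_short", "F_long",
                    "ratio"))
  # noiseless: GM mono mean tracks the spec value of 28 ms
  gm_mono <- rm_$value[rm_$roi == "GM" & rm_$metric == "T_mono"]
  expect_lt(abs(gm_mono - 28), 1)
  # ratio equals the detected share computed directly from the maps
  for (r in unique(rm_$roi)) {
    lin <- which(ph$label_map == match(r, c("background", "GM", "GL", "SOL",
                                            "PER", "TA")))
    expect_equal(rm_$value[rm_$roi == r & rm_$metric == "ratio"],
                 100 * mean(maps$bi_detected[lin] == 1, na.rm = TRUE))
  }
  # F_short and F_long means are complementary
  fs <- rm_$value[rm_$metric == "F_short"]
  fl <- rm_$value[rm_$metric == "F_long"]
  expect_equal(fs + fl, rep(100, length(fs)))
})

test_that("roi_summary averages subjects and degrades gracefully", {
  ph <- generate_phantom(default_phantom_spec("T1rho", c(16, 16, 2),
                                              snr = Inf), seed = 13)
  maps <- fit_volume(ph$series, ph$spec$schedule, phantom_tissue_mask(ph))
  two <- roi_summary(list(maps, maps), ph$label_map)
  expect_true(all(two$sd[!is.na(two$sd)] == 0))  # identical subjects
  one <- roi_summary(maps, ph$label_map)
  expect_true(all(is.na(one$sd)))
  expect_identical(unique(one$n_subjects[one$metric == "T_mono"]), 1L)
  # a label volume missing an ROI simply yields no rows for it
  lab2 <- ph$label_map
  lab2[lab2 == 6L] <- 1L  # drop TA
  expect_false("TA" %in% roi_means(maps, lab2)$roi)
})

test_that("repeatability metrics reproduce their closed forms on a tidy table", {
  d <- tidyr::expand_grid(subject = 1:3, session = 1:2, roi = c("GM", "TA"),
                          metric = c("T_mono", "T_short"))
  set.seed(14)
  d$value <- 30 + 3 * d$subject + rnorm(nrow(d), 0, 0.5)
  res <- repeatability_metrics(d)
  expect_s3_class(res, "repeatability_result")
  expect_identical(nrow(res), 4L)
  one <- d[d$roi == "GM" & d$metric == "T_mono", ]
  wide <- tidyr::pivot_wider(one[, c("subject", "session", "value")],
                             names_from = "session", values_from = "value")
  m <- as.matrix(wide[, -1])
  row <- res[res$roi == "GM" & res$metric == "T_mono", ]
  expect_equal(row$rmscv_pct, 100 * rmscv(rowMeans(m), apply(m, 1, sd)))
  expect_equal(row$icc, icc(m)$icc)
})
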