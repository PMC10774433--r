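test_that("SNR follows the energy-ratio definition", {
  withr::with_seed(1, {
    x <- matrix(stats::rnorm(4 * 500), 4)
    y <- matrix(stats::rnorm(4 * 500), 4)
  })
  expect_equal(snr_pair(x, 2 * x), rep(0, 4), tolerance = 1e-12)
  expect_equal(snr_pair(x, x + 10 * x), rep(-20, 4), tolerance = 1e-12)

  naive <- vapply(1:4, function(ch) {
    es <- 0; ee <- 0
    for (t in 1:500) {
      es <- es + x[ch, t]^2
      ee <- ee + (y[ch, t] - x[ch, t])^2
    }
    10 * log10(es / ee)
  }, 0)
  expect_equal(snr_pair(x, y), naive, tolerance = 1e-10)

  expect_identical(snr_pair(x, x), rep(Inf, 4))
  expect_error(snr_pair(matrix(0, 4, 10), matrix(1, 4, 10)), "zero-energy")
})

test_that("SNR improvement is the out-minus-in identity, channel averaged", {
  withr::with_seed(2, {
    x <- matrix(stats::rnorm(4 * 500), 4)
    n1 <- matrix(stats::rnorm(4 * 500), 4)
  })
  xhat <- x + n1
  expect_equal(as.numeric(snr_improvement(x, xhat, xhat)), 0)
  imp <- snr_improvement(x, xhat, x + 0.1 * n1)
  expect_gt(as.numeric(imp), 0)
  per <- attr(imp, "per_channel")
  expect_equal(as.numeric(imp), mean(per), tolerance = 1e-12)
  expect_equal(per, snr_pair(x, x + 0.1 * n1) - snr_pair(x, xhat),
               tolerance = 1e-12)
})

test_that("RMSE and PRD have their closed-form cases and identity link", {
  withr::with_seed(3, {
    x <- matrix(stats::rnorm(4 * 300), 4)
    y <- x + matrix(stats::rnorm(4 * 300, sd = 0.5), 4)
  })
  expect_equal(as.numeric(rmse(x, x)), 0)
  expect_equal(as.numeric(rmse(x, x + 2)), 2, tolerance = 1e-12)
  expect_equal(as.numeric(prd(x, x)), 0)
  expect_equal(as.numeric(prd(x, 0 * x)), 100, tolerance = 1e-12)

  naive_r <- vapply(1:4, function(ch) sqrt(mean((x[ch, ] - y[ch, ])^2)), 0)
  expect_equal(attr(rmse(x, y), "per_channel"), naive_r, tolerance = 1e-12)

  # PRD = 100 * RMSE * sqrt(T) / sqrt(sum(x^2)) per channel
  link <- 100 * naive_r * sqrt(300) / sqrt(rowSums(x^2))
  expect_equal(attr(prd(x, y), "per_channel"), link, tolerance = 1e-10)

  cm <- channel_metrics(x, y, y)
  expect_equal(cm$snr_imp, rep(0, 5))
  expect_named(cm, c("channel", "snr_in", "snr_out", "snr_imp", "rmse", "prd"))
})

test_that("QRS detection finds clean fetal beats and respects refractoriness", {
  f <- fixture_fetal()
  pk <- detect_qrs(f$signal[1, ], f$fs)
  expect_lte(abs(length(pk) - length(f$peaks)), 2)
  m <- match_peaks(pk, f$peaks, f$fs)
  expect_gte(m$TP / length(f$peaks), 0.95)

  expect_identical(detect_qrs(rep(0, 1000), 250), integer(0))
  for (s in 1:3) {
    noisy <- f$signal[1, ] + withr::with_seed(s, stats::rnorm(15000, sd = 0.3))
    p <- detect_qrs(noisy, f$fs)
    expect_true(all(diff(p) >= 0.2 * f$fs))
  }
  expect_error(detect_qrs(rep(0, 100), 250), "shorter")
})

test_that("peak matching is one-to-one within tolerance and optimal", {
  ref <- c(100, 350, 600, 850)
  m <- match_peaks(ref, ref, 500)
  expect_equal(c(m$TP, m$FN, m$FP), c(4, 0, 0))

  shifted <- ref + 0.06 * 500  # 60 ms at 500 Hz: outside +/-50 ms
  m2 <- match_peaks(shifted, ref, 500)
  expect_equal(m2$TP, 0)
  expect_equal(m2$FN, 4)
  expect_equal(m2$FP, 4)

  # randomized instances with physiological (refractory) spacing:
  # greedy matching must equal brute-force optimal matching
  tol <- 0.05 * 500
  for (s in 1:60) {
    withr::with_seed(s, {
      n_ref <- stats::rpois(1, 5) + 2
      ref_r <- cumsum(stats::runif(n_ref, 100, 250))
      hit <- stats::runif(n_ref) < 0.8
      det_r <- ref_r[hit] + stats::runif(sum(hit), -60, 60)
      det_r <- sort(c(det_r, stats::runif(stats::rpois(1, 1), 0, max(ref_r))))
    })
    m <- match_peaks(det_r, ref_r, 500)
    expect_equal(m$TP, bf_max_matching(det_r, ref_r, tol))
    expect_equal(m$TP + m$FN, length(ref_r))
    expect_equal(m$TP + m$FP, length(det_r))
  }
})

test_that("detection metrics reproduce the worked examples and sentinels", {
  m <- detection_metrics(list(TP = 433, FN = 204, FP = 123))
  expect_equal(round(m$ppv, 2), 77.88)
  expect_equal(round(m$se, 2), 67.97)
  expect_equal(round(m$f1, 2), 72.59)

  w <- detection_metrics(list(TP = 30, FN = 607, FP = 34))
  expect_equal(round(w$f1, 2), 8.56)

  u <- detection_metrics(list(TP = 0, FN = 5, FP = 0))
  expect_true(is.na(u$ppv))
  expect_false(is.na(u$se))

  # F1 is the harmonic mean of PPV and SE to machine precision
  for (s in 1:20) {
    cnt <- withr::with_seed(s, list(TP = sample(1:500, 1),
                                    FN = sample(0:500, 1),
                                    FP = sample(0:500, 1)))
    dm <- detection_metrics(cnt)
    expect_equal(dm$f1, 2 * dm$ppv * dm$se / (dm$ppv + dm$se),
                 tolerance = 1e-14)
  }
})
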