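test_that("beat templates are deterministic and preset modifiers hold", {
  t1 <- generate_beat_template("fetal", seed = 1)
  t2 <- generate_beat_template("fetal", seed = 1)
  expect_identical(t1, t2)
  expect_false(identical(t1, generate_beat_template("fetal", seed = 2)))

  ect <- generate_beat_template("ectopic", seed = 1)
  expect_gte(ect$qrs_width / t1$qrs_width, 1.5)
  expect_gt(abs(ect$waves$amplitude[ect$waves$wave == "R"]),
            abs(t1$waves$amplitude[t1$waves$wave == "R"]))

  expect_true(all(t1$waves$width > 0))
  expect_equal(which.max(abs(t1$waves$amplitude)),
               which(t1$waves$wave == "R"))
  expect_error(generate_beat_template("adult2"), "unknown morphology")
})

test_that("rate profiles have physiological structure", {
  cs <- simulation_case("baseline", 0, duration_s = 60, fs = 250, seed = 5)
  on <- generate_rate_profile(cs, base_bpm = 120)
  expect_true(all(diff(on) > 0))
  # ~120 onsets in 60 s, allowing RR jitter
  expect_gt(length(on), 110)
  expect_lt(length(on), 130)

  for (s in 1:5) {
    cs_s <- simulation_case("case4", 0, duration_s = 60, fs = 250, seed = s)
    on_s <- generate_rate_profile(cs_s)
    expect_true(all(diff(on_s) > 0))
    expect_true(any(attr(on_s, "ectopic")))
  }

  cs2 <- simulation_case("case2", 0, duration_s = 300, fs = 250, seed = 5)
  r <- attr(generate_rate_profile(cs2), "rate_bpm")
  expect_gte(max(r) - min(r), 15)
})

test_that("channel synthesis places beats and applies gain drift", {
  tpl <- generate_beat_template("fetal", seed = 2)
  one <- synthesize_channels(tpl, 1.0, n_channels = 2, movement = "none",
                             fs = 250, seed = 4, duration_s = 2)
  peak <- which.max(abs(one[1, ]))
  expect_lt(abs(peak - 251), 5)  # R peak near t = 1 s

  on <- seq(0.5, 59.5, by = 0.5)
  still <- synthesize_channels(tpl, on, 4, "none", 250, seed = 4,
                               duration_s = 60)
  first_amp <- max(abs(still[1, 1:500]))
  last_amp <- max(abs(still[1, 14501:15000]))
  expect_equal(first_amp / last_amp, 1, tolerance = 1e-6)

  drift <- synthesize_channels(tpl, on, 4, "drift", 250, seed = 4,
                               duration_s = 60)
  ratios <- vapply(1:4, function(ch)
    max(abs(drift[ch, 1:500])) / max(abs(drift[ch, 14501:15000])), 0)
  expect_true(any(abs(ratios - 1) > 0.05))

  expect_message(z <- synthesize_channels(tpl, numeric(0), 4, "none", 250,
                                          seed = 1, duration_s = 1),
                 "empty onset")
  expect_true(all(z == 0))
})

test_that("noise kinds have their stated spectral/temporal structure", {
  wh <- generate_noise("white", 30, 250, seed = 4)
  se <- stats::sd(wh[1, ]) / sqrt(ncol(wh))
  expect_lt(abs(mean(wh[1, ])), 4 * se)

  bw <- generate_noise("baseline_wander", 30, 250, seed = 2)
  ps <- stats::spec.pgram(stats::ts(bw[1, ], frequency = 250), plot = FALSE,
                          taper = 0)
  expect_gte(sum(ps$spec[ps$freq < 1]) / sum(ps$spec), 0.95)

  eb <- generate_noise("emg_burst", 30, 250, seed = 2)
  b <- attr(eb, "burst")
  frac <- (b[2] - b[1] + 1) / ncol(eb)
  expect_gte(frac, 0.1)
  expect_lte(frac, 0.5)
  inside <- eb[1, b[1]:b[2]]
  outside <- eb[1, -(b[1]:b[2])]
  expect_gte(stats::var(inside) / stats::var(outside), 5)

  expect_error(generate_noise("pink", 1, 250), "unknown noise kind")
})

test_that("mix_at_snr calibrates the requested SNR exactly", {
  withr::with_seed(9, {
    clean <- matrix(stats::rnorm(4 * 1000), 4)
    noise <- matrix(stats::rnorm(4 * 1000), 4)
  })
  m0 <- mix_at_snr(clean, noise, 0)
  expect_equal(rowSums((m0 - clean)^2), rowSums(clean^2), tolerance = 1e-12)

  m20 <- mix_at_snr(clean, noise, -20)
  expect_equal(rowSums((m20 - clean)^2), 100 * rowSums(clean^2),
               tolerance = 1e-12)

  m <- mix_at_snr(clean, noise, -12)
  expect_true(all(abs(snr_pair(clean, m) + 12) < 1e-6))

  bad <- clean; bad[2, ] <- 0
  expect_error(mix_at_snr(bad, noise, 0), "zero-energy")
})

test_that("simulate_case produces calibrated, reproducible paired records", {
  rec <- fixture_record()
  expect_equal(dim(rec$clean), dim(rec$noisy))
  expect_equal(nrow(rec$clean), 4L)
  expect_true(all(is.finite(rec$noisy)))
  expect_true(all(abs(snr_pair(rec$clean, rec$noisy) + 6) < 1e-6))
  expect_identical(rec, simulate_case(rec$case))

  base <- simulate_case(simulation_case("baseline", -6, 30, 250, seed = 2))
  expect_identical(base$components, "maternal")
  expect_true(all(c("white", "baseline_wander") %in% rec$components))
})

test_that("uterine-contraction records have a localized high-power interval", {
  # after maternal cancellation the contraction burst dominates the
  # interference, so case3 shows a localized variance peak that the
  # noise-free baseline case lacks
  win_var <- function(r) {
    res <- cancel_maternal(r$noisy, r$maternal_peaks, r$fs)
    z <- res[1, ] - r$clean[1, ]
    n <- length(z) %/% 30
    vapply(seq_len(30), function(i) stats::var(z[((i - 1) * n + 1):(i * n)]), 0)
  }
  for (s in c(4, 14)) {
    v3 <- win_var(simulate_case(simulation_case("case3", -6, 60, 250, seed = s)))
    v0 <- win_var(simulate_case(simulation_case("baseline", -6, 60, 250,
                                                seed = s)))
    expect_gt(max(v3) / stats::median(v3), max(v0) / stats::median(v0))
  }
})

test_that("build_dataset derives distinct seeds per repeat", {
  cases <- lapply(paste0("case", 0:4), simulation_case,
                  snr_db = -3, duration_s = 10, fs = 250, seed = 1)
  ds <- build_dataset(cases, repeats = 5)
  expect_length(ds, 25L)

  one <- build_dataset(cases, repeats = 1)
  expect_identical(vapply(one, function(r) r$case$case_id, ""),
                   paste0("case", 0:4))

  two <- build_dataset(list(cases[[1]]), repeats = 2)
  expect_false(identical(two[[1]]$noisy, two[[2]]$noisy))
})
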