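# Synthetic paired-data simulator.
#
# Emulates fecgsyn-style recordings: a Gaussian-component beat template
# projected onto an onset train and per-channel gains gives the clean fetal
# ECG; maternal interference (slower, much larger), physiological event
# modifiers and noise kinds give the noisy mixture, calibrated per channel to
# a requested input SNR.

SIM_CASES <- c("baseline", "case0", "case1", "case2", "case3", "case4")

#' Simulation case descriptor
#'
#' The six physiological event cases of the synthetic dataset:
#' \describe{
#'   \item{baseline}{abdominal mixture (maternal interference, no added noise)}
#'   \item{case0}{baseline + noise (white + baseline wander)}
#'   \item{case1}{baseline + fetal movement (slow per-channel gain drift)}
#'   \item{case2}{baseline + fetal heart-rate acceleration}
#'   \item{case3}{baseline + uterine contraction (EMG burst)}
#'   \item{case4}{baseline + ectopic beats}
#' }
#'
#' @param case_id One of `"baseline"`, `"case0"` ... `"case4"`.
#' @param snr_db Target per-channel input SNR of the noisy mixture, in dB.
#' @param duration_s Record duration in seconds (default 300, five minutes).
#' @param fs Sampling rate in Hz (default 250).
#' @param seed Integer seed; the whole record is reproducible from it.
#' @return An object of class `simulation_case`.
#' @export
simulation_case <- function(case_id, snr_db = -6, duration_s = 300, fs = 250,
                            seed = 1L) {
  case_id <- match.arg(case_id, SIM_CASES)
  stopifnot(is.numeric(snr_db), length(snr_db) == 1L, is.finite(snr_db),
            duration_s > 0, fs > 0)
  structure(list(case_id = case_id, snr_db = snr_db,
                 duration_s = duration_s, fs = fs, seed = as.integer(seed)),
            class = "simulation_case")
}

#' Generate a beat template
#'
#' A beat is modelled as a sum of five Gaussian components (P, Q, R, S, T) in
#' beat phase theta in \[-pi, pi\], the standard dynamical-model ECG
#' parameterization. A small seed-controlled morphology jitter is applied to
#' the base shape; preset modifiers are then applied deterministically, so for
#' a fixed seed the ectopic template has exactly 1.8x the QRS width and 1.3x
#' the R amplitude of the fetal one, with an inverted T wave.
#'
#' @param morphology_preset `"fetal"`, `"maternal"` or `"ectopic"`.
#' @param seed Integer seed.
#' @return An object of class `beat_template`: data.frame of wave components
#'   (`amplitude`, `center` in radians, `width` in radians), a per-channel
#'   `polarity` vector, and the QRS width.
#' @export
generate_beat_template <- function(morphology_preset, seed = 1L) {
  if (!is.character(morphology_preset) || length(morphology_preset) != 1L ||
      !morphology_preset %in% c("fetal", "maternal", "ectopic"))
    stop("unknown morphology preset: ",
         paste(morphology_preset, collapse = ", "), call. = FALSE)
  base <- withr::with_seed(seed, {
    amp <- c(P = 0.06, Q = -0.12, R = 1.00, S = -0.25, T = 0.22) *
      exp(stats::rnorm(5L, 0, 0.05))
    ctr <- c(P = -1.22, Q = -0.26, R = 0.00, S = 0.26, T = 1.45) +
      stats::rnorm(5L, 0, 0.02)
    wid <- c(P = 0.25, Q = 0.10, R = 0.10, S = 0.10, T = 0.40) *
      exp(stats::rnorm(5L, 0, 0.05))
    pol <- sample(c(-1, 1), 4L, replace = TRUE)
    list(amp = amp, ctr = ctr, wid = wid, pol = pol)
  })
  if (morphology_preset == "ectopic") {
    base$wid[c("Q", "R", "S")] <- base$wid[c("Q", "R", "S")] * 1.8
    base$amp["R"] <- base$amp["R"] * 1.3
    base$amp["T"] <- -base$amp["T"]
  } else if (morphology_preset == "maternal") {
    base$wid <- base$wid * 1.2
  }
  waves <- data.frame(wave = names(base$amp), amplitude = unname(base$amp),
                      center = unname(base$ctr), width = unname(base$wid))
  structure(list(waves = waves, polarity = base$pol,
                 preset = morphology_preset,
                 qrs_width = sum(base$wid[c("Q", "R", "S")])),
            class = "beat_template")
}

#' Generate a beat-onset profile
#'
#' Draws a base fetal heart rate in 110-160 bpm and produces strictly
#' increasing R-peak onset times with mild RR jitter. Case `case2` inserts a
#' heart-rate acceleration: a >= 20 bpm ramp over >= 60 s in the middle of
#' the record. Case `case4` flags a fraction (default 5%) of beats as ectopic
#' and makes them premature (RR shortened to 60%).
#'
#' @param case A [simulation_case()].
#' @param base_bpm Optional fixed base rate in bpm (drawn from 110-160 when `NULL`).
#' @param ectopic_fraction Fraction of beats flagged ectopic in case4.
#' @return Numeric vector of onset times in seconds, with attributes
#'   `ectopic` (logical flags) and `rate_bpm` (per-beat instantaneous rate).
#' @export
generate_rate_profile <- function(case, base_bpm = NULL,
                                  ectopic_fraction = 0.05) {
  stopifnot(inherits(case, "simulation_case"), case$duration_s > 0)
  withr::with_seed(case$seed + 1L, {
    base <- if (is.null(base_bpm)) stats::runif(1, 110, 160) else base_bpm
    dur <- case$duration_s
    # build instantaneous rate as a function of time, then integrate RRs
    ramp_amp <- if (case$case_id == "case2") stats::runif(1, 20, 30) else 0
    ramp_t0 <- dur * 0.3
    ramp_len <- max(60, dur * 0.3)
    rate_at <- function(t) {
      r <- base
      if (ramp_amp > 0) {
        u <- (t - ramp_t0) / ramp_len
        r <- r + ramp_amp * pmin(1, pmax(0, u)) *
          ifelse(t > ramp_t0 + ramp_len, pmax(0, 1 - (t - ramp_t0 - ramp_len) / ramp_len), 1)
      }
      r
    }
    onsets <- numeric(0)
    t <- stats::runif(1, 0, 0.4)
    while (t < dur) {
      onsets <- c(onsets, t)
      rr <- 60 / rate_at(t) * exp(stats::rnorm(1, 0, 0.03))
      t <- t + max(rr, 0.2)
    }
    ect <- rep(FALSE, length(onsets))
    if (case$case_id == "case4" && length(onsets) > 4L) {
      n_ect <- max(1L, round(ectopic_fraction * length(onsets)))
      idx <- sort(sample(2:(length(onsets) - 1L), n_ect))
      # premature beats: pull the flagged onset towards the previous one
      onsets[idx] <- onsets[idx - 1L] + 0.6 * (onsets[idx] - onsets[idx - 1L])
      ect[idx] <- TRUE
      ord <- order(onsets)
      onsets <- onsets[ord]; ect <- ect[ord]
    }
    rate <- 60 / diff(c(onsets, dur + 60 / base))
    structure(onsets, ectopic = ect, rate_bpm = rate)
  })
}

# evaluate a Gaussian-component template over an onset train;
# phase spans [-pi, pi] between beat midpoints, scaled by the local RR
eval_beat_train <- function(template, onsets, duration_s, fs) {
  n <- round(duration_s * fs)
  s <- numeric(n)
  m <- length(onsets)
  if (m == 0L) return(s)
  tt <- (seq_len(n) - 1) / fs
  rr_prev <- if (m > 1L) c(onsets[2L] - onsets[1L], diff(onsets)) else rep(0.5, m)
  rr_next <- if (m > 1L) c(diff(onsets), onsets[m] - onsets[m - 1L]) else rep(0.5, m)
  w <- template$waves
  for (j in seq_len(m)) {
    lo <- max(1L, floor((onsets[j] - rr_prev[j] / 2) * fs) + 1L)
    hi <- min(n, ceiling((onsets[j] + rr_next[j] / 2) * fs) + 1L)
    if (lo > hi) next
    dt <- tt[lo:hi] - onsets[j]
    theta <- ifelse(dt < 0, 2 * pi * dt / rr_prev[j], 2 * pi * dt / rr_next[j])
    keep <- theta >= -pi & theta <= pi
    beat <- numeric(length(dt))
    for (i in seq_len(nrow(w)))
      beat[keep] <- beat[keep] +
        w$amplitude[i] * exp(-(theta[keep] - w$center[i])^2 / (2 * w$width[i]^2))
    s[lo:hi] <- s[lo:hi] + beat
  }
  s
}

#' Project a beat train onto channels
#'
#' Evaluates the template on the onset train and scales it by per-channel
#' gains (sign taken from the template's polarity). With `movement = "drift"`
#' the gains vary smoothly and boundedly over time (never reaching zero),
#' emulating fetal movement; with `movement = "none"` they are constant.
#'
#' @param template A [generate_beat_template()] object.
#' @param onsets R-peak times in seconds.
#' @param n_channels Number of output channels.
#' @param movement `"none"` or `"drift"`.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed for gains and drift phases.
#' @param duration_s Record duration; defaults to covering the last onset.
#' @param gains Optional fixed per-channel gains (overrides seeded draw).
#' @return `n_channels` x samples matrix.
#' @export
synthesize_channels <- function(template, onsets, n_channels = 4L,
                                movement = c("none", "drift"), fs = 250,
                                seed = 1L, duration_s = NULL, gains = NULL) {
  movement <- match.arg(movement)
  stopifnot(n_channels >= 1L)
  if (is.null(duration_s))
    duration_s <- if (length(onsets)) max(onsets) + 1 else 1
  n <- round(duration_s * fs)
  if (length(onsets) == 0L) {
    message("synthesize_channels: empty onset train, returning zeros")
    return(matrix(0, n_channels, n))
  }
  s <- eval_beat_train(template, onsets, duration_s, fs)
  withr::with_seed(seed + 2L, {
    if (is.null(gains)) {
      pol <- rep_len(template$polarity, n_channels)
      gains <- pol * stats::runif(n_channels, 0.5, 1)
    }
    X <- matrix(0, n_channels, n)
    tt <- (seq_len(n) - 1) / fs
    for (c_i in seq_len(n_channels)) {
      g <- rep(gains[c_i], n)
      if (movement == "drift") {
        ph <- stats::runif(1, 0, 2 * pi)
        per <- stats::runif(1, 40, 80)
        g <- gains[c_i] * (1 + 0.35 * sin(2 * pi * tt / per + ph))
      }
      X[c_i, ] <- g * s
    }
    X
  })
}

#' Generate interference noise
#'
#' Three zero-mean noise kinds:
#' \describe{
#'   \item{white}{i.i.d. Gaussian noise}
#'   \item{baseline_wander}{a sum of low-frequency sinusoids (all below
#'     0.5 Hz), so essentially all spectral power lies below 1 Hz}
#'   \item{emg_burst}{band-limited (20 Hz up) colored noise concentrated in a
#'     contiguous burst covering 10-50% of the record, with a small floor
#'     outside the burst - emulating a uterine contraction}
#' }
#'
#' @param kind `"white"`, `"baseline_wander"` or `"emg_burst"`.
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed.
#' @param n_channels Number of channels.
#' @return `n_channels` x samples matrix with exact zero mean per channel.
#'   `emg_burst` carries a `burst` attribute with the burst sample range.
#' @export
generate_noise <- function(kind, duration_s, fs, seed = 1L, n_channels = 4L) {
  if (!is.character(kind) || length(kind) != 1L ||
      !kind %in% c("white", "baseline_wander", "emg_burst"))
    stop("unknown noise kind: ", paste(kind, collapse = ", "), call. = FALSE)
  n <- round(duration_s * fs)
  withr::with_seed(seed + 3L, {
    X <- switch(kind,
      white = matrix(stats::rnorm(n_channels * n), n_channels, n),
      baseline_wander = {
        tt <- (seq_len(n) - 1) / fs
        t(vapply(seq_len(n_channels), function(i) {
          f <- stats::runif(5L, 0.05, 0.45)
          a <- stats::runif(5L, 0.3, 1)
          ph <- stats::runif(5L, 0, 2 * pi)
          colSums(a * sin(outer(2 * pi * f, tt) + ph))
        }, numeric(n)))
      },
      emg_burst = {
        frac <- stats::runif(1, 0.1, 0.5)
        blen <- round(frac * n)
        b0 <- sample.int(n - blen, 1L)
        env <- rep(0.15, n)  # small floor outside the contraction
        ramp <- max(8L, round(0.05 * blen))
        shape <- rep(1, blen)
        shape[seq_len(ramp)] <- seq(0, 1, length.out = ramp)
        shape[(blen - ramp + 1L):blen] <- seq(1, 0, length.out = ramp)
        env[b0:(b0 + blen - 1L)] <- pmax(0.15, shape)
        hi <- min(0.45 * fs, 120) / (fs / 2)
        bf <- signal::butter(4, c(20 / (fs / 2), hi), type = "pass")
        M <- t(vapply(seq_len(n_channels), function(i) {
          signal::filtfilt(bf, stats::rnorm(n)) * env
        }, numeric(n)))
        attr(M, "burst") <- c(start = b0, end = b0 + blen - 1L)
        M
      })
    b <- attr(X, "burst")
    X <- X - rowMeans(X)
    if (!is.null(b)) attr(X, "burst") <- b
    X
  })
}

#' Mix noise into a clean signal at a requested SNR
#'
#' Scales the noise per channel so that the input SNR,
#' `10*log10(sum(x^2) / sum((xhat - x)^2))`, equals `snr_db` on every channel
#' (within numerical precision).
#'
#' @param clean Channels x samples matrix with nonzero energy per channel.
#' @param noise Same-shape matrix with nonzero energy per channel.
#' @param snr_db Target SNR in dB.
#' @return Noisy matrix `clean + scaled noise`.
#' @export
mix_at_snr <- function(clean, noise, snr_db) {
  check_same_shape(clean, noise)
  es <- rowSums(clean^2)
  en <- rowSums(noise^2)
  if (any(es == 0) || any(en == 0))
    stop("zero-energy channel: cannot calibrate SNR", call. = FALSE)
  alpha <- sqrt(es / (en * 10^(snr_db / 10)))
  clean + noise * alpha
}

#' Simulate a paired record
#'
#' Produces a matched pair of clean fetal ECG and noisy mixture for one
#' simulation case. The clean signal is the fetal beat train projected onto
#' four channels (with movement drift for case1, rate acceleration for case2,
#' ectopic beats for case4). The interference is the maternal ECG (60-100
#' bpm, 2-10x fetal amplitude) plus the case's noise kinds (white + wander
#' for case0, EMG burst for case3; none for baseline), calibrated per channel
#' so the noisy mixture sits at the requested input SNR. Identical cases give
#' bitwise-identical records.
#'
#' @param case A [simulation_case()].
#' @return An object of class `paired_record`: `clean` and `noisy` 4 x N
#'   matrices, `fs`, `case`, fetal and maternal R-peak sample indices
#'   (1-based), and the interference component names.
#' @export
simulate_case <- function(case) {
  stopifnot(inherits(case, "simulation_case"))
  fs <- case$fs; dur <- case$duration_s
  fet_tpl <- generate_beat_template("fetal", seed = case$seed)
  onsets <- generate_rate_profile(case)
  ect <- attr(onsets, "ectopic")
  movement <- if (case$case_id == "case1") "drift" else "none"

  if (case$case_id == "case4" && any(ect)) {
    ect_tpl <- generate_beat_template("ectopic", seed = case$seed)
    gains <- withr::with_seed(case$seed + 2L, {
      rep_len(fet_tpl$polarity, 4L) * stats::runif(4L, 0.5, 1)
    })
    clean <- synthesize_channels(fet_tpl, as.numeric(onsets)[!ect], 4L,
                                 movement, fs, seed = case$seed,
                                 duration_s = dur, gains = gains) +
      synthesize_channels(ect_tpl, as.numeric(onsets)[ect], 4L,
                          movement, fs, seed = case$seed,
                          duration_s = dur, gains = gains)
  } else {
    clean <- synthesize_channels(fet_tpl, as.numeric(onsets), 4L, movement,
                                 fs, seed = case$seed, duration_s = dur)
  }

  # maternal interference: slower, much larger, its own morphology
  mat_tpl <- generate_beat_template("maternal", seed = case$seed + 11L)
  mat_case <- simulation_case("baseline", snr_db = 0, duration_s = dur,
                              fs = fs, seed = case$seed + 13L)
  mat_onsets <- withr::with_seed(case$seed + 17L, {
    base <- stats::runif(1, 60, 100)
    t <- stats::runif(1, 0, 0.6); on <- numeric(0)
    while (t < dur) {
      on <- c(on, t)
      t <- t + max(60 / base * exp(stats::rnorm(1, 0, 0.03)), 0.3)
    }
    on
  })
  mat_amp <- withr::with_seed(case$seed + 19L, stats::runif(1, 2, 10))
  maternal <- mat_amp * synthesize_channels(mat_tpl, mat_onsets, 4L, "none",
                                            fs, seed = case$seed + 23L,
                                            duration_s = dur)

  noise_kinds <- switch(case$case_id,
                        baseline = character(0),
                        case0 = c("white", "baseline_wander"),
                        case3 = "emg_burst",
                        character(0))
  interference <- maternal
  fet_rms <- sqrt(mean(clean^2))
  for (k in noise_kinds) {
    nz <- generate_noise(k, dur, fs, seed = case$seed + 29L, n_channels = 4L)
    # a uterine contraction burst overwhelms the fetal signal locally
    k_amp <- if (k == "emg_burst") 4 else 1
    interference <- interference +
      nz * (k_amp * fet_rms / stats::sd(as.vector(nz)))
  }
  noisy <- mix_at_snr(clean, interference, case$snr_db)

  structure(list(
    clean = clean, noisy = noisy, fs = fs, case = case,
    fetal_peaks = pmin(round(as.numeric(onsets) * fs) + 1L, ncol(clean)),
    fetal_ectopic = ect,
    maternal_peaks = pmin(round(mat_onsets * fs) + 1L, ncol(clean)),
    components = c("maternal", noise_kinds)),
    class = "paired_record")
}

#' @export
print.paired_record <- function(x, ...) {
  cat(sprintf("paired_record: %s, %g dB, %d ch x %d samples @ %g Hz, seed %d\n",
              x$case$case_id, x$case$snr_db, nrow(x$clean), ncol(x$clean),
              x$fs, x$case$seed))
  cat(sprintf("  %d fetal beats, %d maternal beats; interference: %s\n",
              length(x$fetal_peaks), length(x$maternal_peaks),
              paste(x$components, collapse = " + ")))
  invisible(x)
}

#' Build a dataset of paired records
#'
#' Runs each case `repeats` times with distinct derived seeds (repeat r of a
#' case uses `seed + 7919 * (r - 1)`), mirroring the practice of running each
#' simulation several times independently for statistical purposes.
#'
#' @param cases List of [simulation_case()] objects.
#' @param repeats Number of independent repeats per case (>= 1).
#' @return List of `length(cases) * repeats` [simulate_case()] records,
#'   ordered case-major.
#' @export
build_dataset <- function(cases, repeats = 1L) {
  stopifnot(repeats >= 1L)
  if (inherits(cases, "simulation_case")) cases <- list(cases)
  out <- list()
  for (cs in cases) {
    for (r in seq_len(repeats)) {
      cs_r <- cs
      cs_r$seed <- as.integer(cs$seed + 7919L * (r - 1L))
      out[[length(out) + 1L]] <- simulate_case(cs_r)
    }
  }
  out
}
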