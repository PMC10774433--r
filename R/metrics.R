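# Evaluation metrics: SNR / SNR improvement, RMSE, PRD (against ground
# truth), and QRS-detection PPV / SE / F1 with +/-50 ms matching tolerance.
# Aggregates are always the arithmetic mean of per-channel values.

#' Per-channel signal-to-noise ratio of an estimate
#'
#' `10*log10(sum(x^2) / sum((y - x)^2))` per channel. Serves both the input
#' SNR (y = noisy) and the output SNR (y = denoised). An exact reconstruction
#' yields the `+Inf` sentinel rather than an error so batch summaries remain
#' computable.
#'
#' @param x Reference (clean) channels x samples matrix.
#' @param y Estimate, same shape.
#' @return Numeric vector of per-channel SNRs in dB.
#' @export
snr_pair <- function(x, y) {
  check_same_shape(x, y)
  es <- rowSums(x^2)
  if (any(es == 0)) stop("zero-energy reference channel", call. = FALSE)
  ee <- rowSums((y - x)^2)
  ifelse(ee == 0, Inf, 10 * log10(es / ee))
}

#' SNR improvement
#'
#' `SNR_imp = SNR_out - SNR_in` per channel, then averaged over channels.
#' When the denoised signal equals the noisy input the improvement is exactly
#' 0 dB.
#'
#' @param x Clean reference.
#' @param xhat Noisy input.
#' @param xt Denoised estimate.
#' @return Average improvement in dB, with the per-channel values in the
#'   `"per_channel"` attribute.
#' @export
snr_improvement <- function(x, xhat, xt) {
  per <- snr_pair(x, xt) - snr_pair(x, xhat)
  structure(channel_average(per), per_channel = per)
}

#' Root mean-square error
#'
#' `sqrt(mean((x - xt)^2))` per channel, then averaged.
#'
#' @inheritParams snr_improvement
#' @return Average RMSE with per-channel attribute.
#' @export
rmse <- function(x, xt) {
  check_same_shape(x, xt)
  per <- sqrt(rowMeans((x - xt)^2))
  structure(mean(per), per_channel = per)
}

#' Percent root-mean-square difference
#'
#' `100 * sqrt(sum((x - xt)^2) / sum(x^2))` per channel, then averaged.
#' A zero estimate yields exactly 100.
#'
#' @inheritParams snr_improvement
#' @return Average PRD (percent) with per-channel attribute.
#' @export
prd <- function(x, xt) {
  check_same_shape(x, xt)
  es <- rowSums(x^2)
  if (any(es == 0)) stop("zero-energy reference channel", call. = FALSE)
  per <- 100 * sqrt(rowSums((x - xt)^2) / es)
  structure(mean(per), per_channel = per)
}

#' Average per-channel metric values
#'
#' The aggregation convention used throughout: metrics are computed along
#' each channel and then averaged arithmetically.
#'
#' @param per_channel Numeric vector of per-channel values.
#' @return Scalar mean.
#' @export
channel_average <- function(per_channel) mean(per_channel)

#' Full divergence-metric report for one window or record
#'
#' @inheritParams snr_improvement
#' @return data.frame with one row per channel plus an `"average"` row and
#'   columns `snr_in`, `snr_out`, `snr_imp`, `rmse`, `prd`.
#' @export
channel_metrics <- function(x, xhat, xt) {
  s_in <- snr_pair(x, xhat)
  s_out <- snr_pair(x, xt)
  r <- attr(rmse(x, xt), "per_channel")
  p <- attr(prd(x, xt), "per_channel")
  df <- data.frame(channel = c(as.character(seq_len(nrow(x))), "average"),
                   snr_in = c(s_in, mean(s_in)),
                   snr_out = c(s_out, mean(s_out)),
                   snr_imp = c(s_out - s_in, mean(s_out - s_in)),
                   rmse = c(r, mean(r)),
                   prd = c(p, mean(p)))
  df
}

# ---- QRS detection ---------------------------------------------------------

#' Detect QRS complexes on a single channel
#'
#' An adaptive-threshold detector in the style of the classic Hamilton
#' algorithm: band-pass filter (8-30 Hz), absolute first difference, 80 ms
#' moving-average envelope, adaptive signal/noise threshold tracking, and a
#' 200 ms refractory period. Detected locations are refined to the local
#' extremum of the filtered signal. An all-zero signal yields no detections.
#'
#' @param x Numeric vector (one channel).
#' @param fs Sampling rate in Hz (> 0); the signal must exceed one second.
#' @return Strictly increasing integer vector of R-peak sample indices
#'   (1-based), successive peaks at least 0.2 * fs apart.
#' @export
detect_qrs <- function(x, fs) {
  stopifnot(is.numeric(x), fs > 0)
  n <- length(x)
  if (n <= fs) stop("signal shorter than one second", call. = FALSE)
  if (all(x == 0)) return(integer(0))
  bf <- signal::butter(2, c(8, 30) / (fs / 2), type = "pass")
  f <- signal::filtfilt(bf, x)
  env <- abs(c(0, diff(f)))
  w <- max(1L, round(0.08 * fs))
  env <- as.numeric(stats::filter(env, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  refr <- round(0.2 * fs)
  # candidate local maxima of the envelope
  cand <- which(diff(sign(diff(env))) < 0) + 1L
  if (!length(cand)) return(integer(0))
  slev <- max(env[seq_len(min(n, round(2 * fs)))])
  nlev <- mean(env[seq_len(min(n, round(2 * fs)))])
  peaks <- integer(0)
  last <- -Inf
  for (p in cand) {
    thr <- nlev + 0.25 * (slev - nlev)
    if (env[p] >= thr && env[p] > 1e-12) {
      if (p - last >= refr) {
        peaks <- c(peaks, p)
        last <- p
        slev <- 0.8 * slev + 0.2 * env[p]
      } else if (length(peaks) && env[p] > env[peaks[length(peaks)]]) {
        # better peak inside the refractory window of the previous detection
        if (length(peaks) == 1L || p - peaks[length(peaks) - 1L] >= refr) {
          slev <- 0.8 * slev + 0.2 * env[p]
          peaks[length(peaks)] <- p
          last <- p
        }
      }
    } else {
      nlev <- 0.9 * nlev + 0.1 * env[p]
    }
  }
  # refine to the extremum of the band-passed signal near each detection
  half <- round(0.06 * fs)
  ref <- vapply(peaks, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    as.integer(lo + which.max(abs(f[lo:hi])) - 1L)
  }, 0L)
  ref <- sort(unique(ref))
  # enforce the refractory period after refinement
  keep <- integer(0)
  for (p in ref) {
    if (!length(keep) || p - keep[length(keep)] >= refr)
      keep <- c(keep, p)
  }
  as.integer(keep)
}

#' Match detected peaks to reference peaks
#'
#' One-to-one matching of detections to reference R peaks within a tolerance
#' of +/-50 ms. Detections are processed in temporal order and matched to
#' the earliest unmatched reference peak within tolerance, which attains the
#' maximum possible number of true positives for this interval-structured
#' problem (verified against brute-force optimal matching). Each reference
#' peak matches at most one detection; `TP + FN = |reference|` and
#' `FP = |detected| - TP`.
#'
#' @param detected Sorted detection sample indices.
#' @param reference Sorted reference sample indices.
#' @param fs Sampling rate, Hz.
#' @param tolerance_ms Matching tolerance in milliseconds (default 50).
#' @return An object of class `detection_counts`: list with `TP`, `FN`, `FP`,
#'   `tolerance_ms`.
#' @export
match_peaks <- function(detected, reference, fs, tolerance_ms = 50) {
  detected <- sort(as.numeric(detected))
  reference <- sort(as.numeric(reference))
  tol <- tolerance_ms / 1000 * fs
  used <- rep(FALSE, length(reference))
  tp <- 0L
  j <- 1L
  for (d in detected) {
    while (j <= length(reference) && (used[j] || reference[j] < d - tol))
      j <- j + 1L
    if (j <= length(reference) && abs(reference[j] - d) <= tol) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  structure(list(TP = tp, FN = length(reference) - tp,
                 FP = length(detected) - tp, tolerance_ms = tolerance_ms),
            class = "detection_counts")
}

#' QRS-detection performance metrics
#'
#' Positive predictive value `TP/(TP+FP)`, sensitivity `TP/(TP+FN)` and their
#' harmonic mean F1, as percentages. An undefined ratio (zero denominator)
#' yields the explicit `NA` sentinel, never a silent zero.
#'
#' @param counts A [match_peaks()] result, or a list with `TP`, `FN`, `FP`.
#' @return An object of class `detection_metrics`: list with `ppv`, `se`,
#'   `f1` (percent).
#' @export
detection_metrics <- function(counts) {
  tp <- counts$TP; fn <- counts$FN; fp <- counts$FP
  stopifnot(tp >= 0, fn >= 0, fp >= 0)
  ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  se <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  f1 <- if (is.na(ppv) || is.na(se)) NA_real_
        else if (ppv + se == 0) 0
        else 2 * ppv * se / (ppv + se)
  structure(list(ppv = ppv, se = se, f1 = f1), class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("PPV = %.2f%%  SE = %.2f%%  F1 = %.2f%%\n", x$ppv, x$se, x$f1))
  invisible(x)
}
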