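# Preprocessing: maternal-ECG cancellation, resampling to 500 Hz, windowing
# into 4 x 1920 segments, per-channel standardization.

WINDOW_LEN <- 1920L
TARGET_FS <- 500

#' Cancel the maternal ECG by synchronized template subtraction
#'
#' For each channel, beats are extracted around the supplied maternal R-peak
#' locations, averaged into a beat template, and the template is subtracted
#' at every peak with a per-beat least-squares amplitude fit. The
#' least-squares fit makes each subtraction an orthogonal projection, so the
#' residual energy never exceeds the input energy on any beat segment.
#' Segments touching the record edges are handled with the template clipped
#' to the overlap.
#'
#' @param abdominal Channels x samples matrix (post-extraction mixture).
#' @param maternal_peaks Maternal R-peak sample indices (1-based, >= 2).
#' @param fs Sampling rate in Hz (sets the beat window from the median RR).
#' @return Residual matrix, same shape as the input.
#' @export
cancel_maternal <- function(abdominal, maternal_peaks, fs = 250) {
  stopifnot(is.matrix(abdominal))
  maternal_peaks <- sort(as.integer(maternal_peaks))
  if (length(maternal_peaks) < 2L)
    stop("maternal cancellation needs at least 2 reference peaks",
         call. = FALSE)
  n <- ncol(abdominal)
  if (any(maternal_peaks < 1L) || any(maternal_peaks > n))
    stop("maternal peaks outside record bounds", call. = FALSE)
  # beat window: half the median RR, capped at 0.35 s (a maternal PQRST
  # complex fits well inside +/-0.35 s at 60-100 bpm)
  half <- min(floor(stats::median(diff(maternal_peaks)) / 2),
              round(0.35 * fs))
  rel <- (-half):half
  out <- abdominal
  for (ch in seq_len(nrow(abdominal))) {
    x <- abdominal[ch, ]
    # average template from fully interior beats
    segs <- vapply(maternal_peaks, function(p) {
      idx <- p + rel
      if (idx[1L] < 1L || idx[length(idx)] > n) rep(NA_real_, length(rel))
      else x[idx]
    }, numeric(length(rel)))
    tpl <- rowMeans(segs, na.rm = TRUE)
    tpl[!is.finite(tpl)] <- 0
    tt2 <- sum(tpl^2)
    if (tt2 == 0) next
    for (p in maternal_peaks) {
      idx <- p + rel
      keep <- idx >= 1L & idx <= n
      ii <- idx[keep]; tk <- tpl[keep]
      denom <- sum(tk^2)
      if (denom == 0) next
      a <- sum(out[ch, ii] * tk) / denom
      out[ch, ii] <- out[ch, ii] - a * tk
    }
  }
  out
}

#' Resample a record to a common frequency
#'
#' Polyphase anti-aliased resampling of every channel to `fs_out` (500 Hz by
#' default). Output length is `round(N * fs_out / fs_in)`; when
#' `fs_in == fs_out` the input is returned unchanged.
#'
#' @param record Channels x samples matrix.
#' @param fs_in Input sampling rate in Hz (> 0).
#' @param fs_out Target sampling rate in Hz.
#' @return Channels x `round(N * fs_out / fs_in)` matrix.
#' @export
resample_record <- function(record, fs_in, fs_out = TARGET_FS) {
  stopifnot(is.matrix(record))
  if (!is.numeric(fs_in) || length(fs_in) != 1L || fs_in <= 0)
    stop("fs_in must be a positive sampling rate", call. = FALSE)
  if (fs_in == fs_out) return(record)
  # rational ratio p/q in lowest terms
  scale <- 1000
  p0 <- round(fs_out * scale); q0 <- round(fs_in * scale)
  g <- gcd2(p0, q0)
  p <- p0 / g; q <- q0 / g
  n_out <- round(ncol(record) * fs_out / fs_in)
  out <- t(vapply(seq_len(nrow(record)), function(ch) {
    y <- signal::resample(record[ch, ], p, q)
    length(y) <- n_out            # crop/zero-pad to the exact target length
    y[is.na(y)] <- 0
    y
  }, numeric(n_out)))
  out
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Segment a record into non-overlapping 4 x 1920 windows
#'
#' Consecutive windows with no overlap; a trailing remainder shorter than
#' 1920 samples is dropped. Offsets (0-based sample index of each window
#' start) are recorded so windows can be mapped back to the record.
#'
#' @param record 4 x N matrix at 500 Hz.
#' @param width Window length in samples.
#' @return List of windows, each a list with `values` (4 x 1920) and
#'   `offset` (0-based).
#' @export
segment_windows <- function(record, width = WINDOW_LEN) {
  stopifnot(is.matrix(record), nrow(record) == 4L)
  n <- ncol(record)
  k <- n %/% width
  if (k == 0L) {
    warning("record shorter than one window (", n, " < ", width,
            " samples); returning no windows")
    return(list())
  }
  lapply(seq_len(k), function(i) {
    off <- (i - 1L) * width
    list(values = record[, (off + 1L):(off + width), drop = FALSE],
         offset = off)
  })
}

#' Standardize a window per channel
#'
#' Subtracts the per-channel mean and divides by the per-channel standard
#' deviation (population convention), storing the statistics so the physical
#' scale can be restored with [destandardize_window()].
#'
#' @param window 4 x L numeric matrix, or a list with a `values` element.
#' @return List with `values` (each channel mean 0, sd 1), `mu`, `sigma`.
#' @export
standardize_window <- function(window) {
  X <- if (is.list(window)) window$values else window
  stopifnot(is.matrix(X))
  mu <- rowMeans(X)
  sigma <- sqrt(rowMeans((X - mu)^2))
  if (any(sigma == 0))
    stop("degenerate window: zero-variance channel", call. = FALSE)
  list(values = (X - mu) / sigma, mu = mu, sigma = sigma)
}

#' @rdname standardize_window
#' @param std A list as returned by [standardize_window()].
#' @export
destandardize_window <- function(std) {
  std$values * std$sigma + std$mu
}

#' Prepare paired training windows from records
#'
#' Full preprocessing pipeline for simulated paired records: optional
#' maternal-ECG cancellation of the noisy mixture (using the record's
#' maternal peak list), resampling of both signals to 500 Hz, windowing into
#' 4 x 1920 segments, and standardization. The noisy window is standardized
#' with its own statistics; the clean target is expressed in the same
#' standardized coordinates (shifted/scaled by the noisy window's
#' statistics), so de-standardizing a model output with the noisy statistics
#' restores physical units.
#'
#' @param records A [paired_record] or list of them.
#' @param cancel Apply [cancel_maternal()] to the noisy mixture first.
#' @return List of paired windows, each with `x` (standardized clean target),
#'   `xhat` (standardized noisy), `x_phys`, `xhat_phys`, `mu`, `sigma`,
#'   `offset`, `record` (index), `fs`.
#' @export
prepare_paired_windows <- function(records, cancel = TRUE) {
  if (inherits(records, "paired_record")) records <- list(records)
  out <- list()
  for (ri in seq_along(records)) {
    rec <- records[[ri]]
    noisy <- rec$noisy
    if (cancel && length(rec$maternal_peaks) >= 2L)
      noisy <- cancel_maternal(noisy, rec$maternal_peaks, rec$fs)
    clean500 <- resample_record(rec$clean, rec$fs)
    noisy500 <- resample_record(noisy, rec$fs)
    wc <- segment_windows(clean500)
    wn <- segment_windows(noisy500)
    for (i in seq_along(wn)) {
      sh <- standardize_window(wn[[i]]$values)
      out[[length(out) + 1L]] <- list(
        x = (wc[[i]]$values - sh$mu) / sh$sigma,
        xhat = sh$values,
        x_phys = wc[[i]]$values,
        xhat_phys = wn[[i]]$values,
        mu = sh$mu, sigma = sh$sigma,
        offset = wn[[i]]$offset, record = ri, fs = TARGET_FS)
    }
  }
  out
}
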