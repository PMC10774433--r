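# Shared fixtures, built once per test run.

# a small standardized random window pair
random_window <- function(seed) {
  withr::with_seed(seed, list(
    x = matrix(stats::rnorm(4 * 1920), 4),
    xhat = matrix(stats::rnorm(4 * 1920), 4)))
}

# short clean fetal signal with known beat times (seconds -> samples)
fixture_fetal <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cs <- simulation_case("baseline", 0, duration_s = 60, fs = 250, seed = 3)
      onsets <- generate_rate_profile(cs, base_bpm = 140)
      tpl <- generate_beat_template("fetal", seed = 3)
      sig <- synthesize_channels(tpl, as.numeric(onsets), 4, "none", 250,
                                 seed = 3, duration_s = 60)
      cache <<- list(signal = sig, onsets = as.numeric(onsets), fs = 250,
                     peaks = round(as.numeric(onsets) * 250) + 1)
    }
    cache
  }
})

# a short simulated paired record shared across tests
fixture_record <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_case(
        simulation_case("case0", snr_db = -6, duration_s = 60, fs = 250,
                        seed = 7))
    cache
  }
})

# brute-force maximum-cardinality matching (reference oracle for match_peaks)
bf_max_matching <- function(detected, reference, tol) {
  if (length(detected) == 0L) return(0L)
  best <- bf_max_matching(detected[-1L], reference, tol)
  for (r in seq_along(reference)) {
    if (abs(detected[1L] - reference[r]) <= tol) {
      cand <- 1L + bf_max_matching(detected[-1L], reference[-r], tol)
      if (cand > best) best <- cand
    }
  }
  best
}
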