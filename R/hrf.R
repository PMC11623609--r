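#' Canonical double-gamma hemodynamic response function
#'
#' Evaluates the canonical two-gamma HRF used throughout the package: a
#' response gamma peaking at `peak` seconds minus an undershoot gamma peaking
#' at `undershoot` seconds scaled by `ratio`, truncated at `duration` seconds
#' and normalised to unit peak.
#'
#' @param t Numeric vector of times in seconds.
#' @param peak Time-to-peak of the positive lobe (seconds). Default 6.
#' @param undershoot Time-to-peak of the undershoot lobe (seconds). Default 16.
#' @param ratio Undershoot amplitude relative to the peak lobe. Default 1/6.
#' @param duration Support of the kernel in seconds; the response is 0 for
#'   `t < 0` or `t > duration`. Default 32.
#' @return Numeric vector of HRF values, same length as `t`.
#' @examples
#' tt <- seq(0, 32, by = 0.1)
#' h <- canonical_hrf(tt)
#' tt[which.max(h)] # ~6 s
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6,
                          duration = 32) {
  stopifnot(peak > 0, undershoot > 0, ratio >= 0, duration > 0)
  # gamma density with unit scale has mode shape-1; choose shapes so the
  # modes land on `peak` and `undershoot`
  h <- stats::dgamma(t, shape = peak + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot + 1, rate = 1)
  h[t < 0 | t > duration] <- 0
  mx <- max(h)
  if (mx > 0) h <- h / mx
  h
}

# Discrete convolution of a TR-sampled amplitude course with the HRF sampled
# on the same TR grid; output truncated to the input length.
#' @keywords internal
#' @noRd
hrf_convolve <- function(x, tr_seconds, hrf_params = list()) {
  kern_t <- seq(0, hrf_params$duration %||% 32, by = tr_seconds)
  kern <- do.call(canonical_hrf, c(list(t = kern_t), hrf_params))
  out <- stats::convolve(x, rev(kern), type = "open")
  out[seq_along(x)]
}
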