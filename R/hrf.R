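#' Double-gamma hemodynamic response function
#'
#' Canonical double-gamma HRF evaluated at times `t` (seconds): a gamma
#' density peaking at `peak` seconds minus an undershoot gamma peaking at
#' `undershoot` seconds, scaled by `1/ratio`. The returned curve is
#' normalized to unit maximum so that event amplitudes are expressed as the
#' peak percent-signal-change of the evoked response.
#'
#' @param t numeric vector of times in seconds (values < 0 return 0).
#' @param peak time-to-peak of the positive lobe, seconds.
#' @param undershoot time-to-peak of the negative lobe, seconds.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @return numeric vector of HRF values, unit peak.
#' @examples
#' h <- hrf_double_gamma(seq(0, 30, by = 0.5))
#' which.max(h) # peak near 5 s
#' @export
hrf_double_gamma <- function(t, peak = 5, undershoot = 15, ratio = 6) {
  stopifnot(peak > 0, undershoot > peak, ratio > 0)
  # shape a, rate b with mode (a-1)/b; fix b = 1 so mode = peak
  a1 <- peak + 1
  a2 <- undershoot + 1
  h <- ifelse(t < 0, 0,
    stats::dgamma(t, shape = a1, rate = 1) -
      stats::dgamma(t, shape = a2, rate = 1) / ratio
  )
  h / max(h)
}

# Convolve an event time course (fine grid, step dt) with the HRF and return
# the response on the same grid, normalized to unit peak so the event's
# amplitude parameter is its peak response.
convolve_events <- function(drive, dt, hrf_params = list()) {
  t_h <- seq(0, 32, by = dt)
  h <- do.call(hrf_double_gamma, c(list(t = t_h), hrf_params))
  n <- length(drive)
  y <- stats::convolve(drive, rev(h), type = "open")[seq_len(n)]
  y
}

# Unit-peak response shape for a boxcar of `width` seconds, sampled on a grid
# of step dt. Used to stamp per-trial preparatory and stimulus responses.
boxcar_response <- function(width, dt, hrf_params = list()) {
  n_box <- max(1L, round(width / dt))
  pad <- round(32 / dt)
  drive <- c(rep(1, n_box), rep(0, pad))
  y <- convolve_events(drive, dt, hrf_params)
  y / max(y)
}
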