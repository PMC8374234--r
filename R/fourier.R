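# Direct frequency-domain deconvolution (the classical alternative to the
# iterative fit) and the low-pass-plus-shift post-processing historically used
# to clean up its output. Included for comparison: on noisy recordings the
# direct quotient produces CDLDs with negative phases and high-frequency
# ripple, which motivates the model-based routine.

#' Direct FFT deconvolution of an eCAP by a unitary response
#'
#' Computes `CDLD = F^-1( F(eCAP) / F(UR) )` on the common sampling grid
#' (circular convolution model; the UR is zero-padded to the eCAP length).
#' Spectral bins where the UR magnitude falls below `eps` times its maximum
#' are floored at that magnitude with the phase preserved, which caps the
#' division blow-up in nearly-empty bins; `eps = 0` reproduces the plain
#' division. With `scale = "dt"` the quotient is divided by the sampling
#' interval, matching the dt-scaled convolution convention of
#' [forward_ecap()].
#'
#' Output sample `i` is at time `t_ecap_start - t_ur_start + i * dt` (times
#' subtract under deconvolution); the result wraps circularly.
#'
#' @param ecap Single-waveform tibble.
#' @param ur Single-waveform tibble sampled at the same `dt`, not identically
#'   zero, no longer than the eCAP.
#' @param eps Relative spectral floor (default 1e-6; 0 disables flooring).
#' @param scale `"dt"` or `"none"`.
#' @param id Waveform id for the output table.
#' @return A waveform tibble with the recovered CDLD samples.
#' @export
fft_deconvolve <- function(ecap, ur, eps = 1e-6, scale = c("dt", "none"),
                           id = "cdld") {
  scale <- match.arg(scale)
  we <- wf_single(ecap, "ecap")
  wu <- wf_single(ur, "ur")
  if (abs(we$dt - wu$dt) > 1e-9 * we$dt) {
    abort("`ecap` and `ur` must share the same sampling interval")
  }
  if (all(wu$v == 0)) abort("`ur` is identically zero")
  if (wu$n > we$n) abort("`ur` must not be longer than `ecap`")
  stopifnot(eps >= 0)
  n <- we$n
  H <- fft(c(wu$v, numeric(n - wu$n)))
  if (eps > 0) {
    mag <- Mod(H)
    floor_mag <- eps * max(mag)
    low <- mag < floor_mag
    H[low] <- ifelse(mag[low] == 0, complex(real = floor_mag),
                     H[low] * floor_mag / mag[low])
  }
  v <- Re(fft(fft(we$v) / H, inverse = TRUE)) / n
  if (scale == "dt") v <- v / we$dt
  wf_tbl(id, we$t0 - wu$t0, we$dt, v)
}

#' Low-pass and upward-shift post-processing of a deconvolved CDLD
#'
#' The regularizing post-processing applied to direct-deconvolution CDLDs:
#' a zero-phase low-pass filter (forward-backward Butterworth, default
#' order 4, cutoff 2.5 kHz) removes the high-frequency ripple, then the trace
#' is shifted upward so its minimum equals zero (no shift if the filtered
#' minimum is already non-negative). The filter design is recorded in the
#' output's attributes (`filter` and `shift_uV`); results depending on it
#' should be treated as comparative, not canonical.
#'
#' @param cdld Single-waveform tibble (time in ms).
#' @param cutoff_khz Low-pass cutoff (kHz, default 2.5); must be below the
#'   Nyquist frequency `1 / (2 dt)`.
#' @param order Butterworth order (default 4; applied forward and backward,
#'   so the effective attenuation is doubled).
#' @return The post-processed waveform tibble, everywhere `>= 0`.
#' @export
strahl_postprocess <- function(cdld, cutoff_khz = 2.5, order = 4) {
  w <- wf_single(cdld, "cdld")
  nyquist_khz <- 1 / (2 * w$dt)
  if (cutoff_khz >= nyquist_khz) {
    abort(sprintf("cutoff %.3g kHz is at or above the Nyquist frequency %.3g kHz",
                  cutoff_khz, nyquist_khz))
  }
  bf <- signal::butter(order, cutoff_khz / nyquist_khz, type = "low")
  filtered <- signal::filtfilt(bf, w$v)
  shift <- max(0, -min(filtered))
  out <- wf_tbl(w$id, w$t0, w$dt, filtered + shift)
  attr(out, "filter") <- sprintf("zero-phase Butterworth order %d, cutoff %.3g kHz",
                                 order, cutoff_khz)
  attr(out, "shift_uV") <- shift
  out
}
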