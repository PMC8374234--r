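# Parameterized unitary response (UR) and compound discharge latency
# distribution (CDLD), and the forward convolution model
#   eCAP(t) = integral CDLD(tau) * UR(t - tau) dtau,
# discretized on a uniform grid.

#' Uniform time grid specification
#'
#' @param start,end First and last sample time (ms).
#' @param dt Sampling interval (ms, > 0).
#' @return A `time_grid` object with fields `start`, `end`, `dt`, `n`.
#' @export
time_grid <- function(start, end, dt) {
  stopifnot(is.numeric(start), is.numeric(end), is.numeric(dt),
            dt > 0, end > start)
  n <- as.integer(round((end - start) / dt)) + 1L
  structure(list(start = start, end = start + (n - 1L) * dt, dt = dt, n = n),
            class = "time_grid")
}

grid_times <- function(grid) grid$start + (seq_len(grid$n) - 1) * grid$dt

as_time_grid <- function(grid) {
  if (inherits(grid, "time_grid")) return(grid)
  if (is.list(grid) && all(c("start", "end", "dt") %in% names(grid))) {
    return(time_grid(grid$start, grid$end, grid$dt))
  }
  abort("`grid` must be a time_grid or a list with start, end, dt")
}

#' Biphasic unitary-response parameters
#'
#' The unitary response — the stereotyped contribution of a single
#' auditory-nerve fiber's action potential to the recording electrode — is
#' modeled as a negative phase followed by a positive phase. For `t < t0` the
#' phase parameters are `(u_n, sigma_n)`, for `t >= t0` they are
#' `(u_p, sigma_p)`, and the value is
#' `U * exp(1/2) * x * exp(-x^2 / 2)` with `x = (t - t0) / sigma`. Under this
#' peak normalization the trough is exactly `-u_n` at `t0 - sigma_n` and the
#' peak exactly `+u_p` at `t0 + sigma_p`, so the amplitude parameters read
#' directly as peak magnitudes in uV.
#'
#' @param u_n Negative-peak magnitude (uV, > 0).
#' @param sigma_n Negative-phase width (ms, > 0).
#' @param u_p Positive-peak magnitude (uV, >= 0).
#' @param sigma_p Positive-phase width (ms, > 0).
#' @param t0 Transition time between the phases (ms).
#' @return A `ur_params` object.
#' @export
ur_params <- function(u_n, sigma_n, u_p, sigma_p, t0) {
  vals <- c(u_n = u_n, sigma_n = sigma_n, u_p = u_p, sigma_p = sigma_p, t0 = t0)
  if (!all(is.finite(vals))) abort("UR parameters must be finite")
  if (u_n <= 0) abort("`u_n` must be > 0")
  if (u_p < 0) abort("`u_p` must be >= 0")
  if (sigma_n <= 0 || sigma_p <= 0) abort("UR widths must be > 0")
  structure(as.list(vals), class = "ur_params")
}

#' @export
print.ur_params <- function(x, ...) {
  cat(sprintf(
    "<ur_params> u_n = %.4g uV, sigma_n = %.4g ms, u_p = %.4g uV, sigma_p = %.4g ms, t0 = %.4g ms\n",
    x$u_n, x$sigma_n, x$u_p, x$sigma_p, x$t0))
  invisible(x)
}

#' @export
tidy.ur_params <- function(x, ...) {
  tibble(term = c("u_n", "sigma_n", "u_p", "sigma_p", "t0"),
         value = c(x$u_n, x$sigma_n, x$u_p, x$sigma_p, x$t0))
}

#' Published human unitary response
#'
#' The human UR estimated from a large clinical eCAP dataset:
#' `u_n = 0.155` uV, `sigma_n = 0.038` ms, `u_p = 0.022` uV,
#' `sigma_p = 0.155` ms, `t0 = -0.128` ms. Suitable as the fixed UR for
#' CDLD-only (step-two) fitting of human recordings.
#'
#' @return A [ur_params()] object.
#' @export
published_human_ur <- function() {
  ur_params(u_n = 0.155, sigma_n = 0.038, u_p = 0.022, sigma_p = 0.155,
            t0 = -0.128)
}

#' Step-one starting unitary response
#'
#' The UR used to initialize joint (step-one) fitting, based on the guinea-pig
#' UR morphology: `u_n = 0.12`, `sigma_n = 0.045`, `u_p = 0.06`,
#' `sigma_p = 0.12`, `t0 = -0.06`.
#'
#' @return A [ur_params()] object.
#' @export
step1_start_ur <- function() {
  ur_params(u_n = 0.12, sigma_n = 0.045, u_p = 0.06, sigma_p = 0.12,
            t0 = -0.06)
}

# Vectorized UR evaluator.
ur_value <- function(p, t) {
  neg <- t < p$t0
  s <- ifelse(neg, p$sigma_n, p$sigma_p)
  U <- ifelse(neg, p$u_n, p$u_p)
  x <- (t - p$t0) / s
  U * exp(0.5) * x * exp(-x^2 / 2)
}

#' Gaussian-mixture latency distribution parameters
#'
#' The compound discharge latency distribution (CDLD) weights unitary
#' responses over time and is modeled as a mixture of `K >= 1` unit-peak
#' Gaussian components: `CDLD(t) = sum_k alpha_k * exp(-(t - mu_k)^2 /
#' (2 sigma_k^2))`. `alpha_k` is the component's peak amplitude (>= 0, which
#' guarantees a non-negative CDLD), `mu_k` its peak latency (ms) and `sigma_k`
#' its width (ms). Components are stored sorted by ascending `mu` (ties broken
#' by ascending `sigma`), which resolves the early/late labeling ambiguity.
#' A width of exactly 0 is the degenerate point-mass limit reached at the
#' lower fit bound; it evaluates to zero everywhere except exactly at `mu`.
#'
#' @param alpha,mu,sigma Numeric vectors of equal length `K`, or `alpha` may be
#'   a data frame with columns `alpha`, `mu`, `sigma`.
#' @return A `cdld_params` object; `$components` is a tibble sorted by `mu`.
#' @export
cdld_params <- function(alpha, mu = NULL, sigma = NULL) {
  if (is.data.frame(alpha)) {
    comp <- alpha
    if (!all(c("alpha", "mu", "sigma") %in% names(comp))) {
      abort("component data frame needs columns 'alpha', 'mu', 'sigma'")
    }
    comp <- as_tibble(comp[, c("alpha", "mu", "sigma")])
  } else {
    comp <- tibble(alpha = alpha, mu = mu, sigma = sigma)
  }
  if (nrow(comp) < 1) abort("CDLD needs at least one component")
  if (!all(vapply(comp, function(x) all(is.finite(x)), logical(1)))) {
    abort("CDLD parameters must be finite")
  }
  if (any(comp$alpha < 0)) abort("component amplitudes `alpha` must be >= 0")
  if (any(comp$sigma < 0)) abort("component widths `sigma` must be >= 0")
  comp <- comp[order(comp$mu, comp$sigma), ]
  structure(list(components = comp), class = "cdld_params")
}

#' @export
print.cdld_params <- function(x, ...) {
  cat(sprintf("<cdld_params> %d Gaussian component(s)\n", nrow(x$components)))
  print(x$components)
  invisible(x)
}

#' @export
tidy.cdld_params <- function(x, ...) {
  dplyr::mutate(x$components, component = dplyr::row_number(),
                .before = "alpha")
}

# Vectorized CDLD evaluator; sigma floored at a tiny value so the sigma = 0
# bound degenerates cleanly to an (off-grid) point mass instead of NaN.
cdld_value <- function(alpha, mu, sigma, t) {
  s <- pmax(sigma, 1e-12)
  out <- numeric(length(t))
  for (k in seq_along(alpha)) {
    out <- out + alpha[k] * exp(-((t - mu[k])^2) / (2 * s[k]^2))
  }
  out
}

#' Evaluate a unitary response on a time grid
#'
#' @param ur A [ur_params()] object.
#' @param grid A [time_grid()].
#' @param id Waveform id for the output table.
#' @return A waveform tibble.
#' @export
eval_ur <- function(ur, grid, id = "ur") {
  stopifnot(inherits(ur, "ur_params"))
  grid <- as_time_grid(grid)
  wf_tbl(id, grid$start, grid$dt, ur_value(ur, grid_times(grid)))
}

#' Evaluate a CDLD on a time grid
#'
#' @param cdld A [cdld_params()] object.
#' @param grid A [time_grid()].
#' @param id Waveform id for the output table.
#' @return A waveform tibble; amplitudes are everywhere `>= 0`.
#' @export
eval_cdld <- function(cdld, grid, id = "cdld") {
  stopifnot(inherits(cdld, "cdld_params"))
  grid <- as_time_grid(grid)
  comp <- cdld$components
  wf_tbl(id, grid$start, grid$dt,
         cdld_value(comp$alpha, comp$mu, comp$sigma, grid_times(grid)))
}

# --- discrete convolution engine ---------------------------------------------

# Linear ("open") convolution via zero-padded FFT. Returns length
# length(x) + length(y) - 1.
conv_open <- function(x, y) {
  nf <- length(x) + length(y) - 1L
  npad <- stats::nextn(nf, 2)
  xf <- fft(c(x, numeric(npad - length(x))))
  yf <- fft(c(y, numeric(npad - length(y))))
  Re(fft(xf * yf, inverse = TRUE))[seq_len(nf)] / npad
}

# Same, with the kernel FFT precomputed (kern = list(npad, yfft, ny)).
conv_open_kern <- function(x, kern) {
  nf <- length(x) + kern$ny - 1L
  xf <- fft(c(x, numeric(kern$npad - length(x))))
  Re(fft(xf * kern$yfft, inverse = TRUE))[seq_len(nf)] / kern$npad
}

make_conv_kernel <- function(y, nx_max) {
  npad <- stats::nextn(nx_max + length(y) - 1L, 2)
  list(npad = npad, yfft = fft(c(y, numeric(npad - length(y)))), ny = length(y))
}

# UR support, in integer multiples of dt, wide enough that the truncated tails
# contribute < 1e-8 of the peak. Bounds on (t0, sigma_n, sigma_p) may be passed
# to fix the support across an optimization.
ur_support_jlim <- function(dt, t0_range, sigma_n_max, sigma_p_max) {
  c(floor((min(t0_range) - 6 * sigma_n_max) / dt),
    ceiling((max(t0_range) + 6 * sigma_p_max) / dt))
}

# Numeric forward model: CDLD (component vectors) convolved with the UR,
# sampled on the grid (t0, dt, n). jlim fixes the UR support in samples.
forward_num <- function(alpha, mu, sigma, ur, t0, dt, n, jlim, scale_dt,
                        kern = NULL) {
  m_idx <- (-jlim[2]):(n - 1L - jlim[1])
  cv <- cdld_value(alpha, mu, sigma, t0 + m_idx * dt)
  full <- if (is.null(kern)) {
    conv_open(cv, ur_value(ur, (jlim[1]:jlim[2]) * dt))
  } else {
    conv_open_kern(cv, kern)
  }
  b <- jlim[2] - jlim[1] + 1L
  out <- full[b:(b + n - 1L)]
  if (scale_dt) out * dt else out
}

#' Forward eCAP model: convolve a CDLD with a unitary response
#'
#' Computes the model eCAP as the discrete convolution of the CDLD with the UR.
#' The UR is evaluated internally on the same sampling interval over
#' `[t0 - 6 sigma_n, t0 + 6 sigma_p]` (tails beyond contribute < 1e-8 of the
#' peak); sample times add under convolution, so the UR's negative `t0` shifts
#' energy earlier; the result is cropped to the requested grid. With
#' `scale = "dt"` (default) the convolution sum is multiplied by the sampling
#' interval, making it a grid-resolution-independent approximation of the
#' convolution integral; `scale = "none"` gives the raw discrete sum.
#'
#' @param cdld A [cdld_params()] object.
#' @param ur A [ur_params()] object.
#' @param grid Recording [time_grid()].
#' @param scale `"dt"` or `"none"`.
#' @param id Waveform id for the output table.
#' @return A waveform tibble on `grid`.
#' @export
forward_ecap <- function(cdld, ur, grid, scale = c("dt", "none"),
                         id = "ecap") {
  stopifnot(inherits(cdld, "cdld_params"), inherits(ur, "ur_params"))
  scale <- match.arg(scale)
  grid <- as_time_grid(grid)
  jlim <- ur_support_jlim(grid$dt, ur$t0, ur$sigma_n, ur$sigma_p)
  comp <- cdld$components
  v <- forward_num(comp$alpha, comp$mu, comp$sigma, ur,
                   grid$start, grid$dt, grid$n, jlim, scale == "dt")
  wf_tbl(id, grid$start, grid$dt, v)
}

#' Discrete convolution of two sampled waveforms
#'
#' Full linear convolution; output sample times are the sums of input sample
#' times. With `scale = "dt"` the sum is multiplied by the common sampling
#' interval (integral approximation).
#'
#' @param a,b Single-waveform tibbles with identical `dt`.
#' @param scale `"dt"` or `"none"`.
#' @param id Waveform id for the output table.
#' @return A waveform tibble of length `n_a + n_b - 1`.
#' @export
convolve_sampled <- function(a, b, scale = c("dt", "none"), id = "conv") {
  scale <- match.arg(scale)
  wa <- wf_single(a, "a")
  wb <- wf_single(b, "b")
  if (abs(wa$dt - wb$dt) > 1e-9 * wa$dt) abort("sampling intervals differ")
  v <- conv_open(wa$v, wb$v)
  if (scale == "dt") v <- v * wa$dt
  wf_tbl(id, wa$t0 + wb$t0, wa$dt, v)
}
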