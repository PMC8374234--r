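# Seeded generator of synthetic eCAP datasets with the generative structure
# the deconvolution model assumes: a known UR convolved with a known
# two-component CDLD, plus a constant baseline offset and additive white
# Gaussian recording noise. Ground-truth parameters are retained so parameter
# recovery can be scored.

#' Specification of a synthetic eCAP dataset
#'
#' Defaults emulate single-pulse human eCAP recordings: the published human
#' UR, a 0–2.2 ms window sampled at 5 µs (441 samples), two Gaussian CDLD
#' components with latencies in 0.3–0.9 ms and widths 0.03–0.15 ms (so the
#' N1 trough falls inside the window and the tail beyond 1.5 ms is flat, as in
#' recorded data), amplitudes 0.05–0.35 with a minimum separation of
#' `2 * (sigma_1 + sigma_2)` between latencies, and additive white Gaussian
#' noise with SD equal to 1% of each waveform's peak absolute amplitude.
#'
#' @param n_waveforms Number of waveforms to simulate.
#' @param ur Generating [ur_params()] (default [published_human_ur()]).
#' @param grid Recording [time_grid()] (default 0–2.2 ms at dt = 0.005 ms).
#' @param n_components Components per CDLD (default 2).
#' @param alpha_range,mu_range,sigma_range Uniform sampling ranges for the
#'   component amplitude, latency (ms) and width (ms).
#' @param min_alpha Minimum accepted component amplitude.
#' @param min_separation Minimum latency separation between any two
#'   components, in units of their summed widths.
#' @param min_onset_ms Earliest allowed discharge mass: every component must
#'   satisfy `mu - 3 * sigma >= min_onset_ms` (default 0.25 ms). Auditory
#'   nerve fibers do not fire before the stimulus reaches them, so a recorded
#'   eCAP is flat at the start of its window; draws violating this would put
#'   response energy before time zero, where it cannot be recorded.
#' @param noise_sd_rel Noise SD as a fraction of the noiseless trace's peak
#'   absolute amplitude (default 0.01).
#' @param baseline_offset Constant offset (µV) added before preprocessing.
#' @param seed Integer seed; every draw is deterministic given it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_waveforms = 100,
                           ur = published_human_ur(),
                           grid = time_grid(0, 2.2, 0.005),
                           n_components = 2,
                           alpha_range = c(0.05, 0.35),
                           mu_range = c(0.3, 0.9),
                           sigma_range = c(0.03, 0.15),
                           min_alpha = 0.05,
                           min_separation = 2,
                           min_onset_ms = 0.25,
                           noise_sd_rel = 0.01,
                           baseline_offset = 0,
                           seed = 1L) {
  stopifnot(inherits(ur, "ur_params"), n_waveforms >= 0,
            n_components >= 1, noise_sd_rel >= 0,
            length(alpha_range) == 2, length(mu_range) == 2,
            length(sigma_range) == 2)
  grid <- as_time_grid(grid)
  b2 <- dmr_bounds_step2(1)
  inside <- function(r, lo, hi) r[1] >= lo - 1e-12 && r[2] <= hi + 1e-12
  if (!inside(alpha_range, b2$lower["alpha1"], b2$upper["alpha1"]) ||
      !inside(mu_range, b2$lower["mu1"], b2$upper["mu1"]) ||
      !inside(sigma_range, b2$lower["sigma1"], b2$upper["sigma1"])) {
    warn("sampler ranges extend beyond the default step-two fit bounds")
  }
  structure(list(n_waveforms = as.integer(n_waveforms), ur = ur, grid = grid,
                 n_components = as.integer(n_components),
                 alpha_range = alpha_range, mu_range = mu_range,
                 sigma_range = sigma_range, min_alpha = min_alpha,
                 min_separation = min_separation,
                 min_onset_ms = min_onset_ms,
                 noise_sd_rel = noise_sd_rel,
                 baseline_offset = baseline_offset,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Draw one set of CDLD parameters from a synthetic specification
#'
#' Uniform draws within the spec's ranges, rejection-resampled (up to 1000
#' attempts) until every amplitude is at least `min_alpha`, every pair of
#' latencies is separated by at least `min_separation` times the pair's summed
#' widths, and every component's mass starts inside the recording window
#' (`mu - 3 sigma >= min_onset_ms`).
#'
#' @param spec A [synthetic_spec()].
#' @param .seed Seed set before drawing; `NULL` uses the current RNG state
#'   (as [simulate_batch()] does for sequential draws). Defaults to
#'   `spec$seed`.
#' @return A [cdld_params()] object.
#' @export
sample_cdld_params <- function(spec, .seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(.seed)) set.seed(.seed)
  k <- spec$n_components
  for (attempt in seq_len(1000)) {
    alpha <- runif(k, spec$alpha_range[1], spec$alpha_range[2])
    mu <- runif(k, spec$mu_range[1], spec$mu_range[2])
    sigma <- runif(k, spec$sigma_range[1], spec$sigma_range[2])
    if (any(alpha < spec$min_alpha)) next
    if (any(mu - 3 * sigma < spec$min_onset_ms)) next
    ok <- TRUE
    if (k > 1) {
      o <- order(mu)
      mu_s <- mu[o]; sg_s <- sigma[o]
      ok <- all(diff(mu_s) >= spec$min_separation * (sg_s[-k] + sg_s[-1]))
    }
    if (ok) return(cdld_params(alpha = alpha, mu = mu, sigma = sigma))
  }
  abort("constraints unsatisfiable: no admissible CDLD draw within 1000 rejections")
}

#' Simulate one eCAP from known CDLD parameters
#'
#' `forward_ecap(cdld, spec$ur, spec$grid)` plus the baseline offset and
#' additive white Gaussian noise with SD `noise_sd_rel` times the noiseless
#' trace's peak absolute amplitude.
#'
#' @param cdld A [cdld_params()] object.
#' @param spec A [synthetic_spec()].
#' @param id Waveform id for the output table.
#' @param .seed Seed set before the noise draw; `NULL` uses the current RNG
#'   state. Defaults to `spec$seed`.
#' @return A waveform tibble on `spec$grid`.
#' @export
simulate_ecap <- function(cdld, spec, id = "ecap", .seed = spec$seed) {
  stopifnot(inherits(cdld, "cdld_params"), inherits(spec, "synthetic_spec"))
  if (!is.null(.seed)) set.seed(.seed)
  clean <- forward_ecap(cdld, spec$ur, spec$grid, id = id)
  v <- clean$amplitude_uV + spec$baseline_offset
  if (spec$noise_sd_rel > 0) {
    v <- v + rnorm(length(v), 0, spec$noise_sd_rel * max(abs(clean$amplitude_uV)))
  }
  clean$amplitude_uV <- v
  clean
}

#' Simulate a batch of eCAPs with retained ground truth
#'
#' Seeds the RNG once with `spec$seed`, then draws `n_waveforms` independent
#' CDLDs and noise realizations sequentially, so the whole batch is
#' reproducible bitwise from the seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `waveforms` (long waveform tibble, ids
#'   `wf001`, `wf002`, ...) and `truth` (tibble `waveform_id`, `component`,
#'   `alpha`, `mu`, `sigma`).
#' @export
simulate_batch <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_waveforms
  if (n == 0) {
    return(list(waveforms = tibble(waveform_id = character(),
                                   time_ms = numeric(),
                                   amplitude_uV = numeric()),
                truth = tibble(waveform_id = character(),
                               component = integer(), alpha = numeric(),
                               mu = numeric(), sigma = numeric())))
  }
  ids <- sprintf("wf%03d", seq_len(n))
  waves <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    cdld <- sample_cdld_params(spec, .seed = NULL)
    waves[[i]] <- simulate_ecap(cdld, spec, id = ids[i], .seed = NULL)
    truths[[i]] <- dplyr::mutate(tidy(cdld), waveform_id = ids[i],
                                 .before = "component")
  }
  list(waveforms = dplyr::bind_rows(waves),
       truth = dplyr::bind_rows(truths))
}
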