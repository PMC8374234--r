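# Desk-scale validation of the two-step procedure on synthetic data: the
# fraction of noisy synthetic eCAPs fitted accurately in step two, and the
# residual-error reductions observed when the CDLD model order grows.

#' Run the synthetic validation suite
#'
#' Simulates a seeded batch of noisy synthetic eCAPs ([synthetic_spec()]
#' defaults: published human UR, 0–2.2 ms at 5 µs, 1% noise), preprocesses
#' them (tail baseline at 1.5 ms, 50-sample extension) and runs step-two
#' fitting on every waveform. On the first `n_sweep` waveforms it additionally
#' sweeps the CDLD model order over `k_range` with nested initialization.
#' Three summary numbers are reported:
#'
#' * `pct_accurate`: percentage of waveforms with `fit_index > 0.9`;
#' * `mean_reduction_1_2`: mean percentage reduction of the residual norm
#'   from K = 1 to K = 2, `100 * (r1 - r2) / r1`;
#' * `mean_reduction_2_6`: mean percentage further reduction from K = 2 to
#'   K = `max(k_range)`, `100 * (r2 - r6) / r2`.
#'
#' @param seed Integer seed for the synthetic batch.
#' @param n_waveforms Batch size (default 100).
#' @param n_sweep Number of waveforms entered into the model-order sweep
#'   (default 20).
#' @param k_range Model orders for the sweep (default `1:6`).
#' @param spec Optional [synthetic_spec()] overriding the defaults.
#' @param config A [fit_config()].
#' @return A list with the three summaries plus `fits` (a `dmr_fit_batch`),
#'   `sweeps` (list of `dmr_sweep` tibbles), `batch` (the simulated data) and
#'   `spec`.
#' @export
run_validation_suite <- function(seed = 1, n_waveforms = 100, n_sweep = 20,
                                 k_range = 1:6, spec = NULL,
                                 config = fit_config()) {
  spec <- spec %||% synthetic_spec(n_waveforms = n_waveforms, seed = seed)
  batch <- simulate_batch(spec)
  pre <- preprocess_waveforms(batch$waveforms)
  fits <- fit_batch(pre, step = "two", ur = spec$ur, config = config,
                    preprocess = FALSE)
  pct_accurate <- 100 * mean(fits$fit_index > 0.9)

  ids <- utils::head(unique(pre$waveform_id), n_sweep)
  sweeps <- lapply(ids, function(id) {
    model_order_sweep(pre[pre$waveform_id == id, ], spec$ur,
                      k_range = k_range, config = config)
  })
  res_at <- function(sw, k) sw$residual_norm[match(k, sw$k)]
  r1 <- vapply(sweeps, res_at, numeric(1), k = 1)
  r2 <- vapply(sweeps, res_at, numeric(1), k = 2)
  rmax <- vapply(sweeps, res_at, numeric(1), k = max(k_range))
  list(pct_accurate = pct_accurate,
       mean_reduction_1_2 = 100 * mean((r1 - r2) / r1),
       mean_reduction_2_6 = 100 * mean((r2 - rmax) / r2),
       fits = fits, sweeps = sweeps, batch = batch, spec = spec)
}
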