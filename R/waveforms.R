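# Waveform tables: a waveform is a set of rows (waveform_id, time_ms,
# amplitude_uV) on a uniform time grid. All times are in ms, amplitudes in uV.

wf_cols <- c("waveform_id", "time_ms", "amplitude_uV")

# Coerce to a tibble with the canonical columns; a missing waveform_id column
# is tolerated for single-waveform input.
as_waveform_tbl <- function(df, arg = "waveforms") {
  if (!is.data.frame(df)) {
    abort(sprintf("`%s` must be a data frame of waveform samples", arg))
  }
  df <- as_tibble(df)
  if (!"waveform_id" %in% names(df)) {
    df$waveform_id <- "waveform"
  }
  missing <- setdiff(wf_cols, names(df))
  if (length(missing)) {
    abort(sprintf("format error: missing column(s) %s in `%s`",
                  paste0("'", missing, "'", collapse = ", "), arg))
  }
  df[, c(wf_cols, setdiff(names(df), wf_cols))]
}

# Split into per-waveform records, validating the uniform grid. Returns a named
# list of list(id, t0, dt, n, v).
wf_split <- function(df, arg = "waveforms") {
  df <- as_waveform_tbl(df, arg)
  ids <- unique(df$waveform_id)
  lapply(setNames(ids, ids), function(id) {
    sub <- df[df$waveform_id == id, ]
    t <- sub$time_ms
    v <- sub$amplitude_uV
    n <- length(t)
    if (n < 2) {
      abort(sprintf("waveform '%s' has fewer than 2 samples", id))
    }
    if (!all(is.finite(t)) || !all(is.finite(v))) {
      abort(sprintf("waveform '%s' contains non-finite values", id))
    }
    dt <- (t[n] - t[1]) / (n - 1)
    if (dt <= 0 || max(abs(diff(t) - dt)) >= 1e-6 * dt) {
      abort(sprintf("non-uniform grid in waveform '%s'", id))
    }
    list(id = id, t0 = t[1], dt = dt, n = n, v = v)
  })
}

# Single-waveform variant; errors if the table holds more than one id.
wf_single <- function(df, arg = "waveform") {
  ws <- wf_split(df, arg)
  if (length(ws) != 1) {
    abort(sprintf("`%s` must contain exactly one waveform (found %d)",
                  arg, length(ws)))
  }
  ws[[1]]
}

wf_tbl <- function(id, t0, dt, v) {
  tibble(waveform_id = id,
         time_ms = t0 + (seq_along(v) - 1) * dt,
         amplitude_uV = v)
}

wf_bind <- function(ws) {
  dplyr::bind_rows(lapply(ws, function(w) wf_tbl(w$id, w$t0, w$dt, w$v)))
}

#' Read eCAP waveforms from delimited text
#'
#' Two dialects are supported. `"long"` is a single table with columns
#' `waveform_id`, `time_ms`, `amplitude_uV`. `"wide"` is one file per waveform
#' with columns `time_ms`, `amplitude_uV`; the waveform id is taken from the
#' file name. Files must carry a header row; comma and tab delimiters are
#' recognized (tab for `.tsv`). Every waveform must sit on a uniform time grid
#' (successive time steps may deviate by at most `1e-6 * dt`); anything else is
#' rejected with an error naming the offending record.
#'
#' @param path File path (`"long"`) or one or more file paths (`"wide"`).
#' @param dialect `"long"` (default) or `"wide"`.
#' @return A tibble with columns `waveform_id`, `time_ms` (ms),
#'   `amplitude_uV` (uV).
#' @export
read_waveforms <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  read_one <- function(p) {
    if (!file.exists(p)) abort(sprintf("input file '%s' does not exist", p))
    delim <- if (grepl("\\.tsv$", p, ignore.case = TRUE)) "\t" else ","
    readr::read_delim(p, delim = delim, show_col_types = FALSE,
                      progress = FALSE)
  }
  if (dialect == "long") {
    if (length(path) != 1) abort("long dialect expects a single file path")
    df <- read_one(path)
    if (!all(wf_cols %in% names(df))) {
      abort(sprintf(
        "format error: long dialect requires columns %s (file '%s')",
        paste0("'", wf_cols, "'", collapse = ", "), path))
    }
  } else {
    df <- dplyr::bind_rows(lapply(path, function(p) {
      one <- read_one(p)
      if (!all(c("time_ms", "amplitude_uV") %in% names(one))) {
        abort(sprintf(
          "format error: wide dialect requires columns 'time_ms', 'amplitude_uV' (file '%s')",
          p))
      }
      one$waveform_id <- sub("\\.[^.]*$", "", basename(p))
      one
    }))
  }
  wf_bind(wf_split(df, "file"))
}

#' Write waveforms to delimited text
#'
#' @param waveforms Waveform tibble (see [read_waveforms()]).
#' @param path Output file path; `.tsv` gets a tab delimiter, anything else a
#'   comma. For the wide dialect `path` must name one file per waveform.
#' @param dialect `"long"` (default) or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_waveforms <- function(waveforms, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  ws <- wf_split(waveforms)
  delim_for <- function(p) if (grepl("\\.tsv$", p, ignore.case = TRUE)) "\t" else ","
  if (dialect == "long") {
    if (length(path) != 1) abort("long dialect expects a single output path")
    readr::write_delim(wf_bind(ws), path, delim = delim_for(path))
  } else {
    if (length(path) != length(ws)) {
      abort(sprintf("wide dialect needs one path per waveform (%d waveforms, %d paths)",
                    length(ws), length(path)))
    }
    for (i in seq_along(ws)) {
      w <- ws[[i]]
      readr::write_delim(wf_tbl(w$id, w$t0, w$dt, w$v)[, c("time_ms", "amplitude_uV")],
                         path[i], delim = delim_for(path[i]))
    }
  }
  invisible(path)
}

#' Baseline-correct waveforms using the flat tail
#'
#' Neural activity is absent from the late part of an eCAP recording, so the
#' mean amplitude of the tail section (all samples at times `>= tail_start`)
#' estimates the recording baseline; it is subtracted from the whole waveform.
#' The operation is idempotent.
#'
#' @param waveforms Waveform tibble; each waveform must have samples at or
#'   beyond `tail_start`.
#' @param tail_start Time (ms) after which the waveform is considered baseline.
#'   Default 1.5 ms.
#' @return The corrected waveform tibble; each tail now has zero mean.
#' @export
baseline_correct <- function(waveforms, tail_start = 1.5) {
  stopifnot(is.numeric(tail_start), length(tail_start) == 1, tail_start > 0)
  ws <- wf_split(waveforms)
  out <- lapply(ws, function(w) {
    t <- w$t0 + (seq_len(w$n) - 1) * w$dt
    in_tail <- t >= tail_start - 1e-9
    if (!any(in_tail)) {
      abort(sprintf("tail window empty for waveform '%s' (no samples at or beyond %g ms)",
                    w$id, tail_start))
    }
    w$v <- w$v - mean(w$v[in_tail])
    w
  })
  wf_bind(out)
}

#' Extend waveforms with linear ramps to baseline
#'
#' Discrete convolution distorts the leading and trailing ends of a
#' finite-length signal. To push those edge effects outside the recording
#' window, `n_extend` samples are added to each end of a baseline-corrected
#' waveform, linearly extrapolated to baseline: the added block ramps from the
#' edge sample value down to zero, reaching exactly zero one virtual sample
#' beyond the block (added sample `k`, counted inward from the outer edge,
#' equals `edge_value * k / (n_extend + 1)`). The original samples are
#' preserved exactly and the start time shifts earlier by `n_extend * dt`.
#'
#' @param waveforms Baseline-corrected waveform tibble.
#' @param n_extend Number of samples added to each end (default 50).
#' @return The extended waveform tibble (`n + 2 * n_extend` samples each).
#' @export
extend_signal <- function(waveforms, n_extend = 50) {
  if (!is.numeric(n_extend) || length(n_extend) != 1 || n_extend < 0 ||
      n_extend != round(n_extend)) {
    abort("`n_extend` must be a single non-negative integer")
  }
  n_extend <- as.integer(n_extend)
  ws <- wf_split(waveforms)
  out <- lapply(ws, function(w) {
    if (n_extend == 0) return(w)
    ramp <- seq_len(n_extend) / (n_extend + 1)
    lead <- w$v[1] * ramp                 # outermost = v1/(n+1), innermost = v1*n/(n+1)
    trail <- w$v[w$n] * rev(ramp)
    w$v <- c(lead, w$v, trail)
    w$t0 <- w$t0 - n_extend * w$dt
    w$n <- length(w$v)
    w
  })
  wf_bind(out)
}

#' Preprocess eCAP waveforms for deconvolution fitting
#'
#' Convenience pipeline: [baseline_correct()] then [extend_signal()].
#'
#' @inheritParams baseline_correct
#' @inheritParams extend_signal
#' @return The preprocessed waveform tibble.
#' @export
preprocess_waveforms <- function(waveforms, tail_start = 1.5, n_extend = 50) {
  extend_signal(baseline_correct(waveforms, tail_start), n_extend)
}

#' NRMSE goodness-of-fit index
#'
#' Normalized root-mean-square error expressed as a fit index:
#' `1 - ||ref - pred|| / ||ref - mean(ref)||`. 1 means a perfect fit, 0 means
#' the prediction does no better than the reference mean, and values below 0
#' indicate a worse fit still. A fit index above 0.9 is conventionally called
#' accurate for eCAP predictions.
#'
#' @param pred Predicted waveform: numeric vector or single-waveform tibble.
#' @param ref Reference waveform on the identical grid.
#' @return The fit index, a scalar in `(-Inf, 1]`.
#' @export
nrmse_fit_index <- function(pred, ref) {
  if (is.data.frame(pred) || is.data.frame(ref)) {
    wp <- wf_single(pred, "pred")
    wr <- wf_single(ref, "ref")
    if (wp$n != wr$n || abs(wp$t0 - wr$t0) > 1e-9 || abs(wp$dt - wr$dt) > 1e-9) {
      abort("`pred` and `ref` must share an identical time grid")
    }
    pred <- wp$v
    ref <- wr$v
  }
  if (length(pred) != length(ref)) {
    abort("`pred` and `ref` must have the same length")
  }
  denom <- sqrt(sum((ref - mean(ref))^2))
  if (denom == 0) abort("reference has no variance")
  1 - sqrt(sum((ref - pred)^2)) / denom
}

#' Quick look at a set of waveforms
#'
#' @param waveforms Waveform tibble.
#' @return A ggplot object, one line per waveform.
#' @export
plot_waveforms <- function(waveforms) {
  df <- as_waveform_tbl(waveforms)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$amplitude_uV,
                                   group = .data$waveform_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "time (ms)", y = "amplitude (µV)")
}
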