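#' Central finite differencing
#'
#' Differentiates each column of a series matrix by repeated application of
#' the central difference `(x[i+1] - x[i-1]) / (2 dt)`. Each application
#' trims one frame at each end, so `order` applications return
#' `frames - 2 * order` rows. Central differences are second-order accurate
#' and exact on polynomials up to degree `order + 1`.
#'
#' @param series numeric vector or `frames x k` matrix.
#' @param order derivative order (positive integer): 2 for acceleration of
#'   positions, 3 for jerk.
#' @param dt sampling interval in seconds.
#' @return A matrix with `frames - 2 * order` rows.
#' @export
differentiate <- function(series, order, dt) {
  series <- as.matrix(series)
  if (!is.numeric(order) || length(order) != 1L || order < 1 || order != round(order)) {
    stop_kin("order must be a positive integer")
  }
  if (!is.numeric(dt) || dt <= 0) stop_kin("dt must be > 0")
  if (nrow(series) <= 2 * order) {
    stop_kin(
      "series of ", nrow(series), " frames too short for derivative order ",
      order, " (need > ", 2 * order, ")"
    )
  }
  out <- series
  for (i in seq_len(order)) {
    n <- nrow(out)
    out <- (out[3:n, , drop = FALSE] - out[1:(n - 2), , drop = FALSE]) / (2 * dt)
  }
  out
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth low-pass applied forward and backward
#' (zero phase lag), columnwise. Intended for marker positions before
#' differentiation: optical noise is strongly amplified by the third
#' derivative.
#'
#' @param series numeric vector or `frames x k` matrix.
#' @param cutoff_hz cutoff frequency; must be below the Nyquist frequency.
#' @param sampling_rate frames per second.
#' @param filter_order Butterworth order of one pass (default 4).
#' @return Filtered matrix, same shape as the input.
#' @export
lowpass_filter <- function(series, cutoff_hz, sampling_rate, filter_order = 4) {
  series <- as.matrix(series)
  nyq <- sampling_rate / 2
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyq) {
    stop_kin("cutoff_hz must lie in (0, Nyquist = ", nyq, ")")
  }
  bf <- signal::butter(filter_order, cutoff_hz / nyq, type = "low")
  n <- nrow(series)
  # odd-reflection padding before the forward-backward pass: suppresses the
  # start/end transients that would otherwise leak a shared artifact into
  # every series
  nfact <- min(n - 1L, 3L * (2L * filter_order + 1L))
  apply(series, 2, function(x) {
    mu <- mean(x)
    x <- x - mu
    head_pad <- 2 * x[1] - x[(nfact + 1):2]
    tail_pad <- 2 * x[n] - x[(n - 1):(n - nfact)]
    y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
    y[(nfact + 1):(nfact + n)] + mu
  })
}

#' Per-axis acceleration or jerk series for all markers of a trial
#'
#' Selects one axis (ML, AP or V) of every marker, optionally low-pass
#' filters the positions, and differentiates: order 2 for acceleration
#' (m/s^2), order 3 for jerk (m/s^3).
#'
#' @param trial a [marker_trial()].
#' @param quantity `"acceleration"` or `"jerk"`.
#' @param axis `"ML"`, `"AP"` or `"V"`.
#' @param filter_policy `NULL` for no filtering (the default, appropriate
#'   for noise-free synthetic data), or a list with elements `cutoff_hz`
#'   (default 10) and `order` (default 4) to low-pass the positions first
#'   (recommended for measured optical data).
#' @return An object of class `axis_series`: list with `values`
#'   (`frames' x markers` matrix, marker-labelled columns), `quantity`,
#'   `axis`, `sampling_rate`, `subject_id`, `session`.
#' @export
axis_series <- function(trial, quantity = c("acceleration", "jerk"),
                        axis = c("ML", "AP", "V"), filter_policy = NULL) {
  stopifnot(inherits(trial, "marker_trial"))
  quantity <- match.arg(quantity)
  axis <- match.arg(axis)
  ord <- if (quantity == "acceleration") 2L else 3L
  x <- trial$positions[, , axis]
  if (!is.null(filter_policy)) {
    x <- lowpass_filter(
      x,
      cutoff_hz = filter_policy$cutoff_hz %||% 10,
      sampling_rate = trial$sampling_rate,
      filter_order = filter_policy$order %||% 4
    )
  }
  v <- differentiate(x, order = ord, dt = 1 / trial$sampling_rate)
  colnames(v) <- trial$marker_set$label
  structure(
    list(
      values = v, quantity = quantity, axis = axis,
      sampling_rate = trial$sampling_rate,
      subject_id = trial$subject_id, session = trial$session
    ),
    class = "axis_series"
  )
}
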