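#' Per-sample median ERP
#'
#' Robust alternative to the mean evoked response: for every channel and
#' sample, the representative value is the median of the signal amplitudes
#' over the accepted trials (even trial counts use the mean of the two
#' central order statistics). The marginal median per sample resists
#' occasional extreme trials, e.g. residual implant artifacts.
#'
#' @param epochs An `eeg_epochs`.
#' @return An `erp_waveform`: list with `data` (channels x samples, uV),
#'   `times`, `srate`, `channels`, `condition`, `n_trials_used`.
#' @export
median_erp <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  keep <- which(epochs$retained)
  if (length(keep) == 0L) {
    stop("no retained trials for condition ", epochs$condition)
  }
  x <- epochs$data[, , keep, drop = FALSE]
  med <- apply(x, c(1, 2), stats::median)
  dimnames(med) <- list(epochs$channels, NULL)
  structure(list(data = med, times = epochs$times, srate = epochs$srate,
                 channels = epochs$channels, condition = epochs$condition,
                 n_trials_used = length(keep)),
            class = "erp_waveform")
}

#' Frontocentral ROI waveform
#'
#' Unweighted per-sample mean over the six-electrode region of interest
#' (F3, Fz, F4, C3, Cz, C4), computed after the per-channel median ERP.
#'
#' @param erp An `erp_waveform`.
#' @param roi Channel labels to average.
#' @return Numeric vector (one value per sample, uV).
#' @export
roi_waveform <- function(erp, roi = c("F3", "Fz", "F4", "C3", "Cz", "C4")) {
  missing_ch <- setdiff(roi, erp$channels)
  if (length(missing_ch) > 0L) {
    stop("missing ROI channel(s): ", paste(missing_ch, collapse = ", "))
  }
  colMeans(erp$data[roi, , drop = FALSE])
}

#' Deviant-minus-standard difference waveform
#'
#' Pointwise subtraction of the standard ERP from a deviant ERP, on the ROI
#' average and per channel (the per-channel traces feed the fallback
#' electrode search during component detection).
#'
#' @param deviant_erp,standard_erp `erp_waveform`s on identical sample grids.
#' @param roi ROI channel labels.
#' @return A `difference_wave`: list with `roi` (numeric vector), `channels`
#'   (matrix, channels x samples), `channel_labels`, `times`, `srate`,
#'   `deviant`, and provenance (`n_deviant_trials`, `n_standard_trials`).
#' @export
difference_waveform <- function(deviant_erp, standard_erp,
                                roi = c("F3", "Fz", "F4", "C3", "Cz", "C4")) {
  if (length(deviant_erp$times) != length(standard_erp$times) ||
      any(deviant_erp$times != standard_erp$times)) {
    stop("sample grids of deviant and standard ERPs differ")
  }
  dch <- deviant_erp$data - standard_erp$data
  structure(list(roi = roi_waveform(deviant_erp, roi) -
                   roi_waveform(standard_erp, roi),
                 channels = dch,
                 channel_labels = deviant_erp$channels,
                 times = deviant_erp$times, srate = deviant_erp$srate,
                 deviant = deviant_erp$condition,
                 n_deviant_trials = deviant_erp$n_trials_used,
                 n_standard_trials = standard_erp$n_trials_used),
            class = "difference_wave")
}

#' Quantification low-pass filter
#'
#' Zero-phase fourth-order Butterworth low-pass (default 20 Hz) applied to
#' ERP-level waveforms immediately before component detection and
#' quantification — not to single trials.
#'
#' @param wave A `difference_wave` (ROI and channel traces are both filtered).
#' @param cutoff_hz Cutoff frequency.
#' @return The filtered `difference_wave`.
#' @export
lowpass_for_quantification <- function(wave, cutoff_hz = 20) {
  stopifnot(inherits(wave, "difference_wave"))
  if (cutoff_hz >= wave$srate / 2) {
    stop("low-pass cutoff must be below Nyquist")
  }
  bf <- signal::butter(4, cutoff_hz / (wave$srate / 2), type = "low")
  wave$roi <- signal::filtfilt(bf, wave$roi)
  wave$channels <- .filtfilt_rows(wave$channels, bf)
  wave
}

#' Build all difference waves of a preprocessed subject
#'
#' Convenience wrapper: per-condition median ERPs, ROI averaging, difference
#' waveforms for every deviant against the standard, and the quantification
#' low-pass.
#'
#' @param epochs_list Named list of `eeg_epochs` including `"standard"`.
#' @param lowpass_hz Cutoff of the quantification low-pass (`NULL` to skip).
#' @param roi ROI channel labels.
#' @return Named list of `difference_wave`s, one per deviant condition.
#' @export
subject_difference_waves <- function(epochs_list, lowpass_hz = 20,
                                     roi = c("F3", "Fz", "F4",
                                             "C3", "Cz", "C4")) {
  if (!"standard" %in% names(epochs_list)) {
    stop("epochs list has no standard condition")
  }
  erps <- lapply(epochs_list, median_erp)
  std <- erps$standard
  devs <- setdiff(names(erps), "standard")
  out <- lapply(devs, function(dv) {
    dw <- difference_waveform(erps[[dv]], std, roi)
    if (!is.null(lowpass_hz)) dw <- lowpass_for_quantification(dw, lowpass_hz)
    dw
  })
  names(out) <- devs
  out
}
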