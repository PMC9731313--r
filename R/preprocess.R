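#' Continuous EEG container
#'
#' @param data Numeric matrix, channels x samples, in uV.
#' @param srate Sampling rate in Hz.
#' @param channels Channel labels (defaults to the rownames of `data`).
#' @param t0_ms Time of the first sample relative to the event clock
#'   (negative when the recording starts before the first stimulus).
#' @return An object of class `eeg_continuous`.
#' @export
eeg_continuous <- function(data, srate, channels = rownames(data),
                           t0_ms = 0) {
  stopifnot(is.matrix(data), srate > 0, length(channels) == nrow(data))
  rownames(data) <- channels
  structure(list(data = data, srate = srate, channels = channels,
                 t0_ms = t0_ms),
            class = "eeg_continuous")
}

.filtfilt_rows <- function(x, filt) {
  t(apply(x, 1, function(ch) signal::filtfilt(filt, ch)))
}

# zero-phase IIR filtering of long multichannel recordings in the frequency
# domain: reflection padding against edge transients, then multiplication by
# the squared magnitude response (the response filtfilt realises in time)
.zero_phase_rows <- function(x, filt, srate) {
  n <- ncol(x)
  pad <- min(n - 1L, 3L * srate)
  refl <- c(pad + 1L - seq_len(pad) + 1L, seq_len(n),
            n - seq_len(pad))
  m <- n + 2L * pad
  m2 <- stats::nextn(m, c(2, 3))
  z <- exp(-2i * pi * seq(0, m2 - 1L) / m2)
  num <- den <- rep(0 + 0i, m2)
  zi <- rep(1 + 0i, m2)
  for (k in seq_len(max(length(filt$b), length(filt$a)))) {
    if (k <= length(filt$b)) num <- num + filt$b[k] * zi
    if (k <= length(filt$a)) den <- den + filt$a[k] * zi
    zi <- zi * z
  }
  g <- Mod(num / den)^2
  out <- x
  for (r in seq_len(nrow(x))) {
    xp <- c(x[r, refl], numeric(m2 - m))
    y <- Re(stats::fft(stats::fft(xp) * g, inverse = TRUE)) / m2
    out[r, ] <- y[(pad + 1L):(pad + n)]
  }
  out
}

#' Zero-phase high-pass filter
#'
#' Removes slow drift and DC offset with a second-order Butterworth high-pass
#' applied with zero phase (squared magnitude response, i.e. the
#' forward-backward fourth-order effective response).
#'
#' @param x An `eeg_continuous`.
#' @param cutoff_hz Cutoff frequency (default 0.5 Hz).
#' @return The filtered `eeg_continuous`.
#' @export
highpass <- function(x, cutoff_hz = 0.5) {
  stopifnot(inherits(x, "eeg_continuous"))
  if (cutoff_hz >= x$srate / 2) {
    stop("high-pass cutoff (", cutoff_hz, " Hz) must be below Nyquist (",
         x$srate / 2, " Hz)")
  }
  bf <- signal::butter(2, cutoff_hz / (x$srate / 2), type = "high")
  x$data <- .zero_phase_rows(x$data, bf, x$srate)
  x
}

#' Anti-aliased integer-factor downsampling
#'
#' Applies a zero-phase fourth-order Butterworth low-pass at 0.45 times the
#' target rate, then keeps every `srate / to_hz`-th sample. The target must
#' divide the source rate (512 -> 256 Hz in the default pipeline); duration
#' is preserved to within one sample.
#'
#' @param x An `eeg_continuous`.
#' @param to_hz Target sampling rate (default 256).
#' @return The downsampled `eeg_continuous`.
#' @export
downsample <- function(x, to_hz = 256) {
  stopifnot(inherits(x, "eeg_continuous"))
  factor <- x$srate / to_hz
  if (factor == 1) return(x)
  if (factor != round(factor) || factor < 1) {
    stop("target rate must divide the source rate (", x$srate, " -> ",
         to_hz, ")")
  }
  bf <- signal::butter(4, (0.45 * to_hz) / (x$srate / 2), type = "low")
  x$data <- .zero_phase_rows(x$data, bf, x$srate)[, seq(1, ncol(x$data),
                                                        by = factor),
                                                  drop = FALSE]
  x$srate <- to_hz
  x
}

#' Re-reference to a recorded channel
#'
#' Subtracts the reference channel's time course from every channel; the
#' reference itself becomes all-zero. Differences between any two
#' non-reference channels are unchanged and the operation is idempotent.
#'
#' @param x An `eeg_continuous`.
#' @param reference_channel Label of the reference channel (default the nose).
#' @return The re-referenced `eeg_continuous`.
#' @export
rereference <- function(x, reference_channel = "Nose") {
  stopifnot(inherits(x, "eeg_continuous"))
  if (!reference_channel %in% x$channels) {
    stop("reference channel not present: ", reference_channel)
  }
  ref <- x$data[reference_channel, ]
  x$data <- sweep(x$data, 2, ref)
  x
}

#' Epoch a continuous recording around stimulus events
#'
#' Cuts per-condition trial stacks on a half-open window (default -100 to
#' +700 ms around each onset; `floor(0.8 s * 256 Hz) = 204` samples at the
#' analysis rate). Sample 0 of the time grid is the sample nearest stimulus
#' onset. Events whose window does not fit the recording are dropped and
#' logged.
#'
#' @param x An `eeg_continuous`.
#' @param events An `event_sequence` (onsets on the same event clock as
#'   `x$t0_ms`).
#' @param window_ms Epoch window (start, end), half-open.
#' @return Named list of `eeg_epochs`, one per condition, each with fields
#'   `data` (channels x samples x trials), `times` (ms), `srate`, `channels`,
#'   `condition`, `retained` (logical mask) and `reject_reason`; dropped
#'   events are recorded in the `dropped_events` attribute of the list.
#' @export
epoch_eeg <- function(x, events, window_ms = c(-100, 700)) {
  stopifnot(inherits(x, "eeg_continuous"), is.data.frame(events),
            diff(window_ms) > 0)
  srate <- x$srate
  start_off <- round(window_ms[1] / 1000 * srate)
  n_samp <- floor(diff(window_ms) / 1000 * srate)
  times <- (start_off + seq_len(n_samp) - 1) / srate * 1000

  onset_samp <- round((events$onset_ms - x$t0_ms) / 1000 * srate) + 1L
  first <- onset_samp + start_off
  ok <- first >= 1L & (first + n_samp - 1L) <= ncol(x$data)
  dropped <- events$index[!ok]

  out <- list()
  for (cond in unique(events$condition)) {
    sel <- which(events$condition == cond & ok)
    if (length(sel) == 0L) next
    arr <- array(NA_real_, dim = c(nrow(x$data), n_samp, length(sel)),
                 dimnames = list(x$channels, NULL, NULL))
    for (k in seq_along(sel)) {
      i0 <- first[sel[k]]
      arr[, , k] <- x$data[, i0:(i0 + n_samp - 1L)]
    }
    out[[cond]] <- structure(
      list(data = arr, times = times, srate = srate, channels = x$channels,
           condition = cond, retained = rep(TRUE, length(sel)),
           reject_reason = rep("", length(sel))),
      class = "eeg_epochs")
  }
  attr(out, "dropped_events") <- dropped
  out
}

#' Baseline correction
#'
#' Subtracts, per trial and channel, the mean over the pre-stimulus baseline
#' window (default the 50 ms before onset, half-open `[-50, 0)` ms).
#'
#' @param epochs An `eeg_epochs` or a list of them.
#' @param window_ms Baseline window; must lie inside the epoch window.
#' @return The corrected object(s).
#' @export
baseline_zero <- function(epochs, window_ms = c(-50, 0)) {
  if (!inherits(epochs, "eeg_epochs")) {
    return(structure(lapply(epochs, baseline_zero, window_ms = window_ms),
                     dropped_events = attr(epochs, "dropped_events")))
  }
  idx <- which(epochs$times >= window_ms[1] & epochs$times < window_ms[2])
  if (length(idx) == 0L) {
    stop("baseline window [", window_ms[1], ", ", window_ms[2],
         ") ms lies outside the epoch")
  }
  for (k in seq_len(dim(epochs$data)[3])) {
    mu <- rowMeans(epochs$data[, idx, k, drop = FALSE])
    epochs$data[, , k] <- epochs$data[, , k] - mu
  }
  epochs
}

.trial_peak_abs <- function(ep) apply(abs(ep$data), 3, max)

#' Adaptive voltage-threshold rejection
#'
#' Scans thresholds upward through the configured range (default +-300 to
#' +-400 uV in 10 uV steps, pooled over all conditions) and applies the
#' smallest threshold that retains at least the required fraction of epochs
#' (default 85%). If no threshold qualifies, the maximum is applied and the
#' subject flagged. A trial is rejected when any sample on any channel
#' exceeds the threshold.
#'
#' @param epochs_list Named list of `eeg_epochs` (all conditions).
#' @param threshold_range_uv Ordered (low, high) scan range.
#' @param step_uv Scan step.
#' @param min_keep_fraction Minimum fraction of all epochs to preserve.
#' @return List with `epochs` (masks updated), `threshold_uv`, `flagged`.
#' @export
adaptive_reject <- function(epochs_list, threshold_range_uv = c(300, 400),
                            step_uv = 10, min_keep_fraction = 0.85) {
  stopifnot(diff(threshold_range_uv) >= 0, step_uv > 0)
  peaks <- lapply(epochs_list, .trial_peak_abs)
  all_peaks <- unlist(peaks, use.names = FALSE)
  thresholds <- seq(threshold_range_uv[1], threshold_range_uv[2],
                    by = step_uv)
  kept_frac <- vapply(thresholds,
                      function(th) mean(all_peaks <= th), numeric(1))
  ok <- which(kept_frac >= min_keep_fraction)
  flagged <- length(ok) == 0L
  threshold <- if (flagged) max(thresholds) else thresholds[min(ok)]

  for (cond in names(epochs_list)) {
    rej <- peaks[[cond]] > threshold & epochs_list[[cond]]$retained
    epochs_list[[cond]]$retained[rej] <- FALSE
    epochs_list[[cond]]$reject_reason[rej] <-
      sprintf("adaptive>%duV", as.integer(threshold))
  }
  list(epochs = epochs_list, threshold_uv = threshold, flagged = flagged)
}

#' Final fixed-threshold rejection
#'
#' Removes from the retained mask every trial with any sample beyond the
#' fixed threshold (default +-150 uV). Rejected trials remain in the data
#' for inspection; only the mask and reason codes change.
#'
#' @param epochs_list Named list of `eeg_epochs`.
#' @param threshold_uv Rejection threshold.
#' @return The list with updated masks.
#' @export
final_reject <- function(epochs_list, threshold_uv = 150) {
  for (cond in names(epochs_list)) {
    rej <- .trial_peak_abs(epochs_list[[cond]]) > threshold_uv &
      epochs_list[[cond]]$retained
    epochs_list[[cond]]$retained[rej] <- FALSE
    epochs_list[[cond]]$reject_reason[rej] <-
      sprintf("final>%duV", as.integer(threshold_uv))
  }
  epochs_list
}

#' Retention accounting against the inclusion floor
#'
#' Per condition: presented count, retained count and fraction; deviant
#' conditions falling below the floor (default 73% of presented epochs) are
#' flagged, and a subject is marked for exclusion when any deviant condition
#' is flagged.
#'
#' @param epochs_list Named list of `eeg_epochs`.
#' @param floor_fraction Minimum acceptable retained fraction.
#' @return List with `table` (per-condition data frame), `floor_fraction`,
#'   `subject_excluded`.
#' @export
retention_report <- function(epochs_list, floor_fraction = 0.73) {
  tab <- do.call(rbind, lapply(names(epochs_list), function(cond) {
    ep <- epochs_list[[cond]]
    presented <- length(ep$retained)
    retained <- sum(ep$retained)
    data.frame(condition = cond, presented = presented, retained = retained,
               fraction = retained / presented, stringsAsFactors = FALSE)
  }))
  tab$flagged <- tab$fraction < floor_fraction & tab$condition != "standard"
  list(table = tab, floor_fraction = floor_fraction,
       subject_excluded = any(tab$flagged))
}

#' Run the full preprocessing chain for one simulated subject
#'
#' Applies, in order: high-pass filtering, downsampling, nose re-referencing,
#' an optional external artifact-removal hook operating on the cleaned
#' continuous data (e.g. ICA performed outside this package), epoching,
#' adaptive voltage rejection, final fixed-threshold rejection, and baseline
#' correction. Every stage is recorded with its parameters in an audit log.
#'
#' @param sim Output of [simulate_subject()] (or any list with `continuous`
#'   and `events`).
#' @param highpass_hz,resample_hz,reference_channel,window_ms,baseline_ms
#'   Stage parameters (defaults: 0.5 Hz, 256 Hz, nose, -100..700 ms,
#'   -50..0 ms).
#' @param adaptive_range_uv,adaptive_step_uv,min_keep_fraction,final_uv
#'   Rejection parameters (defaults +-300..400 uV / 10 uV / 85% / +-150 uV).
#' @param floor_fraction Retention floor (default 0.73).
#' @param clean_hook Optional `function(eeg_continuous) -> eeg_continuous`
#'   supplying externally cleaned data; its use is recorded in the log.
#' @return List with `epochs` (baseline-corrected, masks applied),
#'   `retention`, `threshold_uv`, `adaptive_flagged`, `log` (character).
#' @export
preprocess_subject <- function(sim, highpass_hz = 0.5, resample_hz = 256,
                               reference_channel = "Nose",
                               window_ms = c(-100, 700),
                               baseline_ms = c(-50, 0),
                               adaptive_range_uv = c(300, 400),
                               adaptive_step_uv = 10,
                               min_keep_fraction = 0.85, final_uv = 150,
                               floor_fraction = 0.73, clean_hook = NULL) {
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  x <- highpass(sim$continuous, highpass_hz)
  note("highpass: butterworth order 2 (zero-phase), cutoff %.2f Hz",
       highpass_hz)
  x <- downsample(x, resample_hz)
  note("resample: %d -> %d Hz (zero-phase anti-alias low-pass)",
       sim$continuous$srate, resample_hz)
  x <- rereference(x, reference_channel)
  note("rereference: %s", reference_channel)
  if (!is.null(clean_hook)) {
    x <- clean_hook(x)
    note("external-clean hook: applied")
  } else {
    note("external-clean hook: not used")
  }
  eps <- epoch_eeg(x, sim$events, window_ms)
  note("epoch: window [%g, %g) ms, %d samples, %d events dropped",
       window_ms[1], window_ms[2], length(eps[[1]]$times),
       length(attr(eps, "dropped_events")))
  ar <- adaptive_reject(eps, adaptive_range_uv, adaptive_step_uv,
                        min_keep_fraction)
  note("adaptive_reject: range +-%g..%g uV step %g, chosen +-%g uV%s",
       adaptive_range_uv[1], adaptive_range_uv[2], adaptive_step_uv,
       ar$threshold_uv, if (ar$flagged) " (flagged: floor not reachable)"
       else "")
  eps <- final_reject(ar$epochs, final_uv)
  note("final_reject: +-%g uV", final_uv)
  eps <- baseline_zero(eps, baseline_ms)
  note("baseline_zero: [%g, %g) ms", baseline_ms[1], baseline_ms[2])
  ret <- retention_report(eps, floor_fraction)
  note("retention: floor %.0f%%, subject %s", 100 * floor_fraction,
       if (ret$subject_excluded) "EXCLUDED" else "retained")

  list(epochs = eps, retention = ret, threshold_uv = ar$threshold_uv,
       adaptive_flagged = ar$flagged, log = log)
}
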