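# shared fixtures, all built in code

expected_default_counts <- c(gap = 200, duration = 200, vowel = 200,
                             f0_15 = 100, f0_50 = 100,
                             int_minus6 = 100, int_plus6 = 100)

# small paradigm/cohort configuration for end-to-end tests
tiny_cohort_config <- function(...) {
  cohort_config(n_per_cell = c(ci_preschooler = 2, nh_preschooler = 2,
                               ci_schoolchild = 2, nh_schoolchild = 2),
                n_standard = 100, per_type = 20, per_magnitude = 10, ...)
}

noiseless_config <- function(...) {
  tiny_cohort_config(noise = list(white_sd_uv = 0, pink_sd_uv = 0,
                                  alpha_uv = 0),
                     artifact_rate = 0, ...)
}

nh_preschool_profile <- function(id = "S01") {
  list(subject_id = id, clinical_group = "NH", age_group = "preschooler")
}

# continuous sinusoid test signal on one channel
sine_recording <- function(freq_hz, srate = 512, dur_s = 20, amp = 1) {
  t <- (0:(srate * dur_s - 1)) / srate
  eeg_continuous(matrix(amp * sin(2 * pi * freq_hz * t), 1,
                        dimnames = list("Fz", NULL)), srate)
}

# steady-state amplitude, skipping edges
steady_amp <- function(x, skip_s = 2) {
  skip <- x$srate * skip_s
  max(abs(x$data[1, skip:(ncol(x$data) - skip)]))
}

# hand-built epochs object: channels x samples x trials
make_epochs <- function(data, srate = 256, times = NULL,
                        condition = "deviant") {
  if (is.null(times)) times <- (seq_len(dim(data)[2]) - 1) / srate * 1000
  structure(list(data = data, times = times, srate = srate,
                 channels = dimnames(data)[[1]], condition = condition,
                 retained = rep(TRUE, dim(data)[3]),
                 reject_reason = rep("", dim(data)[3])),
            class = "eeg_epochs")
}

# difference wave with a prescribed ROI trace (channels copy the ROI)
make_diff_wave <- function(roi, srate = 256, window_ms = c(-100, 700)) {
  start_off <- round(window_ms[1] / 1000 * srate)
  times <- (start_off + seq_along(roi) - 1) / srate * 1000
  roi_ch <- c("F3", "Fz", "F4", "C3", "Cz", "C4")
  structure(list(roi = roi,
                 channels = matrix(rep(roi, each = 6), nrow = 6,
                                   dimnames = list(roi_ch, NULL)),
                 channel_labels = roi_ch, times = times, srate = srate,
                 deviant = "test", n_deviant_trials = 1L,
                 n_standard_trials = 1L),
            class = "difference_wave")
}

gaussian_on <- function(times, amp, peak, fwhm) {
  component_waveform(list(amplitude_uv = amp, peak_latency_ms = peak,
                          fwhm_ms = fwhm), times)
}

default_grid <- function(srate = 256, window_ms = c(-100, 700)) {
  start_off <- round(window_ms[1] / 1000 * srate)
  n_samp <- floor(diff(window_ms) / 1000 * srate)
  (start_off + seq_len(n_samp) - 1) / srate * 1000
}
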