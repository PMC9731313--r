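#' Gaussian ERP component template
#'
#' Canonical Gaussian-shaped deflection used to synthesize evoked components:
#' `value(t) = amplitude_uv * exp(-(t - peak_latency_ms)^2 / (2 * sigma^2))`
#' with `sigma = fwhm_ms / 2.3548`, so the template attains exactly
#' `amplitude_uv` at the peak and half of it at `peak +- fwhm / 2`.
#'
#' @param spec List with `amplitude_uv`, `peak_latency_ms` and `fwhm_ms`.
#' @param time_ms Numeric vector of sample times in ms (uniform grid).
#' @return Numeric vector of the template evaluated on `time_ms`, in uV.
#' @export
component_waveform <- function(spec, time_ms) {
  if (length(time_ms) == 0L) stop("empty time grid")
  stopifnot(spec$fwhm_ms > 0)
  sigma <- spec$fwhm_ms / 2.3548
  spec$amplitude_uv * exp(-(time_ms - spec$peak_latency_ms)^2 / (2 * sigma^2))
}

#' Channel montage used by the simulator
#'
#' The six frontocentral ROI electrodes plus the two mastoids and a nose
#' reference channel; a full high-density montage is unnecessary because the
#' analysis operates on the ROI average.
#' @return Character vector of channel labels.
#' @export
sim_channels <- function() c("F3", "Fz", "F4", "C3", "Cz", "C4",
                             "M1", "M2", "Nose")

# per-channel scaling of evoked activity (ROI uniform so that the ROI mean
# reproduces the injected template exactly; mastoids attenuated; reference 0)
.evoked_weights <- c(F3 = 1, Fz = 1, F4 = 1, C3 = 1, Cz = 1, C4 = 1,
                     M1 = 0.2, M2 = 0.2, Nose = 0)
.artifact_weights <- c(F3 = 1, Fz = 1, F4 = 1, C3 = 0.7, Cz = 0.7, C4 = 0.7,
                       M1 = 0.3, M2 = 0.3, Nose = 0)

#' Standard-evoked base response
#'
#' Fixed small P1-N2-like obligatory response injected into every trial
#' (standard and deviant alike), so that deviant-minus-standard difference
#' waves isolate the injected mismatch components.
#'
#' @param time_ms Sample times in ms relative to stimulus onset.
#' @return Numeric vector, uV.
#' @export
standard_evoked <- function(time_ms) {
  component_waveform(list(amplitude_uv = 3, peak_latency_ms = 100,
                          fwhm_ms = 80), time_ms) +
    component_waveform(list(amplitude_uv = -2, peak_latency_ms = 250,
                            fwhm_ms = 120), time_ms)
}

#' Configuration of the synthetic cohort
#'
#' Collects every tunable of the cohort generator. Defaults reproduce the
#' study conditions: cell sizes 11/11/10/11 (21 CI + 22 NH children), the
#' published per-cell component latencies and amplitude moments
#' ([default_response_norms()]), 512 Hz native sampling, a 2,000-event
#' alternating sequence at 900 ms SOA per subject and timepoint, and singing
#' questionnaire scores on a 0-5 Likert scale.
#'
#' @param n_per_cell Named integer vector of subjects per clinical x age cell:
#'   `ci_preschooler`, `nh_preschooler`, `ci_schoolchild`, `nh_schoolchild`.
#' @param component_tables Data frame in the format of
#'   [default_response_norms()] giving, per cell x deviant x component, the
#'   true peak latency and the between-subject amplitude mean and SD.
#' @param noise List with `white_sd_uv` (broadband sensor noise SD),
#'   `pink_sd_uv` (1/f background SD) and `alpha_uv` (10 Hz sinusoid
#'   amplitude, random phase per trial).
#' @param artifact_rate Fraction of trials given a large-voltage excursion
#'   (must stay in \[0, 0.27\] so the 73% retention floor remains attainable
#'   by design).
#' @param artifact_amp_uv Range (min, max) of absolute artifact peak
#'   amplitudes in uV; the minimum must exceed the 150 uV final rejection
#'   threshold for artifact trials to be rejectable.
#' @param sampling_rate_hz Native sampling rate (512).
#' @param fwhm_ms Named vector of component widths (full width at half
#'   maximum) for pMMR, MMN, P3a, LDN.
#' @param singing_scale Questionnaire range for the singing scores (the scale
#'   is a parameter because published descriptions give both 0-5 and 1-5).
#' @param n_standard,per_type,per_magnitude,soa_ms Paradigm design passed to
#'   [generate_sequence()].
#' @param seed Master seed; all randomness in the cohort flows from it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_cell = c(ci_preschooler = 11,
                                         nh_preschooler = 11,
                                         ci_schoolchild = 10,
                                         nh_schoolchild = 11),
                          component_tables = default_response_norms(),
                          noise = list(white_sd_uv = 8, pink_sd_uv = 8,
                                       alpha_uv = 3),
                          artifact_rate = 0.08,
                          artifact_amp_uv = c(200, 500),
                          sampling_rate_hz = 512,
                          fwhm_ms = c(pMMR = 80, MMN = 80, P3a = 80,
                                      LDN = 120),
                          singing_scale = c(0, 5),
                          n_standard = 1000, per_type = 200,
                          per_magnitude = 100, soa_ms = 900,
                          seed = 1) {
  stopifnot(all(n_per_cell >= 2), artifact_rate >= 0, artifact_rate <= 0.27,
            all(unlist(noise) >= 0), all(fwhm_ms > 0),
            all(c("latency_ms", "amp_mean_uv", "amp_sd_uv") %in%
                  names(component_tables)),
            all(component_tables$amp_sd_uv >= 0),
            artifact_amp_uv[1] > 150, diff(artifact_amp_uv) >= 0,
            singing_scale[1] < singing_scale[2])
  cfg <- list(n_per_cell = n_per_cell, component_tables = component_tables,
              noise = noise, artifact_rate = artifact_rate,
              artifact_amp_uv = artifact_amp_uv,
              sampling_rate_hz = sampling_rate_hz, fwhm_ms = fwhm_ms,
              singing_scale = singing_scale, n_standard = n_standard,
              per_type = per_type, per_magnitude = per_magnitude,
              soa_ms = soa_ms, seed = seed)
  class(cfg) <- "cohort_config"
  cfg
}

.lookup_cell <- function(tab, group, age, tp, deviant) {
  rows <- tab[tab$clinical_group == group & tab$age_group == age &
                tab$timepoint == tp & tab$deviant == deviant, ]
  if (nrow(rows) != 4L) {
    stop("component table has no complete cell for (", group, ", ", age,
         ", ", tp, ", ", deviant, ")")
  }
  rows
}

.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Draw the ground-truth component parameters of one subject
#'
#' Subject-level true amplitudes are drawn once per subject and timepoint from
#' the configured cell's (mean, SD); true latencies are the cell latencies.
#' Uses the same random draws as [simulate_subject()] under the same seed, so
#' ground truth can be tabulated cheaply without synthesizing waveforms.
#'
#' @param profile List with `subject_id`, `clinical_group`, `age_group`.
#' @param config A [cohort_config()].
#' @param timepoint `"T1"` or `"T2"`.
#' @param seed Integer seed for this subject x timepoint.
#' @return Data frame with one row per deviant x component: the true
#'   amplitude and latency injected for that subject.
#' @export
draw_component_truth <- function(profile, config, timepoint, seed) {
  deviants <- c("gap", "duration", "vowel", "f0_15", "f0_50",
                "int_minus6", "int_plus6")
  comps <- c("pMMR", "MMN", "P3a", "LDN")
  .with_seed(seed, {
    rows <- lapply(deviants, function(dv) {
      cell <- .lookup_cell(config$component_tables, profile$clinical_group,
                           profile$age_group, timepoint, dv)
      cell <- cell[match(comps, cell$component), ]
      data.frame(subject_id = profile$subject_id,
                 clinical_group = profile$clinical_group,
                 age_group = profile$age_group,
                 timepoint = timepoint,
                 deviant = dv,
                 component = comps,
                 true_amplitude_uv = stats::rnorm(4, cell$amp_mean_uv,
                                                  cell$amp_sd_uv),
                 true_latency_ms = cell$latency_ms,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# 1/f ("pink") background: white noise shaped in the frequency domain by
# 1/sqrt(f), rescaled to the requested SD
.pink_noise <- function(n, sd_uv) {
  if (sd_uv <= 0) return(numeric(n))
  m <- stats::nextn(n, c(2, 3))
  x <- stats::rnorm(m)
  xf <- stats::fft(x)
  f <- c(1, seq_len(m - 1))
  f <- pmin(f, m - f + 1)           # symmetric frequency index
  xf <- xf / sqrt(f)
  y <- Re(stats::fft(xf, inverse = TRUE))[seq_len(n)]
  y * sd_uv / stats::sd(y)
}

#' Synthesize one subject's continuous EEG recording
#'
#' Generates the subject's stimulus sequence, draws the subject's true
#' component amplitudes ([draw_component_truth()]), and synthesizes a
#' multichannel continuous recording at the native rate: every trial carries
#' the standard-evoked base response, deviant trials additionally carry the
#' subject's four Gaussian component templates at the configured cell
#' latencies, and the background is white + 1/f noise plus a 10 Hz sinusoid
#' with random phase per trial. A configured fraction of trials receives a
#' large-voltage artifact excursion (exceeding the 150 uV rejection
#' threshold). Injected activity is aligned to the sample nearest each event
#' onset, so with zero noise the per-condition median ERP reproduces the
#' injected signal exactly.
#'
#' @inheritParams draw_component_truth
#' @return List with `continuous` (an `eeg_continuous`), `events` (the
#'   `event_sequence`), `truth`, `profile`, `timepoint`, `seed`.
#' @export
simulate_subject <- function(profile, config, timepoint, seed) {
  truth <- draw_component_truth(profile, config, timepoint, seed)
  catalog <- build_catalog()
  events <- generate_sequence(catalog, n_standard = config$n_standard,
                              per_type = config$per_type,
                              per_magnitude = config$per_magnitude,
                              soa_ms = config$soa_ms, seed = seed + 1L)

  srate <- config$sampling_rate_hz
  chans <- sim_channels()
  nch <- length(chans)
  t0_ms <- -500                      # recording starts 500 ms before event 0
  total_ms <- max(events$onset_ms) + config$soa_ms + 800
  n <- ceiling((total_ms - t0_ms) / 1000 * srate)

  .with_seed(seed + 2L, {
    data <- matrix(0, nrow = nch, ncol = n, dimnames = list(chans, NULL))

    # background noise, independent per channel (not on the reference)
    for (ch in seq_len(nch - 1L)) {
      bg <- stats::rnorm(n, sd = config$noise$white_sd_uv) +
        .pink_noise(n, config$noise$pink_sd_uv)
      data[ch, ] <- bg
    }

    onset_samp <- round((events$onset_ms - t0_ms) / 1000 * srate) + 1L
    sig_w <- .evoked_weights[chans]
    art_w <- .artifact_weights[chans]
    n_art <- 0L

    # per-trial segment: [-100, +800) ms around onset (contiguous at 900 SOA)
    seg0 <- round(-0.100 * srate)
    seg_len <- round(0.900 * srate)
    seg_rel_ms <- (seg0 + seq_len(seg_len) - 1) / srate * 1000

    for (e in seq_len(nrow(events))) {
      os <- onset_samp[e]
      idx <- os + seg0 + seq_len(seg_len) - 1L
      keep <- idx >= 1L & idx <= n
      rel <- seg_rel_ms[keep]
      idx <- idx[keep]

      evoked <- standard_evoked(rel)
      if (events$condition[e] != "standard") {
        tr <- truth[truth$deviant == events$condition[e], ]
        for (k in seq_len(nrow(tr))) {
          evoked <- evoked + component_waveform(
            list(amplitude_uv = tr$true_amplitude_uv[k],
                 peak_latency_ms = tr$true_latency_ms[k],
                 fwhm_ms = unname(config$fwhm_ms[tr$component[k]])),
            rel)
        }
      }
      if (config$noise$alpha_uv > 0) {
        phase <- stats::runif(1, 0, 2 * pi)
        evoked_bg <- config$noise$alpha_uv * sin(2 * pi * 10 * rel / 1000 +
                                                   phase)
      } else {
        evoked_bg <- 0
      }
      if (config$artifact_rate > 0 &&
          stats::runif(1) < config$artifact_rate) {
        n_art <- n_art + 1L
        amp <- sample(c(-1, 1), 1) *
          stats::runif(1, config$artifact_amp_uv[1], config$artifact_amp_uv[2])
        centre <- stats::runif(1, 0, 600)
        art <- component_waveform(list(amplitude_uv = amp,
                                       peak_latency_ms = centre,
                                       fwhm_ms = 100), rel)
      } else {
        art <- 0
      }
      add <- evoked + evoked_bg
      data[, idx] <- data[, idx] +
        outer(sig_w, add) + if (is.numeric(art) && length(art) > 1)
          outer(art_w, art) else 0
    }

    continuous <- eeg_continuous(data, srate, chans, t0_ms = t0_ms)
    list(continuous = continuous, events = events, truth = truth,
         profile = profile, timepoint = timepoint, seed = seed,
         n_artifact_trials = n_art)
  })
}

#' Reconstruct the injected evoked signal of a condition
#'
#' Ground-truth reference for recovery tests: the noiseless evoked time course
#' a given subject's trials of one condition carry (standard base plus, for
#' deviants, the subject's component templates).
#'
#' @param truth Truth table from [simulate_subject()]/[draw_component_truth()].
#' @param config The [cohort_config()] used.
#' @param condition Condition label (`"standard"` or a deviant).
#' @param time_ms Sample times in ms relative to stimulus onset.
#' @return Numeric vector, uV (ROI scale).
#' @export
injected_waveform <- function(truth, config, condition, time_ms) {
  w <- standard_evoked(time_ms)
  if (condition != "standard") {
    tr <- truth[truth$deviant == condition, ]
    if (nrow(tr) == 0L) stop("condition not in truth table: ", condition)
    for (k in seq_len(nrow(tr))) {
      w <- w + component_waveform(
        list(amplitude_uv = tr$true_amplitude_uv[k],
             peak_latency_ms = tr$true_latency_ms[k],
             fwhm_ms = unname(config$fwhm_ms[tr$component[k]])),
        time_ms)
    }
  }
  w
}

#' Build the cohort roster and metadata
#'
#' Enumerates subjects for the 2 (CI/NH) x 2 (preschooler/schoolchild) design
#' with singing questionnaire responses drawn uniformly on the configured
#' scale at each timepoint, independently of age group, and combined into a
#' per-subject score by averaging ([singing_score()]). Per-subject x timepoint
#' seeds are derived deterministically from the master seed.
#'
#' @param config A [cohort_config()].
#' @return Data frame with one row per subject: id, groups, questionnaire
#'   responses, combined singing scores, and the seeds for T1 and T2.
#' @export
cohort_roster <- function(config) {
  cells <- data.frame(
    cell = c("ci_preschooler", "nh_preschooler", "ci_schoolchild",
             "nh_schoolchild"),
    clinical_group = c("CI", "NH", "CI", "NH"),
    age_group = c("preschooler", "preschooler", "schoolchild", "schoolchild"),
    stringsAsFactors = FALSE
  )
  n <- config$n_per_cell[cells$cell]
  roster <- data.frame(
    clinical_group = rep(cells$clinical_group, n),
    age_group = rep(cells$age_group, n),
    stringsAsFactors = FALSE
  )
  roster$subject_id <- sprintf("S%02d", seq_len(nrow(roster)))
  roster <- roster[, c("subject_id", "clinical_group", "age_group")]

  .with_seed(config$seed, {
    sc <- config$singing_scale
    likert <- function(m) sample(seq(sc[1], sc[2]), m, replace = TRUE)
    m <- nrow(roster)
    roster$parental_singing_t1 <- likert(m)
    roster$parental_singing_t2 <- likert(m)
    roster$child_singing_t1 <- likert(m)
    roster$child_singing_t2 <- likert(m)
  })
  roster$parental_singing <- singing_score(roster$parental_singing_t1,
                                           roster$parental_singing_t2)
  roster$child_singing <- singing_score(roster$child_singing_t1,
                                        roster$child_singing_t2)
  roster$seed_t1 <- config$seed + 1000L + 10L * seq_len(nrow(roster))
  roster$seed_t2 <- config$seed + 100000L + 10L * seq_len(nrow(roster))
  roster
}

#' Simulate a full cohort
#'
#' Draws ground truth for every subject at both timepoints (and optionally the
#' full EEG recordings — feasible only for small designs; the pipeline
#' synthesizes recordings one subject at a time instead).
#'
#' @param config A [cohort_config()].
#' @param keep_data If `TRUE`, also return the full [simulate_subject()]
#'   objects (memory-heavy; intended for small configurations).
#' @return List with `config`, `subjects` (roster), `truth` (all subjects x
#'   timepoints x deviants x components), and optionally `runs`.
#' @export
simulate_cohort <- function(config, keep_data = FALSE) {
  roster <- cohort_roster(config)
  truth <- list()
  runs <- if (keep_data) list() else NULL
  for (i in seq_len(nrow(roster))) {
    profile <- as.list(roster[i, c("subject_id", "clinical_group",
                                   "age_group")])
    for (tp in c("T1", "T2")) {
      sd_i <- roster[[if (tp == "T1") "seed_t1" else "seed_t2"]][i]
      if (keep_data) {
        run <- simulate_subject(profile, config, tp, sd_i)
        runs[[paste(profile$subject_id, tp, sep = "_")]] <- run
        truth[[length(truth) + 1L]] <- run$truth
      } else {
        truth[[length(truth) + 1L]] <- draw_component_truth(profile, config,
                                                            tp, sd_i)
      }
    }
  }
  out <- list(config = config, subjects = roster,
              truth = do.call(rbind, truth))
  if (keep_data) out$runs <- runs
  out
}

#' Synthesize a ROI difference wave directly
#'
#' Fast path for detector studies: builds a `difference_wave` on the analysis
#' grid (default 256 Hz, -100..700 ms) as the sum of the four Gaussian
#' component templates plus white residual noise at the level the median-ERP
#' pipeline leaves on a difference wave, then applies the 20 Hz
#' quantification low-pass. The per-electrode traces get independent noise
#' around the same signal, as after per-channel median ERPs.
#'
#' @param amplitudes Named numeric vector (`pMMR`, `MMN`, `P3a`, `LDN`), uV.
#' @param latencies Named numeric vector of peak latencies, ms from onset.
#' @param fwhm_ms Component widths as in [cohort_config()].
#' @param noise_sd_uv Residual per-sample SD of the ROI trace before
#'   low-passing (default 0.45, the level the default cohort noise leaves on
#'   a 200-deviant-trial difference wave after median ERPs and six-channel
#'   ROI averaging; individual electrodes carry sqrt(6) times as much).
#' @param srate Analysis sampling rate.
#' @param window_ms Epoch window.
#' @param lowpass_hz Quantification low-pass (`NULL` to skip).
#' @param seed Integer seed.
#' @return A `difference_wave`.
#' @export
synthetic_difference_wave <- function(amplitudes, latencies,
                                      fwhm_ms = c(pMMR = 80, MMN = 80,
                                                  P3a = 80, LDN = 120),
                                      noise_sd_uv = 0.45, srate = 256,
                                      window_ms = c(-100, 700),
                                      lowpass_hz = 20, seed = 1) {
  start_off <- round(window_ms[1] / 1000 * srate)
  n_samp <- floor(diff(window_ms) / 1000 * srate)
  times <- (start_off + seq_len(n_samp) - 1) / srate * 1000
  sig <- numeric(n_samp)
  for (cp in names(amplitudes)) {
    sig <- sig + component_waveform(
      list(amplitude_uv = unname(amplitudes[cp]),
           peak_latency_ms = unname(latencies[cp]),
           fwhm_ms = unname(fwhm_ms[cp])), times)
  }
  roi_ch <- c("F3", "Fz", "F4", "C3", "Cz", "C4")
  .with_seed(seed, {
    ch <- t(vapply(roi_ch, function(e)
      sig + stats::rnorm(n_samp, sd = noise_sd_uv * sqrt(6)),
      numeric(n_samp)))
    dw <- structure(list(roi = sig + stats::rnorm(n_samp, sd = noise_sd_uv),
                         channels = ch, channel_labels = roi_ch,
                         times = times, srate = srate,
                         deviant = "synthetic",
                         n_deviant_trials = NA_integer_,
                         n_standard_trials = NA_integer_),
                    class = "difference_wave")
    if (!is.null(lowpass_hz)) dw <- lowpass_for_quantification(dw, lowpass_hz)
    dw
  })
}

#' Simulate an amplitude table directly (no EEG synthesis)
#'
#' Amplitude-level generator for calibration and power studies of the mixed
#' models: per subject and timepoint, `amplitude = cell mean + subject
#' intercept + residual`, with the cell mean built from additive effects on
#' the model's own coding (estimates are CI-NH, preschooler-schoolchild,
#' T1-T2, and singing enters as a slope). Setting all effects to zero gives
#' the null cohort used for type-I calibration.
#'
#' @param n_per_cell Named vector as in [cohort_config()].
#' @param effects List of true effect sizes in uV: `intercept`, `group`
#'   (CI-NH), `age` (preschooler-schoolchild), `time` (T1-T2), `group_age`,
#'   `group_time`, `age_time`, `group_age_time`, `singing` (uV per scale
#'   unit), `singing_time` (uV per scale unit, T1-T2). Omitted entries are 0.
#' @param sd_subject Between-subject (random intercept) SD, uV.
#' @param sd_resid Residual SD, uV.
#' @param singing_scale Questionnaire range for the singing score.
#' @param seed Integer seed.
#' @return Data frame with one row per subject x timepoint: grouping factors,
#'   `parental_singing`, `child_singing` and `amplitude_uv`.
#' @export
simulate_amplitude_table <- function(n_per_cell = c(ci_preschooler = 11,
                                                    nh_preschooler = 11,
                                                    ci_schoolchild = 10,
                                                    nh_schoolchild = 11),
                                     effects = list(),
                                     sd_subject = 1.4, sd_resid = 1.4,
                                     singing_scale = c(0, 5),
                                     seed = 1) {
  eff <- utils::modifyList(
    list(intercept = 0, group = 0, age = 0, time = 0, group_age = 0,
         group_time = 0, age_time = 0, group_age_time = 0,
         singing = 0, singing_time = 0),
    effects)
  cfg <- cohort_config(n_per_cell = n_per_cell, singing_scale = singing_scale,
                       seed = seed)
  roster <- cohort_roster(cfg)
  .with_seed(seed + 1L, {
    u <- stats::rnorm(nrow(roster), sd = sd_subject)
    rows <- lapply(c("T1", "T2"), function(tp) {
      g <- as.numeric(roster$clinical_group == "CI")
      a <- as.numeric(roster$age_group == "preschooler")
      tt <- as.numeric(tp == "T1")
      s <- roster$parental_singing
      mu <- eff$intercept + eff$group * g + eff$age * a + eff$time * tt +
        eff$group_age * g * a + eff$group_time * g * tt +
        eff$age_time * a * tt + eff$group_age_time * g * a * tt +
        eff$singing * s + eff$singing_time * s * tt
      data.frame(subject_id = roster$subject_id,
                 clinical_group = roster$clinical_group,
                 age_group = roster$age_group,
                 timepoint = tp,
                 parental_singing = roster$parental_singing,
                 child_singing = roster$child_singing,
                 amplitude_uv = mu + u +
                   stats::rnorm(nrow(roster), sd = sd_resid),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
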