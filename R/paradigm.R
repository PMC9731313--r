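#' Stimulus catalog for the multifeature /tatata/ oddball paradigm
#'
#' Builds the full stimulus description used by the experiment: a trisyllabic
#' pseudoword standard and seven deviants in which the middle syllable changes
#' in one of five dimensions (gap insertion, vowel duration, vowel identity,
#' fundamental frequency, intensity). The F0 and intensity deviants come in two
#' magnitudes each (F0 +15% / +50%; intensity -6 / +6 dB), so the seven deviant
#' conditions collapse onto five deviant types.
#'
#' All acoustic parameters are carried on each stimulus: total duration, the
#' silence between the first and second syllable, middle-syllable duration,
#' fundamental frequency, the first three formants, the two presentation levels
#' (lower/higher, dB SPL), and the latency at which the deviance begins
#' relative to stimulus onset (198 ms, the onset of the second syllable; `NA`
#' for the standard). The F0 deviant frequencies are the standard's F0 scaled
#' by 1.15 and 1.50 and rounded to the nearest integer Hz.
#'
#' @return An object of class `deviant_catalog`: a list with elements
#'   `standard` (a `stimulus_spec`), `deviants` (named list of seven
#'   `stimulus_spec`s), and `type_of` (named character vector mapping the seven
#'   deviant conditions to the five deviant types).
#' @examples
#' cat7 <- build_catalog()
#' cat7$standard$total_duration_ms          # 480
#' cat7$deviants$gap$total_duration_ms      # 580
#' cat7$deviants$f0_15$mid_f0_hz            # 194
#' @export
build_catalog <- function() {
  std_f0 <- 169

  spec <- function(label, syllables, total, gap1, mid_dur, f0, formants,
                   intensity, change_onset) {
    s <- list(
      label = label,
      syllables = syllables,
      total_duration_ms = total,
      gap1_ms = gap1,
      mid_syllable_duration_ms = mid_dur,
      mid_f0_hz = f0,
      mid_formants_hz = formants,
      mid_intensity_db = intensity,
      change_onset_ms = change_onset
    )
    stopifnot(total > 0, gap1 > 0, mid_dur > 0, f0 > 0, all(formants > 0))
    class(s) <- "stimulus_spec"
    s
  }

  standard <- spec("standard", "/tatata/", 480, 60, 120, std_f0,
                   c(F1 = 730, F2 = 1476, F3 = 2700), c(60, 70), NA_real_)

  dev <- function(label, syllables = standard$syllables,
                  total = standard$total_duration_ms,
                  gap1 = standard$gap1_ms,
                  mid_dur = standard$mid_syllable_duration_ms,
                  f0 = standard$mid_f0_hz,
                  formants = standard$mid_formants_hz,
                  intensity = standard$mid_intensity_db) {
    spec(label, syllables, total, gap1, mid_dur, f0, formants, intensity, 198)
  }

  deviants <- list(
    gap        = dev("gap", syllables = "/tattata/", total = 580, gap1 = 160),
    duration   = dev("duration", syllables = "/tata:ta/", total = 560,
                     mid_dur = 200),
    vowel      = dev("vowel", syllables = "/tatota/",
                     formants = c(F1 = 560, F2 = 1240, F3 = 2750)),
    f0_15      = dev("f0_15", f0 = round(std_f0 * 1.15)),
    f0_50      = dev("f0_50", f0 = round(std_f0 * 1.50)),
    int_minus6 = dev("int_minus6", intensity = standard$mid_intensity_db - 6),
    int_plus6  = dev("int_plus6", intensity = standard$mid_intensity_db + 6)
  )

  type_of <- c(gap = "gap", duration = "duration", vowel = "vowel",
               f0_15 = "f0", f0_50 = "f0",
               int_minus6 = "intensity", int_plus6 = "intensity")

  stopifnot(length(deviants) == 7L, length(unique(type_of)) == 5L)
  structure(list(standard = standard, deviants = deviants, type_of = type_of),
            class = "deviant_catalog")
}

#' Condition labels of a catalog
#' @param catalog A `deviant_catalog`.
#' @return Character vector of the seven deviant condition labels.
#' @export
deviant_conditions <- function(catalog) names(catalog$deviants)

#' Generate the pseudorandom alternating stimulus sequence
#'
#' Standards strictly alternate with deviants, starting with a standard. The
#' deviant subsequence is a random shuffle of the configured condition multiset
#' repaired so that no more than two consecutive deviants share a deviant type:
#' each scan swaps every third-or-later repetition with a deviant drawn from a
#' uniformly random position, and the sequence is rescanned until no such
#' repetition remains (repairs are capped to guard termination).
#'
#' @param catalog A `deviant_catalog` from [build_catalog()].
#' @param n_standard Number of standard presentations (default 1000).
#' @param per_type Presentations per deviant type (default 200); the five types
#'   must sum to `n_standard`.
#' @param per_magnitude Presentations per magnitude for the split F0 and
#'   intensity types (default 100); the two magnitudes of a type sum to
#'   `per_type`.
#' @param soa_ms Stimulus onset asynchrony in ms (default 900).
#' @param seed Integer seed; identical seeds yield identical sequences.
#' @param max_scans Cap on repair scans before aborting with a diagnostic.
#' @return An `event_sequence`: a data frame with columns `index` (0-based),
#'   `onset_ms` (`index * soa_ms`), `duration_ms`, `condition` and `type`, with
#'   attributes `soa_ms` and `seed`.
#' @examples
#' seq1 <- generate_sequence(build_catalog(), seed = 1)
#' nrow(seq1)                       # 2000
#' sum(seq1$condition == "standard")  # 1000
#' @export
generate_sequence <- function(catalog, n_standard = 1000, per_type = 200,
                              per_magnitude = 100, soa_ms = 900, seed,
                              max_scans = 10000) {
  stopifnot(inherits(catalog, "deviant_catalog"), n_standard >= 1,
            soa_ms > 0)
  if (missing(seed)) stop("a seed is required; sequences must be reproducible")
  if (per_type * 5 != n_standard) {
    stop("infeasible configuration: per_type * 5 (", per_type * 5,
         ") must equal n_standard (", n_standard, ")")
  }
  if (per_magnitude * 2 != per_type) {
    stop("infeasible configuration: per_magnitude * 2 (", per_magnitude * 2,
         ") must equal per_type (", per_type, ")")
  }

  counts <- c(gap = per_type, duration = per_type, vowel = per_type,
              f0_15 = per_magnitude, f0_50 = per_magnitude,
              int_minus6 = per_magnitude, int_plus6 = per_magnitude)
  n_dev <- sum(counts)
  type_counts <- tapply(counts, catalog$type_of[names(counts)], sum)
  # a type with m tokens can avoid runs > 2 iff m <= 2 * (n - m + 1)
  bad <- type_counts > 2 * (n_dev - type_counts + 1)
  if (any(bad)) {
    stop("infeasible configuration: type(s) ",
         paste(names(type_counts)[bad], collapse = ", "),
         " cannot avoid runs longer than 2")
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  conds <- sample(rep(names(counts), counts))
  types <- function(x) unname(catalog$type_of[x])

  scans <- 0L
  repeat {
    scans <- scans + 1L
    if (scans > max_scans) {
      stop("sequence repair did not terminate within ", max_scans,
           " scans; seed = ", seed)
    }
    tt <- types(conds)
    viol <- which(tt[3:n_dev] == tt[2:(n_dev - 1)] &
                    tt[2:(n_dev - 1)] == tt[1:(n_dev - 2)]) + 2L
    if (length(viol) == 0L) break
    for (v in viol) {
      tt <- types(conds)
      if (v > 2 && tt[v] == tt[v - 1] && tt[v] == tt[v - 2]) {
        j <- sample.int(n_dev, 1L)
        tmp <- conds[v]
        conds[v] <- conds[j]
        conds[j] <- tmp
      }
    }
  }

  condition <- character(2L * n_dev)
  condition[seq(1L, 2L * n_dev, by = 2L)] <- "standard"
  condition[seq(2L, 2L * n_dev, by = 2L)] <- conds
  if (n_standard != n_dev) {
    stop("internal error: alternation requires equal standard/deviant counts")
  }

  dur_of <- c(standard = catalog$standard$total_duration_ms,
              vapply(catalog$deviants, `[[`, numeric(1), "total_duration_ms"))
  type_col <- ifelse(condition == "standard", "standard",
                     unname(catalog$type_of[condition]))

  events <- data.frame(
    index = seq_along(condition) - 1L,
    onset_ms = (seq_along(condition) - 1L) * soa_ms,
    duration_ms = unname(dur_of[condition]),
    condition = condition,
    type = type_col,
    stringsAsFactors = FALSE
  )
  attr(events, "soa_ms") <- soa_ms
  attr(events, "seed") <- seed
  class(events) <- c("event_sequence", "data.frame")
  events
}

#' Validate an event sequence
#'
#' Report-only check of the paradigm invariants: strict standard/deviant
#' alternation starting with a standard, onsets equal to `index * soa_ms`,
#' per-condition counts (against an expected table when supplied), and the
#' maximum run of identical deviant types within the deviant subsequence.
#'
#' @param seq An `event_sequence`.
#' @param expected_counts Optional named vector of expected per-condition
#'   counts (deviant conditions only).
#' @return A list with `alternation_ok`, `onsets_ok`, `counts`, `counts_ok`,
#'   `max_type_run` and overall `pass` (requires `max_type_run <= 2`).
#' @export
check_sequence <- function(seq, expected_counts = NULL) {
  stopifnot(is.data.frame(seq), nrow(seq) > 0)
  soa <- attr(seq, "soa_ms")
  is_std <- seq$condition == "standard"
  alternation_ok <- all(is_std == (seq$index %% 2L == 0L)) && is_std[1]
  onsets_ok <- is.null(soa) || all(seq$onset_ms == seq$index * soa)
  dev_types <- seq$type[!is_std]
  max_run <- if (length(dev_types)) max(rle(dev_types)$lengths) else 0L
  counts <- table(seq$condition[!is_std])
  counts_ok <- TRUE
  if (!is.null(expected_counts)) {
    counts_ok <- all(names(expected_counts) %in% names(counts)) &&
      all(counts[names(expected_counts)] == expected_counts)
  }
  list(alternation_ok = alternation_ok, onsets_ok = onsets_ok,
       counts = counts, counts_ok = counts_ok, max_type_run = max_run,
       pass = alternation_ok && onsets_ok && counts_ok && max_run <= 2L)
}

#' Total sequence duration in minutes
#'
#' @param seq An `event_sequence`.
#' @return `(event count * soa_ms)` expressed in minutes; the default
#'   2000-event, 900 ms SOA sequence lasts 30 minutes.
#' @export
total_duration <- function(seq) {
  stopifnot(is.data.frame(seq))
  if (nrow(seq) == 0L) stop("empty sequence has no duration")
  soa <- attr(seq, "soa_ms")
  if (is.null(soa)) stop("sequence has no soa_ms attribute")
  nrow(seq) * soa / 60000
}

#' Write / read an events table
#'
#' Tab-separated UTF-8 events file with a header row and columns `onset_ms`,
#' `duration_ms`, `condition`, `type` (one row per event), compatible in
#' spirit with BIDS `events.tsv`. The paired reader reconstructs an
#' `event_sequence` (the SOA is recovered from the onset grid), so a
#' write-read round trip is lossless.
#'
#' @param seq An `event_sequence`.
#' @param path Destination (writing) or source (reading) file path.
#' @return `write_event_table` returns `path` invisibly; `read_event_table`
#'   returns an `event_sequence`.
#' @export
write_event_table <- function(seq, path) {
  stopifnot(is.data.frame(seq))
  out <- seq[, c("onset_ms", "duration_ms", "condition", "type")]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  stopifnot(all(c("onset_ms", "duration_ms", "condition", "type") %in%
                  names(ev)))
  ev$index <- seq_len(nrow(ev)) - 1L
  ev <- ev[, c("index", "onset_ms", "duration_ms", "condition", "type")]
  soa <- unique(diff(ev$onset_ms))
  attr(ev, "soa_ms") <- if (length(soa) == 1L) soa else NULL
  class(ev) <- c("event_sequence", "data.frame")
  ev
}
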