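# Published group-level response norms used to parameterize the synthetic
# cohort: peak latencies (ms from stimulus onset) and amplitude mean/SD (uV)
# for every (clinical group, age group, timepoint, deviant, component) cell.
# Column order within each row: CI-T1-Pr, CI-T1-Sc, CI-T2-Pr, CI-T2-Sc,
# NH-T1-Pr, NH-T1-Sc, NH-T2-Pr, NH-T2-Sc.

.cell_key <- data.frame(
  clinical_group = rep(c("CI", "NH"), each = 4),
  timepoint = rep(c("T1", "T1", "T2", "T2"), 2),
  age_group = rep(c("preschooler", "schoolchild"), 4),
  stringsAsFactors = FALSE
)

.latency_rows <- list(
  pMMR = list(
    gap        = c(266, 254, 266, 250, 281, 250, 254, 262),
    duration   = c(246, 266, 270, 289, 301, 297, 293, 301),
    vowel      = c(277, 254, 262, 254, 277, 270, 273, 258),
    f0_15      = c(293, 262, 262, 297, 285, 254, 266, 231),
    f0_50      = c(254, 250, 270, 281, 250, 262, 289, 231),
    int_minus6 = c(281, 254, 254, 250, 301, 242, 258, 262),
    int_plus6  = c(301, 270, 234, 250, 246, 250, 242, 246)
  ),
  MMN = list(
    gap        = c(371, 356, 371, 340, 324, 316, 324, 324),
    duration   = c(395, 379, 402, 402, 387, 383, 387, 395),
    vowel      = c(383, 352, 383, 383, 410, 422, 418, 426),
    f0_15      = c(328, 305, 340, 352, 336, 344, 340, 336),
    f0_50      = c(387, 375, 422, 371, 332, 301, 348, 375),
    int_minus6 = c(406, 309, 387, 406, 441, 301, 414, 402),
    int_plus6  = c(391, 340, 313, 301, 430, 481, 324, 406)
  ),
  P3a = list(
    gap        = c(453, 465, 488, 457, 445, 441, 445, 445),
    duration   = c(453, 445, 453, 453, 445, 445, 445, 453),
    vowel      = c(430, 438, 441, 441, 449, 504, 449, 473),
    f0_15      = c(461, 473, 438, 441, 391, 383, 386, 453),
    f0_50      = c(461, 473, 520, 453, 363, 391, 391, 406),
    int_minus6 = c(453, 430, 438, 449, 527, 461, 453, 477),
    int_plus6  = c(520, 410, 375, 348, 465, 516, 391, 441)
  ),
  LDN = list(
    gap        = c(547, 535, 559, 535, 543, 543, 539, 539),
    duration   = c(543, 492, 555, 555, 477, 469, 477, 481),
    vowel      = c(570, 535, 578, 578, 551, 551, 543, 547),
    f0_15      = c(598, 523, 586, 574, 430, 477, 520, 488),
    f0_50      = c(539, 598, 578, 586, 493, 547, 574, 500),
    int_minus6 = c(496, 586, 598, 574, 566, 582, 539, 570),
    int_plus6  = c(570, 582, 594, 586, 547, 551, 566, 527)
  )
)

# amplitude mean then SD, interleaved per cell (m1, s1, m2, s2, ...)
.amplitude_rows <- list(
  pMMR = list(
    gap        = c(0.89, 1.88, 1.98, 1.82, -0.95, 2.30, 0.61, 1.43,
                   -1.37, 1.61, -0.90, 1.71, -1.01, 2.82, -0.28, 1.09),
    duration   = c(1.24, 1.37, 1.37, 2.51, 0.84, 1.68, 1.23, 1.75,
                   0.48, 3.06, -1.63, 1.78, -0.16, 2.67, -0.31, 2.02),
    vowel      = c(0.90, 1.92, 2.55, 1.91, 2.46, 1.82, 1.89, 1.81,
                   0.15, 3.08, 0.45, 1.90, 2.35, 2.30, 0.42, 1.17),
    f0_15      = c(-0.18, 1.37, 0.83, 2.79, 0.40, 2.18, -0.57, 2.14,
                   -1.84, 3.38, -0.44, 3.57, -0.19, 2.17, 0.67, 2.64),
    f0_50      = c(1.50, 2.29, 0.02, 3.44, 0.60, 1.90, -0.12, 2.96,
                   -1.05, 2.69, -0.46, 3.22, -1.20, 3.06, -0.75, 1.90),
    int_minus6 = c(1.23, 1.55, 1.04, 2.55, 0.93, 2.65, 1.09, 3.46,
                   -0.87, 3.20, -0.88, 1.86, -0.10, 2.77, 0.10, 2.55),
    int_plus6  = c(0.40, 3.10, 0.34, 2.64, 0.75, 2.92, 1.68, 3.06,
                   -1.02, 3.79, -0.71, 2.54, -1.01, 2.82, -0.14, 1.77)
  ),
  MMN = list(
    gap        = c(-1.85, 1.23, -2.12, 2.05, -1.76, 2.00, -1.86, 2.17,
                   -4.08, 1.94, -2.91, 2.01, -4.84, 2.54, -3.24, 1.62),
    duration   = c(-0.89, 2.35, -0.57, 2.67, -2.53, 2.83, -2.48, 1.81,
                   -3.84, 3.15, -4.62, 2.25, -4.90, 3.02, -3.86, 2.64),
    vowel      = c(0.00, 1.64, 0.82, 2.13, 0.59, 2.05, -1.31, 1.83,
                   -2.77, 4.00, -2.25, 1.65, -1.73, 3.21, -2.38, 2.32),
    f0_15      = c(-0.33, 1.19, -0.11, 2.33, -1.68, 2.56, -1.46, 3.16,
                   -2.66, 3.35, -1.87, 3.96, -1.83, 2.73, -1.71, 3.11),
    f0_50      = c(0.71, 1.75, 0.11, 2.88, -0.29, 2.43, -0.51, 3.21,
                   -2.70, 2.72, -0.77, 3.23, -1.85, 3.69, -1.81, 2.72),
    int_minus6 = c(1.21, 1.07, 0.05, 2.01, 1.15, 3.64, -0.17, 3.57,
                   -1.82, 3.91, -1.19, 2.20, -1.64, 3.39, -1.06, 1.37),
    int_plus6  = c(-0.13, 2.59, -0.43, 2.33, -0.37, 2.49, 0.89, 3.16,
                   -2.75, 4.84, -2.30, 3.17, -2.96, 2.71, -1.46, 2.81)
  ),
  P3a = list(
    gap        = c(1.25, 2.17, 3.56, 2.89, 1.88, 3.05, 3.69, 3.06,
                   0.64, 2.95, 1.96, 2.72, 0.96, 2.46, 1.49, 1.51),
    duration   = c(1.17, 1.63, 1.09, 2.56, 0.09, 1.64, -0.54, 2.34,
                   -2.29, 2.76, -2.76, 2.31, -3.56, 2.76, -1.90, 2.12),
    vowel      = c(1.28, 2.12, 2.43, 1.99, 1.20, 3.45, -0.37, 2.65,
                   -2.30, 3.81, -2.70, 1.29, -1.58, 3.47, -2.55, 2.26),
    f0_15      = c(2.36, 2.44, 1.86, 1.97, -0.32, 2.20, -0.57, 3.10,
                   -1.69, 3.76, -1.65, 3.47, -1.30, 3.65, -0.98, 2.01),
    f0_50      = c(2.49, 3.27, 2.24, 2.71, 1.66, 2.65, 1.11, 2.88,
                   -2.58, 2.28, -0.54, 2.72, -1.27, 4.0, -1.66, 3.06),
    int_minus6 = c(1.80, 2.46, 1.51, 2.04, 1.56, 3.51, 0.21, 4.98,
                   -0.63, 3.42, -0.89, 2.18, -0.94, 2.80, -0.35, 2.34),
    int_plus6  = c(1.42, 2.49, -0.85, 2.79, 0.62, 2.40, 1.27, 3.51,
                   -2.53, 4.87, -2.06, 2.76, -2.00, 2.99, -1.36, 2.51)
  ),
  LDN = list(
    gap        = c(-2.29, 1.47, -1.28, 1.53, -1.39, 2.43, -0.54, 1.89,
                   -1.65, 3.00, -0.48, 2.15, -2.16, 2.91, 0.01, 2.41),
    duration   = c(-0.34, 1.80, -0.75, 2.61, -0.90, 2.22, -1.11, 3.23,
                   -3.02, 3.29, -2.97, 2.16, -4.11, 3.11, -2.12, 2.21),
    vowel      = c(-0.42, 2.18, -0.03, 2.14, -0.22, 3.47, -2.10, 2.76,
                   -3.58, 3.20, -2.68, 1.84, -3.04, 1.82, -2.47, 1.78),
    f0_15      = c(1.20, 2.37, 0.96, 1.83, -0.03, 3.07, -1.20, 3.13,
                   -1.95, 3.66, -1.53, 3.28, -2.18, 3.90, -1.00, 2.95),
    f0_50      = c(1.76, 2.24, 0.74, 3.28, 0.22, 3.13, -0.43, 3.82,
                   -3.60, 2.32, -2.38, 2.95, -3.23, 2.90, -3.20, 3.68),
    int_minus6 = c(1.46, 2.18, 0.13, 2.90, 0.04, 3.73, -0.77, 3.87,
                   -1.68, 3.72, -1.85, 2.37, -1.60, 3.40, -1.38, 2.05),
    int_plus6  = c(0.56, 3.03, -0.79, 2.23, 0.41, 3.11, -1.15, 3.21,
                   -2.44, 5.20, -2.30, 3.67, -3.01, 3.09, -2.12, 2.74)
  )
)

#' Group-level ERP response norms
#'
#' The published group-level component parameters used as defaults by the
#' synthetic cohort generator: for every combination of clinical group (CI,
#' NH), age group (preschooler, schoolchild), timepoint (T1, T2), deviant
#' condition (7) and component (pMMR, MMN, P3a, LDN), the peak latency from
#' stimulus onset and the between-subject amplitude mean and SD.
#'
#' @return A data frame with 224 rows and columns `clinical_group`,
#'   `age_group`, `timepoint`, `deviant`, `component`, `latency_ms`,
#'   `amp_mean_uv`, `amp_sd_uv`.
#' @export
default_response_norms <- function() {
  rows <- list()
  for (comp in names(.latency_rows)) {
    for (dev in names(.latency_rows[[comp]])) {
      lat <- .latency_rows[[comp]][[dev]]
      amp <- .amplitude_rows[[comp]][[dev]]
      rows[[length(rows) + 1L]] <- data.frame(
        .cell_key,
        deviant = dev,
        component = comp,
        latency_ms = lat,
        amp_mean_uv = amp[seq(1, 16, by = 2)],
        amp_sd_uv = amp[seq(2, 16, by = 2)],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(nrow(out) == 224L, all(out$amp_sd_uv > 0))
  out
}
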