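#' Expected component polarities
#'
#' pMMR and P3a are positive deflections; MMN and LDN are negative.
#' @return Named numeric vector of expected signs.
#' @export
component_polarity <- function() c(pMMR = 1, MMN = -1, P3a = 1, LDN = -1)

#' One-sample t-test against zero
#'
#' @param values Numeric vector of amplitudes (n >= 2).
#' @return List with `t`, `p` (two-sided), `mean`, `sd`, `n`, `df`.
#' @export
one_sample_t <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("one-sample t-test needs at least 2 values")
  tt <- stats::t.test(values, mu = 0)
  list(t = unname(tt$statistic), p = tt$p.value, mean = mean(values),
       sd = stats::sd(values), n = length(values),
       df = unname(tt$parameter))
}

#' Per-cell amplitude significance table
#'
#' One-sample t-tests of the component amplitudes against zero in every
#' (clinical group, age group, timepoint, deviant, component) cell, with the
#' polarity bookkeeping used by the inclusion gates: a response counts as
#' polarity-correct when its cell mean has the expected component sign.
#'
#' @param amp_table Amplitude table with columns `clinical_group`,
#'   `age_group`, `timepoint`, `deviant`, `component`, `amplitude_uv`.
#' @param alpha Significance level (default 0.05).
#' @param by Grouping columns (drop `"age_group"` to test the pooled CI
#'   group for the singing analysis).
#' @return Data frame with `n`, `mean`, `sd`, `t`, `p`, `significant`,
#'   `polarity_correct` per cell.
#' @export
significance_table <- function(amp_table, alpha = 0.05,
                               by = c("clinical_group", "age_group",
                                      "timepoint", "deviant", "component")) {
  pol <- component_polarity()
  key <- unique(amp_table[by])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sel <- rep(TRUE, nrow(amp_table))
    for (cl in by) sel <- sel & amp_table[[cl]] == key[[cl]][i]
    v <- amp_table$amplitude_uv[sel]
    tt <- one_sample_t(v)
    cbind(key[i, , drop = FALSE],
          data.frame(n = tt$n, mean = tt$mean, sd = tt$sd, t = tt$t,
                     p = tt$p, significant = tt$p < alpha,
                     polarity_correct =
                       sign(tt$mean) == unname(pol[key$component[i]]),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Inclusion gate for the group comparisons
#'
#' A (deviant, component) response enters the clinical-group mixed models iff
#' it is significant with the expected polarity at at least one timepoint for
#' at least one CI age group AND at least one NH age group.
#'
#' @param sig A [significance_table()] over all group x age x timepoint
#'   cells.
#' @param require_polarity Count only polarity-correct significant cells
#'   (responses of opposite polarity are tracked separately and excluded).
#' @return Data frame with one row per (deviant, component): `ci_ok`,
#'   `nh_ok`, `included`.
#' @export
gate_group_comparison <- function(sig, require_polarity = TRUE) {
  hit <- sig$significant & (!require_polarity | sig$polarity_correct)
  key <- unique(sig[c("deviant", "component")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sel <- sig$deviant == key$deviant[i] & sig$component == key$component[i]
    ci_ok <- any(hit[sel & sig$clinical_group == "CI"])
    nh_ok <- any(hit[sel & sig$clinical_group == "NH"])
    data.frame(deviant = key$deviant[i], component = key$component[i],
               ci_ok = ci_ok, nh_ok = nh_ok, included = ci_ok && nh_ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Inclusion gate for the singing analysis
#'
#' In the combined CI group (both age groups pooled, amplitudes quantified at
#' the age-group latencies), a response enters the singing models iff it is
#' significant with the expected polarity at T1 or T2.
#'
#' @param sig_ci A [significance_table()] computed on the pooled CI group
#'   (grouping columns `clinical_group`, `timepoint`, `deviant`,
#'   `component`).
#' @param require_polarity As in [gate_group_comparison()].
#' @return Data frame with one row per (deviant, component) and `included`.
#' @export
gate_singing <- function(sig_ci, require_polarity = TRUE) {
  hit <- sig_ci$significant & (!require_polarity | sig_ci$polarity_correct)
  key <- unique(sig_ci[c("deviant", "component")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sel <- sig_ci$deviant == key$deviant[i] &
      sig_ci$component == key$component[i]
    data.frame(deviant = key$deviant[i], component = key$component[i],
               included = any(hit[sel]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# factor coding matching the reported estimate conventions: reference levels
# NH, schoolchildren and T2, so coefficients read CI-NH,
# preschooler-schoolchild and T1-T2
.code_factors <- function(d) {
  d$clinical_group <- factor(d$clinical_group, levels = c("NH", "CI"))
  d$age_group <- factor(d$age_group, levels = c("schoolchild", "preschooler"))
  d$timepoint <- factor(d$timepoint, levels = c("T2", "T1"))
  d
}

.fixef_table <- function(model) {
  sm <- summary(model)$coefficients
  ci_lo <- sm[, "Estimate"] - stats::qt(0.975, sm[, "df"]) * sm[, "Std. Error"]
  ci_hi <- sm[, "Estimate"] + stats::qt(0.975, sm[, "df"]) * sm[, "Std. Error"]
  data.frame(Parameter = rownames(sm), Estimate = sm[, "Estimate"],
             SE = sm[, "Std. Error"], df = sm[, "df"],
             t = sm[, "t value"], p = sm[, "Pr(>|t|)"],
             CI_low = ci_lo, CI_high = ci_hi,
             row.names = NULL, stringsAsFactors = FALSE)
}

.term_p <- function(model, order_wanted) {
  sm <- summary(model)$coefficients
  terms <- rownames(sm)[rownames(sm) != "(Intercept)"]
  ord <- lengths(regmatches(terms, gregexpr(":", terms))) + 1L
  p <- sm[terms, "Pr(>|t|)"]
  data.frame(term = terms, order = ord, p = unname(p),
             stringsAsFactors = FALSE)[ord %in% order_wanted, , drop = FALSE]
}

.fit_lmer <- function(formula, data) {
  suppressMessages(lmerTest::lmer(formula, data = data, REML = TRUE))
}

#' Staged linear mixed model for group, age and time effects
#'
#' Fits the amplitude of one gated-in (deviant, component) response with
#' fixed effects clinical group x age group x time (all main effects plus all
#' two- and three-way interactions) and a random intercept per participant,
#' then prunes in stages: a non-significant three-way interaction is removed
#' and the model refitted; afterwards all non-significant two-way
#' interactions are removed and the model refitted. Main effects are never
#' pruned, and nothing is pruned while the three-way term is significant.
#' Restricted maximum likelihood with Satterthwaite degrees of freedom;
#' missing timepoints are handled by likelihood-based estimation rather than
#' listwise deletion. Estimates read CI-NH, preschooler-schoolchild and
#' T1-T2.
#'
#' @param amp_table Amplitude table (see [significance_table()]) with
#'   `subject_id`.
#' @param deviant,component Response to model.
#' @param alpha Pruning significance level.
#' @return A `model_result`: list with `fixed_effects` (Estimate, SE, df, t,
#'   p, 95% CI), `formula`, `pruning` history, `model` (the fitted object),
#'   `unstable` (singular-fit flag), `deviant`, `component`.
#' @export
fit_group_lmm <- function(amp_table, deviant, component, alpha = 0.05) {
  d <- amp_table[amp_table$deviant == deviant &
                   amp_table$component == component, ]
  if (nrow(d) == 0L) stop("no rows for ", deviant, " ", component)
  d <- .code_factors(d)

  pruning <- data.frame(stage = integer(), term = character(),
                        p = numeric(), action = character(),
                        stringsAsFactors = FALSE)
  f_full <- amplitude_uv ~ clinical_group * age_group * timepoint +
    (1 | subject_id)
  m <- .fit_lmer(f_full, d)
  f_final <- f_full

  p3 <- .term_p(m, 3L)
  if (nrow(p3) == 1L && p3$p >= alpha) {
    pruning <- rbind(pruning, data.frame(stage = 2L, term = p3$term,
                                         p = p3$p, action = "removed"))
    f2 <- amplitude_uv ~ (clinical_group + age_group + timepoint)^2 +
      (1 | subject_id)
    m <- .fit_lmer(f2, d)
    f_final <- f2

    p2 <- .term_p(m, 2L)
    drop2 <- p2$term[p2$p >= alpha]
    if (length(drop2) > 0L) {
      pruning <- rbind(pruning,
                       data.frame(stage = 3L, term = drop2,
                                  p = p2$p[p2$p >= alpha],
                                  action = "removed"))
      keep2 <- setdiff(c("clinical_group:age_group",
                         "clinical_group:timepoint",
                         "age_group:timepoint"),
                       .match_terms(drop2))
      rhs <- paste(c("clinical_group", "age_group", "timepoint", keep2),
                   collapse = " + ")
      f3 <- stats::as.formula(paste("amplitude_uv ~", rhs,
                                    "+ (1 | subject_id)"))
      m <- .fit_lmer(f3, d)
      f_final <- f3
    }
  } else if (nrow(p3) == 1L) {
    pruning <- rbind(pruning, data.frame(stage = 2L, term = p3$term,
                                         p = p3$p, action = "kept"))
  }

  structure(list(fixed_effects = .fixef_table(m),
                 formula = deparse1(f_final),
                 pruning = pruning, model = m,
                 unstable = lme4::isSingular(m),
                 deviant = deviant, component = component),
            class = "model_result")
}

# map coefficient-style interaction labels back to variable-level terms
.match_terms <- function(coef_terms) {
  base <- c(clinical_group = "clinical_group", age_group = "age_group",
            timepoint = "timepoint")
  vapply(coef_terms, function(tm) {
    parts <- strsplit(tm, ":")[[1]]
    vars <- vapply(parts, function(p) {
      hit <- names(base)[startsWith(p, names(base))]
      if (length(hit) != 1L) p else hit
    }, character(1))
    paste(vars, collapse = ":")
  }, character(1), USE.NAMES = FALSE)
}

#' Bonferroni-corrected post hoc contrasts of an interaction
#'
#' Simple-effect contrasts of a significant two-way interaction in a final
#' model: each factor's pairwise contrast within every level of the other,
#' with Bonferroni correction over that interaction's contrast family.
#'
#' @param result A `model_result` from [fit_group_lmm()].
#' @param interaction Interaction term, e.g. `"age_group:timepoint"`.
#' @return Data frame of contrasts with raw and Bonferroni-adjusted p-values.
#' @export
bonferroni_posthoc <- function(result, interaction) {
  vars <- strsplit(interaction, ":", fixed = TRUE)[[1]]
  stopifnot(length(vars) == 2L)
  in_model <- attr(stats::terms(stats::formula(result$model)), "term.labels")
  if (!any(.match_terms(in_model) == paste(vars, collapse = ":")) &&
      !any(.match_terms(in_model) == paste(rev(vars), collapse = ":"))) {
    stop("interaction ", interaction,
         " is not present in the final (pruned) model")
  }
  contrasts <- list()
  for (k in 1:2) {
    a <- vars[k]; b <- vars[-k]
    emm <- emmeans::emmeans(result$model, stats::as.formula(paste0("~ ", a,
                                                                   " | ", b)))
    cs <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "none"))
    cs$simple_effect <- a
    contrasts[[k]] <- cs
  }
  out <- do.call(rbind, contrasts)
  fam <- nrow(out)
  out$p_adj <- pmin(1, fam * out$p.value)
  rownames(out) <- NULL
  out
}

#' Combined singing score
#'
#' Averages the questionnaire responses from the two timepoints; when one is
#' missing the other is used (flagged via the `partial` attribute), and the
#' score is missing only when both are.
#'
#' @param q_t1,q_t2 Questionnaire responses (vectors recycle).
#' @return Numeric score(s) with attribute `partial`.
#' @export
singing_score <- function(q_t1, q_t2) {
  score <- rowMeans(cbind(q_t1, q_t2), na.rm = TRUE)
  score[is.na(q_t1) & is.na(q_t2)] <- NA_real_
  structure(score, partial = xor(is.na(q_t1), is.na(q_t2)))
}

#' Staged linear mixed model for singing effects in the CI group
#'
#' For one gated-in response in the combined CI group: fixed effects singing
#' score, time and their interaction, random intercept per participant; the
#' interaction is removed when not significant. Estimates for time read
#' T1-T2 and the singing slope is per questionnaire unit.
#'
#' @param amp_table_ci Amplitude table restricted to CI subjects, with a
#'   singing-score column.
#' @param deviant,component Response to model.
#' @param score Which score to use: `"parental"` or `"child"` (column
#'   `parental_singing` / `child_singing`).
#' @param alpha Pruning significance level.
#' @return A `model_result` (see [fit_group_lmm()]).
#' @export
fit_singing_lmm <- function(amp_table_ci, deviant, component,
                            score = c("parental", "child"), alpha = 0.05) {
  score <- match.arg(score)
  col <- paste0(score, "_singing")
  d <- amp_table_ci[amp_table_ci$deviant == deviant &
                      amp_table_ci$component == component, ]
  if (nrow(d) == 0L) stop("no rows for ", deviant, " ", component)
  if (any(d$clinical_group != "CI")) {
    stop("singing models are defined for the CI group only")
  }
  d$singing <- d[[col]]
  if (all(is.na(d$singing)) || stats::var(d$singing, na.rm = TRUE) == 0) {
    stop("singing score has no variance; the singing model is not estimable")
  }
  d <- .code_factors(d)

  pruning <- data.frame(stage = integer(), term = character(),
                        p = numeric(), action = character(),
                        stringsAsFactors = FALSE)
  f_full <- amplitude_uv ~ singing * timepoint + (1 | subject_id)
  m <- .fit_lmer(f_full, d)
  f_final <- f_full

  p2 <- .term_p(m, 2L)
  if (nrow(p2) == 1L && p2$p >= alpha) {
    pruning <- rbind(pruning, data.frame(stage = 2L, term = p2$term,
                                         p = p2$p, action = "removed"))
    f2 <- amplitude_uv ~ singing + timepoint + (1 | subject_id)
    m <- .fit_lmer(f2, d)
    f_final <- f2
  } else if (nrow(p2) == 1L) {
    pruning <- rbind(pruning, data.frame(stage = 2L, term = p2$term,
                                         p = p2$p, action = "kept"))
  }

  structure(list(fixed_effects = .fixef_table(m),
                 formula = deparse1(f_final),
                 pruning = pruning, model = m,
                 unstable = lme4::isSingular(m),
                 deviant = deviant, component = component,
                 score = score),
            class = "model_result")
}

#' Correlations among singing scores and age
#'
#' Pearson correlations (with p-values) between the two singing scores and
#' between each score and age at T1; used to decide whether age enters the
#' singing models as a covariate (it does not when the correlations are not
#' significant).
#'
#' @param parental,child,age_t1 Paired numeric vectors (n >= 3).
#' @return Data frame with one row per pair: `r`, `p`, `n`.
#' @export
correlate_singing_age <- function(parental, child, age_t1) {
  pairs <- list(parental_vs_child = cbind(parental, child),
                parental_vs_age = cbind(parental, age_t1),
                child_vs_age = cbind(child, age_t1))
  rows <- lapply(names(pairs), function(nm) {
    xy <- pairs[[nm]][stats::complete.cases(pairs[[nm]]), , drop = FALSE]
    if (nrow(xy) < 3L) stop("correlation needs at least 3 complete pairs")
    ct <- stats::cor.test(xy[, 1], xy[, 2])
    data.frame(pair = nm, r = unname(ct$estimate), p = ct$p.value,
               n = nrow(xy), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
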