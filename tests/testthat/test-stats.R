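test_that("one-sample t matches the closed form and handles symmetry", {
  sym <- c(-2, -1, 0, 1, 2)
  res <- one_sample_t(sym)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  # vector constructed with exactly the published cell moments:
  # n = 11, mean -4.08, SD 1.94 -> |t| = 4.08 / (1.94 / sqrt(11))
  set.seed(10)
  base <- rnorm(11)
  x <- -4.08 + 1.94 * as.vector(scale(base))
  res2 <- one_sample_t(x)
  expect_equal(res2$mean, -4.08)
  expect_equal(res2$sd, 1.94)
  expect_equal(abs(res2$t), 4.08 / (1.94 / sqrt(11)), tolerance = 1e-12)
  expect_equal(abs(res2$t), 6.9752, tolerance = 1e-4)
  expect_lt(res2$p, 0.001)

  expect_error(one_sample_t(c(1)), "at least 2")
})

test_that("t-test p agrees with an exact sign-flip enumeration oracle", {
  # enumeration over all 2^n sign assignments; tolerance reflects the
  # granularity of the exact distribution at small n
  sign_flip_p <- function(x) {
    n <- length(x)
    tobs <- abs(mean(x) / (sd(x) / sqrt(n)))
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    tperm <- apply(signs, 1, function(s) {
      y <- x * s
      abs(mean(y) / (sd(y) / sqrt(n)))
    })
    mean(tperm >= tobs - 1e-12)
  }
  set.seed(11)
  x5 <- rnorm(5, mean = 1)
  expect_lt(abs(one_sample_t(x5)$p - sign_flip_p(x5)), 0.15)
  x12 <- rnorm(12, mean = 0.7)
  expect_lt(abs(one_sample_t(x12)$p - sign_flip_p(x12)), 0.05)
})

test_that("significance table computes per-cell moments and polarity", {
  set.seed(12)
  tab <- expand.grid(clinical_group = c("CI", "NH"),
                     age_group = c("preschooler", "schoolchild"),
                     timepoint = c("T1", "T2"),
                     deviant = "gap", component = c("MMN", "P3a"),
                     rep = 1:8, stringsAsFactors = FALSE)
  tab$amplitude_uv <- ifelse(tab$component == "MMN", -2, 2) + rnorm(nrow(tab))
  sig <- significance_table(tab)
  expect_equal(nrow(sig), 16)
  expect_true(all(sig$n == 8))
  i <- which(sig$clinical_group == "CI" & sig$age_group == "preschooler" &
               sig$timepoint == "T1" & sig$component == "MMN")
  v <- tab$amplitude_uv[tab$clinical_group == "CI" &
                          tab$age_group == "preschooler" &
                          tab$timepoint == "T1" & tab$component == "MMN"]
  expect_equal(sig$mean[i], mean(v))
  expect_equal(abs(sig$t[i]), abs(mean(v)) / (sd(v) / sqrt(8)))
  expect_true(all(sig$polarity_correct[sig$component == "MMN" &
                                         sig$mean < 0]))
})

test_that("group gate reproduces exhaustive truth-table enumeration", {
  # all 2^8 significance patterns over the 8 group x age x time cells
  cells <- expand.grid(clinical_group = c("CI", "NH"),
                       age_group = c("preschooler", "schoolchild"),
                       timepoint = c("T1", "T2"), stringsAsFactors = FALSE)
  for (pattern in 0:255) {
    hit <- as.logical(bitwAnd(pattern, 2^(0:7)))
    sig <- data.frame(cells, deviant = "gap", component = "MMN",
                      significant = hit, polarity_correct = TRUE,
                      stringsAsFactors = FALSE)
    got <- gate_group_comparison(sig)$included
    want <- any(hit[cells$clinical_group == "CI"]) &&
      any(hit[cells$clinical_group == "NH"])
    expect_equal(got, want)
  }
  # polarity-incorrect significance does not open the gate
  sig_all <- data.frame(cells, deviant = "gap", component = "MMN",
                        significant = TRUE, polarity_correct = FALSE)
  expect_false(gate_group_comparison(sig_all)$included)
  expect_true(gate_group_comparison(sig_all,
                                    require_polarity = FALSE)$included)
})

test_that("singing gate enumerates its 2^2 timepoint patterns", {
  for (t1 in c(TRUE, FALSE)) {
    for (t2 in c(TRUE, FALSE)) {
      sig <- data.frame(clinical_group = "CI", timepoint = c("T1", "T2"),
                        deviant = "vowel", component = "pMMR",
                        significant = c(t1, t2), polarity_correct = TRUE,
                        stringsAsFactors = FALSE)
      expect_equal(gate_singing(sig)$included, t1 || t2)
    }
  }
})

test_that("singing scores average the two questionnaires, tolerate one missing", {
  expect_equal(as.numeric(singing_score(2, 4)), 3)
  expect_equal(as.numeric(singing_score(5, 5)), 5)
  expect_equal(as.numeric(singing_score(0, 5)), 2.5)
  s <- singing_score(c(3, NA, NA), c(NA, 4, NA))
  expect_equal(as.numeric(s), c(3, 4, NA))
  expect_equal(attr(s, "partial")[1:2], c(TRUE, TRUE))
})

test_that("group LMM recovers an injected group effect and prunes interactions", {
  tab <- simulate_amplitude_table(effects = list(intercept = -3,
                                                 group = 1.9),
                                  sd_subject = 1.2, sd_resid = 1.2,
                                  seed = 42)
  tab$deviant <- "gap"; tab$component <- "MMN"
  res <- fit_group_lmm(tab, "gap", "MMN")
  fe <- res$fixed_effects
  grp <- fe[fe$Parameter == "clinical_groupCI", ]
  expect_equal(nrow(grp), 1)
  # CI contains the injected effect and the estimate is in range
  expect_true(grp$CI_low < 1.9 && 1.9 < grp$CI_high)
  expect_lt(abs(grp$Estimate - 1.9), 1.5)
  # with no injected interactions the three-way term was considered & removed
  expect_true("removed" %in% res$pruning$action)
  expect_false(grepl(":.*:", paste(fe$Parameter, collapse = " ")))

  # a strong injected age x time interaction survives pruning
  tab2 <- simulate_amplitude_table(effects = list(age_time = 4),
                                   sd_subject = 0.8, sd_resid = 0.8,
                                   seed = 43)
  tab2$deviant <- "vowel"; tab2$component <- "pMMR"
  res2 <- fit_group_lmm(tab2, "vowel", "pMMR")
  expect_true(any(grepl("age_grouppreschooler:timepointT1",
                        res2$fixed_effects$Parameter)))
  # pruning history: 3-way first (stage 2), then 2-ways (stage 3)
  expect_true(all(res2$pruning$stage[res2$pruning$action == "removed"] %in%
                    2:3))
  # main effects are always present
  expect_true(all(c("clinical_groupCI", "age_grouppreschooler",
                    "timepointT1") %in% res2$fixed_effects$Parameter))
})

test_that("model estimates carry consistent confidence intervals", {
  tab <- simulate_amplitude_table(effects = list(group = 1), seed = 7)
  tab$deviant <- "gap"; tab$component <- "MMN"
  res <- fit_group_lmm(tab, "gap", "MMN")
  fe <- res$fixed_effects
  expect_true(all(fe$CI_low < fe$Estimate & fe$Estimate < fe$CI_high))
  expect_equal(fe$t, fe$Estimate / fe$SE, tolerance = 1e-10)
})

test_that("Bonferroni post hocs: four simple effects, adjusted p rules", {
  tab <- simulate_amplitude_table(effects = list(age_time = 4),
                                  sd_subject = 0.5, sd_resid = 0.5,
                                  seed = 44)
  tab$deviant <- "vowel"; tab$component <- "pMMR"
  res <- fit_group_lmm(tab, "vowel", "pMMR")
  ph <- bonferroni_posthoc(res, "age_group:timepoint")
  expect_equal(nrow(ph), 4)   # 2 contrasts per factor within the other
  expect_equal(ph$p_adj, pmin(1, 4 * ph$p.value))
  expect_true(all(ph$p_adj >= ph$p.value))
  expect_error(bonferroni_posthoc(res, "clinical_group:age_group"),
               "not present")

  # contrast estimates equal cell-mean differences on a balanced, nearly
  # noiseless table
  tab0 <- simulate_amplitude_table(
    n_per_cell = c(ci_preschooler = 6, nh_preschooler = 6,
                   ci_schoolchild = 6, nh_schoolchild = 6),
    effects = list(age_time = 2), sd_subject = 1e-3, sd_resid = 1e-3,
    seed = 45)
  tab0$deviant <- "vowel"; tab0$component <- "pMMR"
  res0 <- suppressMessages(fit_group_lmm(tab0, "vowel", "pMMR"))
  ph0 <- bonferroni_posthoc(res0, "age_group:timepoint")
  cm <- aggregate(amplitude_uv ~ age_group + timepoint, tab0, mean)
  want <- cm$amplitude_uv[cm$age_group == "schoolchild" &
                            cm$timepoint == "T2"] -
    cm$amplitude_uv[cm$age_group == "preschooler" & cm$timepoint == "T2"]
  got <- ph0$estimate[ph0$simple_effect == "age_group" &
                        grepl("T2", ph0$timepoint)]
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("singing LMM recovers an injected singing x time slope", {
  ci_cells <- c(ci_preschooler = 11, nh_preschooler = 2,
                ci_schoolchild = 10, nh_schoolchild = 2)
  tab <- simulate_amplitude_table(n_per_cell = ci_cells,
                                  effects = list(singing_time = -1.1),
                                  sd_subject = 1.0, sd_resid = 1.0,
                                  seed = 46)
  tab <- tab[tab$clinical_group == "CI", ]
  tab$deviant <- "vowel"; tab$component <- "pMMR"
  res <- fit_singing_lmm(tab, "vowel", "pMMR", score = "parental")
  fe <- res$fixed_effects
  ix <- fe[fe$Parameter == "singing:timepointT1", ]
  expect_equal(nrow(ix), 1)              # interaction retained
  expect_lt(ix$Estimate, 0)              # sign recovered
  expect_true(ix$CI_low < -1.1 && -1.1 < ix$CI_high)

  # degenerate covariate: no variance -> explicit error
  tab$parental_singing <- 3
  expect_error(fit_singing_lmm(tab, "vowel", "pMMR", score = "parental"),
               "no variance")
})

test_that("correlation report covers the three score/age pairs", {
  x <- c(1, 2, 3, 4, 5)
  rep1 <- correlate_singing_age(x, x, rev(x))
  expect_equal(rep1$r[rep1$pair == "parental_vs_child"], 1)
  expect_equal(rep1$r[rep1$pair == "parental_vs_age"], -1)

  set.seed(13)
  n <- 60
  rep2 <- correlate_singing_age(runif(n), runif(n), runif(n, 4, 13))
  expect_true(all(abs(rep2$r) < 0.5))
  expect_error(correlate_singing_age(1:2, 1:2, 1:2), "at least 3")
})
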