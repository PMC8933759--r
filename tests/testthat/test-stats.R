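# Each routine is checked against the frozen hand-computed example from
# its closed form and against the corresponding stats:: oracle on random
# inputs.

test_that("paired_t matches the closed form and the t.test oracle", {
  # d = (1, 2, 3): t = 2 / (1/sqrt(3)) = 3.4641, df = 2
  got <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(got$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(got$t, 3.4641016, tolerance = 1e-6)
  expect_equal(got$df, 2)

  set.seed(41)
  for (rep in 1:30) {
    n <- sample(3:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- paired_t(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    # identical to one-sample t on differences
    ref1 <- t.test(x - y)
    expect_equal(got$p, ref1$p.value, tolerance = 1e-12)
  }

  # NA pairs dropped
  expect_equal(paired_t(c(1, NA, 3, 5), c(0, 1, NA, 2))$n, 2)
  # degenerate inputs refuse to return p = 0 or 1
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)),
               class = "hemifc_error_degenerate")
  expect_error(paired_t(1, 1), class = "hemifc_error_stat_input")
  expect_error(paired_t(1:3, 1:4), class = "hemifc_error_stat_input")
})

test_that("anova_oneway matches the closed form and the aov oracle", {
  got <- anova_oneway(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(got$F, 13.5, tolerance = 1e-12)   # SSB=13.5, MSW=1
  expect_equal(c(got$df_between, got$df_within), c(1, 4))

  set.seed(42)
  for (rep in 1:30) {
    k <- sample(2:4, 1)
    vals <- lapply(seq_len(k), function(i) rnorm(sample(3:10, 1), mean = i / 2))
    names(vals) <- paste0("g", seq_len(k))
    got <- anova_oneway(vals)
    df <- data.frame(y = unlist(vals),
                     g = rep(names(vals), lengths(vals)))
    ref <- summary(aov(y ~ g, df))[[1]]
    expect_equal(got$F, ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(got$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  }

  # two-group F equals the squared pooled t
  x <- rnorm(8); y <- rnorm(9, 1)
  got <- anova_oneway(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(got$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(got$p, tt$p.value, tolerance = 1e-10)

  expect_error(anova_oneway(list(a = 1:3)), class = "hemifc_error_stat_input")
  expect_error(anova_oneway(list(a = c(1, 1), b = c(1, 1))),
               class = "hemifc_error_degenerate")
})

test_that("bonferroni_posthoc uses pooled MSW and caps adjusted p at 1", {
  set.seed(43)
  vals <- list(a = rnorm(6), b = rnorm(7, 0.5), c = rnorm(5, 1))
  ph <- bonferroni_posthoc(vals)
  expect_equal(nrow(ph), 3)                      # 3 groups -> 3 pairs
  expect_true(all(ph$p_bonferroni >= ph$p_raw))  # monotone
  expect_true(all(ph$p_bonferroni <= 1))
  expect_equal(ph$p_bonferroni, pmin(1, ph$p_raw * 3))

  # manual pooled-variance check for one pair
  a <- anova_oneway(vals)
  i <- which(ph$group_a == "a" & ph$group_b == "b")
  se <- sqrt(a$msw * (1 / 6 + 1 / 7))
  expect_equal(ph$t[i], (mean(vals$a) - mean(vals$b)) / se, tolerance = 1e-12)
  expect_equal(ph$df[i], a$df_within)

  # raw p = 0.02 with 3 pairs -> 0.06 by definition
  expect_equal(min(1, 0.02 * 3), 0.06)
  # ANOVA + Bonferroni on 2 groups reproduces the two-sample t decision
  two <- bonferroni_posthoc(vals[1:2])
  tt <- t.test(vals$a, vals$b, var.equal = TRUE)
  expect_equal(two$p_bonferroni, tt$p.value, tolerance = 1e-10)
})

test_that("bh_fdr reproduces the step-up rule, p.adjust, and the brute force", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)

  set.seed(44)
  for (rep in 1:30) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), unname(p.adjust(p, method = "BH")),
                 tolerance = 1e-12)
    expect_equal(bh_fdr(p), ref_bh_q(p), tolerance = 1e-12)
  }

  # NA passthrough keeps order and excludes NAs from m
  p <- c(0.02, NA, 0.04)
  q <- bh_fdr(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], unname(p.adjust(c(0.02, 0.04), "BH")))

  # raising one p never lowers any q
  set.seed(45)
  p <- runif(10)
  q0 <- bh_fdr(p)
  for (i in c(2, 7)) {
    p2 <- p; p2[i] <- min(1, p[i] + 0.3)
    expect_true(all(bh_fdr(p2) >= q0 - 1e-12))
  }

  expect_error(bh_fdr(c(0.5, 1.2)), class = "hemifc_error_stat_input")
})

test_that("clinical_correlation matches cor.test and handles boundaries", {
  expect_equal(clinical_correlation(c(1, 2, 3), c(6, 4, 2))$r, -1)
  perf <- clinical_correlation(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(perf$r, 1)
  expect_equal(perf$p, 0)   # boundary guarded, not NaN

  set.seed(46)
  for (rep in 1:30) {
    n <- sample(5:50, 1)
    x <- rnorm(n); y <- 0.3 * x + rnorm(n)
    got <- clinical_correlation(x, y)
    ref <- cor.test(x, y)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }

  expect_error(clinical_correlation(rep(1, 5), rnorm(5)),
               class = "hemifc_error_degenerate")
  expect_error(clinical_correlation(1:2, 1:2), class = "hemifc_error_stat_input")
})

test_that("mann_whitney_u matches wilcox.test in both regimes", {
  # full separation: U = 0 under the first-sample-wins convention
  got <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$U, 0)
  expect_equal(got$method, "exact")
  ref <- wilcox.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)

  set.seed(47)
  for (rep in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), 0.5)
    got <- mann_whitney_u(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
  for (rep in 1:20) {
    x <- rnorm(12); y <- rnorm(15, 0.3)
    got <- mann_whitney_u(x, y)
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(got$method, "normal")
    expect_equal(got$p, ref$p.value, tolerance = 1e-8)
  }
  # ties force the normal path and match the tie-corrected oracle
  x <- c(1, 2, 2, 3, 5, 5, 8, 9, 10); y <- c(2, 3, 3, 4, 5, 7, 7, 8, 11)
  got <- mann_whitney_u(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(got$p, ref$p.value, tolerance = 1e-8)
})

test_that("chisq_independence matches chisq.test without correction", {
  expect_equal(suppressWarnings(
    chisq_independence(matrix(c(10, 10, 10, 10), 2)))$chisq, 0)

  set.seed(48)
  for (rep in 1:20) {
    tab <- matrix(rpois(6, 20) + 1, 3, 2)
    got <- suppressWarnings(chisq_independence(tab))
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(got$chisq, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  expect_warning(chisq_independence(matrix(c(2, 3, 1, 2), 2)),
                 class = "hemifc_warning_small_cells")
  expect_error(chisq_independence(matrix(c(0, 0, 5, 5), 2)),
               class = "hemifc_error_degenerate")
})

test_that("demographics runs the stated battery on a simulated manifest", {
  d <- cohort_design(groups = c(LMTLE = 10, RMTLE = 10, HC = 12),
                     n_timepoints = 10, cross_correlation = 0.3,
                     random_seed = 77)
  ch <- simulate_cohort(d, demo_atlas(2))
  dem <- demographics(ch$manifest)
  expect_setequal(dem$variable, c("age", "sex", "onset_age", "duration"))
  expect_setequal(dem$test, c("anova", "chisq", "mann_whitney"))
  expect_true(all(dem$p >= 0 & dem$p <= 1))
})

test_that("lateralization_table and tally wiring behave as specified", {
  at <- demo_atlas(3)
  d <- cohort_design(groups = c(HC = 8, LMTLE = 6), n_timepoints = 50,
                     cross_correlation = 0.3, random_seed = 55)
  prof <- profile_cohort(connect_cohort(simulate_cohort(d, at), at), at)
  lat <- lateralization_table(prof)
  expect_equal(nrow(lat), 2 * 6)               # per group x per lateral ROI
  expect_equal(unique(lat$df), unique(lat$n) - 1)
  # q-values recomputable within each group family
  for (g in unique(lat$group)) {
    sub <- lat[lat$group == g, ]
    expect_equal(sub$q_fdr, bh_fdr(sub$p))
  }
  # direction consistent with means and significance
  sig <- !is.na(lat$q_fdr) & lat$q_fdr < 0.05
  expect_true(all(lat$direction[!sig] == "none"))
  expect_true(all(lat$direction[sig & lat$mean_rFC > lat$mean_lFC] == "rightward"))

  # subject order does not matter
  prof_rev <- prof[rev(seq_len(nrow(prof))), ]
  class(prof_rev) <- class(prof)
  lat2 <- lateralization_table(prof_rev)
  key <- function(df) df[order(df$group, df$roi_id), ]
  expect_equal(key(as.data.frame(lat2)), key(as.data.frame(lat)),
               ignore_attr = TRUE)
})

test_that("ai_group_table wires ANOVA, FDR and post hocs per ROI", {
  at <- demo_atlas(2)
  d <- cohort_design(groups = c(HC = 6, LMTLE = 6, RMTLE = 6),
                     n_timepoints = 60, cross_correlation = 0.3,
                     random_seed = 56)
  prof <- profile_cohort(connect_cohort(simulate_cohort(d, at), at), at)
  tab <- ai_group_table(prof)
  expect_equal(nrow(tab), 4)
  expect_equal(unique(tab$df_between), 2)
  expect_equal(tab$q_fdr, bh_fdr(tab$p))
  expect_true(all(c("HC_vs_LMTLE_p_bonf", "HC_vs_RMTLE_p_bonf",
                    "LMTLE_vs_RMTLE_p_bonf") %in% names(tab)))
  # post hoc p recomputable from the raw AI values
  sl <- prof[prof$roi_id == "L_r1", ]
  ph <- bonferroni_posthoc(split(sl$AI, sl$group)[c("HC", "LMTLE", "RMTLE")])
  i <- which(ph$group_a == "HC" & ph$group_b == "LMTLE")
  expect_equal(tab$HC_vs_LMTLE_p_bonf[tab$roi_id == "L_r1"],
               ph$p_bonferroni[i], tolerance = 1e-12)
})

test_that("clinical_correlation_table uses one FDR family over all pairs", {
  set.seed(57)
  feats <- data.frame(f1 = rnorm(20), f2 = rnorm(20))
  clin <- data.frame(onset = rnorm(20), duration = rnorm(20))
  tab <- clinical_correlation_table(feats, clin)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$q_fdr, bh_fdr(tab$p))
})
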