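# Hypothesis-testing machinery: paired-t lateralization, between-group AI
# ANOVA with Bonferroni post hocs, clinical correlations, demographic
# tests, and Benjamini-Hochberg FDR. Implemented from the closed forms so
# every routine can be checked against an independent oracle.

#' Paired t-test
#'
#' Classical paired t on the differences `d = x - y`: `t = mean(d) /
#' (sd(d) / sqrt(n))`, two-sided p from Student t with `n - 1` degrees of
#' freedom. Pairs with a missing value in either member are dropped.
#'
#' @param x,y equal-length numeric vectors of paired observations.
#' @return list with `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
#' @examples
#' paired_t(c(2, 4, 6), c(1, 2, 3))
paired_t <- function(x, y) {
  if (length(x) != length(y)) {
    hemifc_stop("hemifc_error_stat_input", "x and y must have equal length")
  }
  ok <- stats::complete.cases(x, y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 2) {
    hemifc_stop("hemifc_error_stat_input",
                sprintf("need >= 2 complete pairs, got %d", n))
  }
  s <- stats::sd(d)
  if (s == 0) {
    hemifc_stop("hemifc_error_degenerate",
                "zero-variance differences: paired t undefined")
  }
  tval <- mean(d) / (s / sqrt(n))
  list(t = tval, df = n - 1, p = 2 * stats::pt(-abs(tval), n - 1),
       mean_diff = mean(d), n = n)
}

#' One-way ANOVA
#'
#' Classical between/within mean-square ratio across >= 2 groups.
#'
#' @param values_by_group named list of numeric vectors (missing values
#'   dropped per group).
#' @return list with `F`, `df_between`, `df_within`, `p`.
#' @export
#' @examples
#' anova_oneway(list(a = c(1, 2, 3), b = c(4, 5, 6)))
anova_oneway <- function(values_by_group) {
  values_by_group <- lapply(values_by_group, function(v) v[!is.na(v)])
  values_by_group <- values_by_group[vapply(values_by_group, length, 1L) > 0]
  k <- length(values_by_group)
  ns <- vapply(values_by_group, length, 1L)
  if (k < 2 || any(ns < 2)) {
    hemifc_stop("hemifc_error_stat_input",
                "need >= 2 groups with >= 2 values each")
  }
  all_v <- unlist(values_by_group, use.names = FALSE)
  if (stats::var(all_v) == 0) {
    hemifc_stop("hemifc_error_degenerate", "all values identical: F undefined")
  }
  gm <- mean(all_v)
  means <- vapply(values_by_group, mean, numeric(1))
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum(vapply(values_by_group,
                    function(v) sum((v - mean(v))^2), numeric(1)))
  df_b <- k - 1
  df_w <- sum(ns) - k
  Fv <- (ssb / df_b) / (ssw / df_w)
  list(F = Fv, df_between = df_b, df_within = df_w,
       p = stats::pf(Fv, df_b, df_w, lower.tail = FALSE),
       msw = ssw / df_w)
}

#' Bonferroni-corrected pairwise post hocs
#'
#' Pairwise two-sample t-tests following a one-way ANOVA, using the pooled
#' within-group mean square (and its degrees of freedom) from the omnibus
#' fit — the classical post hoc convention — with raw p multiplied by the
#' number of pairs, capped at 1. `welch = TRUE` switches to per-pair Welch
#' tests (still Bonferroni-scaled).
#'
#' @inheritParams anova_oneway
#' @param pairs optional list of 2-element character vectors; default all
#'   unordered group pairs.
#' @param welch use per-pair Welch variances instead of pooled MSW.
#' @return data frame: group_a, group_b, mean_diff, t, df, p_raw,
#'   p_bonferroni.
#' @export
bonferroni_posthoc <- function(values_by_group, pairs = NULL, welch = FALSE) {
  values_by_group <- lapply(values_by_group, function(v) v[!is.na(v)])
  a <- anova_oneway(values_by_group) # validates input, supplies pooled MSW
  labs <- names(values_by_group)
  if (is.null(pairs)) {
    pairs <- utils::combn(labs, 2, simplify = FALSE)
  }
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    x <- values_by_group[[pr[1]]]; y <- values_by_group[[pr[2]]]
    diff <- mean(x) - mean(y)
    if (welch) {
      se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
      df <- se^4 / ((stats::var(x) / length(x))^2 / (length(x) - 1) +
                      (stats::var(y) / length(y))^2 / (length(y) - 1))
    } else {
      se <- sqrt(a$msw * (1 / length(x) + 1 / length(y)))
      df <- a$df_within
    }
    tval <- diff / se
    praw <- 2 * stats::pt(-abs(tval), df)
    data.frame(group_a = pr[1], group_b = pr[2], mean_diff = diff,
               t = tval, df = df, p_raw = praw,
               p_bonferroni = min(1, praw * m), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg FDR q-values
#'
#' Step-up q-values `q(i) = min_{j >= i} p(j) * m / j` over the `m`
#' non-missing p-values, returned in the input order. Missing entries pass
#' through as missing and do not count toward `m`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return q-values, same length and order as the input.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(pvals) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (any(p < 0 | p > 1)) {
    hemifc_stop("hemifc_error_stat_input", "p-values must lie in [0, 1]")
  }
  m <- length(p)
  q <- rep(NA_real_, length(pvals))
  if (m > 0) {
    o <- order(p)
    qo <- p[o] * m / seq_len(m)
    qo <- rev(cummin(rev(qo)))     # enforce step-up monotonicity
    qo <- pmin(qo, 1)
    qq <- numeric(m)
    qq[o] <- qo
    q[ok] <- qq
  }
  q
}

#' Pearson correlation with a clinical covariate
#'
#' Pearson r with a two-sided p from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`. Incomplete pairs are dropped;
#' perfectly (anti)linear input is allowed and yields `p = 0` at the
#' boundary rather than NaN.
#'
#' @param feature_values,clinical numeric vectors of equal length.
#' @return list with `r`, `n`, `p`.
#' @export
clinical_correlation <- function(feature_values, clinical) {
  if (length(feature_values) != length(clinical)) {
    hemifc_stop("hemifc_error_stat_input", "inputs must have equal length")
  }
  ok <- stats::complete.cases(feature_values, clinical)
  x <- feature_values[ok]; y <- clinical[ok]
  n <- length(x)
  if (n < 3) {
    hemifc_stop("hemifc_error_stat_input",
                sprintf("need >= 3 complete pairs, got %d", n))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    hemifc_stop("hemifc_error_degenerate", "constant input vector")
  }
  r <- stats::cor(x, y)
  r2 <- min(r^2, 1)
  if (1 - r2 <= .Machine$double.eps) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  list(r = r, n = n, p = p)
}

#' Mann-Whitney U test
#'
#' `U` counts pairs where the first sample exceeds the second (ties count
#' one half). Exact p by enumeration of the U null distribution when both
#' groups have <= 8 observations and no ties are present; otherwise the
#' normal approximation with tie correction.
#'
#' @param x,y numeric samples.
#' @return list with `U`, `p`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) {
    hemifc_stop("hemifc_error_stat_input", "both samples must be non-empty")
  }
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (n1 <= 8 && n2 <= 8 && !ties) {
    # exact: null distribution of U by the standard recursion
    counts <- u_null_counts(n1, n2)
    total <- sum(counts)
    u_obs <- U
    # two-sided: double the smaller tail (U is symmetric about n1*n2/2)
    lower <- sum(counts[seq_len(u_obs + 1)]) / total
    upper <- sum(counts[(u_obs + 1):length(counts)]) / total
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(c(x, y))
    n <- n1 + n2
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tie_term))
    zval <- (U - mu - sign(U - mu) * 0.5) / sigma
    if (U == mu) zval <- 0
    p <- 2 * stats::pnorm(-abs(zval))
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}

# Number of arrangements giving each U value 0..n1*n2 (no ties).
# C(i, j) = distribution with i sample-1 and j sample-2 values; removing
# the overall maximum gives C(i, j) = shift(C(i-1, j), j) + C(i, j-1).
u_null_counts <- function(n1, n2) {
  maxU <- n1 * n2
  C <- vector("list", n1 + 1)
  for (i in 0:n1) C[[i + 1]] <- vector("list", n2 + 1)
  for (i in 0:n1) {
    for (j in 0:n2) {
      if (i == 0 || j == 0) {
        v <- numeric(maxU + 1)
        v[1] <- 1
      } else {
        a <- C[[i]][[j + 1]]
        v <- numeric(maxU + 1)
        v[(j + 1):(maxU + 1)] <- a[1:(maxU + 1 - j)]
        v <- v + C[[i + 1]][[j]]
      }
      C[[i + 1]][[j + 1]] <- v
    }
  }
  C[[n1 + 1]][[n2 + 1]]
}

#' Pearson chi-square test of independence
#'
#' No continuity correction (any table size). Cells expected under
#' independence; a warning condition is signalled when any expected count
#' is below 5.
#'
#' @param tab a contingency table (matrix).
#' @return list with `chisq`, `df`, `p`.
#' @export
chisq_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || sum(tab) == 0) {
    hemifc_stop("hemifc_error_stat_input", "counts must be non-negative, non-empty")
  }
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts == 0)) {
    hemifc_stop("hemifc_error_degenerate",
                "empty marginal: chi-square undefined")
  }
  if (any(exp_counts < 5)) {
    hemifc_warn("hemifc_warning_small_cells",
                "expected counts < 5; chi-square approximation is rough")
  }
  chisq <- sum((tab - exp_counts)^2 / exp_counts)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Within-group lateralization table
#'
#' For each group and ROI, a paired t-test of rFC against lFC across the
#' group's subjects, with BH-FDR q-values computed within each group
#' across its ROIs. Subjects whose AI is undefined for an ROI are dropped
#' for that ROI (counts kept in `n_dropped`). ROIs with fewer than 2
#' usable subjects or zero-variance differences are reported with missing
#' statistics rather than dropped silently.
#'
#' @param profiles an `asymmetry_profile` from [profile_cohort()].
#' @param alpha significance level for the direction call (default 0.05).
#' @return data frame: group, roi_id, n, n_dropped, mean_rFC, mean_lFC,
#'   t_stat, df, p, q_fdr, direction.
#' @export
lateralization_table <- function(profiles, alpha = 0.05) {
  out <- list()
  for (g in unique(profiles$group)) {
    sub <- profiles[profiles$group == g, , drop = FALSE]
    rois <- unique(sub$roi_id)
    rows <- lapply(rois, function(roi) {
      sl <- sub[sub$roi_id == roi, , drop = FALSE]
      ok <- !is.na(sl$AI)
      n_drop <- sum(!ok)
      sl <- sl[ok, , drop = FALSE]
      row <- data.frame(group = g, roi_id = roi, n = nrow(sl),
                        n_dropped = n_drop,
                        mean_rFC = mean(sl$rFC), mean_lFC = mean(sl$lFC),
                        t_stat = NA_real_, df = NA_integer_, p = NA_real_,
                        q_fdr = NA_real_, direction = "none",
                        stringsAsFactors = FALSE)
      fit <- tryCatch(paired_t(sl$rFC, sl$lFC), hemifc_error = function(e) NULL)
      if (!is.null(fit)) {
        row$t_stat <- fit$t; row$df <- fit$df; row$p <- fit$p
      }
      row
    })
    tab <- do.call(rbind, rows)
    tab$q_fdr <- bh_fdr(tab$p)
    sig <- !is.na(tab$q_fdr) & tab$q_fdr < alpha
    tab$direction <- ifelse(sig & tab$mean_rFC > tab$mean_lFC, "rightward",
                            ifelse(sig & tab$mean_rFC < tab$mean_lFC,
                                   "leftward", "none"))
    out[[g]] <- tab
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "alpha") <- alpha
  class(res) <- c("lateralization_table", "data.frame")
  res
}

#' Between-group AI comparison table
#'
#' For each ROI, a one-way ANOVA of AI across groups with BH-FDR across
#' ROIs, plus Bonferroni pairwise post hocs giving the direction of the
#' differences. Undefined AI values are dropped listwise per ROI.
#'
#' @inheritParams lateralization_table
#' @return data frame: roi_id, F_stat, df_between, df_within, p, q_fdr,
#'   plus one `<A>_vs_<B>_p_bonf` / `<A>_vs_<B>_diff` column pair per
#'   group pair.
#' @export
ai_group_table <- function(profiles, alpha = 0.05) {
  rois <- unique(profiles$roi_id)
  groups <- unique(profiles$group)
  rows <- lapply(rois, function(roi) {
    sl <- profiles[profiles$roi_id == roi, , drop = FALSE]
    byg <- split(sl$AI, sl$group)[groups]
    row <- data.frame(roi_id = roi, F_stat = NA_real_,
                      df_between = NA_integer_, df_within = NA_integer_,
                      p = NA_real_, q_fdr = NA_real_, stringsAsFactors = FALSE)
    fit <- tryCatch(anova_oneway(byg), hemifc_error = function(e) NULL)
    if (!is.null(fit)) {
      row$F_stat <- fit$F
      row$df_between <- fit$df_between
      row$df_within <- fit$df_within
      row$p <- fit$p
      ph <- bonferroni_posthoc(byg)
      for (i in seq_len(nrow(ph))) {
        key <- paste0(ph$group_a[i], "_vs_", ph$group_b[i])
        row[[paste0(key, "_diff")]] <- ph$mean_diff[i]
        row[[paste0(key, "_p_bonf")]] <- ph$p_bonferroni[i]
      }
    }
    row
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res$q_fdr <- bh_fdr(res$p)
  attr(res, "alpha") <- alpha
  class(res) <- c("ai_group_table", "data.frame")
  res
}

#' Clinical correlation screen
#'
#' Pearson correlation of each feature column against each clinical
#' covariate, with one BH-FDR family across all tested (feature,
#' covariate) pairs.
#'
#' @param features data frame (or matrix) of per-subject feature values.
#' @param clinical data frame of per-subject clinical covariates.
#' @return data frame: feature, covariate, n, r, p, q_fdr.
#' @export
clinical_correlation_table <- function(features, clinical) {
  features <- as.data.frame(features)
  clinical <- as.data.frame(clinical)
  rows <- list()
  for (f in names(features)) {
    for (cv in names(clinical)) {
      fit <- tryCatch(clinical_correlation(features[[f]], clinical[[cv]]),
                      hemifc_error = function(e) NULL)
      rows[[paste(f, cv)]] <- data.frame(
        feature = f, covariate = cv,
        n = if (is.null(fit)) NA_integer_ else fit$n,
        r = if (is.null(fit)) NA_real_ else fit$r,
        p = if (is.null(fit)) NA_real_ else fit$p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res$q_fdr <- bh_fdr(res$p)
  res
}

#' Demographic comparability tests
#'
#' One-way ANOVA on age across all groups, chi-square (no continuity
#' correction) on the sex-by-group table, and Mann-Whitney U tests on
#' onset age and epilepsy duration between the two patient groups.
#'
#' @param manifest data frame with columns subject_id, group, age, sex,
#'   onset_age, duration (as produced by [simulate_cohort()]).
#' @return data frame: variable, test, statistic, p.
#' @export
demographics <- function(manifest) {
  rows <- list()
  age_fit <- anova_oneway(split(manifest$age, manifest$group))
  rows$age <- data.frame(variable = "age", test = "anova",
                         statistic = age_fit$F, p = age_fit$p)
  sex_tab <- table(manifest$group, manifest$sex)
  sex_fit <- withCallingHandlers(
    chisq_independence(sex_tab),
    hemifc_warning = function(w) invokeRestart("muffleWarning"))
  rows$sex <- data.frame(variable = "sex", test = "chisq",
                         statistic = sex_fit$chisq, p = sex_fit$p)
  pat <- manifest[manifest$group %in% c("LMTLE", "RMTLE"), , drop = FALSE]
  if (length(unique(pat$group)) == 2) {
    for (v in c("onset_age", "duration")) {
      fit <- mann_whitney_u(pat[[v]][pat$group == "LMTLE"],
                            pat[[v]][pat$group == "RMTLE"])
      rows[[v]] <- data.frame(variable = v, test = "mann_whitney",
                              statistic = fit$U, p = fit$p)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
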