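# Subject-level ROI-to-ROI connectivity and the edge-wise between-group
# comparison.

#' Compute a subject's connectivity matrix
#'
#' Pearson correlation between the time course of every ROI and every
#' other ROI, plus the Fisher z-transform used for parametric group
#' statistics. Correlations are clamped to +/-(1 - 1e-12) before `atanh`;
#' the z diagonal is stored as 0 and never used.
#'
#' @param ts a `subject_ts` (see [simulate_cohort()]) or a plain numeric
#'   matrix, timepoints x ROIs with roi_id column names.
#' @param atlas a [roi_atlas]; columns must match `atlas$roi_id` exactly.
#' @return a `connectivity_matrix`: list with `subject_id`, `group`, `r`,
#'   `z`, `roi_order`.
#' @export
#' @examples
#' at <- demo_atlas(2)
#' set.seed(1)
#' m <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, at$roi_id))
#' cm <- compute_connectivity(m, at)
#' cm$r[1, 2]
compute_connectivity <- function(ts, atlas) {
  stopifnot(inherits(atlas, "roi_atlas"))
  if (inherits(ts, "subject_ts")) {
    data <- ts$data
    sid <- ts$subject_id
    grp <- ts$group
  } else {
    data <- as.matrix(ts)
    sid <- "subject"
    grp <- NA_character_
  }
  if (is.null(colnames(data)) || !identical(colnames(data), atlas$roi_id)) {
    hemifc_stop("hemifc_error_roi_mismatch",
                "time-series columns do not match atlas roi_ids (same set, same order required)")
  }
  if (nrow(data) < 3) {
    hemifc_stop("hemifc_error_too_short",
                sprintf("need >= 3 timepoints, got %d", nrow(data)))
  }
  sds <- apply(data, 2, stats::sd)
  if (any(sds == 0)) {
    hemifc_stop("hemifc_error_zero_variance",
                paste0("zero-variance ROI column(s): ",
                       paste(colnames(data)[sds == 0], collapse = ", ")))
  }
  r <- stats::cor(data)
  r <- pmin(pmax(r, -1), 1)
  z <- fisher_z(r)
  diag(z) <- 0
  structure(list(subject_id = sid, group = grp, r = r, z = z,
                 roi_order = atlas$roi_id),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("Connectivity matrix for %s (%s): %d x %d ROIs\n",
              x$subject_id, x$group, nrow(x$r), ncol(x$r)))
  invisible(x)
}

#' Compute connectivity for every subject of a cohort
#'
#' @param cohort an `fc_cohort`.
#' @param atlas a [roi_atlas].
#' @return named list of `connectivity_matrix`, one per subject.
#' @export
connect_cohort <- function(cohort, atlas) {
  lapply(cohort$subjects, compute_connectivity, atlas = atlas)
}

#' Split connectivity matrices by group label
#'
#' @param conns list of `connectivity_matrix` objects carrying `group`.
#' @return named list of lists, one per group, ready for [compare_edges()].
#' @export
split_by_group <- function(conns) {
  split(conns, vapply(conns, `[[`, character(1), "group"))
}

#' Edge-wise between-group comparison
#'
#' For every unordered ROI pair, a two-sample t-test on the Fisher z
#' values between the two groups of the contrast (pooled-variance Student
#' t by default, mirroring a classical second-level GLM contrast; Welch by
#' flag). Significance uses a two-level rule: an edge must pass the
#' uncorrected height threshold (`p_unc < height_p`) *and* survive
#' Benjamini-Hochberg FDR within its seed ROI's family (`q_fdr < fdr_q`).
#' With the default `fdr_scope = "seed"` the BH family is all edges
#' incident to the seed -- the seed-level analogue of cluster-extent
#' correction, which keeps the falsely-significant-seed rate controlled
#' near `fdr_q` under the null. `"seed_candidates"` restricts the family
#' to the seed's height-thresholded candidates (a more liberal literal
#' two-step: a lone candidate is judged only against itself);
#' `"matrix"` runs one BH pass over all edges. Every pair belongs to two
#' seed families (one per endpoint); the reported `q_fdr` is the smaller
#' of the two, so `significant` means "significant in at least one
#' family".
#'
#' @param matrices_by_group named list (group label -> list of
#'   `connectivity_matrix`).
#' @param contrast character vector of two group labels; the difference is
#'   `mean(first) - mean(second)`.
#' @param height_p uncorrected height threshold (default 0.01).
#' @param fdr_q FDR threshold at the seed level (default 0.05).
#' @param var_equal pooled-variance Student t (default) or Welch.
#' @param fdr_scope `"seed"` (default), `"seed_candidates"` or
#'   `"matrix"`; see Details.
#' @return data frame of class `edge_comparison`: one row per unordered
#'   pair with columns seed_roi, target_roi, contrast, mean_diff_z,
#'   t_stat, p_unc, q_fdr, significant.
#' @export
compare_edges <- function(matrices_by_group, contrast,
                          height_p = 0.01, fdr_q = 0.05,
                          var_equal = TRUE,
                          fdr_scope = c("seed", "seed_candidates",
                                        "matrix")) {
  fdr_scope <- match.arg(fdr_scope)
  if (length(contrast) != 2 || !all(contrast %in% names(matrices_by_group))) {
    hemifc_stop("hemifc_error_contrast",
                "contrast must name two groups present in matrices_by_group")
  }
  g1 <- matrices_by_group[[contrast[1]]]
  g2 <- matrices_by_group[[contrast[2]]]
  if (length(g1) < 2 || length(g2) < 2) {
    hemifc_stop("hemifc_error_contrast", "need >= 2 subjects per group")
  }
  ids <- g1[[1]]$roi_order
  for (m in c(g1, g2)) {
    if (!identical(m$roi_order, ids)) {
      hemifc_stop("hemifc_error_roi_mismatch",
                  "all connectivity matrices must share roi_order")
    }
  }
  p <- length(ids)
  pair_idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  Z1 <- vapply(g1, function(m) m$z[pair_idx], numeric(nrow(pair_idx)))
  Z2 <- vapply(g2, function(m) m$z[pair_idx], numeric(nrow(pair_idx)))
  n1 <- ncol(Z1); n2 <- ncol(Z2)
  m1 <- rowMeans(Z1); m2 <- rowMeans(Z2)
  v1 <- apply(Z1, 1, stats::var); v2 <- apply(Z2, 1, stats::var)
  diff <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- diff / se
  pval <- 2 * stats::pt(-abs(tstat), df)

  res <- data.frame(
    seed_roi = ids[pair_idx[, 1]],
    target_roi = ids[pair_idx[, 2]],
    contrast = paste(contrast, collapse = ">"),
    mean_diff_z = diff, t_stat = tstat, p_unc = pval,
    q_fdr = NA_real_, significant = FALSE,
    stringsAsFactors = FALSE)

  cand <- res$p_unc < height_p
  if (fdr_scope == "matrix") {
    res$q_fdr <- bh_fdr(res$p_unc)
  } else {
    # per-seed families: each pair is judged in both endpoints' families
    qmin <- rep(NA_real_, nrow(res))
    for (s in ids) {
      fam <- which(res$seed_roi == s | res$target_roi == s)
      if (fdr_scope == "seed_candidates") fam <- fam[cand[fam]]
      if (length(fam) == 0) next
      q <- bh_fdr(res$p_unc[fam])
      qmin[fam] <- pmin(qmin[fam], q, na.rm = TRUE)
    }
    res$q_fdr <- qmin
  }
  res$significant <- cand & !is.na(res$q_fdr) & res$q_fdr < fdr_q
  attr(res, "height_p") <- height_p
  attr(res, "fdr_q") <- fdr_q
  class(res) <- c("edge_comparison", "data.frame")
  res
}
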