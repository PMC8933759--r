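# Hemispheric aggregate connectivity (rFC, lFC) and the asymmetry index.
#
# For an ROI, rFC (lFC) is the sum of absolute connection weights over the
# ROI's supra-threshold edges to right- (left-) hemisphere targets. The
# asymmetry index AI = 100 * (rFC - lFC) / ((rFC + lFC) / 2) is positive
# for rightward lateralization and bounded in [-200, 200].

# Shared kernel: hemispheric sums for one ROI given raw r and weight
# matrices. Midline targets never contribute.
hemi_sums <- function(rrow, wrow, hemi, self, threshold_r, mode) {
  keep <- if (mode == "signed") rrow > threshold_r else abs(rrow) > threshold_r
  keep[self] <- FALSE
  keep[is.na(rrow)] <- FALSE
  right <- keep & hemi == "R"
  left <- keep & hemi == "L"
  c(rFC = sum(abs(wrow[right])), lFC = sum(abs(wrow[left])),
    n_edges_right = sum(right), n_edges_left = sum(left))
}

#' Hemispheric aggregate connectivity of one ROI
#'
#' Sums the absolute connection weights of an ROI's supra-threshold edges,
#' split by the target's hemisphere. Thresholding is on the raw Pearson r
#' (`mode = "signed"`: r > threshold, positive connections only, the
#' default reading of "strongly correlated"; `mode = "absolute"`:
#' |r| > threshold). The summed weight is the Fisher z by default
#' (`weight = "r"` sums raw correlations instead). The ROI's homotopic
#' partner is an ordinary target; midline ROIs never contribute.
#'
#' @param conn a `connectivity_matrix` from [compute_connectivity()].
#' @param atlas a [roi_atlas] matching `conn$roi_order`.
#' @param roi roi_id of a lateral (L/R) region.
#' @param threshold_r correlation threshold (default 0.25).
#' @param mode `"signed"` (default) or `"absolute"` thresholding.
#' @param weight `"z"` (default) or `"r"` edge weight.
#' @return named numeric vector: `rFC`, `lFC`, `n_edges_right`,
#'   `n_edges_left`.
#' @export
hemispheric_fc <- function(conn, atlas, roi, threshold_r = 0.25,
                           mode = c("signed", "absolute"),
                           weight = c("z", "r")) {
  mode <- match.arg(mode)
  weight <- match.arg(weight)
  stopifnot(inherits(conn, "connectivity_matrix"), inherits(atlas, "roi_atlas"))
  if (!identical(conn$roi_order, atlas$roi_id)) {
    hemifc_stop("hemifc_error_roi_mismatch",
                "connectivity roi_order does not match atlas")
  }
  i <- match(roi, atlas$roi_id)
  if (is.na(i)) {
    hemifc_stop("hemifc_error_unknown_roi", sprintf("unknown roi_id '%s'", roi))
  }
  if (atlas$hemisphere[i] == "M") {
    hemifc_stop("hemifc_error_midline_roi",
                sprintf("'%s' is a midline ROI; hemispheric FC is undefined", roi))
  }
  w <- if (weight == "z") conn$z[i, ] else conn$r[i, ]
  hemi_sums(conn$r[i, ], w, atlas$hemisphere, i, threshold_r, mode)
}

#' Asymmetry index
#'
#' `AI = 100 * (rFC - lFC) / ((rFC + lFC) / 2)`; positive values indicate
#' rightward lateralization (right-hemisphere aggregate larger). Undefined
#' (`NA`) when `rFC + lFC = 0`; undefined values propagate as missing and
#' are dropped (with logged counts) from group tests.
#'
#' @param rFC,lFC non-negative aggregates, recycled to common length.
#' @return AI in `[-200, 200]`, or `NA` where both inputs are zero.
#' @export
#' @examples
#' asymmetry_index(3, 1) # 100
asymmetry_index <- function(rFC, lFC) {
  if (any(rFC < 0, na.rm = TRUE) || any(lFC < 0, na.rm = TRUE)) {
    hemifc_stop("hemifc_error_negative_fc", "rFC and lFC must be non-negative")
  }
  s <- rFC + lFC
  ifelse(s == 0, NA_real_, 100 * (rFC - lFC) / (s / 2))
}

#' Per-ROI asymmetry of an arbitrary correlation matrix
#'
#' Evaluates the rFC/lFC aggregation and AI directly on a correlation
#' matrix (e.g. a population matrix from
#' [build_population_covariance()]), for every lateral ROI of the atlas.
#'
#' @param rmat square correlation matrix with roi_id dimnames covering the
#'   atlas.
#' @inheritParams hemispheric_fc
#' @return data frame: roi_id, rFC, lFC, AI, n_edges_right, n_edges_left.
#' @export
matrix_asymmetry <- function(rmat, atlas, threshold_r = 0.25,
                             mode = c("signed", "absolute"),
                             weight = c("z", "r")) {
  mode <- match.arg(mode)
  weight <- match.arg(weight)
  ids <- atlas$roi_id
  stopifnot(all(ids %in% rownames(rmat)))
  rmat <- rmat[ids, ids]
  wmat <- if (weight == "z") {
    zz <- fisher_z(rmat); diag(zz) <- 0; zz
  } else {
    rmat
  }
  lateral <- which(atlas$hemisphere %in% c("L", "R"))
  rows <- lapply(lateral, function(i) {
    s <- hemi_sums(rmat[i, ], wmat[i, ], atlas$hemisphere, i, threshold_r, mode)
    data.frame(roi_id = ids[i], rFC = s[["rFC"]], lFC = s[["lFC"]],
               AI = asymmetry_index(s[["rFC"]], s[["lFC"]]),
               n_edges_right = s[["n_edges_right"]],
               n_edges_left = s[["n_edges_left"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# AI of a single ROI on a plain correlation matrix (hot path for the
# generator's bisection).
matrix_roi_ai <- function(rmat, atlas, roi, threshold_r, mode, weight) {
  i <- match(roi, atlas$roi_id)
  rrow <- rmat[i, ]
  wrow <- if (weight == "z") {
    z <- fisher_z(rrow); z[i] <- 0; z
  } else {
    rrow
  }
  s <- hemi_sums(rrow, wrow, atlas$hemisphere, i, threshold_r, mode)
  asymmetry_index(s[["rFC"]], s[["lFC"]])
}

#' Asymmetry profiles for a whole cohort
#'
#' One row per subject per lateral ROI. Midline ROIs are excluded both as
#' rows and as targets. Optionally restrict to a chosen ROI subset (e.g.
#' regions pre-selected by the edge-wise group comparison); by default all
#' lateral ROIs are profiled.
#'
#' @param conns list of `connectivity_matrix` (one per subject), e.g. from
#'   [connect_cohort()].
#' @param atlas a [roi_atlas].
#' @param roi_subset optional character vector of roi_ids to profile.
#' @inheritParams hemispheric_fc
#' @return data frame of class `asymmetry_profile`: subject_id, group,
#'   roi_id, rFC, lFC, AI, n_edges_right, n_edges_left.
#' @export
profile_cohort <- function(conns, atlas, threshold_r = 0.25,
                           mode = c("signed", "absolute"),
                           weight = c("z", "r"), roi_subset = NULL) {
  mode <- match.arg(mode)
  weight <- match.arg(weight)
  lat <- lateral_subset(atlas)
  rois <- if (is.null(roi_subset)) lat$roi_id else {
    bad <- setdiff(roi_subset, lat$roi_id)
    if (length(bad) > 0) {
      hemifc_stop("hemifc_error_unknown_roi",
                  paste0("roi_subset contains non-lateral or unknown ROIs: ",
                         paste(bad, collapse = ", ")))
    }
    roi_subset
  }
  hemi <- atlas_hemi(atlas)
  out <- lapply(conns, function(cm) {
    if (!identical(cm$roi_order, atlas$roi_id)) {
      hemifc_stop("hemifc_error_roi_mismatch",
                  sprintf("roi_order mismatch for subject %s", cm$subject_id))
    }
    wmat <- if (weight == "z") cm$z else cm$r
    rows <- lapply(rois, function(roi) {
      i <- match(roi, cm$roi_order)
      s <- hemi_sums(cm$r[i, ], wmat[i, ], hemi, i, threshold_r, mode)
      data.frame(subject_id = cm$subject_id, group = cm$group, roi_id = roi,
                 rFC = s[["rFC"]], lFC = s[["lFC"]],
                 AI = asymmetry_index(s[["rFC"]], s[["lFC"]]),
                 n_edges_right = s[["n_edges_right"]],
                 n_edges_left = s[["n_edges_left"]],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "threshold_r") <- threshold_r
  attr(res, "mode") <- mode
  attr(res, "weight") <- weight
  class(res) <- c("asymmetry_profile", "data.frame")
  res
}
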