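# Synthetic multi-subject ROI time-series cohorts with known connectivity
# structure. The generator is first-class, tested code: it is the ground
# truth against which the estimation pipeline is calibrated.

#' Default clinical covariate model
#'
#' Group-wise means/SDs for age, onset age and epilepsy duration, and male
#' fractions, matching a three-group mesial temporal lobe epilepsy cohort
#' (left-focus, right-focus, healthy controls). Onset/duration apply to
#' patient groups only.
#'
#' @return a named list, one entry per group label.
#' @export
clinical_defaults <- function() {
  list(
    LMTLE = list(age = c(25.17, 3.69), sex_male = 9 / 12,
                 onset = c(16.42, 8.61), duration = c(12.83, 8.68)),
    RMTLE = list(age = c(29.25, 9.92), sex_male = 6 / 11,
                 onset = c(19.09, 8.81), duration = c(12.73, 6.53)),
    HC = list(age = c(31.82, 10.25), sex_male = 13 / 23,
              onset = NULL, duration = NULL)
  )
}

#' Describe a synthetic cohort
#'
#' A `cohort_design` states the whole simulated world: group sizes, series
#' length, the population correlation structure (within-hemisphere
#' baseline, homotopic coupling, cross-hemisphere baseline), per-ROI
#' asymmetry-index targets, additive group edge effects, the shared AR(1)
#' temporal coefficient, and the clinical covariate model.
#'
#' When `cross_correlation` is `NULL` (the default) it is solved so that
#' the *expected* thresholded hemispheric aggregates (rFC, lFC) balance
#' under sampling at `n_timepoints`, using the Fisher-z normal
#' approximation for sample correlations. This makes a design with an empty
#' `asymmetry_profile` a true lateralization null, which the calibration
#' properties require. It needs equally sized hemispheres; pass an explicit
#' `cross_correlation` otherwise.
#'
#' @param groups named integer vector of subjects per group; labels must be
#'   among `HC`, `LMTLE`, `RMTLE`.
#' @param n_timepoints retained volumes per subject (default 230 = 240
#'   acquired minus 10 discarded for signal stabilization).
#' @param base_correlation within-hemisphere baseline correlation.
#' @param homotopic_correlation correlation between homotopic partners.
#' @param cross_correlation cross-hemisphere (non-homotopic) baseline, or
#'   `NULL` for the balanced-null solve described above.
#' @param asymmetry_profile named numeric vector of target AI values
#'   (percent, in `[-200, 200]`), names are lateral roi_ids.
#' @param group_edge_effects data frame with columns `group`, `roi_a`,
#'   `roi_b`, `delta`: additive change to the population correlation of
#'   that pair in that group.
#' @param correlation_jitter SD of deterministic entry-level heterogeneity
#'   added to the baseline correlations (default 0.02). Real covariance
#'   structure is never uniform; the jitter also keeps the AI-target search
#'   well-posed by preventing whole blocks of edges from crossing the
#'   threshold simultaneously. It is assigned symmetrically under the
#'   hemisphere swap (mirror pairs get the same perturbation), so a
#'   zero-profile design remains exactly swap-invariant, and it is a pure
#'   function of `random_seed`.
#' @param ar1_coefficient shared temporal AR(1) coefficient in `[0, 1)`.
#' @param clinical_model see [clinical_defaults()].
#' @param threshold_r,mode,weight settings the asymmetry module will use;
#'   the generator needs them to realize AI targets (see
#'   [hemispheric_fc()]).
#' @param repair_tolerance maximum entry change allowed by the
#'   positive-semidefinite repair before a warning.
#' @param random_seed master seed; all randomness derives from it.
#' @return a `cohort_design` object.
#' @export
#' @examples
#' d <- cohort_design(groups = c(HC = 4, LMTLE = 3), n_timepoints = 60)
cohort_design <- function(groups = c(LMTLE = 12, RMTLE = 11, HC = 23),
                          n_timepoints = 230,
                          base_correlation = 0.35,
                          homotopic_correlation = 0.6,
                          cross_correlation = NULL,
                          asymmetry_profile = numeric(0),
                          group_edge_effects = NULL,
                          correlation_jitter = 0.02,
                          ar1_coefficient = 0.3,
                          clinical_model = clinical_defaults(),
                          threshold_r = 0.25,
                          mode = c("signed", "absolute"),
                          weight = c("z", "r"),
                          repair_tolerance = 0.05,
                          random_seed = 1L) {
  mode <- match.arg(mode)
  weight <- match.arg(weight)
  if (is.null(names(groups)) || any(!names(groups) %in% c("HC", "LMTLE", "RMTLE"))) {
    hemifc_stop("hemifc_error_design",
                "groups must be a named vector with labels among HC, LMTLE, RMTLE")
  }
  if (any(groups < 1) || any(groups != round(groups))) {
    hemifc_stop("hemifc_error_design", "group sizes must be positive integers")
  }
  if (n_timepoints < 3) {
    hemifc_stop("hemifc_error_design", "n_timepoints must be >= 3")
  }
  for (v in c(base_correlation, homotopic_correlation, cross_correlation)) {
    if (!is.null(v) && (v <= -1 || v >= 1)) {
      hemifc_stop("hemifc_error_design", "correlations must lie in (-1, 1)")
    }
  }
  if (ar1_coefficient < 0 || ar1_coefficient >= 1) {
    hemifc_stop("hemifc_error_design", "ar1_coefficient must lie in [0, 1)")
  }
  if (correlation_jitter < 0 || correlation_jitter >= 0.2) {
    hemifc_stop("hemifc_error_design", "correlation_jitter must lie in [0, 0.2)")
  }
  if (length(asymmetry_profile) > 0) {
    if (is.null(names(asymmetry_profile)) || any(names(asymmetry_profile) == "")) {
      hemifc_stop("hemifc_error_design", "asymmetry_profile must be named by roi_id")
    }
    if (any(abs(asymmetry_profile) > 200)) {
      hemifc_stop("hemifc_error_design", "AI targets must lie in [-200, 200]")
    }
  }
  if (!is.null(group_edge_effects)) {
    need <- c("group", "roi_a", "roi_b", "delta")
    if (!all(need %in% names(group_edge_effects))) {
      hemifc_stop("hemifc_error_design",
                  "group_edge_effects needs columns group, roi_a, roi_b, delta")
    }
  }
  structure(list(
    groups = groups, n_timepoints = as.integer(n_timepoints),
    base_correlation = base_correlation,
    homotopic_correlation = homotopic_correlation,
    cross_correlation = cross_correlation,
    asymmetry_profile = asymmetry_profile,
    group_edge_effects = group_edge_effects,
    correlation_jitter = correlation_jitter,
    ar1_coefficient = ar1_coefficient,
    clinical_model = clinical_model,
    threshold_r = threshold_r, mode = mode, weight = weight,
    repair_tolerance = repair_tolerance,
    random_seed = as.integer(random_seed)
  ), class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("Cohort design:",
      paste(sprintf("%s=%d", names(x$groups), x$groups), collapse = ", "),
      sprintf("| T=%d, AR1=%.2g, seed=%d\n",
              x$n_timepoints, x$ar1_coefficient, x$random_seed))
  invisible(x)
}

#' Expected supra-threshold edge weight under sampling
#'
#' For a pair of series with population correlation `rho`, observed over
#' `n_timepoints` points, returns the expectation of the thresholded
#' aggregate contribution of that edge: `E[w(r_hat) * 1(edge retained)]`
#' where retention and the weight follow the asymmetry module's settings.
#' Uses the Fisher-z normal approximation `atanh(r_hat) ~ N(atanh(rho),
#' 1/(T-3))` and numeric integration.
#'
#' For series that share an AR(1) temporal coefficient `phi`, the sampling
#' variance of the correlation is inflated by `(1 + phi^2) / (1 - phi^2)`
#' (the lag-sum of squared autocorrelations), which matters when baseline
#' correlations sit near the threshold; the inflation is applied to the
#' Fisher-z variance.
#'
#' @inheritParams cohort_design
#' @param rho population correlation.
#' @param phi shared temporal AR(1) coefficient of both series.
#' @return expected contribution (non-negative scalar).
#' @export
expected_edge_weight <- function(rho, n_timepoints, threshold_r = 0.25,
                                 mode = c("signed", "absolute"),
                                 weight = c("z", "r"), phi = 0) {
  mode <- match.arg(mode)
  weight <- match.arg(weight)
  # mean includes the O(1/T) bias of the Fisher z estimator
  mu <- atanh(rho) + rho / (2 * (n_timepoints - 1))
  infl <- (1 + phi^2) / (1 - phi^2)
  sdz <- sqrt(infl / max(n_timepoints - 3, 1))
  f <- function(z) {
    r <- tanh(z)
    keep <- if (mode == "signed") r > threshold_r else abs(r) > threshold_r
    w <- if (weight == "z") abs(z) else abs(r)
    ifelse(keep, w, 0) * stats::dnorm(z, mu, sdz)
  }
  stats::integrate(f, mu - 8 * sdz, mu + 8 * sdz, rel.tol = 1e-9)$value
}

# Solve the cross-hemisphere baseline so that, in expectation under
# sampling, each ROI's left and right thresholded aggregates agree:
#   (n-1) g(base) = g(homotopic) + (n-1) g(cross)
# (equal hemisphere sizes n; the ROI's own hemisphere has one fewer target,
# compensated by the homotopic edge on the other side).
balanced_cross_correlation <- function(base, homotopic, n_per_side,
                                       n_timepoints, threshold_r, mode, weight,
                                       phi = 0) {
  if (n_per_side < 2) {
    hemifc_stop("hemifc_error_design",
                "balanced cross_correlation needs >= 2 ROIs per hemisphere")
  }
  g <- function(rho) expected_edge_weight(rho, n_timepoints, threshold_r,
                                          mode, weight, phi)
  lhs <- (n_per_side - 1) * g(base)
  f <- function(rc) g(homotopic) + (n_per_side - 1) * g(rc) - lhs
  lo <- -0.98; hi <- 0.98
  if (f(lo) > 0 || f(hi) < 0) {
    hemifc_stop("hemifc_error_design", paste0(
      "no cross_correlation balances the hemispheric aggregates for this ",
      "design (homotopic coupling too strong for the atlas size); ",
      "pass cross_correlation explicitly"))
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Project a symmetric matrix to a valid correlation matrix
#'
#' Clips negative eigenvalues at a small floor and rescales to unit
#' diagonal. A single-pass spectral projection (not iterated alternating
#' projections): after additive edits of moderate size the result is within
#' numerical tolerance of the nearest correlation matrix and keeps the
#' edits interpretable.
#'
#' @param mat symmetric matrix with unit diagonal (approximately).
#' @param eig_floor eigenvalue floor.
#' @return list with `matrix` (repaired) and `max_change` (max abs entry
#'   difference from input).
#' @export
nearest_correlation <- function(mat, eig_floor = 1e-8) {
  mat <- (mat + t(mat)) / 2
  e <- eigen(mat, symmetric = TRUE)
  vals <- pmax(e$values, eig_floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  dimnames(out) <- dimnames(mat)
  list(matrix = out, max_change = max(abs(out - mat)))
}

#' Build a group's population correlation matrix
#'
#' Constructs the ROI-by-ROI population correlation matrix implied by a
#' design for one group: within-hemisphere baseline, homotopic coupling,
#' cross-hemisphere baseline (balanced-null solved when unset), additive
#' group edge effects, then a bisection on a two-sided multiplier of each
#' profiled ROI's hemispheric blocks (right-target entries scaled up as
#' left-target entries scale down) so the ROI's *expected sampled* AI at
#' the design's series length hits the target within 2 AI units, with the
#' positive-semidefinite repair evaluated inside the search. Targeting the
#' expectation (rather than the hard-thresholded AI of the population
#' matrix) makes the cohort-mean estimated AI recover the target; the two
#' agree whenever baseline correlations sit clear of the threshold, since
#' thresholding is then effectively deterministic.
#'
#' @param design a [cohort_design].
#' @param group group label to build for.
#' @param atlas a [roi_atlas].
#' @param repair apply the PSD repair (set `FALSE` to inspect the raw
#'   additive construction).
#' @param calibrate_ai after expectation-based targeting, simulate 120
#'   subjects from the candidate matrix and retarget to cancel residual
#'   bias of the hard-thresholded AI estimator (deterministic given the
#'   design seed; only runs when an asymmetry profile is present).
#' @param on_repair_violation what to do if the repair moves any entry by
#'   more than `design$repair_tolerance`.
#' @return correlation matrix with roi_id dimnames, full atlas order.
#' @export
build_population_covariance <- function(design, group, atlas,
                                        repair = TRUE,
                                        calibrate_ai = TRUE,
                                        on_repair_violation = c("warn", "error")) {
  stopifnot(inherits(design, "cohort_design"), inherits(atlas, "roi_atlas"))
  on_repair_violation <- match.arg(on_repair_violation)
  ids <- atlas$roi_id
  hemi <- atlas_hemi(atlas)
  p <- length(ids)
  nL <- sum(hemi == "L"); nR <- sum(hemi == "R")

  b_c <- design$cross_correlation
  if (is.null(b_c)) {
    if (nL != nR) {
      hemifc_stop("hemifc_error_design", paste0(
        "balanced cross_correlation requires equal hemisphere sizes ",
        sprintf("(got %d L, %d R); pass cross_correlation explicitly", nL, nR)))
    }
    b_c <- balanced_cross_correlation(
      design$base_correlation, design$homotopic_correlation, nL,
      design$n_timepoints, design$threshold_r, design$mode, design$weight,
      design$ar1_coefficient)
  }

  R <- matrix(b_c, p, p, dimnames = list(ids, ids))
  same_L <- outer(hemi == "L", hemi == "L")
  same_R <- outer(hemi == "R", hemi == "R")
  R[same_L | same_R] <- design$base_correlation
  partner <- atlas$homotopic_partner
  for (i in seq_len(p)) {
    if (!is.na(partner[i])) {
      j <- match(partner[i], ids)
      R[i, j] <- R[j, i] <- design$homotopic_correlation
    }
  }
  diag(R) <- 1
  R <- apply_symmetric_jitter(R, atlas, design$correlation_jitter,
                              design$random_seed)

  ge <- design$group_edge_effects
  if (!is.null(ge)) {
    ge <- ge[ge$group == group, , drop = FALSE]
    for (k in seq_len(nrow(ge))) {
      i <- match(ge$roi_a[k], ids); j <- match(ge$roi_b[k], ids)
      if (is.na(i) || is.na(j)) {
        hemifc_stop("hemifc_error_design",
                    sprintf("edge effect names unknown ROI: %s-%s",
                            ge$roi_a[k], ge$roi_b[k]))
      }
      v <- min(max(R[i, j] + ge$delta[k], -0.99), 0.99)
      R[i, j] <- R[j, i] <- v
    }
  }

  prof <- design$asymmetry_profile
  if (length(prof) > 0) {
    bad <- setdiff(names(prof), ids[hemi %in% c("L", "R")])
    if (length(bad) > 0) {
      hemifc_stop("hemifc_error_design",
                  paste0("asymmetry_profile names non-lateral or unknown ROI: ",
                         paste(bad, collapse = ", ")))
    }
    exp_ai <- function(M, roi) {
      expected_roi_ai(M, atlas, roi, design$n_timepoints, design$threshold_r,
                      design$mode, design$weight, design$ar1_coefficient)
    }
    if (!repair) {
      for (roi in names(prof)) {
        R <- target_roi_ai(R, atlas, roi, prof[[roi]], design$threshold_r,
                           design$mode, design$weight, design$n_timepoints,
                           design$ar1_coefficient, with_repair = FALSE)
      }
      return(R)
    }
    # repair-aware targeting; extra passes absorb cross-talk between
    # profiled ROIs (scaling one ROI's rows shifts its neighbours' sums)
    retarget <- function(R, targets) {
      for (pass in 1:3) {
        for (roi in names(targets)) {
          R <- target_roi_ai(R, atlas, roi, targets[[roi]], design$threshold_r,
                             design$mode, design$weight, design$n_timepoints,
                             design$ar1_coefficient, with_repair = TRUE)
        }
        got <- vapply(names(targets), function(roi) exp_ai(R, roi),
                      numeric(1))
        if (all(abs(got - unlist(targets)) <= 1.5, na.rm = TRUE)) break
      }
      R
    }
    targets <- unlist(prof)
    R <- retarget(R, targets)

    if (calibrate_ai) {
      # the hard-thresholded AI estimator is biased when entries sit near
      # the threshold; cancel the residual bias by measuring the
      # cohort-mean estimated AI on simulated subjects and retargeting
      adj <- targets
      est <- targets
      for (iter in 1:3) {
        est <- mc_estimate_roi_ai(
          R, atlas, names(prof), design$n_timepoints,
          design$ar1_coefficient, design$threshold_r, design$mode,
          design$weight, K = 160,
          seed = derive_seed(design$random_seed, 104729L + iter))
        err <- est - targets
        if (all(abs(err) <= 1.75, na.rm = TRUE) || iter == 3) break
        # damped correction: profiled ROIs interact, a full Newton step
        # overshoots when entries sit near the threshold
        adj <- pmin(pmax(adj - 0.6 * err, -199), 199)
        R <- tryCatch(retarget(R, adj),
                      hemifc_error_infeasible_ai = function(e) R)
      }
      for (q in seq_along(targets)) {
        if (is.na(est[q]) || abs(est[q] - targets[q]) > 4) {
          hemifc_warn("hemifc_warning_ai_drift", sprintf(
            "estimated cohort-mean AI for %s is %.2f, off target %.2f",
            names(targets)[q], est[q], targets[q]))
        }
      }
    } else {
      for (roi in names(prof)) {
        ai <- exp_ai(R, roi)
        if (is.na(ai) || abs(ai - prof[[roi]]) > 2) {
          hemifc_warn("hemifc_warning_ai_drift", sprintf(
            "achieved AI for %s is %.2f, more than 2 units from target %.2f",
            roi, ai, prof[[roi]]))
        }
      }
    }
    return(R)
  }

  if (!repair) return(R)
  rep <- nearest_correlation(R)
  if (rep$max_change > design$repair_tolerance) {
    msg <- sprintf(
      "PSD repair moved an entry by %.4f (> tolerance %.4f) for group %s",
      rep$max_change, design$repair_tolerance, group)
    if (on_repair_violation == "error") {
      hemifc_stop("hemifc_error_repair", msg)
    }
    hemifc_warn("hemifc_warning_repair", msg)
  }
  rep$matrix
}

# Vectorized expected supra-threshold edge weight (same model as
# expected_edge_weight) for a vector of population correlations; closed
# form for the z weight, numeric integration per entry for the r weight.
g_edge_vec <- function(rho, n_timepoints, threshold_r, mode, weight, phi) {
  mu <- atanh(rho) + rho / (2 * (n_timepoints - 1))
  sdz <- sqrt(((1 + phi^2) / (1 - phi^2)) / max(n_timepoints - 3, 1))
  if (weight == "z") {
    a <- atanh(threshold_r)
    upper <- mu * stats::pnorm((mu - a) / sdz) + sdz * stats::dnorm((a - mu) / sdz)
    if (mode == "signed") return(upper)
    # absolute mode adds the |r| < -threshold tail
    lower <- -mu * stats::pnorm((-a - mu) / sdz) + sdz * stats::dnorm((a + mu) / sdz)
    return(upper + lower)
  }
  vapply(rho, expected_edge_weight, numeric(1),
         n_timepoints = n_timepoints, threshold_r = threshold_r,
         mode = mode, weight = weight, phi = phi)
}

# Expected sampled AI of one ROI: the asymmetry index evaluated on the
# expected thresholded hemispheric aggregates at the design's series
# length. This is the quantity the generator's AI targeting drives to the
# requested value, so that the cohort-mean *estimated* AI recovers the
# target (the hard-thresholded population-matrix AI is biased whenever
# entries sit near the threshold; the expectation model absorbs that).
expected_roi_ai <- function(R, atlas, roi, n_timepoints, threshold_r,
                            mode, weight, phi) {
  i <- match(roi, atlas$roi_id)
  hemi <- atlas$hemisphere
  rrow <- R[i, ]
  g <- g_edge_vec(rrow, n_timepoints, threshold_r, mode, weight, phi)
  rfc <- sum(g[hemi == "R" & seq_along(rrow) != i])
  lfc <- sum(g[hemi == "L" & seq_along(rrow) != i])
  asymmetry_index(max(rfc, 0), max(lfc, 0))
}

# Shared-coefficient AR(1) colouring of pre-correlated innovations E
# (rows = timepoints): stationary start, then the recursion per column.
ar1_colored_series <- function(E, phi) {
  if (phi <= 0) return(E)
  y <- E
  sc <- sqrt(1 - phi^2)
  for (j in seq_len(ncol(E))) {
    y[-1, j] <- stats::filter(sc * E[-1, j], phi, method = "recursive",
                              init = y[1, j])
  }
  y
}

# Monte-Carlo estimate of the cohort-mean estimated AI for selected ROIs
# under a candidate population matrix: simulates K subjects at the
# design's series length / AR(1) coefficient and averages the
# hard-thresholded AI. Deterministic given `seed`; global RNG state is
# preserved.
mc_estimate_roi_ai <- function(R, atlas, rois, n_timepoints, phi,
                               threshold_r, mode, weight, K, seed) {
  e <- eigen(R, symmetric = TRUE)
  A <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  p <- ncol(R)
  idx <- match(rois, atlas$roi_id)
  hemi <- atlas$hemisphere
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  acc <- matrix(NA_real_, K, length(rois))
  for (k in seq_len(K)) {
    y <- ar1_colored_series(
      matrix(stats::rnorm(n_timepoints * p), n_timepoints, p) %*% t(A), phi)
    rr <- stats::cor(y[, idx, drop = FALSE], y)
    for (q in seq_along(rois)) {
      rrow <- rr[q, ]
      keep <- if (mode == "signed") rrow > threshold_r else abs(rrow) > threshold_r
      keep[idx[q]] <- FALSE
      w <- if (weight == "z") abs(fisher_z(rrow)) else abs(rrow)
      rfc <- sum(w[keep & hemi == "R"])
      lfc <- sum(w[keep & hemi == "L"])
      acc[k, q] <- asymmetry_index(rfc, lfc)
    }
  }
  if (had_seed) {
    assign(".Random.seed", envir = globalenv(), old)
  } else {
    rm(".Random.seed", envir = globalenv())
  }
  colMeans(acc, na.rm = TRUE)
}

# Deterministic mean-zero heterogeneity on the off-diagonal baseline,
# assigned per hemisphere-swap orbit so mirror pairs perturb identically
# (a zero-profile design stays exactly swap-invariant). Pure function of
# the design seed; the caller's RNG state is left untouched.
apply_symmetric_jitter <- function(R, atlas, sd_jit, seed) {
  if (sd_jit == 0) return(R)
  p <- nrow(R)
  sw <- ifelse(is.na(atlas$homotopic_partner), seq_len(p),
               match(atlas$homotopic_partner, atlas$roi_id))
  ut <- which(upper.tri(R), arr.ind = TRUE)
  a <- ut[, 1]; b <- ut[, 2]
  a2 <- pmin(sw[a], sw[b]); b2 <- pmax(sw[a], sw[b])
  use_self <- a < a2 | (a == a2 & b <= b2)
  canon <- ifelse(use_self, paste(a, b), paste(a2, b2))
  f <- factor(canon, levels = unique(canon))
  homotopic <- sw[a] == b   # partner pairs keep their stated coupling exactly
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(derive_seed(seed, 0L))
  vals <- stats::rnorm(nlevels(f), 0, sd_jit)
  if (had_seed) {
    assign(".Random.seed", old, envir = globalenv())
  } else {
    rm(".Random.seed", envir = globalenv())
  }
  jit <- vals[as.integer(f)]
  jit[homotopic] <- 0
  R[ut] <- pmin(pmax(R[ut] + jit, -0.98), 0.98)
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  R
}

# Bisection on a multiplier m applied to one ROI's hemispheric blocks
# (right-target entries scaled by m, left-target entries by 1/m), driving
# the population-matrix AI of that ROI to the target. The two-sided scaling
# keeps large targets inside the positive-semidefinite cone; when
# `with_repair` the PSD repair is evaluated inside the objective so the AI
# is measured on the matrix actually returned. AI is monotone in m up to
# threshold-crossing steps, which the entry-level jitter keeps small.
target_roi_ai <- function(R, atlas, roi, target, threshold_r, mode, weight,
                          n_timepoints, phi, with_repair = TRUE) {
  ids <- atlas$roi_id
  hemi <- atlas_hemi(atlas)
  i <- match(roi, ids)
  right_idx <- which(hemi == "R" & ids != roi)
  left_idx <- which(hemi == "L" & ids != roi)
  base_r <- R[i, right_idx]
  base_l <- R[i, left_idx]

  apply_m <- function(m) {
    Rm <- R
    vr <- pmin(pmax(base_r * m, -0.99), 0.99)
    vl <- pmin(pmax(base_l / m, -0.99), 0.99)
    Rm[i, right_idx] <- vr; Rm[right_idx, i] <- vr
    Rm[i, left_idx] <- vl; Rm[left_idx, i] <- vl
    if (with_repair) nearest_correlation(Rm)$matrix else Rm
  }
  ai_at <- function(m) {
    ai <- expected_roi_ai(apply_m(m), atlas, roi, n_timepoints,
                          threshold_r, mode, weight, phi)
    if (is.na(ai)) {
      hemifc_stop("hemifc_error_infeasible_ai", sprintf(
        "AI for %s undefined during targeting (no supra-threshold edges)", roi))
    }
    ai
  }
  lo <- 1; hi <- 1
  ai1 <- ai_at(1)
  if (ai1 < target) {
    while (ai_at(hi) < target && hi < 64) hi <- hi * 2
  } else {
    while (ai_at(lo) > target && lo > 1 / 64) lo <- lo / 2
  }
  lo_val <- ai_at(lo); hi_val <- ai_at(hi)
  if (target < lo_val - 2 || target > hi_val + 2) {
    hemifc_stop("hemifc_error_infeasible_ai", sprintf(
      "AI target %.1f for %s infeasible; achievable range [%.1f, %.1f] under this design",
      target, roi, lo_val, hi_val))
  }
  m <- 1
  for (iter in seq_len(60)) {
    m <- sqrt(lo * hi)
    ai <- ai_at(m)
    if (abs(ai - target) < 0.05) break
    if (ai < target) lo <- m else hi <- m
  }
  apply_m(m)
}

#' Simulate a cohort of ROI time series
#'
#' Draws, for each subject, a zero-mean stationary multivariate AR(1)
#' series whose cross-sectional covariance equals the subject's group
#' population correlation matrix (innovation covariance scaled by
#' `1 - ar1^2`), plus clinical covariates from the design's clinical model
#' (normal draws truncated at zero for onset and duration). Fully
#' reproducible: each subject's sub-seed is derived deterministically from
#' `design$random_seed` and the subject index.
#'
#' @param design a [cohort_design].
#' @param atlas a [roi_atlas].
#' @return an `fc_cohort`: list with `subjects` (list of `subject_ts`) and
#'   `manifest` (data frame: subject_id, group, age, sex, onset_age,
#'   duration).
#' @export
#' @examples
#' d <- cohort_design(groups = c(HC = 2), n_timepoints = 40,
#'                    cross_correlation = 0.3)
#' ch <- simulate_cohort(d, demo_atlas(4))
#' dim(ch$subjects[[1]]$data)
simulate_cohort <- function(design, atlas) {
  stopifnot(inherits(design, "cohort_design"), inherits(atlas, "roi_atlas"))
  ids <- atlas$roi_id
  p <- length(ids)
  Tn <- design$n_timepoints
  phi <- design$ar1_coefficient

  sigmas <- lapply(names(design$groups), function(g)
    build_population_covariance(design, g, atlas))
  names(sigmas) <- names(design$groups)
  factors <- lapply(sigmas, function(S) {
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  })

  subjects <- list()
  manifest <- list()
  k <- 0
  for (g in names(design$groups)) {
    A <- factors[[g]]
    cm <- design$clinical_model[[g]]
    for (s in seq_len(design$groups[[g]])) {
      k <- k + 1
      set.seed(derive_seed(design$random_seed, k))
      E <- matrix(stats::rnorm(Tn * p), Tn, p) %*% t(A)
      if (phi > 0) {
        # stationary start, then shared-coefficient AR(1) recursion
        y <- matrix(0, Tn, p)
        y[1, ] <- E[1, ]
        sc <- sqrt(1 - phi^2)
        for (j in seq_len(p)) {
          y[-1, j] <- stats::filter(sc * E[-1, j], phi, method = "recursive",
                                    init = y[1, j])
        }
      } else {
        y <- E
      }
      colnames(y) <- ids

      rtrunc0 <- function(mean, sd) {
        v <- stats::rnorm(1, mean, sd)
        while (v < 0) v <- stats::rnorm(1, mean, sd)
        v
      }
      age <- if (!is.null(cm$age)) rtrunc0(cm$age[1], cm$age[2]) else NA_real_
      sex <- if (!is.null(cm$sex_male)) {
        if (stats::runif(1) < cm$sex_male) "M" else "F"
      } else NA_character_
      onset <- if (!is.null(cm$onset)) rtrunc0(cm$onset[1], cm$onset[2]) else NA_real_
      duration <- if (!is.null(cm$duration)) {
        rtrunc0(cm$duration[1], cm$duration[2])
      } else NA_real_

      sid <- sprintf("%s_%02d", g, s)
      subjects[[sid]] <- structure(list(
        subject_id = sid, group = g, data = y,
        age = age, sex = sex, onset_age = onset, duration = duration
      ), class = "subject_ts")
      manifest[[sid]] <- data.frame(
        subject_id = sid, group = g, age = age, sex = sex,
        onset_age = onset, duration = duration, stringsAsFactors = FALSE)
    }
  }
  structure(list(
    subjects = subjects,
    manifest = do.call(rbind, c(manifest, list(make.row.names = FALSE))),
    roi_order = ids
  ), class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%s), %d ROIs x %d timepoints\n",
              length(x$subjects),
              paste(sprintf("%s=%d", names(table(x$manifest$group)),
                            as.integer(table(x$manifest$group))), collapse = ", "),
              length(x$roi_order), nrow(x$subjects[[1]]$data)))
  invisible(x)
}

#' Write a cohort to a directory of TSV files
#'
#' One `<subject_id>.tsv` per subject (header = roi_ids, one row per
#' timepoint) plus `manifest.tsv`. Output is deterministic for a given
#' cohort.
#'
#' @param cohort an `fc_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$file <- paste0(man$subject_id, ".tsv")
  for (s in cohort$subjects) {
    df <- as.data.frame(s$data)
    utils::write.table(
      format(df, digits = 10, trim = TRUE, scientific = FALSE),
      file.path(dir, paste0(s$subject_id, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.tsv` and per-subject TSVs.
#' @return an `fc_cohort`.
#' @export
read_cohort <- function(dir) {
  man <- utils::read.delim(file.path(dir, "manifest.tsv"),
                           stringsAsFactors = FALSE)
  subjects <- list()
  roi_order <- NULL
  for (i in seq_len(nrow(man))) {
    df <- utils::read.delim(file.path(dir, man$file[i]), check.names = FALSE)
    y <- as.matrix(df)
    if (is.null(roi_order)) roi_order <- colnames(y)
    subjects[[man$subject_id[i]]] <- structure(list(
      subject_id = man$subject_id[i], group = man$group[i], data = y,
      age = man$age[i], sex = man$sex[i],
      onset_age = man$onset_age[i], duration = man$duration[i]
    ), class = "subject_ts")
  }
  man$file <- NULL
  structure(list(subjects = subjects, manifest = man, roi_order = roi_order),
            class = "fc_cohort")
}

#' Small symmetric demo atlas
#'
#' Convenience constructor for examples and tests: `n_pairs` homotopic
#' left/right pairs (`L_r1`/`R_r1`, ...) and optionally midline regions.
#'
#' @param n_pairs number of homotopic pairs.
#' @param n_midline number of midline regions appended.
#' @return a [roi_atlas] with `2 * n_pairs + n_midline` rows.
#' @export
demo_atlas <- function(n_pairs, n_midline = 0) {
  rows <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    data.frame(
      roi_id = c(sprintf("L_r%d", i), sprintf("R_r%d", i)),
      name = sprintf("region %d", c(i, i)),
      hemisphere = c("L", "R"),
      homotopic_partner = c(sprintf("R_r%d", i), sprintf("L_r%d", i)),
      stringsAsFactors = FALSE)
  }))
  if (n_midline > 0) {
    rows <- rbind(rows, data.frame(
      roi_id = sprintf("M_m%d", seq_len(n_midline)),
      name = sprintf("midline %d", seq_len(n_midline)),
      hemisphere = "M", homotopic_partner = NA_character_,
      stringsAsFactors = FALSE))
  }
  roi_atlas(rows)
}
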