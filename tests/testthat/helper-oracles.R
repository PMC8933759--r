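# Independent reference implementations and fixture builders shared across
# test files. The oracles are deliberately naive (literal loops over the
# definitions) and never call the package code paths they are used to check.

# Literal loop-over-all-pairs reference for the hemispheric aggregation.
ref_hemispheric_fc <- function(r, z, atlas, roi, threshold_r, mode, weight) {
  ids <- atlas$roi_id
  rFC <- 0; lFC <- 0; nr <- 0L; nl <- 0L
  for (j in seq_along(ids)) {
    if (ids[j] == roi) next
    rij <- r[roi, ids[j]]
    keep <- if (mode == "signed") rij > threshold_r else abs(rij) > threshold_r
    if (!keep) next
    w <- if (weight == "z") abs(atanh(min(max(rij, -(1 - 1e-12)), 1 - 1e-12)))
         else abs(rij)
    h <- atlas$hemisphere[j]
    if (h == "R") { rFC <- rFC + w; nr <- nr + 1L }
    if (h == "L") { lFC <- lFC + w; nl <- nl + 1L }
  }
  c(rFC = rFC, lFC = lFC, n_edges_right = nr, n_edges_left = nl)
}

# Literal Benjamini-Hochberg step-up: find the largest i with
# p(i) <= i*q/m, then q-values as the textbook running minimum.
ref_bh_q <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- Inf
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- min(prev, 1)
  }
  q
}

# Random symmetric correlation-like matrix with roi_id dimnames (not
# necessarily PSD; the aggregation ops only read entries).
random_r_matrix <- function(atlas, rng_fun = function(n) runif(n, -1, 1)) {
  p <- nrow(atlas)
  r <- matrix(0, p, p, dimnames = list(atlas$roi_id, atlas$roi_id))
  r[upper.tri(r)] <- rng_fun(p * (p - 1) / 2)
  r <- r + t(r)
  diag(r) <- 1
  r
}

# Wrap a raw correlation matrix as a connectivity_matrix without going
# through compute_connectivity.
as_conn <- function(r, atlas, subject_id = "s", group = "HC") {
  z <- atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
  diag(z) <- 0
  structure(list(subject_id = subject_id, group = group, r = r, z = z,
                 roi_order = atlas$roi_id),
            class = "connectivity_matrix")
}

# Minimal valid two-region atlas used across files.
atlas2 <- function() {
  roi_atlas(data.frame(
    roi_id = c("L_A", "R_A"), name = c("a", "a"),
    hemisphere = c("L", "R"), homotopic_partner = c("R_A", "L_A"),
    stringsAsFactors = FALSE))
}

# Edge-comparison table with a prescribed set of significant ROIs, for the
# reporting ops (the summaries only read seed/target/significant).
make_edge_table <- function(sig_rois, contrast = "LMTLE>HC") {
  if (length(sig_rois) == 0) {
    return(structure(
      data.frame(seed_roi = character(), target_roi = character(),
                 contrast = character(), mean_diff_z = numeric(),
                 t_stat = numeric(), p_unc = numeric(), q_fdr = numeric(),
                 significant = logical(), stringsAsFactors = FALSE),
      class = c("edge_comparison", "data.frame")))
  }
  # chain edges so every listed ROI touches >= 1 significant edge
  n <- length(sig_rois)
  seed <- sig_rois[seq_len(max(n - 1, 1))]
  target <- if (n > 1) sig_rois[-1] else sig_rois
  df <- data.frame(seed_roi = seed, target_roi = target, contrast = contrast,
                   mean_diff_z = 0.3, t_stat = 3, p_unc = 0.001,
                   q_fdr = 0.01, significant = TRUE, stringsAsFactors = FALSE)
  class(df) <- c("edge_comparison", "data.frame")
  df
}
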