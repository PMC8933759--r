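# Delimited-text readers/writers for connectivity matrices.

#' Write a connectivity matrix as a square TSV
#'
#' Header and first column are roi_ids; cells hold Pearson r. The Fisher z
#' matrix is recomputed on read, so one file fully describes the object.
#'
#' @param conn a `connectivity_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(conn, path) {
  df <- as.data.frame(conn$r)
  df <- cbind(roi_id = conn$roi_order, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square connectivity TSV
#'
#' @param path file written by [write_connectivity()] or following the
#'   same layout (first column roi_id, remaining columns one per ROI).
#' @param subject_id subject label for the result.
#' @param group group label for the result.
#' @return a `connectivity_matrix`.
#' @export
read_connectivity <- function(path, subject_id = NA_character_,
                              group = NA_character_) {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  r <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(r), ids)) {
    hemifc_stop("hemifc_error_roi_mismatch",
                "square connectivity file: header and roi_id column disagree")
  }
  dimnames(r) <- list(ids, ids)
  if (max(abs(r - t(r))) > 1e-8) {
    hemifc_stop("hemifc_error_not_symmetric",
                "connectivity matrix is not symmetric")
  }
  r <- (r + t(r)) / 2
  diag(r) <- 1
  z <- fisher_z(r)
  diag(z) <- 0
  structure(list(subject_id = subject_id, group = group, r = r, z = z,
                 roi_order = ids),
            class = "connectivity_matrix")
}

#' Read connectivity matrices from a long-format TSV
#'
#' Columns `subject_id`, `group`, `roi_a`, `roi_b`, `r`, one row per
#' unordered pair per subject; the diagonal is implicit.
#'
#' @param path long-format file.
#' @param atlas a [roi_atlas] fixing the ROI order.
#' @return named list of `connectivity_matrix`.
#' @export
read_connectivity_long <- function(path, atlas) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "roi_a", "roi_b", "r")
  if (!all(need %in% names(df))) {
    hemifc_stop("hemifc_error_roi_mismatch",
                paste0("long connectivity file needs columns: ",
                       paste(need, collapse = ", ")))
  }
  ids <- atlas$roi_id
  lapply(split(df, df$subject_id), function(sub) {
    r <- diag(1, length(ids))
    dimnames(r) <- list(ids, ids)
    i <- match(sub$roi_a, ids)
    j <- match(sub$roi_b, ids)
    if (anyNA(i) || anyNA(j)) {
      hemifc_stop("hemifc_error_unknown_roi",
                  "long connectivity file names ROIs absent from the atlas")
    }
    r[cbind(i, j)] <- sub$r
    r[cbind(j, i)] <- sub$r
    z <- fisher_z(r)
    diag(z) <- 0
    structure(list(subject_id = sub$subject_id[1], group = sub$group[1],
                   r = r, z = z, roi_order = ids),
              class = "connectivity_matrix")
  })
}
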