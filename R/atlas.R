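# ROI atlas: the lateralized parcellation on which all hemispheric
# statistics operate. Hemisphere membership is declared in the table, never
# inferred from coordinates; the package never touches image space.

#' Construct and validate an ROI atlas
#'
#' An atlas is an ordered table of regions with columns `roi_id`, `name`,
#' `hemisphere` (one of `"L"`, `"R"`, `"M"` for midline) and
#' `homotopic_partner` (the `roi_id` of the mirror region, or `NA` for
#' none). Midline regions must not declare a partner, and declared partners
#' must pair a left with a right region bijectively.
#'
#' @param df data frame with the four columns above.
#' @return a validated `roi_atlas` (a data frame subclass, row order kept).
#' @export
#' @examples
#' roi_atlas(data.frame(
#'   roi_id = c("L_A", "R_A"), name = c("a", "a"),
#'   hemisphere = c("L", "R"), homotopic_partner = c("R_A", "L_A")
#' ))
roi_atlas <- function(df) {
  required <- c("roi_id", "name", "hemisphere", "homotopic_partner")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    hemifc_stop("hemifc_error_atlas_schema",
                paste0("atlas is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(df)[required]
  df$roi_id <- as.character(df$roi_id)
  df$name <- as.character(df$name)
  df$hemisphere <- as.character(df$hemisphere)
  df$homotopic_partner <- as.character(df$homotopic_partner)
  df$homotopic_partner[df$homotopic_partner %in% c("", ".")] <- NA_character_

  dup <- df$roi_id[duplicated(df$roi_id)]
  if (length(dup) > 0) {
    hemifc_stop("hemifc_error_duplicate_roi",
                paste0("duplicate roi_id: ", paste(unique(dup), collapse = ", ")))
  }
  bad_hemi <- which(!df$hemisphere %in% c("L", "R", "M"))
  if (length(bad_hemi) > 0) {
    hemifc_stop("hemifc_error_bad_hemisphere",
                sprintf("unknown hemisphere code '%s' for roi_id '%s' (row %d)",
                        df$hemisphere[bad_hemi[1]], df$roi_id[bad_hemi[1]],
                        bad_hemi[1]))
  }
  mid_with_partner <- which(df$hemisphere == "M" & !is.na(df$homotopic_partner))
  if (length(mid_with_partner) > 0) {
    hemifc_stop("hemifc_error_midline_partner",
                sprintf("midline roi_id '%s' (row %d) declares a homotopic partner",
                        df$roi_id[mid_with_partner[1]], mid_with_partner[1]))
  }
  declared <- which(!is.na(df$homotopic_partner))
  for (i in declared) {
    p <- df$homotopic_partner[i]
    j <- match(p, df$roi_id)
    if (is.na(j)) {
      hemifc_stop("hemifc_error_dangling_partner",
                  sprintf("roi_id '%s' (row %d) declares unknown partner '%s'",
                          df$roi_id[i], i, p))
    }
    if (df$hemisphere[j] == df$hemisphere[i]) {
      hemifc_stop("hemifc_error_same_side_partner",
                  sprintf("roi_id '%s' (row %d) and partner '%s' are both hemisphere %s",
                          df$roi_id[i], i, p, df$hemisphere[i]))
    }
    if (is.na(df$homotopic_partner[j]) || df$homotopic_partner[j] != df$roi_id[i]) {
      hemifc_stop("hemifc_error_asymmetric_partner",
                  sprintf("roi_id '%s' (row %d) declares partner '%s' but '%s' declares '%s'",
                          df$roi_id[i], i, p, p,
                          ifelse(is.na(df$homotopic_partner[j]), "none",
                                 df$homotopic_partner[j])))
    }
  }
  rownames(df) <- NULL
  class(df) <- c("roi_atlas", "data.frame")
  df
}

#' Load an ROI atlas from a tab-separated file
#'
#' The file must be UTF-8, tab-separated, with a header row
#' `roi_id  name  hemisphere  homotopic_partner`; `.` or an empty field
#' means no partner.
#'
#' @param path path to the atlas file.
#' @return a validated [roi_atlas].
#' @export
load_atlas <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = NULL,
                          fileEncoding = "UTF-8", check.names = FALSE)
  roi_atlas(df)
}

#' The bundled 105-region atlas
#'
#' A reconstruction of a Harvard-Oxford-style cortical + subcortical
#' parcellation with 105 regions: 50 homotopic left/right pairs plus 5
#' midline regions (frontal medial cortex, subcallosal cortex, anterior and
#' posterior cingulate, precuneus). It is a synthetic stand-in sharing the
#' region count, naming dialect and lateral structure of that parcellation,
#' not a coordinate-accurate copy; any user atlas with the same schema can
#' be used instead via [load_atlas()].
#'
#' @return a 105-row [roi_atlas].
#' @export
#' @examples
#' a <- default_atlas()
#' table(a$hemisphere)
default_atlas <- function() {
  load_atlas(system.file("extdata", "atlas_ho105_synthetic.tsv",
                         package = "hemifc", mustWork = TRUE))
}

#' Restrict an atlas to lateralized regions
#'
#' Drops midline (`M`) regions, which span both hemispheres and are
#' excluded from all lateralized statistics. Row order is preserved and the
#' operation is idempotent.
#'
#' @param atlas a [roi_atlas].
#' @return the atlas restricted to hemisphere `L`/`R`.
#' @export
lateral_subset <- function(atlas) {
  stopifnot(inherits(atlas, "roi_atlas"))
  out <- atlas[atlas$hemisphere %in% c("L", "R"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("roi_atlas", "data.frame")
  out
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat(sprintf("ROI atlas: %d regions (%d L, %d R, %d midline)\n",
              nrow(x), sum(x$hemisphere == "L"), sum(x$hemisphere == "R"),
              sum(x$hemisphere == "M")))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

# hemisphere lookup as a named vector, used throughout
atlas_hemi <- function(atlas) {
  stats::setNames(atlas$hemisphere, atlas$roi_id)
}
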