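#' Construct a longitudinal regional dataset
#'
#' Scan-level records for a longitudinal cohort: one row per scan, with
#' subject metadata and one column per cortical region. Groups follow
#' the three-arm design of familial-risk studies of Alzheimer's disease:
#' healthy controls (`HC`), cognitively normal subjects with a family
#' history of AD (`FHAD`), and clinical AD (`AD`).
#'
#' @param meta data.frame with columns `subject_id`, `group` (one of
#'   `HC`, `FHAD`, `AD`), `age` (years at scan), `sex` (`M`/`F`),
#'   `education_y`, `bmi`, `apoe4` (0, 1 or 2), `site`, `visit`
#'   (integer, 0 = baseline).
#' @param regional numeric matrix, rows matching `meta`, one column per
#'   region.
#' @param region_ids character region identifiers for the columns of
#'   `regional`.
#' @return An object of class `longitudinal_dataset`: a list with
#'   elements `meta` (sorted by subject then visit), `regional`, and
#'   `region_ids`.
#' @export
longitudinal_dataset <- function(meta, regional, region_ids = NULL) {
  regional <- as.matrix(regional)
  if (is.null(region_ids)) region_ids <- paste0("region_", seq_len(ncol(regional)))
  region_ids <- as.character(region_ids)
  required <- c("subject_id", "group", "age", "sex", "education_y",
                "bmi", "apoe4", "site", "visit")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("missing metadata columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(meta) != nrow(regional)) {
    stop("metadata and regional matrix row counts differ", call. = FALSE)
  }
  if (ncol(regional) != length(region_ids)) {
    stop("regional matrix has ", ncol(regional), " columns but ",
         length(region_ids), " region ids", call. = FALSE)
  }
  if (anyDuplicated(region_ids)) stop("duplicate region ids", call. = FALSE)
  meta$subject_id <- as.character(meta$subject_id)
  meta$group <- as.character(meta$group)
  bad_group <- setdiff(unique(meta$group), c("HC", "FHAD", "AD"))
  if (length(bad_group)) {
    stop("unknown group labels: ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(meta$subject_id, meta$visit, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1L]
    stop("duplicate (subject, visit) pair: subject ", meta$subject_id[dup],
         " visit ", meta$visit[dup], " (row ", dup, ")", call. = FALSE)
  }
  grp_per_subj <- tapply(meta$group, meta$subject_id,
                         function(g) length(unique(g)))
  if (any(grp_per_subj > 1L)) {
    bad <- names(grp_per_subj)[grp_per_subj > 1L]
    stop("subject(s) with conflicting group labels: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ord <- order(meta$subject_id, meta$visit)
  meta <- meta[ord, , drop = FALSE]
  regional <- regional[ord, , drop = FALSE]
  rownames(meta) <- NULL
  for (sid in unique(meta$subject_id)) {
    ages <- meta$age[meta$subject_id == sid]
    if (length(ages) > 1L && any(diff(ages) <= 0)) {
      stop("ages not strictly increasing across visits for subject ", sid,
           call. = FALSE)
    }
  }
  colnames(regional) <- region_ids
  structure(list(meta = meta, regional = regional, region_ids = region_ids),
            class = "longitudinal_dataset")
}

#' @export
print.longitudinal_dataset <- function(x, ...) {
  tab <- table(x$meta$group[!duplicated(x$meta$subject_id)])
  cat("<longitudinal_dataset> ", nrow(x$meta), " scans, ",
      length(unique(x$meta$subject_id)), " subjects, ",
      length(x$region_ids), " regions\n", sep = "")
  cat("  subjects per group:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
region_ids.longitudinal_dataset <- function(x) x$region_ids

# Baseline (visit 0, or minimum visit per subject) subset.
baseline_rows <- function(ds) {
  idx <- !duplicated(ds$meta$subject_id)  # rows sorted by (subject, visit)
  which(idx)
}

#' Read a longitudinal dataset from a delimited table
#'
#' Expects one row per scan with metadata columns `subject_id`, `group`,
#' `age`, `sex`, `education_y`, `bmi`, `apoe4`, `site`, `visit` and
#' region columns named `region_*` (or any columns not in the metadata
#' set, taken in file order). Tab and comma separated files are
#' accepted. Validation failures report the offending row or cell.
#'
#' @param path file path.
#' @return a [longitudinal_dataset()].
#' @export
load_longitudinal_table <- function(path) {
  df <- read_delim_auto(path)
  metacols <- c("subject_id", "group", "age", "sex", "education_y",
                "bmi", "apoe4", "site", "visit")
  regcols <- setdiff(names(df), metacols)
  if (!length(regcols)) stop("no region columns found in ", path, call. = FALSE)
  regional <- matrix(NA_real_, nrow(df), length(regcols),
                     dimnames = list(NULL, regcols))
  for (j in seq_along(regcols)) {
    raw <- df[[regcols[j]]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) & !(raw %in% c("NA", "")))
    if (length(bad)) {
      stop("non-numeric value in region column `", regcols[j],
           "`, row ", bad[1L], ": \"", raw[bad[1L]], "\"", call. = FALSE)
    }
    regional[, j] <- num
  }
  longitudinal_dataset(df[intersect(metacols, names(df))], regional, regcols)
}

#' Write a longitudinal dataset to a TSV file
#'
#' Inverse of [load_longitudinal_table()]; numeric values are written at
#' full double precision for exact round-trips.
#'
#' @param ds a `longitudinal_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_longitudinal_table <- function(ds, path) {
  reg <- apply(ds$regional, 2L, function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- "NA"
    out
  })
  if (nrow(ds$meta) == 1L) reg <- matrix(reg, nrow = 1L,
                                         dimnames = list(NULL, ds$region_ids))
  out <- cbind(ds$meta, as.data.frame(reg, stringsAsFactors = FALSE,
                                      check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a 7-network partition of regions
#'
#' Assigns every region to exactly one resting-state network label, in
#' the style of the canonical Yeo 7-network cortical parcellation.
#'
#' @param labels character vector of network labels, one per region.
#' @param region_ids character region identifiers.
#' @return object of class `network_partition` (named character vector).
#' @export
network_partition <- function(labels, region_ids = NULL) {
  labels <- as.character(labels)
  if (is.null(region_ids)) region_ids <- paste0("region_", seq_along(labels))
  if (length(labels) != length(region_ids)) {
    stop("labels and region_ids lengths differ", call. = FALSE)
  }
  if (anyNA(labels)) stop("every region must be assigned a network", call. = FALSE)
  structure(stats::setNames(labels, region_ids),
            region_ids = as.character(region_ids),
            class = "network_partition")
}

#' The canonical 7 resting-state network labels
#' @return character vector of length 7.
#' @export
yeo7_labels <- function() {
  c("visual", "somatomotor", "dorsal_attention", "ventral_attention",
    "limbic", "frontoparietal", "default_mode")
}
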