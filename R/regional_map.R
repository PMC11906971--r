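#' Construct a regional map
#'
#' A `regional_map` holds one scalar per cortical region of a fixed
#' parcellation: a deformation (DBM) value, a W-score, a progression
#' coefficient (units per year), a PET SUVR, or a z-scored receptor
#' density. Region identity is carried by an ordered character vector of
#' unique region ids; every multi-map operation in the package verifies
#' id agreement rather than silently reindexing.
#'
#' @param values numeric vector, one value per region. `NA` marks a
#'   missing region; non-missing values must be finite.
#' @param region_ids character vector of unique region identifiers, same
#'   length as `values`. Defaults to `"region_1" ... "region_R"`.
#' @param measure character tag naming the measure (e.g. `"dbm"`, `"w"`,
#'   `"beta"`, `"suvr"`, `"receptor_z"`).
#' @return An object of class `regional_map`: a named numeric vector with
#'   attributes `region_ids` and `measure`.
#' @examples
#' m <- regional_map(rnorm(10), measure = "dbm")
#' print(m)
#' @export
regional_map <- function(values, region_ids = NULL, measure = "value") {
  values <- as.numeric(values)
  if (is.null(region_ids)) {
    region_ids <- paste0("region_", seq_along(values))
  }
  region_ids <- as.character(region_ids)
  if (length(values) != length(region_ids)) {
    stop("`values` and `region_ids` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(region_ids)) {
    stop("duplicate region ids: ",
         paste(unique(region_ids[duplicated(region_ids)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.na(values) & !is.finite(values)
  if (any(bad)) {
    stop("non-finite values at regions: ",
         paste(region_ids[bad], collapse = ", "), call. = FALSE)
  }
  structure(stats::setNames(values, region_ids),
            region_ids = region_ids, measure = measure,
            class = "regional_map")
}

#' @export
print.regional_map <- function(x, ...) {
  cat("<regional_map> measure:", attr(x, "measure"),
      " regions:", length(x),
      " missing:", sum(is.na(x)), "\n")
  v <- unclass(x)
  attributes(v) <- list(names = names(v))
  print(utils::head(v, 6L))
  if (length(x) > 6L) cat("... (", length(x) - 6L, " more)\n", sep = "")
  invisible(x)
}

#' @export
as.numeric.regional_map <- function(x, ...) {
  v <- unclass(x)
  attributes(v) <- NULL
  v
}

#' Region ids of an object
#'
#' @param x a `regional_map`, `connectome`, or other object carrying
#'   region identifiers.
#' @return character vector of region ids.
#' @export
region_ids <- function(x) UseMethod("region_ids")

#' @export
region_ids.default <- function(x) {
  ids <- attr(x, "region_ids")
  if (is.null(ids) && !is.null(names(x))) ids <- names(x)
  ids
}

# Fails unless all objects share the identical ordered region id vector.
check_regions_match <- function(...) {
  objs <- list(...)
  ids <- lapply(objs, region_ids)
  ref <- ids[[1L]]
  for (k in seq_along(ids)[-1L]) {
    if (!identical(ref, ids[[k]])) {
      stop("region id orderings disagree between inputs; ",
           "reorder explicitly before calling", call. = FALSE)
    }
  }
  invisible(ref)
}

#' Write a regional map to a delimited text file
#'
#' Two-column TSV (`region_id`, `value`); missing regions written as
#' `NA`. Values are written at full double precision so that
#' `load_map(save_map(m))` reproduces `m` exactly.
#'
#' @param map a `regional_map`.
#' @param path output file path.
#' @param sep field separator, tab by default.
#' @return `path`, invisibly.
#' @export
save_map <- function(map, path, sep = "\t") {
  stopifnot(inherits(map, "regional_map"))
  df <- data.frame(region_id = region_ids(map),
                   value = sprintf("%.17g", as.numeric(map)),
                   stringsAsFactors = FALSE)
  df$value[is.na(as.numeric(map))] <- "NA"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a regional map from a delimited text file
#'
#' @param path file written by [save_map()] (or any two-column table with
#'   `region_id` and `value` columns; tab or comma separated).
#' @param measure measure tag to attach.
#' @return a `regional_map`.
#' @export
load_map <- function(path, measure = "value") {
  df <- read_delim_auto(path)
  if (!all(c("region_id", "value") %in% names(df))) {
    stop("map file must have columns `region_id` and `value`: ", path,
         call. = FALSE)
  }
  if (anyDuplicated(df$region_id)) {
    stop("duplicate region ids in ", path, ": ",
         paste(unique(df$region_id[duplicated(df$region_id)]), collapse = ", "),
         call. = FALSE)
  }
  regional_map(as.numeric(df$value), as.character(df$region_id), measure)
}

# Read a TSV/CSV, sniffing the delimiter from the header line.
read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
}

# z-score a numeric vector over its non-missing entries.
zscore <- function(x) {
  mu <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score a zero-variance vector", call. = FALSE)
  }
  (x - mu) / s
}
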