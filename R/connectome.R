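#' Construct a structural connectome
#'
#' A binary, undirected, zero-diagonal adjacency matrix over cortical
#' regions, plus 3-D region coordinates in mm (typically parcel
#' centroids in template space).
#'
#' @param adjacency R x R matrix of 0/1 values; must be symmetric.
#' @param coordinates R x 3 numeric matrix of region coordinates (mm).
#' @param region_ids character region identifiers.
#' @param subject_id optional subject identifier for subject-level
#'   matrices.
#' @return object of class `connectome`.
#' @export
connectome <- function(adjacency, coordinates, region_ids = NULL,
                       subject_id = NULL) {
  adjacency <- as.matrix(adjacency)
  coordinates <- as.matrix(coordinates)
  R <- nrow(adjacency)
  if (ncol(adjacency) != R) stop("adjacency must be square", call. = FALSE)
  if (nrow(coordinates) != R || ncol(coordinates) != 3L) {
    stop("coordinates must be R x 3", call. = FALSE)
  }
  if (!all(is.finite(coordinates))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (!all(adjacency %in% c(0, 1))) {
    stop("adjacency must be binary (0/1)", call. = FALSE)
  }
  if (any(adjacency != t(adjacency))) {
    stop("adjacency is not symmetric", call. = FALSE)
  }
  if (any(diag(adjacency) != 0)) {
    warning("nonzero diagonal in adjacency; forcing to 0")
    diag(adjacency) <- 0
  }
  if (is.null(region_ids)) region_ids <- paste0("region_", seq_len(R))
  region_ids <- as.character(region_ids)
  if (length(region_ids) != R) stop("region_ids length mismatch", call. = FALSE)
  dimnames(adjacency) <- list(region_ids, region_ids)
  rownames(coordinates) <- region_ids
  colnames(coordinates) <- c("x", "y", "z")
  structure(list(adjacency = adjacency, coordinates = coordinates,
                 region_ids = region_ids, subject_id = subject_id),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  R <- length(x$region_ids)
  dens <- sum(x$adjacency) / (R * (R - 1))
  cat("<connectome> ", R, " regions, density ",
      format(dens, digits = 3), sep = "")
  if (!is.null(x$subject_id)) cat(", subject ", x$subject_id, sep = "")
  cat("\n")
  invisible(x)
}

#' @export
region_ids.connectome <- function(x) x$region_ids

#' Read a connectome from adjacency and coordinate files
#'
#' The adjacency file is a dense whitespace- or comma-delimited R x R
#' binary matrix with no header; the coordinate file is a table with
#' columns `region_id`, `x`, `y`, `z` (mm). An asymmetric adjacency is a
#' hard failure; a nonzero diagonal is zeroed with a warning.
#'
#' @param adjacency_path path to the matrix file.
#' @param coords_path path to the coordinate table.
#' @return a [connectome()].
#' @export
load_connectome <- function(adjacency_path, coords_path) {
  adj <- as.matrix(utils::read.table(adjacency_path, header = FALSE,
                                     sep = "", comment.char = ""))
  if (ncol(adj) == 1L) {  # comma-delimited fallback
    adj <- as.matrix(utils::read.table(adjacency_path, header = FALSE,
                                       sep = ","))
  }
  dimnames(adj) <- NULL
  coords <- read_delim_auto(coords_path)
  if (!all(c("region_id", "x", "y", "z") %in% names(coords))) {
    stop("coordinate file must have columns region_id, x, y, z",
         call. = FALSE)
  }
  connectome(adj, as.matrix(coords[, c("x", "y", "z")]),
             as.character(coords$region_id))
}

#' Write a connectome's adjacency and coordinates to text files
#'
#' @param con a `connectome`.
#' @param adjacency_path,coords_path output paths.
#' @return invisibly, the two paths.
#' @export
save_connectome <- function(con, adjacency_path, coords_path) {
  utils::write.table(con$adjacency, adjacency_path, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  df <- data.frame(region_id = con$region_ids,
                   x = sprintf("%.17g", con$coordinates[, 1L]),
                   y = sprintf("%.17g", con$coordinates[, 2L]),
                   z = sprintf("%.17g", con$coordinates[, 3L]))
  utils::write.table(df, coords_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(adjacency_path, coords_path))
}

#' Group-consensus connectome from subject matrices
#'
#' An edge is retained in the consensus iff it is present in at least
#' `retain_fraction` of the subject matrices. The optional
#' distance-binned variant selects, within each edge-length bin, the
#' most consistent edges so that the consensus preserves the
#' subject-mean edge count per bin (and hence approximately the
#' subject-mean edge-length distribution).
#'
#' @param connectomes list of `connectome` objects with identical region
#'   ids.
#' @param retain_fraction fraction of subjects in which an edge must
#'   appear (default 0.5).
#' @param distance_binned logical; use the distance-binned consensus.
#' @param n_bins number of edge-length bins for the binned variant.
#' @return a consensus [connectome()].
#' @export
consensus_connectome <- function(connectomes, retain_fraction = 0.5,
                                 distance_binned = FALSE, n_bins = 10L) {
  if (length(connectomes) < 2L) {
    stop("need at least 2 subject connectomes", call. = FALSE)
  }
  ids <- region_ids(connectomes[[1L]])
  for (con in connectomes[-1L]) {
    if (!identical(region_ids(con), ids)) {
      stop("subject connectomes have mismatched region sets", call. = FALSE)
    }
  }
  R <- length(ids)
  freq <- Reduce(`+`, lapply(connectomes, `[[`, "adjacency")) /
    length(connectomes)
  coords <- connectomes[[1L]]$coordinates
  if (!distance_binned) {
    adj <- (freq >= retain_fraction) * 1
  } else {
    D <- distance_matrix(coords)
    ut <- upper.tri(freq)
    target_edges <- mean(vapply(connectomes,
                                function(x) sum(x$adjacency[ut]), 0))
    d_ut <- D[ut]; f_ut <- freq[ut]
    bins <- cut(d_ut, breaks = stats::quantile(d_ut, seq(0, 1, length.out = n_bins + 1L)),
                include.lowest = TRUE)
    # per-bin quota proportional to the subject-mean edge count in the bin
    per_bin_mean <- tapply(f_ut, bins, sum)
    quota <- round(per_bin_mean / sum(per_bin_mean) * target_edges)
    keep <- logical(length(d_ut))
    for (b in levels(bins)) {
      in_b <- which(bins == b)
      k <- min(quota[[b]], length(in_b))
      if (k > 0) keep[in_b[order(f_ut[in_b], decreasing = TRUE)[seq_len(k)]]] <- TRUE
    }
    adj <- matrix(0, R, R)
    adj[which(ut)[keep]] <- 1
    adj <- adj + t(adj)
  }
  diag(adj) <- 0
  connectome(adj, coords, ids)
}
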