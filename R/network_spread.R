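#' Mean value over structurally connected (or non-connected) neighbors
#'
#' For each region i, the mean of the map over its structurally
#' connected neighbors `{j != i : A_ij = 1}` (mode `"connected"`) or
#' over all other regions it is not connected to
#' `{j != i : A_ij = 0}` (mode `"nonconnected"`). Regions with an empty
#' neighbor set, and missing map values among the neighbors, propagate
#' as missing in the natural pairwise-complete way.
#'
#' @param map numeric vector or `regional_map`.
#' @param con a [connectome()] sharing the map's regions.
#' @param mode `"connected"` or `"nonconnected"`.
#' @return a `regional_map` of neighbor means.
#' @export
neighbor_mean <- function(map, con, mode = c("connected", "nonconnected")) {
  mode <- match.arg(mode)
  stopifnot(inherits(con, "connectome"))
  if (inherits(map, "regional_map")) check_regions_match(map, con)
  x <- as.numeric(map)
  R <- length(x)
  stopifnot(R == nrow(con$adjacency))
  A <- con$adjacency
  if (mode == "nonconnected") {
    A <- 1 - A
    diag(A) <- 0
  }
  xx <- ifelse(is.na(x), 0, x)
  present <- as.numeric(!is.na(x))
  num <- drop(A %*% xx)
  den <- drop(A %*% present)
  out <- ifelse(den > 0, num / den, NA_real_)
  regional_map(out, con$region_ids,
               paste0("neighbor_mean_", mode))
}

# Column-wise neighbor means for a surrogate matrix (R x n_surr).
neighbor_mean_matrix <- function(S, A) {
  den <- rowSums(A)
  M <- A %*% S
  M / ifelse(den == 0, NA_real_, den)
}

# Column-wise Pearson correlation between the columns of X and Y
# restricted to rows `keep`.
colwise_cor <- function(X, Y, keep) {
  X <- X[keep, , drop = FALSE]; Y <- Y[keep, , drop = FALSE]
  Xc <- sweep(X, 2L, colMeans(X)); Yc <- sweep(Y, 2L, colMeans(Y))
  colSums(Xc * Yc) / sqrt(colSums(Xc^2) * colSums(Yc^2))
}

#' Connectome neighbor-spread test
#'
#' The neighbor-spread statistic of network-spread analyses: the
#' Pearson correlation across regions between a map (e.g. atrophy
#' progression beta) and the mean value of each region's structurally
#' connected neighbors, with the analogous correlation over
#' non-connected regions as a specificity contrast. If pathology
#' spreads along connections, the connected-neighbor correlation is
#' positive and the non-connected one is not. Significance is assessed
#' against variogram-matched surrogates of the map, each surrogate
#' passed through the same neighbor operator before correlating, so the
#' null respects both spatial autocorrelation and the joint structure
#' of the statistic. Regions with an empty connected-neighbor set are
#' excluded listwise from both contrasts so the two use identical
#' samples.
#'
#' @param map numeric vector or `regional_map`, finite values.
#' @param con a [connectome()].
#' @param D distance matrix or [surrogate_context()] for surrogate
#'   generation.
#' @param n_surr number of surrogates (default 1000).
#' @param rng_seed integer seed.
#' @return object of class `spread_result`: `connected` and
#'   `nonconnected` (each a [spin_correlation_test()]-style `spin_test`),
#'   `neighbor_means` (list of the two `regional_map`s), `excluded`
#'   (region ids with no connected neighbors), `n_regions_used`.
#' @export
spread_test <- function(map, con, D, n_surr = 1000L, rng_seed = 1L) {
  stopifnot(inherits(con, "connectome"))
  if (inherits(map, "regional_map")) check_regions_match(map, con)
  x <- as.numeric(map)
  A <- con$adjacency
  R <- nrow(A)
  nm_conn <- neighbor_mean(x, con, "connected")
  nm_non <- neighbor_mean(x, con, "nonconnected")
  keep <- !is.na(x) & !is.na(as.numeric(nm_conn)) & !is.na(as.numeric(nm_non))
  excluded <- con$region_ids[!keep]
  if (sum(keep) < 20L) {
    stop("fewer than 20 regions with nonempty neighbor sets", call. = FALSE)
  }
  if (stats::sd(as.numeric(nm_conn)[keep]) == 0) {
    stop("constant neighbor-mean vector", call. = FALSE)
  }
  ens <- generate_surrogates(x, D, n_surr, rng_seed)
  S <- ens$surrogates
  A_non <- 1 - A; diag(A_non) <- 0
  null_conn <- colwise_cor(S, neighbor_mean_matrix(S, A), keep)
  null_non <- colwise_cor(S, neighbor_mean_matrix(S, A_non), keep)
  r_conn <- stats::cor(x[keep], as.numeric(nm_conn)[keep])
  r_non <- stats::cor(x[keep], as.numeric(nm_non)[keep])
  mk <- function(r, null_r) {
    structure(list(r = r,
                   p_spin = (1 + sum(abs(null_r) >= abs(r))) / (n_surr + 1),
                   null_mean = mean(null_r), null_sd = stats::sd(null_r),
                   null_quantiles = stats::quantile(null_r,
                                                    c(0.025, 0.25, 0.5, 0.75, 0.975)),
                   null_r = null_r, n_surr = n_surr, rng_seed = rng_seed,
                   method = "pearson", n_regions = sum(keep)),
              class = "spin_test")
  }
  structure(list(connected = mk(r_conn, null_conn),
                 nonconnected = mk(r_non, null_non),
                 neighbor_means = list(connected = nm_conn,
                                       nonconnected = nm_non),
                 excluded = excluded, n_regions_used = sum(keep),
                 rng_seed = rng_seed),
            class = "spread_result")
}

#' @export
print.spread_result <- function(x, ...) {
  cat("<spread_result> ", x$n_regions_used, " regions used (",
      length(x$excluded), " excluded)\n", sep = "")
  cat("  connected neighbors:    r = ",
      format(x$connected$r, digits = 3), ", p_spin = ",
      format(x$connected$p_spin, digits = 3), "\n", sep = "")
  cat("  non-connected regions:  r = ",
      format(x$nonconnected$r, digits = 3), ", p_spin = ",
      format(x$nonconnected$p_spin, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Neighbor-spread tests over several maps with FDR
#'
#' Runs [spread_test()] for each map in a named list against the same
#' connectome and applies BH-FDR across the collection (separately for
#' the connected and non-connected families).
#'
#' @param maps named list of maps.
#' @param con a [connectome()].
#' @param D distance matrix or context.
#' @param n_surr,rng_seed surrogate settings; seed is advanced by 1 per
#'   map.
#' @param q FDR level.
#' @return data.frame with per-map r and p for both contrasts plus
#'   FDR-adjusted p columns; the individual `spread_result`s as an
#'   attribute `"results"`.
#' @export
spread_test_many <- function(maps, con, D, n_surr = 1000L, rng_seed = 1L,
                             q = 0.05) {
  results <- list()
  for (k in seq_along(maps)) {
    results[[names(maps)[k]]] <-
      spread_test(maps[[k]], con, D, n_surr, rng_seed + k - 1L)
  }
  tab <- data.frame(
    map = names(maps),
    r_connected = vapply(results, function(r) r$connected$r, 0),
    p_connected = vapply(results, function(r) r$connected$p_spin, 0),
    r_nonconnected = vapply(results, function(r) r$nonconnected$r, 0),
    p_nonconnected = vapply(results, function(r) r$nonconnected$p_spin, 0),
    row.names = NULL)
  tab$p_connected_fdr <- bh_fdr(tab$p_connected, q)$p_adjusted
  tab$p_nonconnected_fdr <- bh_fdr(tab$p_nonconnected, q)$p_adjusted
  attr(tab, "results") <- results
  tab
}
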