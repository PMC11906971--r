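#' Euclidean distance matrix between region coordinates
#'
#' @param coordinates R x 3 matrix of coordinates in mm.
#' @return symmetric R x R matrix of Euclidean distances, zero diagonal.
#' @export
distance_matrix <- function(coordinates) {
  coordinates <- as.matrix(coordinates)
  if (!all(is.finite(coordinates))) stop("coordinates must be finite",
                                         call. = FALSE)
  D <- as.matrix(stats::dist(coordinates))
  dimnames(D) <- NULL
  D
}

#' Precomputed context for surrogate-map generation
#'
#' Surrogate generation repeatedly needs quantities that depend only on
#' the distance matrix: the distance-bin pair index (pairs up to the
#' 75th distance percentile, used for the empirical variogram), the
#' bin-smoothing kernel, and one distance-weighted k-nearest-neighbor
#' smoothing matrix per candidate neighborhood size. Building them once
#' and passing the context to [generate_surrogates()],
#' [spin_correlation_test()] or [spread_test()] amortizes the cost over
#' many maps sharing one geometry.
#'
#' @param D R x R distance matrix (mm).
#' @param n_bins number of variogram distance bins (default 25).
#' @param k_grid candidate neighborhood sizes as fractions of R. The
#'   default spans 0.02 ... 0.9: short-correlation-length fields (around
#'   20 mm on a whole-cortex geometry) need very local smoothing, so the
#'   grid reaches well below the coarse fractions.
#' @return object of class `surrogate_context`.
#' @export
surrogate_context <- function(D, n_bins = 25L,
                              k_grid = c(0.02, 0.05, seq(0.1, 0.9, by = 0.1))) {
  R <- nrow(D)
  stopifnot(n_bins >= 5L, R >= 10L)
  ut <- which(upper.tri(D))
  d_ut <- D[ut]
  dmax <- stats::quantile(d_ut, 0.75, names = FALSE)
  use <- d_ut <= dmax
  pair_i <- ((ut - 1L) %% R) + 1L          # row index of upper-tri entry
  pair_j <- ((ut - 1L) %/% R) + 1L         # column index
  pair_i <- pair_i[use]; pair_j <- pair_j[use]; d_use <- d_ut[use]
  edges <- seq(0, dmax, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(d_use, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(bin, n_bins)
  centers <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  keep_bins <- counts > 0L
  if (!all(keep_bins)) {
    # empty bins are merged into their nearest nonempty neighbor
    message("variogram: ", sum(!keep_bins), " empty bin(s) merged")
    nonempty <- which(keep_bins)
    remap <- vapply(seq_len(n_bins), function(b)
      nonempty[which.min(abs(centers[nonempty] - centers[b]))], 0L)
    bin <- remap[bin]
    centers <- centers[nonempty]
    bin <- match(bin, nonempty)
    counts <- tabulate(bin, length(nonempty))
    n_bins <- length(nonempty)
  }
  # Gaussian kernel smoother across bins; bandwidth = 2 bin widths
  h <- 2 * dmax / n_bins
  K <- exp(-0.5 * outer(centers, centers, "-")^2 / h^2)
  S <- K / rowSums(K)
  # k-NN smoothing matrices, exponential distance kernel
  ks <- unique(pmin(R - 1L, pmax(2L, round(k_grid * R))))
  ord <- apply(D, 1L, order)               # column s: regions by distance to s
  W <- lapply(ks, function(k) {
    Wk <- matrix(0, R, R)
    for (i in seq_len(R)) {
      nb <- ord[2:(k + 1L), i]             # k nearest, excluding self
      dk <- D[i, nb]
      w <- exp(-dk / dk[k])
      Wk[i, nb] <- w / sum(w)
    }
    Wk
  })
  structure(list(R = R, pair_i = pair_i, pair_j = pair_j, bin = bin,
                 counts = counts, centers = centers, smoother = S,
                 n_bins = n_bins, ks = ks, W = W, dmax = dmax),
            class = "surrogate_context")
}

# Smoothed empirical variograms for the columns of a matrix X (R x m).
variogram_matrix <- function(ctx, X) {
  X <- as.matrix(X)
  dsq <- (X[ctx$pair_i, , drop = FALSE] - X[ctx$pair_j, , drop = FALSE])^2
  raw <- rowsum(dsq, ctx$bin, reorder = TRUE) / (2 * ctx$counts)
  ctx$smoother %*% raw
}

#' Smoothed empirical variogram of a regional map
#'
#' Computes \eqn{\gamma(d) = \frac{1}{2}\,\mathrm{mean}\,(x_i - x_j)^2}
#' over region pairs binned by distance, spanning distances up to the
#' 75th percentile, then Gaussian-kernel smooths the bin estimates.
#'
#' @param map numeric vector or `regional_map`.
#' @param D distance matrix, or a [surrogate_context()].
#' @param n_bins number of distance bins (>= 5).
#' @return data.frame with columns `distance` (bin center), `gamma`
#'   (smoothed estimate), and `n_pairs`.
#' @export
variogram <- function(map, D, n_bins = 25L) {
  ctx <- if (inherits(D, "surrogate_context")) D else
    surrogate_context(D, n_bins = n_bins)
  x <- as.numeric(map)
  stopifnot(length(x) == ctx$R)
  g <- drop(variogram_matrix(ctx, matrix(x)))
  data.frame(distance = ctx$centers, gamma = g, n_pairs = ctx$counts)
}

#' Variogram-matched surrogate maps
#'
#' Generates null maps that destroy a map's topographic alignment while
#' preserving its spatial autocorrelation, in the variogram-matching
#' style used for parcellated cortical maps. For each surrogate the map
#' values are randomly permuted; the permuted map is smoothed by
#' distance-weighted averaging over each region's k nearest neighbors
#' (exponential kernel) for every candidate k; the candidate whose
#' variogram best matches the source variogram under an affine fit
#' \eqn{\hat\gamma_{src} \approx \beta \hat\gamma_k + \alpha} is
#' selected; the surrogate is
#' \eqn{\sqrt{|\beta|}\,\mathrm{smoothed} + \sqrt{|\alpha|}\,z} with
#' standard normal z, and finally (by default) rank-remapped onto the
#' source map's exact value multiset.
#'
#' @param map numeric vector or `regional_map`, all values finite.
#' @param D distance matrix in mm, or a prebuilt [surrogate_context()].
#' @param n_surr number of surrogates (>= 1; >= 100 recommended for
#'   inference).
#' @param rng_seed integer seed; output is deterministic given
#'   `(map, D, rng_seed, params)`.
#' @param rank_remap remap each surrogate onto the source value multiset
#'   (default TRUE).
#' @param n_bins,k_grid variogram and neighborhood parameters, used only
#'   when `D` is a raw matrix.
#' @return object of class `surrogate_ensemble`: list with `surrogates`
#'   (R x n_surr matrix), `k_selected`, `alpha`, `beta`, `rng_seed`,
#'   and the context parameters.
#' @export
generate_surrogates <- function(map, D, n_surr, rng_seed = 1L,
                                rank_remap = TRUE, n_bins = 25L,
                                k_grid = c(0.02, 0.05,
                                           seq(0.1, 0.9, by = 0.1))) {
  x <- as.numeric(map)
  if (anyNA(x) || !all(is.finite(x))) {
    stop("map must be finite (subset to complete regions first)",
         call. = FALSE)
  }
  stopifnot(n_surr >= 1L)
  ctx <- if (inherits(D, "surrogate_context")) D else
    surrogate_context(D, n_bins = n_bins, k_grid = k_grid)
  R <- ctx$R
  stopifnot(length(x) == R)
  g_target <- drop(variogram_matrix(ctx, matrix(x)))
  v_t <- stats::var(g_target) * (ctx$n_bins - 1L)  # SS around mean
  set.seed(rng_seed)
  P <- vapply(seq_len(n_surr), function(s) x[sample.int(R)],
              numeric(R))                          # R x n_surr
  Z <- matrix(stats::rnorm(R * n_surr), R, n_surr)
  n_k <- length(ctx$ks)
  sse <- matrix(Inf, n_k, n_surr)
  ab <- array(0, c(2L, n_k, n_surr))
  chunk <- max(1L, min(n_surr, floor(2e7 / length(ctx$pair_i))))
  smoothed <- vector("list", n_k)
  gt_c <- g_target - mean(g_target)
  for (k in seq_len(n_k)) {
    Sk <- ctx$W[[k]] %*% P
    smoothed[[k]] <- Sk
    for (s0 in seq(1L, n_surr, by = chunk)) {
      sl <- s0:min(n_surr, s0 + chunk - 1L)
      G <- variogram_matrix(ctx, Sk[, sl, drop = FALSE])  # n_bins x |sl|
      gm <- colMeans(G)
      Gc <- sweep(G, 2L, gm)
      vk <- colSums(Gc^2)
      cov_kt <- drop(crossprod(Gc, gt_c))
      beta <- ifelse(vk > 0, cov_kt / vk, 0)
      alpha <- mean(g_target) - beta * gm
      sse[k, sl] <- v_t - ifelse(vk > 0, cov_kt^2 / vk, 0)
      ab[1L, k, sl] <- alpha
      ab[2L, k, sl] <- beta
    }
  }
  if (all(!is.finite(sse))) {
    stop("all candidate variogram fits are degenerate", call. = FALSE)
  }
  best <- max.col(-t(sse), ties.method = "first")   # per-surrogate argmin k
  surr <- matrix(NA_real_, R, n_surr)
  for (s in seq_len(n_surr)) {
    k <- best[s]
    surr[, s] <- sqrt(abs(ab[2L, k, s])) * smoothed[[k]][, s] +
      sqrt(abs(ab[1L, k, s])) * Z[, s]
  }
  if (rank_remap) {
    xs <- sort(x)
    for (s in seq_len(n_surr)) {
      surr[, s] <- xs[rank(surr[, s], ties.method = "first")]
    }
  }
  idx <- cbind(best, seq_len(n_surr))
  structure(list(surrogates = surr, k_selected = ctx$ks[best],
                 alpha = ab[cbind(1L, idx)],
                 beta = ab[cbind(2L, idx)],
                 rng_seed = rng_seed, n_bins = ctx$n_bins,
                 rank_remap = rank_remap, source_map = x),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat("<surrogate_ensemble> ", ncol(x$surrogates), " surrogates x ",
      nrow(x$surrogates), " regions (seed ", x$rng_seed,
      ", rank_remap ", x$rank_remap, ")\n", sep = "")
  invisible(x)
}

#' Spatially constrained correlation test (spin test)
#'
#' Tests a map-to-map correlation against a null distribution built
#' from variogram-matched surrogates of the first map, so that the
#' test respects the maps' spatial autocorrelation (naive parametric
#' p-values are anticonservative for smooth maps). Two-sided with the
#' +1 permutation correction, so p is never below `1/(n_surr + 1)`.
#'
#' @param x_map,y_map numeric vectors or `regional_map`s over the same
#'   regions; `x_map` is the map that gets surrogated.
#' @param D distance matrix or [surrogate_context()] (ignored if
#'   `ensemble` is supplied).
#' @param n_surr number of surrogates (default 1000).
#' @param rng_seed integer seed.
#' @param method `"pearson"` or `"spearman"`.
#' @param ensemble optional precomputed [generate_surrogates()] ensemble
#'   of `x_map`, reused across many `y_map`s.
#' @return object of class `spin_test` with fields `r`, `p_spin`,
#'   `null_mean`, `null_sd`, `null_quantiles`, `n_surr`, `rng_seed`,
#'   `method`, `n_regions`.
#' @export
spin_correlation_test <- function(x_map, y_map, D = NULL, n_surr = 1000L,
                                  rng_seed = 1L,
                                  method = c("pearson", "spearman"),
                                  ensemble = NULL) {
  method <- match.arg(method)
  if (inherits(x_map, "regional_map") && inherits(y_map, "regional_map")) {
    check_regions_match(x_map, y_map)
  }
  x <- as.numeric(x_map); y <- as.numeric(y_map)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 20L) stop("need at least 20 pairwise-complete regions",
                          call. = FALSE)
  if (!all(ok)) {
    if (is.null(ensemble)) {
      x <- x[ok]; y <- y[ok]
      D <- if (inherits(D, "surrogate_context"))
        stop("cannot subset a prebuilt context; pass D for maps with ",
             "missing regions", call. = FALSE) else D[ok, ok]
    } else stop("ensemble provided but maps have missing regions",
                call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant map passed to spin_correlation_test", call. = FALSE)
  }
  if (is.null(ensemble)) {
    ensemble <- generate_surrogates(x, D, n_surr, rng_seed)
  }
  n_surr <- ncol(ensemble$surrogates)
  r_emp <- stats::cor(x, y, method = method)
  if (method == "spearman") {
    yr <- rank(y)
    null_r <- drop(stats::cor(apply(ensemble$surrogates, 2L, rank), yr))
  } else {
    null_r <- drop(stats::cor(ensemble$surrogates, y))
  }
  p <- (1 + sum(abs(null_r) >= abs(r_emp))) / (n_surr + 1)
  structure(list(r = r_emp, p_spin = p, null_mean = mean(null_r),
                 null_sd = stats::sd(null_r),
                 null_quantiles = stats::quantile(null_r,
                                                  c(0.025, 0.25, 0.5, 0.75, 0.975)),
                 null_r = null_r, n_surr = n_surr, rng_seed = rng_seed,
                 method = method, n_regions = length(x)),
            class = "spin_test")
}

#' @export
print.spin_test <- function(x, ...) {
  cat("<spin_test> r = ", format(x$r, digits = 3),
      ", p_spin = ", format(x$p_spin, digits = 3),
      " (", x$n_surr, " surrogates, ", x$method, ", ",
      x$n_regions, " regions)\n", sep = "")
  invisible(x)
}
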