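#' Spatial colocalization of maps with surrogate-based significance
#'
#' Pearson (or Spearman) correlations between each target map (e.g. an
#' atrophy-progression beta map or baseline W map) and each candidate
#' map (receptor densities, PET SUVR maps, another group's atrophy
#' map), tested against variogram-matched surrogates of the target;
#' BH-FDR across the candidate set within each target. One surrogate
#' ensemble per target is generated and shared across its candidates.
#'
#' @param targets named list of maps (each a `regional_map` or numeric
#'   vector); the target is the map that gets surrogated.
#' @param candidates named list of maps over the same regions.
#' @param D distance matrix or [surrogate_context()].
#' @param n_surr surrogates per target (default 1000).
#' @param rng_seed integer seed; advanced by 1 per target.
#' @param method correlation method.
#' @param q FDR level.
#' @return data.frame with columns `target`, `candidate`, `r`,
#'   `p_spin`, `p_spin_fdr`, `n_regions`.
#' @export
colocalize <- function(targets, candidates, D, n_surr = 1000L,
                       rng_seed = 1L, method = c("pearson", "spearman"),
                       q = 0.05) {
  method <- match.arg(method)
  if (is.null(names(targets)) || is.null(names(candidates))) {
    stop("`targets` and `candidates` must be named lists", call. = FALSE)
  }
  ctx <- if (inherits(D, "surrogate_context")) D else surrogate_context(D)
  rows <- list()
  for (ti in seq_along(targets)) {
    x <- targets[[ti]]
    ens <- generate_surrogates(as.numeric(x), ctx, n_surr,
                               rng_seed + ti - 1L)
    for (ci in seq_along(candidates)) {
      st <- spin_correlation_test(x, candidates[[ci]], ctx,
                                  n_surr = n_surr,
                                  rng_seed = rng_seed + ti - 1L,
                                  method = method, ensemble = ens)
      rows[[length(rows) + 1L]] <- data.frame(
        target = names(targets)[ti], candidate = names(candidates)[ci],
        r = st$r, p_spin = st$p_spin, n_regions = st$n_regions,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$p_spin_fdr <- NA_real_
  for (t in unique(tab$target)) {
    sel <- tab$target == t
    tab$p_spin_fdr[sel] <- bh_fdr(tab$p_spin[sel], q)$p_adjusted
  }
  rownames(tab) <- NULL
  tab
}

# Fisher-z confidence interval for a single correlation.
fisher_ci <- function(r, n, level = 0.95) {
  zc <- stats::qnorm(1 - (1 - level) / 2)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  tanh(c(z - zc * se, z + zc * se))
}

#' Compare two correlations from independent samples
#'
#' Fisher z test: \eqn{z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2)
#' / \sqrt{1/(n_1-3) + 1/(n_2-3)}}, two-sided p. Used for comparing the
#' same map-map correlation between groups (e.g. tau-vs-progression in
#' AD versus FHAD).
#'
#' @param r1,r2 the two correlations (|r| < 1).
#' @param n1,n2 sample sizes (>= 10).
#' @return object of class `correlation_comparison` with `statistic`
#'   (z) and `p_value`.
#' @export
compare_independent <- function(r1, n1, r2, n2) {
  stopifnot(n1 >= 10, n2 >= 10)
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("|r| must be < 1", call. = FALSE)
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(r1 = r1, r2 = r2, n1 = n1, n2 = n2,
                 comparison = "independent",
                 statistic = z, p_value = 2 * stats::pnorm(-abs(z)),
                 ci = NULL),
            class = "correlation_comparison")
}

#' Compare two dependent correlations (Zou confidence interval)
#'
#' Modified-asymptotic confidence interval for the difference r1 - r2
#' between correlations measured on the same sample. In the
#' *overlapping* case the two correlations share a variable (r1 =
#' cor(x, y1), r2 = cor(x, y2)) and `cross` is the single correlation
#' cor(y1, y2). In the *non-overlapping* case (r1 = cor(x1, y1), r2 =
#' cor(x2, y2)) `cross` carries the four correlations between the
#' non-shared pairs, named `r13`, `r14`, `r23`, `r24` for variables
#' ordered (x1 = 1, y1 = 2, x2 = 3, y2 = 4). Each correlation gets a
#' Fisher-z CI; the corner combination is adjusted by the asymptotic
#' correlation between the two estimates. With zero cross-correlations
#' the non-overlapping interval reduces to the independent-samples
#' corner formula
#' \eqn{L = r_1 - r_2 - \sqrt{(r_1-l_1)^2 + (u_2-r_2)^2}}.
#'
#' @param r1,r2 the two correlations.
#' @param cross numeric: length 1 (overlapping) or named length 4
#'   (non-overlapping).
#' @param n common sample size (>= 10).
#' @param level confidence level (default 0.95).
#' @return a `correlation_comparison` with `ci = c(low, high)` for
#'   r1 - r2.
#' @export
compare_dependent <- function(r1, r2, cross, n, level = 0.95) {
  stopifnot(n >= 10)
  if (length(cross) == 1L) {
    comparison <- "dependent_overlapping"
    r12 <- r1; r13 <- r2; r23 <- unname(cross)
    Rm <- matrix(c(1, r12, r13,
                   r12, 1, r23,
                   r13, r23, 1), 3L, 3L)
    check_psd(Rm)
    num <- r23 * (1 - r12^2 - r13^2) -
      0.5 * r12 * r13 * (1 - r12^2 - r13^2 - r23^2)
    corr <- num / ((1 - r12^2) * (1 - r13^2))
  } else if (length(cross) == 4L) {
    comparison <- "dependent_nonoverlapping"
    need <- c("r13", "r14", "r23", "r24")
    if (!all(need %in% names(cross))) {
      stop("non-overlapping case needs named cross-correlations ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    r12 <- r1; r34 <- r2
    r13 <- cross[["r13"]]; r14 <- cross[["r14"]]
    r23 <- cross[["r23"]]; r24 <- cross[["r24"]]
    Rm <- matrix(c(1, r12, r13, r14,
                   r12, 1, r23, r24,
                   r13, r23, 1, r34,
                   r14, r24, r34, 1), 4L, 4L)
    check_psd(Rm)
    num <- 0.5 * ((r13 - r12 * r23) * (r24 - r23 * r34) +
                    (r14 - r13 * r34) * (r23 - r12 * r13) +
                    (r13 - r14 * r34) * (r24 - r12 * r14) +
                    (r14 - r12 * r24) * (r23 - r34 * r24))
    corr <- num / ((1 - r12^2) * (1 - r34^2))
  } else {
    stop("`cross` must have length 1 (overlapping) or 4 (non-overlapping)",
         call. = FALSE)
  }
  ci1 <- fisher_ci(r1, n, level)
  ci2 <- fisher_ci(r2, n, level)
  l1 <- ci1[1L]; u1 <- ci1[2L]; l2 <- ci2[1L]; u2 <- ci2[2L]
  lo <- r1 - r2 - sqrt(max(0, (r1 - l1)^2 + (u2 - r2)^2 -
                             2 * corr * (r1 - l1) * (u2 - r2)))
  hi <- r1 - r2 + sqrt(max(0, (u1 - r1)^2 + (r2 - l2)^2 -
                             2 * corr * (u1 - r1) * (r2 - l2)))
  structure(list(r1 = r1, r2 = r2, n1 = n, n2 = n,
                 comparison = comparison, cross = cross,
                 est_correlation = corr, statistic = NA_real_,
                 p_value = NA_real_, ci = c(low = lo, high = hi),
                 level = level),
            class = "correlation_comparison")
}

check_psd <- function(Rm) {
  ev <- eigen(Rm, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("inconsistent correlation structure (not positive ",
         "semidefinite)", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat("<correlation_comparison> ", x$comparison, ": r1 = ",
      format(x$r1, digits = 3), ", r2 = ", format(x$r2, digits = 3),
      sep = "")
  if (!is.null(x$ci)) {
    cat(", ", round(100 * x$level), "% CI for r1 - r2: [",
        format(x$ci[1L], digits = 3), ", ",
        format(x$ci[2L], digits = 3), "]\n", sep = "")
  } else {
    cat(", z = ", format(x$statistic, digits = 4), ", p = ",
        format(x$p_value, digits = 3), "\n", sep = "")
  }
  invisible(x)
}
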