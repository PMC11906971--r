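#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment, delegating to [stats::p.adjust()]; the
#' rejection mask applies the adjusted values at level `q`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return object of class `fdr_result`: list with `p_raw`,
#'   `p_adjusted`, `rejected` (logical), `q`, `n_rejected`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  p <- as.numeric(p)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values outside [0, 1]",
                                       call. = FALSE)
  adj <- stats::p.adjust(p, method = "BH")
  rej <- !is.na(adj) & adj <= q
  structure(list(p_raw = p, p_adjusted = adj, rejected = rej, q = q,
                 n_rejected = sum(rej)),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat("<fdr_result> ", sum(!is.na(x$p_raw)), " tests, ",
      x$n_rejected, " rejected at q = ", x$q, "\n", sep = "")
  invisible(x)
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' Pearson's chi-square without continuity correction, df = 1; used for
#' sex-by-group comparisons of cohort composition.
#'
#' @param a,b,c,d nonnegative integer cell counts (rows = groups,
#'   columns = categories); all margins must be positive.
#' @return object of class `categorical_test` with `statistic`, `df`,
#'   `p_value`, `method`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  m <- matrix(counts, nrow = 2L, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero margin in 2x2 table", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  structure(list(statistic = unname(ht$statistic), df = 1L,
                 p_value = ht$p.value, method = "pearson_chi_square"),
            class = "categorical_test")
}

#' @export
print.categorical_test <- function(x, ...) {
  cat("<categorical_test> ", x$method, ": statistic = ",
      format(x$statistic, digits = 4), ", df = ", x$df,
      ", p = ", format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Kruskal-Wallis test on per-subject scan counts
#'
#' Checks whether the number of scans per subject differs between the
#' groups (a design-balance check for the longitudinal mixed models);
#' tie-corrected H statistic.
#'
#' @param dataset a [longitudinal_dataset()] with at least 2 groups.
#' @return a `categorical_test` (statistic = H).
#' @export
scan_count_test <- function(dataset) {
  stopifnot(inherits(dataset, "longitudinal_dataset"))
  subj <- !duplicated(dataset$meta$subject_id)
  group <- dataset$meta$group[subj]
  counts <- as.numeric(table(dataset$meta$subject_id)[
    dataset$meta$subject_id[subj]])
  if (length(unique(group)) < 2L) stop("need at least 2 groups",
                                       call. = FALSE)
  if (any(table(group) < 2L)) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  ht <- stats::kruskal.test(counts, factor(group))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 method = "kruskal_wallis"),
            class = "categorical_test")
}

# ---- region-wise linear mixed models ---------------------------------

# Shared model frame for the progression LMMs: complete-covariate scans,
# group factor with HC reference, age centered at the pooled baseline
# mean (units unchanged).
progression_frame <- function(dataset) {
  meta <- dataset$meta
  df <- data.frame(subject_id = meta$subject_id,
                   group = factor(meta$group, levels = c("HC", "FHAD", "AD")),
                   age = meta$age,
                   sex = factor(meta$sex, levels = c("M", "F")),
                   education_y = meta$education_y, bmi = meta$bmi,
                   apoe4 = meta$apoe4, stringsAsFactors = FALSE)
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  age0 <- df$age[!duplicated(df$subject_id)]
  df$age_c <- df$age - mean(age0)
  list(df = df, rows = which(keep), age_center = mean(age0))
}

# finite-difference derivative checks are the dominant cost across
# hundreds of region fits and their warnings are mostly spurious here;
# optimizer-level convergence codes are still checked per fit
lmm_control <- lme4::lmerControl(calc.derivs = FALSE)

lmm_formulas <- list(
  unstructured = y ~ group * age_c + sex + education_y + bmi + apoe4 +
    apoe4:age_c + (1 + age_c | subject_id),
  diagonal = y ~ group * age_c + sex + education_y + bmi + apoe4 +
    apoe4:age_c + (1 | subject_id) + (0 + age_c | subject_id),
  intercept_only = y ~ group * age_c + sex + education_y + bmi + apoe4 +
    apoe4:age_c + (1 | subject_id))

# Fit one lmer, reporting convergence trouble via the `ok` flag.
quiet_fit <- function(expr) {
  ok <- TRUE
  fit <- tryCatch(withCallingHandlers(expr, warning = function(w) {
    if (grepl("converge|singular|Hessian|unable to evaluate",
              conditionMessage(w), ignore.case = TRUE)) ok <<- FALSE
    invokeRestart("muffleWarning")
  }), error = function(e) NULL)
  if (!is.null(fit)) {
    if (!is.null(fit@optinfo$conv$lme4$code)) ok <- FALSE
    oc <- fit@optinfo$conv$opt
    if (!is.null(oc) && length(oc) == 1L && is.numeric(oc) && oc < 0) {
      ok <- FALSE
    }
  }
  list(fit = fit, ok = ok)
}

# Fit one response vector through the fallback ladder. `base_fits` is an
# environment caching one fitted lmer per rung, used as a fast refit
# template; a refit that raises convergence warnings is retried as a
# fresh fit of the same rung (so results do not depend on which region
# seeded the template) before falling down the ladder.
fit_lmm_ladder <- function(df, y, base_fits,
                           ladder = c("unstructured", "diagonal",
                                      "intercept_only")) {
  last_fit <- NULL
  last_rung <- "failed"
  df$y <- y
  for (rung in ladder) {
    if (!is.null(base_fits[[rung]])) {
      res <- quiet_fit(lme4::refit(base_fits[[rung]], newresp = y))
    } else {
      res <- quiet_fit(lme4::lmer(lmm_formulas[[rung]], data = df,
                                  REML = TRUE, control = lmm_control))
      if (!is.null(res$fit)) base_fits[[rung]] <- res$fit
    }
    if (!res$ok && !is.null(base_fits[[rung]])) {  # retry from scratch
      res <- quiet_fit(lme4::lmer(lmm_formulas[[rung]], data = df,
                                  REML = TRUE, control = lmm_control))
    }
    if (!is.null(res$fit)) {
      last_fit <- res$fit
      last_rung <- rung
      if (res$ok) {
        return(list(fit = res$fit, structure = rung,
                    converged = rung == ladder[1L]))
      }
    }
  }
  # every rung warned: keep the simplest fit rather than dropping the
  # region, but mark it unconverged
  list(fit = last_fit, structure = last_rung, converged = FALSE)
}

# Extract contrasts and omnibus interaction test from a fitted lmer.
lmm_extract <- function(fit, n_subjects) {
  b <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  nm <- names(b)
  i_f <- match("groupFHAD:age_c", nm)
  i_a <- match("groupAD:age_c", nm)
  est <- c(FHAD_vs_HC = unname(b[i_f]), AD_vs_HC = unname(b[i_a]),
           AD_vs_FHAD = unname(b[i_a] - b[i_f]))
  se <- c(sqrt(V[i_f, i_f]), sqrt(V[i_a, i_a]),
          sqrt(V[i_f, i_f] + V[i_a, i_a] - 2 * V[i_f, i_a]))
  names(se) <- names(est)
  wald <- est / se
  n_obs <- stats::nobs(fit)
  df2 <- n_obs - length(b)
  p <- 2 * stats::pt(-abs(wald), df2)
  bi <- b[c(i_f, i_a)]
  Vi <- V[c(i_f, i_a), c(i_f, i_a)]
  Fstat <- drop(crossprod(bi, solve(Vi, bi))) / 2
  p_omni <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(beta = est, se = se, wald = wald, p = p,
       omnibus_F = Fstat, omnibus_p = p_omni,
       varcorr = vc, n_obs = n_obs, n_subjects = n_subjects)
}

#' Fit the atrophy-progression mixed model for one region
#'
#' Linear mixed model of a region's deformation trajectory:
#' fixed effects `group + age + group:age + sex + education_y + bmi +
#' apoe4 + apoe4:age`, random intercept and age slope per subject with
#' unstructured 2 x 2 covariance, fitted by REML (via lme4). Age is
#' centered at the pooled baseline mean. The group-by-age interaction
#' coefficients estimate atrophy progression relative to HC: a positive
#' beta means faster deformation change with age than controls. If the
#' fit fails to converge, the model is automatically refitted with a
#' diagonal and then intercept-only random structure, flagged in the
#' result.
#'
#' @param dataset a [longitudinal_dataset()] (>= 2 groups, >= 30
#'   subjects with complete covariates).
#' @param region_id region identifier.
#' @return object of class `lmm_region_result`: contrast estimates
#'   (`FHAD_vs_HC`, `AD_vs_HC`, `AD_vs_FHAD`, units/year), SEs, Wald
#'   statistics, per-contrast p, omnibus interaction F and p,
#'   random-effect variances, convergence state, `n_obs`, `n_subjects`.
#' @export
fit_region_lmm <- function(dataset, region_id) {
  stopifnot(inherits(dataset, "longitudinal_dataset"))
  j <- match(region_id, dataset$region_ids)
  if (is.na(j)) stop("unknown region: ", region_id, call. = FALSE)
  pf <- progression_frame(dataset)
  check_lmm_pre(pf$df)
  y <- dataset$regional[pf$rows, j]
  base_fits <- new.env()
  res <- fit_lmm_ladder(pf$df, y, base_fits)
  if (is.null(res$fit)) {
    stop("mixed model failed for region ", region_id, call. = FALSE)
  }
  out <- lmm_extract(res$fit, length(unique(pf$df$subject_id)))
  out$region_id <- region_id
  out$structure <- res$structure
  out$converged <- res$converged
  class(out) <- "lmm_region_result"
  out
}

check_lmm_pre <- function(df) {
  if (length(unique(df$group)) < 2L) {
    stop("need at least 2 groups present", call. = FALSE)
  }
  if (length(unique(df$subject_id)) < 30L) {
    stop("need at least 30 subjects with complete covariates",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.lmm_region_result <- function(x, ...) {
  cat("<lmm_region_result> region ", x$region_id, " (",
      x$n_obs, " scans, ", x$n_subjects, " subjects; random effects: ",
      x$structure, ")\n", sep = "")
  tab <- data.frame(beta = x$beta, se = x$se, wald = x$wald, p = x$p)
  print(round(tab, 5))
  cat("omnibus group x age: F = ", format(x$omnibus_F, digits = 4),
      ", p = ", format(x$omnibus_p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Region-wise atrophy progression maps
#'
#' Runs the [fit_region_lmm()] model over every region, collects the
#' group-by-age interaction coefficient maps per contrast, applies
#' BH-FDR at level `q` to the omnibus interaction p-values, corrects
#' the post hoc contrast p-values within the omnibus-significant set
#' (optionally over all regions), and splits the significant regions by
#' the sign of beta.
#'
#' @param dataset a [longitudinal_dataset()].
#' @param q FDR level (default 0.05).
#' @param posthoc_scope `"significant"` (default) corrects post hoc
#'   contrasts within the omnibus-significant region set; `"all"`
#'   corrects over all regions.
#' @param progress print a progress message every 50 regions.
#' @return object of class `progression_fit`: `beta` (R x 3 matrix),
#'   `se`, `p_contrast`, `p_contrast_fdr`, `omnibus_F`, `omnibus_p`,
#'   `fdr` ([bh_fdr()] result on the omnibus p), `significant` (region
#'   ids), `sign_split` (per contrast, positive/negative significant
#'   region ids), `structure`, `converged`, `excluded`, `n_obs`,
#'   `n_subjects`, `region_ids`.
#' @export
progression_maps <- function(dataset, q = 0.05,
                             posthoc_scope = c("significant", "all"),
                             progress = FALSE) {
  posthoc_scope <- match.arg(posthoc_scope)
  stopifnot(inherits(dataset, "longitudinal_dataset"))
  pf <- progression_frame(dataset)
  check_lmm_pre(pf$df)
  ids <- dataset$region_ids
  R <- length(ids)
  contrasts <- c("FHAD_vs_HC", "AD_vs_HC", "AD_vs_FHAD")
  beta <- se <- wald <- p_con <- matrix(NA_real_, R, 3L,
                                        dimnames = list(ids, contrasts))
  omni_F <- omni_p <- rep(NA_real_, R)
  structure_used <- character(R)
  converged <- logical(R)
  base_fits <- new.env()
  n_subjects <- length(unique(pf$df$subject_id))
  Y <- dataset$regional[pf$rows, , drop = FALSE]
  for (j in seq_len(R)) {
    y <- Y[, j]
    if (anyNA(y)) {          # refit needs a fixed row set; fit fresh
      sub <- !is.na(y)
      res <- tryCatch({
        dfj <- pf$df[sub, , drop = FALSE]
        fitj <- fit_lmm_ladder(dfj, y[sub], new.env())
        fitj
      }, error = function(e) list(fit = NULL, structure = "failed",
                                  converged = FALSE))
    } else {
      res <- fit_lmm_ladder(pf$df, y, base_fits)
    }
    structure_used[j] <- res$structure
    converged[j] <- res$converged
    if (is.null(res$fit)) next
    ex <- lmm_extract(res$fit, n_subjects)
    beta[j, ] <- ex$beta; se[j, ] <- ex$se; wald[j, ] <- ex$wald
    p_con[j, ] <- ex$p
    omni_F[j] <- ex$omnibus_F; omni_p[j] <- ex$omnibus_p
    if (progress && j %% 50L == 0L) {
      message("progression_maps: ", j, "/", R, " regions")
    }
  }
  excluded <- ids[structure_used == "failed"]
  if (length(excluded)) {
    message("progression_maps: ", length(excluded),
            " region(s) excluded after all model attempts failed")
  }
  fdr <- bh_fdr(omni_p, q)
  sig <- ids[fdr$rejected]
  p_con_fdr <- matrix(NA_real_, R, 3L, dimnames = list(ids, contrasts))
  scope <- if (posthoc_scope == "significant") fdr$rejected else
    !is.na(omni_p)
  if (any(scope)) {
    for (k in seq_len(3L)) {
      p_con_fdr[scope, k] <- stats::p.adjust(p_con[scope, k], method = "BH")
    }
  }
  sign_split <- lapply(stats::setNames(nm = contrasts), function(ct) {
    s <- !is.na(p_con_fdr[, ct]) & p_con_fdr[, ct] <= q & fdr$rejected
    list(positive = ids[s & beta[, ct] > 0],
         negative = ids[s & beta[, ct] < 0])
  })
  structure(list(beta = beta, se = se, wald = wald, p_contrast = p_con,
                 p_contrast_fdr = p_con_fdr, omnibus_F = omni_F,
                 omnibus_p = omni_p, fdr = fdr, significant = sig,
                 sign_split = sign_split, structure = structure_used,
                 converged = converged, excluded = excluded,
                 q = q, posthoc_scope = posthoc_scope,
                 n_obs = nrow(pf$df), n_subjects = n_subjects,
                 age_center = pf$age_center, region_ids = ids),
            class = "progression_fit")
}

#' @export
print.progression_fit <- function(x, ...) {
  cat("<progression_fit> ", length(x$region_ids), " regions, ",
      x$n_obs, " scans, ", x$n_subjects, " subjects\n", sep = "")
  cat("  omnibus group x age FDR: ", length(x$significant),
      " significant regions at q = ", x$q, "\n", sep = "")
  invisible(x)
}

#' @export
summary.progression_fit <- function(object, ...) {
  cat("Region-wise atrophy progression (group x age interaction)\n")
  print(object)
  for (ct in colnames(x = object$beta)) {
    s <- object$sign_split[[ct]]
    cat("  ", ct, ": +beta ", length(s$positive), " regions, -beta ",
        length(s$negative), " regions (post hoc FDR, ",
        object$posthoc_scope, " scope)\n", sep = "")
  }
  cat("  beta ranges (units/year):\n")
  print(apply(object$beta, 2L, range, na.rm = TRUE))
  invisible(object)
}

#' @export
coef.progression_fit <- function(object, contrast = "AD_vs_HC", ...) {
  regional_map(object$beta[, contrast], object$region_ids, "beta")
}

#' @export
region_ids.progression_fit <- function(x) x$region_ids

#' Sex-interaction scan of the progression model
#'
#' Augments the progression fixed effects with group x sex x age,
#' group x sex and sex x age interactions and returns per-region Wald
#' p-values for each interaction family, BH-FDR-corrected per family.
#'
#' @param dataset a [longitudinal_dataset()].
#' @param q FDR level.
#' @return list of class `sex_scan` with per-term matrices `p` and
#'   `p_fdr` (columns `group_sex_age`, `group_sex`, `sex_age`) and the
#'   per-region convergence structure.
#' @export
sex_interaction_scan <- function(dataset, q = 0.05) {
  stopifnot(inherits(dataset, "longitudinal_dataset"))
  pf <- progression_frame(dataset)
  check_lmm_pre(pf$df)
  ids <- dataset$region_ids
  R <- length(ids)
  form <- y ~ group * sex * age_c + education_y + bmi + apoe4 +
    apoe4:age_c + (1 + age_c | subject_id)
  terms3 <- c("groupFHAD:sexF:age_c", "groupAD:sexF:age_c")
  terms_gs <- c("groupFHAD:sexF", "groupAD:sexF")
  terms_sa <- "sexF:age_c"
  p <- matrix(NA_real_, R, 3L,
              dimnames = list(ids, c("group_sex_age", "group_sex", "sex_age")))
  structure_used <- character(R)
  base <- NULL
  Y <- dataset$regional[pf$rows, , drop = FALSE]
  wald_block <- function(V, b, terms, df2) {
    i <- match(terms, names(b))
    Fs <- drop(crossprod(b[i], solve(V[i, i, drop = FALSE], b[i]))) /
      length(i)
    stats::pf(Fs, length(i), df2, lower.tail = FALSE)
  }
  dfj <- pf$df
  for (j in seq_len(R)) {
    dfj$y <- Y[, j]
    if (is.null(base)) {
      r0 <- quiet_fit(lme4::lmer(form, data = dfj, REML = TRUE, control = lmm_control))
      if (!is.null(r0$fit)) base <- r0$fit
    } else {
      r0 <- quiet_fit(lme4::refit(base, newresp = Y[, j]))
      if (!r0$ok) r0 <- quiet_fit(lme4::lmer(form, data = dfj, REML = TRUE, control = lmm_control))
    }
    fit <- r0$fit
    if (is.null(fit)) { structure_used[j] <- "failed"; next }
    structure_used[j] <- if (r0$ok) "unstructured" else "unconverged"
    b <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    df2 <- stats::nobs(fit) - length(b)
    p[j, "group_sex_age"] <- wald_block(V, b, terms3, df2)
    p[j, "group_sex"] <- wald_block(V, b, terms_gs, df2)
    p[j, "sex_age"] <- wald_block(V, b, terms_sa, df2)
  }
  p_fdr <- apply(p, 2L, stats::p.adjust, method = "BH")
  structure(list(p = p, p_fdr = p_fdr, q = q,
                 structure = structure_used, region_ids = ids),
            class = "sex_scan")
}

#' Network-wise atrophy progression
#'
#' Averages the regional values within each of the 7 resting-state
#' networks per scan and fits the same mixed model as
#' [fit_region_lmm()] on the network means; FDR over the networks.
#'
#' @param dataset a [longitudinal_dataset()].
#' @param partition a [network_partition()] covering all regions.
#' @param q FDR level.
#' @return object of class `network_progression`: per-network
#'   `lmm_region_result`s plus an omnibus [bh_fdr()] across networks.
#' @export
network_progression <- function(dataset, partition, q = 0.05) {
  stopifnot(inherits(dataset, "longitudinal_dataset"),
            inherits(partition, "network_partition"))
  check_regions_match(dataset, partition)
  labs <- unique(unname(partition))
  nets <- lapply(stats::setNames(nm = labs), function(l)
    which(unname(partition) == l))
  if (any(lengths(nets) == 0L)) stop("empty network", call. = FALSE)
  netmat <- vapply(nets, function(idx)
    rowMeans(dataset$regional[, idx, drop = FALSE]), numeric(nrow(dataset$meta)))
  netds <- longitudinal_dataset(dataset$meta, netmat, labs)
  results <- lapply(labs, function(l) fit_region_lmm(netds, l))
  names(results) <- labs
  omni_p <- vapply(results, `[[`, 0, "omnibus_p")
  structure(list(results = results, fdr = bh_fdr(omni_p, q),
                 networks = labs, network_means = netds),
            class = "network_progression")
}

#' @export
print.network_progression <- function(x, ...) {
  cat("<network_progression> ", length(x$networks), " networks; ",
      x$fdr$n_rejected, " significant omnibus tests at q = ", x$fdr$q,
      "\n", sep = "")
  tab <- t(vapply(x$results, function(r) c(r$beta["AD_vs_HC"],
                                           r$omnibus_p), numeric(2)))
  colnames(tab) <- c("beta_AD_vs_HC", "omnibus_p")
  print(round(tab, 5))
  invisible(x)
}

#' Partial Spearman correlation of a score with network W-scores
#'
#' Rank-transforms score, W and covariates, residualizes the ranked
#' score and ranked W on the ranked covariates, and correlates the
#' residuals (Pearson on ranks = partial Spearman). Two-sided p from
#' the t reference with n - 2 - k degrees of freedom; BH-FDR across
#' networks.
#'
#' @param score numeric per-subject score (e.g. cognition).
#' @param network_W subjects x networks matrix of per-network mean
#'   W-scores.
#' @param covariates data.frame of per-subject adjustment variables
#'   (e.g. baseline age, BMI, APOE4 count).
#' @param q FDR level.
#' @return data.frame with per-network `rho`, `p`, `p_fdr`, `n`.
#' @export
partial_spearman <- function(score, network_W, covariates, q = 0.05) {
  network_W <- as.matrix(network_W)
  covariates <- as.data.frame(covariates)
  stopifnot(length(score) == nrow(network_W),
            nrow(covariates) == length(score))
  out <- data.frame(network = colnames(network_W), rho = NA_real_,
                    p = NA_real_, n = NA_integer_)
  for (k in seq_len(ncol(network_W))) {
    w <- network_W[, k]
    ok <- stats::complete.cases(score, w, covariates)
    n <- sum(ok)
    if (n < 20L) stop("need at least 20 pairwise-complete subjects",
                      call. = FALSE)
    s_r <- rank(score[ok])
    if (stats::sd(s_r) == 0) stop("constant score vector", call. = FALSE)
    w_r <- rank(w[ok])
    Z <- cbind(1, apply(as.matrix(covariates[ok, , drop = FALSE]), 2L, rank))
    rs <- stats::lm.fit(Z, s_r)$residuals
    rw <- stats::lm.fit(Z, w_r)$residuals
    rho <- stats::cor(rs, rw)
    dfree <- n - 2L - (ncol(Z) - 1L)
    tval <- rho * sqrt(dfree / (1 - rho^2))
    out$rho[k] <- rho
    out$p[k] <- 2 * stats::pt(-abs(tval), dfree)
    out$n[k] <- n
  }
  out$p_fdr <- bh_fdr(out$p, q)$p_adjusted
  out
}

#' Region-wise PET group comparison
#'
#' Ordinary least squares `SUVR ~ group + age + sex + education_y +
#' bmi + apoe4` per region for a two-group PET dataset (one baseline
#' scan per subject); reports the group-coefficient t test per region
#' with BH-FDR over regions.
#'
#' @param pet a `pet_dataset` (list with `meta`, `suvr`, `region_ids`)
#'   as produced by [simulate_cohort()], restricted to the two groups
#'   of interest.
#' @param groups character(2); the contrast is `groups[2] - groups[1]`.
#' @param q FDR level.
#' @return list of class `pet_comparison`: `estimate` (SUVR
#'   difference), `t`, `p`, `fdr`, `n`, `groups`.
#' @export
compare_pet_groups <- function(pet, groups = c("FHAD", "AD"), q = 0.05) {
  meta <- pet$meta
  keep <- meta$group %in% groups
  meta <- meta[keep, , drop = FALSE]
  Y <- pet$suvr[keep, , drop = FALSE]
  ok <- stats::complete.cases(meta[, c("age", "sex", "education_y",
                                       "bmi", "apoe4")])
  meta <- meta[ok, , drop = FALSE]; Y <- Y[ok, , drop = FALSE]
  g <- as.numeric(meta$group == groups[2L])
  X <- cbind(intercept = 1, group = g, age = meta$age,
             sexF = as.numeric(meta$sex == "F"),
             education_y = meta$education_y, bmi = meta$bmi,
             apoe4 = meta$apoe4)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient PET design", call. = FALSE)
  B <- qr.coef(qrX, Y)
  res <- Y - X %*% B
  dfree <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / dfree
  XtXinv_g <- chol2inv(chol(crossprod(X)))[2L, 2L]
  se <- sqrt(sigma2 * XtXinv_g)
  tval <- B["group", ] / se
  p <- 2 * stats::pt(-abs(tval), dfree)
  structure(list(estimate = B["group", ], t = tval, p = p,
                 fdr = bh_fdr(p, q), n = nrow(X), groups = groups,
                 region_ids = pet$region_ids),
            class = "pet_comparison")
}

#' @export
print.pet_comparison <- function(x, ...) {
  cat("<pet_comparison> ", x$groups[2L], " vs ", x$groups[1L], ": ",
      x$n, " subjects, ", length(x$p), " regions, ",
      x$fdr$n_rejected, " significant at q = ", x$fdr$q, "\n", sep = "")
  invisible(x)
}
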