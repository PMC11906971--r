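#' Fit the normative reference model for W-scores
#'
#' Region-wise least-squares regression of the baseline deformation
#' value on age and sex in the healthy-control group:
#' `value ~ intercept + b_age * age + b_sex * sex`. The per-region
#' residual SD (denominator n - 3, for the three fitted parameters)
#' becomes the W-score scaling unit.
#'
#' @param dataset a [longitudinal_dataset()]; only HC baseline scans are
#'   used.
#' @param min_controls minimum number of HC baseline scans (default 20).
#' @return object of class `wscore_reference`: per-region coefficient
#'   matrix (`intercept`, `age`, `sexF`), `residual_sd`, a
#'   `zero_variance` flag vector, `n_controls`, the reference age range,
#'   and the sex coding (F = 1).
#' @export
fit_reference <- function(dataset, min_controls = 20L) {
  stopifnot(inherits(dataset, "longitudinal_dataset"))
  bl <- baseline_rows(dataset)
  hc <- bl[dataset$meta$group[bl] == "HC"]
  n <- length(hc)
  if (n < min_controls) {
    stop("need at least ", min_controls, " HC baseline scans, got ", n,
         call. = FALSE)
  }
  if (n < 3L + 5L) stop("fewer controls than parameters + 5", call. = FALSE)
  age <- dataset$meta$age[hc]
  sexF <- as.numeric(dataset$meta$sex[hc] == "F")
  X <- cbind(intercept = 1, age = age, sexF = sexF)
  Y <- dataset$regional[hc, , drop = FALSE]
  qrX <- qr(X)
  B <- qr.coef(qrX, Y)                       # 3 x R
  res <- Y - X %*% B
  rsd <- sqrt(colSums(res^2) / (n - 3L))
  zero_var <- rsd < 1e-12
  structure(list(coefficients = t(B), residual_sd = rsd,
                 zero_variance = zero_var, n_controls = n,
                 age_range = range(age), sex_coding = c(M = 0, F = 1),
                 region_ids = dataset$region_ids),
            class = "wscore_reference")
}

#' @export
print.wscore_reference <- function(x, ...) {
  cat("<wscore_reference> ", length(x$region_ids), " regions, fitted on ",
      x$n_controls, " HC baseline scans (value ~ age + sex)\n", sep = "")
  cat("  reference age range: ", paste(round(x$age_range, 1), collapse = "-"),
      " y; regions flagged zero-variance: ", sum(x$zero_variance), "\n",
      sep = "")
  invisible(x)
}

#' @export
region_ids.wscore_reference <- function(x) x$region_ids

#' Save / load a W-score reference model as a coefficient TSV
#'
#' @param model a `wscore_reference`.
#' @param path file path.
#' @return `path` invisibly; `load_reference` returns the model.
#' @export
save_reference <- function(model, path) {
  df <- data.frame(region_id = model$region_ids,
                   intercept = sprintf("%.17g", model$coefficients[, "intercept"]),
                   age = sprintf("%.17g", model$coefficients[, "age"]),
                   sexF = sprintf("%.17g", model$coefficients[, "sexF"]),
                   residual_sd = sprintf("%.17g", model$residual_sd),
                   n_controls = model$n_controls)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname save_reference
#' @export
load_reference <- function(path) {
  df <- read_delim_auto(path)
  co <- as.matrix(df[, c("intercept", "age", "sexF")])
  rownames(co) <- df$region_id
  rsd <- as.numeric(df$residual_sd)
  structure(list(coefficients = co, residual_sd = rsd,
                 zero_variance = rsd < 1e-12,
                 n_controls = df$n_controls[1L],
                 age_range = c(NA_real_, NA_real_),
                 sex_coding = c(M = 0, F = 1),
                 region_ids = as.character(df$region_id)),
            class = "wscore_reference")
}

#' Compute baseline W-score maps
#'
#' For each subject's baseline scan,
#' \eqn{W_{ij} = (y_{ij} - \hat y_{ij}(age, sex)) / \hat\sigma_i} with
#' the control-group prediction and residual SD from [fit_reference()].
#' The deformation measure is oriented so that larger W means more
#' atrophy than expected for age and sex. Subjects whose baseline age
#' falls more than 10 years outside the reference age range trigger an
#' extrapolation warning.
#'
#' @param dataset a [longitudinal_dataset()] sharing the model's region
#'   ids.
#' @param model a `wscore_reference`.
#' @param groups which groups to score (default all).
#' @return object of class `wscore_maps`: list with `W` (subjects x
#'   regions matrix), `meta` (baseline metadata rows), and `group_mean`
#'   (named list of per-group mean `regional_map`s).
#' @export
compute_wscores <- function(dataset, model, groups = c("HC", "FHAD", "AD")) {
  stopifnot(inherits(dataset, "longitudinal_dataset"),
            inherits(model, "wscore_reference"))
  check_regions_match(dataset, model)
  bl <- baseline_rows(dataset)
  bl <- bl[dataset$meta$group[bl] %in% groups]
  meta <- dataset$meta[bl, , drop = FALSE]
  if (all(is.finite(model$age_range))) {
    lo <- model$age_range[1L] - 10; hi <- model$age_range[2L] + 10
    out_of_range <- meta$age < lo | meta$age > hi
    if (any(out_of_range)) {
      warning(sum(out_of_range), " subject(s) outside the reference age ",
              "range by more than 10 years (extrapolated W-scores)")
    }
  }
  X <- cbind(1, meta$age, as.numeric(meta$sex == "F"))
  pred <- X %*% t(model$coefficients)
  sdv <- model$residual_sd
  sdv[model$zero_variance] <- NA_real_
  W <- sweep(dataset$regional[bl, , drop = FALSE] - pred, 2L, sdv, "/")
  rownames(W) <- meta$subject_id
  group_mean <- lapply(stats::setNames(nm = intersect(groups, meta$group)),
                       function(g)
                         regional_map(colMeans(W[meta$group == g, , drop = FALSE]),
                                      dataset$region_ids, "w"))
  structure(list(W = W, meta = meta, group_mean = group_mean,
                 region_ids = dataset$region_ids),
            class = "wscore_maps")
}

#' @export
print.wscore_maps <- function(x, ...) {
  cat("<wscore_maps> ", nrow(x$W), " subjects x ", ncol(x$W),
      " regions; groups: ",
      paste(names(x$group_mean), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
region_ids.wscore_maps <- function(x) x$region_ids
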