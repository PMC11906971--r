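#' Simulation configuration for the synthetic cohort generator
#'
#' Defines the generative model used to validate every pipeline stage
#' against known ground truth: a three-group longitudinal cohort (HC,
#' FHAD, AD) whose atrophy-progression signal is concentrated on a
#' connectome-diffused, spatially autocorrelated pattern; PET-like SUVR
#' maps correlated with that pattern with group-dependent gain; receptor
#' maps partially coupled to it; and subject-level connectomes jittered
#' around a group connectome.
#'
#' Regional trajectories follow, for subject j in group g, region i,
#' scan age t:
#' \deqn{y = a_i + u_j + (s_0 + s_g p_i + v_j) t + \gamma^\top c_j +
#'   site_j + \epsilon}
#' with regional intercepts `a_i` carrying a spatially autocorrelated
#' field (exponential covariance, correlation length `lambda_mm`),
#' random intercepts/slopes `u_j, v_j`, covariates `c_j` (sex,
#' education, BMI, APOE4), and the ground-truth pattern `p` scaled to
#' unit maximum.
#'
#' @param R region count (default 200).
#' @param n_per_group subjects per group; single integer or named vector
#'   with entries `HC`, `FHAD`, `AD`.
#' @param visits maximum scans per subject (baseline + annual
#'   follow-ups).
#' @param dropout_prob probability of dropping out at each follow-up.
#' @param age_range baseline age range in years (uniform draw), shared
#'   by the three groups.
#' @param slope_base normal-ageing deformation slope (units/year).
#' @param slope_effect named numeric: extra group slope amplitude
#'   (units/year) for `FHAD` and `AD`; multiplies the pattern.
#' @param n_pattern_seeds number of pattern seed regions.
#' @param diffusion_steps,diffusion_decay network-diffusion parameters
#'   for the ground-truth pattern.
#' @param lambda_mm spatial correlation length of the autocorrelated
#'   fields (mm).
#' @param noise_sd,intercept_sd,slope_sd measurement noise SD and
#'   random-effect SDs.
#' @param spatial_sd SD of the spatially autocorrelated component of the
#'   regional intercepts.
#' @param covariate_effects named numeric effects for `sex` (F = 1),
#'   `education_y`, `bmi`, `apoe4`; small nonzero defaults exercise the
#'   covariate adjustment.
#' @param pet_gain named list with elements `tau` and `abeta`, each a
#'   named numeric of per-group gains multiplying the pattern in the
#'   SUVR model `1 + gain * p + noise`.
#' @param pet_noise_sd SD of the per-subject smooth SUVR noise field.
#' @param receptor_coupling named numeric in `[-1, 1]`: correlation of
#'   each receptor target with the pattern.
#' @param site_count,site_shift_sd number of sites and SD of the
#'   site-specific additive shift.
#' @param connectome_density,connectome_decay_mm target edge density and
#'   distance-decay length of the group connectome.
#' @param n_connectome_subjects subject-level connectomes to simulate.
#' @param edge_flip_rate per-edge flip probability for subject
#'   connectomes around the group connectome.
#' @param rng_seed integer seed; all outputs are reproducible from it.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(R = 200L,
                       n_per_group = 50L,
                       visits = 3L,
                       dropout_prob = 0.1,
                       age_range = c(66, 80),
                       slope_base = 0.005,
                       slope_effect = c(FHAD = 0.008, AD = 0.02),
                       n_pattern_seeds = 20L,
                       diffusion_steps = 8L,
                       diffusion_decay = 0.9,
                       lambda_mm = 20,
                       noise_sd = 0.002,
                       intercept_sd = 0.1,
                       slope_sd = 0.003,
                       spatial_sd = 0.1,
                       covariate_effects = c(sex = 0.02, education_y = -0.002,
                                             bmi = 0.001, apoe4 = 0.02),
                       pet_gain = list(tau = c(HC = 0, FHAD = 0.08, AD = 0.3),
                                       abeta = c(HC = 0, FHAD = 0.08, AD = 0.25)),
                       pet_noise_sd = 0.1,
                       receptor_coupling = c(`5-HT6` = -0.6, `5-HT1B` = -0.4,
                                             D2 = 0, VAChT = 0, mGluR5 = 0.5,
                                             H3 = 0, norepinephrine = 0),
                       site_count = 3L,
                       site_shift_sd = 0.02,
                       connectome_density = 0.1,
                       connectome_decay_mm = 20,
                       n_connectome_subjects = 20L,
                       edge_flip_rate = 0.05,
                       rng_seed = 1L) {
  if (length(n_per_group) == 1L) {
    n_per_group <- c(HC = n_per_group, FHAD = n_per_group, AD = n_per_group)
  }
  stopifnot(all(c("HC", "FHAD", "AD") %in% names(n_per_group)))
  cfg <- list(R = as.integer(R), n_per_group = n_per_group,
              visits = as.integer(visits), dropout_prob = dropout_prob,
              age_range = age_range, slope_base = slope_base,
              slope_effect = slope_effect,
              n_pattern_seeds = as.integer(n_pattern_seeds),
              diffusion_steps = as.integer(diffusion_steps),
              diffusion_decay = diffusion_decay, lambda_mm = lambda_mm,
              noise_sd = noise_sd, intercept_sd = intercept_sd,
              slope_sd = slope_sd, spatial_sd = spatial_sd,
              covariate_effects = covariate_effects, pet_gain = pet_gain,
              pet_noise_sd = pet_noise_sd,
              receptor_coupling = receptor_coupling,
              site_count = as.integer(site_count),
              site_shift_sd = site_shift_sd,
              connectome_density = connectome_density,
              connectome_decay_mm = connectome_decay_mm,
              n_connectome_subjects = as.integer(n_connectome_subjects),
              edge_flip_rate = edge_flip_rate,
              rng_seed = as.integer(rng_seed))
  with(cfg, {
    stopifnot(R >= 10L, visits >= 1L,
              dropout_prob >= 0, dropout_prob < 1,
              noise_sd >= 0, intercept_sd >= 0, slope_sd >= 0,
              spatial_sd >= 0, site_shift_sd >= 0,
              diffusion_decay >= 0, diffusion_decay < 1,
              n_pattern_seeds >= 1L, n_pattern_seeds <= R %/% 2L,
              all(abs(receptor_coupling) <= 1))
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Deterministic two-hemisphere region geometry
#'
#' Places `R` points on two mirrored hemispheric shells (radius 60 mm,
#' separated by a 12 mm inter-hemispheric gap), emulating parcel
#' centroids of a bilateral cortical atlas. Left-hemisphere points have
#' x < 0 and right-hemisphere points x > 0; for even `R` the right
#' hemisphere is the exact mirror image of the left.
#'
#' @param R number of regions (>= 10).
#' @param rng_seed integer seed.
#' @return R x 3 matrix of coordinates in mm.
#' @export
make_geometry <- function(R, rng_seed = 1L) {
  R <- as.integer(R)
  if (R < 10L) stop("R must be at least 10", call. = FALSE)
  n_left <- R %/% 2L
  n_right <- R - n_left
  set.seed(rng_seed)
  sphere_points <- function(n) {
    z <- stats::runif(n, -1, 1)
    th <- stats::runif(n, 0, 2 * pi)
    r <- sqrt(pmax(0, 1 - z^2))
    60 * cbind(r * cos(th), r * sin(th), z)
  }
  left <- sphere_points(n_left)
  left[, 1L] <- -(abs(left[, 1L]) + 6)
  right <- left[seq_len(min(n_left, n_right)), , drop = FALSE]
  right[, 1L] <- -right[, 1L]
  if (n_right > n_left) {
    extra <- sphere_points(n_right - n_left)
    extra[, 1L] <- abs(extra[, 1L]) + 6
    right <- rbind(right, extra)
  }
  coords <- rbind(left, right)
  colnames(coords) <- c("x", "y", "z")
  coords
}

#' Distance-dependent random connectome
#'
#' Draws an undirected binary graph with edge probability proportional
#' to `exp(-d / decay_mm)`, rescaled so that the expected edge density
#' equals `target_density`. Components holding fewer than 10% of the
#' regions are attached to the giant component through their shortest
#' inter-component link so that downstream neighbor statistics are
#' well defined.
#'
#' @param coordinates R x 3 coordinate matrix (mm), e.g. from
#'   [make_geometry()].
#' @param target_density desired edge density in (0, 0.5].
#' @param decay_mm exponential length scale of the distance decay; large
#'   values approach a uniform (Erdos-Renyi) graph.
#' @param rng_seed integer seed.
#' @param region_ids optional region identifiers.
#' @return a [connectome()].
#' @export
make_connectome <- function(coordinates, target_density, decay_mm,
                            rng_seed = 1L, region_ids = NULL) {
  if (target_density <= 0 || target_density > 0.5) {
    stop("target_density must be in (0, 0.5]", call. = FALSE)
  }
  coordinates <- as.matrix(coordinates)
  R <- nrow(coordinates)
  D <- distance_matrix(coordinates)
  ut <- upper.tri(D)
  kernel <- exp(-D[ut] / decay_mm)
  n_pairs <- sum(ut)
  # solve for the scale c with expected density = target under p = min(c*k, 1)
  f <- function(cc) sum(pmin(cc * kernel, 1)) / n_pairs - target_density
  cc <- stats::uniroot(f, lower = 0, upper = 1e12, tol = 1e-12)$root
  p <- pmin(cc * kernel, 1)
  if (mean(p >= 1) > 0.5) {
    stop("target_density ", target_density, " infeasible with decay_mm ",
         decay_mm, ": more than half of the edge probabilities saturate; ",
         "increase decay_mm or lower target_density", call. = FALSE)
  }
  set.seed(rng_seed)
  edges <- stats::runif(n_pairs) < p
  A <- matrix(0, R, R)
  A[which(ut)[edges]] <- 1
  A <- A + t(A)
  A <- connect_components(A, D)
  connectome(A, coordinates, region_ids)
}

# Attach small components (< 0.1 R) to the giant component via the
# shortest inter-component link; deterministic.
connect_components <- function(A, D) {
  R <- nrow(A)
  repeat {
    comp <- graph_components(A)
    sizes <- tabulate(comp)
    if (length(sizes) == 1L) break
    giant <- which.max(sizes)
    small <- which(comp != giant)
    if (length(small) > 0.1 * R) break  # genuinely fragmented; leave as is
    sub <- D[small, comp == giant, drop = FALSE]
    k <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
    i <- small[k[1L]]
    j <- which(comp == giant)[k[2L]]
    A[i, j] <- A[j, i] <- 1
  }
  A
}

# Connected components of a binary adjacency by BFS.
graph_components <- function(A) {
  R <- nrow(A)
  comp <- integer(R)
  cur <- 0L
  for (s in seq_len(R)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(A[v, ] != 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Connectome-diffused ground-truth pattern
#'
#' Implements the network-spread hypothesis generatively: pathology
#' seeded at a few regions and diffused along connections. The pattern
#' is \eqn{\sum_{k=0}^{K} \delta^k (D^{-1}A)^k s} with one-hot seeds
#' `s`, degree-normalized transition matrix, and decay `delta`;
#' rescaled so its maximum value is 1.
#'
#' @param con a [connectome()].
#' @param pattern_seeds integer indices of seed regions.
#' @param steps number of diffusion steps K (>= 0).
#' @param decay per-step decay in `[0, 1)`.
#' @param normalize rescale to unit maximum (default TRUE).
#' @return a `regional_map` (measure `"pattern"`).
#' @export
make_pattern <- function(con, pattern_seeds, steps, decay, normalize = TRUE) {
  stopifnot(inherits(con, "connectome"), steps >= 0)
  A <- con$adjacency
  R <- nrow(A)
  if (any(pattern_seeds < 1 | pattern_seeds > R)) {
    stop("seed indices out of range", call. = FALSE)
  }
  deg <- rowSums(A)
  if (steps > 0 && any(deg[pattern_seeds] == 0)) {
    warning("isolated seed region(s): ",
            paste(pattern_seeds[deg[pattern_seeds] == 0], collapse = ", "))
  }
  Tm <- A / ifelse(deg == 0, 1, deg)  # rows with zero degree stay zero
  s <- numeric(R)
  s[pattern_seeds] <- 1
  pat <- s
  v <- s
  if (steps > 0) {
    for (k in seq_len(steps)) {
      v <- drop(Tm %*% v)
      pat <- pat + decay^k * v
    }
  }
  if (normalize && max(abs(pat)) > 0) pat <- pat / max(abs(pat))
  regional_map(pat, con$region_ids, "pattern")
}

# Spatially autocorrelated Gaussian field with exponential covariance
# exp(-D/lambda); `chol_cache` lets callers reuse the factorization.
field_chol <- function(D, lambda_mm) {
  C <- exp(-D / lambda_mm)
  diag(C) <- diag(C) + 1e-8
  chol(C)
}

smooth_field <- function(chol_upper, sd = 1) {
  n <- nrow(chol_upper)
  drop(crossprod(chol_upper, stats::rnorm(n))) * sd
}

#' Simulate a full synthetic cohort with known ground truth
#'
#' Generates, from a single seed: a group connectome and subject-level
#' jittered connectomes; a connectome-diffused pathology pattern; a
#' longitudinal deformation dataset whose group-specific age slopes are
#' `slope_base + slope_effect[g] * pattern`; per-subject baseline
#' tau-PET and amyloid-PET SUVR maps (`1 + pet_gain * pattern` plus a
#' smooth noise field); and a receptor atlas whose targets are coupled
#' to the pattern with configured correlations.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_cohort` with elements `dataset`
#'   ([longitudinal_dataset()]), `tau` and `abeta` (PET datasets: list
#'   of `meta` + `suvr` matrix), `receptors` ([receptor_atlas()]),
#'   `subject_connectomes` (list of [connectome()]), `connectome` (the
#'   group-truth connectome), and `truth` (pattern, per-group true beta
#'   maps, the config).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$rng_seed)
  ids <- paste0("region_", seq_len(cf$R))

  coords <- make_geometry(cf$R, rng_seed = cf$rng_seed + 1L)
  con <- make_connectome(coords, cf$connectome_density,
                         cf$connectome_decay_mm,
                         rng_seed = cf$rng_seed + 2L, region_ids = ids)
  # seed regions form a bilateral epicenter: half around a random
  # region, half around its contralateral mirror (AD pathology starts
  # focally and roughly symmetrically)
  D <- distance_matrix(coords)
  set.seed(cf$rng_seed + 3L)
  epi <- sample.int(cf$R, 1L)
  mirror <- coords[epi, ] * c(-1, 1, 1)
  d_mirror <- sqrt(colSums((t(coords) - mirror)^2))
  n_half <- cf$n_pattern_seeds %/% 2L
  seeds <- unique(c(order(D[epi, ])[seq_len(cf$n_pattern_seeds - n_half)],
                    order(d_mirror)[seq_len(n_half)]))
  pattern <- make_pattern(con, seeds, cf$diffusion_steps, cf$diffusion_decay)
  pat <- as.numeric(pattern)
  U <- field_chol(D, cf$lambda_mm)

  set.seed(cf$rng_seed + 4L)
  # regional intercepts: smooth field
  a_i <- smooth_field(U, cf$spatial_sd)

  groups <- c("HC", "FHAD", "AD")
  slope_g <- c(HC = 0, cf$slope_effect)[groups]
  n_subj <- sum(cf$n_per_group[groups])
  subj_group <- rep(groups, cf$n_per_group[groups])
  subj_id <- sprintf("S%03d", seq_len(n_subj))

  sex <- stats::rbinom(n_subj, 1L, 0.55)            # 1 = F
  edu <- round(pmin(20, pmax(7, stats::rnorm(n_subj, 16, 2.5))))
  bmi <- round(stats::rnorm(n_subj, 26, 3.5), 1)
  apoe_p <- list(HC = c(0.70, 0.25, 0.05), FHAD = c(0.55, 0.35, 0.10),
                 AD = c(0.35, 0.45, 0.20))
  apoe4 <- vapply(subj_group, function(g)
    sample(0:2, 1L, prob = apoe_p[[g]]), 0L)
  site <- sample.int(cf$site_count, n_subj, replace = TRUE)
  site_shift <- stats::rnorm(cf$site_count, 0, cf$site_shift_sd)
  age0 <- stats::runif(n_subj, cf$age_range[1L], cf$age_range[2L])
  u_j <- stats::rnorm(n_subj, 0, cf$intercept_sd)
  v_j <- stats::rnorm(n_subj, 0, cf$slope_sd)

  ce <- cf$covariate_effects
  meta_list <- list()
  reg_list <- list()
  for (j in seq_len(n_subj)) {
    n_vis <- 1L
    while (n_vis < cf$visits && stats::runif(1) >= cf$dropout_prob) {
      n_vis <- n_vis + 1L
    }
    ages <- age0[j] + seq_len(n_vis) - 1L
    g <- subj_group[j]
    slope_i <- cf$slope_base + slope_g[[g]] * pat + v_j[j]
    cov_term <- ce[["sex"]] * sex[j] + ce[["education_y"]] * edu[j] +
      ce[["bmi"]] * bmi[j] + ce[["apoe4"]] * apoe4[j]
    for (t in seq_len(n_vis)) {
      eps <- stats::rnorm(cf$R, 0, cf$noise_sd)
      y <- a_i + u_j[j] + slope_i * ages[t] + cov_term +
        site_shift[site[j]] + eps
      meta_list[[length(meta_list) + 1L]] <- data.frame(
        subject_id = subj_id[j], group = g, age = ages[t],
        sex = if (sex[j] == 1L) "F" else "M",
        education_y = edu[j], bmi = bmi[j], apoe4 = apoe4[j],
        site = paste0("site_", site[j]), visit = t - 1L,
        stringsAsFactors = FALSE)
      reg_list[[length(reg_list) + 1L]] <- y
    }
  }
  dataset <- longitudinal_dataset(do.call(rbind, meta_list),
                                  do.call(rbind, reg_list), ids)

  # PET datasets: one baseline scan per subject
  make_pet <- function(gain, seed_offset) {
    set.seed(cf$rng_seed + seed_offset)
    suvr <- matrix(NA_real_, n_subj, cf$R, dimnames = list(NULL, ids))
    for (j in seq_len(n_subj)) {
      suvr[j, ] <- 1 + gain[[subj_group[j]]] * pat +
        smooth_field(U, cf$pet_noise_sd) +
        stats::rnorm(cf$R, 0, cf$pet_noise_sd / 2)
    }
    meta <- data.frame(subject_id = subj_id, group = subj_group,
                       age = age0, sex = ifelse(sex == 1L, "F", "M"),
                       education_y = edu, bmi = bmi, apoe4 = apoe4,
                       site = paste0("site_", site),
                       stringsAsFactors = FALSE)
    structure(list(meta = meta, suvr = suvr, region_ids = ids),
              class = "pet_dataset")
  }
  tau <- make_pet(cf$pet_gain$tau, 5L)
  abeta <- make_pet(cf$pet_gain$abeta, 6L)

  # receptor atlas: coupled + independent smooth component, z-scored
  set.seed(cf$rng_seed + 7L)
  pat_z <- zscore(pat)
  targets <- list()
  tracer_n <- c(30, 88, 55, 40, 123, 60, 70)  # nominal study sample sizes
  for (k in seq_along(cf$receptor_coupling)) {
    nm <- names(cf$receptor_coupling)[k]
    cc <- cf$receptor_coupling[[k]]
    n_tracers <- if (k %% 3L == 0L) 2L else 1L  # some targets multi-tracer
    maps <- list()
    for (tr in seq_len(n_tracers)) {
      fld <- zscore(smooth_field(U))
      maps[[tr]] <- regional_map(cc * pat_z + sqrt(1 - cc^2) * fld, ids,
                                 paste0(nm, "_tracer", tr))
    }
    targets[[nm]] <- list(maps = maps,
                          weights = tracer_n[k] * seq_len(n_tracers))
  }
  receptors <- receptor_atlas(targets)

  # subject connectomes: symmetric edge flips around the group matrix
  set.seed(cf$rng_seed + 8L)
  ut <- upper.tri(con$adjacency)
  base_ut <- con$adjacency[ut]
  subject_connectomes <- lapply(seq_len(cf$n_connectome_subjects), function(s) {
    flips <- stats::runif(length(base_ut)) < cf$edge_flip_rate
    e <- ifelse(flips, 1 - base_ut, base_ut)
    A <- matrix(0, cf$R, cf$R)
    A[which(ut)[e == 1]] <- 1
    A <- A + t(A)
    connectome(A, coords, ids, subject_id = sprintf("C%03d", s))
  })

  truth <- list(
    pattern = pattern,
    true_beta = lapply(stats::setNames(nm = groups), function(g)
      regional_map(slope_g[[g]] * pat, ids, "beta")),
    slope_base = cf$slope_base,
    receptor_coupling = cf$receptor_coupling,
    pet_gain = cf$pet_gain,
    pattern_seeds = seeds,
    config = cf)

  structure(list(dataset = dataset, tau = tau, abeta = abeta,
                 receptors = receptors,
                 subject_connectomes = subject_connectomes,
                 connectome = con, truth = truth),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> R =", length(x$dataset$region_ids), "regions\n")
  print(x$dataset)
  cat("  PET: tau + abeta, one baseline scan per subject\n")
  cat("  receptors:", length(x$receptors$targets), "targets;",
      length(x$subject_connectomes), "subject connectomes\n")
  invisible(x)
}
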