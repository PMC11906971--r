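test_that("BH adjustment matches direct step-up enumeration", {
  # independent step-up oracle
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    prev <- 1
    for (i in m:1) {
      prev <- min(prev, m * p[o[i]] / i)
      adj[o[i]] <- prev
    }
    adj
  }
  set.seed(8)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p)$p_adjusted, bh_oracle(p), tolerance = 1e-14)
  }
  r <- bh_fdr(c(0.001, 0.01, 0.02, 0.04, 0.2), q = 0.05)
  expect_equal(r$n_rejected, 4L)
  r1 <- bh_fdr(rep(1, 5))
  expect_equal(r1$n_rejected, 0L)
  expect_true(all(r1$p_adjusted == 1))
  r2 <- bh_fdr(0.04, q = 0.05)
  expect_true(r2$rejected)
  expect_equal(r2$p_adjusted, 0.04)
  expect_error(bh_fdr(c(0.1, 1.2)), "outside")
  # monotone in raw-p order
  set.seed(9)
  p <- runif(30)
  adj <- bh_fdr(p)$p_adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_true(all(adj >= p))
})

test_that("sex-table chi-square reproduces the cohort composition test", {
  ct <- chi_square_2x2(76, 80, 43, 73)
  expect_equal(round(ct$statistic, 2), 3.67)
  expect_equal(ct$df, 1L)
  expect_gt(ct$p_value, 0.05)
  expect_equal(chi_square_2x2(10, 20, 30, 60)$statistic, 0,
               tolerance = 1e-12)
  expect_equal(chi_square_2x2(5, 5, 5, 5)$statistic, 0, tolerance = 1e-12)
  expect_error(chi_square_2x2(0, 0, 3, 4), "margin")
})

test_that("scan-count Kruskal-Wallis matches hand-computed ranks", {
  mk <- function(counts_by_group) {
    rows <- list()
    for (g in names(counts_by_group)) {
      for (k in seq_along(counts_by_group[[g]])) {
        n <- counts_by_group[[g]][k]
        sid <- paste0(g, k)
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sid, group = g, age = 70 + seq_len(n) - 1,
          sex = "F", education_y = 16, bmi = 25, apoe4 = 0, site = "a",
          visit = seq_len(n) - 1)
      }
    }
    meta <- do.call(rbind, rows)
    longitudinal_dataset(meta, matrix(rnorm(nrow(meta) * 2), ncol = 2))
  }
  # identical multisets in all three groups: H = 0
  ds0 <- mk(list(HC = c(1, 2, 3), FHAD = c(1, 2, 3), AD = c(1, 2, 3)))
  expect_equal(scan_count_test(ds0)$statistic, 0, tolerance = 1e-12)
  # {1,2,3} vs {4,5,6}: ranks 1..6, H = 12/(6*7) * 2 * 3 * 1.5^2 = 27/7
  ds1 <- mk(list(HC = c(1, 2, 3), AD = c(4, 5, 6)))
  expect_equal(scan_count_test(ds1)$statistic, 27 / 7, tolerance = 1e-12)
  # invariance under strictly monotone transform of counts (ranks only)
  ds2 <- mk(list(HC = c(1, 4, 9), AD = c(16, 25, 36)))
  expect_equal(scan_count_test(ds2)$statistic,
               scan_count_test(ds1)$statistic, tolerance = 1e-12)
  expect_error(scan_count_test(mk(list(HC = c(1, 2), AD = 3))),
               "at least 2 subjects")
})

test_that("single-region mixed model recovers a null interaction and is
           invariant to subject relabeling", {
  cfg <- sim_config(R = 12, n_per_group = 50, n_pattern_seeds = 4,
                    slope_effect = c(FHAD = 0, AD = 0), rng_seed = 21)
  co <- suppressWarnings(simulate_cohort(cfg))
  r <- fit_region_lmm(co$dataset, "region_5")
  expect_true(abs(r$beta["AD_vs_HC"]) < 2 * r$se["AD_vs_HC"])
  expect_true(abs(r$beta["FHAD_vs_HC"]) < 2 * r$se["FHAD_vs_HC"])

  # relabeling subjects leaves the fixed effects unchanged
  ds2 <- co$dataset
  map <- setNames(sprintf("Z%03d", seq_along(unique(ds2$meta$subject_id))),
                  unique(ds2$meta$subject_id))
  ds2$meta$subject_id <- unname(map[ds2$meta$subject_id])
  ds2 <- longitudinal_dataset(ds2$meta, ds2$regional, ds2$region_ids)
  r2 <- fit_region_lmm(ds2, "region_5")
  expect_equal(r2$beta, r$beta, tolerance = 1e-8)
})

test_that("interaction estimates cover the true effect across seeds", {
  # max-pattern region has pattern exactly 1, so true beta_AD-HC = 0.02
  hits <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(R = 12, n_per_group = 50, n_pattern_seeds = 4,
                      rng_seed = 3000 + s)
    co <- suppressWarnings(simulate_cohort(cfg))
    j <- which.max(as.numeric(co$truth$pattern))
    r <- fit_region_lmm(co$dataset, co$dataset$region_ids[j])
    if (abs(r$beta["AD_vs_HC"] - 0.02) <= 3 * r$se["AD_vs_HC"]) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("progression maps satisfy the linear contrast identity and are
           stable under region reordering", {
  co <- small_cohort()
  pm <- suppressMessages(progression_maps(co$dataset))
  expect_equal(pm$beta[, "AD_vs_FHAD"],
               pm$beta[, "AD_vs_HC"] - pm$beta[, "FHAD_vs_HC"],
               tolerance = 1e-12)
  # permuting region columns permutes results identically
  perm <- sample(ncol(co$dataset$regional))
  ds_p <- longitudinal_dataset(co$dataset$meta,
                               co$dataset$regional[, perm],
                               co$dataset$region_ids[perm])
  pm_p <- suppressMessages(progression_maps(ds_p))
  expect_equal(unname(pm_p$beta[match(rownames(pm$beta), rownames(pm_p$beta)), ]),
               unname(pm$beta), tolerance = 1e-4)
})

test_that("network-wise model degenerates correctly and localizes the
           pattern network", {
  co <- small_cohort()
  ids <- co$dataset$region_ids
  # one network holding all regions equals the LMM on the global mean
  part1 <- network_partition(rep("default_mode", length(ids)), ids)
  np1 <- network_progression(co$dataset, part1)
  gmean <- rowMeans(co$dataset$regional)
  ds_g <- longitudinal_dataset(co$dataset$meta, cbind(gmean), "default_mode")
  direct <- fit_region_lmm(ds_g, "default_mode")
  expect_equal(np1$results$default_mode$beta, direct$beta,
               tolerance = 1e-10)

  # pattern concentrated in one network makes it the largest |beta_AD-HC|
  pat <- as.numeric(co$truth$pattern)
  labs <- rep("other", length(ids))
  labs[order(pat, decreasing = TRUE)[1:9]] <- "pattern_net"
  labs[order(pat)[1:20]] <- "low_net"
  part2 <- network_partition(labs, ids)
  np2 <- network_progression(co$dataset, part2)
  betas <- vapply(np2$results, function(r) abs(r$beta["AD_vs_HC"]), 0)
  expect_equal(names(which.max(betas)), "pattern_net")

  # permuting network labels jointly with regions permutes results
  perm <- sample(length(ids))
  ds_p <- longitudinal_dataset(co$dataset$meta,
                               co$dataset$regional[, perm], ids[perm])
  part_p <- network_partition(labs[perm], ids[perm])
  np_p <- network_progression(ds_p, part_p)
  expect_equal(np_p$results$pattern_net$beta,
               np2$results$pattern_net$beta, tolerance = 1e-8)
})

test_that("partial Spearman correlation has rank-test properties", {
  set.seed(31)
  n <- 120
  covars <- data.frame(age = runif(n, 60, 80), bmi = rnorm(n, 26, 3),
                       apoe4 = rbinom(n, 2, 0.3))
  W <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(NULL, c("n1", "n2", "n3")))
  # monotone transform of W, no covariate effect: rho ~ 1
  score <- exp(W[, 1])
  res <- partial_spearman(score, W, covars)
  expect_gt(res$rho[1], 0.99)
  # invariance to strictly monotone transforms of all inputs
  res_t <- partial_spearman(score^3, W^3,
                            data.frame(age = exp(covars$age / 40),
                                       bmi = covars$bmi^3,
                                       apoe4 = covars$apoe4))
  expect_equal(res_t$rho, res$rho, tolerance = 1e-12)
  expect_error(partial_spearman(rep(1, n), W, covars), "constant")

  # type-I calibration under independence
  set.seed(32)
  rej <- mean(replicate(400, {
    s <- rnorm(100)
    w <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "n1"))
    cv <- data.frame(age = rnorm(100))
    partial_spearman(s, w, cv)$p[1] < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.03)
})

test_that("PET group comparison is calibrated, powered, and location
           invariant", {
  co <- small_cohort()
  pc <- compare_pet_groups(co$tau)
  pet_shift <- co$tau
  pet_shift$suvr <- pet_shift$suvr + 5
  pc_s <- compare_pet_groups(pet_shift)
  expect_equal(pc_s$t, pc$t, tolerance = 1e-10)

  # equal gains in the two groups: few rejections
  set.seed(41)
  fams <- replicate(50, {
    n <- 40; R <- 25
    g <- rep(c("FHAD", "AD"), each = n / 2)
    meta <- data.frame(subject_id = sprintf("p%02d", 1:n), group = g,
                       age = runif(n, 66, 80), sex = sample(c("M", "F"), n, TRUE),
                       education_y = rnorm(n, 16, 2), bmi = rnorm(n, 26, 3),
                       apoe4 = rbinom(n, 2, 0.3), site = "a")
    suvr <- 1 + matrix(rnorm(n * R, 0, 0.1), n, R)
    pet <- structure(list(meta = meta, suvr = suvr,
                          region_ids = paste0("region_", 1:R)),
                     class = "pet_dataset")
    mean(compare_pet_groups(pet)$fdr$rejected)
  })
  expect_lte(mean(fams), 0.07)

  # differential binding on 40% of regions is found with high precision
  set.seed(42)
  n <- 120; R <- 50
  diff_regions <- 1:20
  g <- rep(c("FHAD", "AD"), each = n / 2)
  meta <- data.frame(subject_id = sprintf("q%03d", 1:n), group = g,
                     age = runif(n, 66, 80), sex = sample(c("M", "F"), n, TRUE),
                     education_y = rnorm(n, 16, 2), bmi = rnorm(n, 26, 3),
                     apoe4 = rbinom(n, 2, 0.3), site = "a")
  suvr <- 1 + matrix(rnorm(n * R, 0, 0.1), n, R)
  suvr[g == "AD", diff_regions] <- suvr[g == "AD", diff_regions] + 0.12
  pet <- structure(list(meta = meta, suvr = suvr,
                        region_ids = paste0("region_", 1:R)),
                   class = "pet_dataset")
  pc2 <- compare_pet_groups(pet)
  hits <- which(pc2$fdr$rejected)
  expect_gte(length(hits), 1)
  expect_gte(mean(hits %in% diff_regions), 0.8)
})

test_that("sex-interaction scan is null-calibrated and detects injected
           sex-specific slopes", {
  # null: generator has no sex-by-age effect. Within one cohort the
  # region-wise p-values share the subjects' random slopes and are
  # strongly dependent, so uniformity is checked across independent
  # cohorts (one region each).
  ps <- vapply(1:30, function(s) {
    co <- suppressWarnings(simulate_cohort(
      sim_config(R = 12, n_pattern_seeds = 4, n_per_group = 30,
                 rng_seed = 500 + s)))
    sc <- sex_interaction_scan(co$dataset)
    sc$p[5, "group_sex_age"]
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # inject a female-specific AD slope in 10 regions
  co <- simulate_cohort(sim_config(R = 60, n_per_group = 100,
                                   rng_seed = 77))
  m <- co$dataset$meta
  affected <- 1:10
  bump <- 0.02 * m$age * (m$sex == "F") * (m$group == "AD")
  reg <- co$dataset$regional
  reg[, affected] <- reg[, affected] + bump
  ds <- longitudinal_dataset(m, reg, co$dataset$region_ids)
  sc <- sex_interaction_scan(ds)
  found <- which(sc$p_fdr[, "group_sex_age"] <= 0.05)
  expect_gte(mean(affected %in% found), 0.8)

  # duplicated male/female data: interaction p ~ 1 (estimates ~ 0)
  co2 <- suppressWarnings(simulate_cohort(
    sim_config(R = 15, n_per_group = 20, n_pattern_seeds = 5, rng_seed = 52)))
  m2 <- co2$dataset$meta
  m2m <- m2; m2m$sex <- "M"
  m2f <- m2; m2f$sex <- "F"
  m2f$subject_id <- paste0(m2f$subject_id, "_f")
  ds2 <- longitudinal_dataset(rbind(m2m, m2f),
                              rbind(co2$dataset$regional,
                                    co2$dataset$regional),
                              co2$dataset$region_ids)
  sc2 <- sex_interaction_scan(ds2)
  expect_true(all(sc2$p[, "group_sex_age"] > 0.9, na.rm = TRUE))
})
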