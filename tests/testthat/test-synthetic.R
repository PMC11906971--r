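test_that("geometry is deterministic, mirrored, and hemispheric", {
  c1 <- make_geometry(10, rng_seed = 1)
  c2 <- make_geometry(10, rng_seed = 1)
  expect_identical(c1, c2)

  c3 <- make_geometry(200, rng_seed = 1)
  expect_equal(sum(c3[, 1] < 0), 100)
  expect_equal(sum(c3[, 1] > 0), 100)
  # right hemisphere mirrors the left
  expect_equal(c3[101:200, ], c3[1:100, ] * rep(c(-1, 1, 1), each = 100),
               ignore_attr = TRUE)
  expect_error(make_geometry(9), "at least 10")
})

test_that("random connectomes hit the target density and distance decay", {
  coords <- make_geometry(200, rng_seed = 2)
  con <- make_connectome(coords, 0.1, 30, rng_seed = 2)
  con_b <- make_connectome(coords, 0.1, 30, rng_seed = 2)
  expect_identical(con$adjacency, con_b$adjacency)

  # near-infinite decay: uniform edge probability, density ~ target
  con_u <- make_connectome(coords, 0.1, 1e9, rng_seed = 3)
  R <- 200; n_pairs <- R * (R - 1) / 2
  dens <- sum(con_u$adjacency) / 2 / n_pairs
  expect_lt(abs(dens - 0.1), 4 * sqrt(0.1 * 0.9 / n_pairs))

  # edges are shorter than non-edges on average
  D <- distance_matrix(coords)
  ut <- upper.tri(D)
  e <- con$adjacency[ut] == 1
  expect_lt(mean(D[ut][e]), mean(D[ut][!e]))

  # giant component covers at least 90% of regions
  A <- con$adjacency
  reach <- (diag(R) + A)
  for (i in 1:8) reach <- sign(reach %*% (diag(R) + A))
  expect_gte(max(rowSums(sign(reach))), 0.9 * R)

  expect_error(make_connectome(coords, 0.6, 30), "target_density")
})

test_that("diffusion pattern matches the hand-enumerated path graph", {
  # 5-node path 1-2-3-4-5, seed at node 1, 2 steps, decay 0.5:
  # T s = (0, 1/2, 0, 0, 0); T^2 s = (1/2, 0, 1/4, 0, 0)
  # pattern = s + 0.5 T s + 0.25 T^2 s = (1.125, 0.25, 0.0625, 0, 0)
  A <- matrix(0, 5, 5)
  for (i in 1:4) A[i, i + 1] <- A[i + 1, i] <- 1
  coords <- cbind(1:5 * 10, 0, 0)
  con <- connectome(A, coords)
  p <- make_pattern(con, 1, steps = 2, decay = 0.5, normalize = FALSE)
  expect_equal(as.numeric(p), c(1.125, 0.25, 0.0625, 0, 0))
  p_n <- make_pattern(con, 1, steps = 2, decay = 0.5)
  expect_equal(as.numeric(p_n), c(1.125, 0.25, 0.0625, 0, 0) / 1.125)

  # steps = 0 and decay = 0 both reduce to the seed indicator
  p0 <- make_pattern(con, c(2, 4), steps = 0, decay = 0.5)
  pd0 <- make_pattern(con, c(2, 4), steps = 3, decay = 0)
  expect_equal(as.numeric(p0), c(0, 1, 0, 1, 0))
  expect_equal(as.numeric(pd0), as.numeric(p0))

  # isolated seed warns
  A2 <- A; A2[1, 2] <- A2[2, 1] <- 0
  con2 <- connectome(A2, coords)
  expect_warning(make_pattern(con2, 1, steps = 2, decay = 0.5), "isolated")
})

test_that("cohort simulation is bit-reproducible from its seed", {
  cfg <- sim_config(R = 30, n_per_group = 12, n_pattern_seeds = 10,
                    rng_seed = 7)
  a <- suppressWarnings(simulate_cohort(cfg))
  b <- suppressWarnings(simulate_cohort(cfg))
  expect_identical(a$dataset$regional, b$dataset$regional)
  expect_identical(a$tau$suvr, b$tau$suvr)
  expect_identical(as.numeric(a$truth$pattern), as.numeric(b$truth$pattern))
  expect_identical(a$subject_connectomes[[3]]$adjacency,
                   b$subject_connectomes[[3]]$adjacency)
})

test_that("null and noiseless configurations behave exactly as specified", {
  cfg0 <- sim_config(R = 30, n_per_group = 12, n_pattern_seeds = 10,
                     slope_effect = c(FHAD = 0, AD = 0), rng_seed = 5)
  co0 <- suppressWarnings(simulate_cohort(cfg0))
  expect_true(all(as.numeric(co0$truth$true_beta$AD) == 0))
  expect_true(all(as.numeric(co0$truth$true_beta$FHAD) == 0))

  cfg_n <- sim_config(R = 20, n_per_group = 10, n_pattern_seeds = 6,
                      noise_sd = 0,
                      intercept_sd = 0, slope_sd = 0, site_count = 1,
                      site_shift_sd = 0, dropout_prob = 0, rng_seed = 6)
  co_n <- suppressWarnings(simulate_cohort(cfg_n))
  m <- co_n$dataset$meta
  for (sid in unique(m$subject_id)[1:5]) {
    rows <- which(m$subject_id == sid)
    y <- co_n$dataset$regional[rows, 7]
    # exactly linear in age: second differences vanish
    expect_equal(diff(y) / diff(m$age[rows]),
                 rep((diff(y) / diff(m$age[rows]))[1], length(rows) - 1),
                 tolerance = 1e-12)
  }
})

test_that("group-mean trajectories recover the configured AD slope in
           top-decile pattern regions", {
  co <- default_cohort()   # R = 200, 50/group, 3 visits, slope_effect_AD = 0.02
  pat <- as.numeric(co$truth$pattern)
  top <- order(pat, decreasing = TRUE)[1:20]
  m <- co$dataset$meta
  ad <- m$group == "AD"
  ybar <- rowMeans(co$dataset$regional[ad, top])
  # longitudinal sample slope: OLS with subject intercepts
  slope <- coef(lm(ybar ~ m$age[ad] + factor(m$subject_id[ad])))[2]
  target <- co$truth$slope_base + 0.02 * 1  # pattern ~ 1 in top decile
  expect_lt(abs(slope - target) / target, 0.15)
})

test_that("pattern maps are connectome-coupled in the expected direction", {
  co <- default_cohort()
  con <- co$connectome
  D <- distance_matrix(con$coordinates)
  signs <- sapply(1:20, function(s) {
    set.seed(400 + s)
    epi <- sample.int(200, 1)
    seeds <- order(D[epi, ])[1:20]
    p <- make_pattern(con, seeds, 8, 0.9)
    conn <- cor(as.numeric(p), as.numeric(neighbor_mean(p, con)))
    non <- cor(as.numeric(p),
               as.numeric(neighbor_mean(p, con, "nonconnected")))
    c(conn > 0, non < 0)
  })
  expect_gte(mean(signs[1, ]), 0.95)
  expect_gte(mean(signs[2, ]), 0.95)
})
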