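test_that("neighbor means match hand enumeration and closed forms", {
  # path graph 1-2-3 with values (1, 2, 4)
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  con <- connectome(A, cbind(c(0, 10, 20), 0, 0))
  nm <- neighbor_mean(c(1, 2, 4), con)
  expect_equal(as.numeric(nm), c(2, 2.5, 2))

  # complete graph: connected mean_i = mean of all values excluding i
  R <- 8
  Ac <- matrix(1, R, R); diag(Ac) <- 0
  conc <- connectome(Ac, cbind(seq_len(R) * 5, 0, 0))
  set.seed(4)
  v <- rnorm(R)
  nmc <- neighbor_mean(v, conc)
  expect_equal(as.numeric(nmc),
               (sum(v) - v) / (R - 1), tolerance = 1e-12)

  # empty graph: connected means all missing, nonconnected = LOO mean
  cone <- connectome(matrix(0, R, R), cbind(seq_len(R) * 5, 0, 0))
  expect_true(all(is.na(as.numeric(neighbor_mean(v, cone)))))
  expect_equal(as.numeric(neighbor_mean(v, cone, "nonconnected")),
               (sum(v) - v) / (R - 1), tolerance = 1e-12)
})

test_that("matrix neighbor means equal the brute-force loop on random
           graphs, both modes", {
  brute <- function(x, A, mode) {
    R <- length(x)
    out <- rep(NA_real_, R)
    for (i in seq_len(R)) {
      nb <- if (mode == "connected") which(A[i, ] == 1) else
        setdiff(which(A[i, ] == 0), i)
      if (length(nb)) out[i] <- mean(x[nb])
    }
    out
  }
  set.seed(15)
  for (rep in 1:20) {
    R <- sample(10:100, 1)
    A <- matrix(rbinom(R * R, 1, runif(1, 0.05, 0.5)), R, R)
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    diag(A) <- 0
    con <- connectome(A, matrix(rnorm(R * 3, sd = 20), R, 3))
    x <- rnorm(R)
    for (mode in c("connected", "nonconnected")) {
      expect_equal(unname(as.numeric(neighbor_mean(x, con, mode))),
                   brute(x, A, mode), tolerance = 1e-12)
    }
  }
})

test_that("consensus connectome implements the retention rule", {
  co <- small_cohort()
  cons_same <- consensus_connectome(rep(list(co$connectome), 5))
  expect_equal(cons_same$adjacency, co$connectome$adjacency)

  # edge in 3/10 subjects is dropped at retain_fraction 0.5
  R <- 12
  coords <- cbind(seq_len(R) * 7, 0, 0)
  base <- matrix(0, R, R)
  mk <- function(A) connectome(A, coords)
  subj <- lapply(1:10, function(k) {
    A <- base
    if (k <= 3) A[1, 2] <- A[2, 1] <- 1   # rare edge
    A[3, 4] <- A[4, 3] <- 1               # universal edge
    mk(A)
  })
  cons <- consensus_connectome(subj, retain_fraction = 0.5)
  expect_equal(cons$adjacency[1, 2], 0)
  expect_equal(cons$adjacency[3, 4], 1)

  # simulated subject matrices: consensus density near the group truth
  cons_sim <- consensus_connectome(co$subject_connectomes)
  d_true <- mean(co$connectome$adjacency[upper.tri(co$connectome$adjacency)])
  d_cons <- mean(cons_sim$adjacency[upper.tri(cons_sim$adjacency)])
  expect_lt(abs(d_cons - d_true) / d_true, 0.2)

  # distance-binned variant keeps the subject-mean edge count
  cons_db <- consensus_connectome(co$subject_connectomes,
                                  distance_binned = TRUE)
  target <- mean(vapply(co$subject_connectomes,
                        function(x) sum(x$adjacency) / 2, 0))
  expect_lt(abs(sum(cons_db$adjacency) / 2 - target) / target, 0.1)

  expect_error(consensus_connectome(list(co$connectome)), "at least 2")
})

test_that("a ring-graph eigenmode is a fixed point of the neighbor
           operator (r = 1)", {
  R <- 30
  A <- matrix(0, R, R)
  for (i in seq_len(R)) {
    A[i, (i %% R) + 1] <- 1
    A[(i %% R) + 1, i] <- 1
  }
  th <- 2 * pi * seq_len(R) / R
  con <- connectome(A, cbind(40 * cos(th), 40 * sin(th), 0))
  x <- cos(th)
  # neighbor mean of cos is cos scaled by cos(2*pi/R): perfectly linear
  st <- spread_test(x, con, distance_matrix(con$coordinates),
                    n_surr = 30, rng_seed = 1)
  expect_equal(st$connected$r, 1, tolerance = 1e-10)
})

test_that("spread statistics are equivariant under region relabeling", {
  co <- small_cohort()
  con <- co$connectome
  x <- as.numeric(co$truth$pattern)
  D <- distance_matrix(con$coordinates)
  r0 <- spread_test(x, con, D, n_surr = 50, rng_seed = 3)

  set.seed(20)
  perm <- sample(length(x))
  con_p <- connectome(con$adjacency[perm, perm],
                      con$coordinates[perm, ],
                      con$region_ids[perm])
  r1 <- spread_test(x[perm], con_p, D[perm, perm], n_surr = 50,
                    rng_seed = 3)
  expect_equal(r1$connected$r, r0$connected$r, tolerance = 1e-12)
  expect_equal(r1$nonconnected$r, r0$nonconnected$r, tolerance = 1e-12)
  expect_equal(sort(as.numeric(r1$neighbor_means$connected)),
               sort(as.numeric(r0$neighbor_means$connected)))
})

test_that("zero-neighbor regions are excluded listwise from both
           contrasts", {
  R <- 40
  set.seed(21)
  A <- matrix(rbinom(R * R, 1, 0.2), R, R)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]; diag(A) <- 0
  A[5, ] <- 0; A[, 5] <- 0    # isolate region 5
  con <- connectome(A, matrix(rnorm(R * 3, sd = 25), R, 3))
  st <- spread_test(rnorm(R), con, distance_matrix(con$coordinates),
                    n_surr = 30, rng_seed = 2)
  expect_true("region_5" %in% st$excluded)
  expect_equal(st$n_regions_used, R - length(st$excluded))
  expect_equal(st$connected$n_regions, st$nonconnected$n_regions)
})

test_that("multi-map spread batches carry FDR-adjusted p-values", {
  co <- small_cohort()
  D <- distance_matrix(co$connectome$coordinates)
  maps <- list(pattern = as.numeric(co$truth$pattern),
               noise = rnorm(60))
  tab <- spread_test_many(maps, co$connectome, D, n_surr = 50,
                          rng_seed = 4)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$p_connected_fdr >= tab$p_connected - 1e-15))
})
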