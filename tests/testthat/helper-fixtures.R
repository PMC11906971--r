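# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Small cohort for structural tests (fast).
small_cohort <- function() {
  fixture("small_cohort", function()
    simulate_cohort(sim_config(R = 60, n_per_group = 25, rng_seed = 3)))
}

# Default-scale cohort (R = 200, 50/group) for recovery tests.
default_cohort <- function() {
  fixture("default_cohort", function()
    simulate_cohort(sim_config(rng_seed = 11)))
}

# Surrogate context for the default cohort geometry.
default_context <- function() {
  fixture("default_context", function() {
    co <- default_cohort()
    surrogate_context(distance_matrix(co$connectome$coordinates))
  })
}

# Cholesky factor for smooth-field draws on the default geometry.
default_field_chol <- function() {
  fixture("default_field_chol", function() {
    co <- default_cohort()
    D <- distance_matrix(co$connectome$coordinates)
    chol(exp(-D / 20) + diag(1e-8, nrow(D)))
  })
}

smooth_map <- function(U) drop(crossprod(U, stats::rnorm(nrow(U))))

# Minimal hand-written longitudinal table (2 subjects x 2 visits, R = 5).
write_toy_table <- function(path) {
  lines <- c(
    paste(c("subject_id", "group", "age", "sex", "education_y", "bmi",
            "apoe4", "site", "visit", paste0("region_", 1:5)),
          collapse = "\t"),
    paste(c("s1", "HC", "70", "F", "16", "25", "0", "a", "0",
            sprintf("%g", 1:5 / 10)), collapse = "\t"),
    paste(c("s1", "HC", "71", "F", "16", "25", "0", "a", "1",
            sprintf("%g", 2:6 / 10)), collapse = "\t"),
    paste(c("s2", "AD", "72", "M", "12", "27", "1", "b", "0",
            sprintf("%g", 3:7 / 10)), collapse = "\t"),
    paste(c("s2", "AD", "73.5", "M", "12", "27", "1", "b", "1",
            sprintf("%g", 4:8 / 10)), collapse = "\t"))
  writeLines(lines, path)
  path
}
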