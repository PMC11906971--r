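#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> wscore -> progression -> spread ->
#' colocalize as a configured, logged, reproducible run. Each stage
#' writes its results as delimited text files under `out_dir` and is
#' skipped on re-run if its outputs already exist (delete a stage's
#' files to recompute it and everything downstream of it). One global
#' seed expands to per-stage seeds as `seed + 1000 * stage_index`, so
#' stages are isolated without seed collisions.
#'
#' @param config a [sim_config()], a YAML file path, or a list of
#'   `sim_config()` arguments; YAML files may additionally set
#'   `n_surrogates` and `q` at the top level.
#' @param out_dir output directory (created if needed).
#' @param seed global seed; overrides the config's `rng_seed`.
#' @param n_surrogates surrogates per spin test (default 1000).
#' @param q FDR level (default 0.05).
#' @param stages which stages to run, in dependency order.
#' @param force rerun stages even if their outputs exist.
#' @return the run manifest (list of class `run_manifest`), invisibly;
#'   also written to `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = NULL,
                         n_surrogates = 1000L, q = 0.05,
                         stages = c("simulate", "wscore", "progression",
                                    "spread", "colocalize"),
                         force = FALSE) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    n_surrogates <- raw$n_surrogates %||% n_surrogates
    q <- raw$q %||% q
    raw$n_surrogates <- raw$q <- NULL
    config <- do.call(sim_config, raw)
  } else if (is.list(config) && !inherits(config, "sim_config")) {
    config <- do.call(sim_config, config)
  }
  if (!is.null(seed)) config$rng_seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base_seed <- config$rng_seed
  stage_seed <- function(k) base_seed + 1000L * k
  log_line <- function(...) message("[atroprop] ", ...)
  manifest <- list(config = unclass(config),
                   seeds = list(), timings = list(), ran = list(),
                   version = as.character(utils::packageVersion("atroprop")))
  outputs <- list(
    simulate = file.path(out_dir, c("dataset.tsv", "coords.tsv",
                                    "adjacency.txt", "pattern.tsv")),
    wscore = file.path(out_dir, c("wscore_reference.tsv",
                                  "wscore_group_means.tsv")),
    progression = file.path(out_dir, "progression_regions.tsv"),
    spread = file.path(out_dir, "spread.tsv"),
    colocalize = file.path(out_dir, "colocalization.tsv"))
  needs <- function(stage) {
    force || !all(file.exists(outputs[[stage]]))
  }
  cohort <- NULL
  ensure_cohort <- function() {
    if (is.null(cohort)) {
      cfg <- config
      cfg$rng_seed <- stage_seed(1L)
      cohort <<- simulate_cohort(cfg)
    }
    cohort
  }

  if ("simulate" %in% stages && needs("simulate")) {
    t0 <- proc.time()[[3L]]
    co <- ensure_cohort()
    save_longitudinal_table(co$dataset, outputs$simulate[1L])
    save_connectome(co$connectome, outputs$simulate[3L],
                    outputs$simulate[2L])
    save_map(co$truth$pattern, outputs$simulate[4L])
    manifest$timings$simulate <- proc.time()[[3L]] - t0
    manifest$seeds$simulate <- stage_seed(1L)
    manifest$ran$simulate <- TRUE
    log_line("simulate: ", nrow(co$dataset$meta), " scans, seed ",
             stage_seed(1L))
  }

  load_inputs <- function() {
    ds <- load_longitudinal_table(outputs$simulate[1L])
    con <- load_connectome(outputs$simulate[3L], outputs$simulate[2L])
    list(ds = ds, con = con)
  }

  if ("wscore" %in% stages && needs("wscore")) {
    if (!all(file.exists(outputs$simulate))) {
      stop("wscore stage needs the simulate stage outputs; run ",
           "`simulate` first", call. = FALSE)
    }
    t0 <- proc.time()[[3L]]
    inp <- load_inputs()
    ref <- fit_reference(inp$ds)
    save_reference(ref, outputs$wscore[1L])
    wm <- compute_wscores(inp$ds, ref)
    gm <- do.call(cbind, lapply(wm$group_mean, as.numeric))
    utils::write.table(data.frame(region_id = inp$ds$region_ids, gm),
                       outputs$wscore[2L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$timings$wscore <- proc.time()[[3L]] - t0
    manifest$ran$wscore <- TRUE
    log_line("wscore: reference on ", ref$n_controls, " controls")
  }

  prog <- NULL
  if ("progression" %in% stages && needs("progression")) {
    if (!all(file.exists(outputs$simulate))) {
      stop("progression stage needs the simulate stage outputs; run ",
           "`simulate` first", call. = FALSE)
    }
    t0 <- proc.time()[[3L]]
    inp <- load_inputs()
    prog <- progression_maps(inp$ds, q = q)
    tab <- data.frame(region_id = prog$region_ids, prog$beta,
                      omnibus_p = prog$omnibus_p,
                      omnibus_p_fdr = prog$fdr$p_adjusted,
                      structure = prog$structure)
    utils::write.table(tab, outputs$progression, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$timings$progression <- proc.time()[[3L]] - t0
    manifest$ran$progression <- TRUE
    log_line("progression: ", length(prog$significant),
             " significant regions at q = ", q)
  }

  get_beta_map <- function() {
    tab <- read_delim_auto(outputs$progression)
    regional_map(tab$AD_vs_HC, as.character(tab$region_id), "beta")
  }

  if ("spread" %in% stages && needs("spread")) {
    if (!file.exists(outputs$progression)) {
      stop("spread stage needs the progression stage outputs", call. = FALSE)
    }
    t0 <- proc.time()[[3L]]
    inp <- load_inputs()
    beta_map <- get_beta_map()
    D <- distance_matrix(inp$con$coordinates)
    sp <- spread_test(beta_map, inp$con, D, n_surr = n_surrogates,
                      rng_seed = stage_seed(4L))
    utils::write.table(
      data.frame(contrast = c("connected", "nonconnected"),
                 r = c(sp$connected$r, sp$nonconnected$r),
                 p_spin = c(sp$connected$p_spin, sp$nonconnected$p_spin),
                 n_regions = sp$n_regions_used),
      outputs$spread, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$timings$spread <- proc.time()[[3L]] - t0
    manifest$seeds$spread <- stage_seed(4L)
    manifest$ran$spread <- TRUE
    log_line("spread: connected r = ", round(sp$connected$r, 3),
             ", p_spin = ", sp$connected$p_spin)
  }

  if ("colocalize" %in% stages && needs("colocalize")) {
    if (!file.exists(outputs$progression)) {
      stop("colocalize stage needs the progression stage outputs",
           call. = FALSE)
    }
    t0 <- proc.time()[[3L]]
    inp <- load_inputs()
    co <- ensure_cohort()
    beta_map <- get_beta_map()
    D <- distance_matrix(inp$con$coordinates)
    rec <- standardize_receptors(co$receptors)
    tab <- colocalize(list(beta_AD_vs_HC = beta_map), rec, D,
                      n_surr = n_surrogates, rng_seed = stage_seed(5L),
                      q = q)
    utils::write.table(tab, outputs$colocalize, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$timings$colocalize <- proc.time()[[3L]] - t0
    manifest$seeds$colocalize <- stage_seed(5L)
    manifest$ran$colocalize <- TRUE
    log_line("colocalize: ", sum(tab$p_spin_fdr <= q),
             " receptor associations at q = ", q)
  }

  all_files <- unlist(outputs[stages], use.names = FALSE)
  all_files <- all_files[file.exists(all_files)]
  digests <- tools::md5sum(all_files)
  names(digests) <- basename(all_files)
  manifest$digests <- as.list(digests)
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> atroprop ", x$version, "\n", sep = "")
  for (st in names(x$ran)) {
    cat("  ", st, ": ", round(x$timings[[st]], 2), " s\n", sep = "")
  }
  invisible(x)
}
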