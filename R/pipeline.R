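# Orchestration: participant exclusion and the end-to-end reproducible run.

#' Exclude low-performing participants
#'
#' Removes participants whose overall proportion correct is strictly
#' below the threshold (default 60%): a participant at exactly the
#' threshold is retained.
#'
#' @param trials Trial table (see [fit_oracle()]).
#' @param threshold Exclusion threshold on overall proportion correct
#'   (default 0.60).
#' @return List with the `trials` that survive and the character vector
#'   `excluded` of removed participant ids.
#' @export
exclude_participants <- function(trials, threshold = 0.60) {
  acc <- tapply(trials$correct, trials$participant_id, mean)
  excluded <- names(acc)[acc < threshold]
  list(trials = trials[!trials$participant_id %in% excluded, , drop = FALSE],
       excluded = excluded)
}

#' Run the full distortion-visibility analysis pipeline
#'
#' Simulates (or ingests) trials, generates synthetic stimuli, computes
#' the metric battery over the distortion grid, applies the participant
#' exclusion filter, fits the experiment-based oracle model and one
#' probit model per metric variant, performs per-metric variant selection,
#' and writes the final WAIC ranking. All stages derive their seeds from
#' the single master seed, so a re-run with the same configuration
#' reproduces the ranking exactly.
#'
#' @param out_dir Output directory (created if missing).
#' @param trials Optional trial table; if `NULL` one is simulated from
#'   [observer_truth()] with the design arguments below.
#' @param participants,images_per_type,trials_per_cell Design of the
#'   simulated experiment (used when `trials` is `NULL`).
#' @param grains,reaches Distortion grid.
#' @param image_size Side length of the synthetic images (default 64).
#' @param metrics Metric names for the battery (default: a compact
#'   image-computable subset; see [compute_battery()]).
#' @param ps_config Texture-statistic configuration.
#' @param exclusion_threshold Proportion-correct cutoff (default 0.6).
#' @param chains,warmup,samples MCMC settings used for every fit.
#' @param seed Master seed.
#' @return Invisibly, a list with the ranking table, fits, battery, and
#'   the manifest. Files written: `trials.csv`, `metrics.csv`,
#'   `ranking.csv`, `manifest.txt`.
#' @export
run_pipeline <- function(out_dir, trials = NULL, participants = 6,
                         images_per_type = 5, trials_per_cell = 1,
                         grains = c(1, 5), reaches = c(1, 2, 4, 8),
                         image_size = 64,
                         metrics = c("mse", "rg_mean", "spectrum_manhattan",
                                     "fourier_slope", "ps_euclidean"),
                         ps_config = list(n_scales = 3, n_orientations = 4,
                                          corr_width = 7),
                         exclusion_threshold = 0.6,
                         chains = 2, warmup = 300, samples = 300, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- with_seed(seed, sample.int(2^31 - 2, 4))
  truth <- observer_truth(grains = grains)
  if (is.null(trials))
    trials <- simulate_experiment(truth, participants = participants,
                                  images_per_type = images_per_type,
                                  reaches = reaches,
                                  trials_per_cell = trials_per_cell,
                                  seed = seeds[1])
  imgs <- list()
  for (id in unique(trials$image_id)) {
    isc <- grepl("^scene", id)
    s <- stimulus_seed(id, 0, 0)
    imgs[[id]] <- if (isc) generate_scene_image(image_size, seed = s)
                  else generate_texture_image(image_size, seed = s)
  }
  battery <- compute_battery(imgs, grains, reaches, metrics = metrics,
                             ps_config = ps_config)
  filt <- exclude_participants(trials, exclusion_threshold)
  trials <- filt$trials
  oracle <- fit_oracle(trials, chains = chains, warmup = warmup,
                       samples = samples, seed = seeds[2])
  results <- list()
  for (m in metrics) {
    for (nv in unique(battery$normalized[battery$metric == m])) {
      ser <- battery[battery$metric == m & battery$normalized == nv, ]
      nm <- if (nv) paste0(m, "_norm") else m
      fit <- fit_metric(trials, ser, chains = chains, warmup = warmup,
                        samples = samples, seed = seeds[3])
      results[[nm]] <- waic(fit$loglik)
    }
  }
  selected <- select_all_variants(results)
  ranking <- final_comparison(waic(oracle$loglik), selected)
  write.csv(trials, file.path(out_dir, "trials.csv"), row.names = FALSE)
  write.csv(battery, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  write.csv(ranking, file.path(out_dir, "ranking.csv"), row.names = FALSE)
  manifest <- c(
    sprintf("eidolonvis %s", as.character(utils::packageVersion("eidolonvis"))),
    sprintf("master_seed: %d", seed),
    sprintf("stage_seeds: %s", paste(seeds, collapse = " ")),
    sprintf("config_hash: %s", config_hash(list(participants, images_per_type,
                                                trials_per_cell, grains, reaches,
                                                image_size, metrics, ps_config,
                                                exclusion_threshold, chains,
                                                warmup, samples, seed))),
    sprintf("excluded_participants: %s",
            if (length(filt$excluded)) paste(filt$excluded, collapse = " ")
            else "none"),
    sprintf("R: %s", R.version.string))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(list(ranking = ranking, oracle = oracle, results = results,
                 selected = selected, battery = battery, trials = trials,
                 excluded = filt$excluded, manifest = manifest))
}

# order-sensitive FNV-style hash of a deparsed configuration
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (v in utf8ToInt(s)) h <- (h * 16777619 + v) %% 2^32
  sprintf("%08x", h)
}
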