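#' Process one simulated sample through the analytical pipeline
#'
#' Convenience wrapper chaining the workflow steps on simulator output:
#' length filtering, pileup construction, threshold calling, no-call region
#' detection, haplotype assembly, VarFreq profiling and truth scoring.
#'
#' @param sim A [simulate_sample()] result.
#' @param ref The [mito_reference()] used for the simulation.
#' @param panel The [amplicon_panel()] used.
#' @param cfg A [caller_config()].
#' @param cutoff_bp Read-length cutoff (default 80).
#' @return List: filter report, pileup, calls, nocall intervals, haplotype
#'   profile, varfreq profile, score (with `php_detected` attribute).
#' @export
process_sample <- function(sim, ref, panel, cfg = caller_config(),
                           cutoff_bp = 80L) {
  fl <- filter_reads(sim$reads, cutoff_bp)
  pl <- build_pileup(fl$kept, ref)
  calls <- call_pileup(pl, ref, cfg)
  nc <- detect_nocall_regions(calls, pl, panel, cfg, ref)
  hap <- call_haplotype(nc$calls, nc$intervals)
  prof <- compute_varfreq_profile(pl, nc$calls)
  score <- score_replicate(hap, sim$truth, ref$canonical_length)
  list(filter_report = fl$report, pileup = pl, calls = nc$calls,
       nocall = nc$intervals, haplotype = hap, varfreq = prof, score = score)
}

#' Run the dilution-series sensitivity experiment
#'
#' Simulates the full gDNA dilution ladder (13 steps, `replicates` each)
#' against one shared panel and truth, runs every replicate through the
#' pipeline and scores it against truth. All randomness derives from
#' `seed`.
#'
#' @param seed Master seed.
#' @param replicates Replicates per dilution (default 3).
#' @param config Base [simulation_config()]; `input_pg` is overridden per
#'   dilution and the panel is generated once and shared.
#' @param ladder A [dilution_ladder()].
#' @param cfg A [caller_config()].
#' @param keep_profiles Keep per-replicate VarFreq profiles and ECDFs
#'   (needed for run-quality classification; default TRUE).
#' @return List: `results` (data.frame label, input_pg, replicate,
#'   pct_mtDNA_covered, false_positive_calls, false_negative_calls,
#'   artifact_position_calls, php17_detected, php17_freq, low_php_called),
#'   `scores` (list of [score_replicate()] rows, for
#'   [php_recovery_curve()]), `ecdfs` (list by "label.replicate"), `panel`,
#'   `ref`.
#' @export
run_dilution_experiment <- function(seed, replicates = 3L,
                                    config = simulation_config(),
                                    ladder = dilution_ladder(replicates),
                                    cfg = caller_config(),
                                    keep_profiles = TRUE) {
  seeds <- local_seed_eval(seed, {
    matrix(sample.int(.Machine$integer.max - 1L, nrow(ladder) * replicates),
           nrow = nrow(ladder))
  })
  if (is.null(config$panel)) {
    config$panel <- simulate_panel(config, seed = seed)
  }
  ref <- config$ref
  php17 <- config$php_sites$position[which.max(config$php_sites$true_frequency)]
  low_php <- setdiff(config$php_sites$position, php17)
  rows <- list(); scores <- list(); ecdfs <- list()
  k <- 0L
  for (d in seq_len(nrow(ladder))) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      cfg_d <- config
      cfg_d$input_pg <- ladder$input_pg[d]
      sim <- simulate_sample(cfg_d, seed = seeds[d, r])
      res <- process_sample(sim, ref, config$panel, cfg)
      php <- attr(res$score, "php_detected")
      hit17 <- php[php$position == php17, , drop = FALSE]
      rows[[k]] <- data.frame(
        label = ladder$label[d], input_pg = ladder$input_pg[d], replicate = r,
        pct_mtDNA_covered = res$score$pct_mtDNA_covered,
        false_positive_calls = res$score$false_positive_calls,
        false_negative_calls = res$score$false_negative_calls,
        artifact_position_calls = res$score$artifact_position_calls,
        php17_detected = isTRUE(hit17$detected),
        php17_freq = if (nrow(hit17)) hit17$observed_frequency else NA_real_,
        low_php_called = sum(php$detected[php$position %in% low_php]),
        stringsAsFactors = FALSE
      )
      scores[[k]] <- res$score
      if (keep_profiles && nrow(res$varfreq) > 0L) {
        ecdfs[[paste0(ladder$label[d], ".", r)]] <- compute_ecdf(res$varfreq)
      }
    }
  }
  results <- do.call(rbind, rows)
  list(results = results,
       scores = stats::setNames(scores,
                                paste0(results$label, ".", results$replicate)),
       ecdfs = ecdfs, panel = config$panel, ref = ref,
       php17_site = php17, seeds = seeds)
}

#' Run-quality classification over a dilution experiment
#'
#' Builds the reference envelope from the full-input (X1) replicates of a
#' [run_dilution_experiment()], classifies a held-out full-input replicate
#' and every low-input replicate against it. A replicate with no covered
#' positions (complete dropout) is classified stochastic with infinite
#' distance.
#'
#' @param exp_ A [run_dilution_experiment()] result.
#' @param holdout_seed Seed for the extra full-input replicate.
#' @param low_labels Ladder labels treated as the low-input set (default
#'   X10..X13).
#' @param config The simulation config used for the experiment (panel and
#'   reference are reused).
#' @param cfg Caller config.
#' @param window,tolerance Passed to [classify_run_quality()].
#' @return List: `band`, `holdout` (classification of the extra X1
#'   replicate), `low` (data.frame label, replicate, classification,
#'   distance).
#' @export
run_quality_experiment <- function(exp_, holdout_seed,
                                   low_labels = paste0("X", 10:13),
                                   config = simulation_config(),
                                   cfg = caller_config(),
                                   window = 93:99, tolerance = 0.005) {
  x1 <- exp_$ecdfs[grep("^X1\\.", names(exp_$ecdfs))]
  band <- ecdf_band(x1)
  config$panel <- exp_$panel
  config$ref <- exp_$ref
  config$input_pg <- dilution_ladder()$input_pg[1]
  sim <- simulate_sample(config, seed = holdout_seed)
  res <- process_sample(sim, exp_$ref, exp_$panel, cfg)
  holdout <- classify_run_quality(compute_ecdf(res$varfreq), band,
                                  window, tolerance)
  low_keys <- names(exp_$ecdfs)[sub("\\..*$", "", names(exp_$ecdfs)) %in% low_labels]
  low <- do.call(rbind, lapply(low_keys, function(k) {
    cl <- classify_run_quality(exp_$ecdfs[[k]], band, window, tolerance)
    data.frame(key = k, classification = cl$classification,
               distance = cl$distance, stringsAsFactors = FALSE)
  }))
  # replicates that dropped out completely never made an ECDF: stochastic
  all_low <- expand.grid(label = low_labels,
                         replicate = seq_len(max(exp_$results$replicate)))
  missing <- setdiff(paste0(all_low$label, ".", all_low$replicate),
                     names(exp_$ecdfs))
  if (length(missing)) {
    low <- rbind(low, data.frame(key = missing, classification = "stochastic",
                                 distance = Inf, stringsAsFactors = FALSE))
  }
  list(band = band, holdout = holdout, low = low)
}

#' Run the recurrent-noisy-position blacklist experiment
#'
#' Two sample groups (the two control DNAs) with the catalogued noise means
#' injected at the catalogued positions, `replicates` replicates each at
#' high input and depth, then cross-replicate blacklisting. The injected
#' replicate-level SD is 1 percentage point: the catalogued SDs include
#' run/lot effects the simulator does not model, and a tight replicate
#' dispersion makes recovery measure the detector rather than sampling luck
#' at the 90% threshold. Only the second group carries no heteroplasmy, so
#' the recurrence requirement (>= 2 distinct samples) screens genuine PHPs
#' out of the blacklist.
#'
#' Recall is computed over catalog positions whose configured means are at
#' or below 88 in BOTH groups (positions closer to the threshold are not
#' reliably detectable by any estimator); precision counts any blacklisted
#' position that was genuinely injected (catalog or homopolymer noise) as a
#' true positive.
#'
#' @param seed Master seed.
#' @param replicates Replicates per group (default 3).
#' @param depth Target per-amplicon depth (default 600).
#' @param noise_sd Injected replicate-level VarFreq SD (default 1).
#' @param recall_max_mean Configured-mean ceiling for the recall set
#'   (default 88).
#' @param config Base [simulation_config()].
#' @param cfg Caller config.
#' @return List: `blacklist` (`NoisyPositionTable`), `recall`, `precision`,
#'   `recall_set`, `hits`, `injected`.
#' @export
run_blacklist_experiment <- function(seed, replicates = 3L, depth = 600,
                                     noise_sd = 1, recall_max_mean = 88,
                                     config = simulation_config(),
                                     cfg = caller_config()) {
  if (is.null(config$panel)) config$panel <- simulate_panel(config, seed = seed)
  ref <- config$ref
  seeds <- local_seed_eval(seed, {
    matrix(sample.int(.Machine$integer.max - 1L, 2L * replicates), nrow = 2L)
  })
  groups <- list()
  models <- list(s1 = numt_noise_model("s1"), s2 = numt_noise_model("s2"))
  for (g in 1:2) {
    gname <- names(models)[g]
    nn <- models[[gname]]
    nn$sd_varfreq <- noise_sd
    cfg_g <- config
    cfg_g$numt_noise <- nn
    cfg_g$target_amplicon_depth <- depth
    if (g == 2L) cfg_g$php_sites <- data.frame(position = integer(0),
                                               true_frequency = numeric(0))
    reps <- lapply(seq_len(replicates), function(r) {
      sim <- simulate_sample(cfg_g, seed = seeds[g, r])
      process_sample(sim, ref, config$panel, cfg)$varfreq
    })
    groups[[gname]] <- reps
  }
  bl <- identify_recurrent_noisy_positions(groups, threshold = 90,
                                           min_samples = 2L, ref = ref,
                                           numt_positions =
                                             noisy_position_catalog()$position[
                                               noisy_position_catalog()$numt])
  hits <- attr(bl, "positions")
  cat_ <- noisy_position_catalog()
  recall_set <- cat_$position[cat_$mean_s1 <= recall_max_mean &
                                cat_$mean_s2 <= recall_max_mean]
  hp_pos <- unlist(lapply(config$homopolymer_regions,
                          function(iv) iv$start:iv$end))
  injected <- sort(unique(c(cat_$position, remap_position(hp_pos, ref))))
  list(blacklist = bl,
       recall = mean(recall_set %in% hits),
       precision = if (length(hits)) mean(hits %in% injected) else NA_real_,
       recall_set = recall_set, hits = hits, injected = injected)
}

#' Run the amplification-negative experiment
#'
#' Simulates `n` amplification negatives, clusters each on (length, MAPQ),
#' derives the pooled length cutoff, filters at 80 bp and reports hotspot
#' amplicons of the removed reads.
#'
#' @param seed Master seed.
#' @param n Number of negatives (default 9, the validation's count).
#' @param config Base [simulation_config()].
#' @return List: `reports` (list of `FilterReport`s), `clusters`,
#'   `derived_cutoff` (granularity 10), `hotspots`, `pct_short` (vector),
#'   `panel`.
#' @export
run_negative_experiment <- function(seed, n = 9L,
                                    config = simulation_config()) {
  if (is.null(config$panel)) config$panel <- simulate_panel(config, seed = seed)
  seeds <- local_seed_eval(seed, sample.int(.Machine$integer.max - 1L, n))
  reports <- list(); clusters <- list(); removed_all <- list()
  for (i in seq_len(n)) {
    neg <- simulate_negative(config, seed = seeds[i])
    fl <- filter_reads(neg$reads, 80L)
    reports[[i]] <- fl$report
    clusters[[i]] <- cluster_reads_2means(neg$reads, seed = seeds[i])
    removed_all[[i]] <- fl$removed
  }
  removed <- do.call(rbind, removed_all)
  list(reports = reports, clusters = clusters,
       derived_cutoff = derive_length_cutoff(clusters, granularity = 10L),
       hotspots = hotspot_amplicons(removed, config$panel),
       pct_short = vapply(reports, function(r) r$pct_short, numeric(1)),
       panel = config$panel)
}
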