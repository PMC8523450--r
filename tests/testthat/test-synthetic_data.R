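test_that("identical config and seed give identical reads and truth", {
  cfg <- simulation_config(ref = fixture_ref(), panel = fixture_panel(),
                           target_amplicon_depth = 40)
  a <- simulate_sample(cfg, seed = 99L)
  b <- simulate_sample(cfg, seed = 99L)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth$noise_fractions, b$truth$noise_fractions)
  expect_identical(a$truth$template_count, b$truth$template_count)
  c <- simulate_sample(cfg, seed = 100L)
  expect_false(identical(a$reads$seq, c$reads$seq))
  expect_error(simulate_sample(simulation_config(ref = fixture_ref())),
               "seed is mandatory")
})

test_that("every emitted read is attributable in the truth", {
  sim <- fixture_sample()
  ids <- sim$reads$read_id
  expect_false(anyDuplicated(ids) > 0)
  art <- sim$truth$artifact_read_ids
  bg <- sim$truth$background_read_ids
  genuine <- setdiff(ids, c(art, bg))
  expect_true(all(art %in% ids))
  expect_equal(length(ids), length(genuine) + length(art) + length(bg))
  # artifact reads are short and poorly mapped; genuine reads the opposite
  expect_true(all(sim$reads$length[ids %in% art] < 80))
  expect_true(all(sim$reads$mapq[ids %in% art] <= 20))
  expect_true(all(sim$reads$length[ids %in% genuine] >= 125))
  expect_true(all(sim$reads$mapq[ids %in% genuine] >= 40))
})

test_that("template counts follow the copy-number model", {
  cfg <- simulation_config(ref = fixture_ref(), panel = fixture_panel(),
                           target_amplicon_depth = 5)
  n <- vapply(1:10, function(i) {
    simulate_sample(cfg, seed = 1000L + i)$truth$template_count
  }, integer(1))
  # N ~ Poisson(2900): each draw within 4 SD of the mean
  expect_true(all(abs(n - 2900) < 4 * sqrt(2900)))

  cfg$input_pg <- 0.009375   # ~0.27 copies: mostly 0 or 1 templates
  n_low <- vapply(1:10, function(i) {
    simulate_sample(cfg, seed = 2000L + i)$truth$template_count
  }, integer(1))
  expect_true(all(n_low <= 3))
  expect_true(any(n_low == 0))
})

test_that("the noise-free limit reproduces the truth haplotype in every read", {
  ref <- fixture_ref()
  cfg <- simulation_config(
    ref = ref, panel = fixture_panel(), target_amplicon_depth = 10,
    php_sites = data.frame(position = integer(0), true_frequency = numeric(0)),
    base_error_rate = 0, pcr_error_rate = 0, numt_noise = NULL,
    homopolymer_del_mean = 0, homopolymer_del_sd = 0,
    artifact_fraction = 0, truth_haplotype = c("263G", "249DEL", "455.1T")
  )
  sim <- simulate_sample(cfg, seed = 55L)
  ext <- strsplit(extend_reference(ref), "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(sim$reads))) {
    r <- sim$reads[i, ]
    span <- r$start:(r$start + r$length - 1L)
    canon <- remap_position(span, ref)
    want <- ext[span]
    want[canon == 263L] <- "G"
    want[canon == 249L] <- "-"
    expect_identical(r$seq, paste(want, collapse = ""))
    if (455L %in% canon) expect_match(r$ins, "^455:T$")
  }
})

test_that("heteroplasmy is assigned at template level with the right fraction", {
  cfg <- simulation_config(ref = fixture_ref(), panel = fixture_panel(),
                           target_amplicon_depth = 40)
  sim <- simulate_sample(cfg, seed = 77L)
  php <- sim$truth$php_sites
  f17 <- php$alt_templates[php$position == 7861L] / sim$truth$template_count
  # realized template fraction within binomial error of 17%
  expect_lt(abs(f17 - 0.17), 4 * sqrt(0.17 * 0.83 / sim$truth$template_count))
})

test_that("negatives are artifact-dominated with a trace background", {
  cfg <- simulation_config(ref = fixture_ref(), panel = fixture_panel())
  neg <- simulate_negative(cfg, seed = 31L)
  expect_equal(neg$truth$template_count, 0L)
  expect_gte(mean(neg$reads$length < 80), 0.5)
  art <- neg$reads[neg$reads$read_id %in% neg$truth$artifact_read_ids, ]
  expect_true(all(art$amplicon %in% c("mt_125", "mt_139", "mt_164",
                                      "mt_130", "mt_133")))

  out <- simulate_negative(cfg, seed = 32L, background_depth = 0,
                           artifact_fraction = 0)
  expect_equal(nrow(out$reads), 0L)
})

test_that("infeasible panel geometries are rejected", {
  # 81 amplicons of at most 174 bp cannot tile a 16,569 bp circle
  cfg <- simulation_config(ref = fixture_ref(), n_amplicons = 81L)
  expect_error(simulate_panel(cfg, seed = 1L), "cannot tile")
  # a 300 bp toy circle tiles with 2 amplicons
  toy <- default_reference(canonical_length = 300L, extension_length = 60L,
                           seed = 2L)
  cfg2 <- simulation_config(ref = toy, n_amplicons = 2L, length_mean = 170,
                            length_sd = 3, length_bounds = c(150L, 180L),
                            php_sites = data.frame(position = integer(0),
                                                   true_frequency = numeric(0)),
                            numt_noise = NULL)
  p <- simulate_panel(cfg2, seed = 3L)
  expect_equal(nrow(p), 2L)
  expect_true(panel_tiles_circle(p, toy))
})

test_that("injected recurrent noise realizes near its configured level", {
  cfg <- simulation_config(ref = fixture_ref(), panel = fixture_panel(),
                           target_amplicon_depth = 150)
  # average realized minor fraction at position 13758 over several samples
  cat_ <- noisy_position_catalog()
  want <- (100 - cat_$mean_s1[cat_$position == 13758L]) / 100
  got <- vapply(1:6, function(i) {
    sim <- simulate_sample(cfg, seed = 5000L + i)
    unname(sim$truth$noise_fractions[["13758"]])
  }, numeric(1))
  expect_lt(abs(mean(got) - want), 0.05)
})

test_that("simulation truth survives a JSON round trip", {
  sim <- fixture_sample()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_truth_json(sim$truth, tmp)
  back <- read_truth_json(tmp)
  expect_equal(back$haplotype, sim$truth$haplotype)
  expect_equal(back$template_count, sim$truth$template_count)
  expect_equal(back$php_sites$position, sim$truth$php_sites$position)
})

test_that("read tables round-trip through TSV", {
  sim <- fixture_sample()
  reads <- sim$reads[1:200, ]
  tmp <- withr::local_tempfile(fileext = ".tsv")
  read_table_write(reads, tmp)
  back <- read_table_read(tmp)
  rownames(reads) <- NULL
  expect_equal(back, reads)
})
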