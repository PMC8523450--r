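test_that("VarFreq is the consensus-allele percentage", {
  ref <- mito_reference("TAC", extension_length = 0L)
  reads <- rbind(
    do.call(rbind, lapply(1:83, function(i) toy_read(paste0("t", i), 1L, "TAC"))),
    do.call(rbind, lapply(1:17, function(i) toy_read(paste0("c", i), 1L, "CAC")))
  )
  pl <- build_pileup(reads, ref)
  calls <- call_pileup(pl, ref, caller_config(min_variant_cov = 10L))
  prof <- compute_varfreq_profile(pl, calls)
  expect_equal(calls$call_type[1], "PHP")
  expect_equal(prof$varfreq[prof$position == 1], 83)   # major allele of the PHP
  expect_equal(prof$varfreq[prof$position == 2], 100)  # monomorphic
  expect_equal(prof$second_variant[prof$position == 1], "C")
})

test_that("tied columns report the tie-broken allele at 50%", {
  ref <- mito_reference("A", extension_length = 0L)
  reads <- rbind(
    do.call(rbind, lapply(1:50, function(i) toy_read(paste0("a", i), 1L, "A"))),
    do.call(rbind, lapply(1:50, function(i) toy_read(paste0("g", i), 1L, "G")))
  )
  pl <- build_pileup(reads, ref)
  prof <- compute_varfreq_profile(pl, call_pileup(pl, ref))
  expect_equal(prof$allele, "A")
  expect_equal(prof$varfreq, 50)
})

test_that("the ECDF uses the 0-99 grid with positions at 100 excluded", {
  all100 <- profile_from_values(rep(100, 50))
  e <- compute_ecdf(all100)
  expect_true(all(e$proportion_le == 0))

  mix <- profile_from_values(c(rep(90, 8), 50, 10))
  e2 <- compute_ecdf(mix)
  expect_equal(e2$proportion_le[e2$grid == 49], 0.1)
  expect_equal(e2$proportion_le[e2$grid == 89], 0.2)
  expect_equal(e2$proportion_le[e2$grid == 99], 1.0)

  expect_error(compute_ecdf(profile_from_values(numeric(0))),
               "insufficient data")
})

test_that("ECDFs are nondecreasing and bounded on random profiles", {
  set.seed(77)
  for (i in 1:20) {
    p <- profile_from_values(runif(500, 0, 100))
    e <- compute_ecdf(p)
    expect_true(all(diff(e$proportion_le) >= 0))
    expect_true(all(e$proportion_le >= 0 & e$proportion_le <= 1))
  }
})

test_that("pooled low-purity proportions match printed-count arithmetic", {
  # 503 of 16,648 positions below 99% purity
  vals <- c(rep(95, 503), rep(100, 16648 - 503))
  e <- compute_ecdf(profile_from_values(vals))
  expect_equal(e$proportion_le[e$grid == 98], 503 / 16648)
  cnt <- varfreq_counts(profile_from_values(vals), 99)
  expect_equal(cnt$n_strict, 503L)
  expect_equal(round(cnt$pct_strict), 3)
})

test_that("recurrence across sample groups gates the blacklist", {
  noisy <- profile_from_values(c(rep(100, 20), 70, rep(100, 9)))  # pos 21 low
  clean <- profile_from_values(rep(100, 30))
  # below threshold in both groups -> blacklisted
  bl <- identify_recurrent_noisy_positions(
    list(g1 = list(noisy, noisy), g2 = list(noisy)), threshold = 90)
  expect_equal(attr(bl, "positions"), 21L)
  expect_equal(nrow(bl), 2L)  # one row per group
  expect_equal(bl$mean_varfreq, c(70, 70))
  # below threshold in one group only -> excluded
  bl2 <- identify_recurrent_noisy_positions(
    list(g1 = list(noisy), g2 = list(clean)), threshold = 90)
  expect_length(attr(bl2, "positions"), 0L)
  # nothing below threshold anywhere -> empty
  bl3 <- identify_recurrent_noisy_positions(
    list(g1 = list(clean), g2 = list(clean)), threshold = 90)
  expect_equal(nrow(bl3), 0L)
})

test_that("the packaged noise catalog is complete and well-formed", {
  cat_ <- noisy_position_catalog()
  expect_equal(nrow(cat_), 26L)
  expect_true(all(cat_$mean_s1 < 90 | cat_$mean_s2 < 90))
  expect_true(all(cat_$second_variant %in% c("DEL", "INS", "G")))
  expect_equal(sum(cat_$numt), 8L)
  expect_true(all(diff(cat_$position) > 0))
})

test_that("coverage summaries follow their definitions", {
  ref <- mito_reference(strrep("A", 300), extension_length = 0L)
  panel <- amplicon_panel(name = c("p1", "p2"), start = c(1L, 151L),
                          end = c(150L, 300L), length_bounds = c(100L, 200L))
  uniform <- do.call(rbind, lapply(1:100, function(i)
    toy_read(paste0("u", i), 1L, strrep("A", 300))))
  pl <- build_pileup(uniform, ref)
  cs <- coverage_summary(pl, panel, uniform, ref)
  expect_equal(cs$mean_base_coverage, 100)
  expect_equal(cs$uniformity_pct, 100)
  expect_equal(cs$total_mapped_reads, 100L)

  half <- do.call(rbind, lapply(1:200, function(i)
    toy_read(paste0("h", i), 1L, strrep("A", 150))))
  pl2 <- build_pileup(half, ref)
  cs2 <- coverage_summary(pl2, panel, half, ref)
  expect_equal(cs2$mean_base_coverage, 100)
  expect_equal(cs2$uniformity_pct, 50)
  # conservation over the non-overlapping partition
  expect_equal(sum(cs2$per_amplicon * panel$length), sum(pl2$depth))
})

test_that("simulated coverage lands near the configured amplicon depth", {
  sim <- fixture_sample()  # target depth 60 per amplicon
  res <- process_sample(sim, fixture_ref(), fixture_panel())
  cs <- coverage_summary(res$pileup, fixture_panel(), sim$reads, fixture_ref())
  # amplicon overlap pushes base depth above the per-amplicon target
  mult <- sum(fixture_panel()$length) / 16569
  expect_lt(abs(cs$mean_base_coverage - 60 * mult) / (60 * mult), 0.10)
})

test_that("run-quality classification measures band exceedance", {
  base_vals <- c(rep(50, 5), rep(100, 495))
  ecdfs <- lapply(1:3, function(i) {
    compute_ecdf(profile_from_values(c(base_vals, rep(95, i))))
  })
  band <- ecdf_band(ecdfs)
  inside <- classify_run_quality(ecdfs[[2]], band)
  expect_equal(inside$classification, "stable")
  expect_equal(inside$distance, 0)

  noisy <- compute_ecdf(profile_from_values(c(base_vals, rep(95, 40))))
  out <- classify_run_quality(noisy, band)
  expect_equal(out$classification, "stochastic")
  expect_gt(out$distance, 0.005)

  expect_error(ecdf_band(ecdfs[1:2]), "insufficient reference")
})
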