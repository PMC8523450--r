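toy_ref <- mito_reference(strrep("A", 200), extension_length = 20L)

test_that("pileup columns count bases per canonical position", {
  r <- toy_read("r1", 1L, strrep("A", 100))
  pl <- build_pileup(r, toy_ref)
  expect_equal(sum(pl$depth), 100L)
  expect_equal(pl$depth[1:100], rep(1L, 100))
  expect_equal(unname(pl$counts[1, "A"]), 1L)

  # two reads overlapping at one position with different bases
  two <- rbind(toy_read("r1", 1L, paste0(strrep("A", 49), "T")),
               toy_read("r2", 50L, paste0("C", strrep("A", 49)), strand = "-"))
  pl2 <- build_pileup(two, toy_ref)
  expect_equal(pl2$depth[50], 2L)
  expect_equal(unname(pl2$counts[50, c("T", "C")]), c(1L, 1L))
  expect_equal(unname(pl2$counts_plus[50, "T"]), 1L)
  expect_equal(unname(pl2$counts_minus[50, "C"]), 1L)
})

test_that("wrap-region reads contribute to canonical positions", {
  r <- toy_read("r1", 195L, strrep("A", 15))  # spans 195..209 on extended axis
  pl <- build_pileup(r, toy_ref)
  expect_equal(which(pl$depth > 0), c(1:9, 195:200))
})

test_that("malformed reads are rejected", {
  bad_len <- toy_read("r1", 1L, "ACGT"); bad_len$length <- 10L
  expect_error(build_pileup(bad_len, toy_ref), "seq length")
  expect_error(build_pileup(toy_read("r1", 215L, strrep("A", 10)), toy_ref),
               "beyond the extended axis")
  expect_error(build_pileup(toy_read("r1", 1L, "ACGX"), toy_ref), "only contain")
})

test_that("pileup depth conserves simulated aligned bases", {
  sim <- fixture_sample()
  genuine <- sim$reads[!(sim$reads$read_id %in%
                           c(sim$truth$artifact_read_ids,
                             sim$truth$background_read_ids)), ]
  pl <- build_pileup(genuine, fixture_ref())
  expect_equal(sum(as.numeric(pl$depth)), sim$truth$genuine_aligned_bases)
})

test_that("the decision cascade classifies canonical threshold cases", {
  cfg <- caller_config()
  php <- call_position(list(position = 7861L, counts = c(T = 830L, C = 170L)),
                       "T", cfg)
  expect_equal(php$call_type, "PHP")
  expect_equal(sort(c(php$allele1, php$allele2)), c("C", "T"))
  expect_equal(php$variant_frequency, 17.0)

  low <- call_position(list(counts = c(T = 13L, C = 2L)), "T", cfg)
  expect_equal(low$call_type, "no-call")

  sub <- call_position(list(counts = c(G = 97L, A = 3L)), "A", cfg)
  expect_equal(sub$call_type, "substitution")
  expect_equal(sub$allele1, "G")

  refc <- call_position(list(counts = c(A = 91L, G = 9L)), "A", cfg)
  expect_equal(refc$call_type, "reference")

  del <- call_position(list(counts = c(A = 60L, DEL = 40L)), "A", cfg)
  expect_equal(del$call_type, "deletion")
  expect_equal(del$variant_frequency, 40.0)

  ins <- call_position(list(counts = c(A = 100L), insertions = c(C = 30L)),
                       "A", cfg)
  expect_true("insertion" %in% ins$call_type)
  expect_equal(ins$allele1[ins$call_type == "insertion"], "C")
})

test_that("equal-count ties resolve by reference preference then base order", {
  cfg <- caller_config()
  tie_ref <- call_position(list(counts = c(A = 50L, G = 50L)), "A", cfg)
  expect_equal(tie_ref$allele1, "A")   # reference preferred
  tie_lex <- call_position(list(counts = c(C = 50L, G = 50L)), "A", cfg)
  expect_equal(tie_lex$allele1, "C")   # lexicographic among non-reference
})

test_that("raising the PHP threshold only shrinks the PHP set", {
  set.seed(31)
  ref <- mito_reference(paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                              collapse = ""), extension_length = 0L)
  # random pileup with a spread of minor-allele fractions
  reads <- do.call(rbind, lapply(1:60, function(i) {
    minor <- sample(c(0, 0.05, 0.12, 0.2, 0.35), 1)
    seq <- strsplit(ref$sequence, "")[[1]]
    flip <- runif(400) < minor
    alt <- c(A = "G", C = "T", G = "A", T = "C")
    seq[flip] <- alt[seq[flip]]
    toy_read(paste0("r", i), 1L, paste(seq, collapse = ""))
  }))
  pl <- build_pileup(reads, ref)
  php_set <- function(thr) {
    calls <- call_pileup(pl, ref, caller_config(php_threshold = thr))
    calls$position[calls$call_type == "PHP"]
  }
  s10 <- php_set(10); s20 <- php_set(20); s35 <- php_set(35)
  expect_true(all(s20 %in% s10))
  expect_true(all(s35 %in% s20))
})

test_that("a monomorphic pileup yields the empty reference profile", {
  reads <- do.call(rbind, lapply(1:25, function(i)
    toy_read(paste0("r", i), 1L, strrep("A", 200))))
  pl <- build_pileup(reads, toy_ref)
  calls <- call_pileup(pl, toy_ref)
  hap <- call_haplotype(calls)
  expect_length(hap$variants, 0L)
})

test_that("no-call runs become intervals and low-coverage positions are flagged", {
  ref <- mito_reference(strrep("A", 300), extension_length = 0L)
  panel <- amplicon_panel(name = c("p1", "p2"), start = c(1L, 140L),
                          end = c(150L, 300L), length_bounds = c(100L, 200L))
  # deep coverage except a hole at 101..191 (91 bp) and one thin position
  reads <- do.call(rbind, c(
    lapply(1:40, function(i) toy_read(paste0("a", i), 1L, strrep("A", 100))),
    lapply(1:40, function(i) toy_read(paste0("b", i), 192L, strrep("A", 109))),
    list(toy_read("thin", 101L, strrep("A", 1)))
  ))
  pl <- build_pileup(reads, ref)
  calls <- call_pileup(pl, ref)
  nc <- detect_nocall_regions(calls, pl, panel, caller_config(), ref)
  expect_equal(nrow(nc$intervals), 1L)
  expect_equal(nc$intervals$length, 91L)
  expect_equal(nc$intervals$start, 101L)

  # a position at 3% of its amplicon median depth gets the flag
  reads2 <- do.call(rbind, c(
    lapply(1:1000, function(i) toy_read(paste0("a", i), 1L, strrep("A", 100))),
    lapply(1:30, function(i) toy_read(paste0("t", i), 101L, "A")),
    lapply(1:1000, function(i) toy_read(paste0("b", i), 102L, strrep("A", 199)))
  ))
  pl2 <- build_pileup(reads2, ref)
  calls2 <- call_pileup(pl2, ref)
  nc2 <- detect_nocall_regions(calls2, pl2, panel, caller_config(), ref)
  expect_equal(nrow(nc2$intervals), 0L)
  f101 <- nc2$calls$flags[nc2$calls$position == 101L]
  expect_match(f101, "low-coverage-region")
})

test_that("the caller recovers injected heteroplasmy frequencies at high input", {
  # small circle, full template count: the PHP estimate is dominated by
  # template sampling, so the median over replicates should sit on truth
  toy <- default_reference(canonical_length = 3000L, extension_length = 80L,
                           seed = 12L)
  cfg <- simulation_config(
    ref = toy, n_amplicons = 30L, length_mean = 150, length_sd = 8,
    php_sites = data.frame(position = c(1500L, 2200L),
                           true_frequency = c(17, 3)),
    truth_haplotype = character(0), numt_noise = NULL,
    homopolymer_regions = list(), strand_bias_regions = list(),
    artifact_fraction = 0, target_amplicon_depth = 150
  )
  cfg$panel <- simulate_panel(cfg, seed = 8L)
  cc <- caller_config()
  est17 <- numeric(25); called3 <- logical(25)
  for (i in 1:25) {
    sim <- simulate_sample(cfg, seed = 6000L + i)
    pl <- build_pileup(sim$reads, toy)
    ref_at <- function(p) substr(toy$sequence, p, p)
    c17 <- call_position(list(position = 1500L,
                              counts = pl$counts[1500L, ]), ref_at(1500), cc)
    est17[i] <- if (c17$call_type == "PHP") c17$variant_frequency else NA_real_
    c3 <- call_position(list(position = 2200L,
                             counts = pl$counts[2200L, ]), ref_at(2200), cc)
    called3[i] <- c3$call_type == "PHP"
  }
  expect_true(all(!is.na(est17)))                 # 17% always detected
  expect_lt(abs(median(est17) - 17), 2)           # estimate centred on truth
  expect_false(any(called3))                      # 3% never passes the 10% cut
})

test_that("full coverage yields no no-call intervals", {
  sim <- fixture_sample()
  res <- process_sample(sim, fixture_ref(), fixture_panel())
  expect_equal(nrow(res$nocall), 0L)
})

test_that("strand bias flags one-sided variant support", {
  expect_true(flag_strand_bias(100L, 0L))
  expect_false(flag_strand_bias(50L, 50L))
  expect_true(flag_strand_bias(95L, 5L))   # 5% minority < 10%
  expect_false(flag_strand_bias(0L, 0L))

  # injected one-strand noise alleles get the flag through the caller
  ref <- mito_reference(strrep("A", 200), extension_length = 0L)
  plus_var <- do.call(rbind, lapply(1:30, function(i)
    toy_read(paste0("v", i), 1L, paste0(strrep("A", 99), "G", strrep("A", 100)))))
  bal <- do.call(rbind, lapply(1:70, function(i)
    toy_read(paste0("w", i), 1L, strrep("A", 200),
             strand = if (i %% 2) "+" else "-")))
  pl <- build_pileup(rbind(plus_var, bal), ref)
  calls <- call_pileup(pl, ref)
  i <- which(calls$position == 100L & calls$call_type == "PHP")
  expect_match(calls$flags[i], "strand-bias")
})

test_that("haplotype notation assembles and round-trips", {
  expect_equal(variant_notation(263L, "substitution", "G"), "263G")
  expect_equal(variant_notation(7861L, "PHP", "T", "C"), "7861Y")
  expect_equal(variant_notation(249L, "deletion", "DEL"), "249DEL")
  expect_equal(variant_notation(309L, "insertion", "C"), "309.1C")
  expect_equal(variant_notation(309L, "insertion", "CC"), c("309.1C", "309.2C"))
  expect_equal(variant_notation(524L, "insertion", "AC"), "524.AC")

  toks <- c("263G", "309.1C", "524.AC", "7861Y", "249DEL", "310.1C", "310.2C")
  df <- parse_haplotype(paste(toks, collapse = " "))
  expect_equal(df$allele[df$position == 310], "CC")
  expect_equal(df$allele[df$position == 7861], "Y")
  expect_equal(df$type[df$position == 249], "deletion")
  # round trip through the formatter
  back <- unlist(lapply(seq_len(nrow(df)), function(i) {
    al <- df$allele[i]
    if (df$type[i] == "PHP") {
      b <- iupac_bases(al)
      variant_notation(df$position[i], "PHP", b[1], b[2])
    } else variant_notation(df$position[i], df$type[i], al)
  }))
  expect_setequal(back, toks)
  expect_error(parse_haplotype("263G 263A"), "duplicate")
  expect_error(parse_haplotype("foo"), "cannot parse")
})

test_that("IUPAC codes map base pairs both ways", {
  expect_equal(iupac_code("T", "C"), "Y")
  expect_equal(iupac_code("G", "A"), "R")
  expect_equal(sort(iupac_bases("K")), c("G", "T"))
  expect_error(iupac_code("A", "A"), "not a base pair")
})

test_that("VCF output encodes the variant classes", {
  sim <- fixture_sample()
  res <- process_sample(sim, fixture_ref(), fixture_panel())
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(res$calls, fixture_ref(), tmp)
  lines <- readLines(tmp)
  expect_true(any(grepl("^##fileformat=VCFv4.2", lines)))
  body <- lines[!grepl("^#", lines)]
  expect_gt(length(body), 20L)
  expect_true(all(grepl("VF=", body)))
})

test_that("SAM export produces CIGARs consistent with the dialect", {
  r <- rbind(
    toy_read("plain", 1L, strrep("A", 30)),
    toy_read("del", 1L, paste0(strrep("A", 10), "-", strrep("A", 19))),
    toy_read("ins", 1L, strrep("A", 30), ins = "5:CC")
  )
  tmp <- withr::local_tempfile(fileext = ".sam")
  write_sam(r, toy_ref, tmp)
  lines <- readLines(tmp)
  aln <- lines[!grepl("^@", lines)]
  cig <- vapply(strsplit(aln, "\t"), `[[`, character(1), 6L)
  expect_equal(cig, c("30M", "10M1D19M", "5M2I25M"))
})
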