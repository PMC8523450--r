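test_that("copy-number conversion is linear in input mass", {
  expect_equal(copies_from_input(100)$copies, 2900)
  expect_equal(copies_from_input(100)$copies_rounded, 2900L)
  expect_equal(copies_from_input(0.6)$copies, 17.4)
  expect_equal(copies_from_input(0.6)$copies_rounded, 17L)
  expect_equal(copies_from_input(0)$copies, 0)
  expect_error(copies_from_input(-1), ">= 0")
  a <- 3.7; b <- 12.9
  expect_equal(copies_from_input(a + b)$copies,
               copies_from_input(a)$copies + copies_from_input(b)$copies)
})

make_profile <- function(variants, nocall = NULL) {
  if (is.null(nocall)) {
    nocall <- data.frame(start = integer(0), end = integer(0),
                         length = integer(0))
  }
  df <- parse_haplotype(variants)
  a1 <- df$allele
  a2 <- rep(NA_character_, nrow(df))
  for (i in which(df$type == "PHP")) {
    b <- iupac_bases(df$allele[i])
    a1[i] <- b[1]; a2[i] <- b[2]
  }
  n <- nrow(df)
  calls <- data.frame(
    position = df$position, ref = rep("A", n), call_type = df$type,
    allele1 = a1, allele2 = a2,
    variant_frequency = rep(99, n), depth = rep(1000L, n),
    flags = rep("", n), stringsAsFactors = FALSE
  )
  structure(list(variants = variants, calls = calls, nocall = nocall),
            class = "HaplotypeProfile")
}

test_that("replicate scoring against truth is exact on hand-built fixtures", {
  truth <- list(haplotype = c("263G", "750C", "249DEL"),
                php_sites = data.frame(position = 7861L, true_frequency = 17),
                noisy_positions = c(309L))
  perfect <- make_profile(c("263G", "750C", "249DEL"))
  s <- score_replicate(perfect, truth)
  expect_equal(s$pct_mtDNA_covered, 100)
  expect_equal(s$false_positive_calls, 0L)
  expect_equal(s$false_negative_calls, 0L)

  # one FP, one FN, one artifact-position call
  flawed <- make_profile(c("263G", "1000T", "309DEL"))
  s2 <- score_replicate(flawed, truth)
  expect_equal(s2$false_positive_calls, 1L)      # 1000T
  expect_equal(s2$false_negative_calls, 2L)      # 750C, 249DEL missed
  expect_equal(s2$artifact_position_calls, 1L)   # 309DEL

  # truth variant inside a no-call gap is not an FN
  gappy <- make_profile(c("263G", "249DEL"),
                        nocall = data.frame(start = 700L, end = 800L,
                                            length = 101L))
  s3 <- score_replicate(gappy, truth)
  expect_equal(s3$false_negative_calls, 0L)
  expect_equal(s3$fn_uncovered, 1L)
  expect_lt(s3$pct_mtDNA_covered, 100)
})

test_that("identical and empty profiles are fully concordant", {
  a <- make_profile(c("263G", "7861Y"))
  expect_equal(compare_haplotypes(a, a)$verdict, "full")
  e <- make_profile(character(0))
  expect_equal(compare_haplotypes(e, e)$verdict, "full")
  expect_equal(compare_haplotypes(e, e)$concordant, 0L)
})

test_that("a platform-private homopolymer insertion is one flagged discordance", {
  a <- make_profile(c("263G", "524.AC"))
  b <- make_profile(c("263G"))
  cc <- compare_haplotypes(a, b)
  expect_equal(cc$verdict, "partial")
  expect_equal(nrow(cc$discordant), 1L)
  expect_equal(cc$discordant$position, 524L)
  expect_match(cc$discordant$note, "homopolymer")
  expect_equal(cc$concordant, 1L)
})

test_that("PHP-vs-homoplasmy counts as concordant-with-note unless strict", {
  a <- make_profile(c("263G", "7861Y"))
  b <- make_profile(c("263G"))
  lax <- compare_haplotypes(a, b)
  expect_equal(lax$verdict, "full")
  expect_length(lax$concordant_with_note, 1L)
  strict <- compare_haplotypes(a, b, strict_php = TRUE)
  expect_equal(nrow(strict$discordant), 1L)
})

test_that("no-call positions are excluded from comparison and listed", {
  a <- make_profile(c("263G", "750C"))
  b <- make_profile(c("263G"),
                    nocall = data.frame(start = 740L, end = 760L, length = 21L))
  cc <- compare_haplotypes(a, b)
  expect_equal(cc$verdict, "full")    # 750 not comparable
  expect_true(750L %in% cc$excluded_nocall)
})

test_that("control-region restriction drops coding-region variants", {
  a <- make_profile(c("263G", "8000T"))
  b <- make_profile(c("263G"))
  cc <- compare_haplotypes(a, b, restrict_to = "control-region")
  expect_equal(cc$verdict, "full")
  expect_equal(cc$concordant, 1L)
})

test_that("blacklisted positions are excluded from concordance and listed", {
  a <- make_profile(c("263G", "13758DEL"))
  b <- make_profile(c("263G"))
  cc <- compare_haplotypes(a, b, exclude_positions = c(309L, 13758L))
  expect_equal(cc$verdict, "full")
  expect_equal(cc$excluded_blacklisted, 13758L)
  raw <- compare_haplotypes(a, b)
  expect_equal(raw$verdict, "partial")
})

test_that("duplicate variants in a profile are rejected", {
  expect_error(compare_haplotypes(c("263G", "263G"), "263G"), "duplicate")
})

test_that("the PHP recovery curve reshapes dilution scores", {
  truth <- list(haplotype = "263G",
                php_sites = data.frame(position = 7861L, true_frequency = 17),
                noisy_positions = integer(0))
  s_present <- score_replicate(make_profile(c("263G", "7861Y")), truth)
  s_absent <- score_replicate(make_profile("263G"), truth)
  dil <- list(label = c("X1", "X2"), input_pg = c(100, 20),
              replicate = c(1L, 1L), scores = list(s_present, s_absent))
  tab <- php_recovery_curve(dil, 7861L)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$detected, c(TRUE, FALSE))
  expect_warning(php_recovery_curve(dil, 9999L), "never covered")
})
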