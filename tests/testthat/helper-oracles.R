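# Independent oracles and shared fixtures for the suite.

# Exhaustive minimum within-cluster sum of squares over all 2-partitions,
# on the same standardized coordinates the clustering uses. Independent of
# the k-means path: enumerates every partition.
brute_force_wss2 <- function(x) {
  z <- scale(x)
  z[, apply(x, 2L, stats::sd) == 0] <- 0
  n <- nrow(z)
  stopifnot(n >= 2L, n <= 14L)
  best <- Inf
  for (m in 1:(2^(n - 1L) - 1L)) {
    g <- c(0L, as.integer(intToBits(m))[1:(n - 1L)])
    if (all(g == g[1])) next
    w <- 0
    for (k in 0:1) {
      zi <- z[g == k, , drop = FALSE]
      w <- w + sum(sweep(zi, 2L, colMeans(zi))^2)
    }
    if (w < best) best <- w
  }
  best
}

# Published negative-control read counts (total mapped / shorter than 80 bp)
# for the nine amplification negatives of the validation; the percentages
# derived from them feed the arithmetic checks.
negative_control_counts <- function() {
  data.frame(
    sample = c("Ctrl-1.1", "Ctrl-2.1", "Ctrl-3.1", "Ctrl-4.1", "Ctrl-4.2",
               "Ctrl-4.3", "Ctrl-4.4", "Ctrl-5.1", "Ctrl-5.2"),
    total = c(2972L, 7244L, 3049L, 2829L, 6301L, 2963L, 6386L, 8764L, 6949L),
    short = c(1762L, 3958L, 2094L, 1807L, 5494L, 1852L, 4982L, 6334L, 5247L),
    stringsAsFactors = FALSE
  )
}

# A read table with a prescribed number of short (50 bp) and long (150 bp)
# reads, for exercising the filter on known counts.
reads_with_counts <- function(total, short) {
  data.frame(
    read_id = sprintf("r%d", seq_len(total)),
    start = 1L, length = rep(c(50L, 150L), c(short, total - short)),
    mapq = 50L, strand = "+", amplicon = "mt_1",
    seq = NA_character_, ins = "", stringsAsFactors = FALSE
  )
}

# Gapless read-table rows over a toy reference.
toy_read <- function(id, start, seq, strand = "+", mapq = 50L, ins = "") {
  data.frame(read_id = id, start = as.integer(start),
             length = nchar(seq), mapq = mapq, strand = strand,
             amplicon = NA_character_, seq = seq, ins = ins,
             stringsAsFactors = FALSE)
}

# Small shared simulation objects (computed once per test run).
.fixture_cache <- new.env(parent = emptyenv())

fixture_ref <- function() {
  if (is.null(.fixture_cache$ref)) .fixture_cache$ref <- default_reference()
  .fixture_cache$ref
}

fixture_panel <- function() {
  if (is.null(.fixture_cache$panel)) {
    cfg <- simulation_config(ref = fixture_ref())
    .fixture_cache$panel <- simulate_panel(cfg, seed = 7L)
  }
  .fixture_cache$panel
}

# A light (depth 60) full-input sample shared across unit tests.
fixture_sample <- function() {
  if (is.null(.fixture_cache$sample)) {
    cfg <- simulation_config(ref = fixture_ref(), panel = fixture_panel(),
                             target_amplicon_depth = 60, seed = 301L)
    .fixture_cache$sample <- simulate_sample(cfg)
  }
  .fixture_cache$sample
}

# The dilution-ladder experiment used by the acceptance checks (heavy;
# computed once and shared between the criterion blocks that need it).
fixture_ladder_experiment <- function() {
  if (is.null(.fixture_cache$ladder)) {
    .fixture_cache$ladder <- run_dilution_experiment(seed = 424242L)
  }
  .fixture_cache$ladder
}

# A synthetic VarFreq profile with given varfreq values at positions 1..n.
profile_from_values <- function(varfreq, depth = 1000L) {
  n <- length(varfreq)
  structure(data.frame(
    position = seq_len(n), varfreq = varfreq,
    depth = rep(depth, n), allele = rep("A", n),
    second_variant = rep(NA_character_, n),
    stringsAsFactors = FALSE
  ), class = c("VarFreqProfile", "data.frame"))
}
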