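#' Per-position VarFreq (haplotype purity) profile
#'
#' VarFreq at a position is the percentage of reads supporting the called
#' (consensus) allele — for point heteroplasmies, the MAJOR allele.
#' Depressed values indicate noise, NUMT co-amplification or mixture.
#' Positions with zero depth are absent from the profile; no-call positions
#' with nonzero depth use their majority allele.
#'
#' Reads carrying an insertion anchored at a position count against the
#' consensus there when the insertion is a minority state (their local
#' haplotype differs from the consensus), and as supporting when the
#' insertion itself is the consensus (a called insertion variant).
#'
#' @param pileup A [build_pileup()] result.
#' @param calls Calls from [call_pileup()] over the same pileup.
#' @return `VarFreqProfile`: data.frame position, varfreq (percent), depth,
#'   allele (the consensus allele whose frequency is reported),
#'   second_variant (second most common allele among A/C/G/T/DEL/INS, `NA`
#'   when the column is monomorphic).
#' @export
compute_varfreq_profile <- function(pileup, calls) {
  base_calls <- calls[calls$call_type != "insertion", , drop = FALSE]
  if (!identical(base_calls$position, seq_len(pileup$canonical_length))) {
    stop("consistency error: calls and pileup positions disagree")
  }
  keep <- pileup$depth > 0L
  pos <- which(keep)
  cnt <- pileup$counts[pos, , drop = FALSE]
  depth <- pileup$depth[pos]
  allele <- base_calls$allele1[pos]
  # no-call positions with coverage: majority allele
  nab <- is.na(allele)
  if (any(nab)) {
    allele[nab] <- colnames(cnt)[max.col(cnt[nab, , drop = FALSE],
                                         ties.method = "first")]
  }
  called_cnt <- cnt[cbind(seq_along(pos), match(allele, colnames(cnt)))]
  # insertion-carrying reads at each position (all inserted alleles pooled)
  ins_cnt <- integer(length(pos))
  if (nrow(pileup$ins) > 0L) {
    agg <- tapply(pileup$ins$count, pileup$ins$position, sum)
    hit <- match(pos, as.integer(names(agg)))
    ins_cnt[!is.na(hit)] <- as.integer(agg[hit[!is.na(hit)]])
  }
  # consensus support: minority insertions subtract from it, a consensus
  # (majority) insertion is itself the supported state
  supporting <- ifelse(ins_cnt <= depth / 2,
                       pmax(called_cnt - ins_cnt, 0L),
                       pmin(called_cnt, ins_cnt))
  cnt6 <- cbind(cnt, INS = ins_cnt)
  cnt6[cbind(seq_along(pos), match(allele, colnames(cnt6)))] <- -1L
  sec_i <- max.col(cnt6, ties.method = "first")
  sec_cnt <- cnt6[cbind(seq_along(pos), sec_i)]
  second <- ifelse(sec_cnt > 0L, colnames(cnt6)[sec_i], NA_character_)
  structure(data.frame(
    position = pos,
    varfreq = 100 * supporting / depth,
    depth = depth,
    allele = allele,
    second_variant = second,
    stringsAsFactors = FALSE
  ), class = c("VarFreqProfile", "data.frame"))
}

#' Empirical cumulative VarFreq distribution on the 0-99 integer grid
#'
#' Pools the positions of one or more profiles and reports, for every
#' integer VarFreq value 0..99, the fraction of pooled positions with
#' VarFreq at or below it. Positions at exactly 100 (and any value above
#' 99) contribute to no grid point but stay in the denominator, matching the
#' 0-99 reporting range.
#'
#' @param profiles A `VarFreqProfile` or list of them.
#' @return `VarFreqECDF`: data.frame grid (0..99), proportion_le.
#' @export
compute_ecdf <- function(profiles) {
  if (inherits(profiles, "VarFreqProfile")) profiles <- list(profiles)
  vf <- unlist(lapply(profiles, function(p) p$varfreq), use.names = FALSE)
  if (length(vf) == 0L) stop("insufficient data: no covered positions pooled")
  grid <- 0:99
  n_le <- vapply(grid, function(g) sum(vf <= g), numeric(1))
  structure(data.frame(grid = grid, proportion_le = n_le / length(vf)),
            class = c("VarFreqECDF", "data.frame"))
}

#' Count positions below a VarFreq threshold
#'
#' Both strict (`< threshold`) and inclusive (`<= threshold`) counts over
#' pooled profiles, with the pooled total.
#'
#' @param profiles A `VarFreqProfile` or list of them.
#' @param threshold VarFreq percentage.
#' @return List: n_strict, n_inclusive, n_total, pct_strict, pct_inclusive.
#' @export
varfreq_counts <- function(profiles, threshold) {
  if (inherits(profiles, "VarFreqProfile")) profiles <- list(profiles)
  vf <- unlist(lapply(profiles, function(p) p$varfreq), use.names = FALSE)
  list(n_strict = sum(vf < threshold),
       n_inclusive = sum(vf <= threshold),
       n_total = length(vf),
       pct_strict = 100 * sum(vf < threshold) / length(vf),
       pct_inclusive = 100 * sum(vf <= threshold) / length(vf))
}

#' Recurrent noisy positions across replicated samples
#'
#' A position is blacklisted when its mean VarFreq across the replicates of
#' a sample falls below `threshold` in at least `min_samples` distinct
#' sample groups — recurrence across samples, not merely across replicates
#' of one sample. The result is long-format (one row per position x group),
#' mirroring how such catalogs are reported.
#'
#' @param replicate_profiles Named list of sample groups; each element a
#'   list of `VarFreqProfile`s (the group's replicates).
#' @param threshold VarFreq percentage (default 90).
#' @param min_samples Minimum number of failing groups (default 2).
#' @param ref Optional [mito_reference()] used to fill `ref_base`.
#' @param numt_positions Optional integer vector of positions annotated as
#'   known NUMTs (sets `numt_annotated`).
#' @return `NoisyPositionTable`: data.frame position, ref_base, sample,
#'   mean_varfreq, sd_varfreq, second_most_common_variant, numt_annotated;
#'   attribute `positions` holds the unique blacklisted positions.
#' @export
identify_recurrent_noisy_positions <- function(replicate_profiles,
                                               threshold = 90,
                                               min_samples = 2L,
                                               ref = NULL,
                                               numt_positions = NULL) {
  stopifnot(is.list(replicate_profiles), length(replicate_profiles) >= min_samples)
  groups <- names(replicate_profiles)
  if (is.null(groups)) groups <- paste0("sample", seq_along(replicate_profiles))
  per_group <- lapply(replicate_profiles, function(reps) {
    if (inherits(reps, "VarFreqProfile")) reps <- list(reps)
    pos <- sort(unique(unlist(lapply(reps, function(p) p$position))))
    mat <- vapply(reps, function(p) {
      p$varfreq[match(pos, p$position)]
    }, numeric(length(pos)))
    mat <- matrix(mat, nrow = length(pos))
    sec <- unlist(lapply(reps, function(p) {
      stats::setNames(p$second_variant, p$position)
    }))
    list(pos = pos,
         mean = rowMeans(mat, na.rm = TRUE),
         sd = apply(mat, 1L, stats::sd, na.rm = TRUE),
         second = sec)
  })
  fail <- lapply(per_group, function(g) g$pos[g$mean < threshold])
  tab <- table(unlist(fail))
  black <- sort(as.integer(names(tab)[tab >= min_samples]))
  if (length(black) == 0L) {
    out <- data.frame(position = integer(0), ref_base = character(0),
                      sample = character(0), mean_varfreq = numeric(0),
                      sd_varfreq = numeric(0),
                      second_most_common_variant = character(0),
                      numt_annotated = logical(0), stringsAsFactors = FALSE)
    return(structure(out, class = c("NoisyPositionTable", "data.frame"),
                     positions = black, threshold = threshold,
                     min_samples = min_samples))
  }
  rows <- list()
  refbase <- if (!is.null(ref)) strsplit(ref$sequence, "", fixed = TRUE)[[1]] else NULL
  for (gi in seq_along(per_group)) {
    g <- per_group[[gi]]
    hit <- match(black, g$pos)
    sec_mode <- vapply(black, function(p) {
      s <- g$second[names(g$second) == as.character(p)]
      s <- s[!is.na(s)]
      if (!length(s)) NA_character_ else names(sort(table(s), decreasing = TRUE))[1]
    }, character(1))
    rows[[gi]] <- data.frame(
      position = black,
      ref_base = if (is.null(refbase)) NA_character_ else refbase[black],
      sample = groups[gi],
      mean_varfreq = round(g$mean[hit], 2),
      sd_varfreq = round(g$sd[hit], 2),
      second_most_common_variant = sec_mode,
      numt_annotated = if (is.null(numt_positions)) FALSE else black %in% numt_positions,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$sample), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("NoisyPositionTable", "data.frame"),
            positions = black, threshold = threshold, min_samples = min_samples)
}

#' Packaged catalog of recurrent noisy positions
#'
#' The recurrent low-VarFreq positions observed across replicates of the two
#' forensic standard control DNAs on this panel, with per-sample mean/SD,
#' the second most common allele (mostly DEL — NUMT-like dropped-base
#' noise), and a flag for positions matching published NUMT catalogs. Ships
#' as the default annotation list and as the simulator's default
#' recurrent-noise model.
#'
#' @return Data.frame: position, rcrs_base, second_variant, numt,
#'   mean_s1, sd_s1, mean_s2, sd_s2 (s1/s2 = the two control DNAs).
#' @export
noisy_position_catalog <- function() {
  path <- system.file("extdata", "recurrent_noisy_positions.tsv",
                      package = "mitopanel", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Coverage summary statistics
#'
#' Mean base coverage over canonical positions, uniformity (fraction of
#' positions at or above `uniformity_fraction` of the mean depth — the
#' platform's 0.2x convention), and per-amplicon mean depths.
#'
#' @param pileup A [build_pileup()] result.
#' @param panel An [amplicon_panel()].
#' @param reads Read table (for the mapped-read count); may be `NULL`.
#' @param ref A [mito_reference()].
#' @param uniformity_fraction Depth fraction defining uniformity
#'   (default 0.2).
#' @return `CoverageSummary`: list total_mapped_reads, mean_base_coverage,
#'   uniformity_pct, mean_amplicon_coverage, median_amplicon_coverage,
#'   per_amplicon (named mean depths).
#' @export
coverage_summary <- function(pileup, panel, reads = NULL, ref = NULL,
                             uniformity_fraction = 0.2) {
  depth <- pileup$depth
  mbc <- mean(depth)
  unif <- if (mbc > 0) 100 * mean(depth >= uniformity_fraction * mbc) else 0
  per_amp <- NULL
  if (!is.null(panel) && nrow(panel) > 0L) {
    stopifnot(!is.null(ref))
    per_amp <- vapply(seq_len(nrow(panel)), function(j) {
      pos <- remap_position(panel$start[j]:panel$end[j], ref)
      mean(depth[pos])
    }, numeric(1))
    names(per_amp) <- panel$name
  }
  structure(list(
    total_mapped_reads = if (is.null(reads)) NA_integer_ else nrow(reads),
    mean_base_coverage = mbc,
    uniformity_pct = unif,
    mean_amplicon_coverage = if (is.null(per_amp)) NA_real_ else mean(per_amp),
    median_amplicon_coverage = if (is.null(per_amp)) NA_real_ else stats::median(per_amp),
    per_amplicon = per_amp
  ), class = "CoverageSummary")
}

#' @export
print.CoverageSummary <- function(x, ...) {
  cat(sprintf("coverage: mean %.1fx, uniformity %.2f%%, amplicon mean %.1f / median %.1f\n",
              x$mean_base_coverage, x$uniformity_pct,
              x$mean_amplicon_coverage, x$median_amplicon_coverage))
  invisible(x)
}

#' Empirical reference band from known-good replicate ECDFs
#'
#' Elementwise min/max envelope over the grid, from at least 3 replicates.
#'
#' @param ecdfs List of [compute_ecdf()] results (>= 3).
#' @return List `lower`, `upper` (length-100 vectors over grid 0..99).
#' @export
ecdf_band <- function(ecdfs) {
  if (length(ecdfs) < 3L) {
    stop("insufficient reference: need >= 3 known-good replicate ECDFs")
  }
  mat <- vapply(ecdfs, function(e) e$proportion_le, numeric(100L))
  list(lower = apply(mat, 1L, min), upper = apply(mat, 1L, max))
}

#' Classify a run as stable or stochastic from its VarFreq ECDF
#'
#' Compares a run's cumulative VarFreq distribution with the empirical
#' envelope of known-good replicates over the upper VarFreq window (default
#' 93-99, where haplotype-purity loss from low-template stochasticity shows
#' first). The distance is the largest upward exceedance of the band's
#' upper envelope within the window; a run is called stochastic when it
#' exceeds `tolerance`.
#'
#' @param ecdf A [compute_ecdf()] result for the run under test.
#' @param band An [ecdf_band()].
#' @param window Integer grid values to compare over (default 93:99).
#' @param tolerance Absolute proportion tolerance (default 0.005).
#' @return List: classification ("stable"/"stochastic"), distance.
#' @export
classify_run_quality <- function(ecdf, band, window = 93:99,
                                 tolerance = 0.005) {
  stopifnot(all(window >= 0 & window <= 99))
  idx <- window + 1L
  exceed <- pmax(ecdf$proportion_le[idx] - band$upper[idx], 0)
  d <- max(exceed)
  list(classification = if (d > tolerance) "stochastic" else "stable",
       distance = d)
}

#' Write a noisy-position table or ECDF as TSV
#'
#' @param x A `NoisyPositionTable` or `VarFreqECDF`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
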