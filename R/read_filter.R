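#' Two-cluster analysis of read length vs mapping quality
#'
#' Amplification negatives on the panel are dominated by short, poorly
#' mapping reads (putative micro-amplicons formed between primers of
#' overlapping amplicons). Their footprint in (aligned length, MAPQ) space
#' separates cleanly from genuine amplicon reads, so a k-means with k = 2 on
#' z-score-standardized coordinates recovers the two populations; the
#' midpoint between the two length centroids feeds the length-cutoff
#' derivation.
#'
#' Reads with MAPQ 0 are excluded from the clustering (unmappable noise that
#' would distort the centroids) but still count as mapped elsewhere.
#'
#' @param reads Read table: data.frame with at least `length` and `mapq`.
#' @param seed Integer seed; clustering is deterministic given it
#'   (50 restarts).
#' @return `ClusterResult`: list with `centroid_short` and `centroid_long`
#'   (named vectors, original units, labelled by length order),
#'   `assignment` (factor "short"/"long" per read, `NA` for MAPQ-0 reads),
#'   `midpoint_length`, `midpoint_mapq`.
#' @export
cluster_reads_2means <- function(reads, seed = 1L) {
  stopifnot(is.data.frame(reads), all(c("length", "mapq") %in% names(reads)))
  use <- reads$mapq > 0L
  x <- cbind(length = as.numeric(reads$length[use]),
             mapq = as.numeric(reads$mapq[use]))
  if (nrow(x) < 2L) stop("insufficient data: need >= 2 reads with MAPQ > 0")
  if (nrow(unique(x)) < 2L) {
    stop("degenerate input: all (length, MAPQ) points identical")
  }
  z <- scale(x)
  # a constant column scales to NaN; cluster on the informative axis alone
  z[, apply(x, 2L, stats::sd) == 0] <- 0
  km <- if (nrow(unique(z)) == 2L) {
    # exactly two distinct points: each is its own centroid
    uz <- unique(z)
    d1 <- rowSums(sweep(z, 2L, uz[1L, ])^2)
    d2 <- rowSums(sweep(z, 2L, uz[2L, ])^2)
    cl <- ifelse(d1 <= d2, 1L, 2L)
    list(cluster = cl, centers = uz, tot.withinss = sum(pmin(d1, d2)))
  } else {
    local_seed_eval(seed, stats::kmeans(z, centers = 2L, nstart = 50L))
  }
  cent <- km$centers
  # back to original units
  mu <- attr(z, "scaled:center"); sg <- attr(z, "scaled:scale")
  sg[sg == 0] <- 1
  cent_orig <- sweep(sweep(cent, 2L, sg, `*`), 2L, mu, `+`)
  short_i <- which.min(cent_orig[, "length"])
  long_i <- 3L - short_i
  lab <- ifelse(km$cluster == short_i, "short", "long")
  assignment <- rep(NA_character_, nrow(reads))
  assignment[use] <- lab
  structure(list(
    centroid_short = cent_orig[short_i, ],
    centroid_long = cent_orig[long_i, ],
    assignment = factor(assignment, levels = c("short", "long")),
    midpoint_length = mean(cent_orig[, "length"]),
    midpoint_mapq = mean(cent_orig[, "mapq"]),
    tot_withinss = km$tot.withinss
  ), class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("2-means clusters: short (%.1f bp, MAPQ %.1f) / long (%.1f bp, MAPQ %.1f)\n",
              x$centroid_short["length"], x$centroid_short["mapq"],
              x$centroid_long["length"], x$centroid_long["mapq"]))
  cat(sprintf("midpoints: %.2f bp length, %.2f MAPQ\n",
              x$midpoint_length, x$midpoint_mapq))
  invisible(x)
}

#' Derive a read-length cutoff from cluster midpoints
#'
#' The mean of the length midpoints across negative-control cluster results,
#' rounded UP to the next multiple of `granularity`. A mean midpoint of
#' 74.16 bp gives 75 at granularity 5 and 80 at granularity 10.
#'
#' @param cluster_results List of [cluster_reads_2means()] results (a single
#'   result is also accepted).
#' @param granularity Rounding granularity in bp (default 5).
#' @return Integer cutoff in bp (minimum 1).
#' @export
derive_length_cutoff <- function(cluster_results, granularity = 5L) {
  if (inherits(cluster_results, "ClusterResult")) {
    cluster_results <- list(cluster_results)
  }
  if (length(cluster_results) == 0L) stop("insufficient data: no cluster results")
  mids <- vapply(cluster_results, function(cr) {
    if (!is.null(cr$midpoint_length)) cr$midpoint_length else as.numeric(cr)
  }, numeric(1))
  m <- mean(mids)
  max(1L, as.integer(ceiling(m / granularity) * granularity))
}

#' Remove short artifact reads below a length cutoff
#'
#' The shipped default cutoff is the workflow's literal 80 bp; pass a value
#' from [derive_length_cutoff()] to re-derive it from data. Filtering is on
#' aligned length only (an optional MAPQ floor is available but off by
#' default). Percentages in the report are rounded to 1 decimal for display;
#' raw counts are carried unrounded.
#'
#' @param reads Read table with `length` (aligned reference span) and
#'   optionally `mapq`, `amplicon`.
#' @param cutoff_bp Reads with `length < cutoff_bp` are removed (default 80).
#' @param mapq_floor Optional minimum MAPQ; `NULL` (default) disables it.
#' @return List with `kept`, `removed` (row subsets of `reads`) and `report`
#'   (`FilterReport`: total_mapped, removed, kept, pct_short, cutoff_bp,
#'   per_amplicon_removed).
#' @export
filter_reads <- function(reads, cutoff_bp = 80L, mapq_floor = NULL) {
  cutoff_bp <- as.integer(cutoff_bp)
  if (is.na(cutoff_bp) || cutoff_bp < 1L) stop("cutoff_bp must be >= 1")
  n <- nrow(reads)
  drop <- if (n > 0L) reads$length < cutoff_bp else logical(0)
  if (!is.null(mapq_floor) && n > 0L) drop <- drop | reads$mapq < mapq_floor
  removed <- reads[drop, , drop = FALSE]
  kept <- reads[!drop, , drop = FALSE]
  per_amp <- if (n > 0L && "amplicon" %in% names(reads)) {
    tab <- table(removed$amplicon, useNA = "no")
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  report <- structure(list(
    total_mapped = n,
    removed = nrow(removed),
    kept = nrow(kept),
    pct_short = if (n > 0L) round(100 * nrow(removed) / n, 1) else 0.0,
    cutoff_bp = cutoff_bp,
    per_amplicon_removed = per_amp
  ), class = "FilterReport")
  list(kept = kept, removed = removed, report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("filtered %d / %d mapped reads (<%d bp): %.1f%% short\n",
              x$removed, x$total_mapped, x$cutoff_bp, x$pct_short))
  invisible(x)
}

#' Amplicons enriched for removed artifact reads
#'
#' Flags amplicons whose removed-read count exceeds
#' `enrichment_factor x mean removed-read count` across the whole panel
#' (amplicons with zero removals included in the mean), sorted descending by
#' count. On the real panel artifact reads concentrate in a handful of
#' amplicons, consistent with micro-amplicon formation at specific overlap
#' junctions.
#'
#' @param removed Removed-read table (needs `start`, `length`; `amplicon` is
#'   used when present, otherwise assigned by maximal overlap).
#' @param panel An [amplicon_panel()].
#' @param enrichment_factor Multiplier over the panel mean (default 2).
#' @return Character vector of amplicon names (possibly empty).
#' @export
hotspot_amplicons <- function(removed, panel, enrichment_factor = 2.0) {
  if (is.null(panel) || nrow(panel) == 0L) stop("empty panel")
  if (nrow(removed) == 0L) return(character(0))
  amp <- removed$amplicon
  if (is.null(amp) || anyNA(amp)) {
    amp <- assign_amplicon(removed$start, removed$length, panel)
  }
  counts <- stats::setNames(integer(nrow(panel)), panel$name)
  tab <- table(amp)
  counts[names(tab)] <- as.integer(tab)
  thr <- enrichment_factor * mean(counts)
  hot <- counts[counts > thr]
  names(sort(hot, decreasing = TRUE))
}

#' Write a filter report as JSON or TSV
#'
#' @param report A `FilterReport` from [filter_reads()].
#' @param path Output path; format chosen by extension (`.json` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(
      metric = c("total_mapped", "removed", "kept", "pct_short", "cutoff_bp"),
      value = c(report$total_mapped, report$removed, report$kept,
                report$pct_short, report$cutoff_bp)
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
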