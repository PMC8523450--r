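#' Caller configuration
#'
#' The threshold parameter set of the validated workflow. All thresholds are
#' percentages of column depth; coverages are read counts.
#'
#' * `min_total_cov` (20): positions below it are no-calls.
#' * `min_variant_cov` (20): minimum reads supporting any called variant.
#' * `region_mark_cov` (20): coverage threshold used to mark a region; kept
#'   as a separate knob from `min_total_cov` although both default to 20.
#' * `min_pct_of_amplicon_median` (5.0): positions whose depth falls below
#'   this percentage of their amplicon's median depth get the
#'   `low-coverage-region` flag.
#' * `confirm_threshold` (96.0): frequency confirming a homoplasmic call.
#' * `php_threshold` (10.0): minor-allele frequency calling a point
#'   heteroplasmy.
#' * `ins_threshold` (20.0) / `del_threshold` (30.0): indel allele
#'   frequencies.
#' * `homopolymer_regions`: intervals annotated `homopolymer-adjacent`
#'   (default np 303-310 and 16,184-16,193, the HVS poly-C stretches).
#' * `strand_bias_min_ratio` (0.10): minimum minority-strand fraction of
#'   variant-supporting reads before the `strand-bias` flag fires.
#'
#' @param min_total_cov,min_variant_cov,region_mark_cov Read counts.
#' @param min_pct_of_amplicon_median,confirm_threshold,php_threshold,ins_threshold,del_threshold Percentages.
#' @param homopolymer_regions List of [genomic_interval()]s.
#' @param strand_bias_min_ratio Fraction in `[0, 0.5]`.
#' @return `CallerConfig` list.
#' @export
caller_config <- function(min_total_cov = 20L, min_variant_cov = 20L,
                          region_mark_cov = 20L,
                          min_pct_of_amplicon_median = 5.0,
                          confirm_threshold = 96.0, php_threshold = 10.0,
                          ins_threshold = 20.0, del_threshold = 30.0,
                          homopolymer_regions = list(
                            genomic_interval(303, 310),
                            genomic_interval(16184, 16193)
                          ),
                          strand_bias_min_ratio = 0.10) {
  cfg <- list(
    min_total_cov = as.integer(min_total_cov),
    min_variant_cov = as.integer(min_variant_cov),
    region_mark_cov = as.integer(region_mark_cov),
    min_pct_of_amplicon_median = as.numeric(min_pct_of_amplicon_median),
    confirm_threshold = as.numeric(confirm_threshold),
    php_threshold = as.numeric(php_threshold),
    ins_threshold = as.numeric(ins_threshold),
    del_threshold = as.numeric(del_threshold),
    homopolymer_regions = homopolymer_regions,
    strand_bias_min_ratio = as.numeric(strand_bias_min_ratio)
  )
  if (!(cfg$php_threshold > 0 && cfg$php_threshold < cfg$confirm_threshold &&
        cfg$confirm_threshold <= 100)) {
    stop("need 0 < php_threshold < confirm_threshold <= 100")
  }
  structure(cfg, class = "CallerConfig")
}

#' Read a caller configuration from YAML
#'
#' Scalar fields override the defaults of [caller_config()];
#' `homopolymer_regions` may be given as a list of two-element start/end
#' arrays.
#'
#' @param path YAML path.
#' @return `CallerConfig`.
#' @export
caller_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$homopolymer_regions)) {
    y$homopolymer_regions <- lapply(y$homopolymer_regions, function(iv) {
      genomic_interval(iv[[1]], iv[[2]])
    })
  }
  do.call(caller_config, y)
}

.IUPAC2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' IUPAC ambiguity code for a base pair (and back)
#'
#' @param b1,b2 Two distinct bases among A/C/G/T (order-insensitive).
#' @return `iupac_code` returns the one-letter code (e.g. T/C -> "Y",
#'   G/A -> "R"); `iupac_bases` returns the two bases for a code.
#' @export
iupac_code <- function(b1, b2) {
  key <- paste0(pmin(b1, b2), pmax(b1, b2))
  out <- .IUPAC2[key]
  if (anyNA(out)) stop("not a base pair: ", paste(key[is.na(out)], collapse = ", "))
  unname(out)
}

#' @rdname iupac_code
#' @param code One-letter IUPAC ambiguity code.
#' @export
iupac_bases <- function(code) {
  hit <- names(.IUPAC2)[match(code, .IUPAC2)]
  if (anyNA(hit)) stop("unsupported IUPAC code: ", code)
  strsplit(hit, "")[[1]]
}

#' Strand-bias predicate for variant-supporting reads
#'
#' TRUE when the minority-strand fraction of the reads supporting a variant
#' allele is below `min_ratio` (default 0.10); an allele seen on a single
#' strand only is always flagged.
#'
#' @param plus,minus Variant-supporting read counts per strand (vectorized).
#' @param min_ratio Minimum minority-strand fraction.
#' @return Logical vector.
#' @export
flag_strand_bias <- function(plus, minus, min_ratio = 0.10) {
  tot <- plus + minus
  frac <- ifelse(tot > 0, pmin(plus, minus) / tot, NA_real_)
  !is.na(frac) & frac < min_ratio
}

#' Threshold calling over a whole pileup
#'
#' Applies the decision cascade at every canonical position:
#' (1) depth below `min_total_cov` is a no-call; (2) a top base equal to the
#' reference at or above `confirm_threshold` confirms the reference; (3) a
#' non-reference top base at or above `confirm_threshold` with at least
#' `min_variant_cov` reads is a substitution; (4) a second base at or above
#' `php_threshold` with at least `min_variant_cov` reads makes a point
#' heteroplasmy of the top two bases (IUPAC code, variant frequency = the
#' minor-allele frequency); (5) a DEL allele at or above `del_threshold` is
#' a deletion; insertion alleles are evaluated independently against
#' `ins_threshold` and anchored to the preceding canonical position;
#' (6) anything else is a reference call carrying flags. Ties between
#' equal-count alleles resolve by reference-allele preference then
#' lexicographic base order. Variant frequencies are computed on unrounded
#' counts and reported to 1 decimal.
#'
#' @param pileup A [build_pileup()] result.
#' @param ref A [mito_reference()].
#' @param cfg A [caller_config()].
#' @return Data.frame of calls: one row per canonical position
#'   (`call_type` in reference/substitution/PHP/deletion/no-call) followed by
#'   insertion rows; columns position, ref, call_type, allele1, allele2,
#'   variant_frequency, depth, flags (comma-joined).
#' @export
call_pileup <- function(pileup, ref, cfg = caller_config()) {
  stopifnot(inherits(pileup, "Pileup"), inherits(ref, "MitoReference"))
  L <- pileup$canonical_length
  refbase <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
  cnt <- pileup$counts[, c("A", "C", "G", "T"), drop = FALSE]
  del <- pileup$counts[, "DEL"]
  depth <- pileup$depth
  bases <- c("A", "C", "G", "T")
  is_ref <- outer(refbase, bases, `==`)
  # fractional bonuses only ever break integer-count ties
  score <- cnt + is_ref * 0.5 + matrix((4:1) * 0.01, nrow = L, ncol = 4, byrow = TRUE)
  top <- max.col(score, ties.method = "first")
  sc2 <- score; sc2[cbind(seq_len(L), top)] <- -1
  second <- max.col(sc2, ties.method = "first")
  top_cnt <- cnt[cbind(seq_len(L), top)]
  sec_cnt <- cnt[cbind(seq_len(L), second)]
  top_b <- bases[top]; sec_b <- bases[second]
  safe_depth <- pmax(depth, 1L)
  top_f <- 100 * top_cnt / safe_depth
  sec_f <- 100 * sec_cnt / safe_depth
  del_f <- 100 * del / safe_depth

  type <- rep("reference", L)
  a1 <- top_b; a2 <- NA_character_
  vf <- top_f

  php <- sec_f >= cfg$php_threshold & sec_cnt >= cfg$min_variant_cov
  type[php] <- "PHP"
  sub <- top_b != refbase & top_f >= cfg$confirm_threshold &
    top_cnt >= cfg$min_variant_cov
  type[sub] <- "substitution"    # cascade: confirm beats PHP
  refc <- top_b == refbase & top_f >= cfg$confirm_threshold
  type[refc] <- "reference"
  deln <- type == "reference" & !refc & del_f >= cfg$del_threshold &
    del >= cfg$min_variant_cov
  type[deln] <- "deletion"
  nocall <- depth < cfg$min_total_cov
  type[nocall] <- "no-call"

  a2[type == "PHP"] <- sec_b[type == "PHP"]
  vf[type == "PHP"] <- sec_f[type == "PHP"]     # minor-allele frequency
  a1[type == "deletion"] <- "DEL"
  vf[type == "deletion"] <- del_f[type == "deletion"]
  vf[type == "no-call"] <- NA_real_
  a1[type == "no-call"] <- NA_character_

  flags <- .position_flags(pileup, cfg, type, a1, a2, refbase, L)

  calls <- data.frame(
    position = seq_len(L), ref = refbase, call_type = type,
    allele1 = a1, allele2 = a2,
    variant_frequency = round(vf, 1), depth = depth,
    flags = flags, stringsAsFactors = FALSE
  )
  ins_calls <- .call_insertions(pileup, cfg, depth, nocall)
  if (nrow(ins_calls) > 0L) {
    ins_calls$ref <- refbase[ins_calls$position]
    hp <- .in_regions(ins_calls$position, cfg$homopolymer_regions)
    ins_calls$flags <- ifelse(hp, "homopolymer-adjacent", "")
    calls <- rbind(calls, ins_calls[, names(calls)])
  }
  out <- calls[order(calls$position, calls$call_type == "insertion"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.in_regions <- function(pos, regions) {
  out <- logical(length(pos))
  for (iv in regions) out <- out | (pos >= iv$start & pos <= iv$end)
  out
}

.position_flags <- function(pileup, cfg, type, a1, a2, refbase, L) {
  flags <- vector("list", 0L)
  hp <- .in_regions(seq_len(L), cfg$homopolymer_regions)
  # strand bias, for the variant allele of variant calls
  sb <- logical(L)
  vi <- which(type %in% c("substitution", "PHP", "deletion"))
  if (length(vi)) {
    allele <- ifelse(type[vi] == "PHP",
                     ifelse(a2[vi] == refbase[vi], a1[vi], a2[vi]),
                     a1[vi])
    pc <- pileup$counts_plus[cbind(vi, match(allele, colnames(pileup$counts_plus)))]
    mc <- pileup$counts_minus[cbind(vi, match(allele, colnames(pileup$counts_minus)))]
    sb[vi] <- flag_strand_bias(pc, mc, cfg$strand_bias_min_ratio)
  }
  lowpur <- type == "reference" & !is.na(a1) &
    (100 * pileup$counts[cbind(seq_len(L), match(a1, colnames(pileup$counts)))] /
       pmax(pileup$depth, 1L)) < cfg$confirm_threshold
  vapply(seq_len(L), function(i) {
    f <- c(if (hp[i]) "homopolymer-adjacent",
           if (sb[i]) "strand-bias",
           if (isTRUE(lowpur[i])) "low-purity")
    paste(f, collapse = ",")
  }, character(1))
}

.call_insertions <- function(pileup, cfg, depth, nocall) {
  ins <- pileup$ins
  if (nrow(ins) == 0L) return(.empty_ins_calls())
  d <- depth[ins$position]
  keep <- !nocall[ins$position] & ins$count >= cfg$min_variant_cov &
    100 * ins$count / pmax(d, 1L) >= cfg$ins_threshold
  ins <- ins[keep, , drop = FALSE]
  if (nrow(ins) == 0L) return(.empty_ins_calls())
  # one insertion call per anchor: the major inserted sequence
  ins <- ins[order(ins$position, -ins$count, ins$seq), , drop = FALSE]
  ins <- ins[!duplicated(ins$position), , drop = FALSE]
  data.frame(
    position = ins$position, ref = NA_character_, call_type = "insertion",
    allele1 = ins$seq, allele2 = NA_character_,
    variant_frequency = round(100 * ins$count / pmax(depth[ins$position], 1L), 1),
    depth = depth[ins$position], flags = "", stringsAsFactors = FALSE
  )
}

.empty_ins_calls <- function() {
  data.frame(position = integer(0), ref = character(0),
             call_type = character(0), allele1 = character(0),
             allele2 = character(0), variant_frequency = numeric(0),
             depth = integer(0), flags = character(0), stringsAsFactors = FALSE)
}

#' Call a single pileup column
#'
#' Scalar form of [call_pileup()] for one position.
#'
#' @param col List with `position`, `counts` (named A/C/G/T/DEL reads),
#'   optionally `insertions` (named counts by inserted sequence) and
#'   `strand_depth`.
#' @param ref_base Reference base at the position.
#' @param cfg A [caller_config()].
#' @return One-row (or two-row, when an insertion is also called) calls
#'   data.frame as in [call_pileup()].
#' @export
call_position <- function(col, ref_base, cfg = caller_config()) {
  bases5 <- c("A", "C", "G", "T", "DEL")
  cnts <- stats::setNames(integer(5), bases5)
  cnts[names(col$counts)] <- as.integer(col$counts)
  L <- 1L
  counts <- matrix(cnts, nrow = 1L, dimnames = list(NULL, bases5))
  ins <- if (!is.null(col$insertions) && length(col$insertions)) {
    data.frame(position = 1L, seq = names(col$insertions),
               count = as.integer(col$insertions),
               plus = as.integer(col$insertions), minus = 0L,
               stringsAsFactors = FALSE)
  } else .empty_ins()
  pl <- structure(list(counts = counts, counts_plus = counts,
                       counts_minus = counts * 0L,
                       depth = as.integer(sum(cnts)),
                       ins = ins, canonical_length = 1L), class = "Pileup")
  fake_ref <- mito_reference(ref_base, extension_length = 0L)
  cfg1 <- cfg; cfg1$homopolymer_regions <- list()
  out <- call_pileup(pl, fake_ref, cfg1)
  out$position <- col$position %||% 1L
  out
}

#' Detect no-call regions and low-coverage positions
#'
#' Maximal runs of no-call positions become 1-based inclusive intervals.
#' Positions whose depth is below `min_pct_of_amplicon_median` percent of
#' their amplicon's median depth additionally receive the
#' `low-coverage-region` flag (each position is attributed to the covering
#' amplicon whose midpoint is nearest).
#'
#' @param calls Calls from [call_pileup()].
#' @param pileup The pileup the calls came from.
#' @param panel An [amplicon_panel()] (optional; low-coverage flagging is
#'   skipped without it).
#' @param cfg A [caller_config()].
#' @param ref A [mito_reference()] (needed with `panel` for wrap remapping).
#' @return List: `intervals` (data.frame start/end/length),
#'   `calls` (input with low-coverage flags added).
#' @export
detect_nocall_regions <- function(calls, pileup, panel = NULL,
                                  cfg = caller_config(), ref = NULL) {
  base_rows <- calls$call_type != "insertion"
  bc <- calls[base_rows, , drop = FALSE]
  bc <- bc[order(bc$position), , drop = FALSE]
  isnc <- bc$call_type == "no-call"
  r <- rle(isnc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start = bc$position[starts[r$values]],
                   end = bc$position[ends[r$values]])
  iv$length <- iv$end - iv$start + 1L
  if (!is.null(panel) && nrow(panel) > 0L) {
    stopifnot(!is.null(ref))
    amp_of <- .position_amplicon(panel, ref)
    med <- vapply(seq_len(nrow(panel)), function(j) {
      stats::median(pileup$depth[which(amp_of == j)])
    }, numeric(1))
    low <- pileup$depth < (cfg$min_pct_of_amplicon_median / 100) * med[amp_of]
    low[is.na(low)] <- FALSE
    idx <- which(base_rows)[match(which(low), bc$position)]
    idx <- idx[!is.na(idx)]
    calls$flags[idx] <- ifelse(nzchar(calls$flags[idx]),
                               paste0(calls$flags[idx], ",low-coverage-region"),
                               "low-coverage-region")
  }
  list(intervals = iv, calls = calls)
}

# canonical position -> row index of the panel amplicon with nearest midpoint
.position_amplicon <- function(panel, ref) {
  L <- ref$canonical_length
  amp_of <- rep(NA_integer_, L)
  bestd <- rep(Inf, L)
  mid <- (panel$start + panel$end) / 2
  for (j in seq_len(nrow(panel))) {
    span <- panel$start[j]:panel$end[j]
    pos <- remap_position(span, ref)
    d <- abs(span - mid[j])
    upd <- d < bestd[pos]
    amp_of[pos[upd]] <- j
    bestd[pos[upd]] <- d[upd]
  }
  amp_of
}
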