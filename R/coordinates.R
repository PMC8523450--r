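#' Circular mitochondrial reference with a linearization extension
#'
#' The rCRS mitochondrial genome is circular; reads spanning the origin are
#' aligned against a linearized reference in which the first
#' `extension_length` bases are repeated after the last canonical position
#' ("rCRS + 80"). A `MitoReference` owns that geometry: the canonical
#' sequence, its length (16,569 for rCRS) and the extension length.
#'
#' All public coordinates in this package are 1-based inclusive. Positions on
#' the *extended* axis run 1..canonical_length + extension_length; positions
#' above `canonical_length` are images of positions 1..extension_length and
#' are folded back with [remap_position()].
#'
#' @param sequence Single nucleotide string (A/C/G/T/N), the canonical
#'   (unextended) circle.
#' @param extension_length Number of leading bases repeated after the end of
#'   the circle (default 80).
#' @return An object of class `MitoReference` with fields `sequence`,
#'   `canonical_length`, `extension_length`.
#' @examples
#' ref <- mito_reference("ACGTACGT", extension_length = 3)
#' extend_reference(ref)            # "ACGTACGTACG"
#' remap_position(10, ref)          # 2
#' @export
mito_reference <- function(sequence, extension_length = 80L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("reference sequence may only contain A, C, G, T, N")
  }
  extension_length <- as.integer(extension_length)
  if (is.na(extension_length) || extension_length < 0L) {
    stop("extension_length must be a non-negative integer")
  }
  if (extension_length > nchar(sequence)) {
    stop("invalid configuration: extension_length (", extension_length,
         ") exceeds canonical length (", nchar(sequence), ")")
  }
  structure(
    list(
      sequence = sequence,
      canonical_length = nchar(sequence),
      extension_length = extension_length
    ),
    class = "MitoReference"
  )
}

#' @export
print.MitoReference <- function(x, ...) {
  cat(sprintf("MitoReference: %d bp circle + %d nt extension (%d bp extended)\n",
              x$canonical_length, x$extension_length,
              x$canonical_length + x$extension_length))
  invisible(x)
}

#' Default reference used by the simulator and the test-bench
#'
#' A seeded random sequence of canonical rCRS length (16,569 bp). All
#' position-level logic in this package is sequence-agnostic, so a synthetic
#' sequence stands in for the true rCRS; only coordinates matter.
#'
#' @param canonical_length Length of the circle (default 16,569).
#' @param extension_length Wrap extension (default 80).
#' @param seed Seed for the base draw (default 1203).
#' @return A [mito_reference()].
#' @export
default_reference <- function(canonical_length = 16569L, extension_length = 80L,
                              seed = 1203L) {
  stopifnot(canonical_length >= 1L)
  seq <- local_seed_eval(seed, {
    paste(sample(c("A", "C", "G", "T"), canonical_length, replace = TRUE),
          collapse = "")
  })
  mito_reference(seq, extension_length = extension_length)
}

# Evaluate expr under a given seed without disturbing the caller's RNG state.
local_seed_eval <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Extended (linearized) sequence of a circular reference
#'
#' Appends the first `extension_length` bases after the end of the circle so
#' that reads spanning the origin align contiguously.
#'
#' @param ref A [mito_reference()].
#' @return Nucleotide string of length `canonical_length + extension_length`.
#' @export
extend_reference <- function(ref) {
  stopifnot(inherits(ref, "MitoReference"))
  if (ref$extension_length == 0L) return(ref$sequence)
  paste0(ref$sequence, substr(ref$sequence, 1L, ref$extension_length))
}

#' Fold an extended-axis position back onto the canonical circle
#'
#' Identity on 1..canonical_length; positions in the extension map to
#' 1..extension_length. Vectorized.
#'
#' @param p Integer position(s) on the extended axis.
#' @param ref A [mito_reference()].
#' @return Canonical 1-based position(s).
#' @export
remap_position <- function(p, ref) {
  stopifnot(inherits(ref, "MitoReference"))
  p <- as.integer(p)
  hi <- ref$canonical_length + ref$extension_length
  if (any(is.na(p)) || any(p < 1L) || any(p > hi)) {
    stop("position out of bounds: extended axis runs 1..", hi)
  }
  ifelse(p > ref$canonical_length, p - ref$canonical_length, p)
}

#' 1-based inclusive genomic interval
#'
#' @param start,end 1-based inclusive bounds, `start <= end`. Intervals never
#'   wrap internally; a feature spanning the origin is represented as two
#'   intervals after remapping.
#' @return An object of class `GenomicIntervalMT` (a named list).
#' @export
genomic_interval <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L, !is.na(start), !is.na(end))
  if (start < 1L) stop("interval start must be >= 1")
  if (end < start) stop("invalid interval: end (", end, ") < start (", start, ")")
  structure(list(start = start, end = end), class = "GenomicIntervalMT")
}

#' Length of a 1-based inclusive interval (margins included)
#'
#' @param iv A [genomic_interval()], or anything with `$start`/`$end`.
#' @return `end - start + 1`.
#' @examples
#' interval_length(genomic_interval(13216, 13248))  # 33
#' @export
interval_length <- function(iv) {
  if (is.numeric(iv) && length(iv) == 2L) iv <- genomic_interval(iv[1], iv[2])
  if (is.null(iv$start) || is.null(iv$end)) stop("not an interval")
  if (any(iv$end < iv$start)) stop("invalid interval: end < start")
  as.integer(iv$end - iv$start + 1L)
}

#' Amplicon panel
#'
#' Ordered set of amplicons tiling the mitochondrial circle. Intervals are
#' 1-based inclusive on the extended axis (the final, origin-spanning
#' amplicon may extend into the wrap region).
#'
#' @param name Character vector of amplicon names (e.g. `"mt_1"`).
#' @param start,end Integer 1-based inclusive bounds on the extended axis.
#' @param pool Pool assignment, 1 or 2 (alternating pools are the panel's
#'   multiplex structure).
#' @param chrom Chromosome name used in BED I/O (default `"chrM"`).
#' @param length_bounds Allowed amplicon length range; amplicons outside it
#'   set the `bounds_ok` attribute to `FALSE` (warning, not error).
#' @return `AmpliconPanel`: a data.frame (name, start, end, pool, length)
#'   with attributes `chrom`, `tiles` (full-circle tiling flag given the
#'   reference), `bounds_ok`.
#' @export
amplicon_panel <- function(name, start, end, pool = NULL, chrom = "chrM",
                           length_bounds = c(125L, 174L)) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(name) == length(start), length(start) == length(end))
  if (length(name) == 0L) stop("empty panel")
  if (any(end < start)) stop("invalid amplicon interval(s): end < start")
  if (anyDuplicated(name)) stop("duplicated amplicon names")
  if (is.null(pool)) pool <- rep_len(c(1L, 2L), length(name))
  panel <- data.frame(
    name = as.character(name), start = start, end = end,
    pool = as.integer(pool), length = end - start + 1L,
    stringsAsFactors = FALSE
  )
  panel <- panel[order(panel$start), , drop = FALSE]
  rownames(panel) <- NULL
  bounds_ok <- all(panel$length >= length_bounds[1] & panel$length <= length_bounds[2])
  if (!bounds_ok) {
    warning("some amplicon lengths fall outside [",
            length_bounds[1], ", ", length_bounds[2], "] bp")
  }
  structure(panel,
            class = c("AmpliconPanel", "data.frame"),
            chrom = chrom, bounds_ok = bounds_ok)
}

#' Does a panel tile the whole canonical circle?
#'
#' Every canonical position must be covered by at least one amplicon after
#' folding wrap-region coordinates back onto the circle.
#'
#' @param panel An [amplicon_panel()].
#' @param ref A [mito_reference()].
#' @return Logical.
#' @export
panel_tiles_circle <- function(panel, ref) {
  cov <- logical(ref$canonical_length)
  for (i in seq_len(nrow(panel))) {
    pos <- remap_position(panel$start[i]:panel$end[i], ref)
    cov[pos] <- TRUE
  }
  all(cov)
}

#' Read an amplicon panel from BED
#'
#' BED uses 0-based half-open coordinates; they are converted to the
#' package's 1-based inclusive convention at this boundary. Pool assignment
#' is taken from the BED score column when present (1/2), else alternates.
#'
#' @param bed_source Path to a BED file (3+1 columns minimum).
#' @param chrom Expected chromosome name; records on other chromosomes error.
#' @param ref Optional [mito_reference()]; when supplied, a non-tiling panel
#'   is flagged with a warning (attribute `tiles`), not rejected.
#' @return An [amplicon_panel()].
#' @export
load_panel <- function(bed_source, chrom = "chrM", ref = NULL) {
  if (!file.exists(bed_source)) stop("BED file not found: ", bed_source)
  if (file.size(bed_source) == 0L) stop("empty panel: ", bed_source)
  gr <- tryCatch(
    rtracklayer::import(bed_source, format = "BED"),
    error = function(e) stop("malformed BED (", conditionMessage(e), "): ",
                             bed_source)
  )
  if (length(gr) == 0L) stop("empty panel: ", bed_source)
  seqn <- as.character(GenomicRanges::seqnames(gr))
  if (!all(seqn == chrom)) {
    stop("BED records on unexpected chromosome(s): ",
         paste(unique(setdiff(seqn, chrom)), collapse = ", "))
  }
  nm <- gr$name
  if (is.null(nm) || anyNA(nm)) nm <- paste0("amp_", seq_along(gr))
  pool <- gr$score
  if (is.null(pool) || anyNA(pool) || !all(pool %in% c(1, 2))) pool <- NULL
  panel <- amplicon_panel(
    name = nm,
    start = GenomicRanges::start(gr),  # rtracklayer already converts to 1-based
    end = GenomicRanges::end(gr),
    pool = pool, chrom = chrom
  )
  if (!is.null(ref)) {
    tiles <- panel_tiles_circle(panel, ref)
    if (!tiles) warning("panel does not tile the full circle")
    attr(panel, "tiles") <- tiles
  }
  panel
}

#' Write an amplicon panel to BED
#'
#' Inverse of [load_panel()]: 1-based inclusive intervals are converted to
#' 0-based half-open BED records; pool goes to the score column.
#'
#' @param panel An [amplicon_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  chrom <- attr(panel, "chrom") %||% "chrM"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = panel$start, end = panel$end),
    name = panel$name,
    score = panel$pool
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Assign reads to amplicons by maximal overlap
#'
#' @param start,length Read start (extended axis, 1-based) and aligned
#'   reference span in bp.
#' @param panel An [amplicon_panel()].
#' @return Character vector of amplicon names (`NA` where a read overlaps no
#'   amplicon).
#' @export
assign_amplicon <- function(start, length, panel) {
  if (nrow(panel) == 0L) stop("empty panel")
  rs <- as.integer(start); re <- rs + as.integer(length) - 1L
  # overlap(read i, amplicon j) = min(re_i, aend_j) - max(rs_i, astart_j) + 1
  ov <- outer(re, panel$end, pmin) - outer(rs, panel$start, pmax) + 1L
  ov[ov < 0L] <- 0L
  best <- max.col(ov, ties.method = "first")
  out <- panel$name[best]
  out[apply(ov, 1L, max) == 0L] <- NA_character_
  out
}

#' Read a single-record FASTA reference
#'
#' @param path FASTA path (single record; the canonical, unextended circle).
#' @param extension_length Wrap extension to attach (default 80).
#' @return A [mito_reference()].
#' @export
read_reference_fasta <- function(path, extension_length = 80L) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) stop("expected a single FASTA record, got ", length(ss))
  mito_reference(as.character(ss[[1]]), extension_length = extension_length)
}

#' Write the canonical reference to FASTA
#'
#' @param ref A [mito_reference()].
#' @param path Output path.
#' @param name Record name (default "chrM").
#' @param extended Write the extended (wrapped) sequence instead of the
#'   canonical circle.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path, name = "chrM", extended = FALSE) {
  seq <- if (extended) extend_reference(ref) else ref$sequence
  ss <- Biostrings::DNAStringSet(seq)
  names(ss) <- name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
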