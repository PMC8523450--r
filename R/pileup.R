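#' Build per-position pileups from aligned reads
#'
#' Consumes the package's plain-text read-table dialect: one row per aligned
#' read with `start` (extended-axis 1-based), `length` (aligned reference
#' span), `strand`, `seq` (reference-aligned bases over the span, `-` marking
#' a deleted reference base) and `ins` (semicolon-separated
#' `pos:SEQ` insertions anchored after extended-axis position `pos`; empty
#' string when none). Reads overlapping the wrap extension contribute to
#' canonical positions via [remap_position()], which is how origin-spanning
#' coverage is recovered on the circle.
#'
#' @param reads Read table (see above; [simulate_sample()] emits it).
#' @param ref A [mito_reference()].
#' @return A `Pileup`: list with `counts` (canonical_length x 5 integer
#'   matrix, columns A/C/G/T/DEL), `counts_plus`/`counts_minus` (same shape,
#'   split by read strand), `depth` (rowSums of `counts`), `ins` (data.frame
#'   position/seq/count/plus/minus of insertion alleles, canonical
#'   coordinates) and `canonical_length`.
#' @export
build_pileup <- function(reads, ref) {
  stopifnot(inherits(ref, "MitoReference"))
  L <- ref$canonical_length
  bases5 <- c("A", "C", "G", "T", "DEL")
  empty <- matrix(0L, nrow = L, ncol = 5L, dimnames = list(NULL, bases5))
  if (nrow(reads) == 0L) {
    return(structure(list(counts = empty, counts_plus = empty,
                          counts_minus = empty, depth = integer(L),
                          ins = .empty_ins(), canonical_length = L),
                     class = "Pileup"))
  }
  stopifnot(all(c("start", "length", "strand", "seq") %in% names(reads)))
  lens <- as.integer(reads$length)
  starts <- as.integer(reads$start)
  if (any(nchar(reads$seq) != lens)) {
    stop("malformed read: seq length disagrees with aligned span")
  }
  ends <- starts + lens - 1L
  if (any(starts < 1L) || any(ends > L + ref$extension_length)) {
    stop("malformed read: alignment extends beyond the extended axis")
  }
  pos <- rep.int(starts, lens) + sequence(lens) - 1L
  pos <- ifelse(pos > L, pos - L, pos)
  bases <- unlist(strsplit(reads$seq, "", fixed = TRUE), use.names = FALSE)
  bi <- match(bases, c("A", "C", "G", "T", "-"))
  if (anyNA(bi)) stop("malformed read: seq may only contain A, C, G, T, -")
  plus <- rep.int(reads$strand == "+", lens)
  idx <- (pos - 1L) * 5L + bi
  counts_plus <- t(matrix(tabulate(idx[plus], nbins = 5L * L), nrow = 5L))
  counts_minus <- t(matrix(tabulate(idx[!plus], nbins = 5L * L), nrow = 5L))
  colnames(counts_plus) <- colnames(counts_minus) <- bases5
  counts <- counts_plus + counts_minus
  ins <- .collect_insertions(reads, ref)
  structure(list(
    counts = counts, counts_plus = counts_plus, counts_minus = counts_minus,
    depth = as.integer(rowSums(counts)),
    ins = ins, canonical_length = L
  ), class = "Pileup")
}

.empty_ins <- function() {
  data.frame(position = integer(0), seq = character(0), count = integer(0),
             plus = integer(0), minus = integer(0), stringsAsFactors = FALSE)
}

.collect_insertions <- function(reads, ref) {
  has <- !is.na(reads$ins) & nzchar(reads$ins)
  if (!"ins" %in% names(reads) || !any(has)) return(.empty_ins())
  specs <- strsplit(reads$ins[has], ";", fixed = TRUE)
  n_per <- lengths(specs)
  flat <- unlist(specs, use.names = FALSE)
  parts <- strsplit(flat, ":", fixed = TRUE)
  ipos <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  iseq <- vapply(parts, function(p) p[2], character(1))
  ipos <- remap_position(ipos, ref)
  iplus <- rep.int(reads$strand[has] == "+", n_per)
  key <- paste(ipos, iseq, sep = ":")
  agg_p <- tapply(iplus, key, sum)
  agg_m <- tapply(!iplus, key, sum)
  kk <- strsplit(names(agg_p), ":", fixed = TRUE)
  out <- data.frame(
    position = vapply(kk, function(p) as.integer(p[1]), integer(1)),
    seq = vapply(kk, function(p) p[2], character(1)),
    count = as.integer(agg_p + agg_m),
    plus = as.integer(agg_p), minus = as.integer(agg_m),
    stringsAsFactors = FALSE
  )
  out[order(out$position, out$seq), , drop = FALSE]
}

#' @export
print.Pileup <- function(x, ...) {
  cat(sprintf("Pileup over %d canonical positions; mean depth %.1f, %d insertion alleles\n",
              x$canonical_length, mean(x$depth), nrow(x$ins)))
  invisible(x)
}

#' Read-table I/O
#'
#' The plain-text dialect used throughout: TSV with columns read_id, start,
#' length, mapq, strand, amplicon, seq, ins.
#'
#' @param reads Read table.
#' @param path File path.
#' @return `read_table_read()` returns the data.frame; writers return
#'   `path` invisibly.
#' @export
read_table_write <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_table_write
#' @export
read_table_read <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(read_id = "character",
                                         start = "integer", length = "integer",
                                         mapq = "integer", strand = "character",
                                         amplicon = "character",
                                         seq = "character", ins = "character"),
                          na.strings = NULL, quote = "", comment.char = "")
  df$ins[is.na(df$ins)] <- ""
  df
}

#' Export reads as SAM
#'
#' Converts the read-table dialect to a minimal valid SAM file (header +
#' alignments on the extended reference): `-` runs in `seq` become D CIGAR
#' operations, `ins` entries become I operations. Useful for inspecting
#' simulated data in standard tooling.
#'
#' @param reads Read table.
#' @param ref A [mito_reference()].
#' @param path Output path.
#' @param chrom Reference name (default "chrM").
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, ref, path, chrom = "chrM") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom,
                       ref$canonical_length + ref$extension_length)), con)
  if (nrow(reads) == 0L) return(invisible(path))
  lines <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    aligned <- strsplit(r$seq, "", fixed = TRUE)[[1]]
    ins_at <- integer(0); ins_seq <- character(0)
    if (nzchar(r$ins)) {
      parts <- strsplit(strsplit(r$ins, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
      ins_at <- vapply(parts, function(p) as.integer(p[1]), integer(1))
      ins_seq <- vapply(parts, function(p) p[2], character(1))
    }
    refpos <- r$start + seq_along(aligned) - 1L
    ops <- ifelse(aligned == "-", "D", "M")
    qry <- ifelse(aligned == "-", "", aligned)
    # splice insertions after their anchor position
    if (length(ins_at)) {
      ord <- order(ins_at)
      for (k in rev(ord)) {   # right-to-left keeps indices valid
        at <- which(refpos == ins_at[k])
        if (length(at) != 1L) next   # anchor outside the aligned span
        ops <- append(ops, "I", after = at)
        qry <- append(qry, ins_seq[k], after = at)
      }
    }
    rl <- rle(ops)
    lens <- rl$lengths
    # I runs: length in bases, not ops (ins seq may be multi-base)
    cig <- character(length(lens)); off <- 0L
    for (j in seq_along(lens)) {
      seg <- (off + 1L):(off + lens[j]); off <- off + lens[j]
      nb <- if (rl$values[j] == "D") lens[j] else sum(nchar(qry[seg]))
      cig[j] <- paste0(nb, rl$values[j])
    }
    flag <- if (r$strand == "+") 0L else 16L
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
            r$read_id, flag, chrom, r$start, r$mapq,
            paste(cig, collapse = ""), paste(qry, collapse = ""))
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}
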