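#' EMPOP-style haplotype profile from per-position calls
#'
#' Collects every non-reference call into forensic mtDNA notation:
#' substitutions as `263G`, point heteroplasmies as `7861Y` (IUPAC code of
#' the two alleles), deletions as `249DEL`, single-base insertions as
#' `309.1C` (homopolymer multi-copy insertions as `309.1C 309.2C`), and
#' longer motif insertions as `524.AC`. The profile round-trips through
#' [parse_haplotype()].
#'
#' @param calls Calls data.frame from [call_pileup()].
#' @param nocall_intervals Data.frame of no-call intervals from
#'   [detect_nocall_regions()] (may be empty).
#' @return `HaplotypeProfile`: list with `variants` (character vector,
#'   positions strictly increasing), `calls` (the contributing rows) and
#'   `nocall` (the interval data.frame).
#' @export
call_haplotype <- function(calls, nocall_intervals = NULL) {
  var_rows <- calls$call_type %in% c("substitution", "PHP", "insertion", "deletion")
  vc <- calls[var_rows, , drop = FALSE]
  vc <- vc[order(vc$position, vc$call_type == "insertion"), , drop = FALSE]
  notation <- character(0)
  for (i in seq_len(nrow(vc))) {
    notation <- c(notation, variant_notation(
      vc$position[i], vc$call_type[i], vc$allele1[i], vc$allele2[i]))
  }
  if (is.null(nocall_intervals)) {
    nocall_intervals <- data.frame(start = integer(0), end = integer(0),
                                   length = integer(0))
  }
  structure(list(variants = notation, calls = vc, nocall = nocall_intervals),
            class = "HaplotypeProfile")
}

#' @export
print.HaplotypeProfile <- function(x, ...) {
  cat(sprintf("HaplotypeProfile: %d variants, %d no-call interval(s)\n",
              length(x$variants), nrow(x$nocall)))
  if (length(x$variants)) cat(" ", paste(x$variants, collapse = " "), "\n")
  invisible(x)
}

#' Render one variant in EMPOP-style notation
#'
#' @param position Canonical position.
#' @param call_type One of substitution/PHP/deletion/insertion.
#' @param allele1,allele2 Alleles as in the calls table (for PHP, the two
#'   bases; for insertion, the inserted sequence).
#' @return Character vector (length > 1 only for homopolymer multi-copy
#'   insertions).
#' @export
variant_notation <- function(position, call_type, allele1, allele2 = NA) {
  switch(call_type,
    substitution = paste0(position, allele1),
    PHP = paste0(position, iupac_code(allele1, allele2)),
    deletion = paste0(position, "DEL"),
    insertion = {
      s <- strsplit(allele1, "", fixed = TRUE)[[1]]
      if (length(unique(s)) == 1L) {
        paste0(position, ".", seq_along(s), s)   # 309.1C 309.2C
      } else {
        paste0(position, ".", allele1)           # 524.AC
      }
    },
    stop("not a variant call type: ", call_type)
  )
}

#' Parse EMPOP-style haplotype notation
#'
#' Inverse of the notation emitted by [call_haplotype()]. Accepts a single
#' whitespace-separated string or a character vector of tokens.
#'
#' @param x Haplotype string(s).
#' @return Data.frame: position, type (substitution/PHP/deletion/insertion),
#'   allele (for PHP the IUPAC code; for insertions the full inserted
#'   sequence after merging numbered entries), ins_index (NA except numbered
#'   insertions, which are merged in order).
#' @export
parse_haplotype <- function(x) {
  tok <- unlist(strsplit(x, "[[:space:]]+"), use.names = FALSE)
  tok <- tok[nzchar(tok)]
  out <- data.frame(position = integer(0), type = character(0),
                    allele = character(0), stringsAsFactors = FALSE)
  ins_num <- list()  # numbered insertion parts, merged afterwards
  for (t in tok) {
    if (grepl("^[0-9]+DEL$", t)) {
      out <- rbind(out, data.frame(
        position = as.integer(sub("DEL$", "", t)), type = "deletion",
        allele = "DEL", stringsAsFactors = FALSE))
    } else if (grepl("^[0-9]+\\.[0-9]+[ACGT]$", t)) {
      m <- regmatches(t, regexec("^([0-9]+)\\.([0-9]+)([ACGT])$", t))[[1]]
      key <- m[2]
      ins_num[[key]] <- rbind(ins_num[[key]],
                              data.frame(idx = as.integer(m[3]), base = m[4],
                                         stringsAsFactors = FALSE))
    } else if (grepl("^[0-9]+\\.[ACGT]{2,}$", t)) {
      m <- regmatches(t, regexec("^([0-9]+)\\.([ACGT]+)$", t))[[1]]
      out <- rbind(out, data.frame(
        position = as.integer(m[2]), type = "insertion", allele = m[3],
        stringsAsFactors = FALSE))
    } else if (grepl("^[0-9]+[ACGT]$", t)) {
      m <- regmatches(t, regexec("^([0-9]+)([ACGT])$", t))[[1]]
      out <- rbind(out, data.frame(
        position = as.integer(m[2]), type = "substitution", allele = m[3],
        stringsAsFactors = FALSE))
    } else if (grepl("^[0-9]+[RYSWKM]$", t)) {
      m <- regmatches(t, regexec("^([0-9]+)([RYSWKM])$", t))[[1]]
      out <- rbind(out, data.frame(
        position = as.integer(m[2]), type = "PHP", allele = m[3],
        stringsAsFactors = FALSE))
    } else {
      stop("cannot parse haplotype token: ", t)
    }
  }
  for (key in names(ins_num)) {
    parts <- ins_num[[key]]
    parts <- parts[order(parts$idx), , drop = FALSE]
    out <- rbind(out, data.frame(
      position = as.integer(key), type = "insertion",
      allele = paste(parts$base, collapse = ""), stringsAsFactors = FALSE))
  }
  out <- out[order(out$position, out$type), , drop = FALSE]
  if (anyDuplicated(out[, c("position", "type")])) {
    stop("malformed profile: duplicate variant at one position")
  }
  rownames(out) <- NULL
  out
}

#' Serialize a haplotype profile to a single EMPOP-style line
#'
#' @param profile A `HaplotypeProfile` (or character vector of tokens).
#' @return Single string.
#' @export
format_haplotype <- function(profile) {
  v <- if (inherits(profile, "HaplotypeProfile")) profile$variants else profile
  paste(v, collapse = " ")
}

#' Write calls as VCF 4.2
#'
#' Minimal VCF writer for the calls table: variant rows only, with INFO
#' fields `VF` (variant frequency, percent), `DP` (depth) and `FLAGS`.
#' Insertions/deletions are encoded against the supplied reference
#' (anchored at the preceding base, per VCF convention).
#'
#' @param calls Calls data.frame from [call_pileup()].
#' @param ref A [mito_reference()].
#' @param path Output path.
#' @param chrom Chromosome name (default "chrM").
#' @param sample Sample name for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, ref, path, chrom = "chrM", sample = "sample") {
  refbase <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, ref$canonical_length),
    "##INFO=<ID=VF,Number=1,Type=Float,Description=\"Variant frequency, percent\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=FLAGS,Number=1,Type=String,Description=\"QC flags\">",
    sprintf("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ), con)
  vc <- calls[calls$call_type %in% c("substitution", "PHP", "insertion", "deletion"), ,
              drop = FALSE]
  for (i in seq_len(nrow(vc))) {
    p <- vc$position[i]
    tp <- vc$call_type[i]
    if (tp == "substitution") {
      pos <- p; rf <- refbase[p]; alt <- vc$allele1[i]
    } else if (tp == "PHP") {
      pos <- p; rf <- refbase[p]
      two <- c(vc$allele1[i], vc$allele2[i])
      alt <- paste(setdiff(two, rf), collapse = ",")
      if (!nzchar(alt)) alt <- two[2]
    } else if (tp == "deletion") {
      pos <- max(1L, p - 1L)
      rf <- paste0(refbase[pos], if (pos < p) refbase[p] else "")
      alt <- refbase[pos]
    } else {  # insertion after p
      pos <- p; rf <- refbase[p]
      alt <- paste0(refbase[p], vc$allele1[i])
    }
    info <- sprintf("VF=%.1f;DP=%d%s", vc$variant_frequency[i], vc$depth[i],
                    if (nzchar(vc$flags[i])) paste0(";FLAGS=", vc$flags[i]) else "")
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                       chrom, pos, rf, alt, info), con)
  }
  invisible(path)
}

#' Write no-call intervals as BED
#'
#' @param intervals Data.frame start/end (1-based inclusive).
#' @param path Output path.
#' @param chrom Chromosome name.
#' @return `path`, invisibly.
#' @export
write_nocall_bed <- function(intervals, path, chrom = "chrM") {
  df <- data.frame(chrom = chrom, start = intervals$start - 1L,
                   end = intervals$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
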