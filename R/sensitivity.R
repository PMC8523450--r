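#' The default gDNA dilution ladder
#'
#' Thirteen serial dilutions (X1..X13) of genomic DNA input, 100 pg down to
#' 0.009375 pg, three replicates each — the design used to probe the
#' stochastic limit of whole-mtDNA amplicon sequencing.
#'
#' @param replicates Replicates per dilution (default 3).
#' @return Data.frame: label, input_pg, replicates.
#' @export
dilution_ladder <- function(replicates = 3L) {
  data.frame(
    label = paste0("X", 1:13),
    input_pg = c(100, 20, 10, 5, 2.5, 1.2, 0.6, 0.3, 0.15,
                 0.075, 0.0375, 0.01875, 0.009375),
    replicates = as.integer(replicates),
    stringsAsFactors = FALSE
  )
}

#' mtDNA copy number from gDNA input mass
#'
#' The platform's standard conversion: 0.1 ng of gDNA corresponds to about
#' 2,900 copies of mtDNA, linear in the input mass. The unrounded value is
#' always retained; the reported integer uses round-half-to-even.
#'
#' @param input_pg Input gDNA in picograms (vectorized, >= 0).
#' @return List: `copies` (real), `copies_rounded` (integer).
#' @examples
#' copies_from_input(0.6)$copies_rounded   # about 17 copies
#' copies_from_input(100)$copies           # 2900
#' @export
copies_from_input <- function(input_pg) {
  if (any(input_pg < 0)) stop("input mass must be >= 0")
  copies <- input_pg / 100 * 2900
  list(copies = copies, copies_rounded = as.integer(round(copies)))
}

#' Score a called haplotype against simulation truth
#'
#' False positives are called variants absent from the truth haplotype and
#' truth PHP sites; calls at the simulator's injected recurrent-noise
#' positions (known artifacts, recorded in the truth) are tallied
#' separately as `artifact_position_calls`, mirroring the workflow's
#' interpret-with-caution treatment of blacklisted positions. False
#' negatives are truth variants not called at covered positions (truth
#' variants inside no-call intervals are excluded and counted as
#' `fn_uncovered`). PHP sites are reported with their observed frequency or
#' as absent.
#'
#' @param profile A `HaplotypeProfile` from [call_haplotype()].
#' @param truth A `SimulationTruth` (see [simulate_sample()]) or a list with
#'   `haplotype` (character tokens), `php_sites` (data.frame position, ref,
#'   alt, true_frequency) and optionally `noisy_positions`.
#' @param canonical_length Genome length for percent-covered (default
#'   16,569).
#' @return One-row data.frame: pct_mtDNA_covered, false_positive_calls,
#'   false_negative_calls, fn_uncovered, artifact_position_calls, plus an
#'   attribute `php_detected` (data.frame position, true_frequency,
#'   observed_frequency, detected).
#' @export
score_replicate <- function(profile, truth, canonical_length = 16569L) {
  nocall_pos <- integer(0)
  if (nrow(profile$nocall) > 0L) {
    nocall_pos <- unlist(mapply(seq.int, profile$nocall$start,
                                profile$nocall$end, SIMPLIFY = FALSE))
  }
  covered <- canonical_length - length(unique(nocall_pos))
  truth_df <- parse_haplotype(truth$haplotype)
  php <- truth$php_sites
  called <- profile$calls
  noisy <- truth$noisy_positions %||% integer(0)

  truth_key <- paste(truth_df$position, truth_df$type)
  call_key <- paste(called$position, ifelse(called$call_type == "PHP",
                                            "php_site", called$call_type))
  php_positions <- if (!is.null(php) && nrow(php)) php$position else integer(0)

  is_truth_hap <- paste(called$position, called$call_type) %in% truth_key
  is_truth_php <- called$position %in% php_positions & called$call_type == "PHP"
  is_noise <- called$position %in% noisy
  fp_rows <- !(is_truth_hap | is_truth_php) & !is_noise
  fp <- sum(fp_rows)
  artifact_calls <- sum(!(is_truth_hap | is_truth_php) & is_noise)

  # truth haplotype recovery at covered positions
  t_cov <- !(truth_df$position %in% nocall_pos)
  recovered <- paste(truth_df$position, truth_df$type) %in%
    paste(called$position, called$call_type) &
    truth_df$allele == .called_allele_token(called, truth_df)
  fn <- sum(t_cov & !recovered)
  fn_unc <- sum(!t_cov)

  php_detected <- if (length(php_positions)) {
    obs <- vapply(php_positions, function(p) {
      i <- which(called$position == p & called$call_type == "PHP")
      if (!length(i)) return(NA_real_)
      # observed minor-allele frequency
      called$variant_frequency[i[1]]
    }, numeric(1))
    data.frame(position = php_positions,
               true_frequency = php$true_frequency,
               observed_frequency = obs,
               covered = !(php_positions %in% nocall_pos),
               detected = !is.na(obs))
  } else {
    data.frame(position = integer(0), true_frequency = numeric(0),
               observed_frequency = numeric(0), covered = logical(0),
               detected = logical(0))
  }
  out <- data.frame(
    pct_mtDNA_covered = 100 * covered / canonical_length,
    false_positive_calls = fp,
    false_negative_calls = fn,
    fn_uncovered = fn_unc,
    artifact_position_calls = artifact_calls
  )
  attr(out, "php_detected") <- php_detected
  out
}

# allele token of the call matching each truth row ("" when not called)
.called_allele_token <- function(called, truth_df) {
  vapply(seq_len(nrow(truth_df)), function(i) {
    j <- which(called$position == truth_df$position[i] &
                 called$call_type == truth_df$type[i])
    if (!length(j)) return("")
    if (truth_df$type[i] == "deletion") "DEL" else called$allele1[j[1]]
  }, character(1))
}

#' Compare two haplotype profiles (concordance)
#'
#' Variant-by-variant comparison over a shared range. Positions falling in
#' either profile's no-call intervals are excluded from comparison and
#' listed. A PHP in one profile whose major allele matches the other
#' profile's homoplasmic state counts as concordant-with-note by default
#' (expected platform behaviour for borderline heteroplasmies); strict mode
#' counts it as discordant.
#'
#' @param a,b `HaplotypeProfile`s (or character haplotype strings, in which
#'   case no-call information is empty).
#' @param restrict_to `NULL` for the full genome, `"control-region"` for the
#'   forensic CR preset (np 16,024-16,569 plus 1-576), or a list of
#'   [genomic_interval()]s.
#' @param strict_php Count PHP-vs-homoplasmy mismatches as discordant
#'   (default FALSE).
#' @param exclude_positions Optional integer vector of blacklisted positions
#'   (e.g. the packaged recurrent-noise catalog) whose variants are removed
#'   from both profiles before comparison and listed separately.
#' @param ref Reference (only its canonical length is used; default rCRS
#'   length).
#' @return `ConcordanceResult`: list with `concordant` (count of compared
#'   variant positions agreeing), `discordant` (data.frame position, call_a,
#'   call_b, note), `excluded_nocall` (positions skipped), `verdict`
#'   (full/partial/discordant).
#' @export
compare_haplotypes <- function(a, b, restrict_to = NULL, strict_php = FALSE,
                               ref = NULL, exclude_positions = NULL) {
  ta <- .profile_tokens(a); tb <- .profile_tokens(b)
  excluded_blacklisted <- integer(0)
  if (!is.null(exclude_positions)) {
    hit <- c(ta$df$position[ta$df$position %in% exclude_positions],
             tb$df$position[tb$df$position %in% exclude_positions])
    excluded_blacklisted <- sort(unique(hit))
    ta$df <- ta$df[!(ta$df$position %in% exclude_positions), , drop = FALSE]
    tb$df <- tb$df[!(tb$df$position %in% exclude_positions), , drop = FALSE]
  }
  if (anyDuplicated(paste(ta$df$position, ta$df$type)) ||
      anyDuplicated(paste(tb$df$position, tb$df$type))) {
    stop("malformed profile: overlapping duplicate variants")
  }
  regions <- .concordance_regions(restrict_to)
  in_range <- function(p) {
    if (is.null(regions)) rep(TRUE, length(p)) else .in_regions(p, regions)
  }
  nocall <- sort(unique(c(.nocall_positions(ta), .nocall_positions(tb))))
  da <- ta$df[in_range(ta$df$position) & !(ta$df$position %in% nocall), , drop = FALSE]
  db <- tb$df[in_range(tb$df$position) & !(tb$df$position %in% nocall), , drop = FALSE]
  vkey <- function(d) {
    if (nrow(d) == 0L) return(character(0))
    paste0(d$position, "_", d$type, "_", d$allele)
  }
  ka <- vkey(da); kb <- vkey(db)
  agree <- intersect(ka, kb)
  only_a <- da[!(ka %in% kb), , drop = FALSE]
  only_b <- db[!(kb %in% ka), , drop = FALSE]
  disc <- list(); notes <- character(0)
  handled_b <- logical(nrow(only_b))
  for (i in seq_len(nrow(only_a))) {
    j <- which(only_b$position == only_a$position[i])
    call_b <- if (length(j)) paste0(only_b$allele[j[1]]) else "ref"
    note <- ""
    if (.php_vs_major_match(only_a[i, ], only_b, j)) {
      note <- "PHP-vs-homoplasmy"
      if (length(j)) handled_b[j[1]] <- TRUE
      if (!strict_php) {
        notes <- c(notes, sprintf("%d: %s (concordant with note)",
                                  only_a$position[i], note))
        next
      }
    }
    disc[[length(disc) + 1L]] <- data.frame(
      position = only_a$position[i],
      call_a = paste0(only_a$allele[i]), call_b = call_b, note = note,
      stringsAsFactors = FALSE)
    if (length(j)) handled_b[j[1]] <- TRUE
  }
  for (i in which(!handled_b)) {
    note <- ""
    if (only_b$type[i] == "PHP" && !strict_php) {
      # PHP private to b with no counterpart in a: major allele equals
      # a's homoplasmic state (reference)
      note <- "PHP-vs-homoplasmy"
      notes <- c(notes, sprintf("%d: %s (concordant with note)",
                                only_b$position[i], note))
      next
    }
    disc[[length(disc) + 1L]] <- data.frame(
      position = only_b$position[i], call_a = "ref",
      call_b = paste0(only_b$allele[i]), note = note, stringsAsFactors = FALSE)
  }
  discordant <- if (length(disc)) do.call(rbind, disc) else
    data.frame(position = integer(0), call_a = character(0),
               call_b = character(0), note = character(0))
  hp_regions <- list(genomic_interval(303, 310), genomic_interval(513, 525),
                     genomic_interval(16184, 16193))
  if (nrow(discordant)) {
    hp <- .in_regions(discordant$position, hp_regions)
    discordant$note[hp] <- trimws(paste(discordant$note[hp], "homopolymer"))
  }
  verdict <- if (nrow(discordant) == 0L) "full" else
    if (length(agree) > 0L) "partial" else "discordant"
  structure(list(concordant = length(agree), discordant = discordant,
                 concordant_with_note = notes,
                 excluded_nocall = nocall,
                 excluded_blacklisted = excluded_blacklisted,
                 verdict = verdict),
            class = "ConcordanceResult")
}

.profile_tokens <- function(x) {
  if (inherits(x, "HaplotypeProfile")) {
    list(df = parse_haplotype(x$variants), nocall = x$nocall)
  } else {
    list(df = parse_haplotype(x),
         nocall = data.frame(start = integer(0), end = integer(0)))
  }
}

.nocall_positions <- function(tok) {
  if (nrow(tok$nocall) == 0L) return(integer(0))
  unlist(mapply(seq.int, tok$nocall$start, tok$nocall$end, SIMPLIFY = FALSE))
}

.concordance_regions <- function(restrict_to) {
  if (is.null(restrict_to)) return(NULL)
  if (identical(restrict_to, "control-region")) {
    return(list(genomic_interval(16024, 16569), genomic_interval(1, 576)))
  }
  restrict_to
}

# does row `ra` (private to a) look like a PHP whose major allele matches
# b's homoplasmic state (counterpart j in b, or reference when j empty)?
.php_vs_major_match <- function(ra, only_b, j) {
  if (ra$type == "PHP") {
    return(length(j) == 0L || only_b$type[j[1]] == "substitution")
  }
  if (ra$type == "substitution" && length(j) && only_b$type[j[1]] == "PHP") {
    return(ra$allele %in% iupac_bases(only_b$allele[j[1]]))
  }
  FALSE
}

#' @export
print.ConcordanceResult <- function(x, ...) {
  cat(sprintf("concordance: %s (%d concordant, %d discordant, %d no-call positions excluded)\n",
              x$verdict, x$concordant, nrow(x$discordant),
              length(x$excluded_nocall)))
  invisible(x)
}

#' PHP recovery across a dilution series
#'
#' Long-format table of the observed frequency of one heteroplasmic site per
#' dilution replicate, suitable for plotting against the expected value.
#'
#' @param dilution_results Data.frame with columns label, input_pg,
#'   replicate and an attached list-column or list `php` of per-replicate
#'   php_detected tables (as produced by the sensitivity driver), or a list
#'   of [score_replicate()] rows.
#' @param site Position of the heteroplasmic site.
#' @return Data.frame: label, input_pg, replicate, observed_frequency
#'   (NA = absent), detected.
#' @export
php_recovery_curve <- function(dilution_results, site) {
  rows <- lapply(seq_along(dilution_results$scores), function(i) {
    php <- attr(dilution_results$scores[[i]], "php_detected")
    hit <- php[php$position == site, , drop = FALSE]
    if (nrow(hit) == 0L) return(NULL)
    data.frame(label = dilution_results$label[i],
               input_pg = dilution_results$input_pg[i],
               replicate = dilution_results$replicate[i],
               observed_frequency = hit$observed_frequency,
               covered = hit$covered,
               detected = hit$detected, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    warning("site ", site, " never covered in the supplied results")
    return(data.frame(label = character(0), input_pg = numeric(0),
                      replicate = integer(0), observed_frequency = numeric(0),
                      covered = logical(0), detected = logical(0)))
  }
  do.call(rbind, rows)
}
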