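#' Simulation configuration for the amplicon-panel read generator
#'
#' Bundles every generative choice behind the synthetic data: the reference
#' and panel geometry, the truth haplotype and heteroplasmic sites, the
#' template/amplification model, and the artifact models (micro-amplicons,
#' recurrent NUMT-like noise, homopolymer indel noise, strand bias, PCR
#' jackpot errors).
#'
#' Key defaults and what they emulate:
#' * `input_pg = 100`: the standard 0.1 ng gDNA input (~2,900 mtDNA copies).
#' * `target_amplicon_depth = 400`: desk-scale stand-in for the instrument's
#'   per-amplicon depth; with `reads_per_template = NULL` the sequencing
#'   budget is fixed per amplicon (libraries are pool-normalized on the real
#'   workflow), so reads are spread over however many templates were
#'   captured. Setting `reads_per_template` to a number switches to a
#'   constant per-template Poisson yield instead.
#' * `capture_prob = 0.9`: probability that a given template contributes to
#'   a given amplicon's amplification.
#' * `pcr_error_rate = 1e-4` per base per cycle with `pcr_max_cycles = 8`:
#'   early-cycle polymerase errors that expand clonally; with few founding
#'   templates these create subclonal alleles and the characteristic
#'   low-input loss of haplotype purity.
#' * `numt_noise`: recurrent low-VarFreq noise model, defaulting to the
#'   packaged catalog (see [noisy_position_catalog()], sample `s1`).
#' * `php_sites`: point heteroplasmies assigned per TEMPLATE before
#'   amplification (the mechanism behind low-input heteroplasmy variance);
#'   defaults are a 17% site at 7861, plus low-level sites at 1393 (3.2%)
#'   and 3242 (0.7%) that sit below the 10% calling threshold.
#' * `artifact_fraction = 0.027`: short micro-amplicon reads as a fraction
#'   of all mapped reads (the level seen in positive samples); negatives use
#'   0.69 via [simulate_negative()].
#'
#' @param ref A [mito_reference()] (default [default_reference()]).
#' @param panel An [amplicon_panel()] or `NULL` to auto-generate via
#'   [simulate_panel()].
#' @param n_amplicons,length_mean,length_sd,length_bounds,min_overlap Panel
#'   geometry when auto-generating (164 amplicons — two pools of 82 primer
#'   pairs; lengths ~N(162, 8^2) clamped to 125-174 bp; junction overlaps
#'   at least 11 bp).
#' @param truth_haplotype Character vector of EMPOP-style tokens, or `NULL`
#'   for [default_truth_haplotype()].
#' @param php_sites Data.frame position/true_frequency (percent in (0,100)).
#' @param input_pg Input gDNA mass in picograms.
#' @param target_amplicon_depth Mean reads per amplicon under the fixed
#'   sequencing budget.
#' @param reads_per_template `NULL` (fixed budget) or mean reads per
#'   captured template.
#' @param capture_prob Per-template per-amplicon capture probability.
#' @param amplicon_cv Lognormal coefficient of variation of per-amplicon
#'   depth (uncalibrated; no per-amplicon bias figures exist for the panel).
#' @param base_error_rate Per-base sequencing substitution rate.
#' @param pcr_error_rate,pcr_max_cycles PCR jackpot model (see above).
#' @param numt_noise Data.frame position/allele/mean_varfreq/sd_varfreq or
#'   `NULL` to disable.
#' @param homopolymer_regions List of intervals with elevated single-base
#'   deletion noise; `homopolymer_del_mean`/`homopolymer_del_sd` give the
#'   per-position percentage of reads carrying the deletion.
#' @param strand_bias_regions List of intervals whose noise alleles are
#'   emitted on the forward strand only.
#' @param artifact_hotspots Amplicon names receiving micro-amplicon
#'   artifact reads.
#' @param artifact_fraction Fraction of mapped reads that are short
#'   artifacts.
#' @param background_depth Mean depth of the trace uniform background
#'   (amplification negatives; 0 disables).
#' @param seed Integer seed; mandatory at simulation time.
#' @return `SimulationConfig` list.
#' @export
simulation_config <- function(ref = default_reference(), panel = NULL,
                              n_amplicons = 164L, length_mean = 162,
                              length_sd = 8, length_bounds = c(125L, 174L),
                              min_overlap = 11L,
                              truth_haplotype = NULL, php_sites = NULL,
                              input_pg = 100,
                              target_amplicon_depth = 400,
                              reads_per_template = NULL,
                              capture_prob = 0.9, amplicon_cv = 0.3,
                              base_error_rate = 0.001,
                              pcr_error_rate = 1e-4, pcr_max_cycles = 8L,
                              numt_noise = numt_noise_model("s1"),
                              homopolymer_regions = list(
                                genomic_interval(303, 310),
                                genomic_interval(16184, 16193)),
                              homopolymer_del_mean = 10,
                              homopolymer_del_sd = 3,
                              strand_bias_regions = list(
                                genomic_interval(8248, 8256)),
                              artifact_hotspots = c("mt_125", "mt_139",
                                                    "mt_164", "mt_130",
                                                    "mt_133"),
                              artifact_fraction = 0.027,
                              background_depth = 0,
                              seed = NULL) {
  if (is.null(truth_haplotype)) truth_haplotype <- default_truth_haplotype(ref)
  if (is.null(php_sites)) {
    php_sites <- data.frame(position = c(7861L, 1393L, 3242L),
                            true_frequency = c(17, 3.2, 0.7))
  }
  if (nrow(php_sites) > 0L) {
    stopifnot(all(php_sites$true_frequency > 0 & php_sites$true_frequency < 100),
              all(php_sites$position >= 1 &
                    php_sites$position <= ref$canonical_length))
  }
  structure(list(
    ref = ref, panel = panel, n_amplicons = as.integer(n_amplicons),
    length_mean = length_mean, length_sd = length_sd,
    length_bounds = as.integer(length_bounds),
    min_overlap = as.integer(min_overlap),
    truth_haplotype = truth_haplotype, php_sites = php_sites,
    input_pg = input_pg, target_amplicon_depth = target_amplicon_depth,
    reads_per_template = reads_per_template, capture_prob = capture_prob,
    amplicon_cv = amplicon_cv, base_error_rate = base_error_rate,
    pcr_error_rate = pcr_error_rate, pcr_max_cycles = as.integer(pcr_max_cycles),
    numt_noise = numt_noise, homopolymer_regions = homopolymer_regions,
    homopolymer_del_mean = homopolymer_del_mean,
    homopolymer_del_sd = homopolymer_del_sd,
    strand_bias_regions = strand_bias_regions,
    artifact_hotspots = artifact_hotspots,
    artifact_fraction = artifact_fraction,
    background_depth = background_depth,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "SimulationConfig")
}

#' Recurrent-noise model from the packaged catalog
#'
#' @param sample `"s1"` or `"s2"` — which control DNA's catalogued
#'   means/SDs to use.
#' @return Data.frame position, allele, mean_varfreq, sd_varfreq.
#' @export
numt_noise_model <- function(sample = c("s1", "s2")) {
  sample <- match.arg(sample)
  cat_ <- noisy_position_catalog()
  data.frame(position = cat_$position, allele = cat_$second_variant,
             mean_varfreq = cat_[[paste0("mean_", sample)]],
             sd_varfreq = cat_[[paste0("sd_", sample)]],
             stringsAsFactors = FALSE)
}

#' Default simulated truth haplotype
#'
#' Twenty-six substitutions at classic mtDNA polymorphic positions (away
#' from the noise catalog, homopolymer stretches and the strand-bias
#' region), one insertion and one deletion. Substitution alleles are
#' transitions of whatever base the supplied reference carries, so the
#' haplotype is valid for any reference sequence.
#'
#' @param ref A [mito_reference()].
#' @return Character vector of EMPOP-style tokens.
#' @export
default_truth_haplotype <- function(ref) {
  pos <- c(73L, 146L, 152L, 195L, 263L, 489L, 750L, 1438L, 2706L, 3010L,
           4769L, 5460L, 7028L, 8860L, 9540L, 10398L, 10873L, 11719L,
           12705L, 13368L, 14212L, 14766L, 15326L, 16126L, 16294L, 16519L)
  refbase <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  c(paste0(pos, transition[refbase[pos]]), "455.1T", "249DEL")
}

#' Generate a tiling amplicon panel for a circular reference
#'
#' Draws amplicon lengths from a clamped normal, checks the tiling is
#' feasible (total length must exceed the circle plus the minimum overlap at
#' every junction), then distributes the slack evenly so consecutive
#' amplicons overlap by at least `min_overlap` bp and the last amplicon
#' closes the circle through the wrap extension.
#'
#' @param config A [simulation_config()] (geometry fields are used), or
#'   arguments via `...` overriding it.
#' @param seed Seed (defaults to `config$seed`).
#' @return An [amplicon_panel()] tiling the full circle.
#' @export
simulate_panel <- function(config = simulation_config(), seed = NULL) {
  seed <- seed %||% config$seed
  if (is.null(seed)) stop("seed is mandatory")
  ref <- config$ref
  L <- ref$canonical_length
  n <- config$n_amplicons
  if (n < 2L) stop("configuration error: need at least 2 amplicons")
  local_seed_eval(seed, {
    len <- pmin(pmax(round(stats::rnorm(n, config$length_mean, config$length_sd)),
                     config$length_bounds[1]), config$length_bounds[2])
    slack <- sum(len) - L - n * config$min_overlap
    if (slack < 0) {
      stop("configuration error: amplicon lengths cannot tile the circle ",
           "with >= ", config$min_overlap, " bp junction overlaps (short by ",
           -slack, " bp)")
    }
    extra <- rep(slack %/% n, n)
    extra[seq_len(slack %% n)] <- extra[seq_len(slack %% n)] + 1L
    ov <- config$min_overlap + extra
    # the closing junction must fit inside the wrap extension
    if (ov[n] > ref$extension_length) {
      surplus <- ov[n] - ref$extension_length
      ov[n] <- ref$extension_length
      give <- rep(surplus %/% (n - 1L), n - 1L)
      give[seq_len(surplus %% (n - 1L))] <- give[seq_len(surplus %% (n - 1L))] + 1L
      ov[seq_len(n - 1L)] <- ov[seq_len(n - 1L)] + give
    }
    if (any(len - ov < 1L)) {
      stop("configuration error: junction overlaps would swallow an amplicon")
    }
    starts <- 1L + cumsum(c(0L, (len - ov)[-n]))
    amplicon_panel(name = paste0("mt_", seq_len(n)), start = starts,
                   end = starts + len - 1L,
                   length_bounds = config$length_bounds)
  })
}

#' Simulate an aligned amplicon sequencing run with ground truth
#'
#' The generative pipeline: (1) template count N ~ Poisson(copies from
#' input mass); (2) each template independently carries each heteroplasmic
#' alt allele with probability true_frequency/100; (3) per amplicon,
#' templates are captured by binomial thinning and reads are emitted under
#' the fixed sequencing budget (or a constant per-template Poisson yield),
#' each read spanning its amplicon; (4) micro-amplicon artifact reads
#' (40-79 bp, MAPQ 0-20) are appended at hotspot amplicon junctions;
#' genuine reads carry MAPQ 40-60; (5) at each recurrent-noise position a
#' per-sample noise fraction ~ Normal(100 - mean_varfreq, sd)/100 truncated
#' to `[0, 1]` of reads carries the second allele; (6) homopolymer positions
#' receive elevated single-base deletion noise; noise alleles inside
#' strand-bias regions ride the forward strand only; PCR jackpot errors are
#' layered per founding template; sequencing errors per base. Everything
#' realized is recorded in the truth.
#'
#' Identical config + seed gives identical output.
#'
#' @param config A [simulation_config()].
#' @param seed Seed (defaults to `config$seed`; mandatory).
#' @return List: `reads` (read table), `truth` (`SimulationTruth`: haplotype
#'   tokens, php_sites with realized template fractions, noisy_positions
#'   and realized noise fractions, homopolymer positions,
#'   artifact_read_ids, background_read_ids, template_count, captured per
#'   amplicon, total genuine aligned bases), `panel`.
#' @export
simulate_sample <- function(config = simulation_config(), seed = NULL) {
  seed <- seed %||% config$seed
  if (is.null(seed)) stop("seed is mandatory")
  local_seed_eval(seed, .simulate_sample_impl(config))
}

.simulate_sample_impl <- function(config) {
  ref <- config$ref
  L <- ref$canonical_length
  ext_seq <- strsplit(extend_reference(ref), "", fixed = TRUE)[[1]]
  panel <- config$panel
  if (is.null(panel)) {
    panel <- simulate_panel(config, seed = stats::runif(1, 1, 1e6))
  }
  n_amp <- nrow(panel)

  copies <- copies_from_input(config$input_pg)$copies
  N <- stats::rpois(1L, copies)

  php <- config$php_sites
  n_php <- if (is.null(php)) 0L else nrow(php)
  php_state <- if (n_php > 0L && N > 0L) {
    matrix(stats::runif(N * n_php) < rep(php$true_frequency / 100, each = N),
           nrow = N)
  } else matrix(FALSE, nrow = max(N, 0L), ncol = n_php)
  php_alt <- if (n_php > 0L) {
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    unname(transition[ext_seq[php$position]])
  } else character(0)

  truth_df <- parse_haplotype(config$truth_haplotype)
  tsub <- truth_df[truth_df$type == "substitution", , drop = FALSE]
  tdel <- truth_df[truth_df$type == "deletion", , drop = FALSE]
  tins <- truth_df[truth_df$type == "insertion", , drop = FALSE]

  # per-sample noise fractions, drawn once
  nn <- config$numt_noise
  noise_frac <- if (!is.null(nn) && nrow(nn) > 0L) {
    f <- stats::rnorm(nrow(nn), (100 - nn$mean_varfreq), nn$sd_varfreq) / 100
    pmin(pmax(f, 0), 1)
  } else numeric(0)
  hp_pos <- unlist(lapply(config$homopolymer_regions,
                          function(iv) iv$start:iv$end))
  hp_frac <- if (length(hp_pos)) {
    pmin(pmax(stats::rnorm(length(hp_pos), config$homopolymer_del_mean,
                           config$homopolymer_del_sd) / 100, 0), 1)
  } else numeric(0)
  sb <- logical(L)
  for (iv in config$strand_bias_regions) sb[iv$start:iv$end] <- TRUE

  bias <- if (config$amplicon_cv > 0) {
    sg <- sqrt(log(1 + config$amplicon_cv^2))
    stats::rlnorm(n_amp, -sg^2 / 2, sg)
  } else rep(1, n_amp)

  chunks <- vector("list", n_amp)
  captured_per_amp <- integer(n_amp)
  genuine_bases <- 0
  for (a in seq_len(n_amp)) {
    out <- .simulate_amplicon(
      a, panel, ref, ext_seq, N, php, php_state, php_alt,
      tsub, tdel, tins, nn, noise_frac, hp_pos, hp_frac, sb, bias[a], config)
    chunks[[a]] <- out$reads
    captured_per_amp[a] <- out$captured
    genuine_bases <- genuine_bases + out$bases
  }
  reads <- do.call(rbind, chunks[!vapply(chunks, is.null, logical(1))])
  n_genuine <- if (is.null(reads)) 0L else nrow(reads)

  bg <- .simulate_background(config, ref, panel, ext_seq)
  n_bg <- if (is.null(bg)) 0L else nrow(bg)

  af <- config$artifact_fraction
  n_art_total <- if (af > 0) {
    stats::rpois(1L, af / (1 - af) * (n_genuine + n_bg))
  } else 0L
  art <- .simulate_artifacts(config, panel, ref, ext_seq, n_art_total)

  reads <- do.call(rbind, Filter(Negate(is.null), list(reads, bg, art)))
  if (is.null(reads)) reads <- .empty_reads()
  rownames(reads) <- NULL

  truth <- structure(list(
    haplotype = config$truth_haplotype,
    php_sites = if (n_php > 0L) cbind(
      php,
      alt = php_alt,
      alt_templates = if (N > 0L) colSums(php_state) else rep(0L, n_php),
      template_count = N
    ) else php,
    noisy_positions = if (!is.null(nn) && nrow(nn) > 0L) nn$position else integer(0),
    noise_fractions = if (length(noise_frac)) {
      stats::setNames(noise_frac, nn$position)
    } else numeric(0),
    homopolymer_positions = remap_position(hp_pos, ref),
    artifact_read_ids = if (is.null(art)) character(0) else art$read_id,
    background_read_ids = if (is.null(bg)) character(0) else bg$read_id,
    template_count = N,
    captured_per_amplicon = stats::setNames(captured_per_amp, panel$name),
    genuine_aligned_bases = genuine_bases,
    input_pg = config$input_pg
  ), class = "SimulationTruth")
  list(reads = reads, truth = truth, panel = panel)
}

.empty_reads <- function() {
  data.frame(read_id = character(0), start = integer(0), length = integer(0),
             mapq = integer(0), strand = character(0), amplicon = character(0),
             seq = character(0), ins = character(0), stringsAsFactors = FALSE)
}

.simulate_amplicon <- function(a, panel, ref, ext_seq, N, php, php_state,
                               php_alt, tsub, tdel, tins, nn, noise_frac,
                               hp_pos, hp_frac, sb, bias_a, config) {
  span <- panel$start[a]:panel$end[a]
  len_a <- length(span)
  spanc <- remap_position(span, ref)
  if (N <= 0L) return(list(reads = NULL, captured = 0L, bases = 0))
  captured <- stats::rbinom(1L, N, config$capture_prob)
  if (captured == 0L) return(list(reads = NULL, captured = 0L, bases = 0))
  founders <- sort(sample.int(N, captured))
  if (is.null(config$reads_per_template)) {
    n_reads <- stats::rpois(1L, config$target_amplicon_depth * bias_a)
    founder_of <- founders[sample.int(captured, n_reads, replace = TRUE)]
  } else {
    per <- stats::rpois(captured, config$reads_per_template)
    n_reads <- sum(per)
    founder_of <- rep(founders, per)
  }
  if (n_reads == 0L) return(list(reads = NULL, captured = captured, bases = 0))

  cons <- ext_seq[span]
  # truth haplotype: substitutions and deletions on all templates
  hit <- match(spanc, tsub$position); have <- !is.na(hit)
  cons[have] <- tsub$allele[hit[have]]
  cons[spanc %in% tdel$position] <- "-"
  M <- matrix(rep(cons, each = n_reads), nrow = n_reads)

  forced_plus <- logical(n_reads)
  ins_strings <- rep("", n_reads)
  # truth insertions (all reads); anchored at extended-axis coordinate
  for (k in seq_len(nrow(tins))) {
    cidx <- which(spanc == tins$position[k])
    if (length(cidx)) {
      tag <- paste0(span[cidx[1]], ":", tins$allele[k])
      ins_strings <- ifelse(nzchar(ins_strings),
                            paste(ins_strings, tag, sep = ";"), tag)
    }
  }
  # heteroplasmic sites: template-level alleles
  if (!is.null(php) && nrow(php) > 0L) {
    for (k in seq_len(nrow(php))) {
      cidx <- which(spanc == php$position[k])
      if (length(cidx)) {
        carrier <- php_state[founder_of, k]
        M[carrier, cidx[1]] <- php_alt[k]
      }
    }
  }
  # recurrent NUMT-like noise: read-level second alleles
  if (!is.null(nn) && nrow(nn) > 0L) {
    for (k in which(nn$position %in% spanc)) {
      cidx <- which(spanc == nn$position[k])[1]
      carrier <- stats::runif(n_reads) < noise_frac[k]
      if (!any(carrier)) next
      al <- nn$allele[k]
      if (al == "DEL") {
        M[carrier, cidx] <- "-"
      } else if (al == "INS") {
        tag <- paste0(span[cidx], ":", ext_seq[span[cidx]])
        ins_strings[carrier] <- ifelse(nzchar(ins_strings[carrier]),
                                       paste(ins_strings[carrier], tag, sep = ";"),
                                       tag)
      } else {
        if (al == cons[cidx]) {  # ensure the noise allele differs
          al <- setdiff(c("A", "C", "G", "T"), al)[1]
        }
        M[carrier, cidx] <- al
      }
      if (sb[nn$position[k]]) forced_plus <- forced_plus | carrier
    }
  }
  # homopolymer deletion noise
  if (length(hp_pos)) {
    hpc <- remap_position(hp_pos, ref)
    for (k in which(hpc %in% spanc)) {
      cidx <- which(spanc == hpc[k])[1]
      carrier <- stats::runif(n_reads) < hp_frac[k]
      M[carrier, cidx] <- "-"
    }
  }
  # PCR jackpot errors per founding template
  M <- .apply_pcr_jackpot(M, founder_of, len_a, config)
  # sequencing errors
  M <- .apply_base_errors(M, config$base_error_rate)

  strand <- ifelse(stats::runif(n_reads) < 0.5, "+", "-")
  strand[forced_plus] <- "+"
  seqs <- do.call(paste0, as.data.frame(M, stringsAsFactors = FALSE))
  reads <- data.frame(
    read_id = sprintf("%s_r%05d", panel$name[a], seq_len(n_reads)),
    start = panel$start[a], length = len_a,
    mapq = sample(40:60, n_reads, replace = TRUE),
    strand = strand, amplicon = panel$name[a],
    seq = seqs, ins = ins_strings, stringsAsFactors = FALSE
  )
  list(reads = reads, captured = captured, bases = n_reads * len_a)
}

.apply_pcr_jackpot <- function(M, founder_of, len_a, config) {
  mu <- config$pcr_error_rate
  if (mu <= 0) return(M)
  n_reads <- nrow(M)
  tab <- table(founder_of)
  nf <- as.integer(tab)
  f_ids <- as.integer(names(tab))
  bases <- c("A", "C", "G", "T")
  for (cyc in seq_len(config$pcr_max_cycles)) {
    frac <- 2^-cyc
    elig <- which(nf * frac >= 0.5)   # subclones below half a read are unobservable
    if (!length(elig)) break
    K <- stats::rpois(1L, length(elig) * 2^(cyc - 1) * mu * len_a)
    if (K == 0L) next
    for (e in seq_len(K)) {
      f <- f_ids[elig[sample.int(length(elig), 1L)]]
      rows <- which(founder_of == f)
      aff <- rows[stats::runif(length(rows)) < frac]
      if (!length(aff)) next
      cidx <- sample.int(len_a, 1L)
      cur <- M[aff[1], cidx]
      if (cur == "-") next
      M[aff, cidx] <- sample(setdiff(bases, cur), 1L)
    }
  }
  M
}

.apply_base_errors <- function(M, rate) {
  if (rate <= 0) return(M)
  n <- length(M)
  n_err <- stats::rbinom(1L, n, rate)
  if (n_err == 0L) return(M)
  idx <- sample.int(n, n_err)
  idx <- idx[M[idx] != "-"]
  if (!length(idx)) return(M)
  bases <- c("A", "C", "G", "T")
  repl <- sample(bases, length(idx), replace = TRUE)
  clash <- repl == M[idx]
  nxt <- c(A = "C", C = "G", G = "T", T = "A")
  repl[clash] <- nxt[repl[clash]]
  M[idx] <- repl
  M
}

.simulate_background <- function(config, ref, panel, ext_seq) {
  if (config$background_depth <= 0) return(NULL)
  L <- ref$canonical_length
  mean_len <- mean(config$length_bounds)
  n_bg <- stats::rpois(1L, config$background_depth * L / mean_len)
  if (n_bg == 0L) return(NULL)
  len <- sample(config$length_bounds[1]:config$length_bounds[2], n_bg,
                replace = TRUE)
  start <- sample.int(L, n_bg, replace = TRUE)
  over <- start + len - 1L > L + ref$extension_length
  start[over] <- pmax(1L, L + ref$extension_length - len[over] + 1L)
  seqs <- vapply(seq_len(n_bg), function(i) {
    paste(ext_seq[start[i]:(start[i] + len[i] - 1L)], collapse = "")
  }, character(1))
  reads <- data.frame(
    read_id = sprintf("bg_r%05d", seq_len(n_bg)),
    start = start, length = len,
    mapq = sample(40:60, n_bg, replace = TRUE),
    strand = ifelse(stats::runif(n_bg) < 0.5, "+", "-"),
    amplicon = assign_amplicon(start, len, panel),
    seq = seqs, ins = "", stringsAsFactors = FALSE
  )
  reads$seq <- .error_strings(reads$seq, config$base_error_rate)
  reads
}

.simulate_artifacts <- function(config, panel, ref, ext_seq, n_total) {
  hot <- intersect(config$artifact_hotspots, panel$name)
  if (n_total <= 0L || length(hot) == 0L) return(NULL)
  amp <- sample(hot, n_total, replace = TRUE)
  ai <- match(amp, panel$name)
  len <- sample(40:79, n_total, replace = TRUE)
  # micro-amplicons form at the junction with the next overlapping amplicon:
  # anchor the artifact so it ends at its amplicon's 3' end
  start <- panel$end[ai] - len + 1L
  start <- pmax(start, 1L)
  seqs <- vapply(seq_len(n_total), function(i) {
    paste(ext_seq[start[i]:(start[i] + len[i] - 1L)], collapse = "")
  }, character(1))
  reads <- data.frame(
    read_id = sprintf("art_r%05d", seq_len(n_total)),
    start = start, length = len,
    mapq = sample(0:20, n_total, replace = TRUE),
    strand = ifelse(stats::runif(n_total) < 0.5, "+", "-"),
    amplicon = amp, seq = seqs, ins = "", stringsAsFactors = FALSE
  )
  reads$seq <- .error_strings(reads$seq, config$base_error_rate)
  reads
}

.error_strings <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  ch <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(ch)
  flat <- unlist(ch, use.names = FALSE)
  flat <- .apply_base_errors(matrix(flat, nrow = 1L), rate)[1, ]
  # rebuild
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  vapply(seq_along(seqs), function(i) {
    paste(flat[starts[i]:ends[i]], collapse = "")
  }, character(1))
}

#' Simulate an amplification negative
#'
#' Zero genuine templates: only micro-amplicon artifact reads at the hotspot
#' amplicons plus a trace uniform background of full-length reads. Defaults
#' reproduce the negative-control picture on the panel: roughly 69% of
#' mapped reads shorter than 80 bp and a residual post-filter depth of about
#' 9 reads per position.
#'
#' @param config A [simulation_config()]; `input_pg` is forced to 0.
#' @param seed Seed (defaults to `config$seed`).
#' @param background_depth Mean depth of the trace background (default 9,
#'   the residual post-filter level seen in negatives).
#' @param artifact_fraction Fraction of mapped reads that are short
#'   artifacts (default 0.69, the negative-control level).
#' @return As [simulate_sample()].
#' @export
simulate_negative <- function(config = simulation_config(), seed = NULL,
                              background_depth = 9, artifact_fraction = 0.69) {
  config$input_pg <- 0
  config$background_depth <- background_depth
  config$artifact_fraction <- artifact_fraction
  simulate_sample(config, seed = seed)
}

#' Write / read simulation truth as JSON
#'
#' @param truth A `SimulationTruth`.
#' @param path File path.
#' @return Writer: `path` invisibly; reader: the truth list.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$php_sites <- as.data.frame(x$php_sites)
  structure(x, class = "SimulationTruth")
}
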