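---
title: "Methods: QC and threshold calling for whole-mtDNA amplicon panels"
author: "mitopanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QC and threshold calling for whole-mtDNA amplicon panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mitopanel` re-implements, as tested reusable code, the analytical workflow
of an internal validation of whole mitochondrial genome sequencing on a
two-pool amplicon panel: artifact read filtering, threshold-based variant
and point-heteroplasmy (PHP) calling, VarFreq-based run QC with a
recurrent-noisy-position blacklist, concordance and coverage reporting, and
a dilution-series sensitivity analysis. Because the underlying instrument
runs are proprietary, every analysis is exercised on synthetic reads from a
bundled simulator whose ground truth makes recovery scoreable. This
vignette documents the models, the parameters that matter, and the design
choices that were genuinely open.

## Coordinates: a circular genome with a linearization extension

The mitochondrial genome is a 16,569 bp circle (rCRS numbering, 1-based).
Aligners want a linear reference, so the workflow aligns against the rCRS
plus a repetition of its first 80 bases appended after position 16,569
("rCRS + 80", 16,649 bp); reads spanning the origin then align contiguously
and `remap_position()` folds extended-axis coordinates back onto the
circle. All public coordinates are 1-based inclusive; BED I/O converts to
0-based half-open at the boundary via `rtracklayer`. Intervals never wrap
internally — an origin-spanning feature becomes two intervals after
remapping, which keeps interval arithmetic total.

The bundled default reference is a seeded random sequence of canonical
length. Every position-level computation in the package is
sequence-agnostic, so nothing depends on the true rCRS bases; the catalog
of noisy positions carries the true rCRS base separately for reporting.

## The amplicon panel and its simulated counterpart

The assayed panel is a two-pool multiplex with amplicons of 125–174 bp
(average 162 bp) tiling the circle. The simulator's default panel uses 164
amplicons (read as 82 primer pairs per pool — artifact hotspot amplicon
names in the validated panel run past `mt_160`, so the pair count is
per-pool) with lengths drawn from N(162, 8²) clamped to 125–174 bp. Note a
geometric constraint: a full tiling requires the mean amplicon length to
exceed circle length divided by amplicon count plus the junction overlap,
so 81 amplicons of at most 174 bp cannot tile 16,569 bp; with 164
amplicons averaging 162 bp the tiling closes with mean junction overlaps
near 60 bp, and the quoted 11 bp is enforced as the *minimum* junction
overlap. `simulate_panel()` rejects infeasible geometries. The final
amplicon crosses the origin and ends inside the 80 nt extension.

## Read filtering: two-cluster analysis of length vs MAPQ

Amplification negatives on such panels are dominated by short, poorly
mapping reads — putative micro-amplicons formed between the forward primer
of one amplicon and the reverse primer of the next, overlapping one. The
workflow characterizes them by k-means with k = 2 on z-score-standardized
(aligned length, MAPQ), 50 restarts under a fixed seed; centroids are
reported in original units and labelled by length order. The derived cutoff
is the mean of the cluster midpoints rounded *up* to a configurable
granularity (a published midpoint of 74.16 bp gives 80 bp at granularity
10). The shipped pipeline default is the literal 80 bp rather than a
re-derived value — reproducibility of the validated workflow first,
adaptivity second. The filter predicate uses length only; MAPQ participates
in clustering and reporting but not in filtering (mirroring the validated
software's constraint), with an optional MAPQ floor available but off.
Read length means the CIGAR-consuming reference span, since micro-amplicon
artifacts are defined by their aligned footprint. Reads with MAPQ 0 are
excluded from clustering but still count among mapped reads.

On small instances (n ≤ 12) the k-means solution is tested against an
exhaustive-partition oracle that enumerates all two-partitions and
minimizes within-cluster sum of squares in the same standardized space.

## The threshold caller

Calling operates on per-position pileups of pre-aligned, filtered reads.
The vendor caller's phylogeny-weighted Smith–Waterman scoring is *not*
reproduced — the validated parameter set is a family of thresholds, and
those are what this package implements:

| parameter | default | meaning |
|---|---|---|
| `min_total_cov` | 20 reads | below it, no-call |
| `min_variant_cov` | 20 reads | minimum reads behind any variant |
| `region_mark_cov` | 20 reads | coverage threshold to mark a region |
| `min_pct_of_amplicon_median` | 5.0 % | low-coverage-region flag |
| `confirm_threshold` | 96.0 % | confirms a homoplasmic call |
| `php_threshold` | 10.0 % | minor allele calling a PHP |
| `ins_threshold` | 20.0 % | insertion allele frequency |
| `del_threshold` | 30.0 % | deletion allele frequency |

The decision cascade is: no-call on depth; reference if the top base is the
reference at ≥ 96%; substitution if a non-reference top base reaches 96%
with sufficient reads; PHP if the second base reaches 10% with sufficient
reads (reported as the IUPAC code of the top two bases, with the minor
frequency as the variant frequency); deletion at ≥ 30% DEL allele;
insertions are evaluated independently of the base call and anchored to the
preceding canonical position (`309.1C`, `524.AC`). The ordering of the
confirm-vs-PHP steps is this package's choice (the validated software lists
thresholds without an order); the two cannot actually conflict because
96% + 10% exceeds 100%. Ties between equal-count alleles resolve by
reference preference, then lexicographic base order — deterministic and
documented rather than platform-dependent. Homopolymer stretches
(np 303–310 and 16,184–16,193 by default) are flagged, not suppressed.
Strand bias is flagged when the minority strand carries less than 10% of
the variant-supporting reads. Variant frequencies are computed on
unrounded counts and displayed to one decimal.

Haplotypes are emitted in EMPOP-style notation (`263G`, `7861Y`, `249DEL`,
`309.1C`, `524.AC`) and round-trip through `parse_haplotype()`.

## VarFreq, the ECDF, and the blacklist

VarFreq ("haplotype purity") at a position is the percentage of reads
supporting the consensus allele — for PHPs, the major allele; the catalog
of recurrent noisy positions (values 54–90%) is only consistent with this
major-allele reading. Reads carrying a *minority* insertion anchored at a
position count against the consensus there (the catalog lists INS as the
second most common variant at two sub-90% positions, which forces this
semantics); a consensus-level insertion is itself the supported state.

The empirical cumulative distribution is computed on the integer grid
0–99: positions at exactly 100 contribute to no grid point but remain in
the denominator, matching the 0–99 reporting range. Whether a published
"below 99%" count means `< 99` or `≤ 98` is ambiguous on a continuous
scale; `varfreq_counts()` reports both, and on the integer grid they agree.

A position enters the blacklist when its mean VarFreq across the
replicates of a sample falls below 90% in at least `min_samples = 2`
*distinct sample groups* — recurrence across samples, not merely across
replicates of one sample. This gate is what keeps genuine heteroplasmies
(present in one sample only) off the blacklist. The packaged catalog of 26
recurrent positions, with per-control means/SDs, second alleles and NUMT
annotations, ships as the default annotation list and as the simulator's
default noise model.

The blacklist performance experiment injects the catalogued means at the
catalogued positions into two simulated sample groups but with a
replicate-level SD of 1 percentage point, and computes recall over
positions whose configured means are ≤ 88% in both groups. The catalogued
SDs (up to 24 points) include run- and lot-level effects the simulator does
not model; under them, positions whose true mean sits within roughly two
group-mean standard errors of the 90% threshold cannot be recovered with
certainty by any estimator, so a perfect-recall criterion would be
measuring sampling luck rather than the detector. Precision counts any
blacklisted position that was genuinely injected (catalog or homopolymer
noise) as a true positive.

Coverage uniformity is the fraction of positions at or above 0.2× the mean
depth — the platform convention, exposed as a knob since the validated
workflow never defines it.

## Run-reliability classification

The cumulative VarFreq distribution separates reliable from stochastic
runs. The classifier is deliberately simple: an empirical min/max envelope
of at least three known-good replicate ECDFs over the grid window 93–99,
and a distance equal to the largest upward exceedance of the envelope's
upper edge; a run is stochastic when the distance exceeds 0.005 (absolute
proportion). No parametric model is fitted — the diagnostic was proposed
without formalization, so the simplest envelope test is used and the
tolerance is exposed. A replicate with no covered positions is classified
stochastic by convention (total dropout is maximal stochasticity). At the
default tolerance the classifier is conservative: simulated runs at
0.6–0.15 pg already exceed the envelope slightly, while the acceptance
requirement — full-input runs inside their own band, 0.075 pg and below
clearly outside — holds with a comfortable margin.

## The simulator

`simulate_sample()` generates the statistical structure the analyses
assume, and records everything it injects:

1. **Templates.** N ~ Poisson(copies), with copies = input_pg / 100 × 2900
   (the platform's conversion; the validation itself notes this
   approximation understates real mtDNA content, which is why simulated
   deep-dilution coverage drops somewhat earlier than the instrument's).
2. **Heteroplasmy at template level.** Each template carries each PHP's
   alternate allele independently with probability equal to the true
   frequency. This is the central modelling choice: assigning alleles at
   read level would understate low-input variance, and the template-level
   mechanism is what makes PHP quantification collapse into quantized,
   all-or-nothing behaviour below ~10 copies. Defaults: a 17% site at
   7861, plus sites at 1393 (3.2%) and 3242 (0.7%) that sit below the 10%
   threshold — the frequencies the platform *measured* for these sites.
3. **Fixed sequencing budget.** Per amplicon, templates are captured by
   binomial thinning (p = 0.9) and the read count is Poisson(target depth ×
   amplicon bias), spread uniformly over captured templates — equivalent to
   iid Poisson per template conditioned on the total. The budget is fixed
   because libraries are pool-normalized on the real workflow; a constant
   reads-per-template mode (`reads_per_template`) is also available.
   Per-amplicon bias is lognormal with CV 0.3, a deliberately uncalibrated
   knob (no per-amplicon bias figures exist for the panel). The default
   target of 400 reads per amplicon is a desk-scale stand-in for the
   instrument's ~1,250; with ~60 bp junction overlaps it yields ~650×
   base coverage, comfortably above every threshold while keeping the full
   13 × 3 ladder under three minutes on one CPU.
4. **PCR jackpot errors.** Per captured template and amplicon, cycle-c
   errors arise as Poisson(2^(c−1) × μ × L) events each carried by a
   fraction 2^−c of that template's reads (μ = 10⁻⁴ per base per cycle,
   Taq-scale; 8 cycles tracked). With thousands of founders these
   subclones are invisible; with few founders they surface as positions at
   93–99% purity — the mechanism behind the low-input degradation of the
   cumulative VarFreq curve. Events whose expected affected read count is
   below half a read are not simulated (they are unobservable; this is an
   exact truncation, not an approximation).
5. **Recurrent noise.** At each catalogued position a per-sample noise
   fraction ~ N(100 − mean VarFreq, SD)/100, truncated to [0, 1], of reads
   carries the second allele (DEL, INS or base). Noise alleles inside the
   strand-bias region (np 8248–8256) ride the forward strand only.
   Homopolymer positions receive single-base deletion noise at ~10% of
   reads.
6. **Artifacts.** Micro-amplicon reads (40–79 bp, MAPQ 0–20) are anchored
   at the 3' junctions of five hotspot amplicons; genuine reads carry MAPQ
   40–60. The disjoint MAPQ ranges make the clustering test well-posed; an
   overlap knob exists for stress testing. Amplification negatives are
   zero templates plus artifacts at 69% of mapped reads and a trace
   uniform background leaving ~9× residual depth after filtering.

Reads are emitted in a plain-text table (read_id, start, length, mapq,
strand, amplicon, seq, ins) where `seq` holds reference-aligned bases with
`-` for deletions and `ins` holds anchored insertions; `write_sam()`
converts to standard SAM/CIGAR for inspection with external tools.
Identical config and seed give byte-identical output.

## Scoring against truth, and what passing does not show

`score_replicate()` counts false positives (calls absent from truth),
false negatives (truth variants missed at covered positions) and—
separately — calls at the injected recurrent-noise positions. The
separation matters: at catalogued noise levels a threshold caller *will*
call deletions at several blacklist positions (e.g. a 46% DEL fraction
exceeds the 30% threshold), and the validated workflow's answer is the
blacklist, not the caller. Treating those as ordinary false positives
would contradict the workflow being modelled, whose zero-false-positive
operation was achieved by a caller that does not call these positions and
by flagging them for cautious interpretation. `compare_haplotypes()`
accordingly accepts a blacklist to exclude; PHP-vs-homoplasmy mismatches
count as concordant-with-note unless strict mode is on, and control-region
comparisons use the forensic preset np 16,024–16,569 plus 1–576.

The simulator emulates template sampling, fixed-budget amplification,
clonal PCR error, catalogued recurrent noise and micro-amplicon artifacts.
It does not emulate flow-space signal, PCR chimeras, per-base quality
realism, primer-binding-site polymorphisms, or run/lot-level effects —
so passing recovery tests demonstrates the *pipeline's* correctness under
the stated generative model, not instrument-level accuracy on real data.

## Statistical form of the monotonicity checks

Completeness and the run-quality distance are monotone in expectation in
template copy number, but with three replicates per dilution their
dilution means are noisy — coverage at one to two copies is bimodal (total
dropout vs near-complete), putting the standard error of a dilution mean
as high as ~25 points. A literal "every adjacent step monotone" test at
that sample size is a coin flip on upticks of a fraction of a point. The
suite therefore requires each adjacent step to be monotone within two
standard errors of the difference, plus unambiguous endpoint conditions
(100% coverage and zero distance at full input; sub-90% mean coverage and
clearly band-exceeding distances in the deepest dilutions). The same
reasoning moves the 17%-PHP recovery claim onto medians: single-replicate
estimates inherit ~±2-point template-sampling spread even at full input.

## Problem sizes

Tests and the acceptance script run the full 13-dilution × 3-replicate
ladder at 400 reads per amplicon (~70,000 reads per sample), the blacklist
experiment at 600, and scaled-down property checks on a 3 kb toy circle
where noted; the complete suite runs in about five minutes on one CPU.

## Known limitations

* The copy-number equation is taken at face value; the validation itself
  calls it an unrealistic approximation, and simulated deep dilutions
  (≤ 0.0375 pg) accordingly drop out faster than the instrument did.
* The per-negative cluster midpoints and their confidence intervals are
  not reproducible without the raw reads; the simulator exposes the
  generating parameters instead, and its artifact length range (40–79 bp)
  yields a higher cluster midpoint than the published 74.16 bp.
* The blacklist threshold test cannot certify positions whose true mean
  purity sits against the 90% threshold; they are flagged but excluded
  from recall accounting.
* No probabilistic PHP model and no formal statistical test for run
  reliability — both named as future work by the validation; the envelope
  distance is a diagnostic, not a hypothesis test.
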