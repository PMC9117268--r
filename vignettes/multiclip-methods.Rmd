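---
title: "Models and methods behind multiclip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind multiclip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiclip)
```

# The problem

Multidomain RNA-binding proteins such as the 15-KH-domain vigilin family
bind their targets through several weak contacts at once. In PAR-CLIP
data this shows up as clusters of T→C transitions over CU-rich elements,
and the number of binding elements within reach of a crosslink — its
*multivalency* — predicts binding strength better than any single motif
match. multiclip implements the quantitative pipeline downstream of
alignment: reproducibility filtering of crosslink evidence,
expression-corrected binding summaries, mRNA localization classes from
fractionation RNA-seq, k-mer and multivalency statistics, ribosome
profiling metagenes and codon occupancy shifts, and the filters for the
companion tRNA-seq, BioID and pulsed-SILAC assays.

All coordinates are 0-based half-open internally (BED convention) and in
transcript space on the sense strand; protein coordinates and
human-facing reports are 1-based inclusive. Sequences are stored in the
DNA alphabet; k-mers are displayed with U.

# Crosslink evidence

A position is a reproducible crosslink site when it carries at least one
T-C transition in both replicates and its *transition specificity*
(T-C count / coverage) stays below 0.95 in both; near-1 specificity marks
a genomic variant, not a crosslink. Clusters are reproducible when a
replicate pair overlaps by at least 50% of their length, their T-C peaks
lie at most 10 nt apart, and the pair's mean T-C sum is at least 3. All
three thresholds are boundary-inclusive.

Two readings of "overlap by at least 50% of their length" are possible;
we use the *reciprocal* reading (both clusters must reach the fraction)
because it is symmetric and stricter, with `overlap_mode = "either"`
available. Kept clusters are reported with the replicate-1 interval
(`kept_coords = "union"` available); when a replicate-1 cluster has
several passing partners, the partner with the highest mean T-C wins,
ties going to the earlier cluster. Peak-position ties within a cluster
break toward the smaller coordinate.

Library-size normalization converts T-C counts to T-C per million. The
library total is by convention the replicate's total number of T-C
events rather than its total mapped reads: the former is computable from
the tables the package consumes, and only relative scales matter
downstream.

Gene-level summaries sum per-site T-C (mean of the replicates) by
region; the split exactly conserves the total. The crosslink enrichment
E = TC/TPM corrects for expression; it is undefined (NA) for TPM 0. The
CDS-vs-3'UTR ratio uses a pseudocount of 0.5 on both region sums so that
genes with zero 3'UTR crosslinks remain comparable; genes without a
3'UTR are excluded (NA). Crosslink groups ("low"/"mid"/"high") cut a
configurable gene-level statistic at (0.3, 1.39); the scale of those
cutoffs is not fixed by any invariant, so the statistic is a
configuration choice, defaulting to log2(E + pseudocount) with raw E and
raw TC available.

The meta-transcript profile maps sites to fixed per-region bins
(100/300/200 for 5'UTR/CDS/3'UTR by default) because transcripts differ
in length; per transcript the signal is scaled to its own maximum (so
every included transcript attains exactly 1), a bin takes the maximum
scaled signal of the sites it contains, and bins are averaged over all
included transcripts — the averaged profile therefore lies in [0, 1].
Transcripts below 5 T-C per million in either replicate are excluded.

# Localization classes

Size factors are median-of-ratios: per-gene geometric-mean reference
over samples, excluding genes with any zero count, per-sample median of
count/reference. TPM is (count/length) normalized to one million; since
one isoform per gene is enforced, no EM over isoforms is needed.
Membrane enrichment M is the log2 ratio of mean normalized membrane
counts over mean normalized cytosol counts, pseudocount 1 on both means;
the ratio of means is the default (mean of per-pair ratios available).
Shrinkage of fold changes is deliberately not applied — at the depths
where classification is attempted (TPM ≥ 10) it would only compress the
bimodal separation the classes rest on.

Classification: membrane iff M ≥ 1.5, cytosolic iff M ≤ 0.5, undefined
between, excluded below TPM 10; the cutoffs are inclusive. The
targeting-signal classes use the precedence mtDNA ("MT-" symbol prefix)
→ tail-anchored (TM, no SP, first TM within 50 aa of the C-terminus) →
SP+TM → SP-only → TM-only → nuclear-encoded mitochondrial →
membrane-localized without signal → no signal.

# K-mer and multivalency statistics

A crosslinked k-mer count assigns, for each site, one count to every
k-window of the transcript overlapping the crosslinked nucleotide — up
to k windows, truncated at transcript ends. Whether one should count a
single register or all overlapping registers is ambiguous; all-overlap
is the default (`register = "start"` selects the single register)
because a crosslink anywhere inside a CU repeat should credit the
repeat, not one arbitrary phase of it. For the per-gene normalized
signal a site contributes its T-C once per k-mer *type* regardless of
how many of its windows spell that k-mer, then sums are divided by
region length and whole-cell TPM.

The multivalency score of a site counts occurrences (by start
coordinate, overlapping occurrences all counting) of a four-mer group
within ±40 nt, excluding the open innermost zone (−4, +4) — occurrences
starting exactly 4 nt away count. The exclusion exists because the
site's own element would otherwise dominate every window. Sites are
sorted by (score, transcript, position) and split into five contiguous
near-equal bins (sizes differ by at most 1); the same exclusion zone is
applied to the window T-C signal attached to each site, again so the
anchor's own signal does not swamp the neighborhood. Per-bin positional
profiles report the percentage of window T-C at each of the 81 offsets
and sum to 100 by construction.

Sequence-level z-scores standardize per-k-mer frequency differences
between two sequence sets over all 4^k k-mers; if the standard deviation
is zero (identical sets) all z are defined as 0. Group comparisons use
the standard two-sided Wilcoxon rank-sum test. The sliding-window
potential counts group occurrences in 30-nt windows stepping 1 nt,
discards windows with fewer than 3 hits (a single isolated element is
not multivalent), and averages kept windows per transcript, 0 when none
survive.

# Ribosome profiling

P-sites are footprint 5' ends plus a fixed 13-nt offset; length-
stratified offsets are out of scope. Reads whose shifted position leaves
the transcript are dropped but counted, so totals are conserved. The
start/stop metagene scales each transcript's per-nt coverage by its
trimmed-CDS mean (first and last two codons excluded, as initiation and
termination peaks would dominate the normalization), excludes
transcripts with total codon coverage below 5, averages across
transcripts and smooths with a centered 10-nt rolling mean; rolling
windows shrink at the edges rather than padding. The targeting-signal
metagene normalizes codon coverage to the mean over codons 20–40,
averages codons 1–500 over transcripts with TPM ≥ 10 grouped by signal
kind, and smooths over 5 positions; transcripts with zero coverage in
the normalization window are excluded.

Codon occupancy shifts weight each sense codon by footprint counts at
the P-site (E-site = P-site codon − 1), normalize to the 61 sense codons
so each replicate's frequencies sum to 1, and report mean(KO) −
mean(WT) per codon with the SD of per-replicate-pair differences; the
61 shifts sum to 0 exactly. Frequencies are footprint-weighted rather
than per-transcript-averaged: dwell differences express themselves per
ribosome, and weighting by footprints measures exactly that. The
translation-efficiency contrast is the log2 ratio of ratios of
size-factor-normalized condition means with pseudocount 1 — a point
estimate supporting distribution comparisons between gene groups, not a
test statistic; it is antisymmetric under swapping conditions.

# Auxiliary assays

tRNA enrichment divides library-size-normalized T-C by normalized
abundance reads per tRNA. Dihydrouridine positions cause
reverse-transcription misincorporation indistinguishable from
crosslinking and are masked *before* summation. The BioID filter
applies, per replicate pair (Dox 1/untreated 2, Dox 2/untreated 2,
Dox 3/untreated 3 — the first pairing reuses untreated batch 2, as only
two untreated batches exist), enrichment ≥ 3 on raw ratios and log2 Dox
LFQ ≥ 27, substituting the LFQ criterion alone when the untreated
intensity is zero; at least 3 razor unique peptides are required, and
all three pairs must pass. Display enrichment for zero-denominator
groups is the table-wide maximum mean log2 enrichment plus 2. pSILAC
pairs quantified from two requantified intensities are removed; reverse-
orientation ratios are negated onto the KO/WT scale (the labels are
swapped in the reverse experiment; `invert_reverse = FALSE` disables
this), and proteins need values from both orientations. RIP fold
enrichment is 2^(Ct_control − Ct_bait): lower Ct means more template, so
the control-minus-bait order yields values above 1 for enriched RNAs;
the reverse order is available as an option.

# The synthetic-data generator

The generator produces the statistical structure the analyses assume,
with planted truth that every stage must recover:

* **Transcripts.** One isoform per gene; 5'UTR 60–150 nt, CDS 450–1200 nt
  (a multiple of 3), 3'UTR 150–450 nt over a uniform background.
  Class composition is deterministic from the fractions (default
  0.4/0.4/0.2 membrane/cytosolic/undefined).
* **Motifs.** The CU-rich four-mer set UUCU/CUUC/UCUU/CUCU. Membrane
  CDS receives hotspots (3 per kb) of 2–4 motifs within a 40-nt span;
  cytosolic and undefined transcripts receive sparse single motifs
  (1 per kb) split between CDS and 3'UTR. Membrane transcripts carry a
  targeting signal — signal peptides of 20–24 aa (human signal peptides
  cluster tightly around 22 aa) or a TM helix starting at aa 35–55.
* **PAR-CLIP.** Coverage is Poisson with mean depth × relative
  abundance; T-C counts are Binomial with success probability growing
  with crosslink propensity. Propensity is concentrated on uridines
  *inside* motif occurrences and grows with the local multivalency score
  (0.5 + m inside a motif, 0.15 m within reach of one, 0 elsewhere,
  squashed by w/(w+1)) — PAR-CLIP crosslinks form at the protein
  contact, and multivalent context stabilizes the contact. A sequencing
  error floor (1e-4) adds rare background conversions. Clusters are
  emitted around planted hotspots with replicate-jittered boundaries.
* **Fractionation counts.** Negative Binomial (Poisson at dispersion 0)
  with per-gene means split between fractions by the planted enrichment:
  class means +2.5 (membrane), −1.0 (cytosolic), 0 (undefined), per-gene
  SD 0.3. Note that planted "undefined" genes sit at M ≈ 0, inside the
  cytosolic zone of the classifier; label recovery is therefore
  meaningful only for the membrane and cytosolic classes, and is
  reported over those.
* **Footprints.** Per-codon Poisson counts; WT multiplies a 10-codon
  window starting at the signal-end codon by 2.0, KO by 1.2; KO
  additionally multiplies CUU/CUC/UUC/UUU dwell by 1.3. An optional
  `te_coupling` parameter couples planted motif load to a per-gene KO
  translation deficit; it defaults to 0 so that codon-composition
  effects are not confounded by gene-level scaling.
* **tRNA / proteomics.** One tRNA carries a 3× crosslink excess, one is
  "modification-only" (no genuine crosslinking); all tRNAs receive
  condition-independent conversion noise at masked dihydrouridine
  positions (rate 0.10) and a small sequencing-error floor (0.002)
  elsewhere. The BioID table plants 20 true positives at ratio 8 above
  intensities chosen to clear the log2-27 filter; SILAC pairs come in
  both orientations with a 15% requantification rate per intensity.

One global seed expands into fixed per-stage sub-seeds
(`stage_seed()`), so every simulator is byte-identical across reruns
and stages can be regenerated independently.

What the generator does **not** emulate: PCR duplicates and UMIs,
read-length effects and alignment artifacts, isoform mixtures,
sequence-composition bias in coverage, overdispersion in footprint
counts, and correlated noise between fractions. Passing recovery tests
therefore demonstrates that the implementations measure what they claim
under the stated noise models, not that the thresholds are optimal for
any particular real library.

# Problem sizes and numerical choices

The test suite runs the generator at 100–500 genes and coverage depths
of 40–50×, sizes at which every planted effect is unambiguous while a
full run of all stages completes in well under a minute; the acceptance
script uses 300 genes. Oracle-equivalence checks compare against plain
nested-loop reimplementations on 100 random instances per operation.
Exact identities (region sums, TPM totals, profile percentages, count
conservation, zero-sum codon shifts) are asserted without tolerance;
stochastic recoveries use the margins stated in the test descriptions.
Degenerate inputs error early and explicitly: zero library totals,
CDS shorter than twice the metagene trim, pause windows past the CDS,
coverage 0 with T-C > 0, malformed intervals, unknown configuration
keys.
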