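# multiclip

Downstream analysis of PAR-CLIP experiments for multivalent RNA-binding
proteins, together with the companion assays used to interpret them:
fractionation RNA-seq, ribosome profiling, tRNA-seq, BioID and pulsed
SILAC. The package is aimed at computational biologists who have already
aligned their reads and hold per-position pileup tables, cluster calls and
count matrices in transcript coordinates, and who need the bespoke
statistics downstream of alignment implemented in a tested, reusable form.

## What it computes

**Crosslink quantification.** PAR-CLIP marks protein–RNA contacts by
T→C transitions at crosslinked uridines. `filter_sites()` retains
positions with T-C evidence in both replicates and transition specificity
(T-C count / coverage) below 0.95, removing genomic variants.
`filter_reproducible_clusters()` keeps cluster pairs that overlap
reciprocally by ≥ 50% of their length, whose T-C peaks lie ≤ 10 nt apart,
and whose mean T-C count is ≥ 3. Gene-level summaries divide total
crosslinks by whole-cell TPM (enrichment *E* = TC/TPM) and report the
log2 CDS-vs-3'UTR crosslink density ratio.

**Localization classes.** From membrane/cytosol fractionation counts,
`membrane_enrichment()` computes M = log2(membrane/cytosol) on
median-of-ratios-normalized means, and `classify_localization()` calls
transcripts membrane-bound (M ≥ 1.5), cytosolic (M ≤ 0.5) or undefined,
for genes with TPM ≥ 10. `classify_targeting()` assigns
targeting-signal classes (mtDNA, tail-anchored, SP/TM combinations) from
protein-coordinate annotations.

**K-mer multivalency.** `count_crosslinked_kmers()` counts every k-window
overlapping a crosslink; `multivalency_scores()` counts occurrences of a
four-mer group in ±40 nt around each site (the innermost ±4 nt excluded)
and bins sites into five equal groups — the score is a proxy for how many
protein domains can engage the region simultaneously.
`sliding_window_potential()` scores raw sequences by the same logic in
30-nt windows, keeping windows with ≥ 3 group hits.

**Ribosome profiling.** `apply_psite_offset()` (13 nt),
`metagene_start_stop()`, `metagene_targeting_signal()` (scaled to codons
20–40, revealing elongation pauses downstream of signal peptides and TM
helices), `codon_occupancy_shift()` (P-/E-site codon frequency changes
between conditions) and a normalized `translation_efficiency()` contrast.

**Auxiliary assays.** `trna_enrichment()` (crosslink / abundance per tRNA
with dihydrouridine positions masked), `bioid_filter()` (per-replicate
enrichment ≥ 3, log2 LFQ ≥ 27, ≥ 3 razor peptides), `psilac_aggregate()`
(label-swap-aware ratio averaging) and `rip_fold_enrichment()`.

**Synthetic data.** `simulate_transcriptome()` and its companions plant
CU-rich motif hotspots in the CDS of membrane-class transcripts, bimodal
membrane enrichment, an elongation pause after each targeting signal,
per-codon dwell changes, tRNA crosslink excess and a BioID true-positive
set — so every stage of the pipeline can be verified against a known
ground truth without any deposited data. All simulators are deterministic
given a seed.

## Worked example

```r
library(multiclip)
res <- run_synthetic_pipeline(seed = 1, n_genes = 300)
res$metrics[c("localization_recovery", "top_fourmer",
              "planted_in_top5", "trna_top")]
#> $localization_recovery
#> [1] 0.9958333
#> $top_fourmer
#> [1] "TCTT"
#> $planted_in_top5
#> [1] 4
#> $trna_top
#> [1] "tRNA01"
round(res$metrics$bin_window_tc, 1)
#>     1     2     3     4     5
#> 194.2 249.2 310.9 391.5 575.6
```

With the default planted structure, 99.6% of membrane/cytosolic labels
are recovered from the simulated fractionation counts, the top-ranked
crosslinked four-mer is one of the four planted CU-rich motifs (UCUU
here), four of the top five ranks are planted motifs, the mean window T-C
signal rises monotonically across the five multivalency bins (sites in
the most multivalent contexts carry ~3× the local crosslink signal of the
least), and the tRNA with the planted 3× crosslink excess ranks first.

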