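Package: multiclip
Title: Crosslink Quantification, Multivalency Scoring and Localization
    Analysis for PAR-CLIP and Fractionation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of protein-RNA crosslinking (PAR-CLIP)
    experiments together with companion assays: reproducibility filtering of
    T-C transition sites and clusters, gene-level crosslink summaries
    normalized by expression, membrane/cytosol mRNA localization
    classification from fractionation RNA-seq, crosslinked k-mer counting and
    motif multivalency scoring, ribosome-profiling P-site metagenes and codon
    occupancy shifts, tRNA crosslink enrichment with modification masking,
    and proximity-labeling (BioID) and pulsed-SILAC proteomics filters. A
    synthetic-data generator with planted ground truth makes every stage of
    the pipeline testable without access to deposited sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
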