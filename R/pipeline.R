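#' Run the full synthetic end-to-end pipeline
#'
#' Simulates a transcriptome with planted structure and all downstream raw
#' tables, then runs every analysis stage: reproducible cluster and site
#' filtering, library-size normalization, gene-level crosslink summaries,
#' meta-transcript profile, fraction counts to localization classes,
#' crosslinked k-mer ranking, multivalency binning, sliding-window
#' potential, targeting-signal metagene, codon occupancy shift, tRNA
#' enrichment, BioID filter and pSILAC aggregation. Returns the
#' intermediate objects plus summary metrics comparing the recovered
#' quantities with the planted truth.
#'
#' @param seed Integer seed driving every stage.
#' @param n_genes Number of simulated genes.
#' @param depth PAR-CLIP coverage depth.
#' @param conv_rate 4SU conversion rate.
#' @param footprint_depth Mean footprints per codon.
#' @param quiet Suppress progress messages.
#' @return A list of stage outputs and a \code{metrics} list.
#' @export
run_synthetic_pipeline <- function(seed = 1L, n_genes = 300L, depth = 50,
                                   conv_rate = 0.25, footprint_depth = 2,
                                   quiet = TRUE) {
  say <- function(...) if (!quiet) message(...)
  say("simulating transcriptome")
  sim <- simulate_transcriptome(n_genes = n_genes, seed = seed)
  tx <- sim$transcriptome
  truth <- sim$truth

  say("simulating PAR-CLIP")
  pc <- simulate_parclip(tx, truth, depth = depth, conv_rate = conv_rate,
                         seed = seed)
  clusters <- filter_reproducible_clusters(pc$clusters[[1L]],
                                           pc$clusters[[2L]])
  sites <- filter_sites(pc$pileups[[1L]], pc$pileups[[2L]], tx)
  lib <- c(sum(pc$pileups[[1L]]$tc_count), sum(pc$pileups[[2L]]$tc_count))
  sites <- normalize_tc_per_million(sites, lib)

  say("fraction counts and localization")
  counts <- simulate_fraction_counts(tx, truth, seed = seed)
  lens <- attr(counts, "lengths")
  tpm_wc <- compute_tpm(counts[, "wholecell"], lens)
  M <- membrane_enrichment(counts,
                           membrane = c("membrane_1", "membrane_2"),
                           cytosol = c("cytosol_1", "cytosol_2"))
  cls <- classify_localization(M, tpm_wc)
  planted <- truth$classes$class[match(names(cls), truth$classes$gene_id)]
  considered <- cls != "excluded" & planted %in% c("membrane", "cytosolic")
  recovery <- mean(cls[considered] == planted[considered])
  km <- stats::kmeans(M, centers = 2L, nstart = 5L)
  bimodal_sep <- abs(diff(km$centers[, 1L]))

  say("gene-level crosslink summary")
  summary_genes <- summarize_gene_crosslinks(sites, tx, tpm_wc)
  meta <- meta_transcript_profile(sites, tx)

  say("k-mer and multivalency analysis")
  kc <- count_crosslinked_kmers(sites, tx, k = 4L)
  top10 <- kc$overall$kmer[seq_len(min(10L, nrow(kc$overall)))]
  mv <- multivalency_scores(sites, tx, top10)
  swp <- sliding_window_potential(tx, truth$motif_set)
  cmp <- compare_window_potential(swp)

  say("ribosome profiling")
  fp <- simulate_footprints(tx, truth, depth = footprint_depth,
                            seed = seed)
  ps <- lapply(c("WT", "KO"), function(cond)
    lapply(fp[[cond]], function(r) apply_psite_offset(r, tx)$psites))
  names(ps) <- c("WT", "KO")
  tpm_by_tx <- stats::setNames(tpm_wc[tx$transcripts$gene_id],
                               tx$transcripts$transcript_id)
  mg_wt <- metagene_targeting_signal(ps$WT[[1L]], tx, tpm_by_tx)
  mg_ko <- metagene_targeting_signal(ps$KO[[1L]], tx, tpm_by_tx)
  shift <- codon_occupancy_shift(ps$WT, ps$KO, tx, site = "P")

  say("tRNA and proteomics")
  aux <- simulate_trna_and_proteomics(truth, seed = seed)
  trna <- trna_enrichment(aux$trna$pileup, aux$trna$abundance,
                          aux$trna$masks)
  bioid <- bioid_filter(aux$bioid)
  silac <- psilac_aggregate(aux$silac)

  top_delta <- shift$codon[order(-shift$delta)][1:5]
  metrics <- list(
    n_genes = n_genes,
    localization_recovery = recovery,
    enrichment_mode_separation = as.numeric(bimodal_sep),
    n_reproducible_clusters = nrow(clusters),
    n_reproducible_sites = nrow(sites),
    top_fourmer = kc$overall$kmer[1L],
    top_fourmer_planted = kc$overall$kmer[1L] %in% truth$motif_set,
    planted_in_top5 = sum(kc$overall$kmer[1:5] %in% truth$motif_set),
    bin_window_tc = mv$bin_window_tc,
    sliding_window_p = cmp$p.value,
    median_ratio_membrane = stats::median(
      summary_genes$log2_cds_utr3_ratio[
        tx$transcripts$localization_class == "membrane"], na.rm = TRUE),
    median_ratio_cytosolic = stats::median(
      summary_genes$log2_cds_utr3_ratio[
        tx$transcripts$localization_class == "cytosolic"], na.rm = TRUE),
    top5_delta_codons = top_delta,
    trna_top = trna$trna_id[1L],
    bioid_recovered = mean(aux$truth$true_positive_proteins %in%
                             bioid$protein_group[bioid$enriched])
  )
  list(transcriptome = tx, truth = truth, clusters = clusters,
       sites = sites, counts = counts, tpm = tpm_wc, enrichment = M,
       classes = cls, gene_summary = summary_genes, meta_profile = meta,
       kmer_counts = kc, multivalency = mv, window_potential = swp,
       psites = ps, metagene_wt = mg_wt, metagene_ko = mg_ko,
       codon_shift = shift, trna = trna, bioid = bioid, silac = silac,
       metrics = metrics)
}
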