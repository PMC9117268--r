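#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median across genes of
#' the ratio of each count to the per-gene geometric mean over samples;
#' genes with a zero count in any sample are excluded from the reference.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least two samples")
  if (any(counts < 0)) stop("negative counts")
  ok <- rowSums(counts == 0) == 0L
  if (!any(ok)) stop("no gene with all-positive counts")
  logc <- log(counts[ok, , drop = FALSE])
  ref <- rowMeans(logc)
  apply(exp(logc - ref), 2L, stats::median)
}

#' Transcripts-per-million normalization
#'
#' \code{TPM_g = (counts_g / len_g) / sum_g(counts_g / len_g) * 1e6};
#' sums to 1e6 per sample.
#'
#' @param counts Numeric vector or matrix (genes x samples).
#' @param lengths Per-gene effective lengths (nt), positive.
#' @return Same shape as \code{counts}.
#' @export
compute_tpm <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("non-positive length")
  if (is.matrix(counts)) {
    rate <- counts / lengths
    sweep(rate, 2L, colSums(rate), "/") * 1e6
  } else {
    rate <- counts / lengths
    rate / sum(rate) * 1e6
  }
}

#' Membrane-to-cytosol enrichment
#'
#' Log2 ratio of mean size-factor-normalized membrane counts to mean
#' normalized cytosol counts, with a pseudocount added to both means. By
#' default the ratio of means over replicates is used; \code{mean_mode =
#' "mean_of_ratios"} averages per-replicate-pair log2 ratios instead.
#'
#' @param counts Count matrix genes x samples.
#' @param membrane,cytosol Column names (or indices) of the replicate
#'   samples of each fraction.
#' @param pseudocount Added to both normalized means (normalized counts).
#' @param mean_mode "ratio_of_means" (default) or "mean_of_ratios".
#' @return Named numeric of per-gene log2 enrichment M.
#' @export
membrane_enrichment <- function(counts, membrane, cytosol,
                                pseudocount = 1,
                                mean_mode = c("ratio_of_means",
                                              "mean_of_ratios")) {
  mean_mode <- match.arg(mean_mode)
  counts <- as.matrix(counts)
  sub <- counts[, c(membrane, cytosol), drop = FALSE]
  sf <- size_factors(sub)
  norm <- sweep(sub, 2L, sf, "/")
  nm <- length(membrane)
  memn <- norm[, seq_len(nm), drop = FALSE]
  cytn <- norm[, nm + seq_along(cytosol), drop = FALSE]
  if (mean_mode == "ratio_of_means") {
    M <- log2((rowMeans(memn) + pseudocount) /
                (rowMeans(cytn) + pseudocount))
  } else {
    npair <- min(ncol(memn), ncol(cytn))
    lr <- sapply(seq_len(npair), function(i)
      log2((memn[, i] + pseudocount) / (cytn[, i] + pseudocount)))
    M <- rowMeans(lr)
  }
  stats::setNames(as.numeric(M), rownames(counts))
}

#' Classify mRNA localization from membrane enrichment
#'
#' Membrane when M >= \code{hi}, cytosolic when M <= \code{lo}, undefined
#' in between; genes with whole-cell TPM below \code{min_tpm} are excluded
#' regardless of M. Boundaries are inclusive.
#'
#' @param M Named numeric of log2 membrane enrichment.
#' @param tpm Whole-cell TPM, same order/names.
#' @param hi,lo Classification cutoffs.
#' @param min_tpm Minimum TPM for inclusion.
#' @return Character vector: "membrane", "cytosolic", "undefined",
#'   "excluded".
#' @export
classify_localization <- function(M, tpm, hi = 1.5, lo = 0.5,
                                  min_tpm = 10) {
  out <- ifelse(tpm < min_tpm, "excluded",
                ifelse(M >= hi, "membrane",
                       ifelse(M <= lo, "cytosolic", "undefined")))
  stats::setNames(out, names(M))
}

#' Targeting-signal gene classes
#'
#' Assigns each gene one class by precedence: mtDNA-encoded ("MT-" gene
#' symbol prefix); tail-anchored (TM helix, no signal peptide, first TM
#' starting 50 or fewer amino acids from the C-terminus); SP_and_TM;
#' SP_only; TM_only; mito_nuclear (from the provided nuclear-encoded
#' mitochondrial list); membrane_no_TS (membrane-localized with no signal);
#' no_TS otherwise.
#'
#' @param genes Data frame with \code{gene_id}, \code{gene_symbol},
#'   \code{protein_length} (aa) and \code{localization_class}.
#' @param signals Data frame with \code{gene_id}, \code{kind}
#'   ("signal_peptide"/"tm_helix"), \code{aa_start}, \code{aa_end}.
#' @param mito_genes Character vector of nuclear-encoded mitochondrial gene
#'   symbols.
#' @param tail_anchor_max_dist Maximum C-terminal distance (aa) of the
#'   first TM helix for the tail-anchored call.
#' @return Character vector of ts_class per gene, named by gene_id.
#' @export
classify_targeting <- function(genes, signals,
                               mito_genes = character(),
                               tail_anchor_max_dist = 50L) {
  if (nrow(signals)) {
    idx <- match(signals$gene_id, genes$gene_id)
    if (any(signals$aa_end > genes$protein_length[idx] + 1L)) {
      stop("targeting signal beyond protein length")
    }
  }
  has_sp <- genes$gene_id %in%
    signals$gene_id[signals$kind == "signal_peptide"]
  has_tm <- genes$gene_id %in% signals$gene_id[signals$kind == "tm_helix"]
  first_tm <- rep(NA_integer_, nrow(genes))
  tms <- signals[signals$kind == "tm_helix", , drop = FALSE]
  if (nrow(tms)) {
    f <- tapply(tms$aa_start, tms$gene_id, min)
    first_tm[match(names(f), genes$gene_id)] <- as.integer(f)
  }
  dist_c <- genes$protein_length - first_tm
  out <- rep("no_TS", nrow(genes))
  out[genes$localization_class == "membrane"] <- "membrane_no_TS"
  out[genes$gene_symbol %in% mito_genes] <- "mito_nuclear"
  out[has_tm & !has_sp &
        !is.na(dist_c) & dist_c > tail_anchor_max_dist] <- "TM_only"
  out[has_tm & has_sp] <- "SP_and_TM"
  out[has_sp & !has_tm] <- "SP_only"
  out[has_tm & !has_sp &
        !is.na(dist_c) & dist_c <= tail_anchor_max_dist] <- "tail_anchored"
  out[startsWith(genes$gene_symbol, "MT-")] <- "mtDNA"
  stats::setNames(out, genes$gene_id)
}
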