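#' Apply the P-site offset to footprint 5' ends
#'
#' Shifts every footprint 5'-end position by \code{offset} nt to obtain
#' P-site positions. Reads whose shifted position leaves the transcript are
#' dropped and counted, so retained + dropped equals the input total.
#'
#' @param reads Data frame with \code{transcript_id}, \code{pos5p}
#'   (0-based), \code{count}.
#' @param tx A \code{\link{transcriptome}}.
#' @param offset Non-negative P-site offset (nt), default 13.
#' @return List with \code{psites} (data frame \code{transcript_id},
#'   \code{psite}, \code{count}), \code{retained} and \code{dropped}
#'   (read totals).
#' @export
apply_psite_offset <- function(reads, tx, offset = 13L) {
  if (offset < 0) stop("negative offset")
  df <- tx$transcripts
  idx <- match(reads$transcript_id, df$transcript_id)
  if (anyNA(idx)) stop("footprint on unknown transcript")
  L <- nchar(df$sequence)[idx]
  if (nrow(reads) && any(reads$pos5p < 0 | reads$pos5p >= L)) {
    stop("5'-end position outside transcript bounds")
  }
  psite <- reads$pos5p + offset
  keep <- psite < L
  out <- data.frame(transcript_id = reads$transcript_id[keep],
                    psite = psite[keep], count = reads$count[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(psites = out, retained = sum(reads$count[keep]),
       dropped = sum(reads$count[!keep]))
}

# per-transcript codon coverage from a P-site table: codon i (1-based)
# covers nt [len5utr + 3(i-1), len5utr + 3i); P-sites outside the CDS are
# ignored for codon sums.
.codon_coverage <- function(psites, len5utr, ncodons) {
  cc <- numeric(ncodons)
  if (!nrow(psites)) return(cc)
  ci <- (psites$psite - len5utr) %/% 3L + 1L
  ok <- ci >= 1L & ci <= ncodons
  if (any(ok)) {
    v <- tapply(psites$count[ok], ci[ok], sum)
    cc[as.integer(names(v))] <- v
  }
  cc
}

#' Metagene of P-site coverage around start and stop codons
#'
#' Per transcript, per-nucleotide P-site coverage is scaled to the mean CDS
#' coverage excluding the first and last \code{trim_codons} codons;
#' transcripts whose total codon coverage is below \code{min_codon_cov} are
#' excluded. Scaled coverage is averaged across transcripts at each
#' position relative to the start (and stop) codon, then smoothed with a
#' centered rolling mean.
#'
#' @param psites P-site table (one condition/replicate).
#' @param tx A \code{\link{transcriptome}}.
#' @param min_codon_cov Minimum total codon coverage per transcript.
#' @param trim_codons Codons trimmed at each CDS end for the scaling mean.
#' @param roll Rolling-mean window (nt).
#' @param span Nt around start/stop to report (upstream, downstream).
#' @return List with \code{start} and \code{stop} data frames
#'   (\code{rel_pos}, \code{mean_scaled}) and \code{n_transcripts}.
#' @export
metagene_start_stop <- function(psites, tx, min_codon_cov = 5,
                                trim_codons = 2L, roll = 10L,
                                span = c(30L, 150L)) {
  df <- tx$transcripts
  rel_start <- -span[1L]:span[2L]
  rel_stop <- -span[2L]:span[1L]
  acc_start <- numeric(length(rel_start))
  acc_stop <- numeric(length(rel_stop))
  n_inc <- 0L
  for (tid in unique(psites$transcript_id)) {
    i <- match(tid, df$transcript_id)
    ncod <- df$lencds[i] %/% 3L
    if (ncod <= 2L * trim_codons) stop("CDS shorter than twice the trim")
    p <- psites[psites$transcript_id == tid, , drop = FALSE]
    cc <- .codon_coverage(p, df$len5utr[i], ncod)
    if (sum(cc) < min_codon_cov) next
    core <- cc[(trim_codons + 1L):(ncod - trim_codons)]
    scale_mean <- mean(core) / 3  # per-nt mean of the trimmed CDS
    if (scale_mean == 0) next
    L <- nchar(df$sequence[i])
    nt <- numeric(L)
    nt[p$psite + 1L] <- p$count
    sc <- nt / scale_mean
    n_inc <- n_inc + 1L
    start0 <- df$len5utr[i]          # 0-based first nt of start codon
    stop0 <- df$len5utr[i] + df$lencds[i] - 3L  # first nt of stop codon
    ps <- start0 + rel_start
    ok <- ps >= 0L & ps < L
    acc_start[ok] <- acc_start[ok] + sc[ps[ok] + 1L]
    ps <- stop0 + rel_stop
    ok <- ps >= 0L & ps < L
    acc_stop[ok] <- acc_stop[ok] + sc[ps[ok] + 1L]
  }
  if (n_inc > 0L) {
    acc_start <- acc_start / n_inc
    acc_stop <- acc_stop / n_inc
  }
  list(
    start = data.frame(rel_pos = rel_start,
                       mean_scaled = rolling_mean(acc_start, roll)),
    stop = data.frame(rel_pos = rel_stop,
                      mean_scaled = rolling_mean(acc_stop, roll)),
    n_transcripts = n_inc
  )
}

#' Metagene of codon coverage around targeting signals
#'
#' For transcripts encoding a targeting signal and expressed above
#' \code{min_tpm}, per-codon P-site coverage is scaled to the mean coverage
#' in codons \code{norm_codons[1]}–\code{norm_codons[2]} of the same CDS,
#' averaged across transcripts per codon position 1..\code{span_codons},
#' grouped by signal kind, and smoothed with a centered rolling mean.
#' Transcripts with zero coverage in the normalization window are excluded.
#'
#' @param psites P-site table.
#' @param tx A \code{\link{transcriptome}} with signal annotations.
#' @param tpm Named TPM per transcript id (or gene id matching the
#'   transcripts).
#' @param norm_codons Length-2 normalization codon window (1-based,
#'   inclusive).
#' @param roll Rolling-mean window (codons).
#' @param span_codons Number of codon positions reported.
#' @param min_tpm Minimum TPM for inclusion.
#' @return List with \code{profile} (data frame \code{signal_kind},
#'   \code{codon}, \code{mean_scaled}, \code{n_transcripts}) and
#'   \code{median_signal_end} (per kind, median signal-end codon).
#' @export
metagene_targeting_signal <- function(psites, tx, tpm,
                                      norm_codons = c(20L, 40L),
                                      roll = 5L, span_codons = 500L,
                                      min_tpm = 10) {
  df <- tx$transcripts
  sig <- tx$signals
  first_sig <- sig[order(sig$transcript_id, sig$aa_start), , drop = FALSE]
  first_sig <- first_sig[!duplicated(first_sig$transcript_id), ,
                         drop = FALSE]
  out <- list()
  med_end <- list()
  for (kind in unique(first_sig$kind)) {
    txids <- first_sig$transcript_id[first_sig$kind == kind]
    acc <- numeric(span_codons)
    nvec <- integer(span_codons)
    ends <- integer(0)
    for (tid in txids) {
      i <- match(tid, df$transcript_id)
      key <- if (tid %in% names(tpm)) tid else df$gene_id[i]
      if (!key %in% names(tpm) || is.na(tpm[[key]]) ||
          tpm[[key]] < min_tpm) next
      p <- psites[psites$transcript_id == tid, , drop = FALSE]
      if (!nrow(p)) next
      ncod <- df$lencds[i] %/% 3L
      cc <- .codon_coverage(p, df$len5utr[i], ncod)
      win <- norm_codons[1L]:min(norm_codons[2L], ncod)
      nmean <- mean(cc[win])
      if (nmean == 0) next
      sc <- cc / nmean
      upto <- min(ncod, span_codons)
      acc[1:upto] <- acc[1:upto] + sc[1:upto]
      nvec[1:upto] <- nvec[1:upto] + 1L
      ends <- c(ends, first_sig$aa_end[first_sig$transcript_id == tid])
    }
    prof <- ifelse(nvec > 0, acc / nvec, NA_real_)
    out[[kind]] <- data.frame(signal_kind = kind,
                              codon = seq_len(span_codons),
                              mean_scaled = rolling_mean(prof, roll),
                              n_transcripts = nvec,
                              stringsAsFactors = FALSE)
    med_end[[kind]] <- if (length(ends)) stats::median(ends) else NA_real_
  }
  list(profile = do.call(rbind, out),
       median_signal_end = unlist(med_end))
}

#' Codon occupancy and between-condition frequency shifts
#'
#' Per replicate, the footprint-weighted frequency of each sense codon at
#' the chosen ribosomal site (P, or E = one codon upstream) is computed
#' over the 61 sense codons (each replicate's frequencies sum to 1). The
#' shift is mean(KO) - mean(WT) per codon, with the standard deviation of
#' per-replicate-pair differences; the shifts sum to 0 exactly.
#'
#' @param psites_wt,psites_ko Lists of P-site tables (one per replicate).
#' @param tx A \code{\link{transcriptome}}.
#' @param site "P" or "E".
#' @return Data frame with \code{codon} (61 rows, alphabetical),
#'   \code{freq_wt}, \code{freq_ko}, \code{delta}, \code{delta_sd}.
#' @export
codon_occupancy_shift <- function(psites_wt, psites_ko, tx,
                                  site = c("P", "E")) {
  site <- match.arg(site)
  if (length(psites_wt) != length(psites_ko)) {
    stop("mismatched replicate counts between conditions")
  }
  codons61 <- .sense_codons()
  df <- tx$transcripts
  shift <- if (site == "P") 0L else -1L
  freq_one <- function(psites) {
    idx <- match(psites$transcript_id, df$transcript_id)
    ci <- (psites$psite - df$len5utr[idx]) %/% 3L + 1L + shift
    ncod <- df$lencds[idx] %/% 3L
    ok <- ci >= 1L & ci <= ncod
    st <- df$len5utr[idx] + 3L * (ci - 1L)
    cod <- substring(df$sequence[idx], st + 1L, st + 3L)
    ok <- ok & cod %in% codons61
    v <- tapply(psites$count[ok], factor(cod[ok], levels = codons61), sum)
    v[is.na(v)] <- 0
    as.numeric(v) / sum(v)
  }
  fwt <- vapply(psites_wt, freq_one, numeric(61L))
  fko <- vapply(psites_ko, freq_one, numeric(61L))
  pair_delta <- fko - fwt
  data.frame(
    codon = codons61,
    freq_wt = rowMeans(fwt), freq_ko = rowMeans(fko),
    delta = rowMeans(fko) - rowMeans(fwt),
    delta_sd = apply(pair_delta, 1L, stats::sd),
    stringsAsFactors = FALSE
  )
}

#' Translation-efficiency contrast between conditions
#'
#' Size-factor-normalizes the footprint (RPF) and RNA count matrices
#' separately, then reports the per-gene log2 ratio of ratios
#' \code{(RPF_KO/RNA_KO)/(RPF_WT/RNA_WT)} of condition means, with a
#' pseudocount on every mean. Swapping the conditions negates the result.
#'
#' @param rpf_counts,rna_counts Count matrices genes x samples with
#'   matching rownames.
#' @param wt_cols,ko_cols Named list/vector selections: columns of the WT
#'   and KO samples, given separately for each matrix as
#'   \code{list(rpf = ..., rna = ...)}.
#' @param pseudocount Added to every normalized condition mean.
#' @return Data frame \code{gene_id}, \code{log2_te_change}.
#' @export
translation_efficiency <- function(rpf_counts, rna_counts, wt_cols,
                                   ko_cols, pseudocount = 1) {
  genes <- rownames(rpf_counts)
  if (!identical(sort(genes), sort(rownames(rna_counts)))) {
    stop("gene sets of the two matrices differ")
  }
  rna_counts <- rna_counts[genes, , drop = FALSE]
  nr <- sweep(rpf_counts, 2L, size_factors(rpf_counts), "/")
  nn <- sweep(rna_counts, 2L, size_factors(rna_counts), "/")
  m <- function(x, cols) rowMeans(x[, cols, drop = FALSE]) + pseudocount
  te <- log2((m(nr, ko_cols$rpf) / m(nn, ko_cols$rna)) /
               (m(nr, wt_cols$rpf) / m(nn, wt_cols$rna)))
  data.frame(gene_id = genes, log2_te_change = as.numeric(te),
             stringsAsFactors = FALSE)
}
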