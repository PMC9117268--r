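#' Count crosslinked k-mers
#'
#' For every crosslink site, every k-nucleotide window of the transcript
#' sequence that overlaps the crosslinked position contributes one count to
#' its k-mer (up to k windows per site; truncated at transcript ends). With
#' \code{register = "start"} only the window starting at the site counts.
#' Counts are aggregated overall and per (localization class, region);
#' frequencies are normalized to sum to 1 within the sample and k-mers are
#' ranked by total frequency, ties broken alphabetically.
#'
#' @param sites Site table (\code{transcript_id}, \code{position},
#'   \code{region}).
#' @param tx A \code{\link{transcriptome}}.
#' @param k K-mer length, 4 to 12.
#' @param register "overlap" (default) or "start".
#' @return List with \code{overall} (data frame \code{kmer}, \code{count},
#'   \code{freq}, \code{rank}) and \code{by_class_region} (data frame with
#'   \code{class}, \code{region}, \code{kmer}, \code{count}, \code{freq}).
#' @export
count_crosslinked_kmers <- function(sites, tx, k = 4L,
                                    register = c("overlap", "start")) {
  register <- match.arg(register)
  if (k < 4L || k > 12L) stop("k must be between 4 and 12")
  df <- tx$transcripts
  idx <- match(sites$transcript_id, df$transcript_id)
  if (anyNA(idx)) stop("site on unknown transcript")
  seqs <- df$sequence[idx]
  L <- nchar(seqs)
  pos1 <- sites$position + 1L  # 1-based crosslinked nucleotide
  if (register == "overlap") {
    # window starts pos1-k+1 .. pos1, clipped to [1, L-k+1]
    reps <- rep(seq_along(pos1), each = k)
    st <- rep(pos1, each = k) - (k - 1L):0L
    ok <- st >= 1L & st + k - 1L <= L[reps]
    reps <- reps[ok]; st <- st[ok]
  } else {
    reps <- seq_along(pos1)
    st <- pos1
    ok <- st + k - 1L <= L[reps]
    reps <- reps[ok]; st <- st[ok]
  }
  kmers <- substring(seqs[reps], st, st + k - 1L)
  cls <- df$localization_class[idx][reps]
  reg <- sites$region[reps]

  tab <- table(kmers)
  overall <- data.frame(kmer = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
  overall$freq <- overall$count / sum(overall$count)
  overall <- overall[order(-overall$freq, overall$kmer), , drop = FALSE]
  overall$rank <- seq_len(nrow(overall))
  rownames(overall) <- NULL

  by_cr <- as.data.frame(table(class = cls, region = reg, kmer = kmers),
                         stringsAsFactors = FALSE)
  names(by_cr)[names(by_cr) == "Freq"] <- "count"
  by_cr <- by_cr[by_cr$count > 0, , drop = FALSE]
  tot <- tapply(by_cr$count, paste(by_cr$class, by_cr$region), sum)
  by_cr$freq <- by_cr$count / tot[paste(by_cr$class, by_cr$region)]
  rownames(by_cr) <- NULL
  list(overall = overall, by_class_region = by_cr)
}

#' Normalized per-gene k-mer crosslink signal
#'
#' For each gene and region (CDS and 3'UTR), sums the T-C counts of
#' crosslink sites associated with each k-mer (window-overlap convention as
#' in \code{\link{count_crosslinked_kmers}}), then divides by the region
#' length and by the gene's whole-cell TPM. K-mers are ranked by the median
#' log2 normalized signal across genes carrying them.
#'
#' @param sites Site table; per-site T-C is the mean over replicates.
#' @param tx A \code{\link{transcriptome}}.
#' @param tpm Named TPM per gene; genes with TPM 0 or NA are skipped.
#' @param k K-mer length.
#' @param regions Regions to include.
#' @return List with \code{per_gene} (gene_id, region, kmer, signal) and
#'   \code{ranking} (kmer, median_log2_signal, rank).
#' @export
kmer_crosslink_signal <- function(sites, tx, tpm, k = 4L,
                                  regions = c("cds", "utr3")) {
  df <- tx$transcripts
  s <- sites[sites$region %in% regions, , drop = FALSE]
  gid <- df$gene_id[match(s$transcript_id, df$transcript_id)]
  tpmv <- tpm[gid]
  usable <- !is.na(tpmv) & tpmv > 0
  if (!all(usable)) {
    message(sum(!usable), " sites on genes without TPM skipped")
    s <- s[usable, , drop = FALSE]
    gid <- gid[usable]
  }
  if (!nrow(s)) {
    return(list(per_gene = data.frame(), ranking = data.frame()))
  }
  tc <- (s$tc_1 + s$tc_2) / 2
  idx <- match(s$transcript_id, df$transcript_id)
  seqs <- df$sequence[idx]
  L <- nchar(seqs)
  pos1 <- s$position + 1L
  reps <- rep(seq_len(nrow(s)), each = k)
  st <- rep(pos1, each = k) - (k - 1L):0L
  ok <- st >= 1L & st + k - 1L <= L[reps]
  reps <- reps[ok]; st <- st[ok]
  kmers <- substring(seqs[reps], st, st + k - 1L)
  # a site contributes its T-C once per k-mer type, however many of its
  # overlapping windows spell that k-mer
  first <- !duplicated(paste(reps, kmers))
  reps <- reps[first]; kmers <- kmers[first]
  rlen <- ifelse(s$region[reps] == "cds", df$lencds[idx][reps],
                 ifelse(s$region[reps] == "utr3", df$len3utr[idx][reps],
                        df$len5utr[idx][reps]))
  sig <- tc[reps] / rlen / tpm[gid[reps]]
  key <- paste(gid[reps], s$region[reps], kmers, sep = "\t")
  agg <- tapply(sig, key, sum)
  parts <- strsplit(names(agg), "\t", fixed = TRUE)
  per_gene <- data.frame(
    gene_id = vapply(parts, `[`, "", 1L),
    region = vapply(parts, `[`, "", 2L),
    kmer = vapply(parts, `[`, "", 3L),
    signal = as.numeric(agg), stringsAsFactors = FALSE
  )
  rownames(per_gene) <- NULL
  med <- tapply(log2(per_gene$signal), per_gene$kmer, stats::median)
  ranking <- data.frame(kmer = names(med),
                        median_log2_signal = as.numeric(med),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$median_log2_signal, ranking$kmer), ,
                     drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  list(per_gene = per_gene, ranking = ranking)
}

# k-mer frequency of a set of sequences: all windows of all sequences,
# normalized to sum to 1 over the 4^k k-mers.
.sequence_kmer_freq <- function(seqs, k) {
  all_k <- .all_kmers(k)
  counts <- stats::setNames(numeric(length(all_k)), all_k)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    st <- seq_len(n - k + 1L)
    tab <- table(substring(s, st, st + k - 1L))
    tab <- tab[names(tab) %in% all_k]  # ignore windows with non-ACGT
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  tot <- sum(counts)
  if (tot == 0) stop("no k-mer window of length ", k, " in the sequences")
  counts / tot
}

#' Class-wise k-mer frequency differences and z-scores
#'
#' Computes the background k-mer frequency of two sequence sets (all
#' windows of the full region sequences), their per-k-mer frequency
#' difference \code{delta_f = f(A) - f(B)}, and the z-score of
#' \code{delta_f} standardized over all 4^k k-mers. K-mers are split into a
#' top-crosslinked set and the rest, and the two z-score groups are
#' compared with a two-sided Wilcoxon rank-sum test.
#'
#' @param seqs_a,seqs_b Character vectors of region sequences (set A and
#'   set B).
#' @param k K-mer length.
#' @param top_bound_set Character vector of the top crosslinked k-mers
#'   (e.g. the top 40 from \code{\link{count_crosslinked_kmers}}).
#' @return List with \code{table} (kmer, freq_a, freq_b, delta_f, z,
#'   in_top_set), \code{wilcox_p}.
#' @export
kmer_class_zscores <- function(seqs_a, seqs_b, k = 4L,
                               top_bound_set = character()) {
  if (!length(seqs_a) || !length(seqs_b)) stop("empty sequence set")
  fa <- .sequence_kmer_freq(.norm_seq(seqs_a), k)
  fb <- .sequence_kmer_freq(.norm_seq(seqs_b), k)
  delta <- fa - fb
  sdd <- stats::sd(delta)
  z <- if (is.na(sdd) || sdd == 0) rep(0, length(delta)) else
    (delta - mean(delta)) / sdd
  tab <- data.frame(kmer = names(fa), freq_a = as.numeric(fa),
                    freq_b = as.numeric(fb), delta_f = as.numeric(delta),
                    z = as.numeric(z),
                    in_top_set = names(fa) %in% .norm_seq(top_bound_set),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  p <- if (any(tab$in_top_set) && any(!tab$in_top_set)) {
    stats::wilcox.test(tab$z[tab$in_top_set], tab$z[!tab$in_top_set],
                       exact = FALSE)$p.value
  } else NA_real_
  list(table = tab, wilcox_p = p)
}

#' Multivalency scores around crosslink sites
#'
#' For every T-C anchor, counts occurrences of the four-mer group whose
#' start lies within +/-\code{half_window} nt of the anchor, excluding the
#' open innermost zone (\code{-exclusion}, \code{+exclusion}) — positions
#' exactly at +/-\code{exclusion} are included. Anchors are then binned
#' into \code{n_bins} near-equal-size groups by increasing score (stable
#' tie-break by transcript id and position). Per bin, the distribution of
#' total normalized T-C signal in the window (same exclusion zone, anchor's
#' own signal excluded with it) and the per-offset percentage profile of
#' T-C signal over the 2*half_window+1 offsets are reported.
#'
#' @param sites Site table with \code{tcpm_1}/\code{tcpm_2} (see
#'   \code{\link{normalize_tc_per_million}}); anchors are all sites.
#' @param tx A \code{\link{transcriptome}}.
#' @param fourmer_group Character vector of four-mers (T or U spelling).
#' @param half_window,exclusion Window geometry in nt.
#' @param n_bins Number of multivalency bins.
#' @return List with \code{records} (per-anchor \code{transcript_id},
#'   \code{position}, \code{score}, \code{bin}, \code{window_tc},
#'   \code{truncated}), \code{positional} (matrix bins x offsets, rows sum
#'   to 100), and \code{bin_window_tc} (per-bin mean window_tc).
#' @export
multivalency_scores <- function(sites, tx, fourmer_group,
                                half_window = 40L, exclusion = 4L,
                                n_bins = 5L) {
  if (!length(fourmer_group)) stop("empty four-mer group")
  group <- .norm_seq(fourmer_group)
  df <- tx$transcripts
  has_tcpm <- all(c("tcpm_1", "tcpm_2") %in% names(sites))
  val <- if (has_tcpm) (sites$tcpm_1 + sites$tcpm_2) / 2 else
    (sites$tc_1 + sites$tc_2) / 2

  n <- nrow(sites)
  score <- integer(n)
  window_tc <- numeric(n)
  truncated <- logical(n)
  offsets <- -half_window:half_window
  pos_tc <- matrix(0, nrow = n, ncol = length(offsets))

  for (tid in unique(sites$transcript_id)) {
    i_tx <- which(sites$transcript_id == tid)
    seq_i <- df$sequence[match(tid, df$transcript_id)]
    L <- nchar(seq_i)
    occ <- .occurrence_vector(seq_i, group)
    cs <- c(0L, cumsum(occ))
    tcv <- numeric(L)
    tcv[sites$position[i_tx] + 1L] <- val[i_tx]
    cst <- c(0, cumsum(tcv))
    p1 <- sites$position[i_tx] + 1L
    lo <- pmax(p1 - half_window, 1L); hi <- pmin(p1 + half_window, L)
    elo <- pmax(p1 - (exclusion - 1L), 1L)
    ehi <- pmin(p1 + (exclusion - 1L), L)
    score[i_tx] <- (cs[hi + 1L] - cs[lo]) - (cs[ehi + 1L] - cs[elo])
    window_tc[i_tx] <- (cst[hi + 1L] - cst[lo]) - (cst[ehi + 1L] - cst[elo])
    truncated[i_tx] <- (p1 - half_window < 1L) | (p1 + half_window > L)
    # positional signal: tc value at each offset from the anchor
    for (j in seq_along(i_tx)) {
      offs_ok <- which(p1[j] + offsets >= 1L & p1[j] + offsets <= L)
      pos_tc[i_tx[j], offs_ok] <- tcv[p1[j] + offsets[offs_ok]]
    }
  }

  ord <- order(score, sites$transcript_id, sites$position)
  sizes <- rep(n %/% n_bins, n_bins) +
    c(rep(0L, n_bins - n %% n_bins), rep(1L, n %% n_bins))
  bin <- integer(n)
  bin[ord] <- rep(seq_len(n_bins), sizes)

  records <- data.frame(
    transcript_id = sites$transcript_id, position = sites$position,
    score = score, bin = bin, window_tc = window_tc,
    truncated = truncated, stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  positional <- t(vapply(seq_len(n_bins), function(b) {
    v <- colSums(pos_tc[bin == b, , drop = FALSE])
    tot <- sum(v)
    if (tot > 0) v / tot * 100 else v
  }, numeric(length(offsets))))
  dimnames(positional) <- list(paste0("bin", seq_len(n_bins)), offsets)
  bin_window_tc <- tapply(records$window_tc, records$bin, mean)
  list(records = records, positional = positional,
       bin_window_tc = bin_window_tc)
}

#' Sliding-window multivalency potential of sequences
#'
#' Counts occurrences of a four-mer group (by occurrence start position) in
#' 30-nt windows slid one nt at a time over each region sequence, keeps
#' windows with at least \code{min_count} occurrences and reports the
#' per-transcript mean count over kept windows (0 when no window is kept).
#'
#' @param tx A \code{\link{transcriptome}}.
#' @param fourmer_group Character vector of four-mers.
#' @param window Window width (nt).
#' @param min_count Minimum group occurrences for a window to be kept.
#' @param regions Regions to score.
#' @return Data frame \code{gene_id}, \code{transcript_id}, \code{region},
#'   \code{class}, \code{mean_window_score}, \code{n_kept_windows}.
#' @export
sliding_window_potential <- function(tx, fourmer_group, window = 30L,
                                     min_count = 3L,
                                     regions = c("cds", "utr3")) {
  group <- .norm_seq(fourmer_group)
  df <- tx$transcripts
  out <- vector("list", nrow(df) * length(regions))
  k <- 0L
  for (i in seq_len(nrow(df))) {
    bounds <- list(
      utr5 = c(1L, df$len5utr[i]),
      cds = c(df$len5utr[i] + 1L, df$len5utr[i] + df$lencds[i]),
      utr3 = c(df$len5utr[i] + df$lencds[i] + 1L,
               df$len5utr[i] + df$lencds[i] + df$len3utr[i])
    )
    for (reg in regions) {
      b <- bounds[[reg]]
      rlen <- b[2L] - b[1L] + 1L
      k <- k + 1L
      if (rlen < window) {
        out[[k]] <- data.frame(
          gene_id = df$gene_id[i], transcript_id = df$transcript_id[i],
          region = reg, class = df$localization_class[i],
          mean_window_score = NA_real_, n_kept_windows = 0L,
          stringsAsFactors = FALSE)
        next
      }
      seq_r <- substring(df$sequence[i], b[1L], b[2L])
      occ <- .occurrence_vector(seq_r, group)
      cs <- c(0L, cumsum(occ))
      st <- seq_len(rlen - window + 1L)
      wcount <- cs[st + window] - cs[st]
      kept <- wcount[wcount >= min_count]
      out[[k]] <- data.frame(
        gene_id = df$gene_id[i], transcript_id = df$transcript_id[i],
        region = reg, class = df$localization_class[i],
        mean_window_score = if (length(kept)) mean(kept) else 0,
        n_kept_windows = length(kept), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Compare sliding-window potential between classes
#'
#' Two-sided Wilcoxon rank-sum test on per-transcript mean window scores
#' between two localization classes within one region.
#'
#' @param potential Output of \code{\link{sliding_window_potential}}.
#' @param region Region to compare.
#' @param class_a,class_b Localization classes.
#' @return List with \code{p.value}, \code{median_a}, \code{median_b}.
#' @export
compare_window_potential <- function(potential, region = "cds",
                                     class_a = "membrane",
                                     class_b = "cytosolic") {
  a <- potential$mean_window_score[potential$region == region &
                                     potential$class == class_a]
  b <- potential$mean_window_score[potential$region == region &
                                     potential$class == class_b]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  list(p.value = stats::wilcox.test(a, b, exact = FALSE)$p.value,
       median_a = stats::median(a), median_b = stats::median(b))
}
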