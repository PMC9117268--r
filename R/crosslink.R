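#' Filter clusters for reproducibility between replicates
#'
#' Keeps replicate-1 clusters that have a partner in replicate 2 such that
#' (i) the pair overlaps by at least \code{min_overlap} of the cluster
#' length (reciprocal by default: the overlap must reach the fraction of
#' *each* cluster's length; "either" semantics available), (ii) the
#' positions of the per-cluster maximum T-C value are no more than
#' \code{max_peak_dist} nucleotides apart, and (iii) the mean of the two
#' T-C sums is at least \code{min_mean_tc}. All three thresholds are
#' boundary-inclusive. Kept clusters are reported with the replicate-1
#' interval (or the union, by option) and carry \code{mean_tc}.
#'
#' @param clusters_rep1,clusters_rep2 Data frames with columns
#'   \code{transcript_id}, \code{start}, \code{end} (0-based half-open),
#'   \code{tc_sum}, \code{max_tc_pos}.
#' @param min_overlap Minimum overlap fraction.
#' @param max_peak_dist Maximum distance (nt) between T-C peaks.
#' @param min_mean_tc Minimum mean T-C sum over the pair.
#' @param overlap_mode "reciprocal" (default) or "either".
#' @param kept_coords "rep1" (default) or "union".
#' @return Data frame of kept clusters with \code{mean_tc} attached.
#' @export
filter_reproducible_clusters <- function(clusters_rep1, clusters_rep2,
                                         min_overlap = 0.5,
                                         max_peak_dist = 10L,
                                         min_mean_tc = 3,
                                         overlap_mode = c("reciprocal",
                                                          "either"),
                                         kept_coords = c("rep1", "union")) {
  overlap_mode <- match.arg(overlap_mode)
  kept_coords <- match.arg(kept_coords)
  for (cl in list(clusters_rep1, clusters_rep2)) {
    if (nrow(cl) && any(cl$start >= cl$end)) stop("malformed cluster interval")
    if (nrow(cl) && any(cl$max_tc_pos < cl$start | cl$max_tc_pos >= cl$end))
      stop("max_tc_pos outside cluster interval")
  }
  empty <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), tc_sum_rep1 = numeric(),
                      tc_sum_rep2 = numeric(), mean_tc = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(clusters_rep1) == 0L || nrow(clusters_rep2) == 0L) return(empty)

  # candidate pairs on the same transcript with any overlap
  common <- intersect(clusters_rep1$transcript_id,
                      clusters_rep2$transcript_id)
  out <- vector("list", length(common))
  for (ti in seq_along(common)) {
    a <- clusters_rep1[clusters_rep1$transcript_id == common[ti], ,
                       drop = FALSE]
    b <- clusters_rep2[clusters_rep2$transcript_id == common[ti], ,
                       drop = FALSE]
    ra <- IRanges::IRanges(start = a$start + 1L, end = a$end)
    rb <- IRanges::IRanges(start = b$start + 1L, end = b$end)
    hits <- IRanges::findOverlaps(ra, rb)
    if (length(hits) == 0L) next
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(ra[qi], rb[si]))
    la <- a$end[qi] - a$start[qi]
    lb <- b$end[si] - b$start[si]
    frac_ok <- if (overlap_mode == "reciprocal") {
      ov >= min_overlap * la & ov >= min_overlap * lb
    } else {
      ov >= min_overlap * la | ov >= min_overlap * lb
    }
    peak_ok <- abs(a$max_tc_pos[qi] - b$max_tc_pos[si]) <= max_peak_dist
    mean_tc <- (a$tc_sum[qi] + b$tc_sum[si]) / 2
    tc_ok <- mean_tc >= min_mean_tc
    keep <- frac_ok & peak_ok & tc_ok
    if (!any(keep)) next
    qi <- qi[keep]; si <- si[keep]; mean_tc <- mean_tc[keep]
    # one output row per rep1 cluster: its best partner by mean_tc
    ord <- order(qi, -mean_tc, si)
    qi <- qi[ord]; si <- si[ord]; mean_tc <- mean_tc[ord]
    first <- !duplicated(qi)
    qi <- qi[first]; si <- si[first]; mean_tc <- mean_tc[first]
    st <- if (kept_coords == "rep1") a$start[qi] else
      pmin(a$start[qi], b$start[si])
    en <- if (kept_coords == "rep1") a$end[qi] else
      pmax(a$end[qi], b$end[si])
    out[[ti]] <- data.frame(transcript_id = common[ti], start = st,
                            end = en, tc_sum_rep1 = a$tc_sum[qi],
                            tc_sum_rep2 = b$tc_sum[si], mean_tc = mean_tc,
                            stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$transcript_id, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Reproducible T-C transition sites from two replicate pileups
#'
#' Retains positions with a T-C transition in both replicates whose
#' transition specificity (T-C count over read coverage) stays below
#' \code{max_specificity} in both — positions converting in essentially
#' every read are treated as genomic variants, not crosslinks. Region
#' labels (5'UTR/CDS/3'UTR) are attached from the transcript models.
#'
#' @param pileups_rep1,pileups_rep2 Data frames with
#'   \code{transcript_id}, \code{position} (0-based), \code{coverage},
#'   \code{tc_count}.
#' @param tx A \code{\link{transcriptome}}.
#' @param max_specificity Exclusive upper bound on specificity.
#' @return Data frame of crosslink sites with per-replicate columns
#'   \code{tc_1}, \code{tc_2}, \code{cov_1}, \code{cov_2}, \code{spec_1},
#'   \code{spec_2} and a \code{region} label.
#' @export
filter_sites <- function(pileups_rep1, pileups_rep2, tx,
                         max_specificity = 0.95) {
  for (p in list(pileups_rep1, pileups_rep2)) {
    if (nrow(p) && any(p$tc_count > 0 & p$coverage <= 0))
      stop("tc_count > 0 with zero coverage")
  }
  key1 <- paste(pileups_rep1$transcript_id, pileups_rep1$position)
  key2 <- paste(pileups_rep2$transcript_id, pileups_rep2$position)
  idx <- match(key1, key2)
  has <- !is.na(idx)
  a <- pileups_rep1[has, , drop = FALSE]
  b <- pileups_rep2[idx[has], , drop = FALSE]
  spec1 <- ifelse(a$coverage > 0, a$tc_count / a$coverage, 0)
  spec2 <- ifelse(b$coverage > 0, b$tc_count / b$coverage, 0)
  keep <- a$tc_count > 0 & b$tc_count > 0 &
    spec1 < max_specificity & spec2 < max_specificity
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  res <- data.frame(
    transcript_id = a$transcript_id, position = a$position,
    region = if (nrow(a)) region_of(tx, a$transcript_id, a$position) else
      character(),
    tc_1 = a$tc_count, tc_2 = b$tc_count,
    cov_1 = a$coverage, cov_2 = b$coverage,
    spec_1 = spec1[keep], spec_2 = spec2[keep],
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

#' Library-size normalization of T-C counts
#'
#' Converts per-replicate T-C counts to T-C transitions per million:
#' \code{tc * 1e6 / library_total}. The library total is by convention the
#' replicate's total number of T-C events.
#'
#' @param sites Site table from \code{\link{filter_sites}}.
#' @param lib_totals Numeric length-2 vector of per-replicate totals.
#' @return \code{sites} with \code{tcpm_1} and \code{tcpm_2} columns.
#' @export
normalize_tc_per_million <- function(sites, lib_totals) {
  if (any(lib_totals <= 0)) stop("library totals must be positive")
  sites$tcpm_1 <- sites$tc_1 * 1e6 / lib_totals[[1L]]
  sites$tcpm_2 <- sites$tc_2 * 1e6 / lib_totals[[2L]]
  sites
}

#' Gene-level crosslink summaries
#'
#' Sums reproducible T-C transitions per gene, split by transcript region,
#' computes the expression-corrected crosslink enrichment E =
#' tc_total / TPM, the CDS-vs-3'UTR density ratio (log2, with a
#' pseudocount added to both region sums; genes without a 3'UTR get NA),
#' and assigns a crosslink group by thresholds on a configurable gene-level
#' statistic (default \code{log2(tc_total/TPM + pseudocount)}).
#'
#' @param sites Site table (with region labels); per-site T-C is the mean
#'   of the two replicates.
#' @param tx A \code{\link{transcriptome}}.
#' @param tpm Named numeric of whole-cell TPM per gene.
#' @param group_thresholds Length-2 increasing thresholds on the statistic.
#' @param statistic "log2_enrichment" (default), "enrichment" or "raw_tc".
#' @param pseudocount Pseudocount for the region-density ratio and for the
#'   log2 statistic.
#' @return Data frame with one row per gene carrying \code{tc_total},
#'   \code{tc_5utr}, \code{tc_cds}, \code{tc_3utr}, \code{tpm_wholecell},
#'   \code{enrichment}, \code{log2_cds_utr3_ratio}, \code{statistic},
#'   \code{crosslink_group} ("low"/"mid"/"high").
#' @export
summarize_gene_crosslinks <- function(sites, tx, tpm,
                                      group_thresholds = c(0.3, 1.39),
                                      statistic = c("log2_enrichment",
                                                    "enrichment", "raw_tc"),
                                      pseudocount = 0.5) {
  statistic <- match.arg(statistic)
  df <- tx$transcripts
  if (nrow(sites) && !all(sites$transcript_id %in% df$transcript_id)) {
    stop("site on a transcript absent from the transcriptome")
  }
  tc <- (sites$tc_1 + sites$tc_2) / 2
  gid <- df$gene_id[match(sites$transcript_id, df$transcript_id)]
  agg <- function(sel) {
    v <- tapply(tc[sel], gid[sel], sum)
    out <- stats::setNames(rep(0, nrow(df)), df$gene_id)
    out[names(v)] <- v
    out
  }
  tc5 <- agg(sites$region == "utr5")
  tcc <- agg(sites$region == "cds")
  tc3 <- agg(sites$region == "utr3")
  tot <- tc5 + tcc + tc3
  tpmv <- tpm[df$gene_id]
  enr <- ifelse(!is.na(tpmv) & tpmv > 0, tot / tpmv, NA_real_)
  dens_c <- (tcc + pseudocount) / df$lencds
  dens_3 <- (tc3 + pseudocount) / df$len3utr
  ratio <- ifelse(df$len3utr > 0 & df$lencds > 0,
                  log2(dens_c / dens_3), NA_real_)
  stat <- switch(statistic,
                 log2_enrichment = log2(enr + pseudocount),
                 enrichment = enr,
                 raw_tc = tot)
  grp <- ifelse(is.na(stat), NA_character_,
                ifelse(stat < group_thresholds[1L], "low",
                       ifelse(stat < group_thresholds[2L], "mid", "high")))
  res <- data.frame(
    gene_id = df$gene_id, transcript_id = df$transcript_id,
    tc_total = tot, tc_5utr = tc5, tc_cds = tcc, tc_3utr = tc3,
    tpm_wholecell = as.numeric(tpmv), enrichment = enr,
    log2_cds_utr3_ratio = ratio, statistic = stat, crosslink_group = grp,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

#' Meta-transcript crosslink profile
#'
#' Positions of reproducible T-C sites are mapped to relative coordinates
#' within their region (5'UTR, CDS, 3'UTR, with a fixed number of bins per
#' region), per-site values (mean replicate T-C per million) are scaled to
#' the per-transcript maximum so each included transcript attains exactly
#' 1 somewhere, and the scaled values are averaged across transcripts per
#' bin (bin value per transcript = maximum scaled signal in the bin).
#' Transcripts whose total T-C per million is below \code{min_tcpm} in
#' either replicate are excluded.
#'
#' @param sites Site table with \code{tcpm_1}/\code{tcpm_2} columns (see
#'   \code{\link{normalize_tc_per_million}}).
#' @param tx A \code{\link{transcriptome}}.
#' @param min_tcpm Inclusion threshold on per-transcript total tcpm.
#' @param bins_per_region Integer length-3 vector (5'UTR, CDS, 3'UTR).
#' @return List with \code{profile} (data frame: \code{region}, \code{bin},
#'   \code{mean_scaled}) and \code{n_transcripts} included.
#' @export
meta_transcript_profile <- function(sites, tx, min_tcpm = 5,
                                    bins_per_region = c(100L, 300L, 200L)) {
  stopifnot(all(c("tcpm_1", "tcpm_2") %in% names(sites)))
  tot1 <- tapply(sites$tcpm_1, sites$transcript_id, sum)
  tot2 <- tapply(sites$tcpm_2, sites$transcript_id, sum)
  keep_tx <- names(tot1)[tot1 >= min_tcpm & tot2 >= min_tcpm]
  regions <- c("utr5", "cds", "utr3")
  nb <- stats::setNames(as.integer(bins_per_region), regions)
  grid <- data.frame(
    region = rep(regions, nb),
    bin = unlist(lapply(nb, seq_len), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (!length(keep_tx)) {
    grid$mean_scaled <- NA_real_
    return(list(profile = grid, n_transcripts = 0L))
  }
  s <- sites[sites$transcript_id %in% keep_tx, , drop = FALSE]
  val <- (s$tcpm_1 + s$tcpm_2) / 2
  mx <- tapply(val, s$transcript_id, max)
  scaled <- val / mx[s$transcript_id]
  df <- tx$transcripts
  idx <- match(s$transcript_id, df$transcript_id)
  len5 <- df$len5utr[idx]; lenc <- df$lencds[idx]; len3 <- df$len3utr[idx]
  rel_pos <- ifelse(s$region == "utr5", s$position,
                    ifelse(s$region == "cds", s$position - len5,
                           s$position - len5 - lenc))
  rlen <- ifelse(s$region == "utr5", len5,
                 ifelse(s$region == "cds", lenc, len3))
  bin <- pmin(floor(rel_pos / rlen * nb[s$region]) + 1L, nb[s$region])
  # per transcript x (region, bin): max scaled signal; average over all
  # included transcripts (transcripts without signal in a bin contribute 0)
  key <- paste(s$transcript_id, s$region, bin)
  per_bin <- tapply(scaled, key, max)
  parts <- strsplit(names(per_bin), " ")
  bdf <- data.frame(region = vapply(parts, `[`, "", 2L),
                    bin = as.integer(vapply(parts, `[`, "", 3L)),
                    v = as.numeric(per_bin), stringsAsFactors = FALSE)
  sums <- tapply(bdf$v, paste(bdf$region, bdf$bin), sum)
  gkey <- paste(grid$region, grid$bin)
  grid$mean_scaled <- ifelse(gkey %in% names(sums),
                             as.numeric(sums[gkey]), 0) / length(keep_tx)
  list(profile = grid, n_transcripts = length(keep_tx))
}
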