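#' tRNA crosslink enrichment with modification masking
#'
#' Library-size-normalizes per-tRNA T-C transition counts (summed over
#' non-masked positions only; dihydrouridine positions cause
#' reverse-transcription misincorporation that mimics crosslinking and are
#' removed before summation) and per-tRNA read counts from total-RNA
#' sequencing, and reports their ratio as the enrichment score, ranked
#' descending (ties broken by id).
#'
#' @param pileup Data frame \code{trna_id}, \code{position} (0-based),
#'   \code{coverage}, \code{tc_count}.
#' @param abundance Data frame \code{trna_id}, \code{reads}.
#' @param masks Data frame \code{trna_id}, \code{position} of modified U
#'   positions to exclude.
#' @param lib_totals Named numeric: \code{tc} (crosslink library total) and
#'   \code{reads} (abundance library total); defaults to the respective
#'   column sums.
#' @return Data frame \code{trna_id}, \code{tc_norm}, \code{abundance_norm},
#'   \code{enrichment}, \code{rank}, plus a \code{per_position} attribute
#'   with per-position specificity.
#' @export
trna_enrichment <- function(pileup, abundance, masks = NULL,
                            lib_totals = NULL) {
  if (!all(pileup$trna_id %in% abundance$trna_id)) {
    stop("tRNA in pileup absent from the abundance reference")
  }
  masked <- if (is.null(masks) || nrow(masks) == 0L) rep(FALSE, nrow(pileup))
    else paste(pileup$trna_id, pileup$position) %in%
      paste(masks$trna_id, masks$position)
  if (is.null(lib_totals)) {
    lib_totals <- c(tc = sum(pileup$tc_count[!masked]),
                    reads = sum(abundance$reads))
  }
  if (any(lib_totals <= 0)) stop("library totals must be positive")
  tc_by <- tapply(pileup$tc_count[!masked], pileup$trna_id[!masked], sum)
  tc_norm <- stats::setNames(rep(0, nrow(abundance)), abundance$trna_id)
  tc_norm[names(tc_by)] <- tc_by
  tc_norm <- tc_norm * 1e6 / lib_totals[["tc"]]
  ab_norm <- abundance$reads * 1e6 / lib_totals[["reads"]]
  names(ab_norm) <- abundance$trna_id
  enr <- ifelse(ab_norm > 0, tc_norm / ab_norm, NA_real_)
  res <- data.frame(trna_id = abundance$trna_id,
                    tc_norm = as.numeric(tc_norm[abundance$trna_id]),
                    abundance_norm = as.numeric(ab_norm),
                    enrichment = as.numeric(enr[abundance$trna_id]),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$enrichment, res$trna_id), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  pp <- pileup
  pp$specificity <- ifelse(pp$coverage > 0, pp$tc_count / pp$coverage, 0)
  pp$masked <- masked
  attr(res, "per_position") <- pp
  res
}

#' BioID enrichment filter and ranking
#'
#' Per-replicate enrichment divides Dox-treated LFQ by untreated LFQ with
#' the study's replicate pairing (Dox batches 1,2,3 against untreated
#' batches 2,2,3 — the first Dox batch reuses untreated batch 2). A protein
#' group is enriched when, in all three replicate pairs, either the
#' enrichment is at least \code{min_enrich} and log2 Dox LFQ is at least
#' \code{min_log2_lfq}, or the untreated LFQ is zero and log2 Dox LFQ is at
#' least \code{min_log2_lfq}; razor unique peptides must be at least
#' \code{min_peptides}. Enriched groups are ranked by mean Dox LFQ. The
#' display enrichment is the mean log2 enrichment, replaced for groups with
#' any zero denominator by the table-wide maximum mean log2 enrichment
#' plus 2.
#'
#' @param quant Data frame with \code{protein_group}, \code{lfq_dox_1..3},
#'   \code{lfq_nodox_2..3}, \code{razor_unique_peptides}.
#' @param min_enrich Minimum raw per-replicate enrichment.
#' @param min_log2_lfq Minimum log2 Dox LFQ per replicate.
#' @param min_peptides Minimum razor unique peptides.
#' @return \code{quant} with columns \code{enrichment_1..3},
#'   \code{enriched}, \code{mean_lfq_dox}, \code{display_enrichment} and
#'   \code{rank} (NA for non-enriched), sorted enriched-first by rank.
#' @export
bioid_filter <- function(quant, min_enrich = 3, min_log2_lfq = 27,
                         min_peptides = 3L) {
  need <- c("protein_group", "lfq_dox_1", "lfq_dox_2", "lfq_dox_3",
            "lfq_nodox_2", "lfq_nodox_3", "razor_unique_peptides")
  if (!all(need %in% names(quant))) {
    stop("missing replicate columns: ",
         paste(setdiff(need, names(quant)), collapse = ", "))
  }
  dox <- as.matrix(quant[, c("lfq_dox_1", "lfq_dox_2", "lfq_dox_3")])
  nod <- as.matrix(quant[, c("lfq_nodox_2", "lfq_nodox_2",
                             "lfq_nodox_3")])
  enr <- ifelse(nod > 0, dox / nod, NA_real_)
  lfq_ok <- log2(dox) >= min_log2_lfq
  rep_ok <- ifelse(nod > 0, enr >= min_enrich & lfq_ok, lfq_ok)
  enriched <- rowSums(rep_ok) == 3L &
    quant$razor_unique_peptides >= min_peptides
  mean_log2_enr <- rowMeans(log2(enr))
  max_fin <- suppressWarnings(max(mean_log2_enr, na.rm = TRUE))
  disp <- ifelse(is.na(mean_log2_enr), max_fin + 2, mean_log2_enr)
  out <- quant
  out$enrichment_1 <- enr[, 1L]; out$enrichment_2 <- enr[, 2L]
  out$enrichment_3 <- enr[, 3L]
  out$enriched <- enriched
  out$mean_lfq_dox <- rowMeans(dox)
  out$display_enrichment <- disp
  out <- out[order(-out$enriched, -out$mean_lfq_dox, out$protein_group), ,
             drop = FALSE]
  out$rank <- NA_integer_
  out$rank[out$enriched] <- seq_len(sum(out$enriched))
  rownames(out) <- NULL
  out
}

#' Aggregate pulsed-SILAC ratios per protein
#'
#' Removes SILAC pairs quantified from two requantified intensities,
#' brings reverse-orientation ratios onto the KO/WT scale by negating their
#' log2 ratio (the labels are swapped in the reverse experiment), keeps
#' only proteins with at least one value from both orientations, and
#' reports the mean log2 KO/WT ratio per protein.
#'
#' @param pairs Data frame with \code{protein_group}, \code{orientation}
#'   ("forward"/"reverse"), \code{log2_ratio} (as measured),
#'   \code{requant_num}, \code{requant_den}.
#' @param invert_reverse Negate reverse-orientation log2 ratios (default
#'   TRUE).
#' @return Data frame \code{protein_group}, \code{mean_log2_ko_wt},
#'   \code{n_forward}, \code{n_reverse}.
#' @export
psilac_aggregate <- function(pairs, invert_reverse = TRUE) {
  if (!all(pairs$orientation %in% c("forward", "reverse"))) {
    stop("unknown orientation label")
  }
  keep <- !(pairs$requant_num & pairs$requant_den)
  p <- pairs[keep, , drop = FALSE]
  val <- ifelse(p$orientation == "reverse" & invert_reverse,
                -p$log2_ratio, p$log2_ratio)
  nf <- tapply(p$orientation == "forward", p$protein_group, sum)
  nr <- tapply(p$orientation == "reverse", p$protein_group, sum)
  mu <- tapply(val, p$protein_group, mean)
  ok <- nf > 0 & nr > 0
  res <- data.frame(protein_group = names(mu)[ok],
                    mean_log2_ko_wt = as.numeric(mu[ok]),
                    n_forward = as.integer(nf[ok]),
                    n_reverse = as.integer(nr[ok]),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' RIP-qPCR fold enrichment from Ct values
#'
#' Fold enrichment of bait-bound RNA over the IgG control,
#' \code{2^(ct_igg - ct_flag)} by default (lower Ct means more RNA, so the
#' control-minus-bait exponent yields values above 1 for enriched RNAs);
#' the operand order is configurable.
#'
#' @param ct_flag,ct_igg Ct values of the bait (anti-FLAG) and IgG control
#'   reactions.
#' @param control_minus_bait Use \code{ct_igg - ct_flag} (default TRUE).
#' @return Numeric fold enrichment.
#' @export
rip_fold_enrichment <- function(ct_flag, ct_igg,
                                control_minus_bait = TRUE) {
  if (any(!is.finite(ct_flag)) || any(!is.finite(ct_igg))) {
    stop("non-finite Ct value")
  }
  if (control_minus_bait) 2^(ct_igg - ct_flag) else 2^(ct_flag - ct_igg)
}
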