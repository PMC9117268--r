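# Independent brute-force oracles. These deliberately use plain nested
# loops and no code shared with the implementation.

bf_filter_clusters <- function(a, b, min_overlap = 0.5,
                               max_peak_dist = 10, min_mean_tc = 3,
                               reciprocal = TRUE) {
  rows <- list()
  for (i in seq_len(nrow(a))) {
    best <- NULL
    bsub <- which(b$transcript_id == a$transcript_id[i])
    for (j in bsub) {
      ov <- max(0, min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]))
      la <- a$end[i] - a$start[i]
      lb <- b$end[j] - b$start[j]
      frac_ok <- if (reciprocal) {
        ov >= min_overlap * la && ov >= min_overlap * lb
      } else {
        ov >= min_overlap * la || ov >= min_overlap * lb
      }
      if (!frac_ok) next
      if (abs(a$max_tc_pos[i] - b$max_tc_pos[j]) > max_peak_dist) next
      mtc <- (a$tc_sum[i] + b$tc_sum[j]) / 2
      if (mtc < min_mean_tc) next
      if (is.null(best) || mtc > best$mean_tc) {
        best <- list(j = j, mean_tc = mtc)
      }
    }
    if (!is.null(best)) {
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = a$transcript_id[i], start = a$start[i],
        end = a$end[i], tc_sum_rep1 = a$tc_sum[i],
        tc_sum_rep2 = b$tc_sum[best$j], mean_tc = best$mean_tc,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), tc_sum_rep1 = numeric(),
                      tc_sum_rep2 = numeric(), mean_tc = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$transcript_id, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

bf_count_kmers <- function(sites, tx, k) {
  counts <- new.env()
  df <- tx$transcripts
  for (i in seq_len(nrow(sites))) {
    s <- df$sequence[df$transcript_id == sites$transcript_id[i]]
    L <- nchar(s)
    p1 <- sites$position[i] + 1L
    for (st in (p1 - k + 1L):p1) {
      if (st < 1L || st + k - 1L > L) next
      km <- substr(s, st, st + k - 1L)
      counts[[km]] <- (if (is.null(counts[[km]])) 0L else counts[[km]]) + 1L
    }
  }
  out <- sort(unlist(as.list(counts)))
  out[order(names(out))]
}

bf_multivalency <- function(sites, tx, group, half_window = 40,
                            exclusion = 4) {
  df <- tx$transcripts
  vapply(seq_len(nrow(sites)), function(i) {
    s <- df$sequence[df$transcript_id == sites$transcript_id[i]]
    L <- nchar(s)
    p <- sites$position[i]  # 0-based
    cnt <- 0L
    for (st0 in 0:(L - 4L)) {
      if (!substr(s, st0 + 1L, st0 + 4L) %in% group) next
      d <- abs(st0 - p)
      if (d <= half_window && d >= exclusion) cnt <- cnt + 1L
    }
    cnt
  }, integer(1))
}

bf_sliding_window <- function(seq, group, window = 30, min_count = 3) {
  L <- nchar(seq)
  if (L < window) return(numeric(0))
  kept <- numeric(0)
  for (i in 1:(L - window + 1L)) {
    cnt <- 0L
    for (st in i:(i + window - 1L)) {
      if (st + 3L > L) next
      if (substr(seq, st, st + 3L) %in% group) cnt <- cnt + 1L
    }
    if (cnt >= min_count) kept <- c(kept, cnt)
  }
  kept
}

bf_bioid <- function(quant, min_enrich = 3, min_log2_lfq = 27,
                     min_peptides = 3) {
  pass <- logical(nrow(quant))
  for (i in seq_len(nrow(quant))) {
    dox <- c(quant$lfq_dox_1[i], quant$lfq_dox_2[i], quant$lfq_dox_3[i])
    nod <- c(quant$lfq_nodox_2[i], quant$lfq_nodox_2[i],
             quant$lfq_nodox_3[i])
    ok <- TRUE
    for (r in 1:3) {
      if (log2(dox[r]) < min_log2_lfq) { ok <- FALSE; break }
      if (nod[r] > 0 && dox[r] / nod[r] < min_enrich) { ok <- FALSE; break }
    }
    pass[i] <- ok && quant$razor_unique_peptides[i] >= min_peptides
  }
  quant$protein_group[pass]
}
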