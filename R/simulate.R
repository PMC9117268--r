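#' Simulate a transcriptome with planted localization and motif structure
#'
#' Generates one transcript per gene over a uniform-random background and
#' plants the structure the downstream analyses are designed to detect:
#' membrane-class transcripts carry CU-rich motif hotspots (several motifs
#' within a 40-nt window) in their CDS plus an encoded targeting signal
#' (signal peptide or transmembrane helix); cytosolic-class transcripts
#' carry sparser single motifs split between CDS and 3'UTR. Planted truth
#' (labels, motif positions, enrichments, pause codons) is returned
#' alongside and fully determines every later simulation stage given the
#' seed.
#'
#' @param n_genes Number of genes (one isoform each).
#' @param class_fractions Named numeric, fractions for "membrane",
#'   "cytosolic", "undefined"; must sum to 1.
#' @param motif_params List with \code{motifs} (DNA spellings; default the
#'   CU-rich four-mer set UUCU/CUUC/UCUU/CUCU), \code{hotspot_per_kb}
#'   (membrane CDS hotspot density), \code{motifs_per_hotspot} (range),
#'   \code{sparse_per_kb} (cytosolic/undefined single-motif density).
#' @param region_lengths List with ranges \code{utr5}, \code{cds_codons},
#'   \code{utr3}.
#' @param enrich_means Named numeric: planted mean log2 membrane enrichment
#'   per class (membrane 2.5, cytosolic -1, undefined 0).
#' @param enrich_sd Per-gene spread around the class mean.
#' @param seed Integer seed (expanded by \code{\link{stage_seed}}).
#' @return List with elements \code{transcriptome} (a
#'   \code{\link{transcriptome}}) and \code{truth} (planted ground truth).
#' @export
simulate_transcriptome <- function(n_genes = 300L,
                                   class_fractions = c(membrane = 0.4,
                                                       cytosolic = 0.4,
                                                       undefined = 0.2),
                                   motif_params = list(),
                                   region_lengths = list(
                                     utr5 = c(60L, 150L),
                                     cds_codons = c(150L, 400L),
                                     utr3 = c(150L, 450L)),
                                   enrich_means = c(membrane = 2.5,
                                                    cytosolic = -1.0,
                                                    undefined = 0),
                                   enrich_sd = 0.3,
                                   seed = 1L) {
  stopifnot(n_genes >= 1)
  if (abs(sum(class_fractions) - 1) > 1e-8) {
    stop("class fractions must sum to 1")
  }
  mp <- utils::modifyList(list(
    motifs = c("TTCT", "CTTC", "TCTT", "CTCT"),
    hotspot_per_kb = 3, motifs_per_hotspot = c(2L, 4L),
    sparse_per_kb = 1
  ), motif_params)
  set.seed(stage_seed(seed, "transcriptome"))

  # deterministic class composition from the fractions
  n_mem <- round(class_fractions[["membrane"]] * n_genes)
  n_cyt <- round(class_fractions[["cytosolic"]] * n_genes)
  n_und <- n_genes - n_mem - n_cyt
  if (n_und < 0) stop("class fractions produce a negative class size")
  classes <- sample(rep(c("membrane", "cytosolic", "undefined"),
                        c(n_mem, n_cyt, n_und)))

  bases <- c("A", "C", "G", "T")
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  tx_ids <- sprintf("T%04d", seq_len(n_genes))
  seqs <- character(n_genes)
  len5 <- sample(region_lengths$utr5[1]:region_lengths$utr5[2], n_genes,
                 replace = TRUE)
  ncod <- sample(region_lengths$cds_codons[1]:region_lengths$cds_codons[2],
                 n_genes, replace = TRUE)
  lenc <- 3L * ncod
  len3 <- sample(region_lengths$utr3[1]:region_lengths$utr3[2], n_genes,
                 replace = TRUE)

  motifs <- mp$motifs
  wm <- nchar(motifs[1L])
  motif_rows <- list()
  hotspot_rows <- list()
  signal_rows <- list()
  pause_rows <- list()

  for (i in seq_len(n_genes)) {
    L <- len5[i] + lenc[i] + len3[i]
    s <- sample(bases, L, replace = TRUE)
    cls <- classes[i]

    plant <- function(pos0, motif) {
      # pos0 is 0-based start; returns TRUE when planted
      chars <- strsplit(motif, "")[[1L]]
      s[(pos0 + 1L):(pos0 + wm)] <<- chars
      TRUE
    }

    if (cls == "membrane") {
      n_hot <- max(1L, round(lenc[i] / 1000 * mp$hotspot_per_kb))
      span <- 40L
      lo <- len5[i]
      hi <- len5[i] + lenc[i] - span - wm
      if (hi <= lo) stop("CDS too short for the requested hotspot density")
      starts <- sort(sample(lo:hi, n_hot))
      # keep hotspots at least one window apart
      keep <- c(TRUE, diff(starts) > span + 10L)
      starts <- starts[keep]
      for (h in seq_along(starts)) {
        k <- sample(mp$motifs_per_hotspot[1]:mp$motifs_per_hotspot[2], 1L)
        off <- 0L
        placed <- integer(0)
        for (j in seq_len(k)) {
          m <- sample(motifs, 1L)
          p0 <- starts[h] + off
          if (p0 + wm > starts[h] + span + wm) break
          plant(p0, m)
          placed <- c(placed, p0)
          motif_rows[[length(motif_rows) + 1L]] <-
            data.frame(transcript_id = tx_ids[i], position = p0,
                       motif = m, stringsAsFactors = FALSE)
          off <- off + wm + sample(2:6, 1L)
        }
        hotspot_rows[[length(hotspot_rows) + 1L]] <-
          data.frame(transcript_id = tx_ids[i], start = min(placed),
                     end = max(placed) + wm, n_motifs = length(placed),
                     stringsAsFactors = FALSE)
      }
      # targeting signal: half signal peptides, half TM helices; human
      # signal peptides cluster tightly around 22 aa
      if (i %% 2L == 0L) {
        aa_start <- 1L
        aa_end <- sample(20:24, 1L)
        kind <- "signal_peptide"
      } else {
        aa_start <- sample(35:55, 1L)
        aa_end <- aa_start + 20L
        kind <- "tm_helix"
      }
      signal_rows[[length(signal_rows) + 1L]] <-
        data.frame(transcript_id = tx_ids[i], kind = kind,
                   aa_start = aa_start, aa_end = aa_end,
                   stringsAsFactors = FALSE)
      pause_rows[[length(pause_rows) + 1L]] <-
        data.frame(transcript_id = tx_ids[i], codon = aa_end,
                   stringsAsFactors = FALSE)
    } else {
      dens <- mp$sparse_per_kb
      n_m <- stats::rpois(1L, dens * (lenc[i] + len3[i]) / 1000)
      if (n_m > 0) {
        for (j in seq_len(n_m)) {
          in_cds <- stats::runif(1) < 0.5
          if (in_cds) {
            p0 <- sample(len5[i]:(len5[i] + lenc[i] - wm), 1L)
          } else {
            p0 <- sample((len5[i] + lenc[i]):(L - wm), 1L)
          }
          m <- sample(motifs, 1L)
          plant(p0, m)
          motif_rows[[length(motif_rows) + 1L]] <-
            data.frame(transcript_id = tx_ids[i], position = p0,
                       motif = m, stringsAsFactors = FALSE)
        }
      }
    }
    seqs[i] <- paste0(s, collapse = "")
  }

  planted_m <- enrich_means[classes] + stats::rnorm(n_genes, 0, enrich_sd)
  abundance <- stats::rlnorm(n_genes, meanlog = log(30), sdlog = 0.8)
  tpm_true <- abundance / sum(abundance) * 1e6

  transcripts <- data.frame(
    transcript_id = tx_ids, gene_id = gene_ids, sequence = seqs,
    len5utr = len5, lencds = lenc, len3utr = len3,
    localization_class = classes, is_mt = FALSE, tpm = tpm_true,
    stringsAsFactors = FALSE
  )
  signals <- if (length(signal_rows)) do.call(rbind, signal_rows) else NULL
  tx <- transcriptome(transcripts, signals)

  motif_df <- if (length(motif_rows)) do.call(rbind, motif_rows) else
    data.frame(transcript_id = character(), position = integer(),
               motif = character(), stringsAsFactors = FALSE)
  truth <- list(
    seed = seed,
    classes = data.frame(gene_id = gene_ids, transcript_id = tx_ids,
                         class = classes, planted_enrichment = planted_m,
                         stringsAsFactors = FALSE),
    expression = data.frame(gene_id = gene_ids, transcript_id = tx_ids,
                            tpm_true = tpm_true,
                            rel_expr = abundance / mean(abundance),
                            stringsAsFactors = FALSE),
    motifs = motif_df,
    hotspots = if (length(hotspot_rows)) do.call(rbind, hotspot_rows) else
      data.frame(transcript_id = character(), start = integer(),
                 end = integer(), n_motifs = integer(),
                 stringsAsFactors = FALSE),
    signals = tx$signals,
    pause = if (length(pause_rows)) do.call(rbind, pause_rows) else
      data.frame(transcript_id = character(), codon = integer(),
                 stringsAsFactors = FALSE),
    motif_set = motifs
  )
  list(transcriptome = tx, truth = truth)
}

# Crosslink propensity per position. The protein contacts the U residues
# of its bound motif, so propensity is concentrated on positions inside a
# motif occurrence and grows with the local multivalency m (motif-group
# occurrences within +/-half_window nt, the occurrence's own start zone
# excluded as in the multivalency score); positions outside motifs but
# within reach of one get a weak residual contact. Mapped to (0, 1) by
# w / (w + 1).
.crosslink_propensity <- function(seq, motifs, half_window = 40L,
                                  exclusion = 4L) {
  occ <- .occurrence_vector(seq, motifs)
  n <- length(occ)
  cs <- cumsum(c(0L, occ))
  i <- seq_len(n)
  lo <- pmax(i - half_window, 1L)
  hi <- pmin(i + half_window, n)
  full <- cs[hi + 1L] - cs[lo]
  elo <- pmax(i - (exclusion - 1L), 1L)
  ehi <- pmin(i + (exclusion - 1L), n)
  inner <- cs[ehi + 1L] - cs[elo]
  m <- full - inner
  # positions covered by a motif occurrence (occurrences are width-4)
  wm <- 4L
  d <- integer(n + 1L)
  st <- which(occ > 0L)
  if (length(st)) {
    d[st] <- d[st] + 1L
    en <- pmin(st + wm, n + 1L)
    d[en] <- d[en] - 1L
  }
  in_motif <- cumsum(d[seq_len(n)]) > 0L
  w <- ifelse(in_motif, 0.5 + m, 0.15 * m)
  w / (w + 1)
}

#' Simulate PAR-CLIP pileups and clusters
#'
#' Per-position read coverage follows transcript abundance times the
#' sequencing depth; T-C transition counts are binomial draws whose success
#' probability grows with the local motif multivalency of the planted
#' sequence (crosslinking propensity), plus a sequencing-error floor.
#' Clusters are emitted around planted motif hotspots with
#' replicate-specific jittered boundaries. Replicates are independent
#' draws from the same truth.
#'
#' @param tx A \code{\link{transcriptome}} from
#'   \code{\link{simulate_transcriptome}}.
#' @param truth Matching truth object.
#' @param depth Mean coverage at an average-abundance transcript.
#' @param conv_rate 4SU conversion rate scale in [0, 1].
#' @param err_rate Baseline T-C mismatch (sequencing error) rate.
#' @param n_replicates Number of biological replicates.
#' @param seed Integer seed.
#' @return List with \code{pileups} and \code{clusters}: each a list (one
#'   per replicate) of data frames. Pileups have columns
#'   \code{transcript_id}, \code{position} (0-based, T positions only),
#'   \code{coverage}, \code{tc_count}; clusters have \code{transcript_id},
#'   \code{start}, \code{end}, \code{tc_sum}, \code{max_tc_pos}.
#' @export
simulate_parclip <- function(tx, truth, depth = 50, conv_rate = 0.25,
                             err_rate = 1e-4, n_replicates = 2L, seed = 1L) {
  if (depth <= 0) stop("sequencing depth must be positive")
  if (conv_rate < 0 || conv_rate > 1) stop("conv_rate must be in [0, 1]")
  df <- tx$transcripts
  rel <- truth$expression$rel_expr[match(df$transcript_id,
                                         truth$expression$transcript_id)]
  rel <- pmin(rel, 10)  # cap so very abundant genes do not dominate runtime

  prop <- vector("list", nrow(df))
  tpos <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    chars <- strsplit(df$sequence[i], "")[[1L]]
    tp <- which(chars == "T")
    tpos[[i]] <- tp
    prop[[i]] <- .crosslink_propensity(df$sequence[i], truth$motif_set)[tp]
  }

  pileups <- vector("list", n_replicates)
  clusters <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(stage_seed(seed, "parclip") + r)
    pl <- vector("list", nrow(df))
    cl <- vector("list", nrow(df))
    for (i in seq_len(nrow(df))) {
      tp <- tpos[[i]]
      if (!length(tp)) next
      cov <- stats::rpois(length(tp), depth * rel[i])
      p <- pmin(1, conv_rate * prop[[i]] + err_rate)
      tc <- stats::rbinom(length(tp), cov, p)
      pl[[i]] <- data.frame(transcript_id = df$transcript_id[i],
                            position = tp - 1L, coverage = cov,
                            tc_count = tc, stringsAsFactors = FALSE)
      hs <- truth$hotspots[truth$hotspots$transcript_id ==
                             df$transcript_id[i], , drop = FALSE]
      mo <- truth$motifs[truth$motifs$transcript_id ==
                           df$transcript_id[i], , drop = FALSE]
      regions <- if (nrow(hs)) {
        hs[, c("start", "end")]
      } else if (nrow(mo)) {
        data.frame(start = mo$position, end = mo$position + 4L)
      } else NULL
      if (!is.null(regions) && nrow(regions)) {
        L <- nchar(df$sequence[i])
        tcvec <- integer(L)
        tcvec[tp] <- tc
        rows <- lapply(seq_len(nrow(regions)), function(h) {
          st <- max(0L, regions$start[h] - 10L + sample(-3:3, 1L))
          en <- min(L, regions$end[h] + 10L + sample(-3:3, 1L))
          if (en <= st) return(NULL)
          seg <- tcvec[(st + 1L):en]
          if (sum(seg) < 1L) return(NULL)
          data.frame(transcript_id = df$transcript_id[i], start = st,
                     end = en, tc_sum = sum(seg),
                     max_tc_pos = st + which.max(seg) - 1L,
                     stringsAsFactors = FALSE)
        })
        rows <- rows[!vapply(rows, is.null, logical(1))]
        if (length(rows)) cl[[i]] <- do.call(rbind, rows)
      }
    }
    pileups[[r]] <- do.call(rbind, pl[!vapply(pl, is.null, logical(1))])
    keep <- !vapply(cl, is.null, logical(1))
    clusters[[r]] <- if (any(keep)) do.call(rbind, cl[keep]) else
      data.frame(transcript_id = character(), start = integer(),
                 end = integer(), tc_sum = numeric(),
                 max_tc_pos = integer(), stringsAsFactors = FALSE)
    rownames(pileups[[r]]) <- NULL
    rownames(clusters[[r]]) <- NULL
  }
  list(pileups = pileups, clusters = clusters)
}

#' Simulate fractionation RNA-seq counts
#'
#' Produces a count matrix for whole-cell, two cytosol and two membrane
#' samples. Gene means split between fractions according to the planted
#' log2 membrane enrichment; counts are negative binomial
#' (\code{dispersion} is the NB dispersion alpha so that variance =
#' mu + alpha mu^2); \code{dispersion = 0} gives Poisson counts.
#'
#' @param tx,truth Simulated transcriptome and truth.
#' @param lib_sizes Named numeric of library sizes, names
#'   \code{wholecell}, \code{cytosol_1}, \code{cytosol_2},
#'   \code{membrane_1}, \code{membrane_2}.
#' @param dispersion NB dispersion (alpha); 0 for Poisson.
#' @param seed Integer seed.
#' @return Integer matrix genes x samples with gene ids as rownames and an
#'   attribute \code{lengths} (transcript lengths, for TPM).
#' @export
simulate_fraction_counts <- function(tx, truth,
                                     lib_sizes = c(wholecell = 2e6,
                                                   cytosol_1 = 2e6,
                                                   cytosol_2 = 2e6,
                                                   membrane_1 = 2e6,
                                                   membrane_2 = 2e6),
                                     dispersion = 0.05, seed = 1L) {
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  set.seed(stage_seed(seed, "fractions"))
  df <- tx$transcripts
  M <- truth$classes$planted_enrichment[match(df$gene_id,
                                              truth$classes$gene_id)]
  len <- df$len5utr + df$lencds + df$len3utr
  tpm <- truth$expression$tpm_true[match(df$gene_id,
                                         truth$expression$gene_id)]
  mass <- tpm * len            # read mass ~ molar abundance x length
  q <- mass / sum(mass)
  wc <- q
  wcyt <- q * 2^(-M / 2); wcyt <- wcyt / sum(wcyt)
  wmem <- q * 2^(M / 2); wmem <- wmem / sum(wmem)

  draw <- function(mu) {
    if (dispersion <= 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  counts <- cbind(
    wholecell = draw(wc * lib_sizes[["wholecell"]]),
    cytosol_1 = draw(wcyt * lib_sizes[["cytosol_1"]]),
    cytosol_2 = draw(wcyt * lib_sizes[["cytosol_2"]]),
    membrane_1 = draw(wmem * lib_sizes[["membrane_1"]]),
    membrane_2 = draw(wmem * lib_sizes[["membrane_2"]])
  )
  rownames(counts) <- df$gene_id
  attr(counts, "lengths") <- stats::setNames(len, df$gene_id)
  counts
}

#' Simulate ribosome footprint 5'-end tables
#'
#' Per-codon footprint counts are Poisson with a rate proportional to
#' transcript abundance, modulated by per-codon dwell multipliers: in WT a
#' pause window of \code{pause_codons} codons starting at the end of the
#' targeting signal gets \code{pause_mult_wt}; in KO the pause is reduced
#' to \code{pause_mult_ko} and codons in \code{ko_codon_set} dwell
#' \code{ko_codon_mult} times longer. Footprints are reported as 5' ends at
#' P-site minus \code{offset} nt.
#'
#' @param tx,truth Simulated transcriptome and truth.
#' @param depth Mean footprints per codon at average abundance.
#' @param pause_codons Pause window length in codons.
#' @param pause_mult_wt,pause_mult_ko Dwell multipliers in the pause window.
#' @param ko_codon_set Codons (DNA spelling) with raised dwell in KO.
#' @param ko_codon_mult Multiplier for those codons.
#' @param te_coupling Per-gene log2 KO translation deficit per planted
#'   hotspot motif (0 disables the coupling).
#' @param n_replicates Replicates per condition.
#' @param offset P-site offset in nt.
#' @param seed Integer seed.
#' @return Nested list \code{res[[condition]][[replicate]]}: data frames
#'   with \code{transcript_id}, \code{pos5p} (0-based 5'-end), \code{count}.
#' @export
simulate_footprints <- function(tx, truth, depth = 2,
                                pause_codons = 10L, pause_mult_wt = 2.0,
                                pause_mult_ko = 1.2,
                                ko_codon_set = c("CTT", "CTC", "TTC", "TTT"),
                                ko_codon_mult = 1.3,
                                te_coupling = 0,
                                n_replicates = 2L, offset = 13L,
                                seed = 1L) {
  df <- tx$transcripts
  rel <- pmin(truth$expression$rel_expr[match(df$transcript_id,
                                              truth$expression$transcript_id)],
              10)
  nhot <- table(truth$motifs$transcript_id)
  res <- list(WT = vector("list", n_replicates),
              KO = vector("list", n_replicates))
  for (cond in c("WT", "KO")) {
    for (r in seq_len(n_replicates)) {
      set.seed(stage_seed(seed, "footprints") +
                 (if (cond == "KO") 100L else 0L) + r)
      out <- vector("list", nrow(df))
      for (i in seq_len(nrow(df))) {
        ncod <- df$lencds[i] %/% 3L
        if (ncod < 1L) next
        starts <- df$len5utr[i] + 3L * (seq_len(ncod) - 1L)
        codons <- substring(df$sequence[i], starts + 1L, starts + 3L)
        dwell <- rep(1, ncod)
        p <- truth$pause[truth$pause$transcript_id == df$transcript_id[i],
                         , drop = FALSE]
        if (nrow(p)) {
          win <- p$codon[1L]:min(ncod, p$codon[1L] + pause_codons - 1L)
          if (max(win) > ncod) stop("pause window extends past the CDS")
          dwell[win] <- dwell[win] *
            (if (cond == "WT") pause_mult_wt else pause_mult_ko)
        }
        if (cond == "KO") {
          dwell[codons %in% ko_codon_set] <-
            dwell[codons %in% ko_codon_set] * ko_codon_mult
        }
        gene_scale <- 1
        if (cond == "KO" && te_coupling != 0) {
          nm <- if (df$transcript_id[i] %in% names(nhot))
            nhot[[df$transcript_id[i]]] else 0L
          gene_scale <- 2^(-te_coupling * nm)
        }
        cnt <- stats::rpois(ncod, depth * rel[i] * dwell * gene_scale)
        keep <- cnt > 0 & starts - offset >= 0L
        if (!any(keep)) next
        out[[i]] <- data.frame(transcript_id = df$transcript_id[i],
                               pos5p = starts[keep] - offset,
                               count = cnt[keep], stringsAsFactors = FALSE)
      }
      out <- out[!vapply(out, is.null, logical(1))]
      res[[cond]][[r]] <- if (length(out)) do.call(rbind, out) else
        data.frame(transcript_id = character(), pos5p = integer(),
                   count = integer(), stringsAsFactors = FALSE)
      rownames(res[[cond]][[r]]) <- NULL
    }
  }
  res
}

#' Simulate tRNA crosslinking data and proteomics tables
#'
#' tRNA side: a reference set of synthetic tRNAs with dihydrouridine mask
#' positions; a configurable subset gets a genuine crosslink excess at
#' non-masked U positions, while masked positions receive
#' crosslink-independent T-C noise in every tRNA (the reverse-transcription
#' artifact the mask exists for). Proteomics side: a BioID LFQ table (3 Dox
#' and 2 noDox replicates) with a planted true-positive set, and a pulsed
#' SILAC pair table in forward and reverse label orientation with a
#' configurable requantified fraction.
#'
#' @param truth Truth object (used for the seed; extended and returned).
#' @param params List overriding any of: \code{n_trna}, \code{trna_len},
#'   \code{mask_positions} (0-based), \code{excess} (named per-tRNA factor;
#'   default tRNA 1 gets \code{excess_factor}, tRNA 2 gets 0 =
#'   modification-only), \code{excess_factor}, \code{base_tc_rate},
#'   \code{mask_tc_rate}, \code{trna_depth}; \code{n_proteins},
#'   \code{n_true}, \code{true_ratio}, \code{min_peptides_true};
#'   \code{silac_sd}, \code{requant_rate}.
#' @param seed Integer seed.
#' @return List with \code{trna} (\code{reference}, \code{masks},
#'   \code{pileup}, \code{abundance}), \code{bioid} (LFQ table),
#'   \code{silac} (pair table) and \code{truth} (planted tRNA excess,
#'   true-positive proteins, planted SILAC ratios).
#' @export
simulate_trna_and_proteomics <- function(truth, params = list(), seed = 1L) {
  p <- utils::modifyList(list(
    n_trna = 20L, trna_len = 76L, mask_positions = c(15L, 16L, 19L),
    excess_factor = 3, base_tc_rate = 0.02, mask_tc_rate = 0.10,
    trna_err_rate = 0.002, trna_depth = 2000,
    n_proteins = 200L, n_true = 20L, true_ratio = 8,
    min_peptides_true = 3L,
    silac_sd = 0.3, requant_rate = 0.15
  ), params)
  if (p$excess_factor < 0) stop("excess factor must be non-negative")

  set.seed(stage_seed(seed, "trna"))
  ids <- sprintf("tRNA%02d", seq_len(p$n_trna))
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(p$n_trna), function(i) {
    s <- sample(bases, p$trna_len, replace = TRUE)
    s[p$mask_positions + 1L] <- "T"  # dihydrouridine sits on a U
    paste0(s, collapse = "")
  }, character(1))
  excess <- stats::setNames(rep(1, p$n_trna), ids)
  if (p$n_trna >= 1L) excess[1L] <- p$excess_factor
  if (p$n_trna >= 2L) excess[2L] <- 0  # modification-only control
  if (!is.null(params$excess)) {
    excess[names(params$excess)] <- params$excess
  }
  abund <- stats::rlnorm(p$n_trna, log(1000), 0.5)
  pile <- vector("list", p$n_trna)
  for (i in seq_len(p$n_trna)) {
    chars <- strsplit(seqs[i], "")[[1L]]
    tp <- which(chars == "T")
    cov <- stats::rpois(length(tp), p$trna_depth * abund[i] / mean(abund))
    masked <- (tp - 1L) %in% p$mask_positions
    rate <- ifelse(masked, p$mask_tc_rate,
                   p$trna_err_rate + p$base_tc_rate * excess[i])
    tc <- stats::rbinom(length(tp), cov, pmin(1, rate))
    pile[[i]] <- data.frame(trna_id = ids[i], position = tp - 1L,
                            coverage = cov, tc_count = tc,
                            stringsAsFactors = FALSE)
  }
  trna <- list(
    reference = data.frame(trna_id = ids, sequence = seqs,
                           stringsAsFactors = FALSE),
    masks = do.call(rbind, lapply(ids, function(id)
      data.frame(trna_id = id, position = p$mask_positions,
                 stringsAsFactors = FALSE))),
    pileup = do.call(rbind, pile),
    abundance = data.frame(trna_id = ids,
                           reads = stats::rpois(p$n_trna, abund * 50),
                           stringsAsFactors = FALSE)
  )
  rownames(trna$pileup) <- NULL

  set.seed(stage_seed(seed, "proteomics"))
  prot <- sprintf("P%04d", seq_len(p$n_proteins))
  is_true <- seq_len(p$n_proteins) <= p$n_true
  base_log2 <- ifelse(is_true, stats::runif(p$n_proteins, 24.5, 27),
                      stats::runif(p$n_proteins, 22, 28.5))
  base <- 2^base_log2
  ratio <- ifelse(is_true,
                  p$true_ratio * stats::rlnorm(p$n_proteins, 0, 0.1),
                  stats::rlnorm(p$n_proteins, 0, 0.25))
  noise <- function(n) stats::rlnorm(n, 0, 0.05)
  lfq_nodox_2 <- base * noise(p$n_proteins)
  lfq_nodox_3 <- base * noise(p$n_proteins)
  dropout <- !is_true & stats::runif(p$n_proteins) < 0.05
  lfq_nodox_2[dropout] <- 0
  bioid <- data.frame(
    protein_group = prot,
    lfq_dox_1 = base * ratio * noise(p$n_proteins),
    lfq_dox_2 = base * ratio * noise(p$n_proteins),
    lfq_dox_3 = base * ratio * noise(p$n_proteins),
    lfq_nodox_2 = lfq_nodox_2,
    lfq_nodox_3 = lfq_nodox_3,
    razor_unique_peptides = ifelse(is_true,
                                   sample(p$min_peptides_true:20,
                                          p$n_proteins, replace = TRUE),
                                   sample(1:20, p$n_proteins,
                                          replace = TRUE)),
    stringsAsFactors = FALSE
  )

  planted_silac <- stats::rnorm(p$n_proteins, 0, 0.5)
  rows <- list()
  for (i in seq_len(p$n_proteins)) {
    for (orient in c("forward", "reverse")) {
      for (r in 1:2) {
        raw <- if (orient == "forward")
          planted_silac[i] + stats::rnorm(1, 0, p$silac_sd)
        else
          -planted_silac[i] + stats::rnorm(1, 0, p$silac_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          protein_group = prot[i], orientation = orient, replicate = r,
          log2_ratio = raw,
          requant_num = stats::runif(1) < p$requant_rate,
          requant_den = stats::runif(1) < p$requant_rate,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  silac <- do.call(rbind, rows)

  list(
    trna = trna, bioid = bioid, silac = silac,
    truth = list(
      trna_excess = excess,
      true_positive_proteins = prot[is_true],
      planted_silac_log2 = stats::setNames(planted_silac, prot)
    )
  )
}
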