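test_that("P-site offsetting shifts, drops and conserves reads", {
  tx <- toy_tx(1, len5 = 20, ncod = 40, len3 = 20)  # length 160
  reads <- data.frame(transcript_id = "TX01",
                      pos5p = c(100L, 150L, 5L),
                      count = c(3L, 2L, 1L), stringsAsFactors = FALSE)
  res <- apply_psite_offset(reads, tx, offset = 13)
  expect_equal(res$psites$psite[1], 113L)
  expect_equal(res$dropped, 2L)  # 150 + 13 exits the transcript
  expect_equal(res$retained + res$dropped, sum(reads$count))

  id <- apply_psite_offset(reads, tx, offset = 0)
  expect_equal(id$psites$psite, reads$pos5p)
  expect_error(apply_psite_offset(reads, tx, offset = -1), "negative")
  bad <- reads; bad$pos5p[1] <- 200L
  expect_error(apply_psite_offset(bad, tx), "bounds")
})

test_that("start/stop metagene scales to trimmed CDS mean and filters", {
  tx <- toy_tx(1, len5 = 20, ncod = 40, len3 = 20)
  # uniform coverage of 2 on every codon start
  ps <- data.frame(transcript_id = "TX01",
                   psite = 20L + 3L * (0:39), count = 2L,
                   stringsAsFactors = FALSE)
  mg <- metagene_start_stop(ps, tx, roll = 1, span = c(10L, 60L))
  inside <- mg$start$rel_pos >= 0 & mg$start$rel_pos < 120
  # per-nt scaled coverage: 2 at codon starts, 0 elsewhere; mean 2/3... the
  # scaling mean is per-nt, so codon-start positions sit at 3x the mean
  vals <- mg$start$mean_scaled[inside]
  expect_equal(sort(unique(round(vals, 6))), c(0, 3))
  expect_equal(mg$n_transcripts, 1L)

  # total codon coverage below five is excluded
  ps4 <- data.frame(transcript_id = "TX01", psite = c(50L, 62L),
                    count = c(2L, 2L), stringsAsFactors = FALSE)
  mg4 <- metagene_start_stop(ps4, tx)
  expect_equal(mg4$n_transcripts, 0L)

  expect_error(metagene_start_stop(ps, toy_tx(1, ncod = 3), trim_codons = 2),
               "shorter")
})

test_that("start/stop metagene equals the scale-then-average brute force", {
  set.seed(111)
  tx <- toy_tx(6, len5 = 15, ncod = 30, len3 = 15)
  ps <- do.call(rbind, lapply(tx$transcripts$transcript_id, function(tid) {
    n <- sample(20:40, 1)
    data.frame(transcript_id = tid,
               psite = sample(15:(15 + 89), n),
               count = rpois(n, 3) + 1L, stringsAsFactors = FALSE)
  }))
  mg <- metagene_start_stop(ps, tx, roll = 1, span = c(5L, 30L))
  # brute force at one arbitrary in-CDS offset
  probe <- 7L  # rel_pos +7 from the start codon
  acc <- c(); n_inc <- 0
  for (tid in tx$transcripts$transcript_id) {
    p <- ps[ps$transcript_id == tid, ]
    nt <- rep(0, 120)
    for (j in seq_len(nrow(p))) nt[p$psite[j] + 1] <-
        nt[p$psite[j] + 1] + p$count[j]
    codon_cov <- colSums(matrix(nt[16:105], nrow = 3))
    if (sum(codon_cov) < 5) next
    core <- mean(codon_cov[3:28]) / 3
    acc <- c(acc, nt[15 + probe + 1] / core)
    n_inc <- n_inc + 1
  }
  got <- mg$start$mean_scaled[mg$start$rel_pos == probe]
  expect_equal(got, sum(acc) / n_inc)
  expect_equal(mg$n_transcripts, n_inc)
})

test_that("targeting-signal metagene normalizes to codons 20-40", {
  sim <- simulate_transcriptome(n_genes = 40, seed = 14)
  tx <- sim$transcriptome
  fp <- simulate_footprints(tx, sim$truth, depth = 5, seed = 14)
  ps <- apply_psite_offset(fp$WT[[1]], tx)$psites
  tpm <- stats::setNames(rep(100, nrow(tx$transcripts)),
                         tx$transcripts$transcript_id)
  mg1 <- metagene_targeting_signal(ps, tx, tpm, norm_codons = c(20L, 40L),
                                   roll = 1, span_codons = 120)
  mg2 <- metagene_targeting_signal(ps, tx, tpm, norm_codons = c(30L, 50L),
                                   roll = 1, span_codons = 120)
  # changing the normalization window rescales profiles; both stay finite
  expect_true(any(is.finite(mg1$profile$mean_scaled)))
  expect_true(any(is.finite(mg2$profile$mean_scaled)))
  # low-TPM transcripts are excluded entirely
  mg0 <- metagene_targeting_signal(ps, tx,
                                   stats::setNames(rep(1, length(tpm)),
                                                   names(tpm)))
  expect_true(all(mg0$profile$n_transcripts == 0))
})

test_that("normalization-window rescaling is a per-transcript constant", {
  tx <- toy_tx(1, len5 = 21, ncod = 100, len3 = 30)
  tx$signals <- data.frame(transcript_id = "TX01", kind = "signal_peptide",
                           aa_start = 1L, aa_end = 22L,
                           nt_start = 21L, nt_end = 87L,
                           stringsAsFactors = FALSE)
  set.seed(9)
  ps <- data.frame(transcript_id = "TX01",
                   psite = 21L + 3L * (0:99),
                   count = rpois(100, 10) + 1L, stringsAsFactors = FALSE)
  tpm <- c(TX01 = 100)
  mgA <- metagene_targeting_signal(ps, tx, tpm, norm_codons = c(20L, 40L),
                                   roll = 1, span_codons = 100)
  mgB <- metagene_targeting_signal(ps, tx, tpm, norm_codons = c(30L, 50L),
                                   roll = 1, span_codons = 100)
  ratio <- mgA$profile$mean_scaled / mgB$profile$mean_scaled
  ratio <- ratio[is.finite(ratio)]
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-9)
  expect_equal(unname(mgA$median_signal_end["signal_peptide"]), 22)
})

test_that("codon occupancy shifts are zero-sum and null for equal input", {
  sim <- simulate_transcriptome(n_genes = 30, seed = 15)
  tx <- sim$transcriptome
  fp <- simulate_footprints(tx, sim$truth, depth = 3, seed = 15)
  ps <- lapply(fp$WT, function(r) apply_psite_offset(r, tx)$psites)
  same <- codon_occupancy_shift(ps, ps, tx, site = "P")
  expect_equal(nrow(same), 61L)
  expect_true(all(same$delta == 0))
  expect_equal(sum(same$freq_wt), 1)

  ps_ko <- lapply(fp$KO, function(r) apply_psite_offset(r, tx)$psites)
  shift <- codon_occupancy_shift(ps, ps_ko, tx, site = "P")
  expect_equal(sum(shift$delta), 0, tolerance = 1e-12)
  esite <- codon_occupancy_shift(ps, ps_ko, tx, site = "E")
  expect_equal(sum(esite$delta), 0, tolerance = 1e-12)
  expect_error(codon_occupancy_shift(ps, ps_ko[1], tx), "mismatched")
})

test_that("translation efficiency is a normalized ratio of ratios", {
  set.seed(16)
  genes <- sprintf("g%02d", 1:20)
  base <- rpois(20, 200) + 50L
  rpf <- cbind(wt1 = base, wt2 = base, ko1 = base, ko2 = base)
  rna <- rpf
  rownames(rpf) <- rownames(rna) <- genes
  wt <- list(rpf = c("wt1", "wt2"), rna = c("wt1", "wt2"))
  ko <- list(rpf = c("ko1", "ko2"), rna = c("ko1", "ko2"))
  te0 <- translation_efficiency(rpf, rna, wt, ko)
  expect_true(all(te0$log2_te_change == 0))

  rpf2 <- rpf
  rpf2[, c("ko1", "ko2")] <- rpf2[, c("ko1", "ko2")] %/% 2L
  te <- translation_efficiency(rpf2, rna, wt, ko, pseudocount = 0)
  # size factors absorb the global halving of the KO RPF samples, so a
  # uniform change in every gene reads as no TE change
  expect_equal(te$log2_te_change, rep(0, 20), tolerance = 0.05)

  # a gene-specific halving survives normalization and is antisymmetric
  rpf3 <- rpf
  rpf3[1, c("ko1", "ko2")] <- rpf3[1, c("ko1", "ko2")] %/% 2L
  te3 <- translation_efficiency(rpf3, rna, wt, ko, pseudocount = 0)
  expect_equal(te3$log2_te_change[1], -1, tolerance = 0.05)
  te3r <- translation_efficiency(rpf3, rna, ko, wt, pseudocount = 0)
  expect_equal(te3$log2_te_change, -te3r$log2_te_change)
})
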