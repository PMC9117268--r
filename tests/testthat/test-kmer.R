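test_that("crosslinked k-mer counting handles registers and boundaries", {
  # poly-U run: every overlapping window is UUUU
  seqs <- paste0(strrep("T", 30), rand_seq(60))
  tx <- toy_tx(1, len5 = 12, ncod = 20, len3 = 18, seqs = seqs)
  sites <- data.frame(transcript_id = "TX01", position = 10L,
                      stringsAsFactors = FALSE)
  sites$region <- region_of(tx, sites$transcript_id, sites$position)
  kc <- count_crosslinked_kmers(sites, tx, k = 4)
  expect_equal(kc$overall$kmer, "TTTT")
  expect_equal(kc$overall$freq, 1)
  expect_equal(kc$overall$count, 4L)  # four overlapping registers

  # site at position 0: only one window fits
  sites0 <- data.frame(transcript_id = "TX01", position = 0L,
                       region = "utr5", stringsAsFactors = FALSE)
  kc0 <- count_crosslinked_kmers(sites0, tx, k = 4)
  expect_equal(sum(kc0$overall$count), 1L)

  # single-register mode counts exactly one window per site
  kc1 <- count_crosslinked_kmers(sites, tx, k = 4, register = "start")
  expect_equal(sum(kc1$overall$count), 1L)

  expect_error(count_crosslinked_kmers(sites, tx, k = 3), "between 4 and 12")
})

test_that("crosslinked k-mer counts match brute-force window enumeration", {
  set.seed(51)
  for (rep in 1:10) {
    tx <- toy_tx(4, len5 = 15, ncod = 25, len3 = 20)
    sites <- rand_sites(tx, 100)
    k <- sample(4:7, 1)
    got <- count_crosslinked_kmers(sites, tx, k = k)$overall
    exp <- bf_count_kmers(sites, tx, k)
    expect_equal(stats::setNames(got$count[order(got$kmer)],
                                 sort(got$kmer)), exp)
  }
})

test_that("per-gene k-mer crosslink signal follows the stated normalization", {
  tx <- toy_tx(1, len5 = 10, ncod = 20, len3 = 100,
               seqs = paste0(rand_seq(10), rand_seq(60), strrep("A", 100)))
  # one site deep inside the 3'UTR of an all-A tail: all windows are AAAA
  sites <- data.frame(transcript_id = "TX01", position = 120L,
                      tc_1 = 4, tc_2 = 4, stringsAsFactors = FALSE)
  sites$region <- region_of(tx, sites$transcript_id, sites$position)
  res <- kmer_crosslink_signal(sites, tx, c(GX01 = 2), k = 4)
  aaaa <- res$per_gene[res$per_gene$kmer == "AAAA", ]
  expect_equal(aaaa$signal, 4 / 100 / 2)  # tc / len3utr / tpm
  # doubling TPM halves the signal
  res2 <- kmer_crosslink_signal(sites, tx, c(GX01 = 4), k = 4)
  expect_equal(res2$per_gene$signal[res2$per_gene$kmer == "AAAA"],
               aaaa$signal / 2)
})

test_that("class z-scores are standardized and respond to enrichment", {
  seqs <- replicate(5, rand_seq(200))
  z0 <- kmer_class_zscores(seqs, seqs, k = 4)
  expect_true(all(z0$table$delta_f == 0))
  expect_true(all(z0$table$z == 0))

  set.seed(61)
  base <- replicate(20, rand_seq(300))
  spiked <- vapply(base, function(s)
    paste0(s, strrep("TTCT", 8)), character(1))
  z <- kmer_class_zscores(spiked, base, k = 4,
                          top_bound_set = c("UUCU", "UCUU"))
  expect_equal(mean(z$table$z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z$table$z), 1, tolerance = 1e-12)
  expect_equal(z$table$kmer[which.max(z$table$z)], "TTCT")
  expect_lt(z$wilcox_p, 0.05)
  expect_error(kmer_class_zscores(character(), base), "empty")
})

test_that("background k-mer frequencies match Biostrings", {
  set.seed(71)
  seqs <- replicate(6, rand_seq(150))
  mine <- multiclip:::.sequence_kmer_freq(seqs, 4)
  ref <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), 4))
  expect_equal(unname(mine), unname(ref / sum(ref)))
})

test_that("multivalency scoring applies the window and exclusion zone", {
  # single motif occurrence starting at 0-based 50 in an all-A background
  seqs <- paste0(strrep("A", 50), "TTCT", strrep("A", 96))
  tx <- toy_tx(1, len5 = 30, ncod = 30, len3 = 30, seqs = seqs)
  anchors <- data.frame(
    transcript_id = "TX01",
    position = c(50L, 53L, 54L, 46L, 90L, 91L, 10L, 9L),
    tc_1 = 1, tc_2 = 1, stringsAsFactors = FALSE)
  anchors$region <- region_of(tx, anchors$transcript_id, anchors$position)
  mv <- multivalency_scores(anchors, tx, "UUCU", n_bins = 2)
  sc <- mv$records$score
  # anchor on the motif start (distance 0) and within +/-3: excluded
  expect_equal(sc[1], 0L); expect_equal(sc[2], 0L)
  # distance 4 on either side: included
  expect_equal(sc[3], 1L); expect_equal(sc[4], 1L)
  # distance 40: included; 41: out of the window
  expect_equal(sc[5], 1L); expect_equal(sc[6], 0L)
  expect_equal(sc[7], 1L); expect_equal(sc[8], 0L)
  expect_error(multivalency_scores(anchors, tx, character()), "empty")
})

test_that("multivalency scores match the brute-force window scan", {
  set.seed(81)
  group <- c("TTCT", "CTTC", "TCTT", "CTCT")
  for (rep in 1:8) {
    tx <- toy_tx(3, len5 = 20, ncod = 40, len3 = 30)
    sites <- rand_sites(tx, 60)
    mv <- multivalency_scores(sites, tx, group)
    expect_equal(mv$records$score, bf_multivalency(sites, tx, group))
  }
})

test_that("multivalency bins are near-equal and profiles sum to 100", {
  set.seed(91)
  tx <- toy_tx(4, len5 = 20, ncod = 60, len3 = 40)
  sites <- rand_sites(tx, 83)
  sites <- normalize_tc_per_million(sites, c(1000, 1000))
  mv <- multivalency_scores(sites, tx, c("TTCT", "CTTC"), n_bins = 5)
  sizes <- table(mv$records$bin)
  expect_lte(max(sizes) - min(sizes), 1)
  # bins are ordered by score: each bin's maximum does not exceed the
  # next bin's minimum
  mx <- tapply(mv$records$score, mv$records$bin, max)
  mn <- tapply(mv$records$score, mv$records$bin, min)
  expect_true(all(mx[-length(mx)] <= mn[-1]))
  rows <- rowSums(mv$positional)
  expect_equal(unname(rows[rows > 0]),
               rep(100, sum(rows > 0)))
})

test_that("sliding-window potential keeps windows with enough occurrences", {
  # tandem UUCU repeats: every window of 30 nt holds 7 full starts
  seqs <- paste0(strrep("TTCT", 30), rand_seq(60))
  tx <- toy_tx(1, len5 = 30, ncod = 30, len3 = 60, seqs = seqs)
  pot <- sliding_window_potential(tx, "UUCU", regions = "utr5")
  # 5'UTR is TTCT repeated: windows of width 30 contain 7 or 8 starts
  expect_equal(pot$n_kept_windows, 1L)  # utr5 length 30 -> one window
  expect_gte(pot$mean_window_score, 7)

  # a group absent from the sequence scores zero
  pot0 <- sliding_window_potential(tx, "GGGG", regions = "cds")
  expect_equal(pot0$mean_window_score, 0)
  expect_equal(pot0$n_kept_windows, 0L)

  # windows below min_count are discarded
  seq2 <- paste0("TTCT", strrep("A", 26), "TTCTAATTCT", rand_seq(50))
  tx2 <- toy_tx(1, len5 = 30, ncod = 10, len3 = 30, seqs = seq2)
  pot2 <- sliding_window_potential(tx2, "UUCU", min_count = 3,
                                   regions = "utr5")
  expect_equal(pot2$n_kept_windows, 0L)  # at most 2 occurrences per window
})

test_that("sliding-window counts match the brute-force scan", {
  set.seed(101)
  group <- c("TTCT", "CTCT")
  for (rep in 1:8) {
    seqs <- rand_seq(150)
    tx <- toy_tx(1, len5 = 30, ncod = 30, len3 = 30, seqs = seqs)
    pot <- sliding_window_potential(tx, group, regions = "cds",
                                    min_count = 1)
    cds <- substr(seqs, 31, 120)
    kept <- bf_sliding_window(cds, group, min_count = 1)
    expect_equal(pot$n_kept_windows, length(kept))
    expect_equal(pot$mean_window_score,
                 if (length(kept)) mean(kept) else 0)
  }
})
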