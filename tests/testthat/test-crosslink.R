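mk_cluster <- function(tid, st, en, tc, peak) {
  data.frame(transcript_id = tid, start = st, end = en, tc_sum = tc,
             max_tc_pos = peak, stringsAsFactors = FALSE)
}

test_that("cluster reproducibility thresholds are boundary-inclusive", {
  a <- mk_cluster("T1", 100L, 150L, 3, 120L)
  b <- mk_cluster("T1", 100L, 150L, 3, 121L)
  kept <- filter_reproducible_clusters(a, b)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$mean_tc, 3)
  expect_equal(kept$start, 100L)

  # 10% overlap fails the 50% requirement
  b2 <- mk_cluster("T1", 145L, 195L, 3, 146L)
  expect_equal(nrow(filter_reproducible_clusters(a, b2)), 0L)

  # peaks 11 nt apart fail, 10 nt pass
  b3 <- mk_cluster("T1", 100L, 150L, 3, 131L)
  expect_equal(nrow(filter_reproducible_clusters(a, b3)), 0L)
  b4 <- mk_cluster("T1", 100L, 150L, 3, 130L)
  expect_equal(nrow(filter_reproducible_clusters(a, b4)), 1L)

  # mean T-C just below 3 fails
  b5 <- mk_cluster("T1", 100L, 150L, 2.9, 120L)
  expect_equal(nrow(filter_reproducible_clusters(
    mk_cluster("T1", 100L, 150L, 2.9, 120L), b5)), 0L)

  expect_error(filter_reproducible_clusters(
    mk_cluster("T1", 10L, 10L, 3, 10L), b), "malformed")
})

test_that("reciprocal overlap is stricter than either-cluster overlap", {
  a <- mk_cluster("T1", 100L, 200L, 5, 150L)   # length 100
  b <- mk_cluster("T1", 140L, 180L, 5, 150L)   # length 40, inside a
  expect_equal(nrow(filter_reproducible_clusters(a, b)), 0L)
  expect_equal(nrow(filter_reproducible_clusters(
    a, b, overlap_mode = "either")), 1L)
})

test_that("cluster filter matches the all-pairs brute force on random data", {
  set.seed(101)
  for (rep in 1:20) {
    a <- rand_clusters(sample(5:40, 1))
    b <- rand_clusters(sample(5:40, 1))
    got <- filter_reproducible_clusters(a, b)
    exp <- bf_filter_clusters(a, b)
    expect_equal(got, exp)
  }
})

test_that("site filtering removes irreproducible and variant positions", {
  tx <- toy_tx(1, len5 = 10, ncod = 20, len3 = 10)
  p1 <- data.frame(transcript_id = "TX01", position = c(5L, 15L, 25L),
                   coverage = c(20L, 50L, 30L), tc_count = c(20L, 5L, 4L),
                   stringsAsFactors = FALSE)
  p2 <- data.frame(transcript_id = "TX01", position = c(5L, 15L, 40L),
                   coverage = c(20L, 50L, 30L), tc_count = c(20L, 5L, 4L),
                   stringsAsFactors = FALSE)
  sites <- filter_sites(p1, p2, tx)
  # pos 5: specificity 1.0 in both -> removed; pos 25/40: one replicate
  # only -> removed; pos 15: kept with its region label
  expect_equal(sites$position, 15L)
  expect_equal(sites$region, "cds")
  expect_equal(sites$spec_1, 0.1)

  bad <- p1; bad$coverage[1] <- 0L
  expect_error(filter_sites(bad, p2, tx), "zero coverage")
})

test_that("T-C per million normalization has the closed-form total", {
  tx <- toy_tx(3)
  set.seed(5)
  sites <- rand_sites(tx, 50)
  lib <- c(2000, 4000)
  out <- normalize_tc_per_million(sites, lib)
  expect_equal(out$tcpm_1[1], sites$tc_1[1] * 1e6 / 2000)
  expect_equal(sum(out$tcpm_1), 1e6 * sum(sites$tc_1) / lib[1])
  expect_equal(sum(out$tcpm_2), 1e6 * sum(sites$tc_2) / lib[2])
  expect_equal(normalize_tc_per_million(
    data.frame(transcript_id = "a", position = 1L, tc_1 = 0, tc_2 = 0),
    c(1e6, 1e6))$tcpm_1, 0)
  expect_error(normalize_tc_per_million(sites, c(0, 1)), "positive")
})

test_that("gene summaries conserve the region split and compute E", {
  tx <- toy_tx(2, len5 = 10, ncod = 20, len3 = 60)
  sites <- data.frame(
    transcript_id = "TX01", position = c(2L, 12L, 15L, 70L),
    tc_1 = c(2, 6, 2, 4), tc_2 = c(2, 6, 2, 4),
    stringsAsFactors = FALSE)
  sites$region <- region_of(tx, sites$transcript_id, sites$position)
  tpm <- c(GX01 = 10, GX02 = 5)
  g <- summarize_gene_crosslinks(sites, tx, tpm)
  r1 <- g[g$gene_id == "GX01", ]
  expect_equal(r1$tc_total, 14)
  expect_equal(r1$tc_total, r1$tc_5utr + r1$tc_cds + r1$tc_3utr)
  expect_equal(r1$tc_5utr, 2)
  expect_equal(r1$enrichment, 1.4)
  # gene without sites: zero split, still conserved
  r2 <- g[g$gene_id == "GX02", ]
  expect_equal(r2$tc_total, 0)
  expect_equal(r2$enrichment, 0)
})

test_that("crosslink groups follow the configured statistic thresholds", {
  tx <- toy_tx(1)
  sites <- data.frame(transcript_id = "TX01", position = 20L,
                      tc_1 = 2, tc_2 = 2, stringsAsFactors = FALSE)
  sites$region <- region_of(tx, sites$transcript_id, sites$position)
  # statistic = raw enrichment: TC/TPM = 2/10 = 0.2 < 0.3 -> lowest group
  g <- summarize_gene_crosslinks(sites, tx, c(GX01 = 10),
                                 statistic = "enrichment")
  expect_equal(g$statistic, 0.2)
  expect_equal(g$crosslink_group, "low")
  g2 <- summarize_gene_crosslinks(sites, tx, c(GX01 = 2),
                                  statistic = "enrichment")
  expect_equal(g2$crosslink_group, "mid")   # 1.0 between 0.3 and 1.39
  g3 <- summarize_gene_crosslinks(sites, tx, c(GX01 = 1),
                                  statistic = "enrichment")
  expect_equal(g3$crosslink_group, "high")  # 2.0 >= 1.39
})

test_that("equal region densities give a log2 CDS/3'UTR ratio of zero", {
  tx <- toy_tx(1, len5 = 10, ncod = 20, len3 = 60)  # lencds = len3utr = 60
  sites <- data.frame(transcript_id = "TX01", position = c(15L, 75L),
                      tc_1 = c(4, 4), tc_2 = c(4, 4),
                      stringsAsFactors = FALSE)
  sites$region <- region_of(tx, sites$transcript_id, sites$position)
  g <- summarize_gene_crosslinks(sites, tx, c(GX01 = 1))
  expect_equal(g$log2_cds_utr3_ratio, 0)
  expect_error(summarize_gene_crosslinks(
    data.frame(transcript_id = "nope", position = 1L, tc_1 = 1, tc_2 = 1,
               region = "cds"), tx, c(GX01 = 1)), "absent")
})

test_that("meta profile scales each transcript to a maximum of one", {
  tx <- toy_tx(1, len5 = 10, ncod = 20, len3 = 10)
  sites <- data.frame(transcript_id = "TX01", position = 30L,
                      tc_1 = 5, tc_2 = 5, stringsAsFactors = FALSE)
  sites$region <- region_of(tx, sites$transcript_id, sites$position)
  sites <- normalize_tc_per_million(sites, c(100, 100))
  mp <- meta_transcript_profile(sites, tx, min_tcpm = 5,
                                bins_per_region = c(5L, 10L, 5L))
  expect_equal(mp$n_transcripts, 1L)
  expect_equal(sum(mp$profile$mean_scaled > 0), 1L)
  expect_equal(max(mp$profile$mean_scaled), 1)
  # site at CDS position 20/60 -> bin 4 of 10
  hit <- mp$profile[mp$profile$mean_scaled > 0, ]
  expect_equal(hit$region, "cds")
  expect_equal(hit$bin, 4L)
})

test_that("meta profile excludes transcripts below the tcpm threshold", {
  tx <- toy_tx(2)
  sites <- data.frame(transcript_id = c("TX01", "TX02"),
                      position = c(30L, 30L),
                      tcpm_1 = c(6, 6), tcpm_2 = c(6, 4),
                      stringsAsFactors = FALSE)
  sites$region <- region_of(tx, sites$transcript_id, sites$position)
  mp <- meta_transcript_profile(sites, tx, min_tcpm = 5)
  expect_equal(mp$n_transcripts, 1L)  # TX02 fails in replicate 2
})

test_that("meta profile equals a direct per-bin recomputation", {
  set.seed(31)
  tx <- toy_tx(10, len5 = 20, ncod = 40, len3 = 30)
  sites <- rand_sites(tx, 120)
  sites <- normalize_tc_per_million(sites, c(500, 500))
  nb <- c(4L, 6L, 5L)
  mp <- meta_transcript_profile(sites, tx, min_tcpm = 0,
                                bins_per_region = nb)
  # brute force: per transcript, per bin, max scaled value; then average
  val <- (sites$tcpm_1 + sites$tcpm_2) / 2
  txs <- unique(sites$transcript_id)
  regions <- c(utr5 = 20L, cds = 120L, utr3 = 30L)
  offs <- c(utr5 = 0L, cds = 20L, utr3 = 140L)
  nbv <- c(utr5 = 4L, cds = 6L, utr3 = 5L)
  expected <- 0
  for (tid in txs) {
    sel <- sites$transcript_id == tid
    sc <- val[sel] / max(val[sel])
    grid <- matrix(0, nrow = 3, ncol = 6,
                   dimnames = list(names(regions), NULL))
    for (j in which(sel)) {
      reg <- sites$region[j]
      rel <- sites$position[j] - offs[[reg]]
      b <- min(floor(rel / regions[[reg]] * nbv[[reg]]) + 1L, nbv[[reg]])
      grid[reg, b] <- max(grid[reg, b], val[j] / max(val[sel]))
    }
    expected <- expected + grid
  }
  expected <- expected / length(txs)
  for (reg in names(regions)) {
    got <- mp$profile$mean_scaled[mp$profile$region == reg]
    expect_equal(got, unname(expected[reg, seq_len(nbv[[reg]])]))
  }
})
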