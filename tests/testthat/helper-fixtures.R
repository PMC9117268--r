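# Small fixture builders shared across test files. Everything is generated
# in code; no data files.

rand_seq <- function(n) paste0(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# a toy transcriptome with n transcripts of identical architecture
toy_tx <- function(n = 4L, len5 = 12L, ncod = 20L, len3 = 18L,
                   classes = NULL, seqs = NULL) {
  lenc <- 3L * ncod
  L <- len5 + lenc + len3
  if (is.null(seqs)) seqs <- vapply(seq_len(n), function(i) rand_seq(L),
                                    character(1))
  if (is.null(classes)) {
    classes <- rep(c("membrane", "cytosolic"), length.out = n)
  }
  transcriptome(data.frame(
    transcript_id = sprintf("TX%02d", seq_len(n)),
    gene_id = sprintf("GX%02d", seq_len(n)),
    sequence = seqs, len5utr = len5, lencds = lenc, len3utr = len3,
    localization_class = classes, stringsAsFactors = FALSE
  ))
}

# random cluster table on a handful of transcripts
rand_clusters <- function(n, tx_ids = c("TA", "TB"), max_pos = 500L) {
  st <- sample(0:(max_pos - 60L), n, replace = TRUE)
  w <- sample(20:60, n, replace = TRUE)
  en <- st + w
  peak <- st + vapply(w, function(x) sample(0:(x - 1L), 1L), integer(1))
  data.frame(transcript_id = sample(tx_ids, n, replace = TRUE),
             start = st, end = en,
             tc_sum = stats::rpois(n, 4),
             max_tc_pos = peak, stringsAsFactors = FALSE)
}

# random site table on a toy transcriptome
rand_sites <- function(tx, n) {
  df <- tx$transcripts
  i <- sample(nrow(df), n, replace = TRUE)
  L <- nchar(df$sequence[i])
  pos <- vapply(L, function(l) sample(0:(l - 1L), 1L), integer(1))
  s <- data.frame(transcript_id = df$transcript_id[i], position = pos,
                  tc_1 = stats::rpois(n, 3) + 1L,
                  tc_2 = stats::rpois(n, 3) + 1L,
                  stringsAsFactors = FALSE)
  s <- s[!duplicated(paste(s$transcript_id, s$position)), , drop = FALSE]
  s$region <- region_of(tx, s$transcript_id, s$position)
  rownames(s) <- NULL
  s
}
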