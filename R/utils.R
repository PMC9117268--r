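#' Centered rolling mean with edge shrinkage
#'
#' Smooths a numeric vector with a centered window; at the boundaries the
#' window is truncated rather than padded, so the output has the same length
#' as the input and no positions are lost.
#'
#' @param x Numeric vector.
#' @param width Window width in positions (>= 1). Even widths use the
#'   \code{floor(width/2)} positions on the left and \code{width - 1 -
#'   floor(width/2)} on the right of the center.
#' @return Numeric vector of the same length as \code{x}.
#' @export
rolling_mean <- function(x, width) {
  stopifnot(is.numeric(x), width >= 1)
  n <- length(x)
  if (n == 0L || width == 1L) return(as.numeric(x))
  left <- floor((width - 1) / 2)
  right <- width - 1L - left
  cs <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  cnt <- cumsum(c(0, !is.na(x)))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  s <- cs[hi + 1L] - cs[lo]
  k <- cnt[hi + 1L] - cnt[lo]
  out <- s / k
  out[k == 0] <- NA_real_
  out
}

# Expand one user-facing seed into reproducible per-stage sub-seeds.
# Scheme: sub-seed = (seed * 127 + stage_index * 9973) mod (2^31 - 1).
.stage_offsets <- c(
  transcriptome = 1L, parclip = 2L, fractions = 3L, footprints = 4L,
  trna = 5L, proteomics = 6L
)

#' Derive a per-stage simulation sub-seed from a global seed
#'
#' @param seed Integer global seed.
#' @param stage One of "transcriptome", "parclip", "fractions",
#'   "footprints", "trna", "proteomics".
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stage <- match.arg(stage, names(.stage_offsets))
  as.integer((as.numeric(seed) * 127 + .stage_offsets[[stage]] * 9973) %%
               (2^31 - 1))
}

# Normalize a nucleotide string: uppercase, RNA->DNA (U->T) by default.
.norm_seq <- function(x, alphabet = c("T", "U")) {
  alphabet <- match.arg(alphabet)
  x <- toupper(x)
  if (alphabet == "T") gsub("U", "T", x, fixed = TRUE)
  else gsub("T", "U", x, fixed = TRUE)
}

#' Spell a DNA k-mer in RNA alphabet
#'
#' Reports use U spellings for k-mers while all internal sequence is stored
#' with T.
#'
#' @param kmer Character vector of k-mers.
#' @return Character vector with T replaced by U.
#' @export
to_rna <- function(kmer) gsub("T", "U", toupper(kmer), fixed = TRUE)

#' @rdname to_rna
#' @export
to_dna <- function(kmer) gsub("U", "T", toupper(kmer), fixed = TRUE)

# 0-based half-open internal coordinates <-> 1-based inclusive report
# coordinates. The two converters are mutually inverse.

#' Coordinate convention converters
#'
#' Internal coordinates are 0-based half-open (BED convention); human-facing
#' reports and protein coordinates are 1-based inclusive.
#'
#' @param start,end Interval in the source convention.
#' @return A list with \code{start} and \code{end} in the target convention.
#' @export
zero_to_one_based <- function(start, end) list(start = start + 1L, end = end)

#' @rdname zero_to_one_based
#' @export
one_to_zero_based <- function(start, end) list(start = start - 1L, end = end)

# All 4^k DNA k-mers in alphabetical order.
.all_kmers <- function(k) {
  stopifnot(k >= 1)
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), k), stringsAsFactors = FALSE))
  sort(apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste0,
             collapse = ""))
}

# Occurrence indicator: integer vector v of length nchar(seq) where v[i] = 1
# if a member of `words` (all same length) starts at 1-based position i.
# Overlapping occurrences of distinct members each count.
.occurrence_vector <- function(seq, words) {
  n <- nchar(seq)
  v <- integer(n)
  if (n == 0L || length(words) == 0L) return(v)
  w <- nchar(words[1L])
  if (n < w) return(v)
  starts <- seq_len(n - w + 1L)
  wins <- substring(seq, starts, starts + w - 1L)
  hit <- wins %in% words
  v[starts[hit]] <- 1L
  v
}

# Sense codons (61, stops excluded), alphabetical order, DNA alphabet.
.sense_codons <- function() {
  setdiff(.all_kmers(3L), c("TAA", "TAG", "TGA"))
}
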