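#' Transcript set container
#'
#' A \code{transcriptome} holds one transcript isoform per gene together with
#' region architecture and optional protein targeting-signal annotations.
#' Internally it is a list of two data frames:
#' \describe{
#'   \item{transcripts}{\code{transcript_id}, \code{gene_id},
#'     \code{sequence} (DNA alphabet, T), \code{len5utr}, \code{lencds},
#'     \code{len3utr}, \code{localization_class} (one of "membrane",
#'     "cytosolic", "undefined", "excluded"), \code{is_mt}, \code{tpm}
#'     (NA when unknown).}
#'   \item{signals}{\code{transcript_id}, \code{kind} ("signal_peptide" or
#'     "tm_helix"), \code{aa_start}, \code{aa_end} (1-based inclusive
#'     protein coordinates), \code{nt_start}, \code{nt_end} (0-based
#'     half-open transcript coordinates).}
#' }
#'
#' @param transcripts Data frame as described above.
#' @param signals Optional data frame of targeting signals; nt coordinates
#'   are (re)derived from the protein coordinates.
#' @return An object of class \code{transcriptome}.
#' @export
transcriptome <- function(transcripts, signals = NULL) {
  req <- c("transcript_id", "gene_id", "sequence",
           "len5utr", "lencds", "len3utr")
  missing_cols <- setdiff(req, names(transcripts))
  if (length(missing_cols)) {
    stop("transcripts is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  transcripts$sequence <- .norm_seq(transcripts$sequence)
  if (!"localization_class" %in% names(transcripts))
    transcripts$localization_class <- "undefined"
  if (!"is_mt" %in% names(transcripts))
    transcripts$is_mt <- startsWith(transcripts$gene_id, "MT-")
  if (!"tpm" %in% names(transcripts)) transcripts$tpm <- NA_real_

  lens <- nchar(transcripts$sequence)
  tot <- transcripts$len5utr + transcripts$lencds + transcripts$len3utr
  bad <- which(tot != lens)
  if (length(bad)) {
    stop("region lengths do not sum to sequence length for: ",
         paste(transcripts$transcript_id[bad], collapse = ", "))
  }
  bad_cds <- which(transcripts$lencds %% 3L != 0L)
  if (length(bad_cds)) {
    stop("CDS length not a multiple of 3 for: ",
         paste(transcripts$transcript_id[bad_cds], collapse = ", "))
  }
  if (anyDuplicated(transcripts$gene_id)) {
    if (all(is.na(transcripts$tpm))) {
      stop("multiple isoforms per gene and no tpm column to pick ",
           "the most highly expressed one")
    }
    ord <- order(transcripts$gene_id, -transcripts$tpm,
                 transcripts$transcript_id)
    transcripts <- transcripts[ord, , drop = FALSE]
    transcripts <- transcripts[!duplicated(transcripts$gene_id), ,
                               drop = FALSE]
  }
  rownames(transcripts) <- NULL

  if (is.null(signals) || nrow(signals) == 0L) {
    signals <- data.frame(transcript_id = character(), kind = character(),
                          aa_start = integer(), aa_end = integer(),
                          nt_start = integer(), nt_end = integer(),
                          stringsAsFactors = FALSE)
  } else {
    signals <- signals[signals$transcript_id %in%
                         transcripts$transcript_id, , drop = FALSE]
    idx <- match(signals$transcript_id, transcripts$transcript_id)
    len5 <- transcripts$len5utr[idx]
    naa <- transcripts$lencds[idx] %/% 3L - 1L  # last codon is the stop
    if (any(signals$aa_end > naa + 1L)) {
      stop("targeting signal extends beyond the encoded protein")
    }
    signals$nt_start <- len5 + 3L * (signals$aa_start - 1L)
    signals$nt_end <- len5 + 3L * signals$aa_end
    rownames(signals) <- NULL
  }
  structure(list(transcripts = transcripts, signals = signals),
            class = "transcriptome")
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("transcriptome: %d transcripts (%d with targeting signals)\n",
              nrow(x$transcripts), length(unique(x$signals$transcript_id))))
  cls <- table(x$transcripts$localization_class)
  cat("  classes:", paste(names(cls), cls, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Load a transcriptome from FASTA plus a region table
#'
#' Sequences come from a FASTA file; region architecture (5'UTR/CDS/3'UTR
#' lengths) from a tab-separated table with columns \code{transcript_id},
#' \code{gene_id}, \code{len5utr}, \code{lencds}, \code{len3utr} and
#' optionally \code{tpm}. When several isoforms of a gene are present the
#' most highly expressed one (by \code{tpm}) is retained; without a
#' \code{tpm} column duplicated genes are an error.
#'
#' @param fasta_path Path to the FASTA file of transcript sequences.
#' @param regions_path Path to the region table (TSV with header).
#' @return A \code{\link{transcriptome}}.
#' @export
read_transcriptome <- function(fasta_path, regions_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  regions <- utils::read.delim(regions_path, stringsAsFactors = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  if (!all(regions$transcript_id %in% ids)) {
    stop("region table contains transcripts absent from the FASTA")
  }
  regions$sequence <- as.character(seqs[match(regions$transcript_id, ids)])
  transcriptome(regions)
}

#' Write the transcriptome as FASTA plus region table
#'
#' @param tx A \code{\link{transcriptome}}.
#' @param fasta_path,regions_path Output paths.
#' @export
write_transcriptome <- function(tx, fasta_path, regions_path) {
  df <- tx$transcripts
  set <- Biostrings::DNAStringSet(df$sequence)
  names(set) <- df$transcript_id
  Biostrings::writeXStringSet(set, fasta_path)
  cols <- c("transcript_id", "gene_id", "len5utr", "lencds", "len3utr",
            "localization_class", "tpm")
  utils::write.table(df[, cols], regions_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Assign transcript regions to positions
#'
#' @param tx A \code{\link{transcriptome}}.
#' @param transcript_id Character vector of transcript ids.
#' @param position Integer vector of 0-based transcript positions.
#' @return Character vector with values "utr5", "cds", "utr3".
#' @export
region_of <- function(tx, transcript_id, position) {
  idx <- match(transcript_id, tx$transcripts$transcript_id)
  if (anyNA(idx)) stop("unknown transcript id")
  len5 <- tx$transcripts$len5utr[idx]
  lenc <- tx$transcripts$lencds[idx]
  lent <- len5 + lenc + tx$transcripts$len3utr[idx]
  if (any(position < 0L | position >= lent)) {
    stop("position outside transcript bounds")
  }
  ifelse(position < len5, "utr5",
         ifelse(position < len5 + lenc, "cds", "utr3"))
}

#' Read and write crosslink site tables as BED6
#'
#' Sites live in transcript space: chrom = transcript id, 0-based half-open
#' single-nucleotide intervals, score = T-C transition count, strand fixed
#' to "+". \code{write_sites_bed} and \code{read_sites} are a lossless
#' round trip for the (transcript_id, position, tc_count) triple.
#'
#' @param sites Data frame with columns \code{transcript_id},
#'   \code{position} (0-based), \code{tc_count}.
#' @param path Output (input) file path.
#' @return \code{read_sites} returns the site data frame.
#' @export
write_sites_bed <- function(sites, path) {
  if (nrow(sites) > 0 &&
      (any(sites$position < 0) || any(sites$tc_count < 0))) {
    stop("negative position or count")
  }
  bed <- data.frame(
    chrom = sites$transcript_id,
    start = as.integer(sites$position),
    end = as.integer(sites$position) + 1L,
    name = if (nrow(sites)) paste0("site_", seq_len(nrow(sites))) else
      character(),
    score = sites$tc_count,
    strand = rep("+", nrow(sites)),
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' @rdname write_sites_bed
#' @export
read_sites <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(transcript_id = character(), position = integer(),
                      tc_count = numeric(), stringsAsFactors = FALSE))
  }
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(transcript_id = bed[[1L]], position = as.integer(bed[[2L]]),
             tc_count = bed[[5L]], stringsAsFactors = FALSE)
}
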