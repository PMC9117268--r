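#' Default run configuration
#'
#' Every tunable of every stage, with its published default. The object is a
#' named list of sections, each a named list of scalar values. Unknown
#' sections or keys in a config file are an error, so typos cannot silently
#' fall back to defaults.
#'
#' @return A named list of sections with class \code{multiclip_config}.
#' @export
default_config <- function() {
  cfg <- list(
    simulate = list(
      n_genes = 300L, seed = 1L,
      frac_membrane = 0.4, frac_cytosolic = 0.4, frac_undefined = 0.2,
      depth = 50, conv_rate = 0.25, err_rate = 1e-4, n_replicates = 2L,
      dispersion = 0.05, footprint_depth = 2,
      enrich_membrane = 2.5, enrich_cytosolic = -1.0,
      pause_codons = 10L, pause_mult_wt = 2.0, pause_mult_ko = 1.2,
      ko_codon_mult = 1.3, trna_excess = 3
    ),
    crosslink = list(
      min_overlap = 0.5, max_peak_dist = 10L, min_mean_tc = 3,
      overlap_mode = "reciprocal", kept_coords = "rep1",
      max_specificity = 0.95, min_tcpm = 5,
      group_lo = 0.3, group_hi = 1.39, group_statistic = "log2_enrichment",
      ratio_pseudocount = 0.5,
      bins_utr5 = 100L, bins_cds = 300L, bins_utr3 = 200L
    ),
    localization = list(
      hi = 1.5, lo = 0.5, min_tpm = 10, pseudocount = 1,
      mean_mode = "ratio_of_means", tail_anchor_max_dist = 50L
    ),
    kmer = list(
      k = 4L, register = "overlap", half_window = 40L, exclusion = 4L,
      n_bins = 5L, window = 30L, min_count = 3L, top_n = 40L
    ),
    ribo = list(
      psite_offset = 13L, min_codon_cov = 5, trim_codons = 2L,
      roll_start_stop = 10L, roll_signal = 5L,
      norm_codon_lo = 20L, norm_codon_hi = 40L, span_codons = 500L,
      min_tpm = 10, te_pseudocount = 1
    ),
    auxiliary = list(
      bioid_min_enrich = 3, bioid_min_log2_lfq = 27, bioid_min_peptides = 3L,
      silac_invert_reverse = TRUE, rip_control_minus_bait = TRUE
    )
  )
  class(cfg) <- "multiclip_config"
  cfg
}

#' Write and read the run configuration
#'
#' Flat key-value text, one \code{[section]} header per stage, lines of the
#' form \code{key = value}. Reading is lossless and validates every key
#' against \code{\link{default_config}}.
#'
#' @param cfg A config list as returned by \code{\link{default_config}}.
#' @param path File path.
#' @return \code{read_config} returns the config list.
#' @export
write_config <- function(cfg, path) {
  lines <- character()
  for (sec in names(cfg)) {
    lines <- c(lines, sprintf("[%s]", sec))
    for (key in names(cfg[[sec]])) {
      v <- cfg[[sec]][[key]]
      lines <- c(lines, sprintf("%s = %s", key, format(v, digits = 15)))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(NULL)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ref <- default_config()
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- ref
  sec <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!sec %in% names(ref)) stop("unknown config section: ", sec)
      next
    }
    if (is.null(sec)) stop("config entry before any [section] header")
    kv <- strsplit(ln, "\\s*=\\s*")[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- kv[1L]; val <- kv[2L]
    if (!key %in% names(ref[[sec]])) {
      stop(sprintf("unknown config key: %s.%s", sec, key))
    }
    proto <- ref[[sec]][[key]]
    cfg[[sec]][[key]] <- if (is.integer(proto)) as.integer(val)
      else if (is.numeric(proto)) as.numeric(val)
      else if (is.logical(proto)) as.logical(val)
      else val
  }
  cfg
}
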