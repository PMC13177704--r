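#' Pipeline configuration
#'
#' Assembles and validates the full set of stage parameters.  All coordinates
#' handled by the package are 0-based half-open; GFF3 emission converts to
#' 1-based inclusive.
#'
#' @param window_size self-alignment window for subtelomeric repeat discovery
#'   (bp).
#' @param window_step step between successive windows (bp).
#' @param terminal_span span from each contig end that is scanned for repeats
#'   (bp).
#' @param repeat_len_min,repeat_len_max retained self-repeat alignment length
#'   range (bp).
#' @param repeat_identity_min minimum percent identity for retained
#'   self-repeats.
#' @param block_trim_len,block_trim_gap extremal alignment blocks shorter than
#'   `block_trim_len` bp are trimmed when separated from the next block by more
#'   than `block_trim_gap` bp.
#' @param max_intra_element_gap largest internal alignment gap tolerated when
#'   mapping database entries (bp); accommodates 36-mer stretch length
#'   variation between query and target.
#' @param element_len_min minimum emitted element length (bp).
#' @param element_len_core secondary length threshold reported in the funnel
#'   log (not applied as a filter).
#' @param detect_identity_min minimum percent identity for database-entry hits
#'   during exhaustive detection.
#' @param flank_gap_max maximum gap (bp) between a repeat/element edge and a
#'   telomeric call for the edge to count as telomere-flanked.
#' @param ref_match_min,ref_identity_min minimum aligned length (bp) and
#'   percent identity of a hit against the reference Y' set for a repeat copy
#'   to qualify for the high-confidence database.
#' @param mer_window length of the degenerate repeat unit scanned inside
#'   elements (bp).
#' @param peak_spacing,peak_threshold peak-calling parameters of the sliding
#'   edit-distance scan: minimum distance between retained peaks (positions)
#'   and minimum score.
#' @param max_motifs cap on the refined motif database size.
#' @param ca_window,ca_min_len window and minimum length (bp) for CA-rich
#'   region detection.
#' @param orf_min_len minimum open reading frame length (bp, start through
#'   stop codon inclusive).
#' @param k_min,k_max cluster-count range searched when maximising the mean
#'   silhouette.
#' @param cluster_min_size,cluster_min_strains,heterogeneity_max
#'   cluster-retention filters: minimum size, minimum number of distinct
#'   strains and maximum heterogeneity (100 - mean intra-cluster percent
#'   similarity).
#' @param tel_window,tel_threshold,tel_merge_gap,min_its_len,terminal_margin
#'   telomere caller parameters (see [call_telomeres()]).
#' @param association_window maximum distance (bp) used when associating an
#'   ITS with an element.
#' @param excluded_strains strains excluded from ITS-length and diversity
#'   summaries (none by default).
#' @param seed integer seed controlling every stochastic step of a pipeline
#'   run.
#' @return a validated list of class `yp_config`.
#' @export
pipeline_config <- function(window_size = 25000L,
                            window_step = 5000L,
                            terminal_span = 100000L,
                            repeat_len_min = 4000L,
                            repeat_len_max = 9500L,
                            repeat_identity_min = 90,
                            block_trim_len = 20L,
                            block_trim_gap = 100L,
                            max_intra_element_gap = 1000L,
                            element_len_min = 1000L,
                            element_len_core = 3500L,
                            detect_identity_min = 80,
                            flank_gap_max = 50L,
                            ref_match_min = 500L,
                            ref_identity_min = 80,
                            mer_window = 36L,
                            peak_spacing = 30L,
                            peak_threshold = 0.85,
                            max_motifs = 64L,
                            ca_window = 100L,
                            ca_min_len = 100L,
                            orf_min_len = 300L,
                            k_min = 2L,
                            k_max = 100L,
                            cluster_min_size = 5L,
                            cluster_min_strains = 2L,
                            heterogeneity_max = 15,
                            tel_window = 20L,
                            tel_threshold = 0.8,
                            tel_merge_gap = 10L,
                            min_its_len = 20L,
                            terminal_margin = 50L,
                            association_window = 500L,
                            excluded_strains = character(),
                            seed = 1L) {
  cfg <- as.list(environment())
  num <- vapply(cfg, is.numeric, logical(1))
  bad <- names(cfg)[num][vapply(cfg[num], function(x) any(x <= 0), logical(1))]
  bad <- setdiff(bad, "peak_threshold")
  if (length(bad))
    stop("configuration parameters must be positive: ", paste(bad, collapse = ", "))
  if (cfg$k_min >= cfg$k_max) stop("k_min must be smaller than k_max")
  if (cfg$repeat_len_min >= cfg$repeat_len_max)
    stop("repeat_len_min must be smaller than repeat_len_max")
  if (cfg$peak_threshold <= 0 || cfg$peak_threshold > 1)
    stop("peak_threshold must lie in (0, 1]")
  structure(cfg, class = "yp_config")
}

#' @export
print.yp_config <- function(x, ...) {
  cat("yprimescan pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = ",")))
  invisible(x)
}
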