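# Y' element discovery: windowed self-repeat detection, high-confidence
# database construction, alignment-block trimming, and exhaustive detection
# with orientation normalisation and funnel accounting.

#' Find subtelomeric self-repeats in sliding windows
#'
#' Self-aligns sliding windows over both terminal spans of a contig
#' (telomeres must already be masked) and retains off-diagonal repeat hits
#' with aligned length in `[len_min, len_max]` and identity at least
#' `min_identity`.  Hits found in several overlapping windows are
#' deduplicated after lifting to contig coordinates.
#'
#' @param masked_seq contig sequence with telomeric tracts masked (N).
#' @param terminal_span,window,step scan geometry (bp).
#' @param len_min,len_max retained aligned-length range (bp).
#' @param min_identity minimum percent identity.
#' @param max_gap largest internal alignment gap (bp).
#' @return hit data.frame with contig coordinates in both spans
#'   (`qstart < tstart`).
#' @export
find_window_repeats <- function(masked_seq, terminal_span = 100000L,
                                window = 25000L, step = 5000L,
                                len_min = 4000L, len_max = 9500L,
                                min_identity = 90, max_gap = 100L) {
  s <- toupper(as.character(masked_seq))
  L <- nchar(s)
  if (L <= window) {
    starts <- 0L
    window <- L
  } else {
    span <- min(terminal_span, L)
    left <- seq.int(0L, max(0L, span - window), by = step)
    right <- seq.int(max(0L, L - span), L - window, by = step)
    starts <- sort(unique(c(left, right)))
  }
  all_hits <- list()
  for (w0 in starts) {
    sub <- substr(s, w0 + 1L, w0 + window)
    h <- local_align(sub, sub, min_identity = 0, max_gap = max_gap, self = TRUE,
                     min_seed_bases = max(200L, len_min %/% 5L), max_chains = 32L)
    if (nrow(h) == 0) next
    h$qstart <- h$qstart + w0; h$qend <- h$qend + w0
    h$tstart <- h$tstart + w0; h$tend <- h$tend + w0
    h$blocks <- lapply(h$blocks, function(b) { b[, 1:4] <- b[, 1:4] + w0; b })
    all_hits[[length(all_hits) + 1L]] <- h
  }
  if (!length(all_hits)) { df <- hit_frame(); df$blocks <- list(); return(df) }
  df <- do.call(rbind, all_hits)
  df <- df[df$length >= len_min & df$length <= len_max &
             df$identity >= min_identity, , drop = FALSE]
  if (nrow(df) == 0) return(df)
  dedupe_hits(df, min_recip = 0.9)
}

#' Build the high-confidence Y' element database
#'
#' A repeat copy (either span of a window self-repeat hit) enters the
#' database iff (a) it aligns to some reference Y' over at least
#' `ref_match_min` bp at `ref_identity_min` percent identity, and (b) both of
#' its ends lie within `flank_gap_max` bp of a telomeric call (terminal or
#' ITS).  Reference entries are appended and duplicate sequences collapsed.
#'
#' @param window_hits data.frame of self-repeat hits with columns `strain`,
#'   `contig` added (see [find_window_repeats()]).
#' @param genomes named list of DNAStringSet per strain.
#' @param reference reference Y' sequences (DNAStringSet, or FASTA path).
#' @param telomere_calls data.frame of telomeric calls with `strain`,
#'   `contig`, `start`, `end`.
#' @param flank_gap_max,ref_match_min,ref_identity_min thresholds (see
#'   [pipeline_config()]).
#' @return object of class `yp_db`: list with `entries` (id, seq,
#'   provenance) and `hash`.
#' @export
build_high_confidence_db <- function(window_hits, genomes, reference,
                                     telomere_calls, flank_gap_max = 50L,
                                     ref_match_min = 500L, ref_identity_min = 80) {
  if (is.character(reference) && length(reference) == 1 && file.exists(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  ref <- setNames(toupper(as.character(reference)), names(reference))
  if (length(ref) == 0) stop("empty reference Y' set")
  names(ref) <- names(ref) %||% paste0("ref", seq_along(ref))
  copies <- list()
  if (!is.null(window_hits) && nrow(window_hits) > 0) {
    for (i in seq_len(nrow(window_hits))) {
      h <- window_hits[i, ]
      for (span in list(c(h$qstart, h$qend), c(h$tstart, h$tend)))
        copies[[length(copies) + 1L]] <- list(strain = h$strain, contig = h$contig,
                                              start = span[1], end = span[2])
    }
  }
  flanked <- function(cp) {
    tc <- telomere_calls[telomere_calls$strain == cp$strain &
                           telomere_calls$contig == cp$contig, , drop = FALSE]
    if (nrow(tc) == 0) return(FALSE)
    leftok <- any(tc$end >= cp$start - flank_gap_max & tc$end <= cp$start + 10L)
    rightok <- any(tc$start <= cp$end + flank_gap_max & tc$start >= cp$end - 10L)
    leftok && rightok
  }
  matches_ref <- function(seq) {
    for (r in ref) {
      h <- tryCatch(local_align(seq, r, min_identity = ref_identity_min),
                    error = function(e) NULL)
      if (!is.null(h) && nrow(h) > 0 && any(h$length >= ref_match_min)) return(TRUE)
    }
    FALSE
  }
  entries <- character(0)
  for (cp in copies) {
    if (!flanked(cp)) next
    seq <- as.character(Biostrings::subseq(genomes[[cp$strain]][[cp$contig]],
                                           cp$start + 1L, cp$end))
    if (!matches_ref(seq)) next
    entries <- c(entries, toupper(seq))
  }
  entries <- entries[!duplicated(entries)]
  ids <- if (length(entries)) sprintf("hcY%03d", seq_along(entries)) else character(0)
  prov <- rep("window_repeat", length(entries))
  keepref <- !(ref %in% entries)
  df <- data.frame(id = c(ids, names(ref)[keepref]),
                   seq = c(entries, unname(ref[keepref])),
                   provenance = c(prov, rep("reference_seed", sum(keepref))),
                   stringsAsFactors = FALSE)
  tf <- tempfile(); writeLines(df$seq, tf)
  hash <- unname(tools::md5sum(tf)); unlink(tf)
  structure(list(entries = df, hash = hash), class = "yp_db")
}

#' Trim unreliable extremal alignment blocks
#'
#' Iteratively removes the first/last gap-free block of a hit while the
#' block is shorter than `block_trim_len` bp and the gap separating it from
#' the adjacent block exceeds `block_trim_gap` bp, then recomputes the hit
#' interval, identity and score.
#'
#' @param hit one-row hit data.frame (with `blocks` list-column) as produced
#'   by [local_align()] / [map_spliced()].
#' @param block_trim_len,block_trim_gap trimming thresholds (bp).
#' @return the trimmed one-row hit, or `NULL` when all blocks are trimmed.
#' @export
trim_hit_blocks <- function(hit, block_trim_len = 20L, block_trim_gap = 100L) {
  b <- hit$blocks[[1]]
  if (is.null(b) || nrow(b) == 0) return(NULL)
  repeat {
    n <- nrow(b)
    if (n == 0) return(NULL)
    if (n == 1) break
    first_len <- b[1, 2] - b[1, 1]
    first_gap <- max(b[2, 1] - b[1, 2], b[2, 3] - b[1, 4])
    if (first_len < block_trim_len && first_gap > block_trim_gap) { b <- b[-1, , drop = FALSE]; next }
    last_len <- b[n, 2] - b[n, 1]
    last_gap <- max(b[n, 1] - b[n - 1, 2], b[n, 3] - b[n - 1, 4])
    if (last_len < block_trim_len && last_gap > block_trim_gap) { b <- b[-n, , drop = FALSE]; next }
    break
  }
  cols <- sum(b[, 2] - b[, 1])
  score <- 0L
  if (nrow(b) > 1) for (i in 2:nrow(b)) {
    gq <- b[i, 1] - b[i - 1, 2]; gt <- b[i, 3] - b[i - 1, 4]
    cols <- cols + gq + gt
    if (gq > 0) score <- score - 4L - gq
    if (gt > 0) score <- score - 4L - gt
  }
  matches <- sum(b[, 5])
  mism <- sum(b[, 2] - b[, 1]) - matches
  score <- score + matches - 2L * mism
  hit$qstart <- b[1, 1]; hit$qend <- b[nrow(b), 2]
  hit$tstart <- b[1, 3]; hit$tend <- b[nrow(b), 4]
  hit$length <- cols; hit$matches <- matches
  hit$identity <- 100 * matches / max(1L, cols)
  hit$score <- score
  hit$blocks <- list(b)
  hit
}

empty_elements <- function() {
  data.frame(element_id = character(), strain = character(), contig = character(),
             start = integer(), end = integer(), orientation = character(),
             side = character(), length = integer(), identity = numeric(),
             score = integer(), db_id = character(), edge_truncated = logical(),
             telomere_flanked = character(), stringsAsFactors = FALSE)
}

#' Exhaustive Y' element detection
#'
#' Maps every database entry against every contig with [map_spliced()],
#' trims extremal blocks, merges hits from different entries that overlap
#' reciprocally by more than 50% (best score wins; ties resolved by lower
#' start, then lexical database id), drops elements shorter than
#' `element_len_min`, flags elements adjoining contig extremities as
#' `edge_truncated` (excluded downstream), annotates telomere flanking, and
#' normalises orientation so that element coordinates run from the
#' centromere-proximal end toward the telomere.
#'
#' @param db `yp_db` database.
#' @param genomes named list of DNAStringSet per strain.
#' @param telomere_calls telomeric call table (`strain`, `contig`, `start`,
#'   `end`, `kind`).
#' @param config `yp_config`.
#' @return list with `elements` (data.frame), `seqs` (oriented element
#'   sequences, DNAStringSet) and `funnel` (stage counts).
#' @export
detect_elements <- function(db, genomes, telomere_calls, config = pipeline_config()) {
  stopifnot(inherits(db, "yp_db"))
  if (nrow(db$entries) == 0) stop("empty Y' database")
  cands <- list()
  n_raw <- 0L
  for (strain in names(genomes)) {
    g <- genomes[[strain]]
    for (contig in names(g)) {
      tseq <- toupper(as.character(g[[contig]]))
      hits <- map_spliced_multi(db$entries$seq, tseq,
                                max_intra_element_gap = config$max_intra_element_gap)
      if (nrow(hits) == 0) next
      n_raw <- n_raw + nrow(hits)
      for (i in seq_len(nrow(hits))) {
        h <- trim_hit_blocks(hits[i, ], config$block_trim_len, config$block_trim_gap)
        if (is.null(h) || h$identity < config$detect_identity_min) next
        h$strain <- strain; h$contig <- contig
        h$db_id <- db$entries$id[h$query_index]
        cands[[length(cands) + 1L]] <- h
      }
    }
  }
  funnel <- c(raw_hits = n_raw, trimmed_hits = length(cands))
  if (!length(cands)) {
    return(list(elements = empty_elements(),
                seqs = Biostrings::DNAStringSet(),
                funnel = c(funnel, merged = 0L, length_filtered = 0L,
                           core_length = 0L, edge_truncated = 0L, final = 0L)))
  }
  cd <- do.call(rbind, cands)
  # merge competing db-entry hits per contig: reciprocal overlap > 50%
  merged <- list()
  for (key in unique(paste(cd$strain, cd$contig))) {
    sub <- cd[paste(cd$strain, cd$contig) == key, , drop = FALSE]
    sub <- sub[order(-sub$score, sub$tstart, sub$db_id), , drop = FALSE]
    keep <- rep(TRUE, nrow(sub))
    if (nrow(sub) > 1) for (i in 2:nrow(sub)) {
      covered <- 0L
      for (j in which(keep[seq_len(i - 1)])) {
        if (reciprocal_overlap(sub$tstart[i], sub$tend[i],
                               sub$tstart[j], sub$tend[j]) > 0.5) {
          keep[i] <- FALSE; break
        }
        covered <- covered + max(0L, min(sub$tend[i], sub$tend[j]) -
                                   max(sub$tstart[i], sub$tstart[j]))
      }
      # partial-domain hits (shared domains between classes, or repeats
      # spanning an array junction) are mostly covered by better hits
      if (keep[i] && covered > 0.5 * (sub$tend[i] - sub$tstart[i]))
        keep[i] <- FALSE
    }
    sub <- sub[keep, , drop = FALSE]
    sub <- sub[order(sub$tstart), , drop = FALSE]
    # resolve residual partial overlaps so emitted elements never overlap
    if (nrow(sub) > 1) for (i in 2:nrow(sub))
      if (sub$tstart[i] < sub$tend[i - 1]) sub$tstart[i] <- sub$tend[i - 1]
    merged[[length(merged) + 1L]] <- sub
  }
  md <- do.call(rbind, merged)
  funnel <- c(funnel, merged = nrow(md))
  md$elen <- md$tend - md$tstart
  md <- md[md$elen >= config$element_len_min, , drop = FALSE]
  funnel <- c(funnel, length_filtered = nrow(md),
              core_length = sum(md$elen > config$element_len_core))
  if (nrow(md) == 0) {
    return(list(elements = empty_elements(), seqs = Biostrings::DNAStringSet(),
                funnel = c(funnel, edge_truncated = 0L, final = 0L)))
  }
  rows <- list(); seqs <- character(0)
  for (i in seq_len(nrow(md))) {
    h <- md[i, ]
    clen <- nchar(as.character(genomes[[h$strain]][[h$contig]]))
    edge <- h$tstart <= 0L || h$tend >= clen
    side <- if (h$tstart + (h$tend - h$tstart) / 2 <= clen / 2) "L" else "R"
    tc <- telomere_calls[telomere_calls$strain == h$strain &
                           telomere_calls$contig == h$contig, , drop = FALSE]
    near_left <- nrow(tc) > 0 &&
      any(tc$end >= h$tstart - config$flank_gap_max & tc$end <= h$tstart + 10L)
    near_right <- nrow(tc) > 0 &&
      any(tc$start <= h$tend + config$flank_gap_max & tc$start >= h$tend - 10L)
    distal_ok <- if (side == "R") near_right else near_left
    prox_ok <- if (side == "R") near_left else near_right
    flank <- if (distal_ok && prox_ok) "both" else if (distal_ok) "distal_only"
      else if (prox_ok) "proximal_only" else "none"
    id <- sprintf("%s_%s_%06d", h$strain, h$contig, h$tstart)
    sseq <- as.character(Biostrings::subseq(genomes[[h$strain]][[h$contig]],
                                            h$tstart + 1L, h$tend))
    if (h$strand == "-") sseq <- revcomp(sseq)
    rows[[length(rows) + 1L]] <- data.frame(
      element_id = id, strain = h$strain, contig = h$contig,
      start = h$tstart, end = h$tend, orientation = h$strand, side = side,
      length = h$tend - h$tstart, identity = h$identity, score = h$score,
      db_id = h$db_id, edge_truncated = edge, telomere_flanked = flank,
      stringsAsFactors = FALSE)
    seqs <- c(seqs, setNames(toupper(sseq), id))
  }
  el <- do.call(rbind, rows)
  funnel <- c(funnel, edge_truncated = sum(el$edge_truncated),
              final = sum(!el$edge_truncated))
  list(elements = el, seqs = Biostrings::DNAStringSet(seqs), funnel = funnel)
}
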