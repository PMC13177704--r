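# Internal repeat profiling: degenerate 36-mer stretch detection by sliding
# edit-distance scan with peak calling, CA-rich region detection and
# Pattern-1/Pattern-2 segmentation, masking, and position frequency matrices.

#' Sliding edit-distance score track for a motif database
#'
#' At each position a window of the motif length is extracted and scored as
#' `(L - d) / L` where `d` is the minimum Levenshtein distance to any
#' database motif (IUPAC ambiguity codes in motifs match their allowed
#' bases).  Distances above `max_edit` are clamped, flooring the reported
#' score below any peak-calling threshold of interest.
#'
#' @param seq element sequence (oriented).
#' @param motif_db character vector of motifs of one common length.
#' @param max_edit clamp on the edit distance (default 8).
#' @return numeric score track of length `nchar(seq) - L + 1` (empty when
#'   the element is shorter than the motif).
#' @export
score_36mer_track <- function(seq, motif_db, max_edit = 8L) {
  if (length(motif_db) == 0) stop("empty motif database")
  s <- toupper(as.character(seq))
  cpp_motif_track(s, toupper(motif_db), max_edit)
}

# strict local maxima with leftmost-of-plateau convention, then greedy
# spacing enforcement from the highest score down (ties: leftmost)
find_peaks <- function(score, threshold, spacing) {
  n <- length(score)
  if (n == 0) return(integer(0))
  left <- c(-Inf, score[-n])
  right <- c(score[-1], -Inf)
  cand <- which(score >= threshold & score > left & score >= right)
  if (!length(cand)) return(integer(0))
  ord <- cand[order(-score[cand], cand)]
  sel <- integer(0)
  for (p in ord) if (!length(sel) || all(abs(sel - p) >= spacing)) sel <- c(sel, p)
  sort(sel)
}

#' Call the 36-mer stretch of an element from its score track
#'
#' Peaks are strict local maxima scoring at least `peak_threshold`,
#' separated by at least `peak_spacing` positions.  Units are extracted as
#' windows at the peaks; units whose best-motif alignment spans a length
#' different from the motif length are discarded from the unit list, but the
#' peaks still delimit the stretch, which spans from the first peak through
#' the last peak's window.
#'
#' @param track score track from [score_36mer_track()].
#' @param seq the element sequence the track was computed on.
#' @param motif_db the motif database used.
#' @param peak_spacing,peak_threshold peak-calling parameters.
#' @return a `RepeatStretch` list (`stretch_class`, `start`, `end`
#'   element-local 0-based half-open, `unit_count`, `units`, `n_peaks`,
#'   `composition`) or `NULL` when no peak is found.
#' @export
call_36mer_stretch <- function(track, seq, motif_db, peak_spacing = 30L,
                               peak_threshold = 0.85) {
  peaks <- find_peaks(track, peak_threshold, peak_spacing)
  if (!length(peaks)) return(NULL)
  s <- toupper(as.character(seq))
  L <- nchar(motif_db[1])
  units <- character(0)
  for (p in peaks) {
    p0 <- p - 1L # 0-based window start
    r0 <- max(0L, p0 - 4L); r1 <- min(nchar(s), p0 + L + 4L)
    region <- substr(s, r0 + 1L, r1)
    best <- NULL
    for (m in motif_db) {
      sp <- cpp_motif_span(region, m)
      if (is.null(best) || sp[3] < best[3]) best <- sp
    }
    if ((best[2] - best[1]) == L)
      units <- c(units, substr(region, best[1] + 1L, best[2]))
  }
  start <- peaks[1] - 1L
  end <- peaks[length(peaks)] - 1L + L
  stretch_seq <- substr(s, start + 1L, end)
  # the repeat count of the stretch is the peak count; `units` carries only
  # the sequences whose best alignment spans exactly L bases
  list(stretch_class = "mer36", start = start, end = end,
       unit_count = length(peaks), units = units, n_peaks = length(peaks),
       composition = base_composition(stretch_seq))
}

base_composition <- function(seq) {
  ch <- strsplit(toupper(as.character(seq)), "")[[1]]
  tab <- table(factor(ch, levels = BASES))
  setNames(as.numeric(tab) / max(1L, length(ch)), BASES)
}

#' One bootstrap refinement round of the motif database
#'
#' Detects units in all elements with the seed database, pools the retained
#' 36 bp units, deduplicates them and returns the union of the seed motifs
#' and the (capped) pooled units as the refined database, so that a second
#' detection pass never loses recall.
#'
#' @param element_seqs named character vector / DNAStringSet of oriented
#'   element sequences.
#' @param seed_db seed motif database.
#' @param max_motifs cap on pooled units retained (most frequent first, ties
#'   lexicographic).
#' @param peak_spacing,peak_threshold,max_edit scan parameters.
#' @return character vector: the refined motif database.
#' @export
refine_motif_db <- function(element_seqs, seed_db, max_motifs = 64L,
                            peak_spacing = 30L, peak_threshold = 0.85,
                            max_edit = 8L) {
  if (length(seed_db) == 0) stop("empty seed motif database")
  pooled <- character(0)
  for (s in as.character(element_seqs)) {
    tr <- score_36mer_track(s, seed_db, max_edit)
    if (!length(tr)) next
    st <- call_36mer_stretch(tr, s, seed_db, peak_spacing, peak_threshold)
    if (!is.null(st)) pooled <- c(pooled, st$units)
  }
  if (!length(pooled)) {
    warning("no repeat units found; seed database returned unchanged")
    return(seed_db)
  }
  tab <- sort(table(pooled), decreasing = TRUE)
  uniq <- names(tab)[order(-as.numeric(tab), names(tab))]
  uniq <- head(uniq, max_motifs)
  unique(c(toupper(seed_db), uniq))
}

#' Detect the CA-rich region of an element
#'
#' Scans sliding 100 bp windows for near-equal adenine/cytosine composition
#' (`A+C >= 0.8` and `min(A, C) >= 0.25` of the window), excluding
#' telomere-like windows (cytosine-dominated, `C/(C+A) >= 0.55`, or highly
#' covered by the telomeric repeat motif).  Qualifying windows are merged
#' and reported when the spanned region reaches `min_len`.
#'
#' @param seq oriented element sequence.
#' @param window,min_len scan window and minimum region length (bp).
#' @param merge_gap largest run of non-qualifying window starts bridged.
#' @return a `RepeatStretch` list (`stretch_class = "ca_rich"`) or `NULL`.
#' @export
detect_ca_region <- function(seq, window = 100L, min_len = 100L,
                             merge_gap = 60L) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  if (n < window) return(NULL)
  ch <- strsplit(s, "")[[1]]
  wfrac <- function(mask) {
    cs <- c(0, cumsum(mask))
    (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  }
  fa <- wfrac(ch == "A"); fc <- wfrac(ch == "C")
  telcov <- telomere_coverage(s)
  ftel <- wfrac(telcov$ca | telcov$tg)
  ac <- fa + fc
  cc_ratio <- ifelse(ac > 0, fc / pmax(1e-9, fa + fc), 0)
  ok <- ac >= 0.8 & pmin(fa, fc) >= 0.25 & cc_ratio < 0.55 & ftel < 0.8
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    if (runs$start[i] - merged$end[nrow(merged)] - 1L <= merge_gap)
      merged$end[nrow(merged)] <- runs$end[i]
    else merged <- rbind(merged, runs[i, ])
  }
  merged$len <- merged$end - merged$start + window
  best <- merged[which.max(merged$len), ]
  if (best$len < min_len) return(NULL)
  start <- best$start - 1L; end <- best$end - 1L + window
  comp <- base_composition(substr(s, start + 1L, end))
  # windows straddling a telomeric tract boundary can slip past the
  # window-level filters; the whole region must itself satisfy the CA rules
  # and must not be substantially covered by the telomeric repeat motif
  # (true CA regions sit below ~5% coverage, telomeric tracts at ~100%)
  fa2 <- comp[["A"]]; fc2 <- comp[["C"]]
  regcov <- mean(telcov$ca[(start + 1L):end] | telcov$tg[(start + 1L):end])
  if (fa2 + fc2 < 0.8 || min(fa2, fc2) < 0.25 || fc2 / (fa2 + fc2) >= 0.55 ||
      regcov >= 0.4)
    return(NULL)
  list(stretch_class = "ca_rich", start = start, end = end,
       unit_count = NA_integer_, units = character(0),
       composition = comp)
}

#' Segment a CA-rich region into Pattern-1/Pattern-2 motifs
#'
#' Runs the same sliding edit-distance peak procedure as the 36-mer scan,
#' once per pattern with pattern-specific window lengths, then labels each
#' base by the pattern of the peak window covering it (higher-scoring peaks
#' win; remaining bases are unassigned).
#'
#' @param region_seq CA-rich region sequence.
#' @param pattern_db named character vector of patterns (defaults to the
#'   built-in fixtures).
#' @param peak_threshold minimum peak score.
#' @return list with `labels` (character vector per base: pattern name or
#'   `"unassigned"`) and `fractions` (per-pattern assigned base fractions).
#' @export
segment_ca_patterns <- function(region_seq, pattern_db = ca_patterns(),
                                peak_threshold = 0.85) {
  if (length(pattern_db) == 0) stop("empty pattern database")
  s <- toupper(as.character(region_seq))
  n <- nchar(s)
  labels <- rep("unassigned", n)
  peaks <- list()
  for (pn in names(pattern_db)) {
    L <- nchar(pattern_db[[pn]])
    if (n < L) next
    tr <- cpp_motif_track(s, pattern_db[[pn]], 8L)
    pk <- find_peaks(tr, peak_threshold, max(1L, L - 6L))
    for (p in pk) peaks[[length(peaks) + 1L]] <-
      list(pattern = pn, pos = p - 1L, len = L, score = tr[p])
  }
  if (length(peaks)) {
    ord <- order(-vapply(peaks, `[[`, numeric(1), "score"),
                 vapply(peaks, `[[`, numeric(1), "pos"))
    for (pe in peaks[ord]) {
      span <- (pe$pos + 1L):min(n, pe$pos + pe$len)
      span <- span[labels[span] == "unassigned"]
      labels[span] <- pe$pattern
    }
  }
  fr <- vapply(names(pattern_db), function(pn) mean(labels == pn), numeric(1))
  list(labels = labels, fractions = c(fr, unassigned = mean(labels == "unassigned")),
       n_peaks = length(peaks))
}

#' Mask repeat stretches out of an element
#'
#' Removes the stretch intervals from the element sequence, recording the
#' removals for coordinate lift-back.  The removed lengths and the masked
#' length always sum to the original length.
#'
#' @param seq element sequence.
#' @param stretches list of `RepeatStretch` objects (may be empty); their
#'   intervals must lie within the element and must not overlap.
#' @return `MaskedElement` list: `masked_sequence`, `removed` (data.frame
#'   `start`, `end`, `stretch_class` in original element-local coordinates).
#' @export
mask_stretches <- function(seq, stretches) {
  s <- as.character(seq)
  n <- nchar(s)
  stretches <- Filter(Negate(is.null), stretches)
  if (!length(stretches))
    return(list(masked_sequence = s,
                removed = data.frame(start = integer(), end = integer(),
                                     stretch_class = character())))
  iv <- data.frame(start = vapply(stretches, `[[`, numeric(1), "start"),
                   end = vapply(stretches, `[[`, numeric(1), "end"),
                   stretch_class = vapply(stretches, `[[`, character(1), "stretch_class"),
                   stringsAsFactors = FALSE)
  if (any(iv$start < 0 | iv$end > n | iv$start >= iv$end))
    stop("stretch interval outside element")
  iv <- iv[order(iv$start), , drop = FALSE]
  if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)]))
    stop("overlapping stretch intervals")
  keep <- rep(TRUE, n)
  for (i in seq_len(nrow(iv))) keep[(iv$start[i] + 1L):iv$end[i]] <- FALSE
  list(masked_sequence = paste(strsplit(s, "")[[1]][keep], collapse = ""),
       removed = iv)
}

#' Position frequency matrix of repeat units
#'
#' @param units character vector of unit sequences, all the same length.
#' @return 4 x L matrix (rows A, C, G, T); columns sum to 1.
#' @export
build_pfm <- function(units) {
  if (length(units) == 0) stop("no units given")
  L <- unique(nchar(units))
  if (length(L) != 1) stop("units of mixed lengths")
  m <- do.call(rbind, strsplit(toupper(units), ""))
  pfm <- vapply(seq_len(L), function(j) {
    tab <- table(factor(m[, j], levels = BASES))
    as.numeric(tab) / sum(tab)
  }, numeric(4))
  rownames(pfm) <- BASES
  pfm
}

#' Profile the internal repeats of a set of elements
#'
#' Two-pass 36-mer detection (seed database, then one bootstrap refinement)
#' followed by CA-rich region detection, returning per-element stretch calls.
#'
#' @param element_seqs named character vector / DNAStringSet of oriented
#'   element sequences.
#' @param config `yp_config`.
#' @param motif_db seed 36-mer database (defaults to the built-in consensus).
#' @param refine run the bootstrap refinement pass (default TRUE).
#' @return list with `stretches` (per element: list of RepeatStretch),
#'   `motif_db` (refined database), `masked` (per element: MaskedElement
#'   with the 36-mer stretch removed), `ca_masked` (per CA element: masked
#'   sequence with the CA region also removed).
#' @export
profile_repeats <- function(element_seqs, config = pipeline_config(),
                            motif_db = yprime_motif_36mer(), refine = TRUE) {
  seqs <- setNames(as.character(element_seqs), names(element_seqs))
  db <- toupper(motif_db)
  if (refine)
    db <- refine_motif_db(seqs, db, max_motifs = config$max_motifs,
                          peak_spacing = config$peak_spacing,
                          peak_threshold = config$peak_threshold)
  stretches <- list(); masked <- list(); ca_masked <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    st36 <- NULL
    tr <- score_36mer_track(s, db)
    if (length(tr))
      st36 <- call_36mer_stretch(tr, s, db, config$peak_spacing,
                                 config$peak_threshold)
    stca <- detect_ca_region(s, config$ca_window, config$ca_min_len)
    stl <- Filter(Negate(is.null), list(mer36 = st36, ca = stca))
    # guard against rare overlap of the two calls: keep the longer one
    if (length(stl) == 2 && stl[[1]]$end > stl[[2]]$start && stl[[2]]$end > stl[[1]]$start) {
      lens <- vapply(stl, function(x) x$end - x$start, numeric(1))
      stl <- stl[which.max(lens)]
    }
    stretches[[id]] <- stl
    m36 <- stl[vapply(stl, `[[`, character(1), "stretch_class") == "mer36"]
    masked[[id]] <- mask_stretches(s, m36)
    if (any(vapply(stl, `[[`, character(1), "stretch_class") == "ca_rich"))
      ca_masked[[id]] <- mask_stretches(s, stl)
  }
  list(stretches = stretches, motif_db = db, masked = masked,
       ca_masked = ca_masked)
}
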