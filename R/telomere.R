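# Telomere and interstitial telomeric sequence (ITS) detection.
#
# The telomeric repeat model is degenerate C(1-3)A on the CA strand
# (TG(1-3) on the G-rich strand).  Per-position coverage by maximal runs of
# these units is averaged over sliding windows; both strands are scored and
# the per-position maximum taken, so calls are invariant under
# reverse-complementation of the contig.

# logical coverage of maximal (C{1,3}A)+ / (TG{1,3})+ runs
telomere_coverage <- function(seq, min_run = 8L) {
  # isolated short unit matches (< min_run bases) are too frequent in random
  # sequence to be informative and are not counted
  s <- toupper(as.character(seq))
  n <- nchar(s)
  cov1 <- logical(n); cov2 <- logical(n)
  mark <- function(cov, pattern) {
    m <- gregexpr(pattern, s, perl = TRUE)[[1]]
    if (m[1] != -1) {
      len <- attr(m, "match.length")
      for (i in seq_along(m))
        if (len[i] >= min_run) cov[m[i]:(m[i] + len[i] - 1L)] <- TRUE
    }
    cov
  }
  list(ca = mark(cov1, "(C{1,3}A)+"), tg = mark(cov2, "(TG{1,3})+"))
}

#' Score telomere-likeness in sliding windows
#'
#' The score at position `p` (0-based) is the fraction of the window
#' `[p, p + window)` covered by maximal matches to the degenerate telomere
#' motif, on the better of the two strands.
#'
#' @param seq contig sequence (character or DNAString).
#' @param window window size in bp (default 20).
#' @return object of class `yp_teltrack`: list with per-position `score`,
#'   per-strand window means `ca`/`tg`, coverage masks and sequence length.
#'   Sequences shorter than `window` yield an empty score track.
#' @export
score_telomere_windows <- function(seq, window = 20L) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  if (n < window)
    return(structure(list(score = numeric(0), ca = numeric(0), tg = numeric(0),
                          cov = logical(n), length = n, window = window),
                     class = "yp_teltrack"))
  cov <- telomere_coverage(s)
  wmean <- function(x) {
    cs <- c(0, cumsum(x))
    (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  }
  ca <- wmean(cov$ca); tg <- wmean(cov$tg)
  structure(list(score = pmax(ca, tg), ca = ca, tg = tg,
                 cov = cov$ca | cov$tg, length = n, window = window),
            class = "yp_teltrack")
}

#' Call terminal telomeres and ITSs from a score track
#'
#' Maximal runs of positions scoring at least `threshold` are merged across
#' gaps of at most `merge_gap` positions, refined to the covered motif
#' positions, and classified as `terminal` when within `terminal_margin` of a
#' contig edge, `interstitial` otherwise.  Interstitial calls shorter than
#' `min_its_len` are discarded.
#'
#' @param track an `yp_teltrack` from [score_telomere_windows()].
#' @param threshold minimum window score (default 0.8).
#' @param merge_gap maximum sub-threshold gap bridged when merging runs.
#' @param min_its_len minimum interstitial call length (bp).
#' @param terminal_margin distance from a contig edge within which a call is
#'   terminal (bp).
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `kind`, `score`, `strand_class`, `length`.
#' @export
call_telomeres <- function(track, threshold = 0.8, merge_gap = 10L,
                           min_its_len = 20L, terminal_margin = 50L) {
  stopifnot(inherits(track, "yp_teltrack"))
  empty <- data.frame(start = integer(), end = integer(), kind = character(),
                      score = numeric(), strand_class = character(),
                      length = integer(), stringsAsFactors = FALSE)
  if (length(track$score) == 0) return(empty)
  hot <- track$score >= threshold
  if (!any(hot)) return(empty)
  r <- rle(hot)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  w <- track$window; L <- track$length
  # refine every hot run to its motif-covered bases, then merge the refined
  # intervals across base-space gaps of at most merge_gap
  refined <- lapply(seq_len(nrow(runs)), function(i) {
    a <- runs$start[i]; b <- runs$end[i]
    lo <- a; hi <- b + w - 1L                     # 1-based span covered by windows
    covered <- which(track$cov[lo:hi]) + lo - 1L
    if (!length(covered)) return(NULL)
    data.frame(start = min(covered) - 1L, end = max(covered), # 0-based half-open
               ra = a, rb = b)
  })
  refined <- do.call(rbind, refined)
  if (is.null(refined)) return(empty)
  merged <- refined[1, , drop = FALSE]
  if (nrow(refined) > 1) for (i in 2:nrow(refined)) {
    k <- nrow(merged)
    if (refined$start[i] - merged$end[k] <= merge_gap) {
      merged$end[k] <- max(merged$end[k], refined$end[i])
      merged$rb[k] <- refined$rb[i]
    } else merged <- rbind(merged, refined[i, ])
  }
  out <- lapply(seq_len(nrow(merged)), function(i) {
    s0 <- merged$start[i]; e0 <- merged$end[i]
    a <- merged$ra[i]; b <- merged$rb[i]
    kind <- if (s0 <= terminal_margin || e0 >= L - terminal_margin)
      "terminal" else "interstitial"
    if (kind == "interstitial" && e0 - s0 < min_its_len) return(NULL)
    data.frame(start = s0, end = e0, kind = kind,
               score = mean(track$score[a:b]),
               strand_class = if (mean(track$ca[a:b]) >= mean(track$tg[a:b]))
                 "CA_strand" else "TG_strand",
               length = e0 - s0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Detect telomeric tracts on a contig
#'
#' Convenience wrapper running [score_telomere_windows()] and
#' [call_telomeres()].
#' @inheritParams score_telomere_windows
#' @inheritParams call_telomeres
#' @export
detect_telomeres <- function(seq, window = 20L, threshold = 0.8,
                             merge_gap = 10L, min_its_len = 20L,
                             terminal_margin = 50L) {
  call_telomeres(score_telomere_windows(seq, window), threshold, merge_gap,
                 min_its_len, terminal_margin)
}

#' Mask telomeric calls out of a contig
#'
#' Replaces called telomeric intervals with N so that they are excluded from
#' k-mer seeding in the self-repeat scan.
#' @param seq contig sequence.
#' @param calls call table with `start`, `end` columns.
#' @return masked sequence (character).
#' @export
mask_telomeres <- function(seq, calls) {
  s <- as.character(seq)
  if (nrow(calls) == 0) return(s)
  ch <- strsplit(s, "")[[1]]
  for (i in seq_len(nrow(calls))) ch[(calls$start[i] + 1L):calls$end[i]] <- "N"
  paste(ch, collapse = "")
}
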