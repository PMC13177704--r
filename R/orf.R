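# ORF detection on orientation-normalised elements and per-cluster
# ORF-probability profiles on MSA coordinates.

#' Find open reading frames
#'
#' Scans the three forward frames of an orientation-normalised sequence.  In
#' each frame an ORF opens at the first ATG following the previous stop and
#' closes at the next in-frame stop (TAA, TAG or TGA); nested ATGs do not
#' spawn separate ORFs.  Length is counted from the A of the start codon
#' through the last base of the stop codon; ORFs that never reach a stop are
#' not reported.  Codons containing ambiguity characters are treated as
#' sense codons (neither start nor stop).
#'
#' @param seq character string or DNAString.
#' @param orf_min_len minimum ORF length in bases (default 300).
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `frame` (0, 1, 2) and `length`.
#' @export
find_orfs <- function(seq, orf_min_len = 300L) {
  s <- toupper(as.character(seq))
  L <- nchar(s)
  out <- list()
  for (frame in 0:2) {
    starts <- seq.int(frame + 1L, L - 2L, by = 3L)
    if (length(starts) == 0 || L - frame < 3) next
    codons <- substring(s, starts, starts + 2L)
    is_start <- codons == "ATG"
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    stop_idx <- which(is_stop)
    prev <- 0L
    for (si in stop_idx) {
      cand <- which(is_start[(prev + 1L):(si - 1L)])
      if (si - 1L >= prev + 1L && length(cand)) {
        a <- prev + cand[1L]
        len <- (si - a + 1L) * 3L
        if (len >= orf_min_len) {
          out[[length(out) + 1L]] <- data.frame(
            start = starts[a] - 1L, end = starts[si] + 2L,
            frame = frame, length = len)
        }
      }
      prev <- si
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      frame = integer(), length = integer()))
  res <- do.call(rbind, out)
  res[order(res$start, res$frame), , drop = FALSE]
}

# logical ORF-presence mask (union over frames) for one sequence
orf_mask <- function(seq, orf_min_len = 300L) {
  s <- as.character(seq)
  m <- logical(nchar(s))
  o <- find_orfs(s, orf_min_len)
  if (nrow(o)) for (i in seq_len(nrow(o))) m[(o$start[i] + 1L):o$end[i]] <- TRUE
  m
}

#' Per-column ORF probability profile of a cluster
#'
#' Lifts each member's ORF-presence mask (any frame) through its MSA row
#' (gap columns contribute absence) and reports, per alignment column, the
#' fraction of members covered by an ORF.
#'
#' @param members named character vector (or DNAStringSet) of ungapped member
#'   sequences; names must match the MSA ids.
#' @param msa an `yp_msa` object from [build_msa()] over the same members.
#' @param orf_min_len minimum ORF length (bp).
#' @return numeric vector of length `msa$ncol` with values in \[0, 1\].
#' @export
orf_probability_profile <- function(members, msa, orf_min_len = 300L) {
  stopifnot(inherits(msa, "yp_msa"))
  members <- setNames(as.character(members), names(members))
  if (!all(names(members) %in% msa$ids))
    stop("member missing from MSA: ",
         paste(setdiff(names(members), msa$ids), collapse = ", "))
  prof <- numeric(msa$ncol)
  n <- length(members)
  for (nm in names(members)) {
    row <- msa$rows[[match(nm, msa$ids)]]
    ch <- strsplit(row, "")[[1]]
    notgap <- ch != "-"
    mask <- orf_mask(members[[nm]], orf_min_len)
    lifted <- logical(msa$ncol)
    lifted[notgap] <- mask[seq_len(sum(notgap))]
    prof <- prof + lifted
  }
  prof / n
}
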