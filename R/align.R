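# Alignment primitives: seeded gapped local alignment, spliced mapping with
# bounded internal gaps, and multiple sequence alignment (MAFFT or internal
# progressive backend).  Scoring: match +1, mismatch -2, gap open -4,
# gap extend -1.

hit_frame <- function() {
  data.frame(qstart = integer(), qend = integer(), tstart = integer(),
             tend = integer(), strand = character(), length = integer(),
             matches = integer(), identity = numeric(), score = integer(),
             stringsAsFactors = FALSE)
}

hits_to_df <- function(hits, strand = "+") {
  if (!length(hits)) { df <- hit_frame(); df$blocks <- list(); return(df) }
  df <- do.call(rbind, lapply(hits, function(h)
    data.frame(qstart = h$qstart, qend = h$qend, tstart = h$tstart,
               tend = h$tend, strand = strand, length = h$columns,
               matches = h$matches,
               identity = 100 * h$matches / max(1L, h$columns),
               score = h$score, stringsAsFactors = FALSE)))
  df$blocks <- lapply(hits, `[[`, "blocks")
  df
}

# drop hits whose query AND target spans reciprocally overlap a better hit
dedupe_hits <- function(df, min_recip = 0.5) {
  if (nrow(df) < 2) return(df)
  df <- df[order(-df$score, df$tstart, df$qstart), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in 2:nrow(df)) {
    for (j in which(keep[seq_len(i - 1)])) {
      rq <- reciprocal_overlap(df$qstart[i], df$qend[i], df$qstart[j], df$qend[j])
      rt <- reciprocal_overlap(df$tstart[i], df$tend[i], df$tstart[j], df$tend[j])
      if (rq > min_recip && rt > min_recip) { keep[i] <- FALSE; break }
    }
  }
  df[keep, , drop = FALSE]
}

#' Seeded gapped local alignment
#'
#' Finds maximal local alignments between two sequences via exact k-mer
#' anchoring, collinear chaining and affine-gap DP fill/extension.  In
#' self-comparison mode (`self = TRUE`) the trivial identity diagonal is
#' excluded and hits whose query and target spans overlap reciprocally by
#' more than 50% are discarded.  For small sequence pairs where seeding finds
#' nothing, an exhaustive local DP fallback is used.
#'
#' @param query,target sequences (character or DNAString); both non-empty.
#' @param min_identity minimum percent identity of reported hits.
#' @param max_gap largest internal alignment gap (bp) on either sequence.
#' @param self logical; self-comparison mode.
#' @param k seed length (default 15, or 11 for short inputs).
#' @param min_seed_bases minimum summed anchor length for a chain to be
#'   reported (defaults scale with input size).
#' @param max_chains cap on the number of chains assembled.
#' @return data.frame of hits (`qstart`, `qend`, `tstart`, `tend` 0-based
#'   half-open, `strand`, `length` = aligned columns, `matches`, `identity`,
#'   `score`) with a `blocks` list-column of gap-free segment matrices
#'   (columns: qstart, qend, tstart, tend, matches).
#' @export
local_align <- function(query, target, min_identity = 0, max_gap = 100L,
                        self = FALSE, k = NULL, min_seed_bases = NULL,
                        max_chains = 64L) {
  q <- toupper(as.character(query)); t <- toupper(as.character(target))
  if (nchar(q) == 0 || nchar(t) == 0) stop("empty input sequence")
  small <- min(nchar(q), nchar(t)) < 1500
  if (is.null(k)) k <- if (small) 11L else 15L
  if (is.null(min_seed_bases)) min_seed_bases <- if (small) 16L else 30L
  hits <- cpp_seed_align(q, t, k = k, self = self,
                         max_gap_q = max_gap, max_gap_t = max_gap,
                         min_seed_bases = min_seed_bases,
                         max_chains = max_chains)
  df <- hits_to_df(hits)
  # on small problems the exact local DP is cheap; use it whenever seeding
  # finds nothing or a chain assembled a suboptimal internal alignment
  if (!self && as.double(nchar(q)) * nchar(t) <= 1e6) {
    r <- cpp_align_pair(q, t, 2L)
    if (r$columns > 0 && (nrow(df) == 0 || r$score > max(df$score))) {
      blocks <- ops_to_blocks(r, q, t)
      df <- data.frame(qstart = r$qstart, qend = r$qend, tstart = r$tstart,
                       tend = r$tend, strand = "+", length = r$columns,
                       matches = r$matches,
                       identity = 100 * r$matches / max(1L, r$columns),
                       score = r$score, stringsAsFactors = FALSE)
      df$blocks <- list(blocks)
    }
  }
  if (nrow(df) == 0) return({ d <- hit_frame(); d$blocks <- list(); d })
  if (self) {
    recip <- reciprocal_overlap(df$qstart, df$qend, df$tstart, df$tend)
    df <- df[recip <= 0.5, , drop = FALSE]
  }
  df <- df[df$identity >= min_identity, , drop = FALSE]
  dedupe_hits(df)
}

# expand an ops-string alignment into a gap-free block matrix
ops_to_blocks <- function(r, q, t) {
  ops <- strsplit(r$ops, "")[[1]]
  qi <- r$qstart; tj <- r$tstart
  qs <- qe <- ts <- te <- mm <- integer(0)
  curq <- curt <- curm <- NA_integer_
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  prev <- ""
  close_block <- function() {
    qs <<- c(qs, curq); qe <<- c(qe, qi); ts <<- c(ts, curt); te <<- c(te, tj)
    mm <<- c(mm, curm)
  }
  for (o in ops) {
    if (o == "M") {
      if (prev != "M") { curq <- qi; curt <- tj; curm <- 0L }
      if (qc[qi + 1] == tc[tj + 1] && qc[qi + 1] %in% BASES) curm <- curm + 1L
      qi <- qi + 1L; tj <- tj + 1L
    } else {
      if (prev == "M") close_block()
      if (o == "I") qi <- qi + 1L else tj <- tj + 1L
    }
    prev <- o
  }
  if (prev == "M") close_block()
  cbind(qstart = qs, qend = qe, tstart = ts, tend = te, matches = mm)
}

#' Spliced mapping of a query onto a contig
#'
#' Maps a (database) sequence against both strands of a contig, tolerating
#' internal alignment gaps up to `max_intra_element_gap` on either side --
#' the slack needed when the 36-mer stretch lengths of query and target
#' differ.  Hits below `min_identity` are dropped.
#'
#' For reverse-strand hits the query was reverse-complemented before
#' alignment; `qstart`/`qend` and the `blocks` are reported in that
#' alignment frame, while `tstart`/`tend` are always contig coordinates.
#'
#' @param query query sequence, length >= 500.
#' @param contig target contig sequence.
#' @param max_intra_element_gap largest internal gap (bp).
#' @param min_identity minimum percent identity.
#' @param min_seed_bases minimum summed anchor length per chain.
#' @return hit data.frame as in [local_align()], with `strand` in `+`/`-`.
#' @export
map_spliced <- function(query, contig, max_intra_element_gap = 1000L,
                        min_identity = 80, min_seed_bases = 40L) {
  q <- toupper(as.character(query)); t <- toupper(as.character(contig))
  if (nchar(q) < 500) stop("query shorter than 500 bp")
  fw <- hits_to_df(cpp_seed_align(q, t, k = 15L, self = FALSE,
                                  max_gap_q = max_intra_element_gap,
                                  max_gap_t = max_intra_element_gap,
                                  min_seed_bases = min_seed_bases), "+")
  rcq <- revcomp(q)
  rv <- hits_to_df(cpp_seed_align(rcq, t, k = 15L, self = FALSE,
                                  max_gap_q = max_intra_element_gap,
                                  max_gap_t = max_intra_element_gap,
                                  min_seed_bases = min_seed_bases), "-")
  df <- rbind(fw, rv)
  df <- df[df$identity >= min_identity, , drop = FALSE]
  if (nrow(df) == 0) return(df)
  dedupe_hits(df)
}

# multi-query spliced mapping sharing one target k-mer index; returns hits of
# all queries (with a query_index column), both strands
map_spliced_multi <- function(queries, contig, max_intra_element_gap = 1000L,
                              min_identity = 0, min_seed_bases = 250L) {
  t <- toupper(as.character(contig))
  qs <- toupper(as.character(queries))
  allq <- c(qs, vapply(qs, revcomp, character(1)))
  res <- cpp_seed_align_multi(allq, t,
                              max_gap_q = max_intra_element_gap,
                              max_gap_t = max_intra_element_gap,
                              min_seed_bases = min_seed_bases,
                              max_chains = 32L)
  out <- list()
  nq <- length(qs)
  for (i in seq_along(res)) {
    if (!length(res[[i]])) next
    df <- hits_to_df(res[[i]], if (i <= nq) "+" else "-")
    df$query_index <- if (i <= nq) i else i - nq
    df <- df[df$identity >= min_identity, , drop = FALSE]
    if (nrow(df)) out[[length(out) + 1L]] <- df
  }
  if (!length(out)) { d <- hit_frame(); d$blocks <- list(); d$query_index <- integer(0); return(d) }
  do.call(rbind, out)
}

#' Multiple sequence alignment
#'
#' Default backend shells out to MAFFT (`--auto`) when available; the
#' internal backend is a deterministic progressive aligner (UPGMA guide tree
#' from pairwise global-alignment identities, ties broken by input order,
#' profile-profile merges).  Both are deterministic given the input.
#'
#' @param seqs named character vector or DNAStringSet; at least two
#'   non-empty sequences.
#' @param backend `"auto"`, `"mafft"` or `"internal"`.
#' @param mafft_args extra arguments for the mafft backend (default
#'   `"--auto"`; `"--retree 1"` trades a little accuracy for speed on large
#'   near-identical inputs).
#' @return object of class `yp_msa`: list with `ids`, `rows` (aligned
#'   sequences of equal length, gap character `-`) and `ncol`.  Removing the
#'   gaps from any row reproduces its input sequence exactly.
#' @export
build_msa <- function(seqs, backend = c("auto", "mafft", "internal"),
                      mafft_args = "--auto") {
  backend <- match.arg(backend)
  x <- setNames(toupper(as.character(seqs)), names(seqs))
  if (length(x) < 2) stop("need at least two sequences for an MSA")
  if (any(nchar(x) == 0)) stop("empty input sequence")
  ids <- names(x) %||% paste0("seq", seq_along(x))
  ids[is.na(ids) | ids == ""] <- paste0("seq", which(is.na(ids) | ids == ""))
  if (backend == "auto")
    backend <- if (nzchar(Sys.which("mafft"))) "mafft" else "internal"
  rows <- if (backend == "mafft") msa_mafft(x, mafft_args) else
    as.character(cpp_progressive_msa(x))
  stopifnot(length(unique(nchar(rows))) == 1)
  if (!identical(gsub("-", "", rows, fixed = TRUE), unname(x)))
    stop("MSA backend violated the gap-removal round-trip invariant")
  structure(list(ids = ids, rows = rows, ncol = nchar(rows[1])),
            class = "yp_msa")
}

msa_mafft <- function(x, mafft_args = "--auto") {
  fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(unname(x), paste0("s", seq_along(x)))), fin)
  status <- system2("mafft", c(mafft_args, "--quiet", shQuote(fin)),
                    stdout = fout, stderr = FALSE)
  if (!identical(status, 0L)) stop("mafft failed with status ", status)
  aln <- Biostrings::readBStringSet(fout)
  aln <- aln[order(as.integer(sub("^s", "", sub("\\s.*$", "", names(aln)))))]
  unname(toupper(as.character(aln)))
}

#' @export
print.yp_msa <- function(x, ...) {
  cat(sprintf("MSA: %d sequences x %d columns\n", length(x$ids), x$ncol))
  invisible(x)
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$rows, ""))
}
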