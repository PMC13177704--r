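# Annotation records, FASTA / GFF3 / TSV input-output.
#
# Annotation records are data.frames with required columns
#   contig, start, end (0-based half-open), strand ("+"/"-"), type, id
# plus any number of extra character attribute columns.  The feature-class
# vocabulary is closed (see `feature_classes`).

feature_classes <- c("telomere_terminal", "telomere_interstitial", "yprime",
                     "stretch_36mer", "stretch_ca", "orf",
                     "x_element_placeholder")

#' Construct an annotation record table
#'
#' @param contig,start,end,strand,type,id vectors of equal length; coordinates
#'   are 0-based half-open, `type` must come from the closed feature-class
#'   vocabulary.
#' @param ... additional attribute columns (coerced to character; round-trip
#'   losslessly through GFF3).
#' @return a data.frame of annotation records.
#' @export
annotation_records <- function(contig, start, end, strand, type, id, ...) {
  stopifnot(all(type %in% feature_classes))
  extra <- lapply(list(...), as.character)
  df <- data.frame(contig = as.character(contig), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   type = as.character(type), id = as.character(id),
                   stringsAsFactors = FALSE)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  validate_annotations(df)
  df
}

validate_annotations <- function(df, contig_lengths = NULL) {
  stopifnot(is.data.frame(df))
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0) || any(df$start >= df$end))
    stop("invalid interval: need 0 <= start < end")
  if (!all(df$strand %in% c("+", "-", "*")))
    stop("strand must be '+', '-' or '*'")
  if (!is.null(contig_lengths)) {
    len <- contig_lengths[df$contig]
    if (any(is.na(len)) || any(df$end > len))
      stop("interval exceeds contig length")
  }
  invisible(df)
}

#' Read genome assemblies
#'
#' @param paths named or unnamed character vector of FASTA paths; strain names
#'   default to the file base name.
#' @return a named list of [Biostrings::DNAStringSet] objects, one per strain.
#' @export
read_genomes <- function(paths) {
  if (length(paths) == 0) stop("no input genomes given")
  nm <- names(paths) %||% rep(NA_character_, length(paths))
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    if (!file.exists(paths[[i]])) stop("unreadable FASTA: ", paths[[i]])
    g <- tryCatch(Biostrings::readDNAStringSet(paths[[i]]),
                  error = function(e) stop("unreadable FASTA: ", paths[[i]]))
    if (length(g) == 0 || sum(Biostrings::width(g)) == 0)
      stop("empty genome: ", paths[[i]])
    names(g) <- sub("\\s.*$", "", names(g))
    out[[i]] <- g
    if (is.na(nm[i]) || nm[i] == "")
      nm[i] <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(paths[[i]]))
  }
  names(out) <- nm
  out
}

#' Write annotation records as GFF3
#'
#' Internal 0-based half-open coordinates are converted to the 1-based
#' inclusive GFF3 convention.  Attribute columns round-trip losslessly.
#'
#' @param df annotation record table.
#' @param path output file.
#' @export
write_gff3 <- function(df, path) {
  validate_annotations(df)
  if (nrow(df) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = df$strand)
  gr$type <- df$type
  gr$ID <- df$id
  extras <- setdiff(names(df), c("contig", "start", "end", "strand", "type", "id"))
  for (nm in extras) S4Vectors::mcols(gr)[[nm]] <- as.character(df[[nm]])
  rtracklayer::export.gff3(gr, path)
  # drop the volatile date header so outputs are byte-stable
  lines <- readLines(path)
  lines <- lines[!grepl("^##(date|source-version)", lines)]
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 file back into annotation records
#'
#' @param path GFF3 file.
#' @return annotation record table (0-based half-open coordinates).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import.gff3(path)
  if (length(gr) == 0)
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      strand = character(), type = character(), id = character(),
                      stringsAsFactors = FALSE))
  df <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   id = as.character(gr$ID),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  extras <- setdiff(names(mc), c("source", "type", "score", "phase", "ID"))
  for (nm in extras) df[[nm]] <- as.character(mc[[nm]])
  df
}

# deterministic TSV writer: fixed number formatting, no row names
write_tsv <- function(df, path, digits = 6) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- formatC(df[[nm]], digits = digits, format = "g")
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}
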