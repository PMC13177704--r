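# Distribution and association analyses: count tables, ITS classification,
# within- vs between-strain diversity, telomere-length association tests and
# a generic contingency test.

#' Tabulate element distribution
#'
#' @param elements element table (`element_id`, `strain`, `contig`, `side`).
#' @param labels optional named cluster labels.
#' @param strains optional strain universe (strains without elements keep a
#'   zero row).
#' @return list of tables: `per_strain`, `per_extremity`,
#'   `cluster_by_strain`, `tandem_histogram` (elements per extremity: 0, 1,
#'   2, 3+).
#' @export
tabulate_distribution <- function(elements, labels = NULL, strains = NULL) {
  strains <- strains %||% unique(elements$strain)
  per_strain <- data.frame(
    strain = strains,
    n = as.integer(table(factor(elements$strain, levels = strains))),
    stringsAsFactors = FALSE)
  ext <- paste0(elements$contig, ".", elements$side)
  per_ext <- as.data.frame(table(strain = elements$strain, extremity = ext),
                           stringsAsFactors = FALSE)
  names(per_ext)[3] <- "n"
  per_ext <- per_ext[per_ext$n > 0, , drop = FALSE]
  cl_by_strain <- NULL
  if (!is.null(labels)) {
    cl <- as.character(labels[elements$element_id])
    okc <- !is.na(cl)
    if (any(okc)) {
      cl_by_strain <- as.data.frame(table(strain = elements$strain[okc],
                                          cluster = cl[okc]),
                                    stringsAsFactors = FALSE)
      names(cl_by_strain)[3] <- "n"
    }
  }
  cnt <- table(paste(elements$strain, ext))
  bins <- c(`0` = 0L, `1` = sum(cnt == 1), `2` = sum(cnt == 2),
            `3+` = sum(cnt >= 3))
  list(per_strain = per_strain, per_extremity = per_ext,
       cluster_by_strain = cl_by_strain, tandem_histogram = bins)
}

#' Classify interstitial telomeric sequences by context
#'
#' Each interstitial call is assigned `tandem_junction` when it lies between
#' two elements of one array (both within `association_window`),
#' `centromere_proximal` when within `association_window` of a single
#' element's centromere-proximal end, and `unassigned` otherwise.
#'
#' @param telomere_calls call table with `strain`, `contig`, `start`, `end`,
#'   `kind`.
#' @param elements element table.
#' @param association_window maximum ITS-element distance (bp).
#' @return data.frame of ITS records: interval, `length`, `context`,
#'   `distance_to_element`, flanking element ids.
#' @export
classify_its <- function(telomere_calls, elements, association_window = 500L) {
  its <- telomere_calls[telomere_calls$kind == "interstitial", , drop = FALSE]
  if (nrow(its) == 0)
    return(data.frame(strain = character(), contig = character(),
                      start = integer(), end = integer(), length = integer(),
                      context = character(), distance_to_element = integer(),
                      element_distal = character(), element_proximal = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(its)), function(i) {
    x <- its[i, ]
    el <- elements[elements$strain == x$strain & elements$contig == x$contig, ,
                   drop = FALSE]
    before <- el[el$end <= x$start + 10L, , drop = FALSE] # element left of ITS
    after <- el[el$start >= x$end - 10L, , drop = FALSE]  # element right of ITS
    d_before <- if (nrow(before)) x$start - max(before$end) else NA_integer_
    d_after <- if (nrow(after)) min(after$start) - x$end else NA_integer_
    id_before <- if (nrow(before)) before$element_id[which.max(before$end)] else NA_character_
    id_after <- if (nrow(after)) after$element_id[which.min(after$start)] else NA_character_
    w <- association_window
    context <- "unassigned"; dist <- NA_integer_
    distal <- NA_character_; proximal <- NA_character_
    if (!is.na(d_before) && !is.na(d_after) && d_before <= w && d_after <= w) {
      context <- "tandem_junction"; dist <- min(d_before, d_after)
      distal <- id_after; proximal <- id_before
    } else {
      # centromere-proximal to exactly one element: the ITS sits on the
      # centromere side of that element (element side L: ITS right of it)
      cand <- c()
      if (!is.na(d_after) && d_after <= w) {
        side <- el$side[el$element_id == id_after]
        if (length(side) && side == "R") cand <- c(cand, after = d_after)
      }
      if (!is.na(d_before) && d_before <= w) {
        side <- el$side[el$element_id == id_before]
        if (length(side) && side == "L") cand <- c(cand, before = d_before)
      }
      if (length(cand)) {
        context <- "centromere_proximal"
        dist <- min(cand)
        who <- names(cand)[which.min(cand)]
        distal <- if (who == "after") id_after else id_before
      }
    }
    data.frame(strain = x$strain, contig = x$contig, start = x$start,
               end = x$end, length = x$end - x$start, context = context,
               distance_to_element = dist, element_distal = distal,
               element_proximal = proximal, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Within- vs between-strain diversity of elements
#'
#' Extracts from every element its best local hit against a conserved-region
#' anchor sequence (elements without a hit are skipped), aligns the
#' extracted regions, computes pairwise percent divergence (100 minus
#' percent similarity; shared-gap columns ignored) and partitions the pairs
#' into within-strain and between-strain sets.
#'
#' @param element_seqs named oriented element sequences.
#' @param strains named vector: element id -> strain.
#' @param anchor conserved-region anchor sequence.
#' @param min_anchor_len minimum hit length to accept the region.
#' @param backend MSA backend.
#' @return list with `within`, `between` (numeric divergence vectors),
#'   medians, and the ids skipped.
#' @export
diversity_within_between <- function(element_seqs, strains, anchor,
                                     min_anchor_len = 200L, backend = "auto") {
  seqs <- setNames(as.character(element_seqs), names(element_seqs))
  regions <- list(); skipped <- character(0)
  for (id in names(seqs)) {
    h <- local_align(anchor, seqs[[id]], min_identity = 0, max_gap = 1000L)
    if (nrow(h) == 0 || max(h$length) < min_anchor_len) {
      skipped <- c(skipped, id); next
    }
    hbest <- h[which.max(h$score), ]
    regions[[id]] <- substr(seqs[[id]], hbest$tstart + 1L, hbest$tend)
  }
  if (length(regions) < 2) stop("fewer than two elements carry the conserved region")
  msa <- build_msa(unlist(regions), backend = backend)
  div <- 100 - similarity_from_msa(msa)
  ids <- rownames(div)
  st <- strains[ids]
  within <- c(); between <- c()
  for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
    if (st[i] == st[j]) within <- c(within, div[i, j])
    else between <- c(between, div[i, j])
  }
  if (!length(between)) warning("single strain: between-strain set is empty")
  list(within = within, between = between,
       median_within = if (length(within)) median(within) else NA_real_,
       median_between = if (length(between)) median(between) else NA_real_,
       skipped = skipped)
}

#' Telomere-length association tests
#'
#' Normalises each extremity's telomere length by its strain mean, groups
#' extremities by the class of the telomere-adjacent (distal) element (or
#' "none"), and tests each class against the no-Y' group with a two-tailed
#' two-sample t-test (Welch by default; `var_equal = TRUE` for the pooled
#' form).  Also reports, per class, the Spearman rank correlation between
#' per-strain copy number and per-strain mean telomere length.
#'
#' @param table telomere-length table (`strain`, `extremity`, `length_bp`).
#' @param extremities extremity table with `strain`, `extremity`,
#'   `distal_class` (NA when no element).
#' @param copy_counts optional data.frame `strain`, `class`, `n` for the
#'   correlation part (computed from `elements` tables upstream).
#' @param var_equal use the pooled-variance t-test.
#' @param fdr append Benjamini-Hochberg adjusted p-values.
#' @return data.frame of `AssociationResult` rows: comparison, group sizes,
#'   effect (1 - mean(class)/mean(none)), statistic, p_value, test_name.
#' @export
telomere_association <- function(table, extremities, copy_counts = NULL,
                                 var_equal = FALSE, fdr = FALSE) {
  key <- paste(extremities$strain, extremities$extremity)
  m <- match(paste(table$strain, table$extremity), key)
  cls <- extremities$distal_class[m]
  cls[is.na(cls)] <- "none"
  strain_mean <- tapply(table$length_bp, table$strain, mean)
  norm <- table$length_bp / strain_mean[table$strain]
  res <- list()
  none <- norm[cls == "none"]
  for (cl in setdiff(unique(cls), "none")) {
    grp <- norm[cls == cl]
    if (length(grp) < 2 || length(none) < 2) {
      res[[length(res) + 1L]] <- data.frame(
        comparison = paste0(cl, "_vs_none"), n1 = length(grp), n2 = length(none),
        effect = 1 - mean(grp) / mean(none), statistic = NA_real_,
        p_value = NA_real_, test_name = "t_two_tailed", stringsAsFactors = FALSE)
      next
    }
    tt <- t.test(grp, none, var.equal = var_equal)
    res[[length(res) + 1L]] <- data.frame(
      comparison = paste0(cl, "_vs_none"), n1 = length(grp), n2 = length(none),
      effect = 1 - mean(grp) / mean(none), statistic = unname(tt$statistic),
      p_value = tt$p.value, test_name = "t_two_tailed", stringsAsFactors = FALSE)
  }
  if (!is.null(copy_counts)) {
    for (cl in unique(copy_counts$class)) {
      sub <- copy_counts[copy_counts$class == cl, , drop = FALSE]
      cnt <- setNames(sub$n, sub$strain)[names(strain_mean)]
      cnt[is.na(cnt)] <- 0
      if (length(unique(cnt)) < 2) next
      ct <- suppressWarnings(cor.test(as.numeric(cnt), as.numeric(strain_mean),
                                      method = "spearman", exact = FALSE))
      res[[length(res) + 1L]] <- data.frame(
        comparison = paste0(cl, "_copies_vs_strain_mean"),
        n1 = length(cnt), n2 = length(strain_mean),
        effect = unname(ct$estimate), statistic = unname(ct$statistic),
        p_value = ct$p.value, test_name = "spearman", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (fdr && !is.null(out)) out$p_adj_bh <- p.adjust(out$p_value, "BH")
  out
}

#' Chi-square contingency test
#'
#' @param tab matrix of non-negative integer counts, at least 2 x 2.
#' @return one-row `AssociationResult` data.frame (no continuity
#'   correction); attribute `expected` carries the expected counts, with a
#'   warning when any expected count is below 5.
#' @export
contingency_test <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need at least a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (all(tab == 0)) stop("all-zero table")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5)) warning("expected count below 5; chi-square approximation is weak")
  out <- data.frame(comparison = "contingency", n1 = sum(tab), n2 = NA_integer_,
                    effect = NA_real_, statistic = unname(ct$statistic),
                    p_value = ct$p.value, test_name = "chi_square",
                    stringsAsFactors = FALSE)
  attr(out, "expected") <- ct$expected
  out
}
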