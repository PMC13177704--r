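# MSA-derived percent similarity, silhouette-optimised average-linkage
# hierarchical clustering, CA reclustering, cluster filtering and consensus
# construction.

#' Pairwise percent similarity from an MSA
#'
#' For each pair of rows, columns where both sequences carry a gap are
#' ignored; the similarity is 100 times the fraction of remaining columns
#' with identical non-gap residues (a column with a gap in exactly one row
#' counts as a difference), i.e. shared nucleotides over the full length
#' covered by the union of the two sequences.
#'
#' @param msa an `yp_msa`.
#' @return symmetric numeric matrix (diagonal 100) with dimnames `msa$ids`.
#' @export
similarity_from_msa <- function(msa) {
  stopifnot(inherits(msa, "yp_msa"))
  n <- length(msa$ids)
  if (n < 2) stop("need at least two rows")
  m <- msa_matrix(msa)
  gap <- m == "-"
  sim <- matrix(100, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both_gap <- gap[i, ] & gap[j, ]
      denom <- sum(!both_gap)
      ident <- sum(m[i, ] == m[j, ] & !gap[i, ] & !both_gap)
      sim[i, j] <- sim[j, i] <- if (denom > 0) 100 * ident / denom else 100
    }
  }
  sim
}

# mean silhouette width over a flat partition, from a distance matrix;
# singleton clusters contribute 0
mean_silhouette <- function(labels, d) {
  labels <- as.character(labels)
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(unique(labels[!own]), function(cl) mean(d[i, labels == cl]),
                    numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Silhouette-optimised hierarchical clustering of elements
#'
#' Converts similarity to distance (100 - similarity), builds an
#' average-linkage dendrogram and, for every cluster count in
#' `[k_min, min(k_max, n - 1)]`, cuts it flat and computes the mean
#' silhouette on the same distances.  The cut maximising the silhouette is
#' returned (ties resolved to the smallest k).
#'
#' @param sim similarity matrix from [similarity_from_msa()].
#' @param k_min,k_max cluster-count range.
#' @return object of class `yp_clusters`: list with `labels` (named integer
#'   vector), `k`, `silhouette`, `curve` (data.frame k / silhouette),
#'   `hclust`.
#' @export
cluster_elements <- function(sim, k_min = 2L, k_max = 100L) {
  n <- nrow(sim)
  if (n < 3) stop("need at least three elements to cluster")
  d <- 100 - sim
  if (all(d[upper.tri(d)] == 0))
    stop("degenerate input: all pairwise distances are zero")
  hc <- hclust(as.dist(d), method = "average")
  ks <- seq.int(k_min, min(k_max, n - 1L))
  sil <- vapply(ks, function(k) mean_silhouette(cutree(hc, k = k), d), numeric(1))
  best <- ks[which.max(sil)] # which.max takes the first (smallest k) on ties
  labels <- cutree(hc, k = best)
  structure(list(labels = labels, k = best,
                 silhouette = sil[ks == best],
                 curve = data.frame(k = ks, silhouette = sil),
                 hclust = hc),
            class = "yp_clusters")
}

#' Recluster CA-containing elements after CA-region removal
#'
#' Recomputes MSA, similarity and clustering on the CA-masked sequences of
#' the CA-containing subset only, and replaces their labels with a fresh
#' cluster-id namespace (`CA1`, `CA2`, ...); all other labels are untouched.
#'
#' @param labels named character/integer vector of current labels.
#' @param ca_seqs named character vector of CA-masked sequences (subset).
#' @param k_min,k_max cluster-count range for the subset.
#' @param backend MSA backend.
#' @return list with `labels` (updated, as character) and `solution` (the
#'   subset `yp_clusters`, or NULL when skipped).
#' @export
recluster_ca_elements <- function(labels, ca_seqs, k_min = 2L, k_max = 100L,
                                  backend = "auto") {
  labels <- setNames(as.character(labels), names(labels))
  if (length(ca_seqs) < 3) {
    if (length(ca_seqs) > 0)
      warning("fewer than 3 CA-containing elements; labels unchanged")
    return(list(labels = labels, solution = NULL))
  }
  msa <- build_msa(ca_seqs, backend = backend)
  sim <- similarity_from_msa(msa)
  sol <- cluster_elements(sim, k_min, k_max)
  labels[names(sol$labels)] <- paste0("CA", sol$labels)
  list(labels = labels, solution = sol)
}

#' Summarise clusters and apply retention filters
#'
#' A cluster is retained iff it has at least `min_size` elements from at
#' least `min_strains` distinct strains and its heterogeneity (100 minus the
#' mean intra-cluster percent similarity) does not exceed
#' `heterogeneity_max`.
#'
#' @param labels named vector of cluster labels (element id -> cluster).
#' @param elements element table with `element_id` and `strain`.
#' @param sim similarity matrix over the same elements.
#' @param min_size,min_strains,heterogeneity_max retention thresholds.
#' @return data.frame sorted by size (descending) with per-cluster size,
#'   strain count, mean intra-cluster similarity, heterogeneity and
#'   `retained` flag.
#' @export
summarize_and_filter <- function(labels, elements, sim, min_size = 5L,
                                 min_strains = 2L, heterogeneity_max = 15) {
  labels <- setNames(as.character(labels), names(labels))
  out <- lapply(unique(labels), function(cl) {
    ids <- names(labels)[labels == cl]
    strains <- unique(elements$strain[match(ids, elements$element_id)])
    intra <- if (length(ids) > 1) {
      sm <- sim[ids, ids, drop = FALSE]
      mean(sm[upper.tri(sm)])
    } else 100
    het <- 100 - intra
    data.frame(cluster = cl, size = length(ids), n_strains = length(strains),
               mean_intra_similarity = intra, heterogeneity = het,
               retained = length(ids) >= min_size &&
                 length(strains) >= min_strains && het <= heterogeneity_max,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  df[order(-df$size, df$cluster), , drop = FALSE]
}

#' Majority-rule consensus of cluster members
#'
#' Aligns the members, takes the majority residue per column (ties resolved
#' in A < C < G < T order, gap last), drops columns whose majority is a gap
#' and reports per-kept-column coverage (fraction of non-gap rows).
#'
#' @param seqs named character vector / DNAStringSet of members.
#' @param backend MSA backend.
#' @return list with `consensus` (character string) and `coverage` (numeric
#'   per consensus position).
#' @export
build_consensus <- function(seqs, backend = "auto") {
  x <- toupper(as.character(seqs))
  if (length(x) == 0) stop("no sequences")
  if (length(x) == 1) {
    warning("single member; consensus is the member sequence")
    return(list(consensus = unname(x), coverage = rep(1, nchar(x))))
  }
  msa <- build_msa(x, backend = backend)
  m <- msa_matrix(msa)
  lv <- c(BASES, "-")
  counts <- vapply(seq_len(ncol(m)), function(j)
    tabulate(factor(m[, j], levels = lv), nbins = 5L), integer(5))
  maj <- lv[apply(counts, 2, which.max)] # ties: earliest level (A<C<G<T<-)
  keep <- maj != "-"
  cons <- paste(maj[keep], collapse = "")
  cov <- colSums(counts[1:4, keep, drop = FALSE]) / length(x)
  list(consensus = cons, coverage = cov)
}
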