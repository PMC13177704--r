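# Independent oracles and shared generators for the test suite.

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# brute-force ORF scan: explicit codon walk per frame, minimal logic shared
# with the implementation
bf_orfs <- function(seq, min_len = 300L) {
  s <- toupper(seq)
  L <- nchar(s)
  out <- list()
  for (frame in 0:2) {
    open_at <- NA
    i <- frame + 1L
    while (i + 2L <= L) {
      cod <- substr(s, i, i + 2L)
      if (is.na(open_at) && cod == "ATG") open_at <- i
      if (!is.na(open_at) && cod %in% c("TAA", "TAG", "TGA")) {
        len <- i + 2L - open_at + 1L
        if (len >= min_len)
          out[[length(out) + 1L]] <- data.frame(start = open_at - 1L,
                                                end = i + 2L, frame = frame,
                                                length = len)
        open_at <- NA
      }
      i <- i + 3L
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      length = integer()))
  res <- do.call(rbind, out)
  res[order(res$start, res$frame), , drop = FALSE]
}

# brute-force pairwise percent similarity: per-column loop over two rows
bf_similarity_pair <- function(r1, r2) {
  a <- strsplit(r1, "")[[1]]; b <- strsplit(r2, "")[[1]]
  n_eff <- 0L; n_id <- 0L
  for (i in seq_along(a)) {
    if (a[i] == "-" && b[i] == "-") next
    n_eff <- n_eff + 1L
    if (a[i] == b[i]) n_id <- n_id + 1L
  }
  if (n_eff == 0) 100 else 100 * n_id / n_eff
}

# brute-force mean silhouette: direct formula per point, explicit loops
bf_mean_silhouette <- function(labels, d) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(same)) { s[i] <- 0; next }
    a <- sum(d[i, same]) / length(same)
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      mem <- which(labels == cl)
      b <- min(b, sum(d[i, mem]) / length(mem))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# pair of sequences with a planted homologous segment in random flanks
make_planted_pair <- function(seg_range = c(120, 250), len_range = c(150, 300),
                              sub_rate = 0.05) {
  L1 <- sample(len_range[1]:len_range[2], 1)
  L2 <- sample(len_range[1]:len_range[2], 1)
  seg <- sample(seg_range[1]:min(L1, L2, seg_range[2]), 1)
  core <- rnd_dna(seg)
  mut <- yprimescan:::mutate_seq(core, sub_rate)
  p1 <- sample(0:(L1 - seg), 1); p2 <- sample(0:(L2 - seg), 1)
  list(q = paste0(rnd_dna(p1), core, rnd_dna(L1 - seg - p1)),
       t = paste0(rnd_dna(p2), mut, rnd_dna(L2 - seg - p2)))
}

# element sequences drawn from templates with stretches, for cluster tests
gen_template_elements <- function(templates, classes, sub_rate = 0.01,
                                  stretch_div = 0.1) {
  seqs <- character(length(classes))
  for (i in seq_along(classes)) {
    lay <- templates$layout[[classes[i]]]
    bb <- yprimescan:::mutate_seq(templates$backbones[[classes[i]]], sub_rate)
    st <- if (lay$stretch == "mer36")
      yprimescan:::make_stretch_36(sample(0:36, 1), templates$motif, stretch_div)$seq
    else yprimescan:::make_ca_region(sample(10:30, 1), templates$patterns)$seq
    seqs[i] <- paste0(substr(bb, 1, lay$slot), st,
                      substr(bb, lay$slot + 1, nchar(bb)))
  }
  setNames(seqs, sprintf("e%03d", seq_along(classes)))
}

# run telomere calling + window repeats + db + detection on a simulation
run_detection <- function(sim, cfg = pipeline_config()) {
  tel <- list(); wh <- list()
  for (strain in names(sim$genomes)) for (contig in names(sim$genomes[[strain]])) {
    calls <- detect_telomeres(sim$genomes[[strain]][[contig]],
                              window = cfg$tel_window, threshold = cfg$tel_threshold,
                              merge_gap = cfg$tel_merge_gap,
                              min_its_len = cfg$min_its_len,
                              terminal_margin = cfg$terminal_margin)
    if (nrow(calls)) tel[[length(tel) + 1]] <- cbind(strain = strain,
                                                     contig = contig, calls)
  }
  tel <- do.call(rbind, tel)
  for (strain in names(sim$genomes)) for (contig in names(sim$genomes[[strain]])) {
    sub <- tel[tel$strain == strain & tel$contig == contig, , drop = FALSE]
    m <- mask_telomeres(sim$genomes[[strain]][[contig]], sub)
    h <- find_window_repeats(m, terminal_span = cfg$terminal_span,
                             window = cfg$window_size, step = cfg$window_step,
                             len_min = cfg$repeat_len_min, len_max = cfg$repeat_len_max,
                             min_identity = cfg$repeat_identity_min)
    if (nrow(h)) wh[[length(wh) + 1]] <- cbind(strain = strain, contig = contig, h)
  }
  wh <- if (length(wh)) do.call(rbind, wh) else NULL
  db <- build_high_confidence_db(wh, sim$genomes, yprime_reference(sim$templates),
                                 tel, flank_gap_max = cfg$flank_gap_max,
                                 ref_match_min = cfg$ref_match_min,
                                 ref_identity_min = cfg$ref_identity_min)
  det <- detect_elements(db, sim$genomes, tel, cfg)
  list(tel = tel, window_hits = wh, db = db, det = det)
}

# greedy 1:1 matching of detected elements to truth at a reciprocal-overlap
# threshold; returns TP/FP/FN and boundary errors
match_truth <- function(elements, truth, min_recip = 0.9) {
  used <- rep(FALSE, nrow(elements))
  TP <- 0L; FN <- 0L; errs <- numeric(0)
  for (i in seq_len(nrow(truth))) {
    e <- truth[i, ]
    ov <- pmin(elements$end, e$end) - pmax(elements$start, e$start)
    ri <- which(elements$contig == e$contig & elements$strain == e$strain &
                  !used & ov >= min_recip * pmax(elements$end - elements$start,
                                                 e$end - e$start))
    if (length(ri)) {
      used[ri[1]] <- TRUE; TP <- TP + 1L
      errs <- c(errs, abs(elements$start[ri[1]] - e$start),
                abs(elements$end[ri[1]] - e$end))
    } else FN <- FN + 1L
  }
  list(TP = TP, FN = FN, FP = sum(!used), errs = errs)
}
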