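# End-to-end pipeline orchestration and output emission.

#' Run the full Y' annotation pipeline
#'
#' Stages: telomere/ITS calling, telomere masking, windowed self-repeat
#' discovery, high-confidence database construction, exhaustive element
#' detection, internal repeat profiling and masking, similarity +
#' silhouette-optimised clustering (with CA reclustering), cluster filtering,
#' per-cluster consensus and ORF-probability profiles, and distribution /
#' association statistics.  Deterministic given `config$seed`.
#'
#' @param genomes character vector of FASTA paths, a named list of
#'   DNAStringSet, or an `yp_simulation`.
#' @param config `yp_config`.
#' @param reference reference Y' sequences (DNAStringSet or FASTA path);
#'   defaults to the built-in synthetic template family.
#' @param telomere_table optional telomere-length table (`strain`,
#'   `extremity`, `length_bp`) enabling association tests.
#' @param out_dir optional output directory; when given, GFF3 / FASTA / TSV
#'   outputs and a run manifest are written.
#' @return result bundle: list with `telomere_calls`, `window_hits`, `db`,
#'   `elements`, `element_seqs`, `repeats`, `msa`, `similarity`, `clusters`,
#'   `cluster_summary`, `consensi`, `orf_profiles`, `stats`, `funnel`,
#'   `manifest`.
#' @export
run_pipeline <- function(genomes, config = pipeline_config(), reference = NULL,
                         telomere_table = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "yp_config"))
  if (inherits(genomes, "yp_simulation")) genomes <- genomes$genomes
  if (is.character(genomes)) genomes <- read_genomes(genomes)
  if (length(genomes) == 0) stop("no input genomes given")
  for (g in genomes) if (length(g) == 0 || sum(Biostrings::width(g)) == 0)
    stop("empty genome")
  if (is.null(reference)) reference <- yprime_reference()
  set.seed(config$seed)

  # -- telomeres -------------------------------------------------------------
  tel <- list()
  for (strain in names(genomes)) for (contig in names(genomes[[strain]])) {
    calls <- detect_telomeres(genomes[[strain]][[contig]],
                              window = config$tel_window,
                              threshold = config$tel_threshold,
                              merge_gap = config$tel_merge_gap,
                              min_its_len = config$min_its_len,
                              terminal_margin = config$terminal_margin)
    if (nrow(calls))
      tel[[length(tel) + 1L]] <- cbind(strain = strain, contig = contig, calls,
                                       stringsAsFactors = FALSE)
  }
  tel <- if (length(tel)) do.call(rbind, tel) else
    data.frame(strain = character(), contig = character(), start = integer(),
               end = integer(), kind = character(), score = numeric(),
               strand_class = character(), length = integer())

  # -- windowed self-repeats -------------------------------------------------
  wh <- list()
  for (strain in names(genomes)) for (contig in names(genomes[[strain]])) {
    sub <- tel[tel$strain == strain & tel$contig == contig, , drop = FALSE]
    masked <- mask_telomeres(genomes[[strain]][[contig]], sub)
    h <- find_window_repeats(masked, terminal_span = config$terminal_span,
                             window = config$window_size, step = config$window_step,
                             len_min = config$repeat_len_min,
                             len_max = config$repeat_len_max,
                             min_identity = config$repeat_identity_min,
                             max_gap = config$block_trim_gap)
    if (nrow(h))
      wh[[length(wh) + 1L]] <- cbind(strain = strain, contig = contig, h,
                                     stringsAsFactors = FALSE)
  }
  wh <- if (length(wh)) do.call(rbind, wh) else NULL

  # -- database + detection --------------------------------------------------
  db <- build_high_confidence_db(wh, genomes, reference, tel,
                                 flank_gap_max = config$flank_gap_max,
                                 ref_match_min = config$ref_match_min,
                                 ref_identity_min = config$ref_identity_min)
  det <- detect_elements(db, genomes, tel, config)
  el <- det$elements
  keep <- !el$edge_truncated
  core_ids <- el$element_id[keep]

  # -- repeat profiling ------------------------------------------------------
  rep_prof <- NULL; masked_seqs <- character(0)
  if (length(core_ids)) {
    rep_prof <- profile_repeats(det$seqs[core_ids], config)
    masked_seqs <- vapply(rep_prof$masked, `[[`, character(1), "masked_sequence")
  }

  # -- clustering ------------------------------------------------------------
  msa <- NULL; sim <- NULL; clusters <- NULL; summary_df <- NULL
  labels <- NULL; consensi <- list(); orf_profiles <- list()
  if (length(masked_seqs) >= 3) {
    msa <- build_msa(masked_seqs)
    sim <- similarity_from_msa(msa)
    clusters <- tryCatch(cluster_elements(sim, config$k_min, config$k_max),
                         error = function(e) NULL)
    if (!is.null(clusters)) {
      labels <- setNames(as.character(clusters$labels), names(clusters$labels))
      ca_ids <- names(rep_prof$ca_masked)
      if (length(ca_ids)) {
        ca_seqs <- vapply(rep_prof$ca_masked, `[[`, character(1), "masked_sequence")
        rc <- recluster_ca_elements(labels, ca_seqs, config$k_min, config$k_max)
        labels <- rc$labels
      }
      summary_df <- summarize_and_filter(labels, el, sim,
                                         min_size = config$cluster_min_size,
                                         min_strains = config$cluster_min_strains,
                                         heterogeneity_max = config$heterogeneity_max)
      for (cl in summary_df$cluster[summary_df$retained]) {
        ids <- names(labels)[labels == cl]
        cons <- build_consensus(det$seqs[ids])
        consensi[[cl]] <- cons
        cmsa <- build_msa(setNames(as.character(det$seqs[ids]), ids))
        orf_profiles[[cl]] <- orf_probability_profile(
          setNames(as.character(det$seqs[ids]), ids), cmsa, config$orf_min_len)
      }
    }
  }

  # -- statistics ------------------------------------------------------------
  dist_tabs <- tabulate_distribution(el[keep, , drop = FALSE], labels,
                                     strains = names(genomes))
  its_records <- classify_its(tel, el[keep, , drop = FALSE],
                              config$association_window)
  assoc <- NULL
  if (!is.null(telomere_table) && !is.null(labels)) {
    ext <- element_extremities(el[keep, , drop = FALSE], labels, genomes)
    cc <- copy_counts_by_class(el[keep, , drop = FALSE], labels)
    assoc <- telomere_association(telomere_table, ext, cc)
  }

  funnel <- det$funnel
  manifest <- rbind(
    data.frame(key = paste0("config.", names(unclass(config))),
               value = vapply(unclass(config), function(x)
                 paste(x, collapse = ","), character(1)),
               stringsAsFactors = FALSE),
    data.frame(key = c("n_strains", "n_contigs", "n_telomere_calls",
                       "n_window_hits", "db_size", names(funnel),
                       "n_clusters", "n_retained_clusters"),
               value = as.character(c(length(genomes),
                                      sum(vapply(genomes, length, integer(1))),
                                      nrow(tel),
                                      if (is.null(wh)) 0L else nrow(wh),
                                      nrow(db$entries), unname(funnel),
                                      if (is.null(clusters)) 0L else
                                        length(unique(labels)),
                                      if (is.null(summary_df)) 0L else
                                        sum(summary_df$retained))),
               stringsAsFactors = FALSE))

  res <- list(telomere_calls = tel, window_hits = wh, db = db, elements = el,
              element_seqs = det$seqs, repeats = rep_prof, msa = msa,
              similarity = sim, clusters = clusters, labels = labels,
              cluster_summary = summary_df, consensi = consensi,
              orf_profiles = orf_profiles,
              stats = list(distribution = dist_tabs, its = its_records,
                           association = assoc),
              funnel = funnel, manifest = manifest, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(res, genomes, out_dir)
  invisible(res)
}

# distal element and per-extremity class table from detected elements
element_extremities <- function(elements, labels, genomes) {
  rows <- list()
  for (strain in names(genomes)) for (contig in names(genomes[[strain]])) {
    for (side in c("L", "R")) {
      sub <- elements[elements$strain == strain & elements$contig == contig &
                        elements$side == side, , drop = FALSE]
      distal <- if (nrow(sub) == 0) NA_character_ else {
        i <- if (side == "L") which.min(sub$start) else which.max(sub$end)
        cl <- labels[sub$element_id[i]]
        if (is.na(cl)) NA_character_ else as.character(cl)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        strain = strain, contig = contig, side = side,
        extremity = paste0(contig, ".", side),
        n_elements = nrow(sub), distal_class = distal, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

copy_counts_by_class <- function(elements, labels) {
  cl <- as.character(labels[elements$element_id])
  df <- as.data.frame(table(strain = elements$strain, class = cl),
                      stringsAsFactors = FALSE)
  names(df)[3] <- "n"
  df
}

write_pipeline_outputs <- function(res, genomes, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  el <- res$elements
  # per-strain GFF3 with telomeres, elements, stretches, ORFs
  for (strain in names(genomes)) {
    ann <- list()
    tl <- res$telomere_calls[res$telomere_calls$strain == strain, , drop = FALSE]
    if (nrow(tl))
      ann[[length(ann) + 1L]] <- annotation_records(
        tl$contig, tl$start, tl$end, "+",
        ifelse(tl$kind == "terminal", "telomere_terminal", "telomere_interstitial"),
        sprintf("%s_tel%03d", strain, seq_len(nrow(tl))),
        score = sprintf("%.4f", tl$score), strand_class = tl$strand_class)
    se <- el[el$strain == strain, , drop = FALSE]
    if (nrow(se))
      ann[[length(ann) + 1L]] <- annotation_records(
        se$contig, se$start, se$end, se$orientation, "yprime", se$element_id,
        edge_truncated = se$edge_truncated, telomere_flanked = se$telomere_flanked,
        cluster = if (is.null(res$labels)) NA_character_ else
          unname(res$labels[se$element_id]))
    if (!is.null(res$repeats)) {
      for (id in intersect(names(res$repeats$stretches), se$element_id)) {
        e <- se[se$element_id == id, ]
        for (st in res$repeats$stretches[[id]]) {
          if (e$orientation == "+") {
            cs <- e$start + st$start; ce <- e$start + st$end
          } else {
            cs <- e$start + (e$length - st$end); ce <- e$start + (e$length - st$start)
          }
          ann[[length(ann) + 1L]] <- annotation_records(
            e$contig, cs, ce, e$orientation,
            if (st$stretch_class == "mer36") "stretch_36mer" else "stretch_ca",
            paste0(id, "_", st$stretch_class),
            element_id = id, unit_count = st$unit_count %||% NA_integer_)
        }
      }
    }
    df <- if (length(ann)) do.call(rbind, lapply(ann, function(a) {
      cols <- unique(unlist(lapply(ann, names)))
      for (m in setdiff(cols, names(a))) a[[m]] <- NA_character_
      a[, cols]
    })) else NULL
    if (!is.null(df)) {
      df <- df[order(df$contig, df$start, df$id), , drop = FALSE]
      write_gff3(df, file.path(out_dir, paste0(strain, ".gff3")))
    }
  }
  if (length(res$element_seqs))
    Biostrings::writeXStringSet(res$element_seqs,
                                file.path(out_dir, "elements.fasta"))
  if (!is.null(res$similarity)) {
    sim <- as.data.frame(res$similarity)
    sim <- cbind(element_id = rownames(res$similarity), sim)
    write_tsv(sim, file.path(out_dir, "similarity.tsv"))
  }
  if (!is.null(res$labels)) {
    cl <- data.frame(element_id = names(res$labels),
                     cluster = unname(res$labels), stringsAsFactors = FALSE)
    cl$retained <- cl$cluster %in%
      res$cluster_summary$cluster[res$cluster_summary$retained]
    write_tsv(cl[order(cl$element_id), ], file.path(out_dir, "clusters.tsv"))
    write_tsv(res$clusters$curve, file.path(out_dir, "silhouette.tsv"))
    write_tsv(res$cluster_summary, file.path(out_dir, "cluster_summary.tsv"))
  }
  if (length(res$consensi)) {
    cons <- Biostrings::DNAStringSet(vapply(res$consensi, `[[`, character(1),
                                            "consensus"))
    Biostrings::writeXStringSet(cons, file.path(out_dir, "consensus.fasta"))
  }
  write_tsv(res$stats$distribution$per_strain,
            file.path(out_dir, "counts_per_strain.tsv"))
  if (nrow(res$stats$its))
    write_tsv(res$stats$its, file.path(out_dir, "its.tsv"))
  if (!is.null(res$stats$association))
    write_tsv(res$stats$association, file.path(out_dir, "association.tsv"))
  write_tsv(res$manifest, file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}
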