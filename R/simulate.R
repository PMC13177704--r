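# Synthetic chromosome-end generator: element templates, genomes with planted
# telomeres / Y' arrays / repeat stretches / ITSs, and telomere-length tables,
# together with machine-readable ground truth.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

revcomp <- function(s) {
  ch <- rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]])
  paste(ch, collapse = "")
}

# i.i.d. per-base substitutions at `rate`; substituted bases change to a
# different base uniformly
mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(BASES, b), 1), character(1))
    s <- paste(ch, collapse = "")
  }
  s
}

# exactly round(rate * len) substitutions at distinct positions: per-repeat
# divergence is a property of each repeat unit, not a Bernoulli draw
diverge_unit <- function(s, rate) {
  n <- nchar(s)
  k <- round(rate * n)
  if (k == 0) return(s)
  ch <- strsplit(s, "")[[1]]
  pos <- sample.int(n, k)
  ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(BASES, b), 1), character(1))
  paste(ch, collapse = "")
}

# telomeric tract on the CA strand: tandem C(1-3)A units, C:A ~= 62:38.
# The last unit is kept whole so tracts always end on a unit boundary
# (actual length is len .. len+3).
telomere_tract <- function(len) {
  if (len < 2) return(strrep("A", max(0, len)))
  units <- character(0)
  tot <- 0
  while (tot < len) {
    u <- paste0(strrep("C", sample(1:3, 1, prob = c(0.5, 0.35, 0.15))), "A")
    units <- c(units, u)
    tot <- tot + nchar(u)
  }
  paste(units, collapse = "")
}

make_stretch_36 <- function(n, motif, divergence) {
  if (n == 0) return(list(seq = "", units = character(0)))
  units <- vapply(seq_len(n), function(i) diverge_unit(resolve_iupac(motif), divergence),
                  character(1))
  list(seq = paste(units, collapse = ""), units = units)
}

make_ca_region <- function(n, patterns = ca_patterns(), mix = c(0.7, 0.3),
                           degeneracy = 0.05) {
  if (n == 0) return(list(seq = "", units = character(0), pattern = character(0)))
  which_p <- sample(names(patterns), n, replace = TRUE, prob = mix)
  units <- vapply(which_p, function(p) diverge_unit(patterns[[p]], degeneracy),
                  character(1))
  list(seq = paste(units, collapse = ""), units = units, pattern = which_p)
}

orf_dna <- function(len) { # ATG + sense codons + TAA, length = len (multiple of 3)
  stopifnot(len %% 3 == 0, len >= 9)
  codons <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(sense, len / 3 - 2, replace = TRUE), collapse = ""), "TAA")
}

# ---------------------------------------------------------------------------
# template construction

LONG_LEN <- 6256L
BLOCK1 <- c(1200L, 1665L) # 465 bp, absent from short and mid1
BLOCK2 <- c(2500L, 3100L) # 600 bp, absent from short and mid2
CA_KEEP <- 2500L          # CA classes keep the proximal part of the long backbone
ORF1 <- c(240L, 1140L)    # planted ORF spans in long-backbone coordinates
ORF2 <- c(3896L, 5696L)
SLOT_LONG <- 3800L        # 36-mer stretch insertion offset in the long backbone

# map a coordinate of a derived backbone to its source coordinate
# (long-backbone coordinate, or list(domain, offset) for CA distal domains)
template_source_pos <- function(class, x) {
  b1 <- BLOCK1[2] - BLOCK1[1]; b2 <- BLOCK2[2] - BLOCK2[1]
  switch(class,
    long = list("long", x),
    mid1 = list("long", if (x < BLOCK1[1]) x else x + b1),
    mid2 = list("long", if (x < BLOCK2[1]) x else x + b2),
    short = list("long", if (x < BLOCK1[1]) x
                 else if (x < BLOCK2[1] - b1) x + b1 else x + b1 + b2),
    ca_rich_a = if (x < CA_KEEP) list("long", x) else list("dom_a", x - CA_KEEP),
    ca_rich_b = if (x < CA_KEEP) list("long", x) else list("dom_b", x - CA_KEEP))
}

derive_backbones <- function(long_seq, dom_a, dom_b) {
  drop_block <- function(s, blk) paste0(substr(s, 1, blk[1]), substr(s, blk[2] + 1, nchar(s)))
  list(
    long = long_seq,
    short = drop_block(drop_block(long_seq, BLOCK2), BLOCK1),
    mid1 = drop_block(long_seq, BLOCK1),
    mid2 = drop_block(long_seq, BLOCK2),
    ca_rich_a = paste0(substr(long_seq, 1, CA_KEEP), dom_a),
    ca_rich_b = paste0(substr(long_seq, 1, CA_KEEP), dom_b))
}

template_layout <- function() {
  b1 <- BLOCK1[2] - BLOCK1[1]; b2 <- BLOCK2[2] - BLOCK2[1]
  shift2 <- function(x, cls) { # ORF2 start/end in derived coordinates
    d <- switch(cls, long = 0L, mid1 = b1, mid2 = b2, short = b1 + b2)
    x - d
  }
  list(
    long = list(slot = SLOT_LONG, stretch = "mer36",
                orfs = rbind(ORF1, ORF2)),
    short = list(slot = SLOT_LONG - b1 - b2, stretch = "mer36",
                 orfs = rbind(ORF1, shift2(ORF2, "short"))),
    mid1 = list(slot = SLOT_LONG - b1, stretch = "mer36",
                orfs = rbind(ORF1, shift2(ORF2, "mid1"))),
    mid2 = list(slot = SLOT_LONG - b2, stretch = "mer36",
                orfs = rbind(ORF1, shift2(ORF2, "mid2"))),
    ca_rich_a = list(slot = CA_KEEP + 800L, stretch = "ca",
                     orfs = rbind(ORF1)),
    ca_rich_b = list(slot = CA_KEEP + 700L, stretch = "ca",
                     orfs = rbind(ORF1)))
}

#' Build the Y' element template family
#'
#' Constructs six element templates: canonical `long` and `short` (the short
#' backbone is the long backbone minus one 465 bp and one 600 bp block),
#' `mid1` / `mid2` (each lacking exactly one of the two blocks; `mid1` lacks
#' the 465 bp block by convention), and two CA-rich classes whose distal
#' halves are replaced by distinct 1.6-1.8 kb domains that nest the CA-rich
#' repeats.  Planted ORFs (one ~0.9 kb ORF in the proximal domain, one
#' 1.8 kb ORF in the distal conserved domain of non-CA classes) are the only
#' ORFs >= 300 bp in the backbones.
#'
#' @param seed integer; the template family is deterministic given the seed.
#' @return object of class `yp_templates`: a list with `backbones`, `layout`
#'   (stretch slot, stretch class, planted ORF spans per class), `motif`
#'   (degenerate 36-mer consensus), `patterns` (CA patterns) and `seed`.
#' @export
build_templates <- function(seed = 20090101L) {
  with_seed(seed, {
    dom_len_a <- 1700L; dom_len_b <- 1600L
    build_long <- function() {
      s <- rand_dna(LONG_LEN)
      # frame anchors: a stop immediately before each planted ORF keeps the
      # reported ORF start at the planted ATG
      ins <- function(s, at, piece) paste0(substr(s, 1, at), piece,
                                           substr(s, at + nchar(piece) + 1, nchar(s)))
      s <- ins(s, ORF1[1] - 3L, paste0("TAA", orf_dna(ORF1[2] - ORF1[1])))
      s <- ins(s, ORF2[1] - 3L, paste0("TAA", orf_dna(ORF2[2] - ORF2[1])))
      s
    }
    long_seq <- build_long()
    dom_a <- rand_dna(dom_len_a)
    dom_b <- rand_dna(dom_len_b)
    layout <- template_layout()
    planted_long <- rbind(ORF1, ORF2) # source-coordinate exclusion zones

    scrub <- function(long_seq, dom_a, dom_b) {
      for (iter in 1:300) {
        bb <- derive_backbones(long_seq, dom_a, dom_b)
        bad <- NULL
        for (cls in names(bb)) {
          orfs <- find_orfs(bb[[cls]], 300L)
          spans <- layout[[cls]]$orfs
          for (i in seq_len(nrow(orfs))) {
            o <- orfs[i, ]
            planted <- any(spans[, 1] == o$start & spans[, 2] == o$end)
            nested <- any(spans[, 1] <= o$start & o$end <= spans[, 2])
            if (!planted && !nested) { bad <- list(cls = cls, orf = o); break }
          }
          if (!is.null(bad)) break
        }
        if (is.null(bad)) return(list(long = long_seq, dom_a = dom_a, dom_b = dom_b))
        # place an in-frame TAA in the offending ORF, at a codon whose three
        # bases map to one source segment outside every planted ORF span
        o <- bad$orf
        cods <- seq(o$start, o$end - 3L, by = 3L)
        cods <- cods[order(abs(cods - (o$start + o$end) / 2))]
        done <- FALSE
        for (p in cods) {
          src <- template_source_pos(bad$cls, p)
          src_end <- template_source_pos(bad$cls, p + 2L)
          if (!identical(src[[1]], src_end[[1]]) || src_end[[2]] != src[[2]] + 2L) next
          if (src[[1]] == "long" &&
              any(planted_long[, 1] <= src[[2]] + 2L & src[[2]] < planted_long[, 2])) next
          repl <- function(s, at) paste0(substr(s, 1, at), "TAA", substr(s, at + 4, nchar(s)))
          if (src[[1]] == "long") long_seq <- repl(long_seq, src[[2]])
          else if (src[[1]] == "dom_a") dom_a <- repl(dom_a, src[[2]])
          else dom_b <- repl(dom_b, src[[2]])
          done <- TRUE; break
        }
        if (!done) stop("could not scrub spurious ORF in template ", bad$cls)
      }
      stop("template ORF scrubbing did not converge")
    }
    res <- scrub(long_seq, dom_a, dom_b)
    backbones <- derive_backbones(res$long, res$dom_a, res$dom_b)
    structure(list(backbones = backbones, layout = layout,
                   motif = yprime_motif_36mer(), patterns = ca_patterns(),
                   seed = seed),
              class = "yp_templates")
  })
}

#' Reference Y' element set derived from the templates
#'
#' Inserts a deterministic default repeat stretch (10 36-mer units, or ~20 CA
#' pattern units for the CA classes) into each template backbone, yielding
#' full-length reference elements for database seeding.
#'
#' @param templates an `yp_templates` object.
#' @return [Biostrings::DNAStringSet] named by class.
#' @export
yprime_reference <- function(templates = build_templates()) {
  with_seed(templates$seed + 1L, {
    seqs <- vapply(names(templates$backbones), function(cls) {
      lay <- templates$layout[[cls]]
      st <- if (lay$stretch == "mer36")
        make_stretch_36(10L, templates$motif, 0.1)$seq
      else make_ca_region(20L, templates$patterns)$seq
      bb <- templates$backbones[[cls]]
      paste0(substr(bb, 1, lay$slot), st, substr(bb, lay$slot + 1, nchar(bb)))
    }, character(1))
    Biostrings::DNAStringSet(setNames(seqs, paste0("ref_", names(templates$backbones))))
  })
}

# ---------------------------------------------------------------------------
# simulation specification

#' Simulation specification
#'
#' Collects every knob of the synthetic chromosome-end generator.  Defaults
#' emulate the structures reported for natural S. cerevisiae strains:
#' elements in 0-3 copies per end, stretch sizes 0-36 units with median ~10,
#' ITS lengths from 20 bp up to ~500 bp, terminal telomere tracts of ~300 bp.
#'
#' @param n_strains,contigs_per_strain,contig_length genome dimensions.
#' @param elements_per_end_weights probability weights for 0,1,2,3 elements
#'   at an extremity.
#' @param class_mix named class sampling weights.
#' @param substitution_rate i.i.d. per-base substitution rate applied to each
#'   planted element.
#' @param strain_substitution_rate substitutions applied once per strain to
#'   the class template, shared by all elements of that strain (models
#'   within-strain homogenisation).
#' @param stretch_weights probability weights over 0..36 36-mer units; the
#'   default gives median ~10 units with 5% stretch-free elements.
#' @param per_repeat_divergence fixed per-unit divergence of 36-mer units.
#' @param ca_units_range,ca_pattern_mix,ca_degeneracy CA-region generation.
#' @param its_tandem_prob,its_proximal_prob probabilities of an ITS at a
#'   tandem junction / centromere-proximal to the innermost element.
#' @param its_len_mean mean of the exponential ITS length excess over the
#'   20 bp minimum (capped at 500 bp).
#' @param telomere_len_mean,telomere_len_sd terminal tract length
#'   distribution (bp).
#' @param x_element_prob probability of planting the inert X-element
#'   placeholder at an extremity.
#' @param telomere_table_mean,telomere_table_sd per-extremity telomere-length
#'   table distribution (bp).
#' @param effects named per-class fractional telomere shortening at
#'   extremities carrying that class distally (e.g. `c(long = 0.064)`).
#' @param copy_effects named per-class fractional change of the strain-wide
#'   telomere length per element copy.
#' @param template_seed seed of the template family (kept fixed across
#'   simulation seeds so that genomes share one "species" reference).
#' @param seed simulation seed.
#' @return validated list of class `yp_simspec`.
#' @export
simulation_spec <- function(n_strains = 1L,
                            contigs_per_strain = 5L,
                            contig_length = 60000L,
                            elements_per_end_weights = c(0.35, 0.40, 0.20, 0.05),
                            class_mix = c(long = 0.35, short = 0.30, mid1 = 0.08,
                                          mid2 = 0.07, ca_rich_a = 0.10, ca_rich_b = 0.10),
                            substitution_rate = 0.005,
                            strain_substitution_rate = 0,
                            stretch_weights = NULL,
                            per_repeat_divergence = 0.10,
                            ca_units_range = c(10L, 30L),
                            ca_pattern_mix = c(0.7, 0.3),
                            ca_degeneracy = 0.05,
                            its_tandem_prob = 0.62,
                            its_proximal_prob = 0.5,
                            its_len_mean = 90,
                            telomere_len_mean = 300,
                            telomere_len_sd = 50,
                            x_element_prob = 0.8,
                            telomere_table_mean = 350,
                            telomere_table_sd = 35,
                            effects = numeric(0),
                            copy_effects = numeric(0),
                            template_seed = 20090101L,
                            seed = 1L) {
  if (is.null(stretch_weights)) {
    stretch_weights <- c(0.05, 0.95 * stats::dbinom(0:35, 35, 0.27))
    stretch_weights <- stretch_weights / sum(stretch_weights)
  }
  spec <- as.list(environment())
  rates <- c(spec$substitution_rate, spec$strain_substitution_rate,
             spec$per_repeat_divergence, spec$ca_degeneracy,
             spec$its_tandem_prob, spec$its_proximal_prob, spec$x_element_prob)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (length(spec$stretch_weights) != 37L)
    stop("stretch_weights must cover unit counts 0..36")
  if (its_len_mean < 0 || telomere_len_mean <= 0) stop("invalid length parameters")
  structure(spec, class = "yp_simspec")
}

# one element instance; returns seq (canonical orientation) + local features
make_element <- function(cls, strain_backbones, templates, spec) {
  lay <- templates$layout[[cls]]
  bb <- mutate_seq(strain_backbones[[cls]], spec$substitution_rate)
  if (lay$stretch == "mer36") {
    n <- sample(0:36, 1, prob = spec$stretch_weights)
    st <- make_stretch_36(n, templates$motif, spec$per_repeat_divergence)
    stretch_class <- "mer36"
  } else {
    n <- sample(seq(spec$ca_units_range[1], spec$ca_units_range[2]), 1)
    st <- make_ca_region(n, templates$patterns, spec$ca_pattern_mix, spec$ca_degeneracy)
    stretch_class <- "ca"
  }
  seq <- paste0(substr(bb, 1, lay$slot), st$seq, substr(bb, lay$slot + 1, nchar(bb)))
  list(class = cls, seq = seq, n_units = n,
       stretch_start = if (n > 0) lay$slot else NA_integer_,
       stretch_end = if (n > 0) lay$slot + nchar(st$seq) else NA_integer_,
       stretch_class = stretch_class)
}

#' Simulate chromosome-end genomes with planted ground truth
#'
#' Every contig carries a terminal telomere tract at both ends; extremities
#' carry 0-3 planted Y' elements oriented pointing toward the nearer
#' telomere, optionally separated by ITSs at tandem junctions and preceded
#' by a centromere-proximal ITS; an inert X-element placeholder is planted
#' centromere-proximal of each array.  Ground truth records all planted
#' intervals in contig coordinates, including the mutated element sequences.
#'
#' @param spec an `yp_simspec`.
#' @param templates template family (defaults to `build_templates(spec$template_seed)`).
#' @return object of class `yp_simulation`: list with `genomes` (named list of
#'   DNAStringSet), `truth` (data.frames `elements`, `stretches`, `its`,
#'   `telomeres`, `x_elements`, `extremities`), `spec`, `templates`.
#' @export
simulate_genome <- function(spec, templates = NULL) {
  stopifnot(inherits(spec, "yp_simspec"))
  if (is.null(templates)) templates <- build_templates(spec$template_seed)
  with_seed(spec$seed, {
    x_placeholder <- with_seed(spec$template_seed + 2L, rand_dna(1000L))
    genomes <- list(); el_rows <- list(); its_rows <- list(); tel_rows <- list()
    x_rows <- list(); ext_rows <- list()
    eid <- 0L
    for (si in seq_len(spec$n_strains)) {
      strain <- sprintf("S%02d", si)
      strain_backbones <- lapply(templates$backbones, mutate_seq,
                                 rate = spec$strain_substitution_rate)
      contigs <- character(spec$contigs_per_strain)
      names(contigs) <- sprintf("chr%02d", seq_len(spec$contigs_per_strain))
      for (ci in seq_len(spec$contigs_per_strain)) {
        contig <- names(contigs)[ci]
        # per-end drawing -------------------------------------------------
        end_plan <- lapply(c("L", "R"), function(side) {
          n_el <- sample(0:3, 1, prob = spec$elements_per_end_weights)
          classes <- if (n_el > 0)
            sample(names(spec$class_mix), n_el, replace = TRUE, prob = spec$class_mix)
          else character(0)
          els <- lapply(classes, make_element, strain_backbones = strain_backbones,
                        templates = templates, spec = spec)
          tel_len <- round(max(120, min(600, rnorm(1, spec$telomere_len_mean,
                                                   spec$telomere_len_sd))))
          junction_its <- if (n_el >= 2)
            runif(n_el - 1) < spec$its_tandem_prob else logical(0)
          prox_its <- n_el > 0 && runif(1) < spec$its_proximal_prob
          its_len <- function() round(min(500, 20 + stats::rexp(1, 1 / spec$its_len_mean)))
          list(side = side, els = els, tel_len = tel_len,
               junction_its = junction_its, prox_its = prox_its,
               its_lens = vapply(seq_len(n_el), function(i) its_len(), numeric(1)),
               has_x = runif(1) < spec$x_element_prob,
               x_spacer = sample(0:500, 1))
        })
        # assemble pieces: list of (seq, type, meta); proximal->distal order
        # for one end, then mirrored for the left end
        build_end <- function(plan) {
          pieces <- list()
          add <- function(seq, type, meta = list())
            pieces[[length(pieces) + 1L]] <<- c(list(seq = seq, type = type), meta)
          n_el <- length(plan$els)
          if (plan$has_x) {
            add(x_placeholder, "x")
            if (plan$x_spacer > 0) add(rand_dna(plan$x_spacer), "bg")
          }
          if (n_el > 0) {
            if (plan$prox_its) add(telomere_tract(plan$its_lens[n_el]), "its",
                                   list(context = "centromere_proximal"))
            for (i in rev(seq_len(n_el))) { # el_n (proximal) .. el_1 (distal)
              add(plan$els[[i]]$seq, "element", list(el = plan$els[[i]]))
              if (i > 1 && plan$junction_its[i - 1])
                add(telomere_tract(plan$its_lens[i - 1]), "its",
                    list(context = "tandem_junction"))
            }
          }
          add(telomere_tract(plan$tel_len), "telomere", list(len = plan$tel_len))
          pieces
        }
        left <- build_end(end_plan[[1]])
        right <- build_end(end_plan[[2]])
        used <- sum(vapply(c(left, right), function(p) nchar(p$seq), numeric(1)))
        core_len <- spec$contig_length - used
        if (core_len < 500)
          stop("contig too short to host requested features: ", strain, "/", contig)
        # left end is the mirrored (reverse-complemented) version
        segs <- list(); pos <- 0L
        emit <- function(seq, type, strand, meta) {
          start <- pos; end <- pos + nchar(seq)
          pos <<- end
          segs[[length(segs) + 1L]] <<- list(start = start, end = end, type = type,
                                             strand = strand, meta = meta, seq = seq)
          invisible(NULL)
        }
        for (p in rev(left)) emit(revcomp(p$seq), p$type, "-", p)
        emit(rand_dna(core_len), "bg", "+", list())
        for (p in right) emit(p$seq, p$type, "+", p)
        contig_seq <- paste(vapply(segs, `[[`, character(1), "seq"), collapse = "")
        contigs[ci] <- contig_seq
        # truth records ---------------------------------------------------
        n_by_side <- c(L = length(end_plan[[1]]$els), R = length(end_plan[[2]]$els))
        distal_class <- c(
          L = if (n_by_side[["L"]] > 0) end_plan[[1]]$els[[1]]$class else NA_character_,
          R = if (n_by_side[["R"]] > 0) end_plan[[2]]$els[[1]]$class else NA_character_)
        for (sd2 in c("L", "R"))
          ext_rows[[length(ext_rows) + 1L]] <- data.frame(
            strain = strain, contig = contig, side = sd2,
            extremity = paste0(contig, ".", sd2),
            n_elements = unname(n_by_side[[sd2]]),
            distal_class = unname(distal_class[[sd2]]), stringsAsFactors = FALSE)
        for (sg in segs) {
          side <- if (sg$strand == "-") "L" else "R"
          if (sg$type == "element") {
            el <- sg$meta$el
            eid <- eid + 1L
            id <- sprintf("%s_%s_%05d", strain, contig, sg$start)
            el_rows[[length(el_rows) + 1L]] <- data.frame(
              strain = strain, contig = contig, start = sg$start, end = sg$end,
              class = el$class, orientation = sg$strand, side = side,
              element_id = id, n_units = el$n_units,
              seq = if (sg$strand == "+") sg$seq else revcomp(sg$seq),
              stringsAsFactors = FALSE)
            if (!is.na(el$stretch_start)) {
              len <- sg$end - sg$start
              if (sg$strand == "+") {
                ss <- sg$start + el$stretch_start; se <- sg$start + el$stretch_end
              } else {
                ss <- sg$start + (len - el$stretch_end)
                se <- sg$start + (len - el$stretch_start)
              }
              its_local <- el$stretch_start
              x0 <- data.frame(strain = strain, contig = contig,
                               element_id = id, start = ss, end = se,
                               local_start = its_local, local_end = el$stretch_end,
                               stretch_class = el$stretch_class,
                               unit_count = el$n_units, stringsAsFactors = FALSE)
              its_rows_dummy <- NULL
              attr(x0, "kind") <- "stretch"
              x_rows[[length(x_rows) + 1L]] <- x0
            }
          } else if (sg$type == "its") {
            its_rows[[length(its_rows) + 1L]] <- data.frame(
              strain = strain, contig = contig, start = sg$start, end = sg$end,
              context = sg$meta$context, side = side,
              length = sg$end - sg$start, stringsAsFactors = FALSE)
          } else if (sg$type == "telomere") {
            tel_rows[[length(tel_rows) + 1L]] <- data.frame(
              strain = strain, contig = contig, side = side,
              start = sg$start, end = sg$end, length = sg$end - sg$start,
              stringsAsFactors = FALSE)
          } else if (sg$type == "x") {
            x_rows[[length(x_rows) + 1L]] <- {
              x0 <- data.frame(strain = strain, contig = contig,
                               element_id = NA_character_, start = sg$start,
                               end = sg$end, local_start = NA_integer_,
                               local_end = NA_integer_,
                               stretch_class = "x_placeholder",
                               unit_count = NA_integer_, stringsAsFactors = FALSE)
              attr(x0, "kind") <- "x"
              x0
            }
          }
        }
      }
      genomes[[strain]] <- Biostrings::DNAStringSet(contigs)
    }
    bindrows <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
    allx <- bindrows(x_rows, data.frame())
    stretches <- if (nrow(allx)) allx[allx$stretch_class %in% c("mer36", "ca"), , drop = FALSE] else allx
    xonly <- if (nrow(allx)) allx[allx$stretch_class == "x_placeholder",
                                  c("strain", "contig", "start", "end"), drop = FALSE] else allx
    truth <- list(
      elements = bindrows(el_rows, data.frame(strain = character(), contig = character(),
        start = integer(), end = integer(), class = character(), orientation = character(),
        side = character(), element_id = character(), n_units = integer(), seq = character())),
      stretches = stretches,
      its = bindrows(its_rows, data.frame(strain = character(), contig = character(),
        start = integer(), end = integer(), context = character(), side = character(),
        length = integer())),
      telomeres = bindrows(tel_rows, data.frame()),
      x_elements = xonly,
      extremities = bindrows(ext_rows, data.frame()))
    structure(list(genomes = genomes, truth = truth, spec = spec,
                   templates = templates),
              class = "yp_simulation")
  })
}

#' Write simulated genomes to FASTA
#'
#' @param sim an `yp_simulation`.
#' @param dir output directory (created if needed).
#' @return named character vector of FASTA paths.
#' @export
write_genomes <- function(sim, dir) {
  stopifnot(inherits(sim, "yp_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(sim$genomes), function(strain) {
    p <- file.path(dir, paste0(strain, ".fasta"))
    Biostrings::writeXStringSet(sim$genomes[[strain]], p)
    p
  }, character(1))
  paths
}

#' Draw class assignments per extremity without sequence simulation
#'
#' Lightweight counterpart of [simulate_genome()] for statistical power and
#' calibration studies: draws the number of elements and the distal class per
#' extremity from the same distributions, returning a minimal truth object
#' usable by [simulate_telomere_table()] and [telomere_association()].
#'
#' @param spec an `yp_simspec`.
#' @return list with `extremities` and `elements` data.frames.
#' @export
simulate_end_classes <- function(spec) {
  stopifnot(inherits(spec, "yp_simspec"))
  with_seed(spec$seed, {
    grid <- expand.grid(side = c("L", "R"),
                        contig = sprintf("chr%02d", seq_len(spec$contigs_per_strain)),
                        strain = sprintf("S%02d", seq_len(spec$n_strains)),
                        stringsAsFactors = FALSE)
    n_ends <- nrow(grid)
    n_el <- sample(0:3, n_ends, replace = TRUE, prob = spec$elements_per_end_weights)
    all_classes <- sample(names(spec$class_mix), sum(n_el), replace = TRUE,
                          prob = spec$class_mix)
    first_idx <- cumsum(n_el) - n_el + 1L
    ext <- data.frame(strain = grid$strain, contig = grid$contig, side = grid$side,
                      extremity = paste0(grid$contig, ".", grid$side),
                      n_elements = n_el,
                      distal_class = ifelse(n_el > 0, all_classes[first_idx],
                                            NA_character_),
                      stringsAsFactors = FALSE)
    els <- data.frame(strain = rep(grid$strain, n_el), class = all_classes,
                      stringsAsFactors = FALSE)
    list(extremities = ext, elements = els)
  })
}

#' Simulate a per-extremity telomere-length table
#'
#' Per-extremity lengths are drawn from the spec's table distribution;
#' extremities whose distal element belongs to class `c` are scaled by
#' `1 - effects[c]`, and all extremities of a strain are scaled by
#' `1 + sum(copy_effects[c] * copies_c)` to model strain-level copy-number
#' associations.
#'
#' @param spec an `yp_simspec`.
#' @param truth truth object from [simulate_genome()] (`$truth`) or
#'   [simulate_end_classes()].
#' @param seed optional seed (defaults to `spec$seed + 101`).
#' @return data.frame with columns `strain`, `extremity`, `length_bp`.
#' @export
simulate_telomere_table <- function(spec, truth, seed = NULL) {
  ext <- truth$extremities
  els <- truth$elements
  with_seed(seed %||% (spec$seed + 101L), {
    strain_factor <- setNames(rep(1, length(unique(ext$strain))), unique(ext$strain))
    if (length(spec$copy_effects)) {
      for (cl in names(spec$copy_effects)) {
        cnt <- table(factor(els$strain[els$class == cl], levels = names(strain_factor)))
        strain_factor <- strain_factor * (1 + spec$copy_effects[[cl]] * as.numeric(cnt))
      }
    }
    eff <- rep(1, nrow(ext))
    if (length(spec$effects)) {
      m <- match(ext$distal_class, names(spec$effects))
      eff <- ifelse(is.na(m), 1, 1 - unlist(spec$effects)[ifelse(is.na(m), 1, m)])
    }
    base <- pmax(50, rnorm(nrow(ext), spec$telomere_table_mean, spec$telomere_table_sd))
    data.frame(strain = ext$strain, extremity = ext$extremity,
               length_bp = base * strain_factor[ext$strain] * eff,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}
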