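test_that("window self-repeats honour the length and identity gates", {
  set.seed(51)
  # planted near-perfect tandem pair inside a 25 kb window
  unit <- rnd_dna(5200)
  copy2 <- yprimescan:::mutate_seq(unit, 0.005)
  s <- paste0(rnd_dna(4000), unit, copy2, rnd_dna(6000))
  h <- find_window_repeats(s, window = nchar(s) + 1)
  expect_gte(nrow(h), 1)
  expect_true(any(h$identity >= 99 & h$length >= 5000))
  top <- h[which.max(h$score), ]
  expect_lte(abs(top$qstart - 4000), 10)
  expect_lte(abs(top$tstart - 9200), 10)
  # a 3.9 kb repeat is below the length floor regardless of identity
  short <- rnd_dna(3900)
  s2 <- paste0(rnd_dna(4000), short, short, rnd_dna(6000))
  h2 <- find_window_repeats(s2, window = nchar(s2) + 1)
  expect_equal(nrow(h2), 0)
})

test_that("database admission requires telomere flanking and a reference match", {
  set.seed(52)
  tm <- build_templates()
  ref <- yprime_reference(tm)
  elem <- as.character(ref[["ref_short"]])
  tel <- yprimescan:::telomere_tract(300)
  its <- yprimescan:::telomere_tract(80)
  rnd1 <- rnd_dna(3000); rnd2 <- rnd_dna(3000)
  decoy <- rnd_dna(nchar(elem)) # no reference homology
  contig <- paste0(rnd1, its, elem, rnd2, decoy, yprimescan:::revcomp(tel))
  # (revcomp of tract at the right end mimics the G-strand)
  genomes <- list(S = Biostrings::DNAStringSet(c(c1 = contig)))
  calls <- detect_telomeres(contig)
  tel_tab <- cbind(strain = "S", contig = "c1", calls)
  e_start <- nchar(rnd1) + nchar(its); e_end <- e_start + nchar(elem)
  d_start <- e_end + nchar(rnd2); d_end <- d_start + nchar(decoy)
  hits <- data.frame(strain = "S", contig = "c1",
                     qstart = c(e_start, d_start), qend = c(e_end, d_end),
                     tstart = c(e_start, d_start), tend = c(e_end, d_end))
  db <- build_high_confidence_db(hits, genomes, ref, tel_tab)
  # flanked + reference-matching copy admitted? the element copy is flanked
  # by an ITS on one side but plain sequence on the other -> excluded;
  # construct a properly double-flanked copy instead
  contig2 <- paste0(rnd1, its, elem, yprimescan:::revcomp(tel))
  genomes2 <- list(S = Biostrings::DNAStringSet(c(c1 = contig2)))
  calls2 <- detect_telomeres(contig2)
  tel_tab2 <- cbind(strain = "S", contig = "c1", calls2)
  hits2 <- data.frame(strain = "S", contig = "c1",
                      qstart = e_start, qend = e_end,
                      tstart = e_start, tend = e_end)
  db2 <- build_high_confidence_db(hits2, genomes2, ref, tel_tab2)
  expect_true(any(db2$entries$provenance == "window_repeat"))
  # the unflanked copy and the reference-less decoy were both rejected
  expect_false(any(db$entries$provenance == "window_repeat"))
  # reference entries always appended; empty reference is an input error
  expect_true(all(c("ref_long", "ref_short") %in% db$entries$id))
  expect_error(build_high_confidence_db(NULL, genomes, Biostrings::DNAStringSet(),
                                        tel_tab), "empty reference")
})

test_that("planted elements are recovered with accurate boundaries", {
  cfg <- pipeline_config()
  sim <- simulate_genome(simulation_spec(seed = 61, contigs_per_strain = 3L))
  r <- run_detection(sim, cfg)
  el <- r$det$elements[!r$det$elements$edge_truncated, ]
  m <- match_truth(el, sim$truth$elements)
  expect_equal(m$FN, 0)
  expect_equal(m$FP, 0)
  expect_lte(mean(m$errs), 25)
  # orientation matches planted truth
  tr <- sim$truth$elements
  for (i in seq_len(nrow(tr))) {
    e <- tr[i, ]
    cand <- el[el$contig == e$contig &
                 pmin(el$end, e$end) - pmax(el$start, e$start) > 0.9 * (e$end - e$start), ]
    expect_equal(cand$orientation[1], e$orientation)
  }
  # funnel is monotone
  f <- r$det$funnel
  expect_lte(f[["final"]], f[["length_filtered"]])
  expect_lte(f[["length_filtered"]], f[["merged"]])
})

test_that("tandem arrays yield exactly n elements", {
  for (n in 2:3) {
    w <- c(0, 0, 0, 0); w[n + 1] <- 1
    sim <- simulate_genome(simulation_spec(seed = 70 + n, contigs_per_strain = 1L,
                                           elements_per_end_weights = w,
                                           contig_length = 80000L))
    r <- run_detection(sim, pipeline_config())
    el <- r$det$elements[!r$det$elements$edge_truncated, ]
    m <- match_truth(el, sim$truth$elements)
    expect_equal(m$TP, nrow(sim$truth$elements))
    expect_equal(m$FP, 0)
  }
})

test_that("short fragments and edge-truncated copies are handled per the rules", {
  set.seed(55)
  tm <- build_templates()
  ref <- yprime_reference(tm)
  db <- build_high_confidence_db(NULL, NULL, ref, data.frame())
  # 900 bp fragment of a Y' -> below element_len_min, not emitted
  frag <- substr(as.character(ref[["ref_long"]]), 2001, 2900)
  contig <- paste0(rnd_dna(10000), frag, rnd_dna(10000))
  genomes <- list(S = Biostrings::DNAStringSet(c(c1 = contig)))
  det <- detect_elements(db, genomes, data.frame(strain = character(),
    contig = character(), start = integer(), end = integer()),
    pipeline_config())
  expect_equal(nrow(det$elements), 0)
  # element overlapping the contig end -> edge_truncated and excluded
  half <- substr(as.character(ref[["ref_long"]]), 1, 3500)
  contig2 <- paste0(rnd_dna(10000), half) # element runs into the contig end
  genomes2 <- list(S = Biostrings::DNAStringSet(c(c1 = contig2)))
  det2 <- detect_elements(db, genomes2, data.frame(strain = character(),
    contig = character(), start = integer(), end = integer()),
    pipeline_config())
  expect_equal(nrow(det2$elements), 1)
  expect_true(det2$elements$edge_truncated[1])
  expect_equal(det2$elements$end[1], nchar(contig2))
})
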