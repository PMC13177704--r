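test_that("template family satisfies the deletion relationships", {
  tm <- build_templates()
  len <- vapply(tm$backbones, nchar, numeric(1))
  expect_equal(unname(len["long"] - len["short"]), 465 + 600)
  expect_equal(unname(len["long"] - len["mid1"]), 465)
  expect_equal(unname(len["long"] - len["mid2"]), 600)
  expect_gte(length(tm$backbones), 6)
  # CA classes carry a distinct 1.6-1.8 kb distal domain
  expect_true((nchar(tm$backbones$ca_rich_a) - 2500) %in% 1600:1800)
  expect_true((nchar(tm$backbones$ca_rich_b) - 2500) %in% 1600:1800)
  # determinism
  expect_identical(tm$backbones, build_templates()$backbones)
  # only the planted ORFs are present in each backbone
  for (cls in names(tm$backbones)) {
    orfs <- find_orfs(tm$backbones[[cls]])
    spans <- tm$layout[[cls]]$orfs
    for (i in seq_len(nrow(orfs))) {
      o <- orfs[i, ]
      ok <- any(spans[, 1] == o$start & spans[, 2] == o$end) ||
        any(spans[, 1] <= o$start & o$end <= spans[, 2])
      expect_true(ok, label = paste("unexpected ORF in", cls))
    }
  }
})

test_that("planted truth is self-consistent and orientation-aware", {
  spec <- simulation_spec(seed = 13, contigs_per_strain = 3L)
  sim <- simulate_genome(spec)
  tr <- sim$truth$elements
  expect_gt(nrow(tr), 0)
  for (i in seq_len(nrow(tr))) {
    e <- tr[i, ]
    s <- substr(as.character(sim$genomes[[e$strain]][[e$contig]]),
                e$start + 1, e$end)
    if (e$orientation == "-") s <- yprimescan:::revcomp(s)
    expect_identical(s, e$seq)
  }
  # stretches sit inside their elements; ITSs are disjoint from elements
  st <- sim$truth$stretches
  for (i in seq_len(nrow(st))) {
    e <- tr[tr$element_id == st$element_id[i], ]
    expect_true(e$start <= st$start[i] && st$end[i] <= e$end)
  }
  its <- sim$truth$its
  for (i in seq_len(nrow(its))) {
    same <- tr[tr$contig == its$contig[i], ]
    ov <- pmin(same$end, its$end[i]) - pmax(same$start, its$start[i])
    expect_true(all(ov <= 0))
  }
})

test_that("fixed seed fixes all generator outputs", {
  spec <- simulation_spec(seed = 5, contigs_per_strain = 2L)
  s1 <- simulate_genome(spec); s2 <- simulate_genome(spec)
  expect_identical(lapply(s1$genomes, as.character),
                   lapply(s2$genomes, as.character))
  expect_identical(s1$truth, s2$truth)
})

test_that("planted element divergence matches the substitution rate", {
  # stretch-free elements isolate the backbone substitutions; edit distance
  # to the template then follows Binomial(L, rate)
  spec <- simulation_spec(seed = 21, contigs_per_strain = 2L,
                          substitution_rate = 0.005,
                          class_mix = c(long = 1),
                          elements_per_end_weights = c(0, 1, 0, 0),
                          stretch_weights = c(1, rep(0, 36)))
  sim <- simulate_genome(spec)
  tr <- sim$truth$elements
  e <- tr[1, ]
  d <- as.integer(Biostrings::stringDist(
    Biostrings::DNAStringSet(c(e$seq, sim$templates$backbones$long)),
    method = "levenshtein"))
  L <- nchar(e$seq)
  expected <- 0.005 * L
  tol <- 3 * sqrt(L * 0.005 * 0.995)
  expect_lt(abs(d - expected), tol + 1)
})

test_that("tandem ITSs lie strictly between their elements", {
  spec <- simulation_spec(seed = 31, contigs_per_strain = 4L,
                          elements_per_end_weights = c(0, 0, 1, 0),
                          its_tandem_prob = 1)
  sim <- simulate_genome(spec)
  its <- sim$truth$its
  tj <- its[its$context == "tandem_junction", ]
  expect_gt(nrow(tj), 0)
  tr <- sim$truth$elements
  for (i in seq_len(nrow(tj))) {
    el <- tr[tr$contig == tj$contig[i], ]
    expect_true(any(el$end <= tj$start[i]) && any(el$start >= tj$end[i]))
  }
})

test_that("empty planting yields telomere-only truth", {
  spec <- simulation_spec(seed = 3, contigs_per_strain = 2L,
                          elements_per_end_weights = c(1, 0, 0, 0),
                          x_element_prob = 0)
  sim <- simulate_genome(spec)
  expect_equal(nrow(sim$truth$elements), 0)
  expect_equal(nrow(sim$truth$its), 0)
  expect_equal(nrow(sim$truth$telomeres), 4)
})

test_that("telomeric tracts are C-dominated on the CA strand, CA regions are not", {
  set.seed(99)
  tel <- yprimescan:::telomere_tract(600)
  ch <- strsplit(tel, "")[[1]]
  expect_true(all(ch %in% c("C", "A")))
  expect_gt(mean(ch == "C"), 0.5)
  ca <- yprimescan:::make_ca_region(20)$seq
  cc <- strsplit(ca, "")[[1]]
  fa <- mean(cc == "A"); fc <- mean(cc == "C")
  expect_lt(fc / (fc + fa), 0.55)
  expect_gt(fa + fc, 0.8)
})

test_that("telomere-length table reproduces planted class effects", {
  spec <- simulation_spec(n_strains = 54, contigs_per_strain = 16,
                          effects = c(long = 0.064), seed = 11)
  trx <- simulate_end_classes(spec)
  tab <- simulate_telomere_table(spec, trx)
  norm <- tab$length_bp / tapply(tab$length_bp, tab$strain, mean)[tab$strain]
  cls <- trx$extremities$distal_class[match(paste(tab$strain, tab$extremity),
    paste(trx$extremities$strain, trx$extremities$extremity))]
  r <- mean(norm[!is.na(cls) & cls == "long"]) / mean(norm[is.na(cls)])
  expect_lt(abs(r - 0.936), 0.02)
  # null case: group means equal within sampling error
  spec0 <- simulation_spec(n_strains = 54, contigs_per_strain = 16, seed = 12)
  trx0 <- simulate_end_classes(spec0)
  tab0 <- simulate_telomere_table(spec0, trx0)
  norm0 <- tab0$length_bp / tapply(tab0$length_bp, tab0$strain, mean)[tab0$strain]
  cls0 <- trx0$extremities$distal_class[match(paste(tab0$strain, tab0$extremity),
    paste(trx0$extremities$strain, trx0$extremities$extremity))]
  r0 <- mean(norm0[!is.na(cls0) & cls0 == "long"]) / mean(norm0[is.na(cls0)])
  expect_lt(abs(r0 - 1), 0.02)
  # doubling the base scale leaves normalized ratios unchanged
  spec2 <- simulation_spec(n_strains = 54, contigs_per_strain = 16,
                           effects = c(long = 0.064),
                           telomere_table_mean = 700, telomere_table_sd = 70,
                           seed = 11)
  tab2 <- simulate_telomere_table(spec2, trx)
  norm2 <- tab2$length_bp / tapply(tab2$length_bp, tab2$strain, mean)[tab2$strain]
  r2 <- mean(norm2[!is.na(cls) & cls == "long"]) / mean(norm2[is.na(cls)])
  expect_lt(abs(r2 - r), 0.02)
})
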