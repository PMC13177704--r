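motif <- yprime_motif_36mer()

test_that("36-mer score track matches the matching-proportion definition", {
  set.seed(81)
  res <- yprimescan:::with_seed(1, yprimescan:::resolve_iupac(motif))
  bg <- rnd_dna(400)
  s <- paste0(substr(bg, 1, 200), res, substr(bg, 201, 400))
  tr <- score_36mer_track(s, motif)
  expect_equal(tr[201], 1.0)
  # two substitutions at non-degenerate positions -> 34/36
  ch <- strsplit(res, "")[[1]]
  fixed <- which(strsplit(motif, "")[[1]] %in% c("A", "C", "G", "T"))
  for (p in fixed[c(1, 5)]) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  s2 <- paste0(substr(bg, 1, 200), paste(ch, collapse = ""), substr(bg, 201, 400))
  tr2 <- score_36mer_track(s2, motif)
  expect_equal(tr2[201], 34 / 36)
  # db order invariance of the max
  other <- yprimescan:::with_seed(2, yprimescan:::resolve_iupac(motif))
  expect_equal(score_36mer_track(s, c(motif, other)),
               score_36mer_track(s, c(other, motif)))
})

test_that("random windows essentially never reach the peak threshold", {
  set.seed(82)
  s <- rnd_dna(5000)
  tr <- score_36mer_track(s, motif)
  expect_lt(max(tr), 0.85)
})

test_that("stretch calling recovers planted unit counts and intervals", {
  set.seed(83)
  for (n in c(1, 5, 10, 24, 36)) {
    st <- yprimescan:::make_stretch_36(n, motif, 0.1)
    s <- paste0(rnd_dna(800), st$seq, rnd_dna(800))
    tr <- score_36mer_track(s, motif)
    call <- call_36mer_stretch(tr, s, motif)
    expect_false(is.null(call))
    expect_equal(call$unit_count, n)
    expect_lte(abs(call$start - 800), 36)
    expect_lte(abs(call$end - (800 + n * 36)), 36)
  }
  # zero planted units -> no call
  expect_null(call_36mer_stretch(score_36mer_track(rnd_dna(2000), motif),
                                 rnd_dna(2000), motif))
})

test_that("peak spacing suppresses close secondary peaks", {
  sc <- rep(0, 100)
  sc[40] <- 0.95; sc[60] <- 0.90 # 20 positions apart, below min spacing 30
  pk <- yprimescan:::find_peaks(sc, 0.85, 30)
  expect_equal(pk, 40)
  sc[75] <- 0.92 # 35 from the first -> kept
  expect_equal(yprimescan:::find_peaks(sc, 0.85, 30), c(40, 75))
})

test_that("unit with a net indel is dropped from the unit list", {
  set.seed(84)
  res <- yprimescan:::resolve_iupac(motif)
  broken <- paste0(substr(res, 1, 17), substr(res, 19, 36)) # 1 bp deletion
  s <- paste0(rnd_dna(500), res, res, broken, res, rnd_dna(500))
  tr <- score_36mer_track(s, motif)
  call <- call_36mer_stretch(tr, s, motif)
  expect_false(is.null(call))
  expect_lt(length(call$units), call$n_peaks)
})

test_that("motif database refinement never shrinks recall", {
  set.seed(85)
  seqs <- vapply(1:20, function(i) {
    n <- sample(2:15, 1)
    paste0(rnd_dna(500), yprimescan:::make_stretch_36(n, motif, 0.1)$seq,
           rnd_dna(500))
  }, character(1))
  names(seqs) <- paste0("e", 1:20)
  refined <- refine_motif_db(seqs, motif)
  expect_true(motif %in% refined)
  expect_gt(length(refined), 1)
  for (s in seqs) {
    c1 <- call_36mer_stretch(score_36mer_track(s, motif), s, motif)
    c2 <- call_36mer_stretch(score_36mer_track(s, refined), s, refined)
    expect_gte(c2$unit_count, c1$unit_count)
  }
  # elements without stretches leave the db unchanged (with a warning)
  empty <- setNames(replicate(3, rnd_dna(400)), paste0("r", 1:3))
  expect_warning(out <- refine_motif_db(empty, motif), "no repeat units")
  expect_identical(out, motif)
})

test_that("CA-rich regions are detected and discriminated from telomeric tracts", {
  set.seed(86)
  ca <- yprimescan:::make_ca_region(45)$seq # ~1.6 kb
  s <- paste0(rnd_dna(1500), ca, rnd_dna(1500))
  hit <- detect_ca_region(s)
  expect_false(is.null(hit))
  expect_lte(abs(hit$start - 1500), 50)
  expect_lte(abs(hit$end - (1500 + nchar(ca))), 50)
  expect_lt(abs(hit$composition[["A"]] - 0.45), 0.06)
  expect_lt(abs(hit$composition[["C"]] - 0.43), 0.06)
  # a telomeric ITS tract is not called CA-rich
  tel <- yprimescan:::telomere_tract(400)
  s2 <- paste0(rnd_dna(1000), tel, rnd_dna(1000))
  expect_null(detect_ca_region(s2))
  # random sequence is not called
  for (i in 1:20) expect_null(detect_ca_region(rnd_dna(3000)))
})

test_that("pattern segmentation labels planted CA patterns", {
  pats <- ca_patterns()
  # exact P1 tiling -> all bases labelled P1
  region <- strrep(pats[["P1"]], 10)
  seg <- segment_ca_patterns(region)
  expect_equal(unname(seg$fractions[["P1"]]), 1)
  # mixed content recovers fractions within 10%
  set.seed(87)
  mix <- paste0(strrep(pats[["P1"]], 6), strrep(pats[["P2"]], 4))
  seg2 <- segment_ca_patterns(mix)
  true_p1 <- 6 * nchar(pats[["P1"]]) / nchar(mix)
  expect_lt(abs(seg2$fractions[["P1"]] - true_p1), 0.1)
  # random CA-composition sequence stays mostly unassigned
  rand_ca <- paste(sample(c("A", "C", "G", "T"), 800, TRUE,
                          prob = c(0.45, 0.42, 0.055, 0.075)), collapse = "")
  seg3 <- segment_ca_patterns(rand_ca)
  expect_gte(seg3$fractions[["unassigned"]], 0.8)
  expect_error(segment_ca_patterns(region, pattern_db = character(0)), "empty")
})

test_that("masking preserves length accounting and round-trips", {
  set.seed(88)
  s <- rnd_dna(5452)
  st <- list(stretch_class = "mer36", start = 2000L, end = 2360L)
  m <- mask_stretches(s, list(st))
  expect_equal(nchar(m$masked_sequence) + sum(m$removed$end - m$removed$start),
               nchar(s))
  expect_equal(nchar(m$masked_sequence), 5092)
  # no stretches -> identity
  m0 <- mask_stretches(s, list())
  expect_identical(m0$masked_sequence, s)
  # re-inserting the removed interval reproduces the original exactly
  rebuilt <- paste0(substr(m$masked_sequence, 1, st$start),
                    substr(s, st$start + 1, st$end),
                    substr(m$masked_sequence, st$start + 1,
                           nchar(m$masked_sequence)))
  expect_identical(rebuilt, s)
  # overlapping stretches are an input error
  expect_error(mask_stretches(s, list(st, list(stretch_class = "ca_rich",
                                               start = 2300L, end = 2600L))),
               "overlapping")
})

test_that("position frequency matrices are well-formed", {
  units <- rep("ACGTACGTAC", 10)
  pfm <- build_pfm(units)
  expect_equal(colSums(pfm), rep(1, 10), ignore_attr = TRUE)
  expect_true(all(pfm %in% c(0, 1)))
  expect_error(build_pfm(character(0)), "no units")
  expect_error(build_pfm(c("ACGT", "ACG")), "mixed")
  # empirical PFM approaches the generating distribution
  set.seed(89)
  draw <- vapply(1:400, function(i)
    paste(sample(c("A", "C", "G", "T"), 6, TRUE, prob = c(0.7, 0.1, 0.1, 0.1)),
          collapse = ""), character(1))
  pfm2 <- build_pfm(draw)
  expect_lt(max(abs(pfm2["A", ] - 0.7)), 3 * sqrt(0.7 * 0.3 / 400) + 0.01)
})
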