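sw_oracle <- function(q, t) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(q, t, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 4, gapExtension = 1)
  list(qstart = Biostrings::start(Biostrings::pattern(pa)) - 1L,
       qend = Biostrings::end(Biostrings::pattern(pa)),
       tstart = Biostrings::start(Biostrings::subject(pa)) - 1L,
       tend = Biostrings::end(Biostrings::subject(pa)),
       identity = 100 * Biostrings::nmatch(pa) / Biostrings::nchar(pa),
       score = Biostrings::score(pa))
}

test_that("local alignment agrees with the Smith-Waterman oracle", {
  set.seed(41)
  for (i in 1:40) {
    p <- make_planted_pair()
    h <- local_align(p$q, p$t)
    h <- h[which.max(h$score), ]
    o <- sw_oracle(p$q, p$t)
    expect_equal(nrow(h), 1)
    expect_lte(abs(h$qstart - o$qstart), 2)
    expect_lte(abs(h$qend - o$qend), 2)
    expect_lte(abs(h$tstart - o$tstart), 2)
    expect_lte(abs(h$tend - o$tend), 2)
    expect_lte(abs(h$identity - o$identity), 1)
  }
})

test_that("alignment is symmetric and identity is recounted correctly", {
  set.seed(42)
  p <- make_planted_pair(sub_rate = 0.05)
  h1 <- local_align(p$q, p$t); h1 <- h1[which.max(h1$score), ]
  h2 <- local_align(p$t, p$q); h2 <- h2[which.max(h2$score), ]
  expect_lte(abs(h1$qstart - h2$tstart), 2)
  expect_lte(abs(h1$tstart - h2$qstart), 2)
  expect_lte(abs(h1$identity - h2$identity), 1)
  # a 5%-substituted full-length copy aligns at ~95% identity
  core <- rnd_dna(2000)
  mut <- yprimescan:::mutate_seq(core, 0.05)
  h <- local_align(core, mut)
  h <- h[which.max(h$score), ]
  expect_lt(abs(h$identity - 95), 1.5)
})

test_that("unrelated sequences yield no long high-identity hit", {
  set.seed(43)
  for (i in 1:25) {
    h <- local_align(rnd_dna(5000), rnd_dna(5000), min_identity = 90)
    expect_false(any(h$length >= 4000))
  }
})

test_that("self-alignment excludes the trivial diagonal", {
  set.seed(44)
  s <- rnd_dna(5000)
  h <- local_align(s, s, self = TRUE)
  if (nrow(h) > 0) {
    recip <- yprimescan:::reciprocal_overlap(h$qstart, h$qend, h$tstart, h$tend)
    expect_true(all(recip <= 0.5))
  }
  # a genuine tandem duplication is still found off-diagonal
  dup <- paste0(rnd_dna(500), s, s, rnd_dna(500))
  h2 <- local_align(dup, dup, self = TRUE)
  expect_true(any(h2$length >= 4900 & h2$identity >= 99))
})

test_that("spliced mapping tolerates bounded stretch-length gaps", {
  set.seed(45)
  tm <- build_templates()
  lay <- tm$layout$long
  bare <- tm$backbones$long
  st <- yprimescan:::make_stretch_36(20, tm$motif, 0.1)$seq # 720 bp insertion
  with_st <- paste0(substr(bare, 1, lay$slot), st,
                    substr(bare, lay$slot + 1, nchar(bare)))
  target <- paste0(rnd_dna(2000), with_st, rnd_dna(2000))
  h <- map_spliced(bare, target)
  expect_equal(nrow(h), 1)
  expect_lte(abs(h$tstart - 2000), 5)
  expect_lte(abs(h$tend - (2000 + nchar(with_st))), 5)
  gaps <- diff(h$blocks[[1]][, 3]) # target-side gaps between blocks
  expect_true(any(h$blocks[[1]][-1, 3] - h$blocks[[1]][-nrow(h$blocks[[1]]), 4]
                  >= 700))
  # a gap beyond the bound splits the hit in two
  far <- paste0(rnd_dna(1000), substr(bare, 1, 2500), rnd_dna(1200),
                substr(bare, 2501, nchar(bare)), rnd_dna(1000))
  h2 <- map_spliced(bare, far, max_intra_element_gap = 1000)
  expect_gte(nrow(h2), 2)
  # exact substring maps as a single gap-free block
  sub <- substr(bare, 1001, 3500)
  h3 <- map_spliced(sub, bare)
  expect_equal(nrow(h3), 1)
  expect_equal(nrow(h3$blocks[[1]]), 1)
  expect_equal(h3$tstart, 1000)
  expect_equal(h3$tend, 3500)
})

test_that("block trimming follows the length and gap rules", {
  mkhit <- function(blocks) {
    df <- data.frame(qstart = blocks[1, 1], qend = blocks[nrow(blocks), 2],
                     tstart = blocks[1, 3], tend = blocks[nrow(blocks), 4],
                     strand = "+", length = 0L, matches = 0L, identity = 0,
                     score = 0L)
    df$blocks <- list(blocks)
    df
  }
  b_main <- c(200L, 1200L, 200L, 1200L, 990L)
  # extremal 15 bp block, 150 bp gap -> trimmed
  b <- rbind(c(0L, 15L, 0L, 15L, 15L), b_main)
  h <- trim_hit_blocks(mkhit(b))
  expect_equal(h$qstart, 200)
  # 25 bp block, 150 bp gap -> kept
  b2 <- rbind(c(0L, 25L, 0L, 25L, 25L), b_main)
  expect_equal(trim_hit_blocks(mkhit(b2))$qstart, 0)
  # 15 bp block, 50 bp gap -> kept
  b3 <- rbind(c(150L, 165L, 150L, 165L, 15L), b_main)
  expect_equal(trim_hit_blocks(mkhit(b3))$qstart, 150)
  # two short blocks with a big mutual gap: one side trimmed, a single
  # residual block remains (the last block has no gap and cannot trim)
  b4 <- rbind(c(0L, 10L, 0L, 10L, 10L), c(500L, 510L, 500L, 510L, 10L))
  h4 <- trim_hit_blocks(mkhit(b4))
  expect_equal(nrow(h4$blocks[[1]]), 1)
  expect_equal(h4$length, 10)
})

test_that("MSA contract holds for both backends", {
  for (be in c("internal", if (nzchar(Sys.which("mafft"))) "mafft")) {
    m <- build_msa(c(a = "ACGT", b = "AGT"), backend = be)
    expect_equal(m$ncol, 4)
    expect_equal(sum(strsplit(m$rows[2], "")[[1]] == "-"), 1)
    expect_identical(gsub("-", "", m$rows), c("ACGT", "AGT"))
    ident <- build_msa(c("ACGTACGTGG", "ACGTACGTGG"), backend = be)
    expect_false(any(grepl("-", ident$rows, fixed = TRUE)))
  }
  expect_error(build_msa("ACGT"), "at least two")
  expect_error(build_msa(c("ACGT", "")), "empty")
})

test_that("MSA round-trips and bounds hold on random inputs", {
  set.seed(46)
  for (i in 1:25) {
    n <- sample(2:5, 1)
    seqs <- vapply(seq_len(n), function(j) rnd_dna(sample(30:120, 1)),
                   character(1))
    m <- build_msa(seqs, backend = "internal")
    expect_identical(gsub("-", "", m$rows), unname(seqs))
    expect_gte(m$ncol, max(nchar(seqs)))
    expect_lte(m$ncol, sum(nchar(seqs)))
  }
})

test_that("pairwise MSA of a small pair matches an exhaustive DP oracle", {
  # {ACGT, AGT}: global affine optimum is unique (3 matches, one gap)
  m <- build_msa(c("ACGT", "AGT"), backend = "internal")
  expect_identical(m$rows, c("ACGT", "A-GT"))
})
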