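mk_msa <- function(rows, ids = NULL) {
  structure(list(ids = ids %||% paste0("s", seq_along(rows)), rows = rows,
                 ncol = nchar(rows[1])), class = "yp_msa")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("similarity from MSA follows the shared-gap rule", {
  m <- mk_msa(c("ACGT", "ACGT"))
  expect_equal(similarity_from_msa(m)[1, 2], 100)
  m2 <- mk_msa(c("ACGT", "ACGA"))
  expect_equal(similarity_from_msa(m2)[1, 2], 75)
  # rows 1,2 share a gap column and match on the other 9 columns
  m3 <- mk_msa(c("ACGTACGTA-", "ACGTACGTA-", "ACGTACGTAT"))
  s3 <- similarity_from_msa(m3)
  expect_equal(s3[1, 2], 100)
  expect_equal(s3[1, 3], 90)
  # one-sided gaps count as differences
  m4 <- mk_msa(c("AC-T", "ACGT"))
  expect_equal(similarity_from_msa(m4)[1, 2], 75)
  expect_error(similarity_from_msa(mk_msa("ACGT")), "at least two")
})

test_that("similarity matches the brute-force column count oracle exactly", {
  set.seed(91)
  for (rep in 1:10) {
    n <- sample(3:10, 1); L <- sample(50:200, 1)
    rows <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T", "-"), L, TRUE,
                   prob = c(0.22, 0.22, 0.22, 0.22, 0.12)), collapse = ""),
      character(1))
    m <- mk_msa(rows)
    sim <- similarity_from_msa(m)
    expect_true(isSymmetric(sim))
    expect_equal(unname(diag(sim)), rep(100, n))
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      expect_identical(sim[i, j], bf_similarity_pair(rows[i], rows[j]))
  }
})

test_that("mean silhouette agrees with a brute-force oracle", {
  set.seed(92)
  n <- 20
  d <- as.matrix(dist(matrix(rnorm(n * 3), n)))
  for (k in 2:5) {
    lab <- cutree(hclust(as.dist(d), "average"), k = k)
    expect_equal(yprimescan:::mean_silhouette(lab, d),
                 bf_mean_silhouette(lab, d))
  }
})

test_that("silhouette-optimised clustering recovers planted structure", {
  # two tight groups at 50% between-group similarity -> k = 2
  sim <- matrix(50, 8, 8)
  sim[1:4, 1:4] <- 98; sim[5:8, 5:8] <- 98; diag(sim) <- 100
  dimnames(sim) <- list(paste0("e", 1:8), paste0("e", 1:8))
  sol <- cluster_elements(sim, 2, 7)
  expect_equal(sol$k, 2)
  expect_equal(length(unique(sol$labels[1:4])), 1)
  # all elements identical -> degenerate-input error
  ident <- matrix(100, 5, 5, dimnames = list(paste0("e", 1:5), paste0("e", 1:5)))
  expect_error(cluster_elements(ident), "degenerate")
  expect_error(cluster_elements(sim[1:2, 1:2]), "at least three")
})

test_that("clustering is invariant under element permutation", {
  set.seed(93)
  tm <- build_templates()
  seqs <- gen_template_elements(tm, rep(c("long", "short", "mid1"), each = 5))
  prof <- profile_repeats(seqs, refine = FALSE)
  masked <- vapply(prof$masked, `[[`, character(1), "masked_sequence")
  msa <- build_msa(masked, backend = "internal")
  sol <- cluster_elements(similarity_from_msa(msa))
  perm <- sample(names(masked))
  msa2 <- build_msa(masked[perm], backend = "internal")
  sol2 <- cluster_elements(similarity_from_msa(msa2))
  expect_equal(sol2$k, sol$k)
  expect_equal(mclust::adjustedRandIndex(
    as.integer(factor(sol$labels[names(masked)])),
    as.integer(factor(sol2$labels[names(masked)]))), 1)
})

test_that("CA reclustering replaces only the CA subset labels", {
  set.seed(94)
  tm <- build_templates()
  classes <- c(rep("long", 6), rep("ca_rich_a", 4), rep("ca_rich_b", 4))
  seqs <- gen_template_elements(tm, classes, sub_rate = 0.005)
  prof <- profile_repeats(seqs, refine = FALSE)
  masked <- vapply(prof$masked, `[[`, character(1), "masked_sequence")
  msa <- build_msa(masked)
  sol <- cluster_elements(similarity_from_msa(msa))
  labels <- setNames(as.character(sol$labels), names(sol$labels))
  ca_ids <- names(prof$ca_masked)
  expect_gte(length(ca_ids), 6)
  ca_seqs <- vapply(prof$ca_masked, `[[`, character(1), "masked_sequence")
  rc <- recluster_ca_elements(labels, ca_seqs)
  non_ca <- setdiff(names(labels), ca_ids)
  expect_identical(rc$labels[non_ca], labels[non_ca])
  expect_true(all(grepl("^CA", rc$labels[ca_ids])))
  # the two CA subtypes separate after CA-region removal
  sub_a <- rc$labels[names(seqs)[classes == "ca_rich_a"]]
  sub_b <- rc$labels[names(seqs)[classes == "ca_rich_b"]]
  expect_equal(length(unique(sub_a)), 1)
  expect_equal(length(unique(sub_b)), 1)
  expect_false(unique(sub_a) == unique(sub_b))
  # fewer than 3 CA elements -> warning, labels unchanged
  expect_warning(rc2 <- recluster_ca_elements(labels, ca_seqs[1:2]),
                 "fewer than 3")
  expect_identical(rc2$labels, labels)
  # zero CA elements -> silent no-op
  rc3 <- recluster_ca_elements(labels, character(0))
  expect_identical(rc3$labels, labels)
})

test_that("cluster retention filters match the stated rules", {
  labels <- setNames(c(rep("1", 8), rep("2", 4), rep("3", 8)),
                     paste0("e", 1:20))
  elements <- data.frame(element_id = paste0("e", 1:20),
                         strain = c(rep(c("s1", "s2"), 4), rep("s1", 4),
                                    rep("s3", 8)))
  sim <- matrix(95, 20, 20, dimnames = list(names(labels), names(labels)))
  diag(sim) <- 100
  sm <- summarize_and_filter(labels, elements, sim)
  expect_false(sm$retained[sm$cluster == "2"]) # fewer than five elements
  expect_false(sm$retained[sm$cluster == "3"]) # single strain
  expect_true(sm$retained[sm$cluster == "1"])
  # high heterogeneity blocks retention
  sim2 <- sim; sim2[1:8, 1:8] <- 80; diag(sim2) <- 100
  sm2 <- summarize_and_filter(labels, elements, sim2)
  expect_false(sm2$retained[sm2$cluster == "1"])
})

test_that("consensus construction is majority-rule with gap-column dropping", {
  set.seed(95)
  template <- rnd_dna(2000)
  # identical copies reproduce the template exactly
  cons0 <- build_consensus(setNames(rep(template, 10), paste0("c", 1:10)))
  expect_identical(cons0$consensus, template)
  expect_true(all(cons0$coverage == 1))
  # 1% substitution copies stay within 0.2% Hamming distance
  copies <- vapply(1:10, function(i) yprimescan:::mutate_seq(template, 0.01),
                   character(1))
  cons <- build_consensus(setNames(copies, paste0("c", 1:10)))
  expect_equal(nchar(cons$consensus), nchar(template))
  mism <- sum(strsplit(cons$consensus, "")[[1]] != strsplit(template, "")[[1]])
  expect_lte(mism / nchar(template), 0.002)
  # a deletion shared by the majority drops those columns
  del <- paste0(substr(template, 1, 1000), substr(template, 1466, 2000))
  cons2 <- build_consensus(setNames(c(rep(del, 7), rep(template, 3)),
                                    paste0("c", 1:10)))
  expect_lt(abs(nchar(cons2$consensus) - nchar(del)), 10)
  expect_warning(c1 <- build_consensus(c(x = template)), "single member")
  expect_identical(c1$consensus, template)
})
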