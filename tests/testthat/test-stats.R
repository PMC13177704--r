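test_that("distribution tables conserve counts and keep zero rows", {
  el <- data.frame(element_id = paste0("e", 1:6),
                   strain = c("s1", "s1", "s1", "s1", "s2", "s2"),
                   contig = c("c1", "c1", "c1", "c2", "c1", "c1"),
                   side = c("L", "L", "R", "R", "L", "L"))
  tabs <- tabulate_distribution(el, strains = c("s1", "s2", "s3"))
  expect_equal(sum(tabs$per_strain$n), nrow(el))
  expect_equal(tabs$per_strain$n[tabs$per_strain$strain == "s3"], 0)
  expect_equal(sum(tabs$per_extremity$n), nrow(el))
  # s1 c1.L and s2 c1.L each carry a two-element tandem; two single ends
  expect_equal(unname(tabs$tandem_histogram[["2"]]), 2)
  expect_equal(unname(tabs$tandem_histogram[["1"]]), 2)
})

test_that("ITS classification assigns junction, proximal and unassigned", {
  el <- data.frame(element_id = c("a", "b", "c"), strain = "s1",
                   contig = c("c1", "c1", "c2"),
                   start = c(40000L, 46000L, 40000L),
                   end = c(45900L, 52000L, 46000L), side = "R")
  calls <- data.frame(strain = "s1",
                      contig = c("c1", "c2", "c2"),
                      start = c(45900L, 39900L, 20000L),
                      end = c(46000L, 39980L, 20060L),
                      kind = "interstitial")
  its <- classify_its(calls, el)
  expect_equal(its$context[1], "tandem_junction")
  expect_equal(its$context[2], "centromere_proximal")
  expect_equal(its$distance_to_element[2], 20)
  expect_equal(its$context[3], "unassigned")
})

test_that("ITS classification recovers simulator truth", {
  ok <- 0; tot <- 0
  for (seed in 121:125) {
    sim <- simulate_genome(simulation_spec(seed = seed, contigs_per_strain = 3L))
    r <- run_detection(sim, pipeline_config())
    el <- r$det$elements[!r$det$elements$edge_truncated, ]
    its <- classify_its(r$tel, el)
    truth <- sim$truth$its
    for (i in seq_len(nrow(truth))) {
      tot <- tot + 1
      m <- its[its$contig == truth$contig[i] &
                 pmin(its$end, truth$end[i]) - pmax(its$start, truth$start[i]) > 0, ]
      if (nrow(m) == 1 && m$context == truth$context[i]) ok <- ok + 1
    }
  }
  expect_equal(ok, tot)
})

test_that("within-strain diversity is lower when strains are homogenised", {
  set.seed(131)
  tm <- build_templates()
  anchor <- substr(tm$backbones$long, 4200, 6256) # distal conserved region
  seqs <- c(); strains <- c()
  for (s in 1:4) {
    strain_bb <- yprimescan:::mutate_seq(tm$backbones$long, 0.02)
    for (i in 1:3) {
      id <- sprintf("s%d_e%d", s, i)
      seqs[id] <- yprimescan:::mutate_seq(strain_bb, 0.003)
      strains[id] <- paste0("s", s)
    }
  }
  d <- diversity_within_between(seqs, strains, anchor, backend = "internal")
  expect_lt(d$median_within, d$median_between)
  # degenerate case: identical elements -> all-zero distributions
  same <- setNames(rep(tm$backbones$short, 4), paste0("x", 1:4))
  st2 <- setNames(c("a", "a", "b", "b"), names(same))
  d2 <- diversity_within_between(same, st2, substr(tm$backbones$short, 3200, 5191),
                                 backend = "internal")
  expect_true(all(c(d2$within, d2$between) == 0))
  # single strain -> empty between set with a warning
  st3 <- setNames(rep("a", 4), names(same))
  expect_warning(d3 <- diversity_within_between(same, st3,
    substr(tm$backbones$short, 3200, 5191), backend = "internal"),
    "single strain")
  expect_length(d3$between, 0)
})

test_that("telomere association recovers a planted class effect", {
  spec <- simulation_spec(n_strains = 54, contigs_per_strain = 16,
                          effects = c(long = 0.064), seed = 141)
  trx <- simulate_end_classes(spec)
  tab <- simulate_telomere_table(spec, trx)
  res <- telomere_association(tab, trx$extremities)
  row <- res[res$comparison == "long_vs_none", ]
  expect_lt(row$p_value, 0.05)
  expect_lt(abs(row$effect - 0.064), 0.02)
  # pooled-variance (classic Student) mode also runs
  res2 <- telomere_association(tab, trx$extremities, var_equal = TRUE)
  expect_lt(res2$p_value[res2$comparison == "long_vs_none"], 0.05)
  # normalisation: strain means of normalised lengths are 1
  norm <- tab$length_bp / tapply(tab$length_bp, tab$strain, mean)[tab$strain]
  expect_equal(as.numeric(tapply(norm, tab$strain, mean)), rep(1, 54),
               tolerance = 1e-12)
})

test_that("copy-number correlation is recovered by the Spearman pathway", {
  spec <- simulation_spec(n_strains = 54, contigs_per_strain = 16,
                          copy_effects = c(ca_rich_a = 0.02), seed = 142)
  trx <- simulate_end_classes(spec)
  tab <- simulate_telomere_table(spec, trx)
  cc <- as.data.frame(table(strain = trx$elements$strain,
                            class = trx$elements$class),
                      stringsAsFactors = FALSE)
  names(cc)[3] <- "n"
  res <- telomere_association(tab, trx$extremities, copy_counts = cc)
  row <- res[res$comparison == "ca_rich_a_copies_vs_strain_mean", ]
  expect_gt(row$effect, 0)       # rho positive
  expect_lt(row$p_value, 0.05)
})

test_that("the chi-square pathway matches closed forms", {
  r1 <- contingency_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p_value, 1)
  r2 <- contingency_test(matrix(c(20, 0, 0, 20), 2))
  expect_equal(r2$statistic, 40)
  expect_lt(r2$p_value, 1e-9)
  expect_error(contingency_test(matrix(c(1, 2), 1)), "2x2")
  expect_error(contingency_test(matrix(0, 2, 2)), "all-zero")
  expect_warning(contingency_test(matrix(c(2, 3, 4, 1), 2)), "expected count")
})
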