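test_that("fisher_exact_2x2 matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(0, 100, 0, 100, "greater"), 1.0)
  expect_equal(fisher_exact_2x2(0, 100, 0, 100, "two_sided"), 1.0)

  expect_equal(fisher_exact_2x2(5, 15, 0, 20, "greater"),
               enum_fisher(5, 15, 0, 20, "greater"), tolerance = 1e-14)
  # row-swapped table: the greater-tail is computed on the swapped a-cell
  expect_equal(fisher_exact_2x2(0, 20, 5, 15, "greater"),
               enum_fisher(0, 20, 5, 15, "greater"), tolerance = 1e-14)

  withr::with_seed(9, {
    for (i in 1:50) {
      m <- sample(0:40, 4, replace = TRUE)
      expect_equal(fisher_exact_2x2(m[1], m[2], m[3], m[4], "greater"),
                   enum_fisher(m[1], m[2], m[3], m[4], "greater"),
                   tolerance = 1e-12)
      expect_equal(fisher_exact_2x2(m[1], m[2], m[3], m[4], "two_sided"),
                   enum_fisher(m[1], m[2], m[3], m[4], "two_sided"),
                   tolerance = 1e-12)
    }
  })
  # and agrees with the reference implementation for the two-sided case
  tab <- matrix(c(12, 88, 3, 97), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(tab, alternative = "two_sided"),
               stats::fisher.test(tab)$p.value, tolerance = 1e-12)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "negative")
})

test_that("community calling applies ratio, fold and Fisher gates", {
  mk_pair <- function(td, tx, ud, ux) {
    data.frame(contig = "g1", pos = 10L, strand = "+", gene_id = "g1_tx",
               transcript_base = "U", homopolymer_run = 1L,
               treated_depth = td, treated_del = tx, untreated_depth = ud,
               untreated_del = ux, sample_id = "s", genome_id = "g1",
               stringsAsFactors = FALSE)
  }
  # 5% vs 1% at depth 500: passes ratio and fold; Fisher decides
  p_fisher <- enum_fisher(25, 475, 5, 495, "greater")
  calls <- call_sites_community(mk_pair(500L, 25L, 500L, 5L))
  expect_equal(nrow(calls), as.integer(p_fisher < 0.01))
  if (nrow(calls) == 1) {
    expect_equal(calls$fisher_p, p_fisher, tolerance = 1e-12)
    expect_equal(calls$delta_ratio, 0.05 - 0.01)
  }
  # deletion count below 5
  expect_equal(nrow(call_sites_community(mk_pair(100L, 3L, 100L, 0L))), 0)
  # fold 1.5 below 2
  expect_equal(nrow(call_sites_community(mk_pair(1000L, 30L, 1000L, 20L))), 0)
  # untreated ratio 0 passes the fold rule as written
  strong <- call_sites_community(mk_pair(200L, 20L, 200L, 0L))
  expect_equal(nrow(strong), 1)
  expect_equal(strong$delta_ratio, 0.1)
})

test_that("isolate calls cover community calls on isolate-grade data", {
  sim <- simulate_isolate(n_genes = 10, gene_length = 200, n_sites = 40,
                          stoichiometry = c(0.15, 0.8), depth_mean = 150,
                          seed = 21)
  s <- sim$samples$sample01
  pairs <- pair_sites(s$treated, s$untreated, sim$uridine_sites, sim$genome)
  iso <- call_sites(pairs)
  com <- call_sites_community(pairs)
  com_strong <- com[com$ratio_treated >= 0.05 & com$ratio_untreated < 0.01 &
                      com$treated_depth >= 100, ]
  expect_true(all(paste(com_strong$contig, com_strong$pos) %in%
                    paste(iso$contig, iso$pos)))
})

test_that("genome gating uses strict > in both conditions", {
  cov <- data.frame(genome_id = c("a", "b", "c"),
                    mean_depth_treated = c(25, 25, 20),
                    mean_depth_untreated = c(30, 15, 25),
                    stringsAsFactors = FALSE)
  expect_equal(gate_genomes(cov), "a")
})

test_that("genome summaries normalize sites per covered Kb", {
  mk <- function(depth) {
    data.frame(contig = "g", pos = 1:100, depth = depth,
               stringsAsFactors = FALSE)
  }
  calls <- data.frame(pos = 1:4)
  s <- summarize_genome(calls, mk(rep(c(30L, 10L), each = 50)),
                        mk(rep(30L, 100)), gc_content = 0.5,
                        genome_id = "g")
  expect_equal(s$covered_bases, 50)
  expect_equal(s$sites_per_kb, 4 / (50 / 1000))
  # worked example: 40 sites over 2 Mb covered = 0.02 sites/Kb
  expect_equal(40 / (2e6 / 1000), 0.02)
  # zero sites give rate zero; doubling both leaves the rate unchanged
  s0 <- summarize_genome(calls[0, , drop = FALSE], mk(30L), mk(30L), 0.5, "g")
  expect_equal(s0$sites_per_kb, 0)
  expect_equal(s$n_sites / (s$covered_bases / 1000),
               (2 * s$n_sites) / (2 * s$covered_bases / 1000))
  expect_error(summarize_genome(calls, mk(5L), mk(5L), 0.5, "g"),
               "undefined")
})

test_that("GC-group comparison detects a site-density difference", {
  withr::with_seed(31, {
    lo <- data.frame(genome_id = paste0("lo", 1:50), gc_content = 0.35,
                     sites_per_kb = rpois(50, 5) / 10)
    hi <- data.frame(genome_id = paste0("hi", 1:50), gc_content = 0.65,
                     sites_per_kb = rpois(50, 15) / 10)
  })
  cmp <- compare_gc_groups(rbind(lo, hi))
  expect_equal(cmp$n_low, 50)
  expect_lt(cmp$p_value, 0.01)
  expect_gt(cmp$median_high, cmp$median_low)

  same <- rbind(lo, transform(lo, genome_id = paste0("x", 1:50),
                              gc_content = 0.6))
  expect_gt(compare_gc_groups(same)$p_value, 0.9)
  expect_error(compare_gc_groups(lo), "grouping error")
})

test_that("strict 16S rule needs delta > 0.1 and multi-genome/sample support", {
  mk <- function(pos, delta, genome, sample) {
    data.frame(pos = pos, delta_ratio = delta, genome_id = genome,
               sample_id = sample, stringsAsFactors = FALSE)
  }
  calls <- rbind(
    mk(512L, 0.12, c("gA", "gB", "gC"), "s1"),             # 3 genomes: keep
    mk(700L, 0.09, c("gA", "gB", "gC"), "s1"),             # delta too low
    mk(900L, 0.15, c("gA", "gA", "gB"), c("s1", "s2", "s3"))  # 3 samples
  )
  kept <- strict_16s_filter(calls)
  expect_setequal(unique(kept$pos), c(512L, 900L))
  expect_equal(unique(kept$n_genomes[kept$pos == 900L]), 2L)
  # two genomes, two samples: dropped
  weak <- mk(950L, 0.2, c("gA", "gB"), c("s1", "s2"))
  expect_equal(nrow(strict_16s_filter(weak)), 0)
})
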