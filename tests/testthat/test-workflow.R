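test_that("configurations round-trip through YAML", {
  cfg <- psiscan_config(
    mode = "isolate",
    samples = list(list(sample_id = "s1", treated = "t.tsv",
                        untreated = "u.tsv")),
    fasta = "g.fa", gff = "genes.gff3", out_dir = "out", seed = 7L
  )
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, f)
  cfg2 <- read_config(f)
  expect_equal(unclass(cfg2), unclass(cfg))
  expect_s3_class(cfg2, "psiscan_config")
})

test_that("the isolate workflow runs end to end and is deterministic", {
  sim <- simulate_isolate(n_genes = 6, gene_length = 150, n_sites = 20,
                          seed = 12)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  out1 <- file.path(dir, "run1")
  out2 <- file.path(dir, "run2")
  samples <- lapply(names(sim$samples), function(sid) {
    list(sample_id = sid,
         treated = file.path(dir, paste0(sid, "_treated.tsv")),
         untreated = file.path(dir, paste0(sid, "_untreated.tsv")))
  })
  cfg <- psiscan_config("isolate", samples, file.path(dir, "genome.fa"),
                        file.path(dir, "genes.gff3"), out1)
  res <- run_isolate(cfg)
  expect_true(file.exists(file.path(out1, "high_confidence.tsv")))
  expect_true(file.exists(file.path(out1, "sample01_calls.bed")))
  expect_gt(nrow(res$high_confidence), 0)
  # calls recover simulated sites with no spurious positions
  hc_key <- paste(res$high_confidence$contig, res$high_confidence$pos)
  expect_true(all(hc_key %in% paste(sim$truth$contig, sim$truth$pos)))
  # strength table covers every annotated gene
  expect_setequal(unique(res$strength$gene_id), sim$annotation$gene_id)

  cfg2 <- cfg
  cfg2$out_dir <- out2
  run_isolate(cfg2)
  for (f in c("high_confidence.tsv", "qc_base_enrichment.tsv",
              "psi_strength.tsv", "sample01_calls.bed")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("empty pileups produce valid empty outputs", {
  sim <- simulate_isolate(n_genes = 2, gene_length = 60, n_sites = 2,
                          seed = 13)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  empty <- file.path(dir, "empty.tsv")
  writeLines("contig\tpos\tref\tdepth\tdel", empty)
  cfg <- psiscan_config(
    "isolate",
    list(list(sample_id = "s1", treated = empty,
              untreated = file.path(dir, "sample01_untreated.tsv"))),
    file.path(dir, "genome.fa"), file.path(dir, "genes.gff3"),
    file.path(dir, "out")
  )
  res <- run_isolate(cfg)
  expect_equal(nrow(res$calls$s1), 0)
  expect_equal(nrow(res$high_confidence), 0)
  expect_equal(nrow(read_calls(file.path(dir, "out", "s1_calls.bed"))), 0)
})

test_that("the community workflow gates genomes before calling", {
  g <- data.frame(genome_id = c("gA", "gB", "gC"),
                  length = c(8000, 8000, 8000),
                  gc_content = c(0.35, 0.62, 0.5),
                  abundance = c(0.55, 0.40, 0.05),
                  stringsAsFactors = FALSE)
  sim <- simulate_community(g, total_depth = 300, eta = 0.01,
                            sites_per_kb = 1, seed = 14)
  dir <- withr::local_tempdir()
  Biostrings::writeXStringSet(sim$genome_seqs, file.path(dir, "genomes.fa"))
  gff <- sprintf("%s\tsim\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                 sim$annotation$contig, sim$annotation$start,
                 sim$annotation$end, sim$annotation$gene_id)
  writeLines(c("##gff-version 3", gff), file.path(dir, "genes.gff3"))
  s <- sim$samples$subject01
  write_pileup(s$treated, file.path(dir, "t.tsv"))
  write_pileup(s$untreated, file.path(dir, "u.tsv"))
  utils::write.table(g[, c("genome_id", "gc_content")],
                     file.path(dir, "catalog.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- psiscan_config(
    "community",
    list(list(sample_id = "subject01", treated = file.path(dir, "t.tsv"),
              untreated = file.path(dir, "u.tsv"))),
    file.path(dir, "genomes.fa"), file.path(dir, "genes.gff3"),
    file.path(dir, "out"), genome_catalog = file.path(dir, "catalog.tsv")
  )
  res <- suppressMessages(run_community(cfg))
  # gC sits at ~15x mean depth and must be gated out
  expect_setequal(res$gated_genomes, c("gA", "gB"))
  expect_false("gC" %in% res$calls$genome_id)
  expect_setequal(res$summaries$genome_id, c("gA", "gB"))
  expect_true(file.exists(file.path(dir, "out", "community_calls.tsv")))
  # called positions are true simulated sites
  expect_true(all(paste(res$calls$contig, res$calls$pos) %in%
                    paste(sim$truth$contig, sim$truth$pos)))
})

test_that("a community where nothing passes the gate yields empty outputs", {
  g <- data.frame(genome_id = c("gA", "gB"), length = c(3000, 3000),
                  gc_content = c(0.4, 0.6), abundance = c(0.5, 0.5),
                  stringsAsFactors = FALSE)
  sim <- simulate_community(g, total_depth = 20, seed = 15)
  dir <- withr::local_tempdir()
  Biostrings::writeXStringSet(sim$genome_seqs, file.path(dir, "genomes.fa"))
  gff <- sprintf("%s\tsim\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                 sim$annotation$contig, sim$annotation$start,
                 sim$annotation$end, sim$annotation$gene_id)
  writeLines(c("##gff-version 3", gff), file.path(dir, "genes.gff3"))
  s <- sim$samples$subject01
  write_pileup(s$treated, file.path(dir, "t.tsv"))
  write_pileup(s$untreated, file.path(dir, "u.tsv"))
  utils::write.table(g[, c("genome_id", "gc_content")],
                     file.path(dir, "catalog.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- psiscan_config(
    "community",
    list(list(sample_id = "s1", treated = file.path(dir, "t.tsv"),
              untreated = file.path(dir, "u.tsv"))),
    file.path(dir, "genomes.fa"), file.path(dir, "genes.gff3"),
    file.path(dir, "out"), genome_catalog = file.path(dir, "catalog.tsv")
  )
  expect_message(res <- run_community(cfg), "0 genome")
  expect_length(res$gated_genomes, 0)
  expect_equal(nrow(res$calls), 0)
})
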