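test_that("read_pileup maps fields, sorts, and validates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig\tpos\tref\tdepth\tdel",
               "chr2\t5\tA\t30\t1",
               "chr1\t100\tT\t50\t3"), f)
  p <- read_pileup(f, "s1", "treated")
  expect_equal(nrow(p), 2)
  expect_equal(p$contig, c("chr1", "chr2"))  # sorted by (contig, pos)
  expect_equal(p$pos[1], 100L)
  expect_equal(p$ref_base[1], "T")
  expect_equal(p$depth[1], 50L)
  expect_equal(p$del_count[1], 3L)
  expect_equal(unique(p$condition), "treated")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("contig\tpos\tref\tdepth\tdel", empty)
  expect_equal(nrow(read_pileup(empty, "s1", "treated")), 0)
})

test_that("read_pileup rejects bad input with informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig\tpos\tref\tdepth", "chr1\t1\tT\t10"), f)
  expect_error(read_pileup(f, "s", "treated"), "del")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig\tpos\tref\tdepth\tdel", "chr1\t100\tT\t50\t60"), f2)
  expect_error(read_pileup(f2, "s", "treated"), "chr1:100")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig\tpos\tref\tdepth\tdel",
               "chr1\t7\tT\t50\t1", "chr1\t7\tT\t40\t0"), f3)
  expect_error(read_pileup(f3, "s", "treated"), "duplicate")

  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig\tpos\tref\tdepth\tdel", "chr1\tabc\tT\t50\t1"), f4)
  expect_error(read_pileup(f4, "s", "treated"), "line")
})

test_that("pileups round-trip through write_pileup, including gzip", {
  sim <- simulate_isolate(n_genes = 2, gene_length = 50, n_sites = 3,
                          seed = 5)
  p <- sim$samples$sample01$treated
  f <- withr::local_tempfile(fileext = ".tsv.gz")
  write_pileup(p, f)
  p2 <- read_pileup(f, "sample01", "treated")
  expect_equal(p2, p[order(p$contig, p$pos), ], ignore_attr = TRUE)
})

test_that("transcript_uridine_sites resolves strand", {
  g <- tiny_genome(c(chr = "ATGC"))
  plus <- data.frame(gene_id = "gp", contig = "chr", start = 1, end = 4,
                     strand = "+", stringsAsFactors = FALSE)
  minus <- data.frame(gene_id = "gm", contig = "chr", start = 1, end = 4,
                      strand = "-", stringsAsFactors = FALSE)
  expect_equal(transcript_uridine_sites(plus, g)$pos, 2L)   # the T
  expect_equal(transcript_uridine_sites(minus, g)$pos, 1L)  # the A
  none <- data.frame(gene_id = "gn", contig = "chr", start = 3, end = 4,
                     strand = "+", stringsAsFactors = FALSE)
  expect_equal(nrow(transcript_uridine_sites(none, g)), 0)
  bad <- data.frame(gene_id = "gx", contig = "nope", start = 1, end = 2,
                    strand = "+", stringsAsFactors = FALSE)
  expect_error(transcript_uridine_sites(bad, g), "absent")
})

test_that("pair_sites joins, reports drops and measures homopolymer runs", {
  g <- tiny_genome(c(chr = "AGTTTCA"))  # transcript GUUUC run of 3 at 3..5
  ann <- data.frame(gene_id = "g1", contig = "chr", start = 1, end = 7,
                    strand = "+", stringsAsFactors = FALSE)
  usites <- transcript_uridine_sites(ann, g)
  mk <- function(cond, pos, depth, del) {
    data.frame(sample_id = "s1", condition = cond, contig = "chr", pos = pos,
               ref_base = "T", depth = depth, del_count = del,
               stringsAsFactors = FALSE)
  }
  treated <- mk("treated", c(3L, 4L, 5L), 100L, c(5L, 6L, 7L))
  untreated <- mk("untreated", c(3L, 4L), 100L, c(0L, 0L))
  pairs <- pair_sites(treated, untreated, usites, g)
  expect_equal(nrow(pairs), 2)
  expect_equal(attr(pairs, "join_report")$n_treated_only, 1)
  expect_true(all(pairs$homopolymer_run == 3L))
  expect_true(all(pairs$transcript_base == "U"))
  expect_lte(nrow(pairs), min(nrow(treated), nrow(untreated)))
})

test_that("minus-strand pairs render the complement as uridine", {
  g <- tiny_genome(c(chr = "GGACC"))  # A at 3; minus-strand transcript U
  ann <- data.frame(gene_id = "gm", contig = "chr", start = 1, end = 5,
                    strand = "-", stringsAsFactors = FALSE)
  usites <- transcript_uridine_sites(ann, g)
  expect_equal(usites$pos, 3L)
  treated <- data.frame(sample_id = "s", condition = "treated",
                        contig = "chr", pos = 3L, ref_base = "A",
                        depth = 50L, del_count = 5L, stringsAsFactors = FALSE)
  untreated <- transform(treated, condition = "untreated", del_count = 0L)
  pairs <- pair_sites(treated, untreated, usites, g)
  expect_equal(pairs$transcript_base, "U")
  expect_equal(pairs$strand, "-")
})

test_that("calls round-trip losslessly through BED-like files", {
  pairs <- boundary_pairs()
  calls <- call_sites(pairs)
  f <- withr::local_tempfile(fileext = ".bed")
  write_calls(calls, f)
  lines <- readLines(f)
  # 0-based half-open interval: pos 101 becomes 100..101
  expect_match(lines[2], "^chr\t100\t101\t")
  back <- read_calls(f)
  expect_equal(back, calls, ignore_attr = TRUE)

  write_calls(calls[0, ], f)
  expect_length(readLines(f), 1)  # header only
  expect_equal(nrow(read_calls(f)), 0)
})
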