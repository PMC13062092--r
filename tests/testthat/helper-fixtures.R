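# Shared fixtures and independent oracles, all built in code.

# Site-pair data frame covering every filter boundary: depth 19/20,
# deletion count 4/5, treated ratio 4.9/5.0/6.0%, untreated ratio 0.9/1.0%.
# Rows P* satisfy the isolate filters analytically; rows F* each violate
# exactly the boundary named in their comment.
boundary_pairs <- function() {
  row <- function(pos, td, tx, ud, ux) {
    data.frame(contig = "chr", pos = pos, strand = "+", gene_id = "g1",
               transcript_base = "U", homopolymer_run = 1L,
               treated_depth = td, treated_del = tx,
               untreated_depth = ud, untreated_del = ux,
               sample_id = "s1", stringsAsFactors = FALSE)
  }
  rbind(
    row(101, 100, 10, 100, 0),    # P1 canonical 10% vs 0%
    row(102, 20, 5, 20, 0),       # P2 depth exactly 20 in both
    row(103, 100, 5, 100, 0),     # P3 deletion count exactly 5, ratio 5.0%
    row(104, 200, 10, 200, 1),    # P4 treated ratio exactly 5.0%
    row(105, 1000, 60, 1000, 9),  # P5 untreated 0.9% (passes strict <1%)
    row(106, 100, 10, 20, 0),     # P6 untreated depth exactly 20
    row(201, 19, 10, 100, 0),     # F1 treated depth 19
    row(202, 80, 4, 100, 0),      # F2 ratio 5.0% but deletion count 4
    row(203, 1000, 49, 1000, 0),  # F3 treated ratio 4.9%
    row(204, 200, 12, 200, 2),    # F4 untreated exactly 1.0%
    row(205, 100, 10, 19, 0),     # F5 untreated depth 19
    row(206, 100, 4, 100, 0)      # F6 deletion count 4 and ratio 4%
  )
}

boundary_expected_pass <- c(101L, 102L, 103L, 104L, 105L, 106L)

# Hypergeometric pmf from lchoose sums: an enumeration route independent of
# stats::dhyper/phyper used by the implementation.
enum_hyper <- function(k, n1, n) {
  lo <- max(0, k - (n - n1))
  hi <- min(k, n1)
  x <- lo:hi
  list(x = x,
       p = exp(lchoose(n1, x) + lchoose(n - n1, k - x) - lchoose(n, k)))
}

enum_fisher <- function(a, b, c, d, alternative = "greater") {
  pmf <- enum_hyper(a + c, a + b, a + b + c + d)
  if (alternative == "greater") {
    sum(pmf$p[pmf$x >= a])
  } else {
    p_obs <- pmf$p[pmf$x == a]
    sum(pmf$p[pmf$p <= p_obs * (1 + 1e-7)])
  }
}

# Exact two-sided rank-sum p by enumerating every assignment of ranks.
enum_ranksum <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  w_all <- utils::combn(n, nx, function(idx) sum(idx)) - nx * (nx + 1) / 2
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# RIF-seq benchmark: 200 decaying genes, a stable background pool keeping
# spike-ins a realistic ~1% of the library, 30 ERCC spike-ins.
make_rif_benchmark <- function(seed = 1L, n_genes = 200L, n_background = 300L) {
  withr::with_seed(seed, {
    list(
      genes = data.frame(
        gene_id = sprintf("g%03d", seq_len(n_genes)), length_nt = 1000L,
        A0 = exp(stats::runif(n_genes, log(50), log(200))),
        half_life = exp(stats::runif(n_genes, log(1), log(20))),
        t0 = sample(c(0, 3), n_genes, replace = TRUE),
        stringsAsFactors = FALSE
      ),
      background = data.frame(
        gene_id = sprintf("bg%03d", seq_len(n_background)), length_nt = 1000L,
        A0 = exp(stats::runif(n_background, log(50), log(200))),
        half_life = Inf, t0 = 0, stringsAsFactors = FALSE
      ),
      spikes = data.frame(
        spike_id = sprintf("ERCC-%04d", 1:30),
        level = exp(stats::runif(30, log(5), log(50))),
        stringsAsFactors = FALSE
      )
    )
  })
}

tiny_genome <- function(seqs) Biostrings::DNAStringSet(seqs)
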