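#' Fisher's exact test for a 2x2 deletion table
#'
#' Exact hypergeometric tail probability for the table
#' `[[a, b], [c, d]]` with rows = (treated, untreated) and columns =
#' (deletions, non-deletions). For `alternative = "greater"` the p-value is
#' `P(X >= a)` under the hypergeometric distribution with the observed
#' margins; `"two_sided"` sums the probabilities of all tables at most as
#' likely as the observed one (the standard exact-test convention).
#'
#' `a`, `b`, `c`, `d` are vectorized for `"greater"`, the default used by the
#' community caller since BS chemistry can only add deletions.
#'
#' @param a,b,c,d Non-negative integer cell counts: treated deletions,
#'   treated non-deletions, untreated deletions, untreated non-deletions.
#'   Alternatively `a` may be a 2x2 matrix.
#' @param alternative `"greater"` or `"two_sided"`.
#' @return P-value(s) in `[0, 1]`.
#' @export
#' @examples
#' fisher_exact_2x2(5, 15, 0, 20, alternative = "greater")
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                             alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  if (any(c(a, b, c, d) < 0)) stop("validation error: negative cell count")
  n1 <- a + b      # treated depth (row margin)
  k <- a + c       # total deletions (column margin)
  n <- a + b + c + d
  if (any(n == 0)) stop("validation error: empty table")
  if (alternative == "greater") {
    # P(X >= a), X ~ Hypergeometric(k successes, n - k failures, n1 draws)
    return(stats::phyper(a - 1, k, n - k, n1, lower.tail = FALSE))
  }
  mapply(function(a, n1, k, n) {
    lo <- max(0, k - (n - n1))
    hi <- min(k, n1)
    p <- stats::dhyper(lo:hi, k, n - k, n1)
    p_obs <- stats::dhyper(a, k, n - k, n1)
    sum(p[p <= p_obs * (1 + 1e-7)])
  }, a, n1, k, n)
}

#' Call pseudouridine sites in community mode
#'
#' Metatranscriptome calling tolerant of strain-heterogeneity indels, which
#' appear in both conditions and would violate the isolate `< 1%` untreated
#' rule. A site is emitted when depth is at least `min_depth` in both
#' conditions, the treated deletion count is at least `min_del_count`, the
#' treated deletion ratio is at least `min_treated_ratio`, the treated ratio
#' is at least `min_fold` times the untreated ratio, and Fisher's exact test
#' on the deletions/depth 2x2 table gives `p < max_fisher_p`. The reported
#' `delta_ratio` (the pseudouridine proportion) is the treated-minus-untreated
#' difference in deletion ratio, clamped at 0 from below.
#'
#' An untreated ratio of exactly 0 passes the fold filter as written
#' (`ratio_t >= fold * 0`); no pseudocount is introduced.
#'
#' @param pairs Site pairs from [pair_sites()]; a `genome_id` column, if
#'   present, is carried through.
#' @param thresholds A [community_thresholds()] object.
#' @return A `data.frame` of community calls with columns `genome_id`
#'   (if supplied), `contig`, `pos`, `strand`, `gene_id`, `psi_level`,
#'   `delta_ratio` (identical, kept for clarity), `ratio_treated`,
#'   `ratio_untreated`, `fisher_p`, counts, `homopolymer_flag`, `sample_id`.
#' @export
call_sites_community <- function(pairs, thresholds = community_thresholds()) {
  stopifnot(inherits(thresholds, "community_thresholds"))
  th <- thresholds
  empty <- cbind(.empty_calls(),
                 data.frame(delta_ratio = numeric(), fisher_p = numeric(),
                            genome_id = character(), stringsAsFactors = FALSE))
  if (nrow(pairs) == 0) return(empty)
  ratio_t <- ifelse(pairs$treated_depth > 0,
                    pairs$treated_del / pairs$treated_depth, NA_real_)
  ratio_u <- ifelse(pairs$untreated_depth > 0,
                    pairs$untreated_del / pairs$untreated_depth, NA_real_)
  keep <- pairs$treated_depth >= th$min_depth &
    pairs$untreated_depth >= th$min_depth &
    pairs$treated_del >= th$min_del_count &
    ratio_t >= th$min_treated_ratio &
    ratio_t >= th$min_fold * ratio_u
  keep[is.na(keep)] <- FALSE
  # Fisher's test only for candidates that survive the cheap filters
  p <- rep(NA_real_, nrow(pairs))
  if (any(keep)) {
    p[keep] <- fisher_exact_2x2(
      pairs$treated_del[keep], pairs$treated_depth[keep] - pairs$treated_del[keep],
      pairs$untreated_del[keep],
      pairs$untreated_depth[keep] - pairs$untreated_del[keep],
      alternative = if (th$fisher_alternative == "greater") "greater"
                    else "two_sided"
    )
    keep[keep] <- p[keep] < th$max_fisher_p
  }
  delta <- pmax(ratio_t[keep] - ratio_u[keep], 0)
  out <- data.frame(
    contig = pairs$contig[keep], pos = pairs$pos[keep],
    strand = pairs$strand[keep], gene_id = pairs$gene_id[keep],
    psi_level = delta, delta_ratio = delta,
    ratio_treated = ratio_t[keep], ratio_untreated = ratio_u[keep],
    fisher_p = p[keep],
    treated_depth = pairs$treated_depth[keep],
    treated_del = pairs$treated_del[keep],
    untreated_depth = pairs$untreated_depth[keep],
    untreated_del = pairs$untreated_del[keep],
    homopolymer_flag = if (!is.null(pairs$homopolymer_run)) {
      pairs$homopolymer_run[keep] >= 2L
    } else FALSE,
    sample_id = if (!is.null(pairs$sample_id)) pairs$sample_id[keep]
                else NA_character_,
    genome_id = if (!is.null(pairs$genome_id)) pairs$genome_id[keep]
                else NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Gate genomes on mean coverage
#'
#' Keeps genomes whose mean depth strictly exceeds the coverage gate in both
#' the BS-treated and the untreated sample, the cutoff used to decide which
#' community members are deep enough to call.
#'
#' @param coverage Data frame with columns `genome_id`,
#'   `mean_depth_treated`, `mean_depth_untreated`.
#' @param thresholds A [community_thresholds()] object
#'   (uses `genome_min_coverage`).
#' @return Character vector of retained `genome_id`s.
#' @export
gate_genomes <- function(coverage, thresholds = community_thresholds()) {
  stopifnot(inherits(thresholds, "community_thresholds"),
            all(c("genome_id", "mean_depth_treated",
                  "mean_depth_untreated") %in% names(coverage)))
  keep <- coverage$mean_depth_treated > thresholds$genome_min_coverage &
    coverage$mean_depth_untreated > thresholds$genome_min_coverage
  coverage$genome_id[keep]
}

#' Mean per-genome coverage of paired pileups
#'
#' @param treated,untreated Pileup data frames carrying a `genome_id` column.
#' @param genome_lengths Optional named vector of genome lengths; when
#'   absent, the number of pileup rows per genome is used as the denominator
#'   (i.e. the pileup is assumed to cover every position).
#' @return Data frame suitable for [gate_genomes()].
#' @export
genome_coverage <- function(treated, untreated, genome_lengths = NULL) {
  mean_depth <- function(p) {
    s <- tapply(p$depth, p$genome_id, sum)
    n <- if (is.null(genome_lengths)) {
      tapply(p$depth, p$genome_id, length)
    } else genome_lengths[names(s)]
    s / n
  }
  mt <- mean_depth(treated)
  mu <- mean_depth(untreated)
  ids <- union(names(mt), names(mu))
  data.frame(
    genome_id = ids,
    mean_depth_treated = as.numeric(mt[ids]),
    mean_depth_untreated = as.numeric(mu[ids]),
    stringsAsFactors = FALSE
  )
}

#' Per-genome pseudouridine site summary
#'
#' Counts the genome's called sites and normalizes by its effectively
#' covered length: `covered_bases` is the number of positions of any base
#' with depth above `min_depth` in both conditions, divided by 1000 to give
#' Kb, and `sites_per_kb = n_sites / (covered_bases / 1000)`.
#'
#' @param calls Community calls for one genome.
#' @param treated,untreated Full pileups for the genome (all bases).
#' @param gc_content GC fraction of the genome (taken from the genome
#'   catalog; see [gc_content_from_fasta()] to recompute from sequence).
#' @param genome_id Genome label.
#' @param min_depth Depth cutoff defining a covered base (strict `>`).
#' @return A one-row `data.frame`: `genome_id`, `gc_content`,
#'   `covered_bases`, `n_sites`, `sites_per_kb`.
#' @export
summarize_genome <- function(calls, treated, untreated, gc_content,
                             genome_id, min_depth = 20L) {
  m <- merge(treated[, c("contig", "pos", "depth")],
             untreated[, c("contig", "pos", "depth")],
             by = c("contig", "pos"), suffixes = c("_t", "_u"))
  covered <- sum(m$depth_t > min_depth & m$depth_u > min_depth)
  if (covered == 0) {
    stop("undefined site rate: genome ", genome_id,
         " has no positions covered > ", min_depth, "x in both conditions")
  }
  n_sites <- nrow(calls)
  data.frame(
    genome_id = genome_id, gc_content = gc_content,
    covered_bases = covered, n_sites = n_sites,
    sites_per_kb = n_sites / (covered / 1000),
    stringsAsFactors = FALSE
  )
}

#' GC fraction of a genome sequence
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @return GC fraction over all contigs.
#' @export
gc_content_from_fasta <- function(genome) {
  genome <- .load_genome(genome)
  f <- Biostrings::alphabetFrequency(genome, baseOnly = TRUE)
  f <- colSums(f)
  unname((f["C"] + f["G"]) / sum(f[c("A", "C", "G", "T")]))
}

#' Compare site densities between GC groups
#'
#' Splits genomes at a GC cutoff and compares the normalized site densities
#' (`sites_per_kb`) of the two groups with a two-sided Wilcoxon rank sum
#' test.
#'
#' @param summaries Data frame of [summarize_genome()] rows.
#' @param gc_cut GC fraction splitting the groups (`< gc_cut` vs
#'   `>= gc_cut`).
#' @return A list: `low` and `high` (per-group `sites_per_kb` vectors),
#'   `n_low`, `n_high`, `median_low`, `median_high`, `p_value`.
#' @export
compare_gc_groups <- function(summaries, gc_cut = 0.5) {
  lo <- summaries$sites_per_kb[summaries$gc_content < gc_cut]
  hi <- summaries$sites_per_kb[summaries$gc_content >= gc_cut]
  if (length(lo) < 2 || length(hi) < 2) {
    stop("grouping error: need at least 2 genomes on each side of gc_cut = ",
         gc_cut, " (got ", length(lo), " / ", length(hi), ")")
  }
  list(
    low = lo, high = hi, n_low = length(lo), n_high = length(hi),
    median_low = stats::median(lo), median_high = stats::median(hi),
    p_value = rank_sum_test(lo, hi)
  )
}

#' Strict high-confidence filter for 16S sites
#'
#' 16S rRNA positions are compared across genomes, so a stricter rule is
#' used to suppress false positives: a site is kept only when its delta
#' deletion ratio exceeds `min_delta` and it is identified either in at
#' least `min_genomes` distinct genomes, or in fewer genomes but at least
#' `min_samples` distinct samples.
#'
#' @param calls Community calls annotated to 16S features, with columns
#'   `genome_id`, `sample_id`, `delta_ratio` and a site key: `site_key` if
#'   present (e.g. an aligned 16S position), otherwise `pos`.
#' @param min_delta Exclusive lower bound on `delta_ratio`.
#' @param min_genomes,min_samples Multi-genome / multi-sample support rule.
#' @return The kept calls, with `n_genomes` and `n_samples` columns added.
#' @export
strict_16s_filter <- function(calls, min_delta = 0.1, min_genomes = 3L,
                              min_samples = 3L) {
  if (nrow(calls) == 0) return(calls)
  calls <- calls[calls$delta_ratio > min_delta, , drop = FALSE]
  if (nrow(calls) == 0) return(calls)
  key <- if ("site_key" %in% names(calls)) calls$site_key else calls$pos
  n_genomes <- vapply(split(calls$genome_id, key),
                      function(g) length(unique(g)), integer(1))
  n_samples <- vapply(split(calls$sample_id, key),
                      function(s) length(unique(s)), integer(1))
  calls$n_genomes <- n_genomes[as.character(key)]
  calls$n_samples <- n_samples[as.character(key)]
  keep <- calls$n_genomes >= min_genomes | calls$n_samples >= min_samples
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
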