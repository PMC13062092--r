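#' Isolate-mode calling thresholds
#'
#' Container for the per-site filters applied to matched BS-treated/untreated
#' counts at a uridine position. Defaults are the isolate pipeline's published
#' cutoffs: coverage depth >= 20 in both conditions, deletion count >= 5 and
#' deletion ratio >= 5\% in the treated sample, deletion ratio strictly below
#' 1\% in the untreated sample, and support in >= 2 samples for a
#' high-confidence site.
#'
#' Comparison conventions follow the filter wording exactly: `>=` for depth,
#' deletion count and the treated ratio; strict `<` for the untreated ratio.
#'
#' @param min_depth Minimum coverage depth required in both conditions.
#' @param min_del_count Minimum deletion count in the treated sample.
#' @param min_treated_ratio Minimum deletion ratio (fraction) in the treated
#'   sample.
#' @param max_untreated_ratio Upper bound (exclusive) on the untreated
#'   deletion ratio.
#' @param min_support_samples Minimum number of samples a site must be called
#'   in to be high confidence.
#' @return An object of class `call_thresholds`.
#' @seealso [call_sites()], [aggregate_high_confidence()]
#' @export
#' @examples
#' call_thresholds()
#' call_thresholds(min_depth = 50)
call_thresholds <- function(min_depth = 20L, min_del_count = 5L,
                            min_treated_ratio = 0.05,
                            max_untreated_ratio = 0.01,
                            min_support_samples = 2L) {
  stopifnot(
    min_depth >= 0, min_del_count >= 0, min_treated_ratio >= 0,
    max_untreated_ratio >= 0, min_support_samples >= 1,
    min_treated_ratio > max_untreated_ratio
  )
  structure(
    list(
      min_depth = as.integer(min_depth),
      min_del_count = as.integer(min_del_count),
      min_treated_ratio = as.numeric(min_treated_ratio),
      max_untreated_ratio = as.numeric(max_untreated_ratio),
      min_support_samples = as.integer(min_support_samples)
    ),
    class = "call_thresholds"
  )
}

#' Community-mode calling thresholds
#'
#' Filters for metatranscriptome (community) calling, where strain
#' heterogeneity produces indels shared between conditions and the untreated
#' background can exceed the isolate 1\% rule. Defaults: depth >= 20 in both
#' conditions, treated deletion count >= 5, treated deletion ratio >= 2\%,
#' treated ratio at least 2-fold above the untreated ratio, and Fisher's exact
#' test p-value < 0.01 on the deletion/depth 2x2 table. Genomes are only
#' processed when their mean coverage exceeds `genome_min_coverage` in both
#' conditions (strict `>`).
#'
#' @param min_depth Minimum depth in both conditions at a site.
#' @param min_del_count Minimum treated deletion count.
#' @param min_treated_ratio Minimum treated deletion ratio (fraction).
#' @param min_fold Minimum treated/untreated deletion-ratio fold change.
#' @param max_fisher_p Exclusive upper bound on the Fisher's exact test
#'   p-value.
#' @param genome_min_coverage Mean-depth gate a genome must exceed in both
#'   conditions.
#' @param fisher_alternative Sidedness of the Fisher test. BS chemistry can
#'   only add deletions, so the one-sided `"greater"` test is the default;
#'   `"two_sided"` is available.
#' @return An object of class `community_thresholds`.
#' @seealso [call_sites_community()], [gate_genomes()]
#' @export
community_thresholds <- function(min_depth = 20L, min_del_count = 5L,
                                 min_treated_ratio = 0.02, min_fold = 2,
                                 max_fisher_p = 0.01,
                                 genome_min_coverage = 20,
                                 fisher_alternative = c("greater", "two_sided")) {
  fisher_alternative <- match.arg(fisher_alternative)
  stopifnot(
    min_depth > 0, min_del_count > 0, min_treated_ratio > 0,
    min_fold > 0, max_fisher_p > 0, genome_min_coverage > 0
  )
  structure(
    list(
      min_depth = as.integer(min_depth),
      min_del_count = as.integer(min_del_count),
      min_treated_ratio = as.numeric(min_treated_ratio),
      min_fold = as.numeric(min_fold),
      max_fisher_p = as.numeric(max_fisher_p),
      genome_min_coverage = as.numeric(genome_min_coverage),
      fisher_alternative = fisher_alternative
    ),
    class = "community_thresholds"
  )
}

#' @export
print.call_thresholds <- function(x, ...) {
  cat("Isolate calling thresholds:\n")
  cat(sprintf("  depth >= %d (both conditions)\n", x$min_depth))
  cat(sprintf("  treated deletion count >= %d\n", x$min_del_count))
  cat(sprintf("  treated deletion ratio >= %.3f\n", x$min_treated_ratio))
  cat(sprintf("  untreated deletion ratio < %.3f\n", x$max_untreated_ratio))
  cat(sprintf("  high confidence: called in >= %d samples\n",
              x$min_support_samples))
  invisible(x)
}

#' @export
print.community_thresholds <- function(x, ...) {
  cat("Community calling thresholds:\n")
  cat(sprintf("  depth >= %d (both conditions)\n", x$min_depth))
  cat(sprintf("  treated deletion count >= %d\n", x$min_del_count))
  cat(sprintf("  treated deletion ratio >= %.3f\n", x$min_treated_ratio))
  cat(sprintf("  treated/untreated ratio fold >= %.2f\n", x$min_fold))
  cat(sprintf("  Fisher %s p < %.3g\n", x$fisher_alternative, x$max_fisher_p))
  cat(sprintf("  genome mean depth > %.1fx (both conditions)\n",
              x$genome_min_coverage))
  invisible(x)
}
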