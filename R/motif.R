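#' Extract the transcript-strand motif around a site
#'
#' Returns the `w`-mer on the transcribed strand containing the modified
#' uridine at a fixed offset (0-based from the motif start; default
#' centered). Plus-strand sites read the reference window directly; minus
#' strand sites take the reverse complement of the mirrored window. T is
#' rendered as U.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param contig,pos,strand Site coordinates (vectorized; 1-based `pos`).
#' @param w Motif width.
#' @param offset 0-based offset of the uridine within the motif; default
#'   centers it (requires odd `w`).
#' @param on_boundary `"error"` (default for the scalar contract) or `"na"`:
#'   sites whose window runs past a contig end either abort or yield `NA`
#'   with a warning counting the skipped sites.
#' @return Character vector of RNA motifs (alphabet ACGU), uridine at
#'   `offset`.
#' @export
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr = "AGGTATC"))
#' extract_motif(g, "chr", 4L, "+")  # "GGUAU"
extract_motif <- function(genome, contig, pos, strand, w = 5L,
                          offset = NULL, on_boundary = c("error", "na")) {
  on_boundary <- match.arg(on_boundary)
  genome <- .load_genome(genome)
  if (is.null(offset)) {
    if (w %% 2 == 0) stop("w must be odd when offset is centered")
    offset <- (w - 1L) %/% 2L
  }
  stopifnot(offset >= 0, offset < w)
  widths <- Biostrings::width(genome)[match(contig, names(genome))]
  if (anyNA(widths)) {
    stop("contig(s) absent from FASTA: ",
         paste(unique(contig[is.na(widths)]), collapse = ", "))
  }
  # On the minus strand the transcript reads 3'->5' along the reference, so
  # the window is mirrored before reverse complementing.
  up <- ifelse(strand == "+", offset, w - 1L - offset)
  down <- ifelse(strand == "+", w - 1L - offset, offset)
  start <- pos - up
  end <- pos + down
  oob <- start < 1 | end > widths
  if (any(oob)) {
    if (on_boundary == "error") {
      stop("boundary error: motif window outside contig for ",
           sum(oob), " site(s), first at ",
           contig[oob][1], ":", pos[oob][1])
    }
    warning(sum(oob), " site(s) skipped: motif window outside contig")
  }
  out <- rep(NA_character_, length(pos))
  ok <- which(!oob)
  if (length(ok) > 0) {
    seqs <- vapply(ok, function(i) {
      s <- Biostrings::subseq(genome[[contig[i]]], start[i], end[i])
      if (strand[i] == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1))
    out[ok] <- chartr("T", "U", seqs)
  }
  bad <- which(!is.na(out) & substr(out, offset + 1L, offset + 1L) != "U")
  if (length(bad) > 0) {
    stop("site is not a transcript-strand uridine at ",
         contig[bad][1], ":", pos[bad][1])
  }
  out
}

#' Build the motif table from gated calls
#'
#' Restricts calls to those with a treated deletion ratio above `min_ratio`
#' (the dataset-median gate), extracts the motif around each site, drops
#' motifs observed fewer than `min_occurrence` times in total, and records
#' the per-group deletion-ratio samples used by [pus_preference()].
#'
#' @param calls Call `data.frame` with `contig`, `pos`, `strand`,
#'   `ratio_treated` and a `group` column (strain / PUS-mutant label).
#' @param genome `DNAStringSet` or FASTA path.
#' @param min_ratio Exclusive lower bound on the treated deletion ratio.
#' @param min_occurrence Minimum total occurrences for a motif to be kept
#'   (inclusive).
#' @param w Motif width (odd, uridine centered).
#' @return A list with `sites` (gated per-site rows with a `motif` column;
#'   boundary sites dropped and counted in `attr(, "n_boundary")`) and
#'   `motifs` (per-motif occurrence counts, kept motifs only).
#' @export
build_motif_table <- function(calls, genome, min_ratio = 0.06,
                              min_occurrence = 6L, w = 5L) {
  stopifnot("group" %in% names(calls))
  gated <- calls[calls$ratio_treated > min_ratio, , drop = FALSE]
  if (nrow(gated) == 0) {
    return(list(sites = cbind(gated, motif = character(0)),
                motifs = data.frame(motif = character(),
                                    occurrence_count = integer(),
                                    stringsAsFactors = FALSE)))
  }
  motif <- extract_motif(genome, gated$contig, gated$pos, gated$strand,
                         w = w, on_boundary = "na")
  n_boundary <- sum(is.na(motif))
  gated$motif <- motif
  gated <- gated[!is.na(gated$motif), , drop = FALSE]
  counts <- table(gated$motif)
  kept <- names(counts)[counts >= min_occurrence]
  motifs <- data.frame(motif = kept,
                       occurrence_count = as.integer(counts[kept]),
                       stringsAsFactors = FALSE)
  motifs <- motifs[order(-motifs$occurrence_count, motifs$motif), ,
                   drop = FALSE]
  gated <- gated[gated$motif %in% kept, , drop = FALSE]
  rownames(gated) <- rownames(motifs) <- NULL
  out <- list(sites = gated, motifs = motifs)
  attr(out, "n_boundary") <- n_boundary
  out
}

#' Two-sided Wilcoxon rank sum test
#'
#' Thin wrapper around [stats::wilcox.test()] with the conventions used
#' throughout the package: the exact null distribution when the combined
#' sample size is at most 20 and there are no ties, otherwise the midrank
#' normal approximation with continuity correction.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @return The two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) {
    stop("validation error: empty group in rank sum test")
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= 20 && !has_ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)$p.value
  )
  # fully tied data degenerate the normal approximation; no evidence either way
  if (is.nan(p)) 1 else p
}

#' Per-motif PUS sequence-preference test
#'
#' For every motif, compares the deletion ratios of wild-type sites against
#' those of a PUS-mutant strain with a two-sided Wilcoxon rank sum test,
#' adjusts p-values by Benjamini-Hochberg across the motif family tested for
#' that mutant, and labels a motif `decreased` (a sequence preference of the
#' deleted enzyme) when the mutant median is lower and `p < alpha`.
#'
#' @param motif_table Output of [build_motif_table()].
#' @param wt_group,mutant_group Labels in the table's `group` column.
#' @param alpha Significance level on the unadjusted p-value.
#' @return A `data.frame`: `motif`, `group`, `n_wt`, `n_mutant`,
#'   `median_wt`, `median_mutant`, `p_value`, `q_value`, `direction`.
#' @export
pus_preference <- function(motif_table, wt_group, mutant_group,
                           alpha = 0.05) {
  sites <- motif_table$sites
  res <- lapply(motif_table$motifs$motif, function(m) {
    x <- sites$ratio_treated[sites$motif == m & sites$group == wt_group]
    y <- sites$ratio_treated[sites$motif == m & sites$group == mutant_group]
    if (length(x) == 0 || length(y) == 0) return(NULL)
    p <- rank_sum_test(x, y)
    data.frame(motif = m, group = mutant_group,
               n_wt = length(x), n_mutant = length(y),
               median_wt = stats::median(x), median_mutant = stats::median(y),
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    return(data.frame(motif = character(), group = character(),
                      n_wt = integer(), n_mutant = integer(),
                      median_wt = numeric(), median_mutant = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$direction <- ifelse(
    res$p_value < alpha & res$median_mutant < res$median_wt, "decreased",
    ifelse(res$p_value < alpha & res$median_mutant > res$median_wt,
           "increased", "none")
  )
  res <- res[order(res$p_value, res$motif), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write gated motif windows as a MEME-ready FASTA
#'
#' Consensus discovery is delegated to external tools; this emits the gated
#' site windows in RNA alphabet, one record per site, named
#' `contig:pos(strand)`.
#'
#' @param motif_table Output of [build_motif_table()].
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_meme_fasta <- function(motif_table, path) {
  sites <- motif_table$sites
  headers <- sprintf(">%s:%d(%s)", sites$contig, sites$pos, sites$strand)
  writeLines(as.vector(rbind(headers, sites$motif)), path)
  invisible(path)
}
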