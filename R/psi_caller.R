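#' Deletion ratio at a position
#'
#' The fraction of reads carrying a deletion: `del_count / depth`. Under BS
#' treatment the deletion ratio at a uridine is proportional to the fraction
#' of transcripts carrying pseudouridine at that position — a ratio of 0.5
#' reads as 50\% of transcripts harboring the modification.
#'
#' @param depth Coverage depth (> 0); vectorized.
#' @param del_count Deletion count, `0 <= del_count <= depth`.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
#' @examples
#' deletion_ratio(100, 50)
deletion_ratio <- function(depth, del_count) {
  if (any(depth == 0)) {
    stop("deletion ratio undefined at depth 0; filter zero-depth positions first")
  }
  stopifnot(all(del_count >= 0), all(del_count <= depth))
  del_count / depth
}

#' Call pseudouridine sites in isolate mode
#'
#' Applies the isolate filters to every site pair: coverage depth at or above
#' `min_depth` in both conditions, treated deletion count at or above
#' `min_del_count`, treated deletion ratio at or above `min_treated_ratio`,
#' and untreated deletion ratio strictly below `max_untreated_ratio`. The
#' reported `psi_level` is the treated-minus-untreated difference in deletion
#' ratio (with the untreated background under 1\% this is nearly the treated
#' ratio itself). Sites inside a transcript-strand U homopolymer of length
#' two or more get `homopolymer_flag = TRUE`: left-aligned deletion placement
#' makes the exact modified position within the run ambiguous.
#'
#' @param pairs Site pairs from [pair_sites()].
#' @param thresholds A [call_thresholds()] object.
#' @return A `data.frame` of calls (possibly zero rows) with columns `contig`,
#'   `pos`, `strand`, `gene_id`, `psi_level`, `ratio_treated`,
#'   `ratio_untreated`, `treated_depth`, `treated_del`, `untreated_depth`,
#'   `untreated_del`, `homopolymer_flag`, `sample_id`.
#' @export
call_sites <- function(pairs, thresholds = call_thresholds()) {
  stopifnot(inherits(thresholds, "call_thresholds"))
  th <- thresholds
  if (nrow(pairs) == 0) return(.empty_calls())
  ratio_t <- ifelse(pairs$treated_depth > 0,
                    pairs$treated_del / pairs$treated_depth, NA_real_)
  ratio_u <- ifelse(pairs$untreated_depth > 0,
                    pairs$untreated_del / pairs$untreated_depth, NA_real_)
  keep <- pairs$treated_depth >= th$min_depth &
    pairs$untreated_depth >= th$min_depth &
    pairs$treated_del >= th$min_del_count &
    ratio_t >= th$min_treated_ratio &
    ratio_u < th$max_untreated_ratio
  keep[is.na(keep)] <- FALSE
  out <- data.frame(
    contig = pairs$contig[keep], pos = pairs$pos[keep],
    strand = pairs$strand[keep], gene_id = pairs$gene_id[keep],
    psi_level = ratio_t[keep] - ratio_u[keep],
    ratio_treated = ratio_t[keep], ratio_untreated = ratio_u[keep],
    treated_depth = pairs$treated_depth[keep],
    treated_del = pairs$treated_del[keep],
    untreated_depth = pairs$untreated_depth[keep],
    untreated_del = pairs$untreated_del[keep],
    homopolymer_flag = if (!is.null(pairs$homopolymer_run)) {
      pairs$homopolymer_run[keep] >= 2L
    } else FALSE,
    sample_id = if (!is.null(pairs$sample_id)) pairs$sample_id[keep]
                else NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

.empty_calls <- function() {
  data.frame(contig = character(), pos = integer(), strand = character(),
             gene_id = character(), psi_level = numeric(),
             ratio_treated = numeric(), ratio_untreated = numeric(),
             treated_depth = integer(), treated_del = integer(),
             untreated_depth = integer(), untreated_del = integer(),
             homopolymer_flag = logical(), sample_id = character(),
             stringsAsFactors = FALSE)
}

#' Aggregate per-sample calls into high-confidence sites
#'
#' Groups calls from several samples by exact (contig, pos) identity and
#' keeps positions called in at least `min_support_samples` samples —
#' biological replicates and different growth conditions count alike. The
#' operation is idempotent and independent of input order.
#'
#' @param calls Either one combined call `data.frame` carrying a `sample_id`
#'   column or a list of per-sample call data frames.
#' @param thresholds A [call_thresholds()] object
#'   (uses `min_support_samples`).
#' @return A `data.frame` with columns `contig`, `pos`, `gene_id`, `strand`,
#'   `support`, `mean_psi`, `psi_levels` (comma-joined per-sample values) and
#'   `samples`.
#' @export
aggregate_high_confidence <- function(calls,
                                      thresholds = call_thresholds()) {
  stopifnot(inherits(thresholds, "call_thresholds"))
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- do.call(rbind, calls)
  }
  if (is.null(calls) || nrow(calls) == 0) {
    return(data.frame(contig = character(), pos = integer(),
                      gene_id = character(), strand = character(),
                      support = integer(), mean_psi = numeric(),
                      psi_levels = character(), samples = character(),
                      stringsAsFactors = FALSE))
  }
  # one call per sample per position: duplicates would inflate support
  calls <- calls[!duplicated(calls[, c("contig", "pos", "sample_id")]), ,
                 drop = FALSE]
  key <- paste(calls$contig, calls$pos, sep = ":")
  o <- order(key, calls$sample_id)
  calls <- calls[o, , drop = FALSE]
  key <- key[o]
  first <- !duplicated(key)
  grp <- split(seq_len(nrow(calls)), key)
  support <- vapply(grp, length, integer(1))
  out <- data.frame(
    contig = calls$contig[first], pos = calls$pos[first],
    gene_id = calls$gene_id[first], strand = calls$strand[first],
    support = support[match(key[first], names(grp))],
    mean_psi = vapply(grp, function(i) mean(calls$psi_level[i]),
                      numeric(1))[match(key[first], names(grp))],
    psi_levels = vapply(grp, function(i) {
      paste(sprintf("%.6g", calls$psi_level[i]), collapse = ",")
    }, character(1))[match(key[first], names(grp))],
    samples = vapply(grp, function(i) {
      paste(calls$sample_id[i], collapse = ",")
    }, character(1))[match(key[first], names(grp))],
    stringsAsFactors = FALSE
  )
  out <- out[out$support >= thresholds$min_support_samples, , drop = FALSE]
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-base relative deletion frequency (QC)
#'
#' For each reference base `b` the aggregate deletion ratio
#' `r_b = sum(del) / sum(depth)` over all positions with that base is
#' computed, and the reported enrichment of `b` is the mean of `r_b / r_b'`
#' over the other three bases (for uridine, `mean(U:A, U:G, U:C)`). Under
#' uniform random deletions every value is ~1; BS treatment drives the
#' uridine value far above 1 while leaving other bases flat, which is the
#' expected signature of deletion-based pseudouridine profiling.
#'
#' Pooled (aggregate) ratios are the default because per-site ratio means are
#' noisy at low depth; set `per_site_mean = TRUE` for the per-site variant.
#'
#' @param pileup A pileup `data.frame` from [read_pileup()] covering all four
#'   bases of one sample.
#' @param per_site_mean Use the mean of per-site ratios instead of pooled
#'   counts.
#' @return A named numeric vector over `c("A", "C", "G", "U")`. Pairwise
#'   ratios whose denominator base has zero aggregate deletions are skipped
#'   and reported via a warning and the `"skipped_pairs"` attribute.
#' @export
base_deletion_enrichment <- function(pileup, per_site_mean = FALSE) {
  stopifnot(nrow(pileup) > 0)
  bases <- c("A", "C", "G", "T")
  present <- bases %in% pileup$ref_base[pileup$depth > 0]
  if (!all(present)) {
    stop("all four bases must be observed with depth > 0; missing: ",
         paste(bases[!present], collapse = ", "))
  }
  r <- vapply(bases, function(b) {
    sel <- pileup$ref_base == b & pileup$depth > 0
    if (per_site_mean) {
      mean(pileup$del_count[sel] / pileup$depth[sel])
    } else {
      sum(pileup$del_count[sel]) / sum(pileup$depth[sel])
    }
  }, numeric(1))
  skipped <- character(0)
  out <- vapply(bases, function(b) {
    others <- setdiff(bases, b)
    denom <- r[others]
    usable <- denom > 0
    if (!all(usable)) {
      skipped <<- c(skipped, paste(b, others[!usable], sep = ":"))
    }
    if (!any(usable)) return(NA_real_)
    mean(r[b] / denom[usable])
  }, numeric(1))
  names(out) <- c("A", "C", "G", "U")  # transcript rendering of reference T
  if (length(skipped) > 0) {
    warning("skipped pairwise ratios with zero deletions in denominator: ",
            paste(skipped, collapse = ", "))
    attr(out, "skipped_pairs") <- skipped
  }
  out
}
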