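#' Transcripts per million with a pseudocount
#'
#' Adds a pseudocount to every gene, converts counts to length-normalized
#' rates (`(count + pseudocount) / length_kb`), and scales each sample so the
#' column sums to one million. The pseudocount gives unexpressed genes a
#' small positive TPM, stabilizing downstream ratios.
#'
#' @param counts Integer matrix, genes x samples (rownames = gene ids).
#' @param lengths Gene lengths in nucleotides, recycled by name when named.
#' @param pseudocount Count added to every gene (default 1).
#' @return Numeric matrix of TPM values; every column sums to `1e6`.
#' @export
#' @examples
#' tpm(matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1")),
#'     lengths = c(a = 1000, b = 1000))
tpm <- function(counts, lengths, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  stopifnot(length(lengths) == nrow(counts))
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("validation error: every gene needs a positive length")
  }
  if (any(counts < 0)) stop("validation error: negative counts")
  rate <- (counts + pseudocount) / (lengths / 1000)
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Transcript pseudouridine strength
#'
#' The Psi-strength of a transcript is the sum of the deletion ratios
#' (treated-minus-untreated `psi_level`) over all its called sites in one
#' sample; a transcript with no sites has strength 0.
#'
#' @param calls Call `data.frame` with `gene_id`, `sample_id`, `psi_level`.
#' @param genes Optional character vector of gene ids to report (genes
#'   without calls get strength 0).
#' @return A `data.frame`: `gene_id`, `sample_id`, `psi_strength`.
#' @export
psi_strength <- function(calls, genes = NULL) {
  if (nrow(calls) > 0) {
    agg <- stats::aggregate(psi_level ~ gene_id + sample_id, data = calls,
                            FUN = sum)
    names(agg)[3] <- "psi_strength"
  } else {
    agg <- data.frame(gene_id = character(), sample_id = character(),
                      psi_strength = numeric(), stringsAsFactors = FALSE)
  }
  if (!is.null(genes)) {
    samples <- unique(c(agg$sample_id, calls$sample_id))
    if (length(samples) == 0) samples <- NA_character_
    full <- expand.grid(gene_id = genes, sample_id = samples,
                        stringsAsFactors = FALSE)
    agg <- merge(full, agg, by = c("gene_id", "sample_id"), all.x = TRUE)
    agg$psi_strength[is.na(agg$psi_strength)] <- 0
  }
  agg <- agg[order(agg$gene_id, agg$sample_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Assign genes to a pseudouridine synthase
#'
#' A gene is considered a target of a PUS when knocking the enzyme out
#' lowers the gene's Psi-strength by at least `min_delta` in every replicate
#' pairing (wild type minus mutant, replicate by replicate; the inclusive
#' `>=` keeps boundary cases). A gene may be assigned to several PUS
#' enzymes.
#'
#' @param wt,mutant Data frames with `gene_id`, `replicate`, `psi_strength`
#'   (one row per gene per replicate). Genes absent from one table are
#'   treated as strength 0 in it. Replicate labels must match between the
#'   two strains.
#' @param min_delta Minimum per-replicate Psi-strength drop (inclusive).
#' @return A `data.frame`: `gene_id`, per-replicate `delta_*` columns, and
#'   `assigned` (logical).
#' @export
assign_pus <- function(wt, mutant, min_delta = 0.05) {
  reps <- sort(unique(wt$replicate))
  if (!setequal(reps, unique(mutant$replicate))) {
    stop("pairing error: replicate labels differ between strains (",
         paste(reps, collapse = ","), " vs ",
         paste(sort(unique(mutant$replicate)), collapse = ","), ")")
  }
  genes <- sort(union(wt$gene_id, mutant$gene_id))
  get <- function(df, rep) {
    v <- df$psi_strength[df$replicate == rep]
    names(v) <- df$gene_id[df$replicate == rep]
    out <- v[genes]
    out[is.na(out)] <- 0
    out
  }
  deltas <- vapply(reps, function(r) get(wt, r) - get(mutant, r),
                   numeric(length(genes)))
  deltas <- matrix(deltas, nrow = length(genes),
                   dimnames = list(genes, paste0("delta_", reps)))
  # small tolerance so boundary differences like 0.30 - 0.25 pass the
  # inclusive >= rule despite floating-point representation
  out <- data.frame(gene_id = genes, deltas,
                    assigned = apply(deltas >= min_delta - 1e-9, 1, all),
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' ERCC spike-in normalization of a decay time course
#'
#' For each of the `n_top` spike-ins most abundant at timepoint 0 a
#' normalization constant is computed at every timepoint `n`:
#' \deqn{k = \frac{ERCC_n / ERCC_0}{Total_n / Total_0}}
#' where `ERCC` are the spike-in's read counts and `Total` the full library
#' sizes. The per-timepoint normalization factor is the geometric mean of
#' the `k` values; raw counts divided by the factor give the normalized
#' library (timepoint 0 has factor 1 by construction). Because both
#' numerator and denominator are ratios of library totals, pure
#' sequencing-depth changes cancel and the factor tracks the drift of the
#' mRNA pool relative to the fixed spike-in input.
#'
#' @param counts Count matrix (genes and spike-in rows) with one column per
#'   timepoint.
#' @param timepoints Numeric vector of minutes, one per column; exactly one
#'   must be 0.
#' @param spike_prefix Row-name prefix identifying spike-ins
#'   (default `"ERCC-"`).
#' @param n_top Number of most-abundant spike-ins used (ranked by raw
#'   timepoint-0 counts, ties broken lexicographically by id). A selected
#'   spike-in with zero counts at timepoint 0 is an error; fewer than
#'   `n_top` nonzero spike-ins triggers a warning and uses all available.
#' @return A list: `factors` (per-timepoint normalization factors), `k`
#'   (spike-in x timepoint matrix of constants), `normalized` (counts
#'   divided by their column's factor), `spikes_used`.
#' @export
spike_norm <- function(counts, timepoints, spike_prefix = "ERCC-",
                       n_top = 25L) {
  counts <- as.matrix(counts)
  stopifnot(length(timepoints) == ncol(counts))
  t0 <- which(timepoints == 0)
  if (length(t0) != 1) stop("exactly one timepoint-0 column is required")
  is_spike <- startsWith(rownames(counts), spike_prefix)
  if (!any(is_spike)) stop("no spike-in rows with prefix '", spike_prefix, "'")
  spikes <- counts[is_spike, , drop = FALSE]
  nonzero <- rownames(spikes)[spikes[, t0] > 0]
  if (length(nonzero) < n_top) {
    warning("only ", length(nonzero), " spike-ins with nonzero counts at ",
            "timepoint 0; using all of them")
  }
  ord <- nonzero[order(-spikes[nonzero, t0], nonzero)]
  used <- utils::head(ord, n_top)
  if (length(used) == 0) stop("selection error: no usable spike-ins")
  if (any(spikes[used, t0] == 0)) {
    stop("selection error: selected spike-in has zero counts at timepoint 0")
  }
  total <- colSums(counts)
  k <- sweep(spikes[used, , drop = FALSE], 1, spikes[used, t0], "/")
  k <- sweep(k, 2, total / total[t0], "/")
  if (any(k <= 0)) {
    warning("spike-in(s) with zero counts at a later timepoint excluded ",
            "from that timepoint's geometric mean")
  }
  factors <- apply(k, 2, function(col) exp(mean(log(col[col > 0]))))
  factors[t0] <- 1
  list(
    factors = factors, k = k,
    normalized = sweep(counts, 2, factors, "/"),
    spikes_used = used
  )
}

#' Non-substrate control gene set
#'
#' Genes with at least moderate expression in every sample (`TPM > min_tpm`)
#' but no called pseudouridine site in any sample: consistently expressed,
#' so their absence of calls is unlikely to be a coverage artifact.
#'
#' @param tpm_matrix TPM matrix (genes x samples) computed on the same
#'   samples as `calls`.
#' @param calls Combined call `data.frame` across all samples (`gene_id`
#'   column used).
#' @param min_tpm Exclusive lower bound on TPM in every sample.
#' @return Character vector of gene ids.
#' @export
nonsubstrate_set <- function(tpm_matrix, calls, min_tpm = 20) {
  expressed <- rownames(tpm_matrix)[
    apply(tpm_matrix > min_tpm, 1, all)
  ]
  setdiff(expressed, unique(calls$gene_id))
}
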