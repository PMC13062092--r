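#' Assemble a run configuration
#'
#' Bundles input paths, thresholds and the seed for the two end-to-end
#' workflows. Defaults equal the published filter values. The object
#' serializes losslessly to YAML via [write_config()] / [read_config()].
#'
#' @param mode `"isolate"` or `"community"`.
#' @param samples A data frame (or list of lists) with `sample_id`,
#'   `treated`, `untreated` pileup paths per sample.
#' @param fasta Genome FASTA path.
#' @param gff GFF3 annotation path.
#' @param out_dir Output directory.
#' @param thresholds [call_thresholds()] (isolate mode).
#' @param community [community_thresholds()] (community mode).
#' @param genome_catalog Optional TSV path with `genome_id`, `gc_content`
#'   columns (community mode).
#' @param seed Seed recorded in provenance.
#' @return An object of class `psiscan_config`.
#' @export
psiscan_config <- function(mode = c("isolate", "community"), samples,
                           fasta, gff, out_dir,
                           thresholds = call_thresholds(),
                           community = community_thresholds(),
                           genome_catalog = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.data.frame(samples)) {
    samples <- lapply(seq_len(nrow(samples)), function(i) {
      as.list(samples[i, c("sample_id", "treated", "untreated")])
    })
  }
  structure(
    list(mode = mode, samples = samples, fasta = fasta, gff = gff,
         out_dir = out_dir, thresholds = unclass(thresholds),
         community = unclass(community), genome_catalog = genome_catalog,
         seed = as.integer(seed)),
    class = "psiscan_config"
  )
}

#' @rdname psiscan_config
#' @param cfg A `psiscan_config`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname psiscan_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  structure(x, class = "psiscan_config")
}

# hash over the analysis-relevant configuration: the output destination does
# not change what is computed
.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  x <- unclass(cfg)
  x$out_dir <- NULL
  yaml::write_yaml(x, f)
  unname(tools::md5sum(f))
}

.provenance <- function(cfg) {
  c(sprintf("## psiscan %s",
            as.character(utils::packageVersion("psiscan"))),
    sprintf("## config_hash=%s seed=%d", .config_hash(cfg), cfg$seed))
}

.write_tsv_prov <- function(df, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(prov, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the isolate workflow
#'
#' Stage order: read pileups, pair at transcript uridines, call per sample,
#' aggregate high-confidence sites, QC base enrichment and per-gene
#' Psi-strength. Every output file carries `##` provenance lines (package
#' version, config hash, seed); a rerun with an identical configuration is
#' bit-identical. Stage errors abort with the stage name.
#'
#' @param cfg A [psiscan_config()] with `mode = "isolate"`.
#' @return Invisibly, a list with `calls` (per-sample), `high_confidence`,
#'   `qc`, `strength` and the output paths.
#' @export
run_isolate <- function(cfg) {
  stopifnot(inherits(cfg, "psiscan_config"), cfg$mode == "isolate")
  th <- do.call(call_thresholds, cfg$thresholds)
  prov <- .provenance(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  genome <- stage("load_genome", .load_genome(cfg$fasta))
  ann <- stage("load_annotation", read_gene_annotation(cfg$gff))
  usites <- stage("uridine_sites", transcript_uridine_sites(ann, genome))

  calls <- list()
  qc <- list()
  for (s in cfg$samples) {
    treated <- stage("read_pileup", read_pileup(s$treated, s$sample_id,
                                                "treated"))
    untreated <- stage("read_pileup", read_pileup(s$untreated, s$sample_id,
                                                  "untreated"))
    pairs <- stage("pair_sites", pair_sites(treated, untreated, usites,
                                            genome))
    calls[[s$sample_id]] <- stage("call_sites", call_sites(pairs, th))
    qc[[s$sample_id]] <- tryCatch(
      base_deletion_enrichment(treated),
      error = function(e) stats::setNames(rep(NA_real_, 4),
                                          c("A", "C", "G", "U"))
    )
    path <- file.path(cfg$out_dir, paste0(s$sample_id, "_calls.bed"))
    tmp <- tempfile()
    write_calls(calls[[s$sample_id]], tmp)
    writeLines(c(prov, readLines(tmp)), path)
    unlink(tmp)
  }

  hc <- stage("aggregate", aggregate_high_confidence(calls, th))
  .write_tsv_prov(hc, file.path(cfg$out_dir, "high_confidence.tsv"), prov)

  qc_df <- data.frame(sample_id = rep(names(qc), each = 4),
                      base = rep(c("A", "C", "G", "U"), length(qc)),
                      enrichment = unlist(qc, use.names = FALSE),
                      stringsAsFactors = FALSE)
  .write_tsv_prov(qc_df, file.path(cfg$out_dir, "qc_base_enrichment.tsv"),
                  prov)

  all_calls <- do.call(rbind, calls)
  strength <- psi_strength(all_calls, genes = ann$gene_id)
  .write_tsv_prov(strength, file.path(cfg$out_dir, "psi_strength.tsv"), prov)

  invisible(list(calls = calls, high_confidence = hc, qc = qc_df,
                 strength = strength, out_dir = cfg$out_dir))
}

#' Run the community workflow
#'
#' Genomes are gated on mean coverage before any calling; community calls,
#' per-genome site summaries, the GC-group comparison and the strict 16S
#' table are computed for gated genomes only. In the community inputs each
#' genome is a set of contigs named after it; here `genome_id` is taken as
#' the contig name.
#'
#' @param cfg A [psiscan_config()] with `mode = "community"` and a
#'   `genome_catalog` TSV (`genome_id`, `gc_content`).
#' @return Invisibly, a list with `gated_genomes`, `calls`, `summaries`,
#'   `gc_comparison` (or NULL when a group is too small), `sites_16s`.
#' @export
run_community <- function(cfg) {
  stopifnot(inherits(cfg, "psiscan_config"), cfg$mode == "community")
  th <- do.call(community_thresholds, cfg$community)
  prov <- .provenance(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- .load_genome(cfg$fasta)
  ann <- read_gene_annotation(cfg$gff)
  usites <- transcript_uridine_sites(ann, genome)
  catalog <- utils::read.delim(cfg$genome_catalog, stringsAsFactors = FALSE)
  glen <- stats::setNames(Biostrings::width(genome), names(genome))

  all_calls <- list()
  gated_all <- character(0)
  pileups <- list()
  for (s in cfg$samples) {
    treated <- read_pileup(s$treated, s$sample_id, "treated")
    untreated <- read_pileup(s$untreated, s$sample_id, "untreated")
    treated$genome_id <- treated$contig
    untreated$genome_id <- untreated$contig
    cov <- genome_coverage(treated, untreated, glen)
    gated <- gate_genomes(cov, th)
    message(length(gated), " genome(s) passed the >",
            th$genome_min_coverage, "x coverage gate in sample ",
            s$sample_id)
    gated_all <- union(gated_all, gated)
    treated <- treated[treated$genome_id %in% gated, , drop = FALSE]
    untreated <- untreated[untreated$genome_id %in% gated, , drop = FALSE]
    pileups[[s$sample_id]] <- list(treated = treated, untreated = untreated)
    pairs <- pair_sites(treated, untreated, usites, genome)
    pairs$genome_id <- pairs$contig
    all_calls[[s$sample_id]] <- call_sites_community(pairs, th)
  }
  calls <- do.call(rbind, all_calls)
  .write_tsv_prov(calls, file.path(cfg$out_dir, "community_calls.tsv"), prov)

  summaries <- do.call(rbind, lapply(gated_all, function(gid) {
    gc <- catalog$gc_content[match(gid, catalog$genome_id)]
    tr <- do.call(rbind, lapply(pileups, function(p) {
      p$treated[p$treated$genome_id == gid, ]
    }))
    un <- do.call(rbind, lapply(pileups, function(p) {
      p$untreated[p$untreated$genome_id == gid, ]
    }))
    # pool depth across samples position-wise is not meaningful; use the
    # first sample's pileup for the covered-base mask
    first <- names(pileups)[1]
    summarize_genome(calls[calls$genome_id == gid, , drop = FALSE],
                     pileups[[first]]$treated[
                       pileups[[first]]$treated$genome_id == gid, ],
                     pileups[[first]]$untreated[
                       pileups[[first]]$untreated$genome_id == gid, ],
                     gc_content = gc, genome_id = gid,
                     min_depth = th$min_depth)
  }))
  if (!is.null(summaries)) {
    .write_tsv_prov(summaries, file.path(cfg$out_dir, "genome_summary.tsv"),
                    prov)
  }

  gc_cmp <- tryCatch(compare_gc_groups(summaries), error = function(e) {
    message("GC-group comparison skipped: ", conditionMessage(e))
    NULL
  })

  rrna_genes <- ann$gene_id[ann$biotype == "rRNA"]
  s16 <- calls[calls$gene_id %in% rrna_genes, , drop = FALSE]
  if (nrow(s16) > 0) s16 <- strict_16s_filter(s16)
  .write_tsv_prov(s16, file.path(cfg$out_dir, "sites_16s.tsv"), prov)

  invisible(list(gated_genomes = gated_all, calls = calls,
                 summaries = summaries, gc_comparison = gc_cmp,
                 sites_16s = s16, out_dir = cfg$out_dir))
}
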