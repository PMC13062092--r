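#' Read a per-base pileup count table
#'
#' Reads the tab-separated per-base count dialect produced by parsing
#' bam-readcount output: one row per reference position with the coverage
#' depth (reads spanning the position, deletion-carrying reads included) and
#' the number of reads carrying a deletion at the position. Plain and
#' gzip-compressed files are accepted.
#'
#' Required columns (declared in the header, any order, extra columns are
#' ignored): `contig`, `pos` (1-based), `ref` (A/C/G/T), `depth`, `del`.
#'
#' @param path Path to a TSV (optionally `.gz`).
#' @param sample_id Sample label attached to every record.
#' @param condition `"treated"` (BS-treated) or `"untreated"`.
#' @return A `data.frame` with columns `sample_id`, `condition`, `contig`,
#'   `pos`, `ref_base`, `depth`, `del_count`, sorted by (contig, pos).
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("contig\tpos\tref\tdepth\tdel", "chr1\t100\tT\t50\t3"), f)
#' read_pileup(f, "s1", "treated")
read_pileup <- function(path, sample_id, condition = c("treated", "untreated")) {
  condition <- match.arg(condition)
  if (!file.exists(path)) stop("pileup file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  required <- c("contig", "pos", "ref", "depth", "del")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("pileup format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), " in ", path)
  }
  if (nrow(raw) == 0) {
    return(data.frame(sample_id = character(), condition = character(),
                      contig = character(), pos = integer(),
                      ref_base = character(), depth = integer(),
                      del_count = integer(), stringsAsFactors = FALSE))
  }

  pos <- suppressWarnings(as.integer(raw$pos))
  depth <- suppressWarnings(as.integer(raw$depth))
  del <- suppressWarnings(as.integer(raw$del))
  bad <- which(is.na(pos) | is.na(depth) | is.na(del) |
                 !raw$ref %in% c("A", "C", "G", "T"))
  if (length(bad) > 0) {
    # +1 for the header line so numbers match the file as seen in an editor
    stop("pileup format error: malformed line(s) ",
         paste(utils::head(bad + 1L, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", " in ", path)
  }
  invalid <- which(del > depth | depth < 0 | del < 0 | pos < 1)
  if (length(invalid) > 0) {
    stop("pileup validation error: del_count > depth (or negative field) at ",
         paste(sprintf("%s:%d", raw$contig[invalid[1:min(5, length(invalid))]],
                       pos[invalid[1:min(5, length(invalid))]]),
               collapse = ", "),
         if (length(invalid) > 5) " ..." else "")
  }
  key <- paste(raw$contig, pos)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("pileup validation error: duplicate entry for position ", dup)
  }

  out <- data.frame(
    sample_id = sample_id, condition = condition,
    contig = raw$contig, pos = pos, ref_base = raw$ref,
    depth = depth, del_count = del, stringsAsFactors = FALSE
  )
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a pileup table to TSV
#'
#' Inverse of [read_pileup()]; used by the simulators.
#'
#' @param pileup Data frame as returned by [read_pileup()].
#' @param path Output path (`.gz` supported).
#' @return Invisibly, `path`.
#' @export
write_pileup <- function(pileup, path) {
  out <- data.frame(contig = pileup$contig, pos = pileup$pos,
                    ref = pileup$ref_base, depth = pileup$depth,
                    del = pileup$del_count, stringsAsFactors = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' Imports a GFF3 file and reduces it to the flat gene table the pipeline
#' needs: one row per feature with coordinates, strand and a coarse biotype
#' (`mRNA`, `tRNA`, `rRNA` or `other`). Features of type `gene`, `mRNA`,
#' `CDS`, `tRNA` and `rRNA` are considered; when a `gene` row and its child
#' share an ID the gene row wins.
#'
#' @param path GFF3 file (optionally `.gz`).
#' @return A `data.frame` with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`, `biotype`, `length_nt`.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("gene", "mRNA", "CDS", "tRNA", "rRNA")
  gr <- gr[keep]
  if (length(gr) == 0) stop("no gene-like features found in ", path)
  ids <- gr$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  alt <- if (!is.null(gr$gene_id)) gr$gene_id else if (!is.null(gr$Name)) gr$Name else NULL
  if (!is.null(alt)) ids[is.na(ids)] <- alt[is.na(ids)]
  ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
  type <- as.character(gr$type)
  biotype <- ifelse(type %in% c("gene", "mRNA", "CDS"), "mRNA",
                    ifelse(type == "tRNA", "tRNA",
                           ifelse(type == "rRNA", "rRNA", "other")))
  # a tRNA/rRNA child refines the biotype of an identically named gene row
  ann <- data.frame(
    gene_id = ids,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = biotype, stringsAsFactors = FALSE
  )
  pref <- c(rRNA = 1L, tRNA = 2L, mRNA = 3L, other = 4L)
  ann <- ann[order(ann$gene_id, pref[ann$biotype]), , drop = FALSE]
  ann <- ann[!duplicated(ann$gene_id), , drop = FALSE]
  ann$strand[!ann$strand %in% c("+", "-")] <- "+"
  ann$length_nt <- ann$end - ann$start + 1L
  rownames(ann) <- NULL
  ann
}

.load_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet")) {
    stop("genome must be a DNAStringSet or a FASTA path")
  }
  # FASTA headers often carry descriptions after the contig name
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Enumerate transcript-strand uridine positions
#'
#' Returns every genomic position whose transcribed-strand base is uridine:
#' a reference T inside a plus-strand gene or a reference A inside a
#' minus-strand gene. A position covered by overlapping opposite-strand genes
#' is reported once per gene.
#'
#' @param annotation Gene table from [read_gene_annotation()] (columns
#'   `gene_id`, `contig`, `start`, `end`, `strand` required).
#' @param genome A `Biostrings::DNAStringSet` or FASTA path.
#' @return A `data.frame` with columns `contig`, `pos`, `strand`, `gene_id`.
#' @export
transcript_uridine_sites <- function(annotation, genome) {
  genome <- .load_genome(genome)
  absent <- setdiff(unique(annotation$contig), names(genome))
  if (length(absent) > 0) {
    stop("contig(s) absent from FASTA: ", paste(absent, collapse = ", "))
  }
  res <- vector("list", nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    contig <- annotation$contig[i]
    s <- annotation$start[i]
    e <- min(annotation$end[i], length(genome[[contig]]))
    bases <- strsplit(as.character(Biostrings::subseq(genome[[contig]], s, e)),
                      "")[[1]]
    target <- if (annotation$strand[i] == "+") "T" else "A"
    hit <- which(bases == target)
    if (length(hit) == 0) next
    res[[i]] <- data.frame(
      contig = contig, pos = s + hit - 1L,
      strand = annotation$strand[i], gene_id = annotation$gene_id[i],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(contig = character(), pos = integer(),
                      strand = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$contig, out$pos, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Length of the maximal same-base run containing each position, computed per
# contig with run-length encoding. `base` is the genomic base whose run is a
# transcript-strand uridine homopolymer (T on +, A on -).
.homopolymer_run <- function(genome, contig, pos, base) {
  out <- integer(length(pos))
  for (ct in unique(contig)) {
    sel <- contig == ct
    chars <- strsplit(as.character(genome[[ct]]), "")[[1]]
    r <- rle(chars)
    run_idx <- rep(seq_along(r$lengths), r$lengths)
    idx <- run_idx[pos[sel]]
    len <- r$lengths[idx]
    len[r$values[idx] != base[sel]] <- 1L
    out[sel] <- len
  }
  out
}

#' Pair treated and untreated pileup counts at uridine positions
#'
#' Inner join of a treated and an untreated pileup on (contig, pos),
#' restricted to transcript-strand uridine positions, with the length of the
#' maximal transcript-strand U homopolymer run containing each site.
#' Positions present in only one condition are dropped and counted in a join
#' report stored in `attr(, "join_report")`.
#'
#' @param treated,untreated Pileup data frames from [read_pileup()].
#' @param uridine_sites Data frame from [transcript_uridine_sites()].
#' @param genome `DNAStringSet` or FASTA path (for homopolymer runs and
#'   transcript-base rendering).
#' @return A `data.frame` of site pairs with columns `contig`, `pos`,
#'   `strand`, `gene_id`, `transcript_base`, `homopolymer_run`,
#'   `treated_depth`, `treated_del`, `untreated_depth`, `untreated_del`,
#'   `sample_id`.
#' @export
pair_sites <- function(treated, untreated, uridine_sites, genome) {
  genome <- .load_genome(genome)
  stopifnot(all(treated$condition == "treated"),
            all(untreated$condition == "untreated"))

  tt <- treated[, c("contig", "pos", "ref_base", "depth", "del_count")]
  names(tt)[3:5] <- c("ref_base", "treated_depth", "treated_del")
  uu <- untreated[, c("contig", "pos", "depth", "del_count")]
  names(uu)[3:4] <- c("untreated_depth", "untreated_del")

  u <- merge(uridine_sites, tt, by = c("contig", "pos"), all.x = TRUE)
  u <- merge(u, uu, by = c("contig", "pos"), all.x = TRUE)
  in_t <- !is.na(u$treated_depth)
  in_u <- !is.na(u$untreated_depth)
  report <- list(
    n_pairs = sum(in_t & in_u),
    n_treated_only = sum(in_t & !in_u),
    n_untreated_only = sum(!in_t & in_u),
    n_uncovered = sum(!in_t & !in_u)
  )
  u <- u[in_t & in_u, , drop = FALSE]

  if (nrow(u) > 0) {
    # sanity: reference base must match the uridine-site expectation
    expect <- ifelse(u$strand == "+", "T", "A")
    mismatch <- u$ref_base != expect
    if (any(mismatch)) {
      stop("reference base in pileup disagrees with genome at ",
           paste(sprintf("%s:%d", u$contig[mismatch][1], u$pos[mismatch][1])),
           " (expected ", expect[mismatch][1], ", got ",
           u$ref_base[mismatch][1], ")")
    }
    u$transcript_base <- "U"
    u$homopolymer_run <- .homopolymer_run(genome, u$contig, u$pos,
                                          ifelse(u$strand == "+", "T", "A"))
  } else {
    u$transcript_base <- character(0)
    u$homopolymer_run <- integer(0)
  }
  sample_id <- unique(treated$sample_id)
  u$sample_id <- rep(if (length(sample_id) == 1) sample_id
                     else NA_character_, nrow(u))
  u <- u[order(u$contig, u$pos, u$gene_id),
         c("contig", "pos", "strand", "gene_id", "transcript_base",
           "homopolymer_run", "treated_depth", "treated_del",
           "untreated_depth", "untreated_del", "sample_id")]
  rownames(u) <- NULL
  attr(u, "join_report") <- report
  u
}

.call_columns <- c("contig", "pos", "strand", "gene_id", "psi_level",
                   "ratio_treated", "ratio_untreated", "treated_depth",
                   "treated_del", "untreated_depth", "untreated_del",
                   "homopolymer_flag", "sample_id")

#' Write calls as a BED-like table
#'
#' Writes calls with 0-based half-open coordinates in the first three
#' columns (`contig`, `start` = pos - 1, `end` = pos), then `gene_id`,
#' `psi_level` (score) and `strand`, followed by the supporting counts and
#' ratios. The file round-trips losslessly through [read_calls()].
#'
#' @param calls Data frame of calls from [call_sites()] or
#'   [call_sites_community()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_calls <- function(calls, path) {
  stopifnot(is.data.frame(calls))
  extra <- setdiff(names(calls), .call_columns)
  cols <- c(.call_columns, extra)
  header <- paste(c("#contig", "start", "end", "gene_id", "psi_level",
                    "strand", cols[!cols %in% c("contig", "pos", "gene_id",
                                                "psi_level", "strand")]),
                  collapse = "\t")
  fmt_num <- function(x) {
    if (is.double(x)) sprintf("%.17g", x) else as.character(x)
  }
  body <- character(0)
  if (nrow(calls) > 0) {
    rest <- cols[!cols %in% c("contig", "pos", "gene_id", "psi_level", "strand")]
    mat <- cbind(
      calls$contig, calls$pos - 1L, calls$pos, calls$gene_id,
      fmt_num(calls$psi_level), calls$strand,
      do.call(cbind, lapply(rest, function(cn) fmt_num(calls[[cn]])))
    )
    body <- apply(mat, 1, paste, collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read calls written by [write_calls()]
#'
#' @param path BED-like call file.
#' @return A `data.frame` with the same columns as the written call set
#'   (1-based `pos` reconstructed from the half-open interval).
#' @export
read_calls <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]  # provenance comments
  if (length(lines) == 0) stop("empty call file: ", path)
  header <- sub("^#", "", lines[1])
  cn <- strsplit(header, "\t")[[1]]
  if (length(lines) == 1) {
    out <- data.frame(contig = character(), pos = integer(),
                      strand = character(), gene_id = character(),
                      psi_level = numeric(), ratio_treated = numeric(),
                      ratio_untreated = numeric(), treated_depth = integer(),
                      treated_del = integer(), untreated_depth = integer(),
                      untreated_del = integer(), homopolymer_flag = logical(),
                      sample_id = character(), stringsAsFactors = FALSE)
    return(out)
  }
  tab <- utils::read.delim(text = lines[-1], header = FALSE, sep = "\t",
                           col.names = cn, stringsAsFactors = FALSE)
  tab$pos <- as.integer(tab$end)
  stopifnot(all(tab$start == tab$pos - 1L))
  tab$start <- NULL
  tab$end <- NULL
  if ("homopolymer_flag" %in% names(tab)) {
    tab$homopolymer_flag <- as.logical(tab$homopolymer_flag)
  }
  keep <- intersect(c(.call_columns,
                      setdiff(names(tab), .call_columns)), names(tab))
  tab <- tab[, keep, drop = FALSE]
  rownames(tab) <- NULL
  tab
}
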