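# Simulators generating inputs with the statistical structure the callers
# assume: binomial deletions at true sites over a background indel rate,
# condition-shared strain-heterogeneity indels for community mode, and
# Poisson decay counts with constant-input spike-ins. All are pure functions
# of (parameters, seed).

.random_genome <- function(length, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), length, replace = TRUE, prob = probs),
        collapse = "")
}

.draw_depth <- function(n, mean, dispersion = NULL) {
  if (is.null(dispersion)) rep(as.integer(mean), n)
  else stats::rnbinom(n, mu = mean, size = dispersion)
}

#' Simulate an isolate BS-treatment experiment
#'
#' Builds a random genome with annotated genes on both strands, plants true
#' pseudouridine sites at transcript-strand uridines, and draws paired
#' treated/untreated pileups for `n_samples` samples. At a true site with
#' stoichiometry `s` the treated deletion probability is
#' `s * conversion + bg_treated`; everywhere else it is the background rate,
#' and the untreated library uses `bg_untreated` throughout. Depth is fixed
#' at `depth_mean` or negative-binomially distributed when
#' `depth_dispersion` is given.
#'
#' The deletion ratio estimates `s * conversion`, not `s`: incomplete
#' chemical conversion is confounded with stoichiometry, as in the real
#' assay.
#'
#' @param n_genes,gene_length Gene layout (genes tiled with 10-nt spacers,
#'   alternating strands).
#' @param n_sites Number of true sites (sampled from transcript uridines).
#' @param stoichiometry Either a range `c(lo, hi)` to draw uniformly from,
#'   or one value per site.
#' @param conversion BS conversion efficiency in (0, 1].
#' @param bg_treated,bg_untreated Background deletion probabilities.
#' @param depth_mean,depth_dispersion Depth model (NULL dispersion = fixed).
#' @param n_samples Number of paired samples.
#' @param gc Genome GC fraction.
#' @param seed Random seed; the result is a deterministic function of the
#'   arguments and this seed.
#' @return A list: `genome` (`DNAStringSet`), `annotation`, `uridine_sites`,
#'   `truth` (one row per true site: `contig`, `pos`, `strand`, `gene_id`,
#'   `stoichiometry`, `expected_psi = stoichiometry * conversion`), and
#'   `samples`, a named list of `list(treated = , untreated = )` pileups.
#' @export
simulate_isolate <- function(n_genes = 20L, gene_length = 300L,
                             n_sites = 100L, stoichiometry = c(0.1, 0.8),
                             conversion = 0.9, bg_treated = 0.002,
                             bg_untreated = 0.002, depth_mean = 200,
                             depth_dispersion = NULL, n_samples = 2L,
                             gc = 0.5, seed = 1L) {
  stopifnot(conversion > 0, conversion <= 1)
  withr::with_seed(seed, {
    spacer <- 10L
    glen <- n_genes * (gene_length + spacer)
    genome <- Biostrings::DNAStringSet(
      structure(.random_genome(glen, gc), names = "sim_contig")
    )
    starts <- (seq_len(n_genes) - 1L) * (gene_length + spacer) + 1L
    annotation <- data.frame(
      gene_id = sprintf("gene%03d", seq_len(n_genes)),
      contig = "sim_contig", start = starts,
      end = starts + gene_length - 1L,
      strand = rep(c("+", "-"), length.out = n_genes),
      biotype = "mRNA", length_nt = gene_length, stringsAsFactors = FALSE
    )
    usites <- transcript_uridine_sites(annotation, genome)
    if (nrow(usites) < n_sites) {
      stop("parameter error: fewer transcript uridines (", nrow(usites),
           ") than requested sites (", n_sites, ")")
    }
    pick <- sort(sample(nrow(usites), n_sites))
    truth <- usites[pick, , drop = FALSE]
    s <- if (length(stoichiometry) == 2 && n_sites != 2) {
      stats::runif(n_sites, stoichiometry[1], stoichiometry[2])
    } else rep_len(stoichiometry, n_sites)
    truth$stoichiometry <- s
    truth$expected_psi <- s * conversion
    rownames(truth) <- NULL
    p_site <- s * conversion + bg_treated
    if (any(p_site > 1)) stop("parameter error: deletion probability > 1")

    ref <- strsplit(as.character(genome[[1]]), "")[[1]]
    p_treated <- rep(bg_treated, glen)
    p_treated[truth$pos] <- p_site

    samples <- lapply(seq_len(n_samples), function(i) {
      sid <- sprintf("sample%02d", i)
      make <- function(cond, pvec) {
        depth <- .draw_depth(glen, depth_mean, depth_dispersion)
        data.frame(
          sample_id = sid, condition = cond, contig = "sim_contig",
          pos = seq_len(glen), ref_base = ref, depth = depth,
          del_count = stats::rbinom(glen, depth, pvec),
          stringsAsFactors = FALSE
        )
      }
      list(treated = make("treated", p_treated),
           untreated = make("untreated", rep(bg_untreated, glen)))
    })
    names(samples) <- sprintf("sample%02d", seq_len(n_samples))

    list(genome = genome, annotation = annotation, uridine_sites = usites,
         truth = truth, samples = samples)
  })
}

#' Simulate a microbial-community BS-treatment experiment
#'
#' Each genome is one contig covered by a single plus-strand transcript,
#' with mean depth proportional to its relative abundance. True sites are
#' planted at uridines with rate `sites_per_kb(gc)` per kilobase. A fraction
#' of positions carry strain-heterogeneity indels: a condition-shared
#' deletion probability `eta` applied identically to treated and untreated
#' libraries — these model within-species genomic variation, not BS
#' chemistry, and are what the community filters must reject.
#'
#' @param genomes Data frame with `genome_id`, `length`, `gc_content`,
#'   `abundance` (abundances must sum to 1).
#' @param total_depth Community-wide mean depth; genome depth =
#'   `abundance * total_depth`.
#' @param sites_per_kb True-site density per Kb; either a number or a
#'   function of GC content (e.g. `function(gc) ifelse(gc >= 0.5, 1, 0.5)`).
#' @param eta Shared indel deletion probability at noisy positions.
#' @param noisy_fraction Fraction of positions that are heterogeneity sites.
#' @param stoichiometry,conversion,bg As in [simulate_isolate()].
#' @param n_samples Number of paired samples.
#' @param seed Random seed.
#' @return A list with `genomes` (input plus realized mean depths),
#'   `truth`, `noisy_sites`, `annotation`, `genome_seqs`, and `samples`
#'   (per sample: `treated` / `untreated` pileups carrying a `genome_id`
#'   column).
#' @export
simulate_community <- function(genomes, total_depth = 1000,
                               sites_per_kb = 0.5, eta = 0.01,
                               noisy_fraction = 0.05,
                               stoichiometry = c(0.1, 0.8),
                               conversion = 0.9, bg = 0.002,
                               n_samples = 1L, seed = 1L) {
  stopifnot(abs(sum(genomes$abundance) - 1) < 1e-8)
  rate_fun <- if (is.function(sites_per_kb)) sites_per_kb
              else function(gc) sites_per_kb
  withr::with_seed(seed, {
    seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(genomes)), function(i) {
      .random_genome(genomes$length[i], genomes$gc_content[i])
    }, character(1)))
    names(seqs) <- genomes$genome_id

    per_genome <- lapply(seq_len(nrow(genomes)), function(i) {
      gid <- genomes$genome_id[i]
      glen <- genomes$length[i]
      ref <- strsplit(as.character(seqs[[gid]]), "")[[1]]
      u_pos <- which(ref == "T")
      n_true <- min(stats::rpois(1, rate_fun(genomes$gc_content[i]) *
                                   glen / 1000), length(u_pos))
      true_pos <- sort(sample(u_pos, n_true))
      s <- stats::runif(n_true, stoichiometry[1], stoichiometry[2])
      noisy <- which(stats::runif(glen) < noisy_fraction)
      p_t <- rep(bg, glen)
      p_u <- rep(bg, glen)
      p_t[noisy] <- p_t[noisy] + eta
      p_u[noisy] <- p_u[noisy] + eta
      p_t[true_pos] <- p_t[true_pos] + s * conversion
      list(
        gid = gid, glen = glen, ref = ref,
        depth_mean = genomes$abundance[i] * total_depth,
        p_t = pmin(p_t, 1), p_u = pmin(p_u, 1),
        truth = data.frame(genome_id = rep(gid, n_true),
                           contig = rep(gid, n_true), pos = true_pos,
                           strand = rep("+", n_true),
                           gene_id = rep(paste0(gid, "_tx"), n_true),
                           stoichiometry = s, expected_psi = s * conversion,
                           stringsAsFactors = FALSE),
        noisy = data.frame(genome_id = rep(gid, length(noisy)),
                           contig = rep(gid, length(noisy)), pos = noisy,
                           eta = rep(eta, length(noisy)),
                           stringsAsFactors = FALSE)
      )
    })

    samples <- lapply(seq_len(n_samples), function(si) {
      sid <- sprintf("subject%02d", si)
      one_cond <- function(cond) {
        do.call(rbind, lapply(per_genome, function(g) {
          depth <- stats::rpois(g$glen, g$depth_mean)
          p <- if (cond == "treated") g$p_t else g$p_u
          data.frame(
            sample_id = sid, condition = cond, genome_id = g$gid,
            contig = g$gid, pos = seq_len(g$glen), ref_base = g$ref,
            depth = depth, del_count = stats::rbinom(g$glen, depth, p),
            stringsAsFactors = FALSE
          )
        }))
      }
      list(treated = one_cond("treated"), untreated = one_cond("untreated"))
    })
    names(samples) <- sprintf("subject%02d", seq_len(n_samples))

    annotation <- data.frame(
      gene_id = paste0(genomes$genome_id, "_tx"),
      contig = genomes$genome_id, start = 1L, end = genomes$length,
      strand = "+", biotype = "mRNA", length_nt = genomes$length,
      stringsAsFactors = FALSE
    )
    genomes$mean_depth <- genomes$abundance * total_depth
    list(
      genomes = genomes, genome_seqs = seqs, annotation = annotation,
      truth = do.call(rbind, lapply(per_genome, `[[`, "truth")),
      noisy_sites = do.call(rbind, lapply(per_genome, `[[`, "noisy")),
      samples = samples
    )
  })
}

#' Simulate a rifampicin decay time course with spike-ins
#'
#' Expected gene counts follow the delayed exponential
#' `A0 * 2^(-(t - t0)+ / half_life)` scaled by gene length, the
#' per-timepoint mRNA pool scaler and the sequencing-depth scaler; spike-in
#' expected counts are time-invariant biology (`level`) scaled by
#' sequencing depth only. Counts are Poisson draws, or exact expectations
#' with `noise = FALSE`.
#'
#' `pool_scalers` model drift of the mRNA pool relative to the constant
#' spike-in input (the quantity the ERCC `k` constant is designed to
#' recover); `depth_scalers` model per-library sequencing depth, which
#' cancels in `k` by construction.
#'
#' @param genes Data frame: `gene_id`, `length_nt`, `A0` (abundance units),
#'   `half_life` (minutes, may be `Inf` for a stable gene), `t0` (lag,
#'   minutes).
#' @param spikes Data frame: `spike_id` (must carry the `"ERCC-"` prefix for
#'   downstream recognition), `level` (expected counts at unit depth).
#' @param timepoints Minutes; must include 0.
#' @param pool_scalers,depth_scalers One value per timepoint (default 1).
#' @param depth Global depth multiplier.
#' @param noise Poisson noise (default) or exact expected counts.
#' @param seed Random seed.
#' @return A list: `counts` (genes + spikes by timepoints), `timepoints`,
#'   `genes`, `spikes`, `pool_scalers`, `depth_scalers`.
#' @export
simulate_rifseq <- function(genes, spikes, timepoints = c(0, 3, 6, 12, 24),
                            pool_scalers = 1, depth_scalers = 1, depth = 1,
                            noise = TRUE, seed = 1L) {
  stopifnot(all(genes$half_life > 0), 0 %in% timepoints)
  pool_scalers <- rep_len(pool_scalers, length(timepoints))
  depth_scalers <- rep_len(depth_scalers, length(timepoints))
  decay <- outer(seq_len(nrow(genes)), seq_along(timepoints),
                 function(i, j) {
                   2^(-pmax(timepoints[j] - genes$t0[i], 0) / genes$half_life[i])
                 })
  gene_mu <- genes$A0 * decay * (genes$length_nt / 1000)
  gene_mu <- sweep(gene_mu, 2, pool_scalers * depth_scalers * depth, "*")
  spike_mu <- outer(spikes$level, depth_scalers * depth)
  mu <- rbind(gene_mu, spike_mu)
  rownames(mu) <- c(genes$gene_id, spikes$spike_id)
  colnames(mu) <- paste0("t", timepoints)
  counts <- if (noise) {
    withr::with_seed(seed, matrix(stats::rpois(length(mu), mu), nrow(mu),
                                  dimnames = dimnames(mu)))
  } else mu
  list(counts = counts, timepoints = timepoints, genes = genes,
       spikes = spikes, pool_scalers = pool_scalers,
       depth_scalers = depth_scalers)
}

#' Write a simulated isolate experiment to disk
#'
#' Emits the genome FASTA, a GFF3 annotation, per-sample treated/untreated
#' pileup TSVs and the truth table, using the same coordinate conventions as
#' the call output so files diff directly.
#'
#' @param sim Result of [simulate_isolate()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  gff <- sprintf(
    "%s\tpsiscan_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
    sim$annotation$contig, sim$annotation$start, sim$annotation$end,
    sim$annotation$strand, sim$annotation$gene_id, sim$annotation$biotype
  )
  writeLines(c("##gff-version 3", gff), file.path(dir, "genes.gff3"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (sid in names(sim$samples)) {
    write_pileup(sim$samples[[sid]]$treated,
                 file.path(dir, paste0(sid, "_treated.tsv")))
    write_pileup(sim$samples[[sid]]$untreated,
                 file.path(dir, paste0(sid, "_untreated.tsv")))
  }
  invisible(dir)
}
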