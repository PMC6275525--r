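#' Simulation configuration
#'
#' Captures the stated world of the synthetic DamID experiment: a
#' fly-like reference scaled to a few megabases, two cell types (A and B)
#' each profiled with a PolII-Dam fusion and a Dam-only control, plus one
#' TF-Dam sample with planted binding peaks.
#'
#' Defaults: 3 x 2 Mb chromosomes; i.i.d. nucleotide background with an
#' extra Poisson 1 GATC/kb planted on top of the ~3.9/kb background
#' (~185 bp fragments); 2000 genes with log-normal spans (median 1.5 kb);
#' 15% of genes expressed per cell type with a +2 log2 occupancy shift;
#' 50 TF peaks of 5 fragments at +3 log2; negative-binomial counts with
#' mean depth 20 per fragment and dispersion 0.2.
#'
#' @param seed integer seed driving all randomness.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param motif_rate extra planted GATC motifs per kb (Poisson rate).
#' @param n_genes number of (non-overlapping) gene spans.
#' @param gene_meanlog,gene_sdlog log-normal gene-length parameters (bp).
#' @param expressed_fraction fraction of genes expressed per cell type.
#' @param delta log2 occupancy shift of expressed genes (default +2).
#' @param peak_count,peak_width,peak_height TF peaks: how many, width in
#'   fragments, log2 height (defaults 50, 5, +3).
#' @param depth negative-binomial mean reads per fragment (default 20).
#' @param dispersion negative-binomial dispersion (default 0.2; 0 =
#'   Poisson).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6),
                       motif_rate = 1,
                       n_genes = 2000L,
                       gene_meanlog = log(1500), gene_sdlog = 0.6,
                       expressed_fraction = 0.15,
                       delta = 2,
                       peak_count = 50L, peak_width = 5L, peak_height = 3,
                       depth = 20, dispersion = 0.2) {
  stopifnot(all(chrom_lengths > 0), motif_rate >= 0, n_genes >= 1,
            expressed_fraction > 0, expressed_fraction < 1,
            peak_count >= 0, peak_width >= 1)
  if (depth <= 0) stop("depth must be positive")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a reference genome and gene annotation
#'
#' The genome is i.i.d. uniform A/C/G/T with additional GATC motifs
#' planted as a Poisson process at `motif_rate` per kb. Gene spans are
#' log-normal lengths placed without overlap by splitting the leftover
#' intergenic space with a uniform stick-breaking draw, on random
#' strands. Fully reproducible from the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (a `DNAStringSet`) and `genes` (annotation
#'   `GRanges` with `gene_id`, `symbol`).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lens <- config$chrom_lengths
  seqs <- lapply(seq_along(lens), function(i) {
    len <- as.integer(lens[i])
    chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    n_extra <- stats::rpois(1, config$motif_rate * len / 1000)
    if (n_extra > 0 && len > 10) {
      # plant motifs without destroying or duplicating existing ones, so
      # planted and background counts stay exactly additive: a write at p
      # can only create a motif at p itself, and is rejected (and
      # resampled) when another motif start lies within 3 bp
      is_start <- logical(len)
      hits <- gregexpr("(?=GATC)", paste(chars, collapse = ""),
                       perl = TRUE)[[1]]
      if (hits[1] != -1) is_start[as.integer(hits)] <- TRUE
      planted <- 0L
      attempts <- 0L
      while (planted < n_extra && attempts < 100L * n_extra) {
        attempts <- attempts + 1L
        p <- sample.int(len - 3L, 1L)
        win <- max(1L, p - 3L):min(len, p + 3L)
        if (any(is_start[win])) next
        chars[p] <- "G"; chars[p + 1L] <- "A"
        chars[p + 2L] <- "T"; chars[p + 3L] <- "C"
        is_start[p] <- TRUE
        planted <- planted + 1L
      }
    }
    paste(chars, collapse = "")
  })
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(lens)

  # allocate genes to chromosomes proportionally to length
  n_per <- as.vector(stats::rmultinom(1, config$n_genes, lens / sum(lens)))
  genes <- data.table::rbindlist(lapply(seq_along(lens), function(i) {
    n <- n_per[i]
    if (n == 0) return(NULL)
    len <- as.integer(lens[i])
    glen <- pmax(200L, pmin(as.integer(round(
      stats::rlnorm(n, config$gene_meanlog, config$gene_sdlog))),
      as.integer(len %/% 10)))
    if (sum(glen) > 0.9 * len)
      stop("genome too small for requested gene count/length on ",
           names(lens)[i])
    gap_total <- len - sum(glen)
    gaps <- floor(gap_total * diff(c(0, sort(stats::runif(n)), 1)))
    starts <- cumsum(gaps[seq_len(n)] + c(0L, glen[-n])) + 1L
    data.table::data.table(chrom = names(lens)[i], start = starts,
                           end = starts + glen - 1L)
  }))
  data.table::setorder(genes, chrom, start)
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = sample(c("+", "-"), nrow(genes), replace = TRUE),
    seqinfo = GenomeInfoDb::Seqinfo(names(lens), as.integer(lens)))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  gr$gene_id <- sprintf("gene%05d", seq_along(gr))
  gr$symbol <- gr$gene_id
  list(genome = genome, genes = gr)
}

#' Simulate DamID fragment counts with planted ground truth
#'
#' Builds the GATC fragment map of the simulated genome and draws
#' negative-binomial per-fragment counts for six samples: Dam-only and
#' PolII-Dam for cell types A and B, Dam-only and TF-Dam for the TF
#' profile. The latent log2 occupancy surface is 0 at baseline, +delta on
#' the fragments of each cell type's expressed genes and +peak_height on
#' planted peak fragments; occupancy acts multiplicatively on the fusion
#' sample's mean only (Dam-only is flat accessibility). Truth (expressed
#' gene sets, peak intervals, latent surfaces) is emitted alongside and
#' does not depend on depth.
#'
#' @param reference output of [simulate_reference()].
#' @param config the same [sim_config()].
#' @return list with `map`, `assignment`, `samples` (named list of
#'   `fragment_counts`: `Dam_A`, `PolII_A`, `Dam_B`, `PolII_B`, `Dam_TF`,
#'   `TF`) and `truth` (list: `expressed_A`, `expressed_B`, `peaks`
#'   `GRanges`, `lambda` list of latent surfaces).
#' @export
simulate_damid_counts <- function(reference, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$depth <= 0) stop("depth must be positive")
  set.seed(config$seed + 1000003L)
  map <- build_gatc_map(reference$genome)
  genes <- reference$genes
  assignment <- assign_fragments_to_genes(map, genes)
  nfrag <- length(map)

  pick_expressed <- function() {
    scorable <- setdiff(genes$gene_id, assignment$unscorable)
    sort(sample(scorable, round(config$expressed_fraction *
                                  length(scorable))))
  }
  expressed_A <- pick_expressed()
  expressed_B <- pick_expressed()

  lambda_cells <- function(expr_ids) {
    lam <- numeric(nfrag)
    idx <- unique(unlist(assignment$fragments[expr_ids], use.names = FALSE))
    lam[idx] <- config$delta
    lam
  }
  lambda_A <- lambda_cells(expressed_A)
  lambda_B <- lambda_cells(expressed_B)

  # plant non-overlapping runs of peak_width consecutive internal fragments
  lambda_TF <- numeric(nfrag)
  internal <- which(!map$terminal)
  chrom_i <- as.character(GenomeInfoDb::seqnames(map))[internal]
  peak_rows <- list()
  if (config$peak_count > 0) {
    used <- logical(length(internal))
    # candidate run starts: peak_width consecutive internal frags, one chrom
    ok_start <- seq_len(length(internal) - config$peak_width + 1L)
    ok_start <- ok_start[chrom_i[ok_start] ==
                           chrom_i[ok_start + config$peak_width - 1L]]
    ok_start <- ok_start[vapply(ok_start, function(s)
      all(diff(internal[s:(s + config$peak_width - 1L)]) == 1L),
      logical(1))]
    placed <- 0L
    for (s in sample(ok_start)) {
      run <- s:(s + config$peak_width - 1L)
      if (any(used[run])) next
      used[run] <- TRUE
      lambda_TF[internal[run]] <- config$peak_height
      peak_rows[[length(peak_rows) + 1L]] <- internal[run]
      placed <- placed + 1L
      if (placed == config$peak_count) break
    }
    if (placed < config$peak_count)
      warning("placed only ", placed, " of ", config$peak_count, " peaks")
  }
  peaks <- if (length(peak_rows)) {
    gr <- GenomicRanges::GRanges(
      as.character(GenomeInfoDb::seqnames(map))[vapply(peak_rows, `[`,
                                                       integer(1), 1L)],
      IRanges::IRanges(
        BiocGenerics::start(map)[vapply(peak_rows, `[`, integer(1), 1L)],
        BiocGenerics::end(map)[vapply(peak_rows, function(x)
          x[length(x)], integer(1))]),
      seqinfo = GenomeInfoDb::seqinfo(map))
    GenomicRanges::sort(gr, ignore.strand = TRUE)
  } else {
    GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(map))
  }

  draw <- function(mu) {
    if (config$dispersion == 0) stats::rpois(nfrag, mu)
    else stats::rnbinom(nfrag, size = 1 / config$dispersion, mu = mu)
  }
  d <- config$depth
  samples <- list(
    Dam_A = fragment_counts(draw(rep(d, nfrag)), "Dam_A"),
    PolII_A = fragment_counts(draw(d * 2^lambda_A), "PolII_A"),
    Dam_B = fragment_counts(draw(rep(d, nfrag)), "Dam_B"),
    PolII_B = fragment_counts(draw(d * 2^lambda_B), "PolII_B"),
    Dam_TF = fragment_counts(draw(rep(d, nfrag)), "Dam_TF"),
    TF = fragment_counts(draw(d * 2^lambda_TF), "TF"))

  list(map = map, assignment = assignment, samples = samples,
       truth = list(expressed_A = expressed_A, expressed_B = expressed_B,
                    peaks = peaks,
                    lambda = list(A = lambda_A, B = lambda_B,
                                  TF = lambda_TF)))
}

#' Write all simulation outputs to a directory with a manifest
#'
#' Emits FASTA, GFF3, the fragment BED, per-sample count TSVs and truth
#' TSVs, plus `manifest.json` recording the seed and every file written.
#'
#' @param reference output of [simulate_reference()].
#' @param sim output of [simulate_damid_counts()].
#' @param config the [sim_config()] used.
#' @param out_dir output directory (created if needed).
#' @return the manifest as a list, invisibly.
#' @export
write_simulation <- function(reference, sim, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  Biostrings::writeXStringSet(reference$genome, fp("genome.fa"))
  write_gene_models(reference$genes, fp("genes.gff3"))
  write_fragment_bed(sim$map, fp("fragments.bed"))
  files <- c("genome.fa", "genes.gff3", "fragments.bed")
  for (nm in names(sim$samples)) {
    f <- sprintf("counts_%s.tsv", nm)
    write_counts_tsv(sim$samples[[nm]], fp(f))
    files <- c(files, f)
  }
  data.table::fwrite(
    data.table::data.table(gene_id = sim$truth$expressed_A),
    fp("truth_expressed_A.tsv"), sep = "\t")
  data.table::fwrite(
    data.table::data.table(gene_id = sim$truth$expressed_B),
    fp("truth_expressed_B.tsv"), sep = "\t")
  pk <- sim$truth$peaks
  data.table::fwrite(
    data.table::data.table(
      chrom = as.character(GenomeInfoDb::seqnames(pk)),
      start = BiocGenerics::start(pk) - 1L,
      end = BiocGenerics::end(pk)),
    fp("truth_peaks.bed"), sep = "\t", col.names = FALSE)
  files <- c(files, "truth_expressed_A.tsv", "truth_expressed_B.tsv",
             "truth_peaks.bed")
  manifest <- list(seed = config$seed, files = as.list(files))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
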