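#' Pipeline run configuration
#'
#' Collects input paths and parameters for [run_pipeline()]. Sample
#' tracks are fusion/control pairs; inputs may be aligned reads (BED6 or
#' BAM) or precomputed per-fragment count TSVs (`fragment_id`, `count`).
#' Tracks named in `polII_tracks` are scored at gene level; tracks in
#' `tf_tracks` go through peak calling.
#'
#' @param genome path to the genome FASTA.
#' @param gff path to the gene-model GFF3.
#' @param tracks named list; each element a list with `fusion` and
#'   `control` paths.
#' @param out_dir output directory; every output lands beneath it.
#' @param polII_tracks,tf_tracks names of `tracks` treated as PolII
#'   profiles / TF binding profiles (defaults: all but "TF" / "TF").
#' @param pseudocount,theta,M,M_peaks,fold_min,seed analysis parameters
#'   (see the stage functions).
#' @param tf_list optional path to a 1-column TSV of TF gene ids.
#' @param external optional path to a 2-column TSV (`gene_id`, `value`)
#'   of external expression for [rank_correlation()].
#' @param curated optional path to a 1-column TSV of curated gene ids for
#'   [candidate_report()].
#' @return a `run_config` list.
#' @export
run_config <- function(genome, gff, tracks, out_dir,
                       polII_tracks = NULL, tf_tracks = NULL,
                       pseudocount = 0.5, theta = 0.01, M = 1000,
                       M_peaks = 100, fold_min = 2, seed = 1L,
                       tf_list = NULL, external = NULL, curated = NULL) {
  stopifnot(theta > 0, theta < 1)
  if (is.null(tf_tracks)) tf_tracks <- intersect("TF", names(tracks))
  if (is.null(polII_tracks))
    polII_tracks <- setdiff(names(tracks), tf_tracks)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from a JSON file
#' @param path JSON file whose keys mirror the [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$tracks <- lapply(cfg$tracks, as.list)
  do.call(run_config, cfg)
}

#' Run the DamID analysis pipeline
#'
#' Executes, in order, the selected stages: `fragments` (GATC map),
#' `count` (reads -> per-fragment counts), `track` (normalized log2
#' occupancy), `genecall` (gene scores, permutation FDR, specificity),
#' `peakcall` (TF peaks and targets), `integrate` (set overlaps, TF
#' ranking, candidate report). Each stage reads its inputs from the
#' output directory, so a later stage can be re-run alone provided its
#' upstream intermediates exist (a missing one raises an error naming
#' the stage to rerun). A `manifest.json` with parameters, seed and md5
#' checksums of every output is rewritten at the end; identical config
#' and seed give identical checksums.
#'
#' @param config a [run_config()] (or path to a JSON config).
#' @param stages character vector of stages to run (default: all).
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("fragments", "count", "track",
                                    "genecall", "peakcall", "integrate"),
                         quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("fragments", "count", "track", "genecall", "peakcall",
                  "integrate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out, ...)
  say <- function(stage, fmt, ...) {
    if (!quiet)
      message(sprintf("[%s] %s (%.1fs)", stage, sprintf(fmt, ...),
                      as.numeric(proc.time()[3] - t0)))
  }
  t0 <- proc.time()[3]
  need <- function(path, stage) {
    if (!file.exists(path))
      stop("missing intermediate ", path, "; rerun stage '", stage, "'")
    path
  }
  get_map <- function() read_fragment_bed(need(fp("fragments.bed"),
                                               "fragments"))

  if ("fragments" %in% stages) {
    map <- build_gatc_map(read_genome(config$genome))
    write_fragment_bed(map, fp("fragments.bed"))
    say("fragments", "%d fragments", length(map))
  }

  if ("count" %in% stages) {
    map <- get_map()
    for (nm in names(config$tracks)) {
      for (role in c("fusion", "control")) {
        src <- config$tracks[[nm]][[role]]
        dst <- fp(sprintf("counts_%s_%s.tsv", nm, role))
        if (grepl("\\.(tsv|txt|csv)$", src, ignore.case = TRUE)) {
          fc <- read_counts_tsv(src, sprintf("%s_%s", nm, role))
        } else {
          fc <- count_reads_per_fragment(read_alignments(src), map,
                                         sprintf("%s_%s", nm, role))
        }
        if (length(fc$counts) != length(map))
          stop("counts for ", nm, "/", role,
               " are not aligned to the fragment map")
        write_counts_tsv(fc, dst)
      }
    }
    say("count", "%d sample pairs", length(config$tracks))
  }

  if ("track" %in% stages) {
    map <- get_map()
    for (nm in names(config$tracks)) {
      fus <- read_counts_tsv(need(fp(sprintf("counts_%s_fusion.tsv", nm)),
                                  "count"))
      ctl <- read_counts_tsv(need(fp(sprintf("counts_%s_control.tsv", nm)),
                                  "count"))
      tr <- compute_occupancy_track(fus, ctl, map, config$pseudocount)
      write_track_bedgraph(tr, fp(sprintf("track_%s.bedgraph", nm)))
    }
    say("track", "psi = %g", config$pseudocount)
  }

  if ("genecall" %in% stages) {
    map <- get_map()
    genes <- load_gene_models(config$gff,
                              GenomeInfoDb::seqlevels(map))
    assignment <- assign_fragments_to_genes(map, genes)
    calls <- list()
    for (nm in config$polII_tracks) {
      tr <- read_track_bedgraph(need(fp(sprintf("track_%s.bedgraph", nm)),
                                     "track"), map)
      sc <- score_gene_occupancy(tr, assignment)
      calls[[nm]] <- call_expressed_genes(sc, tr, theta = config$theta,
                                          M = config$M, seed = config$seed)
      write_gene_calls(calls[[nm]], fp(sprintf("genecalls_%s.tsv", nm)),
                       genes)
    }
    if (length(config$polII_tracks) >= 2) {
      ab <- config$polII_tracks[1:2]
      spec <- compare_cell_types(calls[[ab[1]]], calls[[ab[2]]],
                                 theta = config$theta,
                                 fold_min = config$fold_min)
      data.table::fwrite(spec, fp("specificity.tsv"), sep = "\t")
    }
    say("genecall", "%d tracks, M = %d", length(config$polII_tracks),
        config$M)
  }

  if ("peakcall" %in% stages && length(config$tf_tracks)) {
    map <- get_map()
    genes <- load_gene_models(config$gff, GenomeInfoDb::seqlevels(map))
    for (nm in config$tf_tracks) {
      tr <- read_track_bedgraph(need(fp(sprintf("track_%s.bedgraph", nm)),
                                     "track"), map)
      peaks <- call_binding_peaks(tr, theta = config$theta,
                                  M = config$M_peaks, seed = config$seed)
      write_peaks_bed(peaks, fp(sprintf("peaks_%s.bed", nm)))
      targets <- assign_peak_targets(peaks, genes, nm)
      write_targets_tsv(targets, fp(sprintf("targets_%s.tsv", nm)))
      say("peakcall", "%s: %d peaks, %d targets", nm, length(peaks),
          length(targets$genes))
    }
  }

  if ("integrate" %in% stages) {
    sets <- list()
    for (nm in config$polII_tracks) {
      gc <- data.table::fread(need(fp(sprintf("genecalls_%s.tsv", nm)),
                                   "genecall"))
      sets[[paste0("expressed_", nm)]] <- gc[expressed == TRUE, gene_id]
    }
    for (nm in config$tf_tracks) {
      f <- fp(sprintf("targets_%s.tsv", nm))
      if (file.exists(f)) {
        tg <- data.table::fread(f)
        sets[[paste0("targets_", nm)]] <- tg$gene_id
      }
    }
    if (length(sets) >= 2) {
      vc <- venn_counts(sets[seq_len(min(4, length(sets)))])
      data.table::fwrite(vc$regions, fp("venn_regions.tsv"), sep = "\t")
      data.table::fwrite(vc$pairwise, fp("venn_pairwise.tsv"), sep = "\t")
    }
    if (!is.null(config$tf_list) && file.exists(fp("specificity.tsv"))) {
      spec <- data.table::fread(fp("specificity.tsv"))
      tfs <- data.table::fread(config$tf_list, header = TRUE)[[1]]
      data.table::fwrite(
        rank_specific_tfs(spec, tfs, config$fold_min),
        fp("tf_ranking.tsv"), sep = "\t")
    }
    say("integrate", "%d gene sets", length(sets))
  }

  outputs <- sort(setdiff(list.files(out), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("damidcall")),
    seed = config$seed,
    parameters = list(pseudocount = config$pseudocount,
                      theta = config$theta, M = config$M,
                      M_peaks = config$M_peaks, fold_min = config$fold_min),
    outputs = as.list(stats::setNames(
      as.vector(tools::md5sum(file.path(out, outputs))), outputs)))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
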