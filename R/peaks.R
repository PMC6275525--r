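#' Call significant binding peaks from an occupancy track
#'
#' Candidate peaks are maximal runs of at least `min_run` consecutive
#' internal fragments whose occupancy exceeds the track's 95th percentile
#' (computed over internal fragments). Each candidate is scored
#' s = (mean occupancy over the run) x (run length in fragments). The
#' null is obtained by permuting the per-fragment values within each
#' chromosome M times and re-extracting candidates identically
#' (within-chromosome permutation preserves the value distribution but
#' destroys positional clustering). For a score s the empirical FDR is
#' the mean null candidate count with score >= s divided by the observed
#' count with score >= s; q-values are the monotonized (non-increasing in
#' s) minima of that ratio over all thresholds at or below s. Peaks with
#' q < theta are kept.
#'
#' @param track an `occupancy_track`.
#' @param theta peak FDR threshold in (0,1), default 0.01.
#' @param M number of shuffles, >= 100 advised (default 100).
#' @param seed integer seed for the shuffles.
#' @param min_run minimum run length in fragments (default 2).
#' @param prob exceedance quantile defining candidates (default 0.95).
#' @return a [GenomicRanges::GRanges] of non-overlapping peaks with
#'   metadata `peak_id`, `score`, `q`, `n_fragments`, `frag_from`,
#'   `frag_to` (fragment-id bounds), sorted by position.
#' @export
call_binding_peaks <- function(track, theta = 0.01, M = 100, seed = NULL,
                               min_run = 2L, prob = 0.95) {
  stopifnot(methods::is(track, "occupancy_track"), theta > 0, theta < 1,
            M >= 1)
  if (!is.null(seed)) set.seed(seed)
  map <- track$map
  internal <- !map$terminal
  chrom <- as.character(GenomeInfoDb::seqnames(map))
  by_chrom <- split(which(internal), chrom[internal])
  by_chrom <- by_chrom[lengths(by_chrom) >= min_run]
  empty <- GenomicRanges::GRanges(
    peak_id = character(), score = numeric(), q = numeric(),
    n_fragments = integer(), frag_from = integer(), frag_to = integer(),
    seqinfo = GenomeInfoDb::seqinfo(map))
  if (length(by_chrom) == 0L) {
    warning("no chromosome has >= ", min_run, " internal fragments")
    return(empty)
  }
  thr <- stats::quantile(track$values[internal], prob, names = FALSE)

  extract <- function(vals_by_chrom) {
    # returns list(score=..., first=..., len=...) of candidate runs per chrom
    lapply(vals_by_chrom, function(v) {
      rl <- rle(v > thr)
      ends <- cumsum(rl$lengths)
      keep <- rl$values & rl$lengths >= min_run
      first <- (ends - rl$lengths + 1L)[keep]
      len <- rl$lengths[keep]
      score <- vapply(seq_along(first), function(k)
        mean(v[first[k]:(first[k] + len[k] - 1L)]) * len[k], numeric(1))
      list(first = first, len = len, score = score)
    })
  }

  obs_vals <- lapply(by_chrom, function(idx) track$values[idx])
  obs <- extract(obs_vals)
  obs_scores <- unlist(lapply(obs, `[[`, "score"), use.names = FALSE)
  if (length(obs_scores) == 0L) return(empty)

  null_scores <- vector("list", M)
  for (j in seq_len(M)) {
    perm <- lapply(obs_vals, sample)
    null_scores[[j]] <- unlist(lapply(extract(perm), `[[`, "score"),
                               use.names = FALSE)
  }
  null_all <- sort(unlist(null_scores, use.names = FALSE))

  ord <- order(obs_scores, decreasing = TRUE)
  s_desc <- obs_scores[ord]
  null_ge <- (length(null_all) -
                findInterval(s_desc - 1e-12, null_all)) / M
  obs_ge <- seq_along(s_desc)
  raw <- null_ge / obs_ge
  q_desc <- rev(cummin(rev(raw)))       # min over thresholds <= s
  q <- numeric(length(obs_scores))
  q[ord] <- q_desc

  rows <- data.table::rbindlist(lapply(names(obs), function(ch) {
    o <- obs[[ch]]
    if (length(o$first) == 0L) return(NULL)
    idx <- by_chrom[[ch]]
    data.table::data.table(
      chrom = ch,
      frag_from = map$fragment_id[idx[o$first]],
      frag_to = map$fragment_id[idx[o$first + o$len - 1L]],
      n_fragments = o$len, score = o$score)
  }))
  rows[, q := q]
  rows <- rows[q < theta]
  if (nrow(rows) == 0L) return(empty)
  peaks <- GenomicRanges::GRanges(
    rows$chrom,
    IRanges::IRanges(BiocGenerics::start(map)[rows$frag_from],
                     BiocGenerics::end(map)[rows$frag_to]),
    seqinfo = GenomeInfoDb::seqinfo(map))
  peaks$score <- rows$score
  peaks$q <- rows$q
  peaks$n_fragments <- rows$n_fragments
  peaks$frag_from <- rows$frag_from
  peaks$frag_to <- rows$frag_to
  peaks <- GenomicRanges::sort(peaks, ignore.strand = TRUE)
  peaks$peak_id <- sprintf("peak%04d", seq_along(peaks))
  peaks
}

#' Assign target genes to binding peaks
#'
#' A gene is a target of the profiled TF when at least one significant
#' peak overlaps its gene body by >= 1 bp; the supporting peak ids are
#' recorded per gene.
#'
#' @param peaks peak `GRanges` from [call_binding_peaks()].
#' @param genes annotation `GRanges` with `gene_id`.
#' @param tf name of the profiled factor.
#' @return an object of class `target_gene_set`: list with `tf`, `genes`
#'   (character vector of target gene ids, sorted) and `support` (named
#'   list gene id -> supporting peak ids).
#' @export
assign_peak_targets <- function(peaks, genes, tf = "TF") {
  stopifnot(methods::is(genes, "GRanges"))
  hits <- GenomicRanges::findOverlaps(peaks, genes, minoverlap = 1L,
                                      ignore.strand = TRUE)
  support <- split(peaks$peak_id[S4Vectors::queryHits(hits)],
                   genes$gene_id[S4Vectors::subjectHits(hits)])
  structure(list(tf = tf, genes = sort(names(support)),
                 support = support[sort(names(support))]),
            class = "target_gene_set")
}

#' @export
print.target_gene_set <- function(x, ...) {
  cat(sprintf("target_gene_set '%s': %d target genes\n", x$tf,
              length(x$genes)))
  invisible(x)
}

#' Write peaks as BED6+1 (chrom, start, end, name, score, strand, q)
#' @param peaks peak `GRanges`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(peaks)),
    start = BiocGenerics::start(peaks) - 1L,
    end = BiocGenerics::end(peaks),
    name = if (length(peaks)) peaks$peak_id else character(),
    score = if (length(peaks)) round(peaks$score, 6) else numeric(),
    strand = rep(".", length(peaks)),
    q = if (length(peaks)) signif(peaks$q, 6) else numeric())
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a target gene set as TSV (tf, gene_id, peak_ids)
#' @param targets a `target_gene_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_targets_tsv <- function(targets, path) {
  dt <- data.table::data.table(
    tf = targets$tf, gene_id = targets$genes,
    peak_ids = vapply(targets$support, paste, character(1), collapse = ","))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
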