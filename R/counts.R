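#' Read aligned read intervals from BED6 or BAM
#'
#' @param path a BED6 file of read intervals or a coordinate BAM file.
#' @return a [GenomicRanges::GRanges] of read alignments with strand.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    GenomicRanges::granges(GenomicAlignments::readGAlignments(path))
  } else {
    rtracklayer::import(path, format = "BED")
  }
}

#' Count reads per GATC fragment
#'
#' Each read is assigned to exactly one fragment: the fragment containing
#' its 5' end (the alignment start on the + strand, the last aligned base
#' on the - strand; unstranded reads use the start). Reads on chromosomes
#' absent from the map are dropped and counted in the `dropped` field.
#'
#' @param reads a `GRanges` of read intervals (see [read_alignments()]).
#' @param map fragment map from [build_gatc_map()].
#' @param sample_id label stored with the counts.
#' @return an object of class `fragment_counts`: list with `sample_id`,
#'   integer `counts` aligned to map order, `library_size`
#'   (= sum of counts) and `dropped`.
#' @export
count_reads_per_fragment <- function(reads, map, sample_id = "sample") {
  stopifnot(methods::is(map, "GRanges"))
  if (length(reads) == 0L) {
    warning("empty read set for sample ", sample_id)
    return(fragment_counts(integer(length(map)), sample_id, dropped = 0L))
  }
  known <- as.character(GenomeInfoDb::seqnames(reads)) %in%
    GenomeInfoDb::seqlevels(map)
  dropped <- sum(!known)
  reads <- reads[known]
  str <- as.character(BiocGenerics::strand(reads))
  pos <- ifelse(str == "-", BiocGenerics::end(reads),
                BiocGenerics::start(reads))
  p5 <- GenomicRanges::GRanges(
    as.character(GenomeInfoDb::seqnames(reads)),
    IRanges::IRanges(pos, width = 1L),
    seqinfo = GenomeInfoDb::seqinfo(map))
  hit <- GenomicRanges::findOverlaps(p5, map, select = "first")
  dropped <- dropped + sum(is.na(hit))
  idx <- map$fragment_id[hit[!is.na(hit)]]
  counts <- tabulate(idx, nbins = length(map))
  fragment_counts(counts, sample_id, dropped = dropped)
}

#' Construct a fragment_counts object from a raw count vector
#'
#' @param counts non-negative integer vector aligned to fragment map order.
#' @param sample_id sample label.
#' @param dropped number of reads discarded during assignment.
#' @return a `fragment_counts` object.
#' @export
fragment_counts <- function(counts, sample_id = "sample", dropped = 0L) {
  counts <- as.integer(round(counts))
  if (any(counts < 0)) stop("negative fragment counts in ", sample_id)
  structure(
    list(sample_id = sample_id, counts = counts,
         library_size = sum(counts), dropped = as.integer(dropped)),
    class = "fragment_counts")
}

#' @export
print.fragment_counts <- function(x, ...) {
  cat(sprintf("fragment_counts '%s': %d fragments, library size %d (%d dropped)\n",
              x$sample_id, length(x$counts), x$library_size, x$dropped))
  invisible(x)
}

#' Write fragment counts as TSV (fragment_id, count)
#' @param x a `fragment_counts` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(x, path) {
  data.table::fwrite(
    data.table::data.table(fragment_id = seq_along(x$counts),
                           count = x$counts),
    path, sep = "\t")
  invisible(path)
}

#' Read fragment counts written by [write_counts_tsv()]
#' @param path TSV file.
#' @param sample_id sample label (defaults to the file stem).
#' @return a `fragment_counts` object.
#' @export
read_counts_tsv <- function(path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]+$", "", basename(path))
  dt <- data.table::fread(path)
  fragment_counts(dt$count[order(dt$fragment_id)], sample_id)
}
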