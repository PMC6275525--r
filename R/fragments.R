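#' Read a genome from FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that upper-cases
#' residues and validates the alphabet (A, C, G, T and N only; anything
#' else is rejected).
#'
#' @param path path to a (multi-record, possibly line-wrapped) FASTA file.
#' @return a named [Biostrings::DNAStringSet], one entry per chromosome.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  as_genome(genome)
}

#' @keywords internal
as_genome <- function(genome) {
  if (is.character(genome))
    genome <- tryCatch(Biostrings::DNAStringSet(toupper(genome)),
                       error = function(e)
                         stop("non-DNA characters (other than N) in genome: ",
                              conditionMessage(e), call. = FALSE))
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("genome sequences must carry unique chromosome names")
  freq <- Biostrings::alphabetFrequency(genome)
  bad <- rowSums(freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"),
                      drop = FALSE])
  if (any(bad > 0))
    stop("non-DNA characters (other than N) in sequence(s): ",
         paste(names(genome)[bad > 0], collapse = ", "))
  genome
}

#' Build the GATC fragment map of a genome
#'
#' DamID signal is resolved on GATC fragments: the intervals between
#' adjacent DpnI cleavage points. Every exact GATC occurrence on the
#' forward strand (the motif is its own reverse complement, so one strand
#' suffices) contributes a cut point two bases into the motif (GA^TC).
#' Consecutive cut points bound internal fragments; the leading and
#' trailing intervals of each chromosome are flagged `terminal` because
#' their lengths are artifacts of assembly ends, and are excluded from all
#' downstream scoring by default. A chromosome with no motif yields a
#' single terminal fragment spanning it entirely. N inside a motif never
#' matches.
#'
#' @param genome a [Biostrings::DNAStringSet], a named character vector of
#'   sequences, or a path to a FASTA file.
#' @return a [GenomicRanges::GRanges] tiling the genome, sorted, with
#'   metadata columns `fragment_id` (integer, map order) and `terminal`
#'   (logical).
#' @examples
#' map <- build_gatc_map(c(chr = "TTGATCAAAGATCCCGATCG"))
#' # fragments [0,4) [4,11) [11,17) [17,20) in 0-based half-open terms
#' @export
build_gatc_map <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_genome(genome)
  genome <- as_genome(genome)
  per_chrom <- lapply(seq_along(genome), function(i) {
    len <- Biostrings::width(genome)[i]
    m <- Biostrings::matchPattern("GATC", genome[[i]], fixed = TRUE)
    cuts <- BiocGenerics::start(m) + 1L        # 1-based last base before cut
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, len)
    keep <- starts <= ends                     # guard: cut at sequence end
    starts <- starts[keep]; ends <- ends[keep]
    nf <- length(starts)
    GenomicRanges::GRanges(
      names(genome)[i], IRanges::IRanges(starts, ends),
      terminal = seq_len(nf) %in% c(1L, nf)
    )
  })
  map <- suppressWarnings(do.call(c, per_chrom))
  GenomeInfoDb::seqlevels(map) <- names(genome)
  GenomeInfoDb::seqlengths(map) <- Biostrings::width(genome)
  map <- GenomicRanges::sort(map, ignore.strand = TRUE)
  map$fragment_id <- seq_along(map)
  map
}

#' Assign GATC fragments to gene bodies
#'
#' A fragment is assigned to a gene when the two intervals overlap by at
#' least one base; a fragment may belong to several genes and assignment
#' ignores gene strand. Terminal fragments are excluded unless
#' `include_terminal = TRUE`. Genes receiving no fragment are reported as
#' unscorable rather than silently dropped.
#'
#' @param map fragment map from [build_gatc_map()].
#' @param genes a [GenomicRanges::GRanges] of gene spans with a `gene_id`
#'   metadata column (see [load_gene_models()]).
#' @param include_terminal score terminal fragments too (default `FALSE`).
#' @return an object of class `fragment_assignment`: a list with
#'   `fragments` (named list, gene id -> integer vector of `fragment_id`),
#'   and `unscorable` (character vector of gene ids with no fragment).
#' @export
assign_fragments_to_genes <- function(map, genes, include_terminal = FALSE) {
  stopifnot(methods::is(map, "GRanges"), methods::is(genes, "GRanges"))
  if (is.null(genes$gene_id)) stop("`genes` must carry a gene_id column")
  pool <- if (include_terminal) map else map[!map$terminal]
  hits <- GenomicRanges::findOverlaps(pool, genes, minoverlap = 1L,
                                      ignore.strand = TRUE)
  frag_ids <- split(pool$fragment_id[S4Vectors::queryHits(hits)],
                    genes$gene_id[S4Vectors::subjectHits(hits)])
  frag_ids <- lapply(frag_ids, sort)
  unscorable <- setdiff(genes$gene_id, names(frag_ids))
  structure(list(fragments = frag_ids, unscorable = unscorable),
            class = "fragment_assignment")
}

#' @export
print.fragment_assignment <- function(x, ...) {
  cat("fragment_assignment:", length(x$fragments), "scorable genes,",
      length(x$unscorable), "unscorable\n")
  invisible(x)
}

#' Write a fragment map as BED
#'
#' BED4 (0-based half-open), name field `frag<id>|I` or `frag<id>|T` for
#' internal/terminal fragments.
#'
#' @param map fragment map from [build_gatc_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fragment_bed <- function(map, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(map)),
    start = BiocGenerics::start(map) - 1L,
    end = BiocGenerics::end(map),
    name = sprintf("frag%d|%s", map$fragment_id,
                   ifelse(map$terminal, "T", "I"))
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a fragment map written by [write_fragment_bed()]
#' @param path BED file.
#' @return a `GRanges` fragment map.
#' @export
read_fragment_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  parts <- data.table::tstrsplit(gr$name, "|", fixed = TRUE)
  map <- GenomicRanges::granges(gr)
  map$terminal <- parts[[2]] == "T"
  map$fragment_id <- as.integer(sub("^frag", "", parts[[1]]))
  map[order(map$fragment_id)]
}
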