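#' Load gene models from GFF3
#'
#' Reads gene spans from a GFF3 annotation. Features of type `gene` are
#' used directly; where several transcripts (`mRNA`) of one gene exist,
#' the gene span is extended to their union (min start, max end). If the
#' file carries no `gene` features at all, genes are reconstructed from
#' `mRNA` features grouped by their `Parent` (or own `ID`). Strand is kept
#' but plays no role in fragment or peak assignment.
#'
#' Records with end < start are skipped with a warning before parsing
#' (they cannot be represented as ranges). Records on chromosomes absent
#' from `chromosomes` (when supplied) are likewise skipped with a warning.
#'
#' @param path path to a GFF3 file.
#' @param chromosomes optional character vector of valid chromosome names
#'   (e.g. `seqlevels()` of a fragment map).
#' @return a [GenomicRanges::GRanges] with metadata columns `gene_id` and
#'   `symbol`, sorted by position; gene ids are unique.
#' @export
load_gene_models <- function(path, chromosomes = NULL) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  if (any(body)) {
    fields <- data.table::tstrsplit(lines[body], "\t", fixed = TRUE)
    if (length(fields) >= 5) {
      st <- suppressWarnings(as.numeric(fields[[4]]))
      en <- suppressWarnings(as.numeric(fields[[5]]))
      bad <- !is.na(st) & !is.na(en) & en < st
      if (any(bad)) {
        warning(sum(bad), " GFF3 record(s) with end < start skipped")
        drop <- which(body)[bad]
        path <- tempfile(fileext = ".gff3")
        writeLines(lines[-drop], path)
      }
    }
  }
  gff <- rtracklayer::import(path, format = "gff3")
  ftype <- as.character(gff$type)
  genes <- gff[ftype == "gene"]
  if (length(genes) == 0L) {
    tx <- gff[ftype %in% c("mRNA", "transcript")]
    if (length(tx) == 0L) stop("no gene or mRNA features in ", path)
    parent <- vapply(as.list(tx$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
    parent[is.na(parent)] <- as.character(tx$ID)[is.na(parent)]
    spl <- split(tx, parent)
    genes <- unlist(GenomicRanges::GRangesList(lapply(spl, range)))
    genes$ID <- names(genes)
    genes$Name <- names(genes)
  } else {
    # widen gene spans to the union of their transcripts, if any
    tx <- gff[ftype %in% c("mRNA", "transcript")]
    if (length(tx)) {
      parent <- vapply(as.list(tx$Parent), function(p)
        if (length(p)) p[[1]] else NA_character_, character(1))
      ok <- !is.na(parent) & parent %in% as.character(genes$ID)
      if (any(ok)) {
        spl <- split(IRanges::ranges(tx[ok]), parent[ok])
        uni <- unlist(range(spl))
        i <- match(names(uni), as.character(genes$ID))
        new_start <- pmin(BiocGenerics::start(genes)[i],
                          BiocGenerics::start(uni))
        new_end <- pmax(BiocGenerics::end(genes)[i], BiocGenerics::end(uni))
        IRanges::ranges(genes)[i] <- IRanges::IRanges(new_start, new_end)
      }
    }
  }
  out <- GenomicRanges::granges(genes)
  S4Vectors::mcols(out) <- NULL
  out$gene_id <- as.character(genes$ID)
  nm <- if (!is.null(genes$Name)) as.character(genes$Name) else out$gene_id
  out$symbol <- ifelse(is.na(nm) | !nzchar(nm), out$gene_id, nm)
  if (!is.null(chromosomes)) {
    known <- as.character(GenomeInfoDb::seqnames(out)) %in% chromosomes
    if (!all(known)) {
      warning(sum(!known), " gene record(s) on unknown chromosomes skipped")
      out <- out[known]
    }
    GenomeInfoDb::seqlevels(out) <- chromosomes
  }
  if (anyDuplicated(out$gene_id)) stop("duplicate gene ids in annotation")
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Write gene models as GFF3
#'
#' @param genes a `GRanges` with `gene_id` and `symbol` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  out <- genes
  out$type <- "gene"
  out$ID <- genes$gene_id
  out$Name <- genes$symbol
  out$source <- "damidcall"
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}
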