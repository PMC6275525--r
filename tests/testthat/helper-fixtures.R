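# Fixture builders shared across the suite. Everything is generated in
# code; no binary data.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(data.table)
})

# A GRanges fragment map with given fragment widths per chromosome; the
# first and last fragment of each chromosome are terminal.
make_map <- function(widths, chroms = NULL) {
  if (!is.list(widths)) widths <- list(chr1 = widths)
  if (!is.null(chroms)) names(widths) <- chroms
  grs <- lapply(names(widths), function(ch) {
    w <- widths[[ch]]
    ends <- cumsum(w)
    starts <- ends - w + 1L
    GenomicRanges::GRanges(ch, IRanges::IRanges(starts, ends),
                           terminal = seq_along(w) %in% c(1L, length(w)))
  })
  map <- suppressWarnings(do.call(c, grs))
  map <- GenomicRanges::sort(map, ignore.strand = TRUE)
  map$fragment_id <- seq_along(map)
  map
}

# An occupancy_track carrying arbitrary values on a map.
make_track <- function(map, values, fusion_id = "fusion",
                       control_id = "control") {
  stopifnot(length(values) == length(map))
  structure(
    list(values = as.numeric(values), map = map, fusion_id = fusion_id,
         control_id = control_id, pseudocount = 0.5, center = 0),
    class = "occupancy_track")
}

make_assignment <- function(fragments, unscorable = character()) {
  structure(list(fragments = fragments, unscorable = unscorable),
            class = "fragment_assignment")
}

make_genes <- function(chrom, starts, ends, ids = NULL,
                       strand = "*") {
  if (is.null(ids)) ids <- sprintf("g%03d", seq_along(starts))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                               strand = strand)
  gr$gene_id <- ids
  gr$symbol <- ids
  gr
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Independent regular-expression oracle for GATC cut points (0-based
# cut coordinates, motif start + 2).
regex_gatc_cuts <- function(seq) {
  m <- gregexpr("(?=GATC)", seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer())
  as.integer(m) - 1L + 2L
}

# Quadratic all-pairs overlap oracle on 1-based closed intervals.
overlap_oracle <- function(q_start, q_end, s_start, s_end) {
  hits <- list()
  for (i in seq_along(q_start)) {
    for (j in seq_along(s_start)) {
      if (q_start[i] <= s_end[j] && s_start[j] <= q_end[i])
        hits[[length(hits) + 1L]] <- c(i, j)
    }
  }
  if (!length(hits)) return(matrix(integer(), ncol = 2))
  do.call(rbind, hits)
}

# A small simulated data set reused by several files.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 402, chrom_lengths = c(chr1 = 4e5),
                        n_genes = 120, peak_count = 10)
      ref <- simulate_reference(cfg)
      cache <<- list(cfg = cfg, ref = ref,
                     sim = simulate_damid_counts(ref, cfg))
    }
    cache
  }
})
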