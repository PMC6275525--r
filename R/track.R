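#' Compute a normalized log2 occupancy track
#'
#' The occupancy signal contrasts a Dam-fusion sample against the
#' unfused-Dam accessibility control in log space ("control subtracted").
#' With m fragments and pseudocount psi, each library is converted to
#' smoothed fractions F_i = (f_i + psi) / (sum f + m psi) (likewise D_i
#' for the control) and the per-fragment ratio is r_i = log2(F_i / D_i).
#' The track is then median-centered over internal fragments as a simple
#' scaling normalization: the median fragment is assumed unbound. All
#' values are finite by construction.
#'
#' @param fusion,control `fragment_counts` for the Dam-fusion and Dam-only
#'   samples, aligned to the same fragment map.
#' @param map fragment map from [build_gatc_map()].
#' @param pseudocount psi > 0, default 0.5 (half-count smoothing).
#' @param center median-center over internal fragments (default `TRUE`).
#' @return an object of class `occupancy_track`: list with numeric
#'   `values` (log2 units, map order), the `map`, `fusion_id`,
#'   `control_id`, `pseudocount` and the subtracted `center`.
#' @export
compute_occupancy_track <- function(fusion, control, map, pseudocount = 0.5,
                                    center = TRUE) {
  stopifnot(methods::is(fusion, "fragment_counts"),
            methods::is(control, "fragment_counts"))
  if (length(fusion$counts) != length(control$counts))
    stop("fusion and control counts are not aligned to the same map")
  if (length(fusion$counts) != length(map))
    stop("counts are not aligned to the fragment map")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (fusion$library_size == 0)
    stop("sample ", fusion$sample_id, " has zero assigned reads")
  if (control$library_size == 0)
    stop("sample ", control$sample_id, " has zero assigned reads")
  m <- length(map)
  Fi <- (fusion$counts + pseudocount) / (fusion$library_size + m * pseudocount)
  Di <- (control$counts + pseudocount) / (control$library_size + m * pseudocount)
  r <- log2(Fi / Di)
  ctr <- 0
  if (center) {
    ctr <- stats::median(r[!map$terminal])
    r <- r - ctr
  }
  structure(
    list(values = r, map = map, fusion_id = fusion$sample_id,
         control_id = control$sample_id, pseudocount = pseudocount,
         center = ctr),
    class = "occupancy_track")
}

#' @export
print.occupancy_track <- function(x, ...) {
  cat(sprintf(
    "occupancy_track %s / %s: %d fragments, psi = %g, range [%.2f, %.2f]\n",
    x$fusion_id, x$control_id, length(x$values), x$pseudocount,
    min(x$values), max(x$values)))
  invisible(x)
}

#' Write an occupancy track as 4-column bedGraph (one line per fragment)
#' @param track an `occupancy_track`.
#' @param path output file.
#' @param digits decimal places written (default 6).
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, path, digits = 6) {
  map <- track$map
  dt <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(map)),
    start = BiocGenerics::start(map) - 1L,
    end = BiocGenerics::end(map),
    value = formatC(track$values, digits = digits, format = "f"))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a per-fragment bedGraph back onto a fragment map
#'
#' Intervals must match the map's fragments exactly.
#'
#' @param path bedGraph file written by [write_track_bedgraph()].
#' @param map fragment map the track was computed on.
#' @return an `occupancy_track` (ids set from the file name; not
#'   re-centered).
#' @export
read_track_bedgraph <- function(path, map) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (length(gr) != length(map) ||
      any(BiocGenerics::start(gr) != BiocGenerics::start(map)) ||
      any(BiocGenerics::end(gr) != BiocGenerics::end(map)))
    stop("bedGraph intervals do not match the fragment map")
  structure(
    list(values = as.numeric(gr$score), map = map,
         fusion_id = sub("\\.[^.]+$", "", basename(path)),
         control_id = NA_character_, pseudocount = NA_real_, center = 0),
    class = "occupancy_track")
}
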