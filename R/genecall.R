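#' Score gene-level occupancy
#'
#' The gene score g is the fragment-length-weighted mean of the occupancy
#' track over the gene's assigned internal fragments — "average
#' methylation across the gene". Genes with no assigned fragment are
#' omitted (they are listed in the assignment's `unscorable` field).
#'
#' @param track an `occupancy_track`.
#' @param assignment a `fragment_assignment` from
#'   [assign_fragments_to_genes()].
#' @return a [data.table::data.table] with columns `gene_id`, `n`
#'   (fragments) and `g` (log2 units), ordered by gene id.
#' @export
score_gene_occupancy <- function(track, assignment) {
  stopifnot(methods::is(track, "occupancy_track"),
            methods::is(assignment, "fragment_assignment"))
  w <- BiocGenerics::width(track$map)
  r <- track$values
  ids <- names(assignment$fragments)
  g <- vapply(assignment$fragments, function(f)
    sum(w[f] * r[f]) / sum(w[f]), numeric(1))
  n <- lengths(assignment$fragments)
  out <- data.table::data.table(gene_id = ids, n = as.integer(n), g = g)
  data.table::setkey(out, gene_id)
  out[]
}

#' Call expressed genes by permutation FDR
#'
#' Tests each gene's length-weighted mean occupancy g against a
#' genome-wide null: for a gene with n fragments, M random sets of n
#' internal fragments are drawn uniformly without replacement and scored
#' with the same weighted mean. The permutation p-value is
#' p = (1 + #\{null >= g\}) / (M + 1); q-values are Benjamini-Hochberg
#' across all scored genes. A gene is called expressed when q < theta and
#' g > 0 (the positivity guard keeps strongly depleted genes from being
#' "expressed"). Genes sharing n share one null sample, which is
#' statistically exchangeable and much faster. Fully reproducible given
#' `seed`.
#'
#' @param scores output of [score_gene_occupancy()].
#' @param track the `occupancy_track` the scores came from.
#' @param theta FDR threshold in (0,1), default 0.01.
#' @param M permutations per distinct fragment count; >= 1000 advised
#'   (smaller values warn: the attainable p-value floor 1/(M+1) may
#'   exceed the Benjamini-Hochberg cutoff).
#' @param seed integer seed for the null draws.
#' @return the `scores` table with columns `p`, `q` and `expressed` added.
#' @export
call_expressed_genes <- function(scores, track, theta = 0.01, M = 1000,
                                 seed = NULL) {
  stopifnot(theta > 0, theta < 1, M >= 1)
  if (M < 1000) warning("M < 1000 permutations: small p-values unstable")
  if (!is.null(seed)) set.seed(seed)
  internal <- which(!track$map$terminal)
  r <- track$values[internal]
  w <- as.numeric(BiocGenerics::width(track$map)[internal])
  wr <- w * r
  npool <- length(internal)
  out <- data.table::copy(scores)
  data.table::setkey(out, gene_id)  # stable order: null draws reproducible
  out[, p := NA_real_]
  for (nn in sort(unique(out$n))) {
    nn_use <- min(nn, npool)
    null <- numeric(M)
    if (nn_use == 1L) {
      idx <- sample.int(npool, M, replace = TRUE)
      null <- wr[idx] / w[idx]
    } else {
      for (j in seq_len(M)) {
        idx <- sample.int(npool, nn_use)
        null[j] <- sum(wr[idx]) / sum(w[idx])
      }
    }
    gi <- which(out$n == nn)
    out$p[gi] <- vapply(out$g[gi],
                        function(gg) (1 + sum(null >= gg)) / (M + 1),
                        numeric(1))
  }
  out[, q := stats::p.adjust(p, method = "BH")]
  out[, expressed := q < theta & g > 0]
  out[]
}

#' Classify genes by cell-type specificity
#'
#' Given gene calls in two cell types A and B (same annotation), each
#' gene is classed as `A_specific` (q_A < theta, q_B >= theta),
#' `B_specific` (symmetric), `shared` (both < theta) or `neither`
#' (both >= theta); genes scored in only one record set are `unscorable`.
#' Shared genes with fold difference F = 2^(g_A - g_B) at least
#' `fold_min` (resp. at most 1/fold_min) get subclass `A_enriched`
#' (`B_enriched`). F, the linear-scale occupancy ratio, is reported for
#' every gene scored in both.
#'
#' @param records_A,records_B outputs of [call_expressed_genes()] for the
#'   two cell types.
#' @param theta FDR threshold, default 0.01.
#' @param fold_min enrichment fold threshold, default 2.
#' @return a `data.table` keyed by `gene_id` with columns `class_`
#'   (specificity class), `subclass` (`A_enriched`/`B_enriched`/`NA`),
#'   `F_fold`, `g_A`, `g_B`, `q_A`, `q_B`.
#' @export
compare_cell_types <- function(records_A, records_B, theta = 0.01,
                               fold_min = 2) {
  a <- records_A[, .(gene_id, g_A = g, q_A = q)]
  b <- records_B[, .(gene_id, g_B = g, q_B = q)]
  tab <- merge(a, b, by = "gene_id", all = TRUE)
  tab[, F_fold := 2^(g_A - g_B)]
  tab[, class_ := data.table::fcase(
    is.na(q_A) | is.na(q_B), "unscorable",
    q_A < theta & q_B >= theta, "A_specific",
    q_B < theta & q_A >= theta, "B_specific",
    q_A < theta & q_B < theta, "shared",
    default = "neither")]
  tab[, subclass := data.table::fcase(
    class_ == "shared" & F_fold >= fold_min, "A_enriched",
    class_ == "shared" & F_fold <= 1 / fold_min, "B_enriched",
    default = NA_character_)]
  data.table::setkey(tab, gene_id)
  tab[]
}

#' Spearman correlation of occupancy with an external expression table
#'
#' @param records output of [score_gene_occupancy()] or
#'   [call_expressed_genes()] (needs `gene_id`, `g`).
#' @param external a data.frame with columns `gene_id` and `value`
#'   (e.g. RNA-seq expression); at least 3 genes must be shared.
#' @return Spearman's rho (ties by mid-rank) on the shared gene set.
#' @export
rank_correlation <- function(records, external) {
  external <- data.table::as.data.table(external)
  if (!all(c("gene_id", "value") %in% names(external)))
    stop("external table needs columns gene_id and value")
  m <- merge(records[, .(gene_id, g)], external[, .(gene_id, value)],
             by = "gene_id")
  m <- m[stats::complete.cases(m)]
  if (nrow(m) < 3) stop("fewer than 3 genes shared with the external table")
  stats::cor(m$g, m$value, method = "spearman")
}

#' Write a gene-call table as TSV
#' @param records gene-call `data.table`.
#' @param path output file.
#' @param genes optional annotation `GRanges` supplying gene symbols.
#' @return `path`, invisibly.
#' @export
write_gene_calls <- function(records, path, genes = NULL) {
  out <- data.table::copy(records)
  if (!is.null(genes) && !"symbol" %in% names(out))
    out[, symbol := genes$symbol[match(gene_id, genes$gene_id)]]
  data.table::setorder(out, gene_id)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
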