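#' Membership-region counts and pairwise overlaps for 2-4 gene sets
#'
#' Counts every non-empty membership region (2^k - 1 of them) of k named
#' sets, and for every ordered pair (X, Y) reports the overlap fraction
#' |X intersect Y| / |X| as a percentage rounded to the nearest integer
#' (full precision is kept alongside).
#'
#' @param sets named list of 2-4 character vectors (gene ids; duplicates
#'   are collapsed).
#' @return list with `regions` (a `data.table`: `region` is a
#'   `+`-separated set-name combination, `count`), `pairwise` (a
#'   `data.table`: `set_from`, `set_to`, `overlap`, `size_from`,
#'   `fraction`, `fraction_pct`) and `union_size`.
#' @export
venn_counts <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 4)
    stop("venn_counts takes 2-4 sets; iterate pairs for more")
  if (is.null(names(sets)) || any(!nzchar(names(sets))) ||
      anyDuplicated(names(sets)))
    stop("sets must carry unique names")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, ncol = k,
                   dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(z) paste(names(sets)[z], collapse = "+"))
  combos <- unlist(lapply(seq_len(k), function(i)
    utils::combn(names(sets), i, paste, collapse = "+")))
  counts <- table(factor(key, levels = combos))
  regions <- data.table::data.table(region = combos,
                                    count = as.integer(counts))
  pairs <- expand.grid(set_from = names(sets), set_to = names(sets),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$set_from != pairs$set_to, ]
  pw <- data.table::rbindlist(lapply(seq_len(nrow(pairs)), function(i) {
    x <- sets[[pairs$set_from[i]]]; y <- sets[[pairs$set_to[i]]]
    ov <- length(intersect(x, y))
    data.table::data.table(
      set_from = pairs$set_from[i], set_to = pairs$set_to[i],
      overlap = ov, size_from = length(x), fraction = ov / length(x),
      fraction_pct = as.integer(round(100 * ov / length(x))))
  }))
  list(regions = regions, pairwise = pw,
       union_size = length(universe))
}

#' Rank cell-type-specific transcription factors by occupancy fold
#'
#' Restricts a specificity table to A-specific genes that appear in the
#' supplied TF catalog with fold difference F >= `fold_min`, sorted by
#' decreasing F (ties broken by gene id). F is additionally reported
#' rounded to one decimal for display.
#'
#' @param specificity output of [compare_cell_types()].
#' @param tf_list character vector of TF gene ids (non-empty).
#' @param fold_min minimum fold difference, default 2.
#' @return a `data.table` with `gene_id`, `F_fold`, `F_display`, `q_A`,
#'   `q_B`; zero rows is a legal result.
#' @export
rank_specific_tfs <- function(specificity, tf_list, fold_min = 2) {
  if (length(tf_list) == 0) stop("tf_list is empty")
  out <- specificity[class_ == "A_specific" & gene_id %in% tf_list &
                       F_fold >= fold_min,
                     .(gene_id, F_fold, q_A, q_B)]
  data.table::setorder(out, -F_fold, gene_id)
  out[, F_display := round(F_fold, 1)]
  data.table::setcolorder(out, c("gene_id", "F_fold", "F_display"))
  out[]
}

#' Candidate-regulator report
#'
#' Intersects a curated gene list (e.g. signaling-pathway ligands) with
#' A-specific expression and membership in every supplied TF target set,
#' reporting class, fold and the supporting peaks per TF. Curated ids
#' never scored at all are returned separately ("not scored").
#'
#' @param specificity output of [compare_cell_types()].
#' @param target_sets list of `target_gene_set` objects (>= 1).
#' @param curated character vector of curated gene ids.
#' @return list with `report` (a `data.table`: `gene_id`, `class_`,
#'   `F_fold`, one `peaks_<tf>` column per TF) and `not_scored`
#'   (character).
#' @export
candidate_report <- function(specificity, target_sets, curated) {
  if (length(target_sets) == 0) stop("need at least one target set")
  stopifnot(all(vapply(target_sets, inherits, logical(1),
                       "target_gene_set")))
  curated <- unique(curated)
  not_scored <- setdiff(curated, specificity$gene_id)
  keep <- specificity[gene_id %in% curated & class_ == "A_specific"]
  for (ts in target_sets)
    keep <- keep[gene_id %in% ts$genes]
  report <- keep[, .(gene_id, class_, F_fold)]
  for (ts in target_sets) {
    col <- paste0("peaks_", ts$tf)
    report[, (col) := vapply(gene_id, function(gid)
      paste(ts$support[[gid]], collapse = ","), character(1))]
  }
  data.table::setorder(report, gene_id)
  list(report = report[], not_scored = sort(not_scored))
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' For each term, the upper-tail hypergeometric probability of observing
#' at least the seen overlap between the query and the term's genes,
#' drawing |query| genes from the universe. Terms with no member in the
#' universe are skipped with a warning. q-values are Benjamini-Hochberg
#' across tested terms.
#'
#' @param query character vector of gene ids, a subset of `universe`.
#' @param universe character vector of scorable gene ids.
#' @param terms named list: term -> character vector of member gene ids
#'   (members outside the universe are ignored).
#' @return a `data.table` with `term`, `overlap` (k), `term_size` (K in
#'   universe), `query_size`, `universe_size`, `p`, `q`, sorted by p.
#' @export
enrichment_test <- function(query, universe, terms) {
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query contains ids outside the universe")
  N <- length(universe)
  n <- length(query)
  sizes <- vapply(terms, function(tg) length(intersect(tg, universe)),
                  integer(1))
  if (any(sizes == 0)) {
    warning(sum(sizes == 0), " term(s) with no universe member skipped")
    terms <- terms[sizes > 0]
    sizes <- sizes[sizes > 0]
  }
  ks <- vapply(terms, function(tg) length(intersect(query, tg)), integer(1))
  p <- stats::phyper(ks - 1, sizes, N - sizes, n, lower.tail = FALSE)
  out <- data.table::data.table(
    term = names(terms), overlap = ks, term_size = sizes,
    query_size = n, universe_size = N, p = p,
    q = stats::p.adjust(p, method = "BH"))
  data.table::setorder(out, p, term)
  out[]
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Classic df = 1 Pearson chi-square, with an optional Yates continuity
#' correction (subtracting min(0.5, |O - E|) from each absolute
#' deviation, as in base R). A zero row or column marginal leaves the
#' statistic undefined and raises an error.
#'
#' @param tab a 2x2 matrix of non-negative counts.
#' @param correct apply the continuity correction (default `FALSE`).
#' @return list with `statistic`, `df` (= 1), `p.value` and `expected`.
#' @export
contingency_chisq <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("tab must be 2x2")
  if (any(tab < 0) || sum(tab) < 1) stop("counts must be >= 0, total >= 1")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("zero marginal: chi-square statistic undefined")
  E <- outer(rs, cs) / sum(tab)
  dev <- abs(tab - E)
  if (correct) dev <- pmax(dev - pmin(0.5, dev), 0)
  stat <- sum(dev^2 / E)
  list(statistic = stat, df = 1L,
       p.value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       expected = E)
}
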