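test_that("venn regions and pairwise fractions are exact", {
  vc <- venn_counts(list(first = c("a", "b", "c"), second = c("b", "c", "d")))
  reg <- setNames(vc$regions$count, vc$regions$region)
  expect_equal(reg[["first"]], 1L)
  expect_equal(reg[["second"]], 1L)
  expect_equal(reg[["first+second"]], 2L)
  expect_equal(vc$union_size, 4L)
  expect_equal(sum(vc$regions$count), vc$union_size)

  # an ordered overlap of 3266 of 4284 reports as 76%
  tf_targets <- sprintf("gene%05d", 1:4284)
  other <- c(sprintf("gene%05d", 1:3266), sprintf("x%05d", 1:2000))
  vc2 <- venn_counts(list(Sox21a = tf_targets, cic = other))
  pw <- vc2$pairwise
  expect_equal(pw[pw$set_from == "Sox21a", overlap], 3266L)
  expect_equal(pw[pw$set_from == "Sox21a", fraction_pct], 76L)

  expect_error(venn_counts(list(a = "x")), "2-4 sets")
  expect_error(venn_counts(list(a = "x", b = "y", c = "z", d = "w",
                                e = "v")), "2-4 sets")
})

test_that("venn region counts sum to the union for random 3- and 4-set inputs", {
  set.seed(8)
  for (k in c(3, 4)) {
    for (rep in 1:5) {
      sets <- lapply(1:k, function(i) sample(letters, sample(5:20, 1)))
      names(sets) <- paste0("S", 1:k)
      vc <- venn_counts(sets)
      expect_equal(sum(vc$regions$count),
                   length(unique(unlist(sets))))
      expect_equal(nrow(vc$regions), 2^k - 1)
      # brute-force membership oracle for each region
      universe <- unique(unlist(sets))
      for (j in seq_len(nrow(vc$regions))) {
        inset <- strsplit(vc$regions$region[j], "+", fixed = TRUE)[[1]]
        outset <- setdiff(names(sets), inset)
        cnt <- sum(vapply(universe, function(el)
          all(vapply(sets[inset], function(s) el %in% s, logical(1))) &&
          !any(vapply(sets[outset], function(s) el %in% s, logical(1))),
          logical(1)))
        expect_equal(vc$regions$count[j], cnt)
      }
    }
  }
})

test_that("TF ranking sorts A-specific catalog genes by fold", {
  spec <- data.table::data.table(
    gene_id = c("Sox21a", "esg", "Zfh2", "weak", "notTF", "shared1"),
    class_ = c(rep("A_specific", 5), "shared"),
    subclass = NA_character_,
    F_fold = c(6.1, 5.2, 2.8, 1.9, 9.9, 8.0),
    g_A = 1, g_B = 0, q_A = 0.001, q_B = 0.5)
  tfs <- c("Sox21a", "esg", "Zfh2", "weak", "shared1")
  rk <- rank_specific_tfs(spec, tfs, fold_min = 2)
  expect_equal(rk$gene_id, c("Sox21a", "esg", "Zfh2"))
  expect_equal(rk$F_display, c(6.1, 5.2, 2.8))
  expect_error(rank_specific_tfs(spec, character()), "empty")

  # random tables agree with an independent sort oracle
  set.seed(12)
  for (rep in 1:10) {
    n <- 30
    spec2 <- data.table::data.table(
      gene_id = sprintf("g%02d", sample(n)),
      class_ = sample(c("A_specific", "B_specific", "shared", "neither"),
                      n, replace = TRUE),
      subclass = NA_character_,
      F_fold = round(runif(n, 0.2, 8), 3),
      g_A = 0, g_B = 0, q_A = 0, q_B = 0)
    cat_ids <- sample(spec2$gene_id, 15)
    rk2 <- rank_specific_tfs(spec2, cat_ids, fold_min = 2)
    keep <- spec2[class_ == "A_specific" & gene_id %in% cat_ids &
                    F_fold >= 2]
    oracle <- keep[order(-F_fold, gene_id), gene_id]
    expect_equal(rk2$gene_id, oracle)
  }
})

test_that("candidate report filters by specificity and all target sets", {
  spec <- data.table::data.table(
    gene_id = c("lig1", "lig2", "lig3", "lig4"),
    class_ = c("A_specific", "shared", "A_specific", "A_specific"),
    subclass = NA_character_, F_fold = c(4, 1, 3, 5),
    g_A = 1, g_B = 0, q_A = 0.001, q_B = 0.5)
  ts1 <- structure(list(tf = "Sox21a",
                        genes = c("lig1", "lig2", "lig3"),
                        support = list(lig1 = "p1", lig2 = "p2",
                                       lig3 = c("p3", "p4"))),
                   class = "target_gene_set")
  ts2 <- structure(list(tf = "cic", genes = c("lig1", "lig2"),
                        support = list(lig1 = "q1", lig2 = "q2")),
                   class = "target_gene_set")
  out <- candidate_report(spec, list(ts1, ts2),
                          c("lig1", "lig2", "lig3", "lig4", "lig9"))
  # lig1: A_specific and in both target sets -> included
  expect_equal(out$report$gene_id, "lig1")
  expect_equal(out$report$peaks_Sox21a, "p1")
  expect_equal(out$report$peaks_cic, "q1")
  # lig2 shared -> excluded; lig3 not a cic target; lig4 in no set
  expect_false(any(c("lig2", "lig3", "lig4") %in% out$report$gene_id))
  expect_equal(out$not_scored, "lig9")

  # brute-force nested filter oracle on random inputs
  set.seed(77)
  for (rep in 1:10) {
    ids <- sprintf("g%02d", 1:40)
    spec2 <- data.table::data.table(
      gene_id = ids,
      class_ = sample(c("A_specific", "shared", "neither"), 40, TRUE),
      subclass = NA_character_, F_fold = runif(40, 0.5, 6),
      g_A = 0, g_B = 0, q_A = 0, q_B = 0)
    mk <- function(tf) {
      gs <- sort(sample(ids, 20))
      structure(list(tf = tf, genes = gs,
                     support = setNames(as.list(rep(paste0(tf, "_p"),
                                                    length(gs))), gs)),
                class = "target_gene_set")
    }
    t1 <- mk("T1"); t2 <- mk("T2")
    cur <- sample(ids, 15)
    got <- candidate_report(spec2, list(t1, t2), cur)$report$gene_id
    want <- sort(Filter(function(g)
      spec2[gene_id == g, class_] == "A_specific" &&
        g %in% t1$genes && g %in% t2$genes, cur))
    expect_equal(got, want)
  }
})

test_that("hypergeometric enrichment matches closed forms and exact summation", {
  universe <- sprintf("u%02d", 1:10)
  terms <- list(T5 = universe[1:5], Tall = universe)
  res <- enrichment_test(universe[1:3], universe, terms)
  # query of 3 fully inside a term of 5: p = C(5,3)/C(10,3) = 0.0833
  expect_equal(res[term == "T5", p], choose(5, 3) / choose(10, 3),
               tolerance = 1e-12)
  expect_equal(res[term == "Tall", p], 1)
  expect_error(enrichment_test(c("zzz"), universe, terms), "outside")
  expect_warning(
    res2 <- enrichment_test(universe[1:3], universe,
                            c(terms, list(Tnone = "external_id"))),
    "skipped")
  expect_false("Tnone" %in% res2$term)

  # direct combinatorial summation oracle on small universes
  set.seed(4)
  for (rep in 1:10) {
    N <- sample(8:20, 1)
    uni <- sprintf("x%02d", 1:N)
    tg <- sample(uni, sample(2:N, 1))
    qy <- sample(uni, sample(2:(N - 1), 1))
    k <- length(intersect(qy, tg)); K <- length(tg); n <- length(qy)
    p_oracle <- sum(vapply(k:min(K, n), function(i)
      choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
    res3 <- enrichment_test(qy, uni, list(t = tg))
    expect_equal(res3$p, p_oracle, tolerance = 1e-12)
  }

  # BH q monotone non-decreasing in p
  set.seed(5)
  uni <- sprintf("y%03d", 1:200)
  terms_r <- lapply(1:15, function(i) sample(uni, sample(10:80, 1)))
  names(terms_r) <- paste0("rt", 1:15)
  res4 <- enrichment_test(sample(uni, 40), uni, terms_r)
  expect_true(all(diff(res4$q[order(res4$p)]) >= -1e-12))
})

test_that("chi-square matches hand values and the stats oracle", {
  # independence and perfect association
  expect_equal(contingency_chisq(matrix(c(5, 5, 5, 5), 2))$statistic, 0)
  expect_equal(contingency_chisq(matrix(c(5, 5, 5, 5), 2))$p.value, 1)
  expect_equal(contingency_chisq(matrix(c(10, 0, 0, 10), 2))$statistic, 20)

  # printed image classification: 7/11 vs 9/10 double positives
  tab <- matrix(c(7, 1, 4, 9), 2)
  expect_lt(contingency_chisq(tab)$p.value, 0.05)
  expect_lt(contingency_chisq(tab, correct = TRUE)$p.value, 0.05)

  expect_error(contingency_chisq(matrix(c(0, 0, 3, 4), 2)), "marginal")

  # oracle: stats::chisq.test on random tables, both variants
  set.seed(6)
  for (rep in 1:20) {
    m <- matrix(rpois(4, 8) + 1, 2)
    for (corr in c(FALSE, TRUE)) {
      mine <- contingency_chisq(m, correct = corr)
      ref <- suppressWarnings(stats::chisq.test(m, correct = corr))
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
    }
  }
})
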