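test_that("GATC map matches the worked example and handles edge cases", {
  map <- build_gatc_map(c(chr = "TTGATCAAAGATCCCGATCG"))
  # 0-based half-open fragments [0,4) [4,11) [11,17) [17,20)
  expect_equal(start(map), c(1L, 5L, 12L, 18L))
  expect_equal(end(map), c(4L, 11L, 17L, 20L))
  expect_equal(map$terminal, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(map$fragment_id, 1:4)

  # no motif: one terminal fragment spanning the chromosome
  map0 <- build_gatc_map(c(chr = "AAAAAAAA"))
  expect_length(map0, 1L)
  expect_true(map0$terminal)
  expect_equal(width(map0), 8L)

  # N inside the motif never matches; non-DNA characters are rejected
  expect_length(build_gatc_map(c(chr = "AAGANCAA")), 1L)
  expect_error(build_gatc_map(c(chr = "AAGAXCAA")), "non-DNA")
})

test_that("fragment maps agree with a regex oracle on random sequences", {
  set.seed(71)
  for (i in 1:25) {
    seq <- random_dna(5000)
    map <- build_gatc_map(c(chrX = seq))
    cuts <- regex_gatc_cuts(seq)
    expect_equal(start(map), c(1L, cuts + 1L), info = paste("rep", i))
    expect_equal(end(map), c(cuts, 5000L), info = paste("rep", i))
    # tiling: widths sum exactly to chromosome length
    expect_equal(sum(width(map)), 5000L)
    # cut-point soundness: residues[b-2, b+2) == GATC around each boundary
    if (length(cuts))
      expect_true(all(substring(seq, cuts - 1, cuts + 2) == "GATC"))
  }
})

test_that("gene models load with coordinate conversion and span union", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=gA;Name=alpha",
    "chr1\tsrc\tgene\t500\t900\t.\t-\t.\tID=gB;Name=beta",
    "chr1\tsrc\tmRNA\t500\t700\t.\t-\t.\tID=tB1;Parent=gB",
    "chr1\tsrc\tmRNA\t650\t1300\t.\t-\t.\tID=tB2;Parent=gB"), gff)
  genes <- load_gene_models(gff)
  a <- genes[genes$gene_id == "gA"]
  # GFF 1-based closed [101,200] == 0-based half-open [100,200)
  expect_equal(start(a), 101L)
  expect_equal(end(a), 200L)
  expect_equal(a$symbol, "alpha")
  # union of the two transcripts extends the gene span
  b <- genes[genes$gene_id == "gB"]
  expect_equal(start(b), 500L)
  expect_equal(end(b), 1300L)
})

test_that("malformed and unknown-chromosome records are skipped with warnings", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t60\t50\t.\t+\t.\tID=bad",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=ok",
    "chr9\tsrc\tgene\t10\t90\t.\t+\t.\tID=offmap"), gff)
  expect_warning(genes <- load_gene_models(gff), "end < start")
  expect_false("bad" %in% genes$gene_id)
  expect_warning(
    expect_warning(genes2 <- load_gene_models(gff, chromosomes = "chr1"),
                   "unknown chromosome"),
    "end < start")
  expect_equal(genes2$gene_id, "ok")
})

test_that("fragment-gene assignment follows the >=1 bp overlap rule", {
  # internal fragments [90,110) [110,700) [895,950) in 0-based half-open,
  # gene [100,900): all three overlap; [900,950) does not (half-open).
  map <- make_map(c(90, 20, 590, 195, 55, 50, 100))
  # fragments (1-based closed): [91,110] [111,700] [701,895] [896,950] [951,1000]
  genes <- make_genes("chr1", 101, 900, "gene1")
  asn <- assign_fragments_to_genes(map, genes)
  expect_equal(asn$fragments$gene1, c(2L, 3L, 4L, 5L))
  genes2 <- make_genes("chr1", 101, 895, "gene1")  # ends where frag 5 starts
  asn2 <- assign_fragments_to_genes(map, genes2)
  expect_equal(asn2$fragments$gene1, c(2L, 3L, 4L))

  # strand invariance and unscorable flagging
  genes3 <- make_genes("chr1", c(101, 5), c(900, 20), c("gene1", "tiny"),
                       strand = c("-", "+"))
  asn3 <- assign_fragments_to_genes(map, genes3)
  expect_equal(asn3$fragments$gene1, asn$fragments$gene1)
  expect_equal(asn3$unscorable, "tiny")  # only overlaps terminal fragment 1
  asn4 <- assign_fragments_to_genes(map, genes3, include_terminal = TRUE)
  expect_equal(asn4$fragments$tiny, 1L)
})

test_that("assignment equals a quadratic overlap oracle on random layouts", {
  set.seed(99)
  for (rep in 1:20) {
    nfrag <- sample(10:30, 1)
    map <- make_map(sample(5:200, nfrag, replace = TRUE))
    ngene <- sample(3:8, 1)
    gs <- sort(sample.int(sum(width(map)), ngene))
    ge <- pmin(gs + sample(20:400, ngene, replace = TRUE), sum(width(map)))
    genes <- make_genes("chr1", gs, ge)
    asn <- assign_fragments_to_genes(map, genes)
    internal <- which(!map$terminal)
    oracle <- overlap_oracle(start(map)[internal], end(map)[internal],
                             gs, ge)
    expected <- split(internal[oracle[, 1]], genes$gene_id[oracle[, 2]])
    expect_equal(asn$fragments, lapply(expected, sort),
                 info = paste("layout", rep))
  }
})

test_that("fragment BED round-trips through write/read", {
  map <- build_gatc_map(c(a = random_dna(3000), b = random_dna(1000)))
  bed <- tempfile(fileext = ".bed")
  write_fragment_bed(map, bed)
  back <- read_fragment_bed(bed)
  expect_equal(start(back), start(map))
  expect_equal(end(back), end(map))
  expect_equal(back$terminal, map$terminal)
  expect_equal(back$fragment_id, map$fragment_id)
})
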