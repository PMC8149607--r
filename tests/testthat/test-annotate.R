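toy_genes <- tibble::tibble(
  name = c("GENEA", "GENEB", "GENEC"),
  chrom = "chr1",
  strand = c("+", "-", "+"),
  start = c(1000L, 30000L, 80000L),
  end = c(6000L, 40000L, 95000L),
  tss = c(1001L, 40000L, 80001L)
)

test_that("nearest genes rank by TSS distance with containment at zero", {
  # inside GENEA, GENEB far away
  ng <- nearest_genes("chr1", 3000L, toy_genes)
  expect_equal(c(ng$gene1, ng$gene2), c("GENEA", "GENEB"))
  # equidistant between two TSSs: tie broken by smaller TSS coordinate
  mid <- as.integer((1001 + 40000) / 2)
  genes_eq <- dplyr::mutate(toy_genes[1:2, ],
                            start = c(100L, 80000L), end = c(200L, 90000L),
                            tss = c(mid - 500L, mid + 500L))
  ng2 <- nearest_genes("chr1", mid, genes_eq)
  expect_equal(ng2$gene1, "GENEA")
  # empty chromosome warns and returns NA
  expect_warning(ng3 <- nearest_genes("chrX", 1L, toy_genes), "no genes")
  expect_true(is.na(ng3$gene1))
})

test_that("nearest genes equal the exhaustive distance sort on random sets", {
  set.seed(77)
  for (rep in 1:20) {
    ng <- sample(2:50, 1)
    st <- sort(sample.int(5e5, ng))
    genes <- tibble::tibble(
      name = paste0("G", seq_len(ng)), chrom = "c",
      strand = sample(c("+", "-"), ng, TRUE),
      start = st, end = st + sample(500:5000, ng, TRUE))
    genes$tss <- ifelse(genes$strand == "+", genes$start + 1L, genes$end)
    p <- sample.int(6e5, 1)
    got <- nearest_genes("c", p, genes)
    dist <- ifelse(p > genes$start & p <= genes$end, 0, abs(p - genes$tss))
    ord <- order(dist, genes$tss, genes$name)
    expect_equal(got$gene1, genes$name[ord[1]])
    expect_equal(got$gene2, genes$name[ord[2]])
  }
})

test_that("signed TSS distance is negative upstream, in kb, strand-aware", {
  expect_equal(signed_tss_distance(1001L, 1001L, "+"), 0)
  # 55 kb upstream of a + strand gene
  expect_equal(signed_tss_distance(56001L - 55000L, 56001L, "+"), -55)
  # strand flip negates the sign
  p <- 12000L; tss <- 10000L
  expect_equal(signed_tss_distance(p, tss, "+"),
               -signed_tss_distance(p, tss, "-"))
})

test_that("feature classification distinguishes Prom, In and IGR", {
  g <- toy_genes[1, ]   # + strand, tss 1001, transcript 1000-6000
  expect_equal(classify_feature(1001L - 2000L, g), "Prom")   # -2 kb
  expect_equal(classify_feature(1001L - 3000L, g), "IGR")    # -3 kb
  expect_equal(classify_feature(4000L, g), "In")
  expect_equal(classify_feature(1001L + 400L, g), "Prom")
  # totality: every query maps to exactly one class
  for (p in as.integer(seq(1, 20000, by = 997))) {
    expect_true(classify_feature(p, g) %in% c("Prom", "In", "IGR"))
  }
})

test_that("candidate overlap flags hits via either flanking gene", {
  hits <- tibble::tibble(chrom = "chr1", pos = c(3000L, 85000L),
                         pair_id = c("MZ1", "MZ2"))
  ann <- annotate_hits(hits, toy_genes)
  flagged <- candidate_overlap(ann, c("genea"))
  expect_equal(flagged$candidate, c(TRUE, FALSE))
  none <- candidate_overlap(ann, character(0))
  expect_false(any(none$candidate))
})

test_that("enrichment test equals exact enumeration and is monotone", {
  expect_equal(enrichment_test(0, 4, 5, 10), 1)
  expect_equal(enrichment_test(4, 4, 5, 10), 5 / 210)
  expect_equal(enrichment_test(4, 4, 4, 4), 1)
  set.seed(88)
  for (rep in 1:100) {
    N <- sample(1:30, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(max(0, n - (N - K)):min(n, K), 1)
    expect_equal(enrichment_test(k, n, K, N), oracle_hyper_upper(k, n, K, N),
                 tolerance = 1e-12)
  }
  ks <- 0:4
  ps <- vapply(ks, enrichment_test, numeric(1), n = 4, K = 5, N = 10)
  expect_true(all(diff(ps) <= 0))
  expect_error(enrichment_test(5, 4, 5, 10), "impossible")
})

test_that("cross-pair overlap tallies pairs and direction concordance", {
  hits <- tibble::tibble(
    pair_id = c("MZ6", "MZ8", "MZ1", "MZ2"),
    gene1 = c("MAFB", "MAFB", "TP63", "TP63"),
    gene2 = c(NA, "OTHER", NA, NA),
    delta = c(-0.68, -0.59, 0.8, -0.4))
  ov <- cross_pair_overlap(hits)
  mafb <- ov[ov$gene == "MAFB", ]
  expect_equal(mafb$n_pairs, 2L)
  expect_true(mafb$concordant)
  tp63 <- ov[ov$gene == "TP63", ]
  expect_equal(tp63$n_pairs, 2L)
  expect_false(tp63$concordant)
  expect_equal(ov$n_pairs[ov$gene == "OTHER"], 1L)
})

test_that("per-pair enrichment counts candidate and total genes hit", {
  hits <- tibble::tibble(
    pair_id = c("MZ1", "MZ1", "MZ2"),
    gene1 = c("GENEA", "GENEB", "GENEC"),
    gene2 = NA_character_,
    candidate = c(TRUE, TRUE, FALSE))
  res <- enrichment_by_pair(hits, universe = toy_genes$name,
                            candidates = c("GENEA", "GENEB"))
  mz1 <- res[res$pair_id == "MZ1", ]
  expect_equal(mz1$n_candidate_hits, 2L)
  # both candidate genes drawn in two tries from {A,B,C}: p = C(2,2)C(1,0)/C(3,2)
  expect_equal(mz1$p_value, 1 / 3)
})
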