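test_that("beta values follow count arithmetic and reject zero depth", {
  expect_equal(beta_value(15, 5), 0.75)
  expect_equal(beta_value(0, 20), 0)
  expect_equal(beta_value(20, 0), 1)
  expect_error(beta_value(0, 0), "zero depth")
})

test_that("strand concordance uses a strict 20% rule and keeps unjudged dyads", {
  # 0.90 vs 0.60 -> drop; 0.80 vs 0.60 is exactly 0.20 -> keep
  expect_false(strand_concordance_keep(9, 1, 6, 4))
  expect_true(strand_concordance_keep(8, 2, 6, 4))
  expect_false(strand_concordance_keep(10, 0, 0, 10))
  # unobserved strand cannot be judged
  expect_true(strand_concordance_keep(10, 10, 0, 0))
})

test_that("joint coverage rule requires every sample at the threshold", {
  co <- small_sim(seed = 5, n_sites = 300, n_dms = 0, n_dmr = 0)
  res <- cohort_coverage_filter(co$counts, min_reads = 20)
  # brute-force recount over all sites and samples
  depths <- co$counts |>
    dplyr::mutate(depth = fwd_meth + fwd_unmeth + rev_meth + rev_unmeth)
  expected <- 0L
  for (p in unique(depths$pos)) {
    d <- depths$depth[depths$pos == p]
    if (length(d) == nrow(co$meta) && all(d >= 20)) expected <- expected + 1L
  }
  expect_equal(nrow(res$sites), expected)
})

test_that("boundary depths follow the >= rule exactly", {
  mk <- function(d1, d2) {
    tibble::tibble(sample_id = c("a", "b"), pair_id = "MZ1",
                   status = c("affected", "unaffected"), chrom = "c",
                   pos = 1L, fwd_meth = c(d1, d2), fwd_unmeth = 0L,
                   rev_meth = 0L, rev_unmeth = 0L)
  }
  expect_equal(nrow(cohort_coverage_filter(mk(20L, 20L), 20)$sites), 1L)
  expect_equal(nrow(cohort_coverage_filter(mk(19L, 30L), 20)$sites), 0L)
})

test_that("blacklist removal honours the half-open BED boundary", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(100L, 101L, 200L))
  iv <- tibble::tibble(chrom = "chr1", start = 100L, end = 101L)
  kept <- apply_blacklist(sites, iv)
  expect_equal(kept$pos, c(100L, 200L))

  # random toy set equals the brute-force set difference
  set.seed(42)
  sites2 <- tibble::tibble(chrom = "chr1", pos = sort(sample.int(500, 80)))
  iv2 <- tibble::tibble(chrom = "chr1",
                        start = c(50L, 200L, 400L), end = c(90L, 260L, 410L))
  kept2 <- apply_blacklist(sites2, iv2)
  expect_equal(kept2$pos, sites2$pos[!oracle_in_intervals(sites2$pos, iv2)])
})

test_that("conversion efficiency is the converted fraction", {
  expect_equal(conversion_efficiency(980, 20), 0.98)
  expect_equal(conversion_efficiency(1000, 0), 1)
  expect_error(conversion_efficiency(0, 0), "zero total")
  # binomial sampling: estimate close to the simulated truth
  set.seed(7)
  n <- 10000
  unconv <- rbinom(1, n, 0.02)
  est <- conversion_efficiency(n - unconv, unconv)
  se <- sqrt(0.98 * 0.02 / n)
  expect_lt(abs(est - 0.98), 3 * se)
})

test_that("filtering is order-independent: each filter is a site predicate", {
  co <- small_sim(seed = 9, n_sites = 400, n_dms = 3, n_dmr = 1)
  res <- filter_cohort(co$counts, blacklist = co$blacklist)
  # recompute the retained set applying the predicates in another order
  depths <- co$counts |>
    dplyr::mutate(depth = fwd_meth + fwd_unmeth + rev_meth + rev_unmeth)
  all_pos <- sort(unique(co$counts$pos))
  keep <- vapply(all_pos, function(p) {
    rows <- depths[depths$pos == p, ]
    bl <- oracle_in_intervals(p, co$blacklist)
    strand_ok <- all(strand_concordance_keep(rows$fwd_meth, rows$fwd_unmeth,
                                             rows$rev_meth, rows$rev_unmeth))
    cov_ok <- nrow(rows) == nrow(co$meta) && all(rows$depth >= 20)
    !bl && strand_ok && cov_ok
  }, logical(1))
  expect_equal(res$beta$pos, all_pos[keep])
  expect_true(all(res$beta[co$meta$sample_id] >= 0 &
                    res$beta[co$meta$sample_id] <= 1))
})

test_that("the packaged 30-site fixture drops hand-computed counts per filter", {
  dir <- system.file("extdata", "qc_fixture", package = "twinmeth")
  a <- read_cytosine_report(file.path(dir, "MZ1A.CpG_report.txt"),
                            "MZ1A", "MZ1", "affected")
  u <- read_cytosine_report(file.path(dir, "MZ1U.CpG_report.txt"),
                            "MZ1U", "MZ1", "unaffected")
  counts <- dplyr::bind_rows(a, u)
  bl <- read_bed(file.path(dir, "blacklist.bed"))
  res <- filter_cohort(counts, min_reads = 20, max_strand_delta = 0.20,
                       blacklist = bl)
  expect_equal(res$qc$n_sites_in, 30L)
  expect_equal(res$qc$n_dropped_coverage, 2L)   # depth 19 at 3000, 3200
  expect_equal(res$qc$n_dropped_strand, 2L)     # diff 0.30 at 3400, 1.0 at 3600
  expect_equal(res$qc$n_dropped_blacklist, 1L)  # pos 2800 in (2700, 2800]
  expect_equal(res$qc$n_retained, 25L)
  expect_true(2700L %in% res$beta$pos)          # start boundary stays
  expect_false(2800L %in% res$beta$pos)
  # exact-0.20 strand difference is kept, single-strand dyad is kept
  expect_true(all(c(3100L, 3300L, 3500L, 3700L) %in% res$beta$pos))
  # retained betas follow count arithmetic
  expect_equal(res$beta$MZ1A[res$beta$pos == 1000], 0.75)
  expect_equal(res$beta$MZ1A[res$beta$pos == 3700], 0.5)
  lam <- readr::read_tsv(file.path(dir, "lambda.tsv"), show_col_types = FALSE)
  expect_equal(conversion_efficiency(lam$converted, lam$unconverted), 0.98)
})
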