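pos_in_intervals_or <- function(regions, intervals) {
  vapply(seq_len(nrow(regions)), function(i) {
    any(intervals$chrom == regions$chrom[i] &
          regions$start[i] <= intervals$end &
          regions$end[i] > intervals$start)
  }, logical(1))
}

test_that("shrinkage is a beta-binomial posterior mean", {
  expect_equal(shrink_beta(15, 5, c(0, 0)), 0.75)
  expect_equal(shrink_beta(15, 5, c(1, 1)), 16 / 22)
  # prior-dominated limit
  expect_equal(shrink_beta(15, 5, c(2e6, 8e6)), 0.2, tolerance = 1e-4)
  expect_error(shrink_beta(0, 0, c(0, 0)), "zero total")
})

test_that("fit_prior recovers the landscape mean at fixed strength", {
  expect_equal(fit_prior(rep(5, 20), rep(5, 20), 4), c(2, 2))
  set.seed(31)
  b <- rbeta(10000, 2, 8)
  depth <- 50
  m <- round(b * depth)
  pr <- fit_prior(m, depth - m, 10)
  expect_equal(pr[1] / sum(pr), 0.2, tolerance = 0.02)
  # degenerate input falls back to the symmetric prior
  expect_equal(fit_prior(rep(10, 15), rep(0, 15), 2), c(1, 1))
  expect_error(fit_prior(1:5, 5:1), "at least 10")
})

test_that("candidate sites use a strict per-site threshold", {
  expect_equal(candidate_sites(c(0.20, -0.21, 0.3, NA, -0.1)),
               c(FALSE, TRUE, TRUE, FALSE, FALSE))
})

test_that("merge_regions handles the construction and direction examples", {
  # three same-sign sites within gaps -> one region
  r <- merge_regions(c(100L, 900L, 1800L), c(0.30, 0.40, 0.35))
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_cpgs, 3L)
  expect_equal(r$mean_delta, 0.35)
  expect_equal(r$direction, "hyper")
  expect_equal(c(r$start, r$end), c(100L, 1800L))
  # a direction flip breaks the run
  r2 <- merge_regions(c(100L, 200L, 300L), c(0.30, -0.40, 0.35))
  expect_equal(nrow(r2), 0L)
  # a gap beyond 2 kb between members breaks the run
  r3 <- merge_regions(c(100L, 900L, 3000L), c(0.30, 0.40, 0.35))
  expect_equal(nrow(r3), 0L)
  # region mean must exceed 0.25 in magnitude
  r4 <- merge_regions(c(100L, 200L, 300L), c(0.21, 0.21, 0.21))
  expect_equal(nrow(r4), 0L)
})

test_that("strict contiguity breaks runs at interleaved non-qualifying CpGs", {
  pos <- c(100L, 200L, 300L, 400L, 500L)
  delta <- c(0.3, 0.3, 0.1, 0.3, 0.3)
  expect_equal(nrow(merge_regions(pos, delta, strict_contiguity = TRUE)), 0L)
  r <- merge_regions(pos, delta, strict_contiguity = FALSE)
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_cpgs, 4L)
})

test_that("merge_regions equals exhaustive enumeration on random instances", {
  set.seed(404)
  for (rep in 1:40) {
    n <- sample(10:200, 1)
    pos <- sort(sample.int(n * 300L, n))
    delta <- round(runif(n, -0.5, 0.5), 2)
    strict <- rep %% 2 == 0
    got <- merge_regions(pos, delta, strict_contiguity = strict) |>
      dplyr::select(start, end, n_cpgs, mean_delta)
    want <- oracle_merge(pos, delta, strict = strict)
    expect_equal(tibble::as_tibble(got), want, info = paste("rep", rep))
  }
})

test_that("every reported region satisfies all four rule clauses post hoc", {
  set.seed(505)
  for (rep in 1:10) {
    n <- 150
    pos <- sort(sample.int(40000L, n))
    delta <- round(rnorm(n, 0, 0.25), 2)
    r <- merge_regions(pos, delta)
    for (i in seq_len(nrow(r))) {
      mem <- r$member_positions[[i]]
      d <- delta[match(mem, pos)]
      expect_gte(length(mem), 3L)
      expect_true(all(abs(d) > 0.20))
      expect_true(all(d > 0) || all(d < 0))
      expect_gt(abs(mean(d)), 0.25)
      expect_true(all(diff(mem) <= 2000))
    }
  }
})

test_that("raising thresholds never yields more regions", {
  set.seed(606)
  pos <- sort(sample.int(30000L, 120))
  delta <- round(rnorm(120, 0, 0.3), 2)
  base <- nrow(merge_regions(pos, delta))
  expect_lte(nrow(merge_regions(pos, delta, min_sites = 4)), base)
  expect_lte(nrow(merge_regions(pos, delta, site_delta_min = 0.3)), base)
  expect_lte(nrow(merge_regions(pos, delta, region_mean_delta_min = 0.35)),
             base)
  expect_lte(nrow(merge_regions(pos, delta, max_gap = 500)), base)
})

test_that("zero shrinkage reproduces the raw DMS deltas exactly", {
  co <- small_sim(seed = 41, n_sites = 400, n_dms = 3, n_dmr = 1)
  f <- filter_cohort(co$counts, blacklist = co$blacklist)
  sb <- twinmeth:::shrunken_beta_matrix(f$counts, 0)
  d <- call_dms(f$beta, co$meta)
  for (pr in c("MZ1", "MZ4")) {
    raw <- d$delta[d$pair_id == pr]
    sh <- sb[[paste0(pr, "A")]] - sb[[paste0(pr, "U")]]
    expect_equal(raw, sh)
  }
})

test_that("planted regions are recovered and a quiet pair yields nothing", {
  co <- small_sim(seed = 51, n_sites = 3000, n_dms = 0, n_dmr = 4)
  f <- filter_cohort(co$counts, blacklist = co$blacklist)
  r <- call_dmrs(f$counts, co$meta)
  sc <- score_dmr_calls(r, co$truth,
                        dplyr::distinct(f$beta, chrom, pos))
  expect_equal(sc$n_recovered, sc$n_testable)
  expect_gte(sc$n_testable, 3L)
  quiet <- setdiff(unique(co$meta$pair_id),
                   unique(co$truth$pair_id[co$truth$kind == "DMR"]))
  if (length(quiet)) {
    vmr_free <- r[!pos_in_intervals_or(r, co$vmr), ]
    expect_false(any(vmr_free$pair_id %in% quiet))
  }
})

test_that("groupwise mode uses group-mean differences", {
  meta <- tibble::tibble(
    sample_id = c("p1A", "p1U", "p2A", "p2U"),
    pair_id = c("p1", "p1", "p2", "p2"),
    status = rep(c("affected", "unaffected"), 2))
  # 3 nearby sites where both affected samples drop by ~0.4
  counts <- tidyr::expand_grid(
    sample_id = meta$sample_id,
    pos = c(100L, 300L, 500L)) |>
    dplyr::left_join(meta, by = "sample_id") |>
    dplyr::mutate(chrom = "c",
                  fwd_meth = ifelse(status == "affected", 25L, 45L),
                  fwd_unmeth = ifelse(status == "affected", 25L, 5L),
                  rev_meth = 0L, rev_unmeth = 0L)
  r <- call_dmrs(counts, meta, mode = "groupwise", shrinkage_strength = 0)
  expect_equal(nrow(r), 1L)
  expect_equal(r$pair_id, "group")
  expect_equal(r$mean_delta, -0.4)
  expect_equal(r$direction, "hypo")
})
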