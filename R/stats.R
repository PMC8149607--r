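#' Enumerate sample pairings with relationship labels
#'
#' Builds every unordered pair of cohort samples and labels it `co-twin`
#' (same pair), or for samples from different twin pairs
#' `unaffected-unaffected`, `affected-affected`, or `inter-twin`
#' (affected vs unaffected).
#'
#' @param meta Sample metadata (`sample_id`, `pair_id`, `status`).
#' @return Tibble `sample_a`, `sample_b`, `relationship`; all
#'   between-family rows additionally carry `unrelated = TRUE`.
#' @export
build_pairing_scheme <- function(meta) {
  n <- nrow(meta)
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  a <- idx[, 1]; b <- idx[, 2]
  same_pair <- meta$pair_id[a] == meta$pair_id[b]
  rel <- ifelse(same_pair, "co-twin",
         ifelse(meta$status[a] == "unaffected" & meta$status[b] == "unaffected",
                "unaffected-unaffected",
         ifelse(meta$status[a] == "affected" & meta$status[b] == "affected",
                "affected-affected", "inter-twin")))
  tibble(sample_a = meta$sample_id[a], sample_b = meta$sample_id[b],
         relationship = rel, unrelated = !same_pair)
}

#' Pairwise Pearson correlation of methylomes
#'
#' Computes, for each listed sample pair, the Pearson correlation of beta
#' values over sites where both are present, and summarises by
#' relationship. Pairs with a constant vector are excluded with a warning.
#'
#' @param beta Wide beta matrix (`chrom`, `pos`, sample columns).
#' @param scheme Pairing tibble from [build_pairing_scheme()] (or any
#'   tibble with `sample_a`, `sample_b`, `relationship`).
#' @param method Correlation method (default `"pearson"`).
#' @return List with `pairs` (per-pair `r`) and `summary` (per
#'   relationship: `mean_r`, `sd_r`, `n_pairs`).
#' @export
pairwise_correlation <- function(beta, scheme, method = "pearson") {
  r <- map_dbl(seq_len(nrow(scheme)), function(i) {
    x <- beta[[scheme$sample_a[i]]]
    y <- beta[[scheme$sample_b[i]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) return(NA_real_)
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    cor(x[ok], y[ok], method = method)
  })
  if (anyNA(r)) warn("some pairs had constant or insufficient data; excluded")
  pairs <- bind_cols(scheme, tibble(r = r))
  summary <- pairs |>
    filter(!is.na(.data$r)) |>
    group_by(.data$relationship) |>
    summarise(mean_r = mean(.data$r), sd_r = sd(.data$r),
              n_pairs = n(), .groups = "drop")
  list(pairs = pairs, summary = summary)
}

#' Mask sites by genomic intervals
#'
#' `remove` drops the sites falling inside the intervals; `keep_only`
#' retains only those sites. Intervals use the BED convention.
#'
#' @param beta Site-by-sample tibble with `chrom`, `pos`.
#' @param intervals Interval tibble (`chrom`, `start`, `end`) or `NULL`.
#' @param mode `"remove"` or `"keep_only"`.
#' @return The masked tibble.
#' @export
mask_intervals <- function(beta, intervals, mode = c("remove", "keep_only")) {
  mode <- match.arg(mode)
  inside <- pos_in_intervals(beta$chrom, beta$pos, intervals)
  beta[if (mode == "remove") !inside else inside, , drop = FALSE]
}

#' Per-site mean absolute methylation difference for a relationship
#'
#' For each site, averages `|beta_a - beta_b|` over all pairs of the
#' requested relationship.
#'
#' @param beta Wide beta matrix.
#' @param scheme Pairing tibble.
#' @param relationship Relationship label to profile (e.g. `"co-twin"`);
#'   alternatively `"unrelated"` selects all between-family pairs.
#' @return Numeric vector (one value per site) in `[0, 1]`.
#' @export
abs_diff_profile <- function(beta, scheme, relationship) {
  sel <- if (identical(relationship, "unrelated")) scheme$unrelated
         else scheme$relationship == relationship
  sub <- scheme[sel, , drop = FALSE]
  if (nrow(sub) == 0L) abort(sprintf("no pairs with relationship %s",
                                     relationship))
  acc <- rep(0, nrow(beta))
  for (i in seq_len(nrow(sub))) {
    acc <- acc + abs(beta[[sub$sample_a[i]]] - beta[[sub$sample_b[i]]])
  }
  acc / nrow(sub)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' uses the asymptotic Kolmogorov distribution with effective sample size
#' `n_x n_y / (n_x + n_y)` (or, with `exact = TRUE`, the exact method of
#' [stats::ks.test()] where available).
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact Use the exact small-sample p-value (default `FALSE`).
#' @return List with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(x, y, exact = FALSE) {
  if (length(x) == 0L || length(y) == 0L) abort("empty input to KS test")
  res <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Cross-platform concordance of methylation calls
#'
#' Pearson correlation over shared loci plus the fraction of loci whose
#' absolute difference is strictly below `delta_cut`.
#'
#' @param beta_a,beta_b Tibbles with `chrom`, `pos`, `beta` for the two
#'   platforms.
#' @param delta_cut Concordance threshold on `|beta_a - beta_b|`
#'   (default 0.2, strict `<`).
#' @return Tibble `pearson_r`, `frac_small_delta`, `n_loci`.
#' @export
platform_concordance <- function(beta_a, beta_b, delta_cut = 0.2) {
  m <- inner_join(beta_a, beta_b, by = c("chrom", "pos"),
                  suffix = c("_a", "_b"))
  if (nrow(m) < 3L) abort("fewer than 3 shared loci")
  d <- m$beta_a - m$beta_b
  tibble(pearson_r = cor(m$beta_a, m$beta_b),
         frac_small_delta = mean(strict_lt(abs(d), delta_cut)),
         n_loci = nrow(m))
}
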