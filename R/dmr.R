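#' Beta-binomial posterior-mean shrinkage of a methylation level
#'
#' Posterior mean `(meth + a) / (meth + unmeth + a + b)` under a
#' `Beta(a, b)` prior. With `a = b = 0` this is the raw beta value; as the
#' prior grows the estimate approaches `a / (a + b)`.
#'
#' @param meth,unmeth Read counts (vectorised).
#' @param prior Numeric `c(a, b)` pseudo-counts, both `>= 0`.
#' @return Shrunken beta values.
#' @examples
#' shrink_beta(15, 5, c(1, 1))   # 16/22
#' @export
shrink_beta <- function(meth, unmeth, prior) {
  stopifnot(length(prior) == 2L, all(prior >= 0))
  denom <- meth + unmeth + prior[1] + prior[2]
  if (any(denom <= 0)) abort("shrink_beta: zero total (counts + prior)")
  (meth + prior[1]) / denom
}

#' Method-of-moments beta prior for one sample's methylation landscape
#'
#' Fits a beta distribution to the sample's raw beta values by matching
#' mean and variance, then rescales the concentration to
#' `shrinkage_strength` pseudo-counts. Degenerate moments (zero variance,
#' or variance exceeding the Bernoulli bound) fall back to a uniform
#' `Beta(1, 1)` scaled to the requested strength.
#'
#' @param meth,unmeth Vectors of per-site read counts for one sample
#'   (length >= 10).
#' @param shrinkage_strength Total prior pseudo-counts `a + b` (default 2).
#' @return Numeric `c(a, b)`.
#' @export
fit_prior <- function(meth, unmeth, shrinkage_strength = 2) {
  stopifnot(length(meth) == length(unmeth), shrinkage_strength >= 0)
  depth <- meth + unmeth
  keep <- depth > 0
  if (sum(keep) < 10L) abort("fit_prior needs at least 10 covered sites")
  b <- meth[keep] / depth[keep]
  m <- mean(b)
  v <- var(b)
  if (!is.finite(v) || v <= 0 || v >= m * (1 - m) || m <= 0 || m >= 1) {
    prop <- 0.5
  } else {
    # method-of-moments concentration, used only for the mean split here:
    # the strength is fixed by shrinkage_strength
    prop <- m
  }
  shrinkage_strength * c(prop, 1 - prop)
}

#' Sites qualifying for region membership
#'
#' @param delta Signed per-site within-pair differences.
#' @param site_delta_min Per-site magnitude threshold (default 0.20,
#'   strict `>`).
#' @return Logical vector of qualifying sites.
#' @export
candidate_sites <- function(delta, site_delta_min = 0.20) {
  !is.na(delta) & strict_gt(abs(delta), site_delta_min)
}

#' Merge qualifying CpGs into differentially methylated regions
#'
#' Builds maximal runs of same-direction qualifying CpGs in which every
#' pair of consecutive member CpGs lies within `max_gap` bp; runs with at
#' least `min_sites` members and region-mean `|delta| >
#' region_mean_delta_min` are reported. By default, non-qualifying CpGs
#' between members are transparent (they do not break a run); with
#' `strict_contiguity = TRUE` any interleaved non-qualifying CpG breaks
#' the run. An opposite-direction qualifying CpG always breaks the run.
#'
#' @param pos Sorted 1-based positions (one chromosome).
#' @param delta Signed per-site differences aligned with `pos`.
#' @param min_sites Minimum member CpGs (default 3).
#' @param site_delta_min Per-site threshold (default 0.20).
#' @param max_gap Maximum distance between consecutive member CpGs in bp
#'   (default 2000).
#' @param region_mean_delta_min Region-mean magnitude threshold
#'   (default 0.25).
#' @param strict_contiguity Break runs at interleaved non-qualifying CpGs
#'   (default `FALSE`).
#' @return Tibble with `start`, `end` (positions of first/last member),
#'   `n_cpgs`, `direction` (`"hyper"`/`"hypo"` in the affected sample),
#'   `mean_delta`, and `member_positions` (list column).
#' @export
merge_regions <- function(pos, delta, min_sites = 3, site_delta_min = 0.20,
                          max_gap = 2000, region_mean_delta_min = 0.25,
                          strict_contiguity = FALSE) {
  stopifnot(length(pos) == length(delta), min_sites >= 2)
  if (is.unsorted(pos, strictly = TRUE)) {
    abort("merge_regions: positions must be strictly increasing")
  }
  q <- candidate_sites(delta, site_delta_min)
  empty <- tibble(start = integer(), end = integer(), n_cpgs = integer(),
                  direction = character(), mean_delta = double(),
                  member_positions = list())
  if (!any(q)) return(empty)

  if (strict_contiguity) {
    # runs may only contain consecutive qualifying CpGs of one sign
    idx <- seq_along(pos)
    brk <- c(TRUE, diff(idx[q]) > 1L |
               diff(pos[q]) > max_gap |
               diff(sign(delta[q])) != 0)
  } else {
    # non-qualifying CpGs are transparent; gaps measured between members
    brk <- c(TRUE, diff(pos[q]) > max_gap | diff(sign(delta[q])) != 0)
  }
  qi <- which(q)
  run <- cumsum(brk)
  out <- lapply(split(qi, run), function(ii) {
    d <- delta[ii]
    if (length(ii) < min_sites) return(NULL)
    md <- mean(d)
    if (!strict_gt(abs(md), region_mean_delta_min)) return(NULL)
    tibble(start = pos[ii[1]], end = pos[ii[length(ii)]],
           n_cpgs = length(ii),
           direction = if (md > 0) "hyper" else "hypo",
           mean_delta = md,
           member_positions = list(pos[ii]))
  })
  out <- bind_rows(out)
  if (nrow(out) == 0L) empty else arrange(out, .data$start)
}

#' Call differentially methylated regions for a cohort
#'
#' Computes per-site within-pair (or group-wise) differences on shrunken
#' beta values and applies the region rules of [merge_regions()] per
#' chromosome. In `pairwise` mode the difference is affected minus
#' unaffected within each pair; in `groupwise` mode it is the mean of all
#' affected minus the mean of all unaffected samples.
#'
#' Shrinkage uses a per-sample empirical-Bayes beta-binomial posterior
#' mean ([shrink_beta()] with a [fit_prior()] prior); with
#' `shrinkage_strength = 0` the differences equal the raw beta differences
#' used by [call_dms()].
#'
#' @param counts Long tibble of retained per-sample stranded counts (the
#'   `counts` element of [filter_cohort()]).
#' @param meta Sample metadata.
#' @param mode `"pairwise"` or `"groupwise"`.
#' @param min_sites,site_delta_min,max_gap,region_mean_delta_min Region
#'   rules; see [merge_regions()].
#' @param shrinkage_strength Prior pseudo-counts for the shrinkage stage
#'   (default 2; 0 disables shrinkage).
#' @param strict_contiguity Passed to [merge_regions()].
#' @return A tibble of class `twin_dmr`: one row per region with `chrom`,
#'   `start`, `end`, `n_cpgs`, `pair_id` (`"group"` in groupwise mode),
#'   `direction`, `mean_delta`, `member_positions`.
#' @export
call_dmrs <- function(counts, meta, mode = c("pairwise", "groupwise"),
                      min_sites = 3, site_delta_min = 0.20, max_gap = 2000,
                      region_mean_delta_min = 0.25, shrinkage_strength = 2,
                      strict_contiguity = FALSE) {
  mode <- match.arg(mode)
  sb <- shrunken_beta_matrix(counts, shrinkage_strength)
  run_one <- function(delta_tab, label) {
    delta_tab |>
      group_by(.data$chrom) |>
      group_modify(~ merge_regions(.x$pos, .x$delta,
                                   min_sites = min_sites,
                                   site_delta_min = site_delta_min,
                                   max_gap = max_gap,
                                   region_mean_delta_min = region_mean_delta_min,
                                   strict_contiguity = strict_contiguity)) |>
      ungroup() |>
      mutate(pair_id = label)
  }
  if (mode == "pairwise") {
    out <- bind_rows(lapply(unique(meta$pair_id), function(pr) {
      aff <- meta$sample_id[meta$pair_id == pr & meta$status == "affected"]
      una <- meta$sample_id[meta$pair_id == pr & meta$status == "unaffected"]
      tab <- tibble(chrom = sb$chrom, pos = sb$pos,
                    delta = sb[[aff]] - sb[[una]])
      run_one(tab, pr)
    }))
  } else {
    aff <- meta$sample_id[meta$status == "affected"]
    una <- meta$sample_id[meta$status == "unaffected"]
    tab <- tibble(
      chrom = sb$chrom, pos = sb$pos,
      delta = rowMeans(as.matrix(sb[, aff, drop = FALSE])) -
        rowMeans(as.matrix(sb[, una, drop = FALSE]))
    )
    out <- run_one(tab, "group")
  }
  out <- select(out, "chrom", "start", "end", "n_cpgs", "pair_id",
                "direction", "mean_delta", "member_positions")
  class(out) <- c("twin_dmr", class(out))
  out
}

# site-by-sample matrix of (optionally) shrunken dyad beta values
shrunken_beta_matrix <- function(counts, shrinkage_strength) {
  counts <- mutate(counts,
                   m = .data$fwd_meth + .data$rev_meth,
                   u = .data$fwd_unmeth + .data$rev_unmeth)
  if (shrinkage_strength > 0) {
    counts <- counts |>
      group_by(.data$sample_id) |>
      group_modify(function(df, key) {
        pr <- fit_prior(df$m, df$u, shrinkage_strength)
        mutate(df, beta = shrink_beta(.data$m, .data$u, pr))
      }) |>
      ungroup()
  } else {
    counts <- mutate(counts, beta = .data$m / (.data$m + .data$u))
  }
  counts |>
    select("chrom", "pos", "sample_id", "beta") |>
    pivot_wider(names_from = "sample_id", values_from = "beta") |>
    arrange(.data$chrom, .data$pos)
}

#' Export regions as BED6
#'
#' Score is `1000 * |mean_delta|` (capped at 1000), strand `"."`.
#'
#' @param dmrs A `twin_dmr` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                   dmrs$chrom, dmrs$start - 1L, dmrs$end,
                   paste0(dmrs$pair_id, "_", dmrs$direction),
                   pmin(1000L, as.integer(round(1000 * abs(dmrs$mean_delta)))))
  writeLines(lines, path)
  invisible(path)
}
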