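#' Methylation level from read counts
#'
#' beta = methylated / (methylated + unmethylated).
#'
#' @param meth,unmeth Non-negative read counts (vectorised).
#' @return Fraction in `[0, 1]`.
#' @examples
#' beta_value(15, 5)
#' @export
beta_value <- function(meth, unmeth) {
  depth <- meth + unmeth
  if (any(depth <= 0)) abort("beta undefined at zero depth")
  meth / depth
}

#' Strand concordance keep/drop decision
#'
#' A dyad is dropped when both strands are observed and the absolute
#' difference of their per-strand methylation levels strictly exceeds
#' `max_strand_delta`. Dyads with an unobserved strand cannot be judged and
#' are kept.
#'
#' @param fwd_meth,fwd_unmeth,rev_meth,rev_unmeth Per-strand counts
#'   (vectorised).
#' @param max_strand_delta Maximum tolerated |beta_fwd - beta_rev|
#'   (default 0.20).
#' @return Logical vector, `TRUE` = keep.
#' @export
strand_concordance_keep <- function(fwd_meth, fwd_unmeth, rev_meth,
                                    rev_unmeth, max_strand_delta = 0.20) {
  fd <- fwd_meth + fwd_unmeth
  rd <- rev_meth + rev_unmeth
  judged <- fd > 0 & rd > 0
  delta <- abs(fwd_meth / pmax(fd, 1) - rev_meth / pmax(rd, 1))
  !(judged & strict_gt(delta, max_strand_delta))
}

#' Joint coverage filter over a cohort
#'
#' A position is retained only when every sample has total dyad depth of at
#' least `min_reads` there, yielding the common high-confidence site set all
#' downstream comparisons use.
#'
#' @param counts Long tibble of per-sample stranded counts (as returned by
#'   [read_cytosine_report()] or [simulate_twin_cohort()]).
#' @param min_reads Minimum per-sample depth (default 20).
#' @return List with `sites` (tibble `chrom`, `pos` of retained positions)
#'   and `per_sample` (tibble of per-sample site counts before/after).
#' @export
cohort_coverage_filter <- function(counts, min_reads = 20) {
  if (nrow(counts) == 0L) abort("empty cohort")
  n_samples <- dplyr::n_distinct(counts$sample_id)
  tab <- counts |>
    mutate(depth = .data$fwd_meth + .data$fwd_unmeth +
             .data$rev_meth + .data$rev_unmeth) |>
    group_by(.data$chrom, .data$pos) |>
    summarise(n_obs = n(), min_depth = min(.data$depth), .groups = "drop")
  sites <- tab |>
    filter(.data$n_obs == n_samples, .data$min_depth >= min_reads) |>
    select("chrom", "pos") |>
    arrange(.data$chrom, .data$pos)
  per_sample <- counts |>
    group_by(.data$sample_id) |>
    summarise(n_sites_in = n(), .groups = "drop") |>
    mutate(n_sites_retained = nrow(sites))
  list(sites = sites, per_sample = per_sample)
}

#' Remove CpGs overlapping blacklist intervals
#'
#' Intervals use the BED convention (0-based, half-open); a 1-based CpG
#' position `p` is removed when `start < p <= end` for some interval.
#'
#' @param sites Tibble with at least `chrom` and `pos` columns.
#' @param intervals Tibble with `chrom`, `start`, `end`, or `NULL` (no-op).
#' @return `sites` with blacklisted rows removed, sorted by `(chrom, pos)`.
#' @export
apply_blacklist <- function(sites, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    return(arrange(sites, .data$chrom, .data$pos))
  }
  keep <- !pos_in_intervals(sites$chrom, sites$pos, intervals)
  arrange(sites[keep, , drop = FALSE], .data$chrom, .data$pos)
}

#' Bisulfite conversion efficiency from a lambda spike-in
#'
#' The unmethylated lambda-phage spike-in should read as fully converted;
#' the efficiency estimate is converted / (converted + unconverted).
#'
#' @param converted,unconverted Counts of converted (read T) and
#'   unconverted (read C) cytosines on the spike-in.
#' @return Fraction in `[0, 1]`.
#' @examples
#' conversion_efficiency(980, 20)
#' @export
conversion_efficiency <- function(converted, unconverted) {
  tot <- converted + unconverted
  if (any(tot <= 0)) abort("conversion efficiency undefined: zero total")
  converted / tot
}

#' Apply all CpG-level quality filters and build the beta matrix
#'
#' Runs, in order: the strand-concordance filter per sample (a position
#' failing in any sample is removed everywhere, so the retained set stays
#' common to all samples), the joint coverage rule, and blacklist removal.
#' Each filter is a pure per-site predicate, so the retained set does not
#' depend on the order of application.
#'
#' @param counts Long tibble of per-sample stranded counts.
#' @param min_reads Per-sample minimum dyad depth (default 20).
#' @param max_strand_delta Strand discordance threshold (default 0.20).
#' @param blacklist Optional BED-convention interval tibble.
#' @return List with `beta` (wide tibble: `chrom`, `pos`, one beta column
#'   per sample), `counts` (retained long counts) and `qc` (per-filter drop
#'   counts plus per-sample strand-flag tallies).
#' @export
filter_cohort <- function(counts, min_reads = 20, max_strand_delta = 0.20,
                          blacklist = NULL) {
  all_sites <- distinct(counts, .data$chrom, .data$pos)

  disc <- counts |>
    filter(!strand_concordance_keep(.data$fwd_meth, .data$fwd_unmeth,
                                    .data$rev_meth, .data$rev_unmeth,
                                    max_strand_delta)) |>
    distinct(.data$chrom, .data$pos)
  unjudged <- counts |>
    filter(.data$fwd_meth + .data$fwd_unmeth == 0 |
             .data$rev_meth + .data$rev_unmeth == 0) |>
    count(.data$sample_id, name = "n_single_strand_flagged")

  cov <- cohort_coverage_filter(counts, min_reads)
  cov_dropped <- anti_join(all_sites, cov$sites, by = c("chrom", "pos"))

  kept <- cov$sites |>
    anti_join(disc, by = c("chrom", "pos")) |>
    apply_blacklist(blacklist)
  bl_dropped <- nrow(anti_join(cov$sites, disc, by = c("chrom", "pos"))) -
    nrow(kept)

  retained <- counts |>
    semi_join(kept, by = c("chrom", "pos")) |>
    arrange(.data$chrom, .data$pos, .data$sample_id)
  beta <- retained |>
    mutate(beta = (.data$fwd_meth + .data$rev_meth) /
             (.data$fwd_meth + .data$fwd_unmeth +
                .data$rev_meth + .data$rev_unmeth)) |>
    select("chrom", "pos", "sample_id", "beta") |>
    pivot_wider(names_from = "sample_id", values_from = "beta") |>
    arrange(.data$chrom, .data$pos)

  qc <- list(
    n_sites_in = nrow(all_sites),
    n_dropped_coverage = nrow(cov_dropped),
    n_dropped_strand = nrow(semi_join(disc, cov$sites,
                                      by = c("chrom", "pos"))),
    n_dropped_blacklist = bl_dropped,
    n_retained = nrow(kept),
    per_sample_single_strand = unjudged
  )
  list(beta = beta, counts = retained, qc = qc)
}
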