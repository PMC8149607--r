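#' Score DMS calls against the planted truth of a simulated cohort
#'
#' Positions inside planted VMR blocks are excluded from scoring: VMR
#' sites carry genuine large within-pair differences by construction, so
#' calls there are neither planted-signal recoveries nor noise artifacts.
#' A scored call is a true positive when its (position, pair) matches a
#' planted DMS or DMR site, and a false positive otherwise. Sensitivity is
#' measured over planted DMS sites present in the analyzed site set
#' (a site removed by QC cannot be called).
#'
#' @param dms A `twin_dms` tibble from [call_dms()].
#' @param truth Truth tibble from [simulate_twin_cohort()].
#' @param vmr VMR interval tibble (BED convention) or `NULL`.
#' @return Tibble with `n_planted`, `n_testable`, `n_recovered`,
#'   `sensitivity`, `tp`, `fp`, `fdp`.
#' @export
score_dms_calls <- function(dms, truth, vmr = NULL) {
  planted_dms <- filter(truth, .data$kind == "DMS")
  planted_any <- filter(truth, .data$kind %in% c("DMS", "DMR"))
  calls <- filter(dms, .data$passes)
  scored <- calls[!pos_in_intervals(calls$chrom, calls$pos, vmr), ,
                  drop = FALSE]
  key <- function(df) paste(df$chrom, df$pos, df$pair_id)
  tp <- sum(key(scored) %in% key(planted_any))
  fp <- nrow(scored) - tp
  testable <- semi_join(planted_dms, distinct(dms, .data$chrom, .data$pos),
                        by = c("chrom", "pos"))
  recovered <- sum(key(testable) %in% key(scored))
  tibble(
    n_planted = nrow(planted_dms),
    n_testable = nrow(testable),
    n_recovered = recovered,
    sensitivity = if (nrow(testable)) recovered / nrow(testable) else NA_real_,
    tp = tp, fp = fp,
    fdp = if (tp + fp > 0) fp / (tp + fp) else 0
  )
}

#' Score DMR calls against the planted truth
#'
#' A planted region is testable when at least `min_sites` of its member
#' CpGs survive in the analyzed site set, and recovered when a called
#' region of the same pair with at least `min_sites` member CpGs overlaps
#' its span.
#'
#' @param dmrs A `twin_dmr` tibble from [call_dmrs()] (pairwise mode).
#' @param truth Truth tibble.
#' @param analyzed_sites Tibble of analyzed positions (`chrom`, `pos`).
#' @param min_sites Member threshold (default 3).
#' @return Tibble with `n_planted`, `n_testable`, `n_recovered`, and
#'   `n_unmatched_calls` (called regions overlapping no planted region of
#'   their pair).
#' @export
score_dmr_calls <- function(dmrs, truth, analyzed_sites, min_sites = 3) {
  planted <- filter(truth, .data$kind == "DMR")
  if (nrow(planted) == 0L) {
    return(tibble(n_planted = 0L, n_testable = 0L, n_recovered = 0L,
                  n_unmatched_calls = nrow(dmrs)))
  }
  spans <- planted |>
    group_by(.data$feature_id, .data$pair_id, .data$chrom) |>
    summarise(start = min(.data$pos), end = max(.data$pos),
              n_member = n(), .groups = "drop")
  present <- semi_join(planted, analyzed_sites, by = c("chrom", "pos")) |>
    count(.data$feature_id, name = "n_present")
  spans <- left_join(spans, present, by = "feature_id") |>
    mutate(n_present = dplyr::coalesce(.data$n_present, 0L),
           testable = .data$n_present >= min_sites)
  calls <- filter(dmrs, .data$n_cpgs >= min_sites)
  hit <- vapply(seq_len(nrow(spans)), function(i) {
    any(calls$pair_id == spans$pair_id[i] &
          calls$chrom == spans$chrom[i] &
          calls$start <= spans$end[i] &
          calls$end >= spans$start[i])
  }, logical(1))
  matched_call <- vapply(seq_len(nrow(calls)), function(j) {
    any(spans$pair_id == calls$pair_id[j] &
          spans$chrom == calls$chrom[j] &
          spans$start <= calls$end[j] &
          spans$end >= calls$start[j])
  }, logical(1))
  tibble(
    n_planted = nrow(spans),
    n_testable = sum(spans$testable),
    n_recovered = sum(hit & spans$testable),
    n_unmatched_calls = if (nrow(calls)) sum(!matched_call) else 0L
  )
}
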