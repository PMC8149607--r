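#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the passing records of a DMS call set
#'
#' @param x A `twin_dms` tibble.
#' @param all_sites Return every (site, pair) record, not only passing
#'   ones (default `FALSE`).
#' @param ... Unused.
#' @return A plain tibble of passing DMS records.
#' @method tidy twin_dms
#' @export
tidy.twin_dms <- function(x, all_sites = FALSE, ...) {
  out <- as_tibble(x)
  if (!all_sites) out <- filter(out, .data$passes)
  out
}

#' One-row summary of a DMS call set
#'
#' @param x A `twin_dms` tibble.
#' @param ... Unused.
#' @return Tibble with thresholds, site/pair counts and calls per pair.
#' @method glance twin_dms
#' @export
glance.twin_dms <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble(
    delta_min = th$delta_min, cv_max = th$cv_max,
    n_sites = dplyr::n_distinct(paste(x$chrom, x$pos)),
    n_pairs = dplyr::n_distinct(x$pair_id),
    n_calls = sum(x$passes),
    mean_abs_delta_calls = mean(abs(x$delta[x$passes]))
  )
}

#' Tidy a DMR call set
#'
#' @param x A `twin_dmr` tibble.
#' @param ... Unused.
#' @return A plain tibble (member positions flattened to a
#'   comma-separated string).
#' @method tidy twin_dmr
#' @export
tidy.twin_dmr <- function(x, ...) {
  as_tibble(x) |>
    mutate(member_positions = map_chr(.data$member_positions,
                                      paste, collapse = ","))
}

#' One-row summary of a DMR call set
#'
#' @param x A `twin_dmr` tibble.
#' @param ... Unused.
#' @return Tibble with region counts, size and effect summaries.
#' @method glance twin_dmr
#' @export
glance.twin_dmr <- function(x, ...) {
  tibble(
    n_regions = nrow(x),
    n_hyper = sum(x$direction == "hyper"),
    n_hypo = sum(x$direction == "hypo"),
    median_n_cpgs = if (nrow(x)) stats::median(x$n_cpgs) else NA_real_,
    median_span = if (nrow(x)) stats::median(x$end - x$start + 1) else NA_real_,
    mean_abs_delta = if (nrow(x)) mean(abs(x$mean_delta)) else NA_real_
  )
}

#' One-row summary of a pipeline run
#'
#' @param x A `twin_pipeline` object.
#' @param ... Unused.
#' @return Tibble with retained-site count, DMS/DMR recovery metrics,
#'   relationship correlations and conversion efficiency.
#' @method glance twin_pipeline
#' @export
glance.twin_pipeline <- function(x, ...) {
  co <- x$correlations$summary
  mr <- function(rel) {
    v <- co$mean_r[co$relationship == rel]
    if (length(v)) v else NA_real_
  }
  unrel <- x$correlations$pairs |>
    filter(.data$unrelated, !is.na(.data$r))
  tibble(
    n_sites_retained = nrow(x$filtered$beta),
    n_dms_calls = sum(x$dms$passes),
    dms_sensitivity = x$dms_score$sensitivity,
    dms_fdp = x$dms_score$fdp,
    n_dmrs = nrow(x$dmrs),
    dmr_recovered = x$dmr_score$n_recovered,
    dmr_testable = x$dmr_score$n_testable,
    mean_r_cotwin = mr("co-twin"),
    mean_r_unrelated = mean(unrel$r),
    ks_d = x$ks$statistic,
    conversion_efficiency = x$conversion
  )
}
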