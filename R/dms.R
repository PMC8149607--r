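#' Within-pair methylation difference
#'
#' Signed difference affected minus unaffected; negative values mean the
#' affected twin is hypomethylated.
#'
#' @param beta_affected,beta_unaffected Beta values (vectorised).
#' @return Signed fraction in `[-1, 1]`.
#' @examples
#' delta_methylation(0.10, 0.94)   # -0.84, hypomethylated in affected
#' @export
delta_methylation <- function(beta_affected, beta_unaffected) {
  beta_affected - beta_unaffected
}

#' Coefficient of variation across unaffected individuals
#'
#' Sample standard deviation (n-1 denominator) divided by the mean of the
#' unaffected co-twins' beta values at one site. A zero mean returns `Inf`
#' so the site always fails the variability gate.
#'
#' @param betas Numeric vector of unaffected beta values (length >= 2).
#' @return Non-negative real (possibly `Inf`).
#' @examples
#' cv_unaffected(c(0.2, 0.4, 0.6, 0.8))   # ~0.516
#' @export
cv_unaffected <- function(betas) {
  if (length(betas) < 2L) abort("cv_unaffected needs at least 2 values")
  m <- mean(betas)
  if (m == 0) return(Inf)
  sd(betas) / m
}

#' M-value (logit, base 2) of a beta value
#'
#' `log2(beta / (1 - beta))` with beta clamped to `[eps, 1 - eps]` so the
#' boundaries stay finite. `m_value(0.5)` is 0 and
#' `m_value(b) == -m_value(1 - b)`.
#'
#' @param beta Beta values in `[0, 1]` (vectorised).
#' @param eps Clamping bound (default 1e-6).
#' @return Real M-values.
#' @examples
#' m_value(0.8)   # 2
#' @export
m_value <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Call differentially methylated positions within each twin pair
#'
#' For every pair and every site of the filtered beta matrix, computes the
#' within-pair difference (affected - unaffected) and the coefficient of
#' variation of the unaffected group, and flags sites passing both rules:
#' `|delta| > delta_min` (strict) and `cv < cv_max` (strict).
#'
#' @param beta Wide beta matrix (`chrom`, `pos`, one column per sample), as
#'   produced by [filter_cohort()].
#' @param meta Sample metadata (`sample_id`, `pair_id`, `status`).
#' @param delta_min Minimum absolute within-pair difference (default 0.30).
#' @param cv_max Maximum coefficient of variation across unaffected
#'   individuals (default 0.25).
#' @param cv_leave_out If `TRUE`, the unaffected twin of the pair under
#'   test is excluded from its own pair's CV (default `FALSE`: the CV is
#'   computed once over all unaffected individuals).
#' @return A tibble of class `twin_dms` with one row per (site, pair):
#'   `chrom`, `pos`, `pair_id`, `beta_affected`, `beta_unaffected`,
#'   `delta`, `cv_unaffected`, `passes`.
#' @export
call_dms <- function(beta, meta, delta_min = 0.30, cv_max = 0.25,
                     cv_leave_out = FALSE) {
  stopifnot(all(c("chrom", "pos") %in% names(beta)),
            all(c("sample_id", "pair_id", "status") %in% names(meta)),
            delta_min > 0, delta_min <= 1, cv_max > 0, cv_max <= 1)
  miss <- setdiff(meta$sample_id, names(beta))
  if (length(miss)) {
    abort(sprintf("samples missing from beta matrix: %s",
                  paste(miss, collapse = ", ")))
  }
  pairs <- unique(meta$pair_id)
  un_ids <- meta$sample_id[meta$status == "unaffected"]
  un_mat <- as.matrix(beta[, un_ids, drop = FALSE])

  res <- vector("list", length(pairs))
  for (k in seq_along(pairs)) {
    pr <- pairs[k]
    aff <- meta$sample_id[meta$pair_id == pr & meta$status == "affected"]
    una <- meta$sample_id[meta$pair_id == pr & meta$status == "unaffected"]
    if (length(aff) != 1L || length(una) != 1L) {
      abort(sprintf("pair %s must have exactly one affected and one unaffected sample", pr))
    }
    cv_cols <- if (cv_leave_out) setdiff(un_ids, una) else un_ids
    cv_m <- un_mat[, cv_cols, drop = FALSE]
    mu <- rowMeans(cv_m)
    s <- apply(cv_m, 1L, sd)
    cv <- ifelse(mu == 0, Inf, s / mu)
    ba <- beta[[aff]]
    bu <- beta[[una]]
    d <- delta_methylation(ba, bu)
    ok <- !is.na(d)
    res[[k]] <- tibble(
      chrom = beta$chrom, pos = beta$pos, pair_id = pr,
      beta_affected = ba, beta_unaffected = bu,
      delta = d, cv_unaffected = cv,
      passes = ok & strict_gt(abs(d), delta_min) & strict_lt(cv, cv_max)
    )
  }
  out <- bind_rows(res) |>
    filter(!is.na(.data$delta)) |>
    arrange(.data$pair_id, .data$chrom, .data$pos)
  class(out) <- c("twin_dms", class(out))
  attr(out, "thresholds") <- list(delta_min = delta_min, cv_max = cv_max)
  out
}
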