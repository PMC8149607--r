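# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately avoid the package's own code paths: plain loops and
# first-principles arithmetic only.

# beta matrix for a toy cohort: random sites x (2 * n_pairs) samples
random_beta_cohort <- function(n_sites, n_pairs) {
  meta <- tibble::tibble(
    sample_id = paste0("MZ", rep(seq_len(n_pairs), each = 2),
                       rep(c("A", "U"), n_pairs)),
    pair_id = paste0("MZ", rep(seq_len(n_pairs), each = 2)),
    status = rep(c("affected", "unaffected"), n_pairs)
  )
  beta <- tibble::tibble(chrom = "chrS",
                         pos = sort(sample.int(1e6, n_sites)))
  for (sid in meta$sample_id) beta[[sid]] <- round(runif(n_sites), 3)
  list(beta = beta, meta = meta)
}

# double loop over pairs x sites applying the two DMS rules literally
oracle_dms <- function(beta, meta, delta_min = 0.30, cv_max = 0.25) {
  un_ids <- meta$sample_id[meta$status == "unaffected"]
  out <- list()
  for (pr in unique(meta$pair_id)) {
    aff <- meta$sample_id[meta$pair_id == pr & meta$status == "affected"]
    una <- meta$sample_id[meta$pair_id == pr & meta$status == "unaffected"]
    for (i in seq_len(nrow(beta))) {
      d <- beta[[aff]][i] - beta[[una]][i]
      u <- vapply(un_ids, function(s) beta[[s]][i], numeric(1))
      cv <- if (mean(u) == 0) Inf else sd(u) / mean(u)
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = beta$chrom[i], pos = beta$pos[i], pair_id = pr,
        passes = (abs(d) - delta_min) > 1e-9 & (cv_max - cv) > 1e-9
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), pair_id, chrom, pos)
}

# exhaustive enumeration of maximal valid regions: scan all start indices
# of qualifying sites, extend greedily under the gap/direction rules, keep
# runs that no other run contains
oracle_merge <- function(pos, delta, min_sites = 3, site_min = 0.2,
                         max_gap = 2000, region_min = 0.25,
                         strict = FALSE) {
  q <- which(!is.na(delta) & (abs(delta) - site_min) > 1e-9)
  runs <- list()
  for (s in seq_along(q)) {
    members <- q[s]
    for (t in seq_along(q)) {
      if (t <= s) next
      i <- q[t]
      prev <- members[length(members)]
      gap_ok <- pos[i] - pos[prev] <= max_gap
      sign_ok <- sign(delta[i]) == sign(delta[q[s]])
      contig_ok <- !strict || i == prev + 1L
      if (gap_ok && sign_ok && contig_ok) members <- c(members, i)
      else break
    }
    runs[[s]] <- members
  }
  # maximality: drop runs contained in an earlier-starting longer run
  keep <- rep(TRUE, length(runs))
  for (a in seq_along(runs)) {
    for (b in seq_along(runs)) {
      if (a != b && all(runs[[a]] %in% runs[[b]])) keep[a] <- FALSE
    }
  }
  out <- list()
  for (m in runs[keep]) {
    if (length(m) < min_sites) next
    if (!((abs(mean(delta[m])) - region_min) > 1e-9)) next
    out[[length(out) + 1L]] <- tibble::tibble(
      start = pos[m[1]], end = pos[m[length(m)]], n_cpgs = length(m),
      mean_delta = mean(delta[m]))
  }
  if (length(out) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          n_cpgs = integer(), mean_delta = double()))
  }
  dplyr::arrange(dplyr::bind_rows(out), start)
}

# exact upper-tail hypergeometric by enumeration of the support
oracle_hyper_upper <- function(k, n, K, N) {
  xs <- max(0, n - (N - K)):min(n, K)
  probs <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  sum(probs[xs >= k])
}

# KS D as the supremum of |ECDF_x - ECDF_y| over all observed points
oracle_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), numeric(1))))
}

# O(n*m) interval membership: 1-based p in (start, end]
oracle_in_intervals <- function(pos, intervals) {
  vapply(pos, function(p) {
    any(p > intervals$start & p <= intervals$end)
  }, logical(1))
}

# tiny simulated cohort for fast end-to-end tests
small_sim <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(n_sites = 1500, n_dms = 8, n_dmr = 2, n_blacklist = 3,
                   blacklist_width = 300,
                   lambda_sites = 300, vmr_frac = 0.1, vmr_block_sites = 20)
  cfg <- do.call(twinmeth::sim_config, utils::modifyList(defaults, args))
  twinmeth::simulate_twin_cohort(cfg, seed = seed)
}
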