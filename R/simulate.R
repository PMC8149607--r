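#' Configuration for the synthetic discordant-twin cohort generator
#'
#' Builds the parameter list consumed by [simulate_twin_cohort()]. Defaults
#' describe a cohort of six male monozygotic twin pairs, one affected and
#' one unaffected per pair, sequenced to an average dyad depth of 30x, with
#' a strongly bimodal methylation landscape in which three quarters of CpGs
#' are constitutively methylated.
#'
#' The generative model works on the logit scale: each site has a baseline
#' drawn from a two-component beta mixture; each twin pair perturbs it by a
#' pair-shared effect (truncated normal, so the landscape stays bimodal);
#' each individual adds independent residual noise. Variably methylated
#' region (VMR) sites draw their baselines evenly from both mixture
#' components and receive additional individual-specific (not pair-shared)
#' logit noise. Planted differential signals are applied to the affected
#' twin on the beta scale with clipping.
#'
#' Planted features are placed in the analyzable universe: only sites
#' covered at `min_reads` in every sample, outside VMR blocks and blacklist
#' intervals, are eligible, and read counts at planted sites are drawn
#' conditional on strand concordance, so that recovery failures reflect the
#' calling rules rather than the sequencing lottery.
#'
#' @param n_pairs Number of twin pairs (default 6).
#' @param n_sites Number of CpG sites on the synthetic chromosome.
#' @param spacing Range (min, max) of inter-CpG spacing in bp; gaps are
#'   drawn uniformly, giving a mean spacing of ~100 bp.
#' @param coverage_mean Mean dyad depth per CpG (default 30).
#' @param coverage_dispersion Negative-binomial size parameter for depth
#'   overdispersion (larger = tighter; default 100).
#' @param min_reads Depth used for planted-feature eligibility, matching
#'   the downstream coverage filter (default 20).
#' @param max_strand_delta Strand-concordance bound used when conditioning
#'   planted-site counts (default 0.20).
#' @param w_high,mean_low,mean_high,conc_low,conc_high Two-component beta
#'   mixture of the baseline landscape: weight of the methylated component
#'   and the mean/concentration of each component.
#' @param pair_effect_sd Pair-shared logit-scale effect SD (default 0.9).
#' @param pair_effect_trunc Truncation of the pair effect at this many SDs
#'   (default 1.5), keeping pair shifts bounded so the landscape stays
#'   bimodal.
#' @param residual_sd Individual logit-scale residual SD (default 0.1).
#' @param vmr_frac Fraction of sites inside VMR blocks (default 0.12).
#' @param vmr_block_sites Number of consecutive CpGs per VMR block.
#' @param vmr_sd Extra individual-specific logit SD at VMR sites
#'   (default 0.65; see the methods vignette for the calibration).
#' @param n_dms,dms_delta Number and beta-scale effect of planted
#'   differentially methylated sites (default 100 at -0.5, i.e.
#'   hypomethylation of the affected twin at constitutively methylated
#'   sites).
#' @param n_dmr,dmr_sites,dmr_delta Number of planted regions, CpGs per
#'   region, and per-site beta-scale effect (default 20 regions of 5 sites
#'   at -0.4).
#' @param n_blacklist,blacklist_width Number and width (bp) of synthetic
#'   blacklist intervals.
#' @param lambda_sites Number of cytosines on the unmethylated lambda
#'   spike-in.
#' @param true_conversion True bisulfite conversion efficiency of the
#'   spike-in (default 0.98).
#' @param chrom Chromosome name of the synthetic chromosome.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 6,
                       n_sites = 50000,
                       spacing = c(20, 180),
                       coverage_mean = 30,
                       coverage_dispersion = 100,
                       min_reads = 20,
                       max_strand_delta = 0.20,
                       w_high = 0.75,
                       mean_low = 0.03, mean_high = 0.97,
                       conc_low = 120, conc_high = 300,
                       pair_effect_sd = 0.9,
                       pair_effect_trunc = 1.5,
                       residual_sd = 0.1,
                       vmr_frac = 0.12,
                       vmr_block_sites = 40,
                       vmr_sd = 0.65,
                       n_dms = 100, dms_delta = -0.5,
                       n_dmr = 20, dmr_sites = 5, dmr_delta = -0.4,
                       n_blacklist = 20, blacklist_width = 5000,
                       lambda_sites = 10000,
                       true_conversion = 0.98,
                       chrom = "chrS") {
  cfg <- as.list(environment())
  stopifnot(n_pairs >= 1, n_sites >= 10,
            abs(dms_delta) <= 1, abs(dmr_delta) <= 1,
            vmr_frac >= 0, vmr_frac < 1,
            true_conversion > 0, true_conversion <= 1)
  structure(cfg, class = "sim_config")
}

rtrunc_norm <- function(n, sd, trunc) {
  pmin(pmax(rnorm(n, 0, sd), -trunc * sd), trunc * sd)
}

# draw stranded counts for one site/sample; optionally condition on strand
# concordance (planted sites), giving up after `tries` rejections
draw_strands <- function(depth, p, condition = FALSE, max_delta = 0.2,
                         tries = 50) {
  for (k in seq_len(if (condition) tries else 1L)) {
    df <- rbinom(1L, depth, 0.5)
    dr <- depth - df
    xf <- rbinom(1L, df, p)
    xr <- rbinom(1L, dr, p)
    if (!condition || df == 0L || dr == 0L ||
        abs(xf / df - xr / dr) <= max_delta) break
  }
  c(df = df, dr = dr, xf = xf, xr = xr)
}

#' Simulate a discordant-twin WGBS cohort with planted ground truth
#'
#' Generates per-sample stranded CpG counts for `n_pairs` twin pairs under
#' the model described in [sim_config()], together with a truth table of
#' planted differentially methylated sites (DMS), regions (DMR) and
#' variably methylated region (VMR) blocks, synthetic blacklist intervals,
#' and an unmethylated lambda spike-in. The same seed always produces the
#' identical cohort.
#'
#' @param config A [sim_config()] list.
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `twin_cohort`: a list with elements
#'   `counts` (long tibble of per-sample stranded counts), `meta` (sample
#'   metadata: `sample_id`, `pair_id`, `status`), `truth` (planted-feature
#'   tibble: `kind`, `feature_id`, `pair_id`, `chrom`, `pos`, `delta`),
#'   `blacklist` and `vmr` (BED-convention interval tibbles), `lambda`
#'   (spike-in conversion counts), `config`, and `seed`.
#' @examples
#' cohort <- simulate_twin_cohort(sim_config(n_sites = 500, n_dms = 5,
#'                                           n_dmr = 2, lambda_sites = 100),
#'                                seed = 1)
#' dplyr::count(cohort$truth, kind)
#' @export
simulate_twin_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_sites
  np <- config$n_pairs
  ns <- 2L * np

  pos <- cumsum(sample(seq(config$spacing[1], config$spacing[2]), n,
                       replace = TRUE))

  # VMR blocks: consecutive runs of vmr_block_sites CpGs
  n_blocks <- max(0L, round(config$vmr_frac * n / config$vmr_block_sites))
  is_vmr <- rep(FALSE, n)
  vmr_blocks <- tibble(chrom = character(), start = integer(),
                       end = integer())
  if (n_blocks > 0L) {
    slots <- seq(1L, n - config$vmr_block_sites,
                 by = max(config$vmr_block_sites * 3L, 1L))
    starts <- sort(sample(slots, min(n_blocks, length(slots))))
    for (s in starts) is_vmr[s:(s + config$vmr_block_sites - 1L)] <- TRUE
    vmr_blocks <- tibble(
      chrom = config$chrom,
      start = pos[starts] - 1L,   # BED 0-based
      end = pos[starts + config$vmr_block_sites - 1L]
    )
  }

  # baseline landscape; VMR baselines split evenly between the two states
  comp_high <- runif(n) < config$w_high
  comp_high[is_vmr] <- runif(sum(is_vmr)) < 0.5
  a_hi <- config$mean_high * config$conc_high
  b_hi <- (1 - config$mean_high) * config$conc_high
  a_lo <- config$mean_low * config$conc_low
  b_lo <- (1 - config$mean_low) * config$conc_low
  base <- ifelse(comp_high, rbeta(n, a_hi, b_hi), rbeta(n, a_lo, b_lo))
  base <- pmin(pmax(base, 1e-4), 1 - 1e-4)

  # blacklist intervals, away from chromosome ends
  blacklisted <- rep(FALSE, n)
  blacklist <- tibble(chrom = character(), start = integer(),
                      end = integer())
  if (config$n_blacklist > 0L) {
    bl_starts <- sort(sample(seq(min(pos), max(pos) - config$blacklist_width,
                                 length.out = 1000L),
                             config$n_blacklist))
    bl_starts <- as.integer(round(bl_starts))
    blacklist <- tibble(chrom = config$chrom, start = bl_starts,
                        end = bl_starts + config$blacklist_width)
    blacklisted <- pos_in_intervals(rep(config$chrom, n), pos, blacklist)
  }

  # latent per-sample methylation probabilities
  mu <- qlogis(base)
  pmat <- matrix(0, n, ns)
  for (pr in seq_len(np)) {
    pe <- rtrunc_norm(n, config$pair_effect_sd, config$pair_effect_trunc)
    for (tw in 1:2) {
      e <- rnorm(n, 0, config$residual_sd)
      e[is_vmr] <- e[is_vmr] + rnorm(sum(is_vmr), 0, config$vmr_sd)
      pmat[, (pr - 1L) * 2L + tw] <- plogis(mu + pe + e)
    }
  }

  # dyad depths
  dmat <- matrix(rnbinom(n * ns, size = config$coverage_dispersion,
                         mu = config$coverage_mean), n, ns)
  covered <- rowSums(dmat >= config$min_reads) == ns

  # eligibility for planted features: covered everywhere, outside VMR and
  # blacklist, constitutively methylated so a hypomethylation shift fits
  elig <- covered & !is_vmr & !blacklisted & base > 0.85
  planted <- rep(FALSE, n)

  dms_idx <- integer(0)
  if (config$n_dms > 0L) {
    pool <- which(elig)
    if (length(pool) < config$n_dms) {
      abort("not enough eligible sites for the requested planted DMSs")
    }
    dms_idx <- sort(sample(pool, config$n_dms))
    planted[dms_idx] <- TRUE
  }
  dms_pair <- rep(seq_len(np), length.out = length(dms_idx))

  dmr_list <- list()
  if (config$n_dmr > 0L) {
    k <- config$dmr_sites
    win_ok <- covered & !is_vmr & !blacklisted & !planted & base > 0.7
    run_ok <- which(vapply(seq_len(n - k + 1L),
                           function(s) all(win_ok[s:(s + k - 1L)]),
                           logical(1)))
    # enforce non-adjacent windows
    picked <- integer(0)
    run_ok <- sample(run_ok)
    for (s in run_ok) {
      if (length(picked) == config$n_dmr) break
      if (all(abs(picked - s) > 3L * k)) picked <- c(picked, s)
    }
    if (length(picked) < config$n_dmr) {
      abort("not enough eligible windows for the requested planted DMRs")
    }
    picked <- sort(picked)
    dmr_list <- lapply(picked, function(s) s:(s + k - 1L))
    for (ii in dmr_list) planted[ii] <- TRUE
  }
  dmr_pair <- rep(seq_len(np), length.out = length(dmr_list))

  # apply planted effects to the affected twin (column 2*pr-1)
  for (j in seq_along(dms_idx)) {
    col <- (dms_pair[j] - 1L) * 2L + 1L
    pmat[dms_idx[j], col] <-
      pmin(pmax(pmat[dms_idx[j], col] + config$dms_delta, 0), 1)
  }
  for (j in seq_along(dmr_list)) {
    col <- (dmr_pair[j] - 1L) * 2L + 1L
    ii <- dmr_list[[j]]
    pmat[ii, col] <- pmin(pmax(pmat[ii, col] + config$dmr_delta, 0), 1)
  }

  # stranded counts; planted sites conditioned on strand concordance
  meta <- tibble(
    sample_id = paste0("MZ", rep(seq_len(np), each = 2L),
                       rep(c("A", "U"), np)),
    pair_id = paste0("MZ", rep(seq_len(np), each = 2L)),
    status = rep(c("affected", "unaffected"), np)
  )
  plant_rows <- which(planted)
  counts <- vector("list", ns)
  for (i in seq_len(ns)) {
    d <- dmat[, i]
    df <- rbinom(n, d, 0.5)
    dr <- d - df
    xf <- rbinom(n, df, pmat[, i])
    xr <- rbinom(n, dr, pmat[, i])
    for (r in plant_rows) {
      s <- draw_strands(d[r], pmat[r, i], condition = TRUE,
                        max_delta = config$max_strand_delta)
      df[r] <- s["df"]; dr[r] <- s["dr"]; xf[r] <- s["xf"]; xr[r] <- s["xr"]
    }
    counts[[i]] <- tibble(
      sample_id = meta$sample_id[i], pair_id = meta$pair_id[i],
      status = meta$status[i],
      chrom = config$chrom, pos = pos,
      fwd_meth = xf, fwd_unmeth = df - xf,
      rev_meth = xr, rev_unmeth = dr - xr
    )
  }
  counts <- bind_rows(counts)

  # truth table: one row per planted site, plus one row per VMR block
  truth <- bind_rows(
    if (length(dms_idx)) tibble(
      kind = "DMS", feature_id = paste0("dms", seq_along(dms_idx)),
      pair_id = meta$pair_id[2L * dms_pair - 1L],
      chrom = config$chrom, pos = pos[dms_idx], delta = config$dms_delta
    ),
    if (length(dmr_list)) bind_rows(lapply(seq_along(dmr_list), function(j) {
      tibble(kind = "DMR", feature_id = paste0("dmr", j),
             pair_id = meta$pair_id[2L * dmr_pair[j] - 1L],
             chrom = config$chrom, pos = pos[dmr_list[[j]]],
             delta = config$dmr_delta)
    })),
    if (nrow(vmr_blocks)) tibble(
      kind = "VMR", feature_id = paste0("vmr", seq_len(nrow(vmr_blocks))),
      pair_id = NA_character_, chrom = config$chrom,
      pos = NA_integer_, delta = NA_real_
    )
  )

  # unmethylated lambda spike-in
  lam_depth <- rnbinom(config$lambda_sites, size = config$coverage_dispersion,
                       mu = config$coverage_mean)
  lam_unconv <- rbinom(config$lambda_sites, lam_depth,
                       1 - config$true_conversion)
  lambda <- tibble(
    converted = sum(lam_depth) - sum(lam_unconv),
    unconverted = sum(lam_unconv)
  )

  structure(list(counts = counts, meta = meta, truth = truth,
                 blacklist = blacklist, vmr = vmr_blocks, lambda = lambda,
                 config = config, seed = seed),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat(sprintf("twin_cohort: %d pairs (%d samples), %d CpG sites, seed %d\n",
              x$config$n_pairs, nrow(x$meta), x$config$n_sites, x$seed))
  if (nrow(x$truth)) {
    tab <- table(x$truth$kind)
    cat("planted:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a simulated cohort to disk as plain-text fixtures
#'
#' Emits one Bismark coverage file per sample (dyad totals; exact count
#' round trip through [read_cytosine_report()]), the sample metadata table,
#' the planted-feature truth table, the blacklist and VMR BED files, and
#' the lambda spike-in counts.
#'
#' @param cohort A `twin_cohort` from [simulate_twin_cohort()].
#' @param out_dir Output directory (created if missing).
#' @param stranded Write 7-column cytosine reports (preserving the strand
#'   split) instead of coverage files.
#' @return Invisibly, a character vector of the written file paths.
#' @export
write_cohort_fixture <- function(cohort, out_dir, stranded = FALSE) {
  stopifnot(inherits(cohort, "twin_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sid in cohort$meta$sample_id) {
    sites <- filter(cohort$counts, .data$sample_id == sid)
    ext <- if (stranded) ".CpG_report.txt" else ".cov"
    p <- file.path(out_dir, paste0(sid, ext))
    if (stranded) write_cytosine_report(sites, p) else write_coverage_file(sites, p)
    paths <- c(paths, p)
  }
  mp <- file.path(out_dir, "samples.tsv")
  readr::write_tsv(cohort$meta, mp)
  tp <- file.path(out_dir, "truth.tsv")
  readr::write_tsv(cohort$truth, tp)
  bp <- file.path(out_dir, "blacklist.bed")
  write_bed(cohort$blacklist, bp)
  vp <- file.path(out_dir, "vmr.bed")
  write_bed(cohort$vmr, vp)
  lp <- file.path(out_dir, "lambda.tsv")
  readr::write_tsv(cohort$lambda, lp)
  invisible(c(paths, mp, tp, bp, vp, lp))
}
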