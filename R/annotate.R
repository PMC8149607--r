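#' Two nearest genes by TSS distance
#'
#' Genes on the query chromosome are ranked by unsigned distance from the
#' query position to their transcription start site, with distance 0 for
#' positions inside the transcript interval; ties are broken by smaller
#' TSS coordinate, then by name.
#'
#' @param chrom,pos Query position (1-based).
#' @param genes Gene-model tibble (see [read_gene_models()]).
#' @return Tibble with one row: `gene1`, `gene2` (`NA` if fewer than two
#'   genes on the chromosome).
#' @export
nearest_genes <- function(chrom, pos, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0L) {
    warn(sprintf("no genes on chromosome %s", chrom))
    return(tibble(gene1 = NA_character_, gene2 = NA_character_))
  }
  inside <- pos > g$start & pos <= g$end   # BED interval, 1-based query
  dist <- ifelse(inside, 0, abs(pos - g$tss))
  ord <- order(dist, g$tss, g$name)
  tibble(gene1 = g$name[ord[1]],
         gene2 = if (nrow(g) >= 2L) g$name[ord[2]] else NA_character_)
}

#' Signed distance from a position to a gene's TSS, in kb
#'
#' Positive downstream of the TSS in the direction of transcription,
#' negative upstream: `(pos - tss)/1000` on the plus strand and
#' `(tss - pos)/1000` on the minus strand.
#'
#' @param pos 1-based position.
#' @param tss 1-based TSS position.
#' @param strand `"+"` or `"-"`.
#' @return Signed distance in kb.
#' @export
signed_tss_distance <- function(pos, tss, strand) {
  ifelse(strand == "+", (pos - tss) / 1000, (tss - pos) / 1000)
}

#' Classify a position relative to its nearest gene
#'
#' `Prom` if the position lies within the promoter window around the TSS
#' (default 2500 bp upstream to 500 bp downstream, in the gene's
#' orientation), otherwise `In` if inside the transcript interval,
#' otherwise `IGR` (intergenic).
#'
#' @param pos 1-based position.
#' @param gene One-row gene model (`strand`, `start`, `end`, `tss`).
#' @param promoter_up,promoter_down Promoter window in bp upstream /
#'   downstream of the TSS.
#' @return `"Prom"`, `"In"` or `"IGR"`.
#' @export
classify_feature <- function(pos, gene, promoter_up = 2500,
                             promoter_down = 500) {
  d_bp <- signed_tss_distance(pos, gene$tss, gene$strand) * 1000
  if (d_bp >= -promoter_up && d_bp <= promoter_down) return("Prom")
  if (pos > gene$start && pos <= gene$end) return("In")
  "IGR"
}

#' Annotate DMS or DMR hits with genes, TSS distance and feature class
#'
#' Joins each hit to its two nearest genes, the signed TSS distance (kb)
#' to the nearest one, and the Prom/In/IGR feature class. For regions the
#' midpoint of `start`/`end` is used as the query position.
#'
#' @param hits Tibble with `chrom` plus either `pos` or `start`/`end`.
#' @param genes Gene-model tibble.
#' @param promoter_up,promoter_down Promoter window (bp).
#' @return `hits` with added columns `gene1`, `gene2`, `tss_distance_kb`,
#'   `feature`.
#' @export
annotate_hits <- function(hits, genes, promoter_up = 2500,
                          promoter_down = 500) {
  qpos <- if ("pos" %in% names(hits)) hits$pos else
    as.integer(round((hits$start + hits$end) / 2))
  ann <- map_dfr(seq_len(nrow(hits)), function(i) {
    ng <- nearest_genes(hits$chrom[i], qpos[i], genes)
    if (is.na(ng$gene1)) {
      return(tibble(gene1 = NA_character_, gene2 = NA_character_,
                    tss_distance_kb = NA_real_, feature = NA_character_))
    }
    g1 <- genes[genes$name == ng$gene1 & genes$chrom == hits$chrom[i], ][1, ]
    tibble(gene1 = ng$gene1, gene2 = ng$gene2,
           tss_distance_kb = signed_tss_distance(qpos[i], g1$tss, g1$strand),
           feature = classify_feature(qpos[i], g1, promoter_up,
                                      promoter_down))
  })
  bind_cols(hits, ann)
}

#' Flag hits whose nearest genes are in a candidate set
#'
#' A hit overlaps the candidate set when `gene1` or `gene2` matches
#' (case-insensitive).
#'
#' @param hits Annotated hit tibble (from [annotate_hits()]).
#' @param candidates Character vector of candidate gene names.
#' @return `hits` with a logical `candidate` column.
#' @export
candidate_overlap <- function(hits, candidates) {
  cand <- unique(toupper(candidates))
  mutate(hits, candidate = toupper(.data$gene1) %in% cand |
           (!is.na(.data$gene2) & toupper(.data$gene2) %in% cand))
}

#' One-sided hypergeometric over-representation test
#'
#' Probability of observing `k` or more candidate-gene hits among `n`
#' hits, when `K` of the `N` universe genes are candidates:
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k Candidate hits observed.
#' @param n Total hits.
#' @param K Candidate genes in the universe.
#' @param N Universe size.
#' @return Upper-tail probability.
#' @examples
#' enrichment_test(4, 4, 5, 10)   # 5/210
#' @export
enrichment_test <- function(k, n, K, N) {
  if (!(k >= 0 && k <= n && k <= K && K <= N && n <= N)) {
    abort("enrichment_test: impossible parameter combination")
  }
  # P[X >= k] = upper tail of hypergeometric(K white, N-K black, n drawn)
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Genes hit in multiple twin pairs
#'
#' Counts, for each gene, the number of distinct pairs with at least one
#' hit annotated to it (via `gene1` or `gene2`), and flags whether all
#' hits in that gene share one methylation direction.
#'
#' @param hits Annotated hit tibble with `pair_id`, `gene1`, `gene2` and a
#'   signed `delta` (or `mean_delta`) column.
#' @return Tibble `gene`, `n_pairs`, `pairs`, `concordant` sorted by
#'   decreasing `n_pairs`.
#' @export
cross_pair_overlap <- function(hits) {
  dcol <- if ("mean_delta" %in% names(hits)) "mean_delta" else "delta"
  long <- bind_rows(
    tibble(gene = hits$gene1, pair_id = hits$pair_id, d = hits[[dcol]]),
    tibble(gene = hits$gene2, pair_id = hits$pair_id, d = hits[[dcol]])
  ) |>
    filter(!is.na(.data$gene))
  long |>
    group_by(gene = toupper(.data$gene)) |>
    summarise(
      n_pairs = dplyr::n_distinct(.data$pair_id),
      pairs = paste(sort(unique(.data$pair_id)), collapse = ","),
      concordant = all(.data$d > 0) || all(.data$d < 0),
      .groups = "drop"
    ) |>
    arrange(dplyr::desc(.data$n_pairs), .data$gene)
}

#' Over-representation report for annotated hits
#'
#' Applies [enrichment_test()] per pair, with the universe defined as the
#' genes carrying at least one retained CpG.
#'
#' @param hits Annotated hits with a `candidate` flag (see
#'   [candidate_overlap()]).
#' @param universe Character vector: all genes in the testable universe.
#' @param candidates Candidate gene names.
#' @return Tibble per pair: `pair_id`, `n_hits`, `n_candidate_hits`,
#'   `p_value`.
#' @export
enrichment_by_pair <- function(hits, universe, candidates) {
  universe <- unique(toupper(universe))
  K <- sum(universe %in% unique(toupper(candidates)))
  N <- length(universe)
  out <- hits |>
    group_by(.data$pair_id) |>
    summarise(
      n_hits = dplyr::n_distinct(toupper(.data$gene1)),
      n_candidate_hits = dplyr::n_distinct(toupper(.data$gene1)[.data$candidate]),
      .groups = "drop"
    )
  out$p_value <- mapply(function(k, n) enrichment_test(k, min(n, N), K, N),
                        out$n_candidate_hits, out$n_hits)
  out
}
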