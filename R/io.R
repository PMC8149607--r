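#' Read a Bismark-style per-CpG methylation file for one sample
#'
#' Parses either the 7-column cytosine-report dialect
#' (`chrom, pos, strand, count_meth, count_unmeth, context, tricontext`) or
#' the 6-column coverage dialect
#' (`chrom, start, end, pct_meth, count_meth, count_unmeth`); the dialect is
#' detected from the column count. Cytosine-report rows on opposite strands
#' of one CpG dyad (plus-strand cytosine at `pos`, minus-strand cytosine at
#' `pos + 1`) are collapsed into a single record keyed at the plus-strand
#' position; coverage rows are taken as dyad totals with all counts assigned
#' to the forward strand. Non-CpG context rows are skipped.
#'
#' @param path Path to a tab-separated file (plain or gzip).
#' @param sample_id,pair_id Sample and twin-pair identifiers.
#' @param status `"affected"` or `"unaffected"`.
#' @return A tibble with columns `sample_id`, `pair_id`, `status`, `chrom`,
#'   `pos` (1-based plus-strand cytosine), `fwd_meth`, `fwd_unmeth`,
#'   `rev_meth`, `rev_unmeth`, sorted by `(chrom, pos)`.
#' @examples
#' f <- tempfile(fileext = ".cov")
#' writeLines("chr1\t100\t100\t75\t15\t5", f)
#' read_cytosine_report(f, "s1", "MZ1", "affected")
#' @export
read_cytosine_report <- function(path, sample_id, pair_id, status) {
  status <- match.arg(status, c("affected", "unaffected"))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  meta <- tibble(sample_id = sample_id, pair_id = pair_id, status = status)
  if (length(lines) == 0L) {
    return(bind_cols(meta[0, ], empty_sites()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol1 <- length(fields[[1]])
  bad <- which(lengths(fields) != ncol1)
  if (length(bad) > 0L) {
    abort(sprintf("malformed line %d in %s: expected %d fields, got %d",
                  bad[1], path, ncol1, lengths(fields)[bad[1]]))
  }
  mat <- do.call(rbind, fields)
  sites <- switch(as.character(ncol1),
    "7" = parse_cytosine_report(mat, path),
    "6" = parse_coverage(mat, path),
    abort(sprintf("cannot detect dialect of %s: %d columns (expected 6 or 7)",
                  path, ncol1))
  )
  if (anyDuplicated(sites[c("chrom", "pos")]) > 0L) {
    abort(sprintf("duplicate CpG positions in %s", path))
  }
  if (is.unsorted(order(sites$chrom, sites$pos))) {
    warn(sprintf("input %s not sorted; sorting internally", path))
  }
  sites <- arrange(sites, .data$chrom, .data$pos)
  bind_cols(meta[rep(1L, nrow(sites)), ], sites)
}

empty_sites <- function() {
  tibble(chrom = character(), pos = integer(),
         fwd_meth = integer(), fwd_unmeth = integer(),
         rev_meth = integer(), rev_unmeth = integer())
}

parse_num <- function(x, what, path) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out)) {
    abort(sprintf("malformed line %d in %s: non-numeric %s field",
                  which(is.na(out))[1], path, what))
  }
  out
}

parse_cytosine_report <- function(mat, path) {
  ctx <- mat[, 6]
  keep <- ctx %in% c("CpG", "CG")
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) == 0L) return(empty_sites())
  chrom <- mat[, 1]
  pos <- as.integer(parse_num(mat[, 2], "position", path))
  strand <- mat[, 3]
  if (!all(strand %in% c("+", "-"))) {
    abort(sprintf("malformed strand field in %s", path))
  }
  m <- as.integer(parse_num(mat[, 4], "count", path))
  u <- as.integer(parse_num(mat[, 5], "count", path))
  # anchor each row at the plus-strand cytosine of its dyad
  anchor <- ifelse(strand == "+", pos, pos - 1L)
  df <- tibble(chrom = chrom, pos = anchor, strand = strand, m = m, u = u)
  df |>
    group_by(.data$chrom, .data$pos) |>
    summarise(
      fwd_meth = sum(.data$m[.data$strand == "+"]),
      fwd_unmeth = sum(.data$u[.data$strand == "+"]),
      rev_meth = sum(.data$m[.data$strand == "-"]),
      rev_unmeth = sum(.data$u[.data$strand == "-"]),
      .groups = "drop"
    ) |>
    mutate(across(c("fwd_meth", "fwd_unmeth", "rev_meth", "rev_unmeth"),
                  as.integer))
}

parse_coverage <- function(mat, path) {
  # coverage dialect has no strand split; counts are dyad totals and the
  # stated %meth column is ignored in favour of the authoritative counts
  tibble(
    chrom = mat[, 1],
    pos = as.integer(parse_num(mat[, 2], "position", path)),
    fwd_meth = as.integer(parse_num(mat[, 5], "count", path)),
    fwd_unmeth = as.integer(parse_num(mat[, 6], "count", path)),
    rev_meth = 0L,
    rev_unmeth = 0L
  )
}

#' Write one sample's CpG counts as a Bismark coverage file
#'
#' Dyad totals (forward + reverse counts) are written in the 6-column
#' coverage dialect. Reading the file back with [read_cytosine_report()]
#' recovers the total counts exactly (the strand split is not representable
#' in this dialect).
#'
#' @param sites Tibble with `chrom`, `pos`, `fwd_meth`, `fwd_unmeth`,
#'   `rev_meth`, `rev_unmeth` (one sample).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_file <- function(sites, path) {
  m <- sites$fwd_meth + sites$rev_meth
  u <- sites$fwd_unmeth + sites$rev_unmeth
  pct <- ifelse(m + u > 0, 100 * m / (m + u), 0)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                   sites$chrom, sites$pos, sites$pos,
                   format(pct, trim = TRUE, digits = 10), m, u)
  writeLines(lines, path)
  invisible(path)
}

#' Write one sample's stranded counts as a Bismark cytosine report
#'
#' Emits two rows per dyad (plus-strand cytosine at `pos`, minus-strand at
#' `pos + 1`) so that the strand split survives a round trip through
#' [read_cytosine_report()].
#'
#' @inheritParams write_coverage_file
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(sites, path) {
  fwd <- sprintf("%s\t%d\t+\t%d\t%d\tCpG\tCGN",
                 sites$chrom, sites$pos, sites$fwd_meth, sites$fwd_unmeth)
  rev <- sprintf("%s\t%d\t-\t%d\t%d\tCpG\tCGN",
                 sites$chrom, sites$pos + 1L, sites$rev_meth, sites$rev_unmeth)
  ord <- order(rep(sites$chrom, 2L), c(sites$pos, sites$pos + 1L))
  writeLines(c(fwd, rev)[ord], path)
  invisible(path)
}

#' Read a BED3 interval file
#'
#' @param path Path to a 3+ column BED file (0-based, half-open).
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        comment = "#")
  if (ncol(df) < 3L) abort(sprintf("%s: BED needs >= 3 columns", path))
  out <- tibble(chrom = as.character(df[[1]]),
                start = as.integer(df[[2]]), end = as.integer(df[[3]]))
  if (any(out$start >= out$end)) abort(sprintf("%s: interval start >= end", path))
  out
}

#' Write intervals as BED3
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based, half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  writeLines(sprintf("%s\t%d\t%d", intervals$chrom, intervals$start,
                     intervals$end), path)
  invisible(path)
}

#' Read a gene-model table
#'
#' Expects a 6-column TSV with header `name, chrom, strand, start, end, tss`
#' (`start`/`end` in BED convention; `tss` 1-based) or, if the `tss` column
#' is absent, derives it from strand: `start + 1` on `+`, `end` on `-`.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `name`, `chrom`, `strand`, `start`, `end`,
#'   `tss`.
#' @export
read_gene_models <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("name", "chrom", "strand", "start", "end")
  if (!all(need %in% names(df))) {
    abort(sprintf("%s: gene model table needs columns %s", path,
                  paste(need, collapse = ", ")))
  }
  df <- as_tibble(df)
  if (!"tss" %in% names(df)) {
    df$tss <- ifelse(df$strand == "+", df$start + 1L, df$end)
  }
  if (!all(df$strand %in% c("+", "-"))) abort("gene strand must be + or -")
  if (any(df$start >= df$end)) abort("gene start must be < end")
  select(df, "name", "chrom", "strand", "start", "end", "tss") |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end),
           tss = as.integer(.data$tss))
}

#' Read a one-column candidate-gene list
#'
#' Names are uppercased and deduplicated.
#'
#' @param path Path to a headerless one-column TSV (lines starting with `#`
#'   ignored).
#' @return Character vector of unique uppercase gene names.
#' @export
read_candidate_genes <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(toupper(x))
}

#' Write and read a site-by-sample beta matrix
#'
#' The matrix is stored as TSV with columns `chrom`, `pos`, then one beta
#' column per sample.
#'
#' @param beta Wide tibble (`chrom`, `pos`, one numeric column per sample).
#' @param path File path.
#' @return `write_beta_matrix()` returns `path` invisibly;
#'   `read_beta_matrix()` returns the tibble.
#' @export
write_beta_matrix <- function(beta, path) {
  readr::write_tsv(beta, path)
  invisible(path)
}

#' @rdname write_beta_matrix
#' @export
read_beta_matrix <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  mutate(as_tibble(out), pos = as.integer(.data$pos))
}
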