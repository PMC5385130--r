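#' Local alignment of two sequences
#'
#' Seed-and-extend local alignment (k-mer seeding, diagonal clustering,
#' banded affine Smith-Waterman), or the exhaustive full-matrix dynamic
#' program with `method = "exact"`. Percent identity is defined as
#' `100 * matches / alignment_columns`, gap columns included; this single
#' convention is used everywhere in the package.
#'
#' @param query,subject Sequences (scalar character) over the scheme's
#'   alphabet. `N`/`X` are tolerated but never count as matches and break
#'   seeds.
#' @param scheme A [scoring_scheme()].
#' @param method `"seed"` (default) or `"exact"`.
#' @return A one-row tibble (`query_id`, `subject_id`, `percent_identity`,
#'   `alignment_length`, `matches`, `mismatches`, `gapopens`, coordinates
#'   (1-based), `query_coverage`, `subject_coverage`, `score`, `evalue`), or
#'   a zero-row tibble if no alignment reaches the scheme's minimum score.
#' @examples
#' s <- "ATGGCTAGCTAGGCTTACGATCGATCGTTTACGGA"
#' align_pair(s, s)
#' @export
align_pair <- function(query, subject, scheme = scoring_scheme("nucleotide"),
                       method = c("seed", "exact")) {
  method <- match.arg(method)
  q <- check_alphabet(query, scheme, "query")
  s <- check_alphabet(subject, scheme, "subject")
  r <- if (method == "exact")
    sw_align_cpp(q, s, scheme$submat, scheme$alphabet, scheme$wild,
                 scheme$gap_open, scheme$gap_ext)
  else
    seeded_align_cpp(q, s, scheme$submat, scheme$alphabet, scheme$wild,
                     scheme$gap_open, scheme$gap_ext, scheme$k,
                     scheme$band_pad, scheme$max_clusters)
  qn <- names(query) %||% "query"
  sn <- names(subject) %||% "subject"
  if (length(r) == 0L || r$score < scheme$min_score) return(empty_hits(qn[0]))
  tibble::tibble(
    query_id = qn, subject_id = sn,
    percent_identity = 100 * r$matches / r$alen,
    alignment_length = r$alen, matches = r$matches,
    mismatches = r$mismatches, gapopens = r$gapopens,
    qstart = r$qstart, qend = r$qend, sstart = r$sstart, send = r$send,
    query_coverage = (r$qend - r$qstart + 1) / nchar(q),
    subject_coverage = (r$send - r$sstart + 1) / nchar(s),
    score = r$score,
    evalue = estimate_evalue(r$score, nchar(q), nchar(s), scheme))
}

empty_hits <- function(ids) {
  tibble::tibble(query_id = character(0), subject_id = character(0),
                 percent_identity = numeric(0), alignment_length = integer(0),
                 matches = integer(0), mismatches = integer(0),
                 gapopens = integer(0), qstart = integer(0), qend = integer(0),
                 sstart = integer(0), send = integer(0),
                 query_coverage = numeric(0), subject_coverage = numeric(0),
                 score = integer(0), evalue = numeric(0))
}

#' Expectation value of an alignment score
#'
#' `E = K * m * n * exp(-lambda * score)` with the scheme's ungapped
#' Karlin-Altschul constants applied to (possibly gapped) scores, a
#' documented approximation adequate for coarse E-value filters.
#'
#' @param score Raw alignment score (> 0).
#' @param query_len,db_len Query length and total database length.
#' @param scheme A [scoring_scheme()].
#' @return Numeric E-value (monotonically decreasing in score).
#' @examples
#' estimate_evalue(60, 900, 2e6, scoring_scheme("nucleotide"))
#' @export
estimate_evalue <- function(score, query_len, db_len, scheme) {
  stopifnot(all(score > 0))
  scheme$karlin_k * query_len * db_len * exp(-scheme$lambda * score)
}

#' Directional best hits between two gene sets
#'
#' Aligns every query against every subject, applies the recorded filters,
#' and keeps the single best subject per query. Ties on score are broken by
#' higher percent identity, then longer alignment, then lexicographically
#' smallest subject id, so results are deterministic.
#'
#' @param queries,subjects Named character vectors of sequences (names are
#'   gene ids).
#' @param scheme A [scoring_scheme()].
#' @param max_evalue,min_identity Filters on hits (defaults keep
#'   everything above the scheme's minimum score).
#' @param min_cov_shorter Minimum aligned fraction of the shorter of the two
#'   sequences.
#' @param exclude_self Drop hits where query and subject ids are equal
#'   (useful in self-comparisons).
#' @param method `"seed"` or `"exact"` (exhaustive DP; for small inputs).
#' @return A tibble of best hits, one row per query with a qualifying hit
#'   (columns as [align_pair()] plus `cov_shorter`), with attributes
#'   `direction` and `filters`.
#' @export
best_hits <- function(queries, subjects, scheme = scoring_scheme("nucleotide"),
                      max_evalue = Inf, min_identity = 0,
                      min_cov_shorter = 0, exclude_self = FALSE,
                      method = c("seed", "exact")) {
  method <- match.arg(method)
  if (!length(queries) || !length(subjects))
    stopf("queries and subjects must be non-empty")
  qs <- check_alphabet(queries, scheme, "queries")
  ss <- check_alphabet(subjects, scheme, "subjects")
  qn <- names(qs) %||% sprintf("q%d", seq_along(qs))
  sn <- names(ss) %||% sprintf("s%d", seq_along(ss))
  raw <- all_pairs_cpp(unname(qs), unname(ss), scheme$submat, scheme$alphabet,
                       scheme$wild, scheme$gap_open, scheme$gap_ext,
                       scheme$k, scheme$band_pad, scheme$max_clusters,
                       method == "exact")
  hits <- tibble::as_tibble(raw)
  db_len <- sum(nchar(ss))
  hits <- hits |>
    dplyr::mutate(
      query_id = qn[.data$query_idx], subject_id = sn[.data$subject_idx],
      qlen = nchar(qs)[.data$query_idx], slen = nchar(ss)[.data$subject_idx],
      percent_identity = 100 * .data$matches / .data$alen,
      query_coverage = (.data$qend - .data$qstart + 1) / .data$qlen,
      subject_coverage = (.data$send - .data$sstart + 1) / .data$slen,
      cov_shorter = ifelse(.data$qlen <= .data$slen, .data$query_coverage,
                           .data$subject_coverage),
      evalue = estimate_evalue(.data$score, .data$qlen, db_len, scheme)) |>
    dplyr::filter(.data$score >= scheme$min_score,
                  .data$evalue <= max_evalue,
                  .data$percent_identity >= min_identity,
                  .data$cov_shorter >= min_cov_shorter)
  if (exclude_self)
    hits <- dplyr::filter(hits, .data$query_id != .data$subject_id)
  best <- hits |>
    dplyr::arrange(.data$query_idx, dplyr::desc(.data$score),
                   dplyr::desc(.data$percent_identity),
                   dplyr::desc(.data$alen), .data$subject_id) |>
    dplyr::distinct(.data$query_idx, .keep_all = TRUE) |>
    dplyr::select(
      "query_id", "subject_id", "percent_identity",
      alignment_length = "alen", "matches", "mismatches", "gapopens",
      "qstart", "qend", "sstart", "send", "query_coverage",
      "subject_coverage", "cov_shorter", "score", "evalue")
  attr(best, "direction") <- c(from = attr(queries, "genome") %||% NA_character_,
                               to = attr(subjects, "genome") %||% NA_character_)
  attr(best, "filters") <- list(max_evalue = max_evalue,
                                min_identity = min_identity,
                                min_cov_shorter = min_cov_shorter,
                                min_score = scheme$min_score)
  attr(best, "query_order") <- qn
  best
}

#' Reciprocal best hits from two directional best-hit maps
#'
#' A pair (a, b) is kept iff b is a's best hit and a is b's best hit; each
#' gene appears in at most one pair. Output rows follow the query order of
#' `map_ab` (gene-table order, i.e. genome-A coordinate order for genomes
#' built by this package), giving stable link tables.
#'
#' @param map_ab,map_ba Best-hit tibbles from [best_hits()] run in opposite
#'   directions over the same two gene sets.
#' @return Tibble with `gene_a`, `gene_b`, `identity_ab`, `identity_ba`,
#'   `score_ab`, `score_ba`.
#' @export
reciprocal_best_hits <- function(map_ab, map_ba) {
  dir_ab <- attr(map_ab, "direction"); dir_ba <- attr(map_ba, "direction")
  if (!is.null(dir_ab) && !is.null(dir_ba) &&
      !anyNA(c(dir_ab, dir_ba)) &&
      !identical(unname(dir_ab), unname(rev(dir_ba))))
    stopf("best-hit maps do not have opposite directions (%s->%s vs %s->%s)",
          dir_ab[1], dir_ab[2], dir_ba[1], dir_ba[2])
  ba_of <- setNames(map_ba$subject_id, map_ba$query_id)
  keep <- !is.na(ba_of[map_ab$subject_id]) &
    ba_of[map_ab$subject_id] == map_ab$query_id
  ab <- map_ab[keep, , drop = FALSE]
  ba_idx <- match(ab$subject_id, map_ba$query_id)
  out <- tibble::tibble(
    gene_a = ab$query_id, gene_b = ab$subject_id,
    identity_ab = ab$percent_identity,
    identity_ba = map_ba$percent_identity[ba_idx],
    score_ab = ab$score, score_ba = map_ba$score[ba_idx])
  ord <- attr(map_ab, "query_order")
  if (!is.null(ord)) out <- out[order(match(out$gene_a, ord)), , drop = FALSE]
  out
}
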