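#' Cut a genome into non-overlapping fragments
#'
#' Each contig is tiled from position 0 with fragments of length `L`; the
#' trailing remainder shorter than `L` is discarded, so the fragment count
#' is the sum over contigs of `floor(len / L)`.
#'
#' @param genome A [genome()].
#' @param L Fragment length in bp (>= 50; alignment statistics on shorter
#'   fragments are unreliable).
#' @return Tibble with `fragment_id`, `contig`, `offset` (0-based),
#'   `sequence`.
#' @examples
#' g <- genome("t", c(c1 = strrep("ACGT", 300)),
#'             data.frame(gene_id = "g1", contig = "c1", start = 0, end = 99,
#'                        strand = "+"))
#' nrow(fragment_genome(g, 150))  # floor(1200/150) = 8
#' @export
fragment_genome <- function(genome, L = 150L) {
  if (L < 50) stopf("fragment length L must be >= 50 bp (got %s)", L)
  L <- as.integer(L)
  per_contig <- purrr::map2(names(genome$contigs), unname(genome$contigs),
                            function(cn, seq) {
    n <- nchar(seq) %/% L
    if (n == 0L) return(NULL)
    off <- (seq_len(n) - 1L) * L
    tibble::tibble(contig = cn, offset = off,
                   sequence = substring(seq, off + 1L, off + L))
  })
  out <- dplyr::bind_rows(per_contig)
  if (nrow(out) == 0L)
    return(tibble::tibble(fragment_id = character(0), contig = character(0),
                          offset = integer(0), sequence = character(0)))
  dplyr::bind_cols(
    tibble::tibble(fragment_id = sprintf("%s_frag_%06d", genome$id,
                                         seq_len(nrow(out)))),
    out)
}

# Shared mapping core: best qualifying hit per read across reference
# genomes (both strands) plus per-read, per-reference maximum identity.
map_to_references <- function(seqs, references, scheme, min_similarity,
                              min_cov_read) {
  stopifnot(length(references) >= 1L)
  if (is.null(names(references)) || any(!nzchar(names(references))))
    stopf("references must be a named list of genomes")
  contigs <- character(0); ref_id <- integer(0); contig_names <- character(0)
  for (i in seq_along(references)) {
    g <- references[[i]]
    contigs <- c(contigs, unname(g$contigs))
    contig_names <- c(contig_names, names(g$contigs))
    ref_id <- c(ref_id, rep(i, length(g$contigs)))
  }
  res <- map_reads_cpp(toupper(seqs), toupper(contigs), ref_id,
                       length(references), scheme$submat, scheme$alphabet,
                       scheme$wild, scheme$gap_open, scheme$gap_ext,
                       scheme$k, scheme$band_pad, scheme$max_clusters,
                       min_similarity, min_cov_read)
  hits <- tibble::as_tibble(res$hits)
  hits$reference <- names(references)[hits$ref]
  hits$contig <- contig_names[hits$contig_idx]
  mi <- res$max_identity
  colnames(mi) <- names(references)
  list(hits = hits, max_identity = mi)
}

#' Recruit reads against one or more reference genomes
#'
#' Each read is assigned its single best local-alignment hit across all
#' references and both strands, subject to a minimum percent identity
#' (`min_similarity`) and a minimum aligned fraction of the read
#' (`min_cov_read`); reads with no qualifying hit are unmapped. Ties are
#' broken deterministically (score, identity, alignment length, reference
#' order).
#'
#' @param reads Tibble with columns `read_id` and `sequence` (e.g. from
#'   [simulate_reads()]), or a character vector of sequences.
#' @param references Named list of [genome()] objects.
#' @param min_similarity Minimum percent identity (default 75, the
#'   recruitment default).
#' @param scheme Nucleotide [scoring_scheme()].
#' @param min_cov_read Minimum aligned fraction of the read (default 0.8).
#' @return Tibble with one row per read: `read_id`, `mapped`, `reference`,
#'   `contig`, `strand`, `percent_identity`, `score`, `alignment_length`,
#'   `sstart`, `send`.
#' @export
recruit <- function(reads, references, min_similarity = 75,
                    scheme = scoring_scheme("nucleotide"),
                    min_cov_read = 0.8) {
  if (is.character(reads))
    reads <- tibble::tibble(read_id = sprintf("read_%06d", seq_along(reads)),
                            sequence = reads)
  if (nrow(reads) == 0L)
    return(tibble::tibble(read_id = character(0), mapped = logical(0),
                          reference = character(0), contig = character(0),
                          strand = character(0), percent_identity = numeric(0),
                          score = integer(0), alignment_length = integer(0),
                          sstart = integer(0), send = integer(0)))
  m <- map_to_references(reads$sequence, references, scheme,
                         min_similarity, min_cov_read)
  tibble::tibble(
    read_id = reads$read_id, mapped = !is.na(m$hits$ref),
    reference = m$hits$reference, contig = m$hits$contig,
    strand = as.character(m$hits$strand),
    percent_identity = m$hits$identity, score = m$hits$score,
    alignment_length = m$hits$alen, sstart = m$hits$sstart,
    send = m$hits$send)
}

#' Cross-mapping threshold sweep between two genomes
#'
#' Both genomes are cut into non-overlapping fragments of length `L`; each
#' genome's fragments are aligned against the *other* genome alone
#' (cross-mapping) and against the source genome itself (self-mapping). For
#' every threshold T the curve records the fraction of fragments with a
#' qualifying hit of identity >= T, so each curve is non-increasing in T by
#' construction.
#'
#' @param genome_a,genome_b Two distinct [genome()] objects.
#' @param L Fragment length (default 150 bp).
#' @param thresholds Integer percent identity thresholds (default 70:100).
#' @param scheme Nucleotide [scoring_scheme()].
#' @param min_cov_read Minimum aligned fraction of a fragment.
#' @return A `genopair_sweep` tibble: `source`, `target`, `type`
#'   (`"cross"`/`"self"`), `threshold`, `frequency`, `n_fragments`.
#' @export
threshold_sweep <- function(genome_a, genome_b, L = 150L,
                            thresholds = 70:100,
                            scheme = scoring_scheme("nucleotide"),
                            min_cov_read = 0.8) {
  if (identical(genome_a$id, genome_b$id))
    stopf("threshold_sweep needs two distinct genomes")
  if (any(thresholds < 50 | thresholds > 100))
    stopf("thresholds must lie in [50, 100]")
  floor_t <- min(thresholds)
  fa <- fragment_genome(genome_a, L); fb <- fragment_genome(genome_b, L)
  one_curve <- function(frags, target, type) {
    m <- map_to_references(frags$sequence, setNames(list(target), target$id),
                           scheme, floor_t, min_cov_read)
    best <- m$max_identity[, 1]
    purrr::map_dfr(sort(thresholds), function(tt)
      tibble::tibble(source = NA_character_, target = target$id,
                     type = type, threshold = as.integer(tt),
                     frequency = mean(!is.na(best) & best >= tt),
                     n_fragments = nrow(frags)))
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(one_curve(fa, genome_b, "cross"), source = genome_a$id),
    dplyr::mutate(one_curve(fa, genome_a, "self"), source = genome_a$id),
    dplyr::mutate(one_curve(fb, genome_a, "cross"), source = genome_b$id),
    dplyr::mutate(one_curve(fb, genome_b, "self"), source = genome_b$id))
  class(out) <- c("genopair_sweep", class(out))
  attr(out, "L") <- as.integer(L)
  out
}

#' Select the discrimination threshold from a sweep curve
#'
#' The smallest threshold at which the cross-mapping frequency is at most
#' `max_spurious` in *both* directions. Errors (with the curve attached to
#' the condition) if no threshold qualifies, e.g. for identical genomes.
#'
#' @param curve A `genopair_sweep` tibble (or any tibble with `type`,
#'   `source`, `threshold`, `frequency`).
#' @param max_spurious Maximum tolerated cross-mapping frequency
#'   (default 0.01, i.e. ~1% spurious matches).
#' @return The selected threshold (integer percent).
#' @examples
#' curve <- tidyr::expand_grid(source = c("A", "B"), type = "cross",
#'                             threshold = 95:97)
#' curve$frequency <- rep(c(0.025, 0.009, 0.004), 2)
#' select_threshold(curve, 0.01)  # 96
#' @export
select_threshold <- function(curve, max_spurious = 0.01) {
  cross <- dplyr::filter(tibble::as_tibble(curve), .data$type == "cross")
  if (nrow(cross) == 0L) stopf("curve contains no cross-mapping rows")
  worst <- cross |>
    dplyr::group_by(.data$threshold) |>
    dplyr::summarise(freq = max(.data$frequency), n_dir = dplyr::n(),
                     .groups = "drop")
  ok <- worst$threshold[worst$freq <= max_spurious]
  if (!length(ok))
    abort(sprintf(
      "no threshold restricts cross-mapping to <= %.3g in both directions",
      max_spurious), class = "genopair_no_threshold", curve = curve)
  as.integer(min(ok))
}

#' Read-recruitment discrimination ratio between two genomes
#'
#' Recruits reads against the joint two-genome reference at identity
#' threshold `threshold` (single best hit per read) and reports per-genome
#' mapped counts and their ratio, the lineage-discrimination statistic.
#'
#' @param reads Read tibble or character vector (see [recruit()]).
#' @param genome_a,genome_b [genome()] objects.
#' @param threshold Percent identity threshold, typically from
#'   [select_threshold()] (default 96).
#' @param scheme Nucleotide [scoring_scheme()].
#' @param min_cov_read Minimum aligned fraction of the read.
#' @return A `genopair_recruitment` list: `counts` tibble
#'   (`reference`, `n_mapped`), `n_unmapped`, `n_reads`, `ratio_ab`
#'   (`Inf` sentinel when only genome A recruits; `NA` when nothing maps),
#'   `threshold`, and the per-read `assignments` tibble.
#' @export
discrimination_ratio <- function(reads, genome_a, genome_b, threshold = 96,
                                 scheme = scoring_scheme("nucleotide"),
                                 min_cov_read = 0.8) {
  refs <- setNames(list(genome_a, genome_b), c(genome_a$id, genome_b$id))
  asg <- recruit(reads, refs, min_similarity = threshold, scheme = scheme,
                 min_cov_read = min_cov_read)
  n_a <- sum(asg$mapped & asg$reference == genome_a$id)
  n_b <- sum(asg$mapped & asg$reference == genome_b$id)
  ratio <- if (n_a == 0L && n_b == 0L) NA_real_
           else if (n_b == 0L) Inf
           else n_a / n_b
  structure(list(
    counts = tibble::tibble(reference = c(genome_a$id, genome_b$id),
                            n_mapped = c(n_a, n_b)),
    n_unmapped = sum(!asg$mapped), n_reads = nrow(asg),
    ratio_ab = ratio, threshold = threshold, assignments = asg),
    class = "genopair_recruitment")
}

#' @export
print.genopair_recruitment <- function(x, ...) {
  cat(sprintf("<genopair_recruitment> %d reads at T=%s%%\n", x$n_reads,
              format(x$threshold)))
  cat(sprintf("  %s: %d   %s: %d   unmapped: %d\n",
              x$counts$reference[1], x$counts$n_mapped[1],
              x$counts$reference[2], x$counts$n_mapped[2], x$n_unmapped))
  cat(sprintf("  ratio %s:%s = %s\n", x$counts$reference[1],
              x$counts$reference[2], format(x$ratio_ab, digits = 4)))
  invisible(x)
}
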