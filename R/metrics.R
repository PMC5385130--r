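#' Threshold set for genome-pair metrics
#'
#' The operating points used throughout the comparative statistics: ANI
#' pairs require >= 70% identity and >= 70% coverage of the shorter gene;
#' AAI uses proteins of >= 100 aa; homolog inventories use E <= 1e-5 and
#' >= 30% identity; gene-level metagenome profiles use E <= 1e-5 and >= 70%
#' identity.
#'
#' @param ani_min_identity Minimum percent identity for ANI gene pairs.
#' @param ani_min_cov_shorter Minimum aligned fraction of the shorter gene.
#' @param aai_min_protein_len Minimum protein length (aa) entering AAI.
#' @param homolog_max_evalue,homolog_min_identity Homolog-inventory filters.
#' @param profile_max_evalue,profile_min_identity Metagenome-profile filters.
#' @return A `metric_thresholds` list.
#' @export
metric_thresholds <- function(ani_min_identity = 70,
                              ani_min_cov_shorter = 0.70,
                              aai_min_protein_len = 100,
                              homolog_max_evalue = 1e-5,
                              homolog_min_identity = 30,
                              profile_max_evalue = 1e-5,
                              profile_min_identity = 70) {
  check_number(ani_min_identity, "ani_min_identity", 0, 100)
  check_number(ani_min_cov_shorter, "ani_min_cov_shorter", 0, 1)
  check_number(aai_min_protein_len, "aai_min_protein_len", 0, Inf)
  check_number(homolog_max_evalue, "homolog_max_evalue", 0, Inf)
  check_number(homolog_min_identity, "homolog_min_identity", 0, 100)
  check_number(profile_max_evalue, "profile_max_evalue", 0, Inf)
  check_number(profile_min_identity, "profile_min_identity", 0, 100)
  structure(list(ani_min_identity = ani_min_identity,
                 ani_min_cov_shorter = ani_min_cov_shorter,
                 aai_min_protein_len = aai_min_protein_len,
                 homolog_max_evalue = homolog_max_evalue,
                 homolog_min_identity = homolog_min_identity,
                 profile_max_evalue = profile_max_evalue,
                 profile_min_identity = profile_min_identity),
            class = "metric_thresholds")
}

tag_genes <- function(genome, what = "nt") {
  s <- gene_seqs(genome, what)
  attr(s, "genome") <- genome$id
  s
}

#' Average nucleotide identity between two genomes
#'
#' Bidirectional (reciprocal) best hits of nucleotide gene sequences are
#' filtered to pairs with at least `ani_min_identity` percent identity and
#' `ani_min_cov_shorter` coverage of the shorter gene; ANI in each direction
#' is the unweighted mean of the pairs' percent identities, and the A->B
#' value is the headline `ani`. Set `reciprocal = FALSE` for one-way best
#' hits, or `weighted = TRUE` for alignment-length weighting, as sensitivity
#' options.
#'
#' @param genome_a,genome_b [genome()] objects.
#' @param scheme Nucleotide [scoring_scheme()].
#' @param thresholds A [metric_thresholds()].
#' @param reciprocal Use reciprocal (default) or directional best hits.
#' @param weighted Weight gene pairs by alignment length.
#' @return One-row tibble: `ani`, `ani_ab`, `ani_ba`, `n_pairs`. With no
#'   qualifying pairs the ANI fields are `NA` (undefined), not 0.
#' @export
compute_ani <- function(genome_a, genome_b,
                        scheme = scoring_scheme("nucleotide"),
                        thresholds = metric_thresholds(),
                        reciprocal = TRUE, weighted = FALSE) {
  ga <- tag_genes(genome_a, "nt"); gb <- tag_genes(genome_b, "nt")
  ab <- best_hits(ga, gb, scheme,
                  min_identity = thresholds$ani_min_identity,
                  min_cov_shorter = thresholds$ani_min_cov_shorter)
  ba <- best_hits(gb, ga, scheme,
                  min_identity = thresholds$ani_min_identity,
                  min_cov_shorter = thresholds$ani_min_cov_shorter)
  wmean <- function(x, w) if (weighted) sum(x * w) / sum(w) else mean(x)
  if (reciprocal) {
    rbh <- reciprocal_best_hits(ab, ba)
    n <- nrow(rbh)
    if (n == 0L)
      return(tibble::tibble(ani = NA_real_, ani_ab = NA_real_,
                            ani_ba = NA_real_, n_pairs = 0L))
    w <- ab$alignment_length[match(rbh$gene_a, ab$query_id)]
    ani_ab <- wmean(rbh$identity_ab, w)
    ani_ba <- wmean(rbh$identity_ba, w)
  } else {
    n <- min(nrow(ab), nrow(ba))
    if (nrow(ab) == 0L || nrow(ba) == 0L)
      return(tibble::tibble(ani = NA_real_, ani_ab = NA_real_,
                            ani_ba = NA_real_, n_pairs = 0L))
    ani_ab <- wmean(ab$percent_identity, ab$alignment_length)
    ani_ba <- wmean(ba$percent_identity, ba$alignment_length)
  }
  tibble::tibble(ani = ani_ab, ani_ab = ani_ab, ani_ba = ani_ba,
                 n_pairs = as.integer(n))
}

#' Two-way average amino acid identity between two proteomes
#'
#' Proteins shorter than `aai_min_protein_len` are excluded before the
#' search. Reciprocal best hits (E <= `homolog_max_evalue`, identity >=
#' `homolog_min_identity`) define the pairs; the one-way AAI of each
#' direction is the unweighted mean best-hit identity over those pairs, and
#' the two-way AAI is the mean of the two directions.
#'
#' @inheritParams compute_ani
#' @param scheme Protein [scoring_scheme()].
#' @return One-row tibble: `aai_two_way`, `aai_ab`, `aai_ba`, `n_proteins`
#'   (reciprocal pairs used), `n_prots_a`, `n_prots_b` (proteins passing the
#'   length floor in each genome).
#' @export
compute_aai <- function(genome_a, genome_b,
                        scheme = scoring_scheme("protein"),
                        thresholds = metric_thresholds()) {
  pa <- tag_genes(genome_a, "protein"); pb <- tag_genes(genome_b, "protein")
  pa <- pa[!is.na(pa) & nchar(pa) >= thresholds$aai_min_protein_len]
  pb <- pb[!is.na(pb) & nchar(pb) >= thresholds$aai_min_protein_len]
  attr(pa, "genome") <- genome_a$id; attr(pb, "genome") <- genome_b$id
  if (!length(pa) || !length(pb))
    return(tibble::tibble(aai_two_way = NA_real_, aai_ab = NA_real_,
                          aai_ba = NA_real_, n_proteins = 0L,
                          n_prots_a = length(pa), n_prots_b = length(pb)))
  ab <- best_hits(pa, pb, scheme,
                  max_evalue = thresholds$homolog_max_evalue,
                  min_identity = thresholds$homolog_min_identity)
  ba <- best_hits(pb, pa, scheme,
                  max_evalue = thresholds$homolog_max_evalue,
                  min_identity = thresholds$homolog_min_identity)
  rbh <- reciprocal_best_hits(ab, ba)
  n <- nrow(rbh)
  if (n == 0L)
    return(tibble::tibble(aai_two_way = NA_real_, aai_ab = NA_real_,
                          aai_ba = NA_real_, n_proteins = 0L,
                          n_prots_a = length(pa), n_prots_b = length(pb)))
  aai_ab <- mean(rbh$identity_ab); aai_ba <- mean(rbh$identity_ba)
  tibble::tibble(aai_two_way = mean(c(aai_ab, aai_ba)), aai_ab = aai_ab,
                 aai_ba = aai_ba, n_proteins = as.integer(n),
                 n_prots_a = length(pa), n_prots_b = length(pb))
}

#' Percent shared genes of a genome pair
#'
#' `100 * (2 * n_pairs_two_way) / (n_prots_a_ge100 + n_prots_b_ge100)`,
#' where `n_pairs_two_way` is the number of protein pairs used for the
#' two-way AAI and the denominators count proteins passing the AAI length
#' floor in each genome.
#'
#' @param n_pairs_two_way Number of reciprocal protein pairs.
#' @param n_prots_a_ge100,n_prots_b_ge100 Protein counts per genome.
#' @return Numeric percent.
#' @examples
#' percent_shared_genes(8, 10, 10)  # 80
#' @export
percent_shared_genes <- function(n_pairs_two_way, n_prots_a_ge100,
                                 n_prots_b_ge100) {
  if (n_prots_a_ge100 + n_prots_b_ge100 <= 0)
    stopf("percent_shared_genes: denominator protein counts are zero")
  100 * (2 * n_pairs_two_way) / (n_prots_a_ge100 + n_prots_b_ge100)
}

#' Shared and unique homolog inventories of a genome pair
#'
#' A protein-coding gene of one genome is "shared" iff it has at least one
#' hit in the other genome passing `homolog_max_evalue` and
#' `homolog_min_identity` (directional, not reciprocal); "unique" is the
#' complement. Genes lacking translations are excluded.
#'
#' @inheritParams compute_aai
#' @return Tibble with columns `genome`, `gene_id`, `status`
#'   (`"shared"`/`"unique"`).
#' @export
homolog_inventory <- function(genome_a, genome_b,
                              scheme = scoring_scheme("protein"),
                              thresholds = metric_thresholds()) {
  pa <- tag_genes(genome_a, "protein"); pb <- tag_genes(genome_b, "protein")
  pa <- pa[!is.na(pa) & nzchar(pa)]; pb <- pb[!is.na(pb) & nzchar(pb)]
  attr(pa, "genome") <- genome_a$id; attr(pb, "genome") <- genome_b$id
  ab <- best_hits(pa, pb, scheme,
                  max_evalue = thresholds$homolog_max_evalue,
                  min_identity = thresholds$homolog_min_identity)
  ba <- best_hits(pb, pa, scheme,
                  max_evalue = thresholds$homolog_max_evalue,
                  min_identity = thresholds$homolog_min_identity)
  dplyr::bind_rows(
    tibble::tibble(genome = genome_a$id, gene_id = names(pa),
                   status = ifelse(names(pa) %in% ab$query_id,
                                   "shared", "unique")),
    tibble::tibble(genome = genome_b$id, gene_id = names(pb),
                   status = ifelse(names(pb) %in% ba$query_id,
                                   "shared", "unique")))
}

COG_CATEGORIES <- LETTERS[1:22]  # A..V

#' COG-category summary of shared and unique gene sets
#'
#' @param inventory Tibble from [homolog_inventory()].
#' @param annotations Tibble with columns `gene_id` and `cog` (one-letter
#'   COG category, A-V); may cover only part of the genes.
#' @return Tibble with `genome`, `status`, `category`, `n`,
#'   `rel_abundance`. Relative abundances are over annotated genes of each
#'   (genome, status) set and sum to 1 there; a pseudo-category
#'   `"unannotated"` carries the remaining genes with `rel_abundance = NA`.
#' @export
cog_summary <- function(inventory, annotations) {
  annotations <- tibble::as_tibble(annotations)
  if (!all(c("gene_id", "cog") %in% names(annotations)))
    stopf("annotations must have columns `gene_id` and `cog`")
  bad <- !annotations$cog %in% COG_CATEGORIES
  if (any(bad))
    stopf("unknown COG category '%s' for gene %s",
          annotations$cog[bad][1], annotations$gene_id[bad][1])
  inv <- dplyr::left_join(inventory, annotations, by = "gene_id")
  counts <- inv |>
    dplyr::filter(!is.na(.data$cog)) |>
    dplyr::count(.data$genome, .data$status, category = .data$cog)
  grid <- tidyr::expand_grid(
    dplyr::distinct(inventory, .data$genome, .data$status),
    category = COG_CATEGORIES)
  out <- grid |>
    dplyr::left_join(counts, by = c("genome", "status", "category")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::group_by(.data$genome, .data$status) |>
    dplyr::mutate(rel_abundance = if (sum(.data$n) > 0) .data$n / sum(.data$n)
                  else 0) |>
    dplyr::ungroup()
  unann <- inv |>
    dplyr::filter(is.na(.data$cog)) |>
    dplyr::count(.data$genome, .data$status) |>
    dplyr::mutate(category = "unannotated", rel_abundance = NA_real_)
  dplyr::bind_rows(out, unann) |>
    dplyr::arrange(.data$genome, .data$status, .data$category)
}

#' Gene-level metagenome hit profile
#'
#' Fraction of a genome's genes with at least one qualifying hit
#' (E <= `profile_max_evalue`, identity >= `profile_min_identity`) in a set
#' of metagenome genes. The default normalization is per genome gene;
#' `per = "metagenome"` divides by the metagenome gene count instead.
#'
#' @param genome A [genome()].
#' @param metagenome_genes Named character vector of metagenome gene
#'   sequences (nucleotide).
#' @param scheme Nucleotide [scoring_scheme()].
#' @param thresholds A [metric_thresholds()].
#' @param per `"genome"` (default) or `"metagenome"`.
#' @return One-row tibble: `frequency`, `n_hit`, `n_genome_genes`,
#'   `n_metagenome_genes`.
#' @export
metagenome_profile <- function(genome, metagenome_genes,
                               scheme = scoring_scheme("nucleotide"),
                               thresholds = metric_thresholds(),
                               per = c("genome", "metagenome")) {
  per <- match.arg(per)
  if (!length(metagenome_genes))
    stopf("metagenome gene set must be non-empty")
  gg <- tag_genes(genome, "nt")
  hits <- best_hits(gg, metagenome_genes, scheme,
                    max_evalue = thresholds$profile_max_evalue,
                    min_identity = thresholds$profile_min_identity)
  n_hit <- nrow(hits)
  denom <- if (per == "genome") length(gg) else length(metagenome_genes)
  tibble::tibble(frequency = n_hit / denom, n_hit = n_hit,
                 n_genome_genes = length(gg),
                 n_metagenome_genes = length(metagenome_genes))
}

#' All comparative statistics for a genome pair
#'
#' Runs [compute_ani()], [compute_aai()], [percent_shared_genes()] and
#' [homolog_inventory()] and returns them as one object with
#' [generics::tidy()] and [generics::glance()] methods.
#'
#' @inheritParams compute_ani
#' @param nt_scheme,aa_scheme Scoring schemes for the nucleotide and protein
#'   stages.
#' @return A `genopair_metrics` object (list with elements `ani`, `aai`,
#'   `percent_shared_genes`, `inventory`, `genome_a`, `genome_b`).
#' @export
pair_metrics <- function(genome_a, genome_b,
                         nt_scheme = scoring_scheme("nucleotide"),
                         aa_scheme = scoring_scheme("protein"),
                         thresholds = metric_thresholds()) {
  ani <- compute_ani(genome_a, genome_b, nt_scheme, thresholds)
  aai <- compute_aai(genome_a, genome_b, aa_scheme, thresholds)
  psg <- percent_shared_genes(aai$n_proteins, aai$n_prots_a, aai$n_prots_b)
  inv <- homolog_inventory(genome_a, genome_b, aa_scheme, thresholds)
  structure(list(ani = ani, aai = aai, percent_shared_genes = psg,
                 inventory = inv, genome_a = genome_a$id,
                 genome_b = genome_b$id, thresholds = thresholds),
            class = "genopair_metrics")
}

#' @export
print.genopair_metrics <- function(x, ...) {
  cat(sprintf("<genopair_metrics> %s vs %s\n", x$genome_a, x$genome_b))
  cat(sprintf("  ANI (A->B): %.1f%%  (B->A %.1f%%, %d gene pairs)\n",
              x$ani$ani_ab, x$ani$ani_ba, x$ani$n_pairs))
  cat(sprintf("  AAI two-way: %.1f%%  (%d protein pairs)\n",
              x$aai$aai_two_way, x$aai$n_proteins))
  cat(sprintf("  Percent shared genes: %.1f%%\n", x$percent_shared_genes))
  shared_a <- sum(x$inventory$genome == x$genome_a &
                    x$inventory$status == "shared")
  tot_a <- sum(x$inventory$genome == x$genome_a)
  cat(sprintf("  Shared in %s: %d / %d (%.1f%%)\n", x$genome_a, shared_a,
              tot_a, 100 * shared_a / tot_a))
  invisible(x)
}
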