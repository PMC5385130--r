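#' Full comparative report for a genome pair
#'
#' Runs the whole comparative stage — best hits in both directions, ANI,
#' AAI, percent shared genes, homolog inventories, optional COG summary,
#' and the reciprocal-pair link table — and writes one JSON report plus
#' TSVs under `out_dir`. Every output file carries a header line with the
#' package version and a configuration fingerprint.
#'
#' @param genome_a,genome_b [genome()] objects.
#' @param out_dir Output directory.
#' @param annotations Optional tibble (`gene_id`, `cog`) for the COG
#'   summary.
#' @param nt_scheme,aa_scheme,thresholds As in [pair_metrics()].
#' @return The `genopair_metrics` object, invisibly.
#' @export
compare_genomes <- function(genome_a, genome_b, out_dir,
                            annotations = NULL,
                            nt_scheme = scoring_scheme("nucleotide"),
                            aa_scheme = scoring_scheme("protein"),
                            thresholds = metric_thresholds()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- paste(genome_a$id, genome_b$id,
               paste(unlist(thresholds), collapse = ","), sep = "|")
  metrics <- pair_metrics(genome_a, genome_b, nt_scheme, aa_scheme,
                          thresholds)
  ga <- tag_genes(genome_a, "nt"); gb <- tag_genes(genome_b, "nt")
  ab <- best_hits(ga, gb, nt_scheme,
                  min_identity = thresholds$ani_min_identity,
                  min_cov_shorter = thresholds$ani_min_cov_shorter)
  ba <- best_hits(gb, ga, nt_scheme,
                  min_identity = thresholds$ani_min_identity,
                  min_cov_shorter = thresholds$ani_min_cov_shorter)
  write_hits(ab, file.path(out_dir, "hits_ab.tsv"), cfg)
  write_hits(ba, file.path(out_dir, "hits_ba.tsv"), cfg)
  rbh <- reciprocal_best_hits(ab, ba)
  link <- link_table(rbh, genome_a, genome_b)
  write_stamped_tsv(link, file.path(out_dir, "link_table.tsv"), cfg)
  write_stamped_tsv(metrics$inventory,
                    file.path(out_dir, "inventory.tsv"), cfg)
  cog <- NULL
  if (!is.null(annotations)) {
    cog <- cog_summary(metrics$inventory, annotations)
    write_stamped_tsv(cog, file.path(out_dir, "cog_summary.tsv"), cfg)
  }
  report <- list(
    tool = "genopair", version = as.character(packageVersion("genopair")),
    config_hash = config_hash(cfg),
    genome_a = genome_a$id, genome_b = genome_b$id,
    n_genes_a = nrow(genome_a$genes), n_genes_b = nrow(genome_b$genes),
    ani = as.list(metrics$ani), aai = as.list(metrics$aai),
    percent_shared_genes = metrics$percent_shared_genes,
    shared_fraction_a = with(metrics$inventory,
      mean(status[genome == genome_a$id] == "shared")),
    shared_fraction_b = with(metrics$inventory,
      mean(status[genome == genome_b$id] == "shared")),
    n_reciprocal_nt_pairs = nrow(rbh))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(metrics)
}

# Reciprocal pairs as a circular-plot link table.
link_table <- function(rbh, genome_a, genome_b) {
  ga <- genome_a$genes[match(rbh$gene_a, genome_a$genes$gene_id), ]
  gb <- genome_b$genes[match(rbh$gene_b, genome_b$genes$gene_id), ]
  tibble::tibble(contig_a = ga$contig, start_a = ga$start, end_a = ga$end,
                 contig_b = gb$contig, start_b = gb$start, end_b = gb$end,
                 identity = rbh$identity_ab)
}

#' Run the threshold sweep and write its outputs
#'
#' @param genome_a,genome_b [genome()] objects.
#' @param out_dir Output directory.
#' @param L Fragment length.
#' @param thresholds Identity thresholds to test.
#' @param max_spurious Spurious cross-mapping tolerance for
#'   [select_threshold()].
#' @param scheme Nucleotide [scoring_scheme()].
#' @return List with `curve` and `threshold` (NA if no threshold qualifies;
#'   the curve TSV is written either way).
#' @export
run_sweep <- function(genome_a, genome_b, out_dir, L = 150L,
                      thresholds = 70:100, max_spurious = 0.01,
                      scheme = scoring_scheme("nucleotide")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- paste(genome_a$id, genome_b$id, L,
               paste(range(thresholds), collapse = "-"), sep = "|")
  curve <- threshold_sweep(genome_a, genome_b, L, thresholds, scheme)
  write_stamped_tsv(curve, file.path(out_dir, "sweep_curve.tsv"), cfg)
  sel <- tryCatch(select_threshold(curve, max_spurious),
                  genopair_no_threshold = function(e) {
                    warn(conditionMessage(e)); NA_integer_
                  })
  jsonlite::write_json(
    list(threshold = sel, max_spurious = max_spurious, L = L,
         config_hash = config_hash(cfg)),
    file.path(out_dir, "threshold.json"), auto_unbox = TRUE, digits = NA)
  list(curve = curve, threshold = sel)
}

#' Run read recruitment/discrimination and write its outputs
#'
#' @param reads Read tibble or character vector.
#' @param genome_a,genome_b [genome()] objects.
#' @param out_dir Output directory.
#' @param threshold Identity threshold (percent).
#' @param scheme Nucleotide [scoring_scheme()].
#' @return The `genopair_recruitment` object, invisibly.
#' @export
run_recruitment <- function(reads, genome_a, genome_b, out_dir,
                            threshold = 96,
                            scheme = scoring_scheme("nucleotide")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- paste(genome_a$id, genome_b$id, threshold, sep = "|")
  res <- discrimination_ratio(reads, genome_a, genome_b, threshold, scheme)
  write_stamped_tsv(res$assignments,
                    file.path(out_dir, "read_assignments.tsv"), cfg)
  summary_tbl <- tibble::tibble(
    reference = c(res$counts$reference, "unmapped"),
    n = c(res$counts$n_mapped, res$n_unmapped))
  write_stamped_tsv(summary_tbl, file.path(out_dir, "recruitment.tsv"), cfg)
  ratio_tbl <- tibble::tibble(source = res$counts$reference[1],
                              target = res$counts$reference[2],
                              weight = res$ratio_ab)
  write_stamped_tsv(ratio_tbl, file.path(out_dir, "ratio_links.tsv"), cfg)
  invisible(res)
}
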