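#' Write a genome to FASTA + GFF3 + protein FASTA
#'
#' Emits `<basename>.fna` (contigs), `<basename>.gff` (gene models as type
#' CDS, phase 0, 1-based inclusive coordinates, `ID=` attribute) and
#' `<basename>.faa` (protein translations keyed by gene id).
#'
#' @param genome A [genome()].
#' @param dir Output directory (created if needed).
#' @param basename File stem; defaults to the genome id.
#' @return Invisibly, the three paths written.
#' @export
write_genome <- function(genome, dir, basename = genome$id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fna <- file.path(dir, paste0(basename, ".fna"))
  gff <- file.path(dir, paste0(basename, ".gff"))
  faa <- file.path(dir, paste0(basename, ".faa"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$contigs), fna)
  g <- genome$genes
  lines <- c("##gff-version 3",
             sprintf("%s\tgenopair\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     g$contig, g$start + 1L, g$end, g$strand, g$gene_id))
  writeLines(lines, gff)
  prot <- setNames(g$protein, g$gene_id)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(prot), faa)
  invisible(c(fna = fna, gff = gff, faa = faa))
}

#' Read a genome from FASTA + GFF3 (+ optional protein FASTA)
#'
#' Accepts the single GFF3 dialect this package writes: `##gff-version 3`,
#' feature type CDS, `ID=` attribute. Gene coordinates are validated against
#' contig bounds; CDS spans are translated (standard code, strand-aware) and
#' compared to the protein FASTA when one is given, with a warning per
#' mismatching gene.
#'
#' @param fasta_path Contig FASTA.
#' @param gff_path GFF3 file of CDS features.
#' @param protein_path Optional protein FASTA keyed by gene id.
#' @param id Genome id; defaults to the FASTA file stem.
#' @return A [genome()].
#' @export
read_genome <- function(fasta_path, gff_path, protein_path = NULL, id = NULL) {
  for (p in c(fasta_path, gff_path, protein_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  contigs <- Biostrings::readDNAStringSet(fasta_path)
  cs <- setNames(as.character(contigs), sub("\\s.*$", "", names(contigs)))
  id <- id %||% sub("\\.[^.]*$", "", basename(fasta_path))
  tab <- readr::read_tsv(
    gff_path, comment = "#",
    col_names = c("seqid", "source", "type", "start", "end", "score",
                  "strand", "phase", "attributes"),
    col_types = "ccciicccc", progress = FALSE)
  tab <- dplyr::filter(tab, .data$type == "CDS")
  if (any(tab$end < tab$start))
    stopf("GFF3 record with end < start (%s:%d-%d)",
          tab$seqid[tab$end < tab$start][1],
          tab$start[tab$end < tab$start][1], tab$end[tab$end < tab$start][1])
  ids <- stringr::str_match(tab$attributes, "ID=([^;]+)")[, 2]
  if (anyNA(ids)) stopf("GFF3 CDS record without an ID attribute")
  if (anyDuplicated(ids)) stopf("duplicate gene ID in GFF3: %s",
                                ids[duplicated(ids)][1])
  genes <- tibble::tibble(gene_id = ids, contig = tab$seqid,
                          start = as.integer(tab$start - 1L),
                          end = as.integer(tab$end), strand = tab$strand)
  g <- genome(id, cs, genes)
  if (!is.null(protein_path)) {
    prot <- Biostrings::readAAStringSet(protein_path)
    prot <- setNames(as.character(prot), sub("\\s.*$", "", names(prot)))
    have <- intersect(g$genes$gene_id, names(prot))
    mism <- have[g$genes$protein[match(have, g$genes$gene_id)] != prot[have]]
    for (m in mism)
      warn(sprintf("translation of CDS %s does not match the protein FASTA", m))
    # keep the provided proteins where present
    g$genes$protein[match(have, g$genes$gene_id)] <- unname(prot[have])
  }
  g
}

#' Write reads as FASTA or FASTQ
#'
#' FASTQ qualities are fixed ("I", Q40); no computation in this package
#' uses them.
#'
#' @param reads Tibble with `read_id` and `sequence`.
#' @param path Output file.
#' @param format `"fasta"` (default) or `"fastq"`.
#' @return Invisibly, `path`.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fasta") {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id)), path)
  } else {
    lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence, "+",
                             strrep("I", nchar(reads$sequence))))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read reads from FASTA or FASTQ
#'
#' @param path Input file; format detected from the first character.
#' @return Tibble with `read_id` and `sequence`.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  tibble::tibble(read_id = sub("\\s.*$", "", names(x)),
                 sequence = unname(as.character(x)))
}

#' Write a hit table in the 12-column tabular layout
#'
#' Columns: query, subject, percent identity, alignment length, mismatches,
#' gap opens, qstart, qend, sstart, send, evalue, score — the de facto
#' tabular alignment interchange format. A comment header records the
#' package version and a configuration fingerprint.
#'
#' @param hits Best-hit tibble (from [best_hits()]).
#' @param path Output TSV.
#' @param config Character scalar describing the run (hashed into the
#'   header).
#' @return Invisibly, `path`.
#' @export
write_hits <- function(hits, path, config = "") {
  tab <- tibble::tibble(
    query = hits$query_id, subject = hits$subject_id,
    pident = sprintf("%.2f", hits$percent_identity),
    length = hits$alignment_length, mismatch = hits$mismatches,
    gapopen = hits$gapopens, qstart = hits$qstart, qend = hits$qend,
    sstart = hits$sstart, send = hits$send,
    evalue = sprintf("%.3g", hits$evalue), bitscore = hits$score)
  writeLines(output_header(config), path)
  suppressWarnings(readr::write_tsv(tab, path, append = TRUE,
                                    col_names = FALSE, progress = FALSE))
  invisible(path)
}

# TSV writer with the standard header comment line.
write_stamped_tsv <- function(tbl, path, config = "") {
  writeLines(output_header(config), path)
  suppressWarnings(readr::write_tsv(tbl, path, append = TRUE,
                                    col_names = TRUE, progress = FALSE))
  invisible(path)
}
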