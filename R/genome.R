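#' Construct a genome object
#'
#' A `genome` is a light container for one organism: named contig sequences
#' plus a gene table with protein translations. Coordinates are 0-based,
#' half-open throughout the package; they become 1-based inclusive only when
#' written as GFF3.
#'
#' @param id Genome identifier (scalar character).
#' @param contigs Named character vector of contig sequences (A/C/G/T/N).
#' @param genes Data frame with columns `gene_id`, `contig`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`), and optionally `nt` (coding
#'   sequence in gene orientation) and `protein`; missing `nt`/`protein` are
#'   derived from the contigs (standard genetic code).
#'
#' @return An object of class `genome`.
#' @examples
#' g <- genome("toy", c(c1 = "ATGAAATTTGGGTAACCC"),
#'             data.frame(gene_id = "g1", contig = "c1", start = 0, end = 15,
#'                        strand = "+"))
#' g$genes$protein
#' @export
genome <- function(id, contigs, genes) {
  stopifnot(is.character(id), length(id) == 1L)
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stopf("contigs must be a named character vector")
  genes <- tibble::as_tibble(genes)
  need <- c("gene_id", "contig", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stopf("gene table is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stopf("duplicate gene_id in gene table: %s",
          genes$gene_id[duplicated(genes$gene_id)][1])
  if (any(!genes$contig %in% names(contigs)))
    stopf("gene contig not present in contigs: %s",
          setdiff(genes$contig, names(contigs))[1])
  if (any(genes$end <= genes$start))
    stopf("gene with end <= start: %s", genes$gene_id[genes$end <= genes$start][1])
  clen <- nchar(contigs)[genes$contig]
  if (any(genes$end > clen))
    stopf("gene outside contig bounds: %s", genes$gene_id[genes$end > clen][1])
  if (any(!genes$strand %in% c("+", "-")))
    stopf("strand must be '+' or '-'")
  if (!"nt" %in% names(genes) || anyNA(genes$nt))
    genes$nt <- extract_gene_seq(contigs, genes)
  if (!"protein" %in% names(genes))
    genes$protein <- translate_cds(genes$nt)
  structure(list(id = id, contigs = toupper(contigs), genes = genes),
            class = "genome")
}

extract_gene_seq <- function(contigs, genes) {
  s <- substr(rep(contigs[genes$contig], 1L), genes$start + 1L, genes$end)
  minus <- genes$strand == "-"
  if (any(minus)) s[minus] <- revcomp(s[minus])
  unname(s)
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d contig(s), %s bp, %d genes\n", x$id,
              length(x$contigs), format(sum(nchar(x$contigs)), big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

#' Total length of a genome in bp
#' @param x A `genome`.
#' @return Integer total contig length.
#' @export
genome_length <- function(x) sum(nchar(x$contigs))

#' Gene sequences of a genome
#'
#' @param x A `genome`.
#' @param what `"nt"` for coding-orientation nucleotide sequences or
#'   `"protein"` for translations.
#' @return Named character vector keyed by `gene_id`.
#' @export
gene_seqs <- function(x, what = c("nt", "protein")) {
  what <- match.arg(what)
  setNames(x$genes[[what]], x$genes$gene_id)
}
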