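#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a genome-pair metrics object
#'
#' @param x A `genopair_metrics` object from [pair_metrics()].
#' @param ... Ignored.
#' @return A long tibble with one row per statistic (`metric`, `value`).
#' @export
tidy.genopair_metrics <- function(x, ...) {
  tibble::tibble(
    metric = c("ani", "ani_ab", "ani_ba", "n_ani_pairs", "aai_two_way",
               "aai_ab", "aai_ba", "n_aai_proteins", "percent_shared_genes",
               "shared_fraction_a", "shared_fraction_b"),
    value = c(x$ani$ani, x$ani$ani_ab, x$ani$ani_ba, x$ani$n_pairs,
              x$aai$aai_two_way, x$aai$aai_ab, x$aai$aai_ba,
              x$aai$n_proteins, x$percent_shared_genes,
              mean(x$inventory$status[x$inventory$genome == x$genome_a] ==
                     "shared"),
              mean(x$inventory$status[x$inventory$genome == x$genome_b] ==
                     "shared")))
}

#' One-row summary of a genome-pair metrics object
#'
#' @param x A `genopair_metrics` object.
#' @param ... Ignored.
#' @return One-row tibble with the headline statistics.
#' @export
glance.genopair_metrics <- function(x, ...) {
  tibble::tibble(ani = x$ani$ani, aai_two_way = x$aai$aai_two_way,
                 percent_shared_genes = x$percent_shared_genes,
                 n_ani_pairs = x$ani$n_pairs,
                 n_aai_proteins = x$aai$n_proteins)
}

#' Tidy a sweep curve
#'
#' @param x A `genopair_sweep` tibble.
#' @param ... Ignored.
#' @return The curve as a plain tibble.
#' @export
tidy.genopair_sweep <- function(x, ...) tibble::as_tibble(unclass(x))

#' Tidy a recruitment result
#'
#' @param x A `genopair_recruitment` object.
#' @param ... Ignored.
#' @return Tibble of per-reference counts plus the unmapped count.
#' @export
tidy.genopair_recruitment <- function(x, ...) {
  dplyr::bind_rows(
    x$counts,
    tibble::tibble(reference = "unmapped", n_mapped = x$n_unmapped))
}

#' @export
glance.genopair_recruitment <- function(x, ...) {
  tibble::tibble(n_reads = x$n_reads, threshold = x$threshold,
                 n_mapped_a = x$counts$n_mapped[1],
                 n_mapped_b = x$counts$n_mapped[2],
                 n_unmapped = x$n_unmapped, ratio_ab = x$ratio_ab)
}
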