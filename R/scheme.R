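#' Alignment scoring scheme
#'
#' Bundles everything the local aligner needs: substitution scores, affine
#' gap penalties, the k-mer seed length, the banding pad around seeded
#' diagonals, and ungapped Karlin-Altschul constants used for E-values.
#'
#' Defaults follow community practice for the two modes: nucleotide +1/-2
#' with gap open -5 / extend -2 and an 11-mer seed; protein BLOSUM62 with
#' gap open -11 / extend -1 and a 4-mer seed. `N` (nucleotide) and `X`
#' (protein) never count as matches and break seeds.
#'
#' E-values use ungapped Karlin-Altschul constants applied to gapped scores,
#' a documented approximation: downstream use of E is as a coarse filter
#' (e.g. 1e-5), for which monotonicity in score is what matters. For the
#' nucleotide scheme lambda is solved from the score distribution at uniform
#' base composition; K is the published ungapped value for +1/-2 (0.621).
#' The protein scheme uses the published ungapped BLOSUM62 pair
#' (lambda = 0.3176, K = 0.134).
#'
#' @param mode `"nucleotide"` or `"protein"`.
#' @param match,mismatch Nucleotide match/mismatch scores (ignored for
#'   protein mode).
#' @param gap_open,gap_ext Affine gap penalties, both `<= 0`; a gap of
#'   length L costs `-(gap_open + L * gap_ext)`.
#' @param k Seed length (`>= 4` nt, `>= 3` aa).
#' @param band_pad Extra diagonals allowed on each side of a seeded
#'   diagonal cluster during banded extension.
#' @param max_clusters Maximum number of seeded diagonal clusters extended
#'   per query/subject pair (largest first).
#' @param min_score Minimum raw alignment score for a hit to be reported.
#'
#' @return An object of class `genopair_scheme`.
#' @examples
#' scoring_scheme("nucleotide")
#' scoring_scheme("protein", gap_open = -10)
#' @export
scoring_scheme <- function(mode = c("nucleotide", "protein"),
                           match = 1L, mismatch = -2L,
                           gap_open = NULL, gap_ext = NULL,
                           k = NULL, band_pad = 16L, max_clusters = 16L,
                           min_score = NULL) {
  mode <- match.arg(mode)
  if (mode == "nucleotide") {
    gap_open <- gap_open %||% -5L
    gap_ext <- gap_ext %||% -2L
    k <- k %||% 11L
    min_score <- min_score %||% 20L
    alphabet <- "ACGTN"
    sub <- matrix(as.integer(mismatch), 5, 5,
                  dimnames = list(strsplit(alphabet, "")[[1]],
                                  strsplit(alphabet, "")[[1]]))
    diag(sub) <- as.integer(match)
    sub["N", ] <- as.integer(mismatch)
    sub[, "N"] <- as.integer(mismatch)
    wild <- 4L
    lambda <- uniroot(
      function(l) mean(c(rep(exp(l * match), 4), rep(exp(l * mismatch), 12))) - 1,
      c(1e-6, 10), tol = 1e-12)$root
    karlin_k <- 0.621
    if (k < 4L) stopf("invalid value for `k`: nucleotide seed length must be >= 4")
  } else {
    gap_open <- gap_open %||% -11L
    gap_ext <- gap_ext %||% -1L
    k <- k %||% 4L
    min_score <- min_score %||% 40L
    data("BLOSUM62", package = "Biostrings", envir = environment())
    sub <- get("BLOSUM62", envir = environment())
    storage.mode(sub) <- "integer"
    alphabet <- paste(colnames(sub), collapse = "")
    wild <- which(colnames(sub) == "X") - 1L
    lambda <- 0.3176
    karlin_k <- 0.134
    if (k < 3L) stopf("invalid value for `k`: protein seed length must be >= 3")
  }
  if (gap_open > 0 || gap_ext > 0)
    stopf("invalid value for `gap_open`/`gap_ext`: gap penalties must be <= 0")
  structure(
    list(mode = mode, submat = sub, alphabet = alphabet, wild = wild,
         gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext),
         k = as.integer(k), band_pad = as.integer(band_pad),
         max_clusters = as.integer(max_clusters),
         min_score = as.integer(min_score),
         lambda = lambda, karlin_k = karlin_k),
    class = "genopair_scheme")
}

#' @export
print.genopair_scheme <- function(x, ...) {
  cat(sprintf(
    "<genopair_scheme> %s: gap %d/%d, seed k=%d, band_pad=%d, min_score=%d, lambda=%.4f K=%.3f\n",
    x$mode, x$gap_open, x$gap_ext, x$k, x$band_pad, x$min_score,
    x$lambda, x$karlin_k))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate that sequences are writable in the scheme's alphabet.
check_alphabet <- function(seqs, scheme, what = "sequence") {
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs)))
    stopf("%s must be non-empty", what)
  allowed <- strsplit(scheme$alphabet, "")[[1]]
  bad <- !vapply(strsplit(seqs, ""),
                 function(ch) all(ch %in% allowed), logical(1))
  if (any(bad))
    stopf("%s contains characters outside the %s alphabet (first offender: %s)",
          what, scheme$mode, names(seqs)[bad][1] %||% seqs[bad][1])
  seqs
}
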