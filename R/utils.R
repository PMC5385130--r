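# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Reverse complement of a character vector of DNA sequences.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Standard-code translation of in-frame CDS sequences; trailing stop removed.
translate_cds <- function(x) {
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAStringSet(x),
                          if.fuzzy.codon = "solve")))
  sub("\\*$", "", aa)
}

# Polynomial rolling hash of a character scalar; used to stamp output files
# with a short configuration fingerprint.
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "|")))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# One comment line carried at the top of every emitted table.
output_header <- function(config = "") {
  sprintf("# genopair %s config=%s",
          as.character(packageVersion("genopair")), config_hash(config))
}

stopf <- function(...) abort(sprintf(...))

check_number <- function(x, field, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stopf("invalid value for `%s`: must be a number in [%s, %s]",
          field, format(lo), format(hi))
  x
}
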