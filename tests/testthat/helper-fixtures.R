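# Fixture builders shared across the suite. Everything is generated in code
# under fixed seeds; nothing is read from disk.

# Random DNA string.
rdna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Mutate a sequence at approximately rate `d` (substitutions only),
# independently of the package's divergence machinery.
mutate_seq <- function(s, d) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < d)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# Insert/delete a few short indels, avoiding the ends.
jitter_indels <- function(s, n = 1L, max_len = 4L) {
  for (z in seq_len(n)) {
    l <- sample.int(max_len, 1)
    pos <- sample(seq(10, nchar(s) - 10 - l), 1)
    if (runif(1) < 0.5)
      s <- paste0(substr(s, 1, pos), rdna(l), substr(s, pos + 1, nchar(s)))
    else
      s <- paste0(substr(s, 1, pos), substr(s, pos + l + 1, nchar(s)))
  }
  s
}

# A family of related toy gene sets: subjects are diverged copies of the
# queries, so every query has a genuine partner.
toy_gene_sets <- function(n_genes = 8, len = 240, d = 0.1, n_indel = 1,
                          mode = "nucleotide") {
  if (mode == "nucleotide") {
    q <- vapply(seq_len(n_genes), function(i) rdna(len), character(1))
    s <- vapply(q, function(x) jitter_indels(mutate_seq(x, d), n_indel),
                character(1), USE.NAMES = FALSE)
  } else {
    aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
    q <- vapply(seq_len(n_genes), function(i)
      paste(sample(aa, len, replace = TRUE), collapse = ""), character(1))
    s <- vapply(q, function(x) {
      ch <- strsplit(x, "")[[1]]
      hit <- which(runif(length(ch)) < d)
      for (i in hit) ch[i] <- sample(setdiff(aa, ch[i]), 1)
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  list(queries = setNames(q, sprintf("q%02d", seq_len(n_genes))),
       subjects = setNames(s, sprintf("s%02d", seq_len(n_genes))))
}

# Independent best-hit oracle: exhaustive full-matrix DP on every pair via
# align_pair(method = "exact"), best partner chosen by plain loops with the
# documented tie-break (score, identity, alignment length, subject id).
oracle_best_hits <- function(queries, subjects, scheme) {
  out <- list()
  for (qn in names(queries)) {
    best <- NULL
    for (sn in names(subjects)) {
      h <- align_pair(setNames(queries[qn], qn), setNames(subjects[sn], sn),
                      scheme, method = "exact")
      if (nrow(h) == 0) next
      if (is.null(best)) { best <- h; next }
      key <- function(x) c(x$score, x$percent_identity, x$alignment_length)
      a <- key(h); b <- key(best)
      cmp <- (a > b) - (a < b)
      first <- cmp[cmp != 0][1]
      if (!is.na(first) && first > 0) best <- h
      # full tie: keep lexicographically smaller subject id (already held)
    }
    if (!is.null(best)) out[[qn]] <- best
  }
  dplyr::bind_rows(out)
}

# Small deterministic genome pair used by several files.
small_pair <- function(L = 30000, d = 0.05, gene_loss = 0, seed = 42,
                       nonsyn_fraction = 0) {
  anc <- generate_ancestor(ancestor_spec(genome_length = L, seed = seed))
  diverge_pair(anc, divergence_spec(d, gene_loss_fraction = gene_loss,
                                    nonsyn_fraction = nonsyn_fraction,
                                    seed = seed + 1))
}
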