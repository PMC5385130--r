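nt <- scoring_scheme("nucleotide")
aa <- scoring_scheme("protein")

test_that("self-alignment and forced-identity cases behave as defined", {
  set.seed(1)
  s <- rdna(200)
  h <- align_pair(s, s, nt)
  expect_equal(h$percent_identity, 100)
  expect_equal(h$query_coverage, 1.0)
  expect_equal(h$subject_coverage, 1.0)

  # 100 nt differing at exactly 10 interior sites, no indels -> 90.0
  # (mismatches clustered mid-sequence so the flanking match runs keep the
  # full span optimal for the local aligner)
  q <- rdna(100)
  ch <- strsplit(q, "")[[1]]
  pos <- seq(20, 47, by = 3)
  for (i in pos) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  subj <- paste(ch, collapse = "")
  h <- align_pair(q, subj, nt)
  expect_equal(h$alignment_length, 100L)
  expect_equal(h$percent_identity, 90.0)
})

test_that("alphabet mismatches and empty sequences are rejected", {
  expect_error(align_pair("MKVLA", "MKVLA", nt), "alphabet")
  expect_error(align_pair("", "ACGT", nt), "non-empty")
  expect_no_error(align_pair("MKVLAWMKVLAW", "MKVLAWMKVLAW", aa))
})

test_that("ambiguity codes never count as matches and break seeds", {
  set.seed(2)
  core <- rdna(60)
  q <- paste0(core, "NNNNN")
  h <- align_pair(q, q, nt)
  # the N block cannot contribute matches; identity < 100 or Ns trimmed
  expect_true(h$matches <= 60)
})

test_that("exact DP scores agree with an independent aligner on toy pairs", {
  set.seed(3)
  for (i in 1:10) {
    x <- rdna(120)
    y <- jitter_indels(mutate_seq(x, 0.15), n = 1)
    ours <- align_pair(x, y, nt, method = "exact")
    ref <- Biostrings::pairwiseAlignment(
      x, y, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = TRUE),
      gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
    expect_equal(ours$score, as.integer(ref))
  }
  set.seed(4)
  aa_alpha <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (i in 1:5) {
    x <- paste(sample(aa_alpha, 90, replace = TRUE), collapse = "")
    ch <- strsplit(x, "")[[1]]
    hit <- which(runif(90) < 0.2)
    for (j in hit) ch[j] <- sample(setdiff(aa_alpha, ch[j]), 1)
    y <- paste(ch, collapse = "")
    ours <- align_pair(x, y, aa, method = "exact")
    ref <- Biostrings::pairwiseAlignment(
      x, y, type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(ours$score, as.integer(ref))
  }
})

test_that("seeded best hits equal the exhaustive-DP oracle on toy sets", {
  set.seed(5)
  for (rep in 1:6) {
    sets <- toy_gene_sets(n_genes = 6, len = 200, d = 0.1)
    heur <- best_hits(sets$queries, sets$subjects, nt)
    orac <- oracle_best_hits(sets$queries, sets$subjects, nt)
    expect_identical(heur$query_id, orac$query_id)
    expect_identical(heur$subject_id, orac$subject_id)
    expect_identical(heur$score, orac$score)
  }
})

test_that("best hits honour filters and tie-breaking is deterministic", {
  set.seed(6)
  sets <- toy_gene_sets(n_genes = 5, len = 200, d = 0.05, n_indel = 0)
  # a pair at ~20% extra divergence fails a 95% identity floor
  far <- best_hits(sets$queries, sets$subjects, nt, min_identity = 99.9)
  expect_equal(nrow(far), 0L)

  # duplicate subjects: equal scores resolve to the smaller subject id
  q <- sets$queries[1]
  subs <- setNames(rep(unname(q), 2), c("dup_b", "dup_a"))
  h <- best_hits(q, subs, nt)
  expect_identical(h$subject_id, "dup_a")

  # self-comparison: every gene's best hit is itself at 100%
  self <- best_hits(sets$queries, sets$queries, nt)
  expect_identical(self$query_id, self$subject_id)
  expect_true(all(self$percent_identity == 100))
})

test_that("reciprocal best hits implement the intersection definition", {
  mk_map <- function(q, s, score, from, to) {
    m <- tibble::tibble(query_id = q, subject_id = s,
                        percent_identity = 90, score = score)
    attr(m, "direction") <- c(from = from, to = to)
    attr(m, "query_order") <- q
    m
  }
  ab <- mk_map(c("a1", "a2"), c("b1", "b2"), c(100, 90), "A", "B")
  # b2's best is a1, not a2 -> only (a1, b1) survives
  ba <- mk_map(c("b1", "b2"), c("a1", "a1"), c(100, 80), "B", "A")
  rp <- reciprocal_best_hits(ab, ba)
  expect_identical(rp$gene_a, "a1")
  expect_identical(rp$gene_b, "b1")

  # direction mismatch errors
  expect_error(reciprocal_best_hits(ab, ab), "opposite directions")

  # symmetry up to orientation
  rp2 <- reciprocal_best_hits(ba, ab)
  expect_setequal(paste(rp$gene_a, rp$gene_b),
                  paste(rp2$gene_b, rp2$gene_a))
})

test_that("reciprocal pairs on a synthetic pair recover the true orthologs", {
  pair <- small_pair(L = 20000, d = 0.05, seed = 20)
  ga <- gene_seqs(pair$genome_a); gb <- gene_seqs(pair$genome_b)
  ab <- best_hits(ga, gb, nt)
  ba <- best_hits(gb, ga, nt)
  rp <- reciprocal_best_hits(ab, ba)
  expect_setequal(paste(rp$gene_a, rp$gene_b),
                  paste(pair$truth$ortholog_pairs$gene_a,
                        pair$truth$ortholog_pairs$gene_b))
  # output sorted by genome-A gene order (coordinate order)
  expect_identical(rp$gene_a, intersect(names(ga), rp$gene_a))
})

test_that("E-values follow the Karlin-Altschul form", {
  # linear in database length
  e1 <- estimate_evalue(50, 100, 1e6, nt)
  e2 <- estimate_evalue(50, 100, 2e6, nt)
  expect_equal(e2 / e1, 2)
  # vanishing at large scores
  expect_lt(estimate_evalue(5000, 100, 1e6, nt), 1e-300)
  # direct formula evaluation at the scheme's stated constants
  expect_equal(estimate_evalue(60, 900, 2e6, nt),
               nt$karlin_k * 900 * 2e6 * exp(-nt$lambda * 60),
               tolerance = 1e-6)
  # monotone decreasing in score
  sc <- seq(20, 200, by = 20)
  ev <- estimate_evalue(sc, 100, 1e6, nt)
  expect_true(all(diff(ev) < 0))
})

test_that("higher divergence never raises median best-hit identity", {
  anc <- generate_ancestor(ancestor_spec(genome_length = 15000, seed = 30))
  meds <- vapply(c(0.02, 0.08, 0.2), function(d) {
    med <- vapply(1:3, function(r) {
      pair <- diverge_pair(anc, divergence_spec(d, seed = round(100 * d) + r))
      hits <- best_hits(gene_seqs(pair$genome_a),
                        gene_seqs(pair$genome_b), nt)
      stats::median(hits$percent_identity)
    }, numeric(1))
    mean(med)
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("scoring schemes validate their parameters", {
  expect_error(scoring_scheme("nucleotide", gap_open = 2), "gap penalties")
  expect_error(scoring_scheme("nucleotide", k = 3), "seed length")
  expect_error(scoring_scheme("protein", k = 2), "seed length")
  s <- scoring_scheme("nucleotide")
  # lambda solves the ungapped score equation at uniform composition
  expect_equal(mean(c(rep(exp(s$lambda * 1), 4), rep(exp(s$lambda * -2), 12))),
               1, tolerance = 1e-6)
})
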