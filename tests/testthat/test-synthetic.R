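test_that("ancestor generation is deterministic and respects its spec", {
  spec <- ancestor_spec(genome_length = 30000, gene_density = 0.9, seed = 1)
  g1 <- generate_ancestor(spec)
  g2 <- generate_ancestor(spec)
  expect_identical(g1, g2)

  # realized GC within +/- 2 points of the target at 50 kb
  g <- generate_ancestor(ancestor_spec(genome_length = 50000,
                                       gc_content = 0.60, seed = 2))
  gc <- mean(strsplit(g$contigs[[1]], "")[[1]] %in% c("G", "C"))
  expect_gt(gc, 0.58)
  expect_lt(gc, 0.62)

  # gene structure: non-overlapping, in-bounds, lengths multiples of 3,
  # coding density near target
  genes <- g1$genes[order(g1$genes$start), ]
  expect_true(all(diff(genes$start) >= 0))
  expect_true(all(genes$start[-1] >= genes$end[-nrow(genes)]))
  expect_true(all((genes$end - genes$start) %% 3 == 0))
  expect_lt(abs(sum(genes$end - genes$start) / 30000 - 0.9), 0.05)
  expect_setequal(unique(genes$strand), c("+", "-"))
})

test_that("ancestor genes have stop-free interiors and consistent proteins", {
  g <- generate_ancestor(ancestor_spec(genome_length = 20000, seed = 3))
  for (i in seq_len(nrow(g$genes))) {
    nt <- g$genes$nt[i]
    starts <- seq(1, nchar(nt), by = 3)
    codons <- substring(nt, starts, starts + 2)
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
  }
  # every emitted protein equals the strand-aware translation of its span
  derived <- extract_gene_seq(g$contigs, g$genes)
  expect_identical(derived, g$genes$nt)
  expect_identical(translate_cds(g$genes$nt), g$genes$protein)
})

test_that("ancestor and divergence specs reject invalid fields by name", {
  expect_error(ancestor_spec(genome_length = 5000), "genome_length")
  expect_error(ancestor_spec(gene_density = 1.2), "gene_density")
  expect_error(ancestor_spec(gene_length_mean = 901), "gene_length_mean")
  expect_error(divergence_spec(0.6), "site_divergence")
  expect_error(divergence_spec(0.1, ts_tv_ratio = -1), "ts_tv_ratio")
  expect_error(read_mix_spec(10, weights = c(A = -1)), "weights")
})

test_that("zero divergence reproduces the ancestor exactly", {
  anc <- generate_ancestor(ancestor_spec(genome_length = 15000, seed = 4))
  pair <- diverge_pair(anc, divergence_spec(0, indel_rate = 0,
                                            gene_loss_fraction = 0, seed = 5))
  expect_identical(unname(pair$genome_a$contigs), unname(anc$contigs))
  expect_identical(pair$genome_a$genes$nt, anc$genes$nt)
  expect_identical(unname(pair$genome_b$contigs), unname(anc$contigs))
  expect_equal(pair$truth$programmed_ani, 100)
  expect_equal(pair$truth$realized_site_divergence, 0)
})

test_that("realized divergence is calibrated across the divergence range", {
  # mean realized aligned-site mismatch over replicates within +/- 0.005
  anc <- generate_ancestor(ancestor_spec(genome_length = 30000, seed = 6))
  for (d in c(0.02, 0.05, 0.10, 0.231)) {
    realized <- vapply(1:10, function(s) {
      diverge_pair(anc, divergence_spec(d, seed = round(1000 * d) + s)
                   )$truth$realized_site_divergence
    }, numeric(1))
    expect_lt(abs(mean(realized) - d), 0.005)
  }
})

test_that("descendant genes keep reading frame and stop-free interiors", {
  pair <- small_pair(L = 20000, d = 0.15, seed = 7)
  for (g in list(pair$genome_a, pair$genome_b)) {
    expect_true(all((g$genes$end - g$genes$start) %% 3 == 0))
    # no internal stop codons in translations
    expect_false(any(grepl("\\*", g$genes$protein)))
    # translation consistency after substitutions and indels
    expect_identical(extract_gene_seq(g$contigs, g$genes), g$genes$nt)
    expect_identical(translate_cds(g$genes$nt), g$genes$protein)
  }
})

test_that("gene loss is binomial per lineage and recorded in the truth", {
  anc <- generate_ancestor(ancestor_spec(genome_length = 100000, seed = 8))
  n0 <- nrow(anc$genes)
  expect_gte(n0, 90)
  pair <- diverge_pair(anc, divergence_spec(0.05, gene_loss_fraction = 0.2,
                                            seed = 9))
  surv_b <- nrow(pair$genome_b$genes)
  # binomial(n0, 0.8) central interval
  expect_gt(surv_b, qbinom(0.005, n0, 0.8))
  expect_lt(surv_b, qbinom(0.995, n0, 0.8))
  # every gene surviving in both lineages appears exactly once
  op <- pair$truth$ortholog_pairs
  expect_identical(sort(op$gene_a),
                   sort(intersect(pair$genome_a$genes$gene_id,
                                  pair$genome_b$genes$gene_id)))
  expect_false(anyDuplicated(op$gene_a) > 0)
})

test_that("read simulation honours weights, provenance and determinism", {
  pair <- small_pair(L = 15000, d = 0.1, seed = 10)
  gs <- list(A = pair$genome_a, B = pair$genome_b)

  # degenerate mixture: all reads from A
  rd <- simulate_reads(gs, read_mix_spec(500, weights = c(A = 1, B = 0),
                                         seed = 11))
  expect_identical(unique(rd$source), "A")
  expect_identical(nrow(rd), 500L)

  # 4:1 mixture: labeled-A fraction in the binomial interval
  rd <- simulate_reads(gs, read_mix_spec(10000, weights = c(A = 4, B = 1),
                                         seed = 12))
  expect_gt(mean(rd$source == "A"), 0.78)
  expect_lt(mean(rd$source == "A"), 0.82)

  # no errors: every read is an exact substring of its source (or revcomp)
  rd <- simulate_reads(gs, read_mix_spec(50, weights = c(A = 1, B = 1),
                                         read_error_rate = 0, seed = 13))
  for (i in seq_len(nrow(rd))) {
    g <- gs[[rd$source[i]]]
    found <- grepl(rd$sequence[i], g$contigs[[rd$contig[i]]], fixed = TRUE) ||
      grepl(revcomp(rd$sequence[i]), g$contigs[[rd$contig[i]]], fixed = TRUE)
    expect_true(found)
  }

  # determinism and background reads
  r1 <- simulate_reads(gs, read_mix_spec(200, weights = c(A = 1, background = 1),
                                         seed = 14))
  r2 <- simulate_reads(gs, read_mix_spec(200, weights = c(A = 1, background = 1),
                                         seed = 14))
  expect_identical(r1, r2)
  expect_true(any(r1$source == "background"))

  # read length exceeding the shortest contig errors
  expect_error(
    simulate_reads(gs, read_mix_spec(10, read_length = 1e6,
                                     weights = c(A = 1), seed = 1)),
    "shortest contig")
})
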