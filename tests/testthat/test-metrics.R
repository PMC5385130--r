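nt <- scoring_scheme("nucleotide")
aa <- scoring_scheme("protein")

test_that("self-comparison is a fixed point of every pair statistic", {
  g <- generate_ancestor(ancestor_spec(genome_length = 15000, seed = 40))
  g2 <- g; g2$id <- "copy"
  ani <- compute_ani(g, g2)
  expect_equal(ani$ani, 100)
  expect_equal(ani$ani_ba, 100)
  expect_identical(ani$n_pairs, nrow(g$genes))
  aai_res <- compute_aai(g, g2)
  expect_equal(aai_res$aai_two_way, 100)
  expect_equal(percent_shared_genes(aai_res$n_proteins, aai_res$n_prots_a,
                                    aai_res$n_prots_b), 100)
  inv <- homolog_inventory(g, g2)
  expect_false(any(inv$status == "unique"))
})

test_that("ANI is the unweighted mean of qualifying pair identities", {
  # two 2-gene toy genomes with known per-pair identities 90 and 80
  set.seed(41)
  g1 <- rdna(300); g2 <- rdna(300)
  mut_exact <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- seq(3, by = floor((length(ch) - 6) / k), length.out = k)
    for (i in pos) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    paste(ch, collapse = "")
  }
  mkg <- function(id, seqs) {
    genome(id, setNames(paste(seqs, collapse = ""), paste0(id, "_c1")),
           tibble::tibble(gene_id = paste0(id, c("_x", "_y")),
                          contig = paste0(id, "_c1"),
                          start = c(0, 300), end = c(300, 600),
                          strand = "+"))
  }
  A <- mkg("A", c(g1, g2))
  B <- mkg("B", c(mut_exact(g1, 30), mut_exact(g2, 60)))  # 90% and 80%
  ani <- compute_ani(A, B)
  expect_equal(ani$ani, 85, tolerance = 0.01)
  expect_identical(ani$n_pairs, 2L)
})

test_that("no qualifying pairs yields an undefined ANI, not zero", {
  set.seed(42)
  mkg <- function(id, s) genome(id, setNames(s, paste0(id, "_c1")),
                                tibble::tibble(gene_id = paste0(id, "_g1"),
                                               contig = paste0(id, "_c1"),
                                               start = 0, end = nchar(s),
                                               strand = "+"))
  A <- mkg("A", rdna(600)); B <- mkg("B", rdna(600))
  ani <- compute_ani(A, B)
  expect_true(is.na(ani$ani))
  expect_identical(ani$n_pairs, 0L)
})

test_that("AAI recovers the generator's realized protein identity", {
  pair <- small_pair(L = 30000, d = 0.05, seed = 43)
  res <- compute_aai(pair$genome_a, pair$genome_b)
  truth <- mean(pair$truth$ortholog_pairs$aa_identity)
  expect_lt(abs(res$aai_two_way - truth), 2)
  expect_equal(res$aai_two_way, mean(c(res$aai_ab, res$aai_ba)),
               tolerance = 1e-8)
})

test_that("percent shared genes follows the printed formula exactly", {
  expect_equal(percent_shared_genes(8, 10, 10), 80.0)
  expect_equal(percent_shared_genes(7, 7, 7), 100.0)
  expect_error(percent_shared_genes(0, 0, 0), "denominator")
})

test_that("homolog inventories match generator truth under gene loss", {
  pair <- small_pair(L = 50000, d = 0.05, gene_loss = 0.2, seed = 44)
  inv <- homolog_inventory(pair$genome_a, pair$genome_b)
  ga_id <- pair$genome_a$id
  unique_a <- inv$gene_id[inv$genome == ga_id & inv$status == "unique"]
  truth_unique_a <- setdiff(pair$genome_a$genes$gene_id,
                            pair$genome_b$genes$gene_id)
  jac <- length(intersect(unique_a, truth_unique_a)) /
    length(union(unique_a, truth_unique_a))
  expect_gte(jac, 0.95)
})

test_that("raising the homolog identity floor never grows shared sets", {
  pair <- small_pair(L = 20000, d = 0.15, gene_loss = 0.1, seed = 45)
  n_shared <- vapply(c(30, 60, 90), function(mi) {
    th <- metric_thresholds(homolog_min_identity = mi)
    inv <- homolog_inventory(pair$genome_a, pair$genome_b, thresholds = th)
    sum(inv$status == "shared")
  }, numeric(1))
  expect_true(all(diff(n_shared) <= 0))
})

test_that("COG summaries count and normalize per category", {
  inv <- tibble::tibble(
    genome = "G", gene_id = sprintf("g%02d", 1:10),
    status = rep(c("shared", "unique"), each = 5))
  ann <- tibble::tibble(gene_id = sprintf("g%02d", 1:8),
                        cog = c("C", "C", "E", "J", "C", "E", "E", "K"))
  cs <- cog_summary(inv, ann)
  sh <- cs[cs$status == "shared" & cs$category != "unannotated", ]
  expect_equal(sum(sh$rel_abundance), 1)
  expect_equal(sh$rel_abundance[sh$category == "C"], 3 / 5)
  expect_equal(sh$rel_abundance[sh$category == "E"], 1 / 5)
  expect_equal(sh$rel_abundance[sh$category == "Q"], 0)
  un <- cs[cs$status == "unique", ]
  expect_equal(un$rel_abundance[un$category == "E"], 2 / 3)
  expect_identical(un$n[un$category == "unannotated"], 2L)

  # all genes one category
  one <- cog_summary(inv[1:3, ], tibble::tibble(gene_id = inv$gene_id[1:3],
                                                cog = "C"))
  expect_equal(one$rel_abundance[one$category == "C"], 1)

  # empty annotations: everything unannotated, all categories zero
  none <- cog_summary(inv, tibble::tibble(gene_id = character(0),
                                          cog = character(0)))
  expect_true(all(none$n[none$category != "unannotated"] == 0))
  expect_identical(sum(none$n[none$category == "unannotated"]), 10L)

  # unknown category errors naming the gene
  expect_error(cog_summary(inv, tibble::tibble(gene_id = "g01", cog = "Z")),
               "g01")
})

test_that("metagenome profiles count genes with qualifying hits", {
  g <- generate_ancestor(ancestor_spec(genome_length = 15000, seed = 46))
  genes <- gene_seqs(g)
  # the genome's own genes -> every gene hits
  prof <- metagenome_profile(g, genes)
  expect_equal(prof$frequency, 1.0)
  # half the genes verbatim -> 0.5
  half <- genes[seq_len(floor(length(genes) / 2))]
  prof <- metagenome_profile(g, half)
  expect_equal(prof$frequency, length(half) / length(genes))
  # random background recruits nothing at a 70% identity floor
  set.seed(47)
  bg <- setNames(vapply(1:20, function(i) rdna(900), character(1)),
                 paste0("bg", 1:20))
  prof <- metagenome_profile(g, bg)
  expect_equal(prof$frequency, 0)
  # alternative normalization
  prof <- metagenome_profile(g, half, per = "metagenome")
  expect_equal(prof$frequency, 1.0)
})

test_that("pair_metrics bundles the statistics with tidy/glance methods", {
  pair <- small_pair(L = 15000, d = 0.05, seed = 48)
  m <- pair_metrics(pair$genome_a, pair$genome_b)
  td <- tidy(m)
  expect_true(all(c("ani", "aai_two_way", "percent_shared_genes") %in%
                    td$metric))
  gl <- glance(m)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$ani, m$ani$ani)
  expect_output(print(m), "ANI")
})
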