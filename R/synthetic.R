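#' Specification of a simulated ancestor genome
#'
#' Defaults emulate a small, gene-dense prokaryote chromosome of the kind
#' recovered from deep-subsurface metagenomes: ~90% of the genome coding,
#' mean gene length ~900 bp, GC content ~60%.
#'
#' @param genome_length Total length in bp (>= 10,000).
#' @param gene_length_mean Mean gene length in bp, a multiple of 3.
#' @param gene_density Fraction of the genome covered by genes, in (0, 0.95].
#' @param gc_content GC fraction in [0, 1].
#' @param seed Integer RNG seed.
#' @return A `ancestor_spec` list.
#' @export
ancestor_spec <- function(genome_length = 100000L, gene_length_mean = 900L,
                          gene_density = 0.9, gc_content = 0.602, seed = 1L) {
  check_number(genome_length, "genome_length", 10000, Inf)
  check_number(gene_length_mean, "gene_length_mean", 150, Inf)
  if (gene_length_mean %% 3 != 0)
    stopf("invalid value for `gene_length_mean`: must be a multiple of 3")
  check_number(gene_density, "gene_density", 1e-9, 0.95)
  check_number(gc_content, "gc_content", 0, 1)
  check_number(seed, "seed", -2^31, 2^31)
  structure(list(genome_length = as.integer(genome_length),
                 gene_length_mean = as.integer(gene_length_mean),
                 gene_density = gene_density, gc_content = gc_content,
                 seed = as.integer(seed)),
            class = "ancestor_spec")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

rand_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# n random codons with no stop codons, drawn at per-base GC `gc`
rand_codons <- function(n, gc) {
  if (n == 0L) return(character(0))
  cod <- paste0(rand_bases(n, gc), rand_bases(n, gc), rand_bases(n, gc))
  while (any(bad <- cod %in% STOP_CODONS))
    cod[bad] <- paste0(rand_bases(sum(bad), gc), rand_bases(sum(bad), gc),
                       rand_bases(sum(bad), gc))
  cod
}

#' Generate a simulated ancestor genome
#'
#' Emits a single-contig genome with non-overlapping protein-coding genes
#' (ATG start, stop-free interior, terminal stop codon; ~50% on the minus
#' strand) and their standard-code translations. Deterministic for a fixed
#' seed.
#'
#' @param spec An [ancestor_spec()].
#' @param id Genome identifier.
#' @return A [genome()].
#' @examples
#' g <- generate_ancestor(ancestor_spec(genome_length = 20000, seed = 1))
#' @export
generate_ancestor <- function(spec, id = "ancestor") {
  stopifnot(inherits(spec, "ancestor_spec"))
  with_seed(spec$seed, {
    L <- spec$genome_length
    target <- round(spec$gene_density * L)
    mu <- spec$gene_length_mean
    n_draw <- max(4L, ceiling(target / mu * 2))
    lens <- 3L * pmax(50L, round(rnorm(n_draw, mu / 3, mu / 9)))
    k <- which(cumsum(lens) > target)[1]
    k <- if (is.na(k)) n_draw else max(1L, k - 1L)
    lens <- lens[seq_len(k)]
    gap_total <- L - sum(lens)
    gaps <- as.vector(rmultinom(1, gap_total, rep(1, k + 1L)))
    strands <- sample(c("+", "-"), k, replace = TRUE)
    cds <- vapply(lens, function(l) {
      paste0("ATG", paste(rand_codons(l / 3L - 2L, spec$gc_content),
                          collapse = ""),
             sample(STOP_CODONS, 1L))
    }, character(1))
    genomic <- cds
    genomic[strands == "-"] <- revcomp(genomic[strands == "-"])
    pieces <- character(2L * k + 1L)
    pieces[seq(1, 2 * k + 1, by = 2)] <-
      vapply(gaps, function(g) paste(rand_bases(g, spec$gc_content),
                                     collapse = ""), character(1))
    pieces[seq(2, 2 * k, by = 2)] <- genomic
    seq <- paste(pieces, collapse = "")
    # start of gene i = sum(gaps[1:i]) + sum(lens[1:(i-1)])
    starts <- cumsum(gaps)[seq_len(k)] + c(0L, cumsum(lens))[seq_len(k)]
    genes <- tibble::tibble(
      gene_id = sprintf("g%04d", seq_len(k)),
      contig = paste0(id, "_c1"),
      start = as.integer(starts), end = as.integer(starts + lens),
      strand = strands, nt = cds, protein = translate_cds(cds))
    genome(id, setNames(seq, paste0(id, "_c1")), genes)
  })
}

#' Specification of a genome-pair divergence
#'
#' Substitutions are drawn i.i.d. per site with a transition/transversion
#' bias and applied independently on each descendant lineage; the
#' per-lineage substitution probability is solved exactly so that the
#' expected pairwise mismatch fraction at aligned sites equals
#' `site_divergence` (no small-divergence approximation). Indels are
#' codon-aligned inside genes (frames and the stop-free interior are
#' preserved) and free-length between genes. Each gene is deleted from a
#' lineage independently with probability `gene_loss_fraction`.
#'
#' @param site_divergence Expected pairwise substitution fraction per
#'   aligned site, in [0, 0.5].
#' @param ts_tv_ratio Transition/transversion ratio (> 0).
#' @param indel_rate Expected indel events per site (>= 0).
#' @param indel_max_len Maximum indel length in bp.
#' @param gene_loss_fraction Per-lineage probability that a gene is deleted.
#' @param nonsyn_fraction Fraction of in-gene substitutions forced to be
#'   nonsynonymous (0 = draws are unconstrained apart from stop avoidance).
#' @param seed Integer RNG seed.
#' @return A `divergence_spec` list.
#' @export
divergence_spec <- function(site_divergence, ts_tv_ratio = 2,
                            indel_rate = 5e-4, indel_max_len = 6L,
                            gene_loss_fraction = 0, nonsyn_fraction = 0,
                            seed = 1L) {
  check_number(site_divergence, "site_divergence", 0, 0.5)
  check_number(ts_tv_ratio, "ts_tv_ratio", 1e-9, Inf)
  check_number(indel_rate, "indel_rate", 0, 0.1)
  check_number(indel_max_len, "indel_max_len", 1, 1000)
  check_number(gene_loss_fraction, "gene_loss_fraction", 0, 1)
  check_number(nonsyn_fraction, "nonsyn_fraction", 0, 1)
  check_number(seed, "seed", -2^31, 2^31)
  structure(list(site_divergence = site_divergence,
                 ts_tv_ratio = ts_tv_ratio, indel_rate = indel_rate,
                 indel_max_len = as.integer(indel_max_len),
                 gene_loss_fraction = gene_loss_fraction,
                 nonsyn_fraction = nonsyn_fraction,
                 seed = as.integer(seed)),
            class = "divergence_spec")
}

# Per-lineage substitution probability p such that the expected pairwise
# mismatch fraction equals d. Two independent draws at a site coincide with
# probability cc = (kappa^2 + 2) / (kappa + 2)^2 under the ts/tv kernel, so
# M(p) = 2p(1-p) + p^2 (1 - cc) and p solves (1+cc) p^2 - 2p + d = 0.
lineage_sub_prob <- function(d, kappa) {
  if (d == 0) return(0)
  cc <- (kappa^2 + 2) / (kappa + 2)^2
  (1 - sqrt(1 - (1 + cc) * d)) / (1 + cc)
}

TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_PARTNERS <- list(A = c("C", "T"), C = c("A", "G"),
                    G = c("C", "T"), T = c("A", "G"))
BASE_COMP <- c(A = "T", C = "G", G = "C", T = "A")

# Draw mutant bases for `bases` under the ts/tv kernel (vectorized).
mutate_bases <- function(bases, kappa) {
  n <- length(bases)
  if (n == 0L) return(character(0))
  is_ts <- runif(n) < kappa / (kappa + 2)
  pick2 <- 1L + (runif(n) < 0.5)
  out <- character(n)
  out[is_ts] <- TS_PARTNER[bases[is_ts]]
  idx <- which(!is_ts)
  if (length(idx))
    out[idx] <- mapply(function(b, i) TV_PARTNERS[[b]][i],
                       bases[idx], pick2[idx], USE.NAMES = FALSE)
  out
}

# kernel probabilities of the three alternatives to `base`
alt_probs <- function(base, kappa) {
  alts <- c(TS_PARTNER[[base]], TV_PARTNERS[[base]])
  setNames(c(kappa, 1, 1) / (kappa + 2), alts)
}

#' Derive two descendant genomes from an ancestor
#'
#' Applies substitutions, indels and gene loss independently on two
#' lineages and returns both descendants plus a ground-truth record:
#' surviving ortholog pairs with their substitution-level nucleotide and
#' protein identities, the realized aligned-site divergence of the emitted
#' pair, and the programmed values. Descendant genes keep their ancestral
#' `gene_id`, so ortholog pairs share ids.
#'
#' @param ancestor A [genome()] with at least one gene (typically from
#'   [generate_ancestor()]).
#' @param spec A [divergence_spec()].
#' @return A list with elements `genome_a`, `genome_b` (class `genome`) and
#'   `truth` (list: `programmed_ani`, `programmed_shared_fraction_a`,
#'   `programmed_shared_fraction_b`, `realized_site_divergence`,
#'   `ortholog_pairs` tibble with `gene_a`, `gene_b`, `nt_identity`,
#'   `aa_identity`).
#' @examples
#' anc <- generate_ancestor(ancestor_spec(genome_length = 20000, seed = 1))
#' pair <- diverge_pair(anc, divergence_spec(0.05, seed = 2))
#' pair$truth$realized_site_divergence
#' @export
diverge_pair <- function(ancestor, spec) {
  stopifnot(inherits(ancestor, "genome"), inherits(spec, "divergence_spec"))
  if (nrow(ancestor$genes) < 1L) stopf("ancestor must have at least one gene")
  p <- lineage_sub_prob(spec$site_divergence, spec$ts_tv_ratio)
  gc_obs <- local({
    ch <- strsplit(paste(ancestor$contigs, collapse = ""), "")[[1]]
    mean(ch %in% c("G", "C"))
  })
  with_seed(spec$seed, {
    la <- mutate_lineage(ancestor, p, spec, gc_obs, paste0(ancestor$id, "_A"))
    lb <- mutate_lineage(ancestor, p, spec, gc_obs, paste0(ancestor$id, "_B"))
    truth <- build_truth(ancestor, la, lb, spec)
    list(genome_a = la$genome, genome_b = lb$genome, truth = truth)
  })
}

# One descendant lineage: substitutions, then indels, then gene loss, all on
# a per-ancestral-position element vector so that coordinates and the
# ancestral alignment map stay exact.
mutate_lineage <- function(anc, p, spec, gc_obs, new_id) {
  kappa <- spec$ts_tv_ratio
  all_achar <- list(); all_contigs <- character(0); all_genes <- list()
  all_sub_nt <- list()
  for (cn in names(anc$contigs)) {
    sv <- strsplit(anc$contigs[[cn]], "")[[1]]
    L <- length(sv)
    genes <- anc$genes[anc$genes$contig == cn, ]
    gmap <- integer(L)
    for (gi in seq_len(nrow(genes)))
      gmap[(genes$start[gi] + 1L):genes$end[gi]] <- gi

    ## substitutions
    sites <- which(runif(L) < p)
    inter <- sites[gmap[sites] == 0L]
    sv[inter] <- mutate_bases(sv[inter], kappa)
    genic <- sites[gmap[sites] != 0L]
    sv <- substitute_genic_sites(sv, genic, gmap, genes, kappa,
                                 spec$nonsyn_fraction)

    # substitution-level gene sequences (pre-indel) for protein truth
    subseq <- paste(sv, collapse = "")
    sub_nt <- substring(subseq, genes$start + 1L, genes$end)
    minus_g <- genes$strand == "-"
    if (any(minus_g)) sub_nt[minus_g] <- revcomp(sub_nt[minus_g])

    ## indels
    elems <- sv
    if (spec$indel_rate > 0) {
      isites <- which(runif(L) < spec$indel_rate)
      for (pos in isites)
        elems <- apply_indel(elems, pos, genes, gmap, spec, gc_obs, kappa)
    }

    ## gene loss
    lost <- runif(nrow(genes)) < spec$gene_loss_fraction
    for (gi in which(lost))
      elems[(genes$start[gi] + 1L):genes$end[gi]] <- ""

    ## rebuild
    lens <- nchar(elems)
    cums <- cumsum(lens)
    newseq <- paste(elems, collapse = "")
    keep <- which(!lost)
    new_genes <- NULL
    if (length(keep)) {
      ks <- genes$start[keep]
      ns <- integer(length(ks))
      ns[ks > 0L] <- cums[ks[ks > 0L]]
      ne <- cums[genes$end[keep]]
      nt <- substr(rep(newseq, length(keep)), ns + 1L, ne)
      minus <- genes$strand[keep] == "-"
      nt[minus] <- revcomp(nt[minus])
      new_genes <- tibble::tibble(
        gene_id = genes$gene_id[keep],
        contig = sub(anc$id, new_id, cn, fixed = TRUE),
        start = as.integer(ns), end = as.integer(ne),
        strand = genes$strand[keep], nt = nt, protein = translate_cds(nt))
    }
    achar <- substr(elems, 1L, 1L)
    achar[lens == 0L] <- NA_character_
    all_achar[[cn]] <- achar
    cn2 <- if (grepl(anc$id, cn, fixed = TRUE))
      sub(anc$id, new_id, cn, fixed = TRUE) else paste0(new_id, "_", cn)
    if (!is.null(new_genes)) new_genes$contig <- cn2
    all_contigs[cn2] <- newseq
    all_genes[[cn]] <- new_genes
    all_sub_nt[[cn]] <- setNames(sub_nt, genes$gene_id)
  }
  genes_tbl <- dplyr::bind_rows(all_genes)
  if (nrow(genes_tbl) == 0L)
    genes_tbl <- tibble::tibble(gene_id = character(0), contig = character(0),
                                start = integer(0), end = integer(0),
                                strand = character(0), nt = character(0),
                                protein = character(0))
  list(genome = genome(new_id, all_contigs, genes_tbl),
       achar = all_achar, sub_nt = unlist(unname(all_sub_nt)),
       kept = genes_tbl$gene_id)
}

# Apply substitutions at genic sites. The bulk is vectorized: candidate
# mutant bases are drawn under the ts/tv kernel and accepted when the
# resulting in-frame codon is not a stop. Sites that would create a stop,
# sites sharing a codon with another substituted site, and sites under
# nonsynonymous forcing fall back to a careful sequential path.
substitute_genic_sites <- function(sv, genic, gmap, genes, kappa, nsf) {
  if (!length(genic)) return(sv)
  gstart <- genes$start; gend <- genes$end; gplus <- genes$strand == "+"
  gi <- gmap[genic]
  plus <- gplus[gi]
  off <- ifelse(plus, genic - 1L - gstart[gi], gend[gi] - genic)
  ci <- off %/% 3L
  ncod <- (gend[gi] - gstart[gi]) %/% 3L
  terminal <- ci == ncod - 1L
  forced <- nsf > 0 & runif(length(genic)) < nsf
  # codon collisions: two substituted sites in one codon must be sequential
  key <- paste0(gi, "_", ci)
  collide <- key %in% key[duplicated(key)]
  cand <- mutate_bases(sv[genic], kappa)
  # genomic indices of each site's codon (ascending)
  c1 <- ifelse(plus, gstart[gi] + ci * 3L + 1L, gend[gi] - ci * 3L - 2L)
  m <- cbind(c1, c1 + 1L, c1 + 2L)
  b1 <- sv[m[, 1]]; b2 <- sv[m[, 2]]; b3 <- sv[m[, 3]]
  wc <- genic - c1 + 1L  # 1..3, position within ascending-genomic codon
  n1 <- ifelse(wc == 1L, cand, b1)
  n2 <- ifelse(wc == 2L, cand, b2)
  n3 <- ifelse(wc == 3L, cand, b3)
  new_codon <- ifelse(plus, paste0(n1, n2, n3),
                      paste0(BASE_COMP[n3], BASE_COMP[n2], BASE_COMP[n1]))
  ok <- !terminal & !collide & !forced & !(new_codon %in% STOP_CODONS)
  sv[genic[ok]] <- cand[ok]
  slow <- which(!ok & !terminal)
  for (z in slow) {
    pos <- genic[z]; g <- gi[z]
    # the forcing coin for this site has already been flipped
    pick <- pick_genic_sub(sv, pos, gstart[g], gend[g], gplus[g], kappa,
                           if (forced[z]) 1 else 0)
    if (!is.na(pick)) sv[pos] <- pick
  }
  sv
}

# Choose the mutant base for one genic site, avoiding in-frame stop codons
# and optionally forcing a nonsynonymous change; NA means "skip this site"
# (terminal stop codon, or no admissible alternative).
pick_genic_sub <- function(sv, pos, start, end, plus, kappa, nonsyn_fraction) {
  off <- if (plus) (pos - 1L) - start else end - pos  # 0-based coding offset
  ci <- off %/% 3L
  ncod <- (end - start) %/% 3L
  if (ci == ncod - 1L) return(NA_character_)  # terminal stop codon
  idx <- if (plus) (start + ci * 3L + 1L):(start + ci * 3L + 3L)
         else (end - ci * 3L - 2L):(end - ci * 3L)
  codon_g <- sv[idx]
  codon <- if (plus) paste(codon_g, collapse = "")
           else paste(BASE_COMP[rev(codon_g)], collapse = "")
  probs <- alt_probs(sv[pos], kappa)
  cand <- names(probs)
  wc <- match(pos, idx)
  new_codon <- vapply(cand, function(b) {
    cg <- codon_g
    cg[wc] <- b
    if (plus) paste(cg, collapse = "")
    else paste(BASE_COMP[rev(cg)], collapse = "")
  }, character(1))
  ok <- !(new_codon %in% STOP_CODONS)
  if (!any(ok)) return(NA_character_)
  if (nonsyn_fraction > 0 && runif(1) < nonsyn_fraction) {
    aa0 <- GENETIC_CODE_TABLE[codon]
    nonsyn <- ok & (GENETIC_CODE_TABLE[new_codon] != aa0)
    if (any(nonsyn)) ok <- nonsyn
  }
  cand <- cand[ok]; w <- probs[ok]
  if (length(cand) == 1L) cand else sample(cand, 1L, prob = w)
}

GENETIC_CODE_TABLE <- NULL  # populated at load time (Biostrings)

.onLoad <- function(libname, pkgname) {
  GENETIC_CODE_TABLE <<- Biostrings::GENETIC_CODE
}

# One indel event at ancestral position pos (1-based). In genes, whole
# interior codons are inserted or deleted so the reading frame and the
# terminal stop survive; between genes, lengths are free but deletions never
# cross into a gene.
apply_indel <- function(elems, pos, genes, gmap, spec, gc_obs, kappa) {
  L <- length(elems)
  is_ins <- runif(1) < 0.5
  raw_len <- sample.int(spec$indel_max_len, 1L)
  gi <- gmap[pos]
  if (gi == 0L) {
    if (is_ins) {
      elems[pos] <- paste0(elems[pos],
                           paste(rand_bases(raw_len, gc_obs), collapse = ""))
    } else {
      idx <- pos:min(L, pos + raw_len - 1L)
      idx <- idx[gmap[idx] == 0L & nchar(elems[idx]) > 0L]
      elems[idx] <- ""
    }
    return(elems)
  }
  g <- genes[gi, ]
  ncod <- (g$end - g$start) %/% 3L
  if (ncod < 4L) return(elems)  # too small for interior indels
  l3 <- max(1L, ceiling(raw_len / 3))
  plus <- g$strand == "+"
  off <- if (plus) (pos - 1L) - g$start else g$end - pos
  ci <- off %/% 3L
  if (is_ins) {
    # insert after interior codon boundary cb in 1..ncod-2
    cb <- min(max(ci, 1L), ncod - 2L)
    ins <- paste(rand_codons(l3, gc_obs), collapse = "")
    at <- if (plus) g$start + cb * 3L else g$end - cb * 3L
    elems[at] <- paste0(elems[at], if (plus) ins else revcomp(ins))
  } else {
    cstart <- min(max(ci, 1L), ncod - 1L - l3)
    if (cstart < 1L) return(elems)
    cods <- cstart:(cstart + l3 - 1L)  # 0-based interior codon indices
    idx <- unlist(lapply(cods, function(cc) {
      if (plus) (g$start + cc * 3L + 1L):(g$start + cc * 3L + 3L)
      else (g$end - cc * 3L - 2L):(g$end - cc * 3L)
    }))
    elems[idx] <- ""
  }
  elems
}

build_truth <- function(anc, la, lb, spec) {
  shared <- intersect(la$kept, lb$kept)
  anc_genes <- anc$genes[match(shared, anc$genes$gene_id), ]
  # aligned-column comparison over the ancestral coordinate map
  tot <- 0L; mis <- 0L
  per_gene_nt <- numeric(length(shared)); names(per_gene_nt) <- shared
  for (cn in names(anc$contigs)) {
    a <- la$achar[[cn]]; b <- lb$achar[[cn]]
    both <- !is.na(a) & !is.na(b)
    tot <- tot + sum(both); mis <- mis + sum(a[both] != b[both])
    gsub_ <- anc$genes[anc$genes$contig == cn, ]
    for (gid in intersect(shared, gsub_$gene_id)) {
      g <- gsub_[gsub_$gene_id == gid, ]
      span <- (g$start + 1L):g$end
      ok <- both[span]
      per_gene_nt[gid] <- 100 * mean(a[span][ok] == b[span][ok])
    }
  }
  pa <- translate_cds(la$sub_nt[shared]); pb <- translate_cds(lb$sub_nt[shared])
  aa_ident <- mapply(function(x, y) {
    cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
    100 * mean(cx == cy)
  }, pa, pb, USE.NAMES = FALSE)
  if (!length(shared)) aa_ident <- numeric(0)
  list(
    programmed_ani = 100 * (1 - spec$site_divergence),
    programmed_shared_fraction_a = 1 - spec$gene_loss_fraction,
    programmed_shared_fraction_b = 1 - spec$gene_loss_fraction,
    realized_site_divergence = if (tot > 0) mis / tot else NA_real_,
    ortholog_pairs = tibble::tibble(
      gene_a = shared, gene_b = shared,
      nt_identity = unname(per_gene_nt), aa_identity = unname(aa_ident)))
}

#' Specification of a simulated read mixture
#'
#' @param n_reads Number of reads to emit.
#' @param read_length Read length in bp (default 150, the fragment length
#'   used throughout the recruitment procedure).
#' @param weights Named non-negative sampling weights over genome ids; the
#'   reserved name `"background"` draws i.i.d. random-sequence reads.
#' @param read_error_rate Per-base substitution probability (default 0.5%,
#'   a free choice in the absence of a stated error model).
#' @param background_gc GC fraction of background reads.
#' @param seed Integer RNG seed.
#' @return A `read_mix_spec` list.
#' @export
read_mix_spec <- function(n_reads, read_length = 150L, weights,
                          read_error_rate = 0.005, background_gc = 0.5,
                          seed = 1L) {
  check_number(n_reads, "n_reads", 0, Inf)
  check_number(read_length, "read_length", 20, Inf)
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stopf("invalid value for `weights`: must be a named vector")
  if (any(weights < 0) || sum(weights) <= 0)
    stopf("invalid value for `weights`: must be non-negative with positive sum")
  check_number(read_error_rate, "read_error_rate", 0, 0.5)
  check_number(background_gc, "background_gc", 0, 1)
  structure(list(n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length), weights = weights,
                 read_error_rate = read_error_rate,
                 background_gc = background_gc, seed = as.integer(seed)),
            class = "read_mix_spec")
}

#' Simulate a metagenome-like read mixture from genomes
#'
#' Reads are drawn from uniformly random start positions on genomes chosen
#' in proportion to `spec$weights` (both strands), with optional i.i.d.
#' substitution errors, plus an optional random-sequence background
#' component. Per-read provenance is retained for truth-based tests.
#'
#' @param genomes Named list of [genome()] objects covering the non-background
#'   names in `spec$weights`.
#' @param spec A [read_mix_spec()].
#' @return Tibble with columns `read_id`, `source`, `contig`, `start`
#'   (0-based), `strand`, `sequence`.
#' @examples
#' g <- generate_ancestor(ancestor_spec(genome_length = 20000, seed = 1))
#' rd <- simulate_reads(list(ancestor = g),
#'                      read_mix_spec(100, weights = c(ancestor = 1), seed = 3))
#' @export
simulate_reads <- function(genomes, spec) {
  stopifnot(inherits(spec, "read_mix_spec"))
  w <- spec$weights
  src_names <- names(w)
  gen_names <- setdiff(src_names, "background")
  if (any(!gen_names %in% names(genomes)))
    stopf("weights name genomes not supplied: %s",
          setdiff(gen_names, names(genomes))[1])
  rl <- spec$read_length
  for (gn in gen_names[w[gen_names] > 0]) {
    if (min(nchar(genomes[[gn]]$contigs)) < rl)
      stopf("read_length (%d) exceeds the shortest contig of genome %s",
            rl, gn)
  }
  with_seed(spec$seed, {
    n_per <- as.vector(rmultinom(1, spec$n_reads, w))
    out <- vector("list", length(src_names))
    for (si in seq_along(src_names)) {
      n <- n_per[si]
      if (n == 0L) { out[[si]] <- NULL; next }
      sn <- src_names[si]
      if (sn == "background") {
        seqs <- vapply(seq_len(n), function(i)
          paste(rand_bases(rl, spec$background_gc), collapse = ""),
          character(1))
        out[[si]] <- tibble::tibble(source = sn, contig = NA_character_,
                                    start = NA_integer_, strand = NA_character_,
                                    sequence = seqs)
      } else {
        g <- genomes[[sn]]
        cw <- pmax(0L, nchar(g$contigs) - rl + 1L)
        ci <- sample.int(length(g$contigs), n, replace = TRUE, prob = cw)
        starts <- vapply(ci, function(i) sample.int(cw[i], 1L) - 1L, integer(1))
        strands <- sample(c("+", "-"), n, replace = TRUE)
        seqs <- substr(rep(unname(g$contigs)[ci], 1L), starts + 1L, starts + rl)
        seqs[strands == "-"] <- revcomp(seqs[strands == "-"])
        if (spec$read_error_rate > 0)
          seqs <- add_read_errors(seqs, spec$read_error_rate)
        out[[si]] <- tibble::tibble(source = sn,
                                    contig = names(g$contigs)[ci],
                                    start = as.integer(starts),
                                    strand = strands, sequence = seqs)
      }
    }
    reads <- dplyr::bind_rows(out)
    reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
    dplyr::bind_cols(
      tibble::tibble(read_id = sprintf("read_%06d", seq_len(nrow(reads)))),
      reads)
  })
}

add_read_errors <- function(seqs, rate) {
  m <- do.call(rbind, strsplit(seqs, ""))
  hit <- which(matrix(runif(length(m)) < rate, nrow = nrow(m)))
  if (length(hit)) {
    cur <- m[hit]
    alts <- c("A", "C", "G", "T")
    m[hit] <- vapply(cur, function(b) sample(setdiff(alts, b), 1L),
                     character(1))
  }
  apply(m, 1L, paste, collapse = "")
}
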