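# Homologue discovery: seeded local alignment, hit merging, reciprocal
# screening, domain restriction and target excision.

test_that("a gene planted verbatim is found at exactly its range with 100% identity", {
  set.seed(1)
  gene <- random_dna_str(400)
  genome <- c(chr = paste0(random_dna_str(5000), gene, random_dna_str(4600)))
  hits <- search_homologues(c(geneA = gene), genome)
  strong <- hits[hits$aligned_length >= 350, ]
  expect_identical(nrow(strong), 1L)
  expect_identical(strong$start, 5000L)
  expect_identical(strong$end, 5400L)
  expect_identical(strong$strand, "+")
  expect_equal(strong$pct_identity, 100)
})

test_that("a 5%-mutated plant is found with identity near 95%", {
  set.seed(2)
  gene <- random_dna_str(600)
  chars <- strsplit(gene, "")[[1]]
  idx <- sample(600, 30)          # exactly 5% substitutions
  for (i in idx) chars[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                            chars[i]), 1)
  mut <- paste(chars, collapse = "")
  genome <- c(chr = paste0(random_dna_str(2000), mut, random_dna_str(2000)))
  hits <- search_homologues(c(geneA = gene), genome)
  best <- hits[which.max(hits$aligned_length), ]
  expect_gte(best$pct_identity, 93)
  expect_lte(best$pct_identity, 97)
  expect_lt(abs(best$start - 2000L), 25L)
})

test_that("an absent gene yields no hit at high identity (vs local-alignment oracle)", {
  set.seed(3)
  gene <- random_dna_str(400)
  genome <- c(chr = random_dna_str(8000))
  hits <- search_homologues(c(geneA = gene), genome)
  expect_false(any(hits$pct_identity >= 85 & hits$aligned_length >= 50))
  # oracle: best Smith-Waterman alignment of the gene anywhere in the
  # genome is weak
  submat <- Biostrings::nucleotideSubstitutionMatrix(2, -3, baseOnly = FALSE)
  best <- max(
    Biostrings::score(Biostrings::pairwiseAlignment(
      gene, genome[["chr"]], type = "local", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 2)),
    Biostrings::score(Biostrings::pairwiseAlignment(
      gene, reverse_complement(genome[["chr"]]), type = "local",
      substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)))
  expect_lt(best, 100)
})

test_that("search contract errors and warnings", {
  expect_error(search_homologues(character(0), c(chr = "ACGT")),
               "empty gene set")
  expect_warning(
    search_homologues(c(g = random_dna_str(100)),
                      c(ok = random_dna_str(300), bad = "")),
    "zero-length")
})

test_that("hits are found on the reverse strand at mirrored coordinates", {
  set.seed(4)
  gene <- random_dna_str(300)
  genome <- c(chr = paste0(random_dna_str(1000), reverse_complement(gene),
                           random_dna_str(700)))
  hits <- search_homologues(c(g = gene), genome)
  strong <- hits[hits$aligned_length >= 250, ]
  expect_identical(strong$strand, "-")
  expect_identical(strong$start, 1000L)
  expect_identical(strong$end, 1300L)
})

test_that("merge_hits honours merge_within, identity order and minlen", {
  mk <- function(start, end, id, strand = "+") data.frame(
    query_id = "g", seqid = "chr", start = start, end = end,
    strand = strand, pct_identity = id, aligned_length = end - start,
    score = end - start, stringsAsFactors = FALSE)
  params <- homology_params(merge_within = 100)
  merged <- merge_hits(rbind(mk(100, 200, 99), mk(250, 350, 99)), params)
  expect_identical(merged$start, 100L)
  expect_identical(merged$end, 350L)

  merged2 <- merge_hits(rbind(mk(100, 200, 99), mk(250, 350, 99)),
                        homology_params(merge_within = 10))
  expect_identical(nrow(merged2), 2L)

  # identity filter before merging: only the 98% hit seeds the region
  h3 <- rbind(mk(100, 300, 80), mk(150, 250, 98))
  m3 <- merge_hits(h3, homology_params(minid = 95,
                                       check_id_before_merge = TRUE))
  expect_identical(nrow(m3), 1L)
  expect_identical(m3$start, 150L)
  expect_identical(m3$end, 250L)
  # ...whereas merging first dilutes the region below minid
  m4 <- merge_hits(h3, homology_params(minid = 95,
                                       check_id_before_merge = FALSE))
  expect_identical(nrow(m4), 0L)

  # opposite strands never merge
  m5 <- merge_hits(rbind(mk(100, 200, 99), mk(210, 300, 99, "-")),
                   params)
  expect_identical(nrow(m5), 2L)

  expect_identical(nrow(merge_hits(mk(0, 50, 99),
                                   homology_params(minlen = 100))), 0L)
  expect_identical(nrow(merge_hits(empty_df <- merge_hits(
    mk(1, 2, 10)[0, ], params), params)), 0L)
})

test_that("merged regions are pairwise disjoint and sorted per seqid/strand", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    starts <- sample(0:2000, n, replace = TRUE)
    hits <- data.frame(
      query_id = "g", seqid = sample(c("c1", "c2"), n, replace = TRUE),
      start = starts, end = starts + sample(20:200, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      pct_identity = runif(n, 90, 100),
      aligned_length = 50L, score = 100, stringsAsFactors = FALSE)
    merged <- merge_hits(hits, homology_params(merge_within =
                                                 sample(0:100, 1)))
    for (key in split(merged, paste(merged$seqid, merged$strand))) {
      if (nrow(key) < 2L) next
      expect_true(all(diff(key$start) > 0))
      expect_true(all(key$start[-1] > key$end[-nrow(key)]))
    }
  }
})

test_that("excise_targets orients sequences and builds deterministic ids", {
  seqs <- c(s = paste0(strrep("A", 10), strrep("C", 10), strrep("G", 5)))
  t1 <- excise_targets(seqs, genomic_ranges("s", 10, 20, "+"), "acc")
  expect_identical(unname(t1[1]), "CCCCCCCCCC")
  expect_identical(names(t1), "acc|s|10-20|+")
  t2 <- excise_targets(seqs, genomic_ranges("s", 10, 20, "-"), "acc")
  expect_identical(unname(t2[1]), "GGGGGGGGGG")
  # overlapping ranges stay distinct; no dedup
  t3 <- excise_targets(seqs, genomic_ranges("s", c(0, 5), c(15, 20), "+"),
                       "acc")
  expect_length(t3, 2L)
  expect_error(excise_targets(seqs, genomic_ranges("s", 20, 30, "+")),
               "out of bounds")
})

test_that("reciprocal check accepts self-hits and rejects paralogues and noise", {
  set.seed(6)
  target_gene <- random_dna_str(500)
  # paralogue at ~20% divergence
  chars <- strsplit(target_gene, "")[[1]]
  idx <- sample(500, 100)
  for (i in idx) chars[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                            chars[i]), 1)
  paralogue <- paste(chars, collapse = "")
  assembly <- c(chr = paste0(random_dna_str(500), target_gene,
                             random_dna_str(400), paralogue,
                             random_dna_str(500)))
  annotation <- list(
    tg = gene_model("tg", genomic_ranges("chr", 500, 1000, "+")),
    pg = gene_model("pg", genomic_ranges("chr", 1400, 1900, "+")))
  expect_true(reciprocal_check(substr(target_gene, 50, 450), assembly,
                               annotation, "tg"))
  # a target excised from the paralogue aligns best to the paralogue
  expect_false(reciprocal_check(substr(paralogue, 50, 450), assembly,
                                annotation, "tg"))
  expect_false(reciprocal_check(random_dna_str(400), assembly,
                                annotation, "tg"))
})

test_that("restrict_to_domain trims targets through alignment lift-over", {
  set.seed(8)
  gene <- random_dna_str(1200)
  genome <- c(chr = paste0(random_dna_str(300), gene, random_dna_str(300)))
  targets <- excise_targets(genome, genomic_ranges("chr", 300, 1500, "+"),
                            "acc")
  dom <- list(g = data.frame(start = 300L, end = 900L))

  trimmed <- restrict_to_domain(targets, c(g = gene), dom)
  expect_identical(nchar(unname(trimmed[1])), 600L)
  expect_identical(unname(trimmed[1]), substr(gene, 301, 900))

  # a 30-bp insertion inside the domain stretches the trimmed target
  ins_target <- paste0(substr(gene, 1, 600), random_dna_str(30),
                       substr(gene, 601, 1200))
  t2 <- setNames(ins_target, "acc|chr|0-1230|+")
  attr(t2, "ranges") <- data.frame(seqid = "chr", start = 0L, end = 1230L,
                                   strand = "+", alias = "acc",
                                   target_id = names(t2),
                                   stringsAsFactors = FALSE)
  t2_trim <- restrict_to_domain(t2, c(g = gene), dom)
  expect_identical(nchar(unname(t2_trim[1])), 630L)

  # domain interval outside the aligned region drops the target
  short <- excise_targets(genome, genomic_ranges("chr", 300, 500, "+"),
                          "acc")
  expect_length(
    suppressMessages(restrict_to_domain(
      short, c(g = gene), list(g = data.frame(start = 900L, end = 1100L)))),
    0L)
})

test_that("fixture pangenome discovery recovers exactly the planted homologues", {
  fx <- generate_pangenome(fixture_spec(n_accessions = 3,
                                        n_genes_per_cluster = 2,
                                        seed = 42))
  gene_seqs <- setNames(lapply(names(fx$reference$annotation), function(g)
    slice_sequence(fx$reference$assembly,
                   fx$reference$annotation[[g]]$range)),
    names(fx$reference$annotation))
  gene_seqs <- unlist(gene_seqs)
  targets <- discover_targets(gene_seqs, fx$genomes, homology_params())
  prov <- attr(targets, "ranges")
  truth <- fx$truth$homologues
  expect_identical(nrow(prov), nrow(truth))
  for (i in seq_len(nrow(truth))) {
    match_rows <- prov[prov$alias == truth$alias[i] &
                         prov$start < truth$end[i] &
                         prov$end > truth$start[i], ]
    expect_identical(nrow(match_rows), 1L)
  }
})
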