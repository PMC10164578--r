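# gRNA filters: GC, off-target positional thresholds, feature membership,
# and the re-entrant mapping table.

test_that("gc_fraction computes (#G + #C)/length with inclusive default bounds", {
  expect_equal(gc_fraction("ATGC"), 0.5)
  expect_equal(gc_fraction("AAAA"), 0)
  spacer_30 <- paste0(strrep("G", 6), strrep("A", 14))  # 6/20 = 0.30
  expect_equal(gc_fraction(spacer_30), 0.3)
  # boundary value passes the default inclusive filter
  params <- filter_params()
  expect_true(gc_fraction(spacer_30) >= params$gc_min)
  expect_error(gc_fraction(""), "empty spacer")
  expect_error(gc_fraction("ACGN"), "non-ACGT")
})

test_that("parse_ot_pattern implements the clause grammar", {
  p <- parse_ot_pattern("0mg-10,1mg-11-")
  expect_identical(nrow(p), 2L)
  expect_identical(p$max_count, c(0L, 1L))
  expect_identical(p$from_pos, c(-1L, -11L))
  expect_identical(p$to_pos, c(-10L, NA_integer_))

  d <- parse_ot_pattern("")
  expect_identical(d$max_count, 0L)
  expect_identical(d$from_pos, -1L)
  expect_true(is.na(d$to_pos))

  q <- parse_ot_pattern("2m-5-8")
  expect_identical(q$max_count, 2L)
  expect_identical(q$types, "m")
  expect_identical(q$from_pos, -5L)
  expect_identical(q$to_pos, -8L)

  expect_error(parse_ot_pattern("1mg-0"), "positions must be")
  expect_error(parse_ot_pattern("1x-5"), "cannot parse")
  expect_error(parse_ot_pattern("mg-5"), "cannot parse")
})

test_that("off-target scan finds planted copies and masks target regions", {
  set.seed(90)
  spacer <- random_dna_str(20)
  bg <- paste0(random_dna_str(500), spacer, random_dna_str(480), spacer,
               random_dna_str(500))
  # both copies masked -> no hits
  masked <- data.frame(seqid = "b", start = c(500L, 1000L),
                       end = c(520L, 1520L))
  h0 <- find_offtarget_hits(c(g = spacer), c(b = bg), masked, 1L)
  expect_identical(nrow(h0), 0L)
  # one copy masked -> the exact second copy remains
  h1 <- find_offtarget_hits(c(g = spacer), c(b = bg),
                            data.frame(seqid = "b", start = 500L,
                                       end = 520L), 1L)
  exact <- h1[h1$edits == 0L, ]
  expect_identical(nrow(exact), 1L)
  expect_identical(exact$start, 1000L)
  expect_identical(exact$n_mismatch, 0L)
  expect_identical(exact$n_gap, 0L)
})

test_that("a substitution is classified at its PAM-relative position", {
  set.seed(91)
  spacer <- random_dna_str(20)
  # substitute spacer position -15 (3' PAM => 5'->3' index 6)
  chars <- strsplit(spacer, "")[[1]]
  chars[6] <- setdiff(c("A", "C", "G", "T"), chars[6])[1]
  copy <- paste(chars, collapse = "")
  bg <- paste0(random_dna_str(300), copy, random_dna_str(300))
  h <- find_offtarget_hits(c(g = spacer), c(b = bg), NULL, 1L)
  h <- h[h$strand == "+" & h$edits == 1L, ]
  expect_identical(nrow(h), 1L)
  ev <- h$events[[1]]
  expect_identical(which(ev == 1L), 6L)
  relpos <- pangrna:::pam_relative_positions(20L, "three_prime")
  expect_identical(relpos[6], -15L)
})

test_that("reverse-complement copies are found and classified identically", {
  set.seed(92)
  spacer <- random_dna_str(20)
  bg_f <- paste0(random_dna_str(200), spacer, random_dna_str(200))
  bg_r <- paste0(random_dna_str(200), reverse_complement(spacer),
                 random_dna_str(200))
  hf <- find_offtarget_hits(c(g = spacer), c(b = bg_f), NULL, 0L)
  hr <- find_offtarget_hits(c(g = spacer), c(b = bg_r), NULL, 0L)
  expect_identical(nrow(hf), 1L)
  expect_identical(nrow(hr), 1L)
  expect_identical(hr$strand, "-")
  expect_identical(hr$start, 200L)
  expect_identical(hf$events[[1]], hr$events[[1]])
})

test_that("verdicts follow the clause semantics", {
  no_hits <- find_offtarget_hits(c(g = "ACGTACGTACGTACGTACGT"),
                                 c(b = strrep("T", 100)), NULL, 0L)
  expect_identical(offtarget_verdict(no_hits, parse_ot_pattern("")),
                   "pass")

  set.seed(93)
  spacer <- random_dna_str(20)
  bg <- paste0(random_dna_str(100), spacer, random_dna_str(100))
  h <- find_offtarget_hits(c(g = spacer), c(b = bg), NULL, 1L)
  # exact elsewhere fails under the default pattern
  expect_identical(offtarget_verdict(h, parse_ot_pattern("")), "fail")

  # one mismatch at -3 violates clause 1 of '0mg-10,1mg-11-' -> pass
  chars <- strsplit(spacer, "")[[1]]
  chars[18] <- setdiff(c("A", "C", "G", "T"), chars[18])[1]   # pos -3
  bg2 <- paste0(random_dna_str(100), paste(chars, collapse = ""),
                random_dna_str(100))
  h2 <- find_offtarget_hits(c(g = spacer), c(b = bg2), NULL, 2L)
  pat <- parse_ot_pattern("0mg-10,1mg-11-")
  expect_identical(offtarget_verdict(h2, pat), "pass")
  # ...but the same mismatch at -15 satisfies both clauses -> fail
  chars2 <- strsplit(spacer, "")[[1]]
  chars2[6] <- setdiff(c("A", "C", "G", "T"), chars2[6])[1]
  bg3 <- paste0(random_dna_str(100), paste(chars2, collapse = ""),
                random_dna_str(100))
  h3 <- find_offtarget_hits(c(g = spacer), c(b = bg3), NULL, 2L)
  expect_identical(offtarget_verdict(h3, pat), "fail")
})

test_that("tightening a clause can only move verdicts from fail to pass", {
  set.seed(94)
  for (rep in 1:20) {
    spacer <- random_dna_str(20)
    # plant a randomly mutated copy
    chars <- strsplit(spacer, "")[[1]]
    nmut <- sample(0:2, 1)
    for (i in sample(20, nmut))
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    bg <- c(b = paste0(random_dna_str(200), paste(chars, collapse = ""),
                       random_dna_str(200)))
    h <- find_offtarget_hits(c(g = spacer), bg, NULL, 3L)
    loose <- offtarget_verdict(h, parse_ot_pattern("2mg-20"))
    tight <- offtarget_verdict(h, parse_ot_pattern("0mg-20"))
    # anything failing the tight (perfect-match) rule must also fail the
    # looser rule that tolerates more edits
    if (tight == "fail") expect_identical(loose, "fail")
  }
})

test_that("a gRNA failing background keeps failing with more backgrounds", {
  set.seed(95)
  spacer <- random_dna_str(20)
  bg1 <- c(a = paste0(random_dna_str(100), spacer, random_dna_str(100)))
  bg2 <- c(bg1, c(b = random_dna_str(300)))
  h1 <- find_offtarget_hits(c(g = spacer), bg1, NULL, 1L)
  h2 <- find_offtarget_hits(c(g = spacer), bg2, NULL, 1L)
  pat <- parse_ot_pattern("")
  expect_identical(offtarget_verdict(h1, pat), "fail")
  expect_identical(offtarget_verdict(h2, pat), "fail")
  expect_gte(nrow(h2), nrow(h1))
})

test_that("off-target verdicts agree with the exhaustive edit-distance oracle", {
  set.seed(96)
  pats <- list(parse_ot_pattern(""), parse_ot_pattern("0mg-10,1mg-11-"))
  for (rep in 1:15) {
    spacer <- random_dna_str(20)
    copy <- mutated_copy(spacer,
                         c("exact", "mismatch", "gap")[(rep %% 3L) + 1L])
    strand_rc <- runif(1) < 0.5
    planted <- if (strand_rc) reverse_complement(copy) else copy
    bg <- c(b = paste0(random_dna_str(900), planted, random_dna_str(900)))
    pat <- pats[[sample(2, 1)]]
    max_edits <- max(pat$max_count) + 1L
    h <- find_offtarget_hits(c(g = spacer), bg, NULL, max_edits)
    got <- offtarget_verdict(h, pat)
    want <- oracle_ot_verdict(spacer, bg, NULL, pat, max_edits)
    expect_identical(got, want)
  }
})

test_that("feature ranges project through alignments, shifting with indels", {
  set.seed(97)
  exon1 <- random_dna_str(150); intron <- random_dna_str(90)
  exon2 <- random_dna_str(160)
  gene <- paste0(exon1, intron, exon2)
  model <- gene_model("g", genomic_ranges("chr", 0, nchar(gene), "+"),
                      data.frame(type = "CDS", start = c(0L, 240L),
                                 end = c(150L, 400L)))
  # identical intronless target: CDS covers the whole of both exon copies
  fr <- infer_feature_ranges(gene, c(g = gene), list(g = model), "CDS")
  expect_identical(fr$start, c(0L, 240L))
  expect_identical(fr$end, c(150L, 400L))

  # 10-bp insertion upstream shifts everything by +10
  shifted <- paste0(random_dna_str(10), gene)
  fr2 <- infer_feature_ranges(shifted, c(g = gene), list(g = model), "CDS")
  expect_identical(fr2$start, c(10L, 250L))
  expect_identical(fr2$end, c(160L, 410L))

  # projections always stay within the target bounds
  fr3 <- infer_feature_ranges(random_dna_str(60), c(g = gene),
                              list(g = model), "CDS")
  if (nrow(fr3)) {
    expect_gte(min(fr3$start), 0L)
    expect_lte(max(fr3$end), 60L)
  }
  # no annotated feature of the requested type -> empty
  fr4 <- infer_feature_ranges(gene, c(g = gene), list(g = model),
                              "five_prime_UTR")
  expect_identical(nrow(fr4), 0L)
})

test_that("apply_filters builds the mapping with per-check verdicts", {
  set.seed(98)
  # target with a guaranteed all-pass site: balanced spacer + TGG PAM
  spacer <- "ACGTTGCATCAGTACGGTAC"
  target <- paste0(random_dna_str(40), spacer, "TGG", random_dna_str(40))
  targets <- c(t1 = target)
  cands <- enumerate_grna(targets, "cas9")
  mapping <- apply_filters(cands, targets, filter_params())
  expect_s3_class(mapping, "grna_mapping")
  expect_true(all(mapping[["check:GC"]] %in% c("pass", "fail")))
  # no backgrounds / annotation -> NA columns
  expect_true(all(is.na(mapping[["check:background"]]) |
                    mapping[["check:background"]] == "NA"))
  expect_true(all(is.na(mapping[["check:feature"]]) |
                    mapping[["check:feature"]] == "NA"))
  gid <- names(cands$spacers)[cands$spacers == spacer]
  expect_identical(
    unique(mapping[["check:GC"]][mapping$grna_id == gid]), "pass")

  # GC-rich spacer fails on every row
  rich <- strrep("G", 16)
  t2 <- c(t1 = paste0("AAAA", rich, "TGGAAAA"))
  cands2 <- enumerate_grna(t2, "NGG", length = 16)
  map2 <- apply_filters(cands2, t2, filter_params())
  gid2 <- names(cands2$spacers)[cands2$spacers == rich]
  expect_identical(
    unique(map2[["check:GC"]][map2$grna_id == gid2]), "fail")

  # gRNA wholly inside an intron fails the feature check
  set.seed(99)
  exon1 <- random_dna_str(120); intron <- random_dna_str(100)
  exon2 <- random_dna_str(120)
  gene <- paste0(exon1, intron, exon2)
  model <- gene_model("g", genomic_ranges("chr", 0, nchar(gene), "+"),
                      data.frame(type = "CDS", start = c(0L, 220L),
                                 end = c(120L, 340L)))
  tg <- c(t = gene)
  cands3 <- enumerate_grna(tg, "cas9")
  map3 <- apply_filters(cands3, tg,
                        filter_params(gene_seqs = c(g = gene),
                                      annotation = list(g = model)))
  intronic <- map3$start >= 120L & map3$end <= 220L
  if (any(intronic))
    expect_true(all(map3[["check:feature"]][intronic] == "fail"))
  exonic <- map3$end <= 120L
  if (any(exonic))
    expect_true(all(map3[["check:feature"]][exonic] == "pass"))
})

test_that("mapping tables round-trip byte-identically and validate", {
  set.seed(100)
  target <- paste0(random_dna_str(60), "TGG", random_dna_str(60))
  targets <- c(t1 = target)
  cands <- enumerate_grna(targets, "cas9")
  mapping <- apply_filters(cands, targets, filter_params())
  f1 <- withr::local_tempfile(fileext = ".map")
  f2 <- withr::local_tempfile(fileext = ".map")
  write_mapping(mapping, f1)
  back <- read_mapping(f1)
  write_mapping(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  df <- as.data.frame(mapping)
  df[["check:GC"]][1] <- "maybe"
  expect_error(pangrna:::as_grna_mapping(df), "allowed: pass/fail/NA")
  df2 <- as.data.frame(mapping)
  df2 <- rbind(df2, df2[1, ])
  expect_error(pangrna:::as_grna_mapping(df2), "duplicate")
})
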