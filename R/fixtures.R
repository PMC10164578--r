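# Deterministic synthetic pangenomes: a reference multi-gene cluster
# replicated across pseudo-accessions with seeded divergence, planted
# gRNA sites locked against mutation, and diverged decoy paralogues.
# Every downstream stage can be tested hermetically against the emitted
# ground truth.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

instantiate_iupac <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  paste(vapply(chars, function(ch)
    substr(IUPAC_CODES[[ch]], 1L, 1L), character(1)), collapse = "")
}

# seeded point mutations and 1-bp indels outside locked intervals
# locked: data.frame(start, end) in 0-based half-open gene coordinates
mutate_seq <- function(seq, sub_rate, indel_rate, locked = NULL) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  is_locked <- rep(FALSE, n)
  if (!is.null(locked) && nrow(locked) > 0L)
    for (i in seq_len(nrow(locked)))
      is_locked[(locked$start[i] + 1L):locked$end[i]] <- TRUE
  bases <- c("A", "C", "G", "T")
  subs <- which(runif(n) < sub_rate & !is_locked)
  for (i in subs)
    chars[i] <- sample(setdiff(bases, chars[i]), 1L)
  out <- as.list(chars)
  indels <- which(runif(n) < indel_rate & !is_locked)
  for (i in indels) {
    if (runif(1) < 0.5) out[[i]] <- character(0)              # deletion
    else out[[i]] <- c(chars[i], sample(bases, 1L))           # insertion
  }
  paste(unlist(out), collapse = "")
}

#' Specification of a synthetic pangenome fixture
#'
#' The defaults describe the standard study conditions used throughout
#' the test-suite: 16 accessions carrying a five-gene cluster at 2%
#' substitution divergence from the reference, with one universal gRNA
#' site planted in the first exon of every gene (mutation-locked, GC kept
#' within 0.35-0.65 so it clears the default GC filter) and one decoy
#' paralogue per genome at 20% divergence.
#'
#' @param n_accessions number of pseudo-accessions.
#' @param n_genes_per_cluster genes in the tandem cluster.
#' @param intron_layout alternating exon/intron lengths (bp), starting
#'   and ending with an exon.
#' @param substitution_rate,indel_rate per-base mutation rates applied to
#'   accession homologues outside locked windows, in `[0, 1)`.
#' @param n_planted_universal_sites spacer+PAM blocks planted identically
#'   in every gene (and therefore every homologue).
#' @param n_planted_private_sites blocks planted in a single gene each
#'   (round-robin over genes).
#' @param decoy_paralogue_divergence substitution rate of the decoy
#'   paralogue copied from gene 1 (0 disables decoys); planted windows in
#'   decoys are always broken.
#' @param pam concrete PAM pattern planted next to each site (IUPAC codes
#'   are instantiated deterministically).
#' @param pam_orientation `"three_prime"` or `"five_prime"`.
#' @param spacer_length planted spacer length (nt).
#' @param intergenic_length,flank_length random filler lengths (bp).
#' @param seed integer fixing all randomness.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_accessions = 16L, n_genes_per_cluster = 5L,
                         intron_layout = c(220L, 100L, 180L),
                         substitution_rate = 0.02, indel_rate = 0.002,
                         n_planted_universal_sites = 1L,
                         n_planted_private_sites = 0L,
                         decoy_paralogue_divergence = 0.2,
                         pam = "NGG", pam_orientation = "three_prime",
                         spacer_length = 20L,
                         intergenic_length = 300L, flank_length = 200L,
                         seed = 1L) {
  rates <- c(substitution_rate, indel_rate, decoy_paralogue_divergence)
  if (any(rates < 0) || any(rates >= 1))
    stop("rates must lie in [0, 1)")
  if (length(intron_layout) %% 2L == 0L)
    stop("intron_layout must start and end with an exon")
  block <- spacer_length + nchar(instantiate_iupac(gsub("[(|).]", "",
                                                        pam)))
  # planted sites sit >= 30 bp inside the exon so that local-alignment
  # end-trimming of discovered targets can never clip them
  n_sites_exon1 <- n_planted_universal_sites
  if (30L + n_sites_exon1 * (block + 5L) > intron_layout[1L])
    stop("infeasible spec: planted sites do not fit in the first exon")
  structure(list(
    n_accessions = as.integer(n_accessions),
    n_genes_per_cluster = as.integer(n_genes_per_cluster),
    intron_layout = as.integer(intron_layout),
    gene_length = sum(as.integer(intron_layout)),
    substitution_rate = substitution_rate, indel_rate = indel_rate,
    n_planted_universal_sites = as.integer(n_planted_universal_sites),
    n_planted_private_sites = as.integer(n_planted_private_sites),
    decoy_paralogue_divergence = decoy_paralogue_divergence,
    pam = pam, pam_orientation = pam_orientation,
    spacer_length = as.integer(spacer_length),
    intergenic_length = as.integer(intergenic_length),
    flank_length = as.integer(flank_length),
    seed = as.integer(seed)), class = "fixture_spec")
}

# exon intervals (0-based half-open, gene-local) implied by the layout
layout_exons <- function(intron_layout) {
  bounds <- cumsum(c(0L, intron_layout))
  idx <- seq(1L, length(intron_layout), by = 2L)
  data.frame(start = bounds[idx], end = bounds[idx + 1L])
}

random_spacer <- function(len, gc_lo = 0.35, gc_hi = 0.65) {
  repeat {
    sp <- random_dna(len)
    gc <- gc_fraction(sp)
    if (gc >= gc_lo && gc <= gc_hi) return(sp)
  }
}

count_occurrences <- function(pattern, seqs) {
  sum(vapply(seqs, function(s) {
    hits <- gregexpr(pattern, s, fixed = TRUE)[[1]]
    sum(hits > 0L)
  }, double(1)))
}

#' Generate a synthetic pangenome with ground truth
#'
#' Builds a reference cluster (FASTA + gene models), derives each
#' accession's homologues by seeded mutation outside planted-site
#' windows, appends decoy paralogues, and verifies that every planted
#' spacer occurs exactly once per intended homologue and nowhere else in
#' any genome (regenerating deterministically if a random collision is
#' detected).
#'
#' @param spec [fixture_spec()].
#' @param dir optional output directory; when given, writes
#'   `reference.fasta`, `reference.gff3`, one `acc_<i>.fasta` per
#'   accession, a `genome_set.txt` lookup, and the ground truth as
#'   `truth.json` plus `homologues.tsv`.
#' @return list with `reference` (`assembly`, `annotation`), `genomes`
#'   (named list of named character vectors), `truth` (planted spacers,
#'   homologue ranges, decoy ranges, expected minimum cover size) and
#'   `spec`.
#' @export
generate_pangenome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  for (salt in 0:19) {
    set.seed(spec$seed + salt * 1000003L)
    fx <- try(build_fixture_once(spec), silent = TRUE)
    if (!inherits(fx, "try-error")) {
      if (!is.null(dir)) write_fixture(fx, dir)
      return(fx)
    }
  }
  stop("fixture generation failed: ", attr(fx, "condition")$message)
}

build_fixture_once <- function(spec) {
  ng <- spec$n_genes_per_cluster
  na <- spec$n_accessions
  exons <- layout_exons(spec$intron_layout)
  pam_inst <- instantiate_iupac(gsub("[(|).]", "", spec$pam))
  sl <- spec$spacer_length
  block_len <- sl + nchar(pam_inst)

  genes <- vapply(seq_len(ng), function(i) random_dna(spec$gene_length),
                  character(1))
  intergenic_ref <- vapply(seq_len(ng), function(i)
    random_dna(spec$intergenic_length), character(1))
  flanks_ref <- c(random_dna(spec$flank_length),
                  random_dna(spec$flank_length))
  intergenic_acc <- lapply(seq_len(na), function(a)
    vapply(seq_len(ng), function(i) random_dna(spec$intergenic_length),
           character(1)))
  flanks_acc <- lapply(seq_len(na), function(a)
    c(random_dna(spec$flank_length), random_dna(spec$flank_length)))
  material <- c(genes, intergenic_ref, flanks_ref,
                unlist(intergenic_acc), unlist(flanks_acc))

  # choose planted spacers absent from all random material
  pick_spacer <- function(existing) {
    for (try in 1:200) {
      sp <- random_spacer(sl)
      pats <- unique(c(sp, reverse_complement(sp)))
      if (sum(vapply(pats, count_occurrences, double(1), material)) == 0L &&
          !(sp %in% existing))
        return(sp)
    }
    stop("could not choose a unique planted spacer")
  }
  n_univ <- spec$n_planted_universal_sites
  n_priv <- spec$n_planted_private_sites
  spacers <- character(0)
  for (i in seq_len(n_univ + n_priv)) spacers <- c(spacers,
                                                   pick_spacer(spacers))
  univ_spacers <- if (n_univ) spacers[seq_len(n_univ)] else character(0)
  priv_spacers <- if (n_priv) spacers[n_univ + seq_len(n_priv)] else
    character(0)
  priv_gene <- if (n_priv) ((seq_len(n_priv) - 1L) %% ng) + 1L else
    integer(0)

  make_block <- function(sp) {
    if (spec$pam_orientation == "five_prime") paste0(pam_inst, sp)
    else paste0(sp, pam_inst)
  }
  spacer_offset_in_block <- if (spec$pam_orientation == "five_prime")
    nchar(pam_inst) else 0L

  # plant blocks; record locked windows per gene
  locked <- lapply(seq_len(ng), function(g)
    data.frame(start = integer(), end = integer()))
  plant <- function(gene_seq, offset, block) {
    paste0(substr(gene_seq, 1L, offset),
           block,
           substr(gene_seq, offset + nchar(block) + 1L, nchar(gene_seq)))
  }
  univ_offsets <- 30L + (seq_len(n_univ) - 1L) * (block_len + 5L)
  for (s in seq_len(n_univ)) {
    off <- exons$start[1L] + univ_offsets[s]
    for (g in seq_len(ng)) {
      genes[g] <- plant(genes[g], off, make_block(univ_spacers[s]))
      locked[[g]] <- rbind(locked[[g]],
                           data.frame(start = off, end = off + block_len))
    }
  }
  last_exon <- nrow(exons)
  if (n_priv &&
      60L + ceiling(n_priv / ng) * (block_len + 5L) >
      (exons$end[last_exon] - exons$start[last_exon]))
    stop("infeasible spec: private sites do not fit in the last exon")
  for (p in seq_len(n_priv)) {
    g <- priv_gene[p]
    slot <- (p - 1L) %/% ng
    off <- exons$start[last_exon] + 30L + slot * (block_len + 5L)
    genes[g] <- plant(genes[g], off, make_block(priv_spacers[p]))
    locked[[g]] <- rbind(locked[[g]],
                         data.frame(start = off, end = off + block_len))
  }

  make_decoy <- function() {
    if (spec$decoy_paralogue_divergence <= 0) return(NULL)
    d <- mutate_seq(genes[1L], spec$decoy_paralogue_divergence, 0)
    # planted windows must not survive in decoys
    for (i in seq_len(nrow(locked[[1L]]))) {
      a <- locked[[1L]]$start[i]; b <- locked[[1L]]$end[i]
      if (substr(d, a + 1L, b) == substr(genes[1L], a + 1L, b)) {
        mid <- a + (b - a) %/% 2L
        orig <- substr(d, mid + 1L, mid + 1L)
        substr(d, mid + 1L, mid + 1L) <-
          setdiff(c("A", "C", "G", "T"), orig)[1L]
      }
    }
    d
  }

  # assemble reference chromosome and annotation
  ref_parts <- character(0)
  cursor <- 0L
  gene_rows <- list()
  append_part <- function(part) {
    ref_parts <<- c(ref_parts, part)
    cursor <<- cursor + nchar(part)
  }
  append_part(flanks_ref[1L])
  models <- list()
  for (g in seq_len(ng)) {
    gid <- sprintf("gene%02d", g)
    gstart <- cursor
    append_part(genes[g])
    feats <- data.frame(type = "CDS", start = gstart + exons$start,
                        end = gstart + exons$end, stringsAsFactors = FALSE)
    models[[gid]] <- gene_model(
      gid, genomic_ranges("chrR", gstart, cursor, "+"), feats)
    gene_rows[[g]] <- data.frame(gene_id = gid, start = gstart,
                                 end = cursor, stringsAsFactors = FALSE)
    append_part(intergenic_ref[g])
  }
  ref_decoy <- make_decoy()
  decoy_rows <- list()
  if (!is.null(ref_decoy)) {
    decoy_rows[["ref"]] <- data.frame(alias = "ref", seqid = "chrR",
                                      start = cursor,
                                      end = cursor + nchar(ref_decoy),
                                      stringsAsFactors = FALSE)
    append_part(ref_decoy)
  }
  append_part(flanks_ref[2L])
  reference <- list(assembly = c(chrR = paste(ref_parts, collapse = "")),
                    annotation = models)

  # accessions
  genomes <- list()
  hom_rows <- list()
  for (a in seq_len(na)) {
    alias <- sprintf("acc%02d", a)
    parts <- character(0)
    cursor <- 0L
    add <- function(part) {
      parts <<- c(parts, part)
      cursor <<- cursor + nchar(part)
    }
    add(flanks_acc[[a]][1L])
    for (g in seq_len(ng)) {
      mg <- mutate_seq(genes[g], spec$substitution_rate, spec$indel_rate,
                       locked[[g]])
      hom_rows[[length(hom_rows) + 1L]] <- data.frame(
        alias = alias, seqid = "ctg1", start = cursor,
        end = cursor + nchar(mg), strand = "+",
        gene_id = sprintf("gene%02d", g), stringsAsFactors = FALSE)
      add(mg)
      add(intergenic_acc[[a]][g])
    }
    dec <- make_decoy()
    if (!is.null(dec)) {
      decoy_rows[[alias]] <- data.frame(alias = alias, seqid = "ctg1",
                                        start = cursor,
                                        end = cursor + nchar(dec),
                                        stringsAsFactors = FALSE)
      add(dec)
    }
    add(flanks_acc[[a]][2L])
    genomes[[alias]] <- c(ctg1 = paste(parts, collapse = ""))
  }

  # verify planted-site uniqueness: each universal spacer once per
  # homologue (and reference gene), each private spacer once per
  # homologue of its gene, nothing anywhere else
  all_seqs <- c(reference$assembly, unlist(unname(lapply(genomes,
                                                         identity))))
  for (s in seq_len(n_univ)) {
    sp <- univ_spacers[s]
    expect_n <- (na + 1L) * ng
    got <- count_occurrences(sp, all_seqs) +
      count_occurrences(reverse_complement(sp), all_seqs)
    if (got != expect_n)
      stop("planted universal spacer collision (", got, " vs ", expect_n,
           ")")
  }
  for (p in seq_len(n_priv)) {
    sp <- priv_spacers[p]
    expect_n <- na + 1L
    got <- count_occurrences(sp, all_seqs) +
      count_occurrences(reverse_complement(sp), all_seqs)
    if (got != expect_n)
      stop("planted private spacer collision (", got, " vs ", expect_n, ")")
  }

  truth <- list(
    homologues = do.call(rbind, hom_rows),
    universal_sites = if (n_univ) data.frame(
      site = seq_len(n_univ), spacer = univ_spacers,
      offset_in_gene = exons$start[1L] + univ_offsets + spacer_offset_in_block,
      stringsAsFactors = FALSE) else NULL,
    private_sites = if (n_priv) data.frame(
      site = seq_len(n_priv), spacer = priv_spacers,
      gene_id = sprintf("gene%02d", priv_gene),
      stringsAsFactors = FALSE) else NULL,
    decoys = if (length(decoy_rows)) do.call(rbind, c(decoy_rows,
                                                      list(make.row.names =
                                                             FALSE))) else NULL,
    expected_min_cover = if (n_univ > 0L) 1L else NA_integer_)
  structure(list(reference = reference, genomes = genomes, truth = truth,
                 spec = spec), class = "pangenome_fixture")
}

#' @export
print.pangenome_fixture <- function(x, ...) {
  cat(sprintf("<pangenome_fixture> %d accession(s) x %d gene(s), %d planted site(s)\n",
              x$spec$n_accessions, x$spec$n_genes_per_cluster,
              x$spec$n_planted_universal_sites +
                x$spec$n_planted_private_sites))
  invisible(x)
}

write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fx$reference$assembly, file.path(dir, "reference.fasta"))
  write_gff3(fx$reference$annotation, file.path(dir, "reference.gff3"))
  lookup <- character(0)
  for (alias in names(fx$genomes)) {
    f <- file.path(dir, paste0(alias, ".fasta"))
    write_fasta(fx$genomes[[alias]], f)
    lookup <- c(lookup, paste(alias, basename(f), sep = "\t"))
  }
  writeLines(c("# alias\tfasta", lookup), file.path(dir, "genome_set.txt"))
  write.table(fx$truth$homologues, file.path(dir, "homologues.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- fx$truth
  truth$homologues <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
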