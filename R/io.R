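# Readers/writers for FASTA, GFF3 and the alias lookup files, plus the
# gene-model container used by annotation-aware steps.

#' Read a FASTA file
#'
#' Sequences are upper-cased and validated against the IUPAC DNA alphabet;
#' record order is preserved.  Header descriptions (text after the first
#' whitespace) are kept in the `"desc"` attribute.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    out <- character(0)
    attr(out, "desc") <- character(0)
    return(out)
  }
  if (!startsWith(lines[nonempty[1L]], ">"))
    stop("malformed FASTA: line ", nonempty[1L], " does not start with '>'")
  for (i in nonempty) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      if (!nzchar(trimws(substring(ln, 2L))))
        stop("malformed FASTA header at line ", i)
    } else {
      bad <- validate_dna(toupper(trimws(ln)))
      if (length(bad))
        stop("illegal sequence character '", bad[1L], "' at line ", i)
    }
  }
  x <- Biostrings::readBStringSet(path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id: ", ids[duplicated(ids)][1L])
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  out <- toupper(as.character(x))
  names(out) <- ids
  attr(out, "desc") <- setNames(desc, ids)
  out
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  x <- Biostrings::BStringSet(as.character(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = as.integer(width))
  invisible(path)
}

#' Construct a gene model
#'
#' @param gene_id gene identifier.
#' @param range one-row data.frame from [genomic_ranges()] giving the gene
#'   span.
#' @param features data.frame with columns `type`, `start`, `end` (0-based
#'   half-open, on the gene's seqid/strand); may span several isoforms.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, range, features = NULL) {
  stopifnot(is.character(gene_id), nrow(range) == 1L)
  if (is.null(features))
    features <- data.frame(type = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)
  if (nrow(features) > 0L &&
      (any(features$start < range$start) || any(features$end > range$end)))
    stop("features of ", gene_id, " extend beyond the gene range")
  structure(
    list(gene_id = gene_id, range = range, features = features),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s), %d feature(s)\n", x$gene_id,
              x$range$seqid, x$range$start, x$range$end, x$range$strand,
              nrow(x$features)))
  invisible(x)
}

# Reduced (union) feature intervals of one type, in genomic coordinates.
gene_feature_ranges <- function(model, type = "CDS") {
  f <- model$features[model$features$type == type, , drop = FALSE]
  if (nrow(f) == 0L) return(genomic_ranges())
  r <- genomic_ranges(model$range$seqid, f$start, f$end, model$range$strand)
  range_reduce(r, gap = 0L)[, c("seqid", "start", "end", "strand")]
}

# Same intervals in gene-local coordinates oriented 5'->3' along the gene.
gene_local_feature_ranges <- function(model, type = "CDS") {
  g <- gene_feature_ranges(model, type)
  if (nrow(g) == 0L) return(g)
  if (model$range$strand == "-") {
    start <- model$range$end - g$end
    end <- model$range$end - g$start
  } else {
    start <- g$start - model$range$start
    end <- g$end - model$range$start
  }
  out <- genomic_ranges(model$gene_id, start, end, "+")
  out[order(out$start), , drop = FALSE]
}

#' Read gene models from a GFF3 file
#'
#' Parses the gene/mRNA/CDS hierarchy (via `Parent` attributes) and converts
#' the 1-based inclusive GFF3 coordinates to the package's 0-based half-open
#' convention.  Features of all isoforms are grouped under one gene model.
#'
#' @param path path to a GFF3 file.
#' @return named list of [gene_model()] objects.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) as.character(p[1L]) else NA_character_, character(1))
  gene_idx <- which(type == "gene")
  gene_ids <- ids[gene_idx]
  names(gene_idx) <- gene_ids
  # map any feature id to its owning gene id
  owner <- setNames(gene_ids, gene_ids)
  mrna_idx <- which(type == "mRNA")
  for (i in mrna_idx) {
    if (is.na(parents[i]) || !(parents[i] %in% names(owner)))
      stop("mRNA ", ids[i], " has no resolvable gene parent")
    owner[ids[i]] <- owner[[parents[i]]]
  }
  models <- lapply(gene_idx, function(i) {
    rng <- genomic_ranges(as.character(GenomicRanges::seqnames(gr)[i]),
                          GenomicRanges::start(gr)[i] - 1L,
                          GenomicRanges::end(gr)[i],
                          as.character(GenomicRanges::strand(gr)[i]))
    gene_model(ids[i], rng)
  })
  names(models) <- gene_ids
  feat_idx <- which(!(type %in% c("gene", "mRNA")))
  for (i in feat_idx) {
    if (is.na(parents[i]) || !(parents[i] %in% names(owner)))
      stop(type[i], " feature at line for seq ",
           as.character(GenomicRanges::seqnames(gr)[i]),
           " has no resolvable gene parent")
    g <- owner[[parents[i]]]
    models[[g]]$features <- rbind(
      models[[g]]$features,
      data.frame(type = type[i],
                 start = GenomicRanges::start(gr)[i] - 1L,
                 end = GenomicRanges::end(gr)[i],
                 stringsAsFactors = FALSE)
    )
  }
  models
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gff3()]: emits one gene and one mRNA row per model plus
#' its feature rows, converting back to 1-based inclusive coordinates.
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @export
write_gff3 <- function(models, path) {
  rows <- list()
  for (m in models) {
    gid <- m$gene_id
    mid <- paste0(gid, ".1")
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = m$range$seqid, start = m$range$start + 1L, end = m$range$end,
      strand = m$range$strand, type = "gene", ID = gid, Parent = NA_character_,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = m$range$seqid, start = m$range$start + 1L, end = m$range$end,
      strand = m$range$strand, type = "mRNA", ID = mid, Parent = gid,
      stringsAsFactors = FALSE)
    if (nrow(m$features) > 0L) {
      f <- m$features
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = m$range$seqid, start = f$start + 1L, end = f$end,
        strand = m$range$strand, type = f$type,
        ID = paste0(mid, ".", f$type, ".", seq_len(nrow(f))), Parent = mid,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    df$seqid, IRanges::IRanges(df$start, df$end), strand = df$strand)
  gr$type <- df$type
  gr$ID <- df$ID
  gr$Parent <- IRanges::CharacterList(
    lapply(df$Parent, function(p) if (is.na(p)) character() else p))
  gr$phase <- ifelse(df$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

read_lookup <- function(path, ncol_expected) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != ncol_expected)
  if (length(bad))
    stop("lookup file ", path, ": expected ", ncol_expected,
         " tab-separated columns at entry ", bad[1L])
  parts
}

#' Read an alias-to-FASTA lookup file
#'
#' Two tab-separated columns (alias, FASTA path); `#` comment lines allowed.
#' Paths are resolved relative to the lookup file's directory and each must
#' exist.
#'
#' @param path path to the lookup file.
#' @return named character vector mapping alias to FASTA path.
#' @export
read_genome_set <- function(path) {
  parts <- read_lookup(path, 2L)
  aliases <- vapply(parts, `[[`, character(1), 1L)
  files <- vapply(parts, `[[`, character(1), 2L)
  if (anyDuplicated(aliases))
    stop("duplicate alias in ", path, ": ", aliases[duplicated(aliases)][1L])
  files <- ifelse(file.exists(files), files,
                  file.path(dirname(path), files))
  missing <- which(!file.exists(files))
  if (length(missing))
    stop("alias '", aliases[missing[1L]], "' resolves to a missing file: ",
         files[missing[1L]])
  setNames(files, aliases)
}

#' Read a reference-set lookup file
#'
#' Three tab-separated columns (alias, assembly FASTA, annotation GFF3).
#'
#' @param path path to the lookup file.
#' @return named list; each element is `list(assembly =, annotation =)`.
#' @export
read_reference_set <- function(path) {
  parts <- read_lookup(path, 3L)
  aliases <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(aliases))
    stop("duplicate alias in ", path, ": ", aliases[duplicated(aliases)][1L])
  out <- lapply(parts, function(p) {
    files <- p[2:3]
    files <- ifelse(file.exists(files), files,
                    file.path(dirname(path), files))
    missing <- which(!file.exists(files))
    if (length(missing))
      stop("alias '", p[1L], "' resolves to a missing file: ",
           files[missing[1L]])
    list(assembly = files[1L], annotation = files[2L])
  })
  setNames(out, aliases)
}
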