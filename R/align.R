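# Pluggable local-alignment engine.  The built-in engine seeds candidate
# windows with exact k-mer matches on both strands and polishes each window
# with an affine-gap Smith-Waterman (Biostrings::pairwiseAlignment), so the
# whole pipeline runs without shelling out.  External aligners (e.g. a
# BLASTN wrapper) can be substituted as any function with the same
# signature returning the same hit columns.

local_sub_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                           baseOnly = FALSE)
}

global_sub_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

kmer_starts <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

empty_hits <- function() {
  data.frame(query_id = character(), seqid = character(), start = integer(),
             end = integer(), strand = character(), pct_identity = double(),
             aligned_length = integer(), score = double(),
             stringsAsFactors = FALSE)
}

# One query vs one subject strand (subject given already oriented);
# returns hits in the oriented coordinate system.
seeded_hits_one <- function(query, subject, k, min_score, cluster_gap,
                            submat) {
  qk <- kmer_starts(query, k)
  sk <- kmer_starts(subject, k)
  if (!length(qk) || !length(sk)) return(NULL)
  hit_pos <- which(sk %in% qk)        # 1-based subject seed starts
  if (!length(hit_pos)) return(NULL)
  qlen <- nchar(query)
  slen <- nchar(subject)
  # cluster seed positions into candidate windows
  gaps <- diff(hit_pos)
  cluster_id <- cumsum(c(1L, as.integer(gaps > cluster_gap)))
  out <- list()
  for (cl in split(hit_pos, cluster_id)) {
    wstart <- max(0L, min(cl) - 1L - qlen)            # 0-based
    wend <- min(slen, max(cl) - 1L + k + qlen)
    wseq <- substr(subject, wstart + 1L, wend)
    aln <- Biostrings::pairwiseAlignment(
      query, wseq, type = "local", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 2)
    sc <- Biostrings::score(aln)
    if (sc < min_score) next
    srng <- aln@subject@range
    alen <- Biostrings::nchar(aln)
    out[[length(out) + 1L]] <- data.frame(
      start = wstart + BiocGenerics::start(srng) - 1L,
      end = wstart + BiocGenerics::end(srng),
      pct_identity = 100 * Biostrings::nmatch(aln) / alen,
      aligned_length = alen, score = sc, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[!duplicated(res[, c("start", "end")]), , drop = FALSE]
}

#' Built-in seeded local-alignment engine
#'
#' Returns an engine function for [search_homologues()]: exact `k`-mer
#' seeding on both strands, seed clustering into candidate windows, and
#' affine-gap local alignment of the query within each window.
#'
#' @param k seed length in bp.
#' @param min_score minimum local alignment score (match +2, mismatch -3,
#'   gap open 5, gap extend 2) for a hit to be reported.
#' @param cluster_gap maximum distance between seeds grouped into one
#'   candidate window.
#' @return function `(gene_seqs, genome) -> data.frame` of alignment hits
#'   with columns `query_id`, `seqid`, `start`, `end`, `strand`,
#'   `pct_identity`, `aligned_length`, `score`.
#' @export
builtin_engine <- function(k = 11L, min_score = 40, cluster_gap = 100L) {
  submat <- local_sub_matrix()
  function(gene_seqs, genome) {
    hits <- list()
    for (qid in names(gene_seqs)) {
      q <- gene_seqs[[qid]]
      for (sid in names(genome)) {
        s <- genome[[sid]]
        slen <- nchar(s)
        fwd <- seeded_hits_one(q, s, k, min_score, cluster_gap, submat)
        if (!is.null(fwd)) {
          fwd$query_id <- qid; fwd$seqid <- sid; fwd$strand <- "+"
          hits[[length(hits) + 1L]] <- fwd
        }
        rev <- seeded_hits_one(q, reverse_complement(s), k, min_score,
                               cluster_gap, submat)
        if (!is.null(rev)) {
          rc_start <- slen - rev$end
          rev$end <- slen - rev$start
          rev$start <- rc_start
          rev$query_id <- qid; rev$seqid <- sid; rev$strand <- "-"
          hits[[length(hits) + 1L]] <- rev
        }
      }
    }
    if (!length(hits)) return(empty_hits())
    out <- do.call(rbind, hits)
    out <- out[, c("query_id", "seqid", "start", "end", "strand",
                   "pct_identity", "aligned_length", "score")]
    rownames(out) <- NULL
    out
  }
}

#' Find local alignments of reference genes in a genome
#'
#' Step 1 primitive: all local alignments of each gene in each genome
#' record, on both strands, with percent identity computed over alignment
#' columns.
#'
#' @param gene_seqs named character vector of reference gene sequences.
#' @param genome named character vector of genome/contig sequences.
#' @param engine alignment backend; defaults to [builtin_engine()].
#' @return data.frame of alignment hits (see [builtin_engine()]).
#' @export
search_homologues <- function(gene_seqs, genome, engine = NULL) {
  if (length(gene_seqs) == 0L) stop("empty gene set")
  empty <- !nzchar(genome)
  if (any(empty)) {
    warning("skipping zero-length genome record(s): ",
            paste(names(genome)[empty], collapse = ", "))
    genome <- genome[!empty]
  }
  engine <- engine %||% builtin_engine()
  engine(as.list(gene_seqs), as.list(genome))
}

# Global alignment of a target against a gene, trying both target
# orientations; returns the better one together with the orientation used.
align_global_oriented <- function(target_seq, gene_seq) {
  submat <- global_sub_matrix()
  a_fwd <- Biostrings::pairwiseAlignment(
    target_seq, gene_seq, type = "global", substitutionMatrix = submat,
    gapOpening = 4, gapExtension = 1)
  a_rev <- Biostrings::pairwiseAlignment(
    reverse_complement(target_seq), gene_seq, type = "global",
    substitutionMatrix = submat, gapOpening = 4, gapExtension = 1)
  if (Biostrings::score(a_fwd) >= Biostrings::score(a_rev))
    list(aln = a_fwd, orientation = "+")
  else list(aln = a_rev, orientation = "-")
}

# Project intervals given on the alignment SUBJECT (gene-local, 0-based
# half-open) onto the alignment PATTERN (target).  Returns a data.frame of
# 0-based half-open target intervals in the orientation the pattern was
# aligned in; `orientation == "-"` intervals are flipped back to forward
# target coordinates by the caller via flip_interval().
project_intervals <- function(aln, intervals) {
  if (nrow(intervals) == 0L) return(intervals)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ppos <- cumsum(p != "-")      # pattern bases consumed after each column
  spos <- cumsum(s != "-")
  both <- p != "-" & s != "-"
  out <- lapply(seq_len(nrow(intervals)), function(i) {
    a <- intervals$start[i]; b <- intervals$end[i]
    cols <- which(both & spos >= a + 1L & spos <= b)
    if (!length(cols)) return(NULL)
    c(min(ppos[cols]) - 1L, max(ppos[cols]))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1L], end = m[, 2L])
}

flip_interval <- function(start, end, len) {
  data.frame(start = len - end, end = len - start)
}
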