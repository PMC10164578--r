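# Coordinate convention: all internal coordinates are 0-based half-open
# [start, end) on a named sequence, with strand one of "+", "-", ".".
# GFF3 (1-based, closed) is converted at the file boundary and nowhere else.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a table of strand-aware genomic ranges
#'
#' Ranges are 0-based half-open intervals on named sequences; the universal
#' coordinate currency of the package.
#'
#' @param seqid character, sequence name(s).
#' @param start,end integer 0-based half-open bounds, `0 <= start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` (recycled).
#' @return data.frame with columns `seqid`, `start`, `end`, `strand`.
#' @export
genomic_ranges <- function(seqid = character(), start = integer(),
                           end = integer(), strand = "+") {
  n <- max(length(seqid), length(start), length(end))
  df <- data.frame(
    seqid = as.character(rep_len(seqid, n)),
    start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(end, n)),
    strand = as.character(rep_len(strand, n)),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(df)
  if (!all(df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  if (anyNA(df$start) || anyNA(df$end) || any(df$start < 0L) ||
      any(df$end <= df$start))
    stop("ranges must satisfy 0 <= start < end")
  df
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of IUPAC DNA strings.
#' @return character vector of the same length.
#' @export
reverse_complement <- function(x) {
  if (length(x) == 0L) return(character())
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

#' Extract oriented subsequences at genomic ranges
#'
#' Slices `seqs[seqid]` at `[start, end)` and reverse-complements the slice
#' when `strand == "-"`, so the result always reads 5' to 3' on the strand
#' of the range.
#'
#' @param seqs named character vector of sequences.
#' @param ranges data.frame as from [genomic_ranges()].
#' @return character vector, one oriented subsequence per range.
#' @export
slice_sequence <- function(seqs, ranges) {
  if (nrow(ranges) == 0L) return(character())
  missing <- setdiff(unique(ranges$seqid), names(seqs))
  if (length(missing))
    stop("unknown seqid: ", paste(missing, collapse = ", "))
  lens <- nchar(seqs)[ranges$seqid]
  if (any(ranges$end > lens))
    stop("range out of bounds on ", ranges$seqid[which(ranges$end > lens)[1L]])
  out <- substr(seqs[ranges$seqid], ranges$start + 1L, ranges$end)
  neg <- ranges$strand == "-"
  if (any(neg)) out[neg] <- reverse_complement(out[neg])
  unname(out)
}

# Merge ranges on the same seqid (and strand, unless by_strand = FALSE)
# whose gap is <= gap.  Returns sorted, pairwise-disjoint ranges with a
# list-column `members` of contributing row indices.
range_reduce <- function(ranges, gap = 0L, by_strand = TRUE) {
  if (nrow(ranges) == 0L) {
    ranges$members <- list()
    return(ranges)
  }
  key <- if (by_strand) paste(ranges$seqid, ranges$strand) else ranges$seqid
  pieces <- lapply(split(seq_len(nrow(ranges)), key), function(idx) {
    sub <- ranges[idx, , drop = FALSE]
    o <- order(sub$start, sub$end)
    sub <- sub[o, , drop = FALSE]
    idx <- idx[o]
    starts <- ends <- integer(0)
    members <- list()
    cs <- sub$start[1L]; ce <- sub$end[1L]; mem <- idx[1L]
    for (i in seq_len(nrow(sub))[-1L]) {
      if (sub$start[i] - ce <= gap) {
        ce <- max(ce, sub$end[i]); mem <- c(mem, idx[i])
      } else {
        starts <- c(starts, cs); ends <- c(ends, ce)
        members <- c(members, list(mem))
        cs <- sub$start[i]; ce <- sub$end[i]; mem <- idx[i]
      }
    }
    starts <- c(starts, cs); ends <- c(ends, ce)
    members <- c(members, list(mem))
    out <- data.frame(
      seqid = sub$seqid[1L], start = as.integer(starts),
      end = as.integer(ends),
      strand = if (by_strand) sub$strand[1L] else ".",
      stringsAsFactors = FALSE
    )
    out$members <- members
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- out[order(out$seqid, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Strand-agnostic: TRUE for each query row that overlaps any subject row
# on the same seqid.
ranges_overlap_any <- function(query, subject) {
  if (nrow(query) == 0L) return(logical(0))
  if (is.null(subject) || nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  vapply(seq_len(nrow(query)), function(i) {
    s <- subject[subject$seqid == query$seqid[i], , drop = FALSE]
    any(s$start < query$end[i] & s$end > query$start[i])
  }, logical(1))
}

# Width of pairwise intersection of [a1,a2) with each [b1,b2).
overlap_width <- function(a1, a2, b1, b2) {
  pmax(0L, pmin(a2, b2) - pmax(a1, b1))
}

validate_dna <- function(x, allow_ambiguous = TRUE) {
  allowed <- if (allow_ambiguous) names(IUPAC_CODES) else c("A", "C", "G", "T")
  chars <- unique(strsplit(paste(x, collapse = ""), "")[[1]])
  setdiff(chars, allowed)
}
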