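# PAM mini-language and spacer-site enumeration.  A PAM pattern is a
# string of IUPAC codes plus '.' (any base) and at most one parenthesized
# alternation, e.g. "NGG", "TTTV", ".(NG|NNG|GAA|GAT)".  '.' is read as N.
# Orientation is 3' (PAM downstream of the spacer) unless a preset or the
# caller says otherwise.  Matching is strict on the subject side: target
# bases outside A/C/G/T never match.

PAM_PRESETS <- list(
  cas9 = list(pattern = "NGG", orientation = "three_prime",
              spacer_length = 20L),
  cas12a = list(pattern = "TTTV", orientation = "five_prime",
                spacer_length = 23L)
)

#' Compile a PAM specification
#'
#' Accepts a preset name (`"cas9"`: 3' NGG, 20-nt spacer; `"cas12a"`:
#' 5' TTTV, 23-nt spacer), a raw pattern over IUPAC codes and `.` with an
#' optional single alternation group `(A|B|...)`, or `""`/`"none"` for
#' PAM-less enumeration.
#'
#' @param raw pattern or preset name.
#' @param orientation `"three_prime"` or `"five_prime"`; default is the
#'   preset's orientation, or 3' for raw patterns.
#' @param gap bases between spacer and PAM (default 0, adjacency).
#' @return object of class `pam_spec` with fields `raw`, `orientation`,
#'   `gap`, `branches` (expanded IUPAC alternatives), `pamless`, and
#'   `spacer_length` (presets only, else `NA`).
#' @export
parse_pam <- function(raw = "cas9", orientation = NULL, gap = 0L) {
  gap <- as.integer(gap)
  if (is.na(gap) || gap < 0L) stop("gap must be a non-negative integer")
  spacer_length <- NA_integer_
  if (!is.null(raw) && tolower(raw) %in% names(PAM_PRESETS)) {
    preset <- PAM_PRESETS[[tolower(raw)]]
    raw <- preset$pattern
    orientation <- orientation %||% preset$orientation
    spacer_length <- preset$spacer_length
  }
  orientation <- orientation %||% "three_prime"
  if (!orientation %in% c("three_prime", "five_prime"))
    stop("orientation must be 'three_prime' or 'five_prime'")
  if (is.null(raw) || !nzchar(raw) || tolower(raw) == "none") {
    return(structure(list(raw = "", orientation = orientation, gap = gap,
                          branches = character(0), pamless = TRUE,
                          spacer_length = spacer_length),
                     class = "pam_spec"))
  }
  chars <- strsplit(raw, "")[[1]]
  ok <- chars %in% c(names(IUPAC_CODES), tolower(names(IUPAC_CODES)),
                     ".", "(", ")", "|")
  if (!all(ok))
    stop("illegal PAM character '", chars[!ok][1L], "' at position ",
         which(!ok)[1L])
  opens <- which(chars == "(")
  closes <- which(chars == ")")
  if (length(opens) != length(closes) || length(opens) > 1L)
    stop("PAM pattern allows at most one balanced alternation group: ", raw)
  if (length(opens) == 1L && closes < opens)
    stop("unbalanced parentheses in PAM pattern at position ", closes)
  if (length(opens) == 0L && any(chars == "|"))
    stop("'|' outside an alternation group in PAM pattern: ", raw)
  if (length(opens) == 1L) {
    prefix <- substr(raw, 1L, opens - 1L)
    suffix <- substr(raw, closes + 1L, nchar(raw))
    inner <- substr(raw, opens + 1L, closes - 1L)
    alts <- strsplit(inner, "|", fixed = TRUE)[[1]]
    if (grepl("\\|\\||^\\||\\|$", inner) || length(alts) == 0L ||
        any(!nzchar(alts)))
      stop("empty branch in PAM alternation: ", raw)
    branches <- paste0(prefix, alts, suffix)
  } else {
    branches <- raw
  }
  branches <- toupper(gsub(".", "N", branches, fixed = TRUE))
  structure(list(raw = raw, orientation = orientation, gap = gap,
                 branches = branches, pamless = FALSE,
                 spacer_length = spacer_length),
            class = "pam_spec")
}

#' @export
print.pam_spec <- function(x, ...) {
  if (x$pamless) {
    cat("<pam_spec> PAM-less\n")
  } else {
    cat(sprintf("<pam_spec> %s PAM %s (branches: %s), gap %d\n",
                if (x$orientation == "five_prime") "5'" else "3'",
                x$raw, paste(x$branches, collapse = ", "), x$gap))
  }
  invisible(x)
}

# 0-based start positions where `pattern` (IUPAC) matches `seq` exactly
# (subject bases outside ACGT never match).
match_iupac <- function(seq, pattern) {
  n <- nchar(seq)
  p <- nchar(pattern)
  if (n < p || p == 0L) return(integer(0))
  chars <- strsplit(seq, "")[[1]]
  pat <- strsplit(pattern, "")[[1]]
  ok <- rep(TRUE, n - p + 1L)
  for (k in seq_len(p)) {
    allowed <- strsplit(IUPAC_CODES[[pat[k]]], "")[[1]]
    ok <- ok & (chars[k:(n - p + k)] %in% allowed)
  }
  which(ok) - 1L
}

#' Enumerate spacer sites in one target sequence
#'
#' Scans both strands for positions where a full-length spacer window and
#' an adjacent (after `pam$gap`) PAM window matching any branch both fit
#' inside the target.  PAM-less specs report every full-length window on
#' both strands.
#'
#' @param target_seq target sequence (character scalar).
#' @param pam [parse_pam()] result.
#' @param length spacer length in nt.
#' @return data.frame with 0-based target coordinates: `start`, `end`,
#'   `strand`, `pam_start`, `pam_end` (`NA` for PAM-less).
#' @export
find_spacer_sites <- function(target_seq, pam, length) {
  length <- as.integer(length)
  stopifnot(length >= 1L)
  L <- nchar(target_seq)
  one_strand <- function(seq) {
    if (pam$pamless) {
      if (L < length)
        return(data.frame(start = integer(), pam_start = integer(),
                          pam_end = integer()))
      return(data.frame(start = 0:(L - length), pam_start = NA_integer_,
                        pam_end = NA_integer_))
    }
    rows <- list()
    for (br in pam$branches) {
      p <- nchar(br)
      q <- match_iupac(seq, br)
      if (pam$orientation == "three_prime") {
        s <- q - pam$gap - length          # spacer start
        valid <- s >= 0L
      } else {
        s <- q + p + pam$gap
        valid <- s + length <= L
      }
      if (any(valid))
        rows[[base::length(rows) + 1L]] <- data.frame(
          start = s[valid], pam_start = q[valid], pam_end = q[valid] + p)
    }
    if (!base::length(rows))
      return(data.frame(start = integer(), pam_start = integer(),
                        pam_end = integer()))
    out <- do.call(rbind, rows)
    out[!duplicated(out), , drop = FALSE]
  }
  fwd <- one_strand(target_seq)
  if (nrow(fwd)) fwd$strand <- "+"
  rev <- one_strand(reverse_complement(target_seq))
  if (nrow(rev)) {
    # map reverse-complement coordinates back to forward
    new_start <- L - (rev$start + length)
    rev <- data.frame(start = new_start,
                      pam_start = ifelse(is.na(rev$pam_start), NA_integer_,
                                         L - rev$pam_end),
                      pam_end = ifelse(is.na(rev$pam_end), NA_integer_,
                                       L - rev$pam_start),
                      strand = "-")
  }
  out <- rbind(
    if (nrow(fwd)) fwd[, c("start", "strand", "pam_start", "pam_end")],
    if (nrow(rev)) rev[, c("start", "strand", "pam_start", "pam_end")]
  )
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), pam_start = integer(),
                      pam_end = integer(), stringsAsFactors = FALSE))
  out$end <- out$start + length
  out <- out[order(out$start, out$strand, out$pam_start,
                   na.last = TRUE), c("start", "end", "strand",
                                      "pam_start", "pam_end")]
  rownames(out) <- NULL
  out
}

#' Enumerate candidate gRNA across targets
#'
#' Pools spacer sites across all targets, deduplicates by spacer sequence,
#' and drops spacers containing non-ACGT codes (ambiguity codes cannot be
#' synthesized).  gRNA ids are assigned as the zero-padded rank of first
#' discovery in sorted target order, making outputs reproducible.
#'
#' @param targets named character vector of target sequences.
#' @param pam [parse_pam()] result (or a string/preset accepted by it).
#' @param length spacer length in nt; defaults to the preset's length.
#' @return object of class `grna_set`: list with `spacers` (named id ->
#'   sequence) and `hits` (data.frame: `grna_id`, `target_id`, `start`,
#'   `end`, `strand`, `pam_start`, `pam_end`).
#' @export
enumerate_grna <- function(targets, pam = "cas9", length = NULL) {
  if (length(targets) == 0L) stop("no target sequences supplied")
  if (!inherits(pam, "pam_spec")) pam <- parse_pam(pam)
  length <- as.integer(length %||% pam$spacer_length)
  if (is.na(length))
    stop("spacer length must be given for non-preset PAM specs")
  spacer_ids <- character(0)      # spacer sequence -> id
  hits <- list()
  for (tid in sort(names(targets))) {
    sites <- find_spacer_sites(targets[[tid]], pam, length)
    if (nrow(sites) == 0L) next
    spacers <- slice_sequence(setNames(targets[tid], tid),
                              genomic_ranges(tid, sites$start, sites$end,
                                             sites$strand))
    ok <- !grepl("[^ACGT]", spacers)
    sites <- sites[ok, , drop = FALSE]
    spacers <- spacers[ok]
    if (!nrow(sites)) next
    new <- setdiff(unique(spacers), names(spacer_ids))
    if (length(new) > 0L) {
      ids <- sprintf("gRNA_%04d", length(spacer_ids) + seq_along(new))
      spacer_ids <- c(spacer_ids, setNames(ids, new))
    }
    sites$grna_id <- unname(spacer_ids[spacers])
    sites$target_id <- tid
    hits[[length(hits) + 1L]] <- sites
  }
  hit_df <- if (length(hits)) do.call(rbind, hits) else
    data.frame(grna_id = character(), target_id = character(),
               start = integer(), end = integer(), strand = character(),
               pam_start = integer(), pam_end = integer(),
               stringsAsFactors = FALSE)
  hit_df <- hit_df[, c("grna_id", "target_id", "start", "end", "strand",
                       "pam_start", "pam_end")]
  rownames(hit_df) <- NULL
  spacers <- if (length(spacer_ids))
    setNames(names(spacer_ids), unname(spacer_ids)) else
      setNames(character(0), character(0))
  spacers <- spacers[order(names(spacers))]
  structure(list(spacers = spacers, hits = hit_df, pam = pam,
                 spacer_length = length),
            class = "grna_set")
}

#' @export
print.grna_set <- function(x, ...) {
  cat(sprintf("<grna_set> %d unique spacer(s), %d hit(s) on %d target(s)\n",
              length(x$spacers), nrow(x$hits),
              length(unique(x$hits$target_id))))
  invisible(x)
}
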