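# Step 3: candidate gRNA filters.  GC content, off-target screening with
# PAM-relative positional threshold clauses, and within-feature filtering
# by alignment lift-over.  Verdicts are tracked per gRNA-target pair in
# the re-entrant mapping table.

#' GC fraction of a spacer
#'
#' @param spacer character vector of spacers over A/C/G/T.
#' @return numeric vector in `[0, 1]`: (#G + #C) / length.
#' @export
gc_fraction <- function(spacer) {
  if (any(!nzchar(spacer))) stop("empty spacer")
  bad <- grepl("[^ACGT]", spacer)
  if (any(bad)) stop("spacer contains non-ACGT character: ", spacer[bad][1L])
  (nchar(gsub("[AT]", "", spacer))) / nchar(spacer)
}

#' Parse an off-target threshold pattern
#'
#' Comma-separated clauses `<count><types>-<p>[-[<q>]]` with types a
#' subset of `m` (mismatch) and `g` (gap).  Positions are PAM-relative and
#' negative: -1 is the PAM-proximal spacer base.  `0mg-10` bounds
#' positions -1..-10; `1mg-11-` bounds -11 to the 5' end (open);
#' `2m-5-8` bounds -5..-8.  The empty pattern is the default
#' whole-spacer clause `(0, mg, -1..5' end)`: only gRNA with a perfect
#' full-length alignment elsewhere are excluded.
#'
#' @param raw pattern string (may be `""`).
#' @return object of class `ot_pattern`: data.frame of clauses with
#'   columns `max_count`, `types`, `from_pos`, `to_pos` (`NA` = open to
#'   the 5' end).
#' @export
parse_ot_pattern <- function(raw = "") {
  if (is.null(raw) || !nzchar(raw)) {
    cl <- data.frame(max_count = 0L, types = "mg", from_pos = -1L,
                     to_pos = NA_integer_, stringsAsFactors = FALSE)
    return(structure(cl, class = c("ot_pattern", "data.frame")))
  }
  clauses <- strsplit(raw, ",", fixed = TRUE)[[1]]
  rows <- lapply(clauses, function(cl) {
    m <- regmatches(cl, regexec("^([0-9]+)([mg]+)-([0-9]+)(-([0-9]+)?)?$",
                                cl))[[1]]
    if (length(m) == 0L)
      stop("cannot parse off-target clause '", cl, "'")
    types <- paste(sort(unique(strsplit(m[3L], "")[[1]])), collapse = "")
    p <- as.integer(m[4L])
    if (p == 0L) stop("off-target clause positions must be >= 1: ", cl)
    if (!nzchar(m[5L])) {            # "<count><types>-<p>": -1..-p
      from <- -1L; to <- -p
    } else if (!nzchar(m[6L])) {     # trailing dash: -p..5' end
      from <- -p; to <- NA_integer_
    } else {                         # "<p>-<q>": -p..-q
      q <- as.integer(m[6L])
      if (q == 0L) stop("off-target clause positions must be >= 1: ", cl)
      from <- -min(p, q); to <- -max(p, q)
    }
    data.frame(max_count = as.integer(m[2L]), types = types,
               from_pos = from, to_pos = to, stringsAsFactors = FALSE)
  })
  cl <- do.call(rbind, rows)
  structure(cl, class = c("ot_pattern", "data.frame"))
}

#' Scan backgrounds for off-target occurrences of spacers
#'
#' Finds every alignment of each spacer (both strands) within edit
#' distance `max_edits` in the background sequences, excluding alignments
#' that overlap a masked range (target regions and `--mask-gene` genes).
#' A PAM next to the hit is not required: the presence of the sequence
#' alone counts.
#'
#' @param spacers named character vector (gRNA id -> spacer).
#' @param backgrounds named character vector of background sequences.
#' @param masked_ranges data.frame with `seqid`, `start`, `end`; masking
#'   is strand-agnostic.
#' @param max_edits maximum total edits (mismatches + gaps) searched.
#' @return data.frame with one row per hit: `grna_id`, `seqid`, `start`,
#'   `end`, `strand`, `edits`, `n_mismatch`, `n_gap`, `n_unaligned`,
#'   `n_ins`, plus list-columns `events` (per spacer position 5'->3':
#'   0 match, 1 mismatch, 2 gap/unaligned) and `ins` (background
#'   insertions attributed to the following spacer position).
#' @export
find_offtarget_hits <- function(spacers, backgrounds, masked_ranges = NULL,
                                max_edits = 1L) {
  max_edits <- as.integer(max_edits)
  ids <- names(spacers)
  rows <- list()
  for (sid in names(backgrounds)) {
    bg <- backgrounds[[sid]]
    L <- nchar(bg)
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") bg else reverse_complement(bg)
      hits <- ot_scan_multi_cpp(unname(as.character(spacers)), subj,
                                max_edits)
      for (h in hits) {
        start <- h$start; end <- h$end
        if (strand == "-") { tmp <- L - end; end <- L - start; start <- tmp }
        rows[[length(rows) + 1L]] <- list(
          grna_id = ids[h$spacer_index], seqid = sid, start = start,
          end = end, strand = strand, edits = h$edits,
          n_mismatch = h$n_mismatch, n_gap = h$n_gap,
          n_unaligned = h$n_unaligned, n_ins = h$n_ins,
          events = h$events, ins = h$ins)
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(grna_id = character(), seqid = character(),
                      start = integer(), end = integer(),
                      strand = character(), edits = integer(),
                      n_mismatch = integer(), n_gap = integer(),
                      n_unaligned = integer(), n_ins = integer(),
                      stringsAsFactors = FALSE)
    out$events <- list(); out$ins <- list()
    return(out)
  }
  out <- data.frame(
    grna_id = vapply(rows, `[[`, character(1), "grna_id"),
    seqid = vapply(rows, `[[`, character(1), "seqid"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    edits = vapply(rows, `[[`, integer(1), "edits"),
    n_mismatch = vapply(rows, `[[`, integer(1), "n_mismatch"),
    n_gap = vapply(rows, `[[`, integer(1), "n_gap"),
    n_unaligned = vapply(rows, `[[`, integer(1), "n_unaligned"),
    n_ins = vapply(rows, `[[`, integer(1), "n_ins"),
    stringsAsFactors = FALSE)
  out$events <- lapply(rows, `[[`, "events")
  out$ins <- lapply(rows, `[[`, "ins")
  if (!is.null(masked_ranges) && nrow(masked_ranges) > 0L) {
    out <- out[!ranges_overlap_any(out, masked_ranges), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# PAM-relative position of each spacer index (1..m, 5'->3').  -1 is the
# PAM-proximal base: the last spacer base for 3' PAMs, the first for 5'.
pam_relative_positions <- function(m, orientation = "three_prime") {
  if (orientation == "five_prime") -(1:m) else (1:m) - m - 1L
}

# Does one hit satisfy every clause (making it a dangerous off-target)?
hit_is_dangerous <- function(events, ins, pattern, orientation) {
  m <- length(events)
  relpos <- pam_relative_positions(m, orientation)
  for (ci in seq_len(nrow(pattern))) {
    from <- pattern$from_pos[ci]
    to <- if (is.na(pattern$to_pos[ci])) -m else pattern$to_pos[ci]
    inwin <- relpos <= from & relpos >= to
    types <- strsplit(pattern$types[ci], "")[[1]]
    count <- 0L
    if ("m" %in% types) count <- count + sum(events[inwin] == 1L)
    if ("g" %in% types)
      count <- count + sum(events[inwin] == 2L) + sum(ins[inwin])
    if (count > pattern$max_count[ci]) return(FALSE)
  }
  TRUE
}

#' Off-target verdict for one gRNA
#'
#' Fails if and only if at least one hit satisfies every clause of the
#' threshold pattern (i.e. looks close enough to the spacer, position by
#' position, to be cut).  With the default pattern only a perfect
#' full-length match elsewhere fails a gRNA.
#'
#' @param hits data.frame from [find_offtarget_hits()] (rows for one
#'   gRNA).
#' @param pattern [parse_ot_pattern()] result.
#' @param orientation PAM orientation used to anchor positions.
#' @return `"pass"` or `"fail"`.
#' @export
offtarget_verdict <- function(hits, pattern = parse_ot_pattern(),
                              orientation = "three_prime") {
  if (nrow(hits) == 0L) return("pass")
  for (i in seq_len(nrow(hits))) {
    if (hit_is_dangerous(hits$events[[i]], hits$ins[[i]], pattern,
                         orientation))
      return("fail")
  }
  "pass"
}

#' Infer feature ranges on a target by alignment lift-over
#'
#' Globally aligns the target to each reference gene (both orientations,
#' better score wins) and projects the gene's annotated feature intervals
#' through the alignment columns onto target coordinates; the union over
#' reference genes is returned.
#'
#' @param target_seq target sequence.
#' @param gene_seqs named character vector of reference gene sequences.
#' @param annotation named list of [gene_model()] objects (same ids).
#' @param feature feature type to project (e.g. `"CDS"`,
#'   `"five_prime_UTR"`).
#' @return data.frame of 0-based half-open target intervals (`start`,
#'   `end`); empty if the target aligns to no reference gene feature.
#' @export
infer_feature_ranges <- function(target_seq, gene_seqs, annotation,
                                 feature = "CDS") {
  pieces <- list()
  for (gid in names(gene_seqs)) {
    model <- annotation[[gid]]
    if (is.null(model)) next
    local <- gene_local_feature_ranges(model, feature)
    if (nrow(local) == 0L) next
    ori <- align_global_oriented(target_seq, gene_seqs[[gid]])
    proj <- project_intervals(ori$aln, local)
    if (nrow(proj) == 0L) next
    if (ori$orientation == "-")
      proj <- flip_interval(proj$start, proj$end, nchar(target_seq))
    pieces[[length(pieces) + 1L]] <- proj
  }
  if (!length(pieces)) return(data.frame(start = integer(), end = integer()))
  all <- do.call(rbind, pieces)
  red <- range_reduce(genomic_ranges("t", all$start, all$end, "+"))
  red[, c("start", "end")]
}

#' Filter parameters for [apply_filters()]
#'
#' @param gc_min,gc_max inclusive GC-fraction bounds (defaults 0.3, 0.7).
#' @param ot_pattern off-target threshold pattern (string or
#'   [parse_ot_pattern()] result).
#' @param backgrounds named character vector of background sequences to
#'   screen (`NULL` disables the background check).
#' @param masked_ranges data.frame of ranges hidden from the off-target
#'   scan (target regions are always added automatically when target
#'   provenance is available).
#' @param max_edits off-target search radius; default is the largest
#'   clause count plus one.
#' @param gene_seqs,annotation reference genes and models for the feature
#'   filter (`NULL` disables it).
#' @param feature feature type for the within-feature filter.
#' @return list of class `filter_params`.
#' @export
filter_params <- function(gc_min = 0.3, gc_max = 0.7, ot_pattern = "",
                          backgrounds = NULL, masked_ranges = NULL,
                          max_edits = NULL, gene_seqs = NULL,
                          annotation = NULL, feature = "CDS") {
  if (!inherits(ot_pattern, "ot_pattern"))
    ot_pattern <- parse_ot_pattern(ot_pattern)
  max_edits <- as.integer(max_edits %||% (max(ot_pattern$max_count) + 1L))
  structure(list(gc_min = gc_min, gc_max = gc_max, ot_pattern = ot_pattern,
                 backgrounds = backgrounds, masked_ranges = masked_ranges,
                 max_edits = max_edits, gene_seqs = gene_seqs,
                 annotation = annotation, feature = feature),
            class = "filter_params")
}

#' Apply GC, off-target and feature filters to candidate gRNA
#'
#' Produces the gRNA-target mapping table: one row per (gRNA, target hit)
#' with pass/fail/NA verdicts per check.  GC and background verdicts are
#' per gRNA (identical across its targets); the feature verdict is per
#' hit.  Checks without the data they need (no backgrounds, no
#' annotation) record `NA`, which downstream coverage treats as a pass.
#'
#' @param cands `grna_set` from [enumerate_grna()].
#' @param targets named character vector of target sequences (with the
#'   provenance attribute from discovery, if available).
#' @param params [filter_params()].
#' @return object of class `grna_mapping` (see [write_mapping()]).
#' @export
apply_filters <- function(cands, targets, params = filter_params()) {
  spacers <- cands$spacers
  hits <- cands$hits
  gc <- gc_fraction(unname(spacers))
  gc_ok <- ifelse(gc >= params$gc_min & gc <= params$gc_max, "pass", "fail")
  names(gc_ok) <- names(spacers)

  bg_verdict <- setNames(rep(NA_character_, length(spacers)), names(spacers))
  if (!is.null(params$backgrounds)) {
    masked <- params$masked_ranges
    prov <- attr(targets, "ranges")
    if (!is.null(prov))
      masked <- rbind(masked, prov[, c("seqid", "start", "end")],
                      make.row.names = FALSE)
    # targets occurring verbatim in a background are also masked, so the
    # user-supplied-targets path behaves like the discovery path
    masked <- rbind(masked, exact_target_masks(targets, params$backgrounds),
                    make.row.names = FALSE)
    ot <- find_offtarget_hits(spacers, params$backgrounds, masked,
                              params$max_edits)
    orientation <- if (!is.null(cands$pam)) cands$pam$orientation else
      "three_prime"
    for (gid in names(spacers)) {
      sub <- ot[ot$grna_id == gid, , drop = FALSE]
      bg_verdict[gid] <- offtarget_verdict(sub, params$ot_pattern,
                                           orientation)
    }
  }

  feat_verdict <- rep(NA_character_, nrow(hits))
  if (!is.null(params$annotation) && !is.null(params$gene_seqs)) {
    feat_by_target <- lapply(
      setNames(names(targets), names(targets)),
      function(tid) infer_feature_ranges(targets[[tid]], params$gene_seqs,
                                         params$annotation, params$feature))
    for (i in seq_len(nrow(hits))) {
      fr <- feat_by_target[[hits$target_id[i]]]
      inside <- nrow(fr) > 0L &&
        any(fr$start <= hits$start[i] & fr$end >= hits$end[i])
      feat_verdict[i] <- if (inside) "pass" else "fail"
    }
  }

  tab <- data.frame(
    grna_id = hits$grna_id,
    grna_seq = unname(spacers[hits$grna_id]),
    target_id = hits$target_id,
    start = hits$start, end = hits$end, strand = hits$strand,
    pam_site = ifelse(is.na(hits$pam_start), ".",
                      paste0(hits$pam_start, "-", hits$pam_end)),
    stringsAsFactors = FALSE)
  tab[["check:GC"]] <- unname(gc_ok[hits$grna_id])
  tab[["check:background"]] <- unname(bg_verdict[hits$grna_id])
  tab[["check:feature"]] <- feat_verdict
  tab <- tab[order(tab$grna_id, tab$target_id, tab$start, tab$strand), ,
             drop = FALSE]
  rownames(tab) <- NULL
  as_grna_mapping(tab)
}

# Exact (forward or reverse-complement) occurrences of each target
# sequence in the backgrounds, as maskable ranges.
exact_target_masks <- function(targets, backgrounds) {
  rows <- list()
  for (tseq in unique(as.character(targets))) {
    for (pat in unique(c(tseq, reverse_complement(tseq)))) {
      for (sid in names(backgrounds)) {
        mt <- Biostrings::matchPattern(pat, Biostrings::DNAString(
          backgrounds[[sid]]), fixed = TRUE)
        if (length(mt))
          rows[[length(rows) + 1L]] <- data.frame(
            seqid = sid, start = BiocGenerics::start(mt) - 1L,
            end = BiocGenerics::end(mt), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(seqid = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

MAPPING_FIXED_COLUMNS <- c("grna_id", "grna_seq", "target_id", "start",
                           "end", "strand", "pam_site")

as_grna_mapping <- function(df) {
  missing <- setdiff(MAPPING_FIXED_COLUMNS, names(df))
  if (length(missing))
    stop("mapping table lacks column(s): ", paste(missing, collapse = ", "))
  checks <- grep("^check:", names(df), value = TRUE)
  for (cc in checks) {
    bad <- which(!(df[[cc]] %in% c("pass", "fail", "NA", NA)))
    if (length(bad))
      stop("mapping column ", cc, " has value '", df[[cc]][bad[1L]],
           "' at row ", bad[1L], " (allowed: pass/fail/NA)")
  }
  key <- paste(df$grna_id, df$target_id, df$start, df$strand)
  if (anyDuplicated(key))
    stop("duplicate (grna_id, target_id, start, strand) row in mapping")
  structure(df, class = c("grna_mapping", "data.frame"))
}

#' @export
print.grna_mapping <- function(x, ...) {
  checks <- grep("^check:", names(x), value = TRUE)
  cat(sprintf("<grna_mapping> %d row(s), %d gRNA x %d target(s); checks: %s\n",
              nrow(x), length(unique(x$grna_id)),
              length(unique(x$target_id)),
              paste(sub("^check:", "", checks), collapse = ", ")))
  invisible(x)
}

#' Write / read the gRNA-target mapping table
#'
#' Tab-separated with a fixed header (`grna_id`, `grna_seq`, `target_id`,
#' `start`, `end`, `strand`, `pam_site`, then `check:` columns, then any
#' user-appended columns).  Writing then reading reproduces the file
#' byte-identically, which is what makes the pipeline re-entrant: external
#' tools may drop rows or append their own pass/fail columns and feed the
#' file back into [run_minimumset()].
#'
#' @param mapping `grna_mapping` object.
#' @param path file path.
#' @return `read_mapping()` returns a `grna_mapping`.
#' @export
write_mapping <- function(mapping, path) {
  df <- as.data.frame(mapping)
  for (nm in names(df)) df[[nm]] <- as.character(df[[nm]])
  df[is.na(df)] <- "NA"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  df <- read.delim(path, sep = "\t", colClasses = "character",
                   check.names = FALSE, stringsAsFactors = FALSE)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  as_grna_mapping(df)
}
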