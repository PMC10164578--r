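# Step 1: homologue discovery.  Alignment hits against each non-reference
# genome are merged into candidate regions, filtered by identity/length,
# optionally checked reciprocally against the reference, and excised as
# oriented target sequences.

#' Parameters controlling homologue discovery
#'
#' @param merge_within maximum gap (bp) between hits merged into one
#'   candidate region.
#' @param minlen minimum merged-region length (bp).
#' @param minid minimum percent identity (0-100).  Applied to individual
#'   hits before merging when `check_id_before_merge` is `TRUE`, otherwise
#'   to the length-weighted mean identity of each merged region.
#' @param mincdslen minimum total length (bp) of the target sub-regions
#'   that align to reference CDS (0 disables the check).
#' @param check_recip require each candidate target to align back to the
#'   reference best within one of the target genes.
#' @param check_id_before_merge see `minid`.
#' @param domain_ranges optional named list: per reference gene, a
#'   data.frame with `start`/`end` giving the domain interval in
#'   gene-local coordinates; targets are trimmed to the aligned domain.
#' @return list of class `homology_params`.
#' @export
homology_params <- function(merge_within = 100L, minlen = 0L, minid = 95,
                            mincdslen = 0L, check_recip = FALSE,
                            check_id_before_merge = FALSE,
                            domain_ranges = NULL) {
  stopifnot(merge_within >= 0L, minlen >= 0L, minid >= 0, minid <= 100,
            mincdslen >= 0L)
  structure(list(merge_within = as.integer(merge_within),
                 minlen = as.integer(minlen), minid = minid,
                 mincdslen = as.integer(mincdslen),
                 check_recip = isTRUE(check_recip),
                 check_id_before_merge = isTRUE(check_id_before_merge),
                 domain_ranges = domain_ranges),
            class = "homology_params")
}

#' Merge alignment hits into candidate homologue regions
#'
#' Hits on the same seqid and strand whose gap is at most
#' `params$merge_within` are unioned.  Identity filtering happens before
#' merging (`check_id_before_merge = TRUE`) or on the length-weighted mean
#' identity of merged regions; merged regions shorter than `params$minlen`
#' are dropped.  Hits on opposite strands are never merged.
#'
#' @param hits data.frame from [search_homologues()].
#' @param params [homology_params()].
#' @return data.frame of disjoint, sorted ranges with columns `seqid`,
#'   `start`, `end`, `strand`, `genes` (comma-joined contributing query
#'   ids) and `pct_identity` (length-weighted mean).
#' @export
merge_hits <- function(hits, params = homology_params()) {
  empty <- data.frame(seqid = character(), start = integer(),
                      end = integer(), strand = character(),
                      genes = character(), pct_identity = double(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  if (params$check_id_before_merge)
    hits <- hits[hits$pct_identity >= params$minid, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  merged <- range_reduce(hits[, c("seqid", "start", "end", "strand")],
                         gap = params$merge_within, by_strand = TRUE)
  merged$genes <- vapply(merged$members, function(idx)
    paste(sort(unique(hits$query_id[idx])), collapse = ","), character(1))
  # region identity: length-weighted mean identity of the PRINCIPAL
  # supporting gene (the query with the greatest aligned length in the
  # region).  Pooling across genes lets short cross-paralogue fragments
  # dilute a true homologue; taking the max over genes lets a tiny
  # perfect fragment rescue a diverged pseudo-copy.  Judging the region
  # by the gene that explains most of it avoids both failure modes.
  merged$pct_identity <- vapply(merged$members, function(idx) {
    per_gene <- lapply(split(idx, hits$query_id[idx]), function(ii) {
      w <- hits$aligned_length[ii]
      c(len = sum(w), id = sum(hits$pct_identity[ii] * w) / sum(w))
    })
    lens <- vapply(per_gene, `[[`, double(1), "len")
    ids <- vapply(per_gene, `[[`, double(1), "id")
    best <- which(lens == max(lens))
    max(ids[best])
  }, double(1))
  merged$members <- NULL
  if (!params$check_id_before_merge)
    merged <- merged[merged$pct_identity >= params$minid, , drop = FALSE]
  merged <- merged[merged$end - merged$start >= params$minlen, , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Reciprocal best-overlap check of a candidate target
#'
#' Aligns the target back to the reference assembly and accepts it only if
#' the best alignment overlaps at least one of the target genes more than
#' any non-target gene.  Ties and unalignable targets fail closed.
#'
#' @param target_seq candidate target sequence.
#' @param reference_assembly named character vector of reference sequences.
#' @param reference_annotation list of [gene_model()] objects.
#' @param target_gene_ids character vector of gene ids being targeted.
#' @param engine alignment backend (default [builtin_engine()]).
#' @return `TRUE` if the target is accepted.
#' @export
reciprocal_check <- function(target_seq, reference_assembly,
                             reference_annotation, target_gene_ids,
                             engine = NULL) {
  hits <- search_homologues(c(recip_query = unname(target_seq)),
                            reference_assembly, engine = engine)
  if (nrow(hits) == 0L) return(FALSE)
  best <- hits[which.max(hits$score), , drop = FALSE]
  ov <- vapply(reference_annotation, function(m) {
    if (m$range$seqid != best$seqid) return(0L)
    overlap_width(best$start, best$end, m$range$start, m$range$end)
  }, integer(1))
  is_target <- names(reference_annotation) %in% target_gene_ids
  ov_target <- if (any(is_target)) max(ov[is_target]) else 0L
  ov_other <- if (any(!is_target)) max(ov[!is_target]) else 0L
  ov_target > 0L && ov_target > ov_other
}

#' Excise oriented target sequences from a genome
#'
#' Target ids are deterministic:
#' `<alias>|<seqid>|<start>-<end>|<strand>`.  Sequences are oriented by
#' strand (reverse-complemented for `-` ranges).
#'
#' @param genome named character vector of sequences.
#' @param ranges data.frame of ranges (see [genomic_ranges()]).
#' @param alias accession/genome alias used in the target ids.
#' @return named character vector of target sequences; range provenance is
#'   kept in the `"ranges"` attribute for off-target masking.
#' @export
excise_targets <- function(genome, ranges, alias = "seq") {
  seqs <- slice_sequence(genome, ranges)
  ids <- sprintf("%s|%s|%d-%d|%s", alias, ranges$seqid, ranges$start,
                 ranges$end, ranges$strand)
  out <- setNames(seqs, ids)
  prov <- ranges[, c("seqid", "start", "end", "strand")]
  prov$alias <- alias
  prov$target_id <- ids
  attr(out, "ranges") <- prov
  out
}

#' Trim targets to the sub-range aligning to a reference protein domain
#'
#' For each target, reference genes carrying a domain interval (gene-local
#' coordinates) are globally aligned to the target (both orientations) and
#' the domain interval is projected through the alignment columns.  The
#' union (hull) over reference genes is kept; targets with no alignment
#' overlap with any domain are dropped.
#'
#' @param targets named character vector from [excise_targets()].
#' @param gene_seqs named character vector of reference gene sequences.
#' @param domain_ranges named list: per gene id, data.frame with
#'   `start`/`end` (0-based half-open, gene-local).
#' @return trimmed targets (named character vector with updated `"ranges"`
#'   attribute).
#' @export
restrict_to_domain <- function(targets, gene_seqs, domain_ranges) {
  prov <- attr(targets, "ranges")
  keep <- logical(length(targets))
  new_seqs <- character(length(targets))
  new_prov <- prov
  for (i in seq_along(targets)) {
    tseq <- targets[[i]]
    lo <- Inf; hi <- -Inf
    for (gid in names(domain_ranges)) {
      if (!gid %in% names(gene_seqs)) next
      ori <- align_global_oriented(tseq, gene_seqs[[gid]])
      dom <- domain_ranges[[gid]]
      proj <- project_intervals(ori$aln, dom)
      if (nrow(proj) == 0L) next
      if (ori$orientation == "-")
        proj <- flip_interval(proj$start, proj$end, nchar(tseq))
      lo <- min(lo, proj$start); hi <- max(hi, proj$end)
    }
    if (!is.finite(lo) || hi <= lo) {
      message("target ", names(targets)[i],
              " dropped: no alignment overlap with domain")
      next
    }
    keep[i] <- TRUE
    new_seqs[i] <- substr(tseq, lo + 1L, hi)
    if (!is.null(prov)) {
      # oriented offsets back to genomic coordinates
      if (prov$strand[i] == "-") {
        new_prov$start[i] <- prov$end[i] - hi
        new_prov$end[i] <- prov$end[i] - lo
      } else {
        new_prov$start[i] <- prov$start[i] + lo
        new_prov$end[i] <- prov$start[i] + hi
      }
    }
  }
  out <- new_seqs[keep]
  names(out) <- NULL
  if (!is.null(prov)) {
    np <- new_prov[keep, , drop = FALSE]
    np$target_id <- sprintf("%s|%s|%d-%d|%s", np$alias, np$seqid, np$start,
                            np$end, np$strand)
    names(out) <- np$target_id
    attr(out, "ranges") <- np
  } else {
    names(out) <- names(targets)[keep]
  }
  out
}

# Total length of target sub-regions aligning to reference CDS, used by
# the mincdslen check.
aligned_cds_length <- function(target_seq, gene_seqs, models) {
  total_ranges <- list()
  for (gid in names(models)) {
    if (!gid %in% names(gene_seqs)) next
    cds <- gene_local_feature_ranges(models[[gid]], "CDS")
    if (nrow(cds) == 0L) next
    ori <- align_global_oriented(target_seq, gene_seqs[[gid]])
    proj <- project_intervals(ori$aln, cds)
    if (nrow(proj) == 0L) next
    if (ori$orientation == "-")
      proj <- flip_interval(proj$start, proj$end, nchar(target_seq))
    total_ranges[[length(total_ranges) + 1L]] <- proj
  }
  if (!length(total_ranges)) return(0L)
  all <- do.call(rbind, total_ranges)
  red <- range_reduce(genomic_ranges("t", all$start, all$end, "+"))
  sum(red$end - red$start)
}

#' Discover homologue targets of reference genes in query genomes
#'
#' Orchestrates step 1 for a set of query genomes: local alignment of each
#' reference gene, hit merging and filtering, optional reciprocal and
#' CDS-length checks, optional domain restriction, and excision of
#' oriented target sequences.
#'
#' @param gene_seqs named character vector of reference gene sequences.
#' @param genomes named list of genomes (each a named character vector),
#'   names are accession aliases.
#' @param params [homology_params()].
#' @param engine alignment backend (default [builtin_engine()]).
#' @param reference_assembly,reference_annotation needed when
#'   `params$check_recip` or `params$mincdslen > 0`.
#' @return named character vector of targets across all genomes, with a
#'   `"ranges"` provenance attribute and a `"report"` attribute (one row
#'   per target: alias, seqid, start, end, strand, genes, identity).
#' @export
discover_targets <- function(gene_seqs, genomes, params = homology_params(),
                             engine = NULL, reference_assembly = NULL,
                             reference_annotation = NULL) {
  all_targets <- character(0)
  all_prov <- list()
  all_report <- list()
  for (alias in names(genomes)) {
    genome <- genomes[[alias]]
    hits <- search_homologues(gene_seqs, genome, engine = engine)
    merged <- merge_hits(hits, params)
    if (nrow(merged) == 0L) next
    targets <- excise_targets(genome, merged, alias = alias)
    keep <- rep(TRUE, length(targets))
    if (params$check_recip) {
      if (is.null(reference_assembly) || is.null(reference_annotation))
        stop("check_recip requires the reference assembly and annotation")
      keep <- keep & vapply(targets, reciprocal_check, logical(1),
                            reference_assembly, reference_annotation,
                            names(gene_seqs), engine)
    }
    if (params$mincdslen > 0L) {
      if (is.null(reference_annotation))
        stop("mincdslen requires the reference annotation")
      keep <- keep & vapply(targets, function(ts)
        aligned_cds_length(ts, gene_seqs,
                           reference_annotation[names(gene_seqs)]) >=
          params$mincdslen, logical(1))
    }
    targets <- targets[keep]
    prov <- attr(excise_targets(genome, merged[keep, , drop = FALSE],
                                alias = alias), "ranges")
    merged <- merged[keep, , drop = FALSE]
    if (!is.null(params$domain_ranges) && length(targets)) {
      attr(targets, "ranges") <- prov
      targets <- restrict_to_domain(targets, gene_seqs,
                                    params$domain_ranges)
      prov <- attr(targets, "ranges")
      merged <- merged[match(prov$target_id,
                             sprintf("%s|%s|%d-%d|%s", prov$alias,
                                     prov$seqid, prov$start, prov$end,
                                     prov$strand)), , drop = FALSE]
    }
    if (!length(targets)) next
    all_prov[[alias]] <- prov
    rep_df <- prov
    rep_df$genes <- merged$genes
    rep_df$identity <- round(merged$pct_identity, 2)
    all_report[[alias]] <- rep_df
    tv <- as.character(targets)
    names(tv) <- names(targets)
    all_targets <- c(all_targets, tv)
  }
  attr(all_targets, "ranges") <- if (length(all_prov))
    do.call(rbind, c(all_prov, list(make.row.names = FALSE))) else NULL
  attr(all_targets, "report") <- if (length(all_report))
    do.call(rbind, c(all_report, list(make.row.names = FALSE))) else NULL
  all_targets
}
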