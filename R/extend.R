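# Temporarily add genes (with inferred exon structure) to a reference
# assembly/annotation, so unannotated cluster sequences can be used as
# reference genes.  Exon boundaries are inferred by aligning each CDS to
# its gene: gene segments skipped by the CDS become introns.

#' Extend a reference with extra genes and inferred annotations
#'
#' Each gene sequence is appended as a new pseudo-chromosome (named by its
#' record id) and a gene model is synthesised from the pairwise alignment
#' of its CDS to the gene: maximal aligned CDS runs become CDS features,
#' gene segments skipped by the CDS become introns.  Single-isoform genes
#' are assumed (one CDS record per gene id).
#'
#' @param assembly named character vector (reference sequences).
#' @param annotation named list of [gene_model()] objects.
#' @param gene_fasta named character vector of gene (genomic) sequences.
#' @param cds_fasta named character vector of spliced CDS sequences; ids
#'   must match `gene_fasta` ids.
#' @return `list(assembly =, annotation =)` with the new genes appended.
#' @export
extend_reference <- function(assembly, annotation, gene_fasta, cds_fasta) {
  gene_fasta <- setNames(toupper(as.character(gene_fasta)),
                         names(gene_fasta))
  cds_fasta <- setNames(toupper(as.character(cds_fasta)), names(cds_fasta))
  missing <- setdiff(names(cds_fasta), names(gene_fasta))
  if (length(missing))
    stop("CDS record '", missing[1L], "' has no matching gene record")
  clash <- intersect(names(gene_fasta), names(assembly))
  if (length(clash))
    stop("gene id '", clash[1L], "' clashes with an assembly sequence name")
  submat <- global_sub_matrix()
  new_models <- list()
  for (gid in names(cds_fasta)) {
    gene <- gene_fasta[[gid]]
    cds <- cds_fasta[[gid]]
    aln <- Biostrings::pairwiseAlignment(
      cds, gene, type = "global-local", substitutionMatrix = submat,
      gapOpening = 10, gapExtension = 0.5)
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    both <- p != "-" & s != "-"
    ident <- 100 * sum(p == s & both) / sum(both)
    if (!is.finite(ident) || ident < 95)
      stop("CDS '", gid, "' does not align to its gene above 95% identity",
           " (", round(ident, 1), "%)")
    offset <- BiocGenerics::start(aln@subject@range) - 1L  # 0-based
    spos <- cumsum(s != "-")                               # subject bases
    cds_col <- p != "-"
    runs <- rle(cds_col)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    feats <- list()
    for (r in which(runs$values)) {
      cols <- starts[r]:ends[r]
      cols <- cols[s[cols] != "-"]
      if (!length(cols)) next
      feats[[length(feats) + 1L]] <- data.frame(
        type = "CDS",
        start = offset + min(spos[cols]) - 1L,
        end = offset + max(spos[cols]),
        stringsAsFactors = FALSE)
    }
    new_models[[gid]] <- gene_model(
      gid, genomic_ranges(gid, 0L, nchar(gene), "+"),
      do.call(rbind, feats))
  }
  # genes without a CDS record are appended with a whole-gene CDS
  for (gid in setdiff(names(gene_fasta), names(cds_fasta))) {
    new_models[[gid]] <- gene_model(
      gid, genomic_ranges(gid, 0L, nchar(gene_fasta[[gid]]), "+"),
      data.frame(type = "CDS", start = 0L, end = nchar(gene_fasta[[gid]]),
                 stringsAsFactors = FALSE))
  }
  list(assembly = c(assembly, gene_fasta),
       annotation = c(annotation, new_models))
}
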