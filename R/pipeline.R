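# Orchestration of the four pipeline steps (seq -> grna -> filter ->
# minimumset) plus the re-entrant file conventions.  Every step can run
# from the previous step's files, so externally edited mapping tables can
# re-enter at the minimumset step.

#' Pipeline run configuration
#'
#' Collects all pipeline parameters.  Sequence inputs may be given either
#' as file paths or as in-memory objects (named character vectors for
#' FASTA, [gene_model()] lists for annotations), which is how the test
#' fixtures drive the pipeline without touching disk.
#'
#' @param out_dir run directory (created if needed).
#' @param genes character vector of target gene ids (discovery path).
#' @param targets_fasta user-supplied target sequences (path or named
#'   vector); mutually exclusive with `genes`.
#' @param indv query accession aliases, `"all"` (every alias in the
#'   genome set) or `"ref"` (design against the reference genes only).
#' @param genome_set alias -> FASTA lookup (path or named vector/list).
#' @param assembly,annotation reference assembly (FASTA) and annotation
#'   (GFF3), as paths or objects.
#' @param extend_gene,extend_cds optional FASTA of genes/CDS to append to
#'   the reference (see [extend_reference()]).
#' @param background extra background sequences for off-target screening.
#' @param screen_ref also screen the reference assembly for off-targets.
#' @param mask_gene gene ids whose reference ranges are hidden from the
#'   off-target filter.
#' @param pam PAM preset or pattern (see [parse_pam()]).
#' @param length spacer length (defaults to the preset's).
#' @param gc_min,gc_max inclusive GC bounds.
#' @param ot_pattern off-target threshold pattern string.
#' @param feature feature type targeted gRNA must fall within.
#' @param merge_within,minlen,minid,mincdslen,check_recip,
#'   check_id_before_merge,domain_ranges homologue-discovery parameters
#'   (see [homology_params()]).
#' @param sets number of mutually exclusive gRNA sets to emit.
#' @param prioritise_nr prioritise non-redundancy over 5'-proximity.
#' @param sc_algorithm `"auto"` (LAR unless `prioritise_nr`), `"lar"` or
#'   `"enumerate"`.
#' @param seed integer seed fixing all randomised tie-breaks.
#' @param threads accepted for interface compatibility; the implementation
#'   is single-threaded and outputs never depend on this value.
#' @param prefix filename prefix for run artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, genes = NULL, targets_fasta = NULL,
                       indv = "all", genome_set = NULL, assembly = NULL,
                       annotation = NULL, extend_gene = NULL,
                       extend_cds = NULL, background = NULL,
                       screen_ref = FALSE, mask_gene = NULL,
                       pam = "cas9", length = NULL, gc_min = 0.3,
                       gc_max = 0.7, ot_pattern = "", feature = "CDS",
                       merge_within = 100L, minlen = 0L, minid = 95,
                       mincdslen = 0L, check_recip = FALSE,
                       check_id_before_merge = FALSE, domain_ranges = NULL,
                       sets = 1L, prioritise_nr = FALSE,
                       sc_algorithm = c("auto", "lar", "enumerate"),
                       seed = 1L, threads = 1L, prefix = "pangrna") {
  sc_algorithm <- match.arg(sc_algorithm)
  if (is.null(targets_fasta) && is.null(genes))
    stop("either `genes` (discovery) or `targets_fasta` must be given")
  if (!is.null(targets_fasta) && !is.null(genes))
    stop("`genes` and `targets_fasta` are mutually exclusive inputs")
  structure(as.list(environment()), class = "run_config")
}

load_seqs <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) return(read_fasta(x))
  x
}

load_annotation <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(read_gff3(x))
  x
}

load_genomes <- function(config) {
  gs <- config$genome_set
  if (is.null(gs)) return(NULL)
  if (is.character(gs) && length(gs) == 1L && is.null(names(gs)))
    gs <- read_genome_set(gs)
  aliases <- if (identical(config$indv, "all")) names(gs) else config$indv
  missing <- setdiff(aliases, names(gs))
  if (length(missing))
    stop("unknown accession alias: ", paste(missing, collapse = ", "))
  out <- lapply(gs[aliases], load_seqs)
  names(out) <- aliases
  out
}

load_reference <- function(config) {
  assembly <- load_seqs(config$assembly)
  annotation <- load_annotation(config$annotation)
  if (!is.null(config$extend_gene) || !is.null(config$extend_cds)) {
    if (is.null(config$extend_gene) || is.null(config$extend_cds))
      stop("extend_gene and extend_cds must be supplied together")
    ext <- extend_reference(assembly, annotation,
                            load_seqs(config$extend_gene),
                            load_seqs(config$extend_cds))
    assembly <- ext$assembly
    annotation <- ext$annotation
  }
  list(assembly = assembly, annotation = annotation)
}

reference_gene_seqs <- function(reference, gene_ids) {
  missing <- setdiff(gene_ids, names(reference$annotation))
  if (length(missing))
    stop("gene id(s) not in the reference annotation: ",
         paste(missing, collapse = ", "))
  out <- vapply(gene_ids, function(g) {
    m <- reference$annotation[[g]]
    slice_sequence(reference$assembly, m$range)
  }, character(1))
  setNames(out, gene_ids)
}

artifact_path <- function(config, suffix) {
  file.path(config$out_dir, paste0(config$prefix, suffix))
}

write_run_log <- function(config, step) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  scalar <- vapply(config, function(x)
    is.atomic(x) && length(x) <= 8L, logical(1))
  params <- vapply(config[scalar], function(x)
    paste(as.character(x), collapse = ","), character(1))
  lines <- c(sprintf("[%s] step=%s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                     step),
             sprintf("  %s = %s", names(params), params))
  cat(lines, file = artifact_path(config, ".log"), sep = "\n", append = TRUE)
  cat("\n", file = artifact_path(config, ".log"), append = TRUE)
}

#' Step 1: identify target sequences
#'
#' Discovery path: homologues of the reference genes in every query
#' genome.  `indv = "ref"` designs against the reference gene sequences
#' themselves; a user-supplied `targets_fasta` skips discovery entirely.
#' Writes `<prefix>_targets.fasta` and the discovery report
#' `<prefix>_targets.tsv`.
#'
#' @param config [run_config()].
#' @return named character vector of targets (invisible), with provenance
#'   attributes.
#' @export
run_seq <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_run_log(config, "seq")
  if (!is.null(config$targets_fasta)) {
    targets <- load_seqs(config$targets_fasta)
    targets <- setNames(toupper(as.character(targets)), names(targets))
  } else {
    reference <- load_reference(config)
    gene_seqs <- reference_gene_seqs(reference, config$genes)
    if (identical(config$indv, "ref")) {
      ranges <- do.call(rbind, lapply(config$genes, function(g)
        reference$annotation[[g]]$range))
      targets <- excise_targets(reference$assembly, ranges, alias = "ref")
    } else {
      params <- homology_params(
        merge_within = config$merge_within, minlen = config$minlen,
        minid = config$minid, mincdslen = config$mincdslen,
        check_recip = config$check_recip,
        check_id_before_merge = config$check_id_before_merge,
        domain_ranges = config$domain_ranges)
      targets <- discover_targets(
        gene_seqs, load_genomes(config), params,
        reference_assembly = reference$assembly,
        reference_annotation = reference$annotation)
    }
  }
  if (length(targets) == 0L) stop("step seq produced no targets")
  write_fasta(targets, artifact_path(config, "_targets.fasta"))
  prov <- attr(targets, "ranges")
  if (!is.null(prov))
    write.table(prov, artifact_path(config, "_targets.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(targets)
}

load_targets <- function(config) {
  targets <- read_fasta(artifact_path(config, "_targets.fasta"))
  tsv <- artifact_path(config, "_targets.tsv")
  if (file.exists(tsv)) {
    prov <- read.delim(tsv, sep = "\t", stringsAsFactors = FALSE)
    attr(targets, "ranges") <- prov
  }
  targets
}

#' Step 2: enumerate candidate gRNA
#'
#' Writes the candidate FASTA `<prefix>_gRNA_all.fasta` and an unfiltered
#' mapping table (all checks `NA`) that [run_filter()] fills in.
#'
#' @param config [run_config()].
#' @param targets targets from [run_seq()]; reloaded from the run
#'   directory when omitted.
#' @return `grna_set` (invisible).
#' @export
run_grna <- function(config, targets = NULL) {
  write_run_log(config, "grna")
  targets <- targets %||% load_targets(config)
  pam <- parse_pam(config$pam)
  cands <- enumerate_grna(targets, pam, config$length)
  if (length(cands$spacers) == 0L) stop("step grna produced no candidates")
  write_fasta(cands$spacers, artifact_path(config, "_gRNA_all.fasta"))
  mapping <- apply_filters(cands, targets,
                           filter_params(gc_min = -Inf, gc_max = Inf))
  mapping[["check:GC"]] <- "NA"
  write_mapping(mapping, artifact_path(config, "_gRNA_all.map"))
  invisible(cands)
}

#' Step 3: filter candidate gRNA
#'
#' Applies the GC, off-target and within-feature checks and rewrites
#' `<prefix>_gRNA_all.map` with the verdicts.  Backgrounds are the query
#' genomes, any extra `background` sequences, and (with `screen_ref`) the
#' reference assembly; target regions and `mask_gene` genes are masked.
#'
#' @param config [run_config()].
#' @param cands,targets outputs of the previous steps; reloaded from the
#'   run directory when omitted.
#' @return `grna_mapping` (invisible).
#' @export
run_filter <- function(config, cands = NULL, targets = NULL) {
  write_run_log(config, "filter")
  targets <- targets %||% load_targets(config)
  pam <- parse_pam(config$pam)
  if (is.null(cands))
    cands <- enumerate_grna(targets, pam, config$length)
  reference <- tryCatch(load_reference(config),
                        error = function(e) list(assembly = NULL,
                                                 annotation = NULL))
  backgrounds <- character(0)
  genomes <- tryCatch(load_genomes(config), error = function(e) NULL)
  if (!is.null(genomes) && !identical(config$indv, "ref"))
    for (alias in names(genomes))
      backgrounds <- c(backgrounds,
                       setNames(unname(genomes[[alias]]),
                                paste0(alias, "#", names(genomes[[alias]]))))
  extra <- load_seqs(config$background)
  if (!is.null(extra)) backgrounds <- c(backgrounds, extra)
  masked <- NULL
  if (isTRUE(config$screen_ref) && !is.null(reference$assembly)) {
    backgrounds <- c(backgrounds, setNames(unname(reference$assembly),
                                           paste0("ref#",
                                                  names(reference$assembly))))
    if (length(config$mask_gene)) {
      mg <- do.call(rbind, lapply(config$mask_gene, function(g) {
        m <- reference$annotation[[g]]
        if (is.null(m)) stop("mask_gene id not in annotation: ", g)
        m$range
      }))
      mg$seqid <- paste0("ref#", mg$seqid)
      masked <- mg[, c("seqid", "start", "end")]
    }
  }
  # provenance seqids must match the background naming
  prov <- attr(targets, "ranges")
  if (!is.null(prov) && nrow(prov) > 0L && length(backgrounds)) {
    aliased <- paste0(prov$alias, "#", prov$seqid)
    use_alias <- aliased %in% names(backgrounds)
    prov$seqid <- ifelse(use_alias, aliased, prov$seqid)
    attr(targets, "ranges") <- prov
  }
  gene_seqs <- NULL
  if (!is.null(reference$annotation) && !is.null(config$genes))
    gene_seqs <- reference_gene_seqs(reference, config$genes)
  params <- filter_params(
    gc_min = config$gc_min, gc_max = config$gc_max,
    ot_pattern = config$ot_pattern,
    backgrounds = if (length(backgrounds)) backgrounds else NULL,
    masked_ranges = masked, gene_seqs = gene_seqs,
    annotation = reference$annotation, feature = config$feature)
  mapping <- apply_filters(cands, targets, params)
  write_mapping(mapping, artifact_path(config, "_gRNA_all.map"))
  invisible(mapping)
}

#' Step 4: generate minimum gRNA sets
#'
#' Recomputes coverage from the current pass/fail columns of the mapping
#' table (which may have been edited or extended externally) and emits the
#' requested number of mutually exclusive sets: one FASTA per set
#' (`<prefix>_gRNA_final_set<i>.fasta`), the coverage-equivalence listing
#' `<prefix>_pass.eqv`, and an uncovered-target report when coverage is
#' incomplete.
#'
#' @param config [run_config()].
#' @param mapping a `grna_mapping`, a path to one, or `NULL` to reload
#'   `<prefix>_gRNA_all.map` from the run directory.
#' @return list of `cover_solution` objects (invisible).
#' @export
run_minimumset <- function(config, mapping = NULL) {
  write_run_log(config, "minimumset")
  if (is.null(mapping)) mapping <- artifact_path(config, "_gRNA_all.map")
  if (is.character(mapping)) mapping <- read_mapping(mapping)
  set.seed(config$seed)
  cov <- build_coverage(mapping)
  priority <- if (isTRUE(config$prioritise_nr)) "nonredundant" else "pos5"
  if (config$sc_algorithm == "lar") priority <- "pos5"
  if (config$sc_algorithm == "enumerate") priority <- "nonredundant"
  solutions <- mutually_exclusive_sets(cov, n_sets = config$sets,
                                       priority = priority)
  for (i in seq_along(solutions)) {
    sol <- solutions[[i]]
    if (length(sol$grna_ids))
      write_fasta(setNames(unname(cov$spacers[sol$grna_ids]),
                           sol$grna_ids),
                  artifact_path(config,
                                sprintf("_gRNA_final_set%d.fasta", i)))
  }
  eqv <- equivalence_classes(cov)
  eqv_df <- do.call(rbind, lapply(seq_along(eqv), function(i)
    data.frame(class = i, n_targets = length(eqv[[i]]$coverage),
               grna_ids = paste(eqv[[i]]$members, collapse = ","),
               targets = paste(eqv[[i]]$coverage, collapse = ","),
               stringsAsFactors = FALSE)))
  write.table(eqv_df, artifact_path(config, "_pass.eqv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  uncovered <- unique(unlist(lapply(solutions, `[[`, "uncovered")))
  if (length(uncovered))
    writeLines(uncovered, artifact_path(config, "_uncovered.txt"))
  invisible(solutions)
}

#' Run the full four-step pipeline
#'
#' `seq` -> `grna` -> `filter` -> `minimumset`, leaving every intermediate
#' artifact in the run directory.  Step failures abort with the step
#' named; artifacts of completed steps are retained.
#'
#' @param config [run_config()].
#' @return list with `targets`, `candidates`, `mapping` and `solutions`.
#' @export
run_full <- function(config) {
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline step '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  targets <- step("seq", run_seq(config))
  cands <- step("grna", run_grna(config, targets))
  mapping <- step("filter", run_filter(config, cands, targets))
  solutions <- step("minimumset", run_minimumset(config, mapping))
  invisible(list(targets = targets, candidates = cands, mapping = mapping,
                 solutions = solutions))
}
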