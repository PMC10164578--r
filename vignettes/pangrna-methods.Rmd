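---
title: "Designing minimum gRNA sets across pangenomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing minimum gRNA sets across pangenomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangrna)
```

# The problem

CRISPR screens increasingly target gene families across many individuals
of a species (a pangenome) rather than a single reference genome.
Intraspecific variation means a guide RNA (gRNA) designed on the
reference may miss a homologue in another accession, or acquire a new
off-target there.  When a tandem cluster of homologous genes must be
knocked out in several accessions at once, designing guides gene by gene
and genome by genome is wasteful: homologous targets share sequence, so a
small panel of guides can often cover every copy everywhere.

`pangrna` formalises this as a pipeline of four steps:

1. **Target discovery.**  Homologues of the chosen reference genes are
   located in each query assembly by local alignment, hits are merged
   into candidate regions, filtered, and excised as oriented target
   sequences.  Users with their own target FASTA skip this step.
2. **Candidate enumeration.**  Every possible spacer adjacent to a PAM
   (described in a small pattern language) is collected from both strands
   of every target and deduplicated by spacer sequence.
3. **Filtering.**  Candidates are screened for GC content, for off-target
   risk against background genomes under positional mismatch/gap
   thresholds, and for falling within a desired gene feature (CDS by
   default) inferred on unannotated targets by alignment lift-over.
4. **Minimum set cover.**  Each surviving gRNA covers the set of targets
   on which all its checks pass; the solver returns the smallest
   (optionally several mutually exclusive) sets of gRNA that jointly
   cover every target.

Steps are re-entrant through a tab-separated mapping table
(`*_gRNA_all.map`) holding one row per gRNA-target pair with
`pass`/`fail`/`NA` verdicts per check.  External tools may drop rows or
append their own verdict columns and re-run only the set-cover step
(`run_minimumset()`), which recomputes coverage from whatever the table
then says.

# Coordinates and containers

All internal coordinates are 0-based half-open intervals with an explicit
strand; GFF3's 1-based closed convention is converted at the file
boundary and nowhere else, which keeps interval arithmetic (merging,
masking, lift-over) free of off-by-one cases.  Sequences are plain named
character vectors over the IUPAC alphabet (stored upper-case); FASTA and
GFF3 I/O go through Biostrings and rtracklayer.  Genomes may contain
ambiguity codes, but candidate spacers containing them are discarded: an
ambiguous base cannot be synthesised into a guide.

# Homologue discovery

The discovery engine is pluggable: any function mapping (gene sequences,
genome) to a table of local-alignment hits can be used, so an external
BLASTN wrapper drops in without touching the rest of the pipeline.  The
built-in engine (`builtin_engine()`) keeps the test-suite hermetic: exact
k-mer seeds (default k = 11) on both strands are clustered into candidate
windows (seeds within 100 bp), and each window is polished with an
affine-gap Smith-Waterman (match +2, mismatch −3, gap open 5, gap extend
2, via `Biostrings::pairwiseAlignment`); hits scoring below 40 (≈ a 20 bp
perfect match) are dropped.  Percent identity is matches over alignment
columns.

Hits from *all* query genes against one genome are pooled and merged per
sequence and strand when their gap is at most `merge_within` (default
100 bp).  Opposite strands never merge — a homologue is single-stranded.
Identity filtering (`minid`, default 95%) happens either per hit before
merging (`check_id_before_merge`) or on merged regions.  A merged
region's identity is the length-weighted mean identity of its *principal
supporting gene* — the query with the greatest aligned length inside the
region (ties go to the higher identity).  Two cheaper definitions fail in
characteristic ways: pooling all hits lets short cross-paralogue
fragments (for example a shared guide site) dilute a true homologue below
threshold, while taking the best per-gene mean lets one tiny perfect
fragment rescue a strongly diverged pseudo-copy.  Judging the region by
the gene that explains most of it avoids both.

Optional checks:

* `check_recip` aligns each candidate target back to the reference and
  keeps it only if its best hit overlaps a target gene more than any
  non-target gene; ties fail closed (conservative against paralogues).
* `mincdslen` requires a minimum total length of target sequence aligning
  to reference CDS, computed with the same lift-over machinery as the
  feature filter.
* `domain_ranges` trims each target to the hull of the projection of a
  per-gene domain interval (e.g. an NB-ARC domain located by an external
  profile search; running such searches is out of scope — only the
  interval is consumed).

Target ids are deterministic
(`<alias>|<seqid>|<start>-<end>|<strand>`) and targets are excised
oriented 5'→3' on their strand.

# The PAM language and enumeration

A PAM specification is a string of IUPAC codes plus `.` and at most one
alternation group: `NGG`, `TTTV`, `.(NG|NNG|GAA|GAT)`.  `.` is read as
`N`; the alternation is expanded into explicit branches
(`NNG`, `NNNG`, `NGAA`, `NGAT` for the example).  Raw patterns default to
3' orientation (PAM downstream of the spacer); the presets carry their
own orientation and spacer length (`cas9` = 3' NGG/20 nt, `cas12a` = 5'
TTTV/23 nt).  A `gap` parameter allows non-adjacent PAMs (default 0,
matching all common systems), and the empty pattern enumerates every
window PAM-less.  Matching is strict on the target side: a target base
outside A/C/G/T never matches a PAM position, consistent with discarding
ambiguous spacers.

Enumeration scans both strands of every target, pools sites across
targets, and deduplicates by spacer sequence; each unique spacer keeps
the full list of its hits.  Ids are assigned by rank of first discovery
in sorted target order, so outputs are reproducible regardless of input
order.  The engine is validated against an independent regular-expression
oracle on randomly generated sequences.

# Filters

**GC.**  `(#G + #C) / length` on the spacer only (PAM excluded), bounds
inclusive, defaults 0.3–0.7.

**Off-target.**  Off-target risk is assessed by the *presence of the
spacer sequence* in non-target regions — no PAM is required next to the
hit, which errs conservative and also serves PAM-relaxed nucleases.  The
scan is an exact semi-global edit-distance search (spacer end-to-end,
background local; implemented in C++) over every background sequence and
strand, reporting every alignment within `max_edits` edits together with
a per-spacer-position event classification (match / mismatch / gap).
Background insertions are attributed to the following spacer position;
spacer bases falling off a sequence end are tracked as unaligned and
treated as gaps by the clause logic.  Backgrounds are the query genomes
themselves, any extra user sequences, and (with `screen_ref`) the
reference assembly.  Target regions are always masked — both by their
recorded provenance and by exact occurrence matching, so a user-supplied
target FASTA behaves identically to the discovery path — and `mask_gene`
hides chosen reference genes whose non-reference orthologues are
deliberate targets.

Thresholds use a small clause grammar over PAM-relative positions, where
−1 is the PAM-proximal spacer base (the last base for 3' PAM systems,
the first for 5'): `0mg-10` = no mismatches or gaps in positions −1…−10,
`1mg-11-` = at most one from −11 to the 5' end, `2m-5-8` = at most two
mismatches in −5…−8.  A gRNA fails if *some* hit satisfies *every*
clause.  The default (empty pattern) is the single clause
`0mg` over the whole spacer: only a perfect full-length match elsewhere
disqualifies a guide.  The search radius defaults to the largest clause
count plus one.

**Within-feature.**  Targets discovered in unannotated genomes carry no
feature annotation, so feature intervals are inferred: each target is
globally aligned to each reference gene (both orientations, better score
wins) and the gene's feature intervals are projected through the
alignment columns; the union over genes is kept.  A hit passes if its
spacer range lies inside the projected feature union; with no annotation
supplied the verdict is `NA`, which coverage treats as pass.

# Set cover

Coverage maps each gRNA to the targets on which every check passed
(`NA` = pass, so unfiltered columns do not exclude anything).  Two
solvers:

* **Greedy list-and-remove** (`lar_cover()`), prioritising 5'-proximity:
  repeatedly take the gRNA covering the most uncovered targets, breaking
  ties by the smallest minimum hit offset from a target 5' end over its
  uncovered targets (early cuts favour frameshifts), then
  lexicographically; remove what it covers.  The greedy solution carries
  the classical ln(|universe|) guarantee and is exact on most practical
  instances.
* **Exact enumeration** (`enumerate_min_covers()`): a seeded greedy phase
  (each gRNA forced first, randomised tie-breaks for a configurable
  number of iterations) estimates an upper bound on the cover size, then
  a branch-and-bound search (branching on the uncovered target with the
  fewest covering guides, node budget 10⁷ with an explicit warning on
  overflow) enumerates *all* minimum covers.  Covers are ranked by
  non-redundancy — total redundant coverings `Σ|coverage| − |universe|` —
  or by summed 5'-proximity.

The 5'-proximity of a multi-target gRNA is aggregated as the *minimum*
offset over its covered targets (an aggregation had to be chosen; the
minimum reflects the best-case cut and is stable under adding
already-covered targets).  Mutually exclusive sets are computed
sequentially, removing used gRNA from the pool; a later set that cannot
reach full coverage is reported as an explicit partial solution with its
uncovered targets, never dropped.  gRNA with identical coverage form
equivalence classes (`equivalence_classes()`, written as `*_pass.eqv`),
ordered within class by 5'-proximity — interchangeable spares when a
chosen guide is inconvenient to clone.

Uncoverable targets make solutions partial rather than raising errors:
a screen with one stubborn orthologue should still yield the panel for
the rest.

# The synthetic pangenome generator

`generate_pangenome()` emulates, at desk scale, the situation the
pipeline is built for: a tandem cluster of `n_genes_per_cluster` genes
(default 5, each exon–intron–exon, 220/100/180 bp) carried by
`n_accessions` pseudo-accessions (default 16) that diverge from the
reference by seeded substitutions (default 2%, the magnitude typical of
intraspecific divergence in outcrossing plants) and sparse 1-bp indels
(0.2%).  Guide sites — a spacer plus a concrete PAM instance — are
planted identically in the first exon of every gene (universal sites) or
of one gene (private sites).  Planted windows are locked against
mutation so ground-truth coverage is exact, placed ≥30 bp inside exons so
local-alignment end-trimming of discovered targets can never clip them,
and their spacers are constrained to GC 0.35–0.65 so they clear the
default GC filter without interacting with it.  Each genome also carries
a decoy paralogue copied from gene 1 at 20% divergence (with every
planted window deliberately broken), giving the identity filter and the
reciprocal check something to reject.  After assembly the generator
verifies that each planted spacer occurs exactly once per intended
homologue and nowhere else (forward or reverse complement) in any
genome, deterministically regenerating with a salted seed in the
astronomically rare event of a random collision.

What the fixture deliberately does *not* model: structural
rearrangement, segmental duplication, repeat families, coalescent
population structure, and base-composition bias.  Tests passing on it
therefore demonstrate the pipeline's *algorithmic* correctness —
recovery of planted truth under controlled divergence — not performance
on real genomes, where homology detection and off-target screening face
repeats and compositional heterogeneity the fixture never produces.

# Numerical and degenerate-input choices

* Alignment scoring (local: +2/−3, open 5, extend 2; global: +1/−1,
  open 4, extend 1; CDS-to-gene splicing: open 10, extend 0.5 so long
  introns are affordable) are conventional nucleotide parameter sets.
* The off-target scan groups the run of qualifying alignment end-points
  that one physical locus produces and keeps the minimum-distance
  end-point (smallest position on ties); traceback prefers diagonal,
  then deletion, then insertion, making event positions deterministic.
* Reciprocal-check ties fail closed; empty inputs return empty outputs
  everywhere except where the contract demands an error (empty gene set,
  empty mapping table, zero-length spacer).
* `threads` is accepted for interface compatibility; all computation is
  single-threaded and outputs are independent of its value, which makes
  determinism trivial to guarantee.
* All randomised tie-breaks (seeded greedy phase) draw from R's RNG,
  seeded once per run from the `seed` configuration value; identical
  inputs and seed give byte-identical artifacts.

# Default parameters

| parameter | default | meaning |
|---|---|---|
| `minid` | 95 | minimum % identity of a merged homologue region |
| `minlen` | 0 | minimum merged-region length (bp) |
| `merge_within` | 100 | maximum gap (bp) between merged hits |
| `mincdslen` | 0 | minimum target length aligning to reference CDS |
| `gc_min`, `gc_max` | 0.3, 0.7 | inclusive GC bounds |
| `ot_pattern` | `""` | exclude only perfect full-length off-target matches |
| `pam` | `cas9` | 3' NGG, 20-nt spacer |
| `feature` | `CDS` | feature targeted gRNA must fall within |
| `sets` | 1 | mutually exclusive sets to emit |
| `seed_iterations` | 100 | greedy randomisation draws per seed gRNA |

The homology defaults mirror common practice for intraspecific homologue
search (high identity, no length floor, modest merge distance) and are
deliberately permissive: downstream filters, not discovery, are where
specificity is enforced.

# Problem sizes used in the shipped checks

The test-suite and `scripts/acceptance.R` exercise: the full pipeline on
16 accessions × 5 genes (≈4.7 kb per genome, 80 homologues, ≈2 000
candidate spacers); solver optimality on 200 random instances of up to
10 targets × 12 gRNA against exhaustive subset search; off-target
verdicts on 100 two-kilobase backgrounds with planted exact, one-mismatch
and one-gap copies (both strands) against an exhaustive window-scan
oracle; and PAM-site enumeration on 500 random kilobase sequences against
a regex oracle.  These sizes were chosen so each property is checked
densely while a complete run stays comfortably interactive on one core.

# Known limitations

* The built-in discovery engine reports one polished alignment per
  seeded window; tandem duplications closer than the seed-cluster gap can
  collapse into one region (the merge step would fuse them anyway at
  default `merge_within`).
* Off-target screening is purely sequence-based: no PAM requirement at
  the hit, no chromatin, no efficiency model (CFD/MIT scores and
  Doench-style on-target scores are out of scope; their verdicts can be
  appended to the mapping table and re-entered).
* Multi-isoform genes are handled by taking the union of isoform CDS for
  feature inference; `extend_reference()` assumes one CDS per added gene.
* Exact exon boundaries inferred by `extend_reference()` are ambiguous
  when intron edges repeat the flanking exon base; the alignment picks
  one optimal placement deterministically.
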