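# pangrna

Minimum guide RNA sets for multiple targets in multiple genomes.

## The problem

Pangenomic CRISPR screens need guides that work everywhere: a gene
family is to be knocked out not in one reference genome but in every
homologous copy across many accessions of a species, while off-target
risk must be assessed in every one of those genetic backgrounds.
Because homologous targets share sequence, a small panel of guides can
usually cover all copies — if a tool can find the homologues, enumerate
the candidates, screen them per genome, and solve the resulting covering
problem.

`pangrna` does exactly that, in four re-entrant steps:

1. **seq** — homologues of the chosen reference genes are discovered in
   each query assembly by seeded local alignment, merged, filtered
   (identity ≥ `minid`, length ≥ `minlen`, optional reciprocal check and
   domain restriction) and excised as oriented target sequences;
2. **grna** — every spacer of length *L* adjacent to a PAM is collected
   from both strands of every target.  PAMs are written in a small
   pattern language over IUPAC codes with `.` (any base) and one
   alternation: `NGG`, `TTTV`, `.(NG|NNG|GAA|GAT)`; presets `cas9`
   (3' NGG, 20 nt) and `cas12a` (5' TTTV, 23 nt) are built in;
3. **filter** — candidates are checked for GC content (0.3–0.7,
   inclusive), for off-target hits in all query genomes plus optional
   backgrounds under positional threshold clauses (`0mg-10,1mg-11-` =
   "no mismatches/gaps at PAM-relative positions −1…−10 and at most one
   from −11 to the 5' end"; the default excludes only perfect matches
   outside targets), and for lying within a desired feature (CDS by
   default), which on unannotated targets is inferred by projecting
   reference annotations through pairwise alignments;
4. **minimumset** — each gRNA covers the targets on which all checks
   pass, and a set-cover solver (greedy list-and-remove prioritising
   5'-proximal cuts, or exact branch-and-bound enumeration prioritising
   non-redundancy) emits the smallest possible gRNA sets, optionally
   several mutually exclusive ones.

The glue between steps is a tab-separated mapping table
(`*_gRNA_all.map`): one row per gRNA–target pair with `pass`/`fail`/`NA`
columns per check.  You can delete rows, append verdict columns from
other tools, and re-run only `minimumset` — coverage is recomputed from
whatever the table says.

At the core of step 4, a cover is a family of spacer sets
S(g) ⊆ U over the target universe U (S(g) = targets where g passes all
checks); the solver returns argmin |C| subject to ⋃_{g∈C} S(g) = U,
enumerating all optima and ranking them by redundancy
Σ_{g∈C}|S(g)| − |U| or by 5'-proximity.

## A worked example

The package ships a deterministic synthetic pangenome generator, so the
whole pipeline can be demonstrated without any download: a 3-gene
cluster in 4 accessions at 2% divergence, with one universal guide site
planted in every gene copy.

```r
library(pangrna)
fx <- generate_pangenome(fixture_spec(n_accessions = 4,
                                      n_genes_per_cluster = 3, seed = 7))
fx
#> <pangenome_fixture> 4 accession(s) x 3 gene(s), 1 planted site(s)

cfg <- run_config(out_dir = file.path(tempdir(), "demo"),
                  genes = names(fx$reference$annotation),
                  genome_set = fx$genomes,
                  assembly = fx$reference$assembly,
                  annotation = fx$reference$annotation,
                  pam = "cas9", sets = 1, seed = 1)
res <- run_full(cfg)
res$candidates
#> <grna_set> 434 unique spacer(s), 705 hit(s) on 12 target(s)
res$mapping
#> <grna_mapping> 705 row(s), 434 gRNA x 12 target(s); checks: GC, background, feature
res$solutions[[1]]
#> <cover_solution> [LAR/pos5] 1 gRNA covering 12 target(s)

cov <- build_coverage(res$mapping)
unname(cov$spacers[res$solutions[[1]]$grna_ids])
#> [1] "TTCCAAACAACCAATCCCAA"
fx$truth$universal_sites$spacer
#> [1] "TTCCAAACAACCAATCCCAA"
```

Reading the output: discovery found all 12 homologues (3 genes × 4
accessions), enumeration produced 434 unique candidate spacers, and the
solver needed exactly **one** gRNA to cover all 12 targets — the spacer
it selected is precisely the site the generator had planted in every
gene copy.  The run directory contains the targets FASTA, candidate
FASTA, the mapping table, one FASTA per final set
(`*_gRNA_final_set1.fasta`), and the coverage-equivalence listing
(`*_pass.eqv`) of interchangeable guides.

A command-line front end wraps the same functions:

```sh
Rscript inst/scripts/pangrna fixtures --out fx --seed 2
Rscript inst/scripts/pangrna full --out-dir run \
    --gene gene01,gene02 --genome-set fx/genome_set.txt \
    --assembly fx/reference.fasta --annotation fx/reference.gff3 \
    --pam cas9 --set 2 --seed 1
```

Subcommands `seq`, `grna`, `filter` and `minimumset` run the individual
steps; `minimumset --map edited.map` re-enters from an edited mapping
file.

## Package layout

| file | contents |
|---|---|
| `R/ranges.R`, `R/io.R` | coordinates, FASTA/GFF3/lookup I/O, gene models |
| `R/align.R`, `R/homology.R`, `R/extend.R` | alignment engine, homologue discovery, reference extension |
| `R/pam.R` | PAM language and spacer enumeration |
| `R/filters.R`, `src/offtarget.cpp` | GC/off-target/feature filters, mapping table |
| `R/setcover.R` | coverage, greedy and exact set cover, equivalence classes |
| `R/pipeline.R`, `inst/scripts/pangrna` | step orchestration and CLI |
| `R/fixtures.R` | synthetic pangenome generator |
| `vignettes/pangrna-methods.Rmd` | model, assumptions, parameter rationale |
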