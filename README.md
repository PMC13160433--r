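# vus3d — structural triage of missense variants of uncertain significance

Clinical sequencing leaves most missense findings as variants of uncertain
significance (VUS). `vus3d` is a desk-scale, fully offline R toolkit that
triages them in 3D: it maps each variant from genomic or protein coordinates
onto automatically selected protein structures, asks whether the variant sits
inside the spatial constellation of known pathogenic sites, and aggregates
everything — spatial-clustering statistics, stability/interface/PTM
calculator outputs, precomputed per-residue scores, digenic gene-pair
screens — into a case-wide report a geneticist can read.

The pipeline mirrors the phases of production variant-to-structure systems,
with every stage an ordinary function over tibbles:

1. **Ingest** — VCF SNVs (multi-allelic split, non-SNVs skipped with
   reasons) or the pipeline-ready case CSV
   (`gene,transcript_id,protein_id,aa_change,inheritance`); a toy-transcriptome
   consequence caller classifies each SNV (`missense`, `synonymous`,
   `nonsense`, `stop_lost`, `non_coding`) by strand-aware codon arithmetic,
   checked against a full-sequence mutate-and-translate oracle.
2. **Cross-reference reconciliation** — transcript translations versus
   curated protein sequences classify as `PERFECT`,
   `LEN_MATCH_SEQ_MISMATCH`, `LEN_MISMATCH`, or `NO_XREF`; only perfect
   cross-references proceed, everything else halts the case with a
   machine-readable report (`force` to continue). Variants are expanded
   across curated `-N` splice isoforms by alignment-backed position mapping.
3. **Structure selection** — candidates from local catalogs (experimental
   structures and models with quality metrics, SIFTS-style residue maps as
   explicit segment tables) ranked by a greedy additive utility:

   `u(c|S) = 4·covers + 1·new_technique + 1·quality + 1·multimer − 2·overlap`

   verified against an exhaustive subset oracle within the (1−1/e) greedy
   bound.
4. **Spatial clustering** — for a query residue and labeled pathogenic /
   benign Cα sites: `score = mean 1/(1+d_pathogenic) − mean 1/(1+d_benign)`
   (leave-one-out), with a permutation null that relocates both site sets
   uniformly over the chain's mapped residues and the +1 p-value convention
   `p = (1+#{null ≥ obs})/(1+n_perm)`.
5. **Planning & execution** — an architecture-independent `workplan.csv`
   (variant × structure × calculation, plus sequence-level and gene-pair
   jobs) under a GUID-isolated directory tree, with an append-only
   file-based job status protocol and pluggable executors (native
   clustering; deterministic seeded stubs for the licensed/ML calculators;
   a keyed cache for relax artifacts).
6. **Reporting** — per-variant `[min, max]` ranges across structures and
   isoforms, per-transcript reports with a domain-track SVG, a draft case
   summary spreadsheet with configurable flags, and a machine-readable CSV
   twin of everything. Rendering is idempotent and refresh-safe mid-run.

A fixture module generates every input offline — toy transcriptomes with
planted cross-reference discrepancy mixes, ideal-helix PDB structures of
controlled coverage/quality/multimericity, spatially planted site clusters
with ground truth, VCF + expected-case bundles, score tables — all
byte-deterministic under a seed.

## Worked example

Generate a small synthetic case and run the whole pipeline:

```r
library(vus3d)
library(dplyr)

spec <- fixture_spec(seed = 42, n_genes = 4, n_missense = 4,
                     xref_class_mix = c(PERFECT = 1, LEN_MATCH_SEQ_MISMATCH = 0,
                                        LEN_MISMATCH = 0, NO_XREF = 0))
tx  <- make_transcriptome(spec)
dir <- file.path(tempdir(), "demo"); dir.create(dir)
cs  <- make_case(spec, tx, dir)                      # VCF + score tables

pv   <- parse_vcf(cs$vcf)
case <- case_from_consequences("demo",
          annotate_case(pv$variants, tx$transcripts), tx$protein_map)
print(case)
#> <vus_case> demo: 4 variant(s) on 3 protein(s)
#> # A tibble: 4 × 8
#>   gene   protein_id transcript_id position ref_aa alt_aa inheritance provenance
#> 1 GENE02 P00002     T002                87 C      W      unknown     genomic
#> 2 GENE04 P00004     T004                 3 S      T      paternal    genomic
#> 3 GENE03 P00003     T003                90 Q      H      unknown     genomic
#> 4 GENE03 P00003     T003                75 D      E      unknown     genomic
```

Each row is one amino-acid substitution called from the VCF (e.g. `C87W`:
cysteine 87 to tryptophan) with its parental inheritance. Add structures and
planted labeled sites, then run:

```r
structs <- lapply(seq_len(nrow(tx$isoforms)), function(i)
  make_structures(spec, tx$isoforms$isoform_id[i], tx$isoforms$peptide[i],
                  file.path(dir, "pdb")))
structures <- list(catalog    = bind_rows(lapply(structs, `[[`, "catalog")),
                   alignments = bind_rows(lapply(structs, `[[`, "alignments")))

sites_dir <- file.path(dir, "sites"); dir.create(sites_dir)
for (i in seq_len(nrow(structures$catalog))) {
  co <- read_calpha(structures$catalog$coords_path[i])
  pl <- tryCatch(plant_clusters(co, list(n_pathogenic = 5, n_benign = 5,
                                         cluster_radius = 10, separation = 15),
                                seed = 100 + i,
                                structure_id = structures$catalog$structure_id[i]),
                 error = function(e) NULL)
  if (!is.null(pl))
    readr::write_csv(pl$sites, file.path(sites_dir,
      paste0(structures$catalog$structure_id[i], ".csv")))
}

res <- run_pipeline(case, tx, structures, file.path(dir, "out"), seed = 7,
                    sites_dir = sites_dir, n_perm = 199)
table(res$statuses$state)
#> complete
#>      111
```

111 jobs (variant × structure × calculation, sequence-level lookups, and the
digenic gene-pair screen) all reached `complete`. The case summary flags each
variant against the configured thresholds (clustering p ≤ 0.05 here, from the
native permutation test on planted clusters) and tags digenic partners
symmetrically:

```r
readr::read_csv(res$report$summary_csv, show_col_types = FALSE) |>
  select(gene, variant, protein_id, clustering_flag, digenic_partners)
#>   gene   variant protein_id clustering_flag digenic_partners
#> 1 GENE02 C87W    P00002     yes             GENE04
#> 2 GENE02 C87W    P00002-2   yes             GENE04
#> 3 GENE04 S3T     P00004     yes             GENE02
#> 4 GENE04 S3T     P00004-2   yes             GENE02
#> 5 GENE03 Q90H    P00003     yes             NA
#> ...
```

Every variant appears once per impacted isoform (canonical first, `-N`
suffixed after). `res$report$html` is the case landing page;
`res$report$csv` is its machine-readable twin with the per-metric
`[min, max]` ranges across structures. `autoplot()` on a
`pathprox_result`, `plot_score_track()`, and `plot_domain_track()` give the
standard figures.

A thin command-line front end over the same functions ships in
`inst/scripts/vus3d.R` (`ingest`, `run`, `report` subcommands).

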