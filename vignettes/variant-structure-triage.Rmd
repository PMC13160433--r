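---
title: "Structural triage of missense VUS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural triage of missense VUS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Clinical sequencing regularly surfaces missense variants of uncertain
significance (VUS): single-nucleotide changes that swap one amino acid for
another with no established clinical interpretation. Structural context helps:
a substitution that destabilises a fold, sits inside a 3D cluster of known
pathogenic sites, or falls on an interaction interface is a very different
object from one on a disordered loop. `vus3d` implements the computational
core of that triage as a desk-scale, fully offline toolkit: variants in, an
aggregated case report out, with every intermediate stage exposed as an
ordinary R function operating on tibbles.

The pipeline has six stages — ingest, cross-reference reconciliation,
structure selection, work planning/execution, precomputed-score lookup, and
reporting — plus a synthetic-fixture generator that can produce every input
the other stages consume. This vignette records the models, the tunable
parameters, and the design decisions that were genuinely open.

# Consequence calling

VCF SNVs are located within the coding intervals of toy transcript models
(1-based closed intervals in translation order; minus-strand alleles are
complemented), the affected codon is re-translated with the standard genetic
code, and the change is classed `missense`, `synonymous`, `nonsense`,
`stop_lost`, or `non_coding`. Assumptions, all deliberate:

* **CDS-only.** Anything outside the coding intervals — UTRs, splice sites,
  promoters — is `non_coding`. Full consequence calling belongs to a dedicated
  annotator; a pre-annotated consequence table can be imported instead
  (`parse_annotated_csv()`), which is the intended route for real data.
* **Standard genetic code, literal initiation.** Codon 1 is translated by the
  standard table like any other codon, and the independent test oracle
  (`oracle_consequence()`, which mutates the whole CDS string and translates
  both sequences end-to-end with `Biostrings::translate()`) is run with
  `no.init.codon = TRUE` for the same reason: a variant that turns ATG into
  CTG is reported as the missense M→L event it is at the codon level, not
  absorbed by alternative-initiation rules.
* **Stop-affecting variants** (`nonsense`, `stop_lost`) are classified and
  reported but excluded from structural work, which is missense-only.

The invariant backing this stage is blunt: on randomly generated transcript
models (both strands, one- and two-exon layouts) the codon-arithmetic caller
must agree with the full-sequence mutate-and-translate oracle on every single
SNV. The shipped tests run 1,000 such comparisons; agreement below 100% is a
defect, not noise.

# Cross-reference reconciliation

Genome annotation moves: transcript translations and curated protein
sequences disagree often enough that every variant's transcript is classified
against the curated record as `PERFECT`, `LEN_MATCH_SEQ_MISMATCH`,
`LEN_MISMATCH`, or `NO_XREF` — a pure function of the two sequences. Only
`PERFECT` transcripts proceed. Design decisions:

* **Stop by default, `force` to continue.** An unprocessable variant halts the
  case with a machine-readable report grouped by reason, so the analyst can
  patch the inputs; `force = TRUE` continues with the retained subset. The
  default mirrors the conservative clinical workflow; the flag exists so
  automated tests and batch reruns are possible.
* **Same-length mismatches are rejected outright**, even when the mismatch is
  far from the variant. Rescuing them would require a per-variant distance
  argument we chose not to make silently; the rejection report carries enough
  information for a user to force the case through deliberately.
* **Isoform expansion.** Each retained variant is re-addressed on all curated
  `-N` isoforms of its protein. The mapping tries a gap-free coordinate check
  first (identical prefixes up to the variant position), then a global
  pairwise alignment (BLOSUM62, gap opening 10, gap extension 0.5, via
  `Biostrings::pairwiseAlignment`). A position maps only when its alignment
  column pairs the reference residue with an identical residue — never across
  a gap. The unsuffixed identifier (or `-1`) is taken as canonical; that is a
  curation convention, recorded here as an assumption.

# Structure selection

Candidates come from a local catalog (source, method, quality, oligomeric
state, coordinates) with residue maps stored as explicit segment tables —
(transcript start, structure residue start, length) per chain — never
inferred from residue numbering. AlphaFold-style models attach to canonical
isoforms only, since those models cover canonical sequences.

Selection maximises an additive marginal utility:

    u(c | S) = w_cov·covers(c) + w_div·[method(c) ∉ methods(S)]
             + w_qual·q(c) + w_mult·[oligomer(c) > 1] − w_red·overlap(c, S)

with defaults `w_cov = 4, w_div = 1, w_qual = 1, w_mult = 1, w_red = 2`
(`selection_weights()`). Normalised quality `q` maps resolution ≤ 2 Å to 1
linearly down to ≥ 4 Å at 0 for experimental entries, and confidence/100 for
models. `overlap` is the fraction of the candidate's covered positions
already covered by the selected set. The selector is greedy with
deterministic first-pick restarts: the basic loop repeatedly adds the
highest positive marginal candidate up to `max_k` (default 6, a readability
choice for reports), and that loop is run once unrestricted plus once per
candidate forced as the first pick, keeping the run with the highest
sequential total (runs containing a variant-covering structure preferred).
The restarts exist because the single-pass loop has one demonstrable failure
mode: a broad structure picked first can make every complementary,
non-overlapping structure look redundant and stop the selection at a
fraction of the achievable utility; restarting from each candidate recovers
those solutions while staying deterministic. Ties break by quality, then
source order PDB > AlphaFold > SwissModel > ModBase, then lexicographic id,
so identical inputs give byte-identical selections. Two structures with
identical (source, covered interval, oligomeric state) may not both be
selected unless both cover the variant and differ in method.

Why this design: the selection criteria (minimal redundancy, technique
diversity, coverage, quality, multimer priority) are inherently
multi-objective; fixing them as one documented additive utility makes the
selector reproducible and testable against an exhaustive subset oracle. The
coverage weight exceeds the sum of all other bonuses (4 > 1+1+1), so whenever
any candidate covers the variant the first greedy pick covers it — the
coverage guarantee is structural, not incidental. The shipped tests verify,
on hundreds of random instances, that the greedy total stays within the
(1 − 1/e) factor of the brute-force optimum over the same feasible family;
in practice the ratio observed is far closer to 1.

# Spatial clustering statistic

For a query residue and a set of labeled sites (pathogenic / benign) on one
structure, the score is

    score(q) = mean K(d(q, pathogenic Cα)) − mean K(d(q, benign Cα)),
    K(d) = 1 / (1 + d),   d in Å

with the query's own residue excluded from either site set (leave-one-out).
Positive scores mean the query fits the pathogenic constellation better. The
kernel choice is a documented substitute for the published statistic this
stage stands in for: simple, monotone decreasing, heavy-tailed enough that
distant sites still contribute, and exact enough that antisymmetry under a
label swap holds to machine precision and rigid motions leave scores
unchanged to 1e−9 — both are shipped tests. An exponential kernel
`exp(−d/scale)` (scale 8 Å) is available via the `kernel` argument.

The null hypothesis is "randomly placed sites": each permutation relocates
the pathogenic and benign site sets onto residues sampled uniformly without
replacement from the mapped residues of the chain, and the score is
recomputed. The p-value uses the +1 convention,
`p = (1 + #{null ≥ observed}) / (1 + n_perm)`, so p is never 0 and the test
is exact: under the null, `P(p ≤ 0.05)` is 0.05 by exchangeability. The
shipped calibration check runs 2,000 null cases at `n_perm = 199` and
verifies the empirical type-I error sits inside the exact binomial 99% band
and that the p-value distribution passes a KS uniformity check at the 1%
critical value. A uniform-relocation null (rather than a sequence shuffle)
was chosen because the question is spatial: where in the structure the sites
sit, not in what order along the chain.

Multimers: labeled sites are replicated across protomer chains, the query is
evaluated once per chain carrying it, and the minimum p across chains is
reported with per-chain detail retained. No multiple-testing correction is
applied across structures at this layer: reports show per-structure p-values
with their permutation counts so the reader can judge reliability; a
corrected decision rule would hide exactly the information the report exists
to show.

# Planning, execution, and the status protocol

Planning is architecture-independent: the workplan is a flat table — one row
per variant × selected structure × structural calculation, plus
sequence-level rows per variant and one row per unordered gene pair for the
digenic screen — with no scheduler fields (schema-checked in the tests).
Each case lives under `<case_id>_<GUID>/`, each job under
`<variant>/<structure>/<calc>/work` with a sibling `status` directory.
Job state is communicated through append-only timestamped status files
(`planned → submitted → running → complete|failed`, one file per
transition); an empty directory reads as `planned`, partial files are
ignored with a warning, and an unreadable directory reads as `unknown`, so a
monitor can never crash on an in-flight job. Backward transitions are
refused at write time.

Executors are pluggable functions of `(row, params, workdir)`. The
clustering statistic runs natively; the stability, interface, PTM and
digenic calculators — licensed or ML tools out of scope here — ship as
deterministic stubs emitting seeded hash-derived pseudo-scores in documented
ranges (stability in [−1, 7] energy units, probabilities in [0, 1]), so
end-to-end runs, range aggregation and reports are exercised reproducibly.
Stability jobs route through a keyed relax-artifact cache
(structure, chain, protocol, parameter hash): equal keys never recompute,
corrupt entries are recomputed with a warning. Byte-level determinism of a
whole run is achieved by injecting the GUID and the clock
(`run_local(..., clock = )`); with both fixed, two runs of the same case are
byte-identical including the rendered report.

# Precomputed scores

Substitution scores key on (protein, position, alt residue); constraint
scores on (protein, position). Lookups are exact and absent values stay
absent — no imputation, and no canonical fallback for isoform-suffixed
identifiers by default (precomputations cover canonical sequences);
`canonical_fallback = TRUE` enables the fallback and marks the provenance in
the output.

# Reporting

Per variant and metric the report shows `[min, max]` over contributing
result files with the count of contributors and of missing results (failed
jobs are counted, never coerced to 0). Isoform child rows order canonical
first, then `-N` numerically. Rendering is idempotent from the current
result files, so it can run mid-pipeline and refresh as jobs complete
without changing schema. The flag thresholds in the draft case summary —
stability change ≥ 2 energy units, clustering p ≤ 0.05, probability calls ≥
0.5 — live in `report_thresholds()` and are presentation defaults, not
clinical cutoffs; the free-text recommendation column is left blank for the
analyst on purpose. Interactive structure viewers are out of scope; the data
contracts they would consume (per-residue score track CSV, domain-track SVG)
are emitted instead.

# The fixture generator, and what passing tests mean

`fixture_spec()` fixes the study conditions of the test-suite: 6 genes with
2 curated isoforms each by default; a cross-reference class mix of
0.83/0.02/0.01/0.14 (perfect / same-length mismatch / length mismatch / no
cross-reference), echoing at toy scale the proportions observed between a
genome annotation release and a curated proteome, planted exactly by
largest-remainder rounding; peptides of 60–120 residues; 3 candidate
structures per protein with mixed sources, resolutions 1.5–3.5 Å or model
confidences 50–95, about a third homodimers; cluster geometry of 8
pathogenic and 8 benign sites, 8 Å cluster radius, 20 Å separation. Every
generator is byte-deterministic under its seed.

Synthetic structures are ideal α-helix Cα traces (1.5 Å rise, 100° turn,
2.3 Å radius; protomers offset 30 Å). That supports exactly what the tests
need — distances, coverage arithmetic, multimer fan-out, parseable PDB files
— and nothing more. Passing tests therefore demonstrate correctness of the
*machinery* (coordinate mapping, statistics, aggregation, determinism) under
controlled geometry; they say nothing about real fold topology, real
ClinVar/gnomAD site distributions, real allele frequencies, or annotation
edge cases beyond the four discrepancy classes modelled. Those require real
inputs through the import paths.

Problem sizes used by the shipped checks — 1,000 oracle SNVs, 200 selection
instances against brute force, 2,000 null calibration cases at 199
permutations, a 10-variant deterministic end-to-end case — were chosen as
the smallest sizes at which the binomial and KS bands are meaningfully
tight; the same properties hold at larger sizes.

# Numerical choices and degenerate inputs

* Permutation seeds: every stochastic routine takes an explicit integer seed
  and restores the caller's RNG state.
* `proximity()` on an empty site set is an error, not NaN; a missing label
  class yields a flagged one-sided result with the p-value suppressed; too
  few eligible residues (≤ number of sites) skips the test with a recorded
  reason.
* Ties in structure selection are broken deterministically (quality, source
  order, id) so selections never depend on input row order.
* Duplicate variants de-duplicate on (protein, position, ref, alt), keeping
  the first occurrence and logging the rest.
* Path components are sanitised to `[A-Za-z0-9._-]`; a post-sanitisation
  collision is an error, never a silent overwrite.

# Known limitations

* The consequence caller is a deliberate stand-in: no splice, UTR, or
  regulatory effects, no indels, no liftover.
* The clustering kernel and null are declared substitutes for the published
  statistic this stage replaces; conclusions about real variants should use
  the real labeled sites and, where available, the original statistic.
* Stub executors produce pseudo-scores: ranges and flags in reports from
  stub runs exercise the plumbing, not biology.
* Apo/holo structure states and multi-conformation ensembles are not
  modelled; selection treats each catalog entry independently.
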