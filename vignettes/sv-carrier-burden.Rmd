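---
title: "Methods: SV region classification and carrier burden association"
author: "svgenes"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: SV region classification and carrier burden association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svgenes)
```

# The analysis in one paragraph

Given per-sample structural variant (SV) callsets, a gene annotation and a
cohort manifest (case/control status and ancestry stratum per sample),
`svgenes` classifies each SV's relationship to genes, collapses calls to
person-level carrier indicators per `(gene, region class, SV type)` key,
tests case-control carrier burden per stratum with chi-square and Fisher's
exact tests, adjusts with Bonferroni, combines strata with Fisher's
combined probability test, and separately screens merged recurrent loci for
rare, case-enriched events.  This vignette records the model, the
conventions, and the choices made where the design was genuinely open.

# Region classification

## The rule

For every deletion, duplication, inversion or insertion, each gene whose
span overlaps the SV is evaluated independently against the gene's *merged
exon union* (the union of exons over all transcripts):

* **exonic** — both SV breakpoints fall inside exons of the gene;
* **splicing** — the SV overlaps at least one exon without being contained
  in it, i.e. it crosses an exon boundary;
* **intronic** — the SV lies inside the gene, touches no exon and spans no
  exon (equivalently: both breakpoints in the same intron);
* **intergenic** — the SV overlaps no gene span at all; it is assigned to
  its closest gene.

A single SV can earn a gene both `exonic` and `splicing` (an exon-to-exon
deletion across an intron), and an SV overlapping several genes yields one
assignment per gene with no "most severe" pruning — per-gene burden is the
unit of analysis, so every overlapped gene should see the event.

Design points worth making explicit:

* **Exon union across all transcripts** defines "exonic".  The alternative
  (canonical transcript only) shrinks exons and reclassifies borderline
  events as intronic; we default to the union because an SV disrupting any
  annotated exon plausibly disrupts some product of the gene.
* **Strand is carried but ignored**: breakpoint geometry is
  strand-symmetric.
* **Gene biotype is not filtered**: non-coding RNA genes are legitimate
  SV-genes and are retained.
* **A gene entirely contained in an SV is `splicing`** for that gene: both
  of its exon boundaries are crossed, and the intronic definition demands
  that no exon be spanned.  (With the exon-boundary-crossing formulation
  this falls out automatically rather than needing a special case.)
* **Balanced events** (inversions, breakends) use the same breakpoint
  geometry; each breakend of a translocation is classified independently
  as a point.  Point-like events (insertions, breakends) can be exonic,
  intronic or intergenic but never splicing — a point crosses no boundary.
* **Intergenic anchoring**: the SV midpoint selects the nearest gene
  (deterministic ties: smaller span start, then lexicographic gene id),
  while the *reported* distance is the gap between the SV interval and the
  gene span, matching the convention of `bedtools closest`.  Using the
  midpoint for selection gives a single well-defined anchor for long SVs
  lying between two genes.

## Coordinates

Internally everything lives on the GRanges convention: 1-based, closed
intervals.  GTF/GFF3 input is 1-based closed and is taken as-is.  In VCF
input, `POS` is interpreted as the **first affected base**: a deletion with
`POS = p`, `END = e` occupies `[p, e]` and has length `e − p + 1`; an
insertion occupies its single anchor base `[POS, POS]` and takes its length
from `|SVLEN|`; a breakend occupies `[POS, POS]`.  This is the convention
under which a deletion printed as `chr5:171723712–171724032` (a 0-based
start, as UCSC-style browsers print) with VCF `POS = 171723713` comes out
at 320 bp.

## Quality filters

`filterCalls()` keeps records with FILTER `PASS` and length ≥ 50 bp — the
conventional lower bound separating SVs from indels.  Breakends have no
meaningful `SVLEN`, so they are exempt from the length rule and kept on
PASS alone; dropping them entirely would silently discard all
translocations, which are legitimate exonic/splicing events.

# Recurrent locus merging

Callers emit slightly different breakpoints for the same event in
different genomes.  `mergeLoci()` single-links same-type, same-chromosome
calls whose breakpoints agree within ±`window` (default 50 bp) **and**
(for interval types) whose reciprocal overlap is at least
`reciprocal_overlap` (default 0.8); breakends additionally require a
matching mate chromosome and mate position within the window.  No
community-standard criterion exists for "the same SV", so both knobs are
exposed; the defaults are the common middle ground used by callset-merging
tools.  The result is deterministic, input-order invariant, and conserves
the number of underlying calls.

# Association model

The unit of testing is the **person-level carrier indicator**: for key
`(gene, region class, SV type)` a sample either carries ≥ 1 qualifying SV
or does not.  Multiple events in one person count once — carrier counting
is robust to one genome contributing many correlated calls at a locus.  For
stratum totals `N_case`, `N_ctrl` the 2×2 table is

|            | carrier | non-carrier |
|------------|---------|-------------|
| case       | a       | b           |
| control    | c       | d           |

with `a + b = N_case`, `c + d = N_ctrl`.

* **Odds ratio** `(a·d)/(b·c)`; when any cell is zero, Haldane's +0.5 is
  added to every cell (only then — published tables with non-zero cells
  reproduce exactly under the plain cross-product).
* **Chi-square**: Pearson, 1 df, *no* Yates continuity correction by
  default, with a `yates` flag.  Small-sample conventions differ between
  software; we default to the plain Pearson statistic and rely on Fisher's
  exact test where counts are small.  Degenerate tables (a zero margin)
  return statistic 0, p 1, flagged.
* **Fisher's exact test**, two-sided by the standard probability-mass rule:
  sum, over the hypergeometric support at fixed margins, of all table
  probabilities not exceeding the observed table's probability.  A relative
  tie guard of `1e-7` prevents floating-point noise from splitting exact
  ties (the same guard `stats::fisher.test` uses); the implementation is
  checked against exhaustive enumeration for every table of total ≤ 24.
* **Bonferroni** within a family defaulting to stratum × region class,
  with an `m` override because the appropriate family (keys, genes, or
  something between) is a judgement call that belongs to the analyst.
* Reported significance follows common practice for this design: raw-p
  thresholds (0.05 / 0.01) drive the "associated" lists while adjusted
  values are always emitted alongside; at these cohort sizes almost no
  carrier test survives Bonferroni across thousands of keys, and the
  adjusted columns mostly saturate at 1.
* **Risk orientation**: downstream reporting keeps keys with OR > 1
  (`risk_only`, exposed); protective keys remain in the full output,
  flagged.

## Meta-analysis

Strata are analysed independently and combined per key with Fisher's
combined probability test: `X = −2 Σ ln pᵢ` referred to χ² with `2k` df.
For a single stratum this is the identity (`exp(−X/2) = p`), a useful
sanity check; a p of exactly 0 is refused with advice to substitute the
smallest representable double explicitly.  The test is one-sided in
evidence: decreasing any input p never increases the combined p, so a
stratum-specific signal (p = 0.79 in one stratum, 0.0032 in the other →
combined 0.0176) survives combination — which is precisely the behaviour
wanted when effects are ancestry-specific.

## Rare recurrent case-only screen

Association power is negligible for loci carried by a handful of people,
so very rare recurrent loci are screened separately: keep clusters with
≥ 2 distinct case carriers and either zero control carriers (case-only
mode) or control carrier frequency strictly below 0.5 %.

# The synthetic cohort generator

`simulationConfig()` fixes everything: a toy multi-chromosome genome of
non-overlapping multi-exon genes; cohort strata; planted effects; and a
background SV process.  Key choices:

* **Effects are parameterised by the carrier odds ratio directly.**
  Controls carry at frequency `f`; cases at `OR·f / (1 − f + OR·f)`
  (`carrierCaseProb()`), the solution of `odds_case = OR · odds_control`.
  The analysis estimand is then exactly the planted quantity, closing the
  parameter-recovery loop.
* **Placement is validated by the classifier itself**: every planted SV is
  run through `classifySV()` and must produce the intended (gene, class)
  assignment, otherwise configuration fails loudly.
* **Each effect is one recurrent template** shared by its carriers, so it
  merges into a single locus with a clean carrier list.
* **Background SVs** avoid effect genes by default (truth stays clean),
  follow the genome-wide class mix observed in deep WGS callsets
  (exonic 0.96 %, splicing 0.59 %, intronic 42.3 %, intergenic 56.13 %)
  and a MANTA-like type mix, at a default rate of 8 per sample — the
  ~780 SV-per-genome density of a real callset scaled to a 200-gene toy
  genome (1 % of a human gene complement).  5 % of background records are
  labelled `MinQUAL` so the quality filter has work to do.
* **Determinism**: with a fixed seed, the GTF, VCFs, manifest and truth
  table are byte-identical between runs, across the whole pipeline.

`adhdCohortScenario()` is a preset mirroring a two-ancestry ADHD WGS
design: AA 116 cases / 408 controls and EA 89 / 262 (205 cases, 670
controls), 200 genes, and largely disjoint planted effect gene sets per
stratum (2 of 31 effect genes shared, ≈ 6 % overlap) so that cross-stratum
overlap summaries have structure to find.

What the generator deliberately does **not** emulate: linkage
disequilibrium and population structure, realistic human SV length
spectra, genotyping error correlated with phenotype, batch effects, and
read-level evidence.  Green simulation tests therefore demonstrate the
statistical machinery and the classification geometry, not robustness to
those real-data pathologies.

`simulateCarrierMatrix()` skips genome placement and VCF round-tripping
and draws carrier indicators directly — the tool for calibration studies
needing hundreds of replicate cohorts.

# Numerical and testing choices

* Problem sizes in the checks are chosen to finish comfortably on one CPU:
  type-I calibration pools 500 replicate null cohorts of 200 genes at the
  AA stratum size (100 000 tests); parameter recovery uses 100 seeded
  cohorts; the classifier is fuzzed with 500 random SVs against a
  brute-force oracle; Fisher's exact test is enumerated exhaustively to
  table total 24.
* The chi-square test is also compared against a hypergeometric
  permutation null on large tables; at 10⁵ draws the Monte-Carlo precision
  resolves the systematic conditional-versus-asymptotic gap, which is
  allowed for explicitly (±0.005) rather than hidden with fewer draws.
* Nearest-gene ties break deterministically (distance, span start,
  gene id); cluster ids encode `chrom:start-end:type`; output files carry a
  provenance header (package version, a hash of the analytical parameters,
  seed) so identical configurations produce identical bytes.

# Known limitations

* **Top-rank recovery has a ceiling.**  With ~200 genes tested at
  calibrated null p-values, a planted carrier OR of 3 at control frequency
  0.05 in a 116/408 stratum has median chi-square p ≈ 1.3 × 10⁻³, and the
  probability that it beats the minimum of 199 null tests is
  `E[(1 − p)^199] ≈ 0.6` — confirmed at ≈ 0.62 empirically by the
  acceptance checks.  Expecting such an effect to rank first in ≫ 60 % of
  cohorts of this size is not statistically attainable; reliable top
  ranking needs larger effects, larger cohorts, or a smaller test family.
* Carrier-level testing discards allele dosage and within-person event
  counts by design.
* No covariate adjustment (sex, principal components): the model is the
  2×2 table.  Confounding must be handled by stratification, which is why
  strata are first-class.
* The merge criterion is a convention, not an inference; loci split or
  lumped near the window/overlap thresholds will move between the
  association and rare-recurrent branches.
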