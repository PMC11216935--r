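---
title: "Methods: domain census and PUL co-localization scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain census and PUL co-localization scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulcensus)
```

`pulcensus` answers two questions about a protein domain family in a
collection of annotated genomes: *what do the proteins carrying it look
like* (the census), and *is it systematically encoded inside
polysaccharide utilization loci* (the vicinity scan). This vignette
documents the procedures, every tunable that matters, the decisions taken
where the design was genuinely open, and what the synthetic tests do and
do not demonstrate.

## The census

### Hit filtering

Domain hits arrive as tabular calls (`gene_id`, `domain`, `start`, `end`,
`evalue`, `source`) from whatever annotation service produced them; the
package never scans sequences itself. `filter_hits()` keeps hits with
E ≤ ε, default ε = 10⁻⁴. The comparison is **inclusive**: "cutoff of
0.0001" does not specify strictness, and keeping the boundary hit is the
conservative reading — it is a single constant, exposed everywhere as
`cutoff`. Hits without an E-value (curated motif annotations, e.g. from
flat-file MOTIF blocks) are kept by default because there is no score to
test against. Identical `(gene, domain, start, end)` calls from different
sources collapse to the lowest E-value.

### Overlap grouping and canonical labels

Two hits of one protein are *linked* when their intersection covers at
least `min_overlap_frac` of the **shorter** hit; overlap groups are the
connected components of this relation (union–find over the pairwise
relation; proteins carry few hits, so the quadratic pass is irrelevant).
The default fraction is 0.5. This number is a package choice, not an
upstream convention: published tables only describe the DUF1735/DUF4973
pair as "mostly overlapping" without a numeric criterion. 0.5 of the
shorter hit cleanly separates nested or duplicated calls (which should
merge) from merely adjacent domains (which should not), and it is a
parameter precisely because it is a judgment call.

The canonical label joins groups N- to C-terminally with `" + "` and
domains within a group with `"|"` (`paper_style = TRUE` renders `"I"`,
the typesetting used in printed tables, for byte-identical labels). A
group whose two members form a `star_merge` pair — default
{DUF1735, DUF4973} — renders as the primary name plus `*`
(`"DUF1735*"`), folding the question of whether the two calls are really
distinct domains into one row, as census tables do. Repeated domains stay
per-occurrence (`"DUF1735 + DUF1735"`). Within a group, order is start
coordinate then name; ties in start are therefore deterministic. A
protein is *multimodular* iff it has ≥ 2 groups; its N-terminal domain is
the first member of the first group.

Per-protein domain counts (`n_domains`) are taken **after filtering,
before overlap merging**: each named surviving hit counts once. The
alternative (counting merged groups) would make the DUF1735* fold-in
change copy numbers, which the distinction between "domains" and
"proteins" in the copy-number table is meant to avoid.

### Table arithmetic

All printed percentages are `round_half_up`-style **half away from zero**
at one decimal (`round_half_away()`): 31.75 → 31.8. Banker's rounding is
deliberately not used, because the published tables it reproduces do not
use it. Frequency tables sort by count descending then key; rows below
`min_n` collapse into a final `Other (n <= min_n − 1)` row which is
pinned last regardless of its size, again following how such tables are
printed (collapse defaults: 6 for KEGG-scale tables, 21 for
UniProt-scale; both parameters). Copy-number tables report per genome the
number of carrier proteins, domain copies, and their ratio to one
decimal; taxonomy rollups label their count mode (`domains`, `genes`,
`genomes`) explicitly in the output, because the three are easy to
conflate.

One known arithmetic subtlety: a global "mean copies per genome" over
genomes with ≥ 1 copy is attached as an attribute and rounded half away
from zero; with 775 copies in 199 genomes this yields 3.9, and no attempt
is made to chase alternative roundings.

## The vicinity scan

### Gene distance on irregular locus tags

KEGG-style gene identifiers embed the gene's genome position as the
numeric tail of the locus tag (`BT_3987` → 3987); `locus_index()` takes
the longest trailing digit run, which also handles zero-padded fixture
tags. Genomes number genes in steps of 1, 5 or 10, with occasional gaps.
`infer_step()` estimates the step as the **mode of consecutive sorted
index differences**, ties broken toward the smaller candidate (a tie
between 5 and 10 on a gappy step-5 genome should not double the step); a
genome is `regular` when every difference equals the step.

"±5 gene distance" is interpreted as **5 genes (ranks), not 5 index
units**. Neighborhoods are computed by sorting each genome's indices and
taking rank offsets in [−w, +w]; on regular genomes this coincides
exactly with index arithmetic (target ± k·s), which is what step
detection exists to guarantee, and on gapped genomes rank distance is the
biologically meaningful quantity. The equivalence of the two routes on
regular genomes is property-tested against a brute-force oracle.

### SusD evidence tiers

SusD is the PUL marker because it is the consistently KO-annotated member
of the susC/D pair. Evidence is tiered, best tier wins:

| tier | test | default strings |
|---|---|---|
| `SusD-ID` | exact KO match | `K21572` |
| `SusD-D` | domain-hit name contains (case-insensitive substring, whitespace collapsed) | `RagB`, `SusD-like` |
| `SusD-N` | gene name or annotation contains | `SusD`, `RagB` |

All three string sets are configurable (`susd_marker()`), so any other
neighborhood marker — a different KO, different annotations — can be
scanned for without code changes. KO matching is exact by design;
substring matching is reserved for free-text fields.

When several neighbors carry evidence, the recorded one is chosen by
best tier, then smallest |offset|, then the upstream (negative-offset)
gene. The upstream preference reflects the canonical PUL layout
(susC–susD–target); upstream evidence is the more likely true pair
member. This tie rule is a package decision — no published convention
exists — and it is exercised directly by tests.

A gene is a *target* iff it carries ≥ 1 **surviving** hit of the target
domain; multiple copies in one gene yield one scan row with the copy
count carried alongside, preserving the distinction between domain
copies and their containing genes. A target is PUL-positive iff any
evidence falls in its window.

### Position classification

Positive targets are classified by rank distance *d* downstream of the
susD gene: d = 1, 2, 3 → susE-, susF-, susG-like, anything else
(including upstream targets) → `other`. "Downstream" means *away from
the adjacent susC*: the classifier looks for a susC-like gene
(name/annotation containing "SusC", or KO K21573) among susD's two rank
neighbors and walks the other way. Without an adjacent susC it falls
back to the direction of increasing gene index. Strand is ignored
throughout — the input schema has no strand column — so "downstream" is
a locus-order approximation, documented rather than hidden.

## The synthetic generator

`synthetic_config()` + `simulate_dataset()` build KEGG-like datasets in
which every quantity the pipeline should recover is **planted by
counting**: requested fractions are realized with largest-remainder
allocation, so downstream checks are equalities, not statistical tests.
The defaults are the study conditions the package's claims are made
under:

* 12 genomes × 60 genes; steps cycle through {1, 5, 10} so every
  numbering dialect occurs; gap rate 0.1 (a typical annotation-dropout
  level; any value in [0, 0.2] is exercised by the property tests).
* 45 planted susC→susD→target loci plus 1 decoy target: 45/46 = 97.8%
  planted co-localization, the reported rate for DUF1735.
* Downstream offsets d ∈ {1, 2, 3} in the mix 47/35/18% — the reported
  susE/F/G-like position distribution.
* Evidence tiers ID/D/N in the mix 14/43/43%: the 14% KO-identified
  share is reported; the remainder is split evenly because no published
  D/N split exists.
* 84% of target proteins multimodular (reported), with C-terminal
  partners cycling through LamG3, DUF4361, F5/8-typeC, DUF5627, GH18;
  30% get an overlapping DUF4973 call (a package choice — the real
  overlap share is not printed); 15% carry a second target-domain copy
  so copy-number means exceed 1.
* E-values cycle through {10⁻³⁰, 10⁻¹², 10⁻⁶, 10⁻⁴}, deliberately
  including the boundary value, and noise hits straddle the cutoff on
  both sides; a few filler genes get target-domain hits *above* the
  cutoff and must never become targets.
* Phylum labels (marked "synthetic") are planted per gene so the
  requested copy split over taxa is exact — a deliberate departure from
  real data, where taxonomy is a genome property, accepted to keep
  planted fractions equalities.

Loci occupy blocks spaced `2w + 4` ranks apart, so no window can see two
loci at once and decoys are window-clean by construction; the generator
re-verifies this by brute force before returning. `expected_scan()`
recomputes the full expected result by direct sort–rank–scan over the
manifest's gene map, sharing no code with `scan_vicinity()` — the
generator/oracle/implementation triangle must close on every tested
seed, and does over 50 seeds in the acceptance suite.

**What passing these tests does not show:** the generator does not mimic
real annotation noise (misassigned KOs, partial-domain calls, fused
genes), real taxonomy breadth, strand structure, or PUL gene content
beyond the susC/D/target skeleton. Results on real KEGG/UniProt exports
inherit the quality of the upstream annotations; the tests demonstrate
that the *computation* is correct, not that the annotations are.

## Degenerate inputs and numerical details

* Empty hit list → empty label, zero groups, not an error; an unknown
  target domain yields an empty result with a notice (a census of an
  absent domain is a legitimate empty answer).
* Empty census tables (no labels at all) *are* an error — percentages of
  nothing are undefined.
* `round_half_away()` nudges by one double-precision ulp before
  truncating so exactly representable halves (2.5, 31.75·10) round away
  from zero despite binary floating point.
* Parsers reject rather than repair: declared AASEQ lengths must match
  the sequence, duplicate gene ids and out-of-range hit coordinates are
  errors naming the offenders.
* Gene-id dialects `genome:tag` and `genome_tag` are both read; `:` is
  canonical on write.

## Problem sizes

The test suite runs the full default-condition pipeline over 50 seeds,
500 random genomes for the neighborhood oracle, 300 gap-free genomes for
step recovery, and 1000 random hit sets (≤ 15 hits) for the overlap
oracle — sizes chosen so the whole suite completes in a few minutes while
still exercising every numbering dialect, gap rate, tier and offset
combination. `scripts/acceptance.R` reruns the same computations at the
same sizes from a fresh seed.

## Limitations

* SusD vicinity is the sole PUL criterion; no boundary detection or
  regulator/CAZyme content model (matching the scope of marker-based
  mining, not PULDB-style curation).
* Strand-blind: position classes are rank-order approximations.
* Live database access is out of scope by design; the TSV tables are the
  normalized stand-in for service responses, and a REST adapter would be
  an untested optional extra behind the same reader contract.
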