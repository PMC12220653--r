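---
title: "Screening genome annotations for chimeric gene models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening genome annotations for chimeric gene models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeraScreen)
```

## The problem and the model

Automated annotation pipelines occasionally emit a single gene model where
the genome actually encodes two or more adjacent genes — most often in
tandem arrays of related genes, where exons of neighbouring paralogs are
stitched into one "chimeric" model. `chimeraScreen` detects the homology
signature such a fusion leaves behind rather than re-annotating anything:
a chimera of $k$ similar-sized genes, aligned against a curated protein
database containing its single-gene homologs, produces $k$ hits that each
cover roughly $1/k$ of the fused protein (at near-complete target
coverage), occupying distinct, largely disjoint stretches of the query.
An independently produced alternate annotation supplies the
counter-hypothesis: if its models at the same locus each match those same
database proteins near-fully, the reference model — not the locus — is
suspect.

Formally, for a reference gene $g$ with single-isoform protein of length
$L_g$, hit coverage is $q(h) = (q_{end} - q_{start} + 1)/L_g$ with 1-based
inclusive alignment coordinates (the convention of tabular search output).
The cascade retains $g$ as a candidate iff

1. $\mathrm{median}\,q(\text{ref hits}) < c_{ref}$ **and**
   $\mathrm{median}\,q(\text{pooled alt hits}) > c_{alt}$, both strict,
   with defaults $c_{ref} = 0.60$, $c_{alt} = 0.70$;
2. the alternate models' target set is a subset of the reference target
   set (an empty alternate set fails — without alternate evidence the
   locus cannot be adjudicated);
3. the reference hit intervals, shrunk symmetrically by a total fraction
   $s = 0.10$, form at least $m = 2$ clusters under transitive overlap,
   and the union of the **unshrunk** intervals covers $> 0.50$ of $L_g$
   (strict).

The defaults are not free parameters of this implementation: $0.60$ is
the two-component expectation $0.5$ plus a $10\%$ allowance for length
variation between the fused parts, $0.70$ demands that the split models
themselves be well supported, and $0.50$ guards against sparse spurious
hits. The cluster count of a candidate doubles as the component-count
estimate.

### Pooling alternate hits

The alternate side of filter 1 takes the median over the *pooled* hits of
all linked alternate genes rather than per-gene medians. Pooling treats
the locus as a unit, weighs each alternate model by its evidence, and
still lets a locus be flagged when the alternate annotation produced only
a single model there — the reference gene's own hit clusters carry the
signal in that case.

### Shrinking and clustering

Alignment boundaries are noisy: two hits to adjacent components typically
overlap by a handful of residues, which would fuse their clusters. Each
interval of length $L$ therefore loses $\lfloor L \cdot s/2 \rfloor$
residues per end before clustering (an interval that would vanish
collapses to its midpoint residue, a defensive case that cannot trigger
at $s < 1$). Clustering is single-linkage by interval overlap: two
intervals join iff they share at least one residue, chains merge
transitively, and abutting intervals (`[1,10]`, `[11,20]`) stay separate.
Increasing $s$ can only split clusters, never merge them, so the
component-count estimate is conservative in $s$. Total query coverage
deliberately uses the unshrunk intervals: shrinking is a clustering
de-noising device, not a statement about how much of the protein is
covered. Intervals enter clustering once per hit; repeated hits to the
same target contribute repeated intervals.

### What is and is not assessed

Genes with zero database hits are skipped and only counted — a curated
database cannot be mapped to every gene in a genome, and absence of hits
is not evidence of fusion. Genes whose linked alternate models have no
hits fail filter 1 with the missing median recorded as `NA`. Hits above a
permissive e-value ceiling (default $10^{-5}$) are dropped at load time;
the detection search itself is expected to be run at high sensitivity.

## Linking the two annotations

A reference gene links to every alternate gene whose CDS footprint (union
of CDS intervals) overlaps its own on the same strand by at least one
base. Gene spans are not used — the audit concerns coding sequence — and
no minimum overlap fraction is imposed, because a chimera component may
overlap an alternate model only partially. Users who prefer an external
matching tool can import its gene-pair table instead
(`read_gene_links()`).

## Isoform selection and translation

"Longest isoform" is measured in translated protein length — the quantity
the coverage filters operate on — computed as the codon count of the CDS
after the 5′ phase offset, so selection needs no genome access; ties break
to the lexicographically smallest transcript ID for determinism. Either
convention (mRNA length vs protein length) selects the same transcript for
the vast majority of genes; protein length was fixed here because it is
the filters' own scale. Translation uses the standard genetic code only;
codons containing `N` translate to `X`; one trailing stop is trimmed; an
internal stop warns and flags the record but does not abort, since
mis-annotated models are precisely the interesting inputs. Internal
coordinates are 0-based half-open everywhere, converted at the GFF3
boundary, which keeps interval arithmetic free of off-by-one cases.

## RBH length-ratio classification

Reciprocal best hits between two proteomes ("best" = highest bit score,
ties by smaller e-value then lexicographic target ID — the tie policy is
fixed here because search tools' internal defaults vary) are classified by
$r = \log_2(\mathrm{len}_a/\mathrm{len}_b)$ into closed bands:
2:1 split $[0.8, 1.2]$, 3:1 split $[1.4, 1.7]$, 4:1 split $[1.9, 2.1]$,
their mirrored fusion bands, 1:1 match $[-0.3, 0.3]$, and `other`
elsewhere. Endpoints are inclusive; ratios in the gaps between bands stay
`other` with no snapping, because the gaps are genuinely ambiguous. The
output records the ratio convention explicitly (`len_a` is the first
annotation's protein).

## Database coverage screens

`apply_screen_filter()` reproduces a post-search confidence filter:
e-value $\le 10^{-10}$, alignment length $\ge 100$, bit score strictly
$> 200$, and optionally a case-insensitive substring match on the query's
FASTA header ("uncharacterized protein" targets the poorly annotated
entries where chimeras accumulate). `coverage_signature()` bins each
hit's $(q_{cov}, t_{cov})$ pair on a 50×50 grid over $(0,1]$ (bin width
0.02 — fine enough to separate $1/k$ bands for $k \le 6$; counts are
reported raw, log-scaling being a plotting concern) and summarises
per-query means over retained hits. Self-hits are excluded from both
screens: they carry no mis-annotation signal. `length_ratio_audit()`
applies the stricter $e < 10^{-30}$ cutoff (strict, per-hit) and reports
$\log_2(q_{len}/t_{len})$ per hit, with optional corrected-length markers.

## The simulator

`simulate_bundle()` generates the complete input bundle — genome FASTA,
reference and alternate GFF3, component protein database, idealized hit
tables in the tabular search format, and a truth table — deterministically
from a seed. Chimeras are planted by concatenating complete component gene
structures, retaining the inter-component DNA inside the fused model as an
intron-like spacer, and emitting a stop codon only after the last
component in transcription order: the fused protein is then the *exact*
concatenation of the component proteins, and every coverage quantity is
analytic (component $i$ covers exactly $\mathrm{len}_i / \sum_j
\mathrm{len}_j$ of the fused query at full target coverage). Component
proteins within a chimera are drawn from disjoint residue alphabets under
a seeded shuffle so the exact-substring search oracle produces exactly one
hit per component and no cross-hits. Multi-exon structure on both strands,
with per-segment phases, exercises the full coordinate arithmetic of
extraction and translation.

Defaults — 50 genes, 5 chimeras, 2 sequences, 150–500 aa components, 1–5
exons, introns of 60–400 bp, intergenic gaps of 200–2000 bp, GC 0.40, and
component-count weights 499:81:12:6:2 for $k = 2..6$ — mirror the
composition reported in published audits of real annotations, where
two-gene fusions dominate; these sizes keep a full simulate-and-scan cycle
under a second while leaving dozens of genes per condition. An optional
coverage jitter (`perturb_hits()`, seeded Gaussian coordinate noise)
supports robustness checks around the thresholds.

What the simulator does **not** emulate — and therefore what passing tests
do not show about real data: sequence-level homology noise (partial hits,
paralog cross-matches, identity < 100%), e-value structure, codon-usage
realism, alternative splicing in the alternate annotation, split or
overlapping mis-annotations other than fusion, and RNA-Seq evidence. On
real inputs the filters inherit the error characteristics of the external
search tool, and candidates remain candidates: the published workflow's
manual curation step ("chimeric" / "not chimeric" / "unclear") is out of
scope here.

## Numerical and degenerate-input choices

* Medians use the standard even-count mean-of-central-values rule.
* All threshold comparisons are strict exactly where stated above; the
  boundary behaviour (median exactly 0.60 rejected, bit score exactly 200
  dropped, $e = 10^{-30}$ dropped, log2 ratio exactly 0.3 still a match)
  is pinned by tests.
* Interval shrinking uses floor rounding per end; `[5,6]` at 10% shrink
  is unchanged since $\lfloor 0.1 \rfloor = 0$.
* Empty inputs: empty interval sets cluster to zero clusters; an empty
  hit list has no median (callers must handle no-hit genes); an empty
  simulated bundle is impossible by construction
  (`n_chimeras ≤ n_genes` is validated).
* N50 is the descending prefix-sum definition; GC averages per-sequence
  percentages unweighted (pooled GC available as an option); intergenic
  distances count bases strictly between half-open gene spans, excluding
  any gene that overlaps another gene on any strand *before* adjacency is
  formed.
* Spearman correlation is midrank-based (`stats::cor`), with constant
  vectors rejected rather than returned as `NA`.
* Hit-table round trips are bit-exact in the coverage dialect: floating
  columns are written with 17 significant digits.

## Problem sizes used in the shipped checks

The test suite and the reproduction script run entirely on simulated
data: bundles of 8–60 genes with 1–10 planted chimeras across all
component counts 2–6, 1,000 random interval sets (n ≤ 20, coordinates
≤ 500) against a brute-force transitive-overlap oracle, 1,000 random
length multisets against a brute-force N50 scan, and 100 simulated
chimeric queries for the coverage-signature screen. These sizes were
chosen so each property is exercised across its full combinatorial range
while a complete run stays in the minutes range on a single core.

## Known limitations

* Detection requires informative database hits; gene families absent from
  the trusted database are invisible to the screen.
* A fusion of components matching the *same* database protein produces
  distinct clusters only if the alignments occupy distinct query spans;
  tandem fusions of near-identical paralogs hit by one homolog are the
  hard case, partially covered by the repeated-interval policy.
* The subset filter assumes the alternate annotation's hits are drawn
  from the same database; mixing databases between the two searches
  invalidates it.
* Component counts are estimated from hit clustering and can undercount
  when components share homologs, or overcount for multi-domain proteins
  with independently matching domains — the reason candidates are ranked
  for inspection rather than auto-split.
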