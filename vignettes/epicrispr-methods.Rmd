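---
title: "Methods: multicopy CRISPR sites, chromatin annotation and editing outcomes"
author: "epicrispr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multicopy CRISPR sites, chromatin annotation and editing outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicrispr)
```

# The problem and the design

Whether CRISPR–Cas9 cuts and how the break is repaired depends not only
on the 20-nt target sequence but on the chromatin it sits in. Comparing
editing across *different* sequences confounds the two. The design this
package supports holds sequence fixed: find target sequences that occur
at several genomic loci (multicopy sites), annotate each copy's
chromatin context, measure editing at each copy, and associate the two.
Everything from target discovery to association statistics is
implemented here, along with a synthetic-data generator that plants
known families, chromatin contexts and editing outcomes so every stage
can be verified against ground truth.

# Site discovery

`scanPamSites()` enumerates every position on both strands where a
20-mer is immediately followed by NGG. Distinctness is by the literal
23-mer (protospacer + PAM): a sequence and its reverse complement are
separate catalog keys, because Cas9 targeting is strand-specific.
Windows containing non-ACGT bases are excluded — an ambiguous base
cannot be targeted. Minus-strand occurrences are stored with
forward-strand coordinates and strand `-`, so slicing the genome at any
occurrence (reverse-complementing for `-`) reproduces the catalog key
exactly; this invariant is property-tested, and the whole scanner is
tested for exact equality against a naive enumerate-all-windows oracle
on random genomes.

`filterCascade()` applies the candidate filters:

* **copy range** 7–25 occurrences (inclusive), counted on nuclear
  chromosomes only;
* **simple motif**: any homopolymer run of 5 or more bases in the
  protospacer fails;
* **GC content** within 40–60 %. The bounds are inclusive: the removal
  rule targets content *outside* the band, so 40 % and 60 % stay. On a
  20-nt protospacer these are exactly 8 and 12 G/C bases, so the test
  is integer-exact and needs no floating-point tolerance;
* **organellar presence**: a 23-mer found anywhere in a declared
  chloroplast/mitochondrial contig (either strand) fails. Organellar
  sequences never contribute to copy counting — the rule is a separate
  removal filter;
* **restriction overlap**: a candidate is kept only if some restriction
  motif occurrence (IUPAC-expanded, either strand, within the 23-mer)
  covers protospacer base 17 or 18. Cas9 cuts between positions 17 and
  18, so an indel there destroys the site and the locus can be
  genotyped by digestion (CAPS). "Covers 17 or 18" is the deliberate
  reading of overlap with the 17–18 boundary: an indel at the cut
  disrupts any motif touching either flanking base. A table of common
  commercial enzymes ships in `inst/extdata/` and is fully
  configurable; final candidate counts on a real genome depend on the
  enzyme list used, so no specific count is claimed.

The filters are independent predicates; the survivor set is therefore
order-invariant (tested). For reporting, the cascade also records the
first failing filter per sequence and the count surviving each stage.
By default the two expensive predicates (organellar and restriction)
are evaluated lazily, only for sequences that pass the cheap ones;
`lazy = FALSE` evaluates everything for order-invariance checking.

`selectMCsiteFamilies()` applies the chromatin-diversity criteria for a
usable family: members must span open *and* closed chromatin, at least
three methylation-domain labels, and at least two chromatin-state
labels (states are consumed as a pre-made interval annotation; no HMM
is recomputed here).

# Chromatin annotation

**Windowed methylation.** `windowMethylation()` tiles chromosomes into
non-overlapping 100-bp windows and computes the *weighted* methylation
level per context: Σ methylated reads / Σ total reads over all
cytosines of that context, both strands combined. Weighting by read
count (rather than averaging per-cytosine fractions) is the standard
convention for plant methylomes and is robust to uneven coverage; it is
also exactly what the synthetic generator's truth is expressed in, so
the recovery tests are sharp. A context with zero coverage in a window
is undefined (NA) and the window is flagged rather than guessed.

**Domain classification.** `classifyDomain()` maps (mCG, mCHG, mCHH) to
one of five labels with an explicit precedence:

1. unmethylated — all three < 10 %;
2. RdDM — mCHH ≥ 15 %;
3. heterochromatin — mCG > 40 % and mCHG > 40 %;
4. CG-only — mCG > 40 % with mCHG < 10 % and mCHH < 10 %;
5. intermediate — everything else with data.

The published threshold rules overlap (a window can satisfy both the
RdDM and heterochromatin conditions, and CG-only as stated would be a
subset of heterochromatin). Two decisions resolve this: RdDM precedes
heterochromatin because RdDM is defined by its CHH component, and
CG-only additionally requires low mCHG and mCHH — without those
ceilings CG-only and heterochromatin would be ambiguous. With this
precedence the five labels partition the unit cube, which is verified
over a dense grid. A site's domain is that of the single 100-bp tiling
window containing its cut site.

**Accessibility and features.** A site is open iff ≥ 1 bp of an ATAC
peak overlaps its 23-mer interval (half-open intervals; abutment is not
overlap). Feature tracks (bedGraph) are averaged over 1-kb windows —
500 bp each side of the site center, taken as the floor midpoint of the
23-mer — with partially overlapping intervals contributing pro rata and
missing coverage counting as 0; the computation is tested against a
per-base expansion oracle and is invariant to splitting bedGraph
intervals. Features are min–max normalized per column to 0–1 (constant
columns map to 0 with a warning) so heterogeneous assays are
comparable; per-base methylation across the 23 positions of a site is
reported on a 0–100 scale.

# Indel profiling

`ampliconSpec()` locates the protospacer in a reference amplicon
(either strand) and fixes the cut junction 3 bp 5′ of the PAM.
`alignReads()` is a global Needleman–Wunsch/Gotoh aligner (implemented
in C++): match +1, mismatch −1, a gap of length L costs 1 + L, N is
neutral. Traceback preference is fixed, and every indel is then
left-normalized — shifted to its leftmost equivalent placement — so
edit scripts are canonical and deterministic. Unit-magnitude costs keep
a substitution cheaper than an insertion–deletion pair, so sequencing
errors are never explained away as indels. `Biostrings`'
`pairwiseAlignment` under the same scoring scheme serves as an
independent cross-check of alignment scores in the test suite. Reads
with characters outside A/C/G/T/N or length outside 0.5–1.5× the
reference are discarded (and counted).

`classifyAllele()` quantifies within a window of half-width `w = 10` bp
around the cut (configurable). No quantification window is printed in
the source method; 10 bp captures deletions up to the > 10 bp class
around the cut while excluding distal artifacts. A read is edited iff
it has an insertion or deletion overlapping the window; substitutions
never count as edits. Classes: `ins1` (+1 bp) for a net single 1-bp
insertion with no deletion; deletion alleles binned by *total* deleted
length into Δ1–5, Δ6–10, Δ>10 (an allele with both an insertion and a
deletion is binned by its deleted length); rare pure multi-bp
insertions go to an `ins_other` overflow class excluded from the four
printed classes so they cannot silently inflate +1 bp.

`profileAmplicon()` keys alleles by their indel signature inside the
window, so substitution errors do not fragment alleles. The overall
indel frequency (edited / classified × 100) is computed with **no**
allele threshold; the 2 % allele-share threshold applies only to
mutation-profile composition (class distribution and insertion rate),
matching the role the threshold plays in profile extraction. The share
is measured against total classified reads (the ambiguous alternative —
share of mutant reads — is configurable via `threshold`).
`normalizeFrequency()` divides a site's indel frequency by the
same-replicate frequency of a single-copy euchromatic control target
(× 100; values above 100 are legitimate), and `foldChange()` reports
high/low ratios to two decimals.

# Association statistics

`assignGroups()` runs one-way ANOVA across the sites of a family,
then Tukey HSD at α = 0.05, and sweeps sites sorted by descending mean
into homogeneous subsets: a site joins the current subset while it is
non-significantly different from *every* member, and the first
significant pair closes the subset. This disjoint sweep is a documented
choice — with chained non-significance, classic homogeneous subsets can
overlap, and a partition is needed for labeling. Subsets map to H/M/L
by descending mean (1 subset → all M; 2 → H and L; > 3 → middle subsets
all M).

`correlate()` reports Spearman's R with average ranks on ties and a
two-sided P from the t approximation, per feature, with a
Benjamini–Hochberg q column emitted alongside the raw P for
transparency (raw P is the primary report). Efficiency correlations
default to replicate-level observations and insertion-rate correlations
to site means; published correlation P-values are numerically
consistent with replicate-level points for efficiency but site-level
points for insertion rate, which is why both levels are supported.
`clusterFeatures()` uses average-linkage agglomerative clustering on
Euclidean distances over the 0–1-normalized matrix — linkage and
distance are not printed in the source method; this combination is
deterministic and scale-comparable. `compareConditions()` is a
two-sided Mann–Whitney U per site (exact for small untied samples,
normal approximation with tie correction otherwise) plus the fold
change of condition means, and `kruskalWallis()` is the standard
tie-corrected H test; with two groups it agrees with the Mann–Whitney
normal approximation exactly, which is verified numerically.

# The synthetic-data generator

`genomePlan()`/`buildGenome()` make i.i.d.-background chromosomes with
configurable GC (default 0.36, a plant-like genome average) and plant
23-mer families at non-overlapping loci; accidental extra copies of any
planted 23-mer are rejection-sampled out of the background, so planted
occurrence counts are *exact* and scanner acceptance can demand
equality. `simulateMethylation()` emits per-cytosine binomial calls on
both strands realizing planned window levels (read depth 100 by
default; at depth 200 a window recomputation is within ±0.05 of plan,
the binomial bound used in tests). `simulateTracks()` tiles planned
regions into bedGraph bins with optional Gaussian noise.
`simulateAmpliconReads()` draws reads by outcome class; +1-bp alleles
insert at the cut (templated = duplicating the base 5′ of the cut,
mirroring staggered-cut fill-in; or a fixed base), deletions remove a
block straddling the cut with sizes drawn from a small per-bin
candidate set (defaults: 1–5, 6–10, {12, 15}) and, by default,
*anchored* placement — each size is one recurrent allele, reflecting
the concentration of real per-site repair outcomes on a few alleles;
uniform-random placement is available (`placement = "random"`).
Substitution errors (≤ 5 %) are applied after editing, and a truth log
records every read's class.

What the generator does **not** emulate: read-quality structure,
bisulfite conversion error, paired-end overlap (reads are pre-merged),
PCR duplicates/jackpots, microhomology-dependent deletion spectra, or
translocations/large deletions beyond the amplicon. Passing tests
therefore certify the pipeline's bookkeeping and statistics on clean
ground truth, not robustness to those artifacts.

The demo (`runDemo()`) plants two 8-copy families whose copies span
unmethylated-open, CG-only, RdDM and heterochromatic contexts, with
editing efficiency planted monotone in accessibility (0.75 down to
0.003 — a 250-fold contrast) and insertion share planted monotone in an
H3.1-like feature. Replicate-to-replicate Cas9-expression variation is
emulated as a shared lognormal factor that cancels under control
normalization, as it would in the real assay. A 20-bp cassette
containing CG, CHG and CHH cytosines is written into each cut-site
window so window methylation is always defined in all three contexts
regardless of the random background.

# Problem sizes and numerical choices

The test suite runs the scanner oracle on 100 random genomes of 0.5–3
kb, the domain-partition check on the 101³ grid (step 0.01), indel
truth recovery at 10,000 reads per mix (error 0 and 1 %), the null
correlation calibration at n = 45 with 1,000 simulations, and the demo
at 300–600 reads/site; the acceptance script runs the demo at 10,000
reads/site. These sizes give binomial/multinomial standard errors well
inside the stated tolerances (≤ 0.6 pp per class at 10,000 reads).
At n = 45 the large-sample standard deviation of a null Spearman R is
≈ 0.15, so the |R| < 0.3 calibration bound sits near the 95.3 %
quantile — the 95 % requirement is intrinsically tight, not a package
artifact. Degenerate inputs are explicit: zero-coverage methylation
contexts are NA and flagged, constant features normalize to 0 with a
warning, a zero-frequency control leaves normalization undefined for
that replicate, and all-tied condition comparisons report P = 1.

# Limitations

Occurrence counting is exact-match only (no mismatch-tolerant
off-target logic); the indel caller handles merged amplicons with
simple affine-gap alignment and does not quantify substitution editing
or HDR; chromatin states are consumed, not computed; and association
analyses are correlational — no causal or mixed-effects modeling of
plant-to-plant variation is attempted.
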