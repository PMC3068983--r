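---
title: "Methods: measuring cross-species retention of TF binding sites"
author: "tfretain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring cross-species retention of TF binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfretain)
```

## The question and the model

Two transcription factors central to adipocyte biology, C/EBPα and
PPARγ, bind tens of thousands of genomic sites in both mouse and human
fat cells, yet the individual sites are mostly species-specific. This
package operationalises "retention" of a binding site — presence of
detectable binding in the *orthologous region* of the other species,
which is distinct from conservation of the DNA itself — and asks which
features of a site predict it.

The unit of analysis is a ChIP-seq peak ("site"), a 100–400 nt region
that is much wider than the 5–20 nt sequence element actually bound.
All coordinates are 0-based half-open (BED convention); widths are
`end − start`; midpoints are `floor((start + end) / 2)`, so odd widths
round down and every midpoint is a real base of the interval. Ties in
any midpoint-distance comparison resolve toward the smaller coordinate.
ChIP tags are single genomic positions (the tag's 5′ position as given
in the input file); no fragment extension or strand shift is applied,
and strand is ignored for sites — the alternative (midpoint or
full-fragment counting) is not identifiable from peak-level inputs, so
the simplest convention is used and stated.

### Orthology mapping

Sites are carried between genomes through alignment chains (UCSC chain
files or an equivalent block table). A lift succeeds when exactly one
chain covers at least one base of the site and the covered fraction
reaches `min_match = 0.1`, the permissive setting appropriate for
rodent–primate distances; the lifted span runs from the image of the
first to the image of the last covered base, so indels inside a site
stretch or shrink the span rather than failing it. "Uniquely mapped" is
operationalised as *exactly one chain covering ≥ 1 base*: this mirrors
the single-hit behaviour of the standard liftover tool without
re-implementing its netting, and it is deliberately strict — a second
chain covering even one base makes the site `ambiguous`. A mapped site
must then survive the reciprocal test: the lifted span is lifted back,
the back-lift must itself be unique, and the back-image must overlap at
least `back_overlap_frac = 0.90` of the original site. Whole-site loss
by large deletion is out of scope; such sites simply fail the lift.

### Two retention measures

**Binary.** A mapped site is retained when some site in the target
species overlaps *strictly more than* `retention_frac = 0.10` of the
lifted span, or the lifted span overlaps strictly more than 10% of the
target site ("either way" — a small peak inside a wide span counts).
The strict boundary follows the defining wording of the rule; note the
co-binding thresholds below are inclusive, equally by their wording,
and the package follows each literally rather than harmonising them.

**Enrichment.** Peak calling imposes thresholds and an on/off view of
binding. The complementary measure counts target-species tags in a
fixed window centred on the lifted span midpoint and compares with a
random expectation: `log2((obs + 1) / (exp + 1))`, pseudo-count 1
guarding small counts. The window width is the 75th percentile of the
target species' peak widths per factor (520 nt C/EBPα, 605 nt PPARγ on
the real data; recomputed from data when sites are supplied). Windows
of width `w` centred on `c` are `[c − floor(w/2), c − floor(w/2) + w)`,
putting the extra base of an odd window on the right. The expectation
is the mean count over `n_random_regions = 2000` windows whose centres
are uniform over the genome (chromosome chosen proportionally to
length, centre constrained so the window fits). One seeded random
sample is drawn per factor/width and shared across sites: the
per-site values stay comparable and every run is reproducible; the
seed is an explicit argument.

**Turnover.** A lost site whose lifted midpoint lies within
`turnover_max_dist = 10000` nt (inclusive) of a *target-species-specific*
site of the same factor — one failing the 10% either-way overlap against
every lifted site — is a turnover event: regulation plausibly retained
through a repositioned site.

Fate classification (`classify_fates()`) decides `retained` against the
union of both factors' target sites and records which factors matched in
`retained_as`. This keeps the invariant "`retained_as` non-empty iff
retained" and directly supports the cross-factor retention classes
(a mouse C/EBPα site found as a PPARγ-only site in human); same-factor
retention fractions are recovered by filtering `retained_as`.

### Associating sites with genes

A site is labelled with the expression cluster (1 = downregulated,
2 = transiently upregulated, 3 = moderately upregulated, 4 = highly
upregulated) of the *closest clustered* TSS within
`cluster_window = 100` kb of its midpoint — an unclustered gene nearer
by does not win; with genes in range but none clustered the site is
"constitutive" (5), with no TSS in range "distal" (6). The alternative
closest-gene-wins rule is available behind a flag since both give very
similar pictures. Gene orthologs are found by lifting TSS ± 50 nt and
pairing with the nearest target TSS within 5 kb; distance boundaries
are inclusive throughout.

### Sequence correlates

Consensus sites are PWM hits. Count matrices (JASPAR PFM format) become
log2-odds against a uniform background with a Laplace pseudo-count:
`f = (count + 0.25) / (colsum + 1)`, `logodds = log2(f / 0.25)`. The
original scanning tool's internals are unspecified, so this standard
pseudo-count is the package's own documented choice; any monotone
variant preserves the threshold semantics, which are defined on the
*score range*: a hit is any window on either strand scoring at least
`min + 0.80 · (max − min)`. Windows containing non-ACGT characters are
skipped. `threshold_sweep()` reports the bound-vs-random separation
across threshold fractions as a diagnostic; the 0.80 default is fixed,
not auto-selected. The two bundled PFMs are **synthetic**
consensus-shaped stand-ins (files prefixed `synthetic_`), not database
matrices; they exist so simulation and tests are self-contained.

Sequence identity of an aligned region pair is
`#identical columns / min(len1, len2)` over the ungapped lengths,
case-insensitive — by construction it can exceed the matching fraction
of the longer sequence.

### Statistics

Group contrasts on retention use the two-sided Fisher exact test with
the probability-ordering definition of two-sidedness (the common
convention; tested against full hypergeometric enumeration on every
2×2 table with N ≤ 40). Continuous measures use the Wilcoxon rank-sum
test: exact by enumeration with midranks for `n ≤ 12`, otherwise the
normal approximation with tie-corrected variance and continuity
correction; degenerate inputs (zero rank variance) return p = 1 rather
than NaN. Quantiles everywhere — width filters, violin hinges,
enrichment windows — use linear interpolation between order statistics
(R type 7); quartile groupings rank with stable tie-breaking and cut
into near-equal groups, larger groups first. Raw p-values are reported;
a Benjamini–Hochberg column accompanies them for transparency but gates
nothing.

## What the synthetic generator emulates

`generate_fixture()` writes a complete miniature study in the real file
formats (BED, chain blocks, TSV, FASTA), which the pipeline re-reads —
format I/O is exercised, never bypassed. It emulates the *statistical
structure* the methods assume:

* two coordinate spaces linked by chains with unalignable segments,
  insertions/deletions between sites, and duplicated segments that lift
  ambiguously;
* two factors' site sets with a planted co-binding fraction and exact
  per-factor counts of planted fates (largest-remainder apportionment,
  so measured fractions equal planted fractions up to ±1 site);
* Poisson tag tracks: background `λ_bg` per nt plus `Poisson(strength)`
  tags per site;
* genes in clusters with an optional placement bias of cluster-3/4
  genes toward retained sites (the retention-near-upregulated-genes
  association; the fate *fractions* are unaffected);
* region sequences with planted consensus words (sequences are redrawn
  until chance hits are absent, so motif flags have exact ground truth)
  and mouse counterparts mutated to per-fate identity targets by an
  exact substitution count.

Sites are laid out in fate zones — retained, turnover, human-gain, and
lost/unmappable — separated by 25 kb. This zoning is what makes the
construction guarantees simultaneously satisfiable at realistic density
(2000 sites per factor on 2 × 5 Mb): retained sites always have a
same-factor partner overlapping ~70% of their true image; turnover
sites have a human-specific site planted 2–8 kb from the image midpoint
and nothing overlapping; lost sites have no human site within 20 kb.
Site widths come from the discrete set {150, 200, 250, 300, 350} nt
(the realistic peak-width range): because well over 5% of sites share
the top width, the 95th width percentile equals the maximum and the
routine 5% width filter removes nothing from a clean fixture — planted
guarantees survive the full pipeline rather than being eroded by a
filter the fixture does not need.

Defaults are the study conditions: 36% co-binding (the high-confidence
mouse overlap), 75% of sites mappable (20% unalignable + 5%
ambiguous, near the reported 56–63% mapping rates), fates retained
0.2 / turnover 0.1 / lost 0.7 (the reported ~17–20% retention),
human site strength 32 tags against a 4-tag background per 520-nt
window (the enrichment calibration point `log2(33/5) ≈ 2.72`), identity
targets 0.8 / 0.7 / 0.6 by fate.

What it does **not** emulate: genome composition (GC, repeats),
read-level error, peak-width/strength correlations, overlapping or
nested peaks beyond the planted pairs, negative-strand chains (the
mapper supports them; fixtures stay on +), and any dependence between
fate and width or strength. Passing the recovery tests therefore shows
the *pipeline arithmetic* is right under the stated model — not that
the biological conclusions transfer to any particular real dataset.

## Numerical choices and degenerate inputs

* Boundary semantics follow each rule's wording: co-binding thresholds
  inclusive (≥ 1%, ≥ 10%, ≥ 1 nt), retention strict (> 10%), turnover
  inclusive at exactly 10 kb, distance windows inclusive.
* Lift failures are statuses (`unaligned`, `ambiguous`,
  `below_min_match`, `failed_reciprocal`), never exceptions; callers
  must filter to `mapped` before retention/enrichment, and get an error
  otherwise.
* Zero-margin 2×2 tables return p = 1 with a warning; empty violin
  groups and empty gene sets are errors; a report stratum with n = 0
  reports a blank fraction, never divides by zero.
* Every stochastic step (random windows, the generator, tag
  simulation) takes or derives from an explicit integer seed; reruns
  are byte-identical, which the test suite asserts file by file.

## Problem sizes

The shipped tests run the full default fixture (2 chromosomes × 5 Mb,
2000 sites per factor, 400 genes) through generation and the complete
pipeline twice for the determinism check, three 2000-site fixtures for
planted-retention recovery, an exhaustive Fisher sweep over all 2×2
tables with N ≤ 40, 1000 null cross-tabulations for test-size
calibration, and 500 random sequences for scanner/oracle equivalence —
sizes chosen so the whole suite completes in a few minutes on one CPU
while leaving every check at full strength.

## Known limitations

* The analysis direction is mouse → human; human-specific gains appear
  only through the gained-site counts, and gain modelling is out of
  scope.
* Binding "strength" is the tag count stored on a site (input column 5
  or a planted value); no normalisation between factors or experiments
  is attempted.
* The liftover re-implementation matches the standard tool's contract,
  not its netting internals; on real chain files with heavily nested
  chains the `ambiguous` class can be stricter than the original
  tool's.
* PWM hit sets depend on the pseudo-count convention; the 80%-of-range
  threshold semantics are preserved under any monotone rescaling, but
  exact hit lists may differ from other scanners.
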