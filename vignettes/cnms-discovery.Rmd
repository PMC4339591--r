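---
title: "Discovering conserved non-coding microsatellite (CNMS) markers"
author: "cnmscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering conserved non-coding microsatellite (CNMS) markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnmscan)
```

## The method

Microsatellites (SSRs) in the 5' upstream regulatory regions (URRs) of
protein-coding genes are attractive genetic markers: repeat-length
variation in a transcription-factor binding site (TFBS) can alter gene
expression, so such markers are both highly polymorphic and functionally
informative.  A *conserved non-coding microsatellite* (CNMS) is an SSR in
the URR of a gene that satisfies three conditions simultaneously:

1. **SSR** — it is a perfect tandem repeat of a 1--6 nt unit passing the
   mining thresholds;
2. **regulatory-element co-localization** — the tract intersects a match
   of a known regulatory-element signal consensus (e.g. the `(GA)8`
   signal of GAGA8HVBKN3, or `CAACA` of RAV1AAT);
3. **conservation** — the SSR+element composite lies wholly inside a
   non-coding segment conserved in the URR of an orthologous or
   paralogous gene of at least one comparator species.

`cnmscan` implements each condition as a separate, independently tested
detector, combines them into marker calls, designs flanking PCR primers
so that amplicon length tracks repeat variation, and computes the survey
statistics used to characterize marker panels (positional histograms,
physical density, polymorphism percentages, PIC, linkage-map spacing).

All coordinates live in two frames: 1-based inclusive *string positions*
on the stored upstream sequence (whose last base is immediately 5' of
the ATG), and the *ATG-relative frame* in which position 1 is the base
next to the ATG and positions grow moving away from the gene.  For an
interval $(i, j)$ on a string of length $L$ the ATG-relative interval is
$(L - j + 1,\; L - i + 1)$; the transform is its own inverse.

## SSR mining

`findSSRs()` reports every maximal perfect run of a primitive 1--6 nt
unit.  A run that could be written with several unit sizes (`(GAGA)n` is
also `(GA)2n`) is reported once with the smallest unit, anchored at the
earliest phase; runs are broken at `N`; the reported tract is trimmed to
complete units, so `tract_bp == unit_size * repeat_count` always holds.

Two independent thresholds gate the report (`ssrThresholds()`): a
per-unit-size minimum repeat count (defaults 10/6/4/3/3/3 for unit sizes
1--6) and a minimum tract length (default 12 bp).  The defaults are
deliberately more permissive than classic MISA settings so that every
repeat class seen among validated chickpea CNMS markers — down to
`(AG)6`, `(TTCT)3` and `(AAG)4` — is discoverable; both knobs are
user-visible.  Compound or interrupted repeats are *not* modelled: the
markers this pipeline targets are perfect runs.

Tracts of at least 20 bp are class I ("hypervariable"), 12--19 bp class
II — the standard convention for SSR marker panels; shorter tracts are
kept internally as `sub12` but excluded from marker calling by default,
as are mononucleotide runs.

The miner is validated against a brute-force oracle that re-derives loci
by per-position character comparison: exhaustively on *all* strings over
`{A,C,G}` up to length 8 (≈9,800 strings — every branch of the
maximality, primitivity and phase logic is reachable at that size), and
on seeded random strings up to 500 nt containing `N`s and spiked-in
tracts.

## Element scanning

Signal consensi are IUPAC strings, optionally in repeat notation
(`(GA)8`); `readElementLibrary()` expands them on load.  Matching is
exact-degenerate: a consensus letter matches exactly the base set it
denotes, no mismatches are allowed, and both strands are scanned
(minus-strand hits are reported in plus-strand coordinates).  One
deliberate asymmetry: a sequence `N` matches *only* a consensus `N`.
Masked or ambiguous stretches therefore never spawn element hits — the
conservative choice, since a spurious hit inside an N-run could promote
a repeat to marker status.

All overlapping occurrences are reported.  Marker calling only needs
"does some hit of this element intersect the tract", so duplicates are
harmless, and reporting them keeps the scanner trivially comparable to
its per-position oracle.

The package ships a five-element PLACE-style fixture library
(`cnmsElements()`): GAGA8HVBKN3 `(GA)8`, CTRMCAMV35S `TCTCTCTCT`,
RAV1AAT `CAACA`, S1FBOXSORPS1L21 `ATGGTA`, CANBNNAPA `CNAACAC`.  Real
screens should supply their own library (hundreds of elements in
PLACE/PlantCARE/TRANSFAC exports); the library is a plain two-column
TSV.

## Conserved-block detection

`detectCNS()` finds ungapped conserved segments between two upstream
sequences by seed-and-extend: every exact `seedK`-mer (default 8)
shared by the two sequences anchors a diagonal; from each seed the
block grows one base at a time — right first, then left — accepting a
base only while the *running identity* of the grown block stays at or
above `minIdentity` (default 0.70); leading and trailing mismatches are
then trimmed so blocks end on matches, and blocks shorter than `minLen`
(default 20 bp) are dropped.  Overlapping blocks on one diagonal are
resolved by keeping the longer block, then the higher identity, then
the smaller target start.  `N` never matches.

Choosing greedy extension over enumerating all maximal
identity-qualifying segments is a design decision worth spelling out:
with a "maximal segment" semantics, two strong segments joined by a
weak bridge merge under a loose identity floor and split under a strict
one, so tightening the floor can *create* blocks — an unintuitive
non-monotonicity.  Greedy extension stops at the bridge, behaves
monotonically in the useful sense (raising `minLen` filters the same
set; raising `minIdentity` yields blocks nested inside the looser
ones — both are asserted as properties), and is directly testable: the
suite re-derives blocks with a naive per-seed, per-character oracle and
requires exact agreement for all pairs up to 50 nt.

Ungapped extension is itself a simplification: the alignment-plot
methods used for genome-scale conserved non-coding sequence (CNS)
screens tolerate indels.  For the CNMS use-case only the question "is
this composite inside a conserved segment" matters, upstream windows
are short (1 kb), and the ungapped model keeps every reported block
exactly re-checkable from the raw sequences (`identity ==
matches/length` is asserted on every block).

**Support rule.**  A comparator species supports a locus only if one of
its blocks *fully contains* the composite interval
(`conservationSupport()`).  Containment rather than mere overlap is
required because the claim behind a CNMS is that the regulatory element
itself is conserved, not merely nearby sequence.  Self-species paralogs
are legitimate comparators.

## Marker calling and summaries

`callCNMS()` emits one marker per (SSR, element) pair for which some hit
of that element intersects the tract by at least `minOverlap` bp
(default 1 — the weakest faithful reading; validated marker tables show
full nesting) and the composite interval (union span of the tract and
that element's overlapping hits) has non-empty conservation support.
Multiple hits of one element collapse into a single marker with the hit
count kept as metadata; marker ids are assigned serially in (gene,
position) order so reruns are bit-identical.

`binPositions()` histograms markers by the midpoint of their composite
interval in the ATG-relative frame, default 100-bp bins over a 1000-bp
window.  The midpoint (rather than the start) is used because it is
symmetric under the two coordinate frames' reflection.  `markerDensity()`
reports span/markers in kb to one decimal.

## Primer design

`designPrimers()` searches the flanks of the composite for a forward /
reverse pair under hard constraints (`primerConstraints()`): product
size 100--300 bp spanning the locus, primer length 18--24 nt, GC
fraction 0.40--0.60, melting temperature 50--62 °C, 3'-end
self-complementarity at most 4 nt, and each primer occurring exactly
once in the template.  Neither primer may overlap the locus, which
yields the property the markers exist for: expanding the repeat by $k$
units grows the amplicon by exactly $k \times$ unit size bp (asserted
as a test).

Melting temperature uses the standard two-regime convention: the
Wallace rule $2(A{+}T) + 4(G{+}C)$ below 14 nt and
$64.9 + 41\,(n_{GC} - 16.4)/L$ from 14 nt on.  Published annealing
temperatures for validated markers come from empirical optimization and
are not reproduced.  Among all qualifying pairs the one with product
size closest to 200 bp (the window midpoint) is returned; ties fall to
the smaller product, then the leftmost forward primer, then shorter
primers — a total order, so the designer is deterministic.

## Marker statistics

`pic()` implements Botstein's polymorphism information content, the
definition used by PowerMarker:
$PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$ over allele
frequencies estimated from non-missing calls.  Closed-form anchors
(0 for monomorphic, 0.375 for two equifrequent alleles, 0.703125 for
four) and the bound $PIC < 1 - \sum p_i^2$ are asserted.

`summarizeMap()` computes per-linkage-group average intermarker
distance as map length divided by marker *count* (not count minus one):
the bundled eight-chromosome example table's total row (766.9 cM / 238
markers = 3.22 cM) fixes that convention.  Percentages and spacings are
rounded half-up (1 decimal for percentages, 2 for cM) — base R's
round-half-even disagrees with how such tables are reported.  A few
cells in published tables of this kind are internally inconsistent at
the second decimal under any rounding rule; the tests assert only
self-consistent cells.

`constituteHaplotypes()` treats individuals as homozygous inbred lines:
a haplotype is the ordered tuple of allele codes across one gene's
markers; heterozygous calls are an error by design.

## The synthetic test bed

Real CNMS screens need several annotated genomes and a large element
library; those inputs cannot ship with a package.  Instead
`simulateUpstreamSet()` generates the full input bundle with known
truth: 1000-bp upstream windows at GC 0.38 (AT-rich plant promoter
composition), a configurable number of genes carrying a planted
SSR+element composite (e.g. `(GA)12` containing the `(GA)8` signal),
six comparator species of which three carry a copy of the
composite ± 30 bp of flank with 10% point substitutions applied *only
to the flanks*, and decoys for each failure mode of the CNMS predicate:
SSR without element, element without SSR, and composite without
conservation.

The generator *constructs* the guarantees its truth table states rather
than hoping for them: repeat-breaking bases are placed at both tract
edges so planted coordinates are exact; comparators that must not
support a locus are redrawn until they share no 8-mer with the
composite neighbourhood, so no seed can anchor an accidental supporting
block; and each planted neighbourhood is rescanned and redrawn until it
is free of accidental SSR/element co-occurrences.  Those rescans use
the package's own miner and scanner — defensible because both are
independently oracle-tested, but it does mean the end-to-end test is
not evidence about *their* correctness, only about the calling logic.

What passing the planted-recovery test shows, and what it does not: on
backgrounds satisfying the construction (i.i.d. composition, no indels
between conserved copies, mutation rate below `1 - minIdentity`),
recovery of qualifying composites is 100% and decoy emission 0% across
20 seeds.  Real promoters violate i.i.d. in interesting ways — CpG
structure, TA-rich stretches, nested and interrupted repeats,
insertions inside conserved regions — so field results depend on
parameter choices in ways the simulation deliberately does not probe.

## Problem sizes and numerical choices

The shipped test suite uses: the exhaustive `{A,C,G}` sweep to length
8; 200 seeded strings to 500 nt for the SSR oracle; 20 scanner cases to
1 kb; 40 sequence pairs to 50 nt for the conservation oracle; 20
simulation seeds (10 genes, 6 comparators each) for end-to-end
recovery; identity comparisons use a $10^{-9}$ slack so prefix-sum
arithmetic never flips a boundary case.  These sizes were chosen as the
smallest at which every code path and boundary is exercised with slack
to spare.

## Limitations

* Gapped conservation is out of scope; an indel inside a conserved
  region splits or shifts blocks and can cost containment.
* Element matching is presence/absence; no position-weight-matrix
  scores, no mismatch tolerance, and no over-representation statistics.
* Primer screening covers hard constraints only — no full
  thermodynamic dimer/hairpin model, no multiplexing.
* Linkage-map construction, QTL/eQTL mapping, association and
  population-structure analyses are consumers of these markers, not
  part of the package.

## A worked run

```{r example, eval = FALSE}
sim <- simulateUpstreamSet(simConfig(seed = 42))
res <- runDiscover(sim$target, sim$comparators, sim$orthology,
                   sim$elements)
res
cnmsMarkers(res)[, c("marker_id", "gene_id", "unit", "repeat_count",
                     "ssr_class", "element", "n_supporting")]
```
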