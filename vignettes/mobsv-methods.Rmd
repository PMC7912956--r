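---
title: "Detecting IS transposition and large deletions from paired-end reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting IS transposition and large deletions from paired-end reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobsv)
```

## The detection problem

When a bacterial strain is resequenced against its ancestor's reference,
point mutations and small indels are the province of standard short-variant
callers. Structural changes larger than a read — insertion-sequence (IS)
transposition events and multi-hundred-base deletions — leave no clean
base-level signal, but they reshape the *geometry* of paired-end data in two
characteristic ways:

* **Insertions break pairs.** A read that crosses the junction between host
  sequence and a newly inserted element matches the reference nowhere, so it
  goes unmapped — or, if it lies fully inside the element, it maps to another
  copy of that element elsewhere. Either way its mate still maps uniquely
  next to the insertion point. A local excess of such "unpaired" reads,
  forward-stranded on the left flank and reverse-stranded on the right,
  pinpoints an insertion.
* **Deletions stretch pairs.** A fragment spanning sequence that the sample
  has lost maps with its two ends further apart on the reference than the
  physical fragment length: the apparent insert size is inflated by exactly
  the deleted length.

`mobsv` operationalizes both signals. It was built with zinc-adapted
*Cupriavidus metallidurans* CH34 in mind — a four-replicon β-proteobacterium
whose adaptive evolution is dominated by transposition of elements such as
IS*1088*, IS*Rme5* and IS*Rme15* — but nothing in the method is specific to
that organism beyond the bundled simulation scenarios.

## The statistical model

### Insert-size model

Concordant pairs define the null geometry. For every pair with both mates on
the same replicon in head-to-head orientation we record the outer span
(`max(end) − min(start)`, 0-based half-open). The model is deliberately
robust rather than Gaussian-fitted:

* location = median of the defined insert sizes;
* scale `sigma` = 1.4826 × MAD (consistent with the standard deviation for
  normal data);
* before either is computed, the largest 1% of inserts (`floor(0.01 n)`
  observations) are discarded. True deletion-bridging pairs live in that
  upper tail, and without the pre-trim a genome with several large deletions
  would inflate the scale and mute its own deletion signal. Median and MAD
  are barely affected when the tail is clean, so the trim costs nothing on
  null data.

A pair is **stretched** when its insert exceeds `median + k_sd·sigma` with
`k_sd = 5` by default. Five robust standard deviations leave a one-sided
normal tail mass of ~3×10⁻⁷ — about 0.03 expected false stretched pairs in a
100,000-pair library — so stretched-pair clusters are essentially
noise-free, at the price of insensitivity to deletions much smaller than
`k_sd·sigma` (which the 200-bp reporting rule excludes anyway).

### Pair classes

Every pair receives exactly one label, evaluated in this order:
`IS_ANCHORED` (one mate on a genomic replicon, one on an IS catalog entry),
`MATE_UNMAPPED` (one mapped genomic mate, one unmapped), `STRETCHED`,
`CONCORDANT`, `OTHER` (interchromosomal, inverted, both-unmapped,
both-on-catalog, or any mapped mate with MAPQ < 20). The first two classes
jointly operationalize the "unpaired read" insertion signal: at a real IS
junction, both fates occur and they carry the same positional information,
so both count as anchored support. Only `IS_ANCHORED` mates contribute to
element identification, because an unmapped mate names no element.

### Window scan and Poisson background

Anchored-mate positions are binned into 200-bp windows sliding by 50 bp,
separately per replicon and flank side (forward anchored mates support a
breakpoint to their right; reverse ones to their left). Window support `k`
is scored against `P(K ≥ k)` for `K ~ Poisson(λ)` with
`λ = window × (anchored mates on replicon / replicon length)`, floored at
`λ_min = 0.05` so that a replicon with near-zero background cannot declare
every stray mate significant. Windows pass at `α / n_windows` (Bonferroni,
`α = 0.01` family-wise); overlapping significant windows of one side merge,
keeping the best window's support, p-value and target histogram. The
survival-function form of the Poisson tail is numerically exact far beyond
any attainable significance, which matters because a 50× junction easily
produces p-values below 10⁻⁶⁰.

At 50× coverage with a 300±30 library, each flank of a true insertion
collects on the order of 40–100 anchored mates against λ ≈ 0.3 — the
defaults were sized so that a standard experiment yields at least ~15
supporting mates per flank, and the scan operates orders of magnitude away
from both error modes.

### From clusters to calls

A left-flank cluster pairs with the nearest right-flank cluster starting
within `max_gap = median + 3·sigma` downstream; the breakpoint is the
interval between the innermost window edges (collapsed to one base when the
windows overlap — paired-end evidence cannot localize a junction to a base
without split reads, so calls are intervals by design). The element is the
majority vote over the pooled mate-target histograms; ties and empty
histograms yield `"ambiguous"` rather than a guess. Significant clusters
left unpaired (replicon ends, repeat shadow) become single-sided calls at
doubled support (`2 × min_support`), trading a higher evidence bar for not
silently missing edge-case insertions.

### Deletion calls and the size estimator

Stretched pairs cluster by single linkage on their inner intervals
(gap ≤ `sigma`). Each cluster's interval is the intersection of its pairs'
inner intervals — every bridging fragment must contain the deletion — with
the bounding interval as a fallback for inconsistent clusters. The size
estimate is

```
est_size = median(cluster inserts) − model median − sigma² / (median − 2·read_len)
```

The third term corrects a length bias: a fragment bridges a deletion only if
the deletion falls in its inner gap, so bridging fragments are recruited
with probability proportional to `fragment − 2·read_len`. For a normal
fragment law this size-weighting shifts the recruited median upward by about
`sigma²/E[inner gap]` — roughly 9 bp at 300±30 with 100-bp reads, a bias
that simulation resolves clearly at 20 seeds — and the closed-form
correction removes it without reference to the true deletion size. Calls
need `min_support = 4` pairs and `est_size > 200` bp; the 200-bp floor is
the one numeric constant inherited from the experimental design this
package re-enacts (smaller indels belong to point-mutation tooling) and is
overridable.

### Reconciliation

A deletion junction breaks reads exactly as an IS junction does, so an
unreconciled pipeline would emit an element-less "insertion" at every
deletion edge. `run_pipeline()` therefore suppresses insertion calls whose
breakpoint midpoint lies within one insert-median of *any* stretched-pair
cluster — including clusters whose size estimate fell below the 200-bp
reporting rule, since a sub-cutoff deletion still breaks junction reads. The
residual risk (a true insertion within ~300 bp of an active deletion) is
accepted and documented rather than modelled.

## The simulator and what it does (not) emulate

The synthetic mobilome module exists so that every stage is testable with
exact truth and no aligner. Its fixed study conditions:

* **`table4` scenario** — four replicons (200 kb, 130 kb, 30 kb, 40 kb;
  proportions mimicking chromosome, chromid, pMOL28, pMOL30) at GC 0.61;
  seven IS insertions planted at the midpoints of genes carrying the
  adaptation experiment's locus tags and products (five IS*1088*, one
  IS*Rme15*, one IS*Rme5*); elements 1050/1200/1500 bp with 25-bp terminal
  inverted repeats and 8-bp target-site duplications (typical IS-family
  values; the source experiment reports none). Coordinates are synthetic
  stand-ins: the original study reports gene identities, not positions.
* **Library defaults** — 50× coverage, 100-bp mates, 300±30 truncated-normal
  fragments, 0.2% substitution error. The sequencing run being emulated
  published no library parameters; these are conventional Illumina
  paired-end values, chosen once and not revisited.
* **Ideal alignments** — reads are placed by coordinate lift-over through
  the truth events. A mate straddling any junction is emitted unmapped by
  default (`clip_mode = "softclip"` instead maps anchors ≥ `min_anchor`
  bases, for realism experiments); a mate fully inside an inserted element
  maps to the catalog entry. This makes round-trip invariants exact.

Deliberately not emulated: indel and homopolymer sequencing errors (the
lift-over stays exact; substitutions only), quality-score variation,
multi-mapping ambiguity from genomic repeats, chimeric fragments, and
GC-coverage bias. Consequently, passing tests demonstrate the *statistical*
behaviour of the method under clean mapping, not robustness to a real
aligner's soft-clipping or repeat handling — on real data the anchored-mate
signal arrives through the aligner's lens, and MAPQ filtering (default ≥ 20)
is the only repeat guard implemented.

## Numerical and design choices

* Coordinates are 0-based half-open internally; SAM, GFF3 and all TSV
  outputs follow their formats' 1-based conventions.
* `estimate_insert_model()` needs ≥ 500 defined inserts by default — below
  that, MAD-based scale is too noisy to set a 5σ threshold honestly.
* Poisson background floors (`λ_min`), Bonferroni over the actual number of
  scanned windows, and the survival-function tail are all chosen so the
  null simulation's false-call rate is controlled at `α` per genome.
* Element votes break *no* ties: equal top counts return `"ambiguous"`.
* Degenerate inputs: empty cluster/stretched sets return empty,
  well-typed frames; zero-length replicons, overlapping events, unknown
  elements and duplicate locus tags are rejected with informative errors.
* Determinism: one integer seed drives genome, catalog, fragment and error
  sampling; equal seeds give byte-identical FASTQ, SAM and report files.

## Problem sizes used by the test and acceptance suites

The bundled suites run the `table4` scenario at full stated conditions
(~400 kb, 100k pairs) once, and use 40–60 kb single-replicon genomes at the
same 50× coverage for the multi-seed property checks (20-seed null
specificity, 20-seed deletion unbiasedness, 10-seed gene-level
precision/recall). These sizes preserve per-event support — the quantity the
statistics actually see — while keeping a full run in tens of seconds.

## Known limitations

* Breakpoints are intervals, not bases; no split-read refinement.
* Novel (non-catalog) element discovery is out of scope: an insertion of an
  unknown element is called with `element = "ambiguous"` at best.
* Tandem duplications and insertions are not disambiguated.
* Deletion sizes rely on the insert-size excess alone; coverage-drop
  corroboration is not used.
* Insertions closer than about one insert length to each other or to a
  deletion cannot be separated by paired-end evidence at these defaults.
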