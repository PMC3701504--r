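---
title: "Assigning scaffolds to a microdissected chromosome arm from unique-read density"
author: "armAnchor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning scaffolds to a microdissected chromosome arm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(armAnchor))
```

## The problem

Sequencing DNA amplified from a laser-microdissected chromosome arm gives a
read set that is heavily enriched for one genomic region but far from pure:
whole-genome amplification (WGA) duplicates fragments unevenly and leaves
primer sequence on fragment ends, the dissection drags in off-target
material, and short reads from repetitive sequence cannot be placed. The
analytical idea armAnchor implements is that, after aggressive uniqueness
filtering, the *density of uniquely mapping reads per scaffold* cleanly
separates scaffolds belonging to the dissected arm (tens of hits per kb)
from everything else (about one hit per kb), so the read set becomes a
low-resolution physical map: previously unmapped scaffolds can be assigned
to the arm, wrongly placed scaffolds flagged for reassignment, and
misassembled "hybrid" scaffolds betrayed by large internal holes in their
coverage.

## The uniqueness filter

A read is reported only if it aligns to **exactly one** location in the
reference with at most $v$ mismatches (Hamming distance; gaps are not
considered). With the defaults $v = 2$ and read length $L = 80$ every kept
alignment has identity at least $(L - v)/L = 97.5\%$. Multiplicity decides,
not alignment quality: a read with one perfect and one two-mismatch
location is suppressed outright. This is deliberate — the statistic being
accumulated is "evidence that this scaffold position is sampled by the
dissected arm", and a read that could have come from two places is evidence
for neither. Every base compared against an `N` counts as a mismatch (in
the built-in mapper this includes `N` against `N`, a conservative choice
that matters only for references containing `N` runs).

`mapReads()` implements the filter with a pigeonhole seed index: a read
with at most $v$ mismatches over $v + 1$ disjoint segments must match at
least one segment exactly, so candidate locations come from exact k-mer
lookups (k = 26 for 80 bp reads at $v = 2$) and are verified in full, with
the search stopping at the second distinct alignment. `enumerateAlignments()`
is the brute-force reference implementation used to validate the mapper on
small instances; `ingestSam()` accepts external aligner output instead,
under either a record-count or an `NH`-tag uniqueness policy.

One accounting convention worth stating: the `mapped_any` counter is the
number of reads with at least one location within the mismatch budget,
computed on the reads as given — no primer or adapter trimming is applied
first. Where an overall "percent mapped" figure is quoted for a library,
whether trimming preceded mapping changes the denominatorless rate;
armAnchor always reports the untrimmed counters and screens primer
content separately on the unmapped fraction.

## Density, anchor calibration and classification

`scaffoldDensity()` computes hits/kb per scaffold — unique read starts
divided by the full assembled length in kb, `N` runs included, since the
published statistic normalises by scaffold length without qualification.

The on-arm threshold is not a free parameter; it is *calibrated*:

* **Anchor mode** uses a scaffold whose physical location is independently
  known (in the motivating study, a scaffold placed by in situ
  hybridisation just inside the centromere-proximal end of the arm). Its
  own density is the lowest value still compatible with an on-arm
  location, so it becomes the threshold. The comparison downstream is
  inclusive (`>=`): the anchor itself is physically on the arm and must
  pass.
* **Region-mean mode** divides the unique hits inside a designated region
  by the region length in kb — the natural calibration when the reference
  is a chromosome-scale superscaffold whose arm portion is known only
  approximately.

`classifyScaffolds()` then crosses the threshold flag with the prior map
placement: above threshold and previously placed on the target arm →
*confirmed*; above threshold and previously unmapped → *newly assigned*;
above threshold but previously placed elsewhere → *reassignment candidate*
(the density is trusted over the map; no second, higher bar is applied,
because the published argument for reassignment is similarity to the
confirmed on-arm densities, which the threshold already encodes); below
threshold with a target-arm prior → *prior conflict*; all other
below-threshold scaffolds are treated as off-arm. `summarizeCategories()`
re-creates the hit-accounting tables (percentages to two decimals, raw
counts always alongside, a residual row forcing exact conservation).

## Gaps, segments and hybrid scaffolds

`windowProfile()` bins unique-hit starts into 10 kb windows.
`detectGaps()` reports maximal runs of windows below 1 hit/kb spanning at
least 100 kb — an internal hole that large in an otherwise dense scaffold
is the signature of a bad sequence join, because the gapped stretch
receives no arm-specific reads. The 1 hit/kb cutoff is the empirical
off-arm ceiling; 100 kb is the published minimum gap size. Gaps touching a
scaffold end are flagged *terminal* and excluded from hybrid flagging by
default, since a terminal decline can equally be the laser cutting path.

`segmentRegions()` labels windows dense/sparse against the calibrated
threshold, absorbs interior runs of up to 2 contrary windows (published
region bounds are visibly smoothed; a small run-length tolerance stands in
for that unspecified smoothing), and merges regions shorter than 500 kb
into their longer neighbour (leftmost on ties, for determinism). The
result tiles the scaffold exactly with alternating states — the dense
blocks on a chromosome-scale superscaffold are the candidate arm regions.

Window size is the one genuinely free parameter here: 10 kb gives at least
ten windows across the smallest structure of interest (a 100 kb gap) while
keeping profiles small. The published analysis does not state the window
or smoothing it used for its region calls; ours are declared defaults, not
inferences.

## What the simulator emulates

Because the motivating experiment deposited no reads, the package carries
a first-class generator (`buildGenome()`, `simulateReads()`) whose
defaults define the study conditions used by the tests:

| parameter | default | rationale |
|---|---|---|
| scaffolds | 60, uniform 50–300 kb | desk-scale stand-in for a fragmented assembly |
| on-arm fraction | 0.25 | minority of the genome on one arm |
| reads | 200,000 × 80 bp | published read length; desk-scale count |
| contamination | 5% | off-target material survives dissection |
| substitution errors | 0.5%/base | short-read error regime; ~1% of reads exceed v = 2 |
| WGA dispersion | lognormal(0, 1) | no amplification statistics are published; σ = 1 gives visible duplication skew |
| primer chimeras | 10% of reads, ≥11 nt insert | published screen length; rate chosen so chimeras dominate neither mapping nor the unmapped pool |
| repeats | 5 families × 10 copies × 500 bp | enough identical sequence to exercise multi-mapping suppression |
| boundary taper | 350 kb linear | see below |

Mechanically: a pool of `n_reads/2` fragments is drawn per source class
(each fragment a start position, strand and lognormal weight) and reads
resample fragments proportionally to weight, so amplification duplicates
share start positions — which is exactly what stresses the decision to
count *reads* rather than distinct positions downstream. Contaminant reads
are drawn per-read as a Bernoulli(contamination rate) choice between the
on-arm and off-arm pools, keeping the contaminant fraction exactly
binomial. Substitution errors are applied to the read, after which chimera
inserts overwrite a read end verbatim — primer bases are clonal
amplification product, not sequenced template, so they carry no errors.

The laser-cut boundary is modelled as a single linear taper at the far end
of one designated on-arm "border" scaffold: sampling probability falls
linearly to zero over the taper width. The border scaffold's length is
pinned to the midpoint of the length range (175 kb) so the taper geometry
— and hence the anchor calibration — is reproducible across seeds; with a
350 kb taper its mean sampling weight is 0.25, which reproduces the
published geometry of an anchor density about a quarter of the on-arm
plateau (≈17 vs ≈70 hits/kb).

Hybrid scaffolds are concatenations of one on-arm and one off-arm segment
(each ≥ 200 kb by default, order random) with the join coordinate recorded
as truth. Only the on-arm segment is an eligible read source; the off-arm
segment receives no reads at all, including contaminants — contamination
stands for *other* chromosomes, and keeping the implanted gap clean makes
the recovery benchmark interpretable. A consequence of two-segment hybrids
is that their gap always touches a scaffold end; recovery is therefore
scored on gap calls overlapping the true off-arm segment, while the
stricter non-terminal rule in `flagHybrids()` is reserved for real
multi-join candidates.

Deliberately **not** modelled: indels, paired ends, quality-score
structure, GC bias, transposase insertion bias, and centromere-proximal
repeat enrichment. Passing tests therefore demonstrate that the statistics
and decision rules recover truth under the stated noise sources, not that
the pipeline is robust to every artefact of real libraries.

## Numerical and degenerate-case choices

* Interval objects (repeats, hybrid truth, gaps, segments) are `GRanges`,
  1-based closed, the native convention of the container; every file
  boundary (BED, truth TSV, hit tables) converts to 0-based half-open.
  `pos0` in hit tables is the 0-based leftmost aligned base on forward
  coordinates for both strands.
* Ties cannot arise in the uniqueness filter (multiplicity, not best-hit,
  decides). The one tie rule in the package is the segment merge:
  leftmost neighbour wins, making outputs deterministic.
* A zero-density anchor is an error (an uninformative anchor would label
  the whole genome on-arm).
* The last profile window may be short and is normalised by its true
  length, so window densities always reconstruct the scaffold totals.
* Reads with more than $v$ `N` bases are unmapped without search — every
  alignment would exceed the budget.
* Identical configurations produce byte-identical genomes, reads and
  pipeline outputs; the run manifest records no timestamps.

## Problem sizes used by the tests

The test suite runs the full default conditions (60 scaffolds, ~10.5 Mb,
200,000 reads) once and shares that run across checks; the hybrid-recovery
benchmark repeats the full conditions with one implanted join across 20
seeds; the mapper-versus-oracle comparison uses a 100 kb genome and 1,000
reads, the scale at which exhaustive enumeration is practical. The
acceptance script repeats the classification run once and the hybrid runs
eight times at full default scale.

## Limitations

The scaffold-level call is binary per scaffold; a hybrid scaffold's
*density* can sit anywhere between the off-arm floor and the on-arm
plateau depending on its segment proportions, which is why gap evidence,
not density alone, drives the misassembly call. Region-mean calibration
inherits whatever error is in the region bounds. The simulator's uniform
base composition makes unique mapping easier than in a real genome with
nested repeat families; the repeat model creates exact copies only. And
the pipeline labels terminal declines, it does not adjudicate between
laser path and misassembly — that distinction requires physical
validation, which enters the analysis only as prior placements.
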