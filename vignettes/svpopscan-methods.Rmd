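---
title: "Consensus SV maps and deletion selection scans: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus SV maps and deletion selection scans: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svpopscan)
```

This vignette explains the models behind `svpopscan`, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the design choices made where more than one reasonable rule existed.

## The consensus-merge model

Different SV callers see the same deletion through different evidence
(read pairs, split reads, read depth), so their breakpoints disagree by
tens of bases and each caller adds private false calls. The consensus
model treats calls of one type on one chromosome as vertices of a graph
with an edge wherever two calls plausibly describe the same locus:

* spanning types (DEL, INV, DUP): reciprocal overlap strictly greater
  than 0.75, i.e. `min(shared/len_a, shared/len_b) > 0.75` on 1-based
  closed intervals;
* insertions, which have no meaningful span: breakpoints within
  `ins_window` (default 100 bp) *and* min/max inserted-length ratio at
  least 0.75 — reciprocal overlap is undefined for point-like events, so
  this window-plus-ratio rule is this package's own, with both knobs
  exposed in `merge_params()`;
* translocations: both breakends within the same window on the same
  chromosome pair — again a package rule, since the overlap rule
  explicitly exempts translocations and no replacement is standard.

Clusters are the connected components of this graph (single linkage).
That is what the widely used SV mergers do, and it is the only linkage
that needs no extra parameter; its known cost is chaining — A–B and B–C
edges pull A and C together even when A and C themselves do not match.
Chaining is bounded by the per-chromosome, per-type partition and, in the
test suite, clustering is checked exactly against brute-force connected
components on a thousand random instances.

A cluster becomes a consensus SV only when **two or more distinct
callers** contributed (duplicate calls from one caller count once toward
support, but all members contribute to the medians — support is about
software agreement, not call multiplicity). Consensus breakpoints are the
member medians; an even-count median is the floor of the midpoint, which
keeps coordinates integral and deterministic. Size filters follow the
usual practice for short-read SV maps: deletions and insertions must
exceed 50 bp (below that they are indels, a different call class) and
spanning events must stay under 10 Mb (beyond that, read-depth artifacts
dominate). Filtering runs *after* support resolution, so a cluster's
support is judged on everything the callers reported.

## Consensus genotypes and allele frequencies

Only some callers genotype. At each merged site and sample the package
demands two genotyping callers assert the *same* genotype; a lone
non-missing call, or any disagreement, yields missing. This is the
conservative reading of "at least two" — a single caller's genotype is
exactly the evidence the rule distrusts. When one caller contributes
several member calls to a cluster and they conflict for a sample, that
caller's vote is discarded (package choice; conflicts are rare and
ambiguous by construction).

Allele frequencies are allele counts over non-missing genotypes:
`f = (2 n_homalt + n_het) / (2 n_nonmissing)`. The pooled frequency is
**count-pooled** over all samples of the scan populations — allele counts
are summed before dividing — so unequal sample sizes weight it exactly as
they weight the underlying alleles. With 10 samples at frequency 0.8 and
30 at 0.0 the pool is 16/80 = 0.2, not the naive mean 0.4.

## The scan statistics

Deletions are the scan's markers: they are the most reliably genotyped SV
class and behave as biallelic loci. Before scanning, sites longer than
100 kb are removed (breakpoint and genotype quality degrade with length)
as are sites with pooled frequency below 0.01 (a frequency estimated from
one or two alleles carries no population signal and would explode the
ratio statistic). Both filters and both statistics use one shared site
set, so the two empirical tails are comparable.

With focal frequency `f_foc`, reference frequencies `f_r1, f_r2` and
pooled frequency `f_all`:

$$\mathrm{dAF} = \left| f_{foc} - \tfrac{f_{r1}+f_{r2}}{2} \right|,
\qquad
\mathrm{RFD} = \frac{f_{foc} - \tfrac{f_{r1}+f_{r2}}{2}}{f_{all}}.$$

dAF is bounded in [0, 1]; taking the *mean* of the reference frequencies
(rather than their sum) is the only reading under which that bound holds.
RFD is signed — positive when the focal population is enriched — and
rescales the same difference by how common the deletion is overall, so a
0.3 shift at a rare site outranks a 0.3 shift at a common one. The two
statistics are correlated but not redundant, and significance requires
the empirical top 5% of **both**.

Thresholds use the nearest-rank percentile: the cutoff is the
`⌈0.95 n⌉`-th smallest value and a site passes only if *strictly* above
it. This is reproducible, interpolation-free, never flags more than 5% of
sites per statistic, and flags nothing when a distribution is degenerate.
With fewer than 20 sites a 5% tail is not meaningful and the package
warns.

Significant sites chain into regions when the gap between consecutive
sites on a chromosome is at most `join_gap` (default 100 kb — the same
scale as the scan's length cap; how candidate sites become reported
regions has no canonical rule, so the gap is an explicit parameter).
Regions collect every gene whose span they intersect by at least 1 bp.
Single-SV annotation uses the fixed precedence exonic > intronic >
upstream-1 kb > downstream-1 kb > intergenic (strand-aware flanks),
matching the behaviour of standard region-based annotators; the per-base
oracle in the test suite pins this down exactly.

## What the simulator emulates — and what it does not

`sim_config()` defaults define the study conditions used throughout the
tests and the acceptance script:

| parameter | default | why |
|---|---|---|
| genome | 18 chromosomes × 10 Mb | autosome count of a pig-like karyotype, scaled to ~7% of its physical size so suites run in seconds |
| sites | 400 DEL, 200 INS, 20 INV, 50 DUP | deletion-heavy mix with the minority classes present, proportioned like short-read SV maps |
| SV lengths | log-uniform; DEL 0.1–10 kb, INS 50–500 bp, INV/DUP 5–100 kb | matches the observation that deletions centre near 2 kb and insertions are short, while inversions/duplications run much longer |
| populations | MS 50, DU 50, TB 50 (focal MS) | three populations, two references — the minimum the scan accepts — at a size where binomial noise is realistic but small |
| neutral frequency | uniform on [0.05, 0.95] | polymorphic sites; the scan's 0.01 filter is then exercised by sampling noise, not by construction |
| planted sites | focal 0.9 vs reference 0.1 | a strong sweep-like contrast (effect 0.8); power tests sweep the effect over 0.2–0.8 |
| callers | fnr 0.2, 0.5 FP/Mb, jitter sd 30 bp; 3 genotyping + 1 not | no published error profile exists for the caller panel, so these are package defaults chosen to make the merge rules do visible work |
| genotype error | 0.02 | typical SV genotyping discordance |

Genotypes are Hardy–Weinberg draws (dosage ~ Binomial(2, f)) — the
minimal neutral model when no genotype process is specified. Neutral
sites share *one* true frequency across populations, so any observed
focal-reference difference is pure sampling noise and the null
calibration of the scan is exact by construction. Breakpoint jitter is
Gaussian and independent at each end (ends re-ordered if inverted), the
simplest noise that produces the partial-overlap structure the 75% rule
must resolve. False positives are caller-private by design, which encodes
the rationale for the two-caller rule: they are removed *in expectation*.
At realistic FP densities two callers' private false positives can still
collide by chance (about one such pair per ~600-site run at 0.5 FP/Mb on
the default genome), and the acceptance script reports that count rather
than hiding it.

The simulator deliberately omits: linkage disequilibrium between sites,
demographic history/drift (population frequencies are either identical or
set by the planted contrast), read-level evidence, reference-genome
context, and correlated caller errors. Passing tests therefore show the
*rules and statistics* are implemented correctly and calibrated under
their own assumptions — not that any particular biological call set will
behave this way.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere inside the package (VCF
  convention); BED is converted at the boundary in both directions, and
  for insertions `end == start` with the inserted length in `svlen`.
* Deletion `SVLEN` may arrive signed (VCF writes it negative); the
  absolute value is stored and the negative convention restored on write.
* Multi-allelic SV records are rejected outright: every downstream stage
  assumes biallelic sites, and silently splitting records would invent
  genotypes the callers never made.
* Medians of even-sized member sets take the floor of the midpoint;
  ties at a top-5% cutoff are not flagged (strict `>`).
* A population with zero non-missing genotypes at a site makes that
  site's frequency undefined; the scan filter drops such sites instead of
  propagating NaN.
* Fixed seeds make every simulation product byte-identical, including
  the on-disk bundle (no timestamps are written).

## Problem sizes used by the checks

The test suite and acceptance script run entirely on simulated data at
sizes chosen so a full run takes about a minute: ~670-site noisy-pipeline
runs for merge/genotype fidelity, 5,000-site neutral scans (20 replicates)
for calibration against an independent binomial Monte-Carlo oracle,
5,050-site planted scans (50 selected, 20 replicates per effect size) for
power, and 1,000 random ≤12-call instances for exact clustering
equivalence. These sizes are statements about statistical resolution, not
limits of the implementation; the per-chromosome interval indexing keeps
the merge near-linear in practice.

## Known limitations

* Single-linkage chaining can fuse tandem SV clusters connected by an
  intermediate call; inspect `members` on suspicious consensus records.
* The insertion and translocation match rules are heuristics with
  exposed knobs, not community standards.
* The scan assumes exactly one focal population and averages an
  arbitrary number (≥ 2) of references; it does not model admixture
  between them.
* Gene annotation is region-based only — no transcript consequences, no
  coding-frame logic, and the protein-coding/other distinction is
  whatever the gene source's `biotype` says.
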