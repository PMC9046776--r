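---
title: "Methods: CNV, SV and AOH detection from mate-pair low-pass sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV, SV and AOH detection from mate-pair low-pass sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay and its signal structure

A mate-pair library circularizes long DNA fragments (3--8 kb, mean ~5 kb)
so that a single paired-end sequencing read pair reports the two *ends* of a
long fragment. Sequenced to ~4-fold base coverage with 100-bp reads, the
library yields modest per-base depth but very high *physical* coverage: the
expected number of fragments spanning any genomic point is
`pairs x insert / genome length`, roughly 100-fold under the defaults here.
Two orthogonal signals follow:

* **depth** -- the count of aligned read ends per window tracks copy
  number, with enough ends per 50-kb window (~2,000 at 4x) for a
  single-copy change (expected ratio 0.5 or 1.5) to stand far outside
  counting noise;
* **junctions** -- a fragment straddling a rearrangement breakpoint aligns
  as a *chimeric* pair (ends on different chromosomes or far apart), and
  ~100 fragments straddle any given junction, so a real junction produces a
  tight cluster of co-oriented chimeric pairs while stray artifacts do not.

All internal logic assumes the FR (innie) pair convention; raw mate-pair
chemistry is outward-facing, and `read_pairs(..., library_type = "rf")`
flips both strands on ingest so one orientation grammar serves throughout.
Coordinates are 1-based inclusive everywhere except the BED boundary
(0-based half-open on disk, round-trip exact). Pairs with MAPQ < 20 on
either end are dropped at ingest as non-unique alignments; the threshold is
configurable because "uniquely aligned" is a filter whose exact MAPQ
rendering varies between aligners.

## Read-depth CNV model

Read ends are binned on two schemes: sliding 50-kb windows advancing in
5-kb increments (coarse segmentation at 50-kb resolution) and
non-overlapping 5-kb windows (boundary refinement and the
homozygous-deletion rule). Counts are width-normalized (terminal windows
are shorter), divided by the median rate of their 1%-GC stratum (strata
with < 30 windows fall back to the global median -- a deliberate, simple
rule; its cost is that very rare GC extremes are normalized only to the
global scale), optionally divided by a reference-panel per-window median
(`make_panel()` builds one from >= 10 simulated replicates; windows whose
panel median is 0 are masked), and scaled so the autosomal median ratio is

1. Uniform input therefore normalizes to exactly 1.0 -- a fixed point the
tests assert directly.

Segmentation flags windows at `gain_thr = 1.25` / `loss_thr = 0.75` and
reports maximal runs of >= 3 qualifying windows, merging runs separated by
a single discordant window. The thresholds are not physical constants: they
were chosen once so that single-copy events (expectation 1.5 / 0.5) sit
~5 sigma past threshold at 4x coverage while diploid noise (sigma ~ 2% per
50-kb window) essentially never crosses; both are config keys.

Boundary refinement moves each coarse boundary to the 5-kb window edge `b`
maximizing `|mean(ratio in (b, b+W]) - mean(ratio in (b-W, b])|` with flank
W = 50 kb, clipped at the call midpoint so the two boundaries of a short
call do not share windows; the search stays within +/- 50 kb of the coarse
boundary; ties break toward the coarse boundary, and a boundary whose
coarse-position flank is entirely masked is left unrefined and flagged.
This step statistic is this package's concrete rendering of
increment-rate-of-coverage boundary refinement; the published pipelines cite
prior work for the exact mathematics, which is not printed, so the
maximum-step-contrast reading was chosen and is validated against simulated
truth (boundaries within +/- 10 kb in >= 90% of replicates).

Homozygous/hemizygous deletions get a dedicated rule because at 4x a 10-kb
total loss is invisible at 50-kb resolution but unmistakable at 5 kb: runs
of **more than one** consecutive 5-kb window with ratio <= 0.1 (including
0) are reported; a single low window never is -- hence the ~10 kb minimum
reportable size.

## Chimeric-pair SV grammar

Chimeric pairs (different chromosomes, or same-chromosome span >= 10 kb,
inclusive) are clustered by single linkage within their junction key
(chromA, chromB, strandA, strandB), linking two pairs when both side-A and
side-B positions agree within `cluster_radius = 8000` bp (the maximum
insert). A cluster's per-side breakpoint estimate is the innermost member
coordinate (max position on a "+" side, min on a "-" side); the true
junction lies up to one insert beyond, which is the documented uncertainty
of all reported breakpoints. `min_support = 6` was fixed once from the
implied physical coverage (~100 fragments straddle a true junction on one
haplotype => a het event expects ~50; six distinct pairs is far above any
artifact pile-up at this scale yet tolerant of severe local dropout); the
published protocol's own support threshold lives in cited prior work and is
not printed, so both knobs are config keys.

Classification is deliberately *joint* with the depth calls, mirroring the
two-signal design of the assay: a distant (+,-) cluster alone can be a
dispersed-repeat artifact, so DEL requires corroborating depth loss -- an
overlapping loss/homdel call or, for events below coarse resolution (the
interesting cryptic deletions are 8--46 kb), a bracketed mean 5-kb ratio at
or below `loss_thr`. DUP orientation similarly requires the corroborating
gain: one (-,+) cluster bracketing a gain within the cluster radius of both
boundaries is a forward tandem duplication (junction `end::start`, both
"+"), the dominant orientation among real duplications. Inversions require
the matched (+,+)/(-,-) cluster pair with flank-consistent coordinates
(a lone one is emitted single-sided). The insertion pattern is two clusters
joining one locus to both ends of a distant gained segment; the inserted
copy's orientation is read off the site-side strand of the junction meeting
the segment's high end, and extra gain at the insertion site is reported as
a flanking duplication. Remaining inter-chromosomal clusters are
translocations (reciprocal ones merged); components of >= 3 interdependent
leftover clusters are emitted as COMPLEX with their junction graph (no
haplotype assembly is attempted). Finally, a depth gain with no usable
junction whose flanks intersect the segmental-duplication annotation is
`UNRESOLVED_LCR`: low-copy repeats defeat junction mapping by construction,
and the simulator reproduces this by assigning MAPQ 0 inside its LCR mask.

## AOH model

Sites with depth 5--20 and >= 1 alternate read are genotyped: het at alt
fraction 0.2--0.8, hom-alt at >= 0.9, the (0.8, 0.9) band dropped as
ambiguous. The cutoffs were chosen once for binomial separation at 5--20x
(a true het at depth 8 lands in 0.2--0.8 with ~93% probability; a true hom
with 0.5% error lands >= 0.9 with ~96%); note reference-homozygous sites
carry no information under the >= 1-alt gate, so "hom rate" means hom-alt
rate throughout. Counts per fixed 100-kb window are normalized by the
autosome-wide mean of their class, computed over informative windows only
-- empty windows are *missing*, not zero, because zero informative sites is
an evidence gap, not evidence of homozygosity.

AOH is flagged where the het rate falls below 0.3 **and** the hom rate
rises above 1.3 simultaneously; flagged runs bridge up to 5
unflagged/missing windows, and merged regions are reported from 5 Mb.
The window thresholds and gap are stand-ins chosen from the simulated
separation at ~1 informative SNV per 1.5 kb (inside a true AOH the
normalized het rate collapses to the genotyping-error level ~0.02--0.05
while the hom rate roughly doubles, so 0.3/1.3 sit in a wide margin); they
are config keys. One caveat measured in development: the hom-rate
normalizer includes the AOH windows themselves, so a sample where AOH
covers a large genome fraction compresses the hom elevation toward the
threshold -- at the simulated 10 Mb/60 Mb it remains comfortably clear.
Reported regions are terminal if within one window of a chromosome end;
UPD is suspected for interstitial AOH > 15 Mb or terminal AOH > 5 Mb, and
AOH on >= 3 autosomes (configurable) raises a consanguinity flag, the
motivating extreme being hundreds of Mb across a dozen autosomes. Regions
on the classical imprinted chromosomes (6, 7, 11, 14, 15, 20 by default --
shipped as a config default since the clinically relevant list is
assay-policy) are marked. Mosaic AOH is out of core scope; a
`mosaic_het_thr`-style relaxation can be expressed through the config keys
but is untested.

## Nomenclature

Event size is `max(pos) - min(pos)` -- a difference, not a +1 span. This
convention was fixed by checking that it reproduces every verifiable
published size from the printed breakpoints (15/15 in the bundled table);
the insertion rows are the exception: their printed "size" does not equal
the duplicated-segment length under any consistent convention we could
identify, so insertions report segment length and junction coordinates
separately and emit no single size. The formatter emits canonical `"->"`
connectors and underscore coordinate separators; the parser additionally
accepts the spacing/punctuation variants that appear in printed tables
(`"- > "`, hyphenated coordinate pairs, digit-group commas). Band lookup
requires a cytoband map; `synthetic_hg19_map()` builds one whose bands are
anchored at the bundled breakpoints with boundaries midway between
anchors -- sufficient for band lookup at those positions and clearly
labelled synthetic, since true cytogenetic boundaries are not bundled.

## The simulator: what it emulates and what it does not

`simulate_sample()` draws fragments uniformly (with a mild unimodal GC
preference, width 0.25 in GC fraction -- normalized away by the caller's GC
strata) along a *rearranged diploid genome* built from two haplotype
segment maps, and maps both 100-bp reads back through the maps to reference
coordinates: fragments crossing a junction emerge as chimeric pairs with
exactly the orientation the event geometry dictates, which is the property
the geometry tests assert per event type. Fragment count is
`ceiling(coverage x genome / (2 x read length))`; insert sizes are normal
(5,000 +/- 700, truncated to 3--8 kb); a read that itself crosses a
junction is dropped as unalignable (split reads are not modelled -- the
real pipeline's Sanger-grade breakpoints are out of scope). PCR duplicates
(1%) are flagged copies of other fragments. Pileups are simulated
independently at mean site depth 8 rather than 4 so the 5--20x genotyping
gate retains most sites, standing in for a deeper per-site summarization;
het sites occur every ~1.5 kb, hom-alt every ~2.5 kb, and inside AOH
regions het sites collapse to homozygosity with a residual 2% genotyping
error. Hemizygous regions expose the remaining haplotype (het sites become
hom), so heterozygous deletions create short AOH-like stretches exactly as
real data would -- far below the 5 Mb reporting floor.

Not modelled: base-level sequence, sequencing error, mismapping (chimeric
pairs arise only from true junctions; specificity against alignment
artifacts is exercised through the blacklist/known-SV filters, not the
generator), chromosome-scale GC structure, or mosaic fractions. Passing
the recovery suites therefore demonstrates correctness of the calling
logic under the assay's geometry and noise scale, not robustness to
aligner pathology.

## Validation conditions and numerical choices

The standard recovery study (`benchmark_recovery()`) runs 50 seeds on the
default 2 x 30 Mb genome at 4x (about 1.2 million pairs and ~100x physical
coverage per replicate -- sizes chosen to keep one replicate at a few
seconds while preserving the protocol's physical-coverage regime) carrying
a 300-kb heterozygous deletion, a 250-kb forward tandem duplication, a
120-kb inversion and a 10-Mb interstitial AOH region. Measured guarantees,
asserted by the test suite at these conditions: >= 95% CNV recovery at 50%
reciprocal overlap with refined boundaries within 10 kb in >= 90% of
replicates; >= 95% type-correct DEL/DUP/INV recovery with breakpoint error
within one insert (median error in practice ~200 bp); duplication
orientation resolved forward-tandem in >= 95%; AOH recovered within 2
windows in >= 90% with < 0.05 false >= 5 Mb regions per genome.

Degenerate inputs are pinned by tests: empty pair streams produce all-zero
counts; an all-zero sample is an explicit "insufficient coverage" error; a
sample with no het calls at all is "unusable for AOH"; flat profiles
produce no calls and flat-statistic refinement keeps the coarse boundary;
tie-breaks are deterministic (toward the coarse boundary; stable cluster
ordering), and the whole pipeline is a pure function of (inputs, seed) --
the determinism tests compare byte-identical outputs.

## Known limitations

Sex-chromosome ploidy is not modelled (a config ploidy map merely excludes
sex chromosomes from normalization medians and AOH totals). DEL calls
require depth corroboration, so a balanced-looking dispersed duplication
whose junction mimics a deletion is intentionally not called DEL.
COMPLEX events report their junction graph without ordering the segments
when the order is ambiguous. The cytoband map bundled for nomenclature is
synthetic (anchor-based); users with a real cytoBand file should load it
via `read_cytoband()` + `genome_map()`.
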