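# matepairsv

Detection of copy-number variants (CNVs), structural rearrangements (SVs)
and regions with absence of heterozygosity (AOH) from **mate-pair low-pass
genome sequencing** — large-insert (~5 kb) libraries sequenced to ~4-fold
base coverage. At that depth a base is covered four times but a *point* of
the genome is spanned by roughly a hundred 5-kb fragments, so junction
evidence (read pairs whose two ends straddle a rearrangement breakpoint) is
plentiful even though base-level depth is shallow. The package is aimed at
people building or evaluating this kind of assay: it includes a seeded
simulator that generates aligned pair tables, SNV pileups and truth sets
over a toy genome, so every caller is testable offline with no patient data.

## What it computes

**Read-depth CNV calling.** Uniquely aligned read ends are counted on two
windowings: adjustable sliding windows (50 kb advancing in 5 kb increments)
and non-overlapping 5 kb windows. Counts are normalized by GC stratum
(1% strata, median-based, global-median fallback for sparse strata) and
optionally by a reference panel of per-window medians, then scaled so the
autosomal median copy ratio is 1. Coarse calls are maximal runs of at least
3 windows with ratio ≥ 1.25 (gain) or ≤ 0.75 (loss), bridged across single
discordant windows; boundaries are then refined on the 5-kb profile with a
step statistic |mean(ratio in (b, b+W]) − mean(ratio in (b−W, b])|, W = 50 kb.
Homozygous/hemizygous deletions are reported where **more than one**
consecutive 5-kb window has copy ratio ≤ 0.1 (minimum reportable size
~10 kb).

**Chimeric read-pair SV calling.** Pairs mapping to different chromosomes
or ≥ 10 kb apart on one chromosome are selected, single-linkage clustered
within their junction key (chromosome pair + strand pair, linkage radius
8 kb, ≥ 6 supporting pairs), filtered against blacklist/population-SV BED
files, and classified jointly with the depth calls: distant (+,−) clusters
with corroborating depth loss become deletions; (−,+) clusters bracketing a
depth gain become **forward tandem duplications** (junction joins the
segment's end back to its start); matched (+,+)/(−,−) cluster pairs become
inversions; cluster pairs joining one locus to both ends of a distant
gained segment become duplicated-segment insertions (with flanking
duplications at the insertion site recognized); leftover inter-chromosomal
clusters are translocations, and ≥ 3 interdependent clusters are reported
as complex. A depth gain with no usable junction whose flanks hit the
segmental-duplication annotation is reported `UNRESOLVED_LCR` — low-copy
repeats defeat junction mapping.

**AOH / UPD analysis.** Pileup sites with depth 5–20 and at least one
alternate read are genotyped (het at alt fraction 0.2–0.8, hom-alt ≥ 0.9);
het and hom rates are computed per fixed 100-kb window and normalized by
their autosome-wide means. AOH is a run of windows with a simultaneous drop
in the het rate (< 0.3) and rise in the hom rate (> 1.3), bridged across ≤ 5
windows, reported from 5 Mb. Uniparental disomy is suspected for
interstitial AOH > 15 Mb or terminal AOH > 5 Mb; AOH on ≥ 3 autosomes raises
a consanguinity flag.

**Nomenclature.** Calls are rendered in ISCN-like `seq[GRCh37]` strings —
`del(5)(q14.3) chr5:g.90028949_90237360del`,
`dup(13)(q13.3)(pter->q13.3(+)(37430811)::q13.3(+)(37267951)->qter)` — and
parsed back (round-trip identity). Event size is the breakpoint difference
`max(pos) − min(pos)`. Breakpoints can be annotated against gene and TAD
interval files.

## Worked example

```r
library(matepairsv)

cfg <- sim_config(
  genome = data.frame(chrom = c("chr1", "chr2"), length = c(8e6, 8e6)),
  events = list(
    list(type = "del", chrom = "chr1", start = 2e6, end = 2.3e6),
    list(type = "dup", chrom = "chr1", start = 5e6, end = 5.25e6),
    list(type = "inv", chrom = "chr2", start = 3e6, end = 3.12e6)),
  aoh_regions = list(list(chrom = "chr2", start = 6e5, end = 6.6e6)),
  seed = 7)
sim <- simulate_sample(cfg)
res <- run_sample(sim$pairs, sim$pileup, sim$genome)
res
#> mate-pair sample analysis
#>   CNV calls: 2
#>   junction clusters: 4
#>   SV events: 3
#>   AOH regions: 1 (autosomal total 5,999,999 bp)
summary(res)$sv
#>             type chrom   start     end size_bp support notes
#> 1            INV  chr2 2999863 3120031  120168      97
#> 2 DUP_TANDEM_FWD  chr1 5000103 5249875  249772      42
#> 3            DEL  chr1 1999776 2300231  300455      45
```

The two CNV calls land on the implanted deletion (2.0–2.3 Mb, ratio ~0.5)
and duplication (5.0–5.25 Mb, ratio ~1.5) with boundaries refined to the
5-kb grid; the three junction-level events carry breakpoint estimates
within a few hundred bp of the implanted breakpoints (the estimate is the
innermost supporting read end, so the true junction lies up to one insert
beyond); and the homozygous stretch on chr2 is reported at window
resolution. `write_report()` emits BED/VCF(BND)/TSV/JSON reports, and the
`exec/matepairsv` script exposes `simulate / cnv / sv / aoh / report / all`
subcommands over the same engines.

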