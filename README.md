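# chromborders

Graded chromatin borders and domain states from trimodal single-cell
epigenomic data.

Joint single-cell profiling of chromatin accessibility (ATAC) and the
histone modifications H3K27ac (active) and H3K27me3 (Polycomb-repressive)
reveals that developmental gene clusters — most prominently the HOX loci
in spinal-cord oligodendroglia — are not simply "on" or "off". Signal
transitions in the three modalities line up into discrete *borders* whose
strength is graded by how many modalities support them, and the intervals
between borders fall into three regulatory states:

- **inactive** — low signal in all three modalities (flanking chromatin);
- **primed** — accessible and H3K27ac-marked, but with H3K27me3 clearly
  above the flanking background (poised, transcriptionally quiet);
- **silenced** — heavily H3K27me3-marked with little accessibility.

`chromborders` implements that analysis end to end, together with the
supporting computations such a study needs: fragment-file input/output and
insertion binning, per-cell quality control (TSS enrichment), pseudobulk
CPM tracks, within-cell joint-mark grouping with a permutation test,
contact-matrix analytics (ICE balancing, observed/expected, compartment
eigenvector, diamond insulation, virtual 4C, aggregate loop pileup),
transcription-factor network strength statistics, metagene cell-type
scoring, and differential accessibility with Benjamini–Hochberg control.
A synthetic-data generator plants a HOX-like 13-gene cluster with known
borders, cell groups, TADs and loops, so every stage is testable without
any external data.

## The border model

For each modality the pseudobulk CPM track (2-kb bins) is
variance-stabilized (square root), Gaussian-smoothed (σ = 3 bins), and
differenced between adjacent bins. Differences are converted to robust
z-scores by dividing by a noise scale estimated as 1.4826 × MAD of the
*unsmoothed* track differences, propagated through the smoothing kernel
(see the methods vignette for why the raw-diff MAD is the right robust
denominator). Local |z| maxima with |z| ≥ 4 become modality boundaries;
candidates closer than 5 bins are merged greedily, keeping the largest
|z| (ties to the leftmost). Boundaries from the three modalities within
2 bins of each other are single-linkage clustered into one border whose

- **grade** = number of distinct supporting modalities
  (1 = weak, 2 = moderate, 3 = strong), and
- **position** = amplitude-weighted mean of the member boundaries.

Domains between consecutive borders are classified from their
per-modality mean CPM expressed as fold over a flanking baseline
interval: *silenced* if H3K27me3 fold ≥ 4 with ATAC fold < 2; *primed*
if ATAC and H3K27ac folds ≥ 2 with H3K27me3 fold ≥ 1.5; *inactive*
otherwise. All thresholds are exposed as arguments.

## Worked example

```r
library(chromborders)

cfg    <- sim_config(seed = 42)          # 500 cells, Poisson counts
genome <- make_genome(cfg)
fx     <- make_hox_fixture(genome, cfg)  # trimodal fragments + planted truth

scheme <- bin_scheme(setNames(genome$length, genome$chrom), cfg$bin_width)
mats   <- lapply(fx$fragments, bin_counts, scheme = scheme, cells = fx$barcodes)
tracks <- lapply(mats, function(m)
  pseudobulk_track(m, list(all = fx$barcodes), scheme)$all)

locus  <- lapply(tracks, track_subset, start = fx$locus[1], end = fx$locus[2])
called <- call_borders(locus)
called$borders
#>   position grade               support n_members
#> 1   900000     3 ATAC,H3K27ac,H3K27me3         3
#> 2   948777     3 ATAC,H3K27ac,H3K27me3         3
#> 3   972000     1              H3K27me3         1
#> 4  1008000     3 ATAC,H3K27ac,H3K27me3         3
#> 5  1056000     2      H3K27ac,H3K27me3         2

classify_domains(called$borders, tracks, fx$locus,
                 baseline_interval = c(fx$segments$start[1], fx$segments$end[1]))
#>     start     end    state atac_fold k27ac_fold k27me3_fold
#> 1  850000  900000 inactive     1.376      1.428       1.019
#> 2  900000  948777   primed    11.522     12.822       1.891
#> 3  948777  972000   primed     8.027      8.575       2.862
#> 4  972000 1008000   primed     8.008      8.400       4.593
#> 5 1008000 1056000 silenced     1.269      1.396      11.660
#> 6 1056000 1106000 inactive     1.062      4.533       3.040
```

The caller recovers exactly the planted structure: three strong borders
(cluster start, the internal step after gene 4, and the sharp
primed-to-silenced transition at gene 10), one moderate border at the 5′
end where the heavy repressive signature decays, and one weak
(H3K27me3-only) border around gene 7. Positions sit on the planted
transitions to within a bin. The 3′ gene blocks come out *primed*
(accessible, H3K27ac-marked, H3K27me3 1.9–4.6-fold over the flank), the
5′ block *silenced* (H3K27me3 ~12-fold, near-baseline accessibility),
and the flanks *inactive*.

`run_demo(sim_config(seed = 42), out_dir = "demo")` runs every stage
(QC → borders → domains → within-cell grouping → contact matrices →
networks → differential accessibility) in under a minute, writes
bedGraph/BED/JSON outputs, and returns a report whose `checks` field
records the pipeline's internal consistency properties.

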