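# rtepi — enhancer–promoter interaction prediction from replication timing

`rtepi` predicts enhancer–promoter interactions (EPIs) using DNA
replication timing (RT) as the **only** input signal. RT — the early/late
order in which the genome replicates, measured by Repli-seq as a log-ratio
track (early > 0 > late) — mirrors 3D genome organization: early domains
coincide with active A compartments where regulatory contacts live. The
package turns that observation into a complete, testable pipeline for
epigenomics researchers who have RT tracks but no chromatin-interaction
data for their samples.

## What it does

Given chromatin loops (BEDPE; Hi-C / ChIA-PET / Hi-TrAC / 5C style),
element annotations (BED), and an RT profile (bedGraph / wig / bigWig):

1. **Dataset construction** — merge elements within 500 bp, call a positive
   EPI per loop whose anchors overlap an enhancer and a promoter, and draw
   **distance-matched** negatives at a 1:20 ratio (15 log-spaced bins,
   5 kb–2 Mb), so distance alone carries no signal (prevalence baseline
   1/21 ≈ 0.05).
2. **Encoding** — each pair becomes a 482-dimensional multi-scale RT
   vector: per anchor, an anchor mean plus 20 upstream + 20 downstream
   windows at each scale in {0.5, 1, 2, 5, 10, 50} kb.
3. **Classification** — a deterministic random forest (own Rcpp
   implementation: binned CART, Gini, bootstrap; 500 trees, √p features per
   split) with native AUPRC/AUROC, stratified 5-fold CV and 100× resampling
   evaluation, cross-sample matrices and pooled "general" models.
4. **Interpretation** — impurity and permutation feature importance,
   incremental feature selection, promoter-only / enhancer-only / per-scale
   subset evaluation, and the distance-only control.
5. **Cross-platform recovery** — score independent loop catalogues
   (max probability over each loop's enhancer–promoter readings) and
   combine platform models by score-threshold union.
6. **Cancer application** — score millions of candidate pairs, keep the top
   n, re-encode them with each cohort sample's RT profile into a
   sample × EPI probability matrix, call group-specific / common EPIs, and
   cluster samples (average-linkage hierarchical clustering, adjusted Rand
   index, Calinski–Harabasz index).
7. **Synthetic worlds** — a fully seeded generator of RT domain structure,
   elements, RT-coupled loops and two-group cohorts with planted
   group-specific EPIs, so the entire pipeline is testable offline.

## Worked example

```r
library(rtepi)

cfg <- sim_config(chrom_length = 2e7, n_enhancers = 250, n_promoters = 200,
                  n_loops = 60, seed = 42)
sim <- simulate_cell_line(cfg)                      # RT track + elements + loops
ds  <- build_epi_dataset(sim$loops, sim$enhancers, sim$promoters,
                         dataset_config(seed = 42)) # positives + matched negatives
fm  <- encode_dataset(ds$pairs, sim$profile)        # 482 RT features per pair
fm
#> epi_fm: 1287 pair(s) x 482 feature(s) | 66 positive / 1221 negative

cross_validate(fm, k = 5, seed = 42, num_trees = 200)
#> epi_eval: AUPRC 0.8010 | AUROC 0.9334 | baseline 0.0513
#>   over 5 split(s): AUPRC 0.8069 +/- 0.0573, AUROC 0.9352 +/- 0.0550

model <- train(fm, seed = 42, num_trees = 200)
head(importance(model), 3)
#>                feature importance anchor_group scale_group
#> 1:   prom_up_w2000_b11 0.01956533     promoter        2000
#> 2:    prom_up_w500_b01 0.01524029     promoter         500
#> 3: prom_down_w2000_b03 0.01488986     promoter        2000

score_reference_loops(model, sim$loops, ds$enhancers, ds$promoters,
                      sim$profile)$recovery
#> [1] 1
```

Read: on a world where loops are coupled to early-replicating (active)
chromatin, the classifier reaches AUPRC 0.80 against a 0.05 no-skill
baseline and AUROC 0.93; the feature ranking is dominated by
promoter-side, fine-scale windows; and every simulated loop is recovered at
the 0.5 call threshold. Switch the coupling off
(`loop_coupling_strength = 1`) and AUPRC collapses to the baseline — the
distance matching works.

## Command line

Every stage is also a CLI subcommand (config file + `--key value` flags,
explicit `--seed`, run log per output directory):

```sh
Rscript -e 'rtepi::rtepi_cli()' simulate      --seed 5 --out sim/
Rscript -e 'rtepi::rtepi_cli()' build-dataset --seed 5 --out ds/ \
    --loops sim/loops.bedpe --enhancers sim/enhancers.bed --promoters sim/promoters.bed
Rscript -e 'rtepi::rtepi_cli()' encode        --out enc/ --pairs ds/pairs.tsv --rt sim/rt.bedgraph
Rscript -e 'rtepi::rtepi_cli()' train         --seed 5 --out tr/ --features enc/features.tsv
Rscript -e 'rtepi::rtepi_cli()' evaluate      --seed 5 --out ev/ --features enc/features.tsv
```

(Also: `cross-sample`, `interpret`, `recover-loops`, `combine`,
`cancer-diff`.)

## Further reading

`vignettes/rt-epi-methods.Rmd` documents the model and its assumptions, the
synthetic world's design (what it emulates and what it deliberately does
not), the reconstruction decisions behind the 482-feature scheme, and the
numerical conventions (average-precision AUPRC, tie handling, degenerate
cases).
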