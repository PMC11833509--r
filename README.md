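# synaptoquant

Quantitative analysis of synaptic partner matching: proximity-labeling
interactome filtering, volumetric matching indices, single-axon branch
morphometry, and F-actin density profiling.

## The problem

During development, an olfactory receptor neuron (ORN) axon must find
the dendrites of its partner projection neuron (PN) inside one
glomerulus of the fly antennal lobe.  Studying how a transmembrane
bait protein (a teneurin) instructs this choice produces four
quantitative problems, each implemented here as a tested module:

1. **Interactome filtering.**  A six-plex TMT proximity-labeling
   experiment compares the bait condition (`TRT`) against a
   membrane-anchored spatial reference (`SR`) and a negative control
   (`NC`).  Per protein, the model
   `log2TMTratio = b0 + b1·TRT + b2·SR` (NC baseline) gives the
   bait/NC fold change as `b1` and the bait/SR fold change as
   `b1 − b2`.  Variances are shrunk by an empirical-Bayes prior
   (`d0`, `s0²`) estimated across proteins by trigamma inversion;
   moderated t statistics with `d0 + df` degrees of freedom give
   two-sided p-values, Benjamini–Hochberg-adjusted per contrast.
   A three-step filter (unique peptides ≥ 2; fold change over NC ≥ the
   bait's own; fold change over SR > 0) yields the bait's intracellular
   interactome and a shortlist ranked by bait/SR fold change.
2. **Volumetric indices.**  From segmented 3D volumes:
   match index `|A∩D|/|D|`, mismatch index `|A∩D|/|A|`, mistarget
   index `ΣI_A/(ΣI_A + ΣI_B)` — voxel-count ratios quantifying
   axon–dendrite coincidence.
3. **Axon morphometry.**  From SWC traces: the stem axon (thickest
   root-to-leaf path by length-weighted mean radius), antennal-lobe
   entry and end points, developmental stage (stem length
   <100 / 100–170 / >170 μm), normalized primary-branch positions,
   PN-contact and multifurcation calls, branch densities, and the
   ANOVA/Tukey, Kruskal–Wallis and chi-squared comparison battery.
4. **F-actin profiling.**  Field intensities sampled per trace node
   (mean over a 1-voxel-radius sphere), min–max normalized per axon;
   segment density = trapezoidal arc-length integral / length;
   Mann–Whitney between contacting and non-contacting branches, paired
   t within branches on PN(+) versus PN(−) sub-segments.

A synthetic-data module generates TMT tables with planted interactors
and contaminants, paired volumes with programmed overlap, and branched
axons with contact-dependent field boosts — all seed-deterministic with
recorded ground truth.

## Worked example

```r
library(synaptoquant)

sim <- gen_tmt_dataset(tmt_sim_config(seed = 42))   # 2000 proteins
fit <- tmt_fit(sim$quant, mode = "precomputed")
fit
#> Moderated-t TMT enrichment model
#>   proteins fitted: 2000 (of 2000 input)
#>   design: 6 channels (TRT 2 / SR 2 / NC 2)
#>   prior: d0 = 1.03e+03, s0^2 = 0.06271

ia <- run_interactome(fit, bait_id = "BAIT")
ia$trace
#> Ratiometric filter trace
#>   detected: 2000
#>   step 1 (unique peptides): 1958
#>   step 2 (fc_nc >= bait's 2.064): 242
#>   step 3 (fc_sr > 0): 154
```

The trace reads: 2000 proteins detected; 1958 keep ≥ 2 unique peptides;
242 are at least as bait/NC-enriched as the bait itself (its estimated
fold change here is 2.064); 154 are also enriched over the spatial
reference — the recovered interactome.  Of the 50 planted interactors,
92% survive to step 3 and every planted endogenously-biotinylated
contaminant is removed at step 2:

```r
ints <- sim$truth$protein_id[sim$truth$class == "interactor"]
mean(ints %in% ia$interactome$protein_id)
#> [1] 0.92
```

Morphometry and profiling run the same way on a simulated stage-3 axon:

```r
ax <- gen_axon_with_field(axon_sim_config(seed = 5))
m <- axon_morphometry(ax$tree, ax$regions)
m
#> axon_morphometry: stage 3, stem 190.0 um, 11 primary branches (density 0.058 /um)

prof <- normalize_profile(sample_along_trace(ax$tree, ax$field, 1, ax$origin))
dens <- branch_densities(ax$tree, prof, m$records, ax$regions$pn_dendrites)
factin_compare(dens)
#> F-actin density comparison
#>   between branches (Mann-Whitney): U = 29, p = 0.0137 (n = 6 vs 5)
#>   within branches (paired t): t = 26.07, p = 1.55e-06 (6 pairs, mean diff 0.410)
```

The planted contact-zone boost makes PN-contacting sub-segments denser
than non-contacting ones within the same branches (paired t), and
contacting branches denser than non-contacting branches overall.

A configuration-driven runner ties stages together with a manifest and
config hash (`run_config()` / `run_pipeline()`); a thin command-line
wrapper lives at `inst/cli/synaptoquant.R`.

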