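---
title: "Models and methods behind synaptoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synaptoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptoquant)
```

# Scope

`synaptoquant` implements the quantitative layer of a study of synaptic
partner matching in the fly antennal lobe: how a presynaptic olfactory
receptor neuron (ORN) axon finds the dendrites of its partner projection
neuron (PN).  Four analyses are covered — ratiometric TMT interactome
filtering with moderated-t statistics, volumetric partner-matching
indices, single-axon branch morphometry, and F-actin density profiling —
plus synthetic-data generators with recorded ground truth so every stage
can be validated without any external data.

# The TMT enrichment model

A six-plex TMT experiment compares three conditions, two channels each:
the bait proximity-labeling condition (`TRT`, an APEX2 fusion to the
transmembrane bait), a membrane-anchored spatial reference (`SR`) that
biotinylates generic membrane-proximal proteins, and a negative control
(`NC`, a required labeling reagent omitted) that captures endogenously
biotinylated and endogenous-peroxidase background.

For each protein the log2 TMT ratio is modeled as

$$\mathrm{log_2 TMTratio} = b_0 + b_1\,\mathrm{TRT} + b_2\,\mathrm{SR},$$

with `NC` as baseline, so the bait/NC log2 fold change is $b_1$ and the
bait/SR fold change is the $b_1 - b_2$ contrast.  Fitting is ordinary
least squares per protein; on the balanced 2/2/2 design the coefficients
are exactly the group-mean differences, and
$c^\top (X^\top X)^{-1} c = 1$ for both contrasts.

## Ratio normalization

The package accepts either precomputed log2 ratios (passed through
unchanged) or raw reporter intensities.  In raw mode each protein's
channel values are divided by that protein's median intensity across the
channels and log2-transformed, then per-channel medians across proteins
are subtracted to absorb loading differences.  The median-reference
convention is this package's own choice — standard ratiometric TMT
practice and self-contained — not a claim about any particular upstream
search-engine pipeline; tables produced by other conventions should be
supplied as precomputed ratios.

## Empirical-Bayes moderation

Per-protein variances on 3 residual df are noisy, so they are shrunk
toward a prior.  Writing $e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$,
the prior df $d_0$ solves
$\psi'(d_0/2) = \overline{(e_g-\bar e)^2}\,n/(n-1) - \psi'(d_g/2)$ by
Newton trigamma inversion, and
$s_0^2 = \exp(\bar e + \psi(d_0/2) - \log(d_0/2))$.  When the observed
spread of $e_g$ does not exceed its sampling variance the prior df is
flagged infinite and the prior variance falls back to the plain mean of
the sample variances, so a degenerate set of identical variances returns
exactly that common value.  Only proteins with $s_g^2 > 0$ and
$d_g \ge 1$ inform the prior (at least 10 required); proteins with
$s_g^2 = 0$ still receive moderation, which pulls their posterior
variance toward $s_0^2$ rather than dropping the cleanest proteins.

The moderated statistic for contrast estimate $\hat c$ is
$t = \hat c / (\tilde s \sqrt{c^\top (X^\top X)^{-1} c})$ with
$\tilde s^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ on $d_0 + d_g$ df
(normal when $d_0$ is infinite).  At $d_0 = 0$ this is the ordinary t
exactly; as $d_0 \to \infty$ the denominator variance approaches
$s_0^2$, with a deviation of $d_g(s_g^2 - s_0^2)/d_0$ — the package's
tests assert the $10^{-6}$-relative limit in the regime where variances
sit near the prior, which is where that bound is attainable.  P-values
are two-sided (enrichment plots show both tails) and each contrast is
Benjamini–Hochberg-adjusted separately, since the two fold-change axes
are reported independently.

# The three-step interactome filter

Starting from the fitted table: (1) keep proteins with at least 2 unique
peptides; (2) keep proteins whose bait/NC fold change is **greater than
or equal to** the bait's own — the bait biotinylates itself, so anything
below its self-enrichment is dominated by NC-type contamination; the
inclusive inequality means the bait always retains itself; (3) keep
proteins with bait/SR fold change **strictly greater than** 0, removing
generic membrane-proximal background.  The two inequality directions
follow the filter's definitions verbatim; the steps are pure set
operations, so the outputs nest and are invariant to row order.

The ranked shortlist sorts the step-3 interactome by descending bait/SR
fold change.  The shortlist size is a parameter (default 37) rather than
a derived quantity, because the criterion separating "significantly
enriched" from "top-ranked" candidates admits both readings; ties are
broken by smaller q-value and then lexicographic protein id purely for
determinism — the underlying analysis ranks by fold change alone.

# Volumetric indices

All three indices are voxel-count ratios over one grid, so voxel size
cancels (anisotropic voxels are accepted for the same reason):

* **match index** $=|A \cap D| / |D|$ — axon coverage of partner
  dendrites (D = partner-PN dendrite mask);
* **mismatch index** $=|A \cap D| / |A|$ — fraction of a
  non-partner axon inside dendrites it should avoid;
* **mistarget index** $=\Sigma I_A / (\Sigma I_A + \Sigma I_B)$ —
  fluorescence fraction landing in the wrong glomerulus.

Segmentation mirrors a 3D-object-counter workflow: a global threshold
(fixed and inclusive, or automatic Otsu applied strictly above the
computed level so a constant volume segments to empty), followed by
removal of connected components below a minimum voxel count
(26-connectivity by default, the common 3D-object-counter convention).
The original analysis does not state its thresholds; the automatic
default with an explicit override keeps runs reproducible.  Whether
channels were originally thresholded jointly or independently is
unstated; the package thresholds each channel independently.

# Axon morphometry

A traced axon (SWC: 1-based ids, root parent −1, coordinates and radii
in μm) is reduced to:

* **stem axon** — conventionally described as the thickest segment of
  the axon, without a formula; here it is operationalized as the root-to-leaf path
  maximizing the path-length-weighted mean radius, which is robust to
  local radius noise and deterministic (ties: longer path, then
  lexicographic leaf id).
* **entry point** — first stem node inside the antennal lobe region;
  **end point** — the farthest distal stem node from the entry along the
  stem; their geodesic separation is the stem length.  A stem meeting
  the lobe only at its tip degenerates to entry = end, length 0.
* **stage** — stem length < 100 μm is stage 1, 100–170 μm stage 2,
  > 170 μm stage 3.  The middle interval is closed on both ends so the
  three stages partition the axis (the source legend writes "100–170"
  and ">170", leaving the boundaries to the implementation).
* **primary branches** — one record per off-stem child of a stem node,
  at normalized position geodesic(entry→branch point)/stem length.
  Branch points proximal to the entry fall outside [0, 1] and are
  excluded (not clamped) from normalized statistics, since the 0–1
  convention presumes intra-lobe branches; they are kept in an audit
  attribute.  Contralateral branches are normalized on the same axis.
  A branch contacts the PN dendrites when any subtree node lies inside
  the PN region; point-cloud regions carry a contact tolerance
  (default ε = 2 μm, the tracing's node spacing scale — the source says
  "extending to the dendrite region" without a metric), voxel-mask
  regions use ε = 0.  A primary branch is multifurcated when its
  subtree contains at least one internal branch point; each extra child
  beyond the first at any subtree node counts as one secondary branch.

Branch density is primaries per μm of stem; because it is unstated
whether density was computed per antennal-lobe side or whole-axon, both
are emitted, labeled.  Group comparisons use the battery the study
reports: one-way ANOVA with Tukey HSD (gated by Shapiro–Wilk on
residuals and Brown–Forsythe via median-centered Levene),
Kruskal–Wallis with Bonferroni-corrected pairwise Wilcoxon, or
chi-squared on contacting/non-contacting counts with
Bonferroni-corrected pairwise 2×2 tests.

# F-actin profiling

Intensities are sampled per node as the mean over a sphere of radius 1
voxel in voxel index space — matching the line-profile tool convention,
which works in pixels even on anisotropic grids — then min–max
normalized per axon (max → 1, min → 0) over that axon's sampled nodes;
out-of-bounds nodes are flagged missing and excluded from both extremes
and densities.  Whether the original per-axon extremes were taken over
all traced nodes or only branch nodes is unstated; this package uses all
sampled nodes of the axon.

"Total normalized intensity divided by length" is ambiguous between a
node-sum (which depends on node spacing) and an arc-length integral.
The default is the trapezoidal integral divided by segment length —
i.e. the arc-length-weighted mean normalized intensity — because it is
invariant to trace resampling; the node-sum form is available behind a
flag.  The integral form makes concatenation exact: a segment's density
is the length-weighted mean of its parts.  For the within-branch
comparison, each edge of a contacting branch is assigned to the
PN-contacting (+) or non-contacting (−) class by its child node's
membership, so the two class lengths always sum to the branch length.
Between-branch comparisons use the Mann–Whitney U test on whole-branch
densities; within-branch comparisons use a paired t test on per-branch
(+, −) density pairs, restricted to stage-3 axons.  Zero-variance paired
differences with nonzero mean are reported as p = 0 with a degeneracy
warning.

# Synthetic data: what it emulates, and what it does not

All generators are seed-deterministic and return the ground truth needed
to score downstream stages without re-derivation.

**TMT tables.**  Class means on the log2-ratio scale: interactors high
in TRT versus both SR and NC (defaults fc_nc = 3, fc_sr = 2, 50 of
2000); membrane background equally high in TRT and SR (fc_nc = 3,
fc_sr = 0, 200); endogenously biotinylated contaminants high everywhere
including NC, hence flat in ratio space (fc_nc = 0, 100); the rest null.
Noise is i.i.d. Gaussian, sd 0.25 log2 units, a typical TMT
replicate-level spread.  The bait's own fc_nc defaults to 2 — below the
planted interactor class by several noise standard deviations, matching
its role as a permissive floor for true partners — with positive fc_sr.
Unique-peptide counts are 1 + Poisson(4), so a small percentage of rows
fall to the step-1 filter.  Not emulated: peptide-level aggregation,
isotope-impurity leakage, intensity-dependent variance, or correlated
contaminant structure; recovery rates on this generator demonstrate the
filter logic, not performance on real spectra.

**Glomerular volumes.**  Two equal spheres whose separation is solved
from the analytic lens volume for the programmed overlap fraction; truth
indices are recorded from the noiseless voxel masks (so truth is
voxel-exact even where the continuous solution is approximate), and the
observed volumes add Gaussian noise at 5% of the foreground level.  At
64³ the programmed fraction is recovered within ±0.02 through automatic
segmentation.  Real glomeruli are neither spherical nor noise-free in
this simple sense.

**Axons and fields.**  A straight stem (radius 1 μm, nodes every 2 μm)
enters the antennal lobe 20 μm after its root; its length is drawn
per stage (60–95, 105–165, 180–230 μm).  Branch points are drawn along
the stem but strictly proximal to the tip — the growth cone — so the
stem remains a root-to-leaf path and the thickest-path rule is
well-posed.  Contacting branches (probability `p_contact`) are routed to
a random interior target of the PN dendrite sphere (offset 15 μm from
the stem, radius 12 μm): distinct branches enter the dendritic territory
at distinct spots, which matters statistically — aiming every branch at
the sphere center would make different branches' contact zones share
voxels, correlating their intensity samples and invalidating the paired
test's independence across branches.  Non-contacting branches head the
opposite way and can never reach the sphere.  Branch radii are 0.4 μm
(secondaries 0.3 μm), so the stem is always the thickest path.  The
F-actin-like field is a constant baseline (0.5) plus the configured
boost (default Δ = 0.3) on voxels around PN-contact-zone nodes, passed
through a 3-point separable blur and Gaussian noise (sd 0.1).  Because
per-axon min–max normalization and the paired t statistic are both
invariant to common affine transforms, the planted boost is what the
within-branch comparison detects; under Δ = 0 the paired t's type-I
error calibrates to its nominal level.

# Numerical choices and problem sizes

* Trigamma inversion: Newton iteration with the standard stable
  transform, tolerance $10^{-10}$ relative, with asymptotic branches for
  extreme arguments.
* Otsu threshold: 256-bin histogram over the volume's full range.
* Degenerate inputs error loudly rather than returning silent NAs:
  empty denominator masks, zero-length segments, constant profiles,
  all-equal images, missing baits, rank-deficient designs.
* Test and validation problem sizes were chosen so the whole suite runs
  in a couple of minutes on one core: full-scale TMT scenarios (2000
  proteins), 100 random 32³ mask pairs against voxel-loop oracles,
  200 random trees (≤ 50 nodes) against exhaustive path enumeration,
  30 axons for boost detection, and 1000 null simulations (field voxel
  size 2 μm) for the paired-t calibration.  The binomial half-width at
  1000 simulations is about ±0.014 on a 0.05 rate, comfortably inside
  the ±0.02 acceptance band.

# Known limitations

* The filter-count reproduction of the original processed proteomic
  table requires that table as input; the package ships only synthetic
  stand-ins, so those exact counts are checked structurally (nesting and
  brute-force count agreement) rather than numerically.
* Segmentation is global-threshold only; no registration,
  deconvolution, or glomerulus auto-identification.
* The stem-axon rule assumes radii are informative; traces without
  meaningful radii will fall back to geometry-driven ties.
* Generators use straight stems and spherical regions; they validate
  algorithmic correctness and statistical calibration, not anatomical
  realism.
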