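---
title: "Temporal integration of miRNA and mRNA differential expression: methods and design"
author: "miRtempo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal integration of miRNA and mRNA differential expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRtempo)
```

# The problem

Chronic intermittent ethanol exposure perturbs brain gene expression in a
time- and region-dependent way. Because a single microRNA can repress many
transcripts, changes in miRNA abundance measured at intoxication (0 h after
the last exposure), withdrawal (8 h) and protracted abstinence (120 h) can
be linked to downstream mRNA changes *later or at the same time*, never
earlier. `miRtempo` implements that temporal integration as a reusable,
fully testable pipeline for two-group (treated vs control) microarray
designs over three brain regions (amygdala, nucleus accumbens, prefrontal
cortex) and three time points, analyzed independently per region:

1. **Preprocessing** — sample-outlier removal, detection-above-background
   probe filtering, quantile normalization.
2. **Differential expression** — empirical-Bayes moderated t-statistics
   with Benjamini–Hochberg FDR and signed linear fold changes.
3. **Temporal pairing** — confidence filtering of miRNA→target
   interactions and the lag rule producing six paired datasets per region.
4. **Cluster analysis** — hierarchical clustering of centered/scaled
   temporal log-ratio profiles with internal-validation model selection.
5. **Network analysis** — fixed-size, Fisher-exact-scored molecule
   networks grown on an interaction knowledgebase; hub and critical-gene
   calls; cell-type enrichment; a directional consistency score.

Everything runs on data from the package's synthetic generator, so every
stage has a planted ground truth.

# The synthetic study

`simulationConfig()` fixes the study conditions: 3 regions × 3 times × (8
treated + 8 control) animals = 144 samples per platform. Log2 intensities
follow `Normal(mu_probe, noiseSd)`; expressed probes draw baselines from
`Normal(7, 1.5)` and background-level probes from `Normal(4.2, 0.8)`, a
unimodal caricature of microarray dynamic range. Detection p-values are
upper-tail probabilities of each intensity under the background law
`Normal(4, 1)`, so expressed probes detect at p « 0.06 and background
probes do not.

Planted effects use the signed linear fold-change convention (`-1.35`
means control/treated = 1.35). Defaults: 15 DE miRNAs per (region, time)
with |FC| in 1.2–1.6, and 4 targets per DE miRNA with |FC| in 1.03–1.11 —
the magnitude range the critical-gene tables of studies of this design
report. The **lag model** encodes regulation time: miRNAs changed at 0 h
drive target changes at 8 and 120 h; miRNAs changed at 8 h drive targets
at 120 h; 120 h miRNAs have no later time to act on. Targets move opposite
to their miRNA by default (`sameSignFraction` exists because the pairing
itself never requires anti-correlation). Half of each 8 h miRNA's targets
are drawn from the 120 h targets of 0 h miRNAs, planting genes regulated
from both early time points — the ground-truth *critical genes*.

Choices worth stating:

* **noiseSd = 0.04.** The generator's job is to make |FC| ≈ 1.05 planted
  mRNA effects detectable at n = 8/8 (the regime the study's result tables
  live in): with `noiseSd = 0.04` the nominal-0.05 two-sample test has
  ≈ 0.9 power at |FC| = 1.05. Real arrays are noisier; tests that probe
  noise behavior (power, cluster recovery) set their own larger values
  (0.25, 0.15).
* **Outliers.** A *purely* global additive shift is rank-preserving and
  therefore invisible to any correlation-based outlier score, so outlier
  samples receive the global `+3·noiseSd` shift *plus* an independent
  per-probe disturbance of the same scale, which the detection rule sees.
* **Interactions.** Every true pair gets a record passing the confidence
  filter; decoys (50% of the true-pair count by default) are split between
  records that fail the filter (low-confidence prediction, non-conserved
  miRNA, context score above −0.4 without a conserved site) and records
  that pass it but connect molecules not planted as regulator/target.
* **Knowledgebase.** A preferential-attachment graph (heavy-tailed degree)
  over all simulated genes and miRNAs plus filler molecules. Planted hubs
  are filler molecules wired to every molecule of each region's planted
  0 h- and 8 h-derived 120 h-target datasets, i.e. hubs sit at the center
  of both temporal neighborhoods — the property hub identification is
  meant to recover. Gene families of size 3 support merge expansion; one
  cell-type list (`neuron`) is spiked with planted DE targets.

What the generator does **not** emulate: probe-level CEL data and RMA,
probe sequence effects, correlated noise across probes, batch structure,
and annotation migration between miRNA database versions. Passing tests
therefore certify the statistical machinery, not robustness to those
real-data artifacts.

# Preprocessing

**Outliers first, then detection.** Outliers are scored per region on all
mouse probes: each sample's score is its median inter-array Spearman
correlation against its *replicate* arrays (same region, time and
condition, whenever at least three replicates exist; otherwise against
all of the region's arrays), and samples below `median − 3·mad` (scaled
MAD, both estimated over the whole region) are removed. Restricting the
reference to replicate arrays matters: a real treatment effect lowers a
whole group's correlation to the rest of the region in lockstep, and with
region-wide references a strongly responding group can be mistaken for
outliers, whereas replicates share the group effect and cancel it. The
3-MAD rule flags well under 1% of null samples at the study's 48 arrays
per region; regions with fewer than 4 samples are skipped with a
warning.

**Detection filter.** A probe is kept when it is a mature, mouse probe
*and* its detection p-value is `< 0.06` (strict, per the threshold's
wording) on `>= 80%` (inclusive — the boundary is not specified anywhere,
so we state it) of the region's remaining arrays. The filter is evaluated
on whatever samples it is handed; the pipeline hands it one region at a
time, after outlier removal. A flag exists in `preprocessRegion()`'s
building blocks to reorder if desired.

**Quantile normalization** (via `limma::normalizeQuantiles`, ties averaged)
stands in for probe-level RMA, which is out of scope: each sample's sorted
values are replaced by the across-sample mean of sorted vectors, ranks
preserved.

# Moderated t-statistics

For each (region, time) contrast with `n1`/`n2` samples,
`beta = mean(treated) − mean(control)`, pooled variance `s2` on
`d = n1 + n2 − 2` df, and `v = 1/n1 + 1/n2`. The variance prior is fitted
by the closed method of moments on log variances:
`e = log(s2) − digamma(d/2) + log(d/2)`; the excess of `var(e)` over
`mean(trigamma(d/2))` is inverted through the trigamma function (Newton,
tolerance 1e−8) to give `d0`, and
`s0² = exp(mean(e) + digamma(d0/2) − log(d0/2))`. Non-positive excess
variance gives the degenerate prior `d0 = ∞`, `s0² = exp(mean(e))` (note
this carries the log-variance bias correction, so it is *not* numerically
equal to a common `s2` value). Zero-variance probes — possible after
quantile normalization — are excluded from estimation with a warning and
are still shrunk toward `s0²`.

Then `s2_post = (d0·s0² + d·s2)/(d0 + d)` and
`t = beta / sqrt(s2_post · v)` on `d0 + d` df; `d0 = 0` reproduces the
classical pooled t and `d0 = ∞` the normal-tail limit, which the tests
assert to 1e−10, alongside exact agreement with an independent
empirical-Bayes implementation. The prior is constant (no intensity
trend); multi-factor designs and array weights are out of scope.

**Thresholds.** miRNAs: nominal `p <= 0.05` at every time point (an FDR
cutoff at the miRNA stage would starve the downstream network analyses).
mRNA targets: `FDR <= 0.05` at 0 and 8 h, nominal `p <= 0.05` at 120 h —
the late time point produces no FDR-significant genes at this design size,
and dropping it entirely would discard the protracted-abstinence signal
the analysis is about. All boundaries inclusive. Duplicate probes mapping
to one annotation are resolved by minimum p within each time point.

# Temporal pairing

Interaction records pass the confidence filter when experimentally
observed, or predicted with high confidence for a conserved miRNA with at
least one conserved site or a total context score of −0.4 or less
(boundary inclusive). Pairing then forms, per region, the six datasets
`XhDEmiR/YhDEtargets` for every X ≤ Y in {0, 8, 120}: miRNA changes may
precede or accompany target changes, never follow them. Same-time pairs
are included because the six-dataset scheme requires them; a miRNA must be
DE at exactly X (not merely at-or-before) for dataset X, matching the
dataset naming. Empty datasets are emitted under their names. Overlap
summaries (shared-target proportions with the earlier time point as
denominator, multi-time target partitions, three-region Venn classes)
are computed from the same annotation-level DE sets.

# Clustering and validation

Each DE miRNA contributes an ordered triple of log2 ratios (0, 8, 120 h),
centered and scaled per profile (constant profiles map to zero with a
warning). Distances are Euclidean on the scaled triples. Four candidate
algorithms — average, complete and Ward agglomeration plus k-means — are
evaluated over k = 2..8, a range bracketing the cluster counts such
three-point designs produce. The agglomeration is written to be exactly
reproducible: ties in the minimum inter-cluster distance are broken by the
lowest pair of cluster labels, and k-means is initialized from Ward-cut
centroids, so the whole stage is deterministic and permutation-invariant
on tie-free data. Merge heights match `stats::hclust` and a brute-force
recompute-from-scratch oracle in the tests.

Model selection ranks every (algorithm, k) by connectivity (ascending;
with `L = 10` neighbors, the j-th nearest neighbor outside the cluster
contributing 1/j), Dunn index and mean silhouette (descending; points in
singleton clusters contribute 0 — three-point profiles invite ties and the
convention must be fixed), and picks the best mean rank; ties break toward
smaller k, then earlier algorithm. The published analyses report the
number of *visually* non-overlapping patterns; we rely on the
validation-measure ranking alone, which recovers 5 and 6 planted patterns
essentially always at the tested noise level (0.15).

# Networks

The reference implementation of knowledgebase network construction is
proprietary, so `buildNetworks()` is a documented greedy reinterpretation
preserving the published contract: 35-molecule, connectivity-maximizing,
Fisher-scored, ranked networks seeded from dataset ("focus") molecules.
The seed is the unused focus molecule with the most knowledgebase edges to
other focus molecules; growth always prefers a connected focus candidate
over any non-focus connector, and within that preference takes the
candidate with the most edges into the current network (ties: higher total
knowledgebase degree, then lexicographic id). Making focus membership the
primary key keeps networks anchored to the dataset — with edge count
primary, high-degree knowledgebase-core molecules crowd out the dataset
entirely, which contradicts the published networks' focus fractions
(roughly 17–23 focus of 35 molecules). Focus molecules consumed by one
network are unavailable to the dataset's later networks, so ranks are
meaningful. The score is `−log10` of the right-tailed hypergeometric
p-value for the network's focus content against the knowledgebase
universe; published scores were computed inside a proprietary universe and
are not comparable numerically.

`growNetwork()` adds the top-n candidates (default 10) by edge count into
the network, requiring at least one edge, used sequentially with the 0 h
and then 8 h DE target sets. Merging the top 3 networks from the
0 h-miRNA/120 h-target and 8 h-miRNA/120 h-target datasets (expanding gene
families to all members present in the dataset) and intersecting with the
120 h DE genes yields the critical network genes. Hubs are molecules with
top-3 within-network degree in networks from at least two distinct
datasets; `topK = 3` is configurable since no published value exists.
Cell-type enrichment is a right-tailed Fisher exact test against the
platform's gene universe. The directional z-score
`(n_consistent − n_inconsistent)/sqrt(n_total)` is a sign-consistency
summary only, not a causal regulator score, and is labeled as such in
outputs. miRNA→target edges from the filtered interaction table are
injected into the knowledgebase before construction so miRNAs can appear
in networks.

# Numerical and engineering choices

* All randomness flows from one seed; the interaction and knowledgebase
  generators use fixed offsets of it. Identical configuration and seed
  give bit-identical outputs, including the pipeline manifest.
* BH adjustment wraps the standard step-up implementation
  (`stats::p.adjust`); Fisher tails use `stats::phyper`/`fisher.test`.
  Both are checked against brute-force definitional oracles in the tests.
* Degenerate inputs are defined, not accidental: empty detection-filter
  results warn; empty earlier target sets make the overlap proportion
  absent (`NA`); `s2_post = 0` flags the probe's p-value as undefined;
  hub calling without two datasets returns no hubs with a warning.
* Test and acceptance problem sizes (600 miRNA probes, 2400 mRNA probes,
  3500 knowledgebase molecules, 20-seed recovery loops, 50 × 2000-probe
  null replicates) were chosen so the full suite exercises every stage at
  the study's design in minutes on one core.

# Known limitations

Constant-prior variance moderation only; no probe-level preprocessing; no
sequence-based target prediction (interaction tables are inputs); the
greedy network procedure is a reinterpretation, so published network
scores, memberships and functional annotations are not reproduction
targets; and the synthetic noise model is homoscedastic and independent
across probes, which real arrays are not.
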