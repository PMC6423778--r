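---
title: "Methods: detection-call signatures, community detection, and membrane densitometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection-call signatures, community detection, and membrane densitometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rejuvsig)
```

# The problem

Mesenchymal stromal cells (MSCs) from elderly donors carry transcriptomic and
secretory hallmarks of aging; MSCs re-derived from induced pluripotent stem
cells (iMSCs) appear to shed them. `rejuvsig` implements the computational
pipeline by which such "aging" and "rejuvenation" gene signatures are derived
from bead-array detection calls, validated by clustering, expanded into
protein-association networks with community structure, and complemented by
cytokine-membrane secretome quantification. Every stage can be exercised on
synthetic data with planted ground truth, so the pipeline's operating
characteristics are measurable rather than assumed.

# Detection model

Illumina-style bead arrays carry several hundred negative-control beads per
sample. For gene $g$ in sample $s$ with signal $x_{gs}$ and control signals
$c_{1s}, \dots, c_{ns}$, the detection p-value is the add-one empirical
upper tail

$$p_{gs} = \frac{1 + \#\{i : c_{is} \ge x_{gs}\}}{n + 1},$$

with ties counted as exceedances. This never returns exactly 0, lies in
$(0, 1]$, and is monotone nonincreasing in the signal. Its granularity is
$1/(n+1)$: the signature rule below demands $p < 0.001$, which is attainable
only with $n \ge 999$ controls; the simulator therefore defaults to 1,000
negative controls per sample. A gene is called *expressed* in a sample at
$p \le 0.05$.

Background correction subtracts each sample's median control signal from
every gene (and from the controls themselves), flooring at $\varepsilon = 1$
signal unit so logs stay defined. Median-of-controls subtraction is the
simplest defensible reading of bead-array background correction and is
rank-preserving, so detection p-values are unaffected except at the floor.
Quantile normalization maps every column onto the row-mean of the sorted
columns; tied values receive the mean of the reference quantiles their rank
run spans, which makes the result independent of input order and the
transform idempotent. Clustering and heatmaps operate on
$\log_2(\text{normalized} + 1)$; detection p-values always operate on the
linear scale, against controls on that same scale.

# Signature rules

With one detection p-value per gene and group (see below for the collapse),
the two signatures are pure presence/absence combinations with an
"expressed" bound of 0.001 and an "absent" bound of 0.1:

* **aging**: $p_\mathrm{MSC} < 0.001 \wedge p_\mathrm{iMSC} > 0.1 \wedge
  p_\mathrm{iPSC} > 0.1$ — expressed in parental MSCs, absent after
  reprogramming and re-differentiation;
* **rejuvenation**: $p_\mathrm{MSC} > 0.1 \wedge p_\mathrm{iMSC} < 0.001
  \wedge p_\mathrm{iPSC} < 0.001$ — the mirror rule.

All inequalities are strict; a gene in the dead zone $[0.001, 0.1]$ for any
group joins neither set, and the two sets are disjoint because the rules
demand contradictory MSC states.

**Group collapse.** The rules need one p per group, but a group has several
samples. `group_detection()` exposes three policies — `max` (a gene counts
as expressed only if detected in *every* sample of the group), `min`, and
`single:SAMPLE` — and one policy is applied uniformly to all groups rather
than mixing a conservative rule on one side with a liberal one on the
other, which would bias the signature sizes asymmetrically. The default is
`max`; `single:` mode reproduces per-sample analyses. The parental "MSC"
group is the pool of all fetal-MSC and adult-MSC samples.

# Synthetic bead data: what it emulates and what it does not

`sim_config()` / `generate_bead_summary()` emulate the study design: five
groups (fMSC, aMSC, iPSC, iMSC, ESC) with 3/4/5/3/2 samples, mirroring a
typical bead-array study of this kind. Signals are log-normal:
unexpressed genes and negative controls share one null distribution
($\log_2$-normal, mean 7, sd 0.5 — arbitrary fluorescence units at a
HumanHT-12-like scale), expressed genes sit 4 $\log_2$ units above the null
mean (sd 0.25) with additional $\log_2$-normal measurement noise (sd 0.25).
Because the null is shared, null detection p-values are uniform on the
$1/(n+1)$ grid *by construction* — the calibration the pipeline's KS check
verifies. Planted rejuvenation genes draw expressed-level signals in iMSC,
iPSC and ESC samples and null-level signals in fMSC/aMSC; planted aging
genes the converse; all other genes are expressed either in every group or
nowhere.

The background spread matters more than it first appears: at $n = 1000$
controls, $p < 0.001$ is attainable only by beating *every* control, so
power over a group under the `max` policy is governed by the most extreme
control maximum among the group's samples. A direct simulation of the full
rule (per-seed recovery across the 7 MSC and 8 iMSC+iPSC samples, 60
replicate experiments) shows that a null sd of 0.8 lets an occasional
extreme control draw pull recovery below 48/50, whereas at the chosen
sd of 0.5 the per-sample probability that an expressed gene beats all
1,000 controls is indistinguishable from 1 and recovery of planted genes
is complete in every replicate. False positives are essentially impossible
under the `max` policy: a null gene would need to top all 1,000 controls
in every sample of a group, probability $(1/1001)^{\#\text{samples}}$.

The generator does **not** model probe-level effects, batch effects,
cross-hybridization, within-expressed fold-change structure between the two
MSC ages, or correlated noise. Passing tests therefore demonstrate that the
*rules and code* behave as specified under a calibrated signal model — not
that real arrays are free of those artifacts.

# Differential expression

The unmoderated test is the classical pooled-variance two-sample t on
$\log_2$ signals. The moderated variant shrinks each gene's variance toward
the across-gene mean variance $s_0^2$ with a fixed prior weight of
$d_0 = 4$ degrees of freedom,
$\tilde{s}^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, referring $t$ to $d + d_0$
degrees of freedom — a deliberately simple empirical-Bayes scheme whose
behaviour is fully specified here rather than inherited from a fitted
hyperparameter. FDR control defaults to Storey q-values with $\hat\pi_0$
from the natural-spline smoother of
$\#\{p > \lambda\}/(m(1-\lambda))$ over $\lambda = 0.05, \dots, 0.95$
evaluated at $\lambda = 0.95$ (clipped to $(0,1]$); q-values are
$\hat\pi_0$ times the Benjamini–Hochberg step-up values, so they are
monotone in p and at most 1. Plain BH is available.

Up/down calls gate on $q \le 0.05$ and require a linear-scale mean ratio
strictly above 1.33 (up) or strictly below 0.75 (down); the boundary values
themselves are never called. A stricter unadjusted-p 0.01 gate, used by
some analyses of this kind, can be reproduced by passing raw p-values with
`q_threshold = 0.01`; neither gate is hard-coded. Relative qPCR
quantification uses $2^{-\Delta\Delta C_t}$ with a housekeeping reference
gene.

# Clustering and enrichment

Sample similarity is $1 - r$ (Pearson) on $\log_2$ normalized signals,
clustered by average-linkage `hclust` (complete, single and Ward linkage
available; average is the customary default for correlation distances in
expression work). Trees serialize to Newick; cutting at $k$ gives
partitions. Gene-subset heatmap matrices report requested-but-absent genes
explicitly. Over-representation of a gene set against user-supplied
annotation lists uses the one-sided hypergeometric upper tail with BH
adjustment across terms — a generic, offline replacement for web-service
annotation tools.

# Protein-association networks

From a BioGRID-style tab-delimited table, rows are kept only when both
interactors carry taxonomy id 9606; symbols are uppercased, self-loops
dropped, duplicate pairs collapsed (counts retained as provenance). The
signature network keeps every interaction touching at least one seed
(signature-coded protein), then is reduced to the $n = 30$ non-seed
interactors with the most interactions to seed proteins — read as *distinct
seed partners*, since the defining phrase scopes the count to the original
sets; ranking by global degree is available as an alternative. Ties break
lexicographically by symbol so the reduction is deterministic.
Interactor–interactor edges among retained nodes are kept by default
(`seed_edges_only` gives the narrower reading).

Community detection is Girvan–Newman: edge betweenness (Brandes
accumulation on unweighted shortest paths, unordered-pair convention with
endpoints included) is recomputed after every removal of the
highest-betweenness edge (ties again lexicographic by edge label), and the
returned partition is the component structure along the removal sequence
maximizing Newman–Girvan modularity

$$Q = \sum_c \left[\frac{m_c}{m} - \left(\frac{d_c}{2m}\right)^2\right]$$

*on the original graph*, with the pre-removal component partition competing
as well. A new optimum must exceed the incumbent by more than $10^{-12}$ to
replace it, so floating-point noise cannot flip the earliest-cut
preference. Tests cross-check betweenness and modularity against brute-force
path enumeration and exhaustive partition search on graphs of up to 8
nodes, and against an independent graph library.

# Secretome membranes

A membrane layout fixes spot centers, radii and exactly three reference
positions (upper-left, lower-left, lower-right corners — reference spots
are printed in duplicate on real arrays; duplicates, like duplicate analyte
spots, are averaged at the raw-density stage). Spot density is integrated
disc intensity minus disc area times the local background — the median of
an annulus between $r$ and $2r$ — clipped at 0; when another spot's disc
encroaches on the annulus, the global image median substitutes, with a
warning. Analytes are reported as percent of the mean reference density:
constant offsets cancel exactly on noise-free images. Classification is
strict: above 20% of reference is *abundant*, above 5% *secreted*,
otherwise *not secreted*. Mean vs integrated density and rolling-ball vs
annulus background are not canonically fixed by common ImageJ practice;
integrated density with annulus background is the documented choice here.

The membrane simulator renders each spot as a Gaussian blob
(sd = radius/3.5, so over 99% of its mass falls inside the disc) whose
integrated intensity is proportional to planted abundance, with reference
spots at the fixed abundance that defines 100%; images round-trip through
16-bit grayscale TIFF (8-bit storage would quantize faint spots to
nothing). It does not model blooming, saturation, spatial background
gradients, or grid misregistration — layout coordinates are authoritative,
and automatic registration is out of scope.

# Problem sizes and determinism

The test suite and the acceptance script run on deliberately desk-scale
instances — a 1,000-gene universe with 50 + 50 planted signature genes and
1,000 negative controls; 10,000 null draws for the calibration check; 200
random graphs of ≤ 8 nodes for the exact betweenness cross-check; a 2 × 8
planted-partition graph; 12–16-spot membranes — sizes at which the
brute-force oracles are exact and the whole pipeline completes in seconds
while every code path is exercised. All generators take explicit integer
seeds and are bitwise reproducible; equal seeds give equal outputs.

# Known limitations

* The group-collapse policy materially affects signature size on real data
  with heterogeneous preparations; `max` is conservative by design.
* The moderated test is a fixed-prior stand-in, not a replacement for a
  fitted hierarchical model; with very few genes its shrinkage target
  $s_0^2$ is itself noisy.
* $\hat\pi_0$ estimation is unstable for small p-value sets; for fewer
  than a few hundred tests BH is the safer default.
* Girvan–Newman recomputes betweenness after every removal
  ($O(nm^2)$ overall); it is meant for the few-hundred-node networks this
  pipeline produces, not for full interactome graphs.
* Membrane quantification assumes disjoint spot discs and a locally flat
  background.
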