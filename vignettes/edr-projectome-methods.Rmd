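---
title: "Methods: EDR network models for region-level connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EDR network models for region-level connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edrnet)
```

## The scientific problem

The exponential distance rule (EDR) is the empirical observation that the
probability of a neuron projecting over a cable length $d$ decays
exponentially, $p(d) = c\,e^{-\lambda d}$. At the level of brain regions
this single geometric fact, plus a region distance matrix $D_{ij}$ and the
observed number of inter-region connections $M$, defines a one-parameter
maximum-entropy random-network model. Comparing a measured region-level
network (a *projectome*) with EDR-model ensembles separates the network
properties that follow from geometry alone from those that demand a
functional explanation — most notably the strong directional asymmetry of
connection weights, which tracks the functional hierarchy of regions.

`edrnet` implements this entire analysis as reusable, tested functions:
cable-length morphometry on neuron skeletons and decay-rate fitting,
projectome construction from synapse tables, the EDR generator and its
$\lambda = 0$ limit (the constant distance rule, CDR), a binary/weighted
property suite with RMSD model-vs-data comparison over a $\lambda$ grid,
weight-asymmetry and hierarchy measures, and hierarchical clustering of
information-flow profiles. Because the real connectome export cannot be
redistributed, the package ships a synthetic-data generator that emulates
the statistical structure of those inputs with known ground truth; the
test suite and the `analysis/` workflow run end-to-end on it.

## The synthetic-data generator and what it emulates

`make_atlas()` samples region centroids uniformly inside an axis-aligned
ellipsoid (semi-axes $0.5, 0.35, 0.25$ of the 0.6 mm spatial scale — a
fly-brain-like extent) with exact mirror symmetry across the $x = 0$
midplane; bilateral regions carry `_L`/`_R` suffixes, central regions sit
on the midplane. Uniform sampling in an ellipsoid produces a unimodal,
truncated-Gaussian-like pairwise distance distribution, which is the
feature of real neuropil centroid geometry that matters for the EDR model;
no finer anatomy is modelled. The default study scale is 37 bilateral
pairs plus one central region ($N = 75$).

`make_skeletons()` emulates the insect neuron layout: soma on the domain
surface, a primary neurite to an interior branch point, and star-like
dendritic and axonal arbors (3–20 points each, radii 5–20 µm) around the
two arbor anchors. The tree-path length between the closest postsynaptic
and closest presynaptic point — the *main cable* — is drawn from
$\mathrm{Exp}(\lambda_d)$, and the straight-line distance between the same
two points equals the main cable length divided by the tortuosity factor
$a \ge 1$, up to a bounded relative jitter (default $\le 5\%$). The
geometry is arranged so both quantities are *exactly* realized on the tree
(the branch point is offset perpendicular to the post–pre axis by
$\sqrt{L^2 - E^2}/2$), giving the morphometry code a machine-precision
oracle. Defaults are $\lambda_d = 22\ \mathrm{mm^{-1}}$ and $a = 1.5$, so
Euclidean cable lengths decay at $a\lambda_d \approx 33\ \mathrm{mm^{-1}}$
— the regime of the fly measurements. Star arbors are deliberately minimal:
they exercise the closest-point and averaging logic but say nothing about
real arborization, synapse polyadicity, or electron-microscopy artifacts,
so passing tests validate the *measurement pipeline*, not biological
realism.

`make_projectome()` runs the EDR generator on the atlas distance matrix
(by default at the Euclidean rate $a\lambda_d$, since the region model
sees only Euclidean distances) and then imposes directional asymmetry: a
hierarchy score $h \in [0,1]$ per region *base name* (bilateral partners
share a score), and for every reciprocally connected pair a multiplicative
factor $e^{+\beta\,\Delta h}$ on the direction flowing up the hierarchy
and $e^{-\beta\,\Delta h}$ on the reverse, followed by column
renormalization. Homotopic pairs share a score, so their bias factor is
exactly 1 by construction. This injection is a testing device — a minimal
mechanism that produces a right-skewed asymmetry distribution with
symmetric homotopic links — not a claim about how real asymmetries develop.
$\beta = 12$ is the "strong bias" condition under which hierarchy recovery
is tested; at this strength the recovered asymmetry out-strength ranking
correlates with the inverse injected hierarchy at Spearman $\rho > 0.8$.

Two consequences of this design are worth recording because they differ
from what one might naively expect:

* Under the *unbiased* EDR model, homotopic pairs are already much more
  symmetric than average. Mirror partners differ only in $x$, so homotopic
  centroid distances are short, those pairs accumulate many multi-edges,
  and their relative Poisson weight noise — the only source of model
  asymmetry — is small. The geometric model itself predicts symmetric
  homotopic links; tests therefore check that the bias *injection* leaves
  homotopic asymmetry unchanged (an equivalence bound on the
  biased-vs-unbiased shift) rather than pretending the unbiased
  distributions of homotopic and non-homotopic pairs coincide.
* Model-ensemble clustering is spatially local, not bilateral. The
  clustering features are incoming-flow profiles (columns of the
  link-length matrix), and the profiles of mirror partners are mirror
  images with nearly disjoint support, so bilateral partners do *not*
  preferentially co-cluster in EDR ensembles; spatially neighboring
  regions do. The co-clustering test asserts locality
  ($\mathrm{cor}(P, -D) > 0.3$).

## Cable-length measurement and decay-rate fitting

`measure_neuron()` computes soma-path distances to all synaptic points
(`path_length_to_node()` sums Euclidean edge lengths along the unique
root path), takes the closest pre- and postsynaptic points, and measures
the tree path between them; the soma and primary neurite drop out
automatically because the path between two non-root nodes never traverses
the root. The arbor-consistency filter discards neurons whose closest
synaptic point sits more than 0.15 mm (default) nearer the soma than that
arbor's average — the signature of mispredicted or nontraditional
synapses. Hemisphere labels use the sign of $x$ with a configurable
midline band (default half-width 5 µm) because real atlases leave the
midline convention open.

`fit_edr()` mirrors the histogram-based slope reading: for each bin width
(defaults 0.01, 0.02, 0.05 mm — representative small/medium/coarse
resolutions, since the empirical analysis reports a bin-size sensitivity
interval rather than one width) it regresses log bin mass on bin center
over the bins from the modal bin upward with nonzero counts, and reports
the per-bin-size spread as an interval. Two numerical choices matter:

* *Fit range from the modal bin upward*: the left edge of empirical length
  histograms is geometry-depleted; only the tail is exponential.
* *Count-weighted least squares*: the sampling variance of a log-count is
  $\approx 1/\mathrm{count}$, and unweighted regression lets isolated
  single-count tail bins (a flat log floor) drag the slope down by ~10%.
  With weights the estimator recovers $\lambda \in \{20, 33, 50\}$ within
  0.1–2% at $n = 10^4$ and agrees with the closed-form exponential MLE
  `fit_edr_mle()` ($1/\bar x$), which is kept as an independent
  cross-check. For an exponential law the bin mass is exactly
  $\propto e^{-\lambda c}$ at bin center $c$, so binning itself does not
  bias the slope (it only affects the intercept, whether one fits mass or
  density).

`scaling_factor()` fits the cable-on-Euclidean slope through the origin —
zero straight-line separation must imply zero cable — and reports Pearson
correlation.

## Projectome construction

Per neuron, the incoming and outgoing synapse-fraction vectors (fractions
of its postsynaptic / presynaptic points per region) are combined as an
outer product: entry $(i,j)$ is the probability of the neuron receiving in
region $i$ and sending from region $j$. Summing over intrinsic neurons
(afferent/efferent neurons are excluded by the class filter) and
column-normalizing yields $w_{ij}$, the probability of information flowing
from region $i$ to region $j$; every connected region's in-strength is
exactly 1. The five-synapse connection threshold is applied where
neuron-pair counts exist (the real export arrives pre-thresholded).
Diagonal (within-region) mass participates in column sums by default but
is excluded from the adjacency, the link count $M$, and all network
analyses; `include_diagonal` exposes `drop`/`keep` alternatives because
the normalization semantics for self-flow are genuinely open.

## The EDR generator

The generative process: (a) draw a distance bin with probability
$\propto e^{-\lambda c_b}$ among nonempty bins of the region-pair distance
histogram (uniform among nonempty bins at $\lambda = 0$ — the CDR is a
flat *length* distribution, not a flat pair distribution); (b) draw a
region pair uniformly within the bin; (c) orient uniformly; multi-edges
accumulate as weights, and the process stops when the number of distinct
directed binary links reaches $M$, after which multi-edge counts are
column-normalized. Bin width defaults to $\max(D)/50$; bin probabilities
are normalized in log space so large $\lambda\,d$ cannot underflow.

The default realization is the exact continuous-time embedding of this
process: each directed pair $i$ has placement rate $p_i$ (bin probability
$\times$ 1/pairs-in-bin $\times$ 1/2), its first arrival is
$\tau_i \sim \mathrm{Exp}(p_i)$, the process stops at the $M$-th smallest
$\tau$, and each discovered pair receives $1 +
\mathrm{Poisson}((S - \tau_i)\,p_i)$ multi-edges, $S$ being the stopping
time. Because "reach $M$ distinct links" is a stopping time of both the
discrete draw sequence and its Poissonization, the resulting multi-edge
counts are identical in distribution to the literal loop, but generation
is $O(P \log P)$ in the number of directed pairs and *independent of
$\lambda$* — the literal loop needs on the order of $e^{\lambda d}$ draws
to discover the farthest required pairs (prohibitive above
$\lambda \approx 40\ \mathrm{mm^{-1}}$ at fly scale). The literal batched
sampler is retained as `method = "direct"` and the two are cross-checked
distributionally in the tests. Ensembles are seeded per network
(`base seed + index`), analysed strictly per network, and only property
summaries are aggregated — never an averaged network, whose density and
properties would be misleading.

## The property suite and model comparison

Binary properties: sorted in-/out-degree spectra, uni-/bidirectional pair
counts, average binary path length (mean over reachable ordered pairs,
unreachable pairs counted separately), the directed clustering coefficient
(neighborhood = union of in- and out-neighbors, directed links counted
inside, $k_i < 2$ contributing 0), the 16-class directed triad census, and
clique counts on the graph of bidirectional pairs (a directed clique
requires links both ways). Standard graph algorithms (shortest paths,
components, triad census, clique enumeration) are delegated to `igraph`;
every one is verified against hand-rolled brute-force oracles —
exhaustively over all 4,096 labeled 4-node digraphs and on random larger
cases. The paper-specific directed clustering coefficient and local
efficiency are implemented directly, as no installed package provides
those exact variants.

Weighted properties use link lengths $l_{ij} = -\log w_{ij}$ (natural log
internally — shortest paths and argmin $\lambda$ are base-invariant;
histograms are displayed in $\log_{10}$), node distances $r_{ij}$ as
weighted shortest paths, global efficiency as mean inverse resistance
(unreachable pairs contribute zero conductance; exact-zero distances are
excluded and counted), and local efficiency among each node's neighbors
after removing the node. Efficiency-vs-density curves remove links in
weight order *without* renormalizing survivors (renormalization would
change the lengths of untouched links); ties break deterministically by
(weight, source label, target label). Backbone extraction deletes the
weakest link whose removal preserves strong/weak connectivity; since
removals never restore connectivity, a skipped link stays unremovable and
one ascending pass suffices.

`compare_to_ensemble()` computes, per $\lambda$ and property, the RMSD
between the data's property vector and each model network's, then averages
over the ensemble (per-network-then-average, consistent with analysing
networks separately; the alternative of comparing to the ensemble-mean
curve is not offered because it is exactly the averaged-network fallacy in
histogram form). Distribution-valued properties are binned on shared edges
derived from the data network, with model values clamped into the edge
range so no mass is lost. The pooled curve averages per-property curves
after normalizing each by its mean over the grid; curves that are
identically zero are dropped as uninformative — at 85% density every
network has diameter 2, which makes the binary APL a deterministic
function of $M$ and its RMSD curve exactly zero. At the study scale the
pooled argmin recovers a generating $\lambda^* = 33\ \mathrm{mm^{-1}}$
within one grid step (±5) over the grid $0, 5, \dots, 60$.

## Asymmetry and hierarchy

$\mathrm{ASYM}_{ij} = |w_{ij} - w_{ji}|/(w_{ij} + w_{ji})$: 0 for
symmetric pairs, 1 for unidirectional ones; symmetric in its arguments and
scale-invariant. Histograms default to bidirectional pairs only (20 bins
on $[0,1]$), matching the convention of reporting unidirectional pairs
separately. The asymmetry network keeps one directed link per connected
pair, oriented along the dominant direction with weight ASYM;
unidirectional pairs enter with weight 1 by default, and exact ties
produce no link (the weight would be 0). Asymmetry out-strength ranks
regions from hierarchy bottom (sensory-like, mostly outgoing asymmetry) to
top. Central (unsuffixed) regions are classed ipsilateral with each other
and "unpaired" against lateral regions — a convention, since the
left/right scheme does not define them.

## Clustering

Regions are clustered on their incoming-flow profiles — columns of the
link-length matrix — with absent links filled by a large finite constant
(1.05 × the maximum observed length, so absent reads as "very weak"
without breaking Euclidean/correlation geometry; infinity would).
Ward's method (`hclust` "ward.D2") requires the Euclidean metric;
average/complete linkage support correlation and cosine dissimilarities
($1 - $ similarity). The ensemble contingency matrix $P$ (fraction of
networks co-clustering each pair at fixed $k$) is itself clustered with
complete linkage on $1 - P$, which is not a Euclidean embedding.

## Problem sizes and limitations

The shipped study conditions are the fly scale ($N = 75$, $M = 4733$,
$\lambda$ grid 0–60) with ensembles of 100 networks per $\lambda$ and
skeleton cohorts of 10,000 — sizes chosen so the whole workflow and test
suite run comfortably on a laptop-class single core while keeping every
statistical check well-powered; the generator and suite handle larger
ensembles unchanged. Clique *counting* is exponential in dense graphs and
is exercised at sizes 3–5 (maximum-clique search is fast and unrestricted).
Known limitations: the synthetic atlas has no real anatomy, so per-region
results (cluster identities, rankings) are meaningful only against the
injected ground truth; the asymmetry injection is a test device; and the
empirical decay-rate intervals of the real fly data cannot be reproduced
without the original connectome accession — the package reproduces the
*method*, with parameter-recovery tests standing in for the measurement.
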