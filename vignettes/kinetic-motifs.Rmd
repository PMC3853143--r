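---
title: "Kinetic motifs: model, calibration and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic motifs: model, calibration and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinmotif)
```

## The dynamical model

`kinmotif` models a transcriptional circuit in which each gene *i* has at
most one repressor *j*. The protein concentration $x_i(t)$ (nM) evolves in
discrete unit time steps by

$$\dot x_i = p_{i,0} + p_i\, r_i(x_j) - d_i x_i,
\qquad r_i(x) = \frac{1}{1 + (x/K_i)^{n_i}},$$

with basal production $p_{i,0}$ (nM/step), production rate constant $p_i$
(nM/step), degradation rate constant $d_i$ (1/step), and a Hill repression
function with constant $K_i$ (default 1000 nM) and coefficient $n_i$
(default 2); unregulated genes have $r_i = 1$. The noise-perturbed variant
perturbs each kinetic parameter with amplitude proportional to a fresh
standard-normal draw $n_i(t)$ per gene per step, and adds extrinsic noise
$v_i(t)$:

$$\dot y_i = f_i(y) +
\big(\Delta p_{i,0} + \Delta p_i\, r_i(y_j) - \Delta d_i\, y_i\big)\, n_i(t)
+ v_i(t).$$

Both $n_i$ and $v_i/\sigma_v$ are independent standard normal. Gaussian
zero-mean noise is the conventional reading for "randomly generated"
intrinsic/extrinsic perturbations in this modelling literature; nothing in
the pipeline depends on the distributional family beyond zero mean.

The two modes answer different questions: the deterministic run gives the
mean dynamics of a parameter set, the stochastic run asks whether those
dynamics survive parameter fluctuation and extrinsic disturbance. A
parameter set is only accepted into the handbook if it is functional under
*both*, which is what "robust" means operationally here.

## Scoring and the solution map

A target specification gives per-gene steady-state concentrations $z_i$, a
relative tolerance (default 20%) and a sentinel value (default 15). Each
simulated set is scored by the log-summed absolute deviation over all genes
and all recorded steps $t = 1..T$:

$$DD \;(\text{or } DS) = \ln\Big(\sum_i \sum_t |x_i(t) - z_i|\Big).$$

Deviations are deliberately **not** normalised across genes; the 20%
per-gene steady-state rule is what keeps the smallest target (CI at 300 nM)
from being swamped by the 30,000 nM genes in the acceptance decision. The
sentinel replaces the deviation when a run aborts (any concentration above
$10^6$ nM, or non-finite) or when any gene's steady state — the mean of the
last $\lceil T/2\rceil$ recorded steps — misses its target by more than the
tolerance. For the demo conditions the largest deviation a well-behaved run
can attain is $\ln(4 \times 100 \times \max_i 0.2 z_i) \approx 14$, so 15
cleanly dominates it. A trajectory that matches the target exactly at every
step would make the log undefined; the floor value $-30$ is returned instead
(unreachable in practice because transients always contribute).

Every set therefore lands in one of four quadrants — functional in both
modes, only deterministically, only stochastically, or neither — and the
four counts always partition the grid.

## The level grid

Each gene contributes a production and a degradation slot; each slot's range
$[lo, hi]$ is cut into `n_levels` (default 5) uniform bins whose midpoints
represent them, mirroring the weak-to-strong part categories of component
registries. Binning is a partition (right-open bins, closed last bin), so
values round-trip through levels, and the full grid is enumerated in
lexicographic order — which fixes the row order of every scan output and
gives each set a stable index used to derive its noise substream.

## Calibration of the demo configuration

The demo circuit is the TetR ⊣ LacI ⊣ CI ⊣ Eyfp cascade with
$z = (1000, 30000, 300, 30000)$ nM, $T = 100$, ceiling $10^6$ nM, 20%
tolerance, sentinel 15, and initial concentrations at the target (starting
at $z$ is what makes the steady-state tolerance rule meaningful within 100
steps for slow degradation rates). TetR is unregulated by default: the
dynamics of a chain of repressions are what the level analysis probes, and
an optional looped preset (Eyfp ⊣ TetR) is available for users who want the
closed topology; the open form is the one whose gene-by-gene fixed point is
analytic, which the test suite uses as an oracle.

The per-gene level ranges are calibrated so that *level-matched*
production/degradation pairs put each gene's fixed point on its target:

* **TetR** (unregulated): $p \in [0, 200]$, $d \in [0, 0.2]$. Bin midpoints
  sit at the same relative positions in both ranges, so any matched pair
  gives $p/d = 1000$ nM — independent of the number of levels.
* **LacI** (repressed by TetR at 1000 nM, $r = 1/2$): $p \in [0, 12000]$,
  so matched pairs give $0.5\,p/d = 30000$ nM.
* **CI** (repressed by LacI at 30,000 nM): $r = 1/901$, so regulated
  production is negligible no matter the level — this is the mechanistic
  basis of CI's level-indifference. Its concentration is carried by a basal
  rate of 6.5 nM/step against $d \in [0.018, 0.0255]$, a range narrow enough
  that $p_0/d$ stays within 20% of 300 nM across *all* degradation levels.
  Both CI slots are therefore inconsequential, and handbook logos show
  wildcards there.
* **Eyfp** (repressed by CI at ~300 nM, $r \approx 1/1.09$):
  $p \in [0, 6540]$, so matched pairs give ~30,000 nM.

This calibration was derived from the fixed-point equations, not fitted to
any output. Its consequences are emergent: on the full 5-level grid, 2,499
of 390,625 sets (0.64%) are functional under both conditions, a few hundred
in exactly one, and 99.2% in neither; functional sets are strongly enriched
for matched (p, d) pairs; and CI's levels are uniformly represented. A
generic (uncalibrated) scheme defaults to global ranges $p \in [0, 6000]$,
$d \in [0, 0.2]$ for non-demo circuits — users reproducing a published
range set should supply it per gene via the config file, as the demo does.

Noise defaults are 10% of each nominal parameter for the parametric
amplitudes and $\sigma_v = 10$ nM/step extrinsic noise. The relative form is
the natural one for a scan where nominal values differ by orders of
magnitude between sets; 10% parameter fluctuation and a ~10 nM/step
disturbance are moderate perturbations for nM-scale gene expression, strong
enough that a visible fraction of deterministically functional sets fail
stochastically (the interesting quadrant) without wiping out the functional
set entirely.

## Numerical scheme

Integration is explicit Euler with step size 1 per recorded step
(Euler–Maruyama in the stochastic mode, noise scaled by $\sqrt{h}$ when
substeps are used). The default is one substep in **both** modes: the model
is a discrete per-step update, and identical stepping is what makes the
zero-noise stochastic trajectory bit-identical to the deterministic one —
so with all amplitudes zero, $DS = DD$ exactly, a property the tests assert.
Accuracy is adequate because all demo rates satisfy $d \ll 1$ per step; the
suite checks simulated steady states against the analytic cascade fixed
point (solved gene by gene in dependency order, an integrator-independent
route) to within 1% on converged runs. An optional substep count is
available for stiffer configurations. Negative intermediate concentrations
are clamped to zero after every substep — concentrations are physical — and
any non-finite state is treated as an abort, not an error.

Reproducibility: each parameter set's noise stream is an independent
substream seeded from the master seed and the set's lexicographic index, in
a fixed draw order (the full intrinsic block, then the extrinsic block).
Hence a full vectorised scan, a re-run with different chunking, and a
single `evaluate_set()` call all produce bit-identical results, and the
exported tables are byte-identical across runs. One stochastic replicate is
scored per set (one DS per set); the replicate count is not a config
option because averaging replicates would change the meaning of the
stochastic quadrants — users wanting robustness curves can rerun the scan
under different master seeds.

## Clustering, logos and ranking

Functional sequences are clustered agglomeratively on their pairwise Hamming
distances (`stats::hclust`). Average linkage is the default (complete and
single are selectable): Hamming distances between 8-long level sequences
take few distinct values, and average linkage degrades most gracefully under
such heavy tie structure. The flat cut height defaults to 2.5 — between
"differ at two positions" and "differ at three" — which keeps a motif's
members within a couple of substitutions of each other; it is an explicitly
tunable parameter, not a canonical value. Tiny floating-point inversions in
average-linkage merge heights are monotonised before cutting.

A motif's logo records, per position, the modal level if it reaches a 90%
member share and the wildcard `*` otherwise; the per-level share vectors are
retained for rendering. Motifs are ranked by the sum of their mean DD and
mean DS, with **rank 1 = lowest deviation sum**: deviation measures distance
from the specified behaviour, so lower is better performance. Ties go to the
larger cluster, then to the logo string, making ranks deterministic.
Clusters below the minimum size (default 10 members) stay in the handbook
but are flagged, since logos built from a handful of members are weak
evidence of a recurring pattern.

## The advisor

Design queries compare a concrete level sequence against handbook logos with
a wildcard-aware Hamming distance: wildcard positions impose no requirement
(they are exactly the positions where the motif's members showed no
consensus, e.g. both CI slots in the demo). Repair produces one substitution
per mismatch — production slots map to RBS swaps, degradation slots to PDT
swaps — so the route length always equals the distance, and applying the
route lands exactly on the motif. When a parts library is supplied, every
substitution lists its candidate parts and a route missing a (role, level)
part is flagged unrealizable with the missing slots named. When two routes
reach different motifs at the same distance both are reported with their
target ranks; the advisor does not auto-pick. Routes that leave a gene with
unmatched production/degradation levels carry an advisory note (the matched
pairs dominate the top of the handbook), but symmetry is not enforced.
Improvement mode requires the design to match some motif and lists routes
only to strictly better-ranked motifs within the substitution budget.

## What the generator does and does not emulate

The synthetic conditions probe the joint effect of circuit topology and
kinetic-level combinations on reaching a steady-state target under
perturbation. They do **not** emulate transcription/translation delays, mRNA
intermediates, multi-regulator (AND-gate) promoters, cell growth/division,
or realistic molecule-count (birth–death) noise; the noise model is a
parameter-perturbation diffusion, not a chemical master equation. Passing
tests therefore demonstrate the pipeline's internal correctness and the
qualitative structure of the level landscape (sparse functionality,
symmetry enrichment, regulator-saturated indifference) — not quantitative
predictions for a wet-lab construct.

## Problem sizes used by the tests

The unit and property tests run on 2-level (256-set) and 3-level
(6,561-set) grids with $T = 100$, where the full pipeline completes in
seconds and the 256-set scan can be cross-checked against per-set evaluation
exactly; the 5-level, 390,625-set demo is the documented long-form example
(about a minute, vectorised). Published counts that depend on a specific
supplementary range table (e.g. an exact functional count or cluster count)
are not asserted anywhere: the cluster count in particular is sensitive to
the unstated linkage and cut choices, so the tests assert the partition and
enrichment properties instead.

## Known limitations

* Exhaustive enumeration scales as `n_levels^(2 n_genes)`; beyond ~5 genes
  a sampling front-end (Monte-Carlo, Latin hypercube) would be needed ahead
  of the motif analysis.
* One repressor per gene; no combinatorial promoter logic.
* The gene-by-gene analytic fixed point — and with it the oracle tests —
  exists only for acyclic wirings; the looped preset is simulated but not
  analytically checked.
* Hamming distance treats levels as categories: a level-1 vs level-2
  mismatch counts the same as level-1 vs level-5.
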