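---
title: "Multistage optimal transport for snapshot trajectory inference: model and methods"
author: "msot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistage optimal transport: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msot)
```

## The problem

A single-cell snapshot measures the expression state of thousands of cells
drawn from an ongoing differentiation process — hematopoiesis being the
canonical example — but carries no temporal labels. Early and late states
can usually be recognized from marker genes; what is missing is the
ordering of the intermediate cells and their relationship to the terminal
fates. Classical bimarginal optimal transport matches two *known*
distributions and therefore cannot express a progression *within* one
snapshot. `msot` closes this gap by treating differentiation as transport
over `T` discrete stages in which the intermediate stage occupancies are
latent variables of a single convex program.

## The transport program

Cells are partitioned into initial states `X0` (`n0` cells), intermediate
states `X` (`n`) and terminal states `XF` (`nF`). The transition cost
between two cells is the squared Euclidean distance between their states —
the negative log-likelihood of a Gaussian transition kernel. For
expression input the state is the cell's coordinates in the leading 50
principal components of the library-size-normalized, `log(x+1)`-transformed
matrix; 2-D synthetic data are used as coordinates directly.

Decision variables are stagewise plans. `Mtilde[t]` (`t = 0 .. T-2`)
carries mass that continues within the system — the first plan is
`n0 x n`, the rest `n x n` — and `Mhat[t]` (`t = 0 .. T-1`) carries mass
exiting to the terminal tier. Latent marginals are derived sums:
`muTilde`, `muHat` (row sums) and `nuHat` (column sums). The program
minimizes total transport cost subject to

1. `muTilde_0 + muHat_0 >= 1` per initial cell (every designated source
   participates),
2. stage coupling: what an intermediate cell receives at stage `t` it
   forwards at stage `t` (continuing plus exiting),
3. total throughput `>= 1` per intermediate cell (every cell is part of
   the process),
4. total received mass `>= 1` per terminal cell (every designated sink is
   reached).

Two modelling choices deserve emphasis. First, `muTilde_{T-1}` is fixed to
zero: the objective has no transport term that could carry continuing mass
beyond the last stage, so all mass reaching stage `T-1` must exit to the
terminal tier; a free sink on `X` would otherwise absorb everything.
Second, the sum-of-transport-costs form over latent marginals is
implemented in its equivalent joint "flow" form — the plans are optimized
directly and the marginals derived — because each stage term is itself a
minimization over its own plan. The diagonal of the
intermediate-to-intermediate cost block is exactly zero, so mass may wait
at a cell across stages at no cost; this makes `T` an upper bound on the
resolution of the progression rather than a hard path length.

## Entropic solver

The program is solved with entropic regularization
`epsilon * sum m (log m - 1)` by block coordinate ascent on the dual
(generalized Sinkhorn scaling). Equality (coupling) blocks have free duals
— scaling vectors `w_t` obtained in closed form from a geometric-mean
update; the three inequality blocks have nonnegative duals, i.e. scaling
factors clipped at 1 (`u = max(1, 1/(K v))`). One sweep updates, in
order: the stage-0 block, the couplings `t = 1 .. T-1`, the throughput
block, the terminal block. The sweep order affects the iteration path but
not the fixed point. Iterations stop when the maximum over all
dual-variable updates and absolute constraint deviations falls below the
tolerance `tol` (default `1e-4`).

Small `epsilon` values underflow the kernel `exp(-C/epsilon)` directly, so
the solver is nested in a Kullback–Leibler proximal point scheme: each
round re-solves with the previous plans as the entropic prior (kernel
multiplied elementwise by the prior), and after `k` rounds the effective
regularization is `epsilonStart / k`. The default `epsilonStart = 0.05`
with 10 rounds (effective 0.005 on median-normalized costs) is low enough
for sharp plans on the data sizes below while keeping each round stable.
Log-domain updates (`logDomain = TRUE`) replace products by log-sum-exp
and are engaged automatically for a round whose multiplicative kernels
underflow; they are slower but exact. After deep annealing a cell can
become *inactive* at a stage (no incoming and no outgoing kernel support);
its coupling dual is then arbitrary and is left unchanged, while a cell
that can receive but not send (or vice versa) raises an error naming the
cells — those are the "extreme distance" candidates that motivate the
auxiliary-state extension.

Costs are median-normalized before solving: every entry of the four blocks
is divided by the median of their pooled entries (a single global median;
the structural zeros of the `CXX` diagonal participate, their share is
`O(1/n)`). This puts `epsilon` on a comparable scale across datasets and
makes the whole pipeline invariant to uniform rescaling of the embedding.

## Downstream quantities

*Stage distributions.* A cell's probability of transitioning at stage `t`
is proportional to the mass it moves then: outgoing (continuing + exiting)
mass for initial/intermediate cells, incoming mass for terminal cells;
rows are normalized to 1 and initial cells are point masses at stage 0.

*Pseudotime.* The raw value is the expected stage under that distribution.
Terminal cells are shifted by +1 so that a terminal *receiving* at stage
`t` ranks after the cells *transporting* at stage `t`; the rule for
terminal cells is a documented convention of this package. Pseudotime is
the min–max normalization to `[0, 1]` (all-equal raw values map to 0).
Because the initial (and terminal) designations pin those cells to the
extreme stages, ties among them are expected; rank comparisons against a
ground truth are cleanest on the intermediate cells.

*Transitions and fates.* Mass transported between each ordered cell pair
is summed over all stages and both plan families into `A`; transient rows
(initial and intermediate cells) are normalized to probabilities and
terminal cells made absorbing, giving a stationary absorbing Markov chain.
Aggregation precedes normalization. Fate probabilities are the absorption
probabilities per fate class, computed from the linear system
`(I - P_tt) F = P_tf Z` by LU solves (never explicit inversion); a
transient cell that cannot reach any terminal is reported by name. Shannon
entropy of the fate rows (natural log, so values in `[0, log L]`;
the base is configurable) quantifies multipotency, with the mean taken
over non-terminal cells.

*Auxiliary states and outliers.* One artificial initial, intermediate and
terminal state are appended; moving mass between any real cell and any
auxiliary state costs a fixed `Q` on the normalized scale, while
transitions among the auxiliary states are free — so the channel's toll is
`Q` per hop from a real cell and remains interpretable in units of the
median cost. `Q = 3.25` is the default (a conservative value on
median-normalized single-cell data; values around 2 behave similarly, and
the outlier recovery below is insensitive across that range). The
auxiliary terminal forms the fate class `"unknown"`; cells with
`P(unknown) > 0.5` (strict) are flagged as outliers. Auxiliary cells are
excluded from reported pseudotime and from entropy summaries.

*Gating.* `gateCells()` selects cells above a minimum commitment in every
target fate (default 10%) and below a maximum in every other fate
(default 1%), both strict — the rule used to nominate rare bipotent
progenitors such as basophil/mast-cell intermediates.

*Ties.* Dominant-fate lookups break ties by fate-class declaration order
on the prediction side; a reference whose modes tie counts as correct if
the prediction matches any tied mode.

## Baseline and benchmark metrics

The inverse-distance-weighted (IDW) baseline predicts fate probabilities
proportional to `d_c^(-power)` where `d_c` is the distance to the *nearest*
terminal cell of class `c` (power 2 by default, consistent with
squared-distance costs; zero distance yields an indicator). It uses no
transport and serves as the geometric null model.

Clonal lineage-tracing references are built per early-time cell from the
annotated fates of its same-clone sisters at later time points; cells
without annotated sisters are ineligible. Metrics: mean total-variation
distance to the reference, dominant fate accuracy (argmax match), total
fate accuracy (the `k` observed sister fates must be exactly the top-`k`
predicted classes), and a threshold sweep in which a cell is assigned all
fates with probability strictly above `delta` and scored correct only on
exact set equality.

## Synthetic data generator

`makeBranchingSnapshot()` emulates a branching developmental landscape in
the unit square: a trunk from `(0.5, 0.05)` to `(0.5, 0.4)` and, by
default, four arms of length 0.5 toward the sides and upper corners.
Arc-length positions are sampled uniformly, cells beyond the branch point
are assigned a uniformly chosen arm, isotropic Gaussian noise
(sd 0.02) is added and clipped to the unit square (clipping rather than
rejection keeps the cell count exact). The `nInitial = 5` cells nearest
the root and the `nTerminalPerArm = 5` cells nearest each arm tip are
designated initial/terminal. The default size of 400 cells makes a full
`T = 11` solve run in tens of seconds; all counts are configurable. The
generator asserts a minimum inter-tip separation of six noise standard
deviations so arm labels remain separable. Ground truth (`s`, arm label,
outlier mask) drives every validation.

`injectOutliers()` appends a compact Gaussian cluster placed along a
seeded random direction beyond the data radius by at least the requested
displacement, guaranteeing every outlier–inlier distance `>= displacement`
by construction; outliers enter the partition as intermediate states.
`simulateClones()` emulates barcoding: founders among early cells
(`s < 0.3`), sisters drawn without replacement among late arm cells
(`s > 0.7`), arm founders restricted to their own arm and trunk founders
free over all arms.

What the generator does *not* emulate: realistic count noise, dropout,
library-size variation, batch effects, doublets, or high-dimensional
manifold geometry. Tests passing on it therefore validate the transport
model, the solver and the downstream algebra — not robustness to
sequencing artefacts on real data.

## Validation design and problem sizes

The test suite pins every operation to an independent oracle: a generic
linear-programming solution of the identical flow polytope for the solver
(20 random instances with up to 12 cells and 5 stages, checked to `1e-3`
relative at effective epsilon `1e-3`; the entropic bias in the linear cost
scales roughly linearly with epsilon, which dictates that depth), the
closed-form and Monte-Carlo absorption checks for the Markov chain,
brute-force loops for costs and metrics, and the generator's ground truth
for the end-to-end recoveries. The four-arm recovery uses the full
400-cell default; the entropy-versus-regularization grid uses a 200-cell
four-arm dataset so four solves stay quick; the outlier study adds 10
outliers at displacement 3 to the 400-cell landscape. These sizes are the
package's validation choices and are stated here so they can be reproduced
exactly.

## Known limitations

- Memory and time scale as `O(T n^2)`; beyond ~10^4 cells use
  `partitionSubsets()` and pool results, as `runPipeline()` does.
- Designating initial and terminal states is the user's responsibility;
  the model is only as directional as those anchors.
- Pseudotime for designated initial/terminal cells is pinned to the ends
  of the scale by construction.
- The entropic solution is diffuse at large effective epsilon; fate
  entropy rises accordingly (the monotonicity is itself a tested
  property).
- No highly-variable-gene selection, batch correction or doublet handling
  is performed; supply curated input if those matter.
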