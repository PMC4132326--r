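---
title: "Detecting complex expression dependences between sets of coexpressed genes"
author: "pcopnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting complex expression dependences between sets of coexpressed genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcopnet)
```

## The model

`pcopnet` looks for dependences between *sets* of coexpressed genes rather
than between individual genes. Its three working assumptions are:

1. dependences between different sets of coexpressed genes are not linear —
   linearity is what defines membership in the *same* set;
2. if two genes maintain a relationship of a certain curve type, the genes
   coexpressed with each of them maintain relationships of the same type;
3. the curve type of an inter-set relationship describes the
   activation/deactivation dependence between the processes the two sets
   carry out.

The pairwise primitive is the principal curve of oriented points (PCOP): a
nonlinear, non-variable-dependent summary of a 2-D cloud. It rests on the
principal-component property that projection variance onto a hyperplane is
minimised when the hyperplane is orthogonal to the first principal
component; applying that property locally yields one principal oriented
point (POP) per local area, and the chain of POPs is the curve.

### The fit, concretely

`fit_pcop()` is deterministic. The tracer starts at the data point extreme
along the global first principal component and repeatedly: takes the
neighbourhood of the current position (`bandwidth_fraction` = 0.2 of the
points, at least `min_neighbourhood` = 10), computes the local principal
direction sign-aligned with the previous direction, snaps the position
orthogonally onto the local mean, records the POP, and advances by
`step_fraction` = 0.05 of the data diameter. It stops when no data point
lies in a forward corridor scaled by the larger of the step and the local
neighbourhood radius — the corridor, rather than a neighbourhood-only test,
matters in dense clumps of skewed marginals, where the k-NN radius can be
far smaller than the step. If the path returns to its start after roughly
one full turn of *consistent* sign it is closed; the sign-consistency
requirement keeps meandering paths through unstructured clouds from being
mistaken for closed curves.

### The uncorrelation factor

The correlation strength of a pair is summarised by f ∈ [0, 1]:

> f = clip( mean squared orthogonal distance to the polyline
>           / total cloud dispersion × morphology penalty, 0, 1 )

The morphology penalty is `max(1, L/(2·D), W/360, D/D_curve)` with `L` the
polyline length, `D` the cloud diameter, `W` the total unsigned winding of
the polyline in degrees and `D_curve` the polyline's own extent. The first
term punishes over-long curves; the winding term punishes polylines that
keep changing direction (the signature of a curve traced through an
unstructured cloud, where local averaging otherwise *under*-states the
residual by hugging noise); the extent term punishes curves that do not
span the cloud, such as a small loop threaded through a blob. On noiseless
canonical shapes every term is 1 and f reduces to the plain residual ratio;
on isotropic Gaussian pairs the penalties drive f to ≈ 1. A pair whose f
reaches the ceiling 1 is treated as having no detectable correlation and is
never accepted, regardless of how loose the gene-count threshold is.

Because the published account of the original f does not include its exact
formula, this definition is this package's own, built to match the stated
qualitative behaviour: it measures both dispersion around the curve and
curve/cloud morphology mismatch, and it is rotation invariant.

### Turn angles and curvature points

A curvature point is a POP where the slope changes. With a step of 5 % of
the data diameter, the angle between *consecutive* polyline segments is a
poor slope-change measure: a smooth arc (e.g. `e^x` after z-scoring) turns
less than 6° per segment and would never cross a ~159° threshold, while its
total slope change is large. `pop_turn_angles()` therefore measures, at
each POP, the interior angle between the incoming and outgoing *chords*
spanning `baseline_fraction` = 0.3 of the data diameter of arc on each
side. The chord baseline ties the measure to the cloud scale and makes it
independent of how finely the polyline is sampled; it was chosen (and
frozen) because it is the smallest baseline at which every canonical curved
shape shows a deviation comfortably above the threshold while noisy linear
pairs stay far below it. POPs within half a baseline of an open curve's
endpoints are not assessed — curvature there cannot be measured reliably.

Runs of consecutive flagged POPs merge into one curvature point at the
sharpest POP. One special case: on a closed curve whose flagged run wraps
the entire polyline (uniform curvature — a circle has no distinguished
corner), one curvature point is emitted per quarter turn of accumulated
winding.

### The curve-type taxonomy

Classification is shape-based, never a parametric fit of `e^x` or `ln x`:
the relationships of interest only need the right *inner pattern*. The
curve is oriented canonically (traversal of increasing x, or increasing y
when the net x displacement is negligible — the sideways parabolas), cut at
its curvature points, and each segment is reduced to the signs of its net
x- and y-displacement, with a 2° dead zone absorbing fit jitter. The
decision table is then:

| structure | type |
|---|---|
| closed curve | `CLOSED` |
| no curvature points | `LIN_POS` / `LIN_NEG` by slope |
| monotone in x and y, one dominant turn direction | `EXP_POS` (up, convex), `LOG_POS` (up, concave), `LOG_NEG` (down, convex), `EXP_NEG` (down, concave) |
| monotone in x and y, balanced opposing turn directions | `CUBIC_POS` / `CUBIC_NEG` |
| monotone in x only, valley / peak | `QUAD_POS` / `QUAD_NEG` |
| monotone in y only, sideways valley / peak | `SIDE_QUAD_POS` / `SIDE_QUAD_NEG` |
| anything else | `COMPLEX` |

The cubic-versus-exponential split uses the turn-direction weights: a
monotone curve counts as cubic when the minority turn direction carries
more than 35 % of the total turn weight. This aggregate rule is what keeps
classification stable under noise — a spurious extra curvature point with
the same turn sign leaves the verdict unchanged. `COMPLEX` is retained as a
first-class outcome rather than being forced to the nearest named type:
unknown relationship shapes must be processed as reliably as known ones.

`transpose_type()` maps the type of (x, y) to the type of (y, x). One
point deserves emphasis because it is easy to get wrong: reflection across
y = x swaps convex and concave only for *increasing* curves. For a
decreasing f, (f⁻¹)'' = −f''/(f')³ has the sign of f'', so `EXP_NEG` and
`LOG_NEG` are fixed points of the transpose (e.g. y = −ln x reflects to
y = e^(−x), both decreasing convex), while `EXP_POS` ↔ `LOG_POS` and the
parabolas swap with their sideways forms. The implemented table is what
makes `classify(x, y) = transpose(classify(y, x))` hold exactly on
noiseless fixtures.

## Thresholds and the pairwise scan

Acceptance of a pair is driven by two gene-count-dependent thresholds:

* f threshold: `0.12 × (1600/n) − (n/40000)^18` — looser for small
  matrices (where relationships with higher entropy must still be found)
  and collapsing for very large ones; values above 1 are capped by f's own
  range, and a non-positive value is a configuration error requiring an
  explicit override.
* curvature threshold: `160 − ((15.0/20000 + 14.0/18400)/2 × n)` degrees —
  higher for small matrices, i.e. curvature is flagged more readily and the
  linear class is *more* restrictive, because a small curvature between two
  "coexpressed" genes diversifies the curve types they show against a third
  set.

A count-only formula cannot anticipate the nature of the experiments, so
`scan_all()` supports an online correction: every 1 % of the pair sequence
it projects the final number of accepted pairs from the acceptance rate so
far and nudges the f threshold by ±5 % toward a target band (default
2n–20n accepted pairs), never loosening beyond the formula value. The
*final* stabilized threshold is applied uniformly to all pairs: in-force
acceptance would make a pair's fate depend on its position in the
enumeration order, breaking determinism of the output as a function of the
matrix and contaminating the graph stage with pairs accepted under the
loose early threshold.

Pairs are standardized per pair on their complete-case samples; pairs with
fewer than 20 complete samples are skipped with a logged reason. The output
table contains every analysed pair — including rejected ones — for audit.

## From pairs to skeleton networks

The accepted pairs form two edge-disjoint graphs: coexpression (linear) and
nonlinear, the latter edge-labelled with curve types in canonical
orientation (lexicographically smaller gene on x; the other orientation is
recovered with `transpose_type()`).

*Gene cliques* are maximal cliques of ≥ 3 genes in the nonlinear graph.
Maximal (rather than all) cliques are enumerated: sub-cliques carry no
extra information and would explode combinatorially. Two cliques match as
an *isomorphic and linear pair* when a bijection pairs each gene with a
distinct coexpressed gene of the other clique and corresponding edges carry
equal types after orientation normalization; the backtracking matcher
returns the first bijection in deterministic gene-id order (multiple valid
bijections describe the same set structure).

A *clique of cliques* — a maximal clique in the graph whose vertices are
gene cliques and whose edges are matched pairs — resolves into a skeleton
network. The coexpressed sets are the **orbits of the bijections**: each
orbit holds exactly one gene of every member clique, and those genes are
mutually coexpressed by the matching conditions. A clique-of-cliques of k
member cliques of size s therefore yields s sets, each with a k-gene
skeleton; the set count equals the clique size, and the skeleton depth
equals the number of member cliques. Networks whose orbits are inconsistent
or whose set pairs carry more than one curve type are discarded with a
warning. Both `min_sets` (sets per network) and `min_cliques` (skeleton
genes per set) default to 3, mirroring the ≥ 3 definition of a clique at
the gene level; a deeper skeleton makes the sets more representative and,
practically, a three-way mutual match is what makes chance networks from
residual noise pairs vanishingly unlikely.

Raw cliques-of-cliques are massively redundant: a planted 3-module × 10-gene
dataset already contains 1000 transversal gene triangles and over 10⁵
cliques of cliques, all views of the same three modules.
`consolidate_networks()` merges networks with identical signature whose
aligned sets are mutually coexpressed, taking the union of the aligned
skeletons. Deterministic caps (`max_cliques` = 400 gene cliques,
`max_partners` = 20 matched partners per clique, `max_networks` = 2000
cliques of cliques) bound every combinatorial stage and warn on
truncation; truncation costs only skeleton depth, which the halo
compensates.

Before clique enumeration, genes with no accepted coexpression partner are
dropped from the nonlinear graph. This is lossless — every gene of a
matched clique needs a coexpressed counterpart — and it prevents
uncorrelated genes that slipped past the f filter from absorbing the
maximal cliques.

Finally `attach_halo()` collects, for each set, the genes linearly linked
to at least one skeleton gene and not in any skeleton of the network, each
with its strongest (lowest-f) anchor, ordered by f ascending. The closer a
halo gene is to a y = x relationship with its anchor, the more faithfully
it maintains the skeleton's intergroup curve types; the package reports the
halo f values and leaves that judgement to the user. The
`network_signature()` — set count plus the sorted multiset of intergroup
types — is the classification key under which networks are grouped for
display.

## The synthetic benchmark

`gen_network_dataset()` plants the structure the network stages search
for. All modules share one latent sample process (a uniform grid with
seeded Gaussian jitter of a quarter grid spacing — diverse conditions, no
replicates); each module pushes the latent variable through a canonical
template transform (identity, `e^x` on [0, 3], `ln x` on [0.1, 3], `±x²`
and `x³` on [−1, 1], a cos/sin circle-arc pair), rescales per gene with a
*positive* coefficient (a negative one would silently flip the planted
curve type), adds Gaussian noise in standardized units, and z-scores.
Because all modules are driven by one latent variable, every module pair
exhibits the curve type induced by composing its two transforms; the
induced type is derived analytically (monotonicity and the sign of the
parametric curvature on a dense noiseless grid — no curve fitting), and a
requested intergroup map is validated against it rather than attempted
independently, since arbitrary pairwise type assignments are generally
unsatisfiable. Background genes are pure independent noise, giving a clean
specificity check: no recovered set may contain one.

The default study conditions used by the tests and the acceptance script
are 3 modules × 10 genes (identity, `e^x`, `−ln x`) plus 20 background
genes, 60 samples, noise sd 0.05. Sixty samples is the lower end of a
realistic "large sample series"; noise sd 0.05 in standardized units is
mild but non-trivial against within-module signal. The planted signature is
`3:EXP_POS,LOG_NEG,LOG_NEG` — one trigger, two mutual exclusions.

What the generator does *not* emulate: probe effects, batch structure,
heteroscedastic or count noise, partially overlapping modules, or genes
participating in several processes. Passing the benchmark therefore shows
the machinery is correct and specific under its own assumptions, not that
any real dataset will yield networks.

## Numerical choices and degenerate inputs

* All orderings (pair enumeration, clique output, halo sorting, candidate
  order in the matcher) are radix-sorted on ids or f, so identical inputs
  give byte-identical outputs; there is no randomness anywhere outside the
  generator's seeded draws, which restore the caller's RNG state.
* Sign conventions: the global first principal direction points toward
  increasing first coordinate; each local direction is sign-aligned with
  its predecessor.
* The 2° dead zone on displacement signs absorbs fit jitter near
  horizontal/vertical segments; ties in the cubic balance rule fall to the
  exponential/logarithmic side.
* Fewer than 20 points is an insufficient-data error; an all-identical
  cloud is a degenerate-input error; an all-constant matrix is an error,
  and constant gene rows are excluded up front. A pathological cloud where
  the tracer finds no forward structure yields a minimal two-POP segment
  whose extent penalty drives f to 1 (rejection).
* Problem sizes in the shipped tests and acceptance script (60-point
  clouds, 100 noisy replicates per shape, a 50-gene benchmark matrix) were
  chosen so the full suite exercises every stage, including the
  combinatorial ones, at interactive runtimes.

## Known limitations

* PCOP fitting is 2-D only; relationships involving three or more sets are
  reached through the clique machinery, never through higher-dimensional
  curves.
* The f formula is a documented stand-in with the stated qualitative
  behaviour, not the original unpublished one; absolute f values should be
  compared within a run, not across tools.
* Curve types of pairs near the acceptance boundary are sensitive to the
  curvature threshold; the online correction tunes only the f threshold.
* The clique stages are capped; on dense relationship graphs the recovered
  skeletons are a deterministic subset and halo membership should be used
  for set totals.
* Reference counts reported for an NCI60-derived 1416 × 118 correlation
  matrix (4573 nonlinear relationships, 20269 coexpressed pairs) depend on
  that external dataset and on online-correction targets that were never
  stated; they document the scale this method runs at, and are not
  reproduced by the bundled benchmark.
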