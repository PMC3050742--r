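---
title: "Predicting pathway interaction points by cluster-predominance transfer"
author: "moaclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting pathway interaction points by cluster-predominance transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moaclust)
```

## The problem and the model

The NF-κB cascade offers a small set of canonical intervention points: IKK
activation (1), IκB degradation/phosphorylation (2), nuclear translocation
(3) and DNA binding (4), with ROS-mediated effects possible anywhere.
Compounds reported to modulate NF-κB are usually annotated with one of these
six interaction classes — when they are annotated at all. `moaclust` treats
the problem as *label transfer under the similar-property principle*: if a
query compound is structurally similar to a cluster of compounds that
predominantly act at one point, the query is predicted to act there too.

This is deliberately not a per-compound QSAR model. The unit of inference is
the cluster: a partition of the training library into structurally coherent
groups, each annotated by the distribution of its members' labels. The
working assumption — similar structure, similar interaction point — is known
to fail locally (small structural edits can flip activity), so the method is
used as a general rule, with abstention mechanisms (predominance level,
minimum cluster size, similarity threshold) to keep predictions inside the
applicability domain.

## Descriptor sets

Seven 2D representations are supported; everything is computed on heavy-atom
graphs with implicit hydrogens (only 2D information is used; chirality is
ignored).

* **ECFP4** — circular fingerprints of diameter 4 (radius 2). Atom
  environments are grown iteratively from an initial invariant (atomic
  number, heavy degree, implicit H count, formal charge, aromaticity) by
  hashing each atom's previous identifier with its sorted
  (bond type, neighbour identifier) pairs. Environments that stop growing or
  duplicate an already-emitted environment (identical covered-bond set) are
  dropped. Identifiers live in an *unfolded* sparse integer space: no bit
  folding, hence no folding collisions in Tanimoto comparisons. The hash maps
  into a prime modulus below 2^26 so every intermediate product stays exactly
  representable in doubles — the fingerprints are bit-reproducible across
  platforms.
* **Property** — AlogP and molecular weight (delegated to OpenBabel's
  atom-contribution models, implicit hydrogens included), H-bond
  acceptor/donor counts, heavy-atom count, rotatable bonds (acyclic
  non-aromatic single bonds between non-terminal heavy atoms), ring count
  (cyclomatic number) and aromatic ring count (cyclomatic number of the
  aromatic-bond subgraph).
* **BCUT / GCUT** — for each diagonal weight scheme, the lowest and highest
  eigenvalue of the heavy-atom matrix whose off-diagonal entries are bond
  orders (aromatic = 1.5; non-bonded = 0) for BCUT, or topological bond-count
  distances for GCUT (per-fragment blocks for multi-fragment molecules). The
  default weight triple is the canonical one: atomic mass, Gasteiger-type
  partial charge, atomic polarizability, giving six values per molecule.
  Partial charges come from a PEOE (partial equalization of orbital
  electronegativities) iteration implemented in the package — six damped
  iterations, damping (1/2)^k, implicit hydrogens participating as explicit
  partners — and are cross-checked in the test suite against OpenBabel's
  independent Gasteiger implementation at the rank level (the two fold
  hydrogen charges differently, so values are not directly comparable).
  The "modified" distance matrix of the original GCUT implementation is not
  publicly specified; the literal topological distance matrix is used, and
  users comparing against MOE output should expect differences.
* **Combinations** — ECFP4+Property, BCUT+GCUT, GCUT+Property.

## Similarity

Fingerprint components use the Tanimoto coefficient; two empty sets score 1
(identical absence of features). Continuous components use
`1 − mean|x̃ − ỹ|` after per-component min–max scaling, a bounded,
monotone-in-distance, parameter-free choice; commercial clustering tools do not publish their
internal continuous-similarity measures, so no attempt is made to imitate
one. Scaling bounds are computed **once, on the training
library**, then frozen: query values falling outside the training range are
clamped to [0, 1] so similarities stay bounded; a constant training
component is mapped to 0.5 for all compounds and contributes no contrast.
Combined sets average their component similarities with equal weight — the
simplest defensible fusion; anything cleverer would need validation data the
protocol does not assume.

## Clustering and the choice of n

Cluster representatives are selected by MaxMin: the seed compound first,
then repeatedly the compound whose *maximum* similarity to the chosen
representatives is smallest. Ties (common with coarse similarity values)
break by input order, making runs exactly reproducible. Every compound then
joins its most similar representative (earliest representative on ties;
representatives always belong to themselves). The greedy sequence is nested
— the first *n* centers of a long run are exactly the centers of the
shorter run — so the whole grid n = 1..n_max costs a single selection pass
plus incremental reassignment.

The cluster count is chosen from the **avg-s curve**: avg-s(n) is the mean
over clusters of the mean pairwise within-cluster similarity, with
singletons contributing 1.0 (the self-similarity of a lone molecule; note
this biases avg-s upward at large n). The chosen n maximizes the decrease
avg-s(n−1) − avg-s(n), smallest n on ties. On the similarity scale avg-s
*rises* with n for essentially any refinement, so this largest-decrease rule
keys on local dips of the curve; when no decrease exists at all, the n with
the smallest increase is returned and a warning is recorded in the run log.
This is a known fragility, discussed under Limitations.

The grid upper bound is `min(200, floor(N/2))`: 200 corresponds to an
average of two compounds per cluster on a ~400-compound training set, and
the cap scales down with smaller libraries so the average cluster size never
drops below two.

Cluster centres, where a member-valued centre is needed (the CLUSTER_CENTRE
search rule), are **medoids**: the member with maximal mean similarity to
its co-members, lowest input index on ties. A medoid is the only
centre notion compatible with fingerprint similarity (there is no meaningful
mean fingerprint).

Partitions are compared by pair counting: with a and b the numbers of
co-clustered compound pairs in each partition and c the pairs co-clustered
in both, the similarity is c/(a+b−c); two all-singleton partitions score 1
by convention.

## Annotation and prediction

A cluster's profile counts each member's labels — multi-label compounds
increment every class they carry, so fractions can sum above 1. Two modes
exist: **including** unknowns (denominator = all members) or **excluding**
them (denominator = labelled members; unknown members are also dropped from
similarity scoring and size filters in this mode — exclusion removes them
from the analysis, not just from the denominator). A label is predominant at
level L when it is the unique maximal fraction and ≥ L; comparisons carry a
1e-9 absolute tolerance so an exact 2/3 passes the 66.6% level. The levels
are 50%, 2/3 (rendered 66.6%) and 75%.

Prediction searches the size-eligible clusters under one of three rules —
most similar member, similarity to the medoid, or mean member similarity —
and transfers the predominant label of the best-scoring cluster. The query
abstains when no cluster passes the size filter, the best score is below the
similarity threshold (the comparison is inclusive: a score equal to 0.7
predicts), or the nearest cluster has no predominant label. The primary
accuracy metric counts abstentions as incorrect (percentage correct over all
queries); the percentage among predicted queries and the predicted count are
reported alongside, since the two can tell very different stories under
aggressive thresholds.

The **random baseline** assigns each query a cluster drawn uniformly from
the same eligible set and applies the same predominance rule. Besides the
Monte-Carlo estimate (seeded, repetition count configurable), the analytic
expectation `100 · Σ_L f(L) q(L)` is reported, with f(L) the fraction of
eligible clusters predominant for L and q(L) the fraction of queries
carrying L — making baseline comparisons deterministic in tests. Note a
structural fact: with six classes at skewed frequencies and structurally
clean clusters, f ≈ q and the analytic baseline approaches Σ q², which is
~30% for the study's class frequencies. Large accuracy-to-baseline ratios
require many *non-predominant* (abstaining) clusters, as real noisy
libraries produce; clean synthetic libraries cannot produce ratios beyond
≈ 1/Σq² no matter how well the classifier does.

## The protocol

`run_protocol()` reproduces the full experimental design: 5 random
training/test splits (60 labelled test compounds each, redrawn until every
class is represented; unknowns always stay in training), 5 clustering seed
compounds per split (drawn once per split and reused across descriptor sets,
recorded in the manifest), all descriptor sets, the full prediction grid
(3 rules × sizes 1–5 × 3 levels × {no threshold, 0.7} × both unknown
modes), random baselines, and the run-by-run partition-similarity matrix
(cross-split pairs are compared on their shared compounds). Everything is
deterministic given the master seed; per-run warnings (e.g. a never-
decreasing avg-s curve) are collected in the bundle rather than printed.

## The synthetic generator

Real mechanism-annotated NF-κB libraries are not redistributable, so the
package generates libraries with the statistical structure the method
assumes, at two fidelity levels sharing one series plan:

* **Fingerprint space** (`generate_fp_library()`): each analogue series has
  a prototype of 40 features drawn from its own disjoint feature range;
  each member flips every position of the series' 80-feature universe with
  probability ε (default 0.05). ε = 0 makes series members identical;
  ε = 0.05 yields within-series Tanimoto ≈ 0.8 and cross-series Tanimoto
  exactly 0.
* **SMILES** (`generate_library()`): each series is a scaffold template
  (benzophenones, flavones, stilbenes, anilides, quinolines, ...) with one
  substitution site fixed per series and one varied through a substituent
  alphabet; every emitted SMILES parses.

Default composition mirrors the study library: class counts ROS 14,
translocation 7, DNA binding 60, IKK 138, IκB-degradation inhibition 76,
IκB-degradation activation 6; 4 dual-label compounds (union structures of
two series, counted in both classes); 163 unknown-interaction compounds
generated as unstudied analogues of randomly chosen labelled series; series
size 8, a typical published analogue-series size. Totals: 460 compounds,
297 labelled.

What the generator does **not** emulate: shared substructure between series
(cross-series similarity is exactly zero in fingerprint space, whereas real
libraries overlap), activity cliffs (series are label-pure by construction),
label noise, salts/mixtures and tautomers (real inputs must be pre-cleaned),
and class-correlated physicochemistry. Consequently, passing results on
synthetic data demonstrate that the machinery — clustering, annotation,
transfer, abstention accounting — is correct and that the pipeline recovers
structure where structure exists; they do not predict real-data accuracy,
which depends on how well the similar-property principle holds in the
library at hand.

## Numerical choices and degenerate inputs

* Ties: MaxMin selection and cluster assignment break ties by input order /
  earliest centre; medoids by lowest index. Deterministic, documented,
  exercised by tests with coarse (2-decimal) similarity values.
* Predominance comparisons: ≥ with 1e-9 absolute tolerance.
* Singletons: avg-s contribution 1.0; a labelled singleton is 100%
  predominant for its own label, an unlabelled one is unknown-predominant.
* Empty ∩ empty fingerprint: similarity 1.
* All-unknown cluster in exclude mode: no denominator, never predominant,
  ineligible under any size filter.
* No cluster passes a size filter: predominance percentages are reported as
  NA (undefined), not 0; predictions abstain.
* Percentages are on the 0–100 scale throughout.
* RNG: every stochastic entry point (generators, splits, baselines,
  protocol) takes an explicit seed and restores the caller's RNG state.

## Problem sizes

The test suite exercises the full machinery on scaled-down libraries
(~110 compounds, series of 6) and runs the complete protocol at the full
460-compound composition for the end-to-end recovery checks; the
acceptance script runs the 460-compound protocol across minimum cluster
sizes 1–5 with and without the 0.7 threshold, a 1000-matrix brute-force
clustering comparison, and the closed-form identities. These sizes were
chosen so a complete run stays in the tens of seconds on one CPU while
still covering the study-scale composition.

## Known limitations

* **The avg-s selection rule is fragile.** Since avg-s increases along the
  refinement path, the largest-decrease rule selects whichever n carries
  the largest noise dip; nearby seeds can yield very different cluster
  counts (anywhere between ~15 and ~200 on the synthetic library), and
  prediction quality swings with them. Cluster-count heuristics of this
  family are usually stated for scatter-like quantities, where decreases are
  meaningful; on the similarity scale the literal rule is implemented as
  documented, the no-decrease case warns, and `moa_cluster(n_clusters =)`
  lets users pin n explicitly.
* **Applicability domain.** Queries dissimilar to the whole training
  library receive low-similarity assignments; without the threshold these
  are low-confidence guesses. The 0.7 threshold trades coverage for
  precision (fingerprint sets predict for far fewer queries than continuous
  sets at the same threshold, since unfolded Tanimoto values run lower).
* **GCUT fidelity.** The literal distance-matrix reading (above) means GCUT
  values are not interchangeable with MOE's.
* **No structure standardization.** Tautomers, salts and charge states are
  taken as given by the input SMILES.
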