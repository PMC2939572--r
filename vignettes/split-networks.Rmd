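---
title: "Building circular split networks by simulated annealing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building circular split networks by simulated annealing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcnet)
```

## The model

A split `A|B` is a bipartition of the taxon set; a collection of splits with
positive weights induces *phyletic distances*: the distance between two taxa
is the summed weight of the splits separating them. Trees are the special
case of pairwise-compatible splits; *circular* split collections — those
whose splits are all contiguous arcs of one cyclic arrangement of the taxa —
strictly generalize trees while still admitting a planar network drawing.
A distance matrix realizable as phyletic distances of a circular collection
is called circular, or Kalmanson.

`mcnet` fits a circular split system to an arbitrary symmetric dissimilarity
matrix in two stages:

1. **Find a circular ordering** σ minimizing the closed-tour length
   (energy) `η(σ) = d(x_σ(1), x_σ(n)) + Σ d(x_σ(k), x_σ(k+1))`. For data
   that truly are circular, the generating cycle attains the minimum
   `2·Σw`, because the closed tour crosses each split's two arc boundaries
   exactly once each; for additive data the minimum is twice the total
   branch length. Minimizing η is equivalent to a traveling-salesman
   problem, hence the stochastic search.
2. **Weight the ordering's `n(n−1)/2` arc splits** by non-negative least
   squares against the input distances and discard the splits whose fitted
   weight is zero.

The result is deliberately conservative in one specific sense: whatever the
ordering search returns, the weighting stage can only *shrink* the split
system (weights of unsupported splits go to zero under the non-negativity
constraint), so conflict appears in the network only insofar as the
distances support it.

## The search

The greedy construction seeds the path with the globally closest pair of
taxa and repeatedly attaches the unplaced taxon nearest to either end of
the path (head → prepend, tail → append); ties go to the smallest taxon
index, and the tail on end ties, so the construction is deterministic. The
greedy path closed into a cycle is the annealer's default starting point.

The annealing chain perturbs the ordering by extracting the element at a
uniformly chosen interior position and appending it at the end — a
neighborhood of exactly `n − 2` orderings. Downhill proposals are always
accepted; an uphill proposal with energy increase Δ is accepted with
probability `exp(−Δ/T)`. After a fixed number of proposals per temperature,
the temperature is multiplied by the cooling factor, until it falls below
the stopping temperature. Only three tour edges change per move, so each
proposal is evaluated in constant time; the inner loop is compiled. The
result returned is the best ordering seen anywhere in the run (the final
chain state is available with `return_best = FALSE`).

One structural note: this neighborhood is not symmetric (σ′ ∈ N(σ) does not
imply σ ∈ N(σ′)), which the usual reversibility argument for annealing
chains assumes. The chain is nevertheless irreducible, and the package
treats convergence as an empirical matter, validated against exhaustive
enumeration (below).

## Tunable parameters

All search parameters live in `anneal_schedule()`:

* `cooling = 0.9` and `t_low = 1e-4` (same units as the distances). These
  follow the regime where the achieved energy stops improving while the
  run time stays moderate: slower cooling (0.95) costs substantially more
  time for no reliable energy gain, faster cooling degrades the optimum;
  stopping temperatures below ~1e-3 leave the outcome unchanged on typical
  normalized distance scales.
* `t_initial = NULL` → `η(σ₀)/n`, the mean tour-edge length of the start.
  Typical uphill moves then start with appreciable acceptance; empirically
  both much colder (0.2×) and much hotter (5×) starts find the optimum less
  often at fixed effort.
* `reps_per_temp = NULL` → `150·n³` proposals per temperature. This is the
  parameter that buys reliability: each move relocates a single taxon, so
  rearranging a mislabeled region of the cycle requires long coordinated
  move sequences, and the effort needed grows much faster than linearly in
  n. With this default the search attains the exhaustively verified global
  optimum in ≥ 95% of runs on random 7–8-taxon metrics and recovers
  generating trees and cycles essentially always up to n ≈ 20 (the regimes
  the test suite measures). For much larger n this cubic default becomes
  expensive and can be overridden; quality then degrades gracefully toward
  whatever the budget affords.
* `seed`: one seeded generator drives the neighbor choice and, for uphill
  proposals only, the acceptance draw, in that order; identical seeds give
  bit-identical results, traces included.
* `mcnet(..., restarts = k)` runs k independent chains (seeds `seed`,
  `seed+1`, …) and keeps the best; the default is a single run.

The weighting stage has one parameter: the retention threshold of
`filter_splits()`, default `1e-8`. The active-set solver returns exact
zeros for excluded splits in principle, but stray weights up to ~1e-9 occur
on exactly-fitted systems, so the threshold sits above solver noise and far
below weights of scientific interest (which are on the scale of the input
distances).

## Numerical choices

* Energy deltas are evaluated incrementally (three edges), but the energy
  is recomputed exactly at every temperature step and whenever a new best
  is recorded, so float drift cannot accumulate into the reported results.
* The unconstrained fit uses QR, not the literal normal-equations inverse;
  a rank-deficient design (impossible for full circular split systems,
  whose design matrix is full rank) raises an error rather than a silent
  pseudo-inverse.
* Distance matrices are symmetrized on read; asymmetries above `1e-6` are
  treated as data corruption and rejected rather than averaged away.
* Circular orderings are compared in a canonical form (smallest taxon
  first, second element smaller than the last), which quotients out the
  2n rotations/reflections denoting the same cyclic arrangement; ties in
  the exhaustive oracle are broken lexicographically on this form.
* Degenerate schedule (`t_initial ≤ t_low`): the loop runs zero temperature
  steps and returns the starting ordering — useful as an explicit
  "no search" mode.

## What the generators emulate — and what they do not

`random_tree_metric()` draws uniform unrooted binary topologies with
uniform branch lengths and returns exact patristic distances;
`random_circular_metric()` draws a random cycle, a random arc-split subset
always containing the n trivial splits (so distinct taxa stay at positive
distance), and positive weights, returning exact phyletic distances;
`perturb_distances()` adds truncated-at-zero Gaussian noise. These span the
two structured regimes the method is built for (additive, circular) plus a
noise model, and make every test reproducible from a seed with no stored
data.

They do *not* emulate real estimation noise: distances estimated from
sequences have correlated, distance-dependent errors, not i.i.d. Gaussian
perturbations, and real conflict (recombination, hybridization) is
structured rather than random. Passing the recovery tests therefore shows
the machinery is correct on its own model classes — exact recovery of what
generated the data — not that the method resolves any particular biological
conflict well.

## Problem sizes used in the test suite

Exhaustive enumeration of `(n−1)!/2` circular orderings anchors the ground
truth and is capped at `n ≤ 10`. The statistical checks use 50 random
metrics at n=7 plus 20 at n=8 against that oracle, 20 random trees with
5 ≤ n ≤ 20, 20 circular metrics with n ≤ 12, and 100 noisy instances for
the constrained-vs-unconstrained residual ordering; the acceptance script
uses slightly smaller replicate counts at the same sizes. These sizes keep
the whole suite at a few minutes on one core while covering the regime
where the exhaustive oracle is available and the recovery claims are sharp.

## Known limitations

* The energy landscape is that of a TSP; no optimality guarantee exists for
  any finite schedule, and for unstructured (noisy) inputs at larger n the
  returned ordering is only as good as the budget allows. Restarts are the
  cheap insurance.
* The cubic default effort targets tens of taxa. For hundreds of taxa set
  `reps_per_temp` explicitly (linear-in-n budgets still give useful, if not
  certifiably optimal, orderings) — the per-proposal cost itself is O(1).
* The package fits and writes split systems; it does not draw networks.
  SplitsTree4 reads the NEXUS output directly.
* Only the SPLITS dialect of NEXUS is written, and only TAXA + DISTANCES
  blocks are read; alignment-to-distance estimation is out of scope — the
  pipeline begins at the distance matrix.
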