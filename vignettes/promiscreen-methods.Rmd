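---
title: "Methods: coupling analysis, PLS reconstruction and Pareto screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupling analysis, PLS reconstruction and Pareto screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promiscreen)
```

## Overview

promiscreen implements a computational protocol for probing how a
protein's primary activity and a weak promiscuous activity are jointly
modulated by mutations, and for steering a combinatorial screen towards
variants with optimal trade-offs. The canonical application is the
thioredoxin fold: disulfide reduction as the primary activity, catalysis
of oxidative folding as the promiscuous one, and the His-vs-Pro identity
at the CXXC-adjacent position 34 as the functional signature separating
reductases from folding catalysts.

The pipeline has four stages, each usable on its own:

1. **Function-targeted statistical coupling analysis (SCA).** A multiple
   sequence alignment is split by the residue identity at a signature
   position; positions whose residue distribution shifts between the
   signature subalignment and the full alignment are candidate
   co-evolving sites, and a per-position mutation-direction score
   nominates one specific substitution at each.
2. **PLS reconstruction of the combinatorial library.** A library over
   M candidate mutations spans 2^M variants; a sparse screen (tens of
   variants) is fitted with a pairwise-coupling model by partial least
   squares, and the full library is reconstructed, with bootstrap
   replicas quantifying reconstruction uncertainty.
3. **Optimistic Pareto screening.** The non-dominated set of the pooled
   bootstrap predictions proposes the next variants to assay; iterating
   measure-reconstruct-predict expands the measured set toward the true
   Pareto front.
4. **Interpretation aids.** Stochastic conformational-diversity
   simulations reproduce the triangular activity-cloud/trade-off-line
   pattern, and constrained single-mutation walks explore evolutionary
   paths over a reconstructed landscape.

## Statistical coupling analysis

For an alignment split by a `signature_criterion(position, sub, comp)`,
positional frequencies are computed over the 20 standard residues with
gaps excluded from the normalisation,

f[i,x] = (n[i,x] + pc) / (N[i] + 20 pc),

with a Jeffreys-like pseudocount pc = 0.5 by default so that
log-frequencies are finite. Columns with more than half gaps are
flagged; all-gap columns are excluded downstream.

The default coupling energy uses binomial weighting: with g the
background distribution (mean residue frequency over all alignment
columns, so the analysis is self-contained) and N_sub the subalignment
depth at position i,

ddG_i = kT* sqrt( sum_x [ ln P_sub(x) - ln P_full(x) ]^2 ),

where P_sub(x) = dbinom(n_sub_x, N_sub, g_x) and the full-alignment
counts are rescaled to N_sub before weighting (using raw rather than
pseudocounted frequencies in the rescaling, so that a subalignment equal
to the full alignment gives exactly zero). kT* = 1: the energy scale is
arbitrary and only the ranking matters. A simpler frequency-log-ratio
variant (`method = "logratio"`) is provided; the two rank positions very
similarly, which is also why the analysis tolerates the ambiguity in the
choice of binomial background. As an independent cross-check, a
covariance statistic sigma_i (the Euclidean distance between the
subalignment and complement frequency vectors) is computed alongside;
on alignments carrying a graded coupling network the Spearman rank
agreement between sigma and ddG is high (median about 0.8 in the
acceptance suite). On columns carrying no signal at all both statistics
rank pure sampling noise and their agreement is weaker — the agreement
claim is about signal-bearing alignments.

The subalignment must contain at least `min_sub_size = 20` sequences
(refusable with `force = TRUE`); perturbation statistics on fewer
sequences are dominated by sampling noise.

### Mutation-direction score

SCA ranks positions but not substitutions. For each top-ranked position
the target residue X is the most frequent non-reference residue in the
signature subalignment (ties broken alphabetically, for determinism),
and the direction of the statistical shift is scored as the log odds
ratio

Gamma(Ec -> X) = ln( f_sub(X) / f_sub(Ec) ) - ln( f_comp(X) / f_comp(Ec) ).

This is the package's definition of the score; it is pinned by three
contracts: Gamma vanishes on identical conditional distributions, is
positive exactly when the signature subalignment shifts weight from the
reference residue Ec towards X, and is antisymmetric under swapping the
two subalignments. Only candidates with Gamma > 0 are retained — a
shift *toward* the reference residue indicates the wild-type state is
already the signature-associated one. Note that because the two
subalignments have different depths, pseudocounting makes Gamma at an
uninformative column small but not exactly zero; the zero contract holds
for identical frequency tables.

`top_candidate_mutations()` defaults to examining the 13 highest-energy
positions, the depth at which the original protocol operated; with the
package's synthetic alignments the number of retained positive-score
candidates is then determined by how many planted columns shift away
from the reference.

## The pairwise-coupling activity model and PLS

Activities are modelled on the log10 scale (any base is consistent if
used throughout) as

A^k(g) = background^k + sum_i delta_i p_i^k + sum_{i<j} delta_i delta_j p_ij^k,

with binary mutation indicators delta and per-objective main effects and
pairwise couplings. For M = 10 and two objectives this is 110
parameters against, typically, 58 measured values — the
more-parameters-than-data regime PLS is designed for.

Fitting choices:

* **NIPALS PLS2, joint over objectives.** Responses are auto-scaled
  (mean subtracted, divided by the standard deviation) before fitting;
  both activities enter one model, with latent vectors maximising
  covariance with the joint response block. A per-objective mode
  (`joint = FALSE`) is available; at full rank both collapse to ordinary
  least squares, and the test suite verifies the NIPALS implementation
  against the normal equations and against an independent PLS
  implementation (mixOmics).
* **Predictors centered, not variance-scaled.** The indicators are
  binary; variance-scaling would overweight rare pair columns. Scaling
  is applied to responses only.
* **Intercept.** The model as written has no intercept; mean-centering
  supplies one implicitly and the back-transformed coefficients report
  it explicitly, since the background variant's activity is non-zero.
* **Latent-variable count.** Chosen to minimise the mean leave-one-out
  CV squared error averaged over objectives, on the auto-scaled
  response scale, with `max_lv = min(n - 2, 15)`. In bootstrap replicas
  all duplicated copies of a genotype are left out together — naive row
  LOO would place copies of the held-out genotype in the training set
  and be optimistic. The selected counts vary by replica (typically
  5-15 at study scale).
* **Bootstrap.** `bootstrap_reconstruct()` draws B = 20 replicas (rows
  resampled with replacement), refits, and predicts the full library per
  replica; degenerate replicas (a collapsed objective or too few
  distinct genotypes) are redrawn with a bounded retry count. Replica r
  uses seed `seed + r`, so ensembles are reproducible.

Measurement-error weighting and sparsity penalties are out of scope: the
protocol fits unweighted, and the standard-error columns of the TSV
dialect are carried but unused.

## Pareto screening

Dominance is strict in every objective (maximising all): tied points
coexist on the front. A weak-dominance mode exists but is off by
default. Front extraction sorts points in decreasing lexicographic
order — any dominator precedes its victims — and tests each point only
against the current front; the suite verifies equivalence with an
all-pairs oracle up to n = 2000 and 4 objectives.

The optimistic Pareto prediction pools all B x 2^M replica predictions
into one cloud and takes the genotypes appearing in its non-dominated
set: a genotype qualifies if *any* replica places it on the pooled
front, which deliberately widens the candidate set in proportion to
reconstruction uncertainty (the wording "non-dominated solutions in the
ensemble" supports pooling; per-replica-front union is available with
`pool = FALSE`). `screening_round()` emits the unmeasured candidates as
a request sheet; merging measured results and repeating closes the
iterative screening loop, whose measured-set front is non-decreasing in
the dominance order.

Scale discipline: Pareto extraction and screening operate on log
activities; the trade-off-line fit and the triangular-occupancy
statistic are defined on linear activities. `objective_points` carries
an explicit scale tag and mismatches are errors rather than silent
reinterpretations.

The triangle statistic counts points at or below a reference line
(tolerance 0 by default: "at or below") and reports the
order-of-magnitude null probability (1/2)^count. The default reference
is the line connecting the maximum observed primary activity with the
maximum observed promiscuous activity; a fitted trade-off line can be
passed instead.

## Conformational-diversity simulations

The built-in models encode ensembles of conformations with activity
coefficient pairs; per variant, weights w_i ~ U[0,1] are drawn
independently per conformation (no between-variant correlation), mol
fractions X(a_i) = w_i / sum(w) sum to one exactly, and activities are
the mol-fraction-weighted coefficient sums with proportionality
constants 1 (configurable; they only rescale axes). In the
three-conformation trade-off model (one inactive conformation, one
purely primary, one purely promiscuous) every simulated point obeys
primary + promiscuous <= 1, and the Pareto front of even a 40-variant
cloud approaches the trade-off line x + y = 1. The model-variant
coefficients "low" = 0.1 and "high" = 1.0 are package choices — only the
qualitative contrasts (negative vs positive inter-activity correlation,
large linear-like front vs very small front) are asserted anywhere, and
they are robust to these values. In the no-trade-off variant the two
optimal conformations share identical coefficient pairs, so the two
activities are exactly proportional and their correlation is 1 by
construction; any high-both coefficient choice gives the same
qualitative picture.

These simulations are illustrative machinery, not structural evidence;
they show that a simple conformational-equilibrium model reproduces the
triangular pattern, nothing more.

## Mutational paths

`random_walk()` implements the path loop: test all Hamming-1 neighbours
against a rule (strict improvement of one objective in a stated
direction, the other objective held at or above a floor), pick one
passing neighbour uniformly at random, repeat until none passes. Strict
improvement guarantees termination; terminal variants are local optima
under the rule. Adjacency is at the library-mutation level (one
indicator toggled) — codon-level accessibility is deliberately out of
scope. Thresholds are required configuration; the background variant's
constraint activity is the natural default. Path j of a run uses seed
`seed + j`.

## Synthetic data generators

The generators make every stage testable without external data, and
their defaults are the study conditions used throughout the tests.

**MSA generator.** Sequences draw residues independently from a
background distribution (uniform by default, keeping fixtures neutral
with respect to the SCA background, which is estimated from the MSA
itself). The signature column is set to the subalignment residue in a
fixed fraction of sequences (default 0.25 — large enough that the
subalignment clears the minimum-size guard with stable frequencies at
the alignment sizes of a few hundred sequences used in the checks) and
planted coupled columns carry the baseline residue in the complement
while the subalignment draws the shifted residue with probability equal
to the shift strength. A planted column whose `ref` entry is the
shifted residue models the opposite polarity: the signature subalignment
then shifts toward the reference residue, producing a high coupling
energy but a negative Gamma — such columns must be rejected by the
candidate-selection stage. What the generator does *not* emulate:
phylogenetic correlation between sequences, gaps, and realistic
position-specific background composition. Passing tests therefore show
that the statistics recover planted, independent-sequence signal; they
do not certify behaviour on tree-correlated natural alignments.

**Landscape generator.** Activities follow the pairwise-coupling model
exactly, plus homoscedastic Gaussian noise on the log scale — the
simplest noise structure consistent with log-scale fitting.
`paper_scale_scenario()` bundles the canonical geometry: M = 10,
2 objectives, main effects ~ U(-0.5, 0.5), five non-zero couplings
~ U(-0.3, 0.3), noise sd 0.1, a 29-variant random training subset and
B = 20 replicas. Under these conditions the median full-library Spearman
correlation between reconstruction and truth is about 0.93-0.95.

## Problem sizes and numerical choices

The test and acceptance workloads use: alignments of 200-400 sequences
by 40-60 columns (20 seeded repetitions for recovery rates), the M = 10 /
29-variant / B = 20 study geometry (10-20 seeds), 10^4-point
conformational clouds, and 100 seeded path walks — sizes at which every
stage's statistical claims are already stable. Front extraction is
O(n * front size); NIPALS tolerance is 1e-12 on score convergence with a
500-iteration cap; pseudocounts regularise all log frequencies; LOO-CV
folds that lose an objective's variance are skipped in the PRESS
accumulation; and all RNG consumption is derived from user-supplied
integer seeds (replica, path and repetition seeds are `seed + index`).

## Known limitations

* Eq-level SCA variants differ across the literature; the package
  commits to one binomial-weighted form plus a log-ratio alternative and
  argues robustness via the covariance cross-check, not via exact
  replication of any one historical implementation.
* The mutation-direction score is a log odds ratio; other shift measures
  satisfying the same sign contract would order borderline candidates
  differently.
* PLS reconstruction quality degrades gracefully but silently as true
  epistasis density grows beyond the fitted pairwise terms; the
  bootstrap ensemble widths, not point predictions, carry the
  uncertainty.
* The optimistic Pareto set is intentionally permissive; its size is
  seed- and noise-dependent, and the screening loop relies on follow-up
  measurement to discard over-optimistic candidates.
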