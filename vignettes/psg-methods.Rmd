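---
title: "Probabilistic splice graph models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic splice graph models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psgtools)
```

# The model

A **probabilistic splice graph (PSG)** represents a gene as a weighted DAG:
vertices are exonic segments (or exons, or exons with left context) carrying
nucleotide sequences, plus an empty start vertex `v0` and end vertex `vM`;
every isoform is a `v0 -> vM` path; the out-edge weights of each vertex form
a probability simplex and act as conditional probabilities of alternative
processing (AP) events — splicing choices, transcription starts (out-edges
of `v0`) and polyadenylation sites (in-edges of `vM`).  The probability of
an isoform is the product of its edge weights, so the graph factorizes the
isoform distribution Markov-wise in 5'-to-3' order: the choice at a branch
vertex is independent of the choices made upstream.  This factorization is
what buys both statistical identifiability and computational tractability
for genes whose isoform count grows exponentially with the number of AP
events (the `four_domain` fixture, with choice blocks of 12, 48, 33 and 2
alternatives and 38,016 paths, is the canonical stress case).

Three graph flavors trade off dependency structure against parsimony:

* **line graphs** (one vertex per projected segment) assume independence
  between all compatible AP events;
* **exon graphs of order h** (one vertex per annotated exon, duplicated for
  its (h-1)-exon left context when h > 1) allow dependencies between the
  events at an exon's ends, analogous to a higher-order Markov chain;
* **unfactorized graphs** (one disjoint path per annotated transcript) are
  statistically equivalent to full-length-isoform frequency models.

The package's default flavor is the first-order exon graph.

## Derived quantities

All inference rests on three dynamic programs over the DAG, each one
topological sweep:

* the inclusion probability `F(i, j)` that vertex `j` lies on an isoform
  given `i` does, via `F(i, j) = sum_x alpha(i -> x) F(x, j)`;
* expected prefix/suffix lengths `lambda_pre`, `lambda_suf`, and the
  expected transcript length `mu = lambda_suf(v0)`;
* path counts (for the enumeration guard).

## The read model

A fragment is generated by drawing an isoform `t` with probability
proportional to `w(t) * length(t)` and a start position `b` uniformly along
it; reads running past the 3' end continue into an infinite poly(A) tail.
The two length factors cancel, so `P(t, b) = w(t) / mu`, and the marginal
probability of a read placement — a minimal subpath `s` with offset `b` —
is `F(v0, first(s)) * w(s) / mu`.  Two numerical conventions matter here:

* A placement that overhangs into the poly(A) tail certifies that the
  transcript *ends* at its last real vertex, so its chain is terminated
  with `vM` and its weight carries the polyadenylation edge.  Without this
  the placement measure double-counts mass at genes with alternative 3'
  ends (our oracle-equivalence tests fail without it).
* Sequencing error is a uniform per-base substitution rate `eps`
  (`P(r | s, b) = (1-eps)^matches * (eps/3)^mismatches`), default 0 for
  inference on alignments and 0.005 for simulation.  Quality-aware error
  models and indels are out of scope.

For paired-end data the fragment length is drawn from a discretized
truncated normal independent of the transcript and is *not* renormalized
per transcript — the simplest generative story consistent with the
single-end model; placements of a mate pair are summed over spanning
subpaths connecting the two mates' chains.  Reads that align nowhere are
dropped from the likelihood and counted.

# Estimation

## EM

The complete-data log-likelihood of a fragment is `log(w(t)/mu(alpha))`, so
the E-step needs only posterior expected edge-usage counts.  These decompose
into (i) edges inside a placement's chain, (ii) upstream edges `(u, x)`
weighted `F(v0,u) alpha(u,x) F(x, first)/F(v0, first)`, and (iii) downstream
edges weighted `F(last, u) alpha(u, x)`.  The implementation aggregates each
fragment's posterior mass onto its chain's first/last anchor vertices and
resolves all edge expectations with one backward and one forward sweep;
cost per iteration is linear in the number of distinct placements plus the
graph size, never per-isoform.  Reads with several placements are assigned
fractionally (no best-hit filtering), and identical placement sets are
collapsed into groups, which makes the per-gene EM essentially independent
of read depth.

Two M-step variants are provided:

* **multinomial** — `alpha(u,x) = (c + beta - 1) / sum(c + beta - 1)`.
  This ignores the `- N log mu(alpha)` term of the objective and is exact
  only when all complete paths have equal length; with unequal path lengths
  its fixed point is biased (visibly so on the two-cassette fixture), which
  is why it is not the default.
* **exact** (default) — maximizes
  `sum_e c_e log alpha_e - N log mu(alpha) + log prior`.  Because `mu` is
  linear in any single vertex's out-edge simplex, each branch vertex is
  solved by a monotone fixed point on its KKT conditions (a 1-D root find
  for the Lagrange multiplier), cycled over vertices once per M-step.

Both variants run under a generalized-EM guard: if a proposed update would
decrease the log-posterior, the step is halved toward the current iterate
until it does not.  This keeps the trace non-decreasing for the multinomial
approximation too, which is not otherwise guaranteed.  Edge weights are
floored at `1e-12` (then renormalized) so that a zero expected count cannot
produce `log(0)` in later iterations; with `beta = 1` and zero aligned
fragments the ML problem is undefined and the fit errors, while
`beta > 1` returns the prior mode.  Initialization is uniform out-edge
weights (deterministic); convergence is declared when the relative
log-posterior change falls below `1e-8` (at most 1,000 iterations).

## The junction-read baseline

The JR estimator uses only reads whose best placements span splice-graph
edges, with a pseudocount of one per edge; a read spanning several
junctions increments every spanned edge, and multi-placement junction reads
are split equally.  Transcription-start choices produce no junction reads,
so `v0` out-edges are left at the prior mean and flagged.  JR is consistent
under the read model but discards body reads, hence converges more slowly
than EM — the bootstrap utilities quantify this on any dataset.

# Identifiability

The sufficient condition checked per edge: either some length-L read is
derivable from a subpath crossing the edge and from no other placement in
the whole graph collection, or the edge's target vertex can produce such a
globally unique read.  A graph is *certified* when every edge passes;
failure means "not certified", never "proven unidentifiable", because the
condition is sufficient only.  Uniqueness is judged on exact sequence
matches at the working read length across all genes jointly.  For the
full-length-isoform model, `demonstrate_nonidentifiability()` solves the
linear system of placement-class probabilities over the isoform simplex and
returns a concrete witness pair of distinct frequency vectors with
identical expected read distributions whenever the system is rank-deficient
— on the two-cassette fixture at L = 100 this reproduces the classic
failure of full-isoform models where the factorized exon graph is
certified.

# Differential processing

The gene-level test compares separate ML fits (`beta = 1`, exact M-step) on
two samples against a pooled fit:
`2 [l1(a1) + l2(a2) - (l1(a) + l2(a))] ~ chi^2_k`, `k` = number of free
parameters (sum over vertices of out-degree minus one).  The vertex-level
test ties only the chosen vertex's out-simplex across samples (its expected
counts are pooled in the M-step, everything else stays sample-specific) and
uses out-degree minus one degrees of freedom.  Benjamini-Hochberg controls
FDR across the tested genes (default target 0.05).

Design choices the data do not dictate:

* Genes with fewer than 20 aligned fragments in either sample are excluded
  from the test universe (configurable, reported); the chi-square reference
  is asymptotic and small-count genes would be tested far from its regime.
* A negative statistic (incomplete EM convergence) triggers one refit at a
  100-fold tighter tolerance and is then clipped at zero.
* The pooled fit treats the two read sets as one sample with a shared
  parameter vector.

# The simulator and the benchmark

`simulate_fragments()` samples `(t, b)` without isoform enumeration: start
vertex with probability `F(v0,i) l(i)/mu`, offset uniform within it, suffix
extended by out-edge weights, prefix by in-edge posteriors — so it is exact
for the model and works on the 38,016-isoform gene.  Identical seeds give
byte-identical FASTQ.

`make_dp_benchmark()` emulates a two-condition evaluation: 300 synthetic
multi-isoform genes by default (first-order-exon-style chains of 2–6 choice
blocks, vertex sequences i.i.d. uniform ACGT of 80–300 nt — long enough
that placements are effectively unique), four samples (two replicates per
condition), paired-end fragments (L = 100, fragment length 250 +/- 25),
per-gene depths log-normal around 5,000 fragments with sdlog 0.5 drawn
independently per sample, and 10% of genes (floor rule) differentially
processed by randomly permuting the isoform-frequency vector between
conditions (permutations that leave the vector numerically unchanged are
redrawn) and refactorizing it onto the graph — exact for these chain
topologies.  Reads are simulated error-free, and the aligned dataset handed
to the DP analysis is taken from the simulator's truth placements, which
for error-free reads coincide with the internal matcher's output (asserted
property-style at small scale); this keeps the benchmark's cost in the
statistics rather than in string matching.  What passing this benchmark
does *not* show: robustness to sequencing error, positional/sequence bias,
misannotation, or biological replicate variability — none of which the
generator emulates.

## Problem sizes used by the test suite

The suite checks oracle equivalence (read/fragment marginals, E-step
counts, likelihoods, inclusion probabilities and expected lengths) on 200
random graphs of up to 8 internal vertices against brute-force isoform
enumeration at `1e-9`; full-isoform-EM equivalence on 50 random
unfactorized genes at `1e-6`; parameter recovery on the two-cassette gene
at n = 10,000 over 100 replicates (with EM-versus-JR comparisons at
n = 100, 1,000, 10,000); LRT null calibration over 1,000 simulated null
pairs against the exact binomial 99% band at the 0.05 cutoff; and a
150-gene benchmark run.  The acceptance script runs the full 300-gene
benchmark.

# Known limitations

* Single pair of samples per test; no replicate-based variance modeling.
* No sequence/positional bias model; uniform fragment start assumption.
* Identifiability checks are exact-match and error-free.
* The internal matcher is exhaustive and meant for fixtures and small
  studies; large datasets should come in as SAM alignments against the
  emitted reference windows.
* Genes are modeled independently; cross-gene multi-mapping reads are kept
  per-gene (each gene's dataset lists its own placements).
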