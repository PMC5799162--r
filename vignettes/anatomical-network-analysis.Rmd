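---
title: "Anatomical network analysis of musculoskeletal systems with anatnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomical network analysis of musculoskeletal systems with anatnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anatnet)
```

## The model

Anatomical network analysis (AnNA) abstracts a musculoskeletal system into an
undirected, unweighted, simple graph. Nodes are anatomical units — bones,
cartilages, muscles — and a link joins two units that are in physical
contact: a suture or articulation between skeletal elements, or the
attachment of a muscle onto a bone or cartilage. The abstraction deliberately
discards size, shape and geometry: what remains is the connectivity pattern,
which carries its own comparative signal about integration and modularity and
is robust to differences in specimen size or measurement protocol.

Each network is summarized by six parameters:

* **N**, the number of nodes, and **K**, the number of links — counts of
  constitutive parts and their physical connections.
* **D = 2K / (N(N−1))**, the density of connections: the fraction of
  realized links among all possible ones. D is used as a proxy for the
  complexity of the structure, since the number of potential functional
  interactions grows with the number of connections among parts.
* **C**, the mean local clustering coefficient: for each node, the fraction
  of its neighbour pairs that are themselves linked, averaged over nodes.
* **L**, the characteristic path length: the mean shortest-path distance
  over all unordered node pairs, each link counting one length unit.
* **H = σ(k)/μ(k)**, the degree heterogeneity: the coefficient of variation
  of the degree sequence.

Higher D and C with lower L indicate greater integration and complexity;
higher H indicates greater anisomerism — differentiation among repeated
parts. Modules are communities of the graph: groups of units more densely
connected among themselves than to the rest of the network, detected here by
Newman–Girvan modularity optimization.

## Parameter conventions and degenerate inputs

Several small conventions matter for reproducibility, and all are fixed
explicitly:

* Nodes of degree 0 or 1 contribute a local clustering of 0 to C (the
  common convention when no formula is otherwise mandated).
* H uses the **population** standard deviation: the degree sequence is the
  entire population of the network, not a sample, and this choice makes
  results bit-reproducible across implementations.
* **Disconnected graphs**: L is undefined across components, so
  `parameter_set()` computes C, L and H on the largest connected component
  while N, K and D describe the full graph; the `connected` flag and
  `component_used` count record that this happened, and a warning is
  emitted. Published per-taxon tables report a single L per network, which
  implies connected analysis graphs; the policy keeps the statistic defined
  while flagging anomalous inputs instead of silently dropping them.
* Report tables round D to 3 decimals and C, L, H to 2, matching the
  precision at which these statistics are conventionally printed;
  comparisons against reference values round the computed number to the
  reference's printed precision first.
* The matrix reader is strict by default — values in {0, 1}, zero diagonal,
  exact symmetry — because AnNA networks are unweighted, undirected and
  self-contact-free. Two escapes exist for legacy hand-coded files:
  `strip_diagonal` zeroes a nonzero diagonal, and `symmetrize = "union"`
  ORs the two triangles; both warn and both are recorded in pipeline logs.

## Module detection

`detect_modules_greedy()` is a deterministic Clauset–Newman–Moore
agglomeration written for this package: start from singleton modules, and
repeatedly merge the pair of modules with the largest modularity gain while
that gain is positive. Two choices make it reproducible to the byte:

* ties in the gain are broken lexicographically on the pair of module
  labels, where a module's label is the smallest node index it contains;
* the returned partition is the one of maximal Q along the merge trace,
  which the object retains (`merge_trace`) for inspection.

Greedy agglomeration is a heuristic with a known resolution limit, so module
*counts* are treated as algorithm-dependent descriptions, never as a
regression surface (`check_against_fixture()` excludes them from pass/fail).
An exhaustive optimizer (`detect_modules_exhaustive()`) enumerates all set
partitions and certifies the true optimum on small graphs; the Bell numbers
make it practical only to about 10 nodes (it is capped at 12), and the test
suite uses it on graphs of up to 8 nodes to measure — not hide — any greedy
optimality gap. Stochastic methods (Louvain, simulated annealing) are
deliberately excluded from the analysis path: determinism is worth more here
than the last few thousandths of Q.

`modularity_score()` evaluates Q directly from its definition and is checked
in the tests against both a hand-derived oracle and an independent
implementation (igraph's), which is never used in the analysis path itself.

## Module classification

Published module names (neurocranial; left/right/main facial; suprahyoid and
tongue; laryngeal movement; true vocal fold movement; postcranial) are
verbal categories. `profile_module()` makes them operational with an ordered
rule set over a module's composition; every threshold sits in
`classify_config()`:

1. a module is **facial** when at least 50% of its nodes are
   facial-expression muscles or facial bones (bone names matched against a
   configurable pattern of facial skeleton elements). Among facial modules,
   **main_facial** requires both body sides to each hold at least 25% of
   the sided nodes; otherwise the majority side gives **left_facial** or
   **right_facial**, and the module is flagged *asymmetric* when it
   contains any node of the opposite side;
2. **true_vocal_fold_movement** requires every node to be
   arytenoid-associated (the arytenoid cartilages and the muscles acting on
   them); mixtures of arytenoid and cricoid/thyroid structures give
   **laryngeal_and_vocal_fold**, cricoid/thyroid dominance gives
   **laryngeal_movement**;
3. **suprahyoid_tongue**, **postcranial** and **neurocranial** fall out of
   dominant name patterns (plus the hypobranchial muscle group for the
   tongue module); anything else is **other**.

The rules are a reproducible, tunable approximation of a verbal taxonomy;
they are pure functions of module composition, so identical profiles always
receive identical labels. The 50%/25% defaults were chosen once as the
natural majority/presence thresholds and are not fitted to any dataset.

The asymmetry question is about *modules*, not muscles: a left facial
module that captures even one right-side structure is asymmetric in the
network sense, regardless of how symmetric the musculature itself is. A
single main facial module containing both sides is the other side-mixing
configuration; `asymmetry_report()` reports both flags per taxon.
Facial-muscle inclusion (`facial_inclusion()`) is the fraction of all
facial-expression muscles that fall inside facial-labeled modules, with
left and right muscle instances counted as separate nodes — consistent
with published denominators that vary by taxon (44, 46, 48) — and
percentages rounded half-up to integers as conventionally printed. Some
published percentages disagree with their own printed fractions by one
point (apparent truncation); the fixture in `reported_values()` carries
both numbers uncorrected and the tests document the discrepancy set.

## The synthetic generator

`synthetic_spec()` describes a musculoskeletal-like network generator whose
role is to make every pipeline stage testable with known ground truth. It
emulates the structural features that drive the analyses:

* a **connected skeletal scaffold**: a random spanning tree over bones and
  laryngeal cartilages rooted at a median element, plus extra
  block-weighted skeletal links;
* **muscles of degree ≥ 2**: each muscle receives two attachments (origin
  and insertion) plus a small binomial number of extras, drawn from its own
  body side plus the median skeleton, preferring skeletal units of its own
  planted block with weight `p_in` over outsiders at `p_out`;
* **mirrored left/right anatomy**: sampling happens on the left + median
  half and is reflected through the `_L`/`_R` name map, so at
  `asymmetry_rate = 0` the network is exactly isomorphic under left–right
  relabeling; a positive `asymmetry_rate` flips individual sided
  attachments to the mirror-image target, producing the side-mixing that
  detection then surfaces as asymmetric facial modules;
* **planted modules** — left facial, right facial, neurocranial,
  suprahyoid–tongue, laryngeal, postcranial — which double as the ground
  truth for recovery experiments.

The default roster has 37 skeletal units (13 median bones, 10 sided bone
pairs, cricoid/thyroid/arytenoid cartilages) and 129 muscles, including 24
facial-expression muscles per side, for N = 166 — inside the published
muscle–bone range of roughly 141–175 nodes. Default attachment and scaffold
counts were sized so the expected density falls in the published
musculoskeletal band of 0.029–0.035, and a rejection loop (at most 100
tries, then an error — the band is never widened silently) re-samples until
the realized D lands inside the band. A single seeded RNG stream drives all
sampling, so a spec plus seed reproduces byte-identical edge lists.

What the generator does **not** emulate: geometry and biomechanics, real
per-taxon rosters, muscle–muscle fusions (the reader accepts such links,
the generator never makes them), and the idiosyncratic attachment patterns
of real anatomy. Passing recovery tests therefore show that the algorithms
behave correctly on networks with this statistical structure — they do not
certify conclusions about any real taxon.

`planted_spec()` is the plain stochastic-block benchmark used for recovery
calibration: with 4 blocks of 12 nodes at `p_in = 0.9`, `p_out = 0.02`,
greedy detection recovers the planted partition essentially perfectly
(mean adjusted Rand ≥ 0.9 over 20 seeded replicates), and at
`p_in = p_out` the mean ARI sits at chance level near 0. Those two settings
and their thresholds were fixed before the experiments were first run.

## Cross-taxon comparison and reference values

`build_table()` binds one row per (taxon, network kind) with the six
parameters, module count, Q, facial inclusion and asymmetry flags.
`rank_and_correlate()` uses Spearman rank correlation (average ranks at
ties): the published structures-versus-density claim is argued by ranks, so
a rank statistic is the honest level at which to test it, and with the four
text-printed (N, D) muscle–bone pairs the assertable content is the
negative sign, not a magnitude.

`reported_values()` transcribes the text-printed reference values (with a
provenance descriptor per cell). Most of them derive from per-taxon
connectivity matrices published as supplementary material and from the
original study's own detection protocol, so they are **not** recomputable
here: `check_against_fixture()` reports such cells as `unchecked` unless a
matrix with the relevant structure is supplied, reports `excluded` for all
module counts, and checks everything else at printed precision. One
identity is internal to the fixture and always verifiable: D = 2K/(N(N−1))
holds at 3 decimals for the one taxon that prints all of N, K and D.

## Problem sizes used by the test suite

The suite exercises: brute-force oracle equivalence (triangle enumeration,
Floyd–Warshall, direct formulas) on 500 random graphs of at most 8 nodes;
greedy-versus-exhaustive comparison on 30 connected graphs of 4–8 nodes;
two 20-replicate recovery experiments at 48 nodes each; and full-pipeline
runs on generated 166-node musculoskeletal networks. These sizes give
exhaustive or near-exhaustive coverage of the small-graph space while
keeping a complete run in the tens of seconds.

## Known limitations

* Module labels depend on name patterns when metadata alone cannot
  distinguish classes (facial bones, laryngeal structures); unnamed or
  renamed units degrade classification gracefully to `other`, never
  silently into a wrong class with high confidence.
* The greedy optimizer inherits the resolution limit of modularity; small
  true modules (a two-node module, say) may be absorbed. Use the
  exhaustive optimizer where the graph allows it.
* `facial_inclusion()` requires the partition's facial modules to have been
  labeled first; on networks without facial-expression muscles it refuses
  rather than returning 0/0.
* The component policy makes C/L/H silently describe a subgraph when the
  input is disconnected; the warning and the `component_used` field are the
  contract — consumers that need strict connectivity should check the flag.
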