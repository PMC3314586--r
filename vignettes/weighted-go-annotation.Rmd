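---
title: "Weighted GO-term scoring: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted GO-term scoring: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GOsieve)
```

## The problem and the model

Transferring Gene Ontology annotations from database hits to a query
protein is noisy: strong hits carry wrong terms, weak hits carry right
ones, and the GO DAG makes shallow terms trivially "correct" but useless.
GOsieve treats annotation as an evidence-accumulation problem on the DAG.
Every GO term retrieved from a hit is weighted by the hit's reliability
(the e-value exponent, optionally damped by how consistently the term
annotates a domain model's proteins), the weights are propagated along all
root-paths, and a term is reported only when (i) the cumulative weight on
its path stands out against the protein's own weight distribution
(Z-score), (ii) it belongs to a semantically coherent group carrying a
substantial share of the evidence (Group Score over Lin-similarity
clusters), and (iii) its Total Score — information content × evidence
share² / group share × weight — clears a reporting threshold.

The model's assumptions are worth stating plainly. Evidence from different
hits is treated as independent and additive (weights for one term sum); the
annotation corpus used for information content is assumed representative of
the domain of the queries; and the three GO namespaces are assumed
independent — no similarity, grouping or scoring ever crosses them.

## Tunable parameters

All knobs live in one `gosieve_config()` object; file-based runs accept the
same keys from YAML.

| parameter | default | meaning / why this default |
|---|---|---|
| `evalue_ceiling` | 1e-3 | hits weaker than this never enter; a conventional homology-search inclusion cutoff |
| `evalue_floor` | 1e-180 | search tools report 0.0 for very strong hits; the floor caps the weight at 180 instead of infinity |
| `logistic_steepness`, `logistic_midpoint` | 10, 0.5 | the frequency reward for domain-model terms crosses 0.5 at 50% model coverage and saturates within ±0.3 of it; terms present in <20% of a model's proteins are damped to near zero |
| `aggregation` | `"sum"` | convergent evidence for one term accumulates; `"max"` keeps only the strongest contribution |
| `ic_base` | natural log | the base cancels in Lin similarity; IC values are then in nats |
| `sim_threshold` | 0.7 | Lin similarity at which terms chain into one group; 0.7 keeps parent–child pairs of comparable specificity together while separating branches that only share shallow ancestors |
| `z_threshold` | 0 | a term must carry at least the slim-average cumulative weight |
| `grs_threshold` | 0.2 | its group must hold at least 20% of the total internal confidence |
| `ts_threshold` | 0 | report everything that survives; downstream users cut by TS |
| `exclude_self_hits` | FALSE | drop hits whose subject equals the query, for benchmarks that pretend the query is unknown |
| `representatives_only` | FALSE | report every surviving term (flagging each group's top scorer) rather than representatives alone |

The filter thresholds are deliberately conservative-by-default rather than
tuned: the method's design goal is precision over recall, and the Z and
Group Score cutoffs are the two places where that bias is enforced.

## Numerical and degenerate-case choices

* **Weight log base.** Weights use −log₁₀ so they read directly as e-value
  exponents (1e-50 → 50). IC uses the natural log; since Lin similarity is
  a ratio of ICs the choice does not affect grouping, only the scale of IC
  and TS.
* **Unseen terms.** A term never annotated in the corpus would have
  infinite IC. It is assigned the maximum finite IC, −log(1/total), plus a
  small epsilon (1e-6): unseen terms are maximally informative but must
  remain comparable, keeping TS finite.
* **Lin at zero IC.** For two terms with IC 0 (root-like), the Lin ratio is
  0/0. Identical terms score 1, distinct terms 0 — so namespace roots never
  seed similarity groups.
* **σ = 0.** When all slim weights are equal (e.g. a single retrieved term
  on one path) the Z-score denominator vanishes; Z is defined as 0 and the
  term is judged by its Group Score alone.
* **Z-score population.** "The standard deviation of all the weights" is
  ambiguous; the package uses the population standard deviation of the
  cumulative weights over the slim, consistent with Z being a statement
  about W. `sigma_source = "input"` switches to the raw input weights.
  Likewise W̄ divides the root weight by the number of slim nodes
  (`wbar_denominator = "input"` divides by retrieved terms instead).
* **Grouping algorithm.** Single-linkage threshold clustering (connected
  components of the thresholded similarity graph, computed with igraph):
  deterministic, order-independent, and the only clustering whose groups
  are invariant to how members are enumerated. Group ids are assigned by
  smallest member term id.
* **Ties and ordering.** Output rows sort by TS descending, then IC
  descending, then term id — byte-for-byte reproducible. Group
  representatives are the surviving member with maximal TS under the same
  tie-break.
* **Degenerate inputs.** An empty weighted term set yields an empty slim
  and empty output (a protein may legitimately receive no annotation);
  an all-filtered protein likewise. Terms missing from the ontology, BLAST
  subjects missing from the corpus and HMMER models missing from the
  frequency table are skipped with warnings, never errors.
* **Reportability.** Only retrieved terms can be reported. Reconstructed
  ancestors shape the cumulative weights and the Z statistics but carry
  `w = 0`, and the non-cumulative measures exist precisely so descendant
  mass cannot bias a parent's own score.

## The assessment protocols

`pr_curve()` sweeps thresholds from 0 to the maximum observed score
(predictions kept when score > t, strictly, so the top threshold empties
the set). Per-protein precision TP/(TP+FP) is averaged over proteins that
still have predictions — a protein with no annotated term at a threshold
has no precision to calculate — while recall TP/(TP+FN) averages over the
whole pool, so silent proteins keep dragging recall down. Mode `m1`
compares exact term sets; `m2` first propagates predictions and truths to
the root (sets deduplicated, roots included by default; a flag excludes
them), granting partial credit to predictions that lie on a true path.
Curves are computed per namespace or pooled.

## What the synthetic generator emulates — and what it does not

`fixture_spec()` + `make_ontology()` + `make_benchmark()` produce a
complete, parseable study: layered random DAGs (every non-root term draws
1–2 parents from earlier terms, so acyclicity holds by construction), a
background corpus of 120 annotation records that gives IC texture, and per
protein one planted term per namespace backed by either two sequence hits
at e-values 1e-60..1e-30 or a domain-model hit whose model carries the term
at 95% frequency (25% of planted terms, emulating functions that profile
searches see and pairwise searches miss). Decoy hits sit at 1e-8..1e-4 — at
least three orders of magnitude weaker — and point at terms off the planted
term's root path, so true and false evidence are unambiguous by design.
The "with" mode adds the targets themselves to the databank plus an exact
self-hit at the e-value floor, leaving all random draws untouched so the
paired comparison is seed-for-seed.

One planted term per namespace is a deliberate design choice: with the
default Z cutoff of 0, two planted terms on disjoint branches of one
namespace would split the evidence and push each other's Z below the slim
mean, so neither complete recovery nor a clean reading of the filters would
be possible. The generator models the regime the filters are built for —
one dominant true function per namespace plus noise.

What the generator does **not** emulate: real GOA scale and annotation bias
(term frequencies here are roughly uniform, real corpora are heavily
skewed), sequence content (no alignments, only hit tables), correlated
errors between hits (decoys are independent), multi-functional proteins
within a namespace, and obsolete/alt-id churn. Passing tests on these
fixtures therefore demonstrate that the algebra, the filters and the
rankings behave as specified — not that any particular precision/recall
level will be achieved on a real proteome.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
benchmarks of 10 proteins over ~40-term ontologies, property checks over
200 random fixtures of ≤ 12 terms, and brute-force oracle comparisons
(path enumeration, transitive-closure clustering, per-threshold confusion
recomputation) on the same small DAGs, where exhaustive enumeration is
exact. These sizes keep every oracle literally exhaustive; the pipeline
itself is linear in hits and quadratic only in the number of retrieved
terms per protein-namespace, and has no scale-dependent switches.

## Known limitations

* Information content is corpus-relative; with the record-counting default,
  heavily annotated proteins inflate their terms' frequencies
  (`corpus_count = "pairs"` is the stricter alternative).
* Lin similarity with a single shared high-IC ancestor can chain distinct
  functions into one group at low thresholds; the default 0.7 mitigates
  but does not eliminate this.
* The Total Score is a raw ranking score, not a calibrated probability —
  no p-value is attached to it.
* Only `is_a` and (optionally) `part_of` edges are followed; regulatory
  relationships are ignored, and cross-namespace edges are dropped with a
  warning.
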