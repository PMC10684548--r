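---
title: "Detecting protein domain mosaicism in phage proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting protein domain mosaicism in phage proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagemosaic)
```

## The problem and the data model

Phage proteins are frequently mosaics: two proteins that are unrelated over
most of their length may still share a homologous fragment or a domain,
because domains are shuffled between proteins by recombination and related
processes. `phagemosaic` quantifies this from profile–profile (HMM–HMM)
searches over representative protein profiles (rHMMs) — one profile per
protein cluster, the pipeline's atomic unit. Three searches drive
everything: rHMMs against themselves (all-by-all), rHMMs against the ECOD
domain hierarchy, and rHMMs against PHROG-style functional profiles
(optionally complemented by an antidefence profile set). All coordinates
are 1-based inclusive, hhsuite style, and are never converted elsewhere;
probabilities and identities are stored as fractions, accepting hhsuite's
percentage output at read time.

## Pair aggregation

HMM–HMM alignment is non-commutative, so a pair of profiles is searched in
both directions and each direction may yield several local hits. The
package collapses these into one symmetric record:

* **Probability.** Within a direction, each residue of the homologous
  region carries the *maximum* probability among the hits covering it and
  the direction score is the mean over covered residues. The pairwise `p`
  is the minimum over the non-empty directions — the conservative reading
  of a non-commutative comparison. The per-residue maximum is a choice the
  aggregation rule itself does not force: where hits overlap, taking the
  maximum is the least destructive way to say "this residue was detected
  with (at least) this probability".
* **Identity.** Multi-HSP direction identity is the alignment-length
  weighted mean of the hit identities (an explicit choice; the single
  best-hit identity is a defensible alternative, and the aggregation
  function isolates the decision in one place), then again the minimum
  over directions.
* **Coverage.** `qcov` and `scov` are interval-union residue counts over
  the hits of *both* directions divided by sequence length. Merging
  directions makes coverage symmetric: a residue pair either aligns or it
  does not, regardless of which profile was the query. Pairs with hits in
  only one direction are allowed — the minimum is over non-empty
  directions — because asymmetric detection does happen in practice.

Two threshold contexts of the same pair are kept as separate records
rather than one mutable one: the *permissive* context aggregates all hits
at `p >= 0.5` and is the homology background, while the *strict* context
re-aggregates only the `p >= 0.95` hits and describes the high-confidence
fragment. Family construction and mosaic-fragment statistics use the
strict context; only the sequence-mosaicism background test uses the
permissive one.

## Annotation

Functional classes follow the PHROG simplification mapping supplied as an
input table. A hit qualifies at `p >= 0.95` and pairwise coverage
`min(qcov, scov) >= 0.8` (the coverage merge is again the conservative
`min`; the threshold is deliberately strict because fragment-level
annotation is ambiguous — at low coverage a partial match cannot
distinguish a shared domain from a shared function). An rHMM with more
than one qualifying non-generic class is discarded as ambiguous; the
generic classes `tail` and `structural protein` are tolerated alongside a
specific class, and an rHMM with qualifying PHROG evidence plus a
qualifying hit to a specific antidefence profile is overridden to that
antidefence class. The override deliberately requires PHROG-qualifying
evidence as well, so an isolated antidefence hit cannot annotate an
otherwise unknown profile. Class-level statistics only admit classes
backed by at least 500 PHROG sequences and 20 rHMMs.

Domains are ECOD hits with `p >= 0.95` and subject coverage
`scov >= 0.7` — subject coverage, because the question is whether the
*domain* is present in the protein, not the reverse. The domain
architecture of an rHMM is the *set* of detected T-groups; multiplicity
and order are display-only. All thresholds in the package are inclusive
(`>=` / `<=` exactly as stated), and the boundary behaviour is pinned by
tests.

## The two mosaicism definitions

**ECOD-based.** A pair is mosaic when each side has domains from at least
two X-groups, the sides share a T-group, and each side carries an X-group
the other lacks. "At least two distinct domains" is read as at least two
distinct *X-groups*: two T-groups within one X-group may simply be
diverged copies, so they cannot establish that a protein is built from
unrelated parts. Sharing is scored at the T-group level (not H) because a
shared topology is the stronger, more recent signal. The predicate is
symmetric and can never fire on identical architectures or self-pairs.

**Sequence-based.** A pair is mosaic when its strict-context fragment has
`p >= 0.95`, identity `>= 0.30` and length `>= 50` aa while the
permissive-context coverage satisfies `max(qcov, scov) <= 0.5`. The
fragment length criterion uses the *minimum* of the two sides'
union-aligned residue counts — the definition does not name a side, and
requiring both sides to reach 50 aa is the conservative reading. A strict
pair without a permissive counterpart is an error, not a call: the
background test is what separates "shared fragment" from "plain
homologs".

Fragment identity tiers calls into contemporary (`>= 0.5`) and recently
emerged mosaicism at high (`>= 0.7`) and very high (`>= 0.9`) confidence.
An rHMM in at least one call of a basis carries that basis' *mosaic
signal*; a family is mosaic if any member carries the signal.

## Families: in-package Markov clustering

The family graph links strict-context pairs with `p >= 0.95` and
`cov = min(qcov, scov) >= 0.8`, weighted `p * cov`. Markov clustering runs
on the column-stochastic matrix with inflation 2 (the conventional
default granularity): self-loops are set to each node's maximum incident
weight (1 for isolated nodes, matching the loop-adding default of the
reference MCL software), expansion is the matrix square, inflation the
entrywise square followed by renormalisation. Entries below `1e-6` are
pruned each iteration for sparsity; iteration stops when the matrix
changes by less than `1e-8` or after 100 rounds (non-convergence warns
and clusters the current state). Clusters are read from attractor rows;
a node reachable from several attractor systems joins the one holding the
largest mass on its column, ties to the lowest index — a deterministic
tie-break, so node-order permutations change labels only. Singletons stay
as their own families, which matters for the class-enrichment
denominators. The test suite holds this implementation equal to an
independent, unpruned dense-matrix reimplementation on random graphs, so
the pruning approximation is bounded by construction.

## Enrichment and networks

The domain design tests, per T-group, whether the domain is
over-represented among *unique architectures* flagged mosaic (an
architecture is mosaic when any rHMM pair bearing it is in an ECOD-basis
call); the class design tests, per eligible class, mosaic versus
non-mosaic *families* containing the class against those containing only
other eligible classes. Both use the one-tailed Fisher exact test (upper
hypergeometric tail) with odds ratio `(a/b)/(c/d)` reported exactly as
defined: zero cells give 0 or infinity without continuity correction,
since the exact p-value needs no such repair. Bonferroni multiplies by
the number of features actually tested in that run — domains occurring in
at least one architecture, or eligible classes — which the result table
records; this is the defensible multiplicity when the feature list itself
is data-dependent.

The mosaic class network links two classes (self-loops allowed — within-
class mosaicism is real) when at least four distinct unordered
architecture pairs support ECOD-basis calls between them, flagging the
edge contemporary when a supporting rHMM pair shares a fragment at
identity `>= 0.5`; the fragment identity of an ECOD-basis pair comes from
the strict self-search comparison and is simply absent (never
contemporary) when the pair has no self-search hit. The recent-mosaicism
network is built from sequence-basis calls at a tier floor, with
unannotated partners mapped to an explicit `unknown` node.

## Ecology

Lifestyle is classified from temperate probability at inclusive 0.9/0.1
boundaries. An rHMM inherits a group (host genus, ICTV family/genus,
lifestyle) when all its classified member proteins agree; disagreement
gives `conserved_across_groups`, no classified member gives `unassigned`.
Per-genome mosaic fractions divide signal-carrying proteins by
rHMM-mapped proteins, reporting a genome without mapped proteins as
missing rather than zero. Cross-boundary labels stratify calls at 70%
fragment identity into recent and older mosaicism.

## The synthetic-data generator

The generator emulates the *tables*, not the sequences: planted families
are cliques of reciprocal full-length hits (`p = 0.99`, coverage 1);
planted ECOD-mosaic pairs get two-domain architectures built from three
private T-groups (shared, unique-left, unique-right) in X-groups disjoint
from the background pool; planted sequence-mosaic pairs get reciprocal
120-aa fragment hits on 400-aa profiles (coverage 0.3) with identity
drawn from the band of a planted age tier (40% baseline, 30%
contemporary, 20% high, 10% very high by default); background rHMMs draw
1–5 domains *all from one X-group*, so no background pair can satisfy the
ECOD predicate and noiseless precision/recall are exactly 1 by
construction. Unrelated pairs emit no hits (a clean null); an optional
spurious-hit rate adds sub-threshold noise to exercise the permissive
background. Domain dropout removes each true domain independently, so a
two-domain-per-side ECOD pair survives with probability `(1 - d)^4` —
the analytic yardstick the recovery tests use. One integer seed drives
the stream, and the global RNG state is saved and restored around
generation.

What this does *not* emulate: realistic sequence evolution, correlated
domain loss, database incompleteness biases, and architectures whose
background pairs are near-misses of the predicates. Passing the planted
recovery tests therefore demonstrates that the machinery implements its
definitions exactly — not that the definitions are complete on real
proteomes, where under-annotated functional classes are known to hide
mosaicism from the ECOD-based detector.

## Problem sizes and numerical choices

The validation suite runs at desk scale by design: Fisher agreement is
enumerated over all 2x2 tables with total at most 30 (about 46k tables,
tolerance `1e-10`); Markov clustering is compared to its dense oracle on
30 random graphs of up to 40 nodes; pair aggregation against per-residue
brute force on 50 random multi-HSP instances (tolerance `1e-12`);
noiseless end-to-end recovery on 200 rHMMs with 20 + 20 planted pairs and
15 families; dropout recovery on 520 planted pairs at 30% dropout; and
the type-I error of the enrichment test on 1000 permuted-label features
over 400 units with near-balanced margins — balanced deliberately, since
at small margins the Fisher test's discreteness pushes the rejection rate
far below nominal and would test the discreteness, not the
implementation.

## Known limitations

Headline counts from full-scale proteome studies (tens of thousands of
families from hundreds of thousands of proteins) depend on specific
database snapshots and are not reproduced here. The ECOD-based detector
is restrictive by design and misses sub-domain mosaicism and cases with
undetected domains; the sequence-based detector admits false positives
from rate variation along proteins (tape-measure proteins are the classic
offender). Fragment identity for ECOD-basis calls requires a self-search
hit for the pair and is otherwise unknown. The MCL implementation targets
graphs up to the low hundreds of thousands of edges; it is not a
replacement for the reference binary on massive networks.
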