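---
title: "Ranking drug side effects from interaction networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking drug side effects from interaction networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrnet)
```

## The model

`adrnet` treats side-effect prediction as a multi-label ranking problem
solved by guilt-by-association. The working assumption is that compounds
which interact — because they take part in the same reactions, share
structure or activity, or co-occur in the literature — tend to share
biological behaviour, and side effects are part of that behaviour. The
assumption is inherited from the interaction databases themselves: a
STITCH confidence score is precisely a belief that two entities act on
common pathways.

Three scoring routes share one shape: a per-side-effect score that is an
aggregate of pairwise drug–drug affinities weighted by training labels.

* **Direct route.** `score_direct()` sums the chemical-interaction
  confidence `Q^c(d, d_i)` over training drugs labelled with each side
  effect. A drug with many high-confidence interactive partners carrying
  "Nausea" scores high for Nausea. Scores are sums on the native
  confidence scale — they are relative rankings, not probabilities, and
  the package deliberately does no calibration.
* **Hybrid route.** `score_hybrid()` replaces `Q^c` with
  `hybrid_score()`: the average, over the shared chemical and protein
  neighbourhood of the two drugs, of both drugs' confidence against each
  shared entity. It exists for exactly one situation: a query whose
  direct score vector is entirely zero, i.e. no interactive partner in
  the training set. That trigger — *all* entries zero, not "small" — is
  the package's reading of an otherwise unquantified "trivial outcome";
  any positive direct evidence, however weak, takes precedence
  (`predict_two_step()`).
* **Similarity baseline.** `score_similarity()` is the standard
  structure-similarity comparator: the *maximum* Tanimoto similarity to
  any labelled training drug (a best-match rule, not a vote).

Ranks are assigned to strictly positive scores only. An all-zero vector
yields an empty prediction, and the evaluation counts every order of an
empty prediction as a miss rather than shrinking the denominator.

## Numerical and tie-breaking choices

* Ties in a score vector break first by training prevalence of the side
  effect (commoner effects first — the better prior), then by catalog
  position. This makes rankings fully deterministic, which the
  evaluation machinery and the reproducibility contract rely on.
* `Q^h` of two drugs with no shared neighbours is defined as 0 rather
  than 0/0: "no shared evidence" degrades to "no evidence", and the
  two-step predictor then simply returns an empty prediction.
* Chemical and protein identifiers are kept in disjoint namespaces when
  counting the shared-neighbour union, so a protein and a chemical that
  happen to share a raw identifier can never collapse into one union
  member; under that discipline the union size is the sum of the two
  intersection sizes.
* Interaction tables collapse duplicate rows (real STITCH dumps list
  each edge in both directions, occasionally with disagreeing scores) by
  the maximum — the conservative reading that keeps the interaction.
  Self-interactions are dropped at load: a drug never testifies about
  itself through the network. Scores are kept on their native scale; all
  downstream formulas are scale-covariant sums and averages, so global
  rescaling cannot change any ranking.
* The train/test split size uses half-down rounding
  (`ceiling(f·n − 0.5)`): 10% of 835 drugs gives 83 test drugs, matching
  the published benchmark split of 835 into 752 + 83.
* The interaction-coverage filter runs *after* the top-k side-effect
  selection, and any side-effect category emptied by it is dropped with
  a message. The split seed is a required, recorded argument — there is
  no default, so a split can never be an accident.

## Evaluation semantics

`jackknife_evaluate()` singles out each drug in turn and removes only its
*labels* from the training matrix. Its network edges and similarity
scores remain visible: the networks are external knowledge, not
annotations being predicted, and the predictor only ever sums over
training-set labels. The self-exclusion is by identifier; a structural
duplicate registered under a different identifier stays in the training
set, and with the similarity method such a duplicate legitimately scores
1.0. `holdout_evaluate()` predicts disjoint test drugs against the full
training matrix. Both produce `AC(j) = P(j)/N` profiles with `N` fixed at
the number of structure-different drugs evaluated, plus a per-drug log of
which evidence route fired.

The "virtual drug" bookkeeping (`count_virtual_drugs()`) counts one drug
once per side-effect category it belongs to; it is reported in dataset
manifests and bounds the total number of rank hits.

## The synthetic fixture generator

`generate_fixture()` emulates the single premise the predictor exploits:
interacting drugs share side effects. Drugs are partitioned into
communities; each community owns a disjoint block of "characteristic"
side effects; chemical edges are dense within communities
(`p_edge_within = 0.8`) and sparse across (`p_edge_between = 0.05`);
drugs link to community proteins (`p_protein_link = 0.8`); labels follow
the community pattern (`p_label_within = 0.9`) over a small background
rate (`p_label_noise = 0.05`). A fifth of the drugs
(`p_chem_isolated = 0.2`) get no chemical edges at all, only protein
links, so the hybrid fallback is genuinely exercised rather than being
dead code — with the defaults roughly 80% of drugs are predicted through
the direct route and the rest through the hybrid one. Confidence scores
are uniform on [150, 999], the upper region of the STITCH confidence
scale (the low-confidence band under 150 is commonly discarded in
practice; the loaders expose `min_score` for users who wish to do the
same, defaulting to keeping everything positive).

Default sizes (40 drugs, 4 communities, 12 proteins, 10 side effects)
are chosen so that every code path runs in well under a minute while
binomial edge-count checks still have power. Each random component —
edges, protein links, scores, labels, similarity — draws from its own
seed-derived RNG stream, so changing one parameter perturbs only its own
component.

What the fixture does **not** emulate: the heavy-tailed degree
distribution of real chemical networks, correlated label structure
beyond one community membership, chemically meaningful similarity (the
similarity table is generated numerically, high within communities, low
across), and realistic label sparsity (real benchmarks have ~100
categories and drugs carrying dozens of labels). Passing the planted
recovery tests therefore shows the machinery is correct and the signal
is recoverable when the premise holds; it says nothing about accuracy on
real STITCH/SIDER-scale data, which depends on database coverage.

## Fingerprint backend

The similarity baseline is pluggable. The default backend parses SMILES
with ChemmineR, computes atom-pair descriptors, and folds each
descriptor code onto a fixed-length bit vector (512 bits) by a
Lehmer-style scramble modulo the Mersenne prime 2^31 − 1 before
reduction. Plain modulo folding is unusable here — atom-pair codes carry
the topological distance in their low bits, so unrelated molecules would
collide systematically. The scramble spreads codes effectively uniformly;
occasional collisions remain, as in every folded fingerprint. Tanimoto
similarity on the folded bits uses the conventions: two empty
fingerprints compare as 1 (degenerate single-atom molecules remain
self-similar), an empty against a non-empty as 0. Unparseable SMILES
degrade to similarity 0 against everything, with a warning, keeping
pipelines total. For bit-exact reuse of externally computed similarity
scores (e.g. an Open Babel FP2 run), `precomputed_provider()` serves a
validated symmetric table instead.

## Known limitations

* Scores are rankings, not calibrated risks; comparing absolute score
  magnitudes across queries is meaningless.
* One level of indirection only: the hybrid score looks at shared
  neighbours, never at longer network paths.
* Stereo/flat compound identifier merging (CIDm/CIDs) is out of scope;
  identifiers are opaque strings.
* The published benchmark's headline accuracies depend on specific
  database versions and an unrecorded random split; they are not
  reproducible from code alone, which is why the test suite anchors on
  oracle equivalence, invariants, the accuracy arithmetic at the
  published problem sizes, and planted-structure recovery instead.
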