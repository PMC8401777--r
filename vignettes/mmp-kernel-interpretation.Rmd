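---
title: "Interpreting activity-cliff predictions with the MMP kernel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting activity-cliff predictions with the MMP kernel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmpcliff)
```

## The problem

An activity cliff (AC) is a pair of structurally analogous compounds whose
potencies differ by orders of magnitude. On matched molecular pairs (MMPs) —
two compounds sharing a core and differing by one substituent exchange at a
single site — cliffs isolate the exact chemical change responsible for the
potency jump, which makes them both precious and notoriously hard to model:
a tiny change of input flips the output. `mmpcliff` trains a support vector
machine to classify MMPs as cliff (absolute pKi difference above 2 log
units) or non-cliff (below 1; the band in between, including the boundary
values, is discarded as ambiguous), and then explains each prediction
*exactly*, feature by feature, on the atoms and bonds of the molecules.

## From compounds to MMPs

Compounds enter as SMILES with pKi potencies. Fragmentation cuts each
acyclic single bond between heavy atoms in turn; the smaller side is the
substituent, and both fragments keep the attachment point as a dummy atom
in their canonical SMILES. Two size constraints from standard MMP practice
apply: a substituent has at most 13 heavy atoms and the two substituents of
a pair differ by at most 8. Hydrogen "substituents" are not enumerated:
their substructure fingerprints would be empty, and heavy-atom counting is
used throughout.

When a compound pair shares several cores, only the largest core (ties:
lexicographically smallest canonical string) is kept. This is a deliberate
design choice: it guarantees that a compound pair belongs to exactly one
matched molecular series (MMS — all MMPs sharing one core), so the
series-wise evaluation below cannot leak a pair into two folds. Series
containing only cliffs or only non-cliffs are discarded: they carry no
contrast for either training or evaluation.

## Fingerprints built for interpretation

Each MMP is represented by three concatenated sparse segments:

* **core**: circular substructure identifiers of the core fragment,
* **substituent XOR**: features present in exactly one substituent,
* **substituent AND**: features present in both.

Identifiers are unfolded circular (Morgan-style) codes of bond diameter 2
and 4. The diameter-0/1 layers (bare atom types) are excluded so that every
feature spans at least one bond and the explanation focuses on real
substructures rather than atom counts. Features are binary — the XOR/AND
construction and the Tanimoto kernel operate on presence, not counts — and
the attachment dummy participates in environments, so substituent features
know where they sit relative to the cut. Within a training universe,
identifiers are sorted ascending and mapped to bits without folding, so
distinct substructures never collide on one bit; each identifier keeps a
back-map to every atom/bond environment that generated it. Hash collisions
of the 31-bit environment codes themselves are possible in principle, as
in any unfolded circular fingerprint, and are accepted.

## The kernel and the classifier

Similarity between MMPs \(u, v\) is the **MMP kernel**
\[
K_{\mathrm{MMP}}(u,v) \;=\;
K_{\mathrm{Tan}}(u_c, v_c)\, \times\, K_{\mathrm{Tan}}(u_s, v_s),
\qquad
K_{\mathrm{Tan}}(a,b) = \frac{|a \cap b|}{|a| + |b| - |a \cap b|},
\]
the product of core-wise and substituent-wise Tanimoto kernels: two MMPs
are similar only when both their cores *and* their transformations are.
Kernels are computed on identifier sets rather than fixed-length vectors,
so a test MMP carrying features unseen in training has those features
enlarge its self-similarity term without ever contributing overlap — the
union-universe vector formula, without rebuilding vectors. An empty segment
has similarity 0 by convention: absence of features is not evidence of
similarity. Self-similarity of non-empty segments is 1 and all Gram
matrices are positive semidefinite (checked property-style in the tests).

The classifier is a maximum-margin SVM on the precomputed Gram matrix
(backend: `kernlab::ksvm`), with decision function
\(f(x) = \operatorname{sign}(\sum_i \alpha_i y_i K(x_i, x) - b)\); positive
decisions predict a cliff. The backend's internal sign convention is
reconciled empirically against its own predictions at fit time. The box
constraint is chosen from the grid \{0.01, 0.1, 1, 10, 100, 1000\} by
stratified 5-fold cross-validation maximising MCC — MCC because it is the
headline evaluation metric and is robust to the class imbalance typical of
cliff data; ties go to the smaller (more regularised) C.

Evaluation is **series-wise leave-one-out**: one MMS is held out per fold,
the model (including its feature universe) is rebuilt from the remaining
series, and any test MMP containing a compound that occurs in a training
MMP is eliminated from the fold. No core and no compound ever crosses the
train/test boundary, so pooled recall, ROC AUC (from raw decision values)
and MCC measure genuine extrapolation to unseen chemistry.

## Exact feature contributions

For the plain Tanimoto kernel the decision value is already a sum over
shared features: within one support-vector/test pair, the kernel
denominator is a constant, so each shared feature \(d\) carries
\(\alpha_i y_i / (|x_i| + |x| - |x_i \cap x|)\). The product structure of
the MMP kernel breaks this — expanding the product turns each kernel
evaluation into a matrix of core-feature × substituent-feature
*cross-terms*. The package's central operation assigns **half of every
cross-term to its core feature and half to its substituent feature**, per
support vector, before any aggregation. Summing the halves feature-wise
yields per-feature contributions that add up to
\(\sum_i \alpha_i y_i K_{\mathrm{MMP}}(x_i, x)\) *exactly* (machine
precision; the tests require 1e-9 relative), and only features present in
the explained MMP can receive weight. The bias is reported separately: it
is a property of the hyperplane, not of any feature. The split ratio never
varies, so aggregation order cannot change per-feature values.

A degenerate case makes the structure visible: if all fingerprints share
one identical core, the product kernel collapses to the substituent
Tanimoto kernel — the kernel totals coincide with a substituent-only
Tanimoto model, while the half-split still routes half of each cross-term
to the (uninformative) core features, leaving the substituent features
with exactly half their plain-Tanimoto contributions. The tests pin this
factor-of-two relation.

Contributions are painted onto structures by dividing each feature's
contribution evenly over the atoms and bonds of its recorded environments
and accumulating where environments overlap. AND-channel features occur in
both substituents; their contribution is split evenly between the two
fragments first. Features without a back-map (abstract fingerprints) are
collected in an explicit remainder so the conservation identity — mapped
weights plus remainder equals the kernel sum — holds exactly. Colouring
uses warm tones for positive weight and blue for negative, normalised per
MMP by the largest absolute weight; warm-versus-red naming is cosmetic and
configurable.

## Kernel SHAP as the control

`shap_explain()` implements Kernel SHAP over the same decision function:
coalitions of universe bits, weighted by
\((N-1)/\binom{N}{z} z (N-z)\), with off-coalition bits filled in from
training fingerprints (marginal sampling) and the baseline \(\phi_0\)
equal to the mean training decision value. Coalitions are enumerated
exhaustively whenever \(2^N\) fits the sample budget, making the local
accuracy identity \(\phi_0 + \sum_i \phi_i = f(x)\) exact; otherwise
coalitions are sampled from the SHAP-kernel size distribution (default
budget 2048, at least \(N+2\)). The explained feature space defaults to
bits set in the instance or in a support vector, capped (instance bits
first, default 16) with a warning — full universes run to thousands of
bits and the regression cost grows with \(2^N\). The control exists to
exhibit a structural difference, and the comparison report quantifies it:
SHAP freely assigns weight to features *absent* from the explained MMP
(replacing absent features by marginal draws produces fingerprints that
correspond to no actual molecule), whereas the exact decomposition cannot
put weight on an absent feature by construction. Its absent-mass fraction
is identically zero.

## Synthetic study conditions

No external data is required anywhere. `generate_cliff_dataset()` builds
analog series on built-in drug-like scaffolds, each with one variable
position: one compound per series carries a designated cliff substituent
(default cyclopentyl) that raises pKi by `delta_strong = 2.5` log units;
all others draw only Gaussian jitter (`sigma = 0.15`) around a baseline of
6.0. The margin `delta_strong > 2 + 3*sigma` makes planted labels
near-deterministic while leaving enough jitter to exercise the
ambiguous-band filtering. The neutral substituent pool is deliberately
pairwise prefix-free at the attachment point (distinct first atom or
branching); otherwise the maximum-core rule would re-assign prefix-sharing
pairs to an extended core outside their planted series. With the default 8
series of 5 compounds the generator yields about 80 within-series MMPs
(plus a handful of legitimate cross-series pairs that are dropped later as
single-class series) — the problem size used by the recovery study in
`scripts/acceptance.R` (25 generator seeds, full series-wise LOO each, a
few minutes on one CPU).

What the fixture does *not* emulate: real potency noise structure,
correlated assay artefacts, multiple measurement protocols, tautomer and
stereochemistry subtleties, or ChEMBL-scale series-size distributions.
Passing the recovery study shows the machinery identifies a planted,
deterministic transformation under clean conditions; it does not certify
performance on real extracts, for which the CSV input path exists.

## Numerical choices and limitations

* Boundary deltas of exactly 1.0 or 2.0 log units are ambiguous (strict
  inequalities); boundary cases are vanishingly rare on real data.
* Replicate potency measurements are median-aggregated; compounds whose
  replicates span more than 1 log unit are discarded (configurable).
* Salt handling keeps the largest covalent fragment; fragmentation needs
  one connected structure.
* Empty-segment Tanimoto (0/0) is 0, and MMPs with an empty feature
  segment simply contribute nothing through that factor.
* MCC is 0 by convention when a denominator factor vanishes; AUC is `NA`
  for single-class pools.
* Only single cuts of acyclic single bonds are enumerated — no multi-cut
  cores, no transformation-rule extraction, no stereochemistry-aware
  deduplication beyond canonical SMILES.
* Kekulised bond orders from the canonicaliser feed the atom invariants;
  because every fragment is canonicalised before feature extraction,
  identical fragments always produce identical features.

## A worked abstract example

The package ships the two-fingerprint configuration used throughout the
documentation: a support vector with core features \{1,2,3\} and
substituent features \{2,3\}, and a test instance with core \{1,3\} and
substituents \{1,2,3\}.

```{r fig5}
fx <- fig5_fixture()
mmp_kernel(fx$support, fx$test)            # (2/3) * (2/3) = 4/9
frag_fc_mmp(fx$support, 1, fx$test, 1, 3)  # one cross-term: 1/9
explain(manual_ac_svm(list(fx$support), dual_coef = 1, b = 0), fx$test)
```

Four shared cross-terms of 1/9 each, half-split, leave 1/9 on each of the
two shared core features and each of the two shared substituent features;
the test-only substituent feature 1 is present but shares no overlap, so
its contribution is 0 — present features can receive zero weight, absent
features never receive any.
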