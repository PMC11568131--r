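---
title: "Methods: hierarchical GO prediction with composite losses and homology fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical GO prediction with composite losses and homology fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gofuse)
```

# The problem and the model

Predicting protein function means assigning Gene Ontology (GO) terms to
proteins. The label space is large, hierarchical (three DAGs — MFO, BPO,
CCO — under the true-path rule: annotating a term implies all its
ancestors), and extremely imbalanced: a few generic terms are carried by
most proteins while the informative ones are rare. `gofuse` implements a
hybrid predictor built from two complementary sources and is organised as
a classic R modelling package: one fitting function, `gonet()`, returns a
classed object with `predict`, `print`, `summary`, `plot`, `coef` and
`residuals` methods, and the surrounding functions prepare its inputs and
consume its outputs.

## Label preparation

Annotations are restricted to experimental evidence codes (IDA, IPI,
EXP, IGI, IMP, IEP, IC, TAS) and propagated to the aspect root over
is-a/part-of edges only; cross-aspect relationship edges in the OBO file
are dropped so propagation never leaves a sub-ontology. The prediction
vocabulary keeps the terms carried by at least `min_count` training
proteins (defaults: 50 for BPO, 10 for MFO and CCO, the usual choice for
GO benchmarks), ordered lexicographically so column indices are
reproducible.

Each term is weighted by its *information accretion*
$$IA(q) = \log_2 \frac{1 + |\{i : Pa(q) \subseteq T_i\}|}{1 + |\{i : q \in T_i\}|},$$
the information the term adds given its parents. Two conventions are
needed that the IA formula itself does not fix:

* **Multi-parent terms.** "Proteins with the parent terms of $q$" is read
  as proteins carrying *all* parents (set intersection). This is the
  conditional-probability reading — $IA$ is $-\log_2$ of the empirical
  probability of $q$ given its parents — and it guarantees $IA \ge 0$ on
  propagated data, because carrying $q$ implies carrying every parent.
  The union reading loses both properties.
* **Roots.** A root's parent count is defined as the number of annotated
  proteins of the aspect, so after propagation $IA(\text{root}) = 0$:
  the root carries no information.

## The network branch

Per protein the model consumes three fixed-length vectors — one per
extracted hidden layer of an embedding backend, mean-pooled over
residues. The architecture is three parallel ReLU MLP branches (one per
layer), concatenation, a combiner MLP, and a final affine layer with one
logit per vocabulary term. Width defaults (`branch_hidden = c(1024,
512)`, `combiner_hidden = 1024`, dropout 0.3, Adam with learning rate
1e-3, 100 epochs) suit full-scale embeddings of dimension ~2560; every
size is an argument, and the examples and tests use much smaller
networks matched to the synthetic data (dimension 32, hidden 48/64).

The training objective is a **multiplicative composite** of selectable
factors, evaluated from the raw logits:

* `ptf1` / `gof1`: IA-weighted *soft* F1 losses. Per protein (or per
  term), weighted precision and recall are computed from the sigmoid
  probabilities — not thresholded labels, which keeps the loss
  differentiable — then averaged over the dimension, and one F1 is
  formed from the two means (`aggregate = "macro"`). The alternative
  (per-unit F1, then the mean) is available as
  `aggregate = "mean-f1"` since the two orders are both defensible.
  The guard constant `eps = 1e-16` appears in every denominator,
  including the final $2PR/(P+R+\epsilon)$, which makes the empty case
  ($P = R = 0$) return loss 1 instead of NaN. A consequence worth
  knowing: a term with no positive labels and no predicted mass in the
  batch contributes precision = recall = 0 to the term-centric macro
  average, so the term-centric loss reaches 0 only when every term in
  the batch has at least one positive.
* `zlpr`: the zero-bounded log-sum-exp pairwise rank loss
  $\log(e^{-s_0} + \sum_{pos} e^{-s_i}) + \log(e^{s_0} + \sum_{neg} e^{s_j})$
  with $s_0 = 0$, averaged over proteins. It couples the labels —
  every positive logit is pushed above every negative one through the
  shared log-sum-exp — which is how label dependencies enter training.
  Both terms are evaluated with the log-sum-exp trick, so logits up to
  $|s| = 500$ are safe.
* `bce`: standard binary cross-entropy, included for ablations.

The default set `zlpr * ptf1 * gof1` multiplies the three; any
non-empty subset may be configured, and the product's gradient is the
exact product rule with no stop-gradients on any factor. Natural
logarithms are used everywhere except IA (base 2, so IA is in bits).
`loss_gradient()` exposes the analytic gradient; the test suite checks
it against central finite differences for all 15 component subsets.

Because the zlpr mean-per-protein is taken before the multiplication,
the composite is a product of three batch-level scalars; the
alternative (multiplying per-protein) is not defined for the term-
centric factor and is not offered.

Training is full-precision base R matrix algebra with explicit
backpropagation and Adam; given a `seed` (controlling initialisation,
shuffling and dropout masks) a fit is bit-reproducible on a single
thread.

## Hierarchical post-processing

Raw sigmoid scores ignore the hierarchy. `hierarchical_postprocess()`
walks the DAG children-before-parents and raises each parent to the
maximum of its children, so the output satisfies parent ≥ child on
every edge; one pass in reverse-topological order equals iterating the
constraint to a fixpoint (checked against a brute-force fixpoint oracle
in the tests). Scores are only ever raised, and the operator is
idempotent. Ontology terms outside the vocabulary participate as
carriers (initialised to $-\infty$ so they inject nothing): a
high-scoring term raises its in-vocabulary ancestors even when an
intermediate term was filtered out of the vocabulary.

## The homology branch

Given a tabular alignment file (qseqid, sseqid, bitscore, nident, qlen,
slen — request exactly these six columns from DIAMOND or BLAST+ with
`--outfmt 6 qseqid sseqid bitscore nident qlen slen`), each hit votes
for its subject's propagated terms with weight
$bitscore \times ID$, where $ID = nident / \max(qlen, slen)$; the score
of a term is the weighted fraction of votes it receives. Hits whose
subject has no annotation in the vocabulary's aspect are dropped before
counting; no further cap or E-value cutoff is applied (the aligner's
own reporting limits govern), and self-hits are kept unless
`exclude_self = TRUE` (used when scoring training proteins against
their own template set). Scores are scale-invariant in the bitscores
and automatically monotone up the DAG when subject annotations are
propagated.

## Fusion

The two branches are combined per query as
$S = w S_{net} + (1-w) S_{align}$ with
$w = \alpha + (1-\alpha) e^{-k \, \overline{ID}}$, where $\overline{ID}$
is the mean of the query's top `n_top = 5` hit identities. Defaults
$\alpha = 0.33$ and $k = 3$ follow the published calibration of this
gate; `tune_fusion()` re-tunes them on a validation split by grid
search if desired. A query with no hits has $\overline{ID} = 0$, hence
$w = 1$: pure network output. Terms scored by only one source enter
with 0 from the other, and the fused score is always between the two
sources.

## Evaluation

The metrics are the CAFA-style IA-weighted definitions, computed over
the threshold sweep $t = 0.01, 0.02, \ldots, 1.00$:

* **wFmax** — weighted precision is averaged over proteins with at
  least one prediction at $t$ (covered proteins); weighted recall over
  *all* benchmark proteins; $F(t) = 2PR/(P+R)$ and the maximum over the
  sweep is reported with its smallest argmax.
* **Smin** — $\min_t \sqrt{ru(t)^2 + mi(t)^2}$ with remaining
  uncertainty and misinformation as mean IA masses of missed and
  spurious terms.
* **AUWPR** — trapezoidal area of the (recall, precision) points;
  zero-coverage thresholds are dropped and the curve is anchored at
  recall 0 with the precision of the highest retained threshold (no
  standard anchoring exists, so the rule is fixed here explicitly).

Aspect roots are excluded from truth and predictions: they are
trivially predictable and carry IA 0. Truth matrices are checked for
propagation closure when an ontology is supplied. The exhaustive-oracle
tests generate scores on the 0.01 grid, where the sweep provably
attains the same extrema as scanning every distinct score value.

The naive baseline assigns every query the training frequency of each
term — the floor any useful predictor must clear.

## Benchmark construction

`build_time_split()` reproduces the CAFA-style chronological protocol
with half-open windows $(t_0, t_1]$, $(t_1, t_2]$: an annotation dated
exactly $t_0$ belongs to training. A validation/test protein is
*no-knowledge* if it had no experimental annotation in any aspect at or
before its window start and *limited-knowledge* if it had experimental
annotations only in other aspects by then. Knowledge status for the
test window is assessed at that window's start ($t_1$) — the natural
reading when windows are processed independently. By the
first-annotation rule a protein cannot qualify for both validation and
test in the same aspect; this is asserted, not silently repaired.

# The synthetic world

`make_world()` generates everything the pipeline consumes, with a fixed
seed and no downloads: a layered random DAG per aspect (30 terms each by
default, single root, ≤ 2 parents per term), 120 proteins in 5 clusters,
and annotation dates in three bands around 2022-11-30 / 2023-03-31 /
2024-02-29 (70% train, 15%/15% held out; half the held-out proteins get
one aspect annotated early, creating limited-knowledge cases; 10% IEA
decoy records exercise the evidence filter). Each cluster draws a
characteristic set of leaf terms per aspect; each protein copies its
cluster's leaves with a 5% per-leaf flip probability, and its sequence
is sampled from a cluster-specific residue bias (three signature amino
acids with elevated weight). Hit tables give each held-out query
high-identity hits against same-cluster templates and low-identity
cross-cluster hits.

The generator is built so that *both* information channels carry the
cluster signal — embedding similarity for the network, alignment
identity for the transfer — mirroring the premise that the two branches
are complementary. The synthetic embedding backend maps sequences to
k-mer-composition projections under fixed random matrices (layer 1 sees
single-residue composition, layers 2 and 3 di- and tri-peptide
context), so cluster-biased sequences yield cluster-separable
embeddings; it is bit-deterministic and requires no model download. A
real protein language model can be supplied as a backend function
returning three residue-level matrices per sequence.

What the synthetic world does **not** emulate: realistic sequence
evolution (no indels, no phylogeny — identities are drawn, not
aligned), the heavy-tailed term-frequency distribution of real GOA
(cluster profiles make term frequencies roughly uniform within a band),
annotation incompleteness bias, and full-scale dimensions (embedding
dimension 2560, vocabularies of thousands of terms). Passing the test
suite therefore demonstrates correctness of the machinery and
recoverability of planted structure at desk scale — not real-data
accuracy.

# Problem sizes and numerical choices

The test suite and the acceptance script run the end-to-end experiment
on the default world with embedding dimension 32, hidden sizes 48/64,
120 epochs of Adam at batch size 32 and dropout 0.1 on the MFO aspect
(~90 training and ~30 held-out proteins, 30-term vocabulary at
`min_count = 2`) — a configuration chosen to train in seconds on one
CPU while leaving clear headroom above the planted noise floor.
Further numerical conventions, in one place: `eps = 1e-16` in every F1
denominator; log-sum-exp for both ZLPR terms; He initialisation scaled
by fan-in; inverted dropout; the homology vote fraction clamped to
[0, 1] against floating-point round-off; prediction files serialised
with 3 decimals (internal computation at full precision); ties in the
threshold sweep resolved towards the smallest threshold.

# Known limitations

* The backprop engine is single-threaded base R; it is meant for
  vocabulary sizes up to a few thousand terms and datasets that fit in
  memory, not for GPU-scale training.
* The `"plm"` embedding backend is an interface only; using a real
  protein language model requires the user to wrap it as a backend
  function.
* Bootstrap confidence intervals and significance tests for metric
  differences are out of scope; the evaluation layer reports point
  estimates and full curves.
* `compute_ia()` estimates IA from the supplied annotation table alone;
  with very small training sets the counts (and hence the weights) are
  noisy.
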