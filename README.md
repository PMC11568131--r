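# gofuse

Hierarchical multi-label protein function prediction over the Gene
Ontology (GO), for computational biologists who want a self-contained,
fully testable implementation of the modern hybrid recipe: a neural
network trained on protein embeddings, homology-based annotation
transfer from alignment hits, and an identity-gated fusion of the two —
evaluated with CAFA-style weighted metrics on chronologically split
benchmarks.

## The method

**Labels and weights.** Annotations are filtered to experimental
evidence codes (IDA, IPI, EXP, IGI, IMP, IEP, IC, TAS) and propagated to
the root of each GO aspect along is-a/part-of edges (the true-path
rule). Each term *q* is weighted by its information accretion

    IA(q) = log2( (1 + |{i : Pa(q) ⊆ T_i}|) / (1 + |{i : q ∈ T_i}|) )

— the bits of information *q* adds given its parents, estimated from
carrier counts over the (propagated) training proteins.

**Network branch.** Three mean-pooled embedding-layer vectors per
protein feed three parallel MLP branches, a combiner MLP, and an affine
layer emitting one logit per vocabulary term. Training minimises a
multiplicative composite loss

    L = L_ZLPR · L_F1,protein · L_F1,term

where the two F1 factors are IA-weighted soft precision/recall losses
computed over the protein and the term dimension respectively, and the
ZLPR factor is the zero-bounded log-sum-exp pairwise rank loss

    L_zlpr = log(1 + Σ_{i∈pos} e^{−s_i}) + log(1 + Σ_{j∈neg} e^{s_j}),

which drives every positive logit above 0, every negative logit below
0, and positives above negatives jointly. Any non-empty subset of
{ZLPR, BCE, PTF1, GOF1} can be multiplied instead, for loss ablations.
At inference, scores are made hierarchically consistent: each parent's
score is raised to the maximum of its children's.

**Homology branch.** From a DIAMOND/BLAST tabular hit file (qseqid,
sseqid, bitscore, nident, qlen, slen), each query's score for term *q*
is the bitscore·identity-weighted fraction of hits whose (annotated)
subject carries *q*, with identity `nident / max(qlen, slen)`.

**Fusion.** The two branches are mixed per query,
`S = w·S_net + (1−w)·S_align`, with

    w = α + (1 − α) · exp(−k · ID̄),   α = 0.33, k = 3,

where `ID̄` is the mean of the query's top-5 hit identities: queries
without close homologs rely on the network (w → 1), queries with close
templates lean on transfer (w → α).

**Evaluation.** IA-weighted Fmax (wFmax), minimum semantic distance
(Smin) and the area under the weighted precision–recall curve (AUWPR)
over a 0.01-step threshold sweep, plus a naive term-frequency baseline
and a chronological train/validation/test splitter with
no-knowledge/limited-knowledge labels.

A deterministic synthetic generator (`make_world()`) produces toy
ontologies, cluster-structured annotated proteins, biased sequences and
hit tables, so the entire pipeline runs and is tested without any
download; a real protein language model can be plugged into
`embed_sequences()` as a backend function.

## Worked example

```r
library(gofuse)

world <- make_world(seed = 42)              # 3 aspects x 30 terms, 120 proteins
ont   <- world$ontology
ann   <- filter_experimental(world$annotations)
split <- build_time_split(ann, "2022-11-30", "2023-03-31", "2024-02-29", "MFO")
print(split)
#> Chronological MFO split: 91 train, 13 validation, 16 test
#>              limited-knowledge no-knowledge
#>   test                       6           10
#>   validation                 2           11

prop  <- propagate_annotations(ann[ann$protein %in% split$train &
                                   ann$aspect == "MFO", ], ont)
vocab <- select_vocabulary(prop, "MFO", min_count = 2)
ia    <- compute_ia(prop, ont)

emb <- embed_sequences(world$sequences, dim = 32)
fit <- gonet(emb$x[split$train, ], label_matrix(prop, vocab, split$train),
             ia = ia[vocab$terms], vocabulary = vocab,
             branch_hidden = 48, combiner_hidden = 64,
             epochs = 120, batch_size = 32, dropout = 0.1, seed = 7)
print(fit)
#> GO-term neural predictor (gonet)
#>   input: 3 layers x D = 32; vocabulary: 30 terms
#>   branches D -> 48; combiner -> 64 -> 30 logits
#>   loss: zlpr x ptf1 x gof1 (macro F1); 120 epochs, lr 0.001, dropout 0.1, seed 7
#>   final training loss: 0.105132

heldout <- c(split$validation, split$test)
truth <- label_matrix(propagate_annotations(
  ann[ann$protein %in% heldout & ann$aspect == "MFO", ], ont), vocab, heldout)

s_dnn <- hierarchical_postprocess(predict(fit, emb$x[heldout, ]), vocab, ont)
hits  <- make_hits(world, heldout, seed = 99)
s_knn <- hierarchical_postprocess(
  knn_scores(hits, prop, vocab, queries = heldout), vocab, ont)
fused <- fuse_scores(s_dnn, s_knn,
                     fusion_weight(query_mean_identity(hits, heldout)))

evaluate_predictions(truth, fused[heldout, vocab$terms], ia,
                     roots = intersect(ont$roots, vocab$terms),
                     ontology = ont, aspect = "MFO")
#> GO prediction evaluation [MFO] (29 proteins)
#>   wFmax = 0.9092 at t = 0.31
#>   Smin  = 0.8188 at t = 0.31
#>   AUWPR = 0.9146
```

The printed numbers say: on the 29 held-out proteins the fused
predictor recovers 91% of the IA-weighted annotation mass at its best
threshold (0.31), leaves 0.82 bits of combined missing/spurious
information per protein at that threshold, and traces a
precision–recall curve with 0.91 of the unit square beneath it.

## Command line

The same pipeline is available as an executable:

```sh
gofuse simulate --out world --seed 1
gofuse split    --annotations world/annotations.tsv --aspect MFO --out split.tsv
gofuse embed    --fasta world/sequences.fasta --dim 32 --out emb.tsv
gofuse train    --embeddings emb.tsv --obo world/ontology.obo \
                --annotations world/annotations.tsv --aspect MFO --out model.rds
gofuse predict  --model model.rds --embeddings emb.tsv --obo world/ontology.obo --out dnn.tsv
gofuse knn      --hits world/hits.tsv --obo world/ontology.obo \
                --annotations world/annotations.tsv --aspect MFO --out knn.tsv
gofuse fuse     --dnn dnn.tsv --align knn.tsv --hits world/hits.tsv --out fused.tsv
gofuse evaluate --preds fused.tsv --obo world/ontology.obo \
                --truth world/annotations.tsv --aspect MFO --out report.tsv
```

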