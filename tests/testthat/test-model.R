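# Embedding backend, network fitting and methods, hierarchical
# post-processing, checkpointing.

test_that("the synthetic embedder is deterministic and pure", {
  seqs <- c(A = "MKTAYIAKQR", B = "MKTAYIAKQR", C = "GGGSSS")
  e1 <- embed_sequences(seqs, dim = 8)
  e2 <- embed_sequences(seqs, dim = 8)
  expect_identical(e1$x, e2$x)
  expect_identical(e1$x["A", ], e1$x["B", ])     # identical sequences
  expect_false(all(e1$x["A", ] == e1$x["C", ]))
  expect_equal(dim(e1$x), c(3L, 24L))
})

test_that("a length-1 sequence pools to its own residue vector", {
  counting_backend <- function(sequence) {
    L <- nchar(sequence)
    lapply(1:3, function(l) matrix(l * seq_len(L), L, 4))
  }
  e <- embed_sequences(c(P = "M"), backend = counting_backend)
  expect_equal(unname(e$x[1, ]), rep(1:3, each = 4))
})

test_that("embedding errors are informative", {
  expect_error(embed_sequences(c(A = "")), "empty sequence")
  expect_error(embed_sequences(c(A = "MK"), backend = "plm"),
               "'plm' is not available")
  expect_error(embed_sequences("MK"), "named")
})

test_that("network construction is seeded and shape-correct", {
  set.seed(1)
  X <- matrix(rnorm(5 * 12), 5, 12)  # I = 5, D = 4
  y <- matrix(rbinom(5 * 3, 1, 0.5), 5, 3)
  args <- list(branch_hidden = 6, combiner_hidden = 7, epochs = 0,
               dropout = 0, seed = 99)
  f1 <- do.call(gonet, c(list(X, y), args))
  f2 <- do.call(gonet, c(list(X, y), args))
  expect_identical(f1$params, f2$params)
  scores <- predict(f1, X)
  expect_equal(dim(scores), c(5L, 3L))
  expect_true(all(is.finite(scores)))
  expect_true(all(scores > 0 & scores < 1))
  expect_identical(predict(f1, X), scores)  # purity
  expect_error(predict(f1, X[, 1:6]), "expects")
  expect_error(gonet(X, y[, 0]), "Q = 0")
})

test_that("a zero learning rate leaves the parameters unchanged", {
  set.seed(2)
  X <- matrix(rnorm(6 * 9), 6, 9)
  y <- matrix(rbinom(18, 1, 0.5), 6, 3)
  init <- gonet(X, y, branch_hidden = 4, combiner_hidden = 4, epochs = 0,
                dropout = 0, seed = 5)
  frozen <- gonet(X, y, branch_hidden = 4, combiner_hidden = 4, epochs = 5,
                  lr = 0, dropout = 0, seed = 5)
  expect_identical(frozen$params, init$params)
  expect_equal(length(frozen$history), 5L)
})

test_that("training decreases the loss on separable synthetic data", {
  w <- make_world(seed = 3, n_proteins = 60, n_terms_per_aspect = 15)
  ann <- filter_experimental(w$annotations)
  ont <- w$ontology
  prop <- propagate_annotations(ann[ann$aspect == "MFO", ], ont)
  vocab <- select_vocabulary(prop, "MFO", 2)
  emb <- embed_sequences(w$sequences, dim = 16)
  y <- label_matrix(prop, vocab, names(w$sequences))
  ia <- compute_ia(prop, ont)[vocab$terms]
  fit <- gonet(emb$x, y, ia = ia, vocabulary = vocab, branch_hidden = 24,
               combiner_hidden = 32, epochs = 60, batch_size = 1000,
               dropout = 0, seed = 4)
  d <- diff(fit$history)
  expect_gte(mean(d <= 0), 0.9)   # non-increasing in >= 90% of epochs
  expect_lt(fit$history[60], fit$history[1])
  # the loss components are switchable without changing the interface
  fit_bce <- gonet(emb$x, y, ia = ia, loss = "bce", branch_hidden = 8,
                   combiner_hidden = 8, epochs = 3, dropout = 0, seed = 4)
  expect_equal(fit_bce$config$loss, "bce")
  expect_length(fit_bce$history, 3L)
})

test_that("training with the same seed is bit-reproducible", {
  set.seed(77)
  X <- matrix(rnorm(8 * 6), 8, 6)
  y <- matrix(rbinom(8 * 4, 1, 0.4), 8, 4)
  f1 <- gonet(X, y, branch_hidden = 5, combiner_hidden = 5, epochs = 10,
              batch_size = 4, dropout = 0.2, seed = 123)
  f2 <- gonet(X, y, branch_hidden = 5, combiner_hidden = 5, epochs = 10,
              batch_size = 4, dropout = 0.2, seed = 123)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
})

test_that("model methods (print, summary, plot, coef, residuals) work", {
  set.seed(9)
  X <- matrix(rnorm(4 * 6), 4, 6, dimnames = list(paste0("P", 1:4), NULL))
  y <- matrix(rbinom(8, 1, 0.5), 4, 2,
              dimnames = list(paste0("P", 1:4), c("GO:1", "GO:2")))
  fit <- gonet(X, y, branch_hidden = 3, combiner_hidden = 3, epochs = 2,
               dropout = 0, seed = 1)
  expect_output(print(fit), "gonet")
  expect_output(print(summary(fit)), "parameters")
  expect_named(coef(fit), c("branches", "combiner", "out"))
  r <- residuals(fit)
  expect_equal(dim(r), dim(y))
  expect_true(all(abs(r) < 1))
  pdf(NULL); plot(fit); dev.off()
})

test_that("hierarchical post-processing enforces parent >= max(children)", {
  ont <- parse_obo(chain_obo())
  vocab_terms <- unname(chain_terms[c("leaf", "mid", "root")])
  sc <- matrix(c(0.9, 0.2, 0.5), 1, dimnames = list("P1", vocab_terms))
  out <- hierarchical_postprocess(sc, vocab_terms, ont)
  expect_equal(unname(out[1, ]), c(0.9, 0.9, 0.9))

  consistent <- matrix(c(0.3, 0.5, 0.8), 1, dimnames = list("P1", vocab_terms))
  expect_equal(hierarchical_postprocess(consistent, vocab_terms, ont),
               consistent)

  dia <- parse_obo(diamond_obo())
  terms <- c("GO:0000013", "GO:0000011", "GO:0000012", "GO:0000010")
  sc2 <- matrix(c(0.7, 0.1, 0.9, 0.05), 1, dimnames = list("P1", terms))
  out2 <- hierarchical_postprocess(sc2, terms, dia)
  expect_equal(unname(out2[1, ]), c(0.7, 0.7, 0.9, 0.9))
  expect_equal(out2, oracle_postprocess(sc2, terms, dia))

  expect_error(hierarchical_postprocess(sc, c(vocab_terms[1:2], "GO:77"),
                                        ont), "missing from ontology")
})

test_that("post-processing is monotone and idempotent on random fixtures", {
  for (seed in 1:20) {
    ont <- make_ontology(n_terms_per_aspect = sample(6:15, 1),
                         max_parents = 3, seed = seed, aspects = "BPO")
    set.seed(seed + 500)
    sc <- matrix(runif(5 * length(ont$terms)), 5,
                 dimnames = list(paste0("P", 1:5), ont$terms))
    out <- hierarchical_postprocess(sc, ont$terms, ont)
    expect_true(all(out >= sc))                       # never lowers
    expect_equal(hierarchical_postprocess(out, ont$terms, ont), out)
    for (i in seq_len(nrow(ont$edges)))               # parent >= child
      expect_true(all(out[, ont$edges$parent[i]] >=
                        out[, ont$edges$child[i]]))
    expect_equal(out, oracle_postprocess(sc, ont$terms, ont))
  }
})

test_that("out-of-vocabulary terms carry scores up to distant ancestors", {
  ont <- parse_obo(chain_obo())
  vocab_terms <- unname(chain_terms[c("leaf", "root")])  # mid not in vocab
  sc <- matrix(c(0.8, 0.1), 1, dimnames = list("P1", vocab_terms))
  out <- hierarchical_postprocess(sc, vocab_terms, ont)
  expect_equal(unname(out[1, ]), c(0.8, 0.8))
})

test_that("checkpoints round-trip and verify the vocabulary digest", {
  set.seed(13)
  X <- matrix(rnorm(4 * 6), 4, 6)
  y <- matrix(rbinom(8, 1, 0.5), 4, 2)
  vocab <- structure(list(aspect = "MFO", terms = c("GO:0000001", "GO:0000002"),
                          index = c("GO:0000001" = 1L, "GO:0000002" = 2L),
                          min_count = 1L), class = "go_vocabulary")
  fit <- gonet(X, y, vocabulary = vocab, branch_hidden = 3,
               combiner_hidden = 3, epochs = 1, dropout = 0, seed = 1)
  path <- tempfile(fileext = ".rds")
  save_gonet(fit, path)
  back <- load_gonet(path)
  expect_identical(back$params, fit$params)
  expect_identical(predict(back, X), predict(fit, X))
  corrupt <- readRDS(path)
  corrupt$vocabulary$terms[1] <- "GO:0009999"
  saveRDS(corrupt, path)
  expect_error(load_gonet(path), "digest mismatch")
})
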