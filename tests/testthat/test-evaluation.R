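# CAFA-style weighted metrics and the naive frequency baseline.

named_mat <- function(v, prot, terms)
  matrix(v, length(prot), length(terms), byrow = TRUE,
         dimnames = list(prot, terms))

test_that("weighted precision/recall at a threshold match hand evaluation", {
  terms <- c("A", "B", "C")
  ia <- c(A = 2, B = 1, C = 1)
  truth <- named_mat(c(1, 1, 0), "P1", terms)
  scores <- named_mat(c(0.9, 0.1, 0.8), "P1", terms)  # predicts {A, C}
  pt <- weighted_pr_at_threshold(truth, scores, ia, t = 0.5)
  expect_equal(pt$wpr, 2 / 3)
  expect_equal(pt$wrc, 2 / 3)
  expect_equal(pt$n_covered, 1L)

  # perfect prediction at any threshold
  perfect <- weighted_pr_at_threshold(truth, truth, ia, t = 0.7)
  expect_equal(perfect$wpr, 1)
  expect_equal(perfect$wrc, 1)

  # empty predictions: no coverage, zero precision and recall
  none <- weighted_pr_at_threshold(truth, scores * 0, ia, t = 0.5)
  expect_equal(none$wpr, 0)
  expect_equal(none$wrc, 0)
  expect_equal(none$n_covered, 0L)
})

test_that("the propagation precondition on truth is enforced", {
  ont <- parse_obo(chain_obo())
  terms <- unname(chain_terms)
  ia <- setNames(c(1, 1, 0), terms)
  bad_truth <- named_mat(c(1, 0, 0), "P1", terms)  # leaf without parents
  scores <- named_mat(c(0.5, 0.5, 0.5), "P1", terms)
  expect_error(wfmax(bad_truth, scores, ia, ontology = ont),
               "not propagated")
  good <- named_mat(c(1, 1, 1), "P1", terms)
  expect_silent(wfmax(good, scores, ia, ontology = ont))
})

test_that("wfmax sweeps thresholds and reports the smallest argmax", {
  terms <- c("A", "B")
  ia <- c(A = 1, B = 1)
  truth <- named_mat(c(1, 0), "P1", terms)
  scores <- named_mat(c(0.9, 0.3), "P1", terms)
  res <- wfmax(truth, scores, ia)
  expect_equal(res$value, 1)
  expect_equal(res$threshold, 0.31)  # first threshold above 0.3

  perfect <- wfmax(truth, truth, ia)
  expect_equal(perfect$value, 1)
  expect_equal(perfect$threshold, 0.01)
  expect_error(wfmax(truth[0, , drop = FALSE], scores, ia), "empty")
})

test_that("smin matches closed forms", {
  terms <- c("A", "B", "C")
  ia <- c(A = 2, B = 1, C = 0.5)
  truth <- rbind(P1 = c(1, 1, 0), P2 = c(1, 0, 1))
  colnames(truth) <- terms
  expect_equal(smin(truth, truth, ia)$value, 0)
  # predicting nothing leaves only remaining uncertainty
  nothing <- truth * 0
  expect_equal(smin(truth, nothing, ia)$value,
               mean(c(2 + 1, 2 + 0.5)))
})

test_that("auwpr handles perfect and degenerate curves", {
  terms <- c("A", "B")
  ia <- c(A = 1, B = 1)
  truth <- named_mat(c(1, 0), "P1", terms)
  expect_equal(auwpr(truth, truth, ia), 1)
  # all scores equal: single point (wrc, wpr); anchored area = wpr * wrc
  flat <- named_mat(c(0.5, 0.5), "P1", terms)
  expect_equal(auwpr(truth, flat, ia), 0.5 * 1)
})

test_that("sweep metrics equal the brute-force oracles on random fixtures", {
  for (seed in 1:5) {
    truth <- (random_grid_scores(10, 15, seed) > 0.5) * 1
    scores <- random_grid_scores(10, 15, seed + 50)
    set.seed(seed)
    ia <- setNames(runif(15, 0.2, 3), colnames(scores))
    expect_equal(wfmax(truth, scores, ia)$value,
                 unname(oracle_wfmax(truth, scores, ia)), tolerance = 1e-12)
    expect_equal(smin(truth, scores, ia)$value,
                 unname(oracle_smin(truth, scores, ia)), tolerance = 1e-12)
    expect_equal(auwpr(truth, scores, ia),
                 oracle_auwpr(truth, scores, ia), tolerance = 1e-12)
    pt <- weighted_pr_at_threshold(truth, scores, ia, 0.37)
    opt <- oracle_point(truth, scores, ia, 0.37)
    expect_equal(pt$wpr, unname(opt["wpr"]), tolerance = 1e-12)
    expect_equal(pt$wrc, unname(opt["wrc"]), tolerance = 1e-12)
  }
})

test_that("metrics are invariant to protein order and wrc is monotone", {
  truth <- (random_grid_scores(8, 10, 3) > 0.4) * 1
  scores <- random_grid_scores(8, 10, 9)
  ia <- setNames(rep(1, 10), colnames(scores))
  perm <- sample(nrow(truth))
  expect_equal(wfmax(truth, scores, ia),
               wfmax(truth[perm, ], scores[perm, ], ia))
  expect_equal(smin(truth, scores, ia), smin(truth[perm, ], scores[perm, ], ia))
  ev <- evaluate_predictions(truth, scores, ia)
  expect_true(all(diff(ev$curve$wrc) <= 1e-12))
  expect_true(all(diff(ev$curve$n_covered) <= 0))
})

test_that("aspect roots are excluded from the evaluation", {
  terms <- c("root", "leaf")
  ia <- c(root = 0, leaf = 2)
  truth <- named_mat(c(1, 1), "P1", terms)
  scores <- named_mat(c(1, 0.01), "P1", terms)
  with_root <- wfmax(truth, scores, ia)
  without <- wfmax(truth, scores, ia, roots = "root")
  expect_equal(without$value, 1)       # only the leaf remains
  expect_equal(with_root$value, 1)     # root has IA 0 anyway here
  ev <- evaluate_predictions(truth, scores, ia, roots = "root")
  expect_equal(ev$wfmax, 1)
})

test_that("naive_scores assigns training term frequencies to every query", {
  ont <- parse_obo(chain_obo())
  prot <- sprintf("P%03d", 1:100)
  ann <- rbind(
    data.frame(protein = prot, term = chain_terms[["root"]]),
    data.frame(protein = prot[1:30], term = chain_terms[["leaf"]]))
  prop <- propagate_annotations(ann, ont)
  vocab <- select_vocabulary(prop, "MFO", 1)
  s <- naive_scores(prop, vocab, queries = c("Qx", "Qy"))
  expect_equal(unname(s["Qx", chain_terms[["leaf"]]]), 0.30)
  expect_equal(unname(s["Qy", chain_terms[["root"]]]), 1.0)
  expect_equal(s["Qx", ], s["Qy", ])
  empty <- prop[0, ]
  expect_error(naive_scores(empty, vocab, "Qx"), "empty training set")
})

test_that("evaluation reports and prediction files round-trip", {
  truth <- (random_grid_scores(5, 6, 2) > 0.5) * 1
  scores <- random_grid_scores(5, 6, 4)
  ia <- setNames(rep(1, 6), colnames(scores))
  ev <- evaluate_predictions(truth, scores, ia, aspect = "MFO")
  path <- tempfile(fileext = ".tsv")
  write_report(ev, path)
  rep_ <- read.delim(path)
  expect_equal(rep_$value[rep_$metric == "wfmax"], ev$wfmax)
  expect_true(file.exists(paste0(sub("\\.tsv$", "", path), "_curve.tsv")))

  ppath <- tempfile()
  write_predictions(scores, ppath)
  back <- read_predictions(ppath, rownames(scores), colnames(scores))
  expect_equal(back, round(scores, 3), ignore_attr = FALSE)
})
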