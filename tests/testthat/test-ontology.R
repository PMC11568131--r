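# OBO parsing, ancestor queries, true-path propagation, information
# accretion and vocabulary selection.

test_that("parse_obo reads the chain fixture and applies the stanza rules", {
  ont <- parse_obo(chain_obo())
  expect_s3_class(ont, "go_ontology")
  expect_setequal(ont$terms, unname(chain_terms))
  expect_equal(nrow(ont$edges), 2L)
  expect_setequal(ont$edges$relation, c("is_a", "part_of"))
  expect_equal(ont$roots, chain_terms[["root"]])

  # obsolete stanza is skipped entirely
  ont2 <- parse_obo(chain_obo(extra = c(
    "[Term]", "id: GO:0000009", "name: gone",
    "namespace: molecular_function", "is_obsolete: true", "")))
  expect_equal(length(ont2$terms), 3L)

  # alt_id resolves to the canonical id
  ont3 <- parse_obo(chain_obo(extra = c(
    "[Term]", "id: GO:0000004", "name: other leaf",
    "namespace: molecular_function", "alt_id: GO:0099999",
    "is_a: GO:0000002", "")))
  expect_equal(go_ancestors(ont3, "GO:0099999"),
               go_ancestors(ont3, "GO:0000004"))
})

test_that("parse_obo rejects malformed input with informative errors", {
  bad <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "name: nameless",
               "namespace: molecular_function"), bad)
  expect_error(parse_obo(bad), "missing id")

  dangling <- chain_obo(extra = c(
    "[Term]", "id: GO:0000005", "name: orphan child",
    "namespace: molecular_function", "is_a: GO:0777777", ""))
  expect_error(parse_obo(dangling), "GO:0777777")
})

test_that("cross-aspect relationship edges are dropped", {
  mixed <- chain_obo(extra = c(
    "[Term]", "id: GO:0000020", "name: cc root",
    "namespace: cellular_component", "",
    "[Term]", "id: GO:0000021", "name: cc leaf",
    "namespace: cellular_component", "is_a: GO:0000020",
    "relationship: part_of GO:0000003", ""))
  ont <- parse_obo(mixed)
  expect_false(chain_terms[["root"]] %in% go_ancestors(ont, "GO:0000021"))
  expect_equal(go_ancestors(ont, "GO:0000021"), "GO:0000020")
})

test_that("go_ancestors matches reachability on chain and diamond", {
  ont <- parse_obo(chain_obo())
  expect_setequal(go_ancestors(ont, chain_terms[["leaf"]]),
                  chain_terms[c("mid", "root")])
  expect_equal(go_ancestors(ont, chain_terms[["root"]]), character())
  expect_error(go_ancestors(ont, "GO:1234567"), "unknown")

  dia <- parse_obo(diamond_obo())
  anc <- go_ancestors(dia, "GO:0000013")
  expect_setequal(anc, c("GO:0000011", "GO:0000012", "GO:0000010"))
  expect_equal(anc, unique(anc))  # grandparent counted once
  expect_setequal(anc, oracle_ancestors(dia, "GO:0000013"))
})

test_that("propagate_annotations closes annotation sets upward", {
  ont <- parse_obo(chain_obo())
  leaf_only <- data.frame(protein = "P1", term = chain_terms[["leaf"]])
  prop <- propagate_annotations(leaf_only, ont)
  expect_setequal(prop$term, unname(chain_terms))

  root_only <- propagate_annotations(
    data.frame(protein = "P1", term = chain_terms[["root"]]), ont)
  expect_equal(root_only$term, chain_terms[["root"]])

  two <- propagate_annotations(
    data.frame(protein = "P1", term = chain_terms[c("leaf", "mid")]), ont)
  expect_equal(nrow(two), 3L)

  expect_error(
    propagate_annotations(data.frame(protein = "P9", term = "GO:9999999"),
                          ont),
    "P9.*GO:9999999")
})

test_that("propagation is idempotent and ancestor-closed on random DAGs", {
  for (seed in 1:10) {
    ont <- make_ontology(n_terms_per_aspect = 15, max_parents = 3,
                         seed = seed, aspects = "MFO")
    ann <- random_annotation_fixture(ont, n_proteins = 8, seed = seed)
    prop <- propagate_annotations(ann, ont)
    prop2 <- propagate_annotations(prop, ont)
    expect_equal(prop2, prop)
    for (s in split(prop$term, prop$protein)) {
      for (t in s) expect_true(all(go_ancestors(ont, t) %in% s))
    }
  }
})

test_that("compute_ia reproduces hand-evaluated carrier ratios", {
  # 10 proteins; parent P with 7 carriers, child q with 3 of them
  obo <- chain_obo()
  ont <- parse_obo(obo)
  prot <- sprintf("P%02d", 1:10)
  ann <- rbind(
    data.frame(protein = prot, term = chain_terms[["root"]]),
    data.frame(protein = prot[1:7], term = chain_terms[["mid"]]),
    data.frame(protein = prot[1:3], term = chain_terms[["leaf"]]))
  prop <- propagate_annotations(ann, ont)
  ia <- compute_ia(prop, ont)
  expect_equal(unname(ia[chain_terms[["leaf"]]]), log2(8 / 4))  # = 1.0
  expect_equal(unname(ia[chain_terms[["leaf"]]]), 1.0)
  expect_equal(unname(ia[chain_terms[["root"]]]), 0)
  # identical carrier set as the sole parent -> IA 0
  ann2 <- data.frame(protein = prot[1:5], term = chain_terms[["leaf"]])
  ia2 <- compute_ia(propagate_annotations(ann2, ont), ont)
  expect_equal(unname(ia2[chain_terms[["leaf"]]]), 0)
  expect_equal(unname(ia2[chain_terms[["mid"]]]), 0)
})

test_that("compute_ia refuses unpropagated annotations", {
  ont <- parse_obo(chain_obo())
  raw <- data.frame(protein = "P1", term = chain_terms[["leaf"]],
                    aspect = "MFO")
  expect_error(compute_ia(raw, ont), "propagate")
})

test_that("compute_ia equals brute-force carrier enumeration on random DAGs", {
  for (seed in 1:20) {
    ont <- make_ontology(n_terms_per_aspect = sample(5:20, 1), max_parents = 3,
                         seed = seed, aspects = "MFO")
    ann <- random_annotation_fixture(ont, n_proteins = 10, seed = seed + 100)
    prop <- propagate_annotations(ann, ont)
    ia <- compute_ia(prop, ont, aspect = "MFO")
    expect_equal(ia, oracle_ia(prop, ont), tolerance = 0)
    expect_true(all(ia >= 0))
  }
})

test_that("select_vocabulary filters by carrier count deterministically", {
  ont <- make_ontology(n_terms_per_aspect = 10, seed = 3, aspects = "MFO")
  leaves <- ont$terms[lengths(ont$children)[ont$terms] == 0]
  # carrier counts 12, 10, 9, 3, 1 over distinct leaf-descended terms
  counts <- c(12, 10, 9, 3, 1)
  terms <- leaves[1:5]
  ann <- do.call(rbind, lapply(seq_along(terms), function(i)
    data.frame(protein = sprintf("Q%02d_%d", 1:counts[i], i),
               term = terms[i])))
  # distinct proteins per term so internal terms can exceed the threshold
  prop <- propagate_annotations(ann, ont)
  vocab <- select_vocabulary(prop, "MFO", min_count = 10)
  expect_equal(sum(terms %in% vocab$terms), 2L)
  expect_equal(vocab$terms, sort(vocab$terms))
  expect_equal(unname(vocab$index), seq_along(vocab$terms))

  all_terms <- select_vocabulary(prop, "MFO", min_count = 1)
  expect_setequal(all_terms$terms, unique(prop$term))
})

test_that("vocabulary min_count defaults are 50 for BPO and 10 for MFO/CCO", {
  ont <- parse_obo(diamond_obo())  # BPO fixture
  ann <- data.frame(protein = sprintf("P%02d", 1:12), term = "GO:0000013")
  prop <- propagate_annotations(ann, ont)
  expect_warning(v_bpo <- select_vocabulary(prop, "BPO"), "empty")
  expect_equal(length(v_bpo$terms), 0L)
  expect_equal(v_bpo$min_count, 50L)

  ont_m <- parse_obo(chain_obo())
  ann_m <- data.frame(protein = sprintf("P%02d", 1:12),
                      term = chain_terms[["leaf"]])
  v_mfo <- select_vocabulary(propagate_annotations(ann_m, ont_m), "MFO")
  expect_equal(v_mfo$min_count, 10L)
  expect_equal(length(v_mfo$terms), 3L)
})

test_that("ontologies round-trip through write_obo/parse_obo", {
  ont <- make_ontology(n_terms_per_aspect = 8, seed = 5)
  path <- tempfile(fileext = ".obo")
  write_obo(ont, path)
  back <- parse_obo(path)
  expect_setequal(back$terms, ont$terms)
  expect_equal(back$aspect[sort(back$terms)], ont$aspect[sort(ont$terms)])
  eo <- ont$edges[order(ont$edges$child, ont$edges$parent), ]
  eb <- back$edges[order(back$edges$child, back$edges$parent), ]
  expect_equal(eb$parent, eo$parent)
  expect_equal(eb$relation, eo$relation)
})
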