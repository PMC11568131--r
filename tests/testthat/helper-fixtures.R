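# Shared fixtures: small hand-built ontologies (via OBO text, so they
# exercise the real parser) and random worlds for property tests.

# leaf --is_a--> mid --part_of--> root, all MFO
chain_obo <- function(extra = character()) {
  path <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000003", "name: root",
    "namespace: molecular_function", "",
    "[Term]", "id: GO:0000002", "name: mid",
    "namespace: molecular_function",
    "relationship: part_of GO:0000003", "",
    "[Term]", "id: GO:0000001", "name: leaf",
    "namespace: molecular_function", "is_a: GO:0000002", "",
    extra), path)
  path
}

chain_terms <- c(leaf = "GO:0000001", mid = "GO:0000002", root = "GO:0000003")

# diamond: leaf under two parents sharing one grandparent (single root)
diamond_obo <- function() {
  path <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000010", "name: grandparent",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000011", "name: parent A",
    "namespace: biological_process", "is_a: GO:0000010", "",
    "[Term]", "id: GO:0000012", "name: parent B",
    "namespace: biological_process",
    "relationship: part_of GO:0000010", "",
    "[Term]", "id: GO:0000013", "name: leaf",
    "namespace: biological_process", "is_a: GO:0000011",
    "is_a: GO:0000012", ""), path)
  path
}

# random annotation table on an ontology: each protein gets 1..3 random
# (possibly internal) terms of one aspect
random_annotation_fixture <- function(ontology, n_proteins, seed,
                                      aspect = "MFO") {
  set.seed(seed)
  terms <- ontology$terms[ontology$aspect == aspect]
  prot <- sprintf("X%03d", seq_len(n_proteins))
  do.call(rbind, lapply(prot, function(p) {
    data.frame(protein = p,
               term = sample(terms, sample(1:3, 1)),
               stringsAsFactors = FALSE)
  }))
}

# six-protein chronology exercising every rule of the time splitter
six_protein_table <- function() {
  rec <- function(p, aspect, date)
    data.frame(protein = p, term = "GO:0000001", evidence = "EXP",
               date = as.Date(date), aspect = aspect,
               stringsAsFactors = FALSE)
  rbind(
    rec("P1", "BPO", "2022-01-10"),                       # train
    rec("P2", "BPO", "2023-01-15"),                       # val, no-knowledge
    rec("P3", "MFO", "2022-05-01"), rec("P3", "BPO", "2023-06-01"),
    # ^ test, limited-knowledge (prior MFO)
    rec("P4", "BPO", "2022-03-01"), rec("P4", "BPO", "2023-02-01"),
    # ^ train only, despite a new annotation in the validation window
    rec("P5", "CCO", "2023-01-10"), rec("P5", "BPO", "2023-09-09"),
    # ^ test, limited-knowledge: CCO annotation predates the t1 window start
    rec("P6", "BPO", "2023-02-20"), rec("P6", "MFO", "2024-01-01"))
    # ^ val, no-knowledge: the MFO record postdates the window start
}

# score matrix on the 0.01 evaluation grid so sweep == exhaustive oracle
random_grid_scores <- function(n_prot, n_terms, seed) {
  set.seed(seed)
  matrix(sample(seq(0.01, 1, 0.01), n_prot * n_terms, replace = TRUE),
         n_prot, n_terms,
         dimnames = list(sprintf("X%03d", seq_len(n_prot)),
                         sprintf("GO:%07d", seq_len(n_terms))))
}
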