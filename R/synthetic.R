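# Seeded synthetic data: toy ontologies, cluster-structured annotated
# protein sets with chronological bands, biased sequences, and alignment
# hit tables.  Both information channels the pipeline fuses — embedding
# similarity and alignment identity — carry cluster signal, mirroring the
# premise that the network and homology transfer are complementary.

ASPECT_ID_BASE <- c(MFO = 1e6, BPO = 2e6, CCO = 3e6)

#' Generate a random layered GO-like ontology
#'
#' Per aspect: a single root plus `n_terms_per_aspect - 1` terms arranged
#' in layers, every non-root term drawing 1..`max_parents` parents from
#' strictly shallower layers, so the graph is acyclic and rooted by
#' construction.  Roughly half the edges are emitted as part-of, the rest
#' as is-a.
#'
#' @param n_terms_per_aspect terms per aspect (>= 3).
#' @param max_parents maximum number of parents per term (>= 1).
#' @param seed RNG seed; the generator is deterministic in it.
#' @param aspects aspects to generate (default all three).
#' @param n_layers depth of the DAG below the root.
#' @return a `go_ontology`.
#' @export
make_ontology <- function(n_terms_per_aspect = 30L, max_parents = 2L,
                          seed = 1L, aspects = GO_ASPECTS, n_layers = 4L) {
  if (n_terms_per_aspect < 3L) stop("need >= 3 terms per aspect",
                                    call. = FALSE)
  if (max_parents < 1L) stop("`max_parents` must be >= 1", call. = FALSE)
  with_local_seed(seed, {
    terms <- character(); aspect <- character()
    child <- character(); parent <- character(); rel <- character()
    for (a in aspects) {
      ids <- sprintf("GO:%07d", ASPECT_ID_BASE[[a]] + seq_len(n_terms_per_aspect))
      terms <- c(terms, ids)
      aspect[ids] <- a
      layer <- c(0L, sort(sample(rep_len(seq_len(n_layers),
                                         n_terms_per_aspect - 1L))))
      for (i in seq_along(ids)[-1L]) {
        pool <- ids[layer < layer[i]]
        npar <- sample.int(min(max_parents, length(pool)), 1L)
        pars <- if (length(pool) == 1L) pool else sample(pool, npar)
        child <- c(child, rep(ids[i], npar))
        parent <- c(parent, pars)
        rel <- c(rel, sample(c("is_a", "part_of"), npar, replace = TRUE,
                             prob = c(0.6, 0.4)))
      }
    }
    new_ontology(terms,
                 data.frame(child = child, parent = parent, relation = rel,
                            stringsAsFactors = FALSE),
                 aspect,
                 name = stats::setNames(paste("synthetic term",
                                              seq_along(terms)), terms))
  })
}

SYNTH_DATES <- list(t0 = as.Date("2022-11-30"), t1 = as.Date("2023-03-31"),
                    t2 = as.Date("2024-02-29"))

#' Generate a cluster-structured annotated protein world
#'
#' Each cluster draws a characteristic set of leaf terms per aspect; each
#' protein inherits its cluster's leaves with a per-leaf flip probability
#' `noise`, and receives a sequence sampled from a cluster-specific
#' residue bias so within-cluster sequence similarity exceeds
#' between-cluster similarity.  Annotation dates fall in three bands
#' around t0/t1/t2 so the chronological splitter sees non-trivial train,
#' validation and test sets; some validation/test proteins carry one
#' aspect annotated before t0, producing limited-knowledge cases.  A
#' fraction `iea_frac` of additional records carries the IEA
#' (non-experimental) code to exercise evidence filtering.
#'
#' @param ontology a `go_ontology` (see [make_ontology()]).
#' @param n_proteins number of proteins.
#' @param n_clusters number of clusters (<= `n_proteins`).
#' @param noise per-leaf flip probability in [0, 1).
#' @param seed RNG seed.
#' @param p_train,p_val probability of the train and validation date bands
#'   (test gets the rest).
#' @param p_prior probability that a validation/test protein has one
#'   aspect annotated before t0 (limited-knowledge source).
#' @param iea_frac fraction of extra IEA records.
#' @param dates list with Date elements t0, t1, t2.
#' @return object of class `go_world`: list with `ontology`,
#'   `annotations` (protein, term, evidence, date, aspect), `sequences`,
#'   `clusters` (named integer), `partition` (named character:
#'   train/validation/test band per protein), `seed`, `params`.
#' @export
make_proteins <- function(ontology, n_proteins = 120L, n_clusters = 5L,
                          noise = 0.05, seed = 1L, p_train = 0.7,
                          p_val = 0.15, p_prior = 0.5, iea_frac = 0.1,
                          dates = SYNTH_DATES) {
  if (n_clusters > n_proteins)
    stop("n_clusters > n_proteins", call. = FALSE)
  if (noise < 0 || noise >= 1) stop("noise must be in [0, 1)", call. = FALSE)
  aspects <- intersect(GO_ASPECTS, unique(ontology$aspect))
  leaves <- lapply(stats::setNames(aspects, aspects), function(a)
    ontology$terms[lengths(ontology$children)[ontology$terms] == 0L &
                     ontology$aspect == a])

  with_local_seed(seed, {
    prot <- sprintf("P%04d", seq_len(n_proteins))
    clusters <- stats::setNames(
      rep_len(seq_len(n_clusters), n_proteins)[sample.int(n_proteins)], prot)

    profile <- lapply(seq_len(n_clusters), function(cl)
      lapply(leaves, function(lv) {
        sel <- lv[stats::runif(length(lv)) < 0.4]
        if (!length(sel)) sel <- sample(lv, 1L)
        sel
      }))

    partition <- stats::setNames(
      sample(c("train", "validation", "test"), n_proteins, replace = TRUE,
             prob = c(p_train, p_val, 1 - p_train - p_val)), prot)
    # one aspect annotated before t0 for some validation/test proteins
    prior_aspect <- stats::setNames(rep(NA_character_, n_proteins), prot)
    heldout <- prot[partition != "train"]
    pick <- heldout[stats::runif(length(heldout)) < p_prior]
    prior_aspect[pick] <- sample(aspects, length(pick), replace = TRUE)

    rand_date <- function(n, lo, hi)
      lo + floor(stats::runif(n) * as.numeric(hi - lo + 1))

    rows <- vector("list", n_proteins * length(aspects))
    k <- 0L
    for (p in prot) {
      cl <- clusters[[p]]
      for (a in aspects) {
        lv <- leaves[[a]]
        member <- lv %in% profile[[cl]][[a]]
        flip <- stats::runif(length(lv)) < noise
        member <- xor(member, flip)
        if (!any(member)) member[match(profile[[cl]][[a]][1L], lv)] <- TRUE
        sel <- lv[member]
        band <- if (identical(prior_aspect[[p]], a)) "train" else partition[[p]]
        d <- switch(band,
          train = rand_date(length(sel), dates$t0 - 300, dates$t0),
          validation = rand_date(length(sel), dates$t0 + 1, dates$t1),
          test = rand_date(length(sel), dates$t1 + 1, dates$t2))
        k <- k + 1L
        rows[[k]] <- data.frame(
          protein = p, term = sel,
          evidence = sample(EXPERIMENTAL_CODES, length(sel), replace = TRUE),
          date = d, aspect = a, stringsAsFactors = FALSE)
      }
    }
    ann <- do.call(rbind, rows[seq_len(k)])
    # non-experimental decoys, dropped by filter_experimental()
    n_iea <- ceiling(iea_frac * nrow(ann))
    iea <- ann[sample.int(nrow(ann), n_iea), , drop = FALSE]
    iea$evidence <- "IEA"
    ann <- rbind(ann, iea)
    rownames(ann) <- NULL

    # cluster-biased sequences: three signature residues per cluster get
    # strongly elevated sampling weight
    aa20 <- AA_ALPHABET[1:20]
    seqs <- stats::setNames(character(n_proteins), prot)
    sig <- lapply(seq_len(n_clusters), function(cl) sample(aa20, 3L))
    wts <- lapply(seq_len(n_clusters), function(cl) {
      w <- stats::rexp(20) + 0.2
      names(w) <- aa20
      w[sig[[cl]]] <- w[sig[[cl]]] + 8
      w / sum(w)
    })
    for (p in prot) {
      L <- sample(120:200, 1L)
      seqs[[p]] <- paste(sample(aa20, L, replace = TRUE,
                                prob = wts[[clusters[[p]]]]), collapse = "")
    }

    structure(list(ontology = ontology, annotations = ann,
                   sequences = seqs, clusters = clusters,
                   partition = partition, seed = seed,
                   params = list(n_proteins = n_proteins,
                                 n_clusters = n_clusters, noise = noise,
                                 p_train = p_train, p_val = p_val,
                                 p_prior = p_prior, iea_frac = iea_frac,
                                 dates = dates)),
              class = "go_world")
  })
}

#' @export
print.go_world <- function(x, ...) {
  cat(sprintf(paste0("Synthetic GO world: %d proteins, %d clusters, ",
                     "%d annotation records (seed %d)\n"),
              length(x$sequences), x$params$n_clusters, nrow(x$annotations),
              x$seed))
  print(x$ontology)
  invisible(x)
}

#' Default synthetic world
#'
#' Three aspects of 30 terms, 120 proteins in 5 clusters with 5% leaf
#' noise — the study conditions used throughout the test suite.
#'
#' @param seed RNG seed.
#' @param ... overrides forwarded to [make_ontology()] / [make_proteins()].
#' @return a `go_world`.
#' @export
make_world <- function(seed = 1L, ...) {
  dots <- list(...)
  ont_args <- dots[names(dots) %in% names(formals(make_ontology))]
  prot_args <- dots[names(dots) %in% names(formals(make_proteins))]
  ontology <- do.call(make_ontology,
                      c(list(seed = seed), ont_args))
  do.call(make_proteins,
          c(list(ontology = ontology, seed = seed + 1000L), prot_args))
}

#' Generate a synthetic alignment hit table for a world
#'
#' Each query receives hits against same-cluster templates with high
#' identity and bitscore, and against cross-cluster templates with low
#' identity, mimicking an aligner run of the queries against the template
#' database.  All rows satisfy `nident <= min(qlen, slen)`.
#'
#' @param world a `go_world`.
#' @param queries character vector of query protein ids (subset of the
#'   world's proteins).
#' @param seed RNG seed.
#' @param templates template protein ids (default: the world's train-band
#'   proteins).
#' @param n_same,n_cross hits drawn per query from the same and from other
#'   clusters.
#' @param id_same,id_cross identity ranges (length-2 numeric).
#' @return a `go_hits` data.frame.
#' @export
make_hits <- function(world, queries, seed = 1L, templates = NULL,
                      n_same = 5L, n_cross = 3L,
                      id_same = c(0.55, 0.9), id_cross = c(0.05, 0.25)) {
  stopifnot(all(queries %in% names(world$sequences)))
  if (is.null(templates))
    templates <- names(world$partition)[world$partition == "train"]
  tmpl_cl <- world$clusters[templates]
  with_local_seed(seed, {
    out <- vector("list", length(queries))
    for (qi in seq_along(queries)) {
      qy <- queries[qi]
      qlen <- nchar(world$sequences[[qy]])
      same <- setdiff(templates[tmpl_cl == world$clusters[[qy]]], qy)
      cross <- setdiff(templates, c(same, qy))
      pick <- c(if (length(same)) sample(same, min(n_same, length(same))),
                if (length(cross)) sample(cross, min(n_cross, length(cross))))
      if (!length(pick)) next
      is_same <- world$clusters[pick] == world$clusters[[qy]]
      id <- ifelse(is_same,
                   stats::runif(length(pick), id_same[1], id_same[2]),
                   stats::runif(length(pick), id_cross[1], id_cross[2]))
      slen <- nchar(world$sequences[pick])
      nident <- pmin(round(id * pmax(qlen, slen)), pmin(qlen, slen))
      bitscore <- round(2 * nident * stats::runif(length(pick), 0.9, 1.1), 1)
      out[[qi]] <- data.frame(query = qy, subject = pick,
                              bitscore = pmax(bitscore, 1),
                              nident = as.integer(nident),
                              qlen = qlen, slen = as.integer(slen),
                              stringsAsFactors = FALSE)
    }
    hits <- do.call(rbind, out)
    if (is.null(hits))
      hits <- data.frame(query = character(), subject = character(),
                         bitscore = numeric(), nident = integer(),
                         qlen = integer(), slen = integer(),
                         stringsAsFactors = FALSE)
    rownames(hits) <- NULL
    class(hits) <- c("go_hits", "data.frame")
    hits
  })
}

#' Write a world's files (OBO, FASTA, annotations, clusters) to a directory
#'
#' @param world a `go_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_obo(world$ontology, file.path(dir, "ontology.obo"))
  write_fasta(world$sequences, file.path(dir, "sequences.fasta"))
  write_annotations(world$annotations, file.path(dir, "annotations.tsv"))
  utils::write.table(
    data.frame(protein = names(world$clusters),
               cluster = unname(world$clusters),
               partition = unname(world$partition[names(world$clusters)])),
    file.path(dir, "clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
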