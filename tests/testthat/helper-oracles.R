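# Independent brute-force implementations used as oracles.  They share no
# code with the package internals: everything is explicit loops over sets.

# reachability by repeated direct-parent expansion
oracle_ancestors <- function(ontology, term) {
  seen <- character()
  frontier <- term
  while (length(frontier)) {
    pars <- unique(unlist(lapply(frontier, function(t)
      ontology$edges$parent[ontology$edges$child == t])))
    pars <- setdiff(pars, seen)
    seen <- union(seen, pars)
    frontier <- pars
  }
  setdiff(seen, term)
}

# IA by explicit carrier-set enumeration
oracle_ia <- function(propagated, ontology, aspect = "MFO") {
  sub <- propagated[propagated$aspect == aspect, , drop = FALSE]
  sets <- lapply(split(sub$term, sub$protein), unique)
  terms <- ontology$terms[ontology$aspect == aspect]
  out <- numeric(length(terms))
  names(out) <- terms
  for (q in terms) {
    pa <- ontology$edges$parent[ontology$edges$child == q]
    n_q <- sum(vapply(sets, function(s) q %in% s, logical(1)))
    n_pa <- if (!length(pa)) length(sets)
    else sum(vapply(sets, function(s) all(pa %in% s), logical(1)))
    out[q] <- log2((1 + n_pa) / (1 + n_q))
  }
  out
}

# per-term loop over hits (Eq.-style weighted vote)
oracle_knn <- function(hits, propagated, vocabulary) {
  sets <- lapply(split(propagated$term, propagated$protein), unique)
  sets <- lapply(sets, function(s) intersect(s, vocabulary$terms))
  keep <- vapply(hits$subject, function(s)
    length(sets[[s]] %||% character()) > 0, logical(1))
  hits <- hits[keep, , drop = FALSE]
  queries <- sort(unique(hits$query))
  S <- matrix(0, length(queries), length(vocabulary$terms),
              dimnames = list(queries, vocabulary$terms))
  for (qy in queries) {
    h <- hits[hits$query == qy, , drop = FALSE]
    w <- h$bitscore * h$nident / pmax(h$qlen, h$slen)
    for (term in vocabulary$terms) {
      ind <- vapply(h$subject, function(s) term %in% sets[[s]], logical(1))
      S[qy, term] <- sum(w * ind) / sum(w)
    }
  }
  S
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# weighted precision/recall/ru/mi at one threshold, via per-protein sets
oracle_point <- function(truth, scores, ia, t) {
  prots <- rownames(truth)
  prs <- c(); rcs <- c(); rus <- c(); mis <- c(); covered <- 0
  for (p in prots) {
    true_terms <- colnames(truth)[truth[p, ] == 1]
    pred_terms <- colnames(scores)[scores[p, ] >= t]
    tp <- intersect(true_terms, pred_terms)
    if (length(pred_terms)) {
      covered <- covered + 1
      den <- sum(ia[pred_terms])
      prs <- c(prs, if (den > 0) sum(ia[tp]) / den else 0)
    }
    den_r <- sum(ia[true_terms])
    rcs <- c(rcs, if (den_r > 0) sum(ia[tp]) / den_r else 0)
    rus <- c(rus, sum(ia[setdiff(true_terms, pred_terms)]))
    mis <- c(mis, sum(ia[setdiff(pred_terms, true_terms)]))
  }
  c(wpr = if (covered > 0) mean(prs) else 0, wrc = mean(rcs),
    ru = mean(rus), mi = mean(mis), n_covered = covered)
}

# exhaustive maxima/minima over every distinct score value
oracle_wfmax <- function(truth, scores, ia) {
  ts <- sort(unique(as.vector(scores)))
  best <- 0
  for (t in ts) {
    pt <- oracle_point(truth, scores, ia, t)
    f <- if (pt["wpr"] + pt["wrc"] > 0)
      2 * pt["wpr"] * pt["wrc"] / (pt["wpr"] + pt["wrc"]) else 0
    best <- max(best, f)
  }
  best
}

oracle_smin <- function(truth, scores, ia) {
  ts <- sort(unique(as.vector(scores)))
  best <- Inf
  for (t in ts) {
    pt <- oracle_point(truth, scores, ia, t)
    best <- min(best, sqrt(pt["ru"]^2 + pt["mi"]^2))
  }
  best
}

# independent trapezoid over the sweep grid with the recall-0 anchor
oracle_auwpr <- function(truth, scores, ia) {
  pts <- t(vapply(seq(0.01, 1, 0.01), function(t)
    oracle_point(truth, scores, ia, t), numeric(5)))
  pts <- pts[pts[, "n_covered"] > 0, , drop = FALSE]
  if (!nrow(pts)) return(0)
  r <- c(0, pts[, "wrc"])
  p <- c(pts[nrow(pts), "wpr"], pts[, "wpr"])
  o <- order(r, p)
  r <- r[o]; p <- p[o]
  area <- 0
  for (i in seq_len(length(r) - 1))
    area <- area + (r[i + 1] - r[i]) * (p[i] + p[i + 1]) / 2
  unname(area)
}

# central finite-difference gradient of a scalar function of a matrix
numeric_gradient <- function(f, X, h = 1e-5) {
  G <- X * 0
  for (i in seq_along(X)) {
    Xp <- X; Xp[i] <- Xp[i] + h
    Xm <- X; Xm[i] <- Xm[i] - h
    G[i] <- (f(Xp) - f(Xm)) / (2 * h)
  }
  G
}

# fixpoint iteration of the parent >= child constraint (postprocess oracle)
oracle_postprocess <- function(scores, terms, ontology) {
  e <- ontology$edges[ontology$edges$child %in% terms &
                        ontology$edges$parent %in% terms, , drop = FALSE]
  S <- scores
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(e))) {
      upd <- pmax(S[, e$parent[i]], S[, e$child[i]])
      if (any(upd != S[, e$parent[i]])) changed <- TRUE
      S[, e$parent[i]] <- upd
    }
    if (!changed) break
  }
  S
}
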