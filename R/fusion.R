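# Identity-gated fusion of the network and homology-transfer scores.
# The network weight w decays exponentially with the mean of the query's
# top sequence identities: w = alpha + (1 - alpha) * exp(-k * mean_id),
# so remote-homology queries rely on the network (w -> 1) while queries
# with close templates lean on annotation transfer (w -> alpha).

#' Fusion parameters
#'
#' @param alpha minimum network weight, in [0, 1] (default 0.33).
#' @param k exponential decay rate of the network weight with mean top
#'   identity (default 3).
#' @param n_top number of highest identities averaged per query
#'   (default 5).
#' @return list of class `fusion_params`.
#' @export
fusion_params <- function(alpha = 0.33, k = 3, n_top = 5L) {
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]", call. = FALSE)
  if (k < 0) stop("`k` must be >= 0", call. = FALSE)
  if (n_top < 1L) stop("`n_top` must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, k = k, n_top = as.integer(n_top)),
            class = "fusion_params")
}

#' Mean of the top sequence identities of a query
#'
#' Mean of the `n_top` largest identities among the query's hits; the mean
#' of all when fewer are available, and 0 for a query with no hits.
#'
#' @param identities numeric vector of hit identities (see
#'   [hit_identity()]) for one query.
#' @param n_top how many top identities to average.
#' @return scalar in [0, 1].
#' @export
mean_top_identity <- function(identities, n_top = 5L) {
  if (!length(identities)) return(0)
  top <- sort(identities, decreasing = TRUE)
  mean(top[seq_len(min(n_top, length(top)))])
}

#' Per-query mean top identity from a hit table
#'
#' @param hits a `go_hits` data.frame.
#' @param queries character vector of queries to report (queries with no
#'   hits get 0).
#' @param n_top how many top identities to average.
#' @param exclude_self drop self-hits first.
#' @return named numeric vector over `queries`.
#' @export
query_mean_identity <- function(hits, queries, n_top = 5L,
                                exclude_self = FALSE) {
  if (exclude_self) hits <- hits[hits$query != hits$subject, , drop = FALSE]
  ids <- split(hit_identity(hits), hits$query)
  vapply(stats::setNames(queries, queries), function(qy)
    mean_top_identity(ids[[qy]], n_top), numeric(1))
}

#' Identity-gated network weight
#'
#' \deqn{w = \alpha + (1 - \alpha) e^{-k \cdot \bar{ID}}}
#' Strictly decreasing in the mean identity, with w(0) = 1 and
#' w(1) = alpha + (1 - alpha) exp(-k).
#'
#' @param id_mean mean top identity in [0, 1] (vectorised).
#' @param params a [fusion_params()] list.
#' @return weight(s) in [alpha, 1].
#' @export
fusion_weight <- function(id_mean, params = fusion_params()) {
  if (any(id_mean < 0 | id_mean > 1))
    stop("`id_mean` must lie in [0, 1]", call. = FALSE)
  params$alpha + (1 - params$alpha) * exp(-params$k * id_mean)
}

#' Fuse network and homology scores
#'
#' Per-term convex combination `w * s_dnn + (1 - w) * s_align` with a
#' per-query weight `w`.  The two matrices are aligned on the union of
#' their term columns and the union of their query rows; a term or query
#' absent from one source contributes score 0 there.
#'
#' @param s_dnn network score matrix (queries x terms).
#' @param s_align homology score matrix (queries x terms).
#' @param w scalar or per-query named vector of weights in [0, 1].
#' @return fused score matrix over the union of queries and terms.
#' @export
fuse_scores <- function(s_dnn, s_align, w) {
  if (any(w < 0 | w > 1)) stop("`w` must lie in [0, 1]", call. = FALSE)
  terms <- union(colnames(s_dnn) %||% as.character(seq_len(ncol(s_dnn))),
                 colnames(s_align) %||% as.character(seq_len(ncol(s_align))))
  queries <- union(rownames(s_dnn) %||% as.character(seq_len(nrow(s_dnn))),
                   rownames(s_align) %||% as.character(seq_len(nrow(s_align))))
  expand <- function(S) {
    if (is.null(dimnames(S)))
      dimnames(S) <- list(as.character(seq_len(nrow(S))),
                          as.character(seq_len(ncol(S))))
    M <- matrix(0, length(queries), length(terms),
                dimnames = list(queries, terms))
    M[rownames(S), colnames(S)] <- S
    M
  }
  A <- expand(s_dnn)
  B <- expand(s_align)
  if (length(w) == 1L) {
    wv <- rep(w, length(queries))
  } else {
    if (is.null(names(w)))
      stop("per-query `w` must be named by query id", call. = FALSE)
    missing <- setdiff(queries, names(w))
    if (length(missing))
      stop("missing fusion weight for: ", paste(missing, collapse = ", "),
           call. = FALSE)
    wv <- unname(w[queries])
  }
  A * wv + B * (1 - wv)
}

#' Grid-search fusion parameters on a validation benchmark
#'
#' Utility for re-tuning `alpha` and `k` on a validation split: evaluates
#' weighted Fmax of the fused scores over a parameter grid and returns the
#' best cell.
#'
#' @param s_dnn,s_align score matrices for the validation queries.
#' @param id_mean named per-query mean top identity.
#' @param truth binary truth matrix.
#' @param ia IA weights named by term.
#' @param alphas,ks grids to search.
#' @param n_top stored in the returned parameters.
#' @return list with `params` ([fusion_params()]) and `wfmax`, plus the
#'   full `grid` of evaluated cells.
#' @export
tune_fusion <- function(s_dnn, s_align, id_mean, truth, ia,
                        alphas = seq(0, 1, 0.1), ks = c(0, 1, 2, 3, 5, 8),
                        n_top = 5L) {
  grid <- expand.grid(alpha = alphas, k = ks)
  grid$wfmax <- NA_real_
  for (i in seq_len(nrow(grid))) {
    p <- fusion_params(grid$alpha[i], grid$k[i], n_top)
    fused <- fuse_scores(s_dnn, s_align, fusion_weight(id_mean, p))
    grid$wfmax[i] <- wfmax(truth, fused[rownames(truth), colnames(truth),
                                        drop = FALSE], ia)$value
  }
  best <- which.max(grid$wfmax)
  list(params = fusion_params(grid$alpha[best], grid$k[best], n_top),
       wfmax = grid$wfmax[best], grid = grid)
}
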