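# The neural predictor: three parallel per-layer MLP branches, a combiner
# MLP, and a final affine layer emitting one logit per vocabulary term.
# Implemented in base R matrix algebra with explicit backpropagation so
# the composite loss (and any ablation subset of its factors) can drive
# training directly through its analytic gradient.

relu <- function(x) pmax(x, 0)

init_layer <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)),
                  n_in, n_out),
       b = rep(0, n_out))
}

init_mlp <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L),
         function(i) init_layer(sizes[i], sizes[i + 1L]))
}

init_params <- function(D, Q, branch_hidden, combiner_hidden) {
  branches <- lapply(1:3, function(l) init_mlp(c(D, branch_hidden)))
  concat <- 3L * utils::tail(branch_hidden, 1L)
  list(branches = branches,
       combiner = init_mlp(c(concat, combiner_hidden)),
       out = init_layer(utils::tail(combiner_hidden, 1L), Q))
}

# Forward through a ReLU MLP; returns output and per-layer caches.
mlp_forward <- function(layers, X, dropout = 0, masks = NULL) {
  caches <- vector("list", length(layers))
  H <- X
  for (i in seq_along(layers)) {
    Z <- sweep(H %*% layers[[i]]$W, 2L, layers[[i]]$b, "+")
    A <- relu(Z)
    if (dropout > 0 && !is.null(masks))
      A <- A * masks[[i]] / (1 - dropout)
    caches[[i]] <- list(input = H, Z = Z, mask = if (!is.null(masks)) masks[[i]])
    H <- A
  }
  list(out = H, caches = caches)
}

# Backward through a ReLU MLP; dH is the gradient at the MLP output.
mlp_backward <- function(layers, caches, dH, dropout = 0) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    cc <- caches[[i]]
    if (dropout > 0 && !is.null(cc$mask))
      dH <- dH * cc$mask / (1 - dropout)
    dZ <- dH * (cc$Z > 0)
    grads[[i]] <- list(W = crossprod(cc$input, dZ), b = colSums(dZ))
    dH <- tcrossprod(dZ, layers[[i]]$W)
  }
  list(grads = grads, dX = dH)
}

# Full forward pass.  X is I x 3D (three layer blocks).
net_forward <- function(params, X, D, dropout = 0, masks = NULL) {
  bouts <- vector("list", 3L)
  bcaches <- vector("list", 3L)
  for (l in 1:3) {
    Xl <- X[, ((l - 1L) * D + 1L):(l * D), drop = FALSE]
    f <- mlp_forward(params$branches[[l]], Xl, dropout,
                     if (!is.null(masks)) masks$branches[[l]])
    bouts[[l]] <- f$out
    bcaches[[l]] <- f$caches
  }
  C <- do.call(cbind, bouts)
  fc <- mlp_forward(params$combiner, C, dropout,
                    if (!is.null(masks)) masks$combiner)
  logits <- sweep(fc$out %*% params$out$W, 2L, params$out$b, "+")
  list(logits = logits, bcaches = bcaches, ccaches = fc$caches,
       H = fc$out, widths = vapply(bouts, ncol, integer(1)))
}

net_backward <- function(params, fwd, dlogits, dropout = 0) {
  gout <- list(W = crossprod(fwd$H, dlogits), b = colSums(dlogits))
  dH <- tcrossprod(dlogits, params$out$W)
  bc <- mlp_backward(params$combiner, fwd$ccaches, dH, dropout)
  gcomb <- bc$grads
  dC <- bc$dX
  gbr <- vector("list", 3L)
  off <- 0L
  for (l in 1:3) {
    w <- fwd$widths[l]
    dBl <- dC[, (off + 1L):(off + w), drop = FALSE]
    gbr[[l]] <- mlp_backward(params$branches[[l]], fwd$bcaches[[l]], dBl,
                             dropout)$grads
    off <- off + w
  }
  list(branches = gbr, combiner = gcomb, out = gout)
}

# Structure-preserving binary map over parameter trees (leaves: W/b).
tree_map2 <- function(f, a, b) {
  if (is.list(a) && !is.numeric(a))
    return(mapply(tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE))
  f(a, b)
}
tree_map <- function(f, a) {
  if (is.list(a) && !is.numeric(a)) return(lapply(a, tree_map, f = f))
  f(a)
}

#' Fit the GO-term neural predictor
#'
#' Trains a multi-label classifier that maps three mean-pooled embedding
#' layer vectors per protein to logits over a GO term vocabulary.  The
#' architecture is three parallel ReLU MLP branches (one per embedding
#' layer), concatenation, a combiner MLP, and a final affine layer; the
#' training objective is the multiplicative composite of the selected loss
#' components (default ZLPR x protein-centric F1 x term-centric F1, all
#' IA-weighted where applicable), minimised with Adam.  Training is
#' deterministic given `seed` (single-threaded base R arithmetic).
#'
#' @param x a `go_embeddings` object or an I x 3D numeric matrix with
#'   protein row names.
#' @param y binary I x Q label matrix over the vocabulary (see
#'   [label_matrix()]); rows are matched to `x` by name when both are
#'   named.
#' @param ia IA weight per vocabulary term; default all ones.
#' @param vocabulary optional `go_vocabulary` stored for prediction and
#'   post-processing.
#' @param branch_hidden hidden sizes of each per-layer branch MLP.
#' @param combiner_hidden hidden sizes of the combiner MLP.
#' @param loss character vector of loss components
#'   (subset of `"zlpr"`, `"bce"`, `"ptf1"`, `"gof1"`).
#' @param aggregate F1 aggregation mode, see [protein_f1_loss()].
#' @param lr Adam learning rate.
#' @param epochs number of passes over the data.
#' @param batch_size minibatch size; batches are the whole data set when
#'   `batch_size >= I`.
#' @param dropout dropout rate on hidden activations during training.
#' @param seed RNG seed controlling initialisation, shuffling and dropout.
#' @param eps division guard forwarded to the loss.
#' @param verbose print the loss every 10 epochs.
#' @return an object of class `gonet` with components `params`, `config`,
#'   `history` (per-epoch training loss), `fitted` (training score
#'   matrix), `vocabulary`, `ia`.
#' @seealso [predict.gonet()], [hierarchical_postprocess()]
#' @export
gonet <- function(x, y, ia = NULL, vocabulary = NULL,
                  branch_hidden = c(1024, 512), combiner_hidden = 1024,
                  loss = c("zlpr", "ptf1", "gof1"),
                  aggregate = c("macro", "mean-f1"),
                  lr = 1e-3, epochs = 100L, batch_size = 64L,
                  dropout = 0.3, seed = 1L, eps = 1e-16, verbose = FALSE) {
  aggregate <- match.arg(aggregate)
  loss <- normalize_components(loss)
  X <- if (inherits(x, "go_embeddings")) x$x else as.matrix(x)
  if (ncol(X) %% 3L != 0L)
    stop("`x` must have 3 x D columns (three embedding layers)",
         call. = FALSE)
  D <- ncol(X) %/% 3L
  y <- as.matrix(y)
  if (!is.null(rownames(X)) && !is.null(rownames(y))) {
    if (!setequal(rownames(X), rownames(y)))
      stop("proteins in `x` and `y` differ", call. = FALSE)
    y <- y[rownames(X), , drop = FALSE]
  }
  if (nrow(y) != nrow(X)) stop("`x` and `y` disagree on protein count",
                               call. = FALSE)
  stop_if_not_binary(y, "y")
  Q <- ncol(y)
  if (Q == 0L) stop("empty vocabulary (Q = 0)", call. = FALSE)
  if (is.null(ia)) ia <- rep(1, Q)
  check_ia_length(ia, Q)
  if (!is.null(vocabulary) && length(vocabulary$terms) != Q)
    stop("vocabulary size does not match ncol(y)", call. = FALSE)

  I <- nrow(X)
  history <- numeric(epochs)

  with_local_seed(seed, {
    params <- init_params(D, Q, branch_hidden, combiner_hidden)
    m <- tree_map(function(w) w * 0, params)
    v <- tree_map(function(w) w * 0, params)
    b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8; step <- 0L

    hidden_widths <- function() list(
      branches = lapply(1:3, function(l) branch_hidden),
      combiner = combiner_hidden)

    for (ep in seq_len(epochs)) {
      ord <- if (batch_size < I) sample.int(I) else seq_len(I)
      starts <- seq(1L, I, by = batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, I)]
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx, , drop = FALSE]
        masks <- NULL
        if (dropout > 0) {
          hw <- hidden_widths()
          mk <- function(widths) lapply(widths, function(w)
            matrix(stats::rbinom(length(idx) * w, 1L, 1 - dropout),
                   length(idx), w))
          masks <- list(branches = lapply(hw$branches, mk),
                        combiner = mk(hw$combiner))
        }
        fwd <- net_forward(params, Xb, D, dropout, masks)
        lv <- composite_vg(yb, fwd$logits, ia, loss, eps, aggregate)
        if (!is.finite(lv$value))
          stop(sprintf("non-finite loss at epoch %d (batch starting %d)",
                       ep, s), call. = FALSE)
        grads <- net_backward(params, fwd, lv$grad, dropout)
        if (lr > 0) {
          step <- step + 1L
          m <- tree_map2(function(mm, g) b1 * mm + (1 - b1) * g, m, grads)
          v <- tree_map2(function(vv, g) b2 * vv + (1 - b2) * g^2, v, grads)
          corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
          upd <- tree_map2(function(mm, vv)
            lr * (mm / corr1) / (sqrt(vv / corr2) + adam_eps), m, v)
          params <- tree_map2(`-`, params, upd)
        }
        ep_loss <- ep_loss + lv$value * length(idx)
      }
      history[ep] <- ep_loss / I
      if (verbose && ep %% 10L == 0L)
        message(sprintf("epoch %4d  loss %.6f", ep, history[ep]))
    }
  })

  fitted_logits <- net_forward(params, X, D)$logits
  fitted <- sigmoid(fitted_logits)
  dimnames(fitted) <- list(rownames(X),
                           if (!is.null(vocabulary)) vocabulary$terms
                           else colnames(y))
  obj <- structure(list(
    params = params,
    config = list(D = D, Q = Q, branch_hidden = branch_hidden,
                  combiner_hidden = combiner_hidden, loss = loss,
                  aggregate = aggregate, lr = lr, epochs = epochs,
                  batch_size = batch_size, dropout = dropout, seed = seed,
                  eps = eps),
    ia = ia,
    vocabulary = vocabulary,
    history = history,
    fitted = fitted,
    y = y,
    call = match.call()
  ), class = "gonet")
  obj
}

#' @export
print.gonet <- function(x, ...) {
  cfg <- x$config
  cat("GO-term neural predictor (gonet)\n")
  cat(sprintf("  input: 3 layers x D = %d; vocabulary: %d terms\n",
              cfg$D, cfg$Q))
  cat(sprintf("  branches D -> %s; combiner -> %s -> %d logits\n",
              paste(cfg$branch_hidden, collapse = " -> "),
              paste(cfg$combiner_hidden, collapse = " -> "), cfg$Q))
  cat(sprintf("  loss: %s (%s F1); %d epochs, lr %g, dropout %g, seed %d\n",
              paste(cfg$loss, collapse = " x "), cfg$aggregate, cfg$epochs,
              cfg$lr, cfg$dropout, cfg$seed))
  cat(sprintf("  final training loss: %.6f\n", utils::tail(x$history, 1)))
  invisible(x)
}

#' @export
summary.gonet <- function(object, ...) {
  n_par <- sum(unlist(tree_map(length, object$params)))
  structure(list(config = object$config, n_parameters = n_par,
                 history = object$history,
                 final_loss = utils::tail(object$history, 1),
                 n_proteins = nrow(object$fitted)),
            class = "summary.gonet")
}

#' @export
print.summary.gonet <- function(x, ...) {
  cat(sprintf("gonet: %d parameters, %d training proteins, %d epochs\n",
              x$n_parameters, x$n_proteins, x$config$epochs))
  cat(sprintf("  training loss: first %.6f, final %.6f\n",
              x$history[1], x$final_loss))
  invisible(x)
}

#' @export
coef.gonet <- function(object, ...) object$params

#' @export
plot.gonet <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "epoch", ylab = "training loss",
                 main = "gonet training history", ...)
  invisible(x)
}

#' @export
residuals.gonet <- function(object, ...) object$y - object$fitted

#' Predict GO term scores for new proteins
#'
#' @param object a fitted `gonet`.
#' @param newdata a `go_embeddings` or I x 3D matrix.
#' @param ... unused.
#' @return I x Q score matrix (sigmoid probabilities in (0, 1)).
#' @export
predict.gonet <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "go_embeddings")) newdata$x else as.matrix(newdata)
  if (ncol(X) != 3L * object$config$D)
    stop(sprintf("newdata has %d columns; the model expects %d",
                 ncol(X), 3L * object$config$D), call. = FALSE)
  scores <- sigmoid(net_forward(object$params, X, object$config$D)$logits)
  dimnames(scores) <- list(rownames(X),
                           if (!is.null(object$vocabulary))
                             object$vocabulary$terms)
  scores
}

#' Enforce hierarchical consistency of prediction scores
#'
#' Processes the ontology in reverse-topological order (children before
#' parents) and raises each parent's score to the maximum of its
#' children's, so the returned matrix satisfies parent >= child along
#' every is-a/part-of edge.  Scores are only ever raised, and the operator
#' is idempotent.  Out-of-vocabulary ontology terms act as carriers: a
#' high-scoring term raises all of its in-vocabulary ancestors even when
#' intermediate terms are not in the vocabulary.
#'
#' @param scores I x Q score matrix over `vocabulary` columns.
#' @param vocabulary a `go_vocabulary` (or character vector of term ids).
#' @param ontology a `go_ontology`.
#' @return score matrix of the same shape.
#' @export
hierarchical_postprocess <- function(scores, vocabulary, ontology) {
  terms <- if (inherits(vocabulary, "go_vocabulary")) vocabulary$terms
  else as.character(vocabulary)
  scores <- as.matrix(scores)
  if (ncol(scores) != length(terms))
    stop("scores and vocabulary disagree on term count", call. = FALSE)
  missing <- setdiff(terms, ontology$terms)
  if (length(missing))
    stop("vocabulary term(s) missing from ontology: ",
         paste(missing, collapse = ", "), call. = FALSE)

  all_terms <- ontology$terms
  S <- matrix(-Inf, nrow(scores), length(all_terms),
              dimnames = list(rownames(scores), all_terms))
  S[, terms] <- scores

  ord <- names(igraph::topo_sort(ontology$graph, mode = "out"))
  for (t in ord) {
    pars <- ontology$parents[[t]]
    for (p in pars)
      S[, p] <- pmax(S[, p], S[, t])
  }
  out <- S[, terms, drop = FALSE]
  dimnames(out) <- dimnames(scores)
  out
}

#' Save a fitted predictor as a single checkpoint file
#'
#' The checkpoint holds the configuration, weights, IA vector, vocabulary
#' and an MD5 digest of the vocabulary term list, verified on load.
#'
#' @param object a `gonet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_gonet <- function(object, path) {
  object$vocab_md5 <- vocab_md5(object$vocabulary)
  saveRDS(object, path)
  invisible(path)
}

#' Load a predictor checkpoint written by [save_gonet()]
#' @param path checkpoint file.
#' @return a `gonet`.
#' @export
load_gonet <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "gonet")) stop("not a gonet checkpoint", call. = FALSE)
  if (!identical(vocab_md5(object$vocabulary), object$vocab_md5))
    stop("vocabulary digest mismatch in checkpoint", call. = FALSE)
  object
}

vocab_md5 <- function(vocabulary) {
  if (is.null(vocabulary)) return(NA_character_)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(vocabulary$terms, tf)
  unname(tools::md5sum(tf))
}
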