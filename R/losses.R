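# Training losses for hierarchical multi-label GO prediction:
# information-accretion-weighted soft F1 losses (protein-centric and
# term-centric), the zero-bounded log-sum-exp pairwise rank (ZLPR) loss,
# binary cross-entropy, and their multiplicative combinations.
#
# Each loss has a companion internal *_vg() function returning the value
# together with the analytic gradient with respect to the logits, used by
# the network optimiser and checked against central finite differences in
# the test suite.

LOSS_COMPONENTS <- c("zlpr", "bce", "ptf1", "gof1")

normalize_components <- function(components) {
  if (is.character(components) && length(components) == 1L &&
      grepl("[+_]", components))
    components <- strsplit(components, "[+_]")[[1]]
  components <- tolower(components)
  bad <- setdiff(components, LOSS_COMPONENTS)
  if (length(bad))
    stop("unknown loss component(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!length(components)) stop("empty loss component set", call. = FALSE)
  unique(components)
}

# Soft-F1 machinery ---------------------------------------------------------

# Precision/recall sums for one orientation.  With margin = 1 (protein-
# centric) rows are the units; margin = 2 (term-centric) transposes first,
# which realises the structural symmetry between the two variants.
# Returns value and d(loss)/d(p) for the probability matrix p.
f1_vg <- function(y, p, ia, eps, margin, aggregate = "macro") {
  if (margin == 2L) {
    y <- t(y); p <- t(p)
    W <- matrix(ia, nrow(y), ncol(y))  # rows are GO terms after transposing
  } else {
    W <- matrix(ia, nrow(y), ncol(y), byrow = TRUE)
  }

  a <- rowSums(W * y * p)            # weighted true-positive mass
  b <- eps + rowSums(W * p)          # weighted predicted mass
  cc <- eps + rowSums(W * y)         # weighted truth mass
  P <- a / b
  R <- a / cc

  if (aggregate == "macro") {
    Pb <- mean(P); Rb <- mean(R)
    D <- Pb + Rb + eps
    value <- 1 - 2 * Pb * Rb / D
    # dF/dPbar and dF/dRbar of F = 2 Pb Rb / D
    dF_dP <- (2 * Rb * D - 2 * Pb * Rb) / D^2
    dF_dR <- (2 * Pb * D - 2 * Pb * Rb) / D^2
    n <- length(P)
    # dP_i/dp = W (y b - a) / b^2 ; dR_i/dp = W y / c
    gP <- W * (y * b - a) / b^2 / n
    gR <- W * y / cc / n
    grad <- -(dF_dP * gP + dF_dR * gR)
  } else {  # per-unit F1, then mean
    D <- P + R + eps
    f <- 2 * P * R / D
    value <- 1 - mean(f)
    df_dP <- (2 * R * D - 2 * P * R) / D^2
    df_dR <- (2 * P * D - 2 * P * R) / D^2
    n <- length(P)
    gP <- W * (y * b - a) / b^2
    gR <- W * y / cc
    grad <- -(df_dP * gP + df_dR * gR) / n
  }
  if (margin == 2L) grad <- t(grad)
  list(value = value, grad = grad)  # grad wrt p, original orientation
}

#' Protein-centric IA-weighted soft F1 loss
#'
#' For each protein i the weighted soft precision and recall are
#' \deqn{P_i = \frac{\sum_q y_{iq} p_{iq} IA_q}{\epsilon + \sum_q p_{iq} IA_q}, \quad
#'       R_i = \frac{\sum_q y_{iq} p_{iq} IA_q}{\epsilon + \sum_q y_{iq} IA_q}.}
#' With `aggregate = "macro"` (default) precision and recall are averaged
#' over proteins first and the loss is \eqn{1 - 2\bar P\bar R/(\bar P+\bar
#' R+\epsilon)}; with `aggregate = "mean-f1"` a per-protein F1 is formed
#' first and its mean subtracted from 1.  Predictions are soft
#' probabilities, so the loss is differentiable.
#'
#' @param y_true binary I x Q label matrix.
#' @param y_pred numeric I x Q matrix of probabilities in [0, 1].
#' @param ia non-negative IA weight per vocabulary term (length Q).
#' @param eps small constant guarding divisions by zero.
#' @param aggregate `"macro"` or `"mean-f1"`.
#' @return scalar loss in [0, 1].
#' @export
protein_f1_loss <- function(y_true, y_pred, ia, eps = 1e-16,
                            aggregate = c("macro", "mean-f1")) {
  aggregate <- match.arg(aggregate)
  check_same_dim(y_true, y_pred, "y_true", "y_pred")
  check_ia_length(ia, ncol(y_true))
  stop_if_not_binary(y_true)
  f1_vg(y_true, y_pred, ia, eps, margin = 1L, aggregate = aggregate)$value
}

#' Term-centric IA-weighted soft F1 loss
#'
#' As [protein_f1_loss()] but precision and recall are computed per GO term
#' across the batch and averaged over the term dimension.
#'
#' @inheritParams protein_f1_loss
#' @return scalar loss in [0, 1].
#' @export
go_f1_loss <- function(y_true, y_pred, ia, eps = 1e-16,
                       aggregate = c("macro", "mean-f1")) {
  aggregate <- match.arg(aggregate)
  check_same_dim(y_true, y_pred, "y_true", "y_pred")
  check_ia_length(ia, ncol(y_true))
  stop_if_not_binary(y_true)
  f1_vg(y_true, y_pred, ia, eps, margin = 2L, aggregate = aggregate)$value
}

# ZLPR ----------------------------------------------------------------------

zlpr_vg <- function(y, s, s0 = 0) {
  I <- nrow(s)
  grad <- matrix(0, I, ncol(s))
  total <- 0
  for (i in seq_len(I)) {
    pos <- y[i, ] == 1
    # log(e^{-s0} + sum_pos e^{-s}) + log(e^{s0} + sum_neg e^{s})
    l1 <- logsumexp(c(-s0, -s[i, pos]))
    l2 <- logsumexp(c(s0, s[i, !pos]))
    total <- total + l1 + l2
    grad[i, pos] <- -exp(-s[i, pos] - l1)
    grad[i, !pos] <- exp(s[i, !pos] - l2)
  }
  list(value = total / I, grad = grad / I)
}

#' Zero-bounded log-sum-exp pairwise rank (ZLPR) loss
#'
#' Per protein, with positive-term logits \eqn{s_i} and negative-term
#' logits \eqn{s_j} and a pseudo-threshold logit \eqn{s_0 = 0},
#' \deqn{L = \log\Big(e^{-s_0} + \sum_{i \in pos} e^{-s_i}\Big) +
#'       \log\Big(e^{s_0} + \sum_{j \in neg} e^{s_j}\Big),}
#' driving every positive logit above 0 and every negative logit below 0
#' while ranking positives above negatives jointly.  The returned value is
#' the mean per-protein loss.  Both log-sum-exp terms are evaluated
#' stably, so logits up to |s| = 500 do not overflow.
#'
#' @param y_true binary I x Q label matrix.
#' @param logits numeric I x Q matrix of unbounded network outputs.
#' @param s0 pseudo-threshold logit (default 0).
#' @return scalar loss, always >= 0 for `s0 = 0`.
#' @export
zlpr_loss <- function(y_true, logits, s0 = 0) {
  check_same_dim(y_true, logits, "y_true", "logits")
  stop_if_not_binary(y_true)
  if (!all(is.finite(logits))) stop("non-finite logits", call. = FALSE)
  zlpr_vg(y_true, logits, s0)$value
}

# BCE -----------------------------------------------------------------------

#' Binary cross-entropy over all matrix entries
#'
#' Mean over all (protein, term) cells of
#' \eqn{-[y \log p + (1-y)\log(1-p)]} with predictions clamped to
#' `[eps, 1 - eps]`.
#'
#' @param y_true binary I x Q label matrix.
#' @param y_pred numeric I x Q matrix of probabilities.
#' @param eps clamping constant.
#' @return scalar loss >= 0.
#' @export
bce_loss <- function(y_true, y_pred, eps = 1e-16) {
  check_same_dim(y_true, y_pred, "y_true", "y_pred")
  stop_if_not_binary(y_true)
  p <- pmin(pmax(y_pred, eps), 1 - eps)
  -mean(y_true * log(p) + (1 - y_true) * log(1 - p))
}

# value/grad wrt logits, using the stable softplus form
bce_vg <- function(y, s) {
  # -[y log sigma(s) + (1-y) log(1-sigma(s))] = softplus(s) - y s
  sp <- ifelse(s > 0, s + log1p(exp(-s)), log1p(exp(s)))
  n <- length(s)
  list(value = sum(sp - y * s) / n,
       grad = (sigmoid(s) - y) / n)
}

# Composite -----------------------------------------------------------------

component_vg <- function(comp, y, s, ia, eps, aggregate) {
  switch(comp,
    zlpr = zlpr_vg(y, s),
    bce = bce_vg(y, s),
    ptf1 = ,
    gof1 = {
      p <- sigmoid(s)
      r <- f1_vg(y, p, ia, eps, margin = if (comp == "ptf1") 1L else 2L,
                 aggregate = aggregate)
      r$grad <- r$grad * p * (1 - p)  # chain rule through the sigmoid
      r
    })
}

composite_vg <- function(y, s, ia, components, eps = 1e-16,
                         aggregate = "macro") {
  parts <- lapply(components, component_vg, y = y, s = s, ia = ia,
                  eps = eps, aggregate = aggregate)
  vals <- vapply(parts, `[[`, numeric(1), "value")
  value <- prod(vals)
  grad <- matrix(0, nrow(s), ncol(s))
  for (k in seq_along(parts)) {
    others <- prod(vals[-k])
    grad <- grad + others * parts[[k]]$grad
  }
  list(value = value, grad = grad, components = stats::setNames(vals, components))
}

#' Composite multiplicative training loss
#'
#' The product of the selected component losses, evaluated from raw
#' logits: the F1 and BCE components see the logistic transform
#' `sigmoid(logits)` while ZLPR operates on the logits directly.  The
#' default component set `c("zlpr", "ptf1", "gof1")` multiplies the ZLPR
#' rank loss with the protein-centric and term-centric IA-weighted F1
#' losses; any non-empty subset of `"zlpr"`, `"bce"`, `"ptf1"`, `"gof1"`
#' (or a single string like `"zlpr+ptf1+gof1"`) may be supplied, which is
#' how loss-ablation experiments are configured.
#'
#' @param y_true binary I x Q label matrix.
#' @param logits numeric I x Q matrix of network outputs.
#' @param ia IA weight per vocabulary term.
#' @param components character vector (or "+"-joined string) of components.
#' @param eps division guard for the F1/BCE factors.
#' @param aggregate F1 aggregation, see [protein_f1_loss()].
#' @return scalar loss; 0 iff some factor is 0.
#' @export
composite_loss <- function(y_true, logits, ia,
                           components = c("zlpr", "ptf1", "gof1"),
                           eps = 1e-16, aggregate = c("macro", "mean-f1")) {
  aggregate <- match.arg(aggregate)
  components <- normalize_components(components)
  check_same_dim(y_true, logits, "y_true", "logits")
  check_ia_length(ia, ncol(y_true))
  stop_if_not_binary(y_true)
  composite_vg(y_true, logits, ia, components, eps, aggregate)$value
}

#' Analytic gradient of the composite loss with respect to the logits
#'
#' Used by the optimiser; exposed so gradient correctness can be verified
#' against finite differences.
#'
#' @inheritParams composite_loss
#' @return I x Q gradient matrix.
#' @export
loss_gradient <- function(y_true, logits, ia,
                          components = c("zlpr", "ptf1", "gof1"),
                          eps = 1e-16, aggregate = c("macro", "mean-f1")) {
  aggregate <- match.arg(aggregate)
  components <- normalize_components(components)
  check_same_dim(y_true, logits, "y_true", "logits")
  check_ia_length(ia, ncol(y_true))
  stop_if_not_binary(y_true)
  composite_vg(y_true, logits, ia, components, eps, aggregate)$grad
}
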