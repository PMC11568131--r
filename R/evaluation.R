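# CAFA-style IA-weighted evaluation: weighted precision/recall over a
# score-threshold sweep, weighted Fmax, minimum semantic distance, area
# under the weighted precision-recall curve, and the naive
# term-frequency baseline.

#' @noRd
align_eval_matrices <- function(truth, scores, ia, roots = character(),
                                ontology = NULL) {
  truth <- as.matrix(truth)
  scores <- as.matrix(scores)
  if (!nrow(truth)) stop("empty benchmark: no proteins", call. = FALSE)
  if (is.null(colnames(truth)) || is.null(colnames(scores)))
    stop("truth and scores must have term column names", call. = FALSE)
  stop_if_not_binary(truth, "truth")
  common_prot <- rownames(truth)
  terms <- colnames(truth)
  if (!all(terms %in% names(ia)))
    stop("missing IA weight for some truth terms", call. = FALSE)
  if (!is.null(ontology)) {
    # truth must obey the true-path rule on every in-vocabulary edge
    e <- ontology$edges
    e <- e[e$child %in% terms & e$parent %in% terms, , drop = FALSE]
    if (nrow(e) && any(truth[, e$child, drop = FALSE] >
                         truth[, e$parent, drop = FALSE]))
      stop("truth is not propagated (child annotated without its parent)",
           call. = FALSE)
  }
  keep <- setdiff(terms, roots)
  S <- matrix(0, length(common_prot), length(keep),
              dimnames = list(common_prot, keep))
  sc_terms <- intersect(keep, colnames(scores))
  sc_prot <- intersect(common_prot, rownames(scores))
  S[sc_prot, sc_terms] <- scores[sc_prot, sc_terms]
  list(truth = truth[, keep, drop = FALSE], scores = S,
       ia = ia[keep])
}

#' @noRd
sweep_stats <- function(truth, scores, ia, thresholds) {
  W <- matrix(ia, nrow(truth), ncol(truth), byrow = TRUE)
  TIA <- truth * W
  truth_mass <- rowSums(TIA)
  out <- data.frame(threshold = thresholds, wpr = 0, wrc = 0,
                    ru = 0, mi = 0, n_covered = 0L)
  n <- nrow(truth)
  for (j in seq_along(thresholds)) {
    P <- scores >= thresholds[j]
    pred_mass <- rowSums(P * W)
    tp_mass <- rowSums(P * TIA)
    covered <- rowSums(P) > 0
    pr <- ifelse(pred_mass > 0, tp_mass / pred_mass, 0)
    rc <- ifelse(truth_mass > 0, tp_mass / truth_mass, 0)
    out$wpr[j] <- if (any(covered)) mean(pr[covered]) else 0
    out$wrc[j] <- mean(rc)
    out$ru[j] <- mean(truth_mass - tp_mass)
    out$mi[j] <- mean(pred_mass - tp_mass)
    out$n_covered[j] <- sum(covered)
  }
  out
}

#' IA-weighted precision and recall at one threshold
#'
#' A protein is *covered* at threshold t when it has at least one term
#' scored >= t.  Its weighted precision is the IA mass of true positives
#' over the IA mass of predictions; weighted precision is averaged over
#' covered proteins only, while weighted recall (true-positive IA mass
#' over truth IA mass) is averaged over all benchmark proteins — the CAFA
#' convention.
#'
#' @param truth binary protein x term matrix of propagated annotations.
#' @param scores numeric score matrix; rows/columns are matched to `truth`
#'   by name, missing entries count as 0.
#' @param ia named IA weight vector covering the truth terms.
#' @param t threshold in (0, 1].
#' @param roots term ids excluded from evaluation (aspect roots).
#' @param ontology optional `go_ontology` used to verify that `truth` is
#'   propagated.
#' @return list with `wpr`, `wrc`, `n_covered`.
#' @export
weighted_pr_at_threshold <- function(truth, scores, ia, t,
                                     roots = character(), ontology = NULL) {
  al <- align_eval_matrices(truth, scores, ia, roots, ontology)
  st <- sweep_stats(al$truth, al$scores, al$ia, t)
  list(wpr = st$wpr, wrc = st$wrc, n_covered = st$n_covered)
}

EVAL_THRESHOLDS <- seq(0.01, 1, by = 0.01)

#' Maximum IA-weighted F-measure over the threshold sweep
#'
#' Sweeps thresholds 0.01, 0.02, ..., 1.00 and returns the maximum of
#' \eqn{F(t) = 2\,wpr(t)\,wrc(t) / (wpr(t) + wrc(t))} (0 when both are 0)
#' together with the smallest threshold attaining it.
#'
#' @inheritParams weighted_pr_at_threshold
#' @return list with `value` and `threshold`.
#' @export
wfmax <- function(truth, scores, ia, roots = character(), ontology = NULL) {
  al <- align_eval_matrices(truth, scores, ia, roots, ontology)
  st <- sweep_stats(al$truth, al$scores, al$ia, EVAL_THRESHOLDS)
  f <- ifelse(st$wpr + st$wrc > 0, 2 * st$wpr * st$wrc / (st$wpr + st$wrc), 0)
  best <- which.max(f)  # smallest argmax
  list(value = f[best], threshold = st$threshold[best])
}

#' Minimum semantic distance over the threshold sweep
#'
#' At each threshold the remaining uncertainty ru(t) is the mean IA mass
#' of true-but-unpredicted terms and the misinformation mi(t) the mean IA
#' mass of predicted-but-false terms; the semantic distance is
#' \eqn{\sqrt{ru^2 + mi^2}} and its minimum over the sweep is returned.
#'
#' @inheritParams weighted_pr_at_threshold
#' @return list with `value` and `threshold` (smallest argmin).
#' @export
smin <- function(truth, scores, ia, roots = character(), ontology = NULL) {
  al <- align_eval_matrices(truth, scores, ia, roots, ontology)
  st <- sweep_stats(al$truth, al$scores, al$ia, EVAL_THRESHOLDS)
  s <- sqrt(st$ru^2 + st$mi^2)
  best <- which.min(s)
  list(value = s[best], threshold = st$threshold[best])
}

#' Area under the IA-weighted precision-recall curve
#'
#' Trapezoidal area of the (recall, precision) points traced by the
#' threshold sweep.  Thresholds where no protein has a prediction are
#' dropped; the curve is anchored at recall 0 with the precision of the
#' highest retained threshold, and points are integrated in order of
#' increasing recall.
#'
#' @inheritParams weighted_pr_at_threshold
#' @return scalar area in [0, 1].
#' @export
auwpr <- function(truth, scores, ia, roots = character(), ontology = NULL) {
  al <- align_eval_matrices(truth, scores, ia, roots, ontology)
  st <- sweep_stats(al$truth, al$scores, al$ia, EVAL_THRESHOLDS)
  st <- st[st$n_covered > 0L, , drop = FALSE]
  if (!nrow(st)) return(0)
  anchor_pr <- st$wpr[which.max(st$threshold)]
  r <- c(0, st$wrc)
  p <- c(anchor_pr, st$wpr)
  o <- order(r, p)
  r <- r[o]; p <- p[o]
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Naive term-frequency baseline
#'
#' Every query receives, for each vocabulary term, the fraction of
#' training proteins carrying that term (after propagation) — the
#' standard naive baseline of CAFA assessments.
#'
#' @param train_annotations a `go_propagated` table.
#' @param vocabulary a `go_vocabulary`.
#' @param queries character vector of query protein ids.
#' @return score matrix queries x vocabulary terms.
#' @export
naive_scores <- function(train_annotations, vocabulary, queries) {
  sub <- train_annotations[train_annotations$term %in% vocabulary$terms, ,
                           drop = FALSE]
  n_train <- length(unique(train_annotations$protein))
  if (n_train == 0L) stop("empty training set", call. = FALSE)
  counts <- tapply(sub$protein, factor(sub$term, levels = vocabulary$terms),
                   function(p) length(unique(p)))
  freq <- ifelse(is.na(counts), 0, counts) / n_train
  matrix(rep(freq, each = length(queries)), nrow = length(queries),
         dimnames = list(queries, vocabulary$terms))
}

#' Evaluate a prediction matrix against a benchmark
#'
#' Computes wFmax, Smin and AUWPR plus the full per-threshold curve.
#'
#' @inheritParams weighted_pr_at_threshold
#' @param aspect optional label stored in the result.
#' @return object of class `go_eval` with fields `wfmax`,
#'   `wfmax_threshold`, `smin`, `smin_threshold`, `auwpr`, `curve`.
#' @export
evaluate_predictions <- function(truth, scores, ia, roots = character(),
                                 ontology = NULL, aspect = NULL) {
  al <- align_eval_matrices(truth, scores, ia, roots, ontology)
  st <- sweep_stats(al$truth, al$scores, al$ia, EVAL_THRESHOLDS)
  f <- ifelse(st$wpr + st$wrc > 0, 2 * st$wpr * st$wrc / (st$wpr + st$wrc), 0)
  s <- sqrt(st$ru^2 + st$mi^2)
  cov <- st$n_covered > 0L
  area <- 0
  if (any(cov)) {
    stc <- st[cov, , drop = FALSE]
    anchor_pr <- stc$wpr[which.max(stc$threshold)]
    r <- c(0, stc$wrc); p <- c(anchor_pr, stc$wpr)
    o <- order(r, p)
    area <- sum(diff(r[o]) * (utils::head(p[o], -1) + utils::tail(p[o], -1)) / 2)
  }
  structure(list(aspect = aspect,
                 wfmax = f[which.max(f)],
                 wfmax_threshold = st$threshold[which.max(f)],
                 smin = s[which.min(s)],
                 smin_threshold = st$threshold[which.min(s)],
                 auwpr = area,
                 n_proteins = nrow(al$truth),
                 curve = cbind(st, f = f, sdist = s)),
            class = "go_eval")
}

#' @export
print.go_eval <- function(x, ...) {
  cat(sprintf("GO prediction evaluation%s (%d proteins)\n",
              if (!is.null(x$aspect)) paste0(" [", x$aspect, "]") else "",
              x$n_proteins))
  cat(sprintf("  wFmax = %.4f at t = %.2f\n", x$wfmax, x$wfmax_threshold))
  cat(sprintf("  Smin  = %.4f at t = %.2f\n", x$smin, x$smin_threshold))
  cat(sprintf("  AUWPR = %.4f\n", x$auwpr))
  invisible(x)
}

#' Write an evaluation report and its PR curve as TSV
#'
#' @param eval a `go_eval`.
#' @param path report path (metric, value, argthreshold); the PR curve is
#'   written next to it with suffix `"_curve.tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(eval, path) {
  df <- data.frame(
    metric = c("wfmax", "smin", "auwpr"),
    value = c(eval$wfmax, eval$smin, eval$auwpr),
    argthreshold = c(eval$wfmax_threshold, eval$smin_threshold, NA))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  curve_path <- paste0(sub("\\.tsv$", "", path), "_curve.tsv")
  utils::write.table(eval$curve, curve_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Prediction file IO --------------------------------------------------------

#' Write predictions as a CAFA-style TSV (protein, term, score)
#'
#' Scores are serialised with 3 decimal places; zero entries (after
#' rounding) are omitted.
#'
#' @param scores protein x term score matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(scores, path) {
  idx <- which(round(scores, 3) > 0, arr.ind = TRUE)
  df <- data.frame(protein = rownames(scores)[idx[, 1]],
                   term = colnames(scores)[idx[, 2]],
                   score = sprintf("%.3f", pmin(scores[idx], 1)))
  df <- df[order(df$protein, df$term), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a CAFA-style prediction TSV into a score matrix
#'
#' @param path input path (protein, term, score; no header).
#' @param proteins,terms optional row/column universes; defaults to those
#'   present in the file.
#' @return score matrix with absent entries as 0.
#' @export
read_predictions <- function(path, proteins = NULL, terms = NULL) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("protein", "term", "score"),
                          colClasses = c("character", "character", "numeric"))
  if (is.null(proteins)) proteins <- sort(unique(df$protein))
  if (is.null(terms)) terms <- sort(unique(df$term))
  m <- matrix(0, length(proteins), length(terms),
              dimnames = list(proteins, terms))
  keep <- df$protein %in% proteins & df$term %in% terms
  m[cbind(df$protein[keep], df$term[keep])] <- df$score[keep]
  m
}
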