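# Homology-based annotation transfer: parse aligner hit tables and turn
# them into per-term scores by bitscore-and-identity weighted voting over
# the annotated template proteins.
#
# Hit tables are tab-separated with columns qseqid, sseqid, bitscore,
# nident, qlen, slen — the dialect obtained from DIAMOND or BLAST with
#   --outfmt 6 qseqid sseqid bitscore nident qlen slen
# (DIAMOND) or -outfmt "6 qseqid sseqid bitscore nident qlen slen" (BLAST+).

HIT_COLUMNS <- c("qseqid", "sseqid", "bitscore", "nident", "qlen", "slen")

#' Parse an alignment hit table
#'
#' @param path tab-separated file with the six columns qseqid, sseqid,
#'   bitscore, nident, qlen, slen (no header).  Files with a different
#'   column count — e.g. the 12-column default outfmt 6 — are rejected.
#' @return data.frame of class `go_hits` with typed columns `query`,
#'   `subject`, `bitscore`, `nident`, `qlen`, `slen`.  Self-hits are
#'   retained; exclude them downstream where required.
#' @export
parse_hits <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- data.frame(query = character(), subject = character(),
                      bitscore = numeric(), nident = integer(),
                      qlen = integer(), slen = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("go_hits", "data.frame")
    return(out)
  }
  rows <- strsplit(lines, "\t", fixed = TRUE)
  badn <- lengths(rows) != 6L
  if (any(badn))
    stop(sprintf(paste("line %d has %d columns; expected the 6-column",
                       "dialect: %s"),
                 which(badn)[1L], lengths(rows)[which(badn)[1L]],
                 paste(HIT_COLUMNS, collapse = " ")), call. = FALSE)
  m <- do.call(rbind, rows)
  out <- data.frame(query = m[, 1], subject = m[, 2],
                    bitscore = as.numeric(m[, 3]),
                    nident = as.integer(m[, 4]),
                    qlen = as.integer(m[, 5]), slen = as.integer(m[, 6]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$bitscore) || anyNA(out$nident) || anyNA(out$qlen) ||
      anyNA(out$slen))
    stop("non-numeric value in a numeric hit-table column", call. = FALSE)
  if (any(out$bitscore < 0) || any(out$nident < 0))
    stop("negative bitscore or nident in hit table", call. = FALSE)
  if (any(out$qlen < 1) || any(out$slen < 1))
    stop("qlen and slen must be >= 1", call. = FALSE)
  if (any(out$nident > pmin(out$qlen, out$slen)))
    stop("nident exceeds min(qlen, slen)", call. = FALSE)
  class(out) <- c("go_hits", "data.frame")
  out
}

#' Write a hit table in the 6-column dialect
#' @param hits a `go_hits` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits[, c("query", "subject", "bitscore", "nident",
                              "qlen", "slen")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Sequence identity of an alignment hit
#'
#' Identity is the number of identical aligned residues divided by the
#' longer of the two sequences: `nident / max(qlen, slen)`.
#'
#' @param hits a `go_hits` data.frame (or any data.frame with `nident`,
#'   `qlen`, `slen`).
#' @return numeric vector of identities in [0, 1], one per hit.
#' @export
hit_identity <- function(hits) {
  hits$nident / pmax(hits$qlen, hits$slen)
}

#' Homology-transfer scores from a hit table
#'
#' For each query, every retained hit k votes for the (propagated) GO
#' terms of its subject with weight `bitscore_k * identity_k`; the score
#' of term q is the weighted fraction of hits whose subject carries q:
#' \deqn{S_{align}(q) = \frac{\sum_k bitscore_k\, ID_k\, 1(q \in T_k)}
#'                           {\sum_k bitscore_k\, ID_k}.}
#' Hits whose subject has no propagated training annotation in the
#' vocabulary's aspect are dropped before counting (their number is
#' reported via the `dropped_hits` attribute); queries left with no hits
#' get an all-zero row and are flagged in the `covered` attribute.
#'
#' @param hits a `go_hits` data.frame.
#' @param train_annotations a `go_propagated` table of template (training)
#'   annotations.
#' @param vocabulary a `go_vocabulary`.
#' @param queries optional character vector fixing the output rows;
#'   defaults to the queries present in `hits`.
#' @param exclude_self drop hits with query == subject (used when scoring
#'   training-set queries against their own template database).
#' @return score matrix queries x vocabulary terms with values in [0, 1];
#'   attributes `covered` (logical per query) and `dropped_hits` (count).
#' @export
knn_scores <- function(hits, train_annotations, vocabulary, queries = NULL,
                       exclude_self = FALSE) {
  terms <- vocabulary$terms
  aspect_terms <- train_annotations$term %in% terms
  ann <- train_annotations[aspect_terms, , drop = FALSE]
  term_sets <- split(ann$term, ann$protein)

  if (exclude_self) hits <- hits[hits$query != hits$subject, , drop = FALSE]
  # a hit only counts when its subject carries >= 1 vocabulary term
  known <- hits$subject %in% names(term_sets)
  dropped <- sum(!known)
  hits <- hits[known, , drop = FALSE]

  if (is.null(queries))
    queries <- sort(unique(hits$query))
  S <- matrix(0, length(queries), length(terms),
              dimnames = list(queries, terms))
  covered <- stats::setNames(logical(length(queries)), queries)

  if (nrow(hits)) {
    w <- hits$bitscore * hit_identity(hits)
    for (qy in intersect(queries, unique(hits$query))) {
      rows <- which(hits$query == qy)
      wq <- w[rows]
      tot <- sum(wq)
      if (tot <= 0) next
      num <- numeric(length(terms))
      names(num) <- terms
      for (r in seq_along(rows)) {
        ts <- term_sets[[hits$subject[rows[r]]]]
        num[ts] <- num[ts] + wq[r]
      }
      S[qy, ] <- pmin(pmax(num / tot, 0), 1)  # guard FP round-off
      covered[qy] <- TRUE
    }
  }
  attr(S, "covered") <- covered
  attr(S, "dropped_hits") <- dropped
  S
}
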