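# Sequence embeddings.  The network consumes, per protein, three
# fixed-length vectors (one per extracted hidden layer of an embedding
# backend, mean-pooled over residues).  A deterministic synthetic backend
# built from k-mer composition projections is included so the pipeline
# runs without any model download; a real protein language model can be
# plugged in as a user-supplied backend function.

AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

# Fixed random projections (D x 21) for layer l, k-mer offset j.  Seeded
# with a constant so the backend is bit-reproducible across sessions.
synthetic_projection <- function(dim, layer, offset) {
  with_local_seed(90000L + 100L * layer + offset,
                  matrix(stats::rnorm(dim * length(AA_ALPHABET)), dim,
                         length(AA_ALPHABET),
                         dimnames = list(NULL, AA_ALPHABET)))
}

# Residue-level embedding for one sequence and one layer: position i gets
# the sum of offset-specific projections of residues i..i+layer-1, so
# layer 1 sees single-residue composition, layers 2 and 3 see di- and
# tri-peptide context.
synthetic_layer_matrix <- function(chars, dim, layer) {
  L <- length(chars)
  M <- matrix(0, L, dim)
  for (j in seq_len(layer) - 1L) {
    P <- synthetic_projection(dim, layer, j)
    idx <- seq_len(L - j)
    M[idx, ] <- M[idx, ] + t(P[, chars[idx + j], drop = FALSE])
  }
  M
}

synthetic_backend <- function(dim) {
  force(dim)
  function(sequence) {
    chars <- strsplit(toupper(sequence), "")[[1]]
    chars[!chars %in% AA_ALPHABET] <- "X"
    lapply(1:3, function(l) synthetic_layer_matrix(chars, dim, l))
  }
}

#' Embed protein sequences with a pluggable backend
#'
#' A backend maps one sequence to three residue-level matrices (L x D, one
#' per extracted hidden layer); each matrix is mean-pooled over residues to
#' a single length-D vector.  The built-in `"synthetic"` backend derives
#' deterministic embeddings from k-mer composition under fixed random
#' projections — sequences with similar residue composition receive
#' similar embeddings, which is the property the downstream network
#' exploits.  Pass a function to use a real protein language model.
#'
#' @param sequences named character vector of amino-acid sequences, or the
#'   path of a FASTA file.
#' @param backend `"synthetic"`, or a function(sequence) returning a list
#'   of three L x D numeric matrices.  The `"plm"` name is reserved for a
#'   user-configured protein language model and errors if no function is
#'   supplied.
#' @param dim embedding dimension D of the synthetic backend.
#' @return object of class `go_embeddings`: list with `proteins`, `dim`,
#'   `layers = 3`, and `x`, an I x 3D matrix whose columns are the three
#'   layer blocks.
#' @export
embed_sequences <- function(sequences, backend = "synthetic", dim = 64) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences))
    sequences <- read_fasta(sequences)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be named by protein id", call. = FALSE)
  if (any(!nzchar(sequences)))
    stop("empty sequence for protein ",
         names(sequences)[which(!nzchar(sequences))[1L]], call. = FALSE)

  fn <- if (is.function(backend)) backend
  else if (identical(backend, "synthetic")) synthetic_backend(dim)
  else stop(sprintf(paste("backend '%s' is not available; supply a backend",
                          "function (sequence -> list of three L x D",
                          "matrices) or use 'synthetic'"), backend),
            call. = FALSE)

  rows <- lapply(sequences, function(s) {
    layers <- fn(s)
    if (length(layers) != 3L)
      stop("backend must return exactly 3 layer matrices", call. = FALSE)
    pooled <- lapply(layers, colMeans)
    d <- lengths(pooled)
    if (length(unique(d)) != 1L)
      stop("backend layers disagree on embedding dimension", call. = FALSE)
    unlist(pooled, use.names = FALSE)
  })
  x <- do.call(rbind, rows)
  if (!all(is.finite(x))) stop("non-finite embedding values", call. = FALSE)
  D <- ncol(x) / 3L
  rownames(x) <- names(sequences)
  structure(list(proteins = names(sequences), dim = D, layers = 3L, x = x),
            class = "go_embeddings")
}

#' @export
print.go_embeddings <- function(x, ...) {
  cat(sprintf("Embeddings: %d proteins, 3 layers x D = %d\n",
              length(x$proteins), x$dim))
  invisible(x)
}

#' Write an embedding bundle as TSV (protein, then 3D values)
#' @param embeddings a `go_embeddings`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path) {
  df <- data.frame(protein = embeddings$proteins,
                   embeddings$x, check.names = FALSE)
  names(df)[-1] <- paste0("e", seq_len(ncol(embeddings$x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an embedding bundle written by [write_embeddings()]
#' @param path TSV path.
#' @return a `go_embeddings`.
#' @export
read_embeddings <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  if (ncol(x) %% 3L != 0L)
    stop("embedding file width is not a multiple of 3", call. = FALSE)
  rownames(x) <- df$protein
  structure(list(proteins = df$protein, dim = ncol(x) %/% 3L, layers = 3L,
                 x = x), class = "go_embeddings")
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @return named character vector of sequences, named by the first token of
#'   each header.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write sequences as FASTA
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}
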