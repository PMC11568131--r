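# Internal numeric and validation helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Numerically stable log(sum(exp(x)))
#' @noRd
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Run code with a private, seeded RNG stream, restoring global state after.
#' @noRd
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_if_not_binary <- function(y, what = "y_true") {
  if (!all(y %in% c(0, 1)))
    stop(sprintf("`%s` must be binary (0/1)", what), call. = FALSE)
  invisible(y)
}

check_same_dim <- function(a, b, what_a, what_b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("dimensions of `%s` (%s) and `%s` (%s) differ",
                 what_a, paste(dim(a), collapse = "x"),
                 what_b, paste(dim(b), collapse = "x")), call. = FALSE)
  invisible(NULL)
}

check_ia_length <- function(ia, q) {
  if (length(ia) != q)
    stop(sprintf("`ia` has length %d but the matrices have %d columns",
                 length(ia), q), call. = FALSE)
  if (any(ia < 0)) stop("`ia` must be non-negative", call. = FALSE)
  invisible(NULL)
}

# Aspect vocabulary used throughout: MFO, BPO, CCO.
GO_ASPECTS <- c("MFO", "BPO", "CCO")

check_aspect <- function(aspect) {
  if (!is.character(aspect) || length(aspect) != 1L || !aspect %in% GO_ASPECTS)
    stop("`aspect` must be one of ", paste(GO_ASPECTS, collapse = ", "),
         call. = FALSE)
  aspect
}
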