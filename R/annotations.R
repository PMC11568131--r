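# Annotation records: parsing (GAF 2.x / simple TSV), experimental-evidence
# filtering, and chronological benchmark splitting with
# no-knowledge / limited-knowledge classification.

# GO evidence codes accepted as experimental.
EXPERIMENTAL_CODES <- c("IDA", "IPI", "EXP", "IGI", "IMP", "IEP", "IC", "TAS")

GAF_ASPECT <- c(F = "MFO", P = "BPO", C = "CCO")

#' Read protein GO annotations
#'
#' Two dialects are supported: GAF 2.x (columns 2 = object id, 5 = GO id,
#' 7 = evidence code, 9 = aspect letter F/P/C, 14 = date YYYYMMDD; lines
#' starting with "!" are skipped) and a simple 5-column TSV
#' (protein, term, evidence, date YYYY-MM-DD, aspect).
#'
#' @param path input file.
#' @param format `"gaf"` or `"tsv"`.
#' @return data.frame with columns `protein`, `term`, `evidence`,
#'   `date` (class Date), `aspect` (MFO/BPO/CCO).
#' @export
parse_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "!") & nzchar(lines)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  rowno <- which(keep)
  if (!length(rows))
    return(data.frame(protein = character(), term = character(),
                      evidence = character(), date = as.Date(character()),
                      aspect = character(), stringsAsFactors = FALSE))

  if (format == "gaf") {
    need <- 14L
    cols <- c(protein = 2L, term = 5L, evidence = 7L, aspect = 9L, date = 14L)
  } else {
    need <- 5L
    cols <- c(protein = 1L, term = 2L, evidence = 3L, date = 4L, aspect = 5L)
  }
  short <- lengths(rows) < need
  if (any(short))
    stop(sprintf("row %d has %d columns; %d required for format '%s'",
                 rowno[which(short)[1L]], lengths(rows)[which(short)[1L]],
                 need, format), call. = FALSE)
  field <- function(i) vapply(rows, `[[`, character(1), i)

  aspect_raw <- field(cols[["aspect"]])
  if (format == "gaf") {
    aspect <- unname(GAF_ASPECT[aspect_raw])
    if (anyNA(aspect))
      stop(sprintf("row %d: bad aspect letter '%s' (expected F/P/C)",
                   rowno[which(is.na(aspect))[1L]],
                   aspect_raw[which(is.na(aspect))[1L]]), call. = FALSE)
    date <- as.Date(field(cols[["date"]]), format = "%Y%m%d")
  } else {
    aspect <- aspect_raw
    bad <- !aspect %in% GO_ASPECTS
    if (any(bad))
      stop(sprintf("row %d: bad aspect '%s' (expected MFO/BPO/CCO)",
                   rowno[which(bad)[1L]], aspect_raw[which(bad)[1L]]),
           call. = FALSE)
    date <- as.Date(field(cols[["date"]]), format = "%Y-%m-%d")
  }
  if (anyNA(date))
    stop(sprintf("row %d: unparseable date '%s'",
                 rowno[which(is.na(date))[1L]],
                 field(cols[["date"]])[which(is.na(date))[1L]]),
         call. = FALSE)

  data.frame(protein = field(cols[["protein"]]),
             term = field(cols[["term"]]),
             evidence = field(cols[["evidence"]]),
             date = date, aspect = aspect, stringsAsFactors = FALSE)
}

#' Write annotations as the simple 5-column TSV dialect
#'
#' @param table annotation data.frame as returned by [parse_annotations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(table, path) {
  out <- data.frame(table$protein, table$term, table$evidence,
                    format(table$date, "%Y-%m-%d"), table$aspect)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Keep only experimentally supported annotations
#'
#' Retains records whose evidence code is one of IDA, IPI, EXP, IGI, IMP,
#' IEP, IC, TAS (exact, case-sensitive match); everything else — IEA, ISS,
#' unknown codes — is dropped.
#'
#' @param table annotation data.frame.
#' @return the filtered data.frame.
#' @export
filter_experimental <- function(table) {
  out <- table[table$evidence %in% EXPERIMENTAL_CODES, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chronological benchmark split for one aspect
#'
#' Training proteins are those with at least one experimental annotation in
#' the target aspect dated on or before `t0`.  A protein enters the
#' validation (test) set when its first experimental annotation in the
#' aspect falls in the window (t0, t1] ((t1, t2]).  Each validation/test
#' protein is labelled *no-knowledge* if it had no experimental annotation
#' in any aspect at or before the window start, and *limited-knowledge* if
#' it had experimental annotations in at least one other aspect by then but
#' none in the target aspect.
#'
#' @param table experimental annotation data.frame covering all aspects
#'   (apply [filter_experimental()] first).
#' @param t0,t1,t2 window boundaries (coercible to Date), strictly
#'   increasing.
#' @param aspect target aspect (MFO/BPO/CCO).
#' @return list of class `go_split`: `aspect`, `train`, `validation`,
#'   `test` (character vectors of protein ids) and `knowledge`, a
#'   data.frame (protein, partition, knowledge) for validation and test.
#' @export
build_time_split <- function(table, t0, t1, t2, aspect) {
  check_aspect(aspect)
  t0 <- as.Date(t0); t1 <- as.Date(t1); t2 <- as.Date(t2)
  if (!(t0 < t1 && t1 < t2))
    stop("window boundaries must satisfy t0 < t1 < t2", call. = FALSE)

  in_aspect <- table$aspect == aspect
  first_in <- tapply(table$date[in_aspect], table$protein[in_aspect], min)
  first_in <- as.Date(first_in, origin = "1970-01-01")
  first_other <- tapply(table$date[!in_aspect], table$protein[!in_aspect], min)
  first_other <- as.Date(first_other, origin = "1970-01-01")

  train <- sort(names(first_in)[first_in <= t0])
  validation <- sort(names(first_in)[first_in > t0 & first_in <= t1])
  test <- sort(names(first_in)[first_in > t1 & first_in <= t2])
  stopifnot(!any(validation %in% test), !any(train %in% c(validation, test)))

  knowledge_of <- function(proteins, start) {
    if (!length(proteins)) return(character())
    other <- first_other[proteins]
    unname(ifelse(!is.na(other) & other <= start,
                  "limited-knowledge", "no-knowledge"))
  }
  kn <- data.frame(
    protein = c(validation, test),
    partition = rep(c("validation", "test"), c(length(validation), length(test))),
    knowledge = c(knowledge_of(validation, t0), knowledge_of(test, t1)),
    stringsAsFactors = FALSE)

  structure(list(aspect = aspect, train = train, validation = validation,
                 test = test, knowledge = kn, t0 = t0, t1 = t1, t2 = t2),
            class = "go_split")
}

#' @export
print.go_split <- function(x, ...) {
  cat(sprintf("Chronological %s split: %d train, %d validation, %d test\n",
              x$aspect, length(x$train), length(x$validation),
              length(x$test)))
  if (nrow(x$knowledge))
    print(table(x$knowledge$partition, x$knowledge$knowledge))
  invisible(x)
}

#' Write a split manifest as TSV (protein, aspect, partition, knowledge)
#'
#' @param split a `go_split`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  kn <- stats::setNames(split$knowledge$knowledge, split$knowledge$protein)
  prot <- c(split$train, split$validation, split$test)
  part <- rep(c("train", "validation", "test"),
              c(length(split$train), length(split$validation),
                length(split$test)))
  lab <- ifelse(part == "train", "-", unname(kn[prot]))
  utils::write.table(
    data.frame(prot, split$aspect, part, lab),
    path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = c("protein", "aspect", "partition", "knowledge"))
  invisible(path)
}
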