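`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a surface word form for matching
#'
#' Lower-cases, trims whitespace and strips punctuation. Used everywhere a
#' human guess, a model candidate and a corpus target must be compared
#' like-for-like: top-k accuracy, cloze response scoring, type counting and
#' frequency-table lookup all share this one matcher.
#'
#' @param x character vector of surface forms.
#' @return character vector of normalized forms.
#' @export
#' @examples
#' normalize_word(c("The", "don't!", " brain."))
normalize_word <- function(x) {
  gsub("[[:punct:]]", "", tolower(trimws(as.character(x))))
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a delimited table with separator autodetection
#'
#' Tab- and comma-separated files are both accepted; the separator is taken
#' from the header line unless given explicitly.
#'
#' @param path file path.
#' @param sep field separator; autodetected when `NULL`.
#' @return a tibble.
#' @export
read_table_auto <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% detect_sep(path)
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = sep,
    quote = "\"", stringsAsFactors = FALSE, check.names = FALSE,
    comment.char = "", fileEncoding = "UTF-8"))
}

#' Write a delimited table (UTF-8, header row)
#'
#' @param x data frame to write. List columns are not supported; flatten
#'   prediction states with [metrics_to_table()] first.
#' @param path output path.
#' @param sep field separator, tab by default.
#' @return `path`, invisibly.
#' @export
write_table_utf8 <- function(x, path, sep = "\t") {
  if (any(vapply(x, is.list, logical(1)))) {
    stop("cannot write list columns; flatten the table first")
  }
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = TRUE,
    fileEncoding = "UTF-8")
  invisible(path)
}

#' Cosine similarity between two vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return cosine of the angle between `a` and `b`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) {
    stop("cosine similarity is undefined for a zero-norm vector")
  }
  sum(a * b) / (na * nb)
}
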