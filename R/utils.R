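#' One-decimal truncated percentage
#'
#' Every percentage the package prints uses the same convention: the value is
#' floored (truncated), not rounded, to one decimal place. Under this
#' convention the published precision/recall/F1 table and the headline corpus
#' proportions recompute exactly from their integer counts.
#'
#' @param count numerator count.
#' @param denominator denominator count (> 0).
#' @return `100 * count / denominator` truncated to one decimal.
#' @examples
#' pct_of(13671, 34481) # 39.6
#' pct_of(62, 68)       # 91.1 (not 91.2)
#' @export
pct_of <- function(count, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive", call. = FALSE)
  trunc1(100 * count / denominator)
}

# floor to one decimal; the epsilon guards values that are exact decimals but
# sit just below them in binary floating point (e.g. 100 * 0.5 * ...)
trunc1 <- function(x) floor(x * 10 + 1e-9) / 10

# number of whitespace-delimited tokens in a string (NA-safe, "" -> 0)
n_tokens <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(0L)
  length(regmatches(x, gregexpr("\\S+", x))[[1]])
}

split_tokens <- function(x) {
  if (!nzchar(trimws(x))) return(character(0))
  strsplit(trimws(x), "\\s+")[[1]]
}

# is `small` a contiguous token subsequence of `big`?
tokens_contained <- function(small, big) {
  ns <- length(small)
  nb <- length(big)
  if (ns == 0L || ns > nb) return(FALSE)
  for (i in seq_len(nb - ns + 1L)) {
    if (all(big[i:(i + ns - 1L)] == small)) return(TRUE)
  }
  FALSE
}

# JSON-lines helpers -----------------------------------------------------

#' Write a data frame as JSON lines
#'
#' One JSON object per row; list-columns become JSON arrays.
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(x, path) {
  lines <- vapply(seq_len(nrow(x)), function(i) {
    row <- lapply(x[i, , drop = FALSE], function(col) {
      v <- if (is.list(col)) col[[1]] else col
      v
    })
    jsonlite::toJSON(row, auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON-lines file
#'
#' @param path input file path.
#' @return a tibble with one row per line; array fields become list-columns.
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(tibble::tibble())
  rows <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  fields <- unique(unlist(lapply(rows, names)))
  cols <- lapply(fields, function(f) {
    vals <- lapply(rows, function(r) if (is.null(r[[f]])) NA else r[[f]])
    scalar <- all(vapply(vals, function(v) length(v) == 1L && !is.list(v), logical(1)))
    if (scalar) unlist(vals) else vals
  })
  names(cols) <- fields
  tibble::as_tibble(cols)
}
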