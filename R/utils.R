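#' Normalize a surface form
#'
#' Lowercases, collapses internal whitespace to single spaces, trims, and
#' strips trailing sentence punctuation. This is the canonical form under
#' which all dictionary lookups are performed, so that case variants and
#' spacing variants of the same mention collide on one index key.
#'
#' @param x character vector of surface strings.
#' @return character vector of normalized forms.
#' @export
normalize_surface <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[[:space:]]+", " ", x)
  sub("[.,;:!?]+$", "", x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a tab-separated table
#'
#' Fixed dialect used throughout the package: tab-separated, UTF-8, header
#' row, no quoting.
#'
#' @param path file path.
#' @param required_cols character vector of column names that must be present;
#'   a missing column aborts naming the file.
#' @return data.frame with character columns (no factor coercion).
#' @export
read_tsv_table <- function(path, required_cols = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8", comment.char = "")
  if (!is.null(required_cols)) {
    missing <- setdiff(required_cols, names(df))
    if (length(missing)) {
      stop(sprintf("malformed table %s (line 1): missing column(s) %s",
                   path, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  df
}

#' Write a tab-separated table
#'
#' @param df data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Escape a literal string for use inside a PCRE pattern.
regex_escape <- function(x) {
  gsub("([][\\\\^$.|?*+(){}])", "\\\\\\1", x)
}

# Empty data.frame with the given (typed) prototype columns.
empty_df <- function(proto) {
  proto[0L, , drop = FALSE]
}
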