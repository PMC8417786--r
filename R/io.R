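# Corpus (JSONL) and evidence serialization.

#' Write a document corpus as JSONL
#'
#' One JSON object per line with fields `doc_id`, `title`, `abstract`,
#' `sections` (list of `{name, text}`), `pub_year`, `is_review`,
#' `has_fulltext`, `source`.
#'
#' @param documents list of document records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(documents, path) {
  lines <- vapply(documents, function(d) {
    as.character(jsonlite::toJSON(d, auto_unbox = TRUE, null = "null"))
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a document corpus from JSONL
#'
#' @param path JSONL file path.
#' @return list of document records.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  docs <- lapply(seq_along(lines), function(i) {
    d <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                  error = function(e) {
                    stop(sprintf("malformed corpus %s (line %d): %s",
                                 path, i, conditionMessage(e)), call. = FALSE)
                  })
    if (is.null(d$doc_id) || is.null(d$title) || !nzchar(d$title)) {
      stop(sprintf("malformed corpus %s (line %d): doc_id/title required",
                   path, i), call. = FALSE)
    }
    yr <- d$pub_year %||% NA_integer_
    if (!is.na(yr) && (yr < 1900 ||
                       yr > as.integer(format(Sys.Date(), "%Y")))) {
      stop(sprintf("malformed corpus %s (line %d): pub_year out of range",
                   path, i), call. = FALSE)
    }
    d$sections <- lapply(d$sections %||% list(), function(s) {
      list(name = s$name, text = s$text %||% "")
    })
    d
  })
  docs
}

#' Write relation triples as JSONL evidence
#'
#' @param relations data.frame of (filtered) relation triples.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(relations, path) {
  if (!nrow(relations)) {
    writeLines(character(), path, useBytes = TRUE)
    return(invisible(path))
  }
  lines <- vapply(seq_len(nrow(relations)), function(i) {
    as.character(jsonlite::toJSON(as.list(relations[i, , drop = FALSE]),
                                  auto_unbox = TRUE, dataframe = "rows"))
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
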