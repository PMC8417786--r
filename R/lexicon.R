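# Concept dictionaries (diseases, metabolites, mutated genes/proteins,
# cytokines, transcription factors) with linguistic variant expansion and
# gene-symbol normalization.

.greek_map <- c(
  "α" = "alpha",   "β" = "beta",  "γ" = "gamma",
  "δ" = "delta",   "ε" = "epsilon", "ζ" = "zeta",
  "η" = "eta",     "θ" = "theta", "ι" = "iota",
  "κ" = "kappa",   "λ" = "lambda", "μ" = "mu",
  "ν" = "nu",      "ξ" = "xi",    "ο" = "omicron",
  "π" = "pi",      "ρ" = "rho",   "σ" = "sigma",
  "τ" = "tau",     "υ" = "upsilon", "φ" = "phi",
  "χ" = "chi",     "ψ" = "psi",   "ω" = "omega"
)

.lexicon_categories <- c("disease", "metabolite", "gene_protein", "cytokine", "tf")
.disease_tags <- c("GD", "FD", "ASMD", "none")

# Replace every Greek character by its spelled-out English name.
.greek_to_spelled <- function(x) {
  for (i in seq_along(.greek_map)) {
    x <- gsub(names(.greek_map)[i], .greek_map[[i]], x, fixed = TRUE)
  }
  x
}

# Replace whole tokens that are spelled-out Greek names by the Greek letter.
# Token boundaries are spaces and hyphens; fused occurrences are left alone
# so that expansion stays idempotent.
.spelled_to_greek <- function(x) {
  toks <- regmatches(x, gregexpr("[^ -]+|[ -]", x))[[1]]
  rev_map <- stats::setNames(names(.greek_map), .greek_map)
  hit <- toks %in% names(rev_map)
  if (!any(hit)) return(x)
  toks[hit] <- rev_map[toks[hit]]
  paste(toks, collapse = "")
}

# Closure of a normalized string under Greek letter <-> spelled-name
# substitution (both directions, applied until no new form appears).
.greek_closure <- function(s) {
  seen <- character()
  frontier <- s
  while (length(frontier)) {
    seen <- union(seen, frontier)
    nxt <- unique(unlist(lapply(frontier, function(x) {
      c(.greek_to_spelled(x), .spelled_to_greek(x))
    })))
    frontier <- setdiff(nxt, seen)
  }
  seen
}

# All separator alternations of a string: tokens split on runs of spaces and
# hyphens, rejoined with every combination of " ", "-", "" (capped at four
# separators; beyond that only the three uniform variants are produced).
.separator_variants <- function(x) {
  toks <- strsplit(x, "[ -]+")[[1]]
  toks <- toks[nzchar(toks)]
  k <- length(toks) - 1L
  if (k <= 0L) return(x)
  if (k <= 4L) {
    seps <- c(" ", "-", "")
    grid <- expand.grid(rep(list(seps), k), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    out <- apply(grid, 1L, function(ss) {
      pieces <- character(2L * length(toks) - 1L)
      pieces[seq(1L, by = 2L, length.out = length(toks))] <- toks
      pieces[seq(2L, by = 2L, length.out = k)] <- unlist(ss)
      paste(pieces, collapse = "")
    })
  } else {
    out <- c(paste(toks, collapse = " "), paste(toks, collapse = "-"),
             paste(toks, collapse = ""))
  }
  unique(c(x, out))
}

#' Expand a synonym into its linguistic variants
#'
#' Returns the closure of the (normalized) input under three alternations
#' used by the dictionary matcher: hyphen/space/fused separator alternation
#' ("interleukin-6" / "interleukin 6" / "interleukin6"), Greek letter vs
#' spelled-out English name ("α" vs "alpha"), and case-insensitive
#' canonical form. The input itself (normalized) is always included. The
#' expansion is deterministic and idempotent: expanding any returned variant
#' adds nothing new.
#'
#' @param synonym a single non-empty string.
#' @return sorted character vector of normalized variant forms.
#' @examples
#' expand_variants("IFN-γ")
#' expand_variants("neimann-pick")
#' @export
expand_variants <- function(synonym) {
  stopifnot(is.character(synonym), length(synonym) == 1L)
  if (!nzchar(trimws(synonym))) stop("synonym must be non-empty", call. = FALSE)
  s <- normalize_surface(synonym)
  base <- .greek_closure(s)
  sort(unique(unlist(lapply(base, .separator_variants))))
}

.slugify <- function(x) gsub("[^a-z0-9]+", "_", normalize_surface(x))

#' Build a concept lexicon from per-category synonym tables
#'
#' One entry is created per (canonical_name, category, disease_tag) triple;
#' rows sharing the triple contribute synonyms to the same entry. Every
#' synonym (and the canonical name) is variant-expanded with
#' [expand_variants()] and indexed under its normalized form. Cytokine
#' entries whose rows carry zero or more than one distinct gene symbol are
#' flagged ambiguous and carry no symbol; such names are excluded from all
#' downstream gene-level analyses.
#'
#' @param tables a data.frame, a list of data.frames, or a character vector
#'   of TSV file paths. Required columns: `canonical_name`, `synonym`,
#'   `category` (one of disease, metabolite, gene_protein, cytokine, tf),
#'   `disease_tag` (GD, FD, ASMD or none); optional `gene_symbol`.
#' @return an object of class `lexicon`: list with `entries` (named list of
#'   entry records) and `index` (named list mapping normalized surface form
#'   to entry ids).
#' @export
build_lexicon <- function(tables) {
  if (is.character(tables)) {
    tables <- lapply(tables, read_tsv_table,
                     required_cols = c("canonical_name", "synonym",
                                       "category", "disease_tag"))
  }
  if (is.data.frame(tables)) tables <- list(tables)
  tbl <- do.call(rbind, lapply(tables, function(t) {
    if (!"gene_symbol" %in% names(t)) t$gene_symbol <- NA_character_
    t[, c("canonical_name", "synonym", "category", "disease_tag", "gene_symbol")]
  }))
  if (is.null(tbl) || !nrow(tbl)) {
    warning("empty lexicon source: building an empty lexicon")
    return(structure(list(entries = list(), index = list()), class = "lexicon"))
  }
  bad_cat <- setdiff(unique(tbl$category), .lexicon_categories)
  if (length(bad_cat)) {
    stop("unknown category: ", paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  tbl$disease_tag[is.na(tbl$disease_tag) | !nzchar(tbl$disease_tag)] <- "none"
  bad_tag <- setdiff(unique(tbl$disease_tag), .disease_tags)
  if (length(bad_tag)) {
    stop("unknown disease_tag: ", paste(bad_tag, collapse = ", "), call. = FALSE)
  }
  present <- setdiff(.lexicon_categories, c("tf"))
  for (cat in present) {
    if (!any(tbl$category == cat)) {
      warning("lexicon has no entries of category '", cat, "'")
    }
  }

  key <- paste(tbl$category, tbl$disease_tag, .slugify(tbl$canonical_name), sep = ":")
  entries <- list()
  for (k in unique(key)) {
    rows <- tbl[key == k, , drop = FALSE]
    canon <- rows$canonical_name[1L]
    cat <- rows$category[1L]
    tag <- rows$disease_tag[1L]
    raw <- unique(c(canon, rows$synonym))
    raw <- trimws(raw[!is.na(raw) & nzchar(trimws(raw))])
    raw <- raw[nchar(raw) >= 2L]
    syns <- sort(unique(unlist(lapply(raw, expand_variants))))
    cand <- unique(rows$gene_symbol[!is.na(rows$gene_symbol) &
                                      nzchar(rows$gene_symbol)])
    if (cat == "cytokine") {
      ambiguous <- length(cand) != 1L
      symbol <- if (ambiguous) NA_character_ else cand
    } else {
      if (length(cand) > 1L) {
        stop(sprintf(
          "conflicting entries for '%s' (%s/%s): gene symbols %s",
          canon, cat, tag, paste(cand, collapse = ", ")), call. = FALSE)
      }
      ambiguous <- FALSE
      symbol <- if (length(cand)) cand else NA_character_
    }
    entries[[k]] <- list(entry_id = k, canonical_name = canon, category = cat,
                         disease_tag = tag, synonyms = syns,
                         gene_symbol = symbol, ambiguous = ambiguous)
  }
  entries <- entries[order(names(entries))]

  forms <- lapply(entries, `[[`, "synonyms")
  idx_df <- data.frame(
    form = unlist(forms, use.names = FALSE),
    id = rep(vapply(entries, `[[`, "", "entry_id"),
             vapply(forms, length, 0L)),
    stringsAsFactors = FALSE)
  index <- lapply(split(idx_df$id, idx_df$form), unique)
  structure(list(entries = entries, index = index), class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cats <- table(vapply(x$entries, `[[`, "", "category"))
  cat("<lexicon> ", length(x$entries), " entries, ",
      length(x$index), " indexed surface forms\n", sep = "")
  if (length(cats)) {
    cat(paste(sprintf("  %s: %d", names(cats), as.integer(cats)),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Entries of a lexicon as a data.frame
#'
#' @param lexicon a `lexicon` object.
#' @param category optional category filter.
#' @param disease_tag optional disease-tag filter.
#' @return data.frame with one row per entry (synonyms collapsed with `|`).
#' @export
lexicon_entries <- function(lexicon, category = NULL, disease_tag = NULL) {
  es <- lexicon$entries
  if (!length(es)) {
    return(data.frame(entry_id = character(), canonical_name = character(),
                      category = character(), disease_tag = character(),
                      gene_symbol = character(), ambiguous = logical(),
                      n_synonyms = integer(), synonyms = character(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    entry_id = vapply(es, `[[`, "", "entry_id"),
    canonical_name = vapply(es, `[[`, "", "canonical_name"),
    category = vapply(es, `[[`, "", "category"),
    disease_tag = vapply(es, `[[`, "", "disease_tag"),
    gene_symbol = vapply(es, function(e) e$gene_symbol %||% NA_character_, ""),
    ambiguous = vapply(es, `[[`, TRUE, "ambiguous"),
    n_synonyms = vapply(es, function(e) length(e$synonyms), 0L),
    synonyms = vapply(es, function(e) paste(e$synonyms, collapse = "|"), ""),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(category)) df <- df[df$category %in% category, , drop = FALSE]
  if (!is.null(disease_tag)) df <- df[df$disease_tag %in% disease_tag, , drop = FALSE]
  df
}

#' Map a cytokine name to its gene symbol
#'
#' Looks the (variant-expanded) name up among cytokine entries. Names that
#' match no cytokine entry return `"UNMAPPED"`; names whose entry is flagged
#' ambiguous (no unique gene symbol in the registry) return `"AMBIGUOUS"`.
#' Downstream stages drop both.
#'
#' @param name a cytokine surface name.
#' @param lexicon a `lexicon` object.
#' @return the gene symbol, `"UNMAPPED"`, or `"AMBIGUOUS"`.
#' @examples
#' # map_cytokine_to_symbol("erythropoietin", lex)  # "EPO"
#' @export
map_cytokine_to_symbol <- function(name, lexicon) {
  forms <- tryCatch(expand_variants(name), error = function(e) normalize_surface(name))
  ids <- unique(unlist(lexicon$index[forms]))
  if (!length(ids)) return("UNMAPPED")
  es <- lexicon$entries[ids]
  es <- Filter(function(e) e$category == "cytokine", es)
  if (!length(es)) return("UNMAPPED")
  e <- es[[1L]]
  if (isTRUE(e$ambiguous)) return("AMBIGUOUS")
  e$gene_symbol
}

#' All dictionary cytokines mapped to a human gene symbol
#'
#' The universe used for overrepresentation tests: every cytokine entry of
#' the dictionary that carries an unambiguous gene symbol. Membership is
#' dictionary-based, not atlas-based; genes absent from the expression atlas
#' stay in the universe.
#'
#' @param lexicon a `lexicon` object.
#' @return character vector of gene symbols.
#' @export
cytokine_universe <- function(lexicon) {
  df <- lexicon_entries(lexicon, category = "cytokine")
  sort(unique(df$gene_symbol[!df$ambiguous & !is.na(df$gene_symbol)]))
}

#' Serialize a lexicon to JSON
#'
#' @param lexicon a `lexicon` object.
#' @param path output path; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to file).
#' @export
write_lexicon_json <- function(lexicon, path = NULL) {
  js <- jsonlite::toJSON(list(entries = unname(lexicon$entries),
                              index = lexicon$index),
                         auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path, useBytes = TRUE)
  invisible(js)
}
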