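# Sentence segmentation, dictionary entity tagging, directional
# effector-verb-affected relation extraction, filtering rules, and
# per-disease aggregation of cytokine evidence.

.abbreviations <- c("al", "fig", "figs", "ref", "refs", "eg", "ie", "vs",
                    "etc", "ca", "approx", "dr", "prof", "inc", "st",
                    "no", "nos", "resp", "cf")

#' Default trigger-verb list
#'
#' Verbal associations accepted as relation triggers. Shipped as a plain
#' text config file (`inst/extdata/trigger_verbs.txt`, one per line) so the
#' list can be swapped without code changes.
#'
#' @return character vector of lowercase trigger words/phrases.
#' @export
default_trigger_verbs <- function() {
  path <- system.file("extdata", "trigger_verbs.txt", package = "cytolit")
  verbs <- readLines(path, encoding = "UTF-8", warn = FALSE)
  verbs <- trimws(verbs)
  verbs[nzchar(verbs) & !startsWith(verbs, "#")]
}

#' Default methods-like section names
#'
#' Sentences from these sections are excluded from relation mining (their
#' information content is low: protocol text rather than findings).
#' Matching is on the normalized section name.
#'
#' @return character vector of normalized section names.
#' @export
default_methods_sections <- function() {
  c("methods", "materials and methods", "material and methods",
    "experimental procedures", "star methods")
}

#' Segment a document into sentences
#'
#' The title and abstract are treated as sections named `"title"` and
#' `"abstract"`; body sections are used only when the full text is
#' available. Splitting is rule-based and abbreviation-safe: a boundary is
#' a run of `.!?` followed by whitespace and an upper-case letter or digit,
#' unless the preceding word is a known abbreviation (e.g. "et al.",
#' "Fig."). Offsets are 0-based half-open into the section text, and every
#' sentence's text equals the corresponding section slice.
#'
#' @param document a document record (list with `doc_id`, `title`,
#'   `abstract`, `sections`, `pub_year`, `is_review`, `has_fulltext`,
#'   `source`); see [read_corpus()].
#' @return data.frame with columns `doc_id`, `section_name`, `text`,
#'   `start`, `end`, `source`.
#' @export
segment_sentences <- function(document) {
  secs <- list(c("title", document$title %||% ""),
               c("abstract", document$abstract %||% ""))
  if (isTRUE(document$has_fulltext) && length(document$sections)) {
    for (s in document$sections) {
      secs <- c(secs, list(c(s$name %||% s[[1L]], s$text %||% s[[2L]])))
    }
  }
  out <- lapply(secs, function(s) {
    df <- split_sentences(s[[2L]])
    if (nrow(df)) df$section_name <- s[[1L]]
    df
  })
  out <- do.call(rbind, out[vapply(out, nrow, 0L) > 0L])
  if (is.null(out)) {
    return(data.frame(doc_id = character(), section_name = character(),
                      text = character(), start = integer(), end = integer(),
                      source = character(), stringsAsFactors = FALSE))
  }
  out$doc_id <- document$doc_id
  out$source <- document$source %||% "pubmed"
  out[, c("doc_id", "section_name", "text", "start", "end", "source")]
}

#' Split raw text into sentence spans
#'
#' @param text a single string.
#' @return data.frame with `text`, `start`, `end` (0-based half-open
#'   offsets into `text`).
#' @export
split_sentences <- function(text) {
  proto <- data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(proto)
  m <- gregexpr("[.!?]+(?=[ \t\r\n]+[\"'(\\[]?[A-Z0-9])", text, perl = TRUE)[[1L]]
  cuts <- integer()
  if (m[1L] != -1L) {
    for (j in seq_along(m)) {
      p <- m[j]
      len <- attr(m, "match.length")[j]
      prefix <- substr(text, 1L, p - 1L)
      tok <- regmatches(prefix, regexpr("[A-Za-z]+$", prefix))
      if (length(tok) && tolower(tok) %in% .abbreviations) next
      cuts <- c(cuts, p + len)  # first char after punctuation run (1-based)
    }
  }
  bounds <- c(1L, cuts, nchar(text) + 1L)
  rows <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L] - 1L
    if (b < a) next
    piece <- substr(text, a, b)
    lead <- nchar(piece) - nchar(sub("^[[:space:]]+", "", piece))
    trail <- nchar(piece) - nchar(sub("[[:space:]]+$", "", piece))
    a2 <- a + lead; b2 <- b - trail
    if (b2 < a2) next
    rows[[length(rows) + 1L]] <- data.frame(
      text = substr(text, a2, b2), start = a2 - 1L, end = b2,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(proto)
  do.call(rbind, rows)
}

.key_pattern <- function(key) {
  esc <- regex_escape(key)
  esc <- gsub(" ", "[[:space:]]+", esc, fixed = TRUE)
  paste0("(?<![[:alnum:]])", esc, "(?![[:alnum:]])")
}

#' Tag lexicon entities in a sentence
#'
#' Dictionary matching is case-insensitive on the normalized text, at word
#' boundaries only, greedy longest-match left-to-right: at each position the
#' longest matching surface form wins, and matches never overlap. Each
#' mention carries its entry's category and disease tag.
#'
#' @param sentence_text the sentence string.
#' @param lexicon a `lexicon` object.
#' @return data.frame with `start`, `end` (0-based half-open offsets within
#'   the sentence), `surface`, `entry_id`, `category`, `disease_tag`.
#' @export
tag_entities <- function(sentence_text, lexicon) {
  proto <- data.frame(start = integer(), end = integer(), surface = character(),
                      entry_id = character(), category = character(),
                      disease_tag = character(), stringsAsFactors = FALSE)
  if (!nzchar(sentence_text) || !length(lexicon$index)) return(proto)
  low <- tolower(sentence_text)
  cand <- list()
  for (key in names(lexicon$index)) {
    m <- gregexpr(.key_pattern(key), low, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    lens <- attr(m, "match.length")
    for (j in seq_along(m)) {
      cand[[length(cand) + 1L]] <- c(start = m[j] - 1L, len = lens[j],
                                     key = key)
    }
  }
  if (!length(cand)) return(proto)
  cd <- data.frame(start = as.integer(vapply(cand, `[[`, "", "start")),
                   len = as.integer(vapply(cand, `[[`, "", "len")),
                   key = vapply(cand, `[[`, "", "key"),
                   stringsAsFactors = FALSE)
  cd <- cd[order(cd$start, -cd$len), , drop = FALSE]
  picked <- list()
  cursor <- -1L
  for (i in seq_len(nrow(cd))) {
    if (cd$start[i] < cursor) next
    picked[[length(picked) + 1L]] <- cd[i, ]
    cursor <- cd$start[i] + cd$len[i]
  }
  pd <- do.call(rbind, picked)
  rows <- lapply(seq_len(nrow(pd)), function(i) {
    id <- lexicon$index[[pd$key[i]]][1L]
    e <- lexicon$entries[[id]]
    data.frame(start = pd$start[i], end = pd$start[i] + pd$len[i],
               surface = substr(sentence_text, pd$start[i] + 1L,
                                pd$start[i] + pd$len[i]),
               entry_id = id, category = e$category,
               disease_tag = e$disease_tag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.find_triggers <- function(sentence_text, trigger_verbs) {
  low <- tolower(sentence_text)
  out <- list()
  for (v in trigger_verbs) {
    m <- gregexpr(.key_pattern(normalize_surface(v)), low, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    lens <- attr(m, "match.length")
    for (j in seq_along(m)) {
      out[[length(out) + 1L]] <- data.frame(
        t_start = m[j] - 1L, t_end = m[j] - 1L + lens[j], trigger = v,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(t_start = integer(), t_end = integer(),
                      trigger = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Extract directional cytokine relations from one sentence
#'
#' For every pair of one cytokine mention and one disease-concept mention
#' (disease, metabolite, or mutated gene/protein) co-occurring in a
#' sentence that contains a trigger verb, one triple is emitted. When a
#' trigger lies between the two mentions, the mention preceding the trigger
#' is the effector and the one following it the affected; otherwise the
#' earlier mention is taken as effector and the trigger nearest to the pair
#' is recorded. Sentences without any trigger verb emit nothing, as do
#' sentences lacking either a cytokine or a disease-concept mention.
#'
#' @param sentence_text the sentence string.
#' @param mentions data.frame from [tag_entities()].
#' @param trigger_verbs character vector of trigger verbs.
#' @return data.frame, one row per relation triple, with effector/affected
#'   offsets, surfaces, entry ids and categories, the cytokine and concept
#'   entry ids, the concept's disease tag, and the trigger.
#' @export
extract_relations <- function(sentence_text, mentions,
                              trigger_verbs = default_trigger_verbs()) {
  proto <- data.frame(
    effector_surface = character(), effector_entry = character(),
    effector_category = character(), affected_surface = character(),
    affected_entry = character(), affected_category = character(),
    cytokine_entry = character(), cytokine_surface = character(),
    concept_entry = character(), concept_category = character(),
    disease_tag = character(), trigger = character(),
    stringsAsFactors = FALSE)
  if (!nrow(mentions)) return(proto)
  cyt <- mentions[mentions$category == "cytokine", , drop = FALSE]
  conc <- mentions[mentions$category %in% c("disease", "metabolite",
                                            "gene_protein"), , drop = FALSE]
  if (!nrow(cyt) || !nrow(conc)) return(proto)
  trig <- .find_triggers(sentence_text, trigger_verbs)
  if (!nrow(trig)) return(proto)
  rows <- list()
  for (i in seq_len(nrow(cyt))) {
    for (j in seq_len(nrow(conc))) {
      a <- cyt[i, ]; b <- conc[j, ]
      first <- if (a$start <= b$start) a else b
      second <- if (a$start <= b$start) b else a
      between <- trig[trig$t_start >= first$end & trig$t_end <= second$start, ,
                      drop = FALSE]
      if (nrow(between)) {
        tr <- between$trigger[which.min(between$t_start)]
      } else {
        mid <- (first$end + second$start) / 2
        tr <- trig$trigger[which.min(abs((trig$t_start + trig$t_end) / 2 - mid))]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        effector_surface = first$surface, effector_entry = first$entry_id,
        effector_category = first$category,
        affected_surface = second$surface, affected_entry = second$entry_id,
        affected_category = second$category,
        cytokine_entry = a$entry_id, cytokine_surface = a$surface,
        concept_entry = b$entry_id, concept_category = b$category,
        disease_tag = b$disease_tag, trigger = tr,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Classify a Niemann-Pick disease mention into its subtype
#'
#' Returns the subtype letter when a pattern "type X", "NPD X" or "NP-X"
#' (X in A..F) adjoins the mention; `"generic"` otherwise. A sentence
#' without any Niemann-Pick mention is a precondition violation and raises
#' an error. Downstream, the ASMD aggregation keeps only subtypes A, B and
#' generic (types C-F are distinct diseases, not acid sphingomyelinase
#' deficiency).
#'
#' @param sentence_text the sentence string.
#' @return one of `"A"`..`"F"` or `"generic"`.
#' @export
classify_np_subtype <- function(sentence_text) {
  np <- regexpr("(?i)n(?:ie|ei)mann[- ]?pick(?:[- ]?disease)?|\\bNPD\\b|\\bNP\\b",
                sentence_text, perl = TRUE)
  if (np == -1L) {
    stop("sentence contains no Niemann-Pick disease mention", call. = FALSE)
  }
  win_end <- min(nchar(sentence_text),
                 np + attr(np, "match.length") - 1L + 16L)
  window <- substr(sentence_text, np, win_end)
  for (pat in c("(?i)\\btypes?[ -]?([A-F])\\b",
                "(?i)\\bNPD[ -]?([A-F])\\b",
                "(?i)\\bNP[- ]([A-F])\\b")) {
    m <- regexpr(pat, window, perl = TRUE)
    if (m != -1L) {
      cs <- attr(m, "capture.start")[1L]
      return(toupper(substr(window, cs, cs)))
    }
  }
  "generic"
}

#' Mine relations from a sentence table
#'
#' Tags entities and extracts relation triples for every sentence of a
#' segmented corpus (see [segment_sentences()]).
#'
#' @param sentences data.frame of sentences (`doc_id`, `section_name`,
#'   `text`, `start`, `end`, `source`).
#' @param lexicon a `lexicon` object.
#' @param trigger_verbs character vector of trigger verbs.
#' @return data.frame of relation triples with sentence coordinates.
#' @export
extract_corpus_relations <- function(sentences, lexicon,
                                     trigger_verbs = default_trigger_verbs()) {
  rows <- lapply(seq_len(nrow(sentences)), function(i) {
    sen <- sentences[i, ]
    men <- tag_entities(sen$text, lexicon)
    rel <- extract_relations(sen$text, men, trigger_verbs)
    if (!nrow(rel)) return(NULL)
    cbind(sen[rep(1L, nrow(rel)),
              c("doc_id", "section_name", "start", "end", "text", "source")],
          rel, row.names = NULL)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(cbind(
      data.frame(doc_id = character(), section_name = character(),
                 start = integer(), end = integer(), text = character(),
                 source = character(), stringsAsFactors = FALSE),
      extract_relations("", data.frame(start = integer(), end = integer(),
                                       surface = character(),
                                       entry_id = character(),
                                       category = character(),
                                       disease_tag = character()))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the relation filtering rules
#'
#' Drops triples from clinical-trial records, triples located in
#' methods-like sections, and triples whose cytokine name cannot be mapped
#' unambiguously to a gene symbol. Triples tagged ASMD whose sentence
#' mentions a Niemann-Pick subtype other than A or B (or generic) are also
#' dropped. The retained triples gain a `gene_symbol` column.
#'
#' @param relations data.frame from [extract_corpus_relations()].
#' @param lexicon a `lexicon` object (for gene-symbol mapping).
#' @param methods_sections normalized section names treated as methods-like.
#' @return filtered data.frame; attribute `"dropped"` summarizes the counts
#'   removed by each rule.
#' @export
filter_relations <- function(relations, lexicon,
                             methods_sections = default_methods_sections()) {
  n0 <- nrow(relations)
  if (!n0) {
    relations$gene_symbol <- character(0)
    attr(relations, "dropped") <- c(clinical_trial = 0L, methods_section = 0L,
                                    unmapped_cytokine = 0L, np_subtype = 0L)
    return(relations)
  }
  keep_ct <- relations$source != "clinical_trial"
  keep_sec <- !(normalize_surface(relations$section_name) %in% methods_sections)
  sym <- vapply(relations$cytokine_entry, function(id) {
    e <- lexicon$entries[[id]]
    if (is.null(e) || isTRUE(e$ambiguous) || is.na(e$gene_symbol %||% NA)) {
      NA_character_
    } else e$gene_symbol
  }, "")
  keep_sym <- !is.na(sym)
  keep_np <- rep(TRUE, n0)
  asmd <- which(relations$disease_tag == "ASMD")
  for (i in asmd) {
    if (grepl("(?i)n(?:ie|ei)mann[- ]?pick|\\bNPD\\b|\\bNP\\b",
              relations$text[i], perl = TRUE)) {
      sub <- classify_np_subtype(relations$text[i])
      keep_np[i] <- sub %in% c("A", "B", "generic")
    }
  }
  keep <- keep_ct & keep_sec & keep_sym & keep_np
  out <- relations[keep, , drop = FALSE]
  out$gene_symbol <- sym[keep]
  rownames(out) <- NULL
  attr(out, "dropped") <- c(
    clinical_trial = sum(!keep_ct),
    methods_section = sum(keep_ct & !keep_sec),
    unmapped_cytokine = sum(keep_ct & keep_sec & !keep_sym),
    np_subtype = sum(keep_ct & keep_sec & keep_sym & !keep_np))
  out
}

#' Aggregate filtered relations into disease-cytokine associations
#'
#' Groups triples by (disease tag, cytokine entry) and counts distinct
#' sentences (deduplication key: document, section, start, end) and
#' distinct articles; flags associations with at least one sentence in the
#' title or abstract (a likely key finding). Output is sorted by article
#' count, then sentence count, descending.
#'
#' @param filtered data.frame from [filter_relations()].
#' @param lexicon a `lexicon` object.
#' @return data.frame with `disease`, `cytokine_name`, `gene_symbol`,
#'   `n_sentences`, `n_articles`, `in_title_or_abstract`, plus an
#'   `evidence` list-column of the supporting triples.
#' @export
aggregate_associations <- function(filtered, lexicon) {
  proto <- data.frame(disease = character(), cytokine_name = character(),
                      gene_symbol = character(), n_sentences = integer(),
                      n_articles = integer(), in_title_or_abstract = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(filtered)) {
    proto$evidence <- list()
    return(proto)
  }
  grp <- paste(filtered$disease_tag, filtered$cytokine_entry, sep = "\r")
  rows <- lapply(split(seq_len(nrow(filtered)), grp), function(idx) {
    sub <- filtered[idx, , drop = FALSE]
    e <- lexicon$entries[[sub$cytokine_entry[1L]]]
    sent_key <- unique(paste(sub$doc_id, sub$section_name, sub$start, sub$end,
                             sep = "\r"))
    df <- data.frame(
      disease = sub$disease_tag[1L],
      cytokine_name = e$canonical_name,
      gene_symbol = sub$gene_symbol[1L],
      n_sentences = length(sent_key),
      n_articles = length(unique(sub$doc_id)),
      in_title_or_abstract = any(sub$section_name %in% c("title", "abstract")),
      stringsAsFactors = FALSE)
    df$evidence <- list(sub)
    df
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_articles, -out$n_sentences, out$cytokine_name), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full mining stage on a corpus
#'
#' Segmentation, tagging, relation extraction, filtering, and aggregation
#' in one call.
#'
#' @param documents list of document records (see [read_corpus()]).
#' @param lexicon a `lexicon` object.
#' @param trigger_verbs character vector of trigger verbs.
#' @param methods_sections methods-like section names to exclude.
#' @return list of class `mining_result` with `sentences`, `relations`
#'   (unfiltered), `filtered`, and `associations`.
#' @export
mine_corpus <- function(documents, lexicon,
                        trigger_verbs = default_trigger_verbs(),
                        methods_sections = default_methods_sections()) {
  sentences <- do.call(rbind, lapply(documents, segment_sentences))
  relations <- extract_corpus_relations(sentences, lexicon, trigger_verbs)
  filtered <- filter_relations(relations, lexicon, methods_sections)
  associations <- aggregate_associations(filtered, lexicon)
  structure(list(sentences = sentences, relations = relations,
                 filtered = filtered, associations = associations),
            class = "mining_result")
}

#' @export
print.mining_result <- function(x, ...) {
  cat("<mining_result> ", nrow(x$sentences), " sentences, ",
      nrow(x$relations), " raw triples, ", nrow(x$filtered),
      " retained, ", nrow(x$associations), " associations\n", sep = "")
  invisible(x)
}

#' Three-set overlap table of per-disease cytokine lists
#'
#' Computes all seven Venn regions of three gene-symbol sets. Comparison is
#' on gene symbols, not raw cytokine names, so spelling variants of the
#' same gene collapse.
#'
#' @param lists named list of three character vectors of gene symbols.
#' @return data.frame with `region` and `count`; the counts sum to the size
#'   of the union.
#' @export
compare_disease_lists <- function(lists) {
  stopifnot(length(lists) == 3L, !is.null(names(lists)))
  lists <- lapply(lists, function(x) unique(x[!is.na(x)]))
  nm <- names(lists)
  all_genes <- unique(unlist(lists))
  memb <- vapply(lists, function(s) all_genes %in% s,
                 logical(length(all_genes)))
  if (length(all_genes) == 1L) memb <- matrix(memb, nrow = 1L,
                                              dimnames = list(NULL, nm))
  region_of <- apply(memb, 1L, function(r) paste(nm[r], collapse = "&"))
  regions <- c(nm, paste(nm[1L], nm[2L], sep = "&"),
               paste(nm[1L], nm[3L], sep = "&"),
               paste(nm[2L], nm[3L], sep = "&"),
               paste(nm, collapse = "&"))
  counts <- vapply(regions, function(r) sum(region_of == r), 0L)
  out <- data.frame(region = regions, count = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(out, "union_size") <- length(all_genes)
  out
}
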