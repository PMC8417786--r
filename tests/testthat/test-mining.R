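# Sentence segmentation, entity tagging, relation extraction, filtering
# rules, and association aggregation.

test_that("segmentation splits on sentence boundaries and keeps offsets exact", {
  d <- list(doc_id = "D1", title = "A. B.", abstract = "", sections = list(),
            has_fulltext = FALSE, source = "pubmed")
  s <- segment_sentences(d)
  expect_identical(nrow(s), 2L)

  sentences <- c(
    "TNF was elevated in serum.",
    "Samples were analyzed as described by Smith et al. in 2019.",
    "Fig. 2 shows the cytokine profile.",
    "Levels rose, e.g. in plasma and urine.",
    "Treatment started at age 4.",
    "IL-6 decreased afterwards.",
    "The cohort included 12 patients.",
    "No adverse events occurred.",
    "Results were confirmed by ELISA.",
    "Approx. 40% responded.",
    "Further work is needed.",
    "A second cohort was enrolled.",
    "Dr. Jones reviewed all charts.",
    "Cytokine panels were repeated twice.",
    "Values were log-transformed.",
    "Analysis used standard software.",
    "P-values below 0.05 were significant.",
    "The study was approved locally.",
    "Consent was obtained.",
    "Funding sources are listed below.")
  text <- paste(sentences, collapse = " ")
  out <- split_sentences(text)
  expect_identical(nrow(out), length(sentences))
  expect_identical(out$text, sentences)
  # every slice equality holds (0-based half-open offsets)
  for (i in seq_len(nrow(out))) {
    expect_identical(substr(text, out$start[i] + 1L, out$end[i]), out$text[i])
  }
})

test_that("documents without full text contribute only title and abstract", {
  d <- list(doc_id = "D2", title = "A title.",
            abstract = "One sentence. Two sentences here.",
            sections = list(list(name = "Results", text = "Hidden. Text.")),
            has_fulltext = FALSE, source = "pmc")
  s <- segment_sentences(d)
  expect_setequal(unique(s$section_name), c("title", "abstract"))
  expect_identical(sum(s$section_name == "abstract"), 2L)
  expect_identical(nrow(split_sentences("")), 0L)
})

test_that("entity tagging is longest-match, word-bounded, non-overlapping", {
  lex <- tiny_lexicon()
  m <- tag_entities("TNF was elevated in Gaucher disease", lex)
  expect_identical(nrow(m), 2L)
  expect_setequal(m$surface, c("TNF", "Gaucher disease"))
  expect_identical(m$category[m$surface == "TNF"], "cytokine")
  expect_identical(m$disease_tag[m$surface == "Gaucher disease"], "GD")

  expect_identical(nrow(tag_entities("nothing relevant here", lex)), 0L)

  # hand-enumerated longest-match: with only the shorter synonym present the
  # shorter matches; adding a longer synonym makes the longer win
  short_tbl <- data.frame(canonical_name = "IL6", synonym = "interleukin 6",
                          category = "cytokine", disease_tag = "none",
                          gene_symbol = "IL6", stringsAsFactors = FALSE)
  suppressWarnings(lshort <- build_lexicon(short_tbl))
  m1 <- tag_entities("the interleukin 6 receptor complex", lshort)
  expect_identical(m1$surface, "interleukin 6")
  long_tbl <- rbind(short_tbl,
                    data.frame(canonical_name = "IL6R",
                               synonym = "interleukin 6 receptor",
                               category = "cytokine", disease_tag = "none",
                               gene_symbol = "IL6R", stringsAsFactors = FALSE))
  suppressWarnings(llong <- build_lexicon(long_tbl))
  m2 <- tag_entities("the interleukin 6 receptor complex", llong)
  expect_identical(m2$surface, "interleukin 6 receptor")
  # word boundary: no match inside a longer word
  expect_identical(nrow(tag_entities("sphingomyelinase activity",
    build_lexicon(data.frame(canonical_name = "sphingomyelin",
                             synonym = "sphingomyelin",
                             category = "metabolite", disease_tag = "ASMD",
                             gene_symbol = NA, stringsAsFactors = FALSE)) |>
      suppressWarnings())), 0L)
  # mention offsets slice back to the surface
  for (i in seq_len(nrow(m))) {
    expect_identical(substr("TNF was elevated in Gaucher disease",
                            m$start[i] + 1L, m$end[i]), m$surface[i])
  }
})

test_that("relation extraction is directional around the trigger verb", {
  lex <- tiny_lexicon()
  s <- "Glucosylceramide induces TNF secretion."
  r <- extract_relations(s, tag_entities(s, lex))
  expect_identical(nrow(r), 1L)
  expect_identical(r$effector_surface, "Glucosylceramide")
  expect_identical(r$affected_surface, "TNF")
  expect_identical(r$trigger, "induces")

  # cytokine without a disease concept emits nothing
  s2 <- "TNF was elevated in most patients."
  expect_identical(nrow(extract_relations(s2, tag_entities(s2, lex))), 0L)
  # concept without a trigger verb emits nothing
  s3 <- "TNF and Gaucher disease were discussed."
  expect_identical(nrow(extract_relations(s3, tag_entities(s3, lex))), 0L)
  # two cytokines, one concept, one trigger: one triple per cytokine
  s4 <- "Glucosylceramide increased TNF and IL-6 in plasma."
  r4 <- extract_relations(s4, tag_entities(s4, lex))
  expect_identical(nrow(r4), 2L)
  expect_setequal(r4$cytokine_surface, c("TNF", "IL-6"))
  expect_identical(unique(r4$effector_surface), "Glucosylceramide")
})

test_that("filtering removes clinical trials, methods sections, unmappable names", {
  lex <- tiny_lexicon()
  sen <- function(text, section, source = "pubmed", doc = "D1") {
    data.frame(doc_id = doc, section_name = section, text = text,
               start = 0L, end = nchar(text), source = source,
               stringsAsFactors = FALSE)
  }
  sents <- rbind(
    sen("Glucosylceramide induces TNF secretion.", "abstract"),
    sen("Glucosylceramide induces TNF secretion.", "Materials and Methods"),
    sen("Glucosylceramide induces IL-6 secretion.", "Results", "clinical_trial"),
    sen("MIP-1 is elevated in Gaucher disease.", "abstract"))
  rel <- extract_corpus_relations(sents, lex)
  expect_identical(nrow(rel), 4L)
  filt <- filter_relations(rel, lex)
  expect_identical(nrow(filt), 1L)
  expect_identical(filt$section_name, "abstract")
  expect_identical(filt$gene_symbol, "TNF")
  drop <- attr(filt, "dropped")
  expect_identical(unname(drop[c("clinical_trial", "methods_section",
                                 "unmapped_cytokine")]), c(1L, 1L, 1L))
})

test_that("Niemann-Pick subtype classification keeps only A, B and generic", {
  expect_identical(classify_np_subtype("Niemann-Pick disease type C"), "C")
  expect_identical(classify_np_subtype("Niemann-Pick disease"), "generic")
  expect_identical(classify_np_subtype("NPD B fibroblasts"), "B")
  expect_identical(classify_np_subtype("patients with NP-A phenotype"), "A")
  expect_error(classify_np_subtype("no such mention here"), "Niemann-Pick")

  lex <- tiny_lexicon()
  sents <- data.frame(
    doc_id = "D1", section_name = "abstract",
    text = c("TNF is elevated in Niemann-Pick disease type C cells.",
             "TNF is elevated in Niemann-Pick disease fibroblasts.",
             "TNF is elevated in NPD B fibroblasts."),
    start = c(0L, 60L, 120L), end = c(53L, 112L, 157L),
    source = "pubmed", stringsAsFactors = FALSE)
  rel <- extract_corpus_relations(sents, lex)
  filt <- filter_relations(rel, lex)
  expect_identical(nrow(filt), 2L)
  expect_identical(unname(attr(filt, "dropped")["np_subtype"]), 1L)
})

test_that("association aggregation counts distinct sentences and articles", {
  lex <- tiny_lexicon()
  tri <- function(doc, section, start) {
    data.frame(doc_id = doc, section_name = section, start = start,
               end = start + 40L,
               text = "Glucosylceramide induces TNF secretion.",
               source = "pubmed", effector_surface = "Glucosylceramide",
               effector_entry = "metabolite:GD:glucosylceramide",
               effector_category = "metabolite", affected_surface = "TNF",
               affected_entry = "cytokine:none:tnf",
               affected_category = "cytokine",
               cytokine_entry = "cytokine:none:tnf", cytokine_surface = "TNF",
               concept_entry = "metabolite:GD:glucosylceramide",
               concept_category = "metabolite", disease_tag = "GD",
               trigger = "induces", stringsAsFactors = FALSE)
  }
  # 3 triples over 2 distinct sentences in 2 documents (one duplicated)
  filtered <- rbind(tri("DOC1", "Results", 0L), tri("DOC1", "Results", 0L),
                    tri("DOC2", "abstract", 10L))
  filtered$gene_symbol <- "TNF"
  a <- aggregate_associations(filtered, lex)
  expect_identical(nrow(a), 1L)
  expect_identical(a$n_sentences, 2L)
  expect_identical(a$n_articles, 2L)
  expect_true(a$in_title_or_abstract)
  expect_identical(a$gene_symbol, "TNF")
})

test_that("adding documents never removes associations or lowers counts", {
  lex <- tiny_lexicon()
  planted <- default_planted_associations()[1:6, ]
  gc1 <- gen_corpus(list(n_documents = 8, planted_associations = planted,
                         decoy_fraction = 0, seed = 21), lex)
  extra <- gen_corpus(list(n_documents = 4,
                           planted_associations = planted[1:2, ],
                           decoy_fraction = 0, seed = 22), lex)
  extra$documents <- lapply(extra$documents, function(d) {
    d$doc_id <- paste0("X", d$doc_id); d
  })
  a1 <- mine_corpus(gc1$documents, lex)$associations
  a2 <- mine_corpus(c(gc1$documents, extra$documents), lex)$associations
  key <- function(a) paste(a$disease, a$gene_symbol)
  expect_true(all(key(a1) %in% key(a2)))
  m <- merge(a1, a2, by = c("disease", "gene_symbol"))
  expect_true(all(m$n_sentences.y >= m$n_sentences.x))
  expect_true(all(m$n_articles.y >= m$n_articles.x))
})

test_that("three-set overlap table covers all seven regions and sums to union", {
  same <- list(GD = c("A", "B", "C"), FD = c("A", "B", "C"),
               ASMD = c("A", "B", "C"))
  v <- compare_disease_lists(same)
  expect_identical(v$count[v$region == "GD&FD&ASMD"], 3L)
  expect_identical(sum(v$count), 3L)

  disj <- list(GD = c("A", "B"), FD = c("C"), ASMD = character())
  v2 <- compare_disease_lists(disj)
  expect_identical(v2$count[v2$region == "GD"], 2L)
  expect_identical(v2$count[v2$region == "FD"], 1L)
  expect_identical(sum(v2$count), attr(v2, "union_size"))

  # the six-way shared design: default planted lists share exactly six genes
  lex <- tiny_lexicon()
  planted <- default_planted_associations()
  sym <- vapply(planted$cytokine, map_cytokine_to_symbol, "", lexicon = lex)
  lists <- split(sym, planted$disease)
  v3 <- compare_disease_lists(lists[c("GD", "FD", "ASMD")])
  expect_identical(v3$count[v3$region == "GD&FD&ASMD"], 6L)
})
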