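# Synthetic inputs with planted ground truth: literature corpus, lexicon
# source tables, expression atlas, regulatory and ligand-receptor tables,
# pathway sets, and sample-level expression. Every generator is a pure
# function of its spec and seed.

#' Default lexicon source tables
#'
#' Built-in dictionary tables covering the three sphingolipidoses (Gaucher
#' disease, acid sphingomyelinase deficiency / Niemann-Pick A-B, Fabry
#' disease): disease synonyms (including the frequent "neimann-pick"
#' mistyping), accumulated metabolites and their lyso-species, mutated
#' enzymes, and a cytokine registry with gene-symbol mappings. The
#' registry deliberately contains one name ("MIP-1") attached to two gene
#' symbols, which the build flags as ambiguous.
#'
#' @return data.frame with columns `canonical_name`, `synonym`, `category`,
#'   `disease_tag`, `gene_symbol`.
#' @export
default_lexicon_tables <- function() {
  row <- function(canon, syn, cat, tag, sym = NA_character_) {
    data.frame(canonical_name = canon, synonym = syn, category = cat,
               disease_tag = tag, gene_symbol = sym, stringsAsFactors = FALSE)
  }
  rows <- list(
    # --- GD concepts ---
    row("Gaucher disease", "Gaucher disease", "disease", "GD"),
    row("Gaucher disease", "Gaucher's disease", "disease", "GD"),
    row("Gaucher disease", "glucocerebrosidase deficiency", "disease", "GD"),
    row("glucosylceramide", "glucosylceramide", "metabolite", "GD"),
    row("glucosylceramide", "GL1", "metabolite", "GD"),
    row("glucosylceramide", "glucocerebroside", "metabolite", "GD"),
    row("glucosylsphingosine", "glucosylsphingosine", "metabolite", "GD"),
    row("glucosylsphingosine", "lyso-GL1", "metabolite", "GD"),
    row("glucocerebrosidase", "glucocerebrosidase", "gene_protein", "GD", "GBA"),
    row("glucocerebrosidase", "GBA", "gene_protein", "GD", "GBA"),
    row("glucocerebrosidase", "acid beta-glucosidase", "gene_protein", "GD", "GBA"),
    # --- FD concepts ---
    row("Fabry disease", "Fabry disease", "disease", "FD"),
    row("Fabry disease", "Anderson-Fabry disease", "disease", "FD"),
    row("Fabry disease", "alpha-galactosidase A deficiency", "disease", "FD"),
    row("globotriaosylceramide", "globotriaosylceramide", "metabolite", "FD"),
    row("globotriaosylceramide", "Gb3", "metabolite", "FD"),
    row("globotriaosylsphingosine", "globotriaosylsphingosine", "metabolite", "FD"),
    row("globotriaosylsphingosine", "lyso-Gb3", "metabolite", "FD"),
    row("alpha-galactosidase A", "alpha-galactosidase A", "gene_protein", "FD", "GLA"),
    row("alpha-galactosidase A", "GLA", "gene_protein", "FD", "GLA"),
    # --- ASMD concepts ---
    row("acid sphingomyelinase deficiency", "ASMD", "disease", "ASMD"),
    row("acid sphingomyelinase deficiency", "acid sphingomyelinase deficiency",
        "disease", "ASMD"),
    row("Niemann-Pick disease", "Niemann-Pick disease", "disease", "ASMD"),
    row("Niemann-Pick disease", "Niemann-Pick", "disease", "ASMD"),
    row("Niemann-Pick disease", "neimann-pick", "disease", "ASMD"),
    row("Niemann-Pick disease", "NPD", "disease", "ASMD"),
    row("sphingomyelin", "sphingomyelin", "metabolite", "ASMD"),
    row("lyso-sphingomyelin", "lyso-sphingomyelin", "metabolite", "ASMD"),
    row("lyso-sphingomyelin", "lyso-SM", "metabolite", "ASMD"),
    row("acid sphingomyelinase", "acid sphingomyelinase", "gene_protein",
        "ASMD", "SMPD1"),
    row("acid sphingomyelinase", "SMPD1", "gene_protein", "ASMD", "SMPD1"))
  cyto <- list(
    c("TNF", "TNF|tumor necrosis factor|TNF-α|TNF-alpha", "TNF"),
    c("IL6", "IL-6|interleukin-6", "IL6"),
    c("IL1B", "IL-1β|IL-1B|interleukin-1 beta", "IL1B"),
    c("IL4", "IL-4|interleukin-4", "IL4"),
    c("IL10", "IL-10|interleukin-10", "IL10"),
    c("CXCL8", "CXCL8|IL-8|interleukin-8", "CXCL8"),
    c("CCL5", "CCL5|RANTES", "CCL5"),
    c("CCL2", "CCL2|MCP-1", "CCL2"),
    c("CXCL10", "CXCL10|IP-10", "CXCL10"),
    c("CCL18", "CCL18|PARC", "CCL18"),
    c("erythropoietin", "erythropoietin|EPO", "EPO"),
    c("IFN-γ", "IFN-γ|interferon gamma|IFNG", "IFNG"),
    c("IL1RN", "IL1RN|IL-1RA|interleukin-1 receptor antagonist", "IL1RN"),
    c("CCL1", "CCL1", "CCL1"),
    c("CXCL12", "CXCL12|SDF-1", "CXCL12"),
    c("CXCL9", "CXCL9|MIG", "CXCL9"),
    c("CXCL11", "CXCL11", "CXCL11"),
    c("IL13", "IL-13|interleukin-13", "IL13"),
    c("IL18", "IL-18|interleukin-18", "IL18"),
    c("TGF-β1", "TGF-β1|TGF-beta 1|TGFB1", "TGFB1"))
  for (cy in cyto) {
    for (syn in strsplit(cy[2L], "|", fixed = TRUE)[[1L]]) {
      rows[[length(rows) + 1L]] <- row(cy[1L], syn, "cytokine", "none", cy[3L])
    }
  }
  # A name mapping to two symbols: flagged ambiguous and excluded downstream.
  rows[[length(rows) + 1L]] <- row("MIP-1", "MIP-1", "cytokine", "none", "CCL3")
  rows[[length(rows) + 1L]] <- row("MIP-1", "MIP-1", "cytokine", "none", "CCL4")
  tf_pool <- default_tf_pool()
  for (tf in tf_pool) {
    rows[[length(rows) + 1L]] <- row(tf, tf, "tf", "none", tf)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default transcription-factor name pool
#'
#' Immune-relevant TFs used by the regulatory-table generator and the TF
#' dictionary (NF-kB subunits, interferon-regulatory factors, stress and
#' nuclear-receptor TFs).
#'
#' @return character vector of TF gene symbols.
#' @export
default_tf_pool <- function() {
  c("STAT1", "STAT2", "JUN", "NR4A2", "IRF7", "DDIT3", "XBP1", "VDR",
    "RELA", "RELB", "REL", "NFKB1", "IRF1", "SPI1", "CEBPB", "NR3C1",
    "FOS", "ETS1", "GATA3", "RUNX1")
}

#' Default planted disease-cytokine associations
#'
#' The study conditions for the synthetic corpus: per-disease cytokine
#' lists sharing exactly six cytokines across all three diseases (CCL5,
#' CXCL8, IL1B, IL4, IL6, TNF - the shared inflammatory core), with the
#' six monocyte-specific cytokines (CCL1, CCL2, CXCL10, CXCL12, IL1RN,
#' EPO) and the heavily cited CCL18 among the Gaucher list.
#'
#' @return data.frame with `disease`, `cytokine` (canonical dictionary
#'   name), `n_sentences`.
#' @export
default_planted_associations <- function() {
  shared <- c("TNF", "IL6", "IL1B", "IL4", "CXCL8", "CCL5")
  gd <- c(shared, "CCL18", "CCL1", "CCL2", "CXCL10", "CXCL12", "IL1RN",
          "erythropoietin")
  fd <- c(shared, "IFN-γ", "IL13")
  asmd <- c(shared, "IL18", "TGF-β1")
  df <- rbind(
    data.frame(disease = "GD", cytokine = gd, stringsAsFactors = FALSE),
    data.frame(disease = "FD", cytokine = fd, stringsAsFactors = FALSE),
    data.frame(disease = "ASMD", cytokine = asmd, stringsAsFactors = FALSE))
  # heavier evidence for the most cited cytokines, 1-5 sentences each
  df$n_sentences <- 1L + (seq_len(nrow(df)) * 3L) %% 5L
  df$n_sentences[df$disease == "GD" & df$cytokine == "CCL18"] <- 6L
  df$n_sentences[df$cytokine == "TNF"] <- 5L
  df
}

#' Read relation sentence templates
#'
#' @return character vector of templates with `{concept}` / `{cytokine}`
#'   placeholders.
#' @export
default_sentence_templates <- function() {
  path <- system.file("extdata", "sentence_templates.txt", package = "cytolit")
  tpl <- readLines(path, encoding = "UTF-8", warn = FALSE)
  tpl <- trimws(tpl)
  tpl[nzchar(tpl) & !startsWith(tpl, "#")]
}

.fill_template <- function(tpl, concept, cytokine) {
  s <- gsub("{concept}", concept, tpl, fixed = TRUE)
  s <- gsub("{cytokine}", cytokine, s, fixed = TRUE)
  # sentence-initial capitalization
  paste0(toupper(substr(s, 1L, 1L)), substr(s, 2L, nchar(s)))
}

#' Generate a synthetic literature corpus with planted associations
#'
#' Emits templated relation sentences realizing each planted
#' disease-cytokine association, distributed across documents, plus decoy
#' sentences that the filtering rules must remove: cytokine-only sentences
#' (no disease concept), relation sentences placed in methods sections,
#' relation sentences in clinical-trial records, relations with an
#' ambiguous cytokine name, and (when ASMD is planted) a Niemann-Pick
#' type C relation. The first sentence of every association is placed in
#' an abstract, so `in_title_or_abstract` is TRUE for all planted
#' associations. The returned truth table lists exactly the planted
#' associations with their expected sentence and article counts.
#'
#' @param spec list with `n_documents`, `planted_associations` (data.frame
#'   `disease`, `cytokine`, `n_sentences`), `decoy_fraction` in \[0, 1)
#'   (fraction of decoys among all relation-bearing sentences),
#'   `methods_fraction` (fraction of decoys placed in methods sections),
#'   and `seed`.
#' @param lexicon a `lexicon` containing every planted entity.
#' @return list with `documents` (list of document records) and `truth`
#'   (data.frame `disease`, `cytokine_name`, `gene_symbol`, `n_sentences`,
#'   `n_articles`, `in_title_or_abstract`).
#' @export
gen_corpus <- function(spec, lexicon) {
  planted <- spec$planted_associations
  stopifnot(is.data.frame(planted),
            all(c("disease", "cytokine", "n_sentences") %in% names(planted)))
  decoy_fraction <- spec$decoy_fraction %||% 0
  methods_fraction <- spec$methods_fraction %||% 0.3
  stopifnot(decoy_fraction >= 0, decoy_fraction < 1,
            methods_fraction >= 0, methods_fraction <= 1)
  n_documents <- spec$n_documents
  cyto_entries <- lexicon_entries(lexicon, category = "cytokine")
  missing <- setdiff(planted$cytokine, cyto_entries$canonical_name)
  if (length(missing)) {
    stop("planted cytokines missing from lexicon: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  diseases <- unique(planted$disease)
  concept_tbl <- lexicon_entries(lexicon,
                                 category = c("disease", "metabolite",
                                              "gene_protein"))
  for (d in diseases) {
    if (!any(concept_tbl$disease_tag == d)) {
      stop("no lexicon concepts for planted disease ", d, call. = FALSE)
    }
  }
  templates <- default_sentence_templates()

  with_seed(spec$seed, {
    total_planted <- sum(planted$n_sentences)
    n_decoys <- if (decoy_fraction > 0) {
      max(1L, round(decoy_fraction / (1 - decoy_fraction) * total_planted))
    } else 0L
    n_ct_docs <- if (n_decoys > 0L) max(1L, round(0.1 * n_documents)) else 0L
    n_regular <- n_documents - n_ct_docs
    if (n_regular < length(diseases)) {
      stop("n_documents too small for the planted diseases", call. = FALSE)
    }

    # document skeletons: disease assigned round-robin; every disease gets
    # at least one full-text document (methods decoys need one)
    docs <- vector("list", n_documents)
    doc_disease <- rep(diseases, length.out = n_regular)
    for (i in seq_len(n_regular)) {
      d <- doc_disease[i]
      dis_name <- concept_tbl$canonical_name[
        concept_tbl$disease_tag == d & concept_tbl$category == "disease"][1L]
      fulltext <- (i <= length(diseases)) || (i %% 2L == 0L)
      docs[[i]] <- list(
        doc_id = sprintf("DOC%04d", i),
        title = sprintf("Inflammation and cytokine signaling in %s.", dis_name),
        abstract = sprintf("We studied immune activation in %s.", dis_name),
        sections = if (fulltext) {
          list(list(name = "Introduction",
                    text = sprintf("%s is a lysosomal storage disorder.",
                                   dis_name)),
               list(name = "Materials and Methods",
                    text = "Plasma samples were assayed by ELISA."),
               list(name = "Results", text = ""),
               list(name = "Discussion",
                    text = "These findings support an inflammatory component."))
        } else list(),
        pub_year = sample(1990:2020, 1L),
        is_review = stats::runif(1) < 0.1,
        has_fulltext = fulltext,
        source = sample(c("pubmed", "pmc"), 1L),
        disease = d)
    }
    for (i in seq_len(n_ct_docs)) {
      d <- diseases[1L + (i - 1L) %% length(diseases)]
      dis_name <- concept_tbl$canonical_name[
        concept_tbl$disease_tag == d & concept_tbl$category == "disease"][1L]
      docs[[n_regular + i]] <- list(
        doc_id = sprintf("CT%04d", i),
        title = sprintf("A clinical trial of enzyme therapy in %s.", dis_name),
        abstract = "", sections = list(), pub_year = sample(2000:2020, 1L),
        is_review = FALSE, has_fulltext = FALSE, source = "clinical_trial",
        disease = d)
    }

    append_sentence <- function(doc, section, sentence) {
      if (section == "abstract") {
        doc$abstract <- paste(doc$abstract, sentence)
      } else {
        for (k in seq_along(doc$sections)) {
          if (doc$sections[[k]]$name == section) {
            doc$sections[[k]]$text <- trimws(paste(doc$sections[[k]]$text,
                                                   sentence))
          }
        }
      }
      doc
    }

    relation_sentence <- function(d, cyto_canon, idx) {
      concepts <- concept_tbl[concept_tbl$disease_tag == d, , drop = FALSE]
      concept <- concepts$canonical_name[1L + idx %% nrow(concepts)]
      cy_row <- cyto_entries[cyto_entries$canonical_name == cyto_canon, ,
                             drop = FALSE]
      tpl <- templates[1L + idx %% length(templates)]
      .fill_template(tpl, concept, cy_row$canonical_name[1L])
    }

    # plant the associations
    truth_rows <- list()
    tpl_counter <- 0L
    for (r in seq_len(nrow(planted))) {
      d <- planted$disease[r]
      cy <- planted$cytokine[r]
      k <- planted$n_sentences[r]
      host_idx <- which(doc_disease == d)
      used_docs <- character()
      for (s in seq_len(k)) {
        di <- host_idx[1L + (r + s - 2L) %% length(host_idx)]
        sen <- relation_sentence(d, cy, tpl_counter)
        tpl_counter <- tpl_counter + 1L
        if (s == 1L) {
          sec <- "abstract"
        } else if (isTRUE(docs[[di]]$has_fulltext)) {
          sec <- c("Results", "Discussion", "Introduction")[1L + s %% 3L]
        } else {
          sec <- "abstract"
        }
        docs[[di]] <- append_sentence(docs[[di]], sec, sen)
        used_docs <- union(used_docs, docs[[di]]$doc_id)
      }
      sym <- cyto_entries$gene_symbol[cyto_entries$canonical_name == cy][1L]
      truth_rows[[r]] <- data.frame(
        disease = d, cytokine_name = cy, gene_symbol = sym,
        n_sentences = k, n_articles = length(used_docs),
        in_title_or_abstract = TRUE, stringsAsFactors = FALSE)
    }

    # decoys: the filters must remove all of them
    if (n_decoys > 0L) {
      n_methods <- round(methods_fraction * n_decoys)
      unamb <- cyto_entries[!cyto_entries$ambiguous, , drop = FALSE]
      for (j in seq_len(n_decoys)) {
        d <- diseases[1L + (j - 1L) %% length(diseases)]
        kind <- if (j <= n_methods) {
          "methods"
        } else {
          c("cytokine_only", "clinical_trial", "ambiguous",
            "np_type_c")[1L + j %% 4L]
        }
        if (kind == "np_type_c" && !"ASMD" %in% diseases) {
          kind <- "cytokine_only"
        }
        cy <- unamb$canonical_name[1L + j %% nrow(unamb)]
        if (kind == "methods") {
          ft_idx <- which(doc_disease == d &
                            vapply(docs[seq_len(n_regular)],
                                   function(x) isTRUE(x$has_fulltext), TRUE))
          di <- ft_idx[1L + j %% length(ft_idx)]
          docs[[di]] <- append_sentence(docs[[di]], "Materials and Methods",
                                        relation_sentence(d, cy, j))
        } else if (kind == "cytokine_only") {
          di <- which(doc_disease == d)[1L + j %% sum(doc_disease == d)]
          sec <- if (isTRUE(docs[[di]]$has_fulltext)) "Results" else "abstract"
          docs[[di]] <- append_sentence(
            docs[[di]], sec,
            sprintf("%s regulates the innate immune response.", cy))
        } else if (kind == "clinical_trial") {
          ct <- n_regular + 1L + (j %% n_ct_docs)
          docs[[ct]]$abstract <- paste(docs[[ct]]$abstract,
                                       relation_sentence(docs[[ct]]$disease,
                                                         cy, j))
        } else if (kind == "ambiguous") {
          di <- which(doc_disease == d)[1L + j %% sum(doc_disease == d)]
          concepts <- concept_tbl[concept_tbl$disease_tag == d, , drop = FALSE]
          docs[[di]] <- append_sentence(
            docs[[di]], "abstract",
            sprintf("MIP-1 is elevated in %s patients.",
                    concepts$canonical_name[1L]))
        } else if (kind == "np_type_c") {
          di <- which(doc_disease == "ASMD")[1L]
          docs[[di]] <- append_sentence(
            docs[[di]], "abstract",
            sprintf("%s is elevated in Niemann-Pick disease type C cells.", cy))
        }
      }
    }

    docs <- lapply(docs, function(x) { x$disease <- NULL; x })
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    list(documents = docs, truth = truth)
  })
}

#' Generate a synthetic immune-cell expression atlas
#'
#' Background expression is log-normal with median 1, so the "expressed"
#' threshold (NX > 1) bisects the gene pool. Planted cell-specific genes
#' receive elevated expression in their cell(s) and the matching
#' specificity class (cell-type enriched for one cell, group enriched for
#' several); a configurable fraction (or explicit list) of genes is marked
#' not detected. `planted_expressed` elevates expression without changing
#' the specificity class (for planting expression patterns, e.g. receptors
#' in a receiver cell).
#'
#' @param spec list with `n_genes`, optional `genes` (symbols to include),
#'   `cell_types` (default the eight blood types), `planted_specific`
#'   (named list cell type -> genes), `planted_expressed` (named list cell
#'   type -> genes), `expression_noise` (log-normal sdlog, default 0.6),
#'   `not_detected` (gene names or a fraction), `seed`.
#' @return list with `atlas` (an `expression_atlas`) and `truth` (the
#'   planted labels).
#' @export
gen_atlas <- function(spec) {
  cells <- spec$cell_types %||% default_cell_types()
  noise <- spec$expression_noise %||% 0.6
  planted <- spec$planted_specific %||% list()
  planted_expr <- spec$planted_expressed %||% list()
  stopifnot(all(names(planted) %in% cells), all(names(planted_expr) %in% cells))
  planted_genes <- unique(unlist(planted))
  base_genes <- unique(c(planted_genes, unlist(planted_expr), spec$genes))
  n_genes <- spec$n_genes %||% length(base_genes)
  if (n_genes < length(base_genes)) {
    stop("n_genes smaller than the number of named genes", call. = FALSE)
  }
  filler <- sprintf("GENE%04d", seq_len(n_genes - length(base_genes)))
  genes <- c(base_genes, filler)

  with_seed(spec$seed, {
    nx <- matrix(stats::rlnorm(length(cells) * length(genes),
                               meanlog = 0, sdlog = noise),
                 nrow = length(cells), dimnames = list(cells, genes))
    # genes enriched in one or several cells: elevated, class set accordingly
    enriched_in <- list()
    for (ct in names(planted)) {
      for (g in planted[[ct]]) {
        enriched_in[[g]] <- c(enriched_in[[g]], ct)
      }
    }
    for (g in names(enriched_in)) {
      for (ct in enriched_in[[g]]) {
        nx[ct, g] <- stats::rlnorm(1L, meanlog = log(8), sdlog = noise / 2)
      }
    }
    for (ct in names(planted_expr)) {
      for (g in setdiff(planted_expr[[ct]], character())) {
        nx[ct, g] <- stats::rlnorm(1L, meanlog = log(8), sdlog = noise / 2)
      }
    }
    spec_class <- stats::setNames(rep("low_specificity", length(genes)), genes)
    for (g in names(enriched_in)) {
      spec_class[g] <- if (length(enriched_in[[g]]) == 1L) {
        "cell_type_enriched"
      } else "group_enriched"
    }
    nd <- spec$not_detected %||% 0
    nd_genes <- if (is.character(nd)) {
      nd
    } else if (nd > 0) {
      pool <- setdiff(genes, c(names(enriched_in), unlist(planted_expr)))
      sample(pool, min(length(pool), round(nd * length(genes))))
    } else character()
    spec_class[nd_genes] <- "not_detected"
    nx[, nd_genes] <- 0
    atlas <- expression_atlas(nx, spec_class, enriched_in)
    list(atlas = atlas,
         truth = list(planted_specific = planted,
                      planted_expressed = planted_expr,
                      not_detected = sort(nd_genes)))
  })
}

#' Generate a synthetic TF-cytokine regulatory table
#'
#' Random bipartite TF -> cytokine edges with species labels drawn from the
#' given mixture (emulating a curated interaction database that mixes human
#' and mouse evidence).
#'
#' @param spec list with `n_tfs` (or explicit `tfs`), `cytokines` (target
#'   symbols), `edge_probability`, `species_mix` (named proportions,
#'   default all human), `seed`.
#' @return data.frame with `tf`, `cytokine`, `species`.
#' @export
gen_regdb <- function(spec) {
  tfs <- spec$tfs %||% utils::head(default_tf_pool(), spec$n_tfs %||% 10L)
  cyts <- spec$cytokines
  stopifnot(length(tfs) > 0, length(cyts) > 0)
  p <- spec$edge_probability %||% 0.3
  stopifnot(p > 0, p <= 1)
  mix <- spec$species_mix %||% c(human = 1)
  stopifnot(abs(sum(mix) - 1) < 1e-8)
  with_seed(spec$seed, {
    grid <- expand.grid(tf = tfs, cytokine = cyts, stringsAsFactors = FALSE)
    grid <- grid[stats::runif(nrow(grid)) < p, , drop = FALSE]
    grid <- grid[grid$tf != grid$cytokine, , drop = FALSE]
    grid$species <- sample(names(mix), nrow(grid), replace = TRUE, prob = mix)
    rownames(grid) <- NULL
    grid
  })
}

#' Generate a synthetic ligand-receptor pair table
#'
#' Each ligand receives a Poisson-distributed number of receptors (at least
#' one) drawn from a shared receptor pool, emulating a curated
#' ligand-receptor database where receptors are reused across ligands.
#'
#' @param spec list with `ligands` (symbols), `n_receptors` (pool size,
#'   default 30), `mean_pairs_per_ligand` (Poisson mean above 1, default
#'   1.5), `seed`.
#' @return data.frame with `ligand`, `receptor` (pairs unique).
#' @export
gen_lrdb <- function(spec) {
  ligands <- spec$ligands
  stopifnot(length(ligands) > 0)
  n_rec <- spec$n_receptors %||% 30L
  lambda <- spec$mean_pairs_per_ligand %||% 1.5
  pool <- sprintf("RCPT%03d", seq_len(n_rec))
  with_seed(spec$seed, {
    rows <- lapply(ligands, function(lig) {
      k <- min(n_rec, 1L + stats::rpois(1L, lambda))
      data.frame(ligand = lig, receptor = sample(pool, k),
                 stringsAsFactors = FALSE)
    })
    out <- unique(do.call(rbind, rows))
    rownames(out) <- NULL
    out
  })
}

#' Generate synthetic pathway gene sets
#'
#' Random gene sets with sizes straddling the minimum-set-size rule, plus
#' one deliberately enriched set (`planted_enriched`) drawn mostly from a
#' designated query.
#'
#' @param spec list with `pool` (gene universe to sample from),
#'   `n_pathways` (default 10), `enriched_in` (the designated query gene
#'   set; optional), `seed`.
#' @return named list of gene sets.
#' @export
gen_pathways <- function(spec) {
  pool <- unique(spec$pool)
  n <- spec$n_pathways %||% 10L
  stopifnot(length(pool) >= 6L)
  with_seed(spec$seed, {
    sets <- list()
    sizes <- rep(c(3L, 4L, 6L, 8L, 12L), length.out = n)
    for (i in seq_len(n)) {
      sets[[sprintf("PATHWAY_%02d", i)]] <-
        sample(pool, min(sizes[i], length(pool)))
    }
    if (!is.null(spec$enriched_in) && length(spec$enriched_in) >= 5L) {
      q <- unique(spec$enriched_in)
      k <- max(5L, round(0.8 * length(q)))
      extra <- setdiff(pool, q)
      sets[["planted_enriched"]] <- c(sample(q, k),
                                      if (length(extra)) {
                                        sample(extra, min(2L, length(extra)))
                                      })
    }
    sets
  })
}

#' Generate a correlated TF-cytokine expression pair
#'
#' Bivariate-normal latent values per sample with population correlation
#' `rho`, replicated over subtypes with independent noise; averaging over
#' subtypes recovers the target correlation in expectation (attenuated by
#' the factor 1 / (1 + noise_sd^2 / n_subtypes), negligible at the default
#' noise level).
#'
#' @param rho true correlation in \[-1, 1\].
#' @param n_samples number of samples (>= 3).
#' @param n_subtypes number of subtypes per sample (default 3).
#' @param seed RNG seed.
#' @param genes length-2 character vector of gene names.
#' @param noise_sd subtype-level noise standard deviation (default 0.1;
#'   subtype profiles of the same donor are highly concordant).
#' @return long-format data.frame with `sample`, `subtype`, `gene`,
#'   `value`.
#' @export
gen_correlated_expression <- function(rho, n_samples, n_subtypes = 3L,
                                      seed = NULL, genes = c("TF1", "CYT1"),
                                      noise_sd = 0.1) {
  if (!is.finite(rho) || abs(rho) > 1) stop("invalid rho", call. = FALSE)
  stopifnot(n_samples >= 3L, length(genes) == 2L)
  with_seed(seed, {
    sigma <- matrix(c(1, rho, rho, 1), 2L)
    latent <- MASS::mvrnorm(n_samples, mu = c(0, 0), Sigma = sigma)
    subtype_names <- sprintf("subtype%d", seq_len(n_subtypes))
    rows <- expand.grid(sample = sprintf("S%02d", seq_len(n_samples)),
                        subtype = subtype_names, gene = genes,
                        stringsAsFactors = FALSE)
    si <- match(rows$sample, sprintf("S%02d", seq_len(n_samples)))
    gi <- match(rows$gene, genes)
    rows$value <- latent[cbind(si, gi)] + stats::rnorm(nrow(rows), 0, noise_sd)
    rows
  })
}

#' Generate multi-gene sample-level expression with planted correlations
#'
#' Independent standard-normal latent values per gene and sample, except
#' for designated (gene_a, gene_b, rho) triples whose second gene is made
#' to correlate with the first at the given level; replicated over
#' subtypes with independent noise. Used to exercise network-wide
#' co-expression testing.
#'
#' @param genes character vector of gene names.
#' @param n_samples number of samples.
#' @param n_subtypes subtypes per sample.
#' @param rho_pairs list of triples `list(a, b, rho)`; the `b` genes must
#'   be distinct.
#' @param seed RNG seed.
#' @param noise_sd subtype-level noise sd.
#' @return long-format data.frame with `sample`, `subtype`, `gene`,
#'   `value`.
#' @export
gen_sample_expression <- function(genes, n_samples = 6L, n_subtypes = 3L,
                                  rho_pairs = list(), seed = NULL,
                                  noise_sd = 0.1) {
  genes <- unique(genes)
  bs <- vapply(rho_pairs, function(p) p[[2L]], "")
  if (anyDuplicated(bs)) {
    stop("rho_pairs second genes must be distinct", call. = FALSE)
  }
  with_seed(seed, {
    latent <- matrix(stats::rnorm(n_samples * length(genes)),
                     nrow = n_samples, dimnames = list(NULL, genes))
    for (p in rho_pairs) {
      a <- p[[1L]]; b <- p[[2L]]; r <- p[[3L]]
      stopifnot(a %in% genes, b %in% genes, abs(r) <= 1)
      latent[, b] <- r * latent[, a] + sqrt(1 - r^2) * latent[, b]
    }
    rows <- expand.grid(sample = sprintf("S%02d", seq_len(n_samples)),
                        subtype = sprintf("subtype%d", seq_len(n_subtypes)),
                        gene = genes, stringsAsFactors = FALSE)
    si <- match(rows$sample, sprintf("S%02d", seq_len(n_samples)))
    gi <- match(rows$gene, genes)
    rows$value <- latent[cbind(si, gi)] + stats::rnorm(nrow(rows), 0, noise_sd)
    rows
  })
}
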