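# Immune-cell expression atlas: expressed / cell-specific gene
# classification and overrepresentation testing of mined cytokines.

.spec_classes <- c("not_detected", "low_specificity", "cell_type_enriched",
                   "group_enriched", "other")

#' Default blood immune cell types
#'
#' The eight blood cell types of the consensus immune-cell expression
#' atlas.
#'
#' @return character vector of cell-type names.
#' @export
default_cell_types <- function() {
  c("eosinophil", "basophil", "neutrophil", "T-cell", "B-cell",
    "monocyte", "NK-cell", "dendritic-cell")
}

#' Construct an expression atlas
#'
#' @param nx numeric matrix of normalized expression values (NX),
#'   cell types in rows, genes in columns; finite and non-negative.
#' @param spec_class named character vector, one specificity class per gene
#'   (`not_detected`, `low_specificity`, `cell_type_enriched`,
#'   `group_enriched`, `other`).
#' @param enriched_in named list mapping gene to the cell types it is
#'   enriched in; must be non-empty exactly for the cell-type-enriched and
#'   group-enriched genes.
#' @return object of class `expression_atlas`.
#' @export
expression_atlas <- function(nx, spec_class, enriched_in = list()) {
  stopifnot(is.matrix(nx), !is.null(rownames(nx)), !is.null(colnames(nx)))
  if (any(!is.finite(nx)) || any(nx < 0)) {
    stop("nx values must be finite and >= 0", call. = FALSE)
  }
  genes <- colnames(nx)
  stopifnot(setequal(names(spec_class), genes))
  spec_class <- spec_class[genes]
  bad <- setdiff(unique(spec_class), .spec_classes)
  if (length(bad)) stop("unknown spec_class: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  specific <- genes[spec_class %in% c("cell_type_enriched", "group_enriched")]
  for (g in specific) {
    cells <- enriched_in[[g]]
    if (!length(cells)) {
      stop("gene ", g, " is cell-specific but has empty enriched_in",
           call. = FALSE)
    }
    if (!all(cells %in% rownames(nx))) {
      stop("enriched_in for ", g, " names unknown cell types", call. = FALSE)
    }
  }
  structure(list(cell_types = rownames(nx), genes = genes, nx = nx,
                 spec_class = spec_class,
                 enriched_in = enriched_in[intersect(names(enriched_in), specific)]),
            class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat("<expression_atlas> ", length(x$cell_types), " cell types x ",
      length(x$genes), " genes\n", sep = "")
  print(table(x$spec_class))
  invisible(x)
}

#' Read an expression atlas from TSV
#'
#' Long format: one row per (gene, cell_type) with columns `gene`,
#' `cell_type`, `nx`, `spec_class`, `enriched_in` (comma-separated list of
#' cell types, empty when not cell-specific).
#'
#' @param path TSV file path.
#' @return an `expression_atlas`.
#' @export
read_atlas <- function(path) {
  df <- read_tsv_table(path, required_cols = c("gene", "cell_type", "nx",
                                               "spec_class", "enriched_in"))
  df$nx <- as.numeric(df$nx)
  if (any(!is.finite(df$nx)) || any(df$nx < 0)) {
    stop("schema violation in ", path, ": nx must be finite and >= 0",
         call. = FALSE)
  }
  cells <- unique(df$cell_type)
  genes <- unique(df$gene)
  nx <- matrix(0, nrow = length(cells), ncol = length(genes),
               dimnames = list(cells, genes))
  nx[cbind(match(df$cell_type, cells), match(df$gene, genes))] <- df$nx
  first <- df[!duplicated(df$gene), , drop = FALSE]
  spec_class <- stats::setNames(first$spec_class, first$gene)
  enriched_in <- stats::setNames(lapply(first$enriched_in, function(s) {
    if (is.na(s) || !nzchar(s)) character() else trimws(strsplit(s, ",")[[1L]])
  }), first$gene)
  enriched_in <- enriched_in[vapply(enriched_in, length, 0L) > 0L]
  expression_atlas(nx, spec_class, enriched_in)
}

#' Write an expression atlas to TSV
#'
#' @param atlas an `expression_atlas`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  rows <- expand.grid(cell_type = atlas$cell_types, gene = atlas$genes,
                      stringsAsFactors = FALSE)
  rows$nx <- atlas$nx[cbind(rows$cell_type, rows$gene)]
  rows$spec_class <- atlas$spec_class[rows$gene]
  rows$enriched_in <- vapply(rows$gene, function(g) {
    paste(atlas$enriched_in[[g]] %||% character(), collapse = ",")
  }, "")
  write_tsv_table(rows[, c("gene", "cell_type", "nx", "spec_class",
                           "enriched_in")], path)
}

#' Is a gene expressed in a cell type?
#'
#' A gene counts as expressed when its normalized expression value is
#' strictly greater than the threshold (default 1). Genes absent from the
#' atlas or reported as not detected return `"NOT_IN_ATLAS"`; network
#' stages drop such genes with a warning (the CCL18 situation: highly cited
#' in the literature yet not detected in the blood atlas).
#'
#' @param atlas an `expression_atlas`.
#' @param gene gene symbol.
#' @param cell cell-type name (must be one of the atlas's cell types).
#' @param threshold expression threshold; strict inequality.
#' @return `TRUE`, `FALSE`, or the string `"NOT_IN_ATLAS"`.
#' @export
is_expressed <- function(atlas, gene, cell, threshold = 1) {
  if (!cell %in% atlas$cell_types) {
    stop("unknown cell type: ", cell, call. = FALSE)
  }
  if (!gene %in% atlas$genes || atlas$spec_class[[gene]] == "not_detected") {
    return("NOT_IN_ATLAS")
  }
  unname(atlas$nx[cell, gene] > threshold)
}

# Vectorized expression test: TRUE/FALSE per gene, NA for genes absent from
# the atlas or not detected.
.expressed_vec <- function(atlas, genes, cell, threshold = 1) {
  if (!cell %in% atlas$cell_types) {
    stop("unknown cell type: ", cell, call. = FALSE)
  }
  res <- rep(NA, length(genes))
  known <- which(genes %in% atlas$genes)
  if (length(known)) {
    kg <- genes[known]
    detected <- atlas$spec_class[kg] != "not_detected"
    res[known[detected]] <- atlas$nx[cell, kg[detected]] > threshold
  }
  stats::setNames(res, genes)
}

#' Cell-specific gene sets of an atlas
#'
#' A gene belongs to the set of cell type c iff its specificity class is
#' cell-type enriched or group enriched and c is among the cell types it is
#' enriched in; a group-enriched gene therefore appears in every set of its
#' group.
#'
#' @param atlas an `expression_atlas`.
#' @return named list mapping each cell type to a character vector of genes.
#' @export
build_cell_specific_sets <- function(atlas) {
  sets <- stats::setNames(vector("list", length(atlas$cell_types)),
                          atlas$cell_types)
  for (ct in atlas$cell_types) sets[[ct]] <- character()
  specific <- names(atlas$enriched_in)
  for (g in specific) {
    for (ct in atlas$enriched_in[[g]]) {
      sets[[ct]] <- c(sets[[ct]], g)
    }
  }
  lapply(sets, sort)
}

#' One-sided Fisher overrepresentation test
#'
#' Upper-tail hypergeometric probability P(X >= overlap) of observing at
#' least the observed overlap between a query gene set and a target set
#' drawn without replacement from the universe. Sets overlapping the query
#' in fewer than `min_overlap` genes are not tested (no p-value), following
#' the rule that small overlaps carry too little signal.
#'
#' @param query query gene set (subset of `universe`).
#' @param target_set target gene set (subset of `universe`).
#' @param universe the background gene set.
#' @param set_name optional label for the target set.
#' @param min_overlap minimum overlap required to test (default 5).
#' @return one-row data.frame: `set_name`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p_value` (NA when not tested),
#'   `tested`.
#' @export
fisher_enrichment <- function(query, target_set, universe,
                              set_name = NA_character_, min_overlap = 5) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  query <- unique(query)
  target_set <- unique(target_set)
  if (!all(query %in% universe)) {
    stop("query must be a subset of the universe", call. = FALSE)
  }
  if (!all(target_set %in% universe)) {
    stop("target_set must be a subset of the universe", call. = FALSE)
  }
  ov <- length(intersect(query, target_set))
  tested <- ov >= min_overlap
  p <- if (tested) {
    stats::phyper(ov - 1L, length(target_set),
                  length(universe) - length(target_set), length(query),
                  lower.tail = FALSE)
  } else NA_real_
  data.frame(set_name = set_name, overlap = ov,
             set_size = length(target_set), query_size = length(query),
             universe_size = length(universe), p_value = p, tested = tested,
             stringsAsFactors = FALSE)
}

#' Test mined cytokines against every cell-specific set
#'
#' Runs [fisher_enrichment()] of a query gene list against the
#' cell-specific cytokine set of every cell type, with the dictionary
#' cytokines as universe. Query genes outside the universe are dropped
#' with a warning. When more than one set passes the overlap rule, BH
#' (false discovery rate) adjusted p-values are reported alongside the raw
#' ones.
#'
#' @param query mined cytokine gene symbols.
#' @param atlas an `expression_atlas`.
#' @param universe dictionary cytokine symbols (see [cytokine_universe()]).
#' @param min_overlap minimum overlap to test (default 5).
#' @return data.frame, one row per cell type, sorted by p-value, with a
#'   `p_adjust` column (NA for untested sets).
#' @export
cell_specificity_enrichment <- function(query, atlas, universe,
                                        min_overlap = 5) {
  extra <- setdiff(query, universe)
  if (length(extra)) {
    warning("query genes outside the universe dropped: ",
            paste(extra, collapse = ", "))
    query <- intersect(query, universe)
  }
  sets <- build_cell_specific_sets(atlas)
  rows <- lapply(names(sets), function(ct) {
    fisher_enrichment(query, intersect(sets[[ct]], universe), universe,
                      set_name = ct, min_overlap = min_overlap)
  })
  out <- do.call(rbind, rows)
  out$p_adjust <- NA_real_
  if (sum(out$tested) > 0L) {
    out$p_adjust[out$tested] <- stats::p.adjust(out$p_value[out$tested],
                                                method = "BH")
  }
  out[order(out$p_value, -out$overlap), , drop = FALSE]
}
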