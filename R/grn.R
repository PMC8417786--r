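# TF -> cytokine gene regulatory networks: construction from a curated
# regulatory-interaction table filtered by literature evidence and
# cell-type expression, plus co-expression testing at sample level.

#' Build a disease- and cell-specific TF-cytokine regulatory network
#'
#' Three sequential filters are applied to the interaction table:
#' (1) keep human interactions; (2) keep interactions whose cytokine was
#' identified by literature mining; (3) keep interactions whose TF and
#' cytokine are both expressed (NX strictly above the threshold) in the
#' cell type of interest. Genes absent from the atlas (or not detected)
#' are removed at step 3 and reported. Duplicate (tf, cytokine) rows
#' collapse to one directed edge; isolated nodes are never created.
#'
#' @param interactions data.frame with columns `tf`, `cytokine`, `species`.
#' @param mined_cytokines character vector of gene symbols from the mining
#'   stage.
#' @param atlas an `expression_atlas`.
#' @param cell target cell type.
#' @param expression_threshold NX threshold (default 1, strict inequality).
#' @param mined_tfs optional character vector of TF symbols found in the
#'   disease literature (annotated on the nodes).
#' @return a directed `igraph` with vertex attributes `role` (TF, cytokine
#'   or both) and `mined_in_literature`, and graph attributes `cell`,
#'   `expression_threshold` and `dropped_not_in_atlas`.
#' @export
build_grn <- function(interactions, mined_cytokines, atlas, cell,
                      expression_threshold = 1, mined_tfs = character()) {
  stopifnot(all(c("tf", "cytokine", "species") %in% names(interactions)))
  bad <- interactions$tf == interactions$cytokine
  if (any(bad)) {
    stop("self-regulation rows with identical symbols are not allowed",
         call. = FALSE)
  }
  step1 <- interactions[interactions$species == "human", , drop = FALSE]
  step2 <- step1[step1$cytokine %in% mined_cytokines, , drop = FALSE]
  genes <- unique(c(step2$tf, step2$cytokine))
  expr <- .expressed_vec(atlas, genes, cell, expression_threshold)
  not_in_atlas <- genes[is.na(expr)]
  ok <- function(g) !is.na(expr[g]) & expr[g]
  step3 <- step2[ok(step2$tf) & ok(step2$cytokine), , drop = FALSE]
  edges <- unique(step3[, c("tf", "cytokine")])
  if (length(not_in_atlas)) {
    warning("genes not in atlas (or not detected) removed from network: ",
            paste(sort(not_in_atlas), collapse = ", "))
  }
  if (!nrow(edges)) {
    warning("regulatory network is empty after filtering")
    g <- igraph::make_empty_graph(directed = TRUE)
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE)
    tfs <- unique(edges$tf)
    cyts <- unique(edges$cytokine)
    role <- ifelse(igraph::V(g)$name %in% tfs & igraph::V(g)$name %in% cyts,
                   "both",
                   ifelse(igraph::V(g)$name %in% tfs, "TF", "cytokine"))
    igraph::V(g)$role <- role
    igraph::V(g)$mined_in_literature <-
      igraph::V(g)$name %in% c(mined_cytokines, mined_tfs)
  }
  g <- igraph::set_graph_attr(g, "cell", cell)
  g <- igraph::set_graph_attr(g, "expression_threshold", expression_threshold)
  g <- igraph::set_graph_attr(g, "dropped_not_in_atlas",
                              paste(sort(not_in_atlas), collapse = ","))
  g
}

#' Degree profile of a regulatory network
#'
#' In-degree of a cytokine node counts its putative regulators; out-degree
#' of a TF node counts the cytokine genes it regulates.
#'
#' @param net an `igraph` from [build_grn()].
#' @return data.frame with `node`, `role`, `in_degree`, `out_degree`,
#'   sorted by out-degree then in-degree, descending.
#' @export
degree_profile <- function(net) {
  if (igraph::vcount(net) == 0L) {
    return(data.frame(node = character(), role = character(),
                      in_degree = integer(), out_degree = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(node = igraph::V(net)$name,
                   role = igraph::V(net)$role %||% NA_character_,
                   in_degree = as.integer(igraph::degree(net, mode = "in")),
                   out_degree = as.integer(igraph::degree(net, mode = "out")),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$out_degree, -df$in_degree, df$node), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Average subtype expression to sample level
#'
#' For correlation testing the atlas provides per-sample expression of cell
#' subtypes (e.g. classical, intermediate and non-classical monocytes); the
#' sample-level value of a gene is the arithmetic mean across the subtypes
#' measured for that sample. Samples lacking a gene in every subtype yield
#' NA for that gene, with a warning.
#'
#' @param raw long-format data.frame with columns `sample`, `subtype`,
#'   `gene`, `value`.
#' @param subtypes optional subset of subtypes to average over.
#' @return numeric matrix, samples in rows, genes in columns.
#' @export
sample_level_expression <- function(raw, subtypes = NULL) {
  stopifnot(all(c("sample", "subtype", "gene", "value") %in% names(raw)))
  if (!is.null(subtypes)) {
    raw <- raw[raw$subtype %in% subtypes, , drop = FALSE]
  }
  if (!nrow(raw)) stop("no expression rows after subtype selection",
                       call. = FALSE)
  samples <- unique(raw$sample)
  genes <- unique(raw$gene)
  mat <- tapply(raw$value, list(factor(raw$sample, levels = samples),
                                factor(raw$gene, levels = genes)),
                mean)
  mat <- matrix(as.numeric(mat), nrow = length(samples),
                dimnames = list(samples, genes))
  if (anyNA(mat)) {
    miss <- which(is.na(mat), arr.ind = TRUE)
    warning("samples with no measurement for a gene yield NA: ",
            paste(unique(sprintf("%s/%s", samples[miss[, 1L]],
                                 genes[miss[, 2L]])), collapse = ", "))
  }
  mat
}

#' Pearson co-expression test for every network edge
#'
#' For each TF -> cytokine edge, tests the Pearson product-moment
#' correlation of the two genes' sample-level expression: the p-value comes
#' from t = r * sqrt(n - 2) / sqrt(1 - r^2) against a t distribution with
#' n - 2 degrees of freedom, two-sided. Edges whose genes are missing from
#' the expression matrix, have fewer than three paired samples, or have
#' zero variance are excluded with a warning. Both raw and BH-adjusted
#' p-values are reported; `significant` uses the raw p-value against
#' `alpha`, and significant edges are flagged (`correlated`) in the
#' returned network.
#'
#' @param net an `igraph` from [build_grn()].
#' @param expr samples x genes numeric matrix
#'   (see [sample_level_expression()]).
#' @param alpha significance level (default 0.05).
#' @return list of class `grn_correlation` with `results` (data.frame:
#'   `tf`, `cytokine`, `r`, `p`, `p_adjust`, `n_samples`, `significant`)
#'   and `network` (the input graph with a `correlated` edge attribute).
#' @export
correlate_pairs <- function(net, expr, alpha = 0.05) {
  proto <- data.frame(tf = character(), cytokine = character(),
                      r = numeric(), p = numeric(), p_adjust = numeric(),
                      n_samples = integer(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (igraph::ecount(net) == 0L) {
    return(structure(list(results = proto, network = net),
                     class = "grn_correlation"))
  }
  el <- igraph::as_edgelist(net)
  skipped <- character()
  rows <- list()
  for (i in seq_len(nrow(el))) {
    tf <- el[i, 1L]; cyt <- el[i, 2L]
    if (!tf %in% colnames(expr) || !cyt %in% colnames(expr)) {
      skipped <- c(skipped, sprintf("%s->%s (gene missing)", tf, cyt))
      next
    }
    x <- expr[, tf]; y <- expr[, cyt]
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3L) {
      skipped <- c(skipped, sprintf("%s->%s (n < 3)", tf, cyt))
      next
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      skipped <- c(skipped, sprintf("%s->%s (zero variance)", tf, cyt))
      next
    }
    ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
    rows[[length(rows) + 1L]] <- data.frame(
      tf = tf, cytokine = cyt, r = unname(ct$estimate), p = ct$p.value,
      n_samples = length(x), stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    warning("edges excluded from correlation testing: ",
            paste(skipped, collapse = "; "))
  }
  if (!length(rows)) {
    return(structure(list(results = proto, network = net),
                     class = "grn_correlation"))
  }
  res <- do.call(rbind, rows)
  res$p_adjust <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p < alpha
  res <- res[, c("tf", "cytokine", "r", "p", "p_adjust", "n_samples",
                 "significant")]
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  sig_keys <- paste(res$tf[res$significant], res$cytokine[res$significant])
  edge_keys <- paste(el[, 1L], el[, 2L])
  igraph::E(net)$correlated <- edge_keys %in% sig_keys
  structure(list(results = res, network = net), class = "grn_correlation")
}

#' @export
print.grn_correlation <- function(x, ...) {
  cat("<grn_correlation> ", nrow(x$results), " edges tested, ",
      sum(x$results$significant), " significant\n", sep = "")
  invisible(x)
}

#' Export a network as a GraphML file and a TSV edge list
#'
#' @param net an `igraph`.
#' @param path_prefix output path without extension; writes
#'   `<prefix>.graphml` and `<prefix>_edges.tsv`.
#' @return character vector of the two paths, invisibly.
#' @export
export_network <- function(net, path_prefix) {
  gpath <- paste0(path_prefix, ".graphml")
  tpath <- paste0(path_prefix, "_edges.tsv")
  igraph::write_graph(net, gpath, format = "graphml")
  if (igraph::ecount(net) > 0L) {
    el <- as.data.frame(igraph::as_edgelist(net), stringsAsFactors = FALSE)
    names(el) <- c("from", "to")
    for (attr in igraph::edge_attr_names(net)) {
      el[[attr]] <- igraph::edge_attr(net, attr)
    }
  } else {
    el <- data.frame(from = character(), to = character())
  }
  write_tsv_table(el, tpath)
  invisible(c(gpath, tpath))
}
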