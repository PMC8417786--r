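# Ligand-receptor analysis: cytokine-receptor pair lookup, pathway
# overrepresentation against a custom background, and percentile-thresholded
# directed cell-cell communication networks.

#' Cytokine-receptor pairs for a cytokine list
#'
#' Selects from a ligand-receptor database all pairs whose ligand is one of
#' the given cytokines. Cytokines absent from the database contribute no
#' pairs and are returned in the `dropped` report rather than silently
#' ignored.
#'
#' @param cytokines character vector of cytokine gene symbols.
#' @param lrdb data.frame with columns `ligand` and `receptor`; pairs must
#'   be unique.
#' @return list with `pairs` (data.frame `ligand`, `receptor`) and
#'   `dropped` (cytokines not present in the database).
#' @export
find_cr_pairs <- function(cytokines, lrdb) {
  stopifnot(all(c("ligand", "receptor") %in% names(lrdb)))
  if (anyDuplicated(paste(lrdb$ligand, lrdb$receptor, sep = "\r"))) {
    stop("ligand-receptor pairs must be unique in the database",
         call. = FALSE)
  }
  cytokines <- unique(cytokines[!is.na(cytokines)])
  pairs <- lrdb[lrdb$ligand %in% cytokines, c("ligand", "receptor"),
                drop = FALSE]
  rownames(pairs) <- NULL
  dropped <- sort(setdiff(cytokines, lrdb$ligand))
  list(pairs = pairs, dropped = dropped)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False discovery rate control: q_i = min over j >= i of p_(j) * m / j,
#' capped at 1, mapped back to the input order.
#'
#' @param p numeric vector of p-values.
#' @return numeric vector of adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Pathway overrepresentation with a custom background
#'
#' Hypergeometric upper-tail test of each pathway against a query gene set,
#' after restricting every pathway to the background (the dictionary
#' cytokines and their receptors); pathways whose restricted size is below
#' `min_gs_size` are skipped. BH-adjusted q-values control the false
#' discovery rate across the tested pathways.
#'
#' @param genes query gene set; must be a subset of `background`.
#' @param pathways named list of gene sets (e.g. from [read_gmt()]).
#' @param background background gene set.
#' @param min_gs_size minimum restricted pathway size to test (default 5).
#' @return data.frame sorted by p-value with `pathway`, `overlap`,
#'   `set_size`, `p`, `q`; skipped pathways are listed in the `"skipped"`
#'   attribute.
#' @export
pathway_enrichment <- function(genes, pathways, background, min_gs_size = 5) {
  background <- unique(background)
  if (!length(background)) stop("empty background", call. = FALSE)
  genes <- unique(genes)
  if (!all(genes %in% background)) {
    stop("query genes must be a subset of the background", call. = FALSE)
  }
  rows <- list()
  skipped <- character()
  for (nm in names(pathways)) {
    set <- intersect(unique(pathways[[nm]]), background)
    if (length(set) < min_gs_size) {
      skipped <- c(skipped, nm)
      next
    }
    ov <- length(intersect(genes, set))
    p <- stats::phyper(ov - 1L, length(set), length(background) - length(set),
                       length(genes), lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      pathway = nm, overlap = ov, set_size = length(set), p = p,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(pathway = character(), overlap = integer(),
                      set_size = integer(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "skipped") <- skipped
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Percentile of a count distribution (linear interpolation)
#'
#' The quantile convention used for edge retention: linear interpolation
#' between order statistics (R's default type 7), the convention of the
#' analysis environment the workflow was designed in. For counts
#' (1, 2, 3, 4) the 75th percentile is 3.25.
#'
#' @param counts numeric vector.
#' @param percentile percentile in (0, 100).
#' @return the interpolated quantile.
#' @export
percentile_threshold <- function(counts, percentile) {
  stopifnot(percentile > 0, percentile < 100)
  unname(stats::quantile(counts, probs = percentile / 100, type = 7,
                         names = FALSE))
}

#' Build a directed cell-cell communication network
#'
#' For every ordered (sender, receiver) pair of the atlas's cell types
#' (self-pairs included), the edge weight is the number of
#' cytokine-receptor pairs whose ligand is expressed in the sender and
#' whose receptor is expressed in the receiver (NX strictly above the
#' threshold; genes absent from the atlas count as not expressed and are
#' reported). An edge is retained iff its pair count strictly exceeds the
#' requested percentile (linear interpolation) of the count distribution
#' over all ordered pairs; with all counts equal nothing is retained.
#'
#' @param pairs data.frame of ligand-receptor pairs (`ligand`, `receptor`).
#' @param atlas an `expression_atlas`.
#' @param percentile retention percentile in (0, 100), default 75.
#' @param expression_threshold NX threshold (default 1).
#' @param strict use strict `>` against the threshold value (default TRUE);
#'   set FALSE for a `>=` sensitivity analysis.
#' @return data.frame with `sender`, `receiver`, `pair_count`, `retained`,
#'   sorted by pair count descending; attributes `threshold` (the
#'   percentile value) and `dropped_genes` (genes not in the atlas).
#' @export
build_cell_network <- function(pairs, atlas, percentile = 75,
                               expression_threshold = 1, strict = TRUE) {
  stopifnot(percentile > 0, percentile < 100)
  cells <- atlas$cell_types
  genes <- unique(c(pairs$ligand, pairs$receptor))
  dropped <- character()
  expr <- matrix(FALSE, nrow = length(cells), ncol = length(genes),
                 dimnames = list(cells, genes))
  if (length(genes)) {
    for (ct in cells) {
      v <- .expressed_vec(atlas, genes, ct, expression_threshold)
      expr[ct, ] <- !is.na(v) & v
    }
    dropped <- sort(genes[!genes %in% atlas$genes |
                            atlas$spec_class[genes] %in% "not_detected"])
    dropped <- dropped[!is.na(dropped)]
  }
  grid <- expand.grid(sender = cells, receiver = cells,
                      stringsAsFactors = FALSE)
  grid$pair_count <- vapply(seq_len(nrow(grid)), function(i) {
    if (!nrow(pairs)) return(0L)
    sum(expr[grid$sender[i], pairs$ligand] &
          expr[grid$receiver[i], pairs$receptor])
  }, 0L)
  thr <- percentile_threshold(grid$pair_count, percentile)
  grid$retained <- if (strict) grid$pair_count > thr else grid$pair_count >= thr
  grid <- grid[order(-grid$pair_count, grid$sender, grid$receiver), ,
               drop = FALSE]
  rownames(grid) <- NULL
  attr(grid, "threshold") <- thr
  attr(grid, "dropped_genes") <- dropped
  grid
}

#' Convert a cell-cell edge table to an igraph
#'
#' @param cell_net data.frame from [build_cell_network()].
#' @param retained_only keep only retained edges (default TRUE).
#' @return a directed, weighted `igraph`.
#' @export
cell_network_graph <- function(cell_net, retained_only = TRUE) {
  edges <- if (retained_only) cell_net[cell_net$retained, , drop = FALSE]
           else cell_net
  if (!nrow(edges)) return(igraph::make_empty_graph(directed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$sender, to = edges$receiver,
               weight = edges$pair_count, stringsAsFactors = FALSE),
    directed = TRUE)
  g
}

#' Read pathway gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return named list of gene sets.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write pathway gene sets to a GMT file
#'
#' @param pathways named list of gene sets.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, nm, pathways[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
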