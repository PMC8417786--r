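# End-to-end orchestration: mining -> specificity -> regulatory network ->
# cell-cell communication, from a single JSON configuration, with input
# validation and a reproducibility manifest.

#' Read and validate a pipeline configuration
#'
#' @param path JSON config file. Recognized fields: `corpus`,
#'   `lexicon_tables` (path or vector of paths), `atlas`, `regdb`, `lrdb`,
#'   `pathways`, `expression` (optional), `diseases` (subset of GD, FD,
#'   ASMD), `target_cell`, `alpha` (default 0.05), `percentile` (default
#'   75), `min_overlap` (default 5), `min_gs_size` (default 5),
#'   `expression_threshold` (default 1), `seed`.
#' @return a validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  as_pipeline_config(cfg)
}

#' Construct a pipeline configuration from a list
#'
#' @param cfg named list of config fields (see [read_pipeline_config()]).
#' @return config list of class `pipeline_config` with defaults filled in.
#' @export
as_pipeline_config <- function(cfg) {
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$percentile <- cfg$percentile %||% 75
  cfg$min_overlap <- cfg$min_overlap %||% 5
  cfg$min_gs_size <- cfg$min_gs_size %||% 5
  cfg$expression_threshold <- cfg$expression_threshold %||% 1
  cfg$diseases <- cfg$diseases %||% c("GD", "FD", "ASMD")
  cfg$target_cell <- cfg$target_cell %||% "monocyte"
  cfg$seed <- cfg$seed %||% 1L
  stopifnot(cfg$alpha > 0, cfg$alpha < 1,
            cfg$percentile > 0, cfg$percentile < 100,
            cfg$min_overlap >= 1, cfg$min_gs_size >= 1,
            cfg$expression_threshold >= 0,
            all(cfg$diseases %in% c("GD", "FD", "ASMD")))
  structure(cfg, class = "pipeline_config")
}

#' Validate the input bundle of a pipeline configuration
#'
#' Schema-checks every input file and reports symbol-consistency coverage
#' (fractions of regulatory-table and ligand-receptor symbols present in
#' the atlas). Report-only: no error is raised for content issues.
#'
#' @param config a `pipeline_config`.
#' @return list with `issues` (data.frame `file`, `check`, `message`) and
#'   `coverage` (named fractions).
#' @export
validate_inputs <- function(config) {
  issues <- list()
  note <- function(file, check, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      file = file, check = check, message = message, stringsAsFactors = FALSE)
  }
  need <- c("corpus", "lexicon_tables", "atlas", "regdb", "lrdb", "pathways")
  for (f in need) {
    paths <- config[[f]]
    if (is.null(paths)) { note(f, "presence", "path not set"); next }
    for (p in paths) if (!file.exists(p)) note(p, "presence", "file not found")
  }
  coverage <- c(regdb_in_atlas = NA_real_, lrdb_in_atlas = NA_real_)
  atlas <- tryCatch(read_atlas(config$atlas), error = function(e) {
    note(config$atlas, "schema", conditionMessage(e)); NULL
  })
  if (!is.null(config$regdb) && file.exists(config$regdb)) {
    reg <- tryCatch(read_tsv_table(config$regdb,
                                   required_cols = c("tf", "cytokine",
                                                     "species")),
                    error = function(e) {
                      note(config$regdb, "schema", conditionMessage(e)); NULL
                    })
    if (!is.null(reg) && !is.null(atlas)) {
      syms <- unique(c(reg$tf, reg$cytokine))
      missing <- setdiff(syms, atlas$genes)
      coverage["regdb_in_atlas"] <- 1 - length(missing) / max(1L, length(syms))
      if (length(missing)) {
        note(config$regdb, "coverage",
             paste("symbols absent from atlas:",
                   paste(sort(missing), collapse = ", ")))
      }
    }
  }
  if (!is.null(config$lrdb) && file.exists(config$lrdb)) {
    lr <- tryCatch(read_tsv_table(config$lrdb,
                                  required_cols = c("ligand", "receptor")),
                   error = function(e) {
                     note(config$lrdb, "schema", conditionMessage(e)); NULL
                   })
    if (!is.null(lr) && !is.null(atlas)) {
      syms <- unique(c(lr$ligand, lr$receptor))
      missing <- setdiff(syms, atlas$genes)
      coverage["lrdb_in_atlas"] <- 1 - length(missing) / max(1L, length(syms))
      if (length(missing)) {
        note(config$lrdb, "coverage",
             paste("symbols absent from atlas:",
                   paste(sort(missing), collapse = ", ")))
      }
    }
  }
  if (!is.null(config$corpus) && file.exists(config$corpus)) {
    tryCatch(invisible(read_corpus(config$corpus)), error = function(e) {
      note(config$corpus, "schema", conditionMessage(e))
    })
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(file = character(), check = character(), message = character(),
               stringsAsFactors = FALSE)
  list(issues = issues, coverage = coverage)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order (mining, cell-type specificity,
#' regulatory network, cell-cell communication) for every selected
#' disease, writes all result tables plus a run manifest to `out_dir`, and
#' returns the results invisibly. A rerun with identical inputs produces
#' byte-identical result files (timings in the manifest excepted).
#'
#' @param config a `pipeline_config` (or a path to a JSON config).
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the per-stage results and the manifest.
#' @export
run_all <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- unlist(config[c("corpus", "lexicon_tables", "atlas", "regdb",
                            "lrdb", "pathways", "expression")])
  inputs <- inputs[!is.na(inputs) & file.exists(inputs)]
  manifest <- list(config = unclass(config),
                   input_digests = as.list(tools::md5sum(inputs)),
                   versions = list(R = as.character(getRversion()),
                                   cytolit = as.character(
                                     utils::packageVersion("cytolit"))),
                   timings = list(), warnings = character())
  warn_log <- character()
  timed <- function(stage, expr) {
    t0 <- Sys.time()
    res <- withCallingHandlers(expr, warning = function(w) {
      warn_log <<- c(warn_log, paste0(stage, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    manifest$timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs"))
    res
  }
  fail <- function(stage, e) {
    manifest$warnings <- warn_log
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  # --- mining ---
  mining <- tryCatch(timed("mining", {
    lexicon <- build_lexicon(config$lexicon_tables)
    docs <- read_corpus(config$corpus)
    res <- mine_corpus(docs, lexicon)
    res$lexicon <- lexicon
    res
  }), error = function(e) fail("mining", e))
  lexicon <- mining$lexicon
  assoc <- mining$associations[mining$associations$disease %in%
                                 config$diseases, , drop = FALSE]
  write_tsv_table(assoc[, c("disease", "cytokine_name", "gene_symbol",
                            "n_sentences", "n_articles",
                            "in_title_or_abstract")],
                  file.path(out_dir, "associations.tsv"))
  write_evidence(mining$filtered, file.path(out_dir, "evidence.jsonl"))
  mined <- split(assoc$gene_symbol, assoc$disease)
  if (length(config$diseases) == 3L) {
    venn <- compare_disease_lists(lapply(config$diseases, function(d) {
      mined[[d]] %||% character()
    }) |> stats::setNames(config$diseases))
    write_tsv_table(venn, file.path(out_dir, "venn.tsv"))
  }

  # --- specificity ---
  spec_res <- tryCatch(timed("specificity", {
    atlas <- read_atlas(config$atlas)
    universe <- cytokine_universe(lexicon)
    enr <- lapply(config$diseases, function(d) {
      q <- intersect(mined[[d]] %||% character(), universe)
      out <- cell_specificity_enrichment(q, atlas, universe,
                                         min_overlap = config$min_overlap)
      out$disease <- d
      out
    })
    list(atlas = atlas, universe = universe, enrichment = do.call(rbind, enr))
  }), error = function(e) fail("specificity", e))
  write_tsv_table(spec_res$enrichment,
                  file.path(out_dir, "cell_specificity_enrichment.tsv"))

  # --- regulatory network ---
  grn_res <- tryCatch(timed("grn", {
    reg <- read_tsv_table(config$regdb,
                          required_cols = c("tf", "cytokine", "species"))
    nets <- list()
    cors <- list()
    for (d in config$diseases) {
      net <- build_grn(reg, mined[[d]] %||% character(), spec_res$atlas,
                       config$target_cell,
                       expression_threshold = config$expression_threshold)
      nets[[d]] <- net
      export_network(net, file.path(out_dir, sprintf("grn_%s_%s", d,
                                                     config$target_cell)))
      write_tsv_table(degree_profile(net),
                      file.path(out_dir, sprintf("grn_%s_degrees.tsv", d)))
    }
    if (!is.null(config$expression) && file.exists(config$expression)) {
      raw <- read_tsv_table(config$expression,
                            required_cols = c("sample", "subtype", "gene",
                                              "value"))
      raw$value <- as.numeric(raw$value)
      expr <- sample_level_expression(raw)
      d1 <- config$diseases[1L]
      cors <- correlate_pairs(nets[[d1]], expr, alpha = config$alpha)
      write_tsv_table(cors$results, file.path(out_dir, "correlations.tsv"))
    }
    list(networks = nets, correlations = cors)
  }), error = function(e) fail("grn", e))

  # --- cell-cell communication ---
  cc_res <- tryCatch(timed("cellcomm", {
    lr <- read_tsv_table(config$lrdb, required_cols = c("ligand", "receptor"))
    pathways <- read_gmt(config$pathways)
    out <- list()
    for (d in config$diseases) {
      cr <- find_cr_pairs(mined[[d]] %||% character(), lr)
      background <- unique(c(intersect(cytokine_universe(lexicon),
                                       lr$ligand),
                             lr$receptor[lr$ligand %in%
                                           cytokine_universe(lexicon)]))
      genes <- unique(c(cr$pairs$ligand, cr$pairs$receptor))
      enr <- pathway_enrichment(intersect(genes, background), pathways,
                                background,
                                min_gs_size = config$min_gs_size)
      net <- build_cell_network(cr$pairs, spec_res$atlas,
                                percentile = config$percentile,
                                expression_threshold =
                                  config$expression_threshold)
      write_tsv_table(net, file.path(out_dir,
                                     sprintf("cellnet_%s.tsv", d)))
      write_tsv_table(enr, file.path(out_dir,
                                     sprintf("pathway_enrichment_%s.tsv", d)))
      export_network(cell_network_graph(net),
                     file.path(out_dir, sprintf("cellnet_%s", d)))
      out[[d]] <- list(cr_pairs = cr, pathway_enrichment = enr,
                       cell_network = net)
    }
    out
  }), error = function(e) fail("cellcomm", e))

  manifest$warnings <- warn_log
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(mining = mining, specificity = spec_res, grn = grn_res,
                 cellcomm = cc_res, manifest = manifest))
}
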