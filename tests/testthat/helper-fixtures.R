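# Shared fixtures, built in code at test time.

.fixture_env <- new.env(parent = emptyenv())

# Default dictionary, built once per test run.
tiny_lexicon <- function() {
  if (is.null(.fixture_env$lex)) {
    .fixture_env$lex <- build_lexicon(default_lexicon_tables())
  }
  .fixture_env$lex
}

# Minimal atlas: 8 cell types, a planted monocyte-specific cytokine block,
# one group-enriched gene, one not-detected gene.
fixture_atlas <- function(seed = 11) {
  lex <- tiny_lexicon()
  uni <- cytokine_universe(lex)
  mono6 <- c("CCL1", "CCL2", "CXCL10", "CXCL12", "IL1RN", "EPO")
  gen_atlas(list(
    n_genes = 60,
    genes = uni,
    planted_specific = list(monocyte = mono6,
                            "dendritic-cell" = "IL13"),
    expression_noise = 0.5,
    not_detected = "CCL18",
    seed = seed))
}

# The canonical GD cytokine list of the synthetic study: the shared six
# plus the monocyte-specific six plus CCL18.
fixture_gd_cytokines <- function() {
  c("TNF", "IL6", "IL1B", "IL4", "CXCL8", "CCL5", "CCL18",
    "CCL1", "CCL2", "CXCL10", "CXCL12", "IL1RN", "EPO")
}

# Write a complete synthetic input bundle to `dir` and return a pipeline
# config pointing at it.
fixture_bundle <- function(dir, seed = 5, decoy_fraction = 0.5) {
  lex <- tiny_lexicon()
  uni <- cytokine_universe(lex)
  tfs <- default_tf_pool()
  write_tsv_table(default_lexicon_tables(), file.path(dir, "lexicon.tsv"))
  gc <- gen_corpus(list(n_documents = 20,
                        planted_associations = default_planted_associations(),
                        decoy_fraction = decoy_fraction, seed = seed), lex)
  write_corpus(gc$documents, file.path(dir, "corpus.jsonl"))
  lr <- gen_lrdb(list(ligands = uni, n_receptors = 30,
                      mean_pairs_per_ligand = 2, seed = seed + 1))
  write_tsv_table(lr, file.path(dir, "lrdb.tsv"))
  gd <- unique(gc$truth$gene_symbol[gc$truth$disease == "GD"])
  at <- gen_atlas(list(
    n_genes = 140, genes = c(uni, unique(lr$receptor), tfs),
    planted_specific = list(monocyte = c("CCL1", "CCL2", "CXCL10", "CXCL12",
                                         "IL1RN", "EPO")),
    planted_expressed = list(monocyte = c(setdiff(gd, "CCL18"), tfs),
                             "T-cell" = unique(lr$receptor)),
    expression_noise = 0.5, not_detected = "CCL18", seed = seed + 2))
  write_atlas(at$atlas, file.path(dir, "atlas.tsv"))
  reg <- gen_regdb(list(tfs = tfs, cytokines = uni, edge_probability = 0.25,
                        species_mix = c(human = 0.85, mouse = 0.15),
                        seed = seed + 3))
  write_tsv_table(reg, file.path(dir, "regdb.tsv"))
  pw <- gen_pathways(list(pool = c(uni, unique(lr$receptor)), n_pathways = 8,
                          enriched_in = gd, seed = seed + 4))
  write_gmt(pw, file.path(dir, "pathways.gmt"))
  ex <- gen_sample_expression(c(tfs, uni), n_samples = 6,
                              rho_pairs = list(list("STAT2", "CCL2", 0.97),
                                               list("JUN", "TNF", 0.97)),
                              seed = seed + 5)
  write_tsv_table(ex, file.path(dir, "expression.tsv"))
  cfg <- as_pipeline_config(list(
    corpus = file.path(dir, "corpus.jsonl"),
    lexicon_tables = file.path(dir, "lexicon.tsv"),
    atlas = file.path(dir, "atlas.tsv"),
    regdb = file.path(dir, "regdb.tsv"),
    lrdb = file.path(dir, "lrdb.tsv"),
    pathways = file.path(dir, "pathways.gmt"),
    expression = file.path(dir, "expression.tsv"),
    seed = seed))
  list(config = cfg, truth = gc$truth)
}

# Draw k elements from a character pool / one value from an integer range,
# avoiding sample()'s scalar expansion.
take_k <- function(pool, k) if (k <= 0L) character() else sample(pool, k)
pick_one <- function(rng) if (length(rng) == 1L) rng else sample(rng, 1L)

# Independent hypergeometric upper-tail oracle by direct enumeration of
# binomial coefficients (no distribution functions).
hyper_tail_oracle <- function(overlap, set_size, universe_size, query_size) {
  ks <- seq(overlap, min(set_size, query_size))
  if (!length(ks) || overlap > min(set_size, query_size)) return(0)
  sum(choose(set_size, ks) *
        choose(universe_size - set_size, query_size - ks)) /
    choose(universe_size, query_size)
}

# Independent BH step-up oracle: q_i = min_{j >= i} p_(j) * m / j, capped.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# Independent linear-interpolation percentile oracle (sort and interpolate
# between order statistics).
percentile_oracle <- function(x, pct) {
  xs <- sort(x)
  h <- (length(xs) - 1) * pct / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}
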