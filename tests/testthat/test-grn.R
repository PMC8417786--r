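# Regulatory network construction, degree accounting, sample-level
# expression averaging, and Pearson co-expression testing.

grn_fixture_atlas <- function(expressed, absent = character()) {
  genes <- unique(c(names(expressed), absent))
  nx <- matrix(0.5, nrow = 2, ncol = length(genes),
               dimnames = list(c("monocyte", "T-cell"), genes))
  nx["monocyte", names(expressed)] <- unlist(expressed)
  cls <- stats::setNames(rep("low_specificity", length(genes)), genes)
  cls[absent] <- "not_detected"
  expression_atlas(nx, cls)
}

test_that("the three filters are applied in sequence on a hand-checked table", {
  inter <- data.frame(
    tf = c("STAT1", "STAT1", "JUN", "IRF7", "VDR"),
    cytokine = c("TNF", "IL6", "TNF", "CCL2", "TNF"),
    species = c("human", "human", "human", "human", "mouse"),
    stringsAsFactors = FALSE)
  atlas <- grn_fixture_atlas(list(STAT1 = 5, JUN = 5, TNF = 5, IL6 = 5,
                                  IRF7 = 0.2, CCL2 = 5))
  # mouse row out; CCL2 row out (IRF7 below threshold); IL6 not mined
  net <- build_grn(inter, mined_cytokines = c("TNF", "CCL2"), atlas,
                   "monocyte")
  el <- igraph::as_edgelist(net)
  expect_identical(nrow(el), 2L)
  expect_setequal(paste(el[, 1], el[, 2]), c("STAT1 TNF", "JUN TNF"))
  expect_setequal(igraph::V(net)$role[igraph::V(net)$name == "TNF"],
                  "cytokine")
})

test_that("degenerate inputs: no mined cytokines, duplicates, absent genes", {
  inter <- data.frame(tf = c("STAT1", "STAT1"), cytokine = c("TNF", "TNF"),
                      species = "human", stringsAsFactors = FALSE)
  atlas <- grn_fixture_atlas(list(STAT1 = 5, TNF = 5))
  expect_warning(net0 <- build_grn(inter, character(), atlas, "monocyte"),
                 "empty")
  expect_identical(igraph::ecount(net0), 0)
  # duplicated evidence rows collapse to one edge
  net1 <- build_grn(inter, "TNF", atlas, "monocyte")
  expect_identical(igraph::ecount(net1), 1)
  # a not-detected gene is removed with a warning naming it
  atlas2 <- grn_fixture_atlas(list(STAT1 = 5), absent = "TNF")
  expect_warning(
    expect_warning(build_grn(inter, "TNF", atlas2, "monocyte"), "TNF"),
    "empty")
})

test_that("degree profile reports regulator fan-out", {
  # a STAT1-like hub regulating seven cytokines
  targets <- c("IL10", "IL1B", "CCL2", "TNF", "CXCL10", "CXCL11", "CXCL9")
  inter <- data.frame(tf = "STAT1", cytokine = targets, species = "human",
                      stringsAsFactors = FALSE)
  expressed <- stats::setNames(as.list(rep(5, 8)), c("STAT1", targets))
  net <- build_grn(inter, targets, grn_fixture_atlas(expressed), "monocyte")
  prof <- degree_profile(net)
  expect_identical(prof$out_degree[prof$node == "STAT1"], 7L)
  expect_identical(prof$in_degree[prof$node == "STAT1"], 0L)
  expect_true(all(prof$in_degree[prof$role == "cytokine"] == 1L))
  expect_identical(sum(prof$in_degree), sum(prof$out_degree))
  expect_identical(nrow(degree_profile(igraph::make_empty_graph())), 0L)
})

test_that("filters commute and are monotone in the expression threshold", {
  set.seed(404)
  tf_pool <- default_tf_pool()
  cyt_pool <- paste0("CYT", 1:12)
  for (rep in 1:25) {
    inter <- data.frame(
      tf = sample(tf_pool, 30, replace = TRUE),
      cytokine = sample(cyt_pool, 30, replace = TRUE),
      species = sample(c("human", "mouse", "other"), 30, replace = TRUE,
                       prob = c(0.6, 0.3, 0.1)),
      stringsAsFactors = FALSE)
    inter <- inter[inter$tf != inter$cytokine, ]
    genes <- unique(c(inter$tf, inter$cytokine))
    nx <- matrix(stats::rlnorm(2 * length(genes)), nrow = 2,
                 dimnames = list(c("monocyte", "T-cell"), genes))
    atlas <- expression_atlas(
      nx, stats::setNames(rep("low_specificity", length(genes)), genes))
    mined <- sample(cyt_pool, 6)
    net <- suppressWarnings(build_grn(inter, mined, atlas, "monocyte"))
    edge_key <- function(g) {
      if (igraph::ecount(g) == 0) return(character())
      el <- igraph::as_edgelist(g)
      sort(paste(el[, 1], el[, 2]))
    }
    # manual filters applied in every order give the same edge set
    f_species <- function(x) x[x$species == "human", , drop = FALSE]
    f_mined <- function(x) x[x$cytokine %in% mined, , drop = FALSE]
    f_expr <- function(x) {
      ok <- function(g) !is.na(nx["monocyte", g]) & nx["monocyte", g] > 1
      x[ok(x$tf) & ok(x$cytokine), , drop = FALSE]
    }
    for (ord in list(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
      res <- inter
      for (f in list(f_species, f_mined, f_expr)[ord]) res <- f(res)
      expect_setequal(edge_key(net),
                      unique(paste(res$tf, res$cytokine)))
    }
    # raising the threshold never adds edges
    net_hi <- suppressWarnings(build_grn(inter, mined, atlas, "monocyte",
                                         expression_threshold = 2))
    expect_true(all(edge_key(net_hi) %in% edge_key(net)))
    net_inf <- suppressWarnings(build_grn(inter, mined, atlas, "monocyte",
                                          expression_threshold = Inf))
    expect_identical(igraph::ecount(net_inf), 0)
  }
})

test_that("subtype averaging yields sample-level means", {
  raw <- data.frame(
    sample = rep(c("S1", "S2"), each = 3),
    subtype = rep(c("classical", "intermediate", "nonclassical"), 2),
    gene = "TNF",
    value = c(2, 4, 6, 1, 2, 3), stringsAsFactors = FALSE)
  m <- sample_level_expression(raw)
  expect_equal(m["S1", "TNF"], 4)
  expect_equal(m["S2", "TNF"], 2)
  # one subtype missing: mean over the available ones
  m2 <- sample_level_expression(raw[-3, ])
  expect_equal(m2["S1", "TNF"], 3)
  # 6 samples x 3 subtypes x G genes -> 6 x G matrix, direct-average oracle
  ex <- gen_correlated_expression(0.5, 6, 3, seed = 7,
                                  genes = c("STAT2", "CCL2"))
  m3 <- sample_level_expression(ex)
  expect_identical(dim(m3), c(6L, 2L))
  oracle <- tapply(ex$value, list(ex$sample, ex$gene), mean)
  expect_equal(m3["S03", "CCL2"], oracle["S03", "CCL2"])
  # a sample with no measurement for a gene warns
  expect_warning(sample_level_expression(
    rbind(raw, data.frame(sample = "S1", subtype = "classical",
                          gene = "IL6", value = 1))), "NA")
})

test_that("Pearson testing matches the analytic t-tail and flags edges", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("TF1", "TF2", "TF3"),
               to = c("CYT1", "CYT2", "CYT3")), directed = TRUE)
  x <- as.numeric(1:6)
  y_perfect <- 2 * x
  z <- c(3, 1, 4, 1, 5, 9)
  y_orth <- stats::resid(stats::lm(z ~ x))  # exactly uncorrelated with x
  y_strong <- c(1.1, 2.3, 2.9, 4.4, 4.8, 6.5)
  expr <- cbind(TF1 = x, CYT1 = y_perfect, TF2 = x, CYT2 = y_orth,
                TF3 = x, CYT3 = y_strong)
  rownames(expr) <- paste0("S", 1:6)
  out <- correlate_pairs(g, expr)
  res <- out$results
  expect_equal(res$r[res$tf == "TF1"], 1)
  expect_lt(res$p[res$tf == "TF1"], 1e-10)
  expect_equal(res$r[res$tf == "TF2"], 0, tolerance = 1e-12)
  expect_equal(res$p[res$tf == "TF2"], 1, tolerance = 1e-12)
  # independent oracle: r from the definition, p by numeric integration of
  # the t density with n - 2 degrees of freedom
  r_def <- sum((x - mean(x)) * (y_strong - mean(y_strong))) /
    sqrt(sum((x - mean(x))^2) * sum((y_strong - mean(y_strong))^2))
  tval <- r_def * sqrt(4) / sqrt(1 - r_def^2)
  dens <- function(u) {
    gamma(2.5) / (sqrt(4 * pi) * gamma(2)) * (1 + u^2 / 4)^(-2.5)
  }
  p_oracle <- 2 * stats::integrate(dens, abs(tval), Inf,
                                   rel.tol = 1e-12)$value
  expect_equal(res$r[res$tf == "TF3"], r_def, tolerance = 1e-12)
  expect_equal(res$p[res$tf == "TF3"], p_oracle, tolerance = 1e-8)
  expect_true(all(res$n_samples == 6L))
  expect_identical(res$significant, res$p < 0.05)
  expect_identical(sum(igraph::E(out$network)$correlated),
                   sum(res$significant))
  # zero variance excluded with a warning
  expr2 <- cbind(expr, TF4 = rep(1, 6), CYT4 = x)
  g2 <- igraph::graph_from_data_frame(
    data.frame(from = c("TF1", "TF4"), to = c("CYT1", "CYT4")))
  expect_warning(out2 <- correlate_pairs(g2, expr2), "zero variance")
  expect_identical(nrow(out2$results), 1L)
})

test_that("estimated correlations recover the truth at n = 50", {
  # lighter companion to the acceptance check: one rho, 120 replicates
  rho <- 0.5
  inside <- 0L
  for (i in 1:120) {
    ex <- gen_correlated_expression(rho, 50, 3, seed = 5000 + i)
    m <- sample_level_expression(ex)
    r <- stats::cor(m[, 1], m[, 2])
    if (abs(atanh(r) - atanh(rho)) <= stats::qnorm(0.975) / sqrt(50 - 3)) {
      inside <- inside + 1L
    }
  }
  expect_gte(inside / 120, 0.90)
})
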