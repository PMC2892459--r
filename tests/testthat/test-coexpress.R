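make_expr <- function(values, timepoints, replicates) {
  samples <- data.frame(sample = paste0("s", seq_len(ncol(values))),
                        timepoint = timepoints, replicate = replicates,
                        stringsAsFactors = FALSE)
  expression_matrix(values, samples)
}

test_that("the DE filter applies inclusive fold-change and p cut-offs", {
  # 2 timepoints x 3 replicates, constant within group so means are exact
  v <- rbind(big = c(5, 5, 5, 6.5, 6.5, 6.5),    # log2FC 1.5 (~2.8-fold)
             small = c(5, 5, 5, 5.4, 5.4, 5.4),  # log2FC 0.4 (< 1.5-fold)
             exact = c(5, 5, 5, 6, 6, 6))        # log2FC exactly 1 = log2(2)
  expr <- make_expr(v, timepoints = c(0, 0, 0, 4, 4, 4),
                    replicates = c(1:3, 1:3))
  p <- matrix(c(0.01, 0.01, 0.05), ncol = 1,
              dimnames = list(rownames(v), "4"))
  kept <- de_filter(expr, baseline = 0, fc_cut = 2, p_cut = 0.05,
                    p_values = p)
  # both cut-offs inclusive: the exact-boundary transcript is kept
  expect_setequal(kept, c("big", "exact"))
  # low fold change is dropped regardless of p
  expect_false("small" %in% kept)
  expect_error(de_filter(expr, baseline = 99), "unknown baseline")
})

test_that("the built-in Welch test keeps clear signals and drops noise", {
  set.seed(2)
  n <- 60
  v <- matrix(rnorm(n * 6, mean = 7, sd = 0.1), nrow = n,
              dimnames = list(sprintf("TX%02d", 1:n), NULL))
  v[1:5, 4:6] <- v[1:5, 4:6] + 2          # strongly induced
  expr <- make_expr(v, timepoints = c(0, 0, 0, 2, 2, 2),
                    replicates = c(1:3, 1:3))
  kept <- de_filter(expr, baseline = 0)
  expect_setequal(kept, sprintf("TX%02d", 1:5))
})

test_that("the DE filter is monotone in its cut-offs (property)", {
  res <- synth_expression(expression_spec(n_transcripts = 120, seed = 31))
  base <- de_filter(res$expr, 0, fc_cut = 1.5, p_cut = 0.05)
  expect_true(all(base %in% de_filter(res$expr, 0, fc_cut = 1.2,
                                      p_cut = 0.05)))
  expect_true(all(base %in% de_filter(res$expr, 0, fc_cut = 1.5,
                                      p_cut = 0.2)))
})

test_that("the correlation graph thresholds signed Pearson r", {
  # hand-computed 4-sample profiles: r(x, y) = 6.5/sqrt(5 * 8.75) = 0.9827;
  # z is anti-/un-correlated with both
  v <- rbind(x = c(0, 1, 2, 3), y = c(0, 1, 2, 4), z = c(3, 0, 2, 1))
  expr <- make_expr(v, timepoints = c(0, 1, 2, 4), replicates = rep(1L, 4))
  g <- correlation_graph(expr, r_cut = 0.9)
  expect_equal(sort(igraph::V(g)$name), c("x", "y"))
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$weight[1L], 6.5 / sqrt(5 * 8.75),
               tolerance = 1e-12)

  # identical profiles correlate at exactly 1
  v2 <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1))
  g2 <- correlation_graph(make_expr(v2, c(0, 1, 2, 4), rep(1L, 4)),
                          r_cut = 0.9)
  expect_equal(igraph::E(g2)$weight, 1)
  # perfectly anti-correlated profiles do not connect (signed threshold)
  expect_false("c" %in% igraph::V(g2)$name)

  # zero-variance transcripts are excluded with a warning
  v3 <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), flat = c(2, 2, 2, 2))
  expect_warning(g3 <- correlation_graph(make_expr(v3, c(0, 1, 2, 4),
                                                   rep(1L, 4))),
                 "zero-variance")
  expect_false("flat" %in% igraph::V(g3)$name)
  expect_error(correlation_graph(expr, r_cut = 1.2), "r_cut")
})

test_that("MCL separates disconnected cliques exactly and keeps columns
           stochastic at every iteration", {
  el <- rbind(c("a", "b"), c("b", "c"), c("a", "c"),
              c("x", "y"), c("y", "z"), c("x", "z"))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  sums_ok <- TRUE
  part <- mcl_cluster(g, inflation = 2.2, on_iterate = function(M, it) {
    sums_ok <<- sums_ok && all(abs(colSums(M) - 1) < 1e-10)
  })
  expect_true(sums_ok)
  expect_equal(canonical_partition(part$clusters),
               list(c("a", "b", "c"), c("x", "y", "z")))
  expect_true(part$converged)

  # single node -> one singleton cluster
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(g1)$name <- "only"
  expect_equal(mcl_cluster(g1)$clusters, list("only"))
  expect_error(mcl_cluster(g, inflation = 1), "inflation")
})

test_that("MCL at inflation 2.2 splits two 5-cliques at their bridge,
           agreeing with an independent reference iteration", {
  cl1 <- paste0("a", 1:5); cl2 <- paste0("b", 1:5)
  el <- rbind(t(combn(cl1, 2)), t(combn(cl2, 2)), c("a1", "b1"))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  part <- mcl_cluster(g, inflation = 2.2)
  expect_equal(canonical_partition(part$clusters),
               list(sort(cl1), sort(cl2)))
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  expect_equal(canonical_partition(reference_mcl(adj, 2.2)),
               canonical_partition(part$clusters))
})

test_that("class-set export applies the strict size filter and direction
           labels", {
  res <- synth_expression(expression_spec(
    n_transcripts = 60,
    modules = data.frame(size = c(12, 8, 5), peak_lfc = c(2, -2, 1.8),
                         peak_time = c(2, 2, 4), rho = 0.95),
    seed = 7))
  part <- structure(list(clusters = split(res$truth$transcript,
                                          res$truth$module)[c("1", "2", "3")],
                         inflation = 2.2, iterations = 1L, converged = TRUE),
                    class = "mepn_partition")
  sets <- clusters_to_class_sets(part, res$expr, baseline = 0, min_size = 5)
  # size-5 cluster excluded by the strict threshold
  expect_length(sets, 2L)
  expect_equal(vapply(sets, function(s) length(s$members), integer(1L)),
               c(12L, 8L))
  expect_equal(vapply(sets, `[[`, character(1L), "direction"),
               c("up", "down"))
  expect_equal(vapply(sets, `[[`, character(1L), "name"),
               c("cluster1", "cluster2"))
  # everything filtered -> empty list
  expect_length(clusters_to_class_sets(part, res$expr, 0, min_size = 50), 0L)
})

test_that("expression TSV round-trips through read_expression", {
  res <- synth_expression(expression_spec(
    n_transcripts = 30,
    modules = data.frame(size = 10, peak_lfc = 2, peak_time = 2, rho = 0.9),
    seed = 3))
  fv <- tempfile(fileext = ".tsv"); fs <- tempfile(fileext = ".tsv")
  write_expression(res$expr, fv, fs)
  back <- read_expression(fv, fs)
  expect_equal(back$values, res$expr$values, tolerance = 1e-9)
  expect_equal(back$samples$timepoint, res$expr$samples$timepoint)
})
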