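# Co-expression pipeline: differential-expression filter -> Pearson
# correlation graph -> Markov clustering -> class-set export.

#' Construct an expression matrix object
#'
#' @param values Numeric matrix, transcripts x samples, log2-scale normalized
#'   intensities; row names are transcript symbols.
#' @param samples Data frame with columns `sample`, `timepoint`, `replicate`
#'   (one row per column of `values`).
#' @return An object of class `mepn_expr`.
#' @export
expression_matrix <- function(values, samples) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || any(!nzchar(rownames(values)))) {
    stop("transcript symbols (row names) are required and must be non-empty")
  }
  need <- c("sample", "timepoint", "replicate")
  if (!all(need %in% names(samples))) {
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(samples) != ncol(values)) {
    stop("sample sheet rows must match matrix columns")
  }
  if (anyNA(samples$timepoint) || anyNA(samples$replicate)) {
    stop("missing sample annotations")
  }
  colnames(values) <- samples$sample
  structure(list(values = values, samples = samples), class = "mepn_expr")
}

#' @export
print.mepn_expr <- function(x, ...) {
  cat("expression matrix:", nrow(x$values), "transcripts x",
      ncol(x$values), "samples (",
      length(unique(x$samples$timepoint)), "timepoints )\n")
  invisible(x)
}

row_welch_p <- function(v1, v0) {
  m1 <- rowMeans(v1); m0 <- rowMeans(v0)
  n1 <- ncol(v1); n0 <- ncol(v0)
  s1 <- apply(v1, 1L, stats::var); s0 <- apply(v0, 1L, stats::var)
  se2 <- s1 / n1 + s0 / n0
  tt <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((s1 / n1)^2 / (n1 - 1L) + (s0 / n0)^2 / (n0 - 1L))
  p <- 2 * stats::pt(-abs(tt), df)
  # degenerate rows: both groups constant
  zero <- se2 == 0
  p[zero] <- ifelse(m1[zero] == m0[zero], 1, 0)
  p
}

#' Differential-expression filter
#'
#' A transcript is kept iff at any non-baseline timepoint the absolute log2
#' mean difference versus baseline is at least `log2(fc_cut)` AND the
#' per-transcript two-sample test p-value is at most `p_cut` (both cut-offs
#' inclusive). The built-in test is Welch's t on the log2 values; a
#' precomputed p-value table (transcripts x non-baseline timepoints, e.g.
#' from an empirical-Bayes moderated fit) may be supplied instead via
#' `p_values`.
#'
#' @param expr An `mepn_expr`.
#' @param baseline Baseline timepoint value.
#' @param fc_cut Fold-change cut-off on the natural scale (default 1.5).
#' @param p_cut P-value cut-off (default 0.05).
#' @param p_values Optional matrix of p-values (rows matching transcripts,
#'   columns named by non-baseline timepoint).
#' @return Character vector of kept transcript symbols, with attribute
#'   `stats` (per-transcript peak log2 fold change and minimum p).
#' @export
de_filter <- function(expr, baseline, fc_cut = 1.5, p_cut = 0.05,
                      p_values = NULL) {
  stopifnot(inherits(expr, "mepn_expr"))
  tps <- unique(expr$samples$timepoint)
  if (!baseline %in% tps) stop("unknown baseline timepoint: ", baseline)
  others <- setdiff(tps, baseline)
  v0 <- expr$values[, expr$samples$timepoint == baseline, drop = FALSE]
  if (is.null(p_values) && ncol(v0) < 2L) {
    stop("the built-in test needs >= 2 replicates per timepoint")
  }
  lfc <- matrix(NA_real_, nrow(expr$values), length(others),
                dimnames = list(rownames(expr$values), others))
  pmat <- lfc
  for (j in seq_along(others)) {
    v1 <- expr$values[, expr$samples$timepoint == others[j], drop = FALSE]
    lfc[, j] <- rowMeans(v1) - rowMeans(v0)
    pmat[, j] <- if (is.null(p_values)) row_welch_p(v1, v0) else
      p_values[rownames(expr$values), as.character(others[j])]
  }
  hit <- abs(lfc) >= log2(fc_cut) & pmat <= p_cut
  keep <- rownames(expr$values)[rowSums(hit) > 0L]
  peak_j <- apply(abs(lfc), 1L, which.max)
  st <- data.frame(transcript = rownames(expr$values),
                   peak_lfc = lfc[cbind(seq_len(nrow(lfc)), peak_j)],
                   min_p = apply(pmat, 1L, min), stringsAsFactors = FALSE)
  attr(keep, "stats") <- st
  keep
}

#' Pearson correlation graph over transcripts
#'
#' Edge (i, j) exists iff the signed Pearson correlation of the two profiles
#' across all samples is at least `r_cut` (anti-correlated profiles do not
#' connect: co-expression clusters are coherent up- or down-profiles). Edge
#' weight is r. Zero-variance transcripts are excluded with a warning and
#' transcripts with no edge are dropped.
#'
#' @param expr An `mepn_expr`.
#' @param transcripts Optional subset of transcripts (e.g. from
#'   [de_filter()]).
#' @param r_cut Correlation threshold in (-1, 1].
#' @param absolute Use `|r|` instead of signed r (off by default).
#' @return An undirected weighted `igraph` graph with transcript names.
#' @export
correlation_graph <- function(expr, transcripts = NULL, r_cut = 0.9,
                              absolute = FALSE) {
  stopifnot(inherits(expr, "mepn_expr"))
  if (r_cut <= -1 || r_cut > 1) stop("r_cut must be in (-1, 1]")
  v <- expr$values
  if (!is.null(transcripts)) v <- v[rownames(v) %in% transcripts, ,
                                    drop = FALSE]
  if (ncol(v) < 3L) stop("correlation graph needs >= 3 samples")
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance transcript(s) excluded",
            call. = FALSE)
    v <- v[sds > 0, , drop = FALSE]
  }
  r <- stats::cor(t(v))
  score <- if (absolute) abs(r) else r
  score[lower.tri(score, diag = TRUE)] <- NA
  sel <- which(score >= r_cut, arr.ind = TRUE)
  edges <- data.frame(from = rownames(v)[sel[, 1L]],
                      to = rownames(v)[sel[, 2L]],
                      weight = r[sel], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = rownames(v))
  igraph::delete_vertices(g, which(igraph::degree(g) == 0))
}

#' Markov clustering (MCL)
#'
#' From-scratch MCL on the weighted adjacency matrix of `graph`: self-loops
#' of weight 1 are added, columns are normalized to a stochastic matrix, and
#' the iteration alternates expansion (matrix self-product), inflation
#' (entry-wise power `inflation` followed by column renormalization) and
#' pruning (entries below `prune` zeroed, columns renormalized) until the
#' maximum absolute entry change falls below `tol` or `max_iter` is reached.
#' Clusters are read off as connected components of the converged matrix's
#' non-zero structure; singletons are allowed.
#'
#' @param graph Undirected weighted `igraph` graph (e.g. from
#'   [correlation_graph()]).
#' @param inflation Inflation exponent (> 1); larger values give finer
#'   clusters.
#' @param prune Pruning threshold for small entries.
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the maximum entry change.
#' @param on_iterate Optional callback `function(M, iter)` invoked with the
#'   column-stochastic matrix after each iteration (used by invariant tests).
#' @return An object of class `mepn_partition`: `clusters` (list of
#'   transcript-name vectors, largest first), `inflation`, `iterations`,
#'   `converged`.
#' @export
mcl_cluster <- function(graph, inflation = 2.2, prune = 1e-5,
                        max_iter = 100L, tol = 1e-8, on_iterate = NULL) {
  if (inflation <= 1) stop("inflation must be > 1")
  nv <- igraph::vcount(graph)
  if (nv == 0L) stop("empty graph")
  A <- igraph::as_adjacency_matrix(graph, attr = if ("weight" %in%
        igraph::edge_attr_names(graph)) "weight" else NULL, sparse = FALSE)
  A <- abs(A)
  diag(A) <- 1
  colnorm <- function(M) sweep(M, 2L, colSums(M), "/")
  M <- colnorm(A)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    M2 <- M %*% M                      # expansion
    M2 <- colnorm(M2^inflation)        # inflation
    M2[M2 < prune] <- 0                # pruning
    M2 <- colnorm(M2)
    delta <- max(abs(M2 - M))
    if (!is.null(on_iterate)) on_iterate(M2, iter)
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  support <- (M > 0) | t(M > 0)
  sg <- igraph::graph_from_adjacency_matrix(support, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(sg)
  clusters <- split(igraph::V(graph)$name, comp$membership)
  clusters <- clusters[order(vapply(clusters, length, integer(1L)),
                             decreasing = TRUE)]
  names(clusters) <- NULL
  structure(list(clusters = clusters, inflation = inflation,
                 iterations = iter, converged = converged),
            class = "mepn_partition")
}

#' @export
print.mepn_partition <- function(x, ...) {
  sizes <- vapply(x$clusters, length, integer(1L))
  cat("MCL partition:", length(sizes), "clusters (inflation", x$inflation,
      ",", x$iterations, "iterations,",
      if (x$converged) "converged" else "not converged", ")\n")
  cat("  sizes:", paste(utils::head(sizes, 12L), collapse = ", "),
      if (length(sizes) > 12L) "...", "\n")
  invisible(x)
}

#' Convert a partition to class sets
#'
#' Clusters with size strictly greater than `min_size` become class sets
#' named `cluster1`, `cluster2`, ... in decreasing size order, each labelled
#' up- or down-regulated by the sign of its members' mean peak log2 fold
#' change versus baseline.
#'
#' @param partition An `mepn_partition`.
#' @param expr The `mepn_expr` the partition was computed from.
#' @param baseline Baseline timepoint.
#' @param min_size Strict size threshold (cluster kept iff size > `min_size`).
#' @return List of `mepn_class_set` with a `direction` field.
#' @export
clusters_to_class_sets <- function(partition, expr, baseline, min_size = 5L) {
  stopifnot(inherits(partition, "mepn_partition"), inherits(expr, "mepn_expr"))
  sizes <- vapply(partition$clusters, length, integer(1L))
  keep <- partition$clusters[sizes > min_size]
  keep <- keep[order(vapply(keep, length, integer(1L)), decreasing = TRUE)]
  if (!length(keep)) return(list())
  tps <- setdiff(unique(expr$samples$timepoint), baseline)
  v0 <- rowMeans(expr$values[, expr$samples$timepoint == baseline,
                             drop = FALSE])
  lfc <- vapply(tps, function(tp) {
    rowMeans(expr$values[, expr$samples$timepoint == tp, drop = FALSE]) - v0
  }, numeric(nrow(expr$values)))
  peak <- lfc[cbind(seq_len(nrow(lfc)), apply(abs(lfc), 1L, which.max))]
  names(peak) <- rownames(expr$values)
  lapply(seq_along(keep), function(k) {
    mean_peak <- mean(peak[keep[[k]]], na.rm = TRUE)
    class_set(paste0("cluster", k), keep[[k]],
              direction = if (mean_peak >= 0) "up" else "down")
  })
}

#' Read an expression matrix and sample sheet from TSV
#'
#' @param values_path TSV with transcripts in rows (first column symbols)
#'   and samples in columns.
#' @param samples_path TSV sample sheet with columns `sample`, `timepoint`,
#'   `replicate`.
#' @return An `mepn_expr`.
#' @export
read_expression <- function(values_path, samples_path) {
  tab <- utils::read.delim(values_path, stringsAsFactors = FALSE, quote = "")
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- tab[[1L]]
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE,
                               quote = "")
  expression_matrix(values, samples)
}

#' Write an expression matrix and sample sheet as TSV
#'
#' @param expr An `mepn_expr`.
#' @param values_path,samples_path Output paths.
#' @return `values_path`, invisibly.
#' @export
write_expression <- function(expr, values_path, samples_path) {
  tab <- data.frame(transcript = rownames(expr$values), expr$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(expr$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(values_path)
}
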