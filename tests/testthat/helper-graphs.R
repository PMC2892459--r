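# Shared fixture builders and independent oracles.

# Tiny constructed pathway: proteins A, B bind into A:B via process p.
chain_graph <- function(pmid = "1234567") {
  nodes <- mepn_nodes(
    id = c("A", "B", "p", "AB"),
    category = c("component", "component", "process", "component"),
    subtype = c("protein", "protein", "binding", "protein_complex"),
    label = c("RELA", "NFKB1", "B", "NFKB1:RELA"),
    compartment = "cytoplasm",
    pubmed = list(character(), character(), pmid, character()))
  mepn_pathway(nodes, mepn_edges(c("A", "B", "p"), c("p", "p", "AB")),
               metadata = list(title = "chain"))
}

# Generic small builder.
toy_graph <- function(ids, categories, subtypes, labels, from, to,
                      compartment = "cytoplasm", states = NULL,
                      title = "toy") {
  nodes <- mepn_nodes(id = ids, category = categories, subtype = subtypes,
                      label = labels, compartment = compartment,
                      states = states)
  edges <- if (length(from)) mepn_edges(from, to) else NULL
  mepn_pathway(nodes, edges, metadata = list(title = title))
}

# Random feasible pathway spec for property tests.
random_pathway_spec <- function(seed) {
  set.seed(seed)
  n_protein <- sample(6:20, 1L)
  n_complex <- sample(0:min(6L, choose(n_protein, 2L)), 1L)
  n_phospho <- sample(0:min(4L, n_protein), 1L)
  n_gene <- sample(0:4, 1L)
  n_sink <- sample(0:2, 1L)
  n_process <- n_phospho + n_complex + n_gene + n_sink
  pathway_spec(
    n_protein = n_protein,
    n_phospho = n_phospho,
    n_complex = n_complex,
    n_gene = n_gene,
    n_sink = n_sink,
    n_boolean = sample(0:n_complex, 1L),
    p_and = stats::runif(1L),
    n_annotation = sample(0:min(2L, n_process), 1L),
    n_compartments = sample(1:4, 1L),
    pubmed_fraction = stats::runif(1L),
    seed = seed)
}

expect_same_pathway <- function(g1, g2) {
  o1 <- order(g1$nodes$id); o2 <- order(g2$nodes$id)
  n1 <- g1$nodes[o1, ]; n2 <- g2$nodes[o2, ]
  rownames(n1) <- rownames(n2) <- NULL
  expect_equal(n1, n2, ignore_attr = TRUE)
  e1 <- g1$edges[order(g1$edges$source, g1$edges$target), ]
  e2 <- g2$edges[order(g2$edges$source, g2$edges$target), ]
  rownames(e1) <- rownames(e2) <- NULL
  expect_equal(e1, e2, ignore_attr = TRUE)
  expect_setequal(g1$compartments, g2$compartments)
}

# Brute-force all-pairs BFS diameter oracle on the undirected view of the
# largest component; independent of igraph.
bfs_diameter_oracle <- function(graph) {
  ids <- graph$nodes$id
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(graph$edges))) {
    s <- graph$edges$source[i]; t <- graph$edges$target[i]
    adj[[s]] <- union(adj[[s]], t)
    adj[[t]] <- union(adj[[t]], s)
  }
  bfs_dist <- function(start) {
    dist <- stats::setNames(rep(NA_integer_, length(ids)), ids)
    dist[start] <- 0L
    queue <- start
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    dist
  }
  # component sizes via BFS reach
  comp_of <- stats::setNames(rep(0L, length(ids)), ids)
  k <- 0L
  for (v in ids) {
    if (comp_of[v] == 0L) {
      k <- k + 1L
      comp_of[!is.na(bfs_dist(v))] <- k
    }
  }
  big <- names(which.max(table(comp_of)))
  members <- ids[comp_of == as.integer(big)]
  max(vapply(members, function(v) {
    d <- bfs_dist(v)[members]
    max(d, na.rm = TRUE)
  }, integer(1L)))
}

# Minimal reference MCL (plain loops, no pruning) used as an independent
# cross-check of the packaged implementation on small graphs.
reference_mcl <- function(adj, inflation, iters = 60L) {
  n <- nrow(adj)
  M <- adj
  diag(M) <- 1
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  for (it in seq_len(iters)) {
    M <- M %*% M
    M <- M^inflation
    for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  }
  support <- (M > 1e-6) | t(M > 1e-6)
  seen <- rep(FALSE, n)
  clusters <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    members <- i
    repeat {
      grow <- unique(unlist(lapply(members, function(m) which(support[m, ]))))
      grow <- union(members, grow)
      if (length(grow) == length(members)) break
      members <- grow
    }
    seen[members] <- TRUE
    clusters[[length(clusters) + 1L]] <- sort(rownames(adj)[members])
  }
  clusters
}

canonical_partition <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl[order(vapply(cl, paste, character(1L), collapse = ","))]
}
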