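# Network statistics for pathway graphs: node-class census, connectivity and
# diameter, matching how the published map's summary figures are tabulated.

#' Node-class census of a pathway
#'
#' Counts nodes per (category, subtype), plus the summary quantities used to
#' describe curated maps: the number of *unique proteins* (distinct base
#' symbols pooled over protein and protein-complex nodes, so modified forms
#' and complex members are counted once), the number of distinct complexes
#' (complex ComponentKeys with the compartment disregarded) and the number of
#' transcriptionally regulated genes (gene/DNA nodes with an incoming edge
#' from a transcription process).
#'
#' @param graph An `mepn_pathway`.
#' @return An object of class `mepn_census`.
#' @export
census <- function(graph) {
  stopifnot(inherits(graph, "mepn_pathway"))
  n <- graph$nodes
  counts <- if (nrow(n)) {
    tab <- as.data.frame(table(category = n$category, subtype = n$subtype),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0L, , drop = FALSE]
    names(tab)[3L] <- "count"
    tab
  } else {
    data.frame(category = character(), subtype = character(),
               count = integer(), stringsAsFactors = FALSE)
  }
  counts <- counts[order(counts$category, counts$subtype), , drop = FALSE]
  rownames(counts) <- NULL

  prot <- n$category == "component" & n$subtype %in% c("protein",
                                                       "protein_complex")
  syms <- unique(unlist(lapply(n$label[prot], base_identifiers)))

  cx <- which(n$category == "component" & n$subtype == "protein_complex")
  cx_keys <- unique(component_key_string(n$label[cx], n$states[cx],
                                         n$compartment[cx],
                                         with_compartment = FALSE))

  genes <- which(n$category == "component" & n$subtype == "gene_dna")
  n_genes <- 0L
  if (length(genes)) {
    proc_tr <- n$id[n$category == "process" & n$subtype == "transcription"]
    has_tr <- vapply(n$id[genes], function(id) {
      any(predecessors(graph, id) %in% proc_tr)
    }, logical(1L))
    n_genes <- sum(has_tr)
  }

  structure(list(counts = counts,
                 n_nodes = nrow(n), n_edges = nrow(graph$edges),
                 n_unique_proteins = length(syms),
                 n_complexes = length(cx_keys),
                 n_genes = n_genes),
            class = "mepn_census")
}

#' @export
print.mepn_census <- function(x, ...) {
  cat("mEPN census:", x$n_nodes, "nodes,", x$n_edges, "edges\n")
  cat("  unique proteins:", x$n_unique_proteins,
      " complexes:", x$n_complexes,
      " regulated genes:", x$n_genes, "\n")
  by_cat <- tapply(x$counts$count, x$counts$category, sum)
  cat("  ", paste(names(by_cat), by_cat, sep = ": ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Count nodes of a given class
#'
#' @param cen An `mepn_census`.
#' @param category Node category; `subtype` optionally narrows further.
#' @param subtype Optional subtype.
#' @return Integer count.
#' @export
census_count <- function(cen, category, subtype = NULL) {
  stopifnot(inherits(cen, "mepn_census"))
  sel <- cen$counts$category == category
  if (!is.null(subtype)) sel <- sel & cen$counts$subtype == subtype
  sum(cen$counts$count[sel])
}

#' Node connectivity statistics
#'
#' Degree counts inputs plus outputs (in-degree + out-degree).
#'
#' @param graph An `mepn_pathway` with at least one node.
#' @return List with `mean_degree` and `max_degree`.
#' @export
connectivity_stats <- function(graph) {
  stopifnot(inherits(graph, "mepn_pathway"))
  if (nrow(graph$nodes) == 0L) stop("connectivity undefined for empty graph")
  deg <- igraph::degree(as_igraph(graph), mode = "all")
  list(mean_degree = mean(deg), max_degree = as.integer(max(deg)))
}

#' Pathway diameter
#'
#' Maximum unweighted shortest-path distance between any two nodes, computed
#' on the undirected view of the largest connected component (the directed
#' graph has unreachable pairs, e.g. downstream of sinks, so only the
#' undirected interpretation is finite).
#'
#' @param graph An `mepn_pathway` with at least one edge.
#' @return Integer diameter.
#' @export
pathway_diameter <- function(graph) {
  stopifnot(inherits(graph, "mepn_pathway"))
  if (nrow(graph$edges) == 0L) stop("diameter undefined for a graph with no edges")
  g <- as_igraph(graph, directed = FALSE)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  as.integer(igraph::diameter(sub, directed = FALSE, unconnected = FALSE))
}
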