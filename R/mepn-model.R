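# Domain model: notation catalog, node classes, component identity, and the
# mepn_pathway container used by every other module.

#' Load a notation catalog
#'
#' The catalog is a flat tab-separated config with one node class per line:
#' `category`, `subtype`, yEd `shape` name, `fill` color and an optional
#' display `glyph` (e.g. `P` for phosphorylation, `Ø` for the sink).
#' It drives class inference when reading GraphML, shape/color emission when
#' writing, and the vocabulary checked by [validate_pathway()]. The default
#' catalog shipped with the package covers every class named in the mEPN
#' figures (component, process, Boolean and edge-annotation subtypes); users
#' may extend the vocabulary by supplying their own file.
#'
#' @param path Path to a catalog file; `NULL` loads the packaged default.
#' @return A data frame of class `mepn_catalog`.
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mepn_catalog.tsv", package = "mepnkit")
  }
  cat <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
                           quote = "")
  need <- c("category", "subtype", "shape", "fill")
  miss <- setdiff(need, names(cat))
  if (length(miss)) {
    stop("notation catalog is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(cat$glyph)) cat$glyph <- ""
  cat$glyph[is.na(cat$glyph)] <- ""
  if (anyDuplicated(paste(cat$category, cat$subtype))) {
    stop("notation catalog declares a (category, subtype) pair twice")
  }
  class(cat) <- c("mepn_catalog", "data.frame")
  cat
}

#' Node class vocabulary check
#'
#' @param category,subtype Class tokens to validate against `catalog`.
#' @param catalog An `mepn_catalog`.
#' @return Invisibly `TRUE`; errors if the pair is not in the vocabulary.
#' @export
node_class <- function(category, subtype, catalog = load_catalog()) {
  ok <- paste(category, subtype) %in% paste(catalog$category, catalog$subtype)
  if (!all(ok)) {
    bad <- paste(category, subtype)[!ok]
    stop("unknown node class(es): ", paste(unique(bad), collapse = ", "))
  }
  invisible(TRUE)
}

#' Split a component label into base identifiers
#'
#' Complex labels are split on the `:` separator used to join member symbols
#' (e.g. `"NFKB1 (p50):RELA (p65)"`); parenthesised aliases are decoration
#' and are stripped; symbols are trimmed and uppercased so mouse-style
#' symbols (`Ifnb1`) compare equal to HGNC labels (`IFNB1`).
#'
#' @param label A single component label string.
#' @return Character vector of uppercased base symbols.
#' @export
base_identifiers <- function(label) {
  if (length(label) != 1L || is.na(label) || !nzchar(trimws(label))) {
    stop("empty component label")
  }
  x <- gsub("\\([^)]*\\)", "", label)
  parts <- toupper(trimws(strsplit(x, ":", fixed = TRUE)[[1L]]))
  parts <- parts[nzchar(parts)]
  if (!length(parts)) stop("component label '", label, "' has no symbols")
  parts
}

# Canonical identity string for the uniqueness rule. Vectorised over labels.
component_key_string <- function(label, states, compartment,
                                 with_compartment = TRUE) {
  syms <- vapply(label, function(l) {
    paste(sort(base_identifiers(l)), collapse = ":")
  }, character(1L), USE.NAMES = FALSE)
  st <- vapply(states, function(s) paste(sort(as.character(s)), collapse = "|"),
               character(1L))
  if (with_compartment) {
    paste(syms, st, compartment, sep = "//")
  } else {
    paste(syms, st, sep = "//")
  }
}

#' Identity key of component nodes
#'
#' Under the mEPN uniqueness rule a component in a given modification state
#' may appear only once per sub-cellular compartment. The key is the triple
#' (sorted base symbols, sorted states, compartment); it is invariant to the
#' order in which complex members are written in the label.
#'
#' @param graph An `mepn_pathway`.
#' @param ids Node ids (default: all component nodes).
#' @return Named character vector of canonical key strings.
#' @export
identity_key <- function(graph, ids = NULL) {
  stopifnot(inherits(graph, "mepn_pathway"))
  n <- graph$nodes
  if (is.null(ids)) ids <- n$id[n$category == "component"]
  i <- match(ids, n$id)
  if (anyNA(i)) stop("unknown node id(s): ", paste(ids[is.na(i)], collapse = ", "))
  if (any(n$category[i] != "component")) {
    stop("identity_key is defined for component nodes only")
  }
  k <- component_key_string(n$label[i], n$states[i], n$compartment[i])
  names(k) <- ids
  k
}

empty_mepn_nodes <- function() {
  data.frame(id = character(), category = character(), subtype = character(),
             label = character(), compartment = character(), url = character(),
             notes = character(), x = numeric(), y = numeric(),
             width = numeric(), height = numeric(), fill = character(),
             stringsAsFactors = FALSE)
}

empty_mepn_edges <- function() {
  data.frame(source = character(), target = character(), notes = character(),
             stringsAsFactors = FALSE)
}

#' Build a node table for an mEPN pathway
#'
#' Vectorised convenience constructor; geometry defaults to a grid so written
#' files open sensibly in yEd. `states` and `pubmed` are list columns (one
#' character vector per node).
#'
#' @param id,category,subtype,label Required node attributes (recycled where
#'   length one).
#' @param compartment,url,notes,x,y,width,height,fill Optional attributes.
#' @param states,pubmed Lists of character vectors, one element per node.
#' @return A node data frame suitable for [mepn_pathway()].
#' @export
mepn_nodes <- function(id, category, subtype, label,
                       compartment = "", url = "", notes = "",
                       states = NULL, pubmed = NULL,
                       x = NULL, y = NULL, width = 60, height = 30,
                       fill = NA_character_) {
  n <- length(id)
  if (is.null(x)) x <- ((seq_len(n) - 1L) %% 10L) * 120
  if (is.null(y)) y <- ((seq_len(n) - 1L) %/% 10L) * 90
  out <- data.frame(id = as.character(id),
                    category = rep_len(as.character(category), n),
                    subtype = rep_len(as.character(subtype), n),
                    label = rep_len(as.character(label), n),
                    compartment = rep_len(as.character(compartment), n),
                    url = rep_len(as.character(url), n),
                    notes = rep_len(as.character(notes), n),
                    x = rep_len(as.numeric(x), n), y = rep_len(as.numeric(y), n),
                    width = rep_len(as.numeric(width), n),
                    height = rep_len(as.numeric(height), n),
                    fill = rep_len(as.character(fill), n),
                    stringsAsFactors = FALSE)
  out$states <- normalize_listcol(states, n)
  out$pubmed <- normalize_listcol(pubmed, n)
  out
}

#' Build an edge table for an mEPN pathway
#'
#' @param source,target Endpoint node ids.
#' @param notes Free-text annotation.
#' @param pubmed List of character vectors of PubMed ids, one per edge.
#' @return An edge data frame suitable for [mepn_pathway()].
#' @export
mepn_edges <- function(source, target, notes = "", pubmed = NULL) {
  n <- max(length(source), length(target))
  out <- data.frame(source = rep_len(as.character(source), n),
                    target = rep_len(as.character(target), n),
                    notes = rep_len(as.character(notes), n),
                    stringsAsFactors = FALSE)
  out$pubmed <- normalize_listcol(pubmed, n)
  out
}

normalize_listcol <- function(x, n) {
  if (is.null(x)) return(I(rep(list(character()), n)))
  if (!is.list(x)) x <- list(as.character(x))
  x <- lapply(x, function(v) sort(unique(as.character(v))))
  I(rep_len(x, n))
}

#' Construct a pathway graph
#'
#' The central container: a directed graph of typed mEPN nodes plus edges with
#' evidence annotation and compartment assignments. Invariants enforced here:
#' node ids unique, edge endpoints resolve, no self-loops, component nodes
#' labelled, compartments referenced by nodes listed in `compartments`.
#'
#' @param nodes Node table from [mepn_nodes()] (or the same columns).
#' @param edges Edge table from [mepn_edges()]; may be `NULL` for no edges.
#' @param compartments Ordered compartment names; node compartments are
#'   appended automatically if missing.
#' @param metadata Named list of provenance strings (e.g. `title`).
#' @return An object of class `mepn_pathway`.
#' @export
mepn_pathway <- function(nodes = NULL, edges = NULL, compartments = NULL,
                         metadata = list()) {
  if (is.null(nodes)) nodes <- empty_mepn_nodes()
  if (is.null(edges)) edges <- empty_mepn_edges()
  if (is.null(nodes$states)) nodes$states <- normalize_listcol(NULL, nrow(nodes))
  if (is.null(nodes$pubmed)) nodes$pubmed <- normalize_listcol(NULL, nrow(nodes))
  if (is.null(edges$pubmed)) edges$pubmed <- normalize_listcol(NULL, nrow(edges))
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }
  if (nrow(edges)) {
    bad <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(bad)) stop("edge endpoint(s) not in graph: ",
                          paste(bad, collapse = ", "))
    if (any(edges$source == edges$target)) stop("self-loop edges are invalid")
  }
  comp <- nodes$category == "component"
  if (any(comp & !nzchar(nodes$label))) {
    stop("component nodes must have a non-empty label")
  }
  compartments <- union(as.character(compartments %||% character()),
                        setdiff(nodes$compartment, ""))
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, compartments = compartments,
                 metadata = metadata),
            class = "mepn_pathway")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mepn_pathway <- function(x, ...) {
  cat("mEPN pathway", if (!is.null(x$metadata$title)) sQuote(x$metadata$title),
      "\n")
  cat("  nodes:", nrow(x$nodes), " edges:", nrow(x$edges),
      " compartments:", length(x$compartments), "\n")
  tab <- table(x$nodes$category)
  if (length(tab)) {
    cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Convert to an igraph object (vertex attrs: category, subtype, label,
# compartment). Used by netstats, MCL support reading and merge traversal.

#' Convert a pathway to an igraph graph
#'
#' @param graph An `mepn_pathway`.
#' @param directed Keep edge direction (default) or collapse to undirected.
#' @return An `igraph` graph with node attributes.
#' @export
as_igraph <- function(graph, directed = TRUE) {
  stopifnot(inherits(graph, "mepn_pathway"))
  v <- graph$nodes[, c("id", "category", "subtype", "label", "compartment")]
  names(v)[1L] <- "name"
  e <- graph$edges[, c("source", "target"), drop = FALSE]
  g <- igraph::graph_from_data_frame(e, directed = directed, vertices = v)
  if (!directed) g <- igraph::as_undirected(g, mode = "collapse")
  g
}

# Small internal accessors ------------------------------------------------

node_row <- function(graph, id) {
  i <- match(id, graph$nodes$id)
  if (is.na(i)) stop("unknown node id: ", id)
  graph$nodes[i, , drop = FALSE]
}

predecessors <- function(graph, id) graph$edges$source[graph$edges$target == id]
successors   <- function(graph, id) graph$edges$target[graph$edges$source == id]

node_field <- function(graph, ids, field) {
  graph$nodes[[field]][match(ids, graph$nodes$id)]
}
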