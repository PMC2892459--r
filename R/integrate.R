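# Merging independently curated pathway modules and exporting the
# interaction-evidence table.

# Resolve the component inputs of a process node, expanding Boolean
# operators: AND folds its inputs into one joint requirement, OR yields one
# alternative per input branch (nested operators handled recursively).
# Edge-annotation nodes route their component source as a modifier (read for
# catalysis, inhibit for inhibition).
resolve_process_inputs <- function(graph, process_id) {
  n <- graph$nodes
  cat_of <- function(ids) n$category[match(ids, n$id)]
  sub_of <- function(ids) n$subtype[match(ids, n$id)]

  cross_union <- function(A, B) {
    if (!length(A)) return(B)
    if (!length(B)) return(A)
    out <- list()
    for (a in A) for (b in B) out[[length(out) + 1L]] <- sort(union(a, b))
    out
  }

  bool_alternatives <- function(bid, seen = character()) {
    if (bid %in% seen) stop("Boolean operator cycle at node ", bid)
    preds <- predecessors(graph, bid)
    branches <- lapply(preds, function(p) {
      switch(cat_of(p),
             component = list(p),
             boolean = bool_alternatives(p, c(seen, bid)),
             list())   # other classes upstream of a boolean are ignored
    })
    branches <- branches[vapply(branches, length, integer(1L)) > 0L]
    if (!length(branches)) return(list())
    if (sub_of(bid) == "and") {
      alts <- list(character())
      for (b in branches) alts <- cross_union(alts, b)
      alts
    } else {
      unlist(branches, recursive = FALSE)
    }
  }

  preds <- predecessors(graph, process_id)
  comps <- preds[cat_of(preds) == "component"]
  bools <- preds[cat_of(preds) == "boolean"]
  annots <- preds[cat_of(preds) == "edge_annotation"]

  alternatives <- list(sort(comps))
  for (b in bools) alternatives <- cross_union(alternatives, bool_alternatives(b))

  read <- character(); inhibit <- character()
  for (a in annots) {
    src <- predecessors(graph, a)
    src <- src[cat_of(src) == "component"]
    if (sub_of(a) == "inhibition") inhibit <- union(inhibit, src)
    else read <- union(read, src)
  }
  list(alternatives = unique(alternatives), read = sort(read),
       inhibit = sort(inhibit))
}

base_symbol_set <- function(label) paste(sort(base_identifiers(label)),
                                         collapse = ":")

# Direct component->process->component depictions as (source symbols, target
# symbols) -> process subtype; used for cross-curator conflict detection.
pair_subtypes <- function(graph) {
  n <- graph$nodes
  out <- list()
  for (p in n$id[n$category == "process"]) {
    res <- resolve_process_inputs(graph, p)
    ins <- unique(unlist(res$alternatives))
    outs <- successors(graph, p)
    outs <- outs[node_field(graph, outs, "category") == "component"]
    subtype <- n$subtype[match(p, n$id)]
    for (i in ins) for (o in outs) {
      key <- paste(base_symbol_set(node_field(graph, i, "label")),
                   base_symbol_set(node_field(graph, o, "label")),
                   sep = " -> ")
      out[[key]] <- union(out[[key]], subtype)
    }
  }
  out
}

#' Merge curated pathway modules into one diagram
#'
#' Component nodes with an equal ComponentKey (same base symbols, states and
#' compartment) are unified into a single node, with PubMed evidence and
#' notes unioned. Process nodes are never unified across inputs: two
#' curators' depictions of the "same" step may differ in context, mirroring
#' manual re-examination rather than automatic resolution. Where the same
#' ordered pair of components is connected through processes of different
#' subtype in different inputs, both depictions are kept and the pair is
#' flagged as a conflict for curation. Source layouts are carried over with a
#' per-input horizontal translation offset.
#'
#' @param graphs List of `mepn_pathway` objects.
#' @param names Unique source names (default: metadata titles or `graph<i>`).
#' @return List with `graph` (merged `mepn_pathway`) and `report`
#'   (`mepn_merge_report` with `shared_keys`, `conflicts`, `provenance`).
#' @export
merge_pathways <- function(graphs, names = NULL) {
  stopifnot(length(graphs) >= 1L,
            all(vapply(graphs, inherits, logical(1L), "mepn_pathway")))
  if (is.null(names)) {
    names <- vapply(seq_along(graphs), function(i) {
      t <- graphs[[i]]$metadata$title
      if (!is.null(t) && nzchar(t)) t else paste0("graph", i)
    }, character(1L))
  }
  if (anyDuplicated(names)) stop("duplicate graph names: ",
                                 paste(names[duplicated(names)], collapse = ", "))

  key_to_id <- list()
  node_rows <- list()
  edge_rows <- list()
  provenance <- character()
  key_sources <- list()

  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    nm <- names[gi]
    off <- (gi - 1L) * 2000
    idmap <- character(nrow(g$nodes))
    names(idmap) <- g$nodes$id
    for (i in seq_len(nrow(g$nodes))) {
      row <- g$nodes[i, , drop = FALSE]
      new_id <- paste0(nm, "::", row$id)
      if (row$category == "component") {
        key <- component_key_string(row$label, row$states, row$compartment)
        key_sources[[key]] <- union(key_sources[[key]], nm)
        canon <- key_to_id[[key]]
        if (!is.null(canon)) {
          idmap[row$id] <- canon
          j <- match(canon, vapply(node_rows, function(r) r$id, character(1L)))
          node_rows[[j]]$pubmed[[1L]] <-
            sort(union(node_rows[[j]]$pubmed[[1L]], row$pubmed[[1L]]))
          extra <- setdiff(row$notes, c("", node_rows[[j]]$notes))
          if (length(extra) && nzchar(extra)) {
            node_rows[[j]]$notes <- paste(c(node_rows[[j]]$notes[
              nzchar(node_rows[[j]]$notes)], extra), collapse = "; ")
          }
          if (!nzchar(node_rows[[j]]$url)) node_rows[[j]]$url <- row$url
          next
        }
        key_to_id[[key]] <- new_id
      }
      idmap[row$id] <- new_id
      row$id <- new_id
      row$x <- row$x + off
      node_rows[[length(node_rows) + 1L]] <- row
      provenance[new_id] <- nm
    }
    if (nrow(g$edges)) {
      ee <- g$edges
      ee$source <- unname(idmap[ee$source])
      ee$target <- unname(idmap[ee$target])
      edge_rows[[length(edge_rows) + 1L]] <- ee
    }
  }

  nodes <- do.call(rbind, node_rows)
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else NULL
  if (!is.null(edges)) {
    dup <- duplicated(paste(edges$source, edges$target))
    edges <- edges[!dup, , drop = FALSE]
  }
  merged <- mepn_pathway(nodes, edges,
                         compartments = Reduce(union,
                                               lapply(graphs, `[[`, "compartments")),
                         metadata = list(title = paste(names, collapse = "+")))

  shared <- names(key_sources)[vapply(key_sources, length, integer(1L)) >= 2L]

  per_graph <- lapply(graphs, pair_subtypes)
  all_pairs <- unique(unlist(lapply(per_graph, names)))
  conflicts <- list()
  for (pair in all_pairs) {
    subs <- lapply(per_graph, function(ps) ps[[pair]])
    present <- which(!vapply(subs, is.null, logical(1L)))
    if (length(present) < 2L) next
    sets <- lapply(subs[present], sort)
    if (length(unique(vapply(sets, paste, character(1L), collapse = ","))) > 1L) {
      conflicts[[length(conflicts) + 1L]] <- data.frame(
        key_pair = pair,
        description = paste(vapply(seq_along(present), function(k) {
          paste0(names[present[k]], ": ", paste(sets[[k]], collapse = ","))
        }, character(1L)), collapse = " | "),
        stringsAsFactors = FALSE)
    }
  }
  conflicts <- if (length(conflicts)) do.call(rbind, conflicts) else
    data.frame(key_pair = character(), description = character(),
               stringsAsFactors = FALSE)

  report <- structure(list(shared_keys = shared, conflicts = conflicts,
                           provenance = provenance),
                      class = "mepn_merge_report")
  list(graph = merged, report = report)
}

#' @export
print.mepn_merge_report <- function(x, ...) {
  cat("mEPN merge report\n")
  cat("  merged nodes:", length(x$provenance),
      " shared component keys:", length(x$shared_keys),
      " conflicts:", nrow(x$conflicts), "\n")
  invisible(x)
}

entrez_from_url <- function(url) {
  if (is.na(url) || !nzchar(url)) return("")
  m <- regmatches(url, regexec("gene[/=]([0-9]+)", url))[[1L]]
  if (length(m) == 2L) return(m[2L])
  m <- regmatches(url, regexec("list_uids=([0-9]+)", url))[[1L]]
  if (length(m) == 2L) return(m[2L])
  ""
}

#' Extract the interaction-evidence table from a pathway
#'
#' Emits one record per (process node, input components, output component)
#' with Boolean operators expanded: an AND operator contributes all of its
#' inputs to one record, an OR yields one record per alternative input.
#' Catalysis/inhibition annotation sources participate as modifiers. Records
#' are deduplicated on (participant symbols, interaction nature, location)
#' with PubMed ids unioned; Entrez ids are taken from node URLs linking to a
#' gene record.
#'
#' @param graph An `mepn_pathway`.
#' @return A data frame of class `mepn_interactions`.
#' @export
extract_interactions <- function(graph) {
  stopifnot(inherits(graph, "mepn_pathway"))
  n <- graph$nodes
  e <- graph$edges
  lab <- function(ids) n$label[match(ids, n$id)]
  url <- function(ids) n$url[match(ids, n$id)]
  pm_node <- function(ids) unlist(n$pubmed[match(ids, n$id)])
  pm_edges <- function(pid, others) {
    sel <- (e$source == pid & e$target %in% others) |
           (e$target == pid & e$source %in% others)
    unlist(e$pubmed[sel])
  }

  recs <- list()
  for (i in which(n$category == "process")) {
    pid <- n$id[i]
    res <- resolve_process_inputs(graph, pid)
    modifiers <- union(res$read, res$inhibit)
    outs <- successors(graph, pid)
    outs <- outs[node_field(graph, outs, "category") == "component"]
    if (!length(outs)) outs <- NA_character_
    alts <- res$alternatives
    if (!length(alts)) alts <- list(character())
    for (alt in alts) {
      ins <- sort(union(alt, modifiers))
      for (o in outs) {
        if (!length(ins) && is.na(o)) next
        in_syms <- sort(unique(unlist(lapply(lab(ins), base_identifiers))))
        out_syms <- if (is.na(o)) character() else
          sort(unique(base_identifiers(lab(o))))
        participants <- sort(union(in_syms, out_syms))
        if (!length(participants)) next
        touched <- c(ins, if (!is.na(o)) o)
        pmids <- sort(unique(c(n$pubmed[[i]], pm_node(touched),
                               pm_edges(pid, touched))))
        in_entrez <- vapply(url(ins), entrez_from_url, character(1L),
                            USE.NAMES = FALSE)
        recs[[length(recs) + 1L]] <- data.frame(
          process_id = pid,
          nature = n$subtype[i],
          location = n$compartment[i],
          participants = paste(participants, collapse = ";"),
          input_symbols = paste(in_syms, collapse = ";"),
          output_symbols = paste(out_syms, collapse = ";"),
          input_labels = paste(lab(ins), collapse = ";"),
          output_label = if (is.na(o)) "" else lab(o),
          input_entrez = paste(in_entrez, collapse = ";"),
          output_entrez = if (is.na(o)) "" else entrez_from_url(url(o)),
          pubmed_ids = paste(pmids, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(process_id = character(), nature = character(),
               location = character(), participants = character(),
               input_symbols = character(), output_symbols = character(),
               input_labels = character(), output_label = character(),
               input_entrez = character(), output_entrez = character(),
               pubmed_ids = character(), stringsAsFactors = FALSE)

  if (nrow(out)) {
    key <- paste(out$participants, out$nature, out$location, sep = "\r")
    first <- !duplicated(key)
    pm_union <- vapply(split(out$pubmed_ids, key), function(v) {
      ids <- unique(unlist(strsplit(v, ";", fixed = TRUE)))
      paste(sort(ids[nzchar(ids)]), collapse = ";")
    }, character(1L))
    out <- out[first, , drop = FALSE]
    out$pubmed_ids <- unname(pm_union[paste(out$participants, out$nature,
                                            out$location, sep = "\r")])
    rownames(out) <- NULL
  }
  class(out) <- c("mepn_interactions", "data.frame")
  out
}

#' Summarize interaction evidence
#'
#' @param records An `mepn_interactions` table.
#' @return List with `n_interactions` (distinct records) and
#'   `n_publications` (distinct PubMed ids across records).
#' @export
summarize_evidence <- function(records) {
  pmids <- unique(unlist(strsplit(records$pubmed_ids, ";", fixed = TRUE)))
  pmids <- pmids[!is.na(pmids) & nzchar(pmids)]
  list(n_interactions = nrow(records), n_publications = length(pmids))
}

#' Write an interaction table as TSV
#'
#' Columns follow the curated interaction-list schema: PubMedID, SymbolA,
#' EntrezA, SymbolB, EntrezB, AsDepictedA, AsDepictedB, Nature, Location
#' (A = inputs, B = output; multi-member sides joined with `;`).
#'
#' @param records An `mepn_interactions` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(records, path) {
  tab <- data.frame(PubMedID = records$pubmed_ids,
                    SymbolA = records$input_symbols,
                    EntrezA = records$input_entrez,
                    SymbolB = records$output_symbols,
                    EntrezB = records$output_entrez,
                    AsDepictedA = records$input_labels,
                    AsDepictedB = records$output_label,
                    Nature = records$nature,
                    Location = records$location,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
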