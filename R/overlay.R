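# Overlay of class-sets (e.g. co-expression clusters) onto pathway nodes.

OVERLAY_ELIGIBLE_SUBTYPES <- c("protein", "protein_complex", "gene_dna")
DEFAULT_PALETTE <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
                     "#A65628", "#F781BF", "#1B9E77", "#D95F02", "#7570B3")

#' Map class sets onto pathway nodes
#'
#' A class member matches a node iff its case-normalized symbol equals any
#' base identifier of the node's label, so mouse-style symbols (`Ifnb1`)
#' match human-labelled nodes (`IFNB1`) and a single member matches the
#' complexes it belongs to. Protein, gene and complex nodes are eligible;
#' process and Boolean nodes never match. A node maps to at most one class:
#' the first-listed class wins and collisions are logged.
#'
#' @param graph An `mepn_pathway`.
#' @param sets List of `mepn_class_set` (order decides collision priority).
#' @return An object of class `mepn_overlay` with `matches` (node id ->
#'   class), `unmatched_members`, `counts` and `collisions`.
#' @export
map_class_sets <- function(graph, sets) {
  stopifnot(inherits(graph, "mepn_pathway"))
  n <- graph$nodes
  eligible <- which(n$category == "component" &
                    n$subtype %in% OVERLAY_ELIGIBLE_SUBTYPES)
  node_syms <- lapply(n$label[eligible], base_identifiers)

  matches <- character()
  unmatched <- list()
  collisions <- list()
  for (s in sets) {
    hit_any <- rep(FALSE, length(s$members))
    for (mi in seq_along(s$members)) {
      msym <- toupper(trimws(gsub("\\([^)]*\\)", "", s$members[mi])))
      hit <- eligible[vapply(node_syms, function(v) msym %in% v, logical(1L))]
      if (length(hit)) hit_any[mi] <- TRUE
      for (id in n$id[hit]) {
        if (!is.null(matches[id]) && !is.na(matches[id])) {
          if (matches[[id]] != s$name) {
            collisions[[length(collisions) + 1L]] <- data.frame(
              node_id = id, kept = matches[[id]], dropped = s$name,
              stringsAsFactors = FALSE)
          }
        } else {
          matches[id] <- s$name
        }
      }
    }
    unmatched[[s$name]] <- s$members[!hit_any]
  }
  collisions <- if (length(collisions)) do.call(rbind, collisions) else
    data.frame(node_id = character(), kept = character(),
               dropped = character(), stringsAsFactors = FALSE)
  if (nrow(collisions)) {
    message(nrow(collisions),
            " node(s) claimed by multiple classes; first-listed class kept")
  }
  counts <- vapply(sets, function(s) sum(matches == s$name), integer(1L))
  names(counts) <- vapply(sets, `[[`, character(1L), "name")
  structure(list(matches = matches, unmatched_members = unmatched,
                 counts = counts, collisions = collisions,
                 set_names = names(counts)),
            class = "mepn_overlay")
}

#' @export
print.mepn_overlay <- function(x, ...) {
  cat("mEPN overlay:", length(x$matches), "matched node(s) across",
      length(x$set_names), "class set(s)\n")
  for (nm in x$set_names) {
    cat("  ", nm, ": ", x$counts[[nm]], " matched, ",
        length(x$unmatched_members[[nm]]), " unmatched member(s)\n", sep = "")
  }
  invisible(x)
}

#' Apply overlay styling to a pathway
#'
#' Matched nodes receive their class colour and are enlarged; all other nodes
#' are greyed, as in published overlay figures where non-regulated components
#' are grey. Topology is untouched and the result still round-trips through
#' the GraphML writer.
#'
#' @param graph An `mepn_pathway`.
#' @param overlay An `mepn_overlay` computed on this graph.
#' @param palette Named vector class -> colour; classes without an entry get
#'   deterministic colours from a fixed cycle.
#' @param grey Colour for unmatched nodes.
#' @param enlarge Size multiplier for matched nodes.
#' @return The restyled `mepn_pathway`.
#' @export
apply_styling <- function(graph, overlay, palette = NULL, grey = "#D3D3D3",
                          enlarge = 2) {
  stopifnot(inherits(graph, "mepn_pathway"), inherits(overlay, "mepn_overlay"))
  classes <- overlay$set_names
  pal <- stats::setNames(DEFAULT_PALETTE[(seq_along(classes) - 1L) %%
                                           length(DEFAULT_PALETTE) + 1L],
                         classes)
  if (!is.null(palette)) pal[names(palette)] <- palette
  n <- graph$nodes
  n$fill <- rep(grey, nrow(n))
  hit <- match(n$id, names(overlay$matches))
  sel <- !is.na(hit)
  n$fill[sel] <- unname(pal[overlay$matches[hit[sel]]])
  n$width[sel] <- n$width[sel] * enlarge
  n$height[sel] <- n$height[sel] * enlarge
  graph$nodes <- n
  graph
}

#' Summarize overlay match counts
#'
#' @param overlay An `mepn_overlay`.
#' @param direction_labels Optional named vector class -> `"up"`/`"down"`.
#' @return List with `total` matched nodes, per-class `by_class` counts and,
#'   when directions are given, per-direction totals (each node counted once,
#'   under the first-listed-class-wins rule).
#' @export
overlay_counts <- function(overlay, direction_labels = NULL) {
  stopifnot(inherits(overlay, "mepn_overlay"))
  out <- list(total = length(overlay$matches), by_class = overlay$counts)
  if (!is.null(direction_labels)) {
    dirs <- unname(direction_labels[overlay$matches])
    out$by_direction <- c(up = sum(dirs == "up", na.rm = TRUE),
                          down = sum(dirs == "down", na.rm = TRUE))
  }
  out
}
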