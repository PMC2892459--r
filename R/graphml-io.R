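# GraphML reader/writer for the yEd dialect used for mEPN diagrams, plus the
# class-set TSV format consumed by the overlay module.
#
# The key registry is always rebuilt from the file's <key> declarations; no
# yEd key id is ever hard-coded. Compartments are encoded as yEd group nodes
# (yfiles.foldertype="group") whose label names the sub-cellular location.

GRAPHML_NS <- "http://graphml.graphdrawing.org/xmlns"
YFILES_NS <- "http://www.yworks.com/xml/graphml"

# PubMed ids are stored as free text in descriptions; harvest 7-8 digit runs
# (optionally prefixed "PMID").
harvest_pmids <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character())
  m <- regmatches(text, gregexpr("(?<![0-9])[0-9]{7,8}(?![0-9])", text,
                                 perl = TRUE))[[1L]]
  sort(unique(m))
}

strip_pmid_lines <- function(text) {
  if (is.na(text) || !nzchar(text)) return("")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  keep <- !grepl("^\\s*PMID:\\s*[0-9, ]+\\s*$", lines)
  paste(lines[keep], collapse = "\n")
}

build_description <- function(notes, pmids) {
  pm <- if (length(pmids)) paste0("PMID: ", paste(pmids, collapse = ", ")) else ""
  if (nzchar(notes) && nzchar(pm)) paste(notes, pm, sep = "\n")
  else paste0(notes, pm)
}

catalog_row <- function(catalog, category, subtype) {
  i <- which(catalog$category == category & catalog$subtype == subtype)
  if (!length(i)) return(NULL)
  catalog[i[1L], , drop = FALSE]
}

# Infer (category, subtype) for a read node. Preference order: exact
# shape+fill match in the catalog; an explicit mepn.class declaration (as
# written by write_pathway, survives restyled fills); a glyph/label-pattern
# match; a catalog-unique shape; otherwise classed 'other' with a warning.
infer_class <- function(shape, fill, label, declared, catalog) {
  hit <- which(catalog$shape == shape &
               toupper(catalog$fill) == toupper(fill %||% ""))
  if (length(hit) == 1L) {
    return(c(catalog$category[hit], catalog$subtype[hit]))
  }
  if (!is.null(declared) && nzchar(declared)) {
    parts <- strsplit(declared, "/", fixed = TRUE)[[1L]]
    if (length(parts) == 2L &&
        any(catalog$category == parts[1L] & catalog$subtype == parts[2L])) {
      return(parts)
    }
  }
  hit <- which(nzchar(catalog$glyph) & catalog$glyph == label)
  if (length(hit) == 1L) {
    return(c(catalog$category[hit], catalog$subtype[hit]))
  }
  hit <- which(catalog$shape == shape)
  if (length(hit) == 1L) {
    return(c(catalog$category[hit], catalog$subtype[hit]))
  }
  warning("unmappable glyph (shape=", shape, ", fill=", fill,
          ", label=", label, "); node classed component/other_molecule",
          call. = FALSE)
  c("component", "other_molecule")
}

#' Read an mEPN pathway from GraphML
#'
#' Parses the yEd GraphML dialect: the key registry is discovered from the
#' file's `<key>` declarations, node classes are inferred from the notation
#' catalog (shape + fill colour + label glyph), descriptions are scanned for
#' PubMed-id patterns, coordinates are retained as layout metadata and
#' compartments are taken from enclosing yEd group nodes.
#'
#' @param path A `.graphml` file.
#' @param catalog Notation catalog (see [load_catalog()]).
#' @return An `mepn_pathway`.
#' @export
read_pathway <- function(path, catalog = load_catalog()) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "graphml") {
    stop("not a GraphML document (root element is <", xml2::xml_name(doc), ">)")
  }
  keys <- xml2::xml_find_all(doc, "./*[local-name()='key']")
  registry <- list()
  for (k in keys) {
    id <- xml2::xml_attr(k, "id")
    nm <- xml2::xml_attr(k, "attr.name")
    if (is.na(nm)) nm <- xml2::xml_attr(k, "yfiles.type")
    if (!is.na(id) && !is.na(nm)) registry[[id]] <- nm
  }
  acc <- new.env(parent = emptyenv())
  acc$nodes <- list()
  acc$compartments <- character()

  parse_node <- function(nd, compartment) {
    id <- xml2::xml_attr(nd, "id")
    desc <- ""; url <- ""; states <- character(); declared <- NULL
    label <- ""; shape <- ""; fill <- ""; x <- 0; y <- 0; w <- 60; h <- 30
    for (d in xml2::xml_find_all(nd, "./*[local-name()='data']")) {
      kid <- xml2::xml_attr(d, "key")
      sem <- if (is.na(kid)) NULL else registry[[kid]]
      if (is.null(sem)) next   # unknown keys are ignored
      if (sem == "description") desc <- xml2::xml_text(d)
      else if (sem == "url") url <- xml2::xml_text(d)
      else if (sem == "mepn.states") {
        states <- strsplit(trimws(xml2::xml_text(d)), "\\s+")[[1L]]
        states <- states[nzchar(states)]
      } else if (sem == "mepn.class") declared <- trimws(xml2::xml_text(d))
      else if (sem == "nodegraphics") {
        lab <- xml2::xml_find_first(d, ".//*[local-name()='NodeLabel']")
        if (!inherits(lab, "xml_missing")) label <- xml2::xml_text(lab)
        sh <- xml2::xml_find_first(d, ".//*[local-name()='Shape']")
        if (!inherits(sh, "xml_missing")) shape <- xml2::xml_attr(sh, "type")
        fl <- xml2::xml_find_first(d, ".//*[local-name()='Fill']")
        if (!inherits(fl, "xml_missing")) fill <- xml2::xml_attr(fl, "color")
        ge <- xml2::xml_find_first(d, ".//*[local-name()='Geometry']")
        if (!inherits(ge, "xml_missing")) {
          x <- as.numeric(xml2::xml_attr(ge, "x"))
          y <- as.numeric(xml2::xml_attr(ge, "y"))
          w <- as.numeric(xml2::xml_attr(ge, "width"))
          h <- as.numeric(xml2::xml_attr(ge, "height"))
        }
      }
    }
    cls <- infer_class(shape, fill, label, declared, catalog)
    crow <- catalog_row(catalog, cls[1L], cls[2L])
    stored_fill <- if (!is.null(crow) && toupper(fill) == toupper(crow$fill)) {
      NA_character_
    } else fill
    acc$nodes[[length(acc$nodes) + 1L]] <- list(
      id = id, category = cls[1L], subtype = cls[2L], label = label,
      compartment = compartment, url = url,
      notes = strip_pmid_lines(desc), pubmed = harvest_pmids(desc),
      states = states, x = x, y = y, width = w, height = h, fill = stored_fill)
  }

  parse_graph <- function(g, compartment) {
    for (nd in xml2::xml_find_all(g, "./*[local-name()='node']")) {
      sub <- xml2::xml_find_first(nd, "./*[local-name()='graph']")
      if (!inherits(sub, "xml_missing")) {
        lab <- xml2::xml_find_first(nd, ".//*[local-name()='NodeLabel']")
        name <- if (!inherits(lab, "xml_missing")) xml2::xml_text(lab)
                else xml2::xml_attr(nd, "id")
        acc$compartments <- union(acc$compartments, name)
        parse_graph(sub, name)
      } else {
        parse_node(nd, compartment)
      }
    }
  }

  top <- xml2::xml_find_first(doc, "./*[local-name()='graph']")
  if (inherits(top, "xml_missing")) stop("GraphML document contains no <graph>")
  parse_graph(top, "")

  nl <- acc$nodes
  pick_chr <- function(f) vapply(nl, function(n) n[[f]], character(1L))
  pick_num <- function(f) vapply(nl, function(n) n[[f]], numeric(1L))
  nodes <- if (length(nl)) {
    nn <- data.frame(id = pick_chr("id"), category = pick_chr("category"),
                     subtype = pick_chr("subtype"), label = pick_chr("label"),
                     compartment = pick_chr("compartment"), url = pick_chr("url"),
                     notes = pick_chr("notes"), x = pick_num("x"),
                     y = pick_num("y"), width = pick_num("width"),
                     height = pick_num("height"), fill = pick_chr("fill"),
                     stringsAsFactors = FALSE)
    nn$states <- I(lapply(nl, function(n) sort(unique(n$states))))
    nn$pubmed <- I(lapply(nl, function(n) n$pubmed))
    nn
  } else empty_mepn_nodes()

  enodes <- xml2::xml_find_all(doc, ".//*[local-name()='edge']")
  edges <- if (length(enodes)) {
    src <- xml2::xml_attr(enodes, "source")
    tgt <- xml2::xml_attr(enodes, "target")
    desc <- vapply(enodes, function(e) {
      txt <- ""
      for (d in xml2::xml_find_all(e, "./*[local-name()='data']")) {
        kid <- xml2::xml_attr(d, "key")
        sem <- if (is.na(kid)) NULL else registry[[kid]]
        if (!is.null(sem) && sem == "description") txt <- xml2::xml_text(d)
      }
      txt
    }, character(1L))
    ee <- data.frame(source = src, target = tgt,
                     notes = vapply(desc, strip_pmid_lines, character(1L),
                                    USE.NAMES = FALSE),
                     stringsAsFactors = FALSE)
    ee$pubmed <- I(lapply(desc, harvest_pmids))
    ee
  } else empty_mepn_edges()

  title <- xml2::xml_attr(top, "id")
  mepn_pathway(nodes, edges, compartments = acc$compartments,
               metadata = list(title = if (is.na(title)) "" else title))
}

#' Write an mEPN pathway as GraphML
#'
#' Emits the yEd dialect read by [read_pathway()]: shape and fill colour come
#' from the notation catalog (unless a node carries an explicit style, as
#' after [apply_styling()]), compartments become group nodes, PubMed ids are
#' appended to descriptions as `PMID:` lines, and modification states travel
#' in a dedicated `mepn.states` key. `read_pathway(write_pathway(g))` returns
#' a graph equal to `g` field by field.
#'
#' @param graph An `mepn_pathway`.
#' @param path Output file path.
#' @param catalog Notation catalog used to emit shape/colour per class.
#' @return `path`, invisibly.
#' @export
write_pathway <- function(graph, path, catalog = load_catalog()) {
  stopifnot(inherits(graph, "mepn_pathway"))
  n <- graph$nodes
  known <- paste(catalog$category, catalog$subtype)
  bad <- !(paste(n$category, n$subtype) %in% known)
  if (any(bad)) {
    stop("node class absent from catalog for node(s): ",
         paste(n$id[bad], collapse = ", "))
  }
  doc <- xml2::xml_new_root("graphml", xmlns = GRAPHML_NS,
                            "xmlns:y" = YFILES_NS)
  xml2::xml_add_child(doc, "key", id = "d0", "for" = "node",
                      "yfiles.type" = "nodegraphics")
  xml2::xml_add_child(doc, "key", id = "d1", "for" = "node",
                      "attr.name" = "description", "attr.type" = "string")
  xml2::xml_add_child(doc, "key", id = "d2", "for" = "node",
                      "attr.name" = "url", "attr.type" = "string")
  xml2::xml_add_child(doc, "key", id = "d3", "for" = "node",
                      "attr.name" = "mepn.states", "attr.type" = "string")
  xml2::xml_add_child(doc, "key", id = "d4", "for" = "node",
                      "attr.name" = "mepn.class", "attr.type" = "string")
  xml2::xml_add_child(doc, "key", id = "d5", "for" = "edge",
                      "attr.name" = "description", "attr.type" = "string")
  title <- graph$metadata$title %||% "G"
  if (!nzchar(title)) title <- "G"
  top <- xml2::xml_add_child(doc, "graph", id = title, edgedefault = "directed")

  add_node <- function(parent, i) {
    nd <- xml2::xml_add_child(parent, "node", id = n$id[i])
    desc <- build_description(n$notes[i], n$pubmed[[i]])
    if (nzchar(desc)) {
      xml2::xml_set_text(xml2::xml_add_child(nd, "data", key = "d1"), desc)
    }
    if (nzchar(n$url[i])) {
      xml2::xml_set_text(xml2::xml_add_child(nd, "data", key = "d2"), n$url[i])
    }
    if (length(n$states[[i]])) {
      xml2::xml_set_text(xml2::xml_add_child(nd, "data", key = "d3"),
                         paste(n$states[[i]], collapse = " "))
    }
    xml2::xml_set_text(xml2::xml_add_child(nd, "data", key = "d4"),
                       paste(n$category[i], n$subtype[i], sep = "/"))
    crow <- catalog_row(catalog, n$category[i], n$subtype[i])
    fill <- if (is.na(n$fill[i])) crow$fill else n$fill[i]
    g <- xml2::xml_add_child(nd, "data", key = "d0")
    sn <- xml2::xml_add_child(g, "y:ShapeNode")
    xml2::xml_add_child(sn, "y:Geometry",
                        x = format(n$x[i], scientific = FALSE),
                        y = format(n$y[i], scientific = FALSE),
                        width = format(n$width[i], scientific = FALSE),
                        height = format(n$height[i], scientific = FALSE))
    xml2::xml_add_child(sn, "y:Fill", color = fill, transparent = "false")
    if (nzchar(n$label[i])) {
      xml2::xml_set_text(xml2::xml_add_child(sn, "y:NodeLabel"), n$label[i])
    }
    xml2::xml_add_child(sn, "y:Shape", type = crow$shape)
  }

  comp_lv <- ifelse(n$compartment == "", ".top", paste0("c:", n$compartment))
  idx_by_comp <- split(seq_len(nrow(n)),
                       factor(comp_lv, levels = c(".top",
                              paste0("c:", graph$compartments))))
  for (i in idx_by_comp[[".top"]]) add_node(top, i)
  for (comp in graph$compartments) {
    grp <- xml2::xml_add_child(top, "node", id = paste0("grp::", comp),
                               "yfiles.foldertype" = "group")
    gdat <- xml2::xml_add_child(grp, "data", key = "d0")
    gsn <- xml2::xml_add_child(gdat, "y:ShapeNode")
    xml2::xml_add_child(gsn, "y:Fill", color = "#F5F5F5",
                        transparent = "false")
    xml2::xml_set_text(xml2::xml_add_child(gsn, "y:NodeLabel"), comp)
    xml2::xml_add_child(gsn, "y:Shape", type = "rectangle")
    sub <- xml2::xml_add_child(grp, "graph",
                               id = paste0("grp::", comp, ":"),
                               edgedefault = "directed")
    for (i in idx_by_comp[[paste0("c:", comp)]]) add_node(sub, i)
  }

  e <- graph$edges
  if (nrow(e)) {
    for (i in seq_len(nrow(e))) {
      ed <- xml2::xml_add_child(top, "edge", id = paste0("e", i - 1L),
                                source = e$source[i], target = e$target[i])
      desc <- build_description(e$notes[i], e$pubmed[[i]])
      if (nzchar(desc)) {
        xml2::xml_set_text(xml2::xml_add_child(ed, "data", key = "d5"), desc)
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# Class sets ----------------------------------------------------------------

#' Construct a class set
#'
#' A named group of node labels (typically a co-expression cluster) for
#' overlay onto a pathway.
#'
#' @param name Class name.
#' @param members Character vector of node-label strings (deduplicated).
#' @param color Optional display colour.
#' @param direction Optional regulation direction (`"up"`/`"down"`).
#' @return An object of class `mepn_class_set`.
#' @export
class_set <- function(name, members, color = NA_character_,
                      direction = NA_character_) {
  members <- sort(unique(as.character(members)))
  if (!length(members)) stop("class set '", name, "' has no members")
  structure(list(name = as.character(name), members = members,
                 color = color, direction = direction),
            class = "mepn_class_set")
}

#' Read class sets from a TSV file
#'
#' Expects a header and 2-3 tab-separated columns: node label, class name,
#' optional colour. Duplicate (label, class) rows collapse to one member;
#' rows with a missing class are skipped (count available as attribute
#' `n_skipped`).
#'
#' @param path TSV file.
#' @return List of `mepn_class_set`, in order of first appearance.
#' @export
read_class_sets <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
                           quote = "", colClasses = "character")
  if (ncol(tab) < 2L) stop("class-set file needs at least 2 columns")
  label <- trimws(tab[[1L]])
  cls <- trimws(tab[[2L]])
  color <- if (ncol(tab) >= 3L) trimws(tab[[3L]]) else rep("", nrow(tab))
  bad <- is.na(cls) | !nzchar(cls) | is.na(label) | !nzchar(label)
  if (any(bad)) {
    warning(sum(bad), " class-set row(s) with missing label/class skipped",
            call. = FALSE)
  }
  label <- label[!bad]; clsv <- cls[!bad]; color <- color[!bad]
  out <- lapply(unique(clsv), function(cn) {
    sel <- clsv == cn
    col <- color[sel][nzchar(color[sel])]
    class_set(cn, label[sel],
              color = if (length(col)) col[1L] else NA_character_)
  })
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Write class sets to a TSV file
#'
#' @param sets List of `mepn_class_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_class_sets <- function(sets, path) {
  rows <- do.call(rbind, lapply(sets, function(s) {
    data.frame(label = s$members, class = s$name,
               color = if (is.na(s$color)) "" else s$color,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
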