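# Structural validation of mEPN pathway graphs.
#
# Rules:
#   V1  every node's (category, subtype) is in the notation catalog
#   V2  no two component nodes share a ComponentKey within a compartment
#       (the same component-state may recur in *different* compartments, as
#       translocation depictions require)
#   V3  edge grammar: component->process, process->component,
#       component->boolean, boolean->process, boolean->boolean,
#       component->edge_annotation, edge_annotation->process; anything else
#       (notably component->component) violates the component/process
#       alternation. Warning by default, error under strict = TRUE.
#   V4  Boolean operators need in-degree >= 2 (AND always an error; OR is a
#       warning unless strict) and out-degree >= 1
#   V5  sink process nodes have out-degree 0 and in-degree >= 1
#   V6  (warning) process nodes carrying no PubMed evidence on the node or
#       its incident edges

ALLOWED_EDGE_GRAMMAR <- matrix(c(
  "component", "process",
  "process", "component",
  "component", "boolean",
  "boolean", "process",
  "boolean", "boolean",
  "component", "edge_annotation",
  "edge_annotation", "process"
), ncol = 2L, byrow = TRUE)

#' Validate a pathway against mEPN structural rules
#'
#' @param graph An `mepn_pathway`.
#' @param catalog Notation catalog.
#' @param strict Promote edge-grammar (V3) and OR-in-degree findings from
#'   warnings to errors.
#' @return An object of class `mepn_validation` with `errors`, `warnings`
#'   (data frames with columns `rule`, `ids`, `message`) and `passed`
#'   (`TRUE` iff no errors).
#' @export
validate_pathway <- function(graph, catalog = load_catalog(), strict = FALSE) {
  stopifnot(inherits(graph, "mepn_pathway"))
  n <- graph$nodes
  e <- graph$edges
  findings <- list()
  add <- function(rule, ids, message, severity) {
    findings[[length(findings) + 1L]] <<- data.frame(
      rule = rule, ids = paste(ids, collapse = ";"), message = message,
      severity = severity, stringsAsFactors = FALSE)
  }

  # V1 class vocabulary
  known <- paste(catalog$category, catalog$subtype)
  bad <- !(paste(n$category, n$subtype) %in% known)
  for (i in which(bad)) {
    add("V1", n$id[i], paste0("node class '", n$category[i], "/", n$subtype[i],
                              "' not in catalog"), "error")
  }

  # V2 uniqueness rule (per compartment)
  comp <- which(n$category == "component")
  if (length(comp)) {
    keys <- component_key_string(n$label[comp], n$states[comp],
                                 n$compartment[comp])
    for (k in unique(keys[duplicated(keys)])) {
      ids <- n$id[comp[keys == k]]
      add("V2", ids, paste0("component occurrence duplicated in compartment ",
                            "(key ", k, ")"), "error")
    }
  }

  # V3 edge grammar
  if (nrow(e)) {
    sc <- node_field(graph, e$source, "category")
    tc <- node_field(graph, e$target, "category")
    allowed <- paste(sc, tc) %in% paste(ALLOWED_EDGE_GRAMMAR[, 1L],
                                        ALLOWED_EDGE_GRAMMAR[, 2L])
    for (i in which(!allowed)) {
      add("V3", c(e$source[i], e$target[i]),
          paste0("edge ", e$source[i], " -> ", e$target[i], " violates the ",
                 "component/process alternation (", sc[i], " -> ", tc[i], ")"),
          if (strict) "error" else "warning")
    }
  }

  # V4 Boolean operator degrees
  for (i in which(n$category == "boolean")) {
    indeg <- sum(e$target == n$id[i])
    outdeg <- sum(e$source == n$id[i])
    if (indeg < 2L) {
      sev <- if (n$subtype[i] == "and" || strict) "error" else "warning"
      add("V4", n$id[i], paste0(toupper(n$subtype[i]), " operator ", n$id[i],
                                " has in-degree ", indeg, " (needs >= 2)"), sev)
    }
    if (outdeg < 1L) {
      add("V4", n$id[i], paste0("Boolean operator ", n$id[i],
                                " has no downstream node"), "error")
    }
  }

  # V5 sinks
  for (i in which(n$category == "process" & n$subtype == "sink")) {
    outdeg <- sum(e$source == n$id[i])
    indeg <- sum(e$target == n$id[i])
    if (outdeg > 0L) {
      add("V5", n$id[i], paste0("sink ", n$id[i], " has outgoing edge(s)"),
          "error")
    }
    if (indeg < 1L) {
      add("V5", n$id[i], paste0("sink ", n$id[i], " has no incoming edge"),
          "error")
    }
  }

  # V6 evidence (warnings only)
  for (i in which(n$category == "process")) {
    id <- n$id[i]
    epm <- unlist(e$pubmed[e$source == id | e$target == id])
    if (!length(n$pubmed[[i]]) && !length(epm)) {
      add("V6", id, paste0("process ", id, " carries no PubMed evidence"),
          "warning")
    }
  }

  all_f <- if (length(findings)) do.call(rbind, findings) else
    data.frame(rule = character(), ids = character(), message = character(),
               severity = character(), stringsAsFactors = FALSE)
  errors <- all_f[all_f$severity == "error",
                  c("rule", "ids", "message"), drop = FALSE]
  warnings <- all_f[all_f$severity == "warning",
                    c("rule", "ids", "message"), drop = FALSE]
  rownames(errors) <- NULL; rownames(warnings) <- NULL
  structure(list(errors = errors, warnings = warnings,
                 passed = nrow(errors) == 0L),
            class = "mepn_validation")
}

#' @export
print.mepn_validation <- function(x, ...) {
  cat("mEPN validation:", if (x$passed) "PASSED" else "FAILED", "\n")
  cat("  errors:", nrow(x$errors), " warnings:", nrow(x$warnings), "\n")
  show <- function(df, tag) {
    for (i in seq_len(nrow(df))) {
      cat("  [", tag, " ", df$rule[i], "] ", df$message[i], "\n", sep = "")
    }
  }
  show(x$errors, "error")
  show(x$warnings, "warn")
  invisible(x)
}
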