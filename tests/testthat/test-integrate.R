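test_that("disjoint graphs merge additively; shared components unify", {
  g1 <- toy_graph(ids = c("A", "p", "B"),
                  categories = c("component", "process", "component"),
                  subtypes = c("protein", "binding", "protein"),
                  labels = c("TRAF6", "B", "TAB1"),
                  from = c("A", "p"), to = c("p", "B"), title = "tlr")
  g2 <- toy_graph(ids = c("X", "q", "Y"),
                  categories = c("component", "process", "component"),
                  subtypes = c("protein", "binding", "protein"),
                  labels = c("STAT1", "B", "JAK1"),
                  from = c("X", "q"), to = c("q", "Y"), title = "ifn")
  res <- merge_pathways(list(g1, g2))
  expect_equal(nrow(res$graph$nodes), 6L)
  expect_length(res$report$shared_keys, 0L)

  g3 <- toy_graph(ids = c("T", "r", "U"),
                  categories = c("component", "process", "component"),
                  subtypes = c("protein", "phosphorylation", "protein"),
                  labels = c("TRAF6", "P", "UBE2N"),
                  from = c("T", "r"), to = c("r", "U"), title = "ubq")
  res2 <- merge_pathways(list(g1, g3))
  expect_equal(nrow(res2$graph$nodes), 3L + 3L - 1L)  # one shared TRAF6
  expect_length(res2$report$shared_keys, 1L)
  expect_true(validate_pathway(res2$graph)$passed)
  # provenance covers every merged node exactly once
  expect_setequal(names(res2$report$provenance), res2$graph$nodes$id)
  expect_error(merge_pathways(list(g1, g1)), "duplicate graph names")
})

test_that("differing process depictions of the same component pair are
           flagged as conflicts, both depictions kept", {
  # input one: A binds B directly into A:B
  g1 <- toy_graph(ids = c("A", "p", "AB"),
                  categories = c("component", "process", "component"),
                  subtypes = c("protein", "binding", "protein_complex"),
                  labels = c("A1", "B", "A1:B1"),
                  from = c("A", "p"), to = c("p", "AB"), title = "one")
  # input two: A is first phosphorylated, then incorporated by another step
  g2 <- toy_graph(ids = c("A", "q", "Ap", "r", "AB"),
                  categories = c("component", "process", "component",
                                 "process", "component"),
                  subtypes = c("protein", "phosphorylation", "protein",
                               "other_process", "protein_complex"),
                  labels = c("A1", "P", "A1", "", "A1:B1"),
                  states = list(character(), character(), "phosphorylated",
                                character(), character()),
                  from = c("A", "q", "Ap", "r"), to = c("q", "Ap", "r", "AB"),
                  title = "two")
  res <- merge_pathways(list(g1, g2))
  expect_equal(nrow(res$report$conflicts), 1L)
  expect_match(res$report$conflicts$key_pair, "A1 -> A1:B1")
  # both process nodes survive (processes are never auto-unified)
  expect_equal(sum(res$graph$nodes$category == "process"), 3L)
})

test_that("merge is associative on disjoint inputs and self-merge is identity
           on component keys", {
  gs <- lapply(501:503, function(s) synth_pathway(random_pathway_spec(s)))
  left <- merge_pathways(list(
    merge_pathways(gs[1:2], names = c("a", "b"))$graph, gs[[3]]),
    names = c("ab", "c"))$graph
  flat <- merge_pathways(gs, names = c("a", "b", "c"))$graph
  key_census <- function(g) {
    comp <- g$nodes$category == "component"
    sort(identity_key(g, g$nodes$id[comp]))
  }
  expect_equal(unname(key_census(left)), unname(key_census(flat)))
  expect_equal(nrow(left$nodes), nrow(flat$nodes))

  g <- gs[[1L]]
  twice <- merge_pathways(list(g, g), names = c("x", "y"))$graph
  expect_equal(unname(key_census(twice)), unname(key_census(g)))
})

test_that("interaction extraction expands Boolean operators correctly", {
  # A -> binding -> A:B: one record, nature binding, participants {A, B}
  recs <- extract_interactions(chain_graph())
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$nature, "binding")
  expect_equal(recs$participants, "NFKB1;RELA")
  expect_equal(recs$location, "cytoplasm")
  expect_equal(recs$pubmed_ids, "1234567")

  # AND: inputs X, Y through one operator -> a single record with all three
  g_and <- toy_graph(ids = c("X", "Y", "b", "p", "Z"),
                     categories = c("component", "component", "boolean",
                                    "process", "component"),
                     subtypes = c("protein", "protein", "and", "binding",
                                  "protein_complex"),
                     labels = c("TLR4", "LY96", "&", "B", "TLR4:LY96"),
                     from = c("X", "Y", "b", "p"), to = c("b", "b", "p", "Z"))
  recs <- extract_interactions(g_and)
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$participants, "LY96;TLR4")

  # OR: one record per alternative input (distinct output so the alternatives
  # do not collapse under participant-level deduplication)
  g_or <- g_and
  g_or$nodes$subtype[3L] <- "or"
  g_or$nodes$label[3L] <- "OR"
  g_or$nodes$subtype[5L] <- "protein"
  g_or$nodes$label[5L] <- "CD14"
  recs <- extract_interactions(g_or)
  expect_equal(nrow(recs), 2L)
  expect_setequal(recs$input_symbols, c("TLR4", "LY96"))
})

test_that("extraction matches the generator's ground-truth templates
           (property)", {
  for (seed in 511:516) {
    spec <- random_pathway_spec(seed)
    # annotations add modifiers and OR gates multiply alternatives; pin both
    # down so records map 1:1 onto generated process templates
    spec$n_annotation <- 0L
    spec$p_and <- 1
    g <- synth_pathway(spec)
    recs <- extract_interactions(g)
    truth <- attr(g, "interactions")
    expect_equal(nrow(recs), nrow(truth), label = paste("seed", seed))
    expect_setequal(paste(recs$input_symbols, recs$nature),
                    paste(vapply(strsplit(truth$inputs, ";"), function(v)
                      paste(sort(toupper(v)), collapse = ";"), character(1L)),
                      truth$nature))
  }
})

test_that("evidence summaries count distinct records and publications", {
  recs <- data.frame(pubmed_ids = c("1111111;2222222", "2222222;3333333"),
                     stringsAsFactors = FALSE)
  ev <- summarize_evidence(recs)
  expect_equal(ev$n_interactions, 2L)
  expect_equal(ev$n_publications, 3L)
  empty <- summarize_evidence(data.frame(pubmed_ids = character(),
                                         stringsAsFactors = FALSE))
  expect_equal(empty$n_interactions, 0L)
  expect_equal(empty$n_publications, 0L)

  # 3 records sharing one PMID
  shared <- data.frame(pubmed_ids = rep("1234567", 3),
                       stringsAsFactors = FALSE)
  expect_equal(summarize_evidence(shared)$n_publications, 1L)
})

test_that("the interaction TSV has the evidence-table schema", {
  f <- tempfile(fileext = ".tsv")
  write_interactions(extract_interactions(chain_graph()), f)
  tab <- read.delim(f, colClasses = "character")
  expect_equal(names(tab), c("PubMedID", "SymbolA", "EntrezA", "SymbolB",
                             "EntrezB", "AsDepictedA", "AsDepictedB",
                             "Nature", "Location"))
  expect_equal(tab$Nature, "binding")
})
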