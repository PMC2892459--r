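test_that("compilation maps components to places, processes to transitions,
           and expands Boolean operators", {
  net <- compile_spn(chain_graph())
  expect_setequal(net$places, c("A", "B", "AB"))
  expect_equal(net$transitions, "p")
  expect_equal(sort(paste(net$arcs$kind, net$arcs$place)),
               sort(c("consume A", "consume B", "produce AB")))

  # AND folds inputs into consume arcs of one transition
  g_and <- toy_graph(ids = c("X", "Y", "b", "p", "Z"),
                     categories = c("component", "component", "boolean",
                                    "process", "component"),
                     subtypes = c("protein", "protein", "and", "binding",
                                  "protein_complex"),
                     labels = c("X1", "Y1", "&", "B", "X1:Y1"),
                     from = c("X", "Y", "b", "p"), to = c("b", "b", "p", "Z"))
  net <- compile_spn(g_and)
  expect_equal(net$transitions, "p")
  expect_setequal(net$arcs$place[net$arcs$kind == "consume"], c("X", "Y"))

  # OR expands the downstream transition into one copy per alternative
  g_or <- g_and
  g_or$nodes$subtype[3L] <- "or"
  net <- compile_spn(g_or)
  expect_setequal(net$transitions, c("p#1", "p#2"))

  # a Boolean operator with no downstream process is a compile error
  g_bad <- toy_graph(ids = c("X", "b", "Z"),
                     categories = c("component", "boolean", "component"),
                     subtypes = c("protein", "and", "protein"),
                     labels = c("X1", "&", "Z1"),
                     from = c("X", "b"), to = c("b", "Z"))
  expect_error(compile_spn(g_bad), "no downstream process")
})

test_that("annotation arcs: catalysis reads, inhibition blocks", {
  g <- toy_graph(ids = c("A", "E", "I", "ca", "ia", "p", "B"),
                 categories = c("component", "component", "component",
                                "edge_annotation", "edge_annotation",
                                "process", "component"),
                 subtypes = c("protein", "protein", "protein", "catalysis",
                              "inhibition", "cleavage", "protein"),
                 labels = c("A1", "E1", "I1", "C", "I", "X", "B1"),
                 from = c("A", "E", "I", "ca", "ia", "p"),
                 to = c("p", "ca", "ia", "p", "p", "B"))
  net <- compile_spn(g)
  expect_equal(net$arcs$place[net$arcs$kind == "read"], "E")
  expect_equal(net$arcs$place[net$arcs$kind == "inhibit"], "I")

  # enzyme present, inhibitor absent: fires; tokens on the read place persist
  t1 <- simulate_spn(net, c(A = 3L, E = 1L), steps = 5, seed = 1)
  expect_equal(t1$mean_tokens["B", 5], 3)
  expect_equal(t1$mean_tokens["E", 5], 1)
  # inhibitor present: transition never fires
  t2 <- simulate_spn(net, c(A = 3L, E = 1L, I = 1L), steps = 5, seed = 1)
  expect_equal(t2$mean_tokens["B", 5], 0)
})

test_that("a simple chain transfers all tokens deterministically", {
  net <- compile_spn(chain_graph())
  traj <- simulate_spn(net, c(A = 5L, B = 5L), steps = 10, runs = 4, seed = 9)
  expect_equal(traj$mean_tokens["AB", 10], 5)
  expect_equal(traj$mean_tokens["A", 10], 0)
})

test_that("an AND gate with only one marked input never fires", {
  g_and <- toy_graph(ids = c("X", "Y", "b", "p", "Z"),
                     categories = c("component", "component", "boolean",
                                    "process", "component"),
                     subtypes = c("protein", "protein", "and", "binding",
                                  "protein_complex"),
                     labels = c("X1", "Y1", "&", "B", "X1:Y1"),
                     from = c("X", "Y", "b", "p"), to = c("b", "b", "p", "Z"))
  net <- compile_spn(g_and)
  traj <- simulate_spn(net, c(X = 10L), steps = 20, runs = 5, seed = 3)
  expect_true(all(traj$mean_tokens["Z", ] == 0))
  expect_true(all(traj$mean_tokens["X", ] == 10))
})

fork_graph <- function() {
  toy_graph(ids = c("A", "p1", "B", "p2", "C"),
            categories = c("component", "process", "component", "process",
                           "component"),
            subtypes = c("protein", "binding", "protein", "binding",
                         "protein"),
            labels = c("A1", "B", "B1", "B", "C1"),
            from = c("A", "p1", "A", "p2"), to = c("p1", "B", "p2", "C"))
}

test_that("uniform tie-breaking splits a contested token 50/50 in
           expectation", {
  # exact enumeration oracle: two equiprobable visiting orders, the first
  # transition in the shuffle wins the single token -> E[B] = 1/2
  orders <- list(c("p1", "p2"), c("p2", "p1"))
  exact <- mean(vapply(orders, function(o) as.numeric(o[1L] == "p1"),
                       numeric(1L)))
  expect_equal(exact, 0.5)

  net <- compile_spn(fork_graph())
  runs <- 4000L
  traj <- simulate_spn(net, c(A = 1L), steps = 3, runs = runs, seed = 17)
  # binomial error: sd = sqrt(0.25/runs); allow 4 sd
  expect_lt(abs(traj$mean_tokens["B", 3] - exact), 4 * sqrt(0.25 / runs))
  expect_equal(traj$mean_tokens["B", 3] + traj$mean_tokens["C", 3], 1)
})

test_that("tokens are conserved in nets whose transitions preserve counts", {
  # unary chain A -> B -> C: every transition consumes 1 and produces 1
  g <- toy_graph(ids = c("A", "p", "B", "q", "C"),
                 categories = c("component", "process", "component",
                                "process", "component"),
                 subtypes = c("protein", "translocation", "protein",
                              "translocation", "protein"),
                 labels = c("A1", "T", "A1", "T", "A1"),
                 compartment = c("cytoplasm", "cytoplasm", "endosome",
                                 "endosome", "nucleus"),
                 from = c("A", "p", "B", "q"), to = c("p", "B", "q", "C"))
  net <- compile_spn(g)
  traj <- simulate_spn(net, c(A = 7L, B = 2L), steps = 12, runs = 6, seed = 5)
  totals <- colSums(traj$mean_tokens)
  expect_true(all(abs(totals - 9) < 1e-12))
})

test_that("adding an inhibit arc never increases firing (paired seeds)", {
  g <- fork_graph()
  g_inh <- toy_graph(ids = c("A", "p1", "B", "p2", "C", "I", "ia"),
                     categories = c("component", "process", "component",
                                    "process", "component", "component",
                                    "edge_annotation"),
                     subtypes = c("protein", "binding", "protein", "binding",
                                  "protein", "protein", "inhibition"),
                     labels = c("A1", "B", "B1", "B", "C1", "I1", "I"),
                     from = c("A", "p1", "A", "p2", "I", "ia"),
                     to = c("p1", "B", "p2", "C", "ia", "p1"))
  for (seed in 21:24) {
    base <- simulate_spn(compile_spn(g), c(A = 20L), steps = 10, runs = 50,
                         seed = seed)
    inh <- simulate_spn(compile_spn(g_inh), c(A = 20L, I = 1L), steps = 10,
                        runs = 50, seed = seed)
    expect_lte(inh$firing_rates[["p1"]], base$firing_rates[["p1"]])
    expect_equal(unname(inh$firing_rates[["p1"]]), 0)
  }
})

test_that("simulation is bit-reproducible per seed and validates markings", {
  net <- compile_spn(fork_graph())
  # an odd token count leaves the last token to the tie-break, so the split
  # is genuinely stochastic
  a <- simulate_spn(net, c(A = 9L), steps = 8, runs = 100, seed = 33)
  b <- simulate_spn(net, c(A = 9L), steps = 8, runs = 100, seed = 33)
  expect_identical(a$mean_tokens, b$mean_tokens)
  c <- simulate_spn(net, c(A = 9L), steps = 8, runs = 100, seed = 34)
  expect_false(identical(a$mean_tokens, c$mean_tokens))
  expect_error(simulate_spn(net, c(NOPE = 1L), steps = 2), "unknown place")
  # marking by label also resolves
  m <- marking(net, c(A1 = 4L))
  expect_equal(unname(m["A"]), 4L)
})
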