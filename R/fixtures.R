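# Deterministic generators of synthetic mEPN pathways and synthetic
# expression timecourses, so every module is testable offline. All randomness
# flows from the single integer seed in the spec; the caller's RNG state is
# restored on exit.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Macrophage-flavoured symbol pool for generated nodes; overflow falls back
# to GENnnn placeholders.
SYMBOL_POOL <- c(
  "TLR1", "TLR2", "TLR3", "TLR4", "TLR5", "TLR6", "TLR7", "TLR9", "MYD88",
  "IRAK1", "IRAK4", "TRAF6", "TOLLIP", "TIFA", "TICAM1", "TICAM2", "LY96",
  "CD14", "LBP", "RELA", "RELB", "REL", "NFKB1", "NFKB2", "NFKBIA", "NFKBIB",
  "NFKBIE", "CHUK", "IKBKB", "IKBKG", "IKBKE", "TBK1", "MAP3K7", "MAPK1",
  "MAPK3", "MAPK8", "MAPK14", "MAP2K1", "MAP2K2", "JUN", "FOS", "IRF1",
  "IRF3", "IRF7", "IFNB1", "IFNA1", "IFNG", "IFNGR1", "IFNAR1", "IFNAR2",
  "JAK1", "JAK2", "TYK2", "STAT1", "STAT2", "SOCS1", "SOCS3", "TNF",
  "TNFRSF1A", "TRADD", "RIPK1", "FADD", "FAS", "FASLG", "TNFSF10", "CASP1",
  "CASP3", "CASP7", "CASP8", "CASP9", "APAF1", "CYCS", "BCL2", "BAX", "IL1B",
  "IL6", "IL12B", "NOD1", "NOD2", "NLRP3", "DDX58", "IFIH1", "ZBP1", "CD40",
  "CD40LG", "CREBBP", "HDAC3", "UBE2N", "UBC", "PSMA1", "PSMB9", "TAP1",
  "TAP2", "B2M", "CD80", "CD86", "DUSP1", "PRDM1", "NFKBIZ")

#' Specification of a synthetic pathway
#'
#' @param n_protein Base protein nodes.
#' @param n_phospho Phosphorylated variants (each adds a phosphorylation
#'   process and a protein node in the phosphorylated state).
#' @param n_complex Binary complexes (each adds a binding process).
#' @param n_gene Transcribed genes (each adds a transcription process).
#' @param n_sink Sink processes.
#' @param n_boolean Boolean operators gating binding processes.
#' @param p_and Probability a Boolean operator is AND rather than OR.
#' @param n_annotation Catalysis/inhibition edge-annotation nodes.
#' @param n_compartments Number of sub-cellular compartments (1-4).
#' @param pubmed_fraction Fraction of process nodes carrying PubMed ids.
#' @param seed Integer seed.
#' @return A list of class `mepn_pathway_spec`.
#' @export
pathway_spec <- function(n_protein = 14L, n_phospho = 3L, n_complex = 4L,
                         n_gene = 3L, n_sink = 1L, n_boolean = 2L,
                         p_and = 0.5, n_annotation = 2L, n_compartments = 2L,
                         pubmed_fraction = 0.8, seed = 1L) {
  spec <- list(n_protein = as.integer(n_protein),
               n_phospho = as.integer(n_phospho),
               n_complex = as.integer(n_complex),
               n_gene = as.integer(n_gene), n_sink = as.integer(n_sink),
               n_boolean = as.integer(n_boolean), p_and = p_and,
               n_annotation = as.integer(n_annotation),
               n_compartments = as.integer(n_compartments),
               pubmed_fraction = pubmed_fraction, seed = as.integer(seed))
  if (any(unlist(spec[1:6]) < 0L)) stop("counts must be >= 0")
  if (spec$n_complex > 0L && spec$n_protein < 2L) {
    stop("complexes need at least 2 base proteins")
  }
  if (spec$n_complex > choose(spec$n_protein, 2L)) {
    stop("not enough distinct protein pairs for the requested complexes")
  }
  if (spec$n_phospho > spec$n_protein) {
    stop("n_phospho cannot exceed n_protein")
  }
  if (spec$n_boolean > spec$n_complex) {
    stop("Boolean operators gate binding processes: n_boolean <= n_complex")
  }
  if (spec$n_sink > spec$n_protein) stop("n_sink cannot exceed n_protein")
  if (spec$n_annotation > 0L && spec$n_protein < 3L) {
    stop("annotations need at least 3 base proteins")
  }
  n_process <- spec$n_phospho + spec$n_complex + spec$n_gene + spec$n_sink
  if (spec$n_annotation > n_process) {
    stop("n_annotation cannot exceed the number of processes")
  }
  if (spec$n_compartments < 1L || spec$n_compartments > 4L) {
    stop("n_compartments must be in 1..4")
  }
  structure(spec, class = "mepn_pathway_spec")
}

rand_pmids <- function(k) as.character(sample(1000000:99999999, k))

#' Generate a synthetic mEPN pathway
#'
#' Produces a graph with exactly the class counts requested by the spec
#' (proteins = `n_protein + n_phospho` including phosphorylated variants),
#' alternating component/process edges, the uniqueness rule respected, and a
#' ground-truth interaction list attached as attribute `"interactions"`. The
#' output validates in strict mode and is bit-reproducible per seed.
#'
#' @param spec An `mepn_pathway_spec`.
#' @return An `mepn_pathway`.
#' @export
synth_pathway <- function(spec) {
  stopifnot(inherits(spec, "mepn_pathway_spec"))
  with_seed(spec$seed, {
    compartments <- c("cytoplasm", "nucleus", "endosome",
                      "extracellular")[seq_len(spec$n_compartments)]
    n_sym_needed <- spec$n_protein + spec$n_gene
    pool <- if (n_sym_needed <= length(SYMBOL_POOL)) {
      sample(SYMBOL_POOL, n_sym_needed)
    } else {
      c(sample(SYMBOL_POOL),
        sprintf("GEN%03d", seq_len(n_sym_needed - length(SYMBOL_POOL))))
    }
    prot_sym <- pool[seq_len(spec$n_protein)]
    gene_sym <- pool[spec$n_protein + seq_len(spec$n_gene)]

    nodes <- list()
    edges <- list()
    truth <- list()
    add_node <- function(id, category, subtype, label, compartment,
                         states = character(), pubmed = character(),
                         url = "") {
      nodes[[length(nodes) + 1L]] <<- list(id = id, category = category,
                                           subtype = subtype, label = label,
                                           compartment = compartment,
                                           states = states, pubmed = pubmed,
                                           url = url)
    }
    add_edge <- function(s, t) {
      edges[[length(edges) + 1L]] <<- c(s, t)
    }
    add_truth <- function(process, nature, inputs, output) {
      truth[[length(truth) + 1L]] <<- data.frame(
        process = process, nature = nature,
        inputs = paste(sort(inputs), collapse = ";"),
        output = output, stringsAsFactors = FALSE)
    }

    prot_comp <- sample(compartments, spec$n_protein, replace = TRUE)
    prot_id <- sprintf("p%02d", seq_len(spec$n_protein))
    entrez <- sample(1000:999999, spec$n_protein)
    for (i in seq_len(spec$n_protein)) {
      add_node(prot_id[i], "component", "protein", prot_sym[i], prot_comp[i],
               url = paste0("https://www.ncbi.nlm.nih.gov/gene/", entrez[i]))
    }

    proc_k <- 0L
    new_proc <- function(subtype, glyph, compartment, pubmed) {
      proc_k <<- proc_k + 1L
      id <- sprintf("prc%02d", proc_k)
      add_node(id, "process", subtype, glyph, compartment, pubmed = pubmed)
      id
    }
    proc_pm <- function() {
      if (stats::runif(1L) < spec$pubmed_fraction) {
        rand_pmids(sample.int(3L, 1L))
      } else character()
    }

    # phosphorylated variants
    ph_targets <- sample.int(spec$n_protein, spec$n_phospho)
    for (k in seq_len(spec$n_phospho)) {
      i <- ph_targets[k]
      pid <- new_proc("phosphorylation", "P", prot_comp[i], proc_pm())
      vid <- sprintf("p%02dph", i)
      add_node(vid, "component", "protein", prot_sym[i], prot_comp[i],
               states = "phosphorylated")
      add_edge(prot_id[i], pid)
      add_edge(pid, vid)
      add_truth(pid, "phosphorylation", prot_sym[i], prot_sym[i])
    }

    # binary complexes via binding processes, some gated by Boolean operators
    pair_idx <- utils::combn(spec$n_protein, 2L)
    pairs <- pair_idx[, sample.int(ncol(pair_idx), spec$n_complex),
                      drop = FALSE]
    for (k in seq_len(spec$n_complex)) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      compartment <- prot_comp[a]
      pid <- new_proc("binding", "B", compartment, proc_pm())
      cid <- sprintf("cx%02d", k)
      add_node(cid, "component", "protein_complex",
               paste(prot_sym[a], prot_sym[b], sep = ":"), compartment)
      if (k <= spec$n_boolean) {
        sub <- if (stats::runif(1L) < spec$p_and) "and" else "or"
        bid <- sprintf("bool%02d", k)
        add_node(bid, "boolean", sub, if (sub == "and") "&" else "OR",
                 compartment)
        add_edge(prot_id[a], bid)
        add_edge(prot_id[b], bid)
        add_edge(bid, pid)
      } else {
        add_edge(prot_id[a], pid)
        add_edge(prot_id[b], pid)
      }
      add_edge(pid, cid)
      add_truth(pid, "binding", c(prot_sym[a], prot_sym[b]),
                paste(prot_sym[a], prot_sym[b], sep = ":"))
    }

    # transcriptionally regulated genes
    gene_compartment <- if ("nucleus" %in% compartments) "nucleus" else
      compartments[1L]
    for (k in seq_len(spec$n_gene)) {
      tf <- sample.int(spec$n_protein, 1L)
      pid <- new_proc("transcription", "TR", gene_compartment, proc_pm())
      gid <- sprintf("g%02d", k)
      add_node(gid, "component", "gene_dna", gene_sym[k], gene_compartment)
      add_edge(prot_id[tf], pid)
      add_edge(pid, gid)
      add_truth(pid, "transcription", prot_sym[tf], gene_sym[k])
    }

    # sinks (degradation short-cuts)
    victims <- sample.int(spec$n_protein, spec$n_sink)
    for (k in seq_len(spec$n_sink)) {
      i <- victims[k]
      pid <- new_proc("sink", "", prot_comp[i], proc_pm())
      add_edge(prot_id[i], pid)
      add_truth(pid, "sink", prot_sym[i], "")
    }

    graph1 <- build_pathway(nodes, edges, compartments)

    # edge annotations (catalysis/inhibition) on randomly chosen processes
    all_proc <- graph1$nodes$id[graph1$nodes$category == "process"]
    ann_targets <- sample(all_proc, spec$n_annotation)
    for (k in seq_len(spec$n_annotation)) {
      pid <- ann_targets[k]
      involved <- c(predecessors(graph1, pid), successors(graph1, pid))
      cand <- setdiff(prot_id, involved)
      src <- cand[sample.int(length(cand), 1L)]
      sub <- if (k %% 2L == 1L) "catalysis" else "inhibition"
      aid <- sprintf("ann%02d", k)
      add_node(aid, "edge_annotation", sub, if (sub == "catalysis") "C" else
               "I", node_field(graph1, pid, "compartment"))
      add_edge(src, aid)
      add_edge(aid, pid)
    }

    graph <- build_pathway(nodes, edges, compartments,
                           title = sprintf("synthetic-%d", spec$seed))
    attr(graph, "interactions") <- if (length(truth)) do.call(rbind, truth)
      else data.frame(process = character(), nature = character(),
                      inputs = character(), output = character(),
                      stringsAsFactors = FALSE)
    attr(graph, "spec") <- spec
    graph
  })
}

build_pathway <- function(nodes, edges, compartments, title = "synthetic") {
  nt <- mepn_nodes(id = vapply(nodes, `[[`, character(1L), "id"),
                   category = vapply(nodes, `[[`, character(1L), "category"),
                   subtype = vapply(nodes, `[[`, character(1L), "subtype"),
                   label = vapply(nodes, `[[`, character(1L), "label"),
                   compartment = vapply(nodes, `[[`, character(1L),
                                        "compartment"),
                   url = vapply(nodes, `[[`, character(1L), "url"),
                   states = lapply(nodes, `[[`, "states"),
                   pubmed = lapply(nodes, `[[`, "pubmed"))
  et <- if (length(edges)) {
    mepn_edges(source = vapply(edges, `[`, character(1L), 1L),
               target = vapply(edges, `[`, character(1L), 2L))
  } else NULL
  mepn_pathway(nt, et, compartments = compartments,
               metadata = list(title = title))
}

#' Specification of a synthetic expression timecourse
#'
#' Defaults emulate a cytokine-stimulation timecourse in macrophages:
#' 5 timepoints (0/1/2/4/8 h) x 3 replicates, with planted co-expression
#' modules whose members share a pulse-shaped log2 fold-change profile
#' (amplitude `peak_lfc`, maximum at `peak_time`) plus module-correlated
#' noise at correlation `rho`; non-module transcripts are pure noise.
#'
#' @param n_transcripts Total transcripts.
#' @param timepoints Timepoint values (must include the baseline, 0).
#' @param n_replicates Replicates per timepoint.
#' @param modules Data frame with columns `size`, `peak_lfc`, `peak_time`,
#'   `rho`.
#' @param noise_sd Per-measurement noise standard deviation (log2 units).
#' @param pathway_fraction Fraction of module symbols drawn from a supplied
#'   pathway's node labels in [synth_expression()].
#' @param seed Integer seed.
#' @return A list of class `mepn_expression_spec`.
#' @export
expression_spec <- function(n_transcripts = 400L,
                            timepoints = c(0, 1, 2, 4, 8),
                            n_replicates = 3L,
                            modules = data.frame(
                              size = c(40L, 30L, 25L, 20L),
                              peak_lfc = c(2.5, 2.0, 1.5, -2.0),
                              peak_time = c(2, 4, 8, 4),
                              rho = 0.95),
                            noise_sd = 0.1, pathway_fraction = 0.5,
                            seed = 1L) {
  spec <- list(n_transcripts = as.integer(n_transcripts),
               timepoints = timepoints, n_replicates = as.integer(n_replicates),
               modules = modules, noise_sd = noise_sd,
               pathway_fraction = pathway_fraction, seed = as.integer(seed))
  if (sum(modules$size) > spec$n_transcripts) {
    stop("module sizes exceed n_transcripts")
  }
  if (any(modules$rho < 0 | modules$rho >= 1)) stop("rho must be in [0, 1)")
  if (!0 %in% timepoints) stop("timepoints must include the baseline 0")
  structure(spec, class = "mepn_expression_spec")
}

# Pulse profile: 0 at t = 0, 1 at t = peak_time, decaying after.
pulse_profile <- function(t, peak_time) {
  ifelse(t <= 0, 0, (t / peak_time) * exp(1 - t / peak_time))
}

#' Generate a synthetic expression timecourse
#'
#' @param spec An `mepn_expression_spec`.
#' @param pathway Optional `mepn_pathway`: a `pathway_fraction` share of each
#'   module's symbols is drawn from the pathway's component labels so that
#'   downstream overlay recovery can be scored against ground truth.
#' @return List with `expr` (an `mepn_expr`) and `truth` (data frame:
#'   `transcript`, `module` (0 = background), `peak_lfc`, `de`).
#' @export
synth_expression <- function(spec, pathway = NULL) {
  stopifnot(inherits(spec, "mepn_expression_spec"))
  with_seed(spec$seed, {
    tps <- rep(spec$timepoints, each = spec$n_replicates)
    reps <- rep(seq_len(spec$n_replicates), times = length(spec$timepoints))
    samples <- data.frame(sample = sprintf("t%g_r%d", tps, reps),
                          timepoint = tps, replicate = reps,
                          stringsAsFactors = FALSE)
    ns <- nrow(samples)
    mod <- spec$modules
    n_mod_transcripts <- sum(mod$size)

    pool <- character()
    if (!is.null(pathway)) {
      n <- pathway$nodes
      sel <- n$category == "component" &
        n$subtype %in% c("protein", "protein_complex", "gene_dna")
      pool <- unique(unlist(lapply(n$label[sel], base_identifiers)))
      pool <- sample(pool)
    }
    n_from_pathway <- min(length(pool),
                          round(spec$pathway_fraction * n_mod_transcripts))
    mod_syms <- c(pool[seq_len(n_from_pathway)],
                  sprintf("TX%04d", seq_len(n_mod_transcripts -
                                              n_from_pathway)))
    mod_syms <- sample(mod_syms)   # spread pathway symbols across modules
    bg_syms <- sprintf("TX%04d",
                       n_mod_transcripts - n_from_pathway +
                         seq_len(spec$n_transcripts - n_mod_transcripts))
    all_syms <- c(mod_syms, bg_syms)

    values <- matrix(0, nrow = spec$n_transcripts, ncol = ns,
                     dimnames = list(all_syms, samples$sample))
    mu <- stats::runif(spec$n_transcripts, 6, 10)
    membership <- integer(spec$n_transcripts)
    peak_lfc <- numeric(spec$n_transcripts)
    offset <- 0L
    for (m in seq_len(nrow(mod))) {
      idx <- offset + seq_len(mod$size[m])
      offset <- offset + mod$size[m]
      membership[idx] <- m
      peak_lfc[idx] <- mod$peak_lfc[m]
      signal <- mod$peak_lfc[m] * pulse_profile(samples$timepoint,
                                                mod$peak_time[m])
      shared <- stats::rnorm(ns, sd = spec$noise_sd)
      indiv <- matrix(stats::rnorm(length(idx) * ns, sd = spec$noise_sd),
                      nrow = length(idx))
      values[idx, ] <- mu[idx] +
        rep(signal, each = length(idx)) +
        sqrt(mod$rho[m]) * rep(shared, each = length(idx)) +
        sqrt(1 - mod$rho[m]) * indiv
    }
    bg <- which(membership == 0L)
    if (length(bg)) {
      values[bg, ] <- mu[bg] +
        matrix(stats::rnorm(length(bg) * ns, sd = spec$noise_sd),
               nrow = length(bg))
    }
    truth <- data.frame(transcript = all_syms, module = membership,
                        peak_lfc = peak_lfc,
                        de = membership > 0L & abs(peak_lfc) >= log2(1.5),
                        stringsAsFactors = FALSE)
    list(expr = expression_matrix(values, samples), truth = truth)
  })
}
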