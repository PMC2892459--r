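# Signalling Petri net compilation and stochastic token-flow simulation.
#
# Semantics: block-synchronous. At each time step the enabled transitions are
# visited in uniformly shuffled order and each fires at most once, consuming
# then producing immediately (so earlier firings in the shuffle can disable
# later ones). A transition is enabled when every consume and read input
# holds at least the arc weight and every inhibit input holds zero tokens.

#' Compile an mEPN diagram into a signalling Petri net
#'
#' Component nodes become places and process nodes become transitions. AND
#' operators fold their inputs into the consume arcs of the downstream
#' transition; OR operators expand it into one copy per alternative input
#' (suffixed `#1`, `#2`, ...). Catalysis annotations become read arcs,
#' inhibition annotations inhibit arcs. Sink processes compile to transitions
#' with no produce arcs. Arc weights default to 1 (mEPN labels carry no
#' stoichiometry).
#'
#' @param graph An `mepn_pathway`.
#' @return An object of class `mepn_spn` with `places`, `transitions` and an
#'   `arcs` data frame (`place`, `transition`, `kind`, `weight`).
#' @export
compile_spn <- function(graph) {
  stopifnot(inherits(graph, "mepn_pathway"))
  n <- graph$nodes
  for (b in n$id[n$category == "boolean"]) {
    reach <- successors(graph, b)
    ok <- FALSE
    seen <- character()
    while (length(reach)) {
      cats <- node_field(graph, reach, "category")
      if (any(cats == "process")) { ok <- TRUE; break }
      seen <- union(seen, reach)
      reach <- setdiff(unlist(lapply(reach[cats == "boolean"],
                                     successors, graph = graph)), seen)
    }
    if (!ok) stop("Boolean operator ", b, " has no downstream process")
  }

  places <- n$id[n$category == "component"]
  arcs <- list()
  transitions <- character()
  add_arc <- function(place, transition, kind) {
    arcs[[length(arcs) + 1L]] <<- data.frame(place = place,
                                             transition = transition,
                                             kind = kind, weight = 1L,
                                             stringsAsFactors = FALSE)
  }
  for (i in which(n$category == "process")) {
    pid <- n$id[i]
    res <- resolve_process_inputs(graph, pid)
    outs <- successors(graph, pid)
    outs <- outs[node_field(graph, outs, "category") == "component"]
    alts <- res$alternatives
    if (!length(alts)) alts <- list(character())
    multi <- length(alts) > 1L
    for (k in seq_along(alts)) {
      tid <- if (multi) paste0(pid, "#", k) else pid
      transitions <- c(transitions, tid)
      for (pl in alts[[k]]) add_arc(pl, tid, "consume")
      for (pl in res$read) add_arc(pl, tid, "read")
      for (pl in res$inhibit) add_arc(pl, tid, "inhibit")
      for (pl in outs) add_arc(pl, tid, "produce")
    }
  }
  arcs <- if (length(arcs)) do.call(rbind, arcs) else
    data.frame(place = character(), transition = character(),
               kind = character(), weight = integer(),
               stringsAsFactors = FALSE)
  structure(list(places = places, transitions = transitions, arcs = arcs,
                 labels = stats::setNames(n$label[match(places, n$id)],
                                          places)),
            class = "mepn_spn")
}

#' @export
print.mepn_spn <- function(x, ...) {
  cat("signalling Petri net:", length(x$places), "places,",
      length(x$transitions), "transitions,", nrow(x$arcs), "arcs\n")
  invisible(x)
}

#' Create an initial marking
#'
#' @param net An `mepn_spn`.
#' @param tokens Named vector: place id (or unique place label) -> token count.
#' @return Named integer vector over all places.
#' @export
marking <- function(net, tokens = NULL) {
  m <- stats::setNames(integer(length(net$places)), net$places)
  if (!is.null(tokens)) {
    for (nm in names(tokens)) {
      id <- nm
      if (!id %in% net$places) {
        hit <- names(net$labels)[net$labels == nm]
        if (length(hit) == 1L) id <- hit
        else stop("marking references unknown place: ", nm)
      }
      if (tokens[[nm]] < 0) stop("negative token count for ", nm)
      m[id] <- as.integer(tokens[[nm]])
    }
  }
  m
}

#' Simulate stochastic token flow
#'
#' Runs the block-synchronous signalling-Petri-net semantics `runs` times and
#' averages the per-place token trajectories. Identical arguments (including
#' `seed`) give bit-identical output; the caller's RNG state is restored on
#' exit.
#'
#' @param net An `mepn_spn`.
#' @param initial Named integer vector of initial tokens (see [marking()]).
#' @param steps Number of time steps (>= 1).
#' @param runs Number of independent runs (>= 1).
#' @param seed Integer seed driving all randomness.
#' @return An object of class `mepn_trajectories`: `mean_tokens` is a
#'   places x steps matrix of averaged token counts after each step.
#' @export
simulate_spn <- function(net, initial, steps, runs = 1L, seed = 1L) {
  stopifnot(inherits(net, "mepn_spn"), steps >= 1L, runs >= 1L)
  unknown <- setdiff(names(initial), net$places)
  if (length(unknown)) stop("initial marking references unknown place(s): ",
                            paste(unknown, collapse = ", "))
  m0 <- marking(net, initial)

  places <- net$places
  np <- length(places)
  tr <- net$transitions
  nt <- length(tr)
  a <- net$arcs
  pi <- match(a$place, places)
  ti <- match(a$transition, tr)
  consume <- lapply(seq_len(nt), function(k) {
    s <- a$kind == "consume" & ti == k
    list(idx = pi[s], w = a$weight[s])
  })
  produce <- lapply(seq_len(nt), function(k) {
    s <- a$kind == "produce" & ti == k
    list(idx = pi[s], w = a$weight[s])
  })
  readarc <- lapply(seq_len(nt), function(k) {
    s <- a$kind == "read" & ti == k
    list(idx = pi[s], w = a$weight[s])
  })
  inhibit <- lapply(seq_len(nt), function(k) {
    s <- a$kind == "inhibit" & ti == k
    list(idx = pi[s])
  })

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  total <- matrix(0, nrow = np, ncol = steps,
                  dimnames = list(places, seq_len(steps)))
  fire_counts <- stats::setNames(numeric(nt), tr)
  for (r in seq_len(runs)) {
    m <- unname(m0)
    for (s in seq_len(steps)) {
      order <- if (nt > 1L) sample.int(nt) else 1L
      for (k in order) {
        co <- consume[[k]]; rd <- readarc[[k]]; ih <- inhibit[[k]]
        if (length(co$idx) && any(m[co$idx] < co$w)) next
        if (length(rd$idx) && any(m[rd$idx] < rd$w)) next
        if (length(ih$idx) && any(m[ih$idx] > 0L)) next
        if (!length(co$idx) && !length(rd$idx)) next  # source-less: inert
        if (length(co$idx)) m[co$idx] <- m[co$idx] - co$w
        pr <- produce[[k]]
        if (length(pr$idx)) m[pr$idx] <- m[pr$idx] + pr$w
        fire_counts[k] <- fire_counts[k] + 1
      }
      total[, s] <- total[, s] + m
    }
  }
  structure(list(mean_tokens = total / runs, n_runs = as.integer(runs),
                 seed = as.integer(seed), steps = as.integer(steps),
                 initial = m0, firing_rates = fire_counts / runs),
            class = "mepn_trajectories")
}

#' @export
print.mepn_trajectories <- function(x, ...) {
  cat("token trajectories:", nrow(x$mean_tokens), "places x", x$steps,
      "steps, averaged over", x$n_runs, "run(s) (seed ", x$seed, ")\n",
      sep = " ")
  invisible(x)
}

#' Write token trajectories as TSV
#'
#' Long format: columns `place`, `step`, `mean_tokens`.
#'
#' @param traj An `mepn_trajectories`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  mt <- traj$mean_tokens
  tab <- data.frame(place = rep(rownames(mt), ncol(mt)),
                    step = rep(seq_len(ncol(mt)), each = nrow(mt)),
                    mean_tokens = as.vector(mt), stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
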