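#' Build an explicit-state graph (reachable states only)
#'
#' Enumerates every state reachable from the initial-state set under the
#' requested semantics, by breadth-first search over the successor
#' functions ([sync_successor()] / [async_successors()]).  Asynchronous
#' states carry the last-executed-process tag; the fairness constraint
#' family is the partition of states by that tag.  Refuses to enumerate
#' systems whose total state count exceeds \code{cap}: a truncated oracle
#' would be worse than none.
#'
#' @param net a [network()].
#' @param scen a [scenario()] or \code{NULL}.
#' @param semantics \code{"sync"} or \code{"async"}.
#' @param cap hard limit on the total (not reachable) state count.
#' @return Object of class \code{qmc_graph}: \code{states} (integer matrix,
#'   one row per state), \code{sched} (integer tag per state, async),
#'   \code{succ} (sync: successor index vector; async: state x process
#'   index matrix), \code{init} (initial state indices), \code{procs}
#'   (process node names, async).
#' @export
build_graph <- function(net, scen = NULL, semantics = c("sync", "async"),
                        cap = 2e6) {
  semantics <- match.arg(semantics)
  scen <- validate_scenario(net, scen)
  comp <- compile_network(net)
  nms <- node_names(net)
  levs <- node_levels(net)
  procs <- which(vapply(comp, function(ci) ci$kind != "input", TRUE))
  np <- length(procs)
  total <- prod(levs) * (if (semantics == "async") np + 1 else 1)
  if (total > cap) {
    stop(structure(class = c("qmc_size_error", "error", "condition"),
                   list(message = sprintf(
                     "state space too large for explicit enumeration: %.4g states exceeds cap %.4g",
                     total, cap), call = sys.call())))
  }

  sets <- initial_states(net, scen)
  init_states <- as.matrix(do.call(expand.grid, sets))
  storage.mode(init_states) <- "integer"

  key_of <- function(x, sched) paste(paste(x, collapse = ","), sched, sep = ";")
  index <- new.env(parent = emptyenv(), hash = TRUE)
  states <- list()
  scheds <- integer()
  add_state <- function(x, sched) {
    k <- key_of(x, sched)
    i <- index[[k]]
    if (!is.null(i)) return(i)
    i <- length(states) + 1L
    states[[i]] <<- x
    scheds[[i]] <<- sched
    index[[k]] <- i
    i
  }

  init_idx <- integer(nrow(init_states))
  for (r in seq_len(nrow(init_states))) {
    init_idx[r] <- add_state(init_states[r, ], 0L)
  }

  succ <- list()
  frontier <- unique(init_idx)
  seen_expanded <- 0L
  while (seen_expanded < length(states)) {
    i <- seen_expanded + 1L
    x <- states[[i]]
    if (semantics == "sync") {
      nxt <- x
      for (j in seq_along(comp)) {
        if (comp[[j]]$kind != "input") nxt[[j]] <- transfer_compiled(comp[[j]], x)
      }
      succ[[i]] <- add_state(nxt, 0L)
    } else {
      row <- integer(np)
      for (p in seq_len(np)) {
        j <- procs[p]
        nxt <- x
        nxt[[j]] <- transfer_compiled(comp[[j]], x)
        row[p] <- add_state(nxt, p)
      }
      succ[[i]] <- row
    }
    seen_expanded <- i
  }

  smat <- do.call(rbind, states)
  colnames(smat) <- nms
  g <- list(net = net, scen = scen, semantics = semantics,
            states = smat,
            sched = if (semantics == "async") scheds else NULL,
            succ = if (semantics == "sync") unlist(succ)
                   else do.call(rbind, succ),
            init = sort(unique(init_idx)),
            procs = if (semantics == "async") nms[procs] else character())
  class(g) <- "qmc_graph"
  g
}

#' @export
print.qmc_graph <- function(x, ...) {
  cat(sprintf("qmc_graph: %s semantics, %d reachable states, %d initial\n",
              x$semantics, nrow(x$states), length(x$init)))
  invisible(x)
}

# states with >= 1 successor inside S
graph_ex <- function(g, S) {
  if (g$semantics == "sync") return(S[g$succ])
  rowSums(matrix(S[g$succ], nrow = nrow(g$succ))) > 0
}

graph_atom <- function(g, node, cmp, value) {
  x <- g$states[, node]
  switch(cmp, "=" = x == value, ">=" = x >= value, "<=" = x <= value,
         stop("unknown comparator"))
}

graph_eu <- function(g, f, target) {
  y <- target
  repeat {
    y2 <- y | (f & graph_ex(g, y))
    if (identical(y2, y)) return(y)
    y <- y2
  }
}

graph_eg <- function(g, f) {
  z <- f
  repeat {
    z2 <- z & graph_ex(g, z)
    if (identical(z2, z)) return(z)
    z <- z2
  }
}

# fair EG via strongly connected components: restrict the graph to
# f-states, keep nontrivial SCCs that intersect every fairness constraint,
# then close backwards within f.
graph_fair_eg <- function(g, f) {
  n <- nrow(g$states)
  if (g$semantics == "sync") stop("no fairness constraints on this system")
  idx <- which(f)
  if (length(idx) == 0L) return(rep(FALSE, n))
  from <- rep(idx, each = ncol(g$succ))
  to <- as.vector(t(g$succ[idx, , drop = FALSE]))
  keep <- f[to]
  from <- from[keep]; to <- to[keep]
  core <- rep(FALSE, n)
  if (length(from)) {
    gr <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
    if (igraph::vcount(gr) < n) gr <- igraph::add_vertices(gr, n - igraph::vcount(gr))
    comp <- igraph::components(gr, mode = "strong")$membership
    selfloop <- rep(FALSE, n)
    selfloop[from[from == to]] <- TRUE
    np <- length(g$procs)
    for (cid in unique(comp[idx])) {
      members <- idx[comp[idx] == cid]
      nontrivial <- length(members) > 1L || any(selfloop[members])
      if (!nontrivial) next
      tags <- unique(g$sched[members])
      if (all(seq_len(np) %in% tags)) core[members] <- TRUE
    }
  }
  graph_eu(g, f, core)
}

graph_fair_states <- function(g) {
  graph_fair_eg(g, rep(TRUE, nrow(g$states)))
}

#' Explicit-state CTL check (oracle)
#'
#' Textbook explicit-state CTL evaluation over a [build_graph()] result,
#' with fairness handled through strongly connected component analysis:
#' a state admits a fair path iff it can reach a nontrivial SCC
#' intersecting every fairness constraint.  Semantics are identical to
#' the symbolic [check()]; this is the independent oracle used to
#' cross-validate the BDD engine on small systems.
#'
#' @param g a [build_graph()] result.
#' @param f formula string or [parse_ctl()] object.
#' @param fair relativise to fair paths (asynchronous graphs only).
#' @param id optional property id.
#' @return Object of class \code{qmc_verdict_explicit}: \code{holds},
#'   \code{sat} (logical vector over the graph's states), plus metadata.
#' @export
explicit_check <- function(g, f, fair = FALSE, id = NULL) {
  if (is.character(f)) f <- parse_ctl(f, g$net)
  missing_atoms <- setdiff(ctl_atoms(f), node_names(g$net))
  if (length(missing_atoms)) {
    stop("formula references node '", missing_atoms[[1]],
         "' not present in the system")
  }
  if (fair && g$semantics != "async") {
    stop("fairness requested on a system with no fairness constraints")
  }
  n <- nrow(g$states)
  fset <- if (fair) graph_fair_states(g) else rep(TRUE, n)
  ev <- function(f) {
    switch(f$type,
      const = rep(f$value, n),
      atom = graph_atom(g, f$node, f$cmp, f$value),
      not = !ev(f$sub),
      and = ev(f$lhs) & ev(f$rhs),
      or = ev(f$lhs) | ev(f$rhs),
      implies = !ev(f$lhs) | ev(f$rhs),
      EX = graph_ex(g, ev(f$sub) & fset),
      EF = graph_eu(g, rep(TRUE, n), ev(f$sub) & fset),
      EU = graph_eu(g, ev(f$lhs), ev(f$rhs) & fset),
      EG = if (fair) graph_fair_eg(g, ev(f$sub)) else graph_eg(g, ev(f$sub)),
      AX = !graph_ex(g, !ev(f$sub) & fset),
      AF = !(if (fair) graph_fair_eg(g, !ev(f$sub)) else graph_eg(g, !ev(f$sub))),
      AG = !graph_eu(g, rep(TRUE, n), !ev(f$sub) & fset),
      AU = {
        nf <- !ev(f$lhs); ng <- !ev(f$rhs)
        left <- graph_eu(g, ng, nf & ng & fset)
        right <- if (fair) graph_fair_eg(g, ng) else graph_eg(g, ng)
        !(left | right)
      },
      stop("unknown CTL node type: ", f$type)
    )
  }
  sat <- ev(f)
  structure(list(holds = all(sat[g$init]), sat = sat, formula = f,
                 semantics = g$semantics, fair = fair, id = id, graph = g),
            class = "qmc_verdict_explicit")
}

#' @export
print.qmc_verdict_explicit <- function(x, ...) {
  cat(sprintf("qmc_verdict_explicit%s [%s%s]: %s (%d/%d states satisfy)\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              x$semantics, if (x$fair) "+fair" else "",
              if (x$holds) "TRUE" else "FALSE",
              sum(x$sat), length(x$sat)))
  invisible(x)
}

#' Compare a symbolic and an explicit verdict state-by-state
#'
#' Evaluates the symbolic satisfying set at every reachable explicit state
#' and checks it coincides with the oracle's satisfying set (and that the
#' verdicts agree).
#'
#' @param sym a [check()] verdict.
#' @param exp an [explicit_check()] verdict.
#' @return TRUE or a character description of the first disagreement.
#' @export
verdict_agrees <- function(sym, exp) {
  g <- exp$graph
  ts <- sym$ts
  assigns <- graph_assign_matrix(ts, g)
  sym_sat <- .bdd_eval_many(ts$mgr, sym$sat, assigns)
  if (!identical(as.logical(sym_sat), as.logical(exp$sat))) {
    i <- which(sym_sat != exp$sat)[1]
    return(sprintf("satisfying sets differ at state %d (%s): symbolic=%s explicit=%s",
                   i, paste(g$states[i, ], collapse = ","),
                   sym_sat[i], exp$sat[i]))
  }
  if (!identical(sym$holds, exp$holds)) {
    return(sprintf("verdicts differ: symbolic=%s explicit=%s",
                   sym$holds, exp$holds))
  }
  TRUE
}

# vectorised encoding of all graph states as BDD-variable assignments;
# cached on the transition system (one matrix per explicit graph)
graph_assign_matrix <- function(ts, g) {
  key <- paste0("assigns_", nrow(g$states), "_", sum(g$states),
                "_", sum(g$sched %||% 0L))
  hit <- ts$cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- nrow(g$states)
  assigns <- matrix(0L, nrow = n, ncol = .bdd_nvars(ts$mgr))
  for (i in seq_along(ts$nms)) {
    col <- g$states[, ts$nms[i]]
    for (b in seq_along(ts$curv[[i]])) {
      assigns[, ts$curv[[i]][b] + 1L] <- bitwAnd(bitwShiftR(col, b - 1L), 1L)
    }
  }
  if (length(ts$sched_cur) && !is.null(g$sched)) {
    for (b in seq_along(ts$sched_cur)) {
      assigns[, ts$sched_cur[b] + 1L] <- bitwAnd(bitwShiftR(g$sched, b - 1L), 1L)
    }
  }
  ts$cache[[key]] <- assigns
  assigns
}

#' Seeded random network generator
#'
#' Draws a valid network with \code{n_nodes} nodes: the first node is an
#' input; the rest are internal (three levels) or, occasionally, Boolean
#' outputs.  Each ordered pair gets an edge with probability
#' \code{edge_density} (never into inputs), signs uniform; nodes gain a
#' random basal term with probability \code{basal_prob}; internal nodes
#' with two or more activators occasionally use the \code{joint_min}
#' rule.  Identical seeds give identical networks.
#'
#' @param seed integer seed.
#' @param n_nodes node count (>= 1).
#' @param edge_density edge probability per ordered pair.
#' @param basal_prob probability a non-input node gets a positive basal.
#' @return A [network()].
#' @export
random_network <- function(seed, n_nodes, edge_density = 0.3,
                           basal_prob = 0.15) {
  if (n_nodes < 1L) stop("n_nodes must be >= 1")
  with_seed(seed, {
    nms <- paste0("n", seq_len(n_nodes))
    kinds <- c("input", if (n_nodes > 1L)
      sample(c("internal", "output"), n_nodes - 1L, replace = TRUE,
             prob = c(0.8, 0.2)))
    pairs <- expand.grid(from = seq_len(n_nodes), to = seq_len(n_nodes))
    pairs <- pairs[kinds[pairs$to] != "input", , drop = FALSE]
    draw <- stats::runif(nrow(pairs)) < edge_density
    edges <- if (any(draw)) {
      data.frame(from = nms[pairs$from[draw]], to = nms[pairs$to[draw]],
                 sign = sample(c("+", "-"), sum(draw), replace = TRUE),
                 stringsAsFactors = FALSE)
    } else NULL
    nodes <- lapply(seq_len(n_nodes), function(i) {
      levels <- if (kinds[i] == "output") 2L else 3L
      basal <- 0L
      if (kinds[i] != "input" && stats::runif(1) < basal_prob) {
        basal <- sample.int(levels - 1L, 1L)
      }
      nact <- if (is.null(edges)) 0L else
        sum(edges$to == nms[i] & edges$sign == "+")
      rule <- if (nact >= 2L && stats::runif(1) < 0.2) "joint_min" else "additive"
      node_spec(nms[i], kind = kinds[i], levels = levels, basal = basal,
                rule = rule)
    })
    network(nodes, edges)
  })
}

#' Seeded random CTL formula generator
#'
#' Draws a random abstract syntax tree of bounded depth over a network's
#' nodes, covering atoms, Boolean connectives and all eight temporal
#' operators.  Used by the oracle-equivalence fuzz suite.
#'
#' @param seed integer seed.
#' @param net a [network()].
#' @param depth maximum operator nesting depth.
#' @return A \code{qmc_ctl} formula.
#' @export
random_ctl <- function(seed, net, depth = 3L) {
  nms <- node_names(net)
  levs <- node_levels(net)
  with_seed(seed, {
    gen <- function(d) {
      if (d <= 0L || stats::runif(1) < 0.25) {
        if (stats::runif(1) < 0.1) return(list(type = "const",
                                               value = stats::runif(1) < 0.5))
        i <- sample.int(length(nms), 1L)
        return(list(type = "atom", node = nms[i],
                    cmp = sample(c("=", ">=", "<="), 1L),
                    value = sample.int(levs[i], 1L) - 1L))
      }
      op <- sample(c("not", "and", "or", "implies",
                     "EX", "AX", "EF", "AF", "EG", "AG", "EU", "AU"), 1L)
      if (op %in% c("not", "EX", "AX", "EF", "AF", "EG", "AG")) {
        if (op == "not") return(list(type = op, sub = gen(d - 1L)))
        return(list(type = op, sub = gen(d - 1L)))
      }
      list(type = op, lhs = gen(d - 1L), rhs = gen(d - 1L))
    }
    structure(gen(depth), class = "qmc_ctl")
  })
}

# evaluate expr with a private RNG stream; restores the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
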