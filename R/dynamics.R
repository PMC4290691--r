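#' Scenarios: initial-value constraints for a verification run
#'
#' A scenario fixes input nodes to given levels (or level sets) and may
#' override the default initial sets of other nodes.  It constrains only
#' the initial states; the transition relation is unaffected (inputs are
#' frozen along every path regardless).
#'
#' @param input_fix named list: input node -> fixed level or level set.
#' @param init_overrides named list: node -> initial level set.
#' @param name identifier used in reports.
#' @return An object of class \code{qmc_scenario}.
#' @export
scenario <- function(input_fix = list(), init_overrides = list(),
                     name = "scenario") {
  structure(list(input_fix = lapply(input_fix, as.integer),
                 init_overrides = lapply(init_overrides, as.integer),
                 name = name),
            class = "qmc_scenario")
}

validate_scenario <- function(net, scen) {
  if (is.null(scen)) return(scenario())
  nms <- node_names(net)
  kinds <- node_kinds(net)
  levs <- node_levels(net)
  for (nm in names(scen$input_fix)) {
    if (!nm %in% nms) stop("scenario fixes unknown node '", nm, "'")
    if (kinds[[nm]] != "input") stop("scenario input_fix on non-input node '", nm, "'")
    v <- scen$input_fix[[nm]]
    if (any(v < 0L | v > levs[[nm]] - 1L)) {
      stop("scenario fixes '", nm, "' outside its domain")
    }
  }
  for (nm in names(scen$init_overrides)) {
    if (!nm %in% nms) stop("scenario overrides unknown node '", nm, "'")
    v <- scen$init_overrides[[nm]]
    if (any(v < 0L | v > levs[[nm]] - 1L)) {
      stop("scenario overrides '", nm, "' outside its domain")
    }
  }
  scen
}

#' Initial states of a network under a scenario
#'
#' The initial-state set is the Cartesian product of per-node sets: inputs
#' take their scenario-fixed values (else their full domain), internal
#' nodes take \code{{0, 1}} unless overridden, outputs start at 0.  The
#' set is returned in factored form (one level set per node) together with
#' the resulting state count.
#'
#' @param net a [network()].
#' @param scen a [scenario()] or \code{NULL}.
#' @return Object of class \code{qmc_stateset}: named list of integer level
#'   sets with attribute \code{count}.
#' @export
initial_states <- function(net, scen = NULL) {
  scen <- validate_scenario(net, scen)
  sets <- lapply(net$nodes, function(n) {
    s <- n$init
    if (n$name %in% names(scen$init_overrides)) {
      s <- scen$init_overrides[[n$name]]
    }
    if (n$name %in% names(scen$input_fix)) s <- scen$input_fix[[n$name]]
    sort(unique(as.integer(s)))
  })
  names(sets) <- node_names(net)
  count <- prod(vapply(sets, length, 0L))
  if (count == 0) stop("contradictory scenario: empty initial-state set")
  structure(sets, count = count, class = "qmc_stateset")
}

#' @export
print.qmc_stateset <- function(x, ...) {
  cat(sprintf("qmc_stateset: %s states over %d nodes\n",
              format(attr(x, "count"), big.mark = ","), length(x)))
  invisible(x)
}

check_state <- function(net, state) {
  nms <- node_names(net)
  if (is.null(names(state))) {
    if (length(state) != length(nms)) stop("state length mismatch")
    names(state) <- nms
  }
  state <- as.integer(state[nms])
  levs <- node_levels(net)
  if (anyNA(state)) stop("state is missing a node assignment")
  if (any(state < 0L | state > levs - 1L)) {
    bad <- nms[state < 0L | state > levs - 1L][1]
    stop("state assigns '", bad, "' a level outside its domain")
  }
  stats::setNames(state, nms)
}

#' Synchronous successor state
#'
#' Every non-input node simultaneously takes the value of its transfer
#' function evaluated at the argument state; inputs keep their value.  The
#' synchronous relation is deterministic: each state has exactly one
#' successor.
#'
#' @param net a [network()].
#' @param state named integer vector (level per node), or unnamed in node
#'   order.
#' @return Named integer vector: the unique successor.
#' @export
sync_successor <- function(net, state) {
  x <- check_state(net, state)
  comp <- compile_network(net)
  nxt <- x
  for (i in seq_along(comp)) {
    if (comp[[i]]$kind != "input") nxt[[i]] <- transfer_compiled(comp[[i]], x)
  }
  nxt
}

#' Asynchronous successors: one update process per non-input node
#'
#' Entry \code{i} applies the transfer function to node \code{i} only and
#' leaves every other node unchanged (interleaving semantics).  Input
#' nodes are not processes and stay frozen.  Stuttering successors (the
#' updated value equals the current one) are retained so the relation
#' stays total.
#'
#' @inheritParams sync_successor
#' @return Named list (one entry per process, named by node) of successor
#'   states.
#' @export
async_successors <- function(net, state) {
  x <- check_state(net, state)
  comp <- compile_network(net)
  out <- list()
  for (i in seq_along(comp)) {
    if (comp[[i]]$kind == "input") next
    nxt <- x
    nxt[[i]] <- transfer_compiled(comp[[i]], x)
    out[[comp[[i]]$name]] <- nxt
  }
  out
}

#' Simulate a trajectory
#'
#' Synchronous simulation follows the deterministic successor;
#' asynchronous simulation draws the process to execute uniformly from a
#' seeded generator, so traces are reproducible per seed.
#'
#' @inheritParams sync_successor
#' @param steps number of transitions to take.
#' @param semantics \code{"sync"} or \code{"async"}.
#' @param seed integer seed for asynchronous process choice.
#' @return Data frame with one row per visited state (\code{steps + 1}
#'   rows): column \code{step}, column \code{process} (async; the process
#'   executed to reach the row's state, \code{NA} for the start), and one
#'   column per node.
#' @export
simulate_trace <- function(net, start, steps, semantics = c("sync", "async"),
                           seed = 1L) {
  semantics <- match.arg(semantics)
  x <- check_state(net, start)
  comp <- compile_network(net)
  procs <- which(vapply(comp, function(ci) ci$kind != "input", TRUE))
  rows <- matrix(0L, nrow = steps + 1L, ncol = length(x),
                 dimnames = list(NULL, names(x)))
  rows[1L, ] <- x
  proc_col <- rep(NA_character_, steps + 1L)
  rng <- if (steps > 0L) {
    with_seed(seed, sample.int(length(procs), steps, replace = TRUE))
  } else integer()
  for (s in seq_len(steps)) {
    if (semantics == "sync") {
      x <- sync_successor(net, x)
    } else {
      i <- procs[[rng[[s]]]]
      x[[i]] <- transfer_compiled(comp[[i]], x)
      proc_col[[s + 1L]] <- comp[[i]]$name
    }
    rows[s + 1L, ] <- x
  }
  out <- data.frame(step = 0:steps, stringsAsFactors = FALSE)
  if (semantics == "async") out$process <- proc_col
  cbind(out, as.data.frame(rows))
}

#' Write a trace as TSV (step, node, level)
#'
#' @param trace a data frame from [simulate_trace()] or a witness trace.
#' @param path output file.
#' @export
write_trace <- function(trace, path) {
  keep <- setdiff(names(trace), c("step", "process"))
  long <- do.call(rbind, lapply(keep, function(nm) {
    data.frame(step = trace$step, node = nm, level = trace[[nm]],
               stringsAsFactors = FALSE)
  }))
  long <- long[order(long$step, long$node), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
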