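#' Multi-valued logical networks
#'
#' A network is an ordered collection of nodes, each holding a small number
#' of discrete levels \code{0..levels-1}, joined by signed (activating or
#' inhibiting) edges.  Node state advances by a clamped
#' activator-minus-inhibitor transfer rule (see [transfer_level()]).
#'
#' @param nodes list of node specifications built with [node_spec()].
#' @param edges data frame with columns \code{from}, \code{to}, \code{sign}
#'   (\code{"+"} for activation, \code{"-"} for inhibition), or \code{NULL}
#'   for an edgeless network.
#' @return An object of class \code{qmc_network}.
#' @examples
#' net <- network(
#'   nodes = list(
#'     node_spec("S", kind = "input"),
#'     node_spec("X"),
#'     node_spec("fate", kind = "output")
#'   ),
#'   edges = data.frame(from = c("S", "X"), to = c("X", "fate"),
#'                      sign = c("+", "+"))
#' )
#' validate_network(net)
#' @export
network <- function(nodes, edges = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        sign = character(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  for (col in c("from", "to", "sign")) {
    if (!col %in% names(edges)) stop("edges must have column '", col, "'")
    edges[[col]] <- as.character(edges[[col]])
  }
  net <- structure(list(nodes = nodes, edges = edges[c("from", "to", "sign")]),
                   class = "qmc_network")
  diag <- validate_network(net)
  if (length(diag)) stop("invalid network:\n  ", paste(diag, collapse = "\n  "))
  net
}

#' Specify a single network node
#'
#' @param name node identifier (letters, digits, `_`).
#' @param kind one of \code{"input"}, \code{"internal"}, \code{"output"}.
#'   Inputs are chosen nondeterministically at time 0 and then frozen;
#'   outputs are Boolean fate readouts.
#' @param levels number of discrete levels; defaults to 3 for inputs and
#'   internal nodes and 2 (Boolean) for outputs.
#' @param init permitted initial levels.  Defaults: full domain for inputs,
#'   \code{{0, 1}} for internal nodes, \code{{0}} for outputs.
#' @param basal constant production added to the activator sum (see
#'   [transfer_level()]); default 0.
#' @param rule \code{"additive"} (clamped sum) or \code{"joint_min"}
#'   (minimum over activators, expressing required co-factors).
#' @param compartment optional free-text annotation (e.g. "ER", "Golgi").
#' @return A list of class \code{qmc_node}.
#' @export
node_spec <- function(name, kind = c("internal", "input", "output"),
                      levels = NULL, init = NULL, basal = 0L,
                      rule = c("additive", "joint_min"),
                      compartment = NA_character_) {
  kind <- match.arg(kind)
  rule <- match.arg(rule)
  if (is.null(levels)) levels <- if (kind == "output") 2L else 3L
  levels <- as.integer(levels)
  if (is.null(init)) {
    init <- switch(kind,
                   input = seq.int(0L, levels - 1L),
                   internal = intersect(c(0L, 1L), seq.int(0L, levels - 1L)),
                   output = 0L)
  }
  structure(list(name = as.character(name), kind = kind, levels = levels,
                 init = sort(unique(as.integer(init))),
                 basal = as.integer(basal), rule = rule,
                 compartment = as.character(compartment)),
            class = "qmc_node")
}

#' @export
print.qmc_network <- function(x, ...) {
  kinds <- vapply(x$nodes, `[[`, "", "kind")
  cat(sprintf("qmc_network: %d nodes (%d input, %d internal, %d output), %d edges\n",
              length(x$nodes), sum(kinds == "input"), sum(kinds == "internal"),
              sum(kinds == "output"), nrow(x$edges)))
  invisible(x)
}

#' Node names of a network, in declaration order
#' @param net a [network()].
#' @export
node_names <- function(net) vapply(net$nodes, `[[`, "", "name")

#' @rdname node_names
#' @export
node_kinds <- function(net) {
  stats::setNames(vapply(net$nodes, `[[`, "", "kind"), node_names(net))
}

#' @rdname node_names
#' @export
node_levels <- function(net) {
  stats::setNames(vapply(net$nodes, `[[`, 0L, "levels"), node_names(net))
}

get_node <- function(net, name) {
  i <- match(name, node_names(net))
  if (is.na(i)) stop("unknown node '", name, "'")
  net$nodes[[i]]
}

#' Validate a network against the model invariants
#'
#' Checks every structural invariant (unique names, level ranges, basal
#' bounds, edge endpoints, no duplicate edges, no edges into input nodes)
#' and returns one diagnostic message per violation; an empty character
#' vector means the network is valid.  Unlike [network()], this never
#' throws.
#'
#' @param net an object shaped like a \code{qmc_network}.
#' @return Character vector of diagnostics (zero length if valid).
#' @export
validate_network <- function(net) {
  diag <- character()
  nms <- vapply(net$nodes, function(n) as.character(n$name %||% NA), "")
  if (anyDuplicated(nms)) {
    diag <- c(diag, sprintf("duplicate node name '%s'",
                            unique(nms[duplicated(nms)])))
  }
  for (n in net$nodes) {
    if (!n$kind %in% c("input", "internal", "output")) {
      diag <- c(diag, sprintf("node '%s': unknown kind '%s'", n$name, n$kind))
      next
    }
    if (n$levels < 2L) {
      diag <- c(diag, sprintf("node '%s': levels must be >= 2", n$name))
    }
    if (n$kind == "output" && n$levels != 2L) {
      diag <- c(diag, sprintf("node '%s': output nodes are Boolean (levels = 2)",
                              n$name))
    }
    if (length(n$init) == 0L || any(n$init < 0L | n$init > n$levels - 1L)) {
      diag <- c(diag, sprintf("node '%s': init set outside [0, %d]",
                              n$name, n$levels - 1L))
    }
    if (n$basal < 0L || n$basal > n$levels - 1L) {
      diag <- c(diag, sprintf("node '%s': basal must be in [0, %d]",
                              n$name, n$levels - 1L))
    }
    if (!n$rule %in% c("additive", "joint_min")) {
      diag <- c(diag, sprintf("node '%s': unknown rule '%s'", n$name, n$rule))
    }
  }
  e <- net$edges
  bad_from <- !e$from %in% nms
  bad_to <- !e$to %in% nms
  if (any(bad_from)) {
    diag <- c(diag, sprintf("edge %s -> %s: unknown source node",
                            e$from[bad_from], e$to[bad_from]))
  }
  if (any(bad_to)) {
    diag <- c(diag, sprintf("edge %s -> %s: unknown target node",
                            e$from[bad_to], e$to[bad_to]))
  }
  if (any(!e$sign %in% c("+", "-"))) {
    bad <- !e$sign %in% c("+", "-")
    diag <- c(diag, sprintf("edge %s -> %s: sign must be '+' or '-'",
                            e$from[bad], e$to[bad]))
  }
  key <- paste(e$from, e$to)
  if (anyDuplicated(key)) {
    diag <- c(diag, sprintf("duplicate edge %s", unique(key[duplicated(key)])))
  }
  kinds <- stats::setNames(vapply(net$nodes, `[[`, "", "kind"), nms)
  into_input <- e$to %in% nms[kinds[nms] == "input"] & !bad_to
  if (any(into_input)) {
    diag <- c(diag, sprintf("edge %s -> %s targets an input node",
                            e$from[into_input], e$to[into_input]))
  }
  diag
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Node state transfer function
#'
#' Computes the next level of a node from the current levels of its parents.
#' Under the \code{additive} rule the next level is
#' \deqn{clamp(basal + \sum_i A_i - \sum_j I_j,\; 0,\; n - 1)}
#' where the sums run over activator and inhibitor parent levels and
#' \eqn{n} is the node's level count: saturating at the top level when the
#' net drive reaches \eqn{n - 1} and at 0 when it vanishes.  Under
#' \code{joint_min} the activator sum is replaced by the minimum over
#' activator levels (all activators are jointly required), inhibitors still
#' subtract, and the same clamp applies.  A node with no parents and basal
#' 0 returns 0.
#'
#' @param node a [node_spec()].
#' @param parent_levels named integer vector or list: current level per
#'   parent.
#' @param edge_signs named character vector: \code{"+"} or \code{"-"} per
#'   parent.
#' @return Integer level in \code{[0, levels - 1]}.
#' @examples
#' n3 <- node_spec("X")
#' transfer_level(n3, c(eIF2a = 2), c(eIF2a = "+"))  # 2
#' transfer_level(n3, c(ATF4 = 1, NFkB = 1), c(ATF4 = "+", NFkB = "-"))  # 0
#' @export
transfer_level <- function(node, parent_levels = integer(), edge_signs = character()) {
  parent_levels <- unlist(parent_levels)
  if (length(parent_levels)) {
    if (is.null(names(parent_levels)) || is.null(names(edge_signs))) {
      stop("parent_levels and edge_signs must be named by parent")
    }
    missing_sign <- setdiff(names(parent_levels), names(edge_signs))
    if (length(missing_sign)) {
      stop("no edge sign for parent '", missing_sign[[1]], "'")
    }
    if (any(parent_levels < 0L)) stop("parent level outside its domain")
  }
  signs <- edge_signs[names(parent_levels)]
  act <- as.integer(parent_levels[signs == "+"])
  inh <- as.integer(parent_levels[signs == "-"])
  drive <- if (identical(node$rule, "joint_min")) {
    if (length(act)) min(act) else 0L
  } else {
    sum(act)
  }
  v <- node$basal + drive - sum(inh)
  max(0L, min(node$levels - 1L, as.integer(v)))
}

# Precompile parent structure for fast repeated evaluation.  Returns a list
# (one entry per node) of activator/inhibitor index vectors into the node
# order; memoised on the network object via an attribute-free env cache.
compile_network <- function(net) {
  nms <- node_names(net)
  lapply(seq_along(net$nodes), function(i) {
    n <- net$nodes[[i]]
    e <- net$edges[net$edges$to == n$name, , drop = FALSE]
    list(name = n$name, kind = n$kind, levels = n$levels, basal = n$basal,
         rule = n$rule, init = n$init,
         act = match(e$from[e$sign == "+"], nms),
         inh = match(e$from[e$sign == "-"], nms))
  })
}

# Transfer for node entry `ci` (from compile_network) at full state `x`
# (integer vector in node order).
transfer_compiled <- function(ci, x) {
  drive <- if (ci$rule == "joint_min") {
    if (length(ci$act)) min(x[ci$act]) else 0L
  } else {
    sum(x[ci$act])
  }
  v <- ci$basal + drive - sum(x[ci$inh])
  max(0L, min(ci$levels - 1L, v))
}

#' Read and write network model files
#'
#' Models are stored as JSON with top-level keys \code{nodes} (list of
#' \code{{name, kind, levels, init, basal, rule, compartment}}) and
#' \code{edges} (list of \code{{from, to, sign}}, sign \code{"+"} or
#' \code{"-"}).  [parse_network()] validates on load and names the
#' offending field on schema violations; [serialize_network()] emits
#' canonical JSON such that parse--serialize round-trips are stable.
#'
#' @param text JSON model text (for [parse_network()]).
#' @param path file path.
#' @param net a [network()].
#' @return [parse_network()] and [read_network()] return a
#'   \code{qmc_network}; [serialize_network()] returns a JSON string.
#' @export
parse_network <- function(text) {
  obj <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) stop("model file is not valid JSON: ",
                                           conditionMessage(e)))
  if (is.null(obj$nodes)) stop("schema violation at $nodes: missing")
  nodes <- lapply(seq_along(obj$nodes), function(i) {
    nd <- obj$nodes[[i]]
    if (is.null(nd$name)) stop("schema violation at $nodes[", i, "]$name: missing")
    node_spec(name = nd$name,
              kind = nd$kind %||% "internal",
              levels = nd$levels,
              init = if (!is.null(nd$init)) unlist(nd$init),
              basal = nd$basal %||% 0L,
              rule = nd$rule %||% "additive",
              compartment = nd$compartment %||% NA_character_)
  })
  edges <- NULL
  if (length(obj$edges)) {
    edges <- do.call(rbind, lapply(seq_along(obj$edges), function(i) {
      ed <- obj$edges[[i]]
      for (col in c("from", "to", "sign")) {
        if (is.null(ed[[col]])) {
          stop("schema violation at $edges[", i, "]$", col, ": missing")
        }
      }
      data.frame(from = ed$from, to = ed$to, sign = ed$sign,
                 stringsAsFactors = FALSE)
    }))
  }
  network(nodes, edges)
}

#' @rdname parse_network
#' @export
serialize_network <- function(net) {
  nodes <- lapply(net$nodes, function(n) {
    out <- list(name = n$name, kind = n$kind, levels = n$levels,
                init = I(n$init), basal = n$basal, rule = n$rule)
    if (!is.na(n$compartment)) out$compartment <- n$compartment
    out
  })
  edges <- lapply(seq_len(nrow(net$edges)), function(i) {
    list(from = net$edges$from[i], to = net$edges$to[i],
         sign = net$edges$sign[i])
  })
  jsonlite::toJSON(list(nodes = nodes, edges = edges),
                   auto_unbox = TRUE, pretty = TRUE)
}

#' @rdname parse_network
#' @export
read_network <- function(path) {
  parse_network(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' @rdname parse_network
#' @export
write_network <- function(net, path) {
  writeLines(serialize_network(net), path)
  invisible(path)
}

#' Cone-of-influence reduction
#'
#' Restricts a network to the ancestors of a set of target nodes (the
#' nodes that can influence them), dropping everything downstream or
#' causally disconnected.  Because removed nodes cannot affect the
#' targets, a CTL formula whose atoms all lie in the cone has the same
#' verdict at the initial states of the reduced system as of the full
#' one, under both update semantics; the reduction is the standard
#' state-space shrinking device of symbolic model checkers.
#'
#' @param net a [network()].
#' @param targets character vector of node names that must be kept.
#' @return A [network()] containing the targets' ancestor closure, in the
#'   original declaration order.
#' @export
cone_of_influence <- function(net, targets) {
  nms <- node_names(net)
  missing <- setdiff(targets, nms)
  if (length(missing)) stop("unknown node '", missing[[1]], "'")
  keep <- unique(targets)
  repeat {
    parents <- unique(net$edges$from[net$edges$to %in% keep])
    grown <- union(keep, parents)
    if (length(grown) == length(keep)) break
    keep <- grown
  }
  keep <- nms[nms %in% keep]
  edges <- net$edges[net$edges$from %in% keep & net$edges$to %in% keep, ,
                     drop = FALSE]
  network(net$nodes[match(keep, nms)], edges)
}

#' Export the signed interaction graph in Graphviz DOT format
#'
#' Activating edges are drawn with arrowheads, inhibiting edges with tees.
#'
#' @param net a [network()].
#' @return A character scalar of DOT source.
#' @export
network_dot <- function(net) {
  kinds <- node_kinds(net)
  shape <- c(input = "invhouse", internal = "ellipse", output = "doubleoctagon")
  lines <- c("digraph network {",
             sprintf('  "%s" [shape=%s];', names(kinds), shape[kinds]),
             sprintf('  "%s" -> "%s" [arrowhead=%s];',
                     net$edges$from, net$edges$to,
                     ifelse(net$edges$sign == "+", "normal", "tee")),
             "}")
  paste(lines, collapse = "\n")
}
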