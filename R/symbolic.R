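#' Build a symbolic transition system (Kripke structure)
#'
#' Encodes a network's state space over binary decision diagram variables
#' and builds the transition relation(s) for the requested update
#' semantics.  Each n-level node uses \code{ceiling(log2(n))} bits;
#' current- and next-state bits are interleaved in node declaration order
#' (a standard ordering heuristic).  Synchronous systems have one
#' deterministic relation, kept in conjunctively partitioned form (one
#' update constraint per node).  Asynchronous systems have one relation
#' per update process (one process per non-input node); a scheduling
#' variable \code{sched} records the last-executed process, and the
#' fairness constraint family is \code{{sched = p}} for every process
#' ("process p just executed"), the state-set materialisation of
#' process-fairness.  The initial \code{sched} value is a distinguished
#' "uninitialized" tag belonging to no fairness constraint.
#'
#' The scenario only constrains the initial-state set; input nodes are
#' frozen along every path under both semantics.
#'
#' @param net a [network()].
#' @param scen a [scenario()] or \code{NULL}.
#' @param semantics \code{"sync"} or \code{"async"}.
#' @return An environment of class \code{qmc_ts}.
#' @export
transition_system <- function(net, scen = NULL, semantics = c("sync", "async")) {
  semantics <- match.arg(semantics)
  scen <- validate_scenario(net, scen)
  comp <- compile_network(net)
  nms <- node_names(net)
  levs <- node_levels(net)
  nbits <- pmax(1L, ceiling(log2(levs)))

  procs <- which(vapply(comp, function(ci) ci$kind != "input", TRUE))
  np <- length(procs)
  sched_bits <- if (semantics == "async") max(1L, ceiling(log2(np + 1L))) else 0L

  # interleaved layout: cur/next bit pairs per node, sched pairs at the end
  curv <- vector("list", length(nms))
  nxtv <- vector("list", length(nms))
  off <- 0L
  for (i in seq_along(nms)) {
    curv[[i]] <- off + 2L * seq_len(nbits[i]) - 2L
    nxtv[[i]] <- curv[[i]] + 1L
    off <- off + 2L * nbits[i]
  }
  sched_cur <- sched_nxt <- integer()
  if (sched_bits > 0L) {
    sched_cur <- off + 2L * seq_len(sched_bits) - 2L
    sched_nxt <- sched_cur + 1L
    off <- off + 2L * sched_bits
  }
  mgr <- .bdd_manager(off)

  ts <- new.env(parent = emptyenv())
  class(ts) <- "qmc_ts"
  ts$net <- net
  ts$comp <- comp
  ts$scen <- scen
  ts$semantics <- semantics
  ts$mgr <- mgr
  ts$nms <- nms
  ts$levels <- levs
  ts$nbits <- nbits
  ts$curv <- curv
  ts$nxtv <- nxtv
  ts$sched_cur <- sched_cur
  ts$sched_nxt <- sched_nxt
  ts$procs <- procs
  ts$cache <- new.env(parent = emptyenv())

  # permutation maps (monotone because cur/next bits are adjacent)
  perm <- seq_len(off) - 1L
  c2n <- perm; n2c <- perm
  for (i in seq_along(nms)) {
    c2n[curv[[i]] + 1L] <- nxtv[[i]]
    n2c[nxtv[[i]] + 1L] <- curv[[i]]
  }
  if (sched_bits > 0L) {
    c2n[sched_cur + 1L] <- sched_nxt
    n2c[sched_nxt + 1L] <- sched_cur
  }
  ts$perm_c2n <- c2n
  ts$perm_n2c <- n2c
  # per-node renamings (current bits of node i -> its next bits only)
  ts$perm_node <- lapply(seq_along(nms), function(i) {
    p <- seq_len(off) - 1L
    p[curv[[i]] + 1L] <- nxtv[[i]]
    p
  })

  enc <- function(vars, value) {
    f <- 1L
    for (b in seq_along(vars)) {
      v <- .bdd_ithvar(mgr, vars[b])
      bit <- bitwAnd(bitwShiftR(value, b - 1L), 1L)
      f <- .bdd_and(mgr, f, if (bit == 1L) v else .bdd_not(mgr, v))
    }
    f
  }
  ts$enc <- enc

  # care set: valid level codes on current vars (+ valid sched values)
  care <- 1L
  for (i in seq_along(nms)) {
    dom <- 0L
    for (v in 0:(levs[i] - 1L)) dom <- .bdd_or(mgr, dom, enc(curv[[i]], v))
    care <- .bdd_and(mgr, care, dom)
  }
  if (sched_bits > 0L) {
    dom <- 0L
    for (v in 0:np) dom <- .bdd_or(mgr, dom, enc(sched_cur, v))
    care <- .bdd_and(mgr, care, dom)
  }
  ts$care <- care

  # per-node update constraints U[i]: next(i) bits equal the transfer value,
  # as a function of the parents' current bits; frame constraints E[i]:
  # next(i) bits equal current(i) bits.
  frame1 <- function(i) {
    f <- 1L
    for (b in seq_along(curv[[i]])) {
      cv <- .bdd_ithvar(mgr, curv[[i]][b])
      nv <- .bdd_ithvar(mgr, nxtv[[i]][b])
      f <- .bdd_and(mgr, f, .bdd_not(mgr, .bdd_xor(mgr, cv, nv)))
    }
    f
  }
  update1 <- function(i) {
    ci <- comp[[i]]
    parents <- sort(unique(c(ci$act, ci$inh)))
    if (length(parents) == 0L) {
      v <- transfer_compiled(ci, rep(0L, length(nms)))
      return(enc(nxtv[[i]], v))
    }
    doms <- lapply(parents, function(p) 0:(levs[p] - 1L))
    grid <- do.call(expand.grid, doms)
    f <- 0L
    x <- rep(0L, length(nms))
    for (r in seq_len(nrow(grid))) {
      x[parents] <- as.integer(grid[r, ])
      cube <- 1L
      for (k in seq_along(parents)) {
        cube <- .bdd_and(mgr, cube, enc(curv[[parents[k]]], x[parents[k]]))
      }
      v <- transfer_compiled(ci, x)
      f <- .bdd_or(mgr, f, .bdd_and(mgr, cube, enc(nxtv[[i]], v)))
    }
    f
  }
  ts$E <- lapply(seq_along(nms), frame1)
  ts$U <- lapply(seq_along(nms), function(i) {
    if (comp[[i]]$kind == "input") ts$E[[i]] else update1(i)
  })

  # initial states
  sets <- initial_states(net, scen)
  s0 <- 1L
  for (i in seq_along(nms)) {
    dom <- 0L
    for (v in sets[[i]]) dom <- .bdd_or(mgr, dom, enc(curv[[i]], v))
    s0 <- .bdd_and(mgr, s0, dom)
  }
  if (sched_bits > 0L) s0 <- .bdd_and(mgr, s0, enc(sched_cur, 0L))
  ts$S0 <- s0

  # fairness constraints: sched = p (1-based process tag)
  if (semantics == "async") {
    ts$fairness <- lapply(seq_len(np), function(p) {
      .bdd_and(mgr, care, enc(sched_cur, p))
    })
    names(ts$fairness) <- nms[procs]
  } else {
    ts$fairness <- list()
  }
  ts
}

#' @export
print.qmc_ts <- function(x, ...) {
  cat(sprintf("qmc_ts: %s semantics, %d nodes, %d BDD variables, scenario '%s'\n",
              x$semantics, length(x$nms), .bdd_nvars(x$mgr), x$scen$name))
  invisible(x)
}

#' Symbolic state set for an atomic proposition
#'
#' Returns the exact set of states (as a BDD id) satisfying
#' \code{node cmp value}, restricted to valid level codes.
#'
#' @param ts a [transition_system()].
#' @param name node name.
#' @param cmp one of \code{"="}, \code{">="}, \code{"<="}.
#' @param value integer constant within the node's domain.
#' @return Integer BDD id.
#' @export
label_atom <- function(ts, name, cmp = "=", value = 1L) {
  i <- match(name, ts$nms)
  if (is.na(i)) stop("unknown node '", name, "'")
  if (value < 0L || value > ts$levels[i] - 1L) {
    stop("constant outside domain of node '", name, "'")
  }
  keep <- switch(cmp,
                 "=" = value,
                 ">=" = value:(ts$levels[i] - 1L),
                 "<=" = 0L:value,
                 stop("unknown comparator '", cmp, "'"))
  f <- 0L
  for (v in keep) f <- .bdd_or(ts$mgr, f, ts$enc(ts$curv[[i]], v))
  .bdd_and(ts$mgr, f, ts$care)
}

#' Symbolic preimage: states with at least one successor in a target set
#'
#' Computed as the relational product with the (partitioned) transition
#' relation and early quantification of next-state bits; for asynchronous
#' systems the result is the union over the per-process relations.
#'
#' @param ts a [transition_system()].
#' @param target BDD id of a state set over current variables.
#' @return BDD id of \eqn{\{s : \exists s' . R(s, s') \wedge s' \in target\}}.
#' @export
preimage <- function(ts, target) {
  mgr <- ts$mgr
  n <- length(ts$nms)
  if (ts$semantics == "sync") {
    g <- .bdd_permute(mgr, target, ts$perm_c2n)
    for (i in rev(seq_len(n))) {
      g <- .bdd_and_exists(mgr, g, ts$U[[i]], ts$nxtv[[i]])
    }
    return(.bdd_and(mgr, g, ts$care))
  }
  # per-process preimage: only node p's bits change (plus the sched tag),
  # so rename just those bits and conjoin that node's update relation --
  # no frame constraints needed
  out <- 0L
  for (p in seq_along(ts$procs)) {
    tp <- target
    # cofactor on the successor's sched tag (= p)
    for (b in seq_along(ts$sched_cur)) {
      bit <- bitwAnd(bitwShiftR(p, b - 1L), 1L)
      tp <- .bdd_restrict(mgr, tp, ts$sched_cur[b], bit)
    }
    if (tp == 0L) next
    i <- ts$procs[p]
    g <- .bdd_permute(mgr, tp, ts$perm_node[[i]])
    g <- .bdd_and_exists(mgr, g, ts$U[[i]], ts$nxtv[[i]])
    out <- .bdd_or(mgr, out, g)
  }
  .bdd_and(mgr, out, ts$care)
}

# preimage under a single asynchronous process
preimage_proc <- function(ts, target, p) {
  mgr <- ts$mgr
  tp <- target
  for (b in seq_along(ts$sched_cur)) {
    bit <- bitwAnd(bitwShiftR(p, b - 1L), 1L)
    tp <- .bdd_restrict(mgr, tp, ts$sched_cur[b], bit)
  }
  if (tp == 0L) return(0L)
  i <- ts$procs[p]
  g <- .bdd_permute(mgr, tp, ts$perm_node[[i]])
  .bdd_and(mgr, .bdd_and_exists(mgr, g, ts$U[[i]], ts$nxtv[[i]]), ts$care)
}

# forward image under a single asynchronous process
image_proc <- function(ts, from, p) {
  mgr <- ts$mgr
  g <- from
  for (b in ts$sched_cur) g <- .bdd_exists(mgr, g, b)
  i <- ts$procs[p]
  g <- .bdd_and_exists(mgr, g, ts$U[[i]], ts$curv[[i]])
  # surviving next bits are node i's; rename them back to current
  g <- .bdd_permute(mgr, g, ts$perm_n2c)
  .bdd_and(mgr, .bdd_and(mgr, g, ts$enc(ts$sched_cur, p)), ts$care)
}

# forward image of the synchronous relation, with early quantification of
# each current-state variable at the last update constraint that uses it
image_sync <- function(ts, from) {
  mgr <- ts$mgr
  n <- length(ts$nms)
  if (is.null(ts$cache$last_use)) {
    last <- integer(n)
    for (j in seq_len(n)) {
      kids <- which(vapply(ts$comp, function(ci) j %in% c(ci$act, ci$inh), TRUE))
      last[j] <- if (length(kids)) max(kids) else 0L
    }
    ts$cache$last_use <- last
  }
  last <- ts$cache$last_use
  g <- from
  free_now <- unlist(ts$curv[last == 0L])
  if (length(free_now)) g <- .bdd_exists(mgr, g, free_now)
  for (i in seq_len(n)) {
    vars <- unlist(ts$curv[last == i])
    g <- .bdd_and_exists(mgr, g, ts$U[[i]], if (length(vars)) vars else integer())
  }
  .bdd_and(mgr, .bdd_permute(mgr, g, ts$perm_n2c), ts$care)
}

#' Reachable states of a transition system
#'
#' Least fixpoint of forward images from the initial states; cached on the
#' system.  Used to restrict all model-checking fixpoints to the reachable
#' subspace, which leaves every verdict at the initial states unchanged
#' (successors of reachable states are reachable) while keeping
#' intermediate BDDs small.
#'
#' @param ts a [transition_system()].
#' @return BDD id of the reachable state set.
#' @export
reachable_states <- function(ts) {
  if (!is.null(ts$cache$reach)) return(ts$cache$reach)
  mgr <- ts$mgr
  y <- ts$S0
  front <- y
  repeat {
    grow <- if (ts$semantics == "sync") {
      image_sync(ts, front)
    } else {
      out <- 0L
      for (p in seq_along(ts$procs)) {
        out <- .bdd_or(mgr, out, image_proc(ts, front, p))
      }
      out
    }
    y2 <- .bdd_or(mgr, y, grow)
    if (y2 == y) break
    front <- .bdd_and(mgr, grow, .bdd_not(mgr, y))
    y <- y2
  }
  ts$cache$reach <- y
  y
}

# least fixpoint of E[f U target] (no fairness relativisation here); on
# asynchronous systems iterated chaotically, one process at a time, which
# converges much faster than synchronous sweeps of the full relation; on
# synchronous systems iterated frontier-wise (preimage of the newly added
# states only), the standard onion-ring optimisation
eu_set <- function(ts, f, target) {
  mgr <- ts$mgr
  y <- .bdd_and(mgr, target, ts$care)
  if (ts$semantics == "async") {
    repeat {
      y0 <- y
      for (p in seq_along(ts$procs)) {
        y <- .bdd_or(mgr, y, .bdd_and(mgr, f, preimage_proc(ts, y, p)))
      }
      if (y == y0) return(y)
    }
  }
  front <- y
  repeat {
    grow <- .bdd_and(mgr, f, preimage(ts, front))
    y2 <- .bdd_or(mgr, y, grow)
    if (y2 == y) return(y)
    front <- .bdd_and(mgr, grow, .bdd_not(mgr, y))
    y <- y2
  }
}

# greatest fixpoint of EG f (no fairness)
eg_set <- function(ts, f) {
  z <- .bdd_and(ts$mgr, f, ts$care)
  repeat {
    z2 <- .bdd_and(ts$mgr, z, preimage(ts, z))
    if (z2 == z) return(z)
    z <- z2
  }
}

# Emerson-Lei greatest fixpoint: states with a fair path along which f
# holds globally.  nu Z . f  &  AND_c EX E[f U (Z & F_c)]
fair_eg_set <- function(ts, f) {
  mgr <- ts$mgr
  z <- .bdd_and(mgr, f, ts$care)
  repeat {
    zold <- z
    for (fc in ts$fairness) {
      r <- eu_set(ts, f, .bdd_and(mgr, z, fc))
      z <- .bdd_and(mgr, z, preimage(ts, r))
    }
    if (z == zold) return(z)
  }
}

# states with at least one fair path (cached)
fair_states <- function(ts) {
  if (is.null(ts$cache$fair)) ts$cache$fair <- fair_eg_set(ts, ts$care)
  ts$cache$fair
}

sat_ctl <- function(ts, f, fair = FALSE) {
  mgr <- ts$mgr
  care <- ts$care
  fset <- if (fair) fair_states(ts) else care
  neg <- function(x) .bdd_and(mgr, care, .bdd_not(mgr, x))
  if (is.null(ts$cache$sat)) ts$cache$sat <- new.env(parent = emptyenv())
  memo <- ts$cache$sat
  ev <- function(f) {
    key <- paste0(if (fair) "F:" else "U:", deparse_ctl(f))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- ev_raw(f)
    memo[[key]] <- val
    val
  }
  # On synchronous (deterministic) systems each state has exactly one path,
  # so A- and E-quantified operators coincide; evaluating the existential
  # form lets AF/AU run as least fixpoints from the target upward and AG as
  # a greatest fixpoint from its operand downward, which keeps intermediate
  # BDDs far smaller than the complement-of-fixpoint dual.
  deterministic <- ts$semantics == "sync"
  ev_raw <- function(f) {
    if (deterministic) {
      f <- switch(f$type,
        AX = list(type = "EX", sub = f$sub),
        AF = list(type = "EF", sub = f$sub),
        AG = list(type = "EG", sub = f$sub),
        AU = list(type = "EU", lhs = f$lhs, rhs = f$rhs),
        f)
    }
    switch(f$type,
      const = if (f$value) care else 0L,
      atom = label_atom(ts, f$node, f$cmp, f$value),
      not = neg(ev(f$sub)),
      and = .bdd_and(mgr, ev(f$lhs), ev(f$rhs)),
      or = .bdd_or(mgr, ev(f$lhs), ev(f$rhs)),
      implies = .bdd_or(mgr, neg(ev(f$lhs)), ev(f$rhs)),
      EX = preimage(ts, .bdd_and(mgr, ev(f$sub), fset)),
      EF = eu_set(ts, care, .bdd_and(mgr, ev(f$sub), fset)),
      EU = eu_set(ts, ev(f$lhs), .bdd_and(mgr, ev(f$rhs), fset)),
      EG = if (fair) fair_eg_set(ts, ev(f$sub)) else eg_set(ts, ev(f$sub)),
      AX = neg(preimage(ts, .bdd_and(mgr, neg(ev(f$sub)), fset))),
      AF = neg(if (fair) fair_eg_set(ts, neg(ev(f$sub)))
               else eg_set(ts, neg(ev(f$sub)))),
      AG = neg(eu_set(ts, care, .bdd_and(mgr, neg(ev(f$sub)), fset))),
      AU = {
        nf <- neg(ev(f$lhs)); ng <- neg(ev(f$rhs))
        left <- eu_set(ts, ng, .bdd_and(mgr, .bdd_and(mgr, nf, ng), fset))
        right <- if (fair) fair_eg_set(ts, ng) else eg_set(ts, ng)
        neg(.bdd_or(mgr, left, right))
      },
      stop("unknown CTL node type: ", f$type)
    )
  }
  ev(f)
}

#' Decide a CTL formula over a transition system
#'
#' Satisfying sets are computed bottom-up by symbolic fixpoint iteration:
#' EX via [preimage()], EF/EU as least fixpoints, EG as a greatest
#' fixpoint, with the universal operators obtained by duality.  With
#' \code{fair = TRUE} (asynchronous systems only) all existential
#' operators are relativised to fair paths: the fair-state set is the
#' Emerson-Lei greatest fixpoint for "EG True" over the fairness
#' constraint family, EX/EF/EU conjoin it to their targets, and fair EG
#' runs the Emerson-Lei iteration itself.  The property holds iff every
#' initial state is in the satisfying set.
#'
#' @param ts a [transition_system()].
#' @param f a formula string or a parsed [parse_ctl()] object.
#' @param fair relativise to fair paths (asynchronous systems only).
#' @param id optional property identifier carried into the verdict.
#' @return Object of class \code{qmc_verdict}: fields \code{holds},
#'   \code{sat} (BDD id of the satisfying set), \code{formula},
#'   \code{semantics}, \code{fair}, \code{id}, and \code{ts}.
#' @export
check <- function(ts, f, fair = FALSE, id = NULL) {
  if (is.character(f)) f <- parse_ctl(f, ts$net)
  if (fair && length(ts$fairness) == 0L) {
    stop("fairness requested on a system with no fairness constraints")
  }
  missing_atoms <- setdiff(ctl_atoms(f), ts$nms)
  if (length(missing_atoms)) {
    stop("formula references node '", missing_atoms[[1]],
         "' not present in the system")
  }
  if (is.null(ts$cache$restricted) && ts$semantics == "sync") {
    # restrict the universe to reachable states once per system; verdicts
    # at initial states are unaffected.  Worthwhile for synchronous systems,
    # whose reachable set is a small, structured fraction of the state
    # space; asynchronous interleavings reach almost everything, so there
    # the restriction only costs.
    r <- reachable_states(ts)
    if (r != ts$care) {
      ts$care <- r
      ts$cache$fair <- NULL
      ts$cache$sat <- NULL
    }
    ts$cache$restricted <- TRUE
  }
  sat <- sat_ctl(ts, f, fair = fair)
  holds <- .bdd_and(ts$mgr, ts$S0, .bdd_not(ts$mgr, sat)) == 0L
  structure(list(holds = holds, sat = sat, formula = f,
                 semantics = ts$semantics, fair = fair, id = id, ts = ts),
            class = "qmc_verdict")
}

#' @export
print.qmc_verdict <- function(x, ...) {
  cat(sprintf("qmc_verdict%s [%s%s]: %s  --  %s\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              x$semantics, if (x$fair) "+fair" else "",
              if (x$holds) "TRUE (holds at all initial states)" else "FALSE",
              format(structure(x$formula, class = "qmc_ctl"))))
  invisible(x)
}

#' Number of states in a symbolic set
#'
#' @param ts a [transition_system()].
#' @param set BDD id (e.g. \code{ts$S0} or a verdict's \code{sat}).
#' @return A double count of states (level codes times sched tags where
#'   applicable).
#' @export
state_count <- function(ts, set) {
  # sat_count counts over all 2^nvars assignments; divide out next-state
  # bits, which the set does not constrain
  nnext <- sum(ts$nbits) + length(ts$sched_nxt)
  .bdd_sat_count(ts$mgr, set) / 2^nnext
}

# bit assignment (length nvars) for a concrete state; sched NULL for sync
state_to_assign <- function(ts, state, sched = NULL) {
  a <- integer(.bdd_nvars(ts$mgr))
  for (i in seq_along(ts$nms)) {
    v <- state[[ts$nms[i]]]
    for (b in seq_along(ts$curv[[i]])) {
      a[ts$curv[[i]][b] + 1L] <- bitwAnd(bitwShiftR(v, b - 1L), 1L)
    }
  }
  if (length(ts$sched_cur)) {
    s <- if (is.null(sched)) 0L else sched
    for (b in seq_along(ts$sched_cur)) {
      a[ts$sched_cur[b] + 1L] <- bitwAnd(bitwShiftR(s, b - 1L), 1L)
    }
  }
  a
}

# membership of a concrete state in a symbolic set
in_set <- function(ts, set, state, sched = NULL) {
  .bdd_eval(ts$mgr, set, state_to_assign(ts, state, sched))
}

# decode one concrete state from a nonempty symbolic set
pick_state <- function(ts, set) {
  if (set == 0L) stop("empty state set")
  a <- .bdd_sat_one(ts$mgr, set)
  lv <- integer(length(ts$nms))
  for (i in seq_along(ts$nms)) {
    bits <- a[ts$curv[[i]] + 1L]
    lv[i] <- sum(bits * 2L^(seq_along(bits) - 1L))
  }
  sched <- NULL
  if (length(ts$sched_cur)) {
    bits <- a[ts$sched_cur + 1L]
    sched <- sum(bits * 2L^(seq_along(bits) - 1L))
  }
  list(state = stats::setNames(lv, ts$nms), sched = sched)
}
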