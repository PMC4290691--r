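#' Witness and counterexample traces
#'
#' For a verdict produced by [check()], extracts a concrete trace:
#' a witness path for a held existential property, or a counterexample
#' for a failed universal property (obtained by negating the formula into
#' existential form).  Finite reachability witnesses are plain paths;
#' globally-shaped witnesses are lassos (a finite prefix plus a cycle),
#' and on fair systems the lasso's cycle executes every process at least
#' once, so the underlying infinite path is fair.  Successor choices are
#' tie-broken by minimal process index, so traces are deterministic.
#'
#' Not every formula shape admits a linear trace (e.g. a conjunction of
#' two temporal operators, or a passing AG); those return a no-trace
#' marker rather than an artificial path.
#'
#' @param verdict a [check()] verdict.
#' @param max_len safety bound on trace length.
#' @return A data frame of class \code{qmc_trace} (columns \code{step},
#'   \code{process} for asynchronous systems, and one column per node)
#'   with attribute \code{cycle_start} (row index where the lasso cycle
#'   begins, or \code{NA} for a finite path), or an object of class
#'   \code{qmc_no_trace}.
#' @export
witness <- function(verdict, max_len = 10000L) {
  ts <- verdict$ts
  fair <- verdict$fair
  mgr <- ts$mgr
  if (verdict$holds) {
    f <- unclass(verdict$formula)
    start_set <- .bdd_and(mgr, ts$S0, verdict$sat)
  } else {
    f <- push_neg(list(type = "not", sub = unclass(verdict$formula)))
    start_set <- .bdd_and(mgr, ts$S0, .bdd_not(mgr, verdict$sat))
  }
  s <- pick_state(ts, start_set)
  tr <- trace_exist(ts, f, s, fair, max_len)
  if (is.null(tr)) {
    return(structure(list(reason = sprintf(
      "no linear trace derivable for formula shape '%s'", f$type)),
      class = "qmc_no_trace"))
  }
  rows <- do.call(rbind, lapply(tr$rows, function(r) r$state))
  out <- data.frame(step = seq_len(nrow(rows)) - 1L)
  if (ts$semantics == "async") {
    out$process <- vapply(tr$rows, function(r) r$process %||% NA_character_, "")
  }
  out <- cbind(out, as.data.frame(rows))
  attr(out, "cycle_start") <- tr$cycle_start %||% NA_integer_
  class(out) <- c("qmc_trace", "data.frame")
  out
}

#' @export
print.qmc_no_trace <- function(x, ...) {
  cat("qmc_no_trace:", x$reason, "\n")
  invisible(x)
}

#' @export
print.qmc_trace <- function(x, ...) {
  cs <- attr(x, "cycle_start")
  cat(sprintf("qmc_trace: %d states%s\n", nrow(x),
              if (is.na(cs)) " (finite path)"
              else sprintf(" (lasso; cycle starts at row %d)", cs)))
  print.data.frame(x)
  invisible(x)
}

# push negations inward so universal failures become existential witnesses
push_neg <- function(f) {
  if (f$type != "not") {
    return(switch(f$type,
      and = list(type = "and", lhs = push_neg(f$lhs), rhs = push_neg(f$rhs)),
      or = list(type = "or", lhs = push_neg(f$lhs), rhs = push_neg(f$rhs)),
      implies = list(type = "or",
                     lhs = push_neg(list(type = "not", sub = f$lhs)),
                     rhs = push_neg(f$rhs)),
      EX = , AX = , EF = , AF = , EG = , AG =
        list(type = f$type, sub = push_neg(f$sub)),
      EU = , AU = list(type = f$type, lhs = push_neg(f$lhs),
                       rhs = push_neg(f$rhs)),
      f))
  }
  g <- f$sub
  switch(g$type,
    const = list(type = "const", value = !g$value),
    atom = f,
    not = push_neg(g$sub),
    and = list(type = "or",
               lhs = push_neg(list(type = "not", sub = g$lhs)),
               rhs = push_neg(list(type = "not", sub = g$rhs))),
    or = list(type = "and",
              lhs = push_neg(list(type = "not", sub = g$lhs)),
              rhs = push_neg(list(type = "not", sub = g$rhs))),
    implies = list(type = "and", lhs = push_neg(g$lhs),
                   rhs = push_neg(list(type = "not", sub = g$rhs))),
    EX = list(type = "AX", sub = push_neg(list(type = "not", sub = g$sub))),
    AX = list(type = "EX", sub = push_neg(list(type = "not", sub = g$sub))),
    EF = list(type = "AG", sub = push_neg(list(type = "not", sub = g$sub))),
    AF = list(type = "EG", sub = push_neg(list(type = "not", sub = g$sub))),
    EG = list(type = "AF", sub = push_neg(list(type = "not", sub = g$sub))),
    AG = list(type = "EF", sub = push_neg(list(type = "not", sub = g$sub))),
    AU = {
      nf <- push_neg(list(type = "not", sub = g$lhs))
      ng <- push_neg(list(type = "not", sub = g$rhs))
      list(type = "or",
           lhs = list(type = "EU", lhs = ng,
                      rhs = list(type = "and", lhs = nf, rhs = ng)),
           rhs = list(type = "EG", sub = ng))
    },
    EU = {
      nf <- push_neg(list(type = "not", sub = g$lhs))
      ng <- push_neg(list(type = "not", sub = g$rhs))
      list(type = "or",
           lhs = list(type = "AU", lhs = ng,
                      rhs = list(type = "and", lhs = nf, rhs = ng)),
           rhs = list(type = "AG", sub = ng))
    },
    stop("unknown formula type: ", g$type)
  )
}

is_prop <- function(f) {
  switch(f$type,
    const = , atom = TRUE,
    not = is_prop(f$sub),
    and = , or = , implies = is_prop(f$lhs) && is_prop(f$rhs),
    FALSE)
}

# enumerate successors of a concrete state: list of (state, sched, process)
succ_of <- function(ts, state) {
  if (ts$semantics == "sync") {
    return(list(list(state = sync_successor(ts$net, state), sched = NULL,
                     process = NA_character_)))
  }
  out <- vector("list", length(ts$procs))
  for (p in seq_along(ts$procs)) {
    i <- ts$procs[p]
    nxt <- state
    nxt[[i]] <- transfer_compiled(ts$comp[[i]], state)
    out[[p]] <- list(state = nxt, sched = p, process = ts$nms[i])
  }
  out
}

# walk from `s` to a state in `target`, staying in `inside`, guided by the
# onion rings of the EU fixpoint; returns rows s .. e (inclusive)
walk_to <- function(ts, s, inside, target, max_len) {
  mgr <- ts$mgr
  rings <- list(.bdd_and(mgr, target, ts$care))
  while (is.na(ring_index(ts, rings, s))) {
    nxt <- .bdd_or(mgr, rings[[length(rings)]],
                   .bdd_and(mgr, inside, preimage(ts, rings[[length(rings)]])))
    if (nxt == rings[[length(rings)]]) return(NULL)  # unreachable
    rings[[length(rings) + 1L]] <- nxt
  }
  k <- ring_index(ts, rings, s)
  rows <- list(s)
  while (k > 1L) {
    found <- FALSE
    for (cand in succ_of(ts, s$state)) {
      j <- ring_index(ts, rings, cand)
      if (!is.na(j) && j < k) {
        s <- cand; k <- j
        rows[[length(rows) + 1L]] <- s
        found <- TRUE
        break
      }
    }
    if (!found || length(rows) > max_len) return(NULL)
  }
  rows
}

# smallest ring containing the state, NA if none (rings are nested)
ring_index <- function(ts, rings, s) {
  for (j in seq_along(rings)) {
    if (in_set(ts, rings[[j]], s$state, s$sched)) return(j)
  }
  NA_integer_
}

state_key <- function(s) paste(paste(s$state, collapse = ","), s$sched %||% 0L)

trace_exist <- function(ts, f, s, fair, max_len) {
  mgr <- ts$mgr
  fset <- if (fair) fair_states(ts) else ts$care
  if (is_prop(f)) return(list(rows = list(s), cycle_start = NA_integer_))
  switch(f$type,
    and = {
      pl <- is_prop(f$lhs); pr <- is_prop(f$rhs)
      if (pl && !pr) return(trace_exist(ts, f$rhs, s, fair, max_len))
      if (pr && !pl) return(trace_exist(ts, f$lhs, s, fair, max_len))
      NULL
    },
    or = {
      satl <- sat_ctl(ts, f$lhs, fair)
      if (in_set(ts, satl, s$state, s$sched)) {
        trace_exist(ts, f$lhs, s, fair, max_len)
      } else {
        trace_exist(ts, f$rhs, s, fair, max_len)
      }
    },
    EX = {
      satg <- .bdd_and(mgr, sat_ctl(ts, f$sub, fair), fset)
      for (cand in succ_of(ts, s$state)) {
        if (in_set(ts, satg, cand$state, cand$sched)) {
          sub <- trace_exist(ts, f$sub, cand, fair, max_len)
          if (is.null(sub)) return(NULL)
          return(splice_prefix(list(s), sub))
        }
      }
      NULL
    },
    EF = trace_exist(ts, list(type = "EU", lhs = list(type = "const", value = TRUE),
                              rhs = f$sub), s, fair, max_len),
    EU = {
      inside <- sat_ctl(ts, f$lhs, fair)
      satg <- .bdd_and(mgr, sat_ctl(ts, f$rhs, fair), fset)
      rows <- walk_to(ts, s, inside, satg, max_len)
      if (is.null(rows)) return(NULL)
      e <- rows[[length(rows)]]
      if (is_prop(f$rhs)) return(list(rows = rows, cycle_start = NA_integer_))
      sub <- trace_exist(ts, f$rhs, e, fair, max_len)
      if (is.null(sub)) return(NULL)
      splice_prefix(rows[-length(rows)], sub)
    },
    EG = trace_eg(ts, f, s, fair, max_len),
    NULL
  )
}

splice_prefix <- function(prefix, sub) {
  cs <- sub$cycle_start
  list(rows = c(prefix, sub$rows),
       cycle_start = if (is.na(cs)) NA_integer_ else cs + length(prefix))
}

trace_eg <- function(ts, f, s, fair, max_len) {
  mgr <- ts$mgr
  satg <- sat_ctl(ts, f$sub, fair)
  z <- if (fair) fair_eg_set(ts, satg) else eg_set(ts, satg)
  if (!in_set(ts, z, s$state, s$sched)) return(NULL)
  if (ts$semantics == "sync") {
    rows <- list(s)
    seen <- stats::setNames(1L, state_key(s))
    repeat {
      s <- succ_of(ts, s$state)[[1]]
      k <- state_key(s)
      if (!is.na(seen[k])) {
        return(list(rows = rows, cycle_start = unname(seen[k])))
      }
      rows[[length(rows) + 1L]] <- s
      seen[k] <- length(rows)
      if (length(rows) > max_len) return(NULL)
    }
  }
  if (!fair) {
    # any infinite walk inside the EG set will do; cut at the first repeat
    rows <- list(s)
    seen <- stats::setNames(1L, state_key(s))
    repeat {
      stepped <- FALSE
      for (cand in succ_of(ts, s$state)) {
        if (in_set(ts, z, cand$state, cand$sched)) {
          s <- cand; stepped <- TRUE; break
        }
      }
      if (!stepped) return(NULL)
      k <- state_key(s)
      if (!is.na(seen[k])) {
        return(list(rows = rows, cycle_start = unname(seen[k])))
      }
      rows[[length(rows) + 1L]] <- s
      seen[k] <- length(rows)
      if (length(rows) > max_len) return(NULL)
    }
  }
  # fair lasso: tour every fairness constraint, then repeat tours until a
  # tour-boundary state recurs; the cycle then contains a full tour
  rows <- list(s)
  boundary <- stats::setNames(integer(), character())
  boundary[state_key(s)] <- 1L
  for (tour in seq_len(max_len)) {
    for (p in seq_along(ts$fairness)) {
      tgt <- .bdd_and(mgr, z, ts$fairness[[p]])
      seg <- walk_to(ts, rows[[length(rows)]], satg, tgt, max_len)
      if (is.null(seg)) return(NULL)
      rows <- c(rows, seg[-1])
    }
    k <- state_key(rows[[length(rows)]])
    if (length(boundary) && !is.na(boundary[k])) {
      return(list(rows = rows, cycle_start = unname(boundary[k])))
    }
    boundary[k] <- length(rows)
    if (length(rows) > max_len) return(NULL)
  }
  NULL
}
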