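# Bridges between symbolic sets and explicit graphs used by several tests.

in_set_states <- function(ts, set, state, sched = NULL) {
  qualmc:::in_set(ts, set, state, sched)
}

# membership vector of a symbolic set over an explicit graph's states
graph_membership <- function(ts, g, set) {
  assigns <- t(vapply(seq_len(nrow(g$states)), function(i) {
    qualmc:::state_to_assign(ts, g$states[i, ],
                             if (is.null(g$sched)) NULL else g$sched[i])
  }, integer(qualmc:::.bdd_nvars(ts$mgr))))
  as.logical(qualmc:::.bdd_eval_many(ts$mgr, set, assigns))
}

# build the symbolic set containing exactly the flagged graph states
states_to_bdd <- function(ts, g, flag) {
  mgr <- ts$mgr
  out <- 0L
  for (i in which(flag)) {
    cube <- 1L
    for (j in seq_along(ts$nms)) {
      cube <- qualmc:::.bdd_and(mgr, cube,
        ts$enc(ts$curv[[j]], g$states[i, ts$nms[j]]))
    }
    if (!is.null(g$sched)) {
      cube <- qualmc:::.bdd_and(mgr, cube, ts$enc(ts$sched_cur, g$sched[i]))
    }
    out <- qualmc:::.bdd_or(mgr, out, cube)
  }
  out
}
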