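test_that("label_atom returns the exact comparison set", {
  net <- network(list(node_spec("N", kind = "input")))
  ts <- transition_system(net, semantics = "sync")
  ge1 <- label_atom(ts, "N", ">=", 1L)
  expect_false(in_set_states(ts, ge1, c(N = 0L)))
  expect_true(in_set_states(ts, ge1, c(N = 1L)))
  expect_true(in_set_states(ts, ge1, c(N = 2L)))
  eq2 <- label_atom(ts, "N", "=", 2L)
  le0 <- label_atom(ts, "N", "<=", 0L)
  expect_true(in_set_states(ts, le0, c(N = 0L)))
  expect_false(in_set_states(ts, eq2, c(N = 1L)))
  expect_error(label_atom(ts, "N", "=", 7L), "domain")
  expect_error(label_atom(ts, "Q", "=", 1L), "unknown node")
})

test_that("conjunction of atoms equals intersection of their sets (fuzz)", {
  for (s in 1:10) {
    net <- random_network(s, 4)
    ts <- transition_system(net, semantics = "sync")
    g <- build_graph(net, semantics = "sync")
    levs <- node_levels(net)
    nm <- sample(names(levs), 2, replace = TRUE)
    a1 <- label_atom(ts, nm[1], ">=", 1L)
    a2 <- label_atom(ts, nm[2], "<=", 0L)
    both <- .bdd_and(ts$mgr, a1, a2)
    expl <- g$states[, nm[1]] >= 1 & g$states[, nm[2]] <= 0
    got <- vapply(seq_len(nrow(g$states)), function(i)
      in_set_states(ts, both, g$states[i, ]), TRUE)
    expect_equal(got, unname(expl))
  }
})

test_that("preimage matches brute-force predecessor enumeration", {
  set.seed(3)
  for (s in 1:12) {
    net <- random_network(s, 4)
    for (sem in c("sync", "async")) {
      ts <- transition_system(net, semantics = sem)
      g <- build_graph(net, semantics = sem)
      n <- nrow(g$states)
      target <- runif(n) < 0.3
      tset <- states_to_bdd(ts, g, target)
      pre <- preimage(ts, tset)
      # brute force: s in pre iff some successor of s is in target
      expl <- if (sem == "sync") target[g$succ]
              else rowSums(matrix(target[g$succ], nrow = n)) > 0
      got <- graph_membership(ts, g, pre)
      expect_equal(got, as.logical(expl))
    }
  }
  # preimage of everything is everything (R total); of nothing is nothing
  net <- chain_net()
  ts <- transition_system(net, semantics = "async")
  expect_equal(preimage(ts, ts$care), ts$care)
  expect_equal(preimage(ts, 0L), 0L)
})

test_that("AG True holds on any system; False fails; verdict reflects S0", {
  for (sem in c("sync", "async")) {
    ts <- transition_system(nfkb_toy(), semantics = sem)
    expect_true(check(ts, "AG True")$holds)
    expect_false(check(ts, "EF False")$holds)
  }
})

test_that("check errors: fairness without constraints, unbound atoms", {
  ts <- transition_system(chain_net(), semantics = "sync")
  expect_error(check(ts, "AG True", fair = TRUE), "no fairness")
  f <- parse_ctl("EF (NFkB = 1)", nfkb_toy())
  expect_error(check(ts, f), "not present")
})

test_that("duality, monotone weakening and sync collapse (fuzzed)", {
  for (s in 1:6) {
    net <- random_network(s, 4)
    for (sem in c("sync", "async")) {
      ts <- transition_system(net, semantics = sem)
      for (k in 1:4) {
        f <- random_ctl(1000 * s + k, net, depth = 2)
        txt <- format(f)
        for (fair in if (sem == "async") c(FALSE, TRUE) else FALSE) {
          agf <- check(ts, sprintf("AG (%s)", txt), fair = fair)
          nefn <- check(ts, sprintf("!(EF (!(%s)))", txt), fair = fair)
          expect_identical(agf$sat, nefn$sat)
          axf <- check(ts, sprintf("AX (%s)", txt), fair = fair)
          nexn <- check(ts, sprintf("!(EX (!(%s)))", txt), fair = fair)
          expect_identical(axf$sat, nexn$sat)
          aff <- check(ts, sprintf("AF (%s)", txt), fair = fair)
          negn <- check(ts, sprintf("!(EG (!(%s)))", txt), fair = fair)
          expect_identical(aff$sat, negn$sat)
          # AF f implies EF f (satisfying-set inclusion)
          eff <- check(ts, sprintf("EF (%s)", txt), fair = fair)
          expect_equal(.bdd_and(ts$mgr, aff$sat,
                                .bdd_not(ts$mgr, eff$sat)), 0L)
          if (sem == "sync") {
            # deterministic systems: one path per state, so AF = EF, AG = EG
            expect_identical(aff$sat, eff$sat)
            egf <- check(ts, sprintf("EG (%s)", txt), fair = fair)
            expect_identical(agf$sat, egf$sat)
          }
        }
      }
    }
  }
})

test_that("EF fixpoint is closed: one extra preimage iteration adds nothing", {
  for (s in 1:5) {
    net <- random_network(s, 4)
    ts <- transition_system(net, semantics = "async")
    f <- random_ctl(s + 99, net, depth = 1)
    v <- check(ts, sprintf("EF (%s)", format(f)))
    base <- check(ts, format(f))$sat
    extra <- .bdd_or(ts$mgr, .bdd_or(ts$mgr, v$sat, base),
                     preimage(ts, v$sat))
    expect_identical(extra, v$sat)
  }
})

test_that("a single trivially-true fairness constraint changes nothing", {
  for (s in 1:6) {
    net <- random_network(s, 4)
    # same manager for both runs so satisfying-set BDD ids are comparable
    ts <- transition_system(net, semantics = "async")
    plain <- lapply(1:4, function(k) {
      check(ts, format(random_ctl(7 * s + k, net, depth = 2)), fair = FALSE)
    })
    ts$fairness <- list(all = ts$care)     # one constraint: the whole space
    ts$cache <- new.env(parent = emptyenv())
    for (k in 1:4) {
      f <- format(random_ctl(7 * s + k, net, depth = 2))
      v <- check(ts, f, fair = TRUE)
      expect_identical(v$holds, plain[[k]]$holds)
      expect_identical(v$sat, plain[[k]]$sat)
    }
  }
})

test_that("state_count agrees with explicit enumeration", {
  net <- chain_net()
  ts <- transition_system(net, semantics = "sync")
  expect_equal(state_count(ts, ts$care), 3 * 3 * 2)
  expect_equal(state_count(ts, ts$S0), 3 * 2 * 1)
})
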