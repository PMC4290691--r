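test_that("transfer_level implements the clamped activator-minus-inhibitor rule", {
  n3 <- node_spec("X")
  # saturation at the top level when the drive reaches n-1
  expect_equal(transfer_level(n3, c(eIF2a = 2), c(eIF2a = "+")), 2L)
  # bottom clamp when inhibition cancels activation
  expect_equal(transfer_level(n3, c(ATF4 = 1, NFkB = 1),
                              c(ATF4 = "+", NFkB = "-")), 0L)
  # no parents, basal 0 -> 0
  expect_equal(transfer_level(n3), 0L)
  # joint_min: min over activators, then clamp
  nm <- node_spec("ATF6f", rule = "joint_min")
  expect_equal(transfer_level(nm, c(ATF6 = 2, S1_2P = 1),
                              c(ATF6 = "+", S1_2P = "+")), 1L)
  # basal adds to the drive
  nb <- node_spec("N", basal = 2)
  expect_equal(transfer_level(nb, c(I = 1), c(I = "-")), 1L)
  expect_equal(transfer_level(nb, c(I = 2), c(I = "-")), 0L)
})

test_that("transfer_level errors on unknown parents and invalid levels", {
  n3 <- node_spec("X")
  expect_error(transfer_level(n3, c(A = 1), c(B = "+")), "no edge sign")
  expect_error(transfer_level(n3, c(A = -1), c(A = "+")), "outside its domain")
})

test_that("transfer_level range, monotonicity and clamp limits hold on fuzzed inputs", {
  set.seed(42)
  for (rep in 1:200) {
    lev <- sample(2:4, 1)
    basal <- sample(0:(lev - 1), 1)
    node <- node_spec("X", levels = lev, basal = basal)
    k <- sample(0:4, 1)
    if (k > 0) {
      sgn <- sample(c("+", "-"), k, replace = TRUE)
      names(sgn) <- paste0("p", seq_len(k))
      lv <- sapply(seq_len(k), function(i) sample(0:2, 1))
      names(lv) <- names(sgn)
    } else {
      sgn <- character(); lv <- integer()
    }
    v <- transfer_level(node, lv, sgn)
    expect_true(v >= 0L && v <= lev - 1L)
    # determinism
    expect_identical(v, transfer_level(node, lv, sgn))
    # clamp limits
    s <- basal + sum(lv[sgn == "+"]) - sum(lv[sgn == "-"])
    if (s >= lev - 1L) expect_identical(v, lev - 1L)
    if (s <= 0L) expect_identical(v, 0L)
    # monotone in each activator, antitone in each inhibitor
    if (k > 0) {
      i <- sample(k, 1)
      lv2 <- lv
      lv2[i] <- min(lv[i] + 1L, 2L)
      v2 <- transfer_level(node, lv2, sgn)
      if (sgn[i] == "+") expect_gte(v2, v) else expect_lte(v2, v)
    }
  }
})

test_that("network construction validates invariants", {
  net <- chain_net()
  expect_length(validate_network(net), 0)
  expect_equal(node_names(net), c("A", "B", "fate"))
  # edge into an input node
  expect_error(
    network(list(node_spec("A", kind = "input"), node_spec("B")),
            data.frame(from = "B", to = "A", sign = "+")),
    "targets an input node")
  # duplicate edges
  expect_error(
    network(list(node_spec("A", kind = "input"), node_spec("B")),
            data.frame(from = c("A", "A"), to = c("B", "B"), sign = c("+", "-"))),
    "duplicate edge")
})

test_that("validate_network reports diagnostics without throwing", {
  bad <- chain_net()
  bad$nodes[[2]]$basal <- 5L
  expect_match(validate_network(bad), "basal", all = FALSE)
  bad2 <- chain_net()
  bad2$nodes[[2]]$name <- "A"
  expect_match(validate_network(bad2), "duplicate node name", all = FALSE)
  bad3 <- chain_net()
  bad3$nodes[[3]]$levels <- 3L
  expect_match(validate_network(bad3), "Boolean", all = FALSE)
})

test_that("network serialization round-trips", {
  for (net in list(chain_net(), nfkb_toy(),
                   network(list(node_spec("solo", kind = "input"))))) {
    txt <- serialize_network(net)
    back <- parse_network(txt)
    expect_equal(back, net)
  }
  # seeded random networks round-trip
  for (s in 1:25) {
    net <- random_network(s, n_nodes = sample(1:6, 1))
    expect_equal(parse_network(serialize_network(net)), net)
  }
})

test_that("parse_network reports schema violations with a field path", {
  expect_error(parse_network("{\"edges\": []}"), "\\$nodes")
  expect_error(parse_network('{"nodes": [{"kind": "input"}]}'), "name")
  expect_error(
    parse_network(paste0('{"nodes": [{"name": "A", "kind": "input"},',
                         '{"name": "B"}], "edges": [{"from": "A", "to": "B"}]}')),
    "sign")
  expect_error(parse_network("not json"), "JSON")
})

test_that("DOT export contains every node and edge", {
  dot <- network_dot(chain_net())
  expect_match(dot, '"A" -> "B"')
  expect_match(dot, "arrowhead=normal")
  dot2 <- network_dot(nfkb_toy())
  expect_match(dot2, "arrowhead=tee")
})
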