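test_that("the shipped ER-Golgi model matches its published shape", {
  net <- er_golgi_network()
  expect_length(net$nodes, 30L)
  expect_length(validate_network(net), 0L)
  kinds <- node_kinds(net)
  expect_setequal(names(kinds)[kinds == "input"],
                  c("ATF6", "PERK", "IRE1", "S1_2P"))
  expect_setequal(names(kinds)[kinds == "output"],
                  c("Cancer", "Apoptosis", "Alzheimer"))
  expect_equal(sum(kinds == "internal"), 23L)
  # fates are Boolean, signaling nodes three-valued
  levs <- node_levels(net)
  expect_true(all(levs[kinds == "output"] == 2L))
  expect_true(all(levs[kinds != "output"] == 3L))
  # ATF6f requires both ATF6 and the Golgi proteases (joint_min)
  atf6f <- net$nodes[[match("ATF6f", node_names(net))]]
  expect_equal(atf6f$rule, "joint_min")
  parents <- net$edges$from[net$edges$to == "ATF6f"]
  expect_setequal(parents, c("ATF6", "S1_2P"))
  # configuration count: 3^27 * 2^3
  expect_equal(prod(levs), 3^27 * 2^3)
})

test_that("anchored pathway arms are present", {
  net <- er_golgi_network()
  has_edge <- function(from, to, sign) {
    any(net$edges$from == from & net$edges$to == to & net$edges$sign == sign)
  }
  arms <- list(
    c("PERK", "eIF2a"), c("eIF2a", "ATF4"), c("ATF4", "CHOP"),
    c("CHOP", "GADD34"), c("GADD34", "P53"), c("P53", "Apoptosis"),
    c("ATF6f", "XBP1"), c("XBP1", "cMYC"), c("XBP1", "Bcl2"),
    c("IRE1", "TRAF2"), c("TRAF2", "ASK1"), c("ASK1", "JNK"),
    c("JNK", "BACE1"), c("BACE1", "Abeta"), c("Abeta", "Alzheimer"),
    c("TRAF2", "IKK"), c("NFkB", "CyclinD"), c("NFkB", "A20"),
    c("JNK", "BAX"), c("BAX", "Cytoc"), c("Cytoc", "Caspase9"),
    c("Caspase9", "Apoptosis"))
  for (e in arms) expect_true(has_edge(e[1], e[2], "+"),
                              label = paste(e[1], "->", e[2]))
  inh <- list(c("IKK", "IkB"), c("IkB", "NFkB"), c("A20", "IKK"))
  for (e in inh) expect_true(has_edge(e[1], e[2], "-"),
                             label = paste(e[1], "-|", e[2]))
})

test_that("initial conventions: inputs free, internals {0,1}, fates off", {
  net <- er_golgi_network()
  s0 <- initial_states(net)
  expect_equal(s0$PERK, 0:2)
  expect_equal(s0$NFkB, 0:1)
  expect_equal(s0$Apoptosis, 0L)
  ts <- transition_system(net, semantics = "async")
  # 26 update processes: one per non-input node
  expect_length(ts$fairness, 26L)
})

test_that("the property suite matches the published expectation table", {
  props <- property_suite()
  expect_equal(nrow(props), 32L)  # P1..P19 with primed variants, P3 at j=1,2
  tbl <- function(id) props[props$id == id, ]
  expect_true(tbl("P1")$expect_sync && tbl("P1")$expect_async)
  expect_false(tbl("P3j1")$expect_sync || tbl("P3j1")$expect_async)
  expect_true(tbl("P9")$expect_sync); expect_false(tbl("P9")$expect_async)
  expect_true(tbl("P9p")$expect_sync && tbl("P9p")$expect_async)
  for (id in c("P5", "P6", "P7", "P15", "P16", "P17", "P18", "P19")) {
    expect_true(tbl(id)$expect_sync, label = paste(id, "sync"))
    expect_false(tbl(id)$expect_async, label = paste(id, "async"))
  }
  for (id in c("P5p", "P6p", "P7p", "P15p", "P16p", "P17p", "P18p", "P19p")) {
    expect_true(tbl(id)$expect_sync && tbl(id)$expect_async, label = id)
  }
  # monotone pairs: an AF expectation implies its EF weakening
  pairs <- c(P5 = "P5p", P6 = "P6p", P7 = "P7p", P9 = "P9p", P11 = "P11p",
             P12 = "P12p", P13 = "P13p", P15 = "P15p", P16 = "P16p",
             P17 = "P17p", P18 = "P18p", P19 = "P19p")
  for (af in names(pairs)) {
    ef <- pairs[[af]]
    expect_true(!tbl(af)$expect_sync || tbl(ef)$expect_sync)
    expect_true(!tbl(af)$expect_async || tbl(ef)$expect_async)
  }
})

test_that("all formulas parse against the shipped network", {
  net <- er_golgi_network()
  props <- property_suite()
  for (i in seq_len(nrow(props))) {
    expect_s3_class(parse_ctl(props$formula[i], net), "qmc_ctl")
  }
})

test_that("the full model exceeds the explicit oracle's cap", {
  err <- tryCatch(build_graph(er_golgi_network(), semantics = "sync"),
                  qmc_size_error = function(e) e)
  expect_s3_class(err, "qmc_size_error")
})

test_that("reproduce() runs and reports on a property subset", {
  rep <- reproduce(semantics = "sync", ids = c("P1", "P17", "P8"), quiet = TRUE)
  expect_equal(nrow(rep), 3L)
  expect_true(all(rep$match))
  expect_named(rep, c("id", "semantics", "fair", "tier", "expected",
                      "observed", "match", "runtime_s"))
  # deterministic backend: a rerun gives the identical table
  rep2 <- reproduce(semantics = "sync", ids = c("P1", "P17", "P8"), quiet = TRUE)
  expect_identical(rep[names(rep) != "runtime_s"],
                   rep2[names(rep2) != "runtime_s"])
})

test_that("CLI scaffolding: report writing and option parsing", {
  opts <- qualmc:::parse_cli_opts(c("--model", "m.json", "--fair",
                                   "--semantics", "async"))
  expect_equal(opts$model, "m.json")
  expect_true(opts$fair)
  expect_equal(opts$semantics, "async")
  rep <- reproduce(semantics = "sync", ids = "P17", quiet = TRUE)
  path <- tempfile(fileext = ".tsv")
  write_report(rep, path)
  back <- read.delim(path)
  expect_equal(back$id, "P17")
})
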