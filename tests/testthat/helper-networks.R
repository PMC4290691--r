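# Small fixture networks built in code, shared across test files.

# linear chain: input -> internal -> output
chain_net <- function() {
  network(
    list(node_spec("A", kind = "input"), node_spec("B"),
         node_spec("fate", kind = "output")),
    data.frame(from = c("A", "B"), to = c("B", "fate"), sign = c("+", "+")))
}

# the 2-node negative-feedback toy: NFkB (basal 2) -| by IkB, IkB <- NFkB
nfkb_toy <- function() {
  network(
    list(node_spec("NFkB", basal = 2), node_spec("IkB")),
    data.frame(from = c("IkB", "NFkB"), to = c("NFkB", "IkB"),
               sign = c("-", "+")))
}

# an input-free pair used for deterministic-attractor tests
toggle_net <- function() {
  network(
    list(node_spec("X", kind = "input", levels = 2), node_spec("Y"),
         node_spec("Z")),
    data.frame(from = c("X", "Y"), to = c("Y", "Z"), sign = c("+", "-")))
}
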