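# Shared fixtures built in code.

# Tiny hand-built 2-gene mutual-activation network.
toy_network <- function() {
  grn_network(c("a", "b"), regulator = c("a", "b"),
              target = c("b", "a"), sign = c("+", "+"))
}

toy_params <- function() {
  grn_params(P = c(2, 3), S = c(0.5, 0.8), Q = c(1.5, 2.5), R = c(2, 1.5),
             network = toy_network())
}
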