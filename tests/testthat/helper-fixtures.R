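# Small hand-built ultrametric trees (<= 10 tips) used across the suite.

hand_newicks <- c(
  t3  = "((A:1,B:1):1,C:2);",
  t5  = "((A:1.5,(B:0.5,C:0.5):1.0):2.0,(D:2.0,E:2.0):1.5);",
  t6  = "(((A:0.4,B:0.4):1.6,(C:1.2,D:1.2):0.8):1.0,(E:2.2,F:2.2):0.8);",
  t8  = "(((((A:1,B:1):1,C:2):1,D:3):1,E:4):1,((F:2.5,G:2.5):1.5,H:4):1);"
)

hand_trees <- function() {
  trees <- lapply(hand_newicks, function(s) read_chronogram(text = s))
  trees$t10 <- generate_chronogram("yule", seed = 99L, n_tips = 10L, lam = 0.3)
  trees
}

# two-timescale 6-tip tree for GMYC oracle checks
gmyc_hand_tree <- function() {
  read_chronogram(text = paste0(
    "(((a1:0.1,a2:0.1):2.9,(b1:0.2,b2:0.2):2.8):1.0,",
    "(c1:0.15,c2:0.15):3.85);"))
}
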