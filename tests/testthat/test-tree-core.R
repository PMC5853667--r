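test_that("newick parsing reconstructs ages, crown and stem", {
  tr <- read_chronogram(text = "(A:1.0,B:1.0):0.5;")
  expect_equal(tr$n_tips, 2L)
  expect_equal(tr$crown_age, 1.0)
  expect_equal(tr$stem_age, 1.5)

  tr3 <- read_chronogram(text = "((A:1,B:1):1,C:2);")
  expect_equal(sort(as.numeric(branching_times(tr3))), c(1, 2))
})

test_that("NEXUS input with TRANSLATE block and bracketed annotations parses", {
  nex <- paste(
    "#NEXUS",
    "BEGIN TREES;",
    "  TRANSLATE",
    "    1 tipA,",
    "    2 tipB,",
    "    3 tipC;",
    "  TREE mcc = [&R] ((1:1.0[&height=1],2:1.0[&rate=0.3]):1.0[&posterior=0.99],3:2.0);",
    "END;", sep = "\n")
  tr <- read_chronogram(text = nex)
  expect_setequal(tr$phy$tip.label, c("tipA", "tipB", "tipC"))
  expect_equal(tr$crown_age, 2.0)
})

test_that("round-trip serialization preserves topology and ages to 1e-9", {
  for (s in 1:5) {
    tr <- generate_chronogram("birth_death", seed = s, n_tips = 15L)
    rt <- read_chronogram(text = write_chronogram(tr))
    expect_equal(sort(rt$phy$tip.label), sort(tr$phy$tip.label))
    expect_lt(max(abs(sort(rt$node_age) - sort(tr$node_age))), 1e-9)
    expect_equal(rt$stem_age, tr$stem_age, tolerance = 1e-9)
    expect_true(ape::all.equal.phylo(rt$phy, tr$phy, use.edge.length = FALSE))
  }
})

test_that("non-ultrametric and degenerate inputs are rejected with diagnostics", {
  expect_error(read_chronogram(text = "((A:1,B:2):1,C:3);"),
               "not ultrametric")
  expect_error(suppressWarnings(read_chronogram(text = "((A:1,B:2):1,C:3")), "parse")
  expect_error(branching_times(read_chronogram(text = "(A:1,B:1);")),
               "insufficient")
  expect_error(as_chronogram(ape::read.tree(text = "((A:1,B:1,C:1):1,D:2);")),
               "polytom")
  expect_warning(
    tr <- as_chronogram(ape::read.tree(text = "((A:1,B:1,C:1):1,D:2);"),
                        resolve_polytomies = TRUE),
    "zero-length")
  expect_equal(tr$n_tips, 4L)
})

test_that("branching_times returns descending crown-group ages", {
  for (s in 1:5) {
    n <- sample(5:30, 1)
    tr <- generate_chronogram("yule", seed = 100 + s, n_tips = n)
    bt <- branching_times(tr)
    expect_length(bt, n - 1L)
    expect_equal(as.numeric(bt)[1L], tr$crown_age)
    expect_false(is.unsorted(rev(as.numeric(bt))))
  }
})

test_that("pure-birth MLE from branching times recovers the generating rate", {
  lam <- 0.3
  set.seed(7)
  ests <- vapply(1:200, function(s) {
    bt <- branching_times(generate_chronogram("yule", seed = 5000 + s,
                                              n_tips = 100L, lam = lam))
    f <- fit_model(bt, "pureBirth")
    f$parameters$r1
  }, numeric(1))
  se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - lam), 2 * se + 0.01)
})

test_that("pruning keeps one representative per unit and preserves ages", {
  tr <- generate_chronogram("birth_death", seed = 21, n_tips = 39L)
  ## identity map: tree unchanged
  ident <- data.frame(tip_label = tr$phy$tip.label,
                      unit_id = tr$phy$tip.label)
  pid <- prune_to_units(tr, ident)
  expect_equal(pid$n_tips, 39L)
  expect_equal(sort(pid$node_age), sort(tr$node_age))

  ## study-shaped maps: 23 and 27 units from a 39-tip tree
  fx <- synthetic_study(seed = 42, n_posterior = 0)
  expect_equal(prune_to_units(fx$mcc, fx$maps$NS)$n_tips, 23L)
  expect_equal(prune_to_units(fx$mcc, fx$maps$NSP)$n_tips, 27L)
  expect_equal(prune_to_units(fx$mcc, fx$maps$GMYC)$n_tips, 39L)

  ## retained internal ages are a subset of the original ones
  pr <- prune_to_units(fx$mcc, fx$maps$NS)
  orig <- sort(fx$mcc$node_age[-seq_len(39)])
  kept <- sort(pr$node_age[-seq_len(23)])
  expect_true(all(vapply(kept, function(a)
    any(abs(orig - a) < 1e-9), logical(1))))
})

test_that("pruning errors name units with no member tips", {
  tr <- read_chronogram(text = "((A:1,B:1):1,C:2);")
  map <- data.frame(tip_label = c("A", "B", "C", "ghost"),
                    unit_id = c("u1", "u1", "u2", "u3"))
  expect_error(prune_to_units(tr, map), "u3")
  expect_error(prune_to_units(tr, map[1:2, ]), "missing from delimitation map")
})

test_that("pruning representative is the oldest-diverging member", {
  ## B attaches at age 2 (deeper) while A attaches at age 1
  tr <- read_chronogram(text = "(((A:1,C:1):1,B:2):1,D:3);")
  map <- data.frame(tip_label = c("A", "B", "C", "D"),
                    unit_id = c("u1", "u1", "u2", "u3"))
  pr <- prune_to_units(tr, map)
  expect_true("B" %in% pr$phy$tip.label)
  expect_false("A" %in% pr$phy$tip.label)
})

test_that("LTT curve is a monotone step function from (crown, 2) to (0, n)", {
  tr <- read_chronogram(text = "((A:1,B:1):1,C:2);")
  lt <- ltt_curve(tr)
  expect_equal(lt$age, c(2, 1, 0))
  expect_equal(lt$n_lineages, c(2, 3, 3))
  for (s in 1:5) {
    g <- generate_chronogram("yule", seed = 200 + s, n_tips = 20L)
    lt <- ltt_curve(g)
    expect_equal(lt$n_lineages[1L], 2)
    expect_equal(lt$n_lineages[nrow(lt)], 20)
    expect_false(is.unsorted(lt$n_lineages))
    expect_equal(lt$log_n, log(lt$n_lineages))
  }
})

test_that("mean log-LTT slope on Yule trees approximates the birth rate", {
  lam <- 0.3
  slopes <- vapply(1:200, function(s) {
    tr <- generate_chronogram("yule", seed = 3000 + s, n_tips = 50L,
                              lam = lam)
    lt <- ltt_curve(tr)
    ## linear regime: regress log N on elapsed time since the crown
    el <- lt$age[1L] - lt$age
    stats::coef(stats::lm(log_n ~ el, data = cbind(lt, el = el)))[["el"]]
  }, numeric(1))
  expect_lt(abs(mean(slopes) - lam), 0.05)
})
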