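test_that("GMYC likelihood matches the direct tree-walking oracle", {
  tr <- gmyc_hand_tree()
  for (T in c(0.5, 1.5, 2.5)) {
    for (pars in list(c(2, 1, 8, 1), c(0.5, 1.4, 3, 0.6))) {
      expect_equal(
        gmyc_loglik(tr, T, pars[1], pars[2], pars[3], pars[4]),
        oracle_gmyc(tr$phy, T, pars[1], pars[2], pars[3], pars[4]),
        tolerance = 1e-10)
    }
  }
  sc <- generate_chronogram("species_coalescent", seed = 3, n_species = 5L,
                            tips_per_species = 3L)
  expect_equal(gmyc_loglik(sc, 1.0, 1.2, 0.9, 6, 1.1),
               oracle_gmyc(sc$phy, 1.0, 1.2, 0.9, 6, 1.1),
               tolerance = 1e-10)
})

test_that("with all nodes older than T the coalescent class vanishes", {
  tr <- hand_trees()$t10          # pure Yule tree
  b <- as.numeric(branching_times(tr))
  T <- min(b) / 2                 # below every node age
  ll <- gmyc_loglik(tr, T, 0.9, 1.3, 5, 1)
  ## pure diversification-class evaluation: b_i = lam * n_i^p over intervals
  n_i <- 2:(length(b))
  x <- b[-length(b)] - b[-1L]
  expect_equal(ll, sum(log(0.9 * n_i^1.3) - 0.9 * n_i^1.3 * x),
               tolerance = 1e-10)
  ## and the alternative at the null's parameters equals the null exactly
  nf <- divtempo:::.gmyc_null_fit(divtempo:::.gmyc_data(tr))
  expect_equal(gmyc_loglik(tr, T, nf$lambda, nf$p, nf$lambda, nf$p),
               nf$logL, tolerance = 1e-8)
})

test_that("GMYC domain errors are raised", {
  tr <- gmyc_hand_tree()
  expect_error(gmyc_loglik(tr, 10, 1, 1, 1, 1), "crown")
  expect_error(gmyc_loglik(tr, 1, -1, 1, 1, 1), "positive")
  expect_error(fit_gmyc(read_chronogram(text = "((A:1,B:1):1,C:2);")),
               "at least 4")
})

test_that("fit_gmyc separates species from populations on two-level trees", {
  hits <- vapply(1:15, function(s) {
    tr <- generate_chronogram("species_coalescent", seed = 7000 + s)
    truth <- attr(tr, "truth")
    f <- fit_gmyc(tr)
    ## threshold between deepest within-species and shallowest
    ## between-species node
    tmrca <- vapply(truth$species_map, function(tips)
      tr$node_age[ape::getMRCA(tr$phy, tips)], numeric(1))
    c(f$n_entities == truth$n_species,
      f$threshold_T > max(tmrca) && f$threshold_T < truth$min_species_depth,
      f$p_value < 0.01)
  }, logical(3))
  expect_gte(mean(hits[1, ]), 0.9)
  expect_gte(mean(hits[2, ]), 0.9)
  expect_gte(mean(hits[3, ]), 0.9)
})

test_that("alternative never fits worse than the null and entities partition tips", {
  for (s in 1:6) {
    tr <- generate_chronogram("species_coalescent", seed = 500 + s,
                              n_species = 8L, tips_per_species = 3L)
    f <- fit_gmyc(tr)
    expect_gte(f$logL_alt, f$logL_null - 1e-6)
    expect_gte(f$LR, -1e-6)
    all_tips <- unlist(lapply(f$entities, `[[`, "tips"))
    expect_setequal(all_tips, tr$phy$tip.label)
    expect_equal(anyDuplicated(all_tips), 0L)
    for (e in f$entities)
      expect_equal(e$is_singleton, length(e$tips) == 1L)
  }
})

test_that("entity count is invariant under tip relabelling and ladderization", {
  tr <- generate_chronogram("species_coalescent", seed = 77, n_species = 10L,
                            tips_per_species = 3L)
  f0 <- fit_gmyc(tr)
  ## permute labels
  perm <- tr$phy
  set.seed(1)
  perm$tip.label <- sample(perm$tip.label)
  f1 <- fit_gmyc(as_chronogram(perm))
  ## ladderize
  f2 <- fit_gmyc(as_chronogram(ape::ladderize(tr$phy)))
  expect_equal(f1$n_entities, f0$n_entities)
  expect_equal(f2$n_entities, f0$n_entities)
  expect_equal(f1$threshold_T, f0$threshold_T, tolerance = 1e-9)
  expect_equal(f2$logL_alt, f0$logL_alt, tolerance = 1e-6)
})

test_that("entities_to_map yields a partition consumable by pruning", {
  tr <- generate_chronogram("species_coalescent", seed = 11)
  f <- fit_gmyc(tr)
  m <- entities_to_map(f)
  expect_setequal(m$tip_label, tr$phy$tip.label)
  expect_equal(anyDuplicated(m$tip_label), 0L)
  expect_equal(length(unique(m$unit_id)), f$n_entities)
  pr <- prune_to_units(tr, m)
  expect_equal(pr$n_tips, f$n_entities)

  ## all-singleton fit gives an identity-like map
  y <- generate_chronogram("yule", seed = 5, n_tips = 12L)
  fy <- fit_gmyc(y)
  my <- entities_to_map(fy)
  expect_equal(nrow(my), 12L)
})

test_that("GMYC JSON report writes the fit surface", {
  f <- fit_gmyc(gmyc_hand_tree())
  tf <- tempfile(fileext = ".json")
  write_gmyc_report(f, tf)
  rep <- jsonlite::read_json(tf)
  expect_equal(rep$n_entities, f$n_entities)
  expect_equal(length(rep$entities), f$n_entities)
})
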