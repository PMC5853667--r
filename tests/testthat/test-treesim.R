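test_that("conditioned simulation honours tip count and stem age exactly", {
  cfg <- sim_config(lam = 0.25, mu = 0, stem_age = 22.46, n_tips = 39L,
                    rho = 1, n_sims = 20, seed = 3)
  trees <- simulate_conditioned(cfg)
  expect_length(trees, 20L)
  for (tr in trees) {
    expect_equal(tr$n_tips, 39L)
    expect_equal(tr$stem_age, 22.46)
    expect_lt(tr$crown_age, 22.46)
    expect_true(ape::is.ultrametric(tr$phy, tol = 1e-8))
  }
})

test_that("incomplete sampling simulates ceiling(n/rho) lineages then drops to n", {
  cfg <- sim_config(lam = 0.3, mu = 0.1, stem_age = 15, n_tips = 20L,
                    rho = 0.7, n_sims = 10, seed = 9)
  trees <- simulate_conditioned(cfg)
  for (tr in trees) {
    expect_equal(tr$n_tips, 20L)
    expect_equal(tr$stem_age, 15)
  }
  ## tip labels come from the larger pre-sampling tree (29 lineages)
  labs <- unlist(lapply(trees, function(tr) tr$phy$tip.label))
  idx <- as.integer(sub("^t", "", labs))
  expect_lte(max(idx), ceiling(20 / 0.7))
  expect_gt(max(idx), 20)
})

test_that("identical config and seed reproduce byte-identical Newick", {
  cfg <- sim_config(lam = 0.25, mu = 0.05, stem_age = 22.46, n_tips = 15L,
                    rho = 0.9, n_sims = 5, seed = 11)
  s1 <- write_chronogram(simulate_conditioned(cfg))
  s2 <- write_chronogram(simulate_conditioned(cfg))
  expect_identical(s1, s2)
})

test_that("sim_config validates its domain", {
  expect_error(sim_config(lam = 0.1, mu = 0.2, stem_age = 10, n_tips = 10,
                          seed = 1), "lam > mu")
  expect_error(sim_config(lam = 0.3, mu = 0, stem_age = 10, n_tips = 10,
                          rho = 1.2, seed = 1), "rho")
  expect_error(sim_config(lam = 0.3, mu = 0, stem_age = 10, n_tips = 10,
                          rho = 1, n_sims = 0, seed = 1), "n_sims")
})

test_that("pure-birth rate is recovered on average from conditioned trees", {
  ## stem age chosen consistent with the rate and tip count
  ## (E[N] = exp(lam * T) ~ 39); conditioning on an incompatible pair
  ## would bias the conditional estimator by construction
  cfg <- sim_config(lam = 0.25, mu = 0, stem_age = log(39) / 0.25,
                    n_tips = 39L, rho = 1, n_sims = 300, seed = 17)
  trees <- simulate_conditioned(cfg)
  ests <- vapply(trees, function(tr) {
    b <- as.numeric(branching_times(tr))
    (length(b) - 1) / (b[1] + sum(b))
  }, numeric(1))
  se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.25), 2 * se + 0.005)
})

test_that("envelope of identical trees collapses to its center", {
  tr <- generate_chronogram("birth_death", seed = 5, n_tips = 15L)
  expect_warning(env <- ltt_envelope(rep(list(tr), 30), grid_size = 40),
                 "fewer than 100")
  expect_equal(env$lower, env$center)
  expect_equal(env$upper, env$center)
  expect_error(ltt_envelope(list()), "empty")
})

test_that("envelope bands are ordered and median is monotone toward the present", {
  cfg <- sim_config(lam = 0.25, mu = 0.05, stem_age = 20, n_tips = 30L,
                    rho = 1, n_sims = 150, seed = 23)
  env <- ltt_envelope(simulate_conditioned(cfg), grid_size = 60)
  expect_true(all(env$lower <= env$center + 1e-12))
  expect_true(all(env$center <= env$upper + 1e-12))
  ## age decreases along the grid; median log-count must not decrease
  expect_false(is.unsorted(env$center))
})

test_that("departure test flags curves outside the band and passes the median", {
  cfg <- sim_config(lam = 0.25, mu = 0, stem_age = 20, n_tips = 30L,
                    rho = 1, n_sims = 200, seed = 31)
  trees <- simulate_conditioned(cfg)
  env <- ltt_envelope(trees, grid_size = 50)
  ## a typical simulated tree should usually stay inside
  dep <- departure_test(ltt_curve(trees[[1L]]), env)
  expect_s3_class(dep$points, "data.frame")
  expect_true(all(dep$points$status %in%
                    c("inside", "outside-below", "outside-above")))
  ## push the band down so the curve must exit above at some point
  env_shifted <- env
  env_shifted$upper <- env$upper - 2
  env_shifted$lower <- env$lower - 4
  dep2 <- departure_test(ltt_curve(trees[[1L]]), env_shifted)
  expect_true(dep2$departs)
  expect_true(any(dep2$points$status == "outside-above"))
})

test_that("departure test rejects curves that do not span the grid", {
  cfg <- sim_config(lam = 0.25, mu = 0, stem_age = 20, n_tips = 20L,
                    rho = 1, n_sims = 120, seed = 41)
  env <- ltt_envelope(simulate_conditioned(cfg), grid_size = 30)
  short <- generate_chronogram("yule", seed = 2, n_tips = 10L, lam = 0.5)
  expect_error(departure_test(ltt_curve(short), env), "span")
})

test_that("envelope coverage at a fixed grid point is close to nominal", {
  cfg <- sim_config(lam = 0.25, mu = 0, stem_age = 18, n_tips = 25L,
                    rho = 1, n_sims = 400, seed = 51)
  env <- ltt_envelope(simulate_conditioned(cfg), grid_size = 40)
  cfg2 <- sim_config(lam = 0.25, mu = 0, stem_age = 18, n_tips = 25L,
                     rho = 1, n_sims = 200, seed = 52)
  fresh <- simulate_conditioned(cfg2)
  j <- 20L  # mid-grid age
  inside <- vapply(fresh, function(tr) {
    dep <- departure_test(ltt_curve(tr), env)
    dep$points$status[j] == "inside"
  }, logical(1))
  expect_gte(mean(inside), 0.85)
  expect_lte(mean(inside), 1.0)
})
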