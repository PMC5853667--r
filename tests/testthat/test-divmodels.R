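test_that("pure-birth and two-rate likelihoods match the waiting-time oracle", {
  for (tr in hand_trees()) {
    b <- as.numeric(branching_times(tr))
    for (r in c(0.15, 0.6)) {
      expect_equal(loglik_constant(b, r, 0), oracle_pure_birth(b, r),
                   tolerance = 1e-12)
    }
    st <- b[1L] * 0.4
    expect_equal(loglik_yule2rate(b, 0.5, 0.1, st),
                 oracle_yule2rate(b, 0.5, 0.1, st), tolerance = 1e-12)
  }
})

test_that("density-dependent likelihoods match the waiting-time oracle", {
  for (tr in hand_trees()) {
    b <- as.numeric(branching_times(tr))
    n <- length(b) + 1L
    expect_equal(loglik_density_dependent(b, 0.4, n + 4, "DDL"),
                 oracle_ddl(b, 0.4, n + 4), tolerance = 1e-10)
    expect_equal(loglik_density_dependent(b, 0.4, 0.7, "DDX"),
                 oracle_ddx(b, 0.4, 0.7), tolerance = 1e-10)
  }
  expect_equal(loglik_density_dependent(c(3, 2, 1), 0.4, 2.5, "DDL"), -Inf)
})

test_that("constant birth-death matches the textbook reconstructed-process formula", {
  for (tr in hand_trees()) {
    b <- as.numeric(branching_times(tr))
    for (a in c(0.2, 0.7)) {
      expect_equal(loglik_constant(b, 0.3, a), oracle_bd_nee(b, 0.3, a),
                   tolerance = 1e-10)
    }
  }
})

test_that("time-varying likelihoods match fine-grid integration", {
  tr <- hand_trees()$t8
  b <- as.numeric(branching_times(tr))
  crown <- b[1L]
  ## SPVAR: decaying speciation, constant extinction
  lam_age <- function(x) 0.5 * exp(-0.3 * (crown - x))
  mu_age <- function(x) rep_len(0.1, length(x))
  expect_equal(loglik_time_varying(b, 0.5, 0.3, 0.1, variant = "SPVAR"),
               oracle_tv_grid(b, lam_age, mu_age), tolerance = 1e-5)
  ## BOTHVAR
  mu2 <- function(x) 0.2 * (1 - exp(-0.4 * (crown - x)))
  expect_equal(loglik_time_varying(b, 0.5, 0.3, 0.2, 0.4, "BOTHVAR"),
               oracle_tv_grid(b, lam_age, mu2), tolerance = 1e-5)
})

test_that("nested model collapses hold", {
  b <- as.numeric(branching_times(hand_trees()$t10))
  pb <- loglik_constant(b, 0.31, 0)
  expect_equal(loglik_yule2rate(b, 0.31, 0.31, b[1L] / 2), pb)
  expect_equal(loglik_density_dependent(b, 0.31, 0, "DDX"), pb)
  expect_lt(abs(loglik_density_dependent(b, 0.31, 1e9, "DDL") - pb), 1e-6)
  bd <- loglik_constant(b, 0.3, 0.25)  # lam = 0.4, mu = 0.1
  expect_lt(abs(loglik_time_varying(b, 0.4, 0, 0.1, variant = "SPVAR") - bd),
            1e-6)
  expect_lt(abs(loglik_time_varying(b, 0.4, 0, 0.1, 0, "BOTHVAR") -
                  loglik_constant(b, 0.4, 0)), 1e-6)
})

test_that("shift time older than all events collapses to the young rate", {
  b <- c(5, 3, 2, 1)
  ll <- loglik_yule2rate(b, 0.9, 0.2, 4.999999)
  ## every event and almost all exposure sits below st
  expect_equal(ll, oracle_yule2rate(b, 0.9, 0.2, 4.999999), tolerance = 1e-10)
  expect_lt(abs(ll - loglik_constant(b, 0.2, 0)), 1e-3)
})

test_that("closed-form pure-birth MLE agrees with a grid search", {
  b <- as.numeric(branching_times(hand_trees()$t10))
  n <- length(b) + 1L
  S <- b[1L] + sum(b)
  r_hat <- (n - 2) / S
  grid <- seq(r_hat / 3, r_hat * 3, length.out = 20001)
  lg <- vapply(grid, function(r) loglik_constant(b, r, 0), numeric(1))
  expect_lt(abs(grid[which.max(lg)] - r_hat), 1e-4)
  expect_equal(fit_model(b, "pureBirth")$parameters$r1, r_hat,
               tolerance = 1e-6)
})

test_that("domain violations raise parameter errors", {
  b <- c(3, 2, 1)
  expect_error(loglik_constant(b, -0.1), "positive")
  expect_error(loglik_constant(b, 0.2, 1.0), "must lie")
  expect_error(loglik_yule2rate(b, 0.2, 0.3, 5), "crown")
  expect_error(loglik_density_dependent(b, 0.2, 1.5, "DDL"), "kappa")
  expect_error(loglik_time_varying(b, 0.2, -1, variant = "SPVAR"),
               "non-negative")
})

test_that("fitted logL is never below nested special cases", {
  for (s in 1:4) {
    tr <- generate_chronogram("birth_death", seed = 60 + s, n_tips = 25L)
    tab <- fit_all_models(branching_times(tr))
    get <- function(m) tab$logL[tab$model == m]
    expect_gte(get("birthDeath"), get("pureBirth") - 1e-6)
    expect_gte(get("yule2rate"), get("pureBirth") - 1e-6)
    expect_gte(get("DDX"), get("pureBirth") - 1e-6)
    expect_gte(get("DDL"), get("pureBirth") - 1e-4)
    expect_gte(get("SPVAR"), get("birthDeath") - 1e-5)
    ## EXVAR nests pure birth (z = 0 switches extinction off); BOTHVAR
    ## nests EXVAR exactly at k_decay = 0
    expect_gte(get("EXVAR"), get("pureBirth") - 1e-5)
    expect_gte(get("BOTHVAR"), get("EXVAR") - 1e-5)
    expect_gte(get("BOTHVAR"), get("SPVAR") - 0.05)
  }
})

test_that("AIC is consistent with logL and parameter counts", {
  tab <- fit_all_models(branching_times(hand_trees()$t10))
  expect_equal(tab$n_params,
               c(1L, 2L, 3L, 2L, 2L, 3L, 3L, 4L))
  expect_equal(tab$AIC, 2 * tab$n_params - 2 * tab$logL)
})

test_that("Akaike weights follow the closed-form normalisation", {
  w <- divtempo:::.akaike_weights(c(10, 12))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)))
  expect_equal(divtempo:::.akaike_weights(c(5, 5, 5)), rep(1 / 3, 3))
  ## invariant under adding a constant to all logL (i.e. to all AIC)
  aic <- c(3.2, 7.9, 4.4, 12.1)
  expect_equal(divtempo:::.akaike_weights(aic),
               divtempo:::.akaike_weights(aic + 17.3))
  expect_equal(sum(divtempo:::.akaike_weights(aic)), 1, tolerance = 1e-9)
})

test_that("compare_models is deterministic under a seed and reports coherent results", {
  tr <- generate_chronogram("yule2rate", seed = 77)
  bt <- branching_times(tr)
  c1 <- compare_models(bt, n_null = 50, seed = 5)
  c2 <- compare_models(bt, n_null = 50, seed = 5)
  expect_identical(c1$table, c2$table)
  expect_identical(c1$null_daic, c2$null_daic)
  expect_true(c1$best_rc %in% c("pureBirth", "birthDeath"))
  expect_false(c1$best_rv %in% c("pureBirth", "birthDeath"))
  expect_equal(c1$delta_aic_rc,
               c1$table$AIC[c1$table$model == c1$best_rc] -
                 c1$table$AIC[c1$table$model == c1$best_rv])
  expect_equal(sum(c1$table$weight), 1, tolerance = 1e-9)
  expect_true(c1$p_value >= 0 && c1$p_value <= 1)
})

test_that("reduced comparison optimizer budget agrees with the full fit budget", {
  set.seed(31)
  for (s in 1:5) {
    tr <- generate_chronogram("birth_death", seed = 400 + s, n_tips = 30L)
    b <- as.numeric(branching_times(tr))
    cheap <- divtempo:::cpp_daic_rc(b, 2L, 120L, 1L)
    full <- divtempo:::cpp_daic_rc(b, 5L, 500L, 1L)
    expect_lt(abs(cheap - full), 0.1)
  }
})

test_that("yule2rate recovers the r1 > r2 ordering on shift trees", {
  hits <- vapply(1:40, function(s) {
    tr <- generate_chronogram("yule2rate", seed = 900 + s)
    tab <- fit_all_models(branching_times(tr), n_starts = 2, maxit = 120)
    row <- tab[tab$model == "yule2rate", ]
    row$r1 > row$r2
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})
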