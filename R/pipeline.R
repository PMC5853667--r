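## Study-level driver: per delimitation strategy, prune, LTT, BDL model
## comparison, conditioned-simulation envelopes and departure tests.

#' Uniform random subsample of a posterior tree set
#'
#' @param trees list of trees.
#' @param k subsample size (without replacement).
#' @param seed integer seed.
#' @export
subsample_posterior <- function(trees, k, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (k > length(trees))
    stop("cannot sample ", k, " trees from ", length(trees))
  set.seed(seed)
  trees[sort(sample.int(length(trees), k))]
}

#' Study configuration
#'
#' @param fractions sampling fractions for the simulation envelopes.
#' @param n_sims simulated trees per sampling fraction.
#' @param n_null null simulations for the delta-AIC_RC test.
#' @param grid_size envelope grid points.
#' @param stem_age stem age (Ma) used for the conditioned simulations; if
#'   \code{NULL}, each strategy uses its pruned tree's stem age (the tree
#'   must then carry a root edge).
#' @param seed master integer seed; per-strategy and per-stage seeds are
#'   derived from it deterministically.
#' @param n_starts,maxit optimizer budget for [compare_models()].
#' @export
study_config <- function(fractions = c(1, 0.9, 0.8, 0.7, 0.5),
                         n_sims = 10000, n_null = 500, grid_size = 100,
                         stem_age = NULL, seed, n_starts = 2, maxit = 120) {
  if (missing(seed)) stop("'seed' is mandatory")
  stopifnot(all(fractions > 0), all(fractions <= 1))
  structure(list(fractions = fractions, n_sims = as.integer(n_sims),
                 n_null = as.integer(n_null),
                 grid_size = as.integer(grid_size), stem_age = stem_age,
                 seed = as.integer(seed), n_starts = as.integer(n_starts),
                 maxit = as.integer(maxit)),
            class = "study_config")
}

## stage seeds derive from the master seed and the map content (not the
## strategy's position or label), so identical maps yield identical results
.map_key <- function(map) {
  s <- paste(map$tip_label, map$unit_id, sep = "=", collapse = ";")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97L + 1L)) %% 9973L
}

.strategy_seed <- function(seed, key, stage) {
  (seed + 7919L * key + 104729L * stage) %% .Machine$integer.max
}

#' Run the full diversification study for several delimitation strategies
#'
#' For each delimitation map: prunes the dated consensus tree and every
#' posterior tree to one tip per unit, builds LTT curves, runs the BDL
#' model comparison on the pruned consensus tree, estimates birth-death
#' rates from it, simulates conditioned trees at each sampling fraction,
#' and tests the empirical LTT against the simulation envelopes.  A
#' failure in one strategy is recorded and does not abort the others.
#'
#' @param mcc the dated consensus \code{chronogram}.
#' @param posterior list of posterior \code{chronogram}s (may be empty).
#' @param maps named list of delimitation maps (names are the strategy
#'   labels, e.g. GMYC / NS / NSP).
#' @param config a [study_config()].
#' @return object of class \code{study_report}: per-strategy results plus
#'   the configuration.
#' @export
run_study <- function(mcc, posterior = list(), maps, config) {
  stopifnot(inherits(config, "study_config"))
  mcc <- as_chronogram(mcc)
  if (is.null(names(maps)) || any(names(maps) == ""))
    stop("'maps' must be a named list (strategy labels)")
  strategies <- names(maps)
  res <- vector("list", length(strategies))
  names(res) <- strategies
  for (i in seq_along(strategies)) {
    strat <- strategies[i]
    res[[i]] <- tryCatch({
      map <- maps[[i]]
      key <- .map_key(map)
      pruned <- prune_to_units(mcc, map)
      pruned_post <- lapply(posterior, prune_to_units, map = map)
      ltt_mcc <- ltt_curve(pruned)
      ltt_post <- lapply(pruned_post, ltt_curve)
      bt <- branching_times(pruned)
      cmp <- compare_models(bt, n_null = config$n_null,
                            seed = .strategy_seed(config$seed, key, 1L),
                            n_starts = config$n_starts, maxit = config$maxit)
      lam <- unname(cmp$null_rates["lam"])
      mu <- unname(cmp$null_rates["mu"])
      bd_row <- cmp$table[cmp$table$model == "birthDeath", ]
      lam_bd <- bd_row$r1 / (1 - bd_row$a)
      mu_bd <- lam_bd * bd_row$a
      stem <- if (!is.null(config$stem_age)) config$stem_age else pruned$stem_age
      if (is.na(stem))
        stop("no stem age available: give study_config(stem_age=) or use ",
             "a tree with a root edge")
      envs <- list()
      deps <- list()
      for (j in seq_along(config$fractions)) {
        rho <- config$fractions[j]
        cfg <- sim_config(lam = lam_bd, mu = mu_bd, stem_age = stem,
                          n_tips = pruned$n_tips, rho = rho,
                          n_sims = config$n_sims,
                          seed = .strategy_seed(config$seed, key, 10L + j))
        sims <- simulate_conditioned(cfg)
        env <- ltt_envelope(sims, grid_size = config$grid_size)
        envs[[sprintf("rho_%g", rho)]] <- env
        deps[[sprintf("rho_%g", rho)]] <- departure_test(ltt_mcc, env)
      }
      list(strategy = strat, n_units = pruned$n_tips, pruned_mcc = pruned,
           ltt_mcc = ltt_mcc, ltt_posterior = ltt_post, comparison = cmp,
           rates = c(lam = lam_bd, mu = mu_bd), stem_age = stem,
           envelopes = envs, departures = deps, error = NULL)
    }, error = function(e) {
      warning("strategy '", strat, "' failed: ", conditionMessage(e))
      list(strategy = strat, error = conditionMessage(e))
    })
  }
  structure(list(strategies = res, config = config), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("study report:\n")
  for (s in x$strategies) {
    if (!is.null(s$error)) {
      cat(sprintf("  %s: FAILED (%s)\n", s$strategy, s$error))
    } else {
      dep <- vapply(s$departures, `[[`, logical(1), "departs")
      cat(sprintf(
        "  %s: %d units; best RV %s, delta-AIC_RC %.4f (p = %.3g); departures: %s\n",
        s$strategy, s$n_units, s$comparison$best_rv,
        s$comparison$delta_aic_rc, s$comparison$p_value,
        paste(sprintf("%s=%s", names(dep), ifelse(dep, "yes", "no")),
              collapse = " ")))
    }
  }
  invisible(x)
}

#' Write the per-strategy report surfaces as TSV files
#'
#' Writes, per strategy: the pruned consensus tree (Newick), the BDL model
#' table, the LTT step curves (consensus and posterior, long format), the
#' simulation envelopes and the departure tables.  Output is plain text
#' and byte-reproducible for a fixed configuration.
#'
#' @param report a \code{study_report}.
#' @param dir output directory (created if needed).
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in report$strategies) {
    if (!is.null(s$error)) next
    pre <- file.path(dir, s$strategy)
    write_chronogram(s$pruned_mcc, paste0(pre, "_pruned.nwk"))
    write_model_table(s$comparison, paste0(pre, "_models.tsv"))
    ltt <- s$ltt_mcc
    ltt$tree <- "mcc"
    post <- do.call(rbind, lapply(seq_along(s$ltt_posterior), function(k) {
      d <- s$ltt_posterior[[k]]
      d$tree <- sprintf("post_%04d", k)
      d
    }))
    out <- rbind(ltt, post)
    out[, c("age", "log_n")] <- lapply(out[, c("age", "log_n")],
                                       function(v) sprintf("%.8f", v))
    utils::write.table(out[, c("tree", "age", "n_lineages", "log_n")],
                       paste0(pre, "_ltt.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (nm in names(s$envelopes)) {
      env <- s$envelopes[[nm]]
      env[] <- lapply(env, function(v) sprintf("%.8f", v))
      utils::write.table(env, paste0(pre, "_envelope_", nm, ".tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      dep <- s$departures[[nm]]$points
      dep[, c("age", "log_n", "lower", "upper")] <-
        lapply(dep[, c("age", "log_n", "lower", "upper")],
               function(v) sprintf("%.8f", v))
      utils::write.table(dep, paste0(pre, "_departure_", nm, ".tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  cfg <- report$config
  jsonlite::write_json(
    list(fractions = cfg$fractions, n_sims = cfg$n_sims,
         n_null = cfg$n_null, grid_size = cfg$grid_size,
         stem_age = cfg$stem_age, seed = cfg$seed,
         n_starts = cfg$n_starts, maxit = cfg$maxit),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Synthetic study-shaped fixture
#'
#' A complete synthetic input set at the scale of the motivating newt
#' radiation: a 39-tip dated tree with stem age 22.46 Ma, a set of
#' pseudo-posterior trees, and three nested delimitation maps with 39
#' ("GMYC"-like: every tip its own unit), 23 ("NS") and 27 ("NSP") units
#' obtained by cutting the tree at the ages where it has exactly that many
#' lineages.
#'
#' @param seed integer seed.
#' @param n_posterior number of pseudo-posterior trees.
#' @return list with elements \code{mcc}, \code{posterior}, \code{maps}.
#' @export
synthetic_study <- function(seed, n_posterior = 100) {
  mcc <- generate_chronogram("birth_death", seed = seed, n_tips = 39L,
                             lam = 0.25, mu = 0.05, stem_age = 22.46)
  posterior <- if (n_posterior > 0) {
    cfg <- sim_config(lam = 0.25, mu = 0.05, stem_age = 22.46, n_tips = 39L,
                      rho = 1, n_sims = n_posterior, seed = seed + 1L)
    simulate_conditioned(cfg)
  } else list()

  cut_map <- function(tree, k, strategy) {
    bt <- as.numeric(branching_times(tree))
    ## age at which the tree has exactly k lineages: between bt[k-1], bt[k]
    h <- (bt[k - 1L] + bt[k]) / 2
    gd <- .gmyc_data(tree)
    ents <- .gmyc_entities(gd, h)
    m <- do.call(rbind, lapply(seq_along(ents), function(i)
      data.frame(tip_label = ents[[i]]$tips,
                 unit_id = sprintf("%s_%02d", strategy, i),
                 stringsAsFactors = FALSE)))
    attr(m, "strategy") <- strategy
    m
  }
  gmyc_map <- data.frame(tip_label = mcc$phy$tip.label,
                         unit_id = sprintf("GMYC_%02d",
                                           seq_len(mcc$n_tips)),
                         stringsAsFactors = FALSE)
  attr(gmyc_map, "strategy") <- "GMYC"
  maps <- list(GMYC = gmyc_map,
               NS = cut_map(mcc, 23L, "NS"),
               NSP = cut_map(mcc, 27L, "NSP"))
  list(mcc = mcc, posterior = posterior, maps = maps)
}
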