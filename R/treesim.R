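## Conditioned birth-death tree simulation under incomplete sampling, LTT
## simulation envelopes, and the envelope departure test.

#' Configuration for conditioned birth-death simulation
#'
#' @param lam,mu speciation and extinction rates (events/lineage/Myr);
#'   \code{lam > mu >= 0}.
#' @param stem_age stem (origin) age in Ma: every simulated tree has
#'   exactly this origin.
#' @param n_tips number of sampled extant lineages per tree (after
#'   incomplete sampling).
#' @param rho sampling fraction in (0, 1]; \code{ceiling(n_tips/rho)}
#'   extant lineages are simulated and tips are dropped uniformly at random
#'   down to \code{n_tips}.
#' @param n_sims number of replicate trees.
#' @param seed integer seed (mandatory).
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(lam, mu = 0, stem_age, n_tips, rho = 1,
                       n_sims = 10000, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (!(lam > mu) || mu < 0)
    stop("conditioned simulation needs lam > mu >= 0")
  if (rho <= 0 || rho > 1) stop("'rho' must lie in (0, 1]")
  if (n_sims < 1) stop("'n_sims' must be at least 1")
  if (n_tips < 3) stop("'n_tips' must be at least 3")
  if (stem_age <= 0) stop("'stem_age' must be positive")
  structure(list(lam = lam, mu = mu, stem_age = stem_age,
                 n_tips = as.integer(n_tips), rho = rho,
                 n_sims = as.integer(n_sims), seed = as.integer(seed)),
            class = "sim_config")
}

## one conditioned reconstructed tree: ages iid with CDF Q(x)/Q(T)
## (exact; the reconstructed process conditioned on origin age and tip
## count), topology uniform over labelled histories
.sim_one_tree <- function(lam, mu, stem_age, m, n_keep) {
  ages <- sort(cpp_rcond_ages(m - 1L, stem_age, lam, mu), decreasing = TRUE)
  phy <- .assemble_tree(ages, sprintf("t%d", seq_len(m)), stem_age = stem_age)
  if (n_keep < m) {
    keep <- sort(sample.int(m, n_keep))
    phy <- ape::keep.tip(phy, sprintf("t%d", keep))
  }
  out <- as_chronogram(phy, tol = 1e-6)
  out$phy$root.edge <- stem_age - out$crown_age
  out$stem_age <- stem_age
  out
}

#' Simulate reconstructed birth-death trees conditioned on stem age and
#' tip count
#'
#' Each tree has exactly \code{cfg$stem_age} as its origin and exactly
#' \code{ceiling(n_tips/rho)} extant lineages before sampling, obtained by
#' exact inverse-CDF sampling of the conditioned reconstructed process
#' (branching ages are independent draws from the conditioned age
#' distribution; the topology is uniform over labelled histories).
#' Incomplete sampling then drops extant tips uniformly at random down to
#' \code{n_tips}.
#'
#' @param cfg a [sim_config()].
#' @return list of \code{chronogram}s, reproducible under \code{cfg$seed}.
#' @export
simulate_conditioned <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  m <- as.integer(ceiling(cfg$n_tips / cfg$rho))
  set.seed(cfg$seed)
  lapply(seq_len(cfg$n_sims), function(i)
    .sim_one_tree(cfg$lam, cfg$mu, cfg$stem_age, m, cfg$n_tips))
}

#' Pointwise LTT quantile envelope of a set of trees
#'
#' Quantiles of log lineage count on a uniform age grid from the common
#' stem age down to the present.
#'
#' @param trees list of \code{chronogram}s (>= 100 recommended; fewer draws
#'   a warning).
#' @param grid_size number of grid points.
#' @param probs lower/upper quantile probabilities (default the central 95%
#'   band).
#' @return data frame of class \code{ltt_envelope} with columns \code{age},
#'   \code{lower}, \code{center} (median), \code{upper} (all natural-log
#'   lineage counts).
#' @export
ltt_envelope <- function(trees, grid_size = 100, probs = c(0.025, 0.975)) {
  if (!length(trees)) stop("empty tree list")
  if (length(trees) < 100)
    warning("fewer than 100 trees; envelope quantiles will be noisy")
  stems <- vapply(trees, function(tr)
    if (is.na(tr$stem_age)) tr$crown_age else tr$stem_age, numeric(1))
  top <- max(stems)
  grid <- seq(top, 0, length.out = grid_size)
  counts <- vapply(trees, function(tr) {
    bt <- sort(tr$node_age[-seq_len(tr$n_tips)], decreasing = TRUE)
    log(.lineages_at(bt, tr$crown_age, grid))
  }, numeric(grid_size))
  qs <- apply(counts, 1L, stats::quantile, probs = c(probs[1L], 0.5, probs[2L]),
              names = FALSE)
  out <- data.frame(age = grid, lower = qs[1L, ], center = qs[2L, ],
                    upper = qs[3L, ])
  structure(out, probs = probs, n_trees = length(trees),
            class = c("ltt_envelope", "data.frame"))
}

#' Test an empirical LTT curve against a simulation envelope
#'
#' The empirical curve departs if its log lineage count exits the envelope
#' band at any grid point (a conservative any-point rule); per-point detail
#' is retained.
#'
#' @param empirical an [ltt_curve()].
#' @param env an [ltt_envelope()].
#' @return list of class \code{ltt_departure}: per-point data frame
#'   (\code{age}, \code{log_n}, \code{lower}, \code{upper}, \code{status})
#'   and the overall \code{departs} flag.
#' @export
departure_test <- function(empirical, env) {
  stopifnot(inherits(empirical, "ltt_curve"), inherits(env, "ltt_envelope"))
  crown <- attr(empirical, "crown_age")
  stem <- attr(empirical, "stem_age")
  reach <- if (is.na(stem)) crown else stem
  if (max(env$age) > reach + 1e-8)
    stop("empirical curve does not span the envelope grid (grid reaches ",
         sprintf("%.4g", max(env$age)), " Ma, curve spans ",
         sprintf("%.4g", reach), " Ma)")
  ## lineage count just younger than each grid age, from the step curve
  n_at <- vapply(env$age, function(g) {
    older <- which(empirical$age > g)
    if (!length(older)) {
      if (g >= crown) 1L else empirical$n_lineages[nrow(empirical)]
    } else empirical$n_lineages[max(older)]
  }, numeric(1))
  n_at[env$age > crown] <- 1L
  log_n <- log(n_at)
  status <- ifelse(log_n < env$lower, "outside-below",
                   ifelse(log_n > env$upper, "outside-above", "inside"))
  structure(list(points = data.frame(age = env$age, log_n = log_n,
                                     lower = env$lower, upper = env$upper,
                                     status = status),
                 departs = any(status != "inside")),
            class = "ltt_departure")
}

#' @export
print.ltt_departure <- function(x, ...) {
  tb <- table(x$points$status)
  cat(sprintf("LTT departure test: %s (%s)\n",
              if (x$departs) "DEPARTS from the envelope" else
                "inside the envelope",
              paste(sprintf("%s: %d", names(tb), tb), collapse = ", ")))
  invisible(x)
}
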