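## Maximum-likelihood fitting of the eight diversification models on
## branching times, AIC comparison, the delta-AIC rate-constant versus
## rate-variable statistic with simulated one-tailed significance, and
## Akaike weights.
##
## Likelihood convention (package-wide, shared with the simulator and the
## brute-force oracles in the test suite): every model is conditioned on
## the crown age; models with extinction are additionally conditioned on
## survival of both crown lineages (the reconstructed-process form).  For
## the pure-birth class this is the product of inter-event waiting-time
## densities with total rate R_k while k lineages are extant, times the
## terminal no-event survival factor over the youngest interval.

.DIV_MODELS <- c("pureBirth", "birthDeath", "yule2rate", "DDL", "DDX",
                 "SPVAR", "EXVAR", "BOTHVAR")
.RC_MODELS <- c("pureBirth", "birthDeath")
.N_PARAMS <- c(pureBirth = 1L, birthDeath = 2L, yule2rate = 3L, DDL = 2L,
               DDX = 2L, SPVAR = 3L, EXVAR = 3L, BOTHVAR = 4L)

#' Constant-rate log-likelihoods (pure birth and birth-death)
#'
#' With \code{a = 0} the Yule waiting-time likelihood; with \code{a > 0}
#' the constant-rate birth-death likelihood of the reconstructed process
#' conditioned on crown age and survival.
#'
#' @param bt branching times (a \code{branching_times} vector, a
#'   \code{chronogram}, or a raw descending age vector).
#' @param r net diversification rate (events/lineage/Myr), positive.
#' @param a extinction fraction mu/lambda, in [0, 1).
#' @return log-likelihood.
#' @export
loglik_constant <- function(bt, r, a = 0) {
  bt <- .as_bt(bt)
  if (r <= 0) stop("'r' must be positive")
  if (a < 0 || a >= 1) stop("'a' must lie in [0, 1)")
  cpp_loglik_constant(as.numeric(bt), r, a)
}

#' Two-rate pure-birth (yule2rate) log-likelihood
#'
#' Rate \code{r1} applies to ages older than the shift time \code{st},
#' \code{r2} to younger ages; the interval containing \code{st} is split
#' pro rata.
#'
#' @inheritParams loglik_constant
#' @param r1,r2 pre- and post-shift net rates, positive.
#' @param st shift age (Ma), strictly inside (0, crown age).
#' @export
loglik_yule2rate <- function(bt, r1, r2, st) {
  bt <- .as_bt(bt)
  if (r1 <= 0 || r2 <= 0) stop("rates must be positive")
  if (st <= 0 || st >= bt[1L])
    stop("'st' must lie strictly inside (0, crown age)")
  cpp_loglik_yule2rate(as.numeric(bt), r1, r2, st)
}

#' Density-dependent log-likelihoods (DDL and DDX)
#'
#' Per-lineage speciation rate while k lineages are extant:
#' \code{r1 * (1 - k/kappa)} for DDL (logistic) and \code{r1 * k^(-x)} for
#' DDX (exponential).  DDL rates that become non-positive for any observed
#' lineage count yield \code{-Inf}.
#'
#' @inheritParams loglik_constant
#' @param r1 initial per-lineage speciation rate, positive.
#' @param shape \code{kappa} (> 2) for DDL, \code{x} (>= 0) for DDX.
#' @param variant \code{"DDL"} or \code{"DDX"}.
#' @export
loglik_density_dependent <- function(bt, r1, shape, variant = c("DDL", "DDX")) {
  bt <- .as_bt(bt)
  variant <- match.arg(variant)
  if (r1 <= 0) stop("'r1' must be positive")
  if (variant == "DDL") {
    if (shape <= 2) stop("'kappa' must exceed 2")
    cpp_loglik_ddl(as.numeric(bt), r1, shape)
  } else {
    if (shape < 0) stop("'x' must be non-negative")
    cpp_loglik_ddx(as.numeric(bt), r1, shape)
  }
}

#' Time-varying-rate log-likelihoods (SPVAR, EXVAR, BOTHVAR)
#'
#' Speciation \code{lambda(t) = lam0 * exp(-k_decay * t)} and/or extinction
#' \code{mu(t) = mu_final * (1 - exp(-z * t))}, with t the time since the
#' crown; SPVAR holds extinction constant at \code{mu_final}, EXVAR holds
#' speciation constant at \code{lam0}.  The rate integrals of the
#' reconstructed-process likelihood are evaluated by composite
#' Gauss-Legendre quadrature with adaptive refinement to \code{tol}.
#'
#' @inheritParams loglik_constant
#' @param lam0 initial (crown) speciation rate, positive.
#' @param k_decay exponential decay constant of speciation, >= 0.
#' @param mu_final asymptotic (present-day) extinction rate, >= 0.
#' @param z exponential-change constant of extinction, >= 0.
#' @param variant \code{"SPVAR"}, \code{"EXVAR"} or \code{"BOTHVAR"}.
#' @param tol relative quadrature tolerance (default 1e-8).
#' @export
loglik_time_varying <- function(bt, lam0, k_decay = 0, mu_final = 0, z = 0,
                                variant = c("SPVAR", "EXVAR", "BOTHVAR"),
                                tol = 1e-8) {
  bt <- .as_bt(bt)
  variant <- match.arg(variant)
  if (lam0 <= 0) stop("'lam0' must be positive")
  if (k_decay < 0 || mu_final < 0 || z < 0)
    stop("'k_decay', 'mu_final' and 'z' must be non-negative")
  vid <- match(variant, c("SPVAR", "EXVAR", "BOTHVAR"))
  b <- as.numeric(bt)
  nsub <- 1L
  val <- cpp_loglik_tv(b, lam0, k_decay, mu_final, z, vid, nsub)
  repeat {
    nsub <- nsub * 2L
    ref <- cpp_loglik_tv(b, lam0, k_decay, mu_final, z, vid, nsub)
    if (!is.finite(val) || !is.finite(ref)) return(ref)
    if (abs(ref - val) <= tol * max(1, abs(ref)) || nsub >= 64L) return(ref)
    val <- ref
  }
}

.fit_matrix_to_table <- function(fm, n_tips) {
  tab <- data.frame(model = .DIV_MODELS, r1 = NA_real_, r2 = NA_real_,
                    a = NA_real_, st = NA_real_, kappa = NA_real_,
                    x = NA_real_, lam0 = NA_real_, k_decay = NA_real_,
                    mu_final = NA_real_, z = NA_real_,
                    logL = fm[, 1L], n_params = as.integer(fm[, 3L]),
                    AIC = fm[, 2L], stringsAsFactors = FALSE)
  tab$r1[1L] <- fm[1L, 4L]
  tab$r1[2L] <- fm[2L, 4L]; tab$a[2L] <- fm[2L, 5L]
  tab$r1[3L] <- fm[3L, 4L]; tab$r2[3L] <- fm[3L, 5L]; tab$st[3L] <- fm[3L, 6L]
  tab$r1[4L] <- fm[4L, 4L]; tab$kappa[4L] <- fm[4L, 5L]
  tab$r1[5L] <- fm[5L, 4L]; tab$x[5L] <- fm[5L, 5L]
  tab$lam0[6L] <- fm[6L, 4L]; tab$k_decay[6L] <- fm[6L, 5L]
  tab$mu_final[6L] <- fm[6L, 6L]
  tab$lam0[7L] <- fm[7L, 4L]; tab$mu_final[7L] <- fm[7L, 5L]
  tab$z[7L] <- fm[7L, 6L]
  tab$lam0[8L] <- fm[8L, 4L]; tab$k_decay[8L] <- fm[8L, 5L]
  tab$mu_final[8L] <- fm[8L, 6L]; tab$z[8L] <- fm[8L, 7L]
  tab
}

#' Fit all eight diversification models by maximum likelihood
#'
#' @inheritParams loglik_constant
#' @param n_starts optimizer starts for the numerically fitted models
#'   (deterministic nested warm starts first, then random restarts).
#' @param maxit Nelder-Mead iteration cap per start.
#' @return a data frame (one row per model) with the fitted parameters in
#'   the field's standard vocabulary (r1, r2, a, st, kappa, x, lam0,
#'   k_decay, mu_final, z), logL, n_params and AIC.
#' @export
fit_all_models <- function(bt, n_starts = 5, maxit = 500) {
  bt <- .as_bt(bt)
  if (length(bt) < 4L)
    stop("model fitting needs at least 5 tips (4 branching events)")
  fm <- cpp_fit_all(as.numeric(bt), as.integer(n_starts), as.integer(maxit), 1L)
  .fit_matrix_to_table(fm, attr(bt, "n_tips"))
}

#' Fit a single diversification model
#'
#' @inheritParams fit_all_models
#' @param model one of \code{"pureBirth"}, \code{"birthDeath"},
#'   \code{"yule2rate"}, \code{"DDL"}, \code{"DDX"}, \code{"SPVAR"},
#'   \code{"EXVAR"}, \code{"BOTHVAR"}.
#' @return an object of class \code{rate_model_fit}: model name, named
#'   parameter list, logL, n_params and AIC.
#' @export
fit_model <- function(bt, model, n_starts = 5, maxit = 500) {
  model <- match.arg(model, .DIV_MODELS)
  tab <- fit_all_models(bt, n_starts = n_starts, maxit = maxit)
  row <- tab[tab$model == model, ]
  pars <- as.list(row[, c("r1", "r2", "a", "st", "kappa", "x", "lam0",
                          "k_decay", "mu_final", "z")])
  pars <- pars[!vapply(pars, is.na, logical(1))]
  structure(list(model = model, parameters = pars, logL = row$logL,
                 n_params = row$n_params, AIC = row$AIC),
            class = "rate_model_fit")
}

#' @export
print.rate_model_fit <- function(x, ...) {
  cat(sprintf("%s fit: logL = %.4f, AIC = %.4f (%d parameters)\n",
              x$model, x$logL, x$AIC, x$n_params))
  cat("  ", paste(sprintf("%s = %.5g", names(x$parameters),
                          unlist(x$parameters)), collapse = ", "), "\n")
  invisible(x)
}

.akaike_weights <- function(aic) {
  d <- aic - min(aic, na.rm = TRUE)
  w <- exp(-d / 2)
  w / sum(w, na.rm = TRUE)
}

#' Compare rate-constant and rate-variable diversification models
#'
#' Fits the eight models, computes delta-AIC_RC = AIC(best rate-constant) -
#' AIC(best rate-variable) (positive favours rate variation), assesses its
#' one-tailed significance against trees simulated under the best
#' rate-constant model's MLE with the same tip count and crown age, and
#' reports Akaike weights.  Ties in "best model" resolve toward fewer
#' parameters.  The observed statistic and every null replicate share one
#' fixed optimizer budget (\code{n_starts}, \code{maxit}), so the
#' Monte-Carlo test is internally consistent.
#'
#' @inheritParams loglik_constant
#' @param n_null number of null-model simulations for the one-tailed test.
#' @param seed integer seed driving the null simulations (mandatory).
#' @param n_starts,maxit optimizer budget shared by the observed fits and
#'   the null-replicate fits.
#' @return an object of class \code{model_comparison}: the model table with
#'   deltaAIC and Akaike weights, the best RC/RV models, delta_aic_rc, the
#'   simulated p-value and the null sample.
#' @export
compare_models <- function(bt, n_null = 500, seed, n_starts = 2, maxit = 120) {
  bt <- .as_bt(bt)
  if (missing(seed)) stop("'seed' is mandatory")
  set.seed(seed)
  b <- as.numeric(bt)
  fm <- cpp_fit_all(b, as.integer(n_starts), as.integer(maxit), 1L)
  tab <- .fit_matrix_to_table(fm, attr(bt, "n_tips"))
  ok <- is.finite(tab$AIC)
  if (!all(ok))
    warning("models excluded from comparison (fit failed): ",
            paste(tab$model[!ok], collapse = ", "))

  pick_best <- function(models) {
    cand <- tab[ok & tab$model %in% models, ]
    cand <- cand[order(cand$AIC, cand$n_params), ]
    cand$model[1L]
  }
  best_rc <- pick_best(.RC_MODELS)
  best_rv <- pick_best(setdiff(.DIV_MODELS, .RC_MODELS))
  delta <- tab$AIC[tab$model == best_rc] - tab$AIC[tab$model == best_rv]

  ## null simulation under the best rate-constant MLE
  rc <- tab[tab$model == best_rc, ]
  if (best_rc == "pureBirth") {
    lam <- rc$r1; mu <- 0
  } else {
    lam <- rc$r1 / (1 - rc$a); mu <- lam * rc$a
  }
  null_daic <- cpp_daic_null(as.integer(n_null), attr(bt, "n_tips"), b[1L],
                             lam, mu, as.integer(n_starts),
                             as.integer(maxit), 1L)
  p <- mean(null_daic >= delta)

  tab$deltaAIC <- tab$AIC - min(tab$AIC[ok])
  tab$weight <- NA_real_
  tab$weight[ok] <- .akaike_weights(tab$AIC[ok])
  structure(list(table = tab, best_rc = best_rc, best_rv = best_rv,
                 delta_aic_rc = delta, p_value = p, n_null = n_null,
                 null_daic = null_daic, seed = seed,
                 null_rates = c(lam = lam, mu = mu),
                 n_tips = attr(bt, "n_tips"), crown_age = b[1L]),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("BDL model comparison (n = %d tips, crown %.4g Ma)\n",
              x$n_tips, x$crown_age))
  tab <- x$table
  tab[, c("logL", "AIC", "deltaAIC", "weight")] <-
    round(tab[, c("logL", "AIC", "deltaAIC", "weight")], 4)
  print(tab[, c("model", "n_params", "logL", "AIC", "deltaAIC", "weight")],
        row.names = FALSE)
  cat(sprintf("best RC: %s, best RV: %s; delta-AIC_RC = %.5f, one-tailed p = %.4g (%d null sims)\n",
              x$best_rc, x$best_rv, x$delta_aic_rc, x$p_value, x$n_null))
  invisible(x)
}

#' Write a model-comparison table as TSV
#'
#' Columns mirror the standard BDL report vocabulary: model, r1, r2, a, st,
#' kappa, x, lam0, k_decay, mu_final, z, logL, AIC, deltaAIC, weight.
#'
#' @param cmp a \code{model_comparison}.
#' @param file output path.
#' @export
write_model_table <- function(cmp, file) {
  tab <- cmp$table[, c("model", "r1", "r2", "a", "st", "kappa", "x", "lam0",
                       "k_decay", "mu_final", "z", "logL", "AIC",
                       "deltaAIC", "weight")]
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) ifelse(is.na(v), NA,
                                                  sprintf("%.6f", v)))
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
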