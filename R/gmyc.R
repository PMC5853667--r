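## Single-threshold Generalized Mixed Yule Coalescent delimitation.
##
## A threshold age T splits branching into a diversification (Yule-like)
## class and, inside each cluster whose stem crosses T, a coalescent class.
## Each branch is classified by the age of its subtending node.  During the
## i-th inter-event interval the total branching rate is
##   b_i = lambda_div * A_i^p_div + lambda_coal * sum_j (c_ij(c_ij-1))^p_coal
## (A_i diversification-class branches, c_ij sampled branches in cluster j)
## and logL = sum_i [log b_i - b_i x_i] over the n-2 intervals, each ending
## with an event; zero-length intervals (tied ages) contribute the log-rate
## term only.

## interval bookkeeping shared by likelihood and fit: node ages, interval
## durations, and the branch x interval presence matrix
.gmyc_data <- function(tree) {
  tree <- as_chronogram(tree)
  phy <- tree$phy
  n <- tree$n_tips
  age <- tree$node_age
  nodes <- sort(age[-seq_len(n)], decreasing = TRUE)   # n-1 ages, crown first
  K <- n - 2L
  x <- nodes[seq_len(K)] - nodes[seq_len(K) + 1L]
  ## evaluation time inside each interval (midpoint; the interval's start age
  ## for degenerate zero-length intervals)
  tmid <- ifelse(x > 0, (nodes[seq_len(K)] + nodes[seq_len(K) + 1L]) / 2,
                 nodes[seq_len(K)])
  pa <- age[phy$edge[, 1L]]
  ca <- age[phy$edge[, 2L]]
  P <- outer(pa, tmid, ">") & outer(ca, tmid, "<")
  list(tree = tree, phy = phy, n = n, age = age, nodes = nodes, K = K,
       x = x, tmid = tmid, pa = pa, ca = ca, P = P)
}

## per-threshold class structure: diversification counts per interval plus
## the multiplicity table of within-cluster c(c-1) values
.gmyc_threshold_data <- function(gd, T) {
  n <- gd$n
  age <- gd$age
  phy <- gd$phy
  internal <- order(age[(n + 1L):(2L * n - 1L)], decreasing = TRUE) + n
  parent <- integer(2L * n - 1L)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  croot <- integer(2L * n - 1L)            # 0 = diversification class
  for (v in internal) {
    if (age[v] > T) { croot[v] <- 0L; next }
    p <- parent[v]
    croot[v] <- if (p == 0L || age[p] > T) v else croot[p]
  }
  edge_cluster <- croot[phy$edge[, 1L]]     # cluster of each branch
  is_div <- edge_cluster == 0L
  A <- colSums(gd$P[is_div, , drop = FALSE])
  cl <- edge_cluster[!is_div]
  if (length(cl)) {
    C <- rowsum(gd$P[!is_div, , drop = FALSE] + 0, cl)   # clusters x K
    G <- C * (C - 1)
    ug <- sort(unique(G[G > 0]))
    M <- vapply(ug, function(u) colSums(G == u), numeric(gd$K))
    if (is.null(dim(M))) M <- matrix(M, nrow = gd$K)
  } else {
    ug <- numeric(0)
    M <- matrix(0, gd$K, 0L)
  }
  list(A = as.numeric(A), M = M, ug = as.numeric(ug), croot = croot)
}

#' GMYC mixed-model log-likelihood at fixed threshold and parameters
#'
#' @param tree an ultrametric \code{chronogram} (or \code{phylo}).
#' @param threshold threshold age T, strictly inside (0, crown age).
#' @param lambda_div,p_div rate and scaling exponent of the
#'   diversification class.
#' @param lambda_coal,p_coal rate and scaling exponent of the coalescent
#'   class.
#' @return the log-likelihood (deterministic given its inputs).
#' @export
gmyc_loglik <- function(tree, threshold, lambda_div, p_div,
                        lambda_coal, p_coal) {
  gd <- .gmyc_data(tree)
  if (threshold <= 0 || threshold >= gd$nodes[1L])
    stop("'threshold' must lie strictly inside (0, crown age)")
  if (lambda_div <= 0 || lambda_coal <= 0)
    stop("rate parameters must be positive")
  if (p_div < 0 || p_coal < 0)
    stop("scaling exponents must be non-negative")
  td <- .gmyc_threshold_data(gd, threshold)
  cpp_gmyc_loglik(gd$x, td$A, td$M, td$ug, lambda_div, p_div,
                  lambda_coal, p_coal)
}

## single-process null model b_i = lambda * n_i^p, profiled over p
.gmyc_null_fit <- function(gd) {
  ni <- seq_len(gd$K) + 1
  obj <- function(p) {
    s <- sum(ni^p * gd$x)
    lam <- min(max(gd$K / s, 1e-8), 1e3)
    -(sum(p * log(ni)) + gd$K * log(lam) - lam * s)
  }
  op <- stats::optimize(obj, c(0, 3), tol = 1e-10)
  cand_p <- c(op$minimum, 0, 3)
  vals <- vapply(cand_p, obj, numeric(1))
  p <- cand_p[which.min(vals)]
  s <- sum(ni^p * gd$x)
  lam <- min(max(gd$K / s, 1e-8), 1e3)
  list(lambda = lam, p = p, logL = -min(vals))
}

## entities implied by a threshold: cluster subtrees whose stem crosses T,
## plus tips whose terminal branch crosses T alone
.gmyc_entities <- function(gd, T) {
  td <- .gmyc_threshold_data(gd, T)
  n <- gd$n
  phy <- gd$phy
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  desc_tips <- function(v) {
    out <- integer(0)
    stack <- v
    while (length(stack)) {
      u <- stack[[1L]]; stack <- stack[-1L]
      if (u <= n) out <- c(out, u) else stack <- c(stack, kids[[as.character(u)]])
    }
    out
  }
  croots <- which(td$croot == seq_along(td$croot))  # cluster root nodes
  clusters <- lapply(croots, function(v)
    sort(phy$tip.label[desc_tips(v)]))
  parent <- integer(2L * n - 1L)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  singles <- which(gd$age[parent[seq_len(n)]] > T)
  ents <- c(lapply(clusters, function(tp) list(tips = tp, is_singleton = FALSE)),
            lapply(phy$tip.label[singles], function(tp)
              list(tips = tp, is_singleton = TRUE)))
  ## stable order: by oldest attachment, then first tip label
  ord <- order(vapply(ents, function(e) -max(gd$age[parent[match(e$tips, phy$tip.label)]]),
                      numeric(1)),
               vapply(ents, function(e) e$tips[1L], character(1)))
  ents[ord]
}

#' Fit the single-threshold GMYC model
#'
#' Profiles the threshold over midpoints between consecutive distinct node
#' ages (plus one candidate below the youngest node age, the all-singleton
#' configuration), maximising the four process parameters at each candidate
#' by multi-start bounded Nelder-Mead, and compares the optimum against a
#' single-process null (one rate, one exponent for the whole tree) with a
#' likelihood-ratio test.
#'
#' @param tree ultrametric \code{chronogram} with at least 4 tips.
#' @param df degrees of freedom for the chi-square reference of the LR test.
#'   The default 3 counts the two extra process parameters plus the
#'   threshold; the reference is contested in the delimitation literature,
#'   so 2 is accepted as well.
#' @param n_starts optimizer starts per threshold candidate (the first is
#'   the deterministic null-collapse start, then the previous candidate's
#'   optimum, then random starts).
#' @param maxit Nelder-Mead iteration cap per start.
#' @return an object of class \code{gmyc_fit}: threshold, process
#'   parameters, log-likelihoods, LR test, delimited entities and the full
#'   threshold profile.
#' @export
fit_gmyc <- function(tree, df = 3, n_starts = 5, maxit = 400) {
  gd <- .gmyc_data(tree)
  if (gd$n < 4L) stop("GMYC fitting needs at least 4 tips")
  d <- unique(gd$nodes)
  cand <- c((d[-length(d)] + d[-1L]) / 2, d[length(d)] / 2)
  null <- .gmyc_null_fit(gd)
  thr_data <- lapply(cand, function(T) .gmyc_threshold_data(gd, T)[c("A", "M", "ug")])
  prof <- cpp_gmyc_profile(gd$x, thr_data, c(null$lambda, null$p),
                           as.integer(n_starts), as.integer(maxit))
  best <- which.max(prof[, 1L])
  T_hat <- cand[best]
  LR <- 2 * (prof[best, 1L] - null$logL)
  ents <- .gmyc_entities(gd, T_hat)
  structure(list(
    threshold_T = T_hat,
    lambda_div = prof[best, 2L], p_div = prof[best, 3L],
    lambda_coal = prof[best, 4L], p_coal = prof[best, 5L],
    logL_alt = prof[best, 1L], logL_null = null$logL,
    null_lambda = null$lambda, null_p = null$p,
    LR = LR, df = df,
    p_value = stats::pchisq(max(LR, 0), df = df, lower.tail = FALSE),
    entities = ents,
    n_entities = length(ents),
    profile = data.frame(threshold = cand, logL = prof[, 1L]),
    tree = gd$tree), class = "gmyc_fit")
}

#' @export
print.gmyc_fit <- function(x, ...) {
  ns <- sum(vapply(x$entities, `[[`, logical(1), "is_singleton"))
  cat(sprintf("GMYC single-threshold fit\n  threshold: %.4g Ma\n", x$threshold_T))
  cat(sprintf("  entities: %d (%d clusters + %d singletons)\n",
              x$n_entities, x$n_entities - ns, ns))
  cat(sprintf("  logL alt/null: %.4f / %.4f   LR = %.4f, p = %.4g (df = %g)\n",
              x$logL_alt, x$logL_null, x$LR, x$p_value, x$df))
  invisible(x)
}

#' Turn a GMYC fit into a delimitation map
#'
#' @param fit a \code{gmyc_fit}.
#' @param strategy strategy label recorded on the map.
#' @return a delimitation-map data frame consumable by [prune_to_units()].
#' @export
entities_to_map <- function(fit, strategy = "GMYC") {
  stopifnot(inherits(fit, "gmyc_fit"))
  rows <- lapply(seq_along(fit$entities), function(i)
    data.frame(tip_label = fit$entities[[i]]$tips,
               unit_id = sprintf("entity_%03d", i),
               stringsAsFactors = FALSE))
  m <- do.call(rbind, rows)
  attr(m, "strategy") <- strategy
  m
}

#' Write a GMYC fit report as JSON
#'
#' @param fit a \code{gmyc_fit}.
#' @param file output path.
#' @export
write_gmyc_report <- function(fit, file) {
  rep <- list(threshold_T = fit$threshold_T,
              lambda_div = fit$lambda_div, p_div = fit$p_div,
              lambda_coal = fit$lambda_coal, p_coal = fit$p_coal,
              logL_alt = fit$logL_alt, logL_null = fit$logL_null,
              LR = fit$LR, df = fit$df, p_value = fit$p_value,
              n_entities = fit$n_entities,
              entities = lapply(fit$entities, function(e)
                list(tips = e$tips, is_singleton = e$is_singleton)))
  jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
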