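# Independent reference implementations used as oracles.  These are coded
# from the model definitions directly (explicit per-interval loops, the
# textbook constant-rate reconstructed-process formula, and fine-grid
# numerical integration) and share no code with the package's likelihood
# path.

# product of inter-event waiting-time densities for a pure-birth-class
# model with total rate total_rate(k) while k lineages are extant, plus the
# terminal no-event factor
oracle_pb_class <- function(b, total_rate) {
  n <- length(b) + 1L
  ll <- 0
  for (k in 2:(n - 1L)) {
    w <- b[k - 1L] - b[k]
    ll <- ll + log(total_rate(k)) - total_rate(k) * w
  }
  ll - total_rate(n) * b[n - 1L]
}

oracle_pure_birth <- function(b, r) oracle_pb_class(b, function(k) k * r)

oracle_yule2rate <- function(b, r1, r2, st) {
  n <- length(b) + 1L
  ll <- 0
  for (k in 2:(n - 1L)) {
    hi <- b[k - 1L]; lo <- b[k]
    older <- max(0, hi - max(lo, st))
    younger <- (hi - lo) - older
    ll <- ll + log(k * (if (b[k] > st) r1 else r2)) -
      k * (r1 * older + r2 * younger)
  }
  hi <- b[n - 1L]
  older <- max(0, hi - st)
  ll - n * (r1 * older + r2 * (hi - older))
}

oracle_ddl <- function(b, r1, kappa)
  oracle_pb_class(b, function(k) k * r1 * (1 - k / kappa))

oracle_ddx <- function(b, r1, x)
  oracle_pb_class(b, function(k) k * r1 * k^(-x))

# textbook constant-rate reconstructed-process (birth-death) likelihood
# conditioned on crown age and survival of both crown lineages
oracle_bd_nee <- function(b, r, a) {
  n <- length(b) + 1L
  x <- c(NA, b)  # x[2] = crown age, x[3..n] remaining branching times
  lfactorial(n - 1) + (n - 2) * log(r) + r * sum(x[3:n]) +
    n * log(1 - a) - 2 * sum(log(exp(r * x[2:n]) - a))
}

# generalized reconstructed-process likelihood with arbitrary age-dependent
# rates, all integrals by fine-grid trapezoid integration
oracle_tv_grid <- function(b, lam_age, mu_age, nstep = 2e5) {
  n <- length(b) + 1L
  crown <- b[1L]
  xs <- seq(0, crown, length.out = nstep + 1L)
  dx <- crown / nstep
  lam <- lam_age(xs)
  mu <- mu_age(xs)
  dif <- mu - lam
  rho <- c(0, cumsum((dif[-1L] + dif[-length(dif)]) / 2) * dx)
  integrand <- mu * exp(-rho)
  G <- c(0, cumsum((integrand[-1L] + integrand[-length(integrand)]) / 2) * dx)
  rho_at <- stats::approx(xs, rho, xout = b)$y
  G_at <- stats::approx(xs, G, xout = b)$y
  F_at <- exp(-rho_at) + G_at
  lgamma(n) + sum(log(lam_age(b[-1L])) - rho_at[-1L]) - 2 * sum(log(F_at))
}

# direct GMYC mixed-model evaluation: classifies every branch by walking
# the tree explicitly at each inter-event interval
oracle_gmyc <- function(phy, T, lam_div, p_div, lam_coal, p_coal) {
  n <- ape::Ntip(phy)
  depth <- ape::node.depth.edgelength(phy)
  age <- max(depth[seq_len(n)]) - depth
  age[seq_len(n)] <- 0
  nodes <- sort(age[-seq_len(n)], decreasing = TRUE)
  parent <- integer(max(phy$edge))
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  cluster_root <- function(v) {
    # topmost ancestor-or-self with age < T whose parent is older than T
    repeat {
      p <- parent[v]
      if (p == 0L || age[p] > T) return(v)
      v <- p
    }
  }
  ll <- 0
  for (i in seq_len(n - 2L)) {
    hi <- nodes[i]; lo <- nodes[i + 1L]
    tm <- if (hi > lo) (hi + lo) / 2 else hi
    present <- which(age[phy$edge[, 1L]] > tm & age[phy$edge[, 2L]] < tm)
    pa <- phy$edge[present, 1L]
    is_div <- age[pa] > T
    A <- sum(is_div)
    coal <- 0
    if (any(!is_div)) {
      roots <- vapply(pa[!is_div], cluster_root, integer(1))
      cnt <- table(roots)
      coal <- sum((cnt * (cnt - 1))^p_coal)
    }
    bi <- lam_div * (if (A > 0) A^p_div else 0) + lam_coal * coal
    ll <- ll + log(bi) - bi * (hi - lo)
  }
  ll
}

# conditioned reconstructed-process age CDF (stem conditioning)
oracle_cond_age_cdf <- function(lam, mu, T) {
  r <- lam - mu
  Q <- function(x) (1 - exp(-r * x)) / (lam - mu * exp(-r * x))
  function(x) Q(x) / Q(T)
}
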