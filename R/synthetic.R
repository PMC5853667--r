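## Synthetic chronogram generator: constant-rate trees, single-shift trees,
## and two-level species/population trees for delimitation testing.  Every
## generated tree carries a "truth" attribute recording the generating
## parameters, so recovery tests can compare estimates against them.

## assemble an ultrametric phylo from descending branching ages by uniform
## pair joins (the labelled-history distribution shared by the Yule process,
## the conditioned reconstructed birth-death process and the Kingman
## coalescent)
.assemble_tree <- function(ages_desc, tip_labels, stem_age = NA_real_) {
  n <- length(ages_desc) + 1L
  stopifnot(length(tip_labels) == n)
  nedge <- 2L * n - 2L
  edge <- matrix(0L, nedge, 2L)
  elen <- numeric(nedge)
  age <- numeric(2L * n - 1L)
  ## internal node ids n+1 (root, oldest) .. 2n-1 (youngest)
  age[n + seq_len(n - 1L)] <- ages_desc
  active <- seq_len(n)
  k <- 0L
  for (j in rev(seq_len(n - 1L))) {      # youngest join first
    node <- n + j
    pick <- sample.int(length(active), 2L)
    for (ch in active[pick]) {
      k <- k + 1L
      edge[k, ] <- c(node, ch)
      elen[k] <- age[node] - age[ch]
    }
    active <- c(active[-pick], node)
  }
  phy <- list(edge = edge, edge.length = elen, tip.label = tip_labels,
              Nnode = n - 1L)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  if (!is.na(stem_age)) phy$root.edge <- stem_age - ages_desc[1L]
  phy
}

## forward Yule waiting times from the crown (2 lineages) until n tips;
## returns descending branching ages (crown first)
.yule_forward_ages <- function(lam, n) {
  w <- stats::rexp(n - 1L, rate = lam * (2:n))   # durations with k = 2..n lineages
  rev(cumsum(rev(w)))[seq_len(n - 1L)]
}

## piecewise-exponential forward simulation of a two-rate pure-birth
## process on a fixed crown age, accepted only when exactly n tips reach the
## present (rate r1 at ages > st, r2 below)
.yule2rate_ages <- function(r1, r2, st, n, crown_age, max_tries = 100000L) {
  for (try in seq_len(max_tries)) {
    a <- crown_age
    k <- 2L
    ages <- crown_age
    repeat {
      rate <- if (a > st) r1 else r2
      w <- stats::rexp(1L, rate = k * rate)
      if (a > st && a - w < st) { a <- st; next }   # no event before the shift
      a <- a - w
      if (a <= 0) break
      k <- k + 1L
      if (k > n) break
      ages <- c(ages, a)
    }
    if (a <= 0 && k == n) return(ages)
  }
  stop("yule2rate generator: no acceptance in ", max_tries,
       " attempts; parameters are infeasible for the requested tip count")
}

## Kingman coalescent ages for k tips with pairwise rate 1/theta
.coalescent_ages <- function(k, theta) {
  if (k < 2L) return(numeric(0))
  j <- k:2
  sort(cumsum(stats::rexp(k - 1L, rate = choose(j, 2) / theta)),
       decreasing = TRUE)
}

#' Generate a synthetic chronogram with known generating parameters
#'
#' Four generators cover the package's study conditions:
#' \describe{
#'   \item{\code{yule}}{constant-rate pure birth.  With \code{crown_age}
#'     \code{NULL}, forward waiting times until \code{n_tips} lineages;
#'     otherwise exact conditioned sampling on (\code{n_tips},
#'     \code{crown_age}).}
#'   \item{\code{birth_death}}{constant-rate birth-death conditioned on
#'     \code{stem_age} and \code{n_tips} (exact reconstructed-process
#'     sampling; see [simulate_conditioned()]).}
#'   \item{\code{yule2rate}}{pure birth with one rate shift at age
#'     \code{st}, simulated by piecewise-exponential waiting times on a
#'     fixed crown age and accepted when exactly \code{n_tips} lineages
#'     reach the present.  If \code{crown_age} is \code{NULL} it is
#'     calibrated so the expected richness matches \code{n_tips}.}
#'   \item{\code{species_coalescent}}{a two-timescale tree for delimitation
#'     testing: a Yule species tree whose divergences are all pushed older
#'     than \code{min_species_depth}, with each species tip expanded into a
#'     Kingman coalescent subtree of \code{tips_per_species} samples at
#'     coalescent scale \code{min_species_depth / depth_ratio}.}
#' }
#'
#' Default parameter values are chosen at the scale of the motivating newt
#' radiation (stem ~22.5 Ma, crown ~14 Ma, a few tens of lineages).
#'
#' @param kind generator, one of \code{"yule"}, \code{"birth_death"},
#'   \code{"yule2rate"}, \code{"species_coalescent"}.
#' @param seed integer seed (mandatory; every draw is derived from it).
#' @param n_tips number of tips (not used by \code{species_coalescent}).
#' @param lam,mu speciation and extinction rates (events/lineage/Myr).
#' @param crown_age,stem_age conditioning ages in Ma (see details).
#' @param r1,r2,st yule2rate rates before/after the shift and shift age.
#' @param n_species,tips_per_species,species_rate,min_species_depth,depth_ratio
#'   species_coalescent settings.
#' @return a \code{chronogram}; \code{attr(x, "truth")} records every
#'   generating parameter (and, for \code{species_coalescent}, the true
#'   tip-to-species map).
#' @export
generate_chronogram <- function(kind = c("yule", "birth_death", "yule2rate",
                                         "species_coalescent"),
                                seed,
                                n_tips = 39L,
                                lam = 0.2, mu = 0.05,
                                crown_age = NULL, stem_age = 22.46,
                                r1 = 0.35, r2 = 0.08, st = 2.6,
                                n_species = 20L, tips_per_species = 4L,
                                species_rate = 0.3, min_species_depth = 5,
                                depth_ratio = 25) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("'seed' is mandatory")
  set.seed(seed)
  truth <- list(kind = kind, seed = seed)

  if (kind == "yule") {
    stopifnot(lam > 0, n_tips >= 3L)
    ages <- if (is.null(crown_age)) {
      .yule_forward_ages(lam, n_tips)
    } else {
      c(crown_age,
        sort(cpp_rcond_ages(n_tips - 2L, crown_age, lam, 0), decreasing = TRUE))
    }
    phy <- .assemble_tree(ages, sprintf("t%d", seq_len(n_tips)))
    truth <- c(truth, list(lam = lam, n_tips = n_tips, crown_age = ages[1L]))
  } else if (kind == "birth_death") {
    stopifnot(lam > mu, mu >= 0, n_tips >= 3L)
    ages <- sort(cpp_rcond_ages(n_tips - 1L, stem_age, lam, mu),
                 decreasing = TRUE)
    phy <- .assemble_tree(ages, sprintf("t%d", seq_len(n_tips)),
                          stem_age = stem_age)
    truth <- c(truth, list(lam = lam, mu = mu, n_tips = n_tips,
                           stem_age = stem_age, crown_age = ages[1L]))
  } else if (kind == "yule2rate") {
    stopifnot(r1 > 0, r2 > 0, n_tips >= 4L)
    if (is.null(crown_age)) {
      ## crown age at which E[tip count] = n_tips under the two-rate process
      crown_age <- st + (log(n_tips / 2) - r2 * st) / r1
      if (crown_age <= st)
        stop("yule2rate generator: requested tip count unreachable; ",
             "give crown_age explicitly")
    }
    if (st <= 0 || st >= crown_age) stop("'st' must lie inside (0, crown_age)")
    ages <- .yule2rate_ages(r1, r2, st, n_tips, crown_age)
    phy <- .assemble_tree(ages, sprintf("t%d", seq_len(n_tips)))
    truth <- c(truth, list(r1 = r1, r2 = r2, st = st, n_tips = n_tips,
                           crown_age = crown_age))
  } else {  # species_coalescent
    stopifnot(n_species >= 1L, all(tips_per_species >= 1L),
              species_rate > 0, min_species_depth > 0, depth_ratio > 0)
    tps <- rep_len(tips_per_species, n_species)
    coal_depth <- min_species_depth / depth_ratio
    if (n_species > 1L && coal_depth >= min_species_depth)
      stop("within-species coalescent depth scale (", coal_depth,
           " Ma) exceeds the species stem; increase depth_ratio")
    sp_labels <- sprintf("zzSPX%dXzz", seq_len(n_species))
    if (n_species > 1L) {
      sp_ages <- .yule_forward_ages(species_rate, n_species) + min_species_depth
      sp_phy <- .assemble_tree(sp_ages, sp_labels)
      nwk <- ape::write.tree(sp_phy, digits = 12)
    } else {
      nwk <- sprintf("%s;", sp_labels[1L])
    }
    species_map <- list()
    for (s in seq_len(n_species)) {
      labs <- sprintf("sp%02d_t%d", s, seq_len(tps[s]))
      species_map[[sprintf("sp%02d", s)]] <- labs
      if (tps[s] == 1L) {
        sub_nwk <- labs
        depth <- 0
      } else {
        ## coal_depth bounds the realised within-species depth: the
        ## coalescent is conditioned on TMRCA <= coal_depth (the tail is
        ## dominated by the final two-lineage stage, Exp with mean theta,
        ## so with theta = coal_depth/3 the conditioning accepts ~95% of
        ## draws).  This realises the advertised species/population
        ## timescale separation in every tree, not just on average.
        theta_s <- coal_depth / 3
        repeat {
          ca <- .coalescent_ages(tps[s], theta_s)
          if (ca[1L] <= coal_depth) break
        }
        depth <- ca[1L]
        sub_phy <- .assemble_tree(ca, labs)
        sub_nwk <- sub(";\\s*$", "", ape::write.tree(sub_phy, digits = 12))
      }
      if (n_species > 1L) {
        ## species terminal branch is shortened by the subtree depth
        pat <- sprintf("%s:([0-9.eE+-]+)", sp_labels[s])
        mlen <- regmatches(nwk, regexpr(pat, nwk))
        blen <- as.numeric(sub(pat, "\\1", mlen))
        if (blen <= depth)
          stop("within-species coalescent depth exceeds the species stem; ",
               "increase depth_ratio or min_species_depth")
        nwk <- sub(pat, sprintf("%s:%.12f", sub_nwk, blen - depth), nwk)
      } else {
        nwk <- sprintf("%s;", sub_nwk)
      }
    }
    phy <- ape::read.tree(text = nwk)
    truth <- c(truth, list(n_species = n_species, tips_per_species = tps,
                           species_rate = species_rate,
                           coal_depth = coal_depth,
                           min_species_depth = min_species_depth,
                           depth_ratio = depth_ratio,
                           species_map = species_map))
  }
  out <- as_chronogram(phy, tol = 1e-6)
  attr(out, "truth") <- truth
  out
}

#' True delimitation map of a species_coalescent chronogram
#'
#' @param tree a chronogram generated with \code{kind =
#'   "species_coalescent"}.
#' @param strategy strategy label for the map.
#' @return a delimitation-map data frame (see [read_delimitation_map()]).
#' @export
truth_map <- function(tree, strategy = "truth") {
  truth <- attr(tree, "truth")
  if (is.null(truth$species_map))
    stop("tree carries no species_map truth record")
  m <- do.call(rbind, lapply(names(truth$species_map), function(s)
    data.frame(tip_label = truth$species_map[[s]], unit_id = s,
               stringsAsFactors = FALSE)))
  attr(m, "strategy") <- strategy
  m
}
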