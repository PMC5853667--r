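## Chronogram container, I/O, validation, pruning, branching times, LTT.

#' Coerce a phylogeny to a validated chronogram
#'
#' A chronogram is a rooted, bifurcating, ultrametric time-calibrated tree
#' with node ages in Ma before present (tips at age 0).  Validation checks
#' ultrametricity within a relative tolerance of the crown age, snaps tip
#' ages to exactly 0, and rebuilds branch lengths from the snapped ages so
#' that downstream arithmetic is exact.
#'
#' @param phy an \code{ape} \code{phylo} object (or a \code{chronogram}).
#' @param tol relative ultrametricity tolerance, as a fraction of the crown
#'   age.  Dated consensus trees carry rounding noise; the default 1e-3
#'   accepts it while rejecting genuinely non-clock trees.
#' @param resolve_polytomies if \code{TRUE}, polytomies are resolved to
#'   zero-length bifurcations (with a warning); if \code{FALSE} (default)
#'   polytomous trees are rejected, because the waiting-time likelihoods
#'   assume bifurcation.
#' @return an object of class \code{chronogram}: the tree plus node ages,
#'   crown age and (if the tree has a root edge) stem age.
#' @export
as_chronogram <- function(phy, tol = 1e-3, resolve_polytomies = FALSE) {
  if (inherits(phy, "chronogram")) return(phy)
  if (!inherits(phy, "phylo")) stop("'phy' must be a 'phylo' object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  n <- length(phy$tip.label)
  if (n < 2L) stop("tree must have at least 2 tips")
  if (anyDuplicated(phy$tip.label))
    stop("tip labels are not unique: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (!ape::is.binary(phy)) {
    if (resolve_polytomies) {
      warning("polytomies resolved to zero-length bifurcations")
      phy <- ape::multi2di(phy)
    } else {
      stop("tree contains polytomies; set resolve_polytomies = TRUE to ",
           "resolve them to zero-length bifurcations")
    }
  }
  if (any(phy$edge.length < 0))
    stop("tree has negative branch lengths")

  depth <- ape::node.depth.edgelength(phy)
  tip_depth <- depth[seq_len(n)]
  crown <- max(tip_depth)
  spread <- crown - min(tip_depth)
  if (spread > tol * crown) {
    worst <- phy$tip.label[which.max(abs(tip_depth - stats::median(tip_depth)))]
    stop(sprintf(paste0("tree is not ultrametric within tolerance ",
                        "(tip-depth spread %.6g > %.6g); worst tip: %s"),
                 spread, tol * crown, worst))
  }

  age <- crown - depth
  age[seq_len(n)] <- 0                       # snap tips to the present
  ## rebuild branch lengths from the snapped ages
  el <- age[phy$edge[, 1L]] - age[phy$edge[, 2L]]
  if (any(el < -tol * crown)) stop("node ages are not monotone along the tree")
  phy$edge.length <- pmax(el, 0)

  root <- n + 1L
  crown_age <- age[root]
  stem_age <- if (!is.null(phy$root.edge) && phy$root.edge > 0)
    crown_age + phy$root.edge else NA_real_
  structure(list(phy = phy, node_age = age, crown_age = crown_age,
                 stem_age = stem_age, n_tips = n),
            class = "chronogram")
}

#' @export
print.chronogram <- function(x, ...) {
  cat(sprintf("chronogram: %d tips, crown age %.4g Ma%s\n", x$n_tips,
              x$crown_age,
              if (is.na(x$stem_age)) "" else
                sprintf(", stem age %.4g Ma", x$stem_age)))
  invisible(x)
}

#' @importFrom ape as.phylo
#' @method as.phylo chronogram
#' @export
as.phylo.chronogram <- function(x, ...) x$phy

## strip bracketed comments/annotations ([&...] metadata written by Bayesian
## dating software) outside of quoted labels
.strip_tree_comments <- function(text) {
  gsub("\\[[^]\\[]*\\]", "", text)
}

#' Read a time-calibrated tree
#'
#' Reads Newick or NEXUS (including TRANSLATE blocks; bracketed node
#' annotations such as posterior supports and HPD intervals are tolerated
#' and discarded) and validates the result as a chronogram.
#'
#' @param file path to a tree file, or \code{NULL} if \code{text} is given.
#' @param text tree as a character string (alternative to \code{file}).
#' @param format \code{"auto"} (detect NEXUS by its header), \code{"newick"}
#'   or \code{"nexus"}.
#' @param tol,resolve_polytomies passed to [as_chronogram()].
#' @return a \code{chronogram}, or a list of chronograms if the input holds
#'   several trees.
#' @export
read_chronogram <- function(file = NULL, text = NULL,
                            format = c("auto", "newick", "nexus"),
                            tol = 1e-3, resolve_polytomies = FALSE) {
  format <- match.arg(format)
  if (is.null(text)) {
    if (is.null(file)) stop("supply 'file' or 'text'")
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  if (format == "auto")
    format <- if (grepl("^\\s*#NEXUS", text, ignore.case = TRUE))
      "nexus" else "newick"
  text <- .strip_tree_comments(text)
  phy <- tryCatch({
    if (format == "nexus") {
      tf <- tempfile(fileext = ".nex")
      on.exit(unlink(tf), add = TRUE)
      writeLines(text, tf)
      ape::read.nexus(tf)
    } else {
      ape::read.tree(text = text)
    }
  }, error = function(e) stop("failed to parse ", format, " tree: ",
                              conditionMessage(e)))
  if (is.null(phy)) stop("failed to parse ", format, " tree")
  if (inherits(phy, "multiPhylo"))
    return(lapply(phy, as_chronogram, tol = tol,
                  resolve_polytomies = resolve_polytomies))
  as_chronogram(phy, tol = tol, resolve_polytomies = resolve_polytomies)
}

#' Write a chronogram (or list of chronograms) as plain Newick
#'
#' @param x a \code{chronogram} or a list of them.
#' @param file output path; if \code{NULL} the Newick string(s) are returned.
#' @param digits significant digits for branch lengths; the default
#'   round-trips ages to better than 1e-9.
#' @export
write_chronogram <- function(x, file = NULL, digits = 12) {
  trees <- if (inherits(x, "chronogram")) list(x) else x
  nwk <- vapply(trees, function(tr)
    ape::write.tree(tr$phy, digits = digits), character(1))
  if (is.null(file)) {
    if (length(nwk) == 1L) nwk else nwk
  } else {
    writeLines(nwk, file)
    invisible(file)
  }
}

#' Branching times of the crown group
#'
#' The descending vector of the n-1 internal node ages — the sufficient
#' statistic for every birth-death likelihood in the package.
#'
#' @param tree a \code{chronogram} (or \code{phylo}).
#' @return numeric vector of class \code{branching_times} (descending ages,
#'   Ma), with attributes \code{n_tips}, \code{crown_age} and
#'   \code{stem_age}.
#' @export
branching_times <- function(tree) {
  tree <- as_chronogram(tree)
  n <- tree$n_tips
  if (n < 3L)
    stop("insufficient branching events: need at least 3 tips, got ", n)
  ages <- sort(tree$node_age[-seq_len(n)], decreasing = TRUE)
  structure(as.numeric(ages), n_tips = n, crown_age = tree$crown_age,
            stem_age = tree$stem_age, class = "branching_times")
}

## accept branching_times, chronogram, or a raw descending age vector
.as_bt <- function(bt) {
  if (inherits(bt, "chronogram")) return(branching_times(bt))
  if (inherits(bt, "branching_times")) return(bt)
  bt <- as.numeric(bt)
  if (length(bt) < 2L) stop("need at least 2 branching times")
  if (is.unsorted(rev(bt))) stop("branching times must be descending ages")
  if (any(bt < 0)) stop("branching times must be non-negative ages")
  structure(bt, n_tips = length(bt) + 1L, crown_age = bt[1L],
            stem_age = NA_real_, class = "branching_times")
}

#' Read / write a delimitation map
#'
#' A delimitation map assigns every tip label to a biodiversity unit under
#' some delimitation strategy (e.g. GMYC clusters, nominal species).  The
#' on-disk format is two-column tab-separated text with a header
#' (\code{tip_label}, \code{unit_id}).
#'
#' @param file path to a TSV file.
#' @param strategy optional strategy label stored as an attribute.
#' @return a data frame with columns \code{tip_label} and \code{unit_id}.
#' @export
read_delimitation_map <- function(file, strategy = NA_character_) {
  m <- utils::read.delim(file, header = TRUE, sep = "\t",
                         colClasses = "character")
  if (ncol(m) < 2L) stop("delimitation map needs columns tip_label, unit_id")
  m <- m[, 1:2]
  names(m) <- c("tip_label", "unit_id")
  attr(m, "strategy") <- strategy
  m
}

#' @rdname read_delimitation_map
#' @param map a delimitation-map data frame.
#' @export
write_delimitation_map <- function(map, file) {
  utils::write.table(map[, c("tip_label", "unit_id")], file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Prune a chronogram to one representative tip per unit
#'
#' For each unit the retained representative is the member whose lineage
#' diverges from the rest of the tree earliest (oldest parent-node age),
#' ties broken by lexicographic tip label; all other tips are removed and
#' the resulting degree-2 nodes suppressed.  Node ages are preserved.
#'
#' @param tree a \code{chronogram}.
#' @param map a delimitation map (see [read_delimitation_map()]) covering
#'   every tip of the tree exactly once.
#' @return the pruned \code{chronogram}, with one tip per unit.
#' @export
prune_to_units <- function(tree, map) {
  tree <- as_chronogram(tree)
  phy <- tree$phy
  tips <- phy$tip.label
  if (!all(tips %in% map$tip_label))
    stop("tips missing from delimitation map: ",
         paste(utils::head(setdiff(tips, map$tip_label), 5), collapse = ", "))
  if (anyDuplicated(map$tip_label))
    stop("delimitation map assigns some tips more than once")
  unit_of <- stats::setNames(as.character(map$unit_id), map$tip_label)
  units <- unique(unit_of[tips])
  empty <- setdiff(unique(as.character(map$unit_id)), units)
  if (length(empty))
    stop("units with no member tips in the tree: ",
         paste(empty, collapse = ", "))

  ## parent-node age of each tip = age at which its terminal lineage attaches
  parent_of_tip <- phy$edge[match(seq_along(tips), phy$edge[, 2L]), 1L]
  attach_age <- tree$node_age[parent_of_tip]

  keep <- vapply(units, function(u) {
    members <- which(unit_of[tips] == u)
    members <- members[order(-attach_age[members], tips[members])]
    tips[members[1L]]
  }, character(1))

  pruned <- ape::keep.tip(phy, keep)
  out <- as_chronogram(pruned, tol = 1e-6)
  if (!is.na(tree$stem_age)) {
    out$phy$root.edge <- tree$stem_age - out$crown_age
    out$stem_age <- tree$stem_age
  }
  out
}

#' Lineage-through-time curve
#'
#' Step curve of the number of reconstructed lineages against age, from
#' (crown age, 2) to (0, n); the count increments by the multiplicity of
#' each distinct node age.  \code{log_n} holds natural-log counts for the
#' conventional log-transformed LTT plot.
#'
#' @param tree a \code{chronogram}.
#' @return data frame of class \code{ltt_curve} with columns \code{age},
#'   \code{n_lineages}, \code{log_n}.
#' @export
ltt_curve <- function(tree) {
  bt <- branching_times(tree)
  ages <- as.numeric(bt)
  d <- unique(ages)                      # descending distinct ages
  mult <- as.integer(table(factor(ages, levels = d)))
  counts <- 1L + cumsum(mult)            # lineages after the event(s)
  out <- data.frame(age = c(d, 0), n_lineages = c(counts, counts[length(counts)]))
  out$log_n <- log(out$n_lineages)
  structure(out, crown_age = attr(bt, "crown_age"),
            stem_age = attr(bt, "stem_age"), n_tips = attr(bt, "n_tips"),
            class = c("ltt_curve", "data.frame"))
}

## lineage count of a chronogram/curve at arbitrary ages (vectorised)
.lineages_at <- function(ages_desc, crown, query) {
  vapply(query, function(g) {
    if (g >= crown) 1L else 1L + sum(ages_desc > g)
  }, integer(1))
}
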