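# Shared imports are declared in NAMESPACE (written by hand).

# Age/height conventions: "present" (age 0) is the deepest tip, so extant tips
# have age exactly 0 and fossil tips have positive ages. Node ages are times
# before present; depths are times since the root.

#' Depth of every node and tip from the root
#'
#' @param phy a rooted `phylo` object with branch lengths.
#' @return numeric vector of length `Ntip + Nnode`, indexed like the `edge`
#'   matrix (tips `1..Ntip`, root `Ntip + 1`).
#' @export
node_depths <- function(phy) {
  stopifnot(inherits(phy, "phylo"), !is.null(phy$edge.length))
  n_all <- length(phy$tip.label) + phy$Nnode
  depth <- numeric(n_all)
  eo <- ape::reorder.phylo(phy, "postorder")
  ed <- eo$edge
  el <- eo$edge.length
  # reverse postorder = parents before children
  for (k in rev(seq_len(nrow(ed)))) {
    depth[ed[k, 2L]] <- depth[ed[k, 1L]] + el[k]
  }
  depth
}

#' Tree height (maximum root-to-tip path length)
#' @param phy a rooted `phylo` with branch lengths.
#' @export
tree_height <- function(phy) {
  max(node_depths(phy)[seq_along(phy$tip.label)])
}

#' Ages (time before present) of all nodes and tips
#'
#' The present is anchored at the deepest tip, so extant tips get age 0 and
#' extinct tips positive ages.
#'
#' @inheritParams node_depths
#' @return numeric vector over tips then internal nodes.
#' @export
node_ages <- function(phy) {
  d <- node_depths(phy)
  max(d[seq_along(phy$tip.label)]) - d
}

#' Tip ages, named by tip label
#' @inheritParams node_depths
#' @export
tip_ages <- function(phy) {
  a <- node_ages(phy)[seq_along(phy$tip.label)]
  names(a) <- phy$tip.label
  a
}

#' Labels of extinct (non-contemporary) tips
#'
#' The default tolerance scales with tree height so that branch-length
#' round-off from Newick round-trips never promotes extant tips to fossils.
#'
#' @param phy a rooted `phylo` with branch lengths.
#' @param tol ages greater than this count as extinct; default
#'   `1e-6 * max(1, tree height)`.
#' @export
extinct_tips <- function(phy, tol = NULL) {
  a <- tip_ages(phy)
  if (is.null(tol)) tol <- 1e-6 * max(1, max(a))
  names(a)[a > tol]
}

#' Validate the dated-tree invariants
#'
#' Checks: rooted; branch lengths present and non-negative; unique tip labels;
#' parent older than child wherever the connecting branch is positive; ages
#' consistent with branch lengths.
#'
#' @param phy a `phylo` object.
#' @param tol numeric tolerance for the age bookkeeping.
#' @return `phy`, invisibly; stops with a message on violation.
#' @export
validate_dated_tree <- function(phy, tol = 1e-9) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' object")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(phy$edge.length < -tol)) stop("negative branch length")
  if (anyDuplicated(phy$tip.label)) stop("duplicated tip labels")
  age <- node_ages(phy)
  ed <- phy$edge
  gap <- age[ed[, 1L]] - age[ed[, 2L]] - phy$edge.length
  if (any(abs(gap) > 1e-6)) stop("node ages inconsistent with branch lengths")
  pos <- phy$edge.length > tol
  if (any(age[ed[pos, 1L]] <= age[ed[pos, 2L]] - tol)) {
    stop("parent not older than child on a positive branch")
  }
  invisible(phy)
}

#' Read one or more rooted, dated trees from a Newick file
#'
#' Polytomies are resolved into zero-length binary splits in input order; the
#' resolution is recorded in the `"polytomy_log"` attribute of the returned
#' list. Missing branch lengths or unrooted trees raise an error naming the
#' offending tree index.
#'
#' @param path path to a Newick file (one or more trees).
#' @return a list of `phylo` objects, order preserved.
#' @export
read_trees <- function(path) {
  if (!file.exists(path)) stop("cannot read tree file: ", path)
  trees <- ape::read.tree(path)
  if (is.null(trees)) stop("no trees parsed from ", path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  log <- character(0)
  out <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (is.null(tr$edge.length)) {
      stop(sprintf("tree %d has no branch lengths", i))
    }
    if (!ape::is.binary(tr) || !ape::is.rooted(tr)) {
      tr <- ape::multi2di(tr, random = FALSE)
      log <- c(log, sprintf("tree %d: polytomies resolved to zero-length binary splits", i))
    }
    if (!ape::is.rooted(tr)) stop(sprintf("tree %d is not rooted", i))
    validate_dated_tree(tr)
    out[[i]] <- tr
  }
  attr(out, "polytomy_log") <- log
  out
}

#' Minimum-branch-length stratigraphic time-scaling
#'
#' Enforces a floor `min_bl` on every branch duration while keeping the input
#' internal node ages except where a descendant tip or node age forces a
#' rootward shift; shifted ancestors are moved by the minimal amount, and the
#' shift cascades rootward as needed. Nodes are never moved tipward.
#'
#' @param phy a rooted dated `phylo`.
#' @param tip_ages optional named numeric vector of tip ages (time before
#'   present) overriding the ages implied by the current branch lengths;
#'   typically the resampled fossil ages. Tips not named keep their ages.
#' @param min_bl the minimum branch duration (same units as the tree, > 0
#'   except for the degenerate `min_bl = 0` no-op).
#' @return the rescaled `phylo`; attribute `"mbl_shifts"` is a data frame of
#'   internal nodes whose ages moved (`node`, `old_age`, `new_age`).
#' @export
timescale_mbl <- function(phy, tip_ages = NULL, min_bl = 1) {
  if (min_bl < 0) stop("min_bl must be >= 0")
  n_tip <- length(phy$tip.label)
  age <- node_ages(phy)
  if (!is.null(tip_ages)) {
    idx <- match(names(tip_ages), phy$tip.label)
    if (anyNA(idx)) stop("unknown tip in tip_ages: ",
                         paste(names(tip_ages)[is.na(idx)], collapse = ", "))
    age[idx] <- tip_ages
  }
  input_age <- age
  eo <- ape::reorder.phylo(phy, "postorder")
  ed <- eo$edge
  # postorder: all child edges of a node appear before its own parent edge,
  # so one sweep propagates the constraint rootward.
  req <- rep(-Inf, n_tip + phy$Nnode)
  for (k in seq_len(nrow(ed))) {
    p <- ed[k, 1L]; ch <- ed[k, 2L]
    if (ch > n_tip) age[ch] <- max(input_age[ch], req[ch])
    req[p] <- max(req[p], age[ch] + min_bl)
  }
  root <- n_tip + 1L
  age[root] <- max(input_age[root], req[root])
  new_phy <- phy
  new_phy$edge.length <- age[phy$edge[, 1L]] - age[phy$edge[, 2L]]
  moved <- which(abs(age - input_age) > 1e-12 & seq_along(age) > n_tip)
  attr(new_phy, "mbl_shifts") <- data.frame(
    node = moved, old_age = input_age[moved], new_age = age[moved])
  validate_dated_tree(new_phy)
  new_phy
}

#' Resample fossil tip ages over their stratigraphic ranges
#'
#' Draws every extinct tip's age independently and uniformly on
#' `[lad, fad]`, then re-applies [timescale_mbl()]. Extant tips are untouched.
#'
#' @param phy a rooted dated `phylo`.
#' @param ranges data frame with columns `taxon`, `fad`, `lad` (Ma,
#'   `fad >= lad >= 0`) covering every extinct tip.
#' @param n_trees number of replicate trees.
#' @param seed integer seed; replicates are reproducible.
#' @param min_bl minimum branch length passed to [timescale_mbl()].
#' @return list of `n_trees` rescaled `phylo` objects.
#' @export
sample_fossil_tip_ages <- function(phy, ranges, n_trees, seed, min_bl = 1) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  stopifnot(all(c("taxon", "fad", "lad") %in% names(ranges)))
  if (any(ranges$fad < ranges$lad) || any(ranges$lad < 0)) {
    stop("invalid stratigraphic range: need fad >= lad >= 0")
  }
  fossils <- extinct_tips(phy)
  missing <- setdiff(fossils, ranges$taxon)
  if (length(missing)) {
    stop("extinct tips without stratigraphic range: ",
         paste(missing, collapse = ", "))
  }
  rg <- ranges[match(fossils, ranges$taxon), , drop = FALSE]
  out <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    set.seed(child_seed(seed, i))
    ages <- stats::runif(nrow(rg), min = rg$lad, max = rg$fad)
    names(ages) <- rg$taxon
    out[[i]] <- timescale_mbl(phy, tip_ages = ages, min_bl = min_bl)
  }
  out
}

#' Prune a dated tree to a taxon set
#'
#' Degree-2 nodes are suppressed with branch lengths summed, so root-to-tip
#' distances (and hence node ages of retained nodes) are preserved.
#'
#' @param phy a rooted dated `phylo`.
#' @param taxa character vector of tip labels to keep (at least 2).
#' @export
prune_to_taxa <- function(phy, taxa) {
  unknown <- setdiff(taxa, phy$tip.label)
  if (length(unknown)) stop("unknown tip labels: ", paste(unknown, collapse = ", "))
  if (length(taxa) < 2) stop("need at least 2 taxa")
  ape::keep.tip(phy, taxa)
}

#' Rescale a tree to unit height
#'
#' Divides every branch length by the tree height (maximum root-to-tip path),
#' preserving relative tip depths. Idempotent.
#'
#' @param phy a rooted dated `phylo`.
#' @export
rescale_unit_height <- function(phy) {
  h <- tree_height(phy)
  if (h <= 0) stop("zero-height tree cannot be rescaled")
  phy$edge.length <- phy$edge.length / h
  phy
}

#' Phylogenetic covariance structure
#'
#' Returns the matrix of shared root-to-MRCA path lengths `S` for all tip
#' pairs and the root-to-tip depths `T` (`S[i, i] == T[i]`), in tip order.
#'
#' @param phy a rooted dated `phylo`.
#' @return list with elements `S` (matrix) and `depths` (vector).
#' @export
phylo_covariance <- function(phy) {
  S <- ape::vcv.phylo(phy)
  S <- S[phy$tip.label, phy$tip.label]
  list(S = S, depths = diag(S))
}

#' Deterministic child seed derived from a run seed
#'
#' Splits one run seed into per-replicate seeds (kept below 2^31) so every
#' source of randomness flows from a single documented seed.
#'
#' @param seed integer run seed.
#' @param i replicate index (>= 1).
#' @export
child_seed <- function(seed, i) {
  m <- 2147483647
  as.integer((((as.numeric(seed) %% m) * 16807) %% m + 48271 * as.numeric(i)) %% m)
}
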