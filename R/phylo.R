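#' Distance-based phylogeny with pseudo-bootstrap support
#'
#' Tree inference from intergenomic distance matrices (balanced minimum
#' evolution or neighbor joining via ape), pseudo-bootstrap by resampling
#' retained HSPs, bipartition support mapping, support-based collapsing and
#' outgroup rooting. Trees are `ape::phylo` objects; supports are stored as
#' internal node labels (the common Newick dialect).
#'
#' @name phylogenomics
NULL

validate_dist_matrix <- function(dm) {
  if (!is.matrix(dm) || !is.numeric(dm))
    stop("distance matrix must be a numeric matrix")
  if (nrow(dm) != ncol(dm)) stop("distance matrix must be square")
  if (is.null(rownames(dm)) || !identical(rownames(dm), colnames(dm)))
    stop("distance matrix needs matching row/column ids")
  if (any(!is.finite(dm))) stop("distance matrix contains non-finite values")
  if (any(abs(dm - t(dm)) > 1e-12)) stop("distance matrix is not symmetric")
  if (any(diag(dm) != 0)) stop("distance matrix diagonal must be zero")
  invisible(dm)
}

#' Infer a distance-based phylogeny
#'
#' Default method is balanced minimum evolution (the FastME criterion) with
#' topology improvement, computed by `ape::fastme.bal`; `"nj"` selects
#' neighbor joining. Negative branch-length estimates are clamped to zero.
#' Deterministic given the matrix and method.
#'
#' @param dm Symmetric numeric matrix with zero diagonal and ids as
#'   dimnames.
#' @param method `"bme"` (default) or `"nj"`.
#' @return An unrooted `phylo` tree.
#' @export
infer_tree <- function(dm, method = c("bme", "nj")) {
  method <- match.arg(method)
  validate_dist_matrix(dm)
  if (nrow(dm) < 3) stop("need at least 3 taxa")
  tree <- if (method == "nj" || nrow(dm) == 3) {
    ape::nj(stats::as.dist(dm))
  } else {
    ape::fastme.bal(stats::as.dist(dm), nni = TRUE, spr = TRUE)
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Pseudo-bootstrap replicate distance matrices
#'
#' For each replicate and each genome pair, the retained post-trimming HSP
#' set is resampled with replacement (same cardinality) and the distance
#' recomputed. Pairs with no HSPs keep the capped maximum in every
#' replicate. Fully reproducible for a fixed seed.
#'
#' @param ps A `pairwise_set` from [all_pairwise()] (holds each pair's
#'   retained HSPs).
#' @param replicates Number of replicates (default 100).
#' @param seed Integer seed.
#' @param formula Distance formula (default `"d5"`).
#' @return List of `replicates` distance matrices.
#' @export
pseudo_bootstrap <- function(ps, replicates = 100L, seed = 1L,
                             formula = "d5") {
  stopifnot(inherits(ps, "pairwise_set"), replicates >= 1)
  ids <- ps$ids
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- vector("list", replicates)
  np <- nrow(ps$pairs)
  for (r in seq_len(replicates)) {
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (i in seq_len(np)) {
      a <- ps$pairs$genome_a[i]; b <- ps$pairs$genome_b[i]
      hs <- ps$hsps[[i]]
      d <- if (is.null(hs) || nrow(hs) == 0L) {
        gbdp_distance_from_hsps(hs, ps$lengths[[a]], ps$lengths[[b]],
                                formula)
      } else {
        take <- sample.int(nrow(hs), nrow(hs), replace = TRUE)
        gbdp_distance_from_hsps(hs[take, , drop = FALSE],
                                ps$lengths[[a]], ps$lengths[[b]], formula)
      }
      m[a, b] <- m[b, a] <- as.numeric(d)
    }
    out[[r]] <- m
  }
  out
}

# Bipartition keys of a tree's internal edges, normalized to the side not
# containing the alphabetically first tip, so keys are rooting-invariant.
bipartition_keys <- function(tree) {
  tips <- tree$tip.label
  anchor <- sort(tips)[1]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  nt <- length(tips)
  keys <- character(0)
  nodes <- integer(0)
  for (i in seq_along(pp)) {
    set <- labs[pp[[i]]]
    if (length(set) == nt) next                    # root / full set
    if (anchor %in% set) set <- setdiff(tips, set)
    if (length(set) < 2 || length(set) > nt - 2) next  # trivial
    keys <- c(keys, paste(sort(set), collapse = "\r"))
    nodes <- c(nodes, nt + i)
  }
  list(keys = keys, nodes = nodes)
}

#' Map pseudo-bootstrap support onto a tree
#'
#' Each internal bipartition's support is the percentage of replicate trees
#' containing that bipartition, rounded to the nearest integer, and is
#' stored as the internal node label.
#'
#' @param main The tree to annotate.
#' @param replicate_trees List of trees over the identical leaf set.
#' @return `main` with `node.label` support values.
#' @export
map_support <- function(main, replicate_trees) {
  for (t in replicate_trees)
    if (!setequal(t$tip.label, main$tip.label))
      stop("replicate tree leaf set differs from the main tree")
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (t in replicate_trees) {
    # unique(): in a rooted tree both root children induce the same
    # bipartition, which must count once
    for (k in unique(bipartition_keys(t)$keys)) {
      cur <- counts[[k]]
      counts[[k]] <- if (is.null(cur)) 1L else cur + 1L
    }
  }
  R <- length(replicate_trees)
  bk <- bipartition_keys(main)
  nnode <- main$Nnode
  labels <- rep(NA_character_, nnode)
  nt <- length(main$tip.label)
  for (i in seq_along(bk$keys)) {
    cnt <- counts[[bk$keys[i]]]
    if (is.null(cnt)) cnt <- 0L
    labels[bk$nodes[i] - nt] <- as.character(round(100 * cnt / R))
  }
  main$node.label <- labels
  main
}

#' Collapse weakly supported edges to polytomies
#'
#' Every internal edge with support less than or equal to `threshold`
#' (default: 50 percent or less) is contracted; the leaf set and the
#' remaining supports are unchanged.
#'
#' @param tree A `phylo` with numeric support in `node.label`.
#' @param threshold Collapse when support `<= threshold` (default 50).
#' @return The collapsed tree.
#' @export
collapse_low_support <- function(tree, threshold = 50) {
  if (is.null(tree$node.label)) stop("tree has no support values")
  support <- suppressWarnings(as.numeric(tree$node.label))
  nt <- length(tree$tip.label)
  # nodes whose stem edge is to be contracted
  drop_nodes <- which(!is.na(support) & support <= threshold) + nt
  if (!length(drop_nodes)) return(tree)
  # mark target stem edges with length 0, shift all others by +1, then use
  # ape's zero-length collapser and undo the shift
  el <- tree$edge.length
  if (is.null(el)) el <- rep(1, nrow(tree$edge))
  shifted <- el + 1
  target <- tree$edge[, 2] %in% drop_nodes
  shifted[target] <- 0
  tmp <- tree
  tmp$edge.length <- shifted
  tmp <- ape::di2multi(tmp, tol = 1e-9)
  tmp$edge.length <- tmp$edge.length - 1
  tmp$edge.length[tmp$edge.length < 0] <- 0
  if (is.null(tree$edge.length)) tmp$edge.length <- NULL
  tmp
}

#' Root a tree on an outgroup
#'
#' @param tree Unrooted `phylo`.
#' @param outgroup_ids Tip labels of the outgroup; must be monophyletic in
#'   the unrooted sense.
#' @return Rooted tree (support labels follow edges on rerooting).
#' @export
root_with_outgroup <- function(tree, outgroup_ids) {
  missing <- setdiff(outgroup_ids, tree$tip.label)
  if (length(missing))
    stop("outgroup id(s) not in tree: ", paste(missing, collapse = ", "))
  ingroup <- setdiff(tree$tip.label, outgroup_ids)
  ok <- length(outgroup_ids) == 1 ||
    ape::is.monophyletic(tree, outgroup_ids) ||
    ape::is.monophyletic(tree, ingroup)
  if (!ok)
    stop("outgroup is not monophyletic; conflicting leaves: ",
         paste(outgroup_ids, collapse = ", "))
  ape::root(tree, outgroup = outgroup_ids, resolve.root = TRUE,
            edgelabel = TRUE)
}

#' Write a square PHYLIP distance matrix
#'
#' @param dm Distance matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm)))
    writeLines(paste(formatC(rownames(dm)[i], width = -10),
                     paste(sprintf("%.8f", dm[i, ]), collapse = " ")), con)
  invisible(path)
}
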