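# Bottom-up agglomerative clustering from a distance matrix.
#
# Linkage distances are recomputed from the full distance matrix at every
# round (no Lance-Williams update): O(n^3), ample for a few hundred items,
# and literal with respect to the single/average/complete definitions.

.check_dist_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("expected a square distance matrix")
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("item", seq_len(nrow(d)))
  }
  d
}

#' Linkage distance between two clusters
#'
#' Distance between disjoint item sets under the three classical rules:
#' `single` = minimum, `average` = mean, `complete` = maximum over all
#' cross pairs.
#'
#' @param P,Q Disjoint non-empty sets of items, as labels or indices
#'   into `d`.
#' @param d Symmetric distance matrix with item labels as dimnames.
#' @param linkage `"single"`, `"average"` or `"complete"`.
#' @return Scalar linkage distance.
#' @export
cluster_linkage_distance <- function(P, Q, d,
                                     linkage = c("single", "average",
                                                 "complete")) {
  linkage <- match.arg(linkage)
  d <- .check_dist_matrix(d)
  idx <- function(x) if (is.character(x)) match(x, rownames(d)) else
    as.integer(x)
  pi <- idx(P); qi <- idx(Q)
  if (anyNA(pi) || anyNA(qi)) stop("unknown item label")
  if (length(pi) == 0L || length(qi) == 0L) stop("empty cluster")
  if (length(intersect(pi, qi)) > 0L) stop("clusters P and Q overlap")
  cross <- d[pi, qi, drop = FALSE]
  switch(linkage, single = min(cross), average = mean(cross),
         complete = max(cross))
}

#' Agglomerative hierarchical clustering
#'
#' Starts from singletons and repeatedly merges the pair of clusters with the
#' smallest linkage distance, recording that distance as the merge height,
#' until one root remains. Ties are broken deterministically by the
#' lexicographically smallest pair of cluster representative labels (the
#' representative of a cluster is its smallest member label), so permuting
#' the input rows yields an isomorphic tree.
#'
#' @param d Symmetric non-negative matrix with zero diagonal, labelled
#'   dimnames (e.g. from [kmer_distance_matrix()]).
#' @param linkage `"single"`, `"average"` or `"complete"`.
#' @return An object of class `hclust` (fields `merge`, `height`, `order`,
#'   `labels`, `method`), directly usable with [stats::cutree()],
#'   [stats::cophenetic()], `plot()` and [dendrogram_to_newick()].
#' @export
agglomerative_cluster <- function(d, linkage = c("single", "average",
                                                 "complete")) {
  linkage <- match.arg(linkage)
  d <- .check_dist_matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 items to cluster")
  labels <- rownames(d)

  members <- as.list(seq_len(n))       # leaf indices per active cluster
  node <- as.integer(-seq_len(n))      # hclust merge code per active cluster
  rep_lab <- labels                    # representative label per cluster

  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- length(members)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        cross <- d[members[[i]], members[[j]], drop = FALSE]
        dij <- switch(linkage, single = min(cross), average = mean(cross),
                      complete = max(cross))
        key <- sort(c(rep_lab[i], rep_lab[j]))
        if (is.null(best) || dij < best$d ||
            (dij == best$d && (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = dij, key = key)
        }
      }
    }
    merge[step, ] <- sort(c(node[best$i], node[best$j]))
    height[step] <- best$d
    members[[best$i]] <- c(members[[best$i]], members[[best$j]])
    node[best$i] <- step
    rep_lab[best$i] <- min(rep_lab[best$i], rep_lab[best$j])
    members[[best$j]] <- NULL
    node <- node[-best$j]
    rep_lab <- rep_lab[-best$j]
  }

  structure(
    list(merge = merge, height = height, order = .leaf_order(merge, n),
         labels = labels, method = linkage,
         call = match.call(), dist.method = attr(d, "metric")),
    class = "hclust")
}

# left-to-right leaf ordering from a merge matrix (for plotting/validity)
.leaf_order <- function(merge, n) {
  res <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    kids <- merge[i, ]
    res[[i]] <- unlist(lapply(kids, function(x)
      if (x < 0) -x else res[[x]]))
  }
  as.integer(res[[n - 1L]])
}

#' Export a dendrogram as a Newick string
#'
#' Converts the merge tree to a rooted `phylo` object (branch lengths derived
#' from merge-height differences) and writes Newick. The string round-trips
#' through [ape::read.tree()] with topology preserved.
#'
#' @param tree An `hclust` object (from [agglomerative_cluster()] or
#'   [random_binary_tree()]).
#' @param file Optional path; when given the Newick string is also written
#'   there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
dendrogram_to_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  nwk <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(nwk, file)
    return(invisible(nwk))
  }
  nwk
}
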