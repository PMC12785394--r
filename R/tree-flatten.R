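# Rand-optimal conversion of a dendrogram into a flat clustering.
#
# Among all partitions whose clusters are leaf sets of tree nodes
# ("tree-consistent" partitions), the dynamic program below returns one that
# maximizes the Rand index against the reference classification. The Rand
# numerator TP + TN decomposes over clusters: making a subtree one cluster
# contributes its same-class pairs (as TP) and removes its different-class
# pairs (from TN), so each node carries an integer gain and the optimum is a
# max over independent child subproblems.

#' Rand gain of merging a subtree into one cluster
#'
#' For a leaf multiset with per-class counts `m_c` (total `M`), the change in
#' TP + TN relative to keeping all leaves apart:
#' `2 * sum_c choose(m_c, 2) - choose(M, 2)` (same-class pairs minus
#' different-class pairs).
#'
#' @param class_counts Integer vector of per-class leaf counts (zeros
#'   allowed).
#' @return Integer gain; 0 for a single leaf, positive when same-class pairs
#'   dominate.
#' @export
subtree_gain <- function(class_counts) {
  m <- as.numeric(class_counts)
  M <- sum(m)
  if (M < 1) stop("empty subtree")
  2 * sum(choose(m, 2)) - choose(M, 2)
}

# reference as a named vector item -> class; returns factor aligned to items
.ref_classes <- function(ref, items) {
  if (is.null(names(ref))) stop("reference classification must be named")
  miss <- setdiff(items, names(ref))
  if (length(miss) > 0L)
    stop("items missing from reference classification: ",
         paste(utils::head(miss, 5), collapse = ", "))
  factor(as.character(ref[items]))
}

# core DP on an hclust merge matrix; class_idx = integer class per leaf.
# Returns list(assign = integer cluster per leaf, score = root score).
.flatten_merge <- function(merge, class_idx, n_class) {
  n <- nrow(merge) + 1L
  counts <- matrix(0, nrow(merge), n_class)
  size <- numeric(nrow(merge))
  score <- numeric(nrow(merge))
  merged <- logical(nrow(merge))

  child_counts <- function(x) {
    if (x < 0) {
      v <- numeric(n_class); v[class_idx[-x]] <- 1; v
    } else counts[x, ]
  }
  child_score <- function(x) if (x < 0) 0 else score[x]

  for (v in seq_len(nrow(merge))) {
    a <- merge[v, 1L]; b <- merge[v, 2L]
    cc <- child_counts(a) + child_counts(b)
    counts[v, ] <- cc
    size[v] <- sum(cc)
    g <- 2 * sum(choose(cc, 2)) - choose(size[v], 2)
    cs <- child_score(a) + child_score(b)
    merged[v] <- g >= cs      # merge preferred on ties (fewer clusters)
    score[v] <- max(g, cs)
  }

  assign <- integer(n)
  next_id <- 0L
  # pre-order walk from the root; chosen nodes become clusters
  stack <- nrow(merge)
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v < 0) {
      next_id <- next_id + 1L
      assign[-v] <- next_id
    } else if (merged[v]) {
      next_id <- next_id + 1L
      assign[.merge_leaves(merge, v)] <- next_id
    } else {
      # push right then left so the left child is visited first
      stack <- c(stack, merge[v, 2L], merge[v, 1L])
    }
  }
  list(assign = assign, score = score[nrow(merge)])
}

# leaf indices under internal node v of a merge matrix
.merge_leaves <- function(merge, v) {
  out <- integer(0)
  stack <- v
  while (length(stack) > 0L) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (x < 0) out <- c(out, -x) else stack <- c(stack, merge[x, ])
  }
  out
}

#' Rand-optimal flat clustering of a dendrogram
#'
#' Converts a binary merge tree into the flat clustering, among all
#' tree-consistent partitions, that maximizes the Rand index against a
#' reference classification. Exact dynamic program: `score(leaf) = 0`,
#' `score(v) = max(gain(v), score(left) + score(right))`; a node becomes one
#' cluster iff its gain reaches its children's summed score (merging
#' preferred on ties). Two same-class sibling leaves therefore always share
#' a label, while a leaf whose sibling belongs to another class can open a
#' new cluster of its own.
#'
#' @param tree An `hclust` object.
#' @param ref Named vector mapping every leaf label to its reference class.
#' @return Named integer vector: cluster id (dense, assigned in pre-order)
#'   per leaf label, with attribute `score` = the DP root score
#'   (TP + TN above the all-singleton baseline).
#' @export
optimal_flat_clustering <- function(tree, ref) {
  stopifnot(inherits(tree, "hclust"))
  items <- tree$labels
  cls <- .ref_classes(ref, items)
  res <- .flatten_merge(tree$merge, as.integer(cls), nlevels(cls))
  structure(stats::setNames(res$assign, items), score = res$score)
}

#' Enumerate all tree-consistent partitions
#'
#' Every partition of the leaves into leaf sets of non-overlapping tree nodes
#' (each antichain covering all leaves), yielded exactly once. Brute-force
#' companion of [optimal_flat_clustering()]; guarded to small trees.
#'
#' @param tree An `hclust` object with at most 16 leaves.
#' @return List of partitions; each partition is a list of character vectors
#'   of leaf labels.
#' @export
enumerate_tree_partitions <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  if (n > 16L) stop("enumeration guarded to <= 16 leaves (got ", n, ")")
  merge <- tree$merge
  labels <- tree$labels
  parts_of <- function(x) {
    if (x < 0) return(list(list(labels[-x])))
    left <- parts_of(merge[x, 1L])
    right <- parts_of(merge[x, 2L])
    out <- vector("list", length(left) * length(right) + 1L)
    pos <- 0L
    for (pl in left) for (pr in right) {
      pos <- pos + 1L
      out[[pos]] <- c(pl, pr)
    }
    out[[pos + 1L]] <- list(labels[.merge_leaves(merge, x)])
    out
  }
  parts_of(nrow(merge))
}
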