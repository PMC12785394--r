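# Abundant-k-mer intersection and within/between-group average distances.

#' Most abundant k-mers shared across vectors
#'
#' For each vector, takes its top `round(top_pct/100 * n)` most frequent
#' k-mer types (ties broken by ascending k-mer index, as in
#' [top_kmer_set()]), then keeps the k-mers appearing in at least
#' `ceiling(common_pct/100 * n_vectors)` of these top sets.
#'
#' @param vectors Non-empty list of `kmer_vector`s of one spec.
#' @param top_pct Top-fraction percentage `I_t` in (0, 100), e.g. 5, 10, 15.
#' @param common_pct Commonality percentage `I_c` in (0, 100], e.g. 90, 100.
#' @return List with `kmers` (sorted integer k-mer indices), `count`
#'   (their number), `top_set_size` (size of each per-vector top set) and
#'   `min_vectors` (the absolute commonality threshold used).
#' @export
common_abundant_kmers <- function(vectors, top_pct = 10, common_pct = 90) {
  stopifnot(is.list(vectors), length(vectors) >= 1L)
  stopifnot(top_pct > 0, top_pct < 100, common_pct > 0, common_pct <= 100)
  a <- top_pct / 100
  sets <- lapply(vectors, top_kmer_set, a = a)
  s <- attr(sets[[1]], "s")
  need <- ceiling(common_pct / 100 * length(vectors))
  hits <- table(unlist(sets))
  kmers <- sort(as.integer(names(hits)[hits >= need]))
  list(kmers = kmers, count = length(kmers), top_set_size = s,
       min_vectors = as.integer(need))
}

#' Average within-group distance
#'
#' Mean pairwise distance over all unordered distinct pairs of a group:
#' `2 * sum_{p < q} d(p, q) / (N (N - 1))`. A 2-element group yields its
#' single pairwise distance.
#'
#' @param group List of at least 2 `kmer_vector`s.
#' @param metric,a,b Metric selector as in [kmer_distance_matrix()].
#' @return Scalar mean distance.
#' @export
within_group_distance <- function(group, metric = "l1", a = NULL, b = NULL) {
  N <- length(group)
  if (N < 2L) stop("within-group distance needs at least 2 members")
  m <- .metric_fun(metric, a = a, b = b)
  tot <- 0
  for (i in seq_len(N - 1L))
    for (j in (i + 1L):N)
      tot <- tot + m$fun(group[[i]], group[[j]])
  2 * tot / (N * (N - 1))
}

#' Average between-group distance
#'
#' Mean distance over all cross pairs of two groups:
#' `sum_{p in Qi, q in Qj} d(p, q) / (N_i * N_j)`.
#'
#' @param group_i,group_j Non-empty lists of `kmer_vector`s.
#' @inheritParams within_group_distance
#' @return Scalar mean distance.
#' @export
between_group_distance <- function(group_i, group_j, metric = "l1",
                                   a = NULL, b = NULL) {
  if (length(group_i) == 0L || length(group_j) == 0L)
    stop("between-group distance needs two non-empty groups")
  m <- .metric_fun(metric, a = a, b = b)
  tot <- 0
  for (p in group_i) for (q in group_j) tot <- tot + m$fun(p, q)
  tot / (length(group_i) * length(group_j))
}

#' Group-separation report
#'
#' Within-group distances `D_i` for every group, all pairwise between-group
#' distances `D_ij`, their means and standard deviations, and the separation
#' margin `(m_between - sd_between) - (m_within + sd_within)`. A positive
#' margin means the groups remain separated even when both statistics are
#' pushed one standard deviation towards each other -- the cloud of each
#' group is tighter than the spacing between clouds.
#'
#' @param grouped Named list: group label -> list of `kmer_vector`s (each
#'   group needs >= 2 members for its within-group distance; >= 2 groups).
#' @inheritParams within_group_distance
#' @return List with `within` (named vector of D_i), `between` (symmetric
#'   matrix of D_ij with NA diagonal), `within_mean`, `within_sd`,
#'   `between_mean`, `between_sd`, `margin` and `degenerate` (TRUE when all
#'   distances are zero).
#' @export
group_separation_report <- function(grouped, metric = "l1", a = NULL,
                                    b = NULL) {
  stopifnot(is.list(grouped), length(grouped) >= 2L)
  labs <- names(grouped)
  if (is.null(labs) || any(!nzchar(labs)))
    stop("grouped must be a named list of groups")
  within <- vapply(grouped, within_group_distance, numeric(1),
                   metric = metric, a = a, b = b)
  g <- length(grouped)
  between <- matrix(NA_real_, g, g, dimnames = list(labs, labs))
  for (i in seq_len(g - 1L)) {
    for (j in (i + 1L):g) {
      between[i, j] <- between[j, i] <-
        between_group_distance(grouped[[i]], grouped[[j]],
                               metric = metric, a = a, b = b)
    }
  }
  bvals <- between[upper.tri(between)]
  wm <- mean(within)
  ws <- if (length(within) < 2L) 0 else stats::sd(within)
  bm <- mean(bvals)
  bs <- if (length(bvals) < 2L) 0 else stats::sd(bvals)
  list(within = within, between = between,
       within_mean = wm, within_sd = ws,
       between_mean = bm, between_sd = bs,
       margin = (bm - bs) - (wm + ws),
       degenerate = all(within == 0) && all(bvals == 0))
}
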