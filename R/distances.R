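# Distance functions between k-mer frequency vectors and distance matrices.

# round-half-up; base round() is banker's rounding
.round_half_up <- function(x) floor(x + 0.5)

#' General Minkowski-family distance
#'
#' Computes `(sum_i |p_i - q_i|^b)^(1/a)`. The two parameters are exposed
#' independently; `a = b = 1` is the L1 (Manhattan) distance and `a = b = 2`
#' the L2 (Euclidean) distance, the two settings used for proteome
#' comparison. L1 between probability vectors lies in [0, 2].
#'
#' @param p,q `kmer_vector`s (or bare numeric vectors) of equal dimension.
#' @param a,b Positive reals: outer-root and inner-exponent parameters.
#' @return Non-negative scalar distance.
#' @examples
#' minkowski_distance(c(1, 0), c(0, 1), 1, 1)  # 2
#' minkowski_distance(c(1, 0), c(0, 1), 2, 2)  # sqrt(2)
#' @export
minkowski_distance <- function(p, q, a = 1, b = 1) {
  pv <- .vec_values(p); qv <- .vec_values(q)
  if (length(pv) != length(qv))
    stop("dimension mismatch: ", length(pv), " vs ", length(qv))
  stopifnot(a > 0, b > 0)
  sum(abs(pv - qv)^b)^(1 / a)
}

#' Pearson-correlation distance
#'
#' `(1 - r) / 2` with `r` the Pearson correlation of the two frequency
#' vectors, mapping r in [-1, 1] to a distance in [0, 1] (0 for identical,
#' 1 for perfectly anti-correlated vectors).
#'
#' @inheritParams minkowski_distance
#' @return Distance in [0, 1]. A constant (zero-variance) vector is an error:
#'   its correlation is undefined.
#' @export
correlation_distance <- function(p, q) {
  pv <- .vec_values(p); qv <- .vec_values(q)
  if (length(pv) != length(qv))
    stop("dimension mismatch: ", length(pv), " vs ", length(qv))
  if (length(pv) < 2L) stop("correlation needs dimension >= 2")
  if (stats::sd(pv) == 0 || stats::sd(qv) == 0)
    stop("correlation distance undefined for a constant vector")
  (1 - stats::cor(pv, qv)) / 2
}

#' Top-fraction k-mer set
#'
#' The indices of the `round(a * n)` most frequent k-mer types of a vector.
#' Ties at the cutoff are broken by ascending k-mer index, so the set is
#' deterministic and stable under the canonical alphabet order.
#'
#' @param v A `kmer_vector` or numeric vector.
#' @param a Fraction in (0, 1) of the `n` k-mer types to keep.
#' @return Integer vector of k-mer indices (sorted ascending), with
#'   attribute `s` = its exact size.
#' @export
top_kmer_set <- function(v, a) {
  vals <- .vec_values(v)
  n <- length(vals)
  stopifnot(a > 0, a < 1)
  s <- .round_half_up(a * n)
  if (s < 1) stop("a * n rounds to zero; no k-mers would be selected")
  o <- order(-vals, seq_len(n))
  members <- sort(o[seq_len(s)])
  attr(members, "s") <- as.integer(s)
  members
}

#' Top-set intersection distance
#'
#' `1 - |P_a intersect Q_a| / s` where `P_a`, `Q_a` are the two vectors'
#' top-`round(a*n)` k-mer sets and `s = round(a*n)`: 0 when the top sets
#' coincide, 1 when they are disjoint. (The underlying overlap fraction
#' `|P_a intersect Q_a| / (a n)` is a similarity; it is flipped so that
#' smaller means more alike, as distance-based clustering requires.)
#'
#' @inheritParams minkowski_distance
#' @param a Top-set fraction in (0, 1); 0.1 and 0.05 are the conventional
#'   settings for proteome comparison.
#' @return Distance in [0, 1].
#' @export
intersection_distance <- function(p, q, a = 0.1) {
  pv <- .vec_values(p); qv <- .vec_values(q)
  if (length(pv) != length(qv))
    stop("dimension mismatch: ", length(pv), " vs ", length(qv))
  ps <- top_kmer_set(pv, a)
  qs <- top_kmer_set(qv, a)
  1 - length(intersect(ps, qs)) / attr(ps, "s")
}

# resolve a metric selector to (function(p, q), tag)
.metric_fun <- function(metric = c("l1", "l2", "minkowski", "corr", "inter"),
                        a = NULL, b = NULL) {
  metric <- match.arg(metric)
  switch(metric,
    l1 = list(fun = function(p, q) minkowski_distance(p, q, 1, 1),
              tag = "l1"),
    l2 = list(fun = function(p, q) minkowski_distance(p, q, 2, 2),
              tag = "l2"),
    minkowski = {
      stopifnot(!is.null(a), !is.null(b))
      force(a); force(b)
      list(fun = function(p, q) minkowski_distance(p, q, a, b),
           tag = sprintf("minkowski(a=%g,b=%g)", a, b))
    },
    corr = list(fun = correlation_distance, tag = "corr"),
    inter = {
      if (is.null(a)) a <- 0.1
      force(a)
      list(fun = function(p, q) intersection_distance(p, q, a),
           tag = sprintf("inter_%g", a))
    })
}

#' Pairwise distance matrix over labelled k-mer vectors
#'
#' @param vectors Named list of `kmer_vector`s (>= 2, same spec/dimension).
#' @param metric One of `"l1"`, `"l2"`, `"minkowski"`, `"corr"`, `"inter"`.
#' @param a,b Metric parameters: outer/inner exponents for `"minkowski"`,
#'   top-set fraction for `"inter"` (default 0.1).
#' @return Symmetric numeric matrix with zero diagonal, `dimnames` from the
#'   list names and attribute `metric` recording the metric tag.
#' @export
kmer_distance_matrix <- function(vectors, metric = "l1", a = NULL, b = NULL) {
  stopifnot(is.list(vectors), length(vectors) >= 2L)
  ids <- names(vectors)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("vectors must be a named list with unique non-empty names")
  dims <- vapply(vectors, function(v) length(.vec_values(v)), integer(1))
  if (length(unique(dims)) != 1L)
    stop("all vectors must share one dimension")
  m <- .metric_fun(metric, a = a, b = b)
  nv <- length(vectors)
  d <- matrix(0, nv, nv, dimnames = list(ids, ids))
  for (i in seq_len(nv - 1L)) {
    for (j in (i + 1L):nv) {
      dij <- tryCatch(m$fun(vectors[[i]], vectors[[j]]), error = function(e)
        stop("metric failed for pair (", ids[i], ", ", ids[j], "): ",
             conditionMessage(e), call. = FALSE))
      d[i, j] <- d[j, i] <- dij
    }
  }
  attr(d, "metric") <- m$tag
  d
}

#' Serialize / read a distance matrix as JSON
#'
#' Plain-text exchange format: `{"ids": [...], "metric": "...",
#' "matrix": [[...]]}`.
#'
#' @param d Matrix from [kmer_distance_matrix()].
#' @param path Output / input file path.
#' @return `read_distance_matrix_json()` returns the matrix with its
#'   `metric` attribute restored.
#' @export
write_distance_matrix_json <- function(d, path) {
  jsonlite::write_json(
    list(ids = rownames(d),
         metric = if (is.null(attr(d, "metric"))) "unknown"
                  else attr(d, "metric"),
         matrix = unname(d)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_distance_matrix_json
#' @export
read_distance_matrix_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- as.matrix(obj$matrix)
  dimnames(d) <- list(obj$ids, obj$ids)
  attr(d, "metric") <- obj$metric
  d
}
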