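# Rand index, random-tree null distribution, Student-t fit, significance.

# align two named partitions over one item domain -> list of two factors
.align_partitions <- function(x, y) {
  if (is.null(names(x)) || is.null(names(y))) {
    if (length(x) != length(y))
      stop("unnamed partitions must have equal length")
    return(list(factor(as.character(x)), factor(as.character(y))))
  }
  if (!setequal(names(x), names(y)))
    stop("partitions cover different item sets")
  items <- names(x)
  list(factor(as.character(x[items])), factor(as.character(y[items])))
}

#' Pair-level contingency counts of two partitions
#'
#' Over all unordered item pairs: `TP` together in both partitions, `FP`
#' together in the clustering but split in the reference, `FN` split in the
#' clustering but together in the reference, `TN` split in both. The four
#' counts always sum to `choose(N, 2)`.
#'
#' @param clustering,ref Named vectors (same item names) giving cluster /
#'   class labels.
#' @return List with integer components `TP`, `FP`, `FN`, `TN`.
#' @export
pair_counts <- function(clustering, ref) {
  p <- .align_partitions(clustering, ref)
  tab <- table(p[[1]], p[[2]])
  same_both <- sum(choose(tab, 2))
  same_clus <- sum(choose(rowSums(tab), 2))
  same_class <- sum(choose(colSums(tab), 2))
  total <- choose(sum(tab), 2)
  list(TP = same_both,
       FP = same_clus - same_both,
       FN = same_class - same_both,
       TN = total - same_clus - same_class + same_both)
}

#' Rand index of a clustering against a reference classification
#'
#' Fraction of unordered item pairs on which the two partitions agree
#' (placed together in both, or apart in both):
#' `(TP + TN) / (TP + FP + FN + TN)`, in [0, 1], with 1 iff the partitions
#' coincide up to label renaming.
#'
#' @inheritParams pair_counts
#' @return Scalar in [0, 1].
#' @export
rand_index <- function(clustering, ref) {
  pc <- pair_counts(clustering, ref)
  (pc$TP + pc$TN) / (pc$TP + pc$FP + pc$FN + pc$TN)
}

#' Uniform random binary merge tree
#'
#' Starts with every leaf its own root and repeatedly joins two roots chosen
#' uniformly at random (without replacement) until one root remains --
#' an exchangeable coalescent-style join process. Merge heights are the join
#' step indices 1, 2, ..., N-1.
#'
#' @param leaf_labels Character vector of at least 2 leaf labels.
#' @param seed Optional integer; when given the draw is made under this seed
#'   without disturbing the caller's RNG state.
#' @return An `hclust` object.
#' @export
random_binary_tree <- function(leaf_labels, seed = NULL) {
  n <- length(leaf_labels)
  if (n < 2L) stop("need at least 2 leaves")
  draw <- function() {
    roots <- -seq_len(n)
    merge <- matrix(0L, n - 1L, 2L)
    for (step in seq_len(n - 1L)) {
      pick <- sample.int(length(roots), 2L)
      merge[step, ] <- sort(roots[pick])
      roots <- c(roots[-pick], step)
    }
    merge
  }
  merge <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(
    list(merge = merge, height = as.numeric(seq_len(n - 1L)),
         order = .leaf_order(merge, n), labels = as.character(leaf_labels),
         method = "random_join"),
    class = "hclust")
}

# location-scale Student-t MLE on standardized samples (MASS::fitdistr);
# returns list(loc, scale, df) on the original scale, or NAs on failure
.fit_t <- function(x) {
  mu <- mean(x); sdev <- stats::sd(x)
  z <- (x - mu) / sdev
  fit <- NULL
  for (df0 in c(8, 4, 20)) {
    fit <- tryCatch(
      suppressWarnings(MASS::fitdistr(z, "t",
                                      start = list(m = 0, s = 0.9, df = df0),
                                      lower = c(-Inf, 1e-8, 1))),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    return(list(loc = NA_real_, scale = NA_real_, df = NA_real_))
  est <- fit$estimate
  list(loc = mu + est[["m"]] * sdev, scale = est[["s"]] * sdev,
       df = est[["df"]])
}

#' Critical value of a location-scale Student t
#'
#' Upper-tail critical value `loc + scale * qt(1 - alpha, df)`. The spread
#' may be given either as the t scale parameter itself or as a sample
#' standard deviation, which is converted via
#' `scale = sd * sqrt((df - 2) / df)` (valid for `df > 2`).
#'
#' @param loc Location of the fitted t.
#' @param spread Scale parameter or sample standard deviation (see
#'   `spread_is`).
#' @param df Degrees of freedom.
#' @param alpha Right-tail significance level (default 0.05).
#' @param spread_is `"sd"` (default) or `"scale"`.
#' @return The critical value.
#' @export
t_critical_value <- function(loc, spread, df, alpha = 0.05,
                             spread_is = c("sd", "scale")) {
  spread_is <- match.arg(spread_is)
  scale <- if (spread_is == "sd") {
    if (df <= 2) stop("sd -> scale conversion needs df > 2")
    spread * sqrt((df - 2) / df)
  } else spread
  loc + scale * stats::qt(1 - alpha, df)
}

#' Random-tree null distribution of the Rand index
#'
#' Calibrates how large a Rand index arises by chance: for each of `n_trees`
#' uniform random binary trees over the reference's items, the tree is
#' flattened with the Rand-maximizing conversion and its Rand index against
#' the reference recorded. A location-scale Student t is fitted to the
#' samples by maximum likelihood and the upper `1 - alpha` critical value
#' derived from the fit. Because the flattening itself maximizes Rand, the
#' null is concentrated close to (but below) the values of genuinely
#' informative trees, which is exactly why this calibration is needed.
#'
#' @param ref Named vector mapping item label to reference class (>= 2
#'   items).
#' @param n_trees Number of random trees (>= 100).
#' @param alpha Right-tail significance level.
#' @param seed Integer seed; the draw leaves the caller's RNG untouched.
#' @return An object of class `rand_null` with fields `samples`, `n_trees`,
#'   `mean`, `sd`, `fitted_loc`, `fitted_scale`, `fitted_df`,
#'   `critical_value`, `alpha`, `seed`. If the samples are degenerate
#'   (zero spread) the fit fields are `NA` and the critical value equals the
#'   common sample value.
#' @export
null_rand_distribution <- function(ref, n_trees = 10000, alpha = 0.05,
                                   seed = 1L) {
  if (length(ref) < 2L) stop("reference must contain at least 2 items")
  if (n_trees < 100L) stop("n_trees must be at least 100")
  items <- names(ref)
  if (is.null(items)) stop("reference classification must be named")
  cls <- factor(as.character(ref))
  class_idx <- as.integer(cls)
  n_class <- nlevels(cls)
  n <- length(items)
  total_pairs <- choose(n, 2)

  samples <- withr::with_seed(seed, {
    vapply(seq_len(n_trees), function(i) {
      roots <- -seq_len(n)
      merge <- matrix(0L, n - 1L, 2L)
      for (step in seq_len(n - 1L)) {
        pick <- sample.int(length(roots), 2L)
        merge[step, ] <- sort(roots[pick])
        roots <- c(roots[-pick], step)
      }
      res <- .flatten_merge(merge, class_idx, n_class)
      # honest Rand of the returned partition (not the DP identity)
      key <- (res$assign - 1L) * n_class + class_idx
      nij <- tabulate(key, nbins = max(res$assign) * n_class)
      tabm <- matrix(nij, ncol = n_class, byrow = TRUE)
      tp <- sum(choose(tabm, 2))
      same_clus <- sum(choose(rowSums(tabm), 2))
      same_class <- sum(choose(colSums(tabm), 2))
      (tp + (total_pairs - same_clus - same_class + tp)) / total_pairs
    }, numeric(1))
  })

  sdev <- stats::sd(samples)
  if (sdev == 0) {
    fit <- list(loc = NA_real_, scale = NA_real_, df = NA_real_)
    crit <- samples[1]
  } else {
    fit <- .fit_t(samples)
    crit <- if (is.na(fit$df)) stats::quantile(samples, 1 - alpha,
                                               names = FALSE)
            else t_critical_value(fit$loc, fit$scale, fit$df, alpha,
                                  spread_is = "scale")
  }
  structure(
    list(samples = samples, n_trees = as.integer(n_trees),
         mean = mean(samples), sd = sdev,
         fitted_loc = fit$loc, fitted_scale = fit$scale, fitted_df = fit$df,
         critical_value = crit, alpha = alpha, seed = as.integer(seed)),
    class = "rand_null")
}

#' @export
print.rand_null <- function(x, ...) {
  cat(sprintf(paste0("rand_null: %d random trees, mean = %.4f, sd = %.4f\n",
                     "  t fit: loc = %.4f, scale = %.2g, df = %.2f\n",
                     "  critical value (alpha = %g): %.4f\n"),
              x$n_trees, x$mean, x$sd, x$fitted_loc, x$fitted_scale,
              x$fitted_df, x$alpha, x$critical_value))
  invisible(x)
}

#' Significance of an observed Rand index against the random-tree null
#'
#' Right-sided test: the observed value is significant iff it strictly
#' exceeds the null's critical value. The p-value from the fitted t is
#' reported alongside the empirical tail fraction for transparency.
#'
#' @param observed_rand Observed Rand index in [0, 1].
#' @param null A `rand_null` from [null_rand_distribution()].
#' @return List with `significant` (logical), `p_fitted`, `p_empirical` and
#'   the null's `critical_value`.
#' @export
significance_test <- function(observed_rand, null) {
  stopifnot(inherits(null, "rand_null"))
  p_fit <- if (is.na(null$fitted_df)) NA_real_ else
    stats::pt((observed_rand - null$fitted_loc) / null$fitted_scale,
              null$fitted_df, lower.tail = FALSE)
  list(significant = observed_rand > null$critical_value,
       p_fitted = p_fit,
       p_empirical = mean(null$samples >= observed_rand),
       critical_value = null$critical_value)
}
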