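# Shared fixtures, built in code.

# random probability vector of dimension n
rand_prob_vec <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}

# random labelled distance matrix from points in R^m under L1 (a true metric,
# continuous entries so ties have probability zero)
rand_metric_matrix <- function(n, m = 3) {
  pts <- matrix(stats::runif(n * m), n)
  d <- as.matrix(stats::dist(pts, method = "manhattan"))
  dimnames(d) <- list(sprintf("it%02d", seq_len(n)),
                      sprintf("it%02d", seq_len(n)))
  d
}

# independent window-scan k-mer counting oracle (string operations only)
oracle_count_kmers <- function(sequence, spec) {
  k <- spec$k
  counts <- stats::setNames(integer(spec$n), kmer_strings(spec))
  nc <- nchar(sequence)
  if (nc >= k) {
    for (i in seq_len(nc - k + 1)) {
      w <- substr(sequence, i, i + k - 1)
      if (w %in% names(counts)) counts[w] <- counts[w] + 1L
    }
  }
  unname(counts)
}

# random amino-acid sequence, optionally salted with ambiguity characters
rand_aa_seq <- function(len, ambig_rate = 0) {
  pool <- protkmer:::AA20
  chars <- sample(pool, len, replace = TRUE)
  if (ambig_rate > 0) {
    hit <- stats::runif(len) < ambig_rate
    chars[hit] <- sample(c("X", "B", "Z", "U", "O", "*"), sum(hit),
                         replace = TRUE)
  }
  paste(chars, collapse = "")
}

# Rand index via e1071 (independent oracle)
oracle_rand <- function(clustering, ref) {
  items <- names(clustering)
  e1071::classAgreement(table(clustering[items], ref[items]))$rand
}

# brute-force best Rand over all tree-consistent partitions
oracle_best_tree_rand <- function(tree, ref) {
  parts <- enumerate_tree_partitions(tree)
  best <- -Inf
  for (p in parts) {
    cl <- integer(0)
    for (i in seq_along(p)) cl[p[[i]]] <- i
    best <- max(best, rand_index(cl, ref[names(cl)]))
  }
  best
}

# small synthetic dataset for I/O and pipeline tests
tiny_dataset <- function(seed = 11L, mu = 0.05) {
  generate_dataset(sim_config(n_clades = 3L, organisms_per_clade = 3L,
                              proteins_per_proteome = 30L,
                              protein_length = c(60L, 90L),
                              mutation_rate = mu, seed = seed))
}
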