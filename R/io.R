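# FASTA / metadata I/O, dataset assembly, and the end-to-end pipeline.
#
# Dataset exchange format: one protein FASTA per organism plus one metadata
# JSON with schema
#   {"schema_version": 1,
#    "organisms": [{"organism_id": ..., "fasta": ..., "clade": ...}, ...],
#    "protein_groups": {"<protein id>": ["membrane", ...], ...}}
# FASTA paths are resolved relative to the metadata file.

#' Write a synthetic dataset to FASTA + metadata JSON
#'
#' @param dataset A `synthetic_dataset` from [generate_dataset()] (or any
#'   list with `proteomes` and `reference` in the same shape).
#' @param dir Output directory (created if needed).
#' @return The metadata path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(is.list(dataset$proteomes), length(dataset$proteomes) >= 1L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  organisms <- list()
  groups <- list()
  for (pr in dataset$proteomes) {
    fasta <- paste0(pr$organism_id, ".fasta")
    seqs <- Biostrings::AAStringSet(
      vapply(pr$proteins, function(p) p$sequence, character(1)))
    names(seqs) <- vapply(pr$proteins, function(p) p$id, character(1))
    Biostrings::writeXStringSet(seqs, file.path(dir, fasta), width = 60)
    organisms[[length(organisms) + 1L]] <-
      list(organism_id = pr$organism_id, fasta = fasta, clade = pr$clade)
    for (p in pr$proteins)
      if (length(p$groups) > 0) groups[[p$id]] <- as.list(p$groups)
  }
  meta <- file.path(dir, "metadata.json")
  jsonlite::write_json(
    list(schema_version = 1L, organisms = organisms,
         protein_groups = groups),
    meta, auto_unbox = TRUE, pretty = TRUE)
  invisible(meta)
}

#' Read one proteome from a protein FASTA file
#'
#' One [protein_record()] per FASTA record; ids are the first whitespace
#' token of each header; sequences are upper-cased. Group labels and the
#' clade are attached later from metadata.
#'
#' @param path FASTA file path.
#' @param organism_id Organism id; defaults to the file name without
#'   extension.
#' @param clade Optional clade label.
#' @return A [proteome_record()].
#' @export
read_proteome_fasta <- function(path, organism_id = NULL,
                                clade = NA_character_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate protein ids in ", path)
  if (is.null(organism_id))
    organism_id <- sub("\\.[^.]*$", "", basename(path))
  proteins <- lapply(seq_along(seqs), function(i)
    protein_record(ids[i], toupper(as.character(seqs[[i]]))))
  proteome_record(organism_id, proteins, clade = clade)
}

#' Load a dataset from metadata JSON
#'
#' Reads every organism's FASTA, attaches clade and protein-group labels and
#' builds the reference classification. Distinct errors for a missing FASTA,
#' a duplicate organism id, and a group-map protein id that matches no
#' loaded protein.
#'
#' @param metadata_path Path to the metadata JSON written by
#'   [write_dataset()] (or hand-authored to the same schema).
#' @return List with `proteomes` (named list of [proteome_record()]s) and
#'   `reference` (named vector organism -> clade).
#' @export
load_dataset <- function(metadata_path) {
  if (!file.exists(metadata_path))
    stop("metadata file not found: ", metadata_path)
  meta <- jsonlite::read_json(metadata_path)
  base <- dirname(metadata_path)
  ids <- vapply(meta$organisms, function(o) o$organism_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate organism_id in metadata: ",
         ids[duplicated(ids)][1])
  groups <- lapply(meta$protein_groups, function(g)
    vapply(g, as.character, character(1)))
  seen <- character(0)
  proteomes <- list()
  reference <- character(0)
  for (o in meta$organisms) {
    fp <- file.path(base, o$fasta)
    if (!file.exists(fp))
      stop("FASTA file referenced by metadata not found: ", fp)
    pr <- read_proteome_fasta(fp, organism_id = o$organism_id,
                              clade = as.character(o$clade))
    pr$proteins <- lapply(pr$proteins, function(p) {
      if (!is.null(groups[[p$id]])) p$groups <- groups[[p$id]]
      p
    })
    seen <- c(seen, vapply(pr$proteins, function(p) p$id, character(1)))
    proteomes[[o$organism_id]] <- pr
    reference[o$organism_id] <- as.character(o$clade)
  }
  unknown <- setdiff(names(groups), seen)
  if (length(unknown) > 0)
    stop("protein_groups refers to unknown protein id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  list(proteomes = proteomes, reference = reference)
}

#' Run the full proteome-clustering pipeline
#'
#' Vectorize -> distance matrix -> agglomerative clustering -> Rand-optimal
#' flattening -> Rand index, optionally followed by the random-tree null
#' test. Deterministic given `seed`.
#'
#' @param proteomes Named list of [proteome_record()]s, or a
#'   `synthetic_dataset` (its `proteomes`/`reference` are used and
#'   `reference` may be omitted).
#' @param reference Named vector organism -> clade.
#' @param k k-mer length (1--3 is the supported analysis grid).
#' @param alphabet `"aa20"` or `"reduced5"`.
#' @param groups,exclude_groups Optional protein-group filter passed to
#'   [proteome_vector()] (e.g. `groups = "ribosomal"`).
#' @param metric,a,b Metric selector as in [kmer_distance_matrix()].
#' @param linkage Linkage rule for [agglomerative_cluster()].
#' @param alpha Significance level for the null test.
#' @param n_null_trees Number of random trees for the null distribution;
#'   0 skips the significance test.
#' @param seed Integer seed (used by the null model).
#' @return List of class `pipeline_report`: parameters, `newick`,
#'   `clustering`, `rand`, `n_clusters`, and (when the null model runs)
#'   `null_mean`, `null_sd`, `critical_value`, `significant`, `p_fitted`,
#'   `p_empirical`.
#' @export
run_pipeline <- function(proteomes, reference = NULL, k = 3,
                         alphabet = "aa20", groups = NULL,
                         exclude_groups = FALSE, metric = "l1",
                         a = NULL, b = NULL,
                         linkage = "average", alpha = 0.05,
                         n_null_trees = 0, seed = 1L) {
  if (inherits(proteomes, "synthetic_dataset")) {
    if (is.null(reference)) reference <- proteomes$reference
    proteomes <- proteomes$proteomes
  }
  stopifnot(is.list(proteomes), length(proteomes) >= 2L,
            !is.null(reference))
  spec <- kmer_spec(k, alphabet)
  vectors <- lapply(proteomes, proteome_vector, spec = spec,
                    groups = groups, exclude = exclude_groups)
  names(vectors) <- vapply(proteomes, function(p) p$organism_id,
                           character(1))
  .pipeline_from_vectors(vectors, reference, metric, a, b, linkage,
                         alpha, n_null_trees, seed,
                         params = list(k = k, alphabet = alphabet,
                                       groups = groups,
                                       exclude_groups = exclude_groups))
}

.pipeline_from_vectors <- function(vectors, reference, metric, a, b,
                                   linkage, alpha, n_null_trees, seed,
                                   params) {
  d <- kmer_distance_matrix(vectors, metric = metric, a = a, b = b)
  tree <- agglomerative_cluster(d, linkage = linkage)
  clustering <- optimal_flat_clustering(tree, reference)
  rand <- rand_index(clustering, reference[names(clustering)])
  report <- c(params,
              list(metric = attr(d, "metric"), linkage = linkage,
                   seed = as.integer(seed),
                   newick = dendrogram_to_newick(tree),
                   clustering = clustering,
                   n_clusters = max(clustering),
                   rand = rand))
  if (n_null_trees > 0) {
    null <- null_rand_distribution(reference[names(clustering)],
                                   n_trees = n_null_trees,
                                   alpha = alpha, seed = seed)
    sig <- significance_test(rand, null)
    report <- c(report,
                list(null_mean = null$mean, null_sd = null$sd,
                     critical_value = null$critical_value,
                     significant = sig$significant,
                     p_fitted = sig$p_fitted,
                     p_empirical = sig$p_empirical))
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(paste0("pipeline_report: k = %s, alphabet = %s, metric = %s,",
                     " linkage = %s\n  Rand = %.4f (%d clusters)\n"),
              x$k, x$alphabet, x$metric, x$linkage, x$rand, x$n_clusters))
  if (!is.null(x$significant))
    cat(sprintf("  null mean = %.4f, critical value = %.4f, %s\n",
                x$null_mean, x$critical_value,
                if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' The standard analysis parameter grid
#'
#' All combinations of k in 1..3, both alphabets, the five metrics (L1, L2,
#' correlation, intersection at a = 0.1 and 0.05) and the three linkages,
#' optionally crossed with protein-group selections.
#'
#' Combinations for which the metric is undefined on the representation are
#' dropped: an intersection distance needs a top set of at least one k-mer,
#' which `inter_0.05` lacks at k = 1 on the 5-symbol alphabet
#' (`round(0.05 * 5) = 0`).
#'
#' @param groups Character vector of group selectors; `NA` means the whole
#'   proteome, a label prefixed with `"non_"` means the complement.
#' @return Data frame with one row per parameter combination.
#' @export
default_parameter_grid <- function(groups = NA_character_) {
  g <- expand.grid(k = 1:3, alphabet = c("aa20", "reduced5"),
                   metric = c("l1", "l2", "corr", "inter_0.1", "inter_0.05"),
                   linkage = c("single", "average", "complete"),
                   group = groups,
                   stringsAsFactors = FALSE)
  n <- ifelse(g$alphabet == "aa20", 20, 5)^g$k
  afrac <- rep(NA_real_, nrow(g))
  is_inter <- grepl("^inter_", g$metric)
  afrac[is_inter] <- as.numeric(sub("^inter_", "", g$metric[is_inter]))
  ok <- is.na(afrac) | .round_half_up(afrac * n) >= 1
  g[ok, , drop = FALSE]
}

# parse "inter_0.1"-style metric labels -> list(metric, a)
.parse_metric <- function(m) {
  if (grepl("^inter_", m))
    list(metric = "inter", a = as.numeric(sub("^inter_", "", m)))
  else list(metric = m, a = NULL)
}

# parse group selector: NA -> none, "non_x" -> complement of x
.parse_group <- function(g) {
  if (is.na(g)) return(list(groups = NULL, exclude = FALSE))
  if (grepl("^non_", g))
    list(groups = sub("^non_", "", g), exclude = TRUE)
  else list(groups = g, exclude = FALSE)
}

#' Parameter sweep over the analysis grid
#'
#' Runs the pipeline for every grid row, sharing cached proteome vectors
#' across rows with the same (k, alphabet, group) so the expensive counting
#' happens once per representation.
#'
#' @param proteomes Named list of [proteome_record()]s or a
#'   `synthetic_dataset`.
#' @param reference Named vector organism -> clade.
#' @param grid Data frame with columns `k`, `alphabet`, `metric`, `linkage`
#'   and optionally `group` (see [default_parameter_grid()]).
#' @param seed Integer seed recorded in each run.
#' @return The grid, one row per combination, with a `rand` column, sorted
#'   by descending Rand (ties by parameter order).
#' @export
parameter_sweep <- function(proteomes, reference = NULL, grid =
                              default_parameter_grid(), seed = 1L) {
  if (inherits(proteomes, "synthetic_dataset")) {
    if (is.null(reference)) reference <- proteomes$reference
    proteomes <- proteomes$proteomes
  }
  if (is.null(grid$group)) grid$group <- NA_character_
  cache <- new.env(parent = emptyenv())
  get_vectors <- function(k, alphabet, group) {
    key <- paste(k, alphabet, group, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    spec <- kmer_spec(k, alphabet)
    gf <- .parse_group(group)
    v <- lapply(proteomes, proteome_vector, spec = spec,
                groups = gf$groups, exclude = gf$exclude)
    names(v) <- vapply(proteomes, function(p) p$organism_id, character(1))
    cache[[key]] <- v
    v
  }
  grid$rand <- vapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    mt <- .parse_metric(row$metric)
    rep <- tryCatch(
      .pipeline_from_vectors(get_vectors(row$k, row$alphabet, row$group),
                             reference, mt$metric, mt$a, NULL,
                             row$linkage, 0.05, 0, seed,
                             params = list(k = row$k,
                                           alphabet = row$alphabet)),
      error = function(e)
        stop("pipeline failed for combination (k=", row$k, ", ",
             row$alphabet, ", ", row$metric, ", ", row$linkage, ", group=",
             row$group, "): ", conditionMessage(e), call. = FALSE))
    rep$rand
  }, numeric(1))
  ord <- order(-grid$rand, grid$k, grid$alphabet, grid$metric,
               grid$linkage, grid$group)
  grid[ord, , drop = FALSE]
}
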