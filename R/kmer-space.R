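# k-mer space: alphabets, counting, and protein/proteome frequency vectors.

# Canonical 20-letter alphabet, fixed order (stable k-mer indexing).
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Five physicochemical classes, ordered: 1 aliphatic, 2 aromatic, 3 uncharged,
# 4 positively charged, 5 negatively charged.
RED5 <- c("1", "2", "3", "4", "5")

# per-letter class of AA20 (same order as AA20)
.red5_map <- c("1", "3", "5", "5", "2", "3", "4", "1", "4", "1",
               "1", "3", "1", "3", "4", "3", "3", "1", "2", "2")

#' k-mer space specification
#'
#' Fixes the window length `k` and the symbol alphabet, and with them the
#' vector dimension `n = |alphabet|^k` and a canonical lexicographic k-mer
#' ordering (first character most significant, alphabet order as declared).
#'
#' @param k Window length. Supported range 1--4; `k = 4` triggers a warning
#'   because 4-mer vectors over 20 symbols (160,000 types) are very sparse for
#'   bacterial-sized proteomes.
#' @param alphabet `"aa20"` for the 20 canonical amino acids or `"reduced5"`
#'   for the 5-class physicochemical reduction (see [reduce_alphabet()]).
#' @return An object of class `kmer_spec` with fields `k`, `alphabet`
#'   (character vector of symbols), `alphabet_id` and `n`.
#' @examples
#' kmer_spec(3)              # n = 8000
#' kmer_spec(2, "reduced5")  # n = 25
#' @export
kmer_spec <- function(k, alphabet = c("aa20", "reduced5")) {
  alphabet_id <- match.arg(alphabet)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 4L)
    stop("k must be an integer in 1..4")
  if (k == 4L)
    warning("k = 4 gives very sparse vectors for bacterial-sized proteomes; ",
            "k = 3 is the recommended maximum")
  symbols <- if (alphabet_id == "aa20") AA20 else RED5
  structure(
    list(k = k, alphabet = symbols, alphabet_id = alphabet_id,
         n = length(symbols)^k),
    class = "kmer_spec")
}

#' @export
print.kmer_spec <- function(x, ...) {
  cat(sprintf("kmer_spec: k = %d, alphabet = %s (%d symbols), n = %d\n",
              x$k, x$alphabet_id, length(x$alphabet), x$n))
  invisible(x)
}

#' Reduce an amino-acid sequence to the 5-class alphabet
#'
#' Maps each canonical residue to its physicochemical class symbol:
#' aliphatic (A, I, L, M, P, V) -> "1", aromatic (F, W, Y) -> "2",
#' uncharged (C, G, N, Q, S, T) -> "3", positively charged (H, K, R) -> "4",
#' negatively charged (D, E) -> "5". Characters outside the 20 canonical
#' residues pass through unchanged; they are filtered later, at counting time.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @return Character vector of class-symbol sequences, same lengths.
#' @examples
#' reduce_alphabet("ALWKD")  # "11245"
#' @export
reduce_alphabet <- function(sequence) {
  chartr(paste(AA20, collapse = ""), paste(.red5_map, collapse = ""), sequence)
}

# integer codes (1..K) for one sequence; NA for symbols outside the alphabet
.encode <- function(sequence, spec) {
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt(paste(spec$alphabet, collapse = ""))] <-
    seq_along(spec$alphabet)
  raw <- utf8ToInt(sequence)
  raw[raw > 127L | raw < 1L] <- 1L  # non-ASCII -> invalid
  lut[raw]
}

#' Count k-mer occurrences in a sequence
#'
#' Slides a window of length `k` at step 1 and counts each k-mer type.
#' Windows containing any character outside the spec's alphabet (ambiguity
#' codes such as X, B, Z, the rare residues U and O, gaps, stops) contribute
#' nothing. A sequence shorter than `k` yields all-zero counts.
#'
#' @param sequence A single character string.
#' @param spec A [kmer_spec()].
#' @return Integer vector of length `spec$n`, in canonical k-mer order.
#' @examples
#' sp <- kmer_spec(1)
#' count_kmers("AAA", sp)[1]  # 3
#' @export
count_kmers <- function(sequence, spec) {
  stopifnot(inherits(spec, "kmer_spec"), is.character(sequence),
            length(sequence) == 1L)
  k <- spec$k
  K <- length(spec$alphabet)
  codes <- .encode(sequence, spec)
  L <- length(codes)
  if (L < k) return(integer(spec$n))
  nw <- L - k + 1L
  idx <- rep.int(0L, nw)
  ok <- rep.int(TRUE, nw)
  for (j in seq_len(k)) {
    cj <- codes[j:(j + nw - 1L)]
    ok <- ok & !is.na(cj)
    cj[is.na(cj)] <- 1L
    idx <- idx + (cj - 1L) * K^(k - j)
  }
  tabulate(idx[ok] + 1L, nbins = spec$n)
}

#' Enumerate k-mer strings in canonical order
#'
#' @param spec A [kmer_spec()].
#' @return Character vector of length `spec$n`: the k-mer whose frequency sits
#'   at position `i` of any vector built with this spec.
#' @export
kmer_strings <- function(spec) {
  stopifnot(inherits(spec, "kmer_spec"))
  cols <- do.call(expand.grid,
                  c(rep(list(spec$alphabet), spec$k),
                    stringsAsFactors = FALSE))
  do.call(paste0, rev(cols))
}

#' Protein and proteome records
#'
#' Lightweight containers for labelled sequences. A `protein_record` holds one
#' sequence plus its (possibly empty) set of functional-group labels; a
#' `proteome_record` holds an organism's proteins and its reference clade.
#'
#' @param id,organism_id Identifier string.
#' @param sequence Amino-acid string (upper-cased on construction).
#' @param groups Character vector of group labels (e.g. "membrane",
#'   "ribosomal", "nucleotide_binding").
#' @param clade Reference clade label (may be `NA` until metadata is attached).
#' @param proteins List of `protein_record` objects, at least one.
#' @return An object of class `protein_record` / `proteome_record`.
#' @export
protein_record <- function(id, sequence, groups = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("protein ", id, " has an empty sequence")
  structure(list(id = id, sequence = toupper(sequence),
                 groups = as.character(groups)),
            class = "protein_record")
}

#' @rdname protein_record
#' @export
proteome_record <- function(organism_id, proteins, clade = NA_character_) {
  stopifnot(is.character(organism_id), length(organism_id) == 1L,
            is.list(proteins), length(proteins) >= 1L)
  if (!all(vapply(proteins, inherits, logical(1), "protein_record")))
    stop("proteins must be a list of protein_record objects")
  structure(list(organism_id = organism_id, clade = clade,
                 proteins = proteins),
            class = "proteome_record")
}

#' @export
print.proteome_record <- function(x, ...) {
  cat(sprintf("proteome_record: %s (clade %s), %d proteins\n",
              x$organism_id, x$clade, length(x$proteins)))
  invisible(x)
}

.new_kmer_vector <- function(counts, spec) {
  tot <- sum(counts)
  vals <- if (tot > 0) counts / tot else rep.int(0, spec$n)
  structure(list(spec = spec, values = as.numeric(vals),
                 total_kmers = as.integer(tot)),
            class = "kmer_vector")
}

#' @export
print.kmer_vector <- function(x, ...) {
  cat(sprintf("kmer_vector: n = %d (k = %d, %s), %d k-mers pooled\n",
              x$spec$n, x$spec$k, x$spec$alphabet_id, x$total_kmers))
  invisible(x)
}

# accept kmer_vector or bare numeric in the distance layer
.vec_values <- function(v) {
  if (inherits(v, "kmer_vector")) v$values else as.numeric(v)
}

#' Normalized k-mer frequency vector of a single protein
#'
#' Counts all overlapping k-mers of the sequence and normalizes to relative
#' frequencies `p_i = c_i / sum_j c_j`. With a `"reduced5"` spec the sequence
#' is recoded with [reduce_alphabet()] before counting.
#'
#' @param protein A [protein_record()] or a plain sequence string.
#' @param spec A [kmer_spec()].
#' @return A `kmer_vector` (fields `spec`, `values`, `total_kmers`). The
#'   vector is all-zero if the sequence has no valid window.
#' @export
protein_vector <- function(protein, spec) {
  seqstr <- if (inherits(protein, "protein_record")) protein$sequence
            else as.character(protein)
  if (spec$alphabet_id == "reduced5") seqstr <- reduce_alphabet(seqstr)
  .new_kmer_vector(count_kmers(seqstr, spec), spec)
}

# which proteins match a group selector (NULL = all; exclude = complement)
.select_proteins <- function(proteome, groups = NULL, exclude = FALSE) {
  if (is.null(groups)) return(seq_along(proteome$proteins))
  hit <- vapply(proteome$proteins,
                function(p) any(p$groups %in% groups), logical(1))
  which(if (exclude) !hit else hit)
}

#' Normalized k-mer frequency vector of a proteome
#'
#' Pools raw k-mer counts across the selected proteins *before* normalizing
#' (`P_i = sum_j c_ij / sum_i sum_j c_ij`), i.e. proteins contribute in
#' proportion to their length -- not a mean of per-protein vectors.
#'
#' @param proteome A [proteome_record()].
#' @param spec A [kmer_spec()].
#' @param groups Optional character vector of group labels: restrict pooling
#'   to proteins carrying at least one of them (`exclude = TRUE` takes the
#'   complement instead, e.g. "non-membrane").
#' @param exclude Logical; complement the group selection.
#' @return A `kmer_vector` over the pooled counts.
#' @export
proteome_vector <- function(proteome, spec, groups = NULL, exclude = FALSE) {
  stopifnot(inherits(proteome, "proteome_record"))
  sel <- .select_proteins(proteome, groups, exclude)
  if (length(sel) == 0L)
    stop("group filter selects no proteins in proteome ",
         proteome$organism_id)
  counts <- integer(spec$n)
  for (i in sel) {
    seqstr <- proteome$proteins[[i]]$sequence
    if (spec$alphabet_id == "reduced5") seqstr <- reduce_alphabet(seqstr)
    counts <- counts + count_kmers(seqstr, spec)
  }
  .new_kmer_vector(counts, spec)
}
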