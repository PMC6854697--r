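# Protein and enzyme sequence embeddings via shifted non-overlapping
# 3-gram word vectors.
#
# Each sequence is split into k reading frames of non-overlapping k-grams
# (offsets 0..k-1); each frame's k-gram vectors are aggregated (sum by
# default) into one dim-length vector and the k frame vectors are
# concatenated, giving a 3*100 = 300-dimensional sequence vector under the
# defaults. The k-gram -> vector table is pluggable; the built-in table
# assigns each k-gram a seeded random unit vector, a deterministic
# stand-in carrying sequence-composition information, and any pre-trained
# embedding table with the same shape can be loaded instead.

#' Split a sequence into shifted non-overlapping k-grams
#'
#' Frame \code{r} (r = 0..k-1) contains \code{seq[r+1 .. r+k]},
#' \code{seq[r+k+1 .. r+2k]}, ... stopping before any incomplete k-gram;
#' trailing residues are dropped. Every length-k window of the sequence
#' appears in exactly one frame.
#'
#' @param seq a character string of length >= k
#' @param k word size (default 3)
#' @return list of k character vectors, one per frame offset
#' @export
#' @examples
#' split_nonoverlapping_ngrams("ABCDEFG")
#' # $offset0: "ABC" "DEF"; $offset1: "BCD" "EFG"; $offset2: "CDE"
split_nonoverlapping_ngrams <- function(seq, k = 3L) {
  abort_if(!is.character(seq) || length(seq) != 1, "seq must be a single string")
  n <- nchar(seq)
  abort_if(n < k, "sequence of length %d is shorter than the k-gram size %d", n, k)
  frames <- lapply(seq_len(k) - 1L, function(r) {
    starts <- seq.int(r + 1L, n, by = k)
    starts <- starts[starts + k - 1L <= n]
    if (length(starts) == 0) return(character())
    substring(seq, starts, starts + k - 1L)
  })
  names(frames) <- paste0("offset", seq_len(k) - 1L)
  frames
}

#' Build a seeded random k-gram embedding table
#'
#' Enumerates every k-gram over the alphabet (sorted) and assigns each a
#' seeded standard-normal vector scaled to unit norm. The table is fully
#' determined by \code{(k, dim, alphabet, seed)}.
#'
#' @param k word size
#' @param dim embedding dimension per k-gram (default 100)
#' @param alphabet residue alphabet (default the 20 canonical amino acids
#'   plus \code{X})
#' @param seed integer seed
#' @return object of class \code{ngram_table}: list with \code{k},
#'   \code{dim} and \code{vectors} (matrix, one named row per k-gram)
#' @export
ngram_embedding_table <- function(k = 3L, dim = 100L,
                                  alphabet = aa_alphabet(), seed = 1L) {
  alphabet <- sort(alphabet, method = "radix")
  grams <- do.call(paste0, rev(expand.grid(rep(list(alphabet), k),
                                           stringsAsFactors = FALSE)))
  grams <- sort(grams, method = "radix")
  vecs <- with_seed(seed, matrix(stats::rnorm(length(grams) * dim),
                                 nrow = length(grams), ncol = dim))
  vecs <- vecs / sqrt(rowSums(vecs^2))
  rownames(vecs) <- grams
  structure(list(k = as.integer(k), dim = as.integer(dim), vectors = vecs),
            class = "ngram_table")
}

#' @export
print.ngram_table <- function(x, ...) {
  cat(sprintf("ngram_table: %d %d-grams -> %d dims\n",
              nrow(x$vectors), x$k, x$dim))
  invisible(x)
}

#' Write / read a k-gram embedding table as TSV
#'
#' One line per k-gram: \code{ngram<TAB>v1<TAB>...<TAB>v_dim}.
#'
#' @param table an \code{ngram_table}
#' @param path file path
#' @return \code{write_ngram_table} returns the table invisibly;
#'   \code{read_ngram_table} returns an \code{ngram_table}
#' @export
write_ngram_table <- function(table, path) {
  body <- apply(table$vectors, 1, function(v) paste(sprintf("%.15g", v), collapse = "\t"))
  writeLines(paste(rownames(table$vectors), body, sep = "\t"), path)
  invisible(table)
}

#' @rdname write_ngram_table
#' @export
read_ngram_table <- function(path) {
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  abort_if(length(rows) == 0, "empty ngram table '%s'", path)
  grams <- vapply(rows, `[[`, "", 1L)
  dim <- length(rows[[1]]) - 1L
  abort_if(any(lengths(rows) != dim + 1L), "ragged ngram table '%s'", path)
  vecs <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(dim)))
  rownames(vecs) <- grams
  structure(list(k = nchar(grams[1]), dim = dim, vectors = vecs),
            class = "ngram_table")
}

#' Embed one protein sequence
#'
#' Splits the sequence into k shifted non-overlapping frames, aggregates
#' each frame's k-gram vectors (sum by default, mean optional) and
#' concatenates the frame vectors in offset order. An empty frame
#' contributes a zero block. k-grams absent from the table map to the
#' zero vector with a warning (or an error if \code{missing = "error"}).
#'
#' @param seq amino-acid sequence string
#' @param table an \code{ngram_table}
#' @param aggregate per-frame aggregation, \code{"sum"} or \code{"mean"}
#' @param missing policy for k-grams absent from the table
#' @return numeric vector of length \code{k * table$dim}
#' @export
embed_protein_sequence <- function(seq, table,
                                   aggregate = c("sum", "mean"),
                                   missing = c("zero", "error")) {
  aggregate <- match.arg(aggregate)
  missing <- match.arg(missing)
  frames <- split_nonoverlapping_ngrams(seq, k = table$k)
  blocks <- lapply(frames, function(grams) {
    if (length(grams) == 0) return(numeric(table$dim))
    idx <- match(grams, rownames(table$vectors))
    if (anyNA(idx)) {
      absent <- unique(grams[is.na(idx)])
      if (missing == "error") {
        stop(sprintf("k-gram(s) not in embedding table: %s",
                     paste(absent, collapse = ", ")), call. = FALSE)
      }
      warning(sprintf("k-gram(s) not in embedding table mapped to zero: %s",
                      paste(absent, collapse = ", ")), call. = FALSE)
    }
    m <- table$vectors[idx[!is.na(idx)], , drop = FALSE]
    s <- if (nrow(m) == 0) numeric(table$dim) else colSums(m)
    if (aggregate == "mean") s / length(grams) else s
  })
  unlist(blocks, use.names = FALSE)
}

#' Build the sequence-vector set of one drug
#'
#' One embedded vector per sequence; duplicates are retained (multiset),
#' used identically for target proteins and for drug-related enzymes.
#'
#' @param drug_id drug identifier
#' @param seqs character vector of sequences (length >= 1)
#' @param table an \code{ngram_table}
#' @param aggregate passed to \code{\link{embed_protein_sequence}}
#' @return numeric matrix, one row per sequence, \code{k * dim} columns,
#'   with attribute \code{drug_id}
#' @export
build_sequence_vector_set <- function(drug_id, seqs, table,
                                      aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  abort_if(length(seqs) == 0, "drug '%s' has zero sequences", drug_id)
  m <- t(vapply(seqs, embed_protein_sequence, numeric(table$k * table$dim),
                table = table, aggregate = aggregate))
  rownames(m) <- NULL
  attr(m, "drug_id") <- drug_id
  m
}

#' Embed the sequence sets of many drugs
#'
#' @param seq_map named list drug id -> character vector of sequences (as
#'   from \code{\link{read_grouped_fasta}})
#' @inheritParams build_sequence_vector_set
#' @return named list of per-drug vector-set matrices
#' @export
embed_sequence_sets <- function(seq_map, table, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  out <- lapply(names(seq_map), function(d) {
    build_sequence_vector_set(d, seq_map[[d]], table, aggregate = aggregate)
  })
  stats::setNames(out, names(seq_map))
}
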