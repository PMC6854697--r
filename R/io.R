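# Readers and writers for every file the pipeline touches.
#
# All tables are tab-separated (no CSV autodetection, to keep parsing
# bit-exact); entity ordering everywhere is lexicographic on the id strings,
# and every matrix built downstream inherits that order.

#' Read a drug SMILES table
#'
#' Parses a two-column tab-separated file, one line per drug:
#' \code{drug_id<TAB>SMILES}. Lines starting with \code{#} are ignored.
#' Whitespace around fields is stripped. Duplicate drug ids and empty
#' SMILES fields are errors.
#'
#' @param path path to the TSV file
#' @return named character vector of SMILES strings, names are drug ids in
#'   lexicographic order
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines(c("D1\tCCO", "D2\tC1CC1"), tf)
#' read_smiles_table(tf)
read_smiles_table <- function(path) {
  abort_if(!file.exists(path), "cannot read SMILES table: '%s' does not exist", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  abort_if(length(lines) == 0, "SMILES table '%s' contains no data lines", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  abort_if(any(lengths(parts) < 2),
           "malformed SMILES line (need 'drug_id<TAB>SMILES'): '%s'",
           lines[which(lengths(parts) < 2)[1]])
  ids <- trimws(vapply(parts, `[[`, "", 1L))
  smiles <- trimws(vapply(parts, `[[`, "", 2L))
  dup <- ids[duplicated(ids)]
  abort_if(length(dup) > 0, "duplicate drug id(s) in SMILES table: %s",
           paste(unique(dup), collapse = ", "))
  abort_if(any(!nzchar(ids)), "blank drug id in SMILES table")
  abort_if(any(!nzchar(smiles)), "empty SMILES field for drug(s): %s",
           paste(ids[!nzchar(smiles)], collapse = ", "))
  ord <- order(ids, method = "radix")
  stats::setNames(smiles[ord], ids[ord])
}

# canonical amino-acid alphabet (20 residues + ambiguous X)
aa_alphabet <- function(include_x = TRUE) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (include_x) c(aa, "X") else aa
}

#' Read a grouped protein FASTA file
#'
#' Headers must follow the \code{>drug_id|sequence_id} dialect; a drug may
#' appear any number of times (multi-target drugs). Sequences are validated
#' against the 20 canonical amino-acid letters plus \code{X}.
#'
#' @param path path to a FASTA file
#' @return named list mapping drug id (lexicographic order) to a character
#'   vector of sequences in file order
#' @export
read_grouped_fasta <- function(path) {
  abort_if(!file.exists(path), "cannot read FASTA: '%s' does not exist", path)
  set <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      # the parser silently drops characters outside the amino-acid code;
      # for validated input that is an error, not a cleanup
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop(sprintf("illegal residue character(s) in FASTA '%s'", path),
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  abort_if(length(set) == 0, "FASTA '%s' contains no records", path)
  headers <- names(set)
  bad <- !grepl("^[^|]+\\|[^|]+$", headers)
  abort_if(any(bad),
           "malformed FASTA header (expected 'drug_id|sequence_id'): '>%s'",
           headers[which(bad)[1]])
  seqs <- as.character(set)
  legal <- paste0("^[", paste(aa_alphabet(), collapse = ""), "]+$")
  ill <- !grepl(legal, seqs)
  abort_if(any(ill), "illegal residue character in sequence under header '>%s'",
           headers[which(ill)[1]])
  drug <- sub("\\|.*$", "", headers)
  out <- split(unname(seqs), drug)
  out[order(names(out), method = "radix")]
}

#' Construct an expression table
#'
#' Container for a genes x samples expression matrix plus per-sample
#' metadata (drug id or \code{CONTROL}, cell line, replicate index) and a
#' flag saying whether values are already log2-scaled.
#'
#' @param values numeric matrix genes x samples with dimnames
#' @param sample_meta data.frame with columns \code{sample_id},
#'   \code{drug_id}, \code{cell_line}, \code{replicate}
#' @param logged logical; \code{TRUE} if \code{values} are already log2
#' @return object of class \code{expression_table}
#' @export
expression_table <- function(values, sample_meta, logged = FALSE) {
  abort_if(!is.matrix(values) || !is.numeric(values),
           "expression values must be a numeric matrix")
  abort_if(is.null(rownames(values)) || is.null(colnames(values)),
           "expression values need gene and sample dimnames")
  need <- c("sample_id", "drug_id", "cell_line", "replicate")
  abort_if(!all(need %in% names(sample_meta)),
           "sample metadata must have columns: %s", paste(need, collapse = ", "))
  missing <- setdiff(colnames(values), sample_meta$sample_id)
  abort_if(length(missing) > 0,
           "sample(s) present in values but missing from metadata: %s",
           paste(missing, collapse = ", "))
  abort_if(anyNA(sample_meta[need]), "incomplete sample metadata")
  meta <- sample_meta[match(colnames(values), sample_meta$sample_id), need]
  rownames(meta) <- NULL
  structure(list(values = values, sample_meta = meta, logged = isTRUE(logged)),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$logged) "log2" else "raw"))
  invisible(x)
}

#' Read an expression table and its sample metadata
#'
#' The value table is genes x samples TSV with a header row of sample ids
#' and gene ids in the first column; the metadata TSV maps
#' \code{sample_id} to \code{drug_id} (or \code{CONTROL}),
#' \code{cell_line} and \code{replicate}.
#'
#' @param path path to the genes x samples value TSV
#' @param meta_path path to the sample metadata TSV
#' @param logged whether the values are already log2-scaled
#' @return an \code{\link{expression_table}}
#' @export
read_expression_table <- function(path, meta_path, logged = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, row.names = 1,
                           check.names = FALSE, colClasses = "character")
  vals <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, names(raw)))
  rownames(vals) <- rownames(raw)
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                 rownames(vals)[idx[1]], colnames(vals)[idx[2]]), call. = FALSE)
  }
  meta <- utils::read.delim(meta_path, header = TRUE, colClasses = "character")
  if ("replicate" %in% names(meta)) meta$replicate <- as.integer(meta$replicate)
  expression_table(vals, meta, logged = logged)
}

#' Write an expression table to a pair of TSV files
#'
#' @param expr an \code{\link{expression_table}}
#' @param path output path for the value matrix
#' @param meta_path output path for the sample metadata
#' @return invisibly, the input
#' @export
write_expression_table <- function(expr, path, meta_path) {
  write_matrix(expr$values, path)
  utils::write.table(expr$sample_meta, meta_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(expr)
}

#' Read a known drug-disease association list
#'
#' Lines are \code{drug_id<TAB>disease_id}. Duplicate pairs are dropped
#' (set semantics) with a message giving the count.
#'
#' @param path path to the TSV file
#' @return data.frame with character columns \code{drug} and
#'   \code{disease}, unique rows, sorted
#' @export
read_associations <- function(path) {
  abort_if(!file.exists(path), "cannot read associations: '%s' does not exist", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(drug = character(), disease = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  abort_if(any(lengths(parts) < 2), "malformed association line: '%s'",
           lines[which(lengths(parts) < 2)[1]])
  drug <- trimws(vapply(parts, `[[`, "", 1L))
  disease <- trimws(vapply(parts, `[[`, "", 2L))
  blank <- !nzchar(drug) | !nzchar(disease)
  abort_if(any(blank), "blank field in association line: '%s'",
           lines[which(blank)[1]])
  df <- data.frame(drug = drug, disease = disease, stringsAsFactors = FALSE)
  ndup <- sum(duplicated(df))
  if (ndup > 0) message(sprintf("read_associations: dropped %d duplicate pair(s)", ndup))
  df <- unique(df)
  df <- df[order(df$drug, df$disease, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a drug-disease association list
#' @param assoc data.frame with columns \code{drug}, \code{disease}
#' @param path output path
#' @return invisibly, the input
#' @export
write_associations <- function(assoc, path) {
  writeLines(paste(assoc$drug, assoc$disease, sep = "\t"), path)
  invisible(assoc)
}

#' Read disease term annotations
#'
#' Lines are \code{disease_id<TAB>term_id}; duplicates collapse to set
#' semantics. The global vocabulary (sorted union of all observed terms)
#' is attached as attribute \code{vocabulary}.
#'
#' @param path path to the TSV file
#' @return named list mapping disease id (lexicographic order) to a sorted
#'   character vector of term ids, with attribute \code{vocabulary}
#' @export
read_term_annotations <- function(path) {
  abort_if(!file.exists(path), "cannot read annotations: '%s' does not exist", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  abort_if(length(lines) == 0, "annotation file '%s' contains no data lines", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  abort_if(any(lengths(parts) < 2), "malformed annotation line: '%s'",
           lines[which(lengths(parts) < 2)[1]])
  disease <- trimws(vapply(parts, `[[`, "", 1L))
  term <- trimws(vapply(parts, `[[`, "", 2L))
  blank <- !nzchar(disease) | !nzchar(term)
  abort_if(any(blank), "blank field in annotation line: '%s'", lines[which(blank)[1]])
  ann <- lapply(split(term, disease), function(t) sort(unique(t), method = "radix"))
  ann <- ann[order(names(ann), method = "radix")]
  attr(ann, "vocabulary") <- sort(unique(term), method = "radix")
  ann
}

#' Write disease term annotations
#' @param annotations named list of term-id character vectors
#' @param path output path
#' @return invisibly, the input
#' @export
write_term_annotations <- function(annotations, path) {
  lines <- unlist(lapply(names(annotations), function(d) {
    paste(d, annotations[[d]], sep = "\t")
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(annotations)
}

#' Write a labelled numeric matrix to TSV
#'
#' Values are formatted with \code{\%.15g} so that a write/read round trip
#' is an identity to well below 1e-12 per cell. The first column holds row
#' labels; the first header field is empty.
#'
#' @param m numeric matrix with unique row and column dimnames
#' @param path output path
#' @param comment optional character vector written as leading
#'   \code{#}-prefixed header lines (e.g. fusion constants)
#' @return invisibly, the matrix
#' @export
write_matrix <- function(m, path, comment = NULL) {
  abort_if(!is.matrix(m) || !is.numeric(m), "write_matrix needs a numeric matrix")
  abort_if(is.null(rownames(m)) || is.null(colnames(m)),
           "write_matrix needs row and column labels")
  abort_if(anyDuplicated(rownames(m)) > 0, "duplicate row label(s): %s",
           paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  abort_if(anyDuplicated(colnames(m)) > 0, "duplicate column label(s): %s",
           paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(row) paste(sprintf("%.15g", row), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(m)
}

#' Read a labelled numeric matrix written by \code{\link{write_matrix}}
#' @param path path to the TSV file
#' @return numeric matrix with dimnames; any \code{#} header lines are
#'   attached as attribute \code{comment}
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  is_comment <- grepl("^#", lines)
  comments <- sub("^# ?", "", lines[is_comment])
  lines <- lines[!is_comment]
  abort_if(length(lines) < 2, "matrix file '%s' has no data rows", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  rn <- vapply(rows, `[[`, "", 1L)
  abort_if(anyDuplicated(rn) > 0, "duplicate row label(s) in '%s'", path)
  abort_if(anyDuplicated(header) > 0, "duplicate column label(s) in '%s'", path)
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
  if (length(header) == 1) m <- matrix(m, ncol = 1)
  dimnames(m) <- list(rn, header)
  if (length(comments) > 0) attr(m, "comment") <- comments
  m
}
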