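# SMILES preprocessing and the continuous chemical-structure encoding.
#
# A SMILES string is first validated against a fixed 35-character alphabet
# (34 structural characters plus the space used as right-padding) and
# one-hot encoded to a 120 x 35 binary matrix, the input contract of
# character-level molecular encoders. The continuous vector itself comes
# from a pluggable encoder; the built-in default is a deterministic
# character-trigram feature-hashing map into 192 dimensions followed by
# unit-norm scaling, so the pipeline is self-contained and reproducible
# while any pre-trained molecular encoder honouring the length contract
# can be swapped in.

#' The default SMILES character alphabet
#'
#' 35 characters: 34 structural SMILES characters (organic-subset atoms in
#' both aromatic and aliphatic case, bond, branch, ring-bond and charge
#' symbols, digits) plus the space character used for right-padding.
#'
#' @return character vector of length 35; the pad character is \code{" "}
#' @export
smiles_alphabet <- function() {
  c(" ",                                               # pad
    "C", "c", "N", "n", "O", "o", "S", "s", "P", "p",  # atoms
    "F", "I", "B", "H", "l", "r",                      # F, I, B/Br, H, Cl/Br
    "=", "#", "(", ")", "[", "]", "@", "+", "-", "/", "\\",
    "1", "2", "3", "4", "5", "6", "7")
}

#' One-hot encode a SMILES string
#'
#' Validates every character against the alphabet, right-pads with the pad
#' character (the alphabet's first element) to \code{max_len}, and returns
#' the \code{max_len x length(alphabet)} binary indicator matrix with
#' exactly one 1 per row.
#'
#' @param smiles a SMILES string
#' @param alphabet character vector of allowed single characters; the
#'   first element is the pad character
#' @param max_len maximum (and padded) string length
#' @return binary matrix \code{max_len x length(alphabet)} with the
#'   alphabet as column names
#' @export
#' @examples
#' enc <- preprocess_smiles("CCO")
#' dim(enc)           # 120 x 35
#' which(enc[1, ] == 1)
preprocess_smiles <- function(smiles, alphabet = smiles_alphabet(), max_len = 120L) {
  abort_if(!is.character(smiles) || length(smiles) != 1, "smiles must be a single string")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  abort_if(length(chars) > max_len,
           "SMILES string has %d characters, exceeding the maximum length %d",
           length(chars), max_len)
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    pos <- which(is.na(idx))[1]
    stop(sprintf("character '%s' at position %d is not in the SMILES alphabet",
                 chars[pos], pos), call. = FALSE)
  }
  padded <- c(idx, rep(1L, max_len - length(idx)))  # pad = first alphabet entry
  m <- matrix(0L, nrow = max_len, ncol = length(alphabet),
              dimnames = list(NULL, alphabet))
  m[cbind(seq_len(max_len), padded)] <- 1L
  m
}

# default continuous encoder: counts of hashed character trigrams, unit norm
hash_trigram_encoder <- function(dim = 192L) {
  force(dim)
  function(smiles) {
    s <- smiles
    if (nchar(s) < 3) s <- formatC(s, width = 3, flag = "-")  # right-pad short strings
    n <- nchar(s)
    v <- numeric(dim)
    for (i in seq_len(n - 2L)) {
      tri <- substr(s, i, i + 2L)
      slot <- str_hash(tri) %% dim + 1L
      v[slot] <- v[slot] + 1
    }
    v / sqrt(sum(v^2))
  }
}

#' Encode a SMILES string as a fixed-length continuous vector
#'
#' The string is first validated through \code{\link{preprocess_smiles}}.
#' The default encoder is deterministic character-trigram feature hashing
#' into \code{dim} slots followed by unit Euclidean scaling; any function
#' \code{f(smiles) -> numeric(dim)} may be supplied instead (for example a
#' wrapper around a pre-trained molecular variational auto-encoder).
#'
#' @param smiles a SMILES string
#' @param encoder optional replacement encoder function
#' @param dim output vector length (default 192)
#' @param alphabet,max_len passed to \code{\link{preprocess_smiles}}
#' @return numeric vector of length \code{dim}
#' @export
#' @examples
#' v <- encode_smiles("C1CC1NC(=O)O")
#' length(v)       # 192
#' sum(v^2)        # 1
encode_smiles <- function(smiles, encoder = NULL, dim = 192L,
                          alphabet = smiles_alphabet(), max_len = 120L) {
  preprocess_smiles(smiles, alphabet = alphabet, max_len = max_len)
  f <- encoder %||% hash_trigram_encoder(dim)
  v <- f(smiles)
  abort_if(!is.numeric(v) || length(v) != dim,
           "SMILES encoder returned length %d, expected %d", length(v), dim)
  abort_if(any(!is.finite(v)), "SMILES encoder returned non-finite values")
  as.numeric(v)
}

#' Encode a table of SMILES strings
#'
#' @param smiles named character vector (as from
#'   \code{\link{read_smiles_table}})
#' @inheritParams encode_smiles
#' @return numeric matrix drugs x \code{dim}, row names are drug ids
#' @export
encode_smiles_table <- function(smiles, encoder = NULL, dim = 192L,
                                alphabet = smiles_alphabet(), max_len = 120L) {
  out <- t(vapply(smiles, encode_smiles, numeric(dim),
                  encoder = encoder, dim = dim,
                  alphabet = alphabet, max_len = max_len))
  rownames(out) <- names(smiles)
  out
}
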