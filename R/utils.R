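# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic 31-bit string hash
#'
#' Polynomial rolling hash over UTF-8 code points, reduced modulo the
#' Mersenne prime 2^31 - 1. Used for feature hashing and for deriving
#' independent seed streams from one master seed; stable across platforms
#' and R sessions (pure double arithmetic, no overflow).
#'
#' @param x character scalar
#' @return integer in [0, 2^31 - 2]
#' @keywords internal
str_hash <- function(x) {
  h <- 0
  for (c in utf8ToInt(x)) {
    h <- (h * 131 + c) %% 2147483647
  }
  as.integer(h)
}

#' Derive a sub-seed for a named random stream
#'
#' All stochastic stages draw from streams derived from one master seed so
#' that stages are reproducible independently of evaluation order.
#'
#' @param seed master integer seed
#' @param label stream name, e.g. "ngram-table"
#' @return integer seed below 2^31
#' @keywords internal
derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + str_hash(label)) %% 2147483647)
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# stopifnot with a formatted message
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
}

# check a square labelled numeric matrix
check_square_labelled <- function(m, what = "matrix") {
  abort_if(!is.matrix(m) || !is.numeric(m), "%s must be a numeric matrix", what)
  abort_if(nrow(m) != ncol(m), "%s must be square", what)
  abort_if(is.null(rownames(m)) || is.null(colnames(m)),
           "%s must carry row and column labels", what)
  abort_if(!identical(rownames(m), colnames(m)),
           "%s row and column labels must agree", what)
  invisible(m)
}
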