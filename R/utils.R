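#' Encode Phred quality values as a Sanger (Phred+33) string
#'
#' @param q integer vector of Phred values, each in \[0, 93\].
#' @return A single character string, one ASCII character per value.
#' @examples
#' phred_encode(c(10, 10))  # "++"
#' @export
phred_encode <- function(q) {
  q <- as.integer(q)
  if (length(q) == 0) return("")
  if (anyNA(q) || any(q < 0L) || any(q > 93L)) {
    stop("Phred quality values must lie in [0, 93]", call. = FALSE)
  }
  intToUtf8(q + 33L)
}

#' Decode a Sanger (Phred+33) quality string to integer Phred values
#'
#' @param s a single character string.
#' @return Integer vector of Phred values.
#' @export
phred_decode <- function(s) {
  if (!nzchar(s)) return(integer(0))
  q <- utf8ToInt(s) - 33L
  if (any(q < 0L) || any(q > 93L)) {
    stop("quality string encodes values outside [0, 93]", call. = FALSE)
  }
  q
}

#' Round half away from zero
#'
#' Fixed-point reporting rounds 0.005 up to 0.01 (unlike [round()], which
#' rounds half to even), matching how megabase tables are usually printed.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route their seed through this, so
# there is no hidden global RNG dependence.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else if
    (exists(".Random.seed", envir = env, inherits = FALSE)) rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Reverse complement of DNA sequences
#'
#' Standard Watson-Crick complement over \{A, C, G, T, N\} (N maps to N),
#' with the order reversed. Vectorised; an involution.
#'
#' @param x character vector of uppercase DNA strings.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("AACN")  # "NGTT"
#' @export
reverse_complement <- function(x) {
  if (length(x) == 0) return(character(0))
  if (any(grepl("[^ACGTN]", x))) {
    stop("sequence contains characters outside {A, C, G, T, N}", call. = FALSE)
  }
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}
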