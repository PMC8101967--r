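#' @import methods
#' @importFrom stats setNames runif rbinom
#' @importFrom utils read.table write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# minimal IUPAC code table, base set -> code (sorted, comma-free key)
IUPAC_FROM_BASES <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AG" = "R", "CT" = "Y", "CG" = "S", "AT" = "W", "GT" = "K", "AC" = "M",
  "CGT" = "B", "AGT" = "D", "ACT" = "H", "ACG" = "V", "ACGT" = "N"
)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                B = "V", V = "B", D = "H", H = "D")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a fixed RNG seed, restoring the caller's RNG state
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Reverse complement of a DNA string
#'
#' Plain-character implementation used throughout the internal detectors,
#' tolerant of IUPAC ambiguity codes.
#'
#' @param x single character string of DNA
#' @return reverse-complemented string
#' @export
revcomp <- function(x) {
  stopifnot(length(x) == 1L)
  ch <- rev(strsplit(toupper(x), "", fixed = TRUE)[[1]])
  out <- COMPLEMENT[ch]
  if (anyNA(out)) stop("non-DNA alphabet in sequence: ", paste(unique(ch[is.na(out)]), collapse = ","))
  paste(out, collapse = "")
}

#' Hamming distance between two equal-length strings
#' @param a,b character strings of equal length
#' @return integer count of differing positions
#' @export
hamming <- function(a, b) {
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(va) != length(vb)) stop("hamming: unequal lengths")
  sum(va != vb)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

substr1 <- function(x, start, end) substr(x, start, end)

# split a string to a character vector of single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

check_dna <- function(x, what = "sequence") {
  if (!grepl("^[ACGTNacgtn]*$", x))
    stop(what, " contains non-DNA characters")
  invisible(toupper(x))
}
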