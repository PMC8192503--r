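#' @useDynLib edscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rpois rbeta runif median prcomp cor cor.test
#'   wilcox.test complete.cases sd ave setNames p.adjust
#' @importFrom utils write.table read.table
NULL

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

comp_base <- function(b) unname(COMPLEMENT[b])

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over plain character strings (DNA alphabet;
#' `N` is preserved).
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgtN", "TGCAtgcaN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

## integer codes 1..4 for A,C,G,T; NA otherwise
base_codes <- function(s) {
  code <- integer(256)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  v <- code[utf8ToInt(s)]
  v[v == 0L] <- NA_integer_
  v
}

## split one long string into fixed-width pieces (fast path for qualities)
chunk_string <- function(s, width, n) {
  starts <- seq.int(1L, by = width, length.out = n)
  substring(s, starts, starts + width - 1L)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
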