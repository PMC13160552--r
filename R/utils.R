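#' @useDynLib wtfkit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbinom runif rgeom setNames uniroot quantile sd
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper used throughout the package; input may
#' contain `N` (complemented to `N`) and gap characters (left as is).
#'
#' @param x single character string over `A,C,G,T,N,-`.
#' @return the reverse complement as a character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
}

# integer coding (1..4 = A,C,G,T; 0 = anything else) used by the simulator
# and the recombination statistics
seq_to_int <- function(x) {
  m <- match(strsplit(toupper(x), "", fixed = TRUE)[[1L]], DNA_BASES)
  m[is.na(m)] <- 0L
  as.integer(m)
}

int_to_seq <- function(v) {
  out <- character(length(v))
  ok <- v >= 1L & v <= 4L
  out[ok] <- DNA_BASES[v[ok]]
  out[!ok] <- "N"
  paste(out, collapse = "")
}

random_dna_int <- function(n) sample.int(4L, n, replace = TRUE)

random_dna <- function(n) int_to_seq(random_dna_int(n))

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                 format(lo), format(hi)), call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# run code with a private RNG stream, leaving the caller's stream untouched
with_private_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
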