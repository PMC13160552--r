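#' Sequence record sets
#'
#' A `SeqRecordSet` is the package's lightweight container for DNA sequence
#' collections: a data frame with columns `id`, `seq` and `desc`, in input
#' order. Identifiers must be unique and sequences non-empty; the alphabet
#' is restricted to `A,C,G,T,N` (case-insensitive) unless `alphabet` widens
#' it (aligned FASTA additionally allows `-`).
#'
#' @param id character vector of unique identifiers.
#' @param seq character vector of sequences, same length as `id`.
#' @param desc optional character vector of free-text descriptions.
#' @param alphabet characters permitted in `seq`.
#' @return an object of class `SeqRecordSet` (a data frame).
#' @export
seq_record_set <- function(id, seq, desc = NULL,
                           alphabet = c("A", "C", "G", "T", "N")) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq))
    stop("'id' and 'seq' must have the same length")
  dup <- id[duplicated(id)]
  if (length(dup))
    stop(sprintf("duplicate sequence identifier: '%s'", dup[[1L]]))
  if (any(!nzchar(seq))) {
    bad <- id[!nzchar(seq)][[1L]]
    stop(sprintf("empty sequence for record '%s'", bad))
  }
  pat <- sprintf("^[%s]*$", paste(alphabet, collapse = ""))
  ok <- grepl(pat, seq)
  if (!all(ok))
    stop(sprintf("record '%s' contains characters outside the declared alphabet",
                 id[!ok][[1L]]))
  desc <- if (is.null(desc)) rep("", length(id)) else as.character(desc)
  out <- data.frame(id = id, seq = seq, desc = desc,
                    stringsAsFactors = FALSE)
  class(out) <- c("SeqRecordSet", "data.frame")
  out
}

#' Read a FASTA file
#'
#' @param path path to a FASTA file.
#' @param alphabet permitted sequence characters; use
#'   `c("A","C","G","T","N","-")` for aligned FASTA.
#' @return a [seq_record_set()].
#' @export
read_fasta <- function(path, alphabet = c("A", "C", "G", "T", "N")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  x <- Biostrings::readBStringSet(path)
  nm <- names(x)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  seq_record_set(id, as.character(x), desc, alphabet = alphabet)
}

#' Write a FASTA file
#'
#' Round-trips with [read_fasta()] byte-identically up to line-wrap
#' normalisation at the declared width.
#'
#' @param x a `SeqRecordSet`.
#' @param path output path.
#' @param width line-wrap width in characters.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "SeqRecordSet"))
  nm <- ifelse(nzchar(x$desc), paste(x$id, x$desc), x$id)
  s <- Biostrings::BStringSet(setNames(x$seq, nm))
  Biostrings::writeXStringSet(s, path, width = width)
  invisible(path)
}

#' Read one sequence from a SeqRecordSet by identifier
#' @keywords internal
get_seq <- function(x, id) {
  i <- match(id, x$id)
  if (is.na(i)) stop(sprintf("no sequence with id '%s'", id))
  x$seq[[i]]
}
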