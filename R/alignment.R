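#' Alignment matrices
#'
#' An `AlignmentMatrix` is a character matrix over `A,C,G,T,-,N` with one
#' row per taxon (rownames are the taxon identifiers) and one column per
#' alignment site. It is the substrate for all recombination statistics.
#'
#' @param x a character matrix, or a (named) character vector of
#'   equal-length aligned sequences.
#' @return a character matrix of class `AlignmentMatrix`.
#' @export
alignment_matrix <- function(x) {
  if (inherits(x, "AlignmentMatrix")) return(x)
  if (is.matrix(x)) {
    m <- toupper(x)
  } else {
    nm <- names(x)
    x <- toupper(as.character(x))
    n <- nchar(x)
    if (length(unique(n)) != 1L)
      stop("aligned sequences must all have the same length")
    m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
    rownames(m) <- nm %||% paste0("t", seq_along(x))
  }
  if (nrow(m) < 2L) stop("an alignment needs at least 2 taxa")
  if (is.null(rownames(m))) rownames(m) <- paste0("t", seq_len(nrow(m)))
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad))
    stop(sprintf("alignment contains characters outside {A,C,G,T,-,N}: %s",
                 paste(bad, collapse = ",")))
  class(m) <- c("AlignmentMatrix", class(m))
  m
}

#' Read an aligned FASTA file as an AlignmentMatrix
#' @param path path to an aligned FASTA file.
#' @export
read_alignment <- function(path) {
  rs <- read_fasta(path, alphabet = c("A", "C", "G", "T", "N", "-"))
  alignment_matrix(setNames(rs$seq, rs$id))
}

#' Write an AlignmentMatrix as aligned FASTA
#' @param aln an `AlignmentMatrix`.
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln, 1L, paste, collapse = "")
  write_fasta(seq_record_set(rownames(aln), seqs,
                             alphabet = c("A", "C", "G", "T", "N", "-")),
              path)
}

# integer coding of alignment columns: A..T -> 1..4, gap/N -> 0
aln_codes <- function(aln) {
  codes <- match(aln, DNA_BASES)
  codes[is.na(codes)] <- 0L
  matrix(as.integer(codes), nrow = nrow(aln),
         dimnames = list(rownames(aln), NULL))
}

# physical coordinate of each column on the ungapped consensus: a column
# counts iff its majority character is not a gap; any column containing N
# still counts but N taxa are dropped site-wise by the statistics
consensus_positions <- function(aln) {
  gap_frac <- colMeans(aln == "-")
  cumsum(gap_frac < 0.5)
}

# parsimony-informative flags on an integer-coded matrix
informative_sites <- function(codes) {
  apply(codes, 2L, function(col) {
    tab <- tabulate(col[col > 0L], nbins = 4L)
    sum(tab >= 2L) >= 2L
  })
}
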