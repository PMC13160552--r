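#' Gene models
#'
#' A `GeneModel` describes one family member: its unspliced sequence in
#' gene orientation (5' to 3' on the coding strand), an ordered,
#' non-overlapping exon table in gene-local 1-based inclusive coordinates,
#' and optional placement metadata (strain, contig, genomic span, strand).
#' Exons are coding here: the spliced CDS is the concatenation of the exon
#' sequences.
#'
#' @param gene_id identifier for the gene.
#' @param seq unspliced gene sequence (character string, coding strand).
#' @param exons data frame or 2-column matrix of exon `start`/`end`
#'   positions, gene-local, 1-based inclusive, ordered 5' to 3'.
#' @param strain,contig,start,end,strand optional placement metadata;
#'   `start`/`end` are genomic 1-based inclusive.
#' @param status `"intact"` or `"pseudogene"` (normally set by
#'   [call_pseudogene()]).
#' @param locus_id assigned locus label, or `NA` if unassigned.
#' @return an object of class `GeneModel`.
#' @export
gene_model <- function(gene_id, seq, exons, strain = NA_character_,
                       contig = NA_character_, start = NA_integer_,
                       end = NA_integer_, strand = "+",
                       status = NA_character_, locus_id = NA_character_) {
  seq <- toupper(as.character(seq))
  exons <- as.data.frame(exons)
  names(exons)[1:2] <- c("start", "end")
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$start > exons$end)) stop("exon start > end")
  if (nrow(exons) > 1L) {
    if (any(diff(exons$start) <= 0))
      stop("exons must be ordered 5' to 3'")
    if (any(exons$start[-1L] <= exons$end[-nrow(exons)]))
      stop("exons must not overlap")
  }
  if (max(exons$end) > nchar(seq)) stop("exon coordinates exceed sequence")
  obj <- list(gene_id = gene_id, seq = seq, exons = exons, strain = strain,
              contig = contig, start = start, end = end, strand = strand,
              status = status, locus_id = locus_id)
  class(obj) <- "GeneModel"
  obj
}

#' Spliced CDS of a gene model
#' @param model a [gene_model()].
#' @return character string: the exon sequences concatenated 5' to 3'.
#' @export
spliced_seq <- function(model) {
  stopifnot(inherits(model, "GeneModel"))
  paste(substring(model$seq, model$exons$start, model$exons$end),
        collapse = "")
}

#' Intron sequence between exon `i` and exon `i + 1`
#' @param model a [gene_model()].
#' @param i intron index (the intron following exon `i`).
#' @return character string (may be empty).
#' @export
intron_seq <- function(model, i) {
  ex <- model$exons
  if (i < 1L || i >= nrow(ex)) stop("no such intron")
  if (ex$end[i] + 1L > ex$start[i + 1L] - 1L) return("")
  substring(model$seq, ex$end[i] + 1L, ex$start[i + 1L] - 1L)
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("<GeneModel %s: %d bp, %d exon(s), strand %s%s>\n",
              x$gene_id, nchar(x$seq), nrow(x$exons), x$strand,
              if (!is.na(x$status)) paste0(", ", x$status) else ""))
  invisible(x)
}

#' Translate a coding sequence
#'
#' Thin wrapper over [Biostrings::translate()] that tolerates a trailing
#' partial codon (dropped) and returns a plain character string.
#'
#' @param cds DNA character string.
#' @return amino-acid character string (stops as `*`).
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds) - nchar(cds) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(cds, 1L, n)),
                                     if.fuzzy.codon = "X"))
}

# feature-table rows for one gene model placed on a contig
gene_model_features <- function(model, source = "wtfkit") {
  gstart <- model$start
  ex <- model$exons
  n <- nrow(ex)
  # gene-local -> contig coordinates (forward-strand placement)
  estart <- gstart + ex$start - 1L
  eend <- gstart + ex$end - 1L
  id <- model$gene_id
  mrna <- paste0(id, ".t1")
  data.frame(
    seqid = model$contig, source = source,
    type = c("gene", "mRNA", rep("exon", n)),
    start = c(model$start, model$start, estart),
    end = c(model$end, model$end, eend),
    score = ".", strand = model$strand, phase = ".",
    attributes = c(sprintf("ID=%s;locus=%s", id, model$locus_id),
                   sprintf("ID=%s;Parent=%s", mrna, id),
                   sprintf("ID=%s.exon%d;Parent=%s", id, seq_len(n), mrna)),
    stringsAsFactors = FALSE)
}
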