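#' Pairwise nucleotide identity between two sequences
#'
#' Global alignment with free end gaps (match +1, mismatch -1, gap -2 per
#' gapped position). Identity is coverage-aware: the number of matching
#' columns divided by the total alignment length, counting internal gap
#' columns as mismatches and counting the unaligned terminal overhangs of
#' both sequences in the denominator. This keeps the identity of unrelated
#' sequences near zero (free end gaps would otherwise let a short
#' high-scoring overlap masquerade as high identity) while two sequences
#' differing by a few substitutions still score near one. The value is
#' symmetric: the pair is scored in a canonical order.
#'
#' @param a,b DNA character strings (non-empty).
#' @return identity in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  stopifnot(nzchar(a), nzchar(b))
  if (a == b) return(1)
  # canonical order so that identity(a, b) == identity(b, a) even when the
  # optimal alignment is not unique
  if (nchar(a) > nchar(b) || (nchar(a) == nchar(b) && a > b)) {
    tmp <- a; a <- b; b <- tmp
  }
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                      Biostrings::DNAString(b),
                                      type = "overlap",
                                      substitutionMatrix = sm,
                                      gapOpening = 0, gapExtension = 2)
  s1 <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  s2 <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  # alignedPattern/alignedSubject of an overlap alignment span the aligned
  # region only; add the unaligned overhangs back into the denominator
  matches <- sum(s1 == s2 & s1 != "-")
  cols <- length(s1)
  overhang <- (nchar(a) - sum(s1 != "-")) + (nchar(b) - sum(s2 != "-"))
  if (cols + overhang == 0L) return(0)
  matches / (cols + overhang)
}

#' Build an exon similarity graph
#'
#' All-vs-all [pairwise_identity()] over a set of exon sequences; an edge
#' joins two exons whose identity reaches the threshold (`>=` by default;
#' `strict = TRUE` demands `>`). Node order is deterministic (sorted by
#' label).
#'
#' @param exons named character vector of exon sequences (names are node
#'   labels, e.g. `"wtf4_e2"`), or a data frame with columns `gene_id`,
#'   `exon_index`, `sequence`.
#' @param threshold identity threshold in `[0, 1]`; the family-wide
#'   analysis this package targets uses 0.5.
#' @param strict if `TRUE`, require identity strictly greater than the
#'   threshold.
#' @return a list of class `ExonGraph` with elements `nodes` (data frame:
#'   `label`, `sequence`), `edges` (data frame: `from`, `to`, `identity`)
#'   and `threshold`.
#' @export
build_exon_graph <- function(exons, threshold = 0.5, strict = FALSE) {
  assert_scalar_number(threshold, "threshold", 0, 1)
  if (is.data.frame(exons)) {
    labs <- paste0(exons$gene_id, "_e", exons$exon_index)
    exons <- setNames(as.character(exons$sequence), labs)
  }
  if (is.null(names(exons)) || anyNA(names(exons)) ||
      any(duplicated(names(exons))))
    stop("exons must have unique names")
  if (!length(exons)) stop("at least one exon is required")
  exons <- exons[order(names(exons))]
  n <- length(exons)
  from <- character(0); to <- character(0); idn <- numeric(0)
  if (n >= 2L) {
    pairs <- utils::combn(n, 2L)
    ids <- apply(pairs, 2L, function(p)
      pairwise_identity(exons[[p[1L]]], exons[[p[2L]]]))
    keep <- if (strict) ids > threshold else ids >= threshold
    from <- names(exons)[pairs[1L, keep]]
    to <- names(exons)[pairs[2L, keep]]
    idn <- ids[keep]
  }
  out <- list(nodes = data.frame(label = names(exons),
                                 sequence = unname(exons),
                                 stringsAsFactors = FALSE),
              edges = data.frame(from = from, to = to, identity = idn,
                                 stringsAsFactors = FALSE),
              threshold = threshold, strict = strict)
  class(out) <- "ExonGraph"
  out
}

#' Extract clusters and singletons from an exon graph
#'
#' Connected components of the thresholded similarity graph; components
#' with at least `min_size` members are reported as clusters (ordered by
#' decreasing size, ties broken by the lexicographically smallest member),
#' size-1 components as singletons.
#'
#' @param g an [build_exon_graph()] result.
#' @param min_size minimum component size to count as a cluster (default 2).
#' @return list with `clusters` (list of character vectors), `singletons`
#'   (character vector) and `membership` (data frame `label`, `component`).
#' @export
extract_clusters <- function(g, min_size = 2L) {
  stopifnot(inherits(g, "ExonGraph"))
  ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")],
                                      directed = FALSE,
                                      vertices = g$nodes$label)
  comp <- igraph::components(ig)
  groups <- split(names(comp$membership), comp$membership)
  sizes <- lengths(groups)
  smallest <- vapply(groups, function(x) min(x), "")
  ord <- order(-sizes, smallest)
  groups <- lapply(groups[ord], function(x) sort(x))
  clusters <- groups[lengths(groups) >= min_size]
  singletons <- sort(unlist(groups[lengths(groups) == 1L], use.names = FALSE))
  if (is.null(singletons)) singletons <- character(0)
  membership <- data.frame(label = names(comp$membership),
                           component = unname(comp$membership),
                           stringsAsFactors = FALSE)
  list(clusters = unname(clusters), singletons = singletons,
       membership = membership)
}

#' Full pairwise identity matrix for a set of exons
#'
#' Symmetric matrix with unit diagonal, suitable for heatmap plotting or
#' TSV export.
#'
#' @param exons named character vector of exon sequences (at least 2).
#' @param path optional path; if given the matrix is also written as TSV.
#' @return numeric matrix of identities.
#' @export
identity_heatmap_table <- function(exons, path = NULL) {
  if (length(exons) < 2L) stop("at least two exons are required")
  if (is.null(names(exons))) names(exons) <- paste0("e", seq_along(exons))
  n <- length(exons)
  m <- diag(1, n)
  dimnames(m) <- list(names(exons), names(exons))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- pairwise_identity(exons[[i]], exons[[j]])
  }
  if (!is.null(path))
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  m
}
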