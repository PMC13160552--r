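#' Pairwise distance matrix from an alignment
#'
#' Pairwise-deletion distances under the p-distance, JC69 or K2P model.
#' JC69 distances saturate at p >= 0.75 (and K2P when `1 - 2P - Q <= 0`);
#' saturated entries are set to a declared cap and flagged.
#'
#' @param aln an [alignment_matrix()].
#' @param model `"p"`, `"JC69"` or `"K2P"`.
#' @param cap value substituted for saturated (infinite) distances.
#' @return numeric distance matrix with attributes `model` and
#'   `saturated` (logical matrix).
#' @export
distance_matrix <- function(aln, model = c("p", "JC69", "K2P"), cap = 5) {
  model <- match.arg(model)
  aln <- alignment_matrix(aln)
  chars <- tolower(unclass(aln))  # plain character matrix for ape
  dna <- ape::as.DNAbin(chars)
  p <- as.matrix(ape::dist.dna(dna, model = "raw",
                               pairwise.deletion = TRUE))
  d <- switch(model,
              p = p,
              JC69 = as.matrix(ape::dist.dna(dna, model = "JC69",
                                             pairwise.deletion = TRUE)),
              K2P = as.matrix(ape::dist.dna(dna, model = "K80",
                                            pairwise.deletion = TRUE)))
  saturated <- !is.finite(d) | is.nan(d)
  d[saturated] <- cap
  diag(d) <- 0
  diag(saturated) <- FALSE
  attr(d, "model") <- model
  attr(d, "saturated") <- saturated
  d
}

#' Neighbor-joining tree
#'
#' Canonical NJ on a distance matrix; negative branch-length estimates are
#' clamped to zero and flagged.
#'
#' @param d a distance matrix (from [distance_matrix()] or any symmetric
#'   matrix / `dist`).
#' @return an unrooted `phylo` tree with attribute `negative_branches`
#'   (number clamped).
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(as.dist(d))
  neg <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "negative_branches") <- neg
  tr
}

#' Assign genes to groups by anchor clades
#'
#' Each group is defined by a set of anchor gene ids; a gene belongs to
#' the group whose anchors' smallest enclosing clade (on the midpoint-
#' rooted tree) contains it. When anchor clades are nested, the smallest
#' enclosing clade wins (with a warning). Genes outside every anchor
#' clade are left unassigned (`NA`).
#'
#' @param tree a `phylo` tree (rooted or unrooted; midpoint rooting is
#'   applied when unrooted).
#' @param anchors named list: group label -> character vector of anchor
#'   tip labels. All anchors must be present in the tree.
#' @return named character vector: tip label -> group (or `NA`).
#' @export
assign_groups <- function(tree, anchors) {
  stopifnot(inherits(tree, "phylo"), is.list(anchors),
            !is.null(names(anchors)))
  missing <- setdiff(unlist(anchors), tree$tip.label)
  if (length(missing))
    stop(sprintf("anchor gene(s) missing from the tree: %s",
                 paste(missing, collapse = ", ")))
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  clades <- lapply(anchors, function(a) {
    if (length(a) == 1L) return(a)
    node <- ape::getMRCA(tree, a)
    ape::extract.clade(tree, node)$tip.label
  })
  sizes <- lengths(clades)
  out <- setNames(rep(NA_character_, length(tree$tip.label)),
                  tree$tip.label)
  nested <- FALSE
  for (tip in tree$tip.label) {
    hit <- which(vapply(clades, function(cl) tip %in% cl, logical(1L)))
    if (!length(hit)) next
    if (length(hit) > 1L) nested <- TRUE
    out[tip] <- names(clades)[hit[which.min(sizes[hit])]]
  }
  if (nested)
    warning("nested anchor clades: the smallest enclosing clade wins")
  out
}

# tips under each node of a rooted binary tree (edges must be in postorder:
# children precede their parents)
.tip_counts <- function(tree) {
  n <- length(tree$tip.label)
  counts <- c(rep(1L, n), rep(0L, tree$Nnode))
  for (e in seq_len(nrow(tree$edge))) {
    counts[tree$edge[e, 1L]] <- counts[tree$edge[e, 1L]] +
      counts[tree$edge[e, 2L]]
  }
  counts
}

#' Ladder-likeness of a tree (normalized Colless imbalance)
#'
#' The Colless index (sum over internal nodes of the absolute difference
#' in descendant-tip counts of the two child clades) divided by its
#' caterpillar maximum `(n-1)(n-2)/2`. A perfectly ladder-like
#' (caterpillar) tree scores 1, a fully balanced tree 0. Unrooted trees
#' are midpoint-rooted first; trees with fewer than 3 tips score 0.
#'
#' @param tree a `phylo` tree; must be binary once rooted.
#' @return value in `[0, 1]`.
#' @export
ladder_index <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 3L) return(0)
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  tree <- ape::reorder.phylo(tree, "postorder")
  counts <- .tip_counts(tree)
  internal <- unique(tree$edge[, 1L])
  colless <- sum(vapply(internal, function(nd) {
    kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
    abs(counts[kids[1L]] - counts[kids[2L]])
  }, numeric(1L)))
  colless / ((n - 1) * (n - 2) / 2)
}
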