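#' Refined incompatibility score for a pair of alignment sites
#'
#' The minimum number of homoplasies (extra character steps) that any tree
#' requires to fit the two sites jointly, computed from the joint-state
#' structure of the pair (the cycle rank of the partition intersection
#' graph). The score is 0 iff the sites are compatible; the classic
#' four-gamete incompatibility of a binary pair scores 1. Taxa with a gap
#' or `N` at either site are dropped pairwise; pairs with fewer than 4
#' complete taxa score 0 and carry a `low_data` attribute.
#'
#' @param site_i,site_j character vectors (one entry per taxon) over
#'   `A,C,G,T,-,N`, or integer-coded vectors (1..4, 0 = missing).
#' @return non-negative score (integer-valued); attribute `low_data` is
#'   `TRUE` when fewer than 4 complete taxa were available.
#' @export
refined_incompatibility <- function(site_i, site_j) {
  code <- function(s) {
    if (is.numeric(s)) return(as.integer(s))
    m <- match(toupper(s), DNA_BASES)
    m[is.na(m)] <- 0L
    as.integer(m)
  }
  x <- code(site_i); y <- code(site_j)
  if (length(x) != length(y)) stop("sites must cover the same taxa")
  complete <- sum(x > 0L & y > 0L)
  out <- .ri_pair_cpp(x, y)
  attr(out, "low_data") <- complete < 4L
  out
}

#' Pairwise homoplasy index (PHI) test for recombination
#'
#' The statistic is the mean refined incompatibility over all
#' parsimony-informative site pairs lying within `w` bp of each other,
#' distance measured on the ungapped consensus coordinate. Significance
#' comes from permuting the assignment of informative-site contents to
#' their physical positions: under clonal evolution homoplasy is not
#' spatially clustered, so nearby pairs are exchangeable with distant
#' ones, whereas under recombination nearby sites share genealogies and
#' are *more* compatible than random pairs. The test is therefore
#' one-sided low, with the add-one correction
#' `p = (1 + #{perm <= obs}) / (1 + permutations)`. When every
#' informative pair is compatible (all scores 0), each permutation
#' statistic is also exactly 0, so `p = 1` is returned directly without
#' spending permutations.
#'
#' @param aln an [alignment_matrix()] with at least 4 taxa.
#' @param w window in bp (default 100).
#' @param permutations number of permutations (default 1000).
#' @param seed optional seed for the permutation stream.
#' @return list of class `PhiResult`: `statistic`, `window_w`, `p_perm`,
#'   `n_informative`, `permutations_used`, `testable` (FALSE when fewer
#'   than 2 informative sites or no pair falls inside the window).
#' @export
phi_test <- function(aln, w = 100, permutations = 1000, seed = NULL) {
  aln <- alignment_matrix(aln)
  if (nrow(aln) < 4L) stop("the PHI test needs at least 4 taxa")
  assert_count(permutations, "permutations")
  codes <- aln_codes(aln)
  info <- which(informative_sites(codes))
  res <- list(statistic = NA_real_, window_w = w, p_perm = 1,
              n_informative = length(info), permutations_used = 0L,
              testable = FALSE)
  class(res) <- "PhiResult"
  if (length(info) < 2L) return(res)
  pos <- consensus_positions(aln)[info]
  ri <- .ri_matrix_cpp(codes[, info, drop = FALSE])
  stat <- .phi_stat_cpp(ri, as.numeric(pos), as.numeric(w))
  if (is.na(stat)) return(res)  # no informative pair within the window
  res$statistic <- stat
  res$testable <- TRUE
  if (all(ri == 0)) { res$p_perm <- 1; return(res) }
  if (!is.null(seed)) set.seed(seed)
  perm <- .phi_perm_cpp(ri, as.numeric(pos), as.numeric(w),
                        as.integer(permutations))
  perm <- perm[!is.na(perm)]
  res$permutations_used <- length(perm)
  res$p_perm <- (1 + sum(perm <= stat)) / (1 + length(perm))
  res
}

#' @export
print.PhiResult <- function(x, ...) {
  if (!x$testable)
    cat("<PhiResult: not testable (too few informative sites)>\n")
  else
    cat(sprintf("<PhiResult: statistic %.4f over %d informative sites, p = %.4g (%d permutations)>\n",
                x$statistic, x$n_informative, x$p_perm,
                x$permutations_used))
  invisible(x)
}

# informative sites and the +/-1 walk for one (P, Q, C) triplet
triplet_walk <- function(codes, p, q, c) {
  ok <- codes[p, ] > 0L & codes[q, ] > 0L & codes[c, ] > 0L
  mP <- codes[c, ] == codes[p, ]
  mQ <- codes[c, ] == codes[q, ]
  info <- which(ok & xor(mP, mQ))
  steps <- ifelse(mP[info], 1L, -1L)
  list(cols = info, steps = steps)
}

#' Triplet breakpoint scan for recombination
#'
#' For each ordered triplet (parent P, parent Q, candidate recombinant C),
#' the informative sites are the columns where C matches exactly one of P
#' and Q. Encoding matches to P as +1 and matches to Q as -1 gives a walk
#' whose maximum descent (largest drop from a running maximum) is the test
#' statistic: a recombinant that switches from P-derived to Q-derived
#' sequence produces a long descent. The exact p-value is the probability
#' that a uniformly random arrangement of the m up-steps and n down-steps
#' attains a descent at least as large, computed by dynamic programming.
#' The reported breakpoint interval spans the maximal-descent run (from the
#' column where the running maximum was last attained to the column where
#' the maximum descent is reached).
#'
#' @param aln an [alignment_matrix()] with at least 3 taxa.
#' @param candidate_triplets optional data frame with columns `P`, `Q`,
#'   `C` (taxon names); defaults to all ordered triplets.
#' @param correction multiple-testing correction over the triplets tested:
#'   `"dunn-sidak"` (default) or `"bonferroni"`.
#' @return data frame of class `TripletScan`, one row per tested triplet:
#'   `child`, `parentP`, `parentQ`, `m`, `n`, `max_descent`, `p_exact`,
#'   `p_corrected`, `bp_start`, `bp_end` (alignment columns). Triplets with
#'   no informative sites are skipped.
#' @export
triplet_scan <- function(aln, candidate_triplets = NULL,
                         correction = c("dunn-sidak", "bonferroni")) {
  correction <- match.arg(correction)
  aln <- alignment_matrix(aln)
  if (nrow(aln) < 3L) stop("the triplet scan needs at least 3 taxa")
  codes <- aln_codes(aln)
  taxa <- rownames(aln)
  if (is.null(candidate_triplets)) {
    idx <- seq_along(taxa)
    grid <- expand.grid(P = idx, Q = idx, C = idx)
    grid <- grid[grid$P != grid$Q & grid$C != grid$P & grid$C != grid$Q, ,
                 drop = FALSE]
    candidate_triplets <- data.frame(P = taxa[grid$P], Q = taxa[grid$Q],
                                     C = taxa[grid$C],
                                     stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(candidate_triplets)), function(r) {
    p <- candidate_triplets$P[r]; q <- candidate_triplets$Q[r]
    ch <- candidate_triplets$C[r]
    wk <- triplet_walk(codes, p, q, ch)
    m <- sum(wk$steps == 1L); n <- sum(wk$steps == -1L)
    if (m + n == 0L) return(NULL)
    h <- cumsum(wk$steps)
    # running maximum including the height-0 start of the walk
    runmax <- cummax(c(0L, h))[-1L]
    drop <- runmax - h
    k <- max(0L, drop)
    p_exact <- .descent_pvalue_cpp(m, n, k)
    if (k > 0L) {
      trough <- which.max(drop)
      # the informative site where the running maximum was last attained
      # before the trough; when the maximum is the virtual start (height 0
      # before any step), the descent begins at the alignment start
      cand <- which(h[seq_len(trough)] == runmax[trough])
      bp_start <- if (length(cand)) wk$cols[max(cand)] else 1L
      bp_end <- wk$cols[trough]
    } else {
      bp_start <- NA_integer_; bp_end <- NA_integer_
    }
    data.frame(child = ch, parentP = p, parentQ = q, m = m, n = n,
               max_descent = k, p_exact = p_exact,
               bp_start = bp_start, bp_end = bp_end,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    out <- data.frame(child = character(), parentP = character(),
                      parentQ = character(), m = integer(), n = integer(),
                      max_descent = integer(), p_exact = numeric(),
                      bp_start = integer(), bp_end = integer(),
                      p_corrected = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("TripletScan", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  ntest <- nrow(out)
  out$p_corrected <- if (correction == "dunn-sidak")
    1 - (1 - out$p_exact)^ntest
  else pmin(1, out$p_exact * ntest)
  class(out) <- c("TripletScan", "data.frame")
  out
}

#' Minimum number of recombination events (four-gamete test with
#' Hudson-Kaplan thinning)
#'
#' Sites with exactly two states (after dropping gaps/N) are kept; every
#' pair is tested for the four-gamete condition; incompatible pairs define
#' open intervals in which at least one recombination event must fall.
#' Hudson-Kaplan thinning reduces these to a maximal set of disjoint
#' intervals whose size is the lower bound `rmin`.
#'
#' @param aln an [alignment_matrix()] with at least 4 taxa.
#' @return list of class `RminResult`: `rmin`, `incompatible_intervals`
#'   (data frame of thinned intervals, alignment columns), `per_bp`
#'   (`rmin` divided by the ungapped consensus length), `n_biallelic`.
#' @export
rmin <- function(aln) {
  aln <- alignment_matrix(aln)
  if (nrow(aln) < 4L) stop("rmin needs at least 4 taxa")
  codes <- aln_codes(aln)
  nstates <- apply(codes, 2L, function(col) length(unique(col[col > 0L])))
  bi <- which(nstates == 2L)
  ungapped_len <- max(consensus_positions(aln))
  intervals <- matrix(integer(0), ncol = 2L)
  if (length(bi) >= 2L) {
    pairs <- utils::combn(length(bi), 2L)
    inc <- apply(pairs, 2L, function(pr) {
      i <- bi[pr[1L]]; j <- bi[pr[2L]]
      x <- codes[, i]; y <- codes[, j]
      ok <- x > 0L & y > 0L
      if (sum(ok) < 4L) return(FALSE)
      length(unique(paste(x[ok], y[ok]))) == 4L
    })
    if (any(inc))
      intervals <- cbind(bi[pairs[1L, inc]], bi[pairs[2L, inc]])
  }
  if (nrow(intervals) == 0L) {
    out <- list(rmin = 0L,
                incompatible_intervals = data.frame(start = integer(),
                                                    end = integer()),
                per_bp = 0, n_biallelic = length(bi))
    class(out) <- "RminResult"
    return(out)
  }
  # Hudson-Kaplan: drop intervals containing another, then greedily pick
  # disjoint open intervals by increasing right endpoint
  ord <- order(intervals[, 2L], -intervals[, 1L])
  intervals <- intervals[ord, , drop = FALSE]
  chosen <- matrix(integer(0), ncol = 2L)
  last_right <- -Inf
  for (r in seq_len(nrow(intervals))) {
    a <- intervals[r, 1L]; b <- intervals[r, 2L]
    # open intervals (a, b): disjoint from the last chosen iff a >= last b
    if (a >= last_right) {
      chosen <- rbind(chosen, c(a, b))
      last_right <- b
    }
  }
  out <- list(rmin = nrow(chosen),
              incompatible_intervals = data.frame(start = chosen[, 1L],
                                                  end = chosen[, 2L]),
              per_bp = nrow(chosen) / ungapped_len,
              n_biallelic = length(bi))
  class(out) <- "RminResult"
  out
}

#' Per-region recombination-rate comparison across groups
#'
#' For each group alignment, computes the per-bp minimum-recombination rate
#' ([rmin()] divided by ungapped length) on three partitions: the full
#' sequence, exon 1 alone, and the sequence without exon 1. The exon-1
#' boundary is given per group as an alignment column. Groups are ranked
#' by their full-length per-bp rate.
#'
#' @param alignments named list of [alignment_matrix()] objects, one per
#'   group.
#' @param exon1_end named numeric vector: for each group, the last
#'   alignment column of exon 1 (`NA` to mark the partition undefined).
#' @return data frame with one row per group: per-bp rates for `full`,
#'   `exon1` and `rest` partitions, plus `rank_full`.
#' @export
compare_regions <- function(alignments, exon1_end) {
  stopifnot(is.list(alignments), !is.null(names(alignments)))
  rate <- function(aln) {
    if (is.null(aln) || nrow(aln) < 4L || ncol(aln) < 2L) return(NA_real_)
    rmin(aln)$per_bp
  }
  rows <- lapply(names(alignments), function(g) {
    aln <- alignment_matrix(alignments[[g]])
    e1 <- if (g %in% names(exon1_end)) exon1_end[[g]] else NA
    full <- rate(aln)
    exon1 <- rest <- NA_real_
    if (!is.na(e1) && e1 >= 2 && e1 < ncol(aln)) {
      exon1 <- rate(aln[, seq_len(e1), drop = FALSE])
      rest <- rate(aln[, (e1 + 1L):ncol(aln), drop = FALSE])
    }
    data.frame(group = g, full = full, exon1 = exon1, rest = rest,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rank_full <- rank(-out$full, ties.method = "min", na.last = "keep")
  out[order(out$rank_full), , drop = FALSE]
}
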