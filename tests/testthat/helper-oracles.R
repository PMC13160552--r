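# Independent oracles used across the suite.  Each re-derives a quantity by
# brute force / closed form, never through the code path it checks.

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

# mutate a DNA string at k random positions (always to a different base)
mutate_dna <- function(x, k) {
  v <- strsplit(x, "")[[1L]]
  idx <- sample(length(v), k)
  for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  paste(v, collapse = "")
}

# --- exhaustive free-end-gap alignment oracle -------------------------------
# Enumerates every monotone alignment path of two short sequences, finds the
# maximum score (match +1, mismatch -1, gap -2, end gaps free), and returns
# the set of identities (matches / total columns) achieved by score-optimal
# alignments.
oracle_identity_set <- function(a, b) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  best <- new.env(); best$score <- -Inf; best$ids <- numeric(0)
  rec <- function(i, j, score, matches, cols) {
    if (i > n && j > m) {
      if (score > best$score) { best$score <- score; best$ids <- numeric(0) }
      if (score == best$score)
        best$ids <- c(best$ids, matches / cols)
      return(invisible())
    }
    # bound: even matching everything left cannot beat the best score
    if (score + min(n - i + 1L, m - j + 1L) < best$score)
      return(invisible())
    # terminal gaps are free
    if (i > n) return(rec(i, m + 1L, score, matches, cols + (m - j + 1L)))
    if (j > m) return(rec(n + 1L, j, score, matches, cols + (n - i + 1L)))
    rec(i + 1L, j + 1L,
        score + if (av[i] == bv[j]) 1L else -1L,
        matches + (av[i] == bv[j]), cols + 1L)
    gap_cost_a <- if (j == 1L || j > m) 0L else -2L
    gap_cost_b <- if (i == 1L || i > n) 0L else -2L
    rec(i + 1L, j, score + gap_cost_a, matches, cols + 1L)
    rec(i, j + 1L, score + gap_cost_b, matches, cols + 1L)
  }
  rec(1L, 1L, 0L, 0L, 0L)
  unique(round(best$ids, 10))
}

# --- transitive-closure component oracle ------------------------------------
# Components of an undirected graph by repeated closure over an adjacency
# matrix (no igraph).
oracle_components <- function(n, edges) {
  adj <- diag(TRUE, n)
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    adj[edges[r, 1L], edges[r, 2L]] <- TRUE
    adj[edges[r, 2L], edges[r, 1L]] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  comp <- integer(n); cur <- 0L
  for (i in seq_len(n)) if (!comp[i]) {
    cur <- cur + 1L
    comp[which(adj[i, ] > 0)] <- cur
  }
  comp
}

# --- descent-statistic enumeration oracle -----------------------------------
# P(max descent >= k) by enumerating every arrangement of m up and n down
# steps.
oracle_descent_p <- function(m, n, k) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  idx <- utils::combn(m + n, m)
  hit <- 0L
  for (i in seq_len(ncol(idx))) {
    s <- rep(-1L, m + n); s[idx[, i]] <- 1L
    h <- cumsum(s)
    d <- cummax(c(0L, h))[-1L] - h
    if (max(d) >= k) hit <- hit + 1L
  }
  hit / ncol(idx)
}

# random binary alignment whose columns carry 1-4 minor alleles (a skewed
# site-frequency spectrum, like real polymorphism data); keeps the number of
# incompatible pairs moderate so the exhaustive oracle below stays exact and
# fast
random_binary_aln <- function(ntaxa, nsites) {
  m <- matrix("A", ntaxa, nsites,
              dimnames = list(paste0("t", seq_len(ntaxa)), NULL))
  for (j in seq_len(nsites)) {
    minor <- sample(ntaxa, sample(1:4, 1L))
    m[minor, j] <- "C"
  }
  m
}

# --- minimal recombination-interval oracle ----------------------------------
# Minimal number of inter-site breakpoints hitting every incompatible
# interval, by exhaustive subset search of increasing size.
oracle_rmin <- function(aln) {
  m <- aln
  S <- ncol(m)
  codes <- apply(m, 2L, function(col) match(col, c("A", "C", "G", "T")))
  nst <- apply(codes, 2L, function(col) length(unique(col[!is.na(col)])))
  bi <- which(nst == 2L)
  ivs <- list()
  if (length(bi) >= 2L) {
    prs <- utils::combn(length(bi), 2L)
    for (c2 in seq_len(ncol(prs))) {
      i <- bi[prs[1L, c2]]; j <- bi[prs[2L, c2]]
      ok <- !is.na(codes[, i]) & !is.na(codes[, j])
      if (sum(ok) < 4L) next
      if (length(unique(paste(codes[ok, i], codes[ok, j]))) == 4L)
        ivs[[length(ivs) + 1L]] <- c(i, j)
    }
  }
  if (!length(ivs)) return(0L)
  # drop intervals that contain another interval: hitting the inner one
  # hits the outer one too
  keep <- vapply(seq_along(ivs), function(i) {
    !any(vapply(seq_along(ivs), function(j) {
      j != i && ivs[[j]][1L] >= ivs[[i]][1L] && ivs[[j]][2L] <= ivs[[i]][2L] &&
        !(ivs[[j]][1L] == ivs[[i]][1L] && ivs[[j]][2L] == ivs[[i]][2L] && j > i)
    }, logical(1L)))
  }, logical(1L))
  ivs <- ivs[keep]
  # exact branch and bound: every hitting set stabs the earliest-ending
  # interval, so branch over all breakpoints inside it
  solve <- function(rem, bound) {
    if (!length(rem)) return(0L)
    if (bound <= 0L) return(Inf)
    rends <- vapply(rem, `[`, integer(1L), 2L)
    iv <- rem[[which.min(rends)]]
    best <- Inf
    for (bp in iv[1L]:(iv[2L] - 1L)) {
      rest <- Filter(function(v) !(bp >= v[1L] && bp < v[2L]), rem)
      sub <- solve(rest, min(bound, best) - 1L)
      if (sub + 1L < best) best <- sub + 1L
    }
    best
  }
  solve(ivs, length(ivs))
}

# --- parsimony oracle for the refined incompatibility -----------------------
# Minimum extra steps for a site pair over every unrooted topology, scored
# by phangorn parsimony.
oracle_ri <- function(site_i, site_j) {
  taxa <- paste0("t", seq_along(site_i))
  mat <- rbind(site_i, site_j)
  colnames(mat) <- taxa
  dat <- phangorn::phyDat(t(mat), type = "USER",
                          levels = sort(unique(c(site_i, site_j))))
  trees <- phangorn::allTrees(length(taxa), rooted = FALSE,
                              tip.label = taxa)
  total <- min(phangorn::parsimony(trees, dat))
  k_i <- length(unique(site_i)); k_j <- length(unique(site_j))
  total - (k_i - 1L) - (k_j - 1L)
}

# --- drive mating-class enumeration oracle ----------------------------------
# Expected next-generation driver frequency by enumerating the three mating
# classes and their surviving spores.
oracle_next_gen <- function(p, c) {
  # D x D: 4 driver spores, all rescued
  wDD <- p^2;          survD_DD <- 4; survN_DD <- 0
  # D x N: 2 driver spores rescued, 2 non-driver spores die w.p. c
  wDN <- 2 * p * (1 - p); survD_DN <- 2; survN_DN <- 2 * (1 - c)
  # N x N: no poison
  wNN <- (1 - p)^2;    survD_NN <- 0; survN_NN <- 4
  num <- wDD * survD_DD + wDN * survD_DN + wNN * survD_NN
  den <- num + wDD * survN_DD + wDN * survN_DN + wNN * survN_NN
  num / den
}

# --- small builders ----------------------------------------------------------

aln_from_strings <- function(x) alignment_matrix(x)

# a six-exon toy gene model with controllable exon-1 length (mod 3) and a
# clean reading frame
toy_gene <- function(exon_lens = c(24, 18, 15, 12, 18, 21),
                     intron_lens = c(8, 9, 7, 8, 10), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  anc <- ancestor_model(exon_lens, intron_lens)
  layout <- wtfkit:::anc_layout(anc)
  gene <- wtfkit:::build_ancestor_gene(anc, layout)
  gene_model("toy", wtfkit:::int_to_seq(gene), layout$exons)
}

# destroy any incidental poison-start ATGs so a test can start from an
# antidote-only gene
strip_poison_starts <- function(model) {
  repeat {
    ps <- suppressWarnings(detect_poison_starts(model))
    if (!ps$exon2_atg && !ps$intron1_atg) return(model)
    v <- strsplit(model$seq, "")[[1L]]
    if (ps$exon2_atg)
      v[model$exons$start[2L] + ps$exon2_atg_pos - 1L] <- "C"
    if (ps$intron1_atg)
      v[model$exons$end[1L] + ps$intron1_atg_pos] <- "C"
    model <- gene_model(model$gene_id, paste(v, collapse = ""),
                        model$exons)
  }
}
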