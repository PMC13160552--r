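test_that("refined incompatibility scores the classic gamete configurations", {
  # binary pair with 3 of 4 gametes: compatible
  expect_equal(as.numeric(refined_incompatibility(c("A", "A", "C", "C"),
                                                  c("A", "C", "C", "C"))),
               0)
  # all four gametes: one homoplasy required
  expect_equal(as.numeric(refined_incompatibility(c("A", "A", "C", "C"),
                                                  c("A", "C", "A", "C"))),
               1)
  # gaps drop taxa pairwise; < 4 complete taxa scores 0 with a flag
  r <- refined_incompatibility(c("A", "A", "C", "-"), c("A", "C", "-", "C"))
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "low_data"))
})

test_that("refined incompatibility equals the brute-force parsimony minimum", {
  # the 8-taxon 3-state x 2-state case: exhaustive search over all 10395
  # unrooted topologies scored by parsimony
  s1 <- c("A", "A", "C", "C", "G", "G", "A", "C")
  s2 <- c("A", "C", "A", "C", "A", "C", "C", "A")
  expect_equal(as.numeric(refined_incompatibility(s1, s2)), oracle_ri(s1, s2))
  # random 6-taxon site pairs against the 105-topology oracle
  set.seed(19)
  for (i in 1:8) {
    a <- sample(c("A", "C", "G"), 6, TRUE)
    b <- sample(c("A", "C"), 6, TRUE)
    expect_equal(as.numeric(refined_incompatibility(a, b)), oracle_ri(a, b),
                 info = paste(paste(a, collapse = ""), paste(b, collapse = "")))
  }
})

test_that("phi_test handles degenerate alignments and is seed-reproducible", {
  # duplicated identical rows: no informative sites, not testable, p = 1
  a <- alignment_matrix(matrix(rep(strsplit("ACGTACGT", "")[[1L]], 4),
                               nrow = 4, byrow = TRUE,
                               dimnames = list(paste0("t", 1:4), NULL)))
  r <- phi_test(a)
  expect_false(r$testable)
  expect_equal(r$p_perm, 1)
  expect_error(phi_test(a[1:3, ]), "4 taxa")

  # recombinant mosaic alignment: permutation p-value reproducible by seed
  set.seed(5)
  blockA <- rnd_dna(120); blockB <- mutate_dna(blockA, 45)
  taxa <- c(a1 = paste0(blockA, blockA), a2 = paste0(blockA, blockA),
            b1 = paste0(blockB, blockB), b2 = paste0(blockB, blockB),
            rec = paste0(blockA, blockB), rec2 = paste0(blockA, blockB))
  aln <- alignment_matrix(taxa)
  r1 <- phi_test(aln, permutations = 300, seed = 9L)
  r2 <- phi_test(aln, permutations = 300, seed = 9L)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_true(r1$testable)
})

test_that("triplet scan scores clean mosaics and exact descent p-values", {
  # C identical to P: no down steps, k = 0, p = 1
  P <- "ACACACACAC"; Q <- "GTGTGTGTGT"
  aln <- alignment_matrix(c(P = P, Q = Q, C = P))
  ts <- triplet_scan(aln, data.frame(P = "P", Q = "Q", C = "C"))
  expect_equal(ts$max_descent, 0L)
  expect_equal(ts$p_exact, 1)

  # hand-built walk UUUDDD (both orientations scanned; the descent of the
  # better orientation is 3) with the enumeration oracle
  p <- "AAAAAA"; q <- "CCCCCC"; ch <- "AAACCC"
  aln2 <- alignment_matrix(c(P = p, Q = q, C = ch, O = "GGGGGG"))
  ts2 <- triplet_scan(aln2, data.frame(P = "P", Q = "Q", C = "C"))
  expect_equal(ts2$m, 3L)
  expect_equal(ts2$n, 3L)
  expect_equal(ts2$max_descent, 3L)
  expect_equal(ts2$p_exact, oracle_descent_p(3, 3, 3))
  # the reported interval spans the crossover
  expect_true(ts2$bp_start <= 4L && ts2$bp_end >= 3L)

  # Dunn-Sidak correction over the number of triplets tested
  full <- triplet_scan(aln2)
  expect_equal(full$p_corrected,
               1 - (1 - full$p_exact)^nrow(full))
})

test_that("descent DP equals exhaustive enumeration for all m, n <= 6", {
  for (m in 0:6) for (n in 0:6) {
    if (m + n == 0) next
    for (k in 1:max(1, n)) {
      expect_equal(wtfkit:::.descent_pvalue_cpp(m, n, k),
                   oracle_descent_p(m, n, k), tolerance = 1e-12,
                   info = sprintf("m=%d n=%d k=%d", m, n, k))
    }
  }
})

test_that("rmin matches hand cases and the exhaustive interval oracle", {
  # two sites with all four gametes: one event
  a <- alignment_matrix(c(t1 = "AA", t2 = "AC", t3 = "CA", t4 = "CC"))
  r <- rmin(a)
  expect_equal(r$rmin, 1L)
  expect_equal(nrow(r$incompatible_intervals), 1L)

  # fully compatible alignment
  b <- alignment_matrix(c(t1 = "AAAA", t2 = "AACC", t3 = "CCCC",
                          t4 = "CCCC"))
  expect_equal(rmin(b)$rmin, 0L)

  # skewed site-frequency fixtures (1-4 minor alleles per column) alongside
  # the dense ones exercised in the acceptance suite
  set.seed(23)
  for (i in 1:10) {
    aln <- alignment_matrix(random_binary_aln(8L, 20L))
    expect_equal(rmin(aln)$rmin, oracle_rmin(aln), info = paste("rep", i))
  }
})

test_that("regional rate comparison ranks conversion-rich partitions first", {
  # incompatibilities only inside the first 50 columns ("exon 1")
  four_gamete_block <- function(ncol_block) {
    rows <- c("AA", "AC", "CA", "CC", "AA", "CC", "AC", "CA")
    vapply(rows, function(x) strsplit(x, "")[[1L]], character(2L))
  }
  set.seed(9)
  m <- matrix("A", nrow = 8, ncol = 200,
              dimnames = list(paste0("t", 1:8), NULL))
  blk <- four_gamete_block()
  m[, 10] <- blk[1L, ]; m[, 30] <- blk[2L, ]
  g_hot <- alignment_matrix(m)
  m2 <- m; m2[, 10] <- "A"; m2[, 30] <- "A"
  g_cold <- alignment_matrix(m2)
  tab <- compare_regions(list(hot = g_hot, cold = g_cold),
                         exon1_end = c(hot = 50, cold = 50))
  expect_equal(tab$group[tab$rank_full == 1L], "hot")
  hot <- tab[tab$group == "hot", ]
  expect_gt(hot$exon1, hot$rest)
  expect_equal(hot$rest, 0)
  cold <- tab[tab$group == "cold", ]
  expect_equal(cold$full, 0)
  expect_equal(cold$exon1, 0)
})
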