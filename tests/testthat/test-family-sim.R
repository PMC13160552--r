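small_params <- function(...) {
  family_sim_params(n_strains = 4L, n_loci = 3L, generations = 60L,
                    flank_len = 120L,
                    anc = ancestor_model(c(60, 45, 45), c(20, 20)), ...)
}

test_that("identical parameters and seed give identical output", {
  s1 <- simulate_family(small_params(seed = 11L))
  s2 <- simulate_family(small_params(seed = 11L))
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$alignments, s2$alignments)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$tree$newick, s2$tree$newick)
  s3 <- simulate_family(small_params(seed = 12L))
  expect_false(identical(s1$genomes, s3$genomes))
})

test_that("rate-zero channels are silent and mu = 0 freezes the sequences", {
  s <- simulate_family(small_params(conv_rate = 0, seed = 5L))
  expect_false(any(s$truth$kind == "conversion"))

  s0 <- simulate_family(small_params(mu = 0, dup_rate = 0, conv_rate = 0,
                                     pseudo_rate = 0, seed = 5L))
  anc <- s0$ancestor$seq
  for (gm in s0$gene_models) expect_identical(gm$seq, anc)
  expect_equal(nrow(s0$truth), 0L)
})

test_that("gene models embed correctly in the emitted genomes and GFF", {
  s <- simulate_family(small_params(seed = 9L))
  for (strain in names(s$genomes)) {
    g <- s$genomes[[strain]]
    ft <- s$models[[strain]]
    genes <- ft[ft$type == "gene", ]
    for (r in seq_len(nrow(genes))) {
      gm <- s$gene_models[[sub("ID=([^;]+);.*", "\\1",
                               genes$attributes[r])]]
      expect_identical(substring(g$seq, genes$start[r], genes$end[r]),
                       gm$seq)
    }
  }
})

test_that("duplication counts follow the branching-process expectation", {
  # one strain, one starting gene, per-generation duplication d: every gene
  # duplicates independently, so E[N_G] = (1 + d)^G
  d <- 0.05; G <- 30L; R <- 200L
  counts <- vapply(seq_len(R), function(r) {
    p <- family_sim_params(n_strains = 1L, n_loci = 1L, generations = G,
                           mu = 0, dup_rate = d, conv_rate = 0,
                           pseudo_rate = 0, flank_len = 0L,
                           anc = ancestor_model(c(30, 30), c(10)),
                           seed = 100L + r)
    length(simulate_family(p)$gene_models)
  }, numeric(1L))
  expected <- (1 + d)^G
  se <- sd(counts) / sqrt(R)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("event counts per channel match their binomial rate laws", {
  # fixed gene count (no duplication): conversion and pseudogenization are
  # Bernoulli per gene-generation, so totals are Binomial(n_genes * G, rate)
  G <- 50L; rate <- 0.02; R <- 200L; n_genes <- 2L
  conv <- integer(R); pseu <- integer(R)
  for (r in seq_len(R)) {
    p <- family_sim_params(n_strains = 1L, n_loci = n_genes,
                           generations = G, mu = 0, dup_rate = 0,
                           conv_rate = rate, pseudo_rate = rate,
                           flank_len = 0L,
                           anc = ancestor_model(c(30, 30), c(10)),
                           seed = 300L + r)
    s <- simulate_family(p)
    conv[r] <- sum(s$truth$kind == "conversion")
    pseu[r] <- sum(s$truth$kind == "pseudogenization")
  }
  ntrial <- n_genes * G
  for (counts in list(conv, pseu)) {
    breaks <- c(-0.5, 0.5, 1.5, 2.5, 3.5, Inf)
    obs <- table(cut(counts, breaks))
    pr <- c(dbinom(0:3, ntrial, rate), 1 - pbinom(3, ntrial, rate))
    gof <- suppressWarnings(chisq.test(as.vector(obs), p = pr))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("clonal-null output is exactly homoplasy-free", {
  for (s in 1:3) {
    nul <- make_clonal_null(small_params(seed = 40L + s))
    pooled <- pooled_alignment(nul)
    expect_equal(rmin(pooled)$rmin, 0L)
    r <- phi_test(pooled)
    expect_true(r$statistic == 0 || !r$testable)
    expect_equal(r$p_perm, 1)
  }
})

test_that("infinite-sites saturation raises the advisory error", {
  p <- small_params(mu = 0.05, seed = 1L, infinite_sites = TRUE)
  expect_error(simulate_family(p), "longer ancestor")
})

test_that("single-crossover injection honours its boundary contracts", {
  set.seed(2)
  A <- rnd_dna(50); B <- rnd_dna(50)
  expect_identical(inject_single_crossover(A, B, 50)$seq, A)
  expect_identical(inject_single_crossover(A, B, 0)$seq, B)
  mid <- inject_single_crossover(A, B, 25)
  expect_identical(mid$seq, paste0(substr(A, 1, 25), substr(B, 26, 50)))
  expect_false(mid$seq == A || mid$seq == B)
  expect_equal(mid$truth$breakpoint, 25)
  expect_error(inject_single_crossover(A, B, 51), "breakpoint")
  expect_error(inject_single_crossover(A, substr(B, 1, 49), 10),
               "same alignment")
})
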