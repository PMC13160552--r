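test_that("seeded search finds planted queries on both strands only", {
  set.seed(101)
  query <- rnd_dna(600)
  genome_seq <- paste0(rnd_dna(2000), query, rnd_dna(2500))
  genome <- seq_record_set("chr1", genome_seq)
  hits <- find_family_members(genome, seq_record_set("q", query))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
  expect_lte(hits$start, 2001L)
  expect_gte(hits$end, 2600L)
  expect_equal(hits$identity, 1)
  expect_lt(hits$evalue, 1e-5)

  # reverse-complement placement is reported on the minus strand
  genome_rc <- seq_record_set("chr1",
                              paste0(rnd_dna(1500), revcomp(query),
                                     rnd_dna(1000)))
  hits_rc <- find_family_members(genome_rc, seq_record_set("q", query))
  expect_equal(nrow(hits_rc), 1L)
  expect_equal(hits_rc$strand, "-")
  expect_lte(hits_rc$start, 1501L)
  expect_gte(hits_rc$end, 2100L)

  # no shared seed-length word: no hits
  none <- find_family_members(seq_record_set("chr1", rnd_dna(4000)),
                              seq_record_set("q", rnd_dna(500)))
  expect_equal(nrow(none), 0L)

  expect_error(find_family_members(genome,
                                   seq_record_set("q", "ACGTACG")),
               "seed length")
})

test_that("diverged copies are still found under the E-value cutoff", {
  set.seed(102)
  query <- rnd_dna(800)
  copy <- mutate_dna(query, 80)  # 10% divergence
  genome <- seq_record_set("chr1",
                           paste0(rnd_dna(1200), copy, rnd_dna(900)))
  hits <- find_family_members(genome, seq_record_set("q", query))
  expect_equal(nrow(hits), 1L)
  expect_gt(hits$identity, 0.85)
})

test_that("exon-structure transfer maps boundaries through the alignment", {
  ref <- toy_gene(seed = 111)
  genome <- seq_record_set("c1", paste0(rnd_dna(300), ref$seq,
                                        rnd_dna(250)))
  cand <- list(contig = "c1", start = 301L,
               end = 300L + nchar(ref$seq), strand = "+", strain = "S1")
  m <- transfer_exon_structure(cand, genome, list(ref))
  expect_identical(m$exons, ref$exons)
  expect_identical(spliced_seq(m), spliced_seq(ref))
  expect_equal(attr(m, "ref_identity"), 1)
  expect_false(attr(m, "tie"))

  # one substitution: same structure, identity < 1
  mut <- mutate_dna(ref$seq, 1)
  genome2 <- seq_record_set("c1", paste0(rnd_dna(300), mut, rnd_dna(250)))
  m2 <- transfer_exon_structure(cand, genome2, list(ref))
  expect_identical(m2$exons, ref$exons)
  expect_lt(attr(m2, "ref_identity"), 1)

  # equal-identity references: deterministic first-in-order tie, flagged
  ref2 <- ref; ref2$gene_id <- "toy_copy"
  m3 <- transfer_exon_structure(cand, genome, list(ref, ref2))
  expect_equal(attr(m3, "ref_used"), "toy")
  expect_true(attr(m3, "tie"))

  # identity below the floor: candidate rejected
  stranger <- gene_model("x", rnd_dna(nchar(ref$seq)), ref$exons)
  expect_null(transfer_exon_structure(cand, genome2, list(stranger)))
})

test_that("pseudogene calling implements the three disruption rules", {
  intact <- gene_model("ok", "ATGAAATAG", data.frame(start = 1, end = 9))
  r <- call_pseudogene(intact)
  expect_equal(r$status, "intact")
  expect_equal(nrow(r$disruptions), 0L)

  # internal stop at codon 2 of a 100-codon CDS
  cds <- paste0("ATG", "TAA", paste(rep("GGA", 97), collapse = ""), "TGA")
  ps <- call_pseudogene(gene_model("p", cds,
                                   data.frame(start = 1, end = 300)))
  expect_equal(ps$status, "pseudogene")
  expect_true("stop_gain" %in% ps$disruptions$type)
  expect_equal(ps$disruptions$codon[ps$disruptions$type == "stop_gain"], 2L)

  # stop within the final 10% of codons does not count as premature
  cds_late <- paste0("ATG", paste(rep("GGA", 97), collapse = ""), "TAATGA")
  late <- call_pseudogene(gene_model("l", cds_late,
                                     data.frame(start = 1, end = 300)))
  expect_equal(late$status, "intact")

  # frameshift: spliced length not a multiple of 3
  fs <- call_pseudogene(gene_model("f", paste0("ATG", rnd_dna(298)),
                                   data.frame(start = 1, end = 301)))
  expect_equal(fs$status, "pseudogene")
  expect_true("frameshift" %in% fs$disruptions$type)

  ms <- call_pseudogene(gene_model("m", "CTGAAATTTGGG",
                                   data.frame(start = 1, end = 12)))
  expect_true("missing_start" %in% ms$disruptions$type)
})

test_that("poison-start detection respects frame and window", {
  g <- strip_poison_starts(toy_gene(seed = 121))
  ps0 <- detect_poison_starts(g)
  expect_false(ps0$exon2_atg)
  expect_false(ps0$intron1_atg)
  # in-frame ATG at the start of exon 2 (exon 1 length 24 = 0 mod 3)
  v <- strsplit(g$seq, "")[[1L]]
  e2 <- g$exons$start[2L]
  v[e2:(e2 + 2L)] <- c("A", "T", "G")
  ps1 <- detect_poison_starts(gene_model("g", paste(v, collapse = ""),
                                         g$exons))
  expect_true(ps1$exon2_atg)
  expect_equal(ps1$exon2_atg_pos, 1L)
  # an out-of-frame exon-2 ATG is ignored
  v2 <- strsplit(g$seq, "")[[1L]]
  v2[(e2 + 1L):(e2 + 3L)] <- c("A", "T", "G")
  v2[e2] <- "C"
  ps2 <- detect_poison_starts(gene_model("g", paste(v2, collapse = ""),
                                         g$exons))
  expect_false(ps2$exon2_atg)
  # single-exon models warn and return FALSE flags
  single <- gene_model("s", "ATGAAATAG", data.frame(start = 1, end = 9))
  expect_warning(psx <- detect_poison_starts(single), "single-exon")
  expect_false(psx$exon2_atg)
})

test_that("flank-identity locus assignment groups true orthologs", {
  set.seed(131)
  flank_a5 <- rnd_dna(400); flank_a3 <- rnd_dna(400)
  flank_b5 <- rnd_dna(400); flank_b3 <- rnd_dna(400)
  gene1 <- rnd_dna(300); gene2 <- rnd_dna(300)
  mk <- function(strain, f5a, f3a, f5b, f3b) {
    contig <- paste0(f5a, gene1, f3a, f5b, gene2, f3b)
    list(genome = seq_record_set(paste0(strain, "_c"), contig),
         m1 = gene_model(paste0(strain, "_g1"), gene1,
                         data.frame(start = 1, end = 300), strain = strain,
                         contig = paste0(strain, "_c"), start = 401L,
                         end = 700L),
         m2 = gene_model(paste0(strain, "_g2"), gene2,
                         data.frame(start = 1, end = 300), strain = strain,
                         contig = paste0(strain, "_c"), start = 1501L,
                         end = 1800L))
  }
  s1 <- mk("S1", flank_a5, flank_a3, flank_b5, flank_b3)
  # strain 2 shares slightly mutated flanks: same loci
  s2 <- mk("S2", mutate_dna(flank_a5, 10), mutate_dna(flank_a3, 10),
           mutate_dna(flank_b5, 10), mutate_dna(flank_b3, 10))
  res <- assign_loci(list(s1$m1, s1$m2, s2$m1, s2$m2),
                     list(S1 = s1$genome, S2 = s2$genome),
                     flank_len = 400L)
  a <- res$assignment
  expect_equal(a$locus[a$gene_id == "S1_g1"], a$locus[a$gene_id == "S2_g1"])
  expect_equal(a$locus[a$gene_id == "S1_g2"], a$locus[a$gene_id == "S2_g2"])
  expect_false(a$locus[a$gene_id == "S1_g1"] == a$locus[a$gene_id == "S1_g2"])
  expect_equal(dim(res$presence), c(2L, 2L))
  expect_true(all(res$presence == 1L))

  # unrelated random flanks in a third strain: its genes get fresh loci
  s3 <- mk("S3", rnd_dna(400), rnd_dna(400), rnd_dna(400), rnd_dna(400))
  res3 <- assign_loci(list(s1$m1, s1$m2, s2$m1, s2$m2, s3$m1, s3$m2),
                      list(S1 = s1$genome, S2 = s2$genome,
                           S3 = s3$genome), flank_len = 400L)
  expect_equal(length(unique(res3$assignment$locus)), 4L)

  # permutation invariance of the resulting partition
  perm <- c(4, 1, 5, 3, 6, 2)
  res_p <- assign_loci(list(s1$m1, s1$m2, s2$m1, s2$m2, s3$m1, s3$m2)[perm],
                       list(S1 = s1$genome, S2 = s2$genome,
                            S3 = s3$genome), flank_len = 400L)
  part <- function(res) {
    sp <- split(res$assignment$gene_id, res$assignment$locus)
    unname(lapply(sp, sort)[order(vapply(sp, min, ""))])
  }
  expect_identical(part(res3), part(res_p))
})

test_that("solo-LTR flagging needs identity, coverage and proximity", {
  set.seed(141)
  ltr <- rnd_dna(250)
  gene <- rnd_dna(300)
  lib <- seq_record_set("ltr1", ltr)
  mk_genome <- function(upstream) {
    seq_record_set("c", paste0(rnd_dna(400), upstream, gene, rnd_dna(700)))
  }
  model_at <- function(genome_len_before) {
    gene_model("g", gene, data.frame(start = 1, end = 300), contig = "c",
               start = genome_len_before + 1L,
               end = genome_len_before + 300L)
  }
  # LTR copy planted 50 bp upstream of the gene
  g1 <- mk_genome(paste0(ltr, rnd_dna(50)))
  expect_true(flag_solo_ltr(model_at(400 + 250 + 50), g1, lib))
  # no LTR anywhere near
  g2 <- mk_genome(rnd_dna(300))
  expect_false(flag_solo_ltr(model_at(700), g2, lib))
  # a decayed copy at ~0.6 identity stays below the floor
  g3 <- mk_genome(paste0(mutate_dna(ltr, 100), rnd_dna(50)))
  expect_false(flag_solo_ltr(model_at(700), g3, lib))
  expect_error(flag_solo_ltr(model_at(700), g3,
                             seq_record_set(character(0), character(0))),
               "non-empty")
})
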