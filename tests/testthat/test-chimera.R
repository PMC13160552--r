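test_that("chimeras concatenate the parental exon content", {
  A <- toy_gene(seed = 51)
  B <- toy_gene(seed = 52)
  B$gene_id <- "toyB"
  chi <- build_chimera(A, B, k = 5)
  spl <- function(m, idx) paste(substring(m$seq, m$exons$start[idx],
                                          m$exons$end[idx]), collapse = "")
  # exons 1-5 from A, exon 6 from B (the last-exon swap design)
  expect_identical(spliced_seq(chi), paste0(spl(A, 1:5), spl(B, 6)))
  expect_equal(nchar(spliced_seq(chi)),
               nchar(spl(A, 1:5)) + nchar(spl(B, 6)))
  # deterministic
  expect_identical(spliced_seq(build_chimera(A, B, k = 5)),
                   spliced_seq(chi))
  # k = 2 variant takes B's introns downstream of the junction
  chi2 <- build_chimera(A, B, k = 2)
  expect_identical(spliced_seq(chi2), paste0(spl(A, 1:2), spl(B, 3:6)))
  expect_identical(intron_seq(chi2, 3), intron_seq(B, 3))
  expect_error(build_chimera(A, B, k = 6), "no exons")
  shortB <- gene_model("sB", B$seq, B$exons[1:3, ])
  expect_error(build_chimera(A, shortB, k = 4), "no exons")
})

test_that("isoform derivation follows the exon2 > intron1 start priority", {
  g <- toy_gene(exon_lens = c(24, 18, 15, 12, 18, 21), seed = 61)
  # build an exon-2 ATG in frame: exon1 length 24, so spliced position 25
  v <- strsplit(g$seq, "")[[1L]]
  e2 <- g$exons$start[2L]
  v[e2:(e2 + 2L)] <- c("A", "T", "G")
  g2 <- gene_model("g2", paste(v, collapse = ""), g$exons)
  ps <- detect_poison_starts(g2)
  expect_true(ps$exon2_atg)
  iso <- derive_isoforms(g2)
  expect_equal(iso$start_used, "exon2_atg")
  expect_true(startsWith(iso$poison_cds, "ATG"))
  # the poison is an in-frame suffix of the antidote
  expect_true(endsWith(iso$antidote_cds, iso$poison_cds))
  expect_equal(nchar(iso$poison_cds) %% 3L, 0L)

  # a gene with neither start is antidote-only (suppressor-like)
  g0 <- strip_poison_starts(toy_gene(seed = 62))
  iso0 <- derive_isoforms(g0)
  expect_equal(iso0$start_used, "none")
  expect_equal(iso0$poison_cds, "")
})

test_that("intron-1 poison starts must be frame-continuous with exon 2", {
  g <- strip_poison_starts(toy_gene(exon_lens = c(24, 18, 15, 12, 18, 21),
                                    seed = 63))
  # place an ATG in the intron-1 tail with tail length t == o1 mod 3:
  # o1 = 24 so t must be 0 mod 3; tail of 6 nt ending at the intron end
  v <- strsplit(g$seq, "")[[1L]]
  iend <- g$exons$start[2L] - 1L
  v[(iend - 5L):(iend - 3L)] <- c("A", "T", "G")
  gi <- gene_model("gi", paste(v, collapse = ""), g$exons)
  ps <- detect_poison_starts(gi)
  expect_true(ps$intron1_atg)
  iso <- derive_isoforms(gi)
  expect_equal(iso$start_used, "intron1_atg")
  # retained tail + exon 2..end, in frame
  expect_true(startsWith(iso$poison_cds, "ATG"))
  expect_equal(nchar(iso$poison_cds) %% 3L, 0L)
  # frame-breaking placement (tail length not 0 mod 3) is not a start
  v2 <- strsplit(g$seq, "")[[1L]]
  v2[(iend - 4L):(iend - 2L)] <- c("A", "T", "G")
  gb <- gene_model("gb", paste(v2, collapse = ""), g$exons)
  expect_false(detect_poison_starts(gb)$intron1_atg)
})

test_that("poison-start insertion is detectable, shifted by 3, reversible", {
  g <- strip_poison_starts(toy_gene(seed = 64))
  expect_false(detect_poison_starts(g)$exon2_atg)
  gi <- insert_poison_start(g)
  ps <- detect_poison_starts(gi)
  expect_true(ps$exon2_atg || ps$intron1_atg)
  expect_equal(nchar(spliced_seq(gi)), nchar(spliced_seq(g)) + 3L)
  expect_equal(nchar(gi$seq), nchar(g$seq) + 3L)
  # derive after insertion: the poison begins at the inserted ATG
  iso <- derive_isoforms(gi)
  expect_true(startsWith(iso$poison_cds, "ATG"))
  # idempotence rule: a second insertion errors unless forced
  expect_error(insert_poison_start(gi), "already present")
  expect_s3_class(insert_poison_start(gi, force = TRUE), "GeneModel")
  # byte-identical round trip
  back <- remove_poison_start(gi)
  expect_identical(back$seq, g$seq)
  expect_identical(back$exons, g$exons)
})

test_that("PY motif scanning matches the [LP]P.Y pattern", {
  expect_equal(py_motif_scan("MLPAYQQ"), 2L)
  expect_equal(py_motif_scan("MPPNYAA"), 2L)
  expect_equal(py_motif_scan("MAAAA"), integer(0))
  # overlapping and windowed matches ("LPPY" at 1, "PPAY" at 5)
  expect_equal(py_motif_scan("LPPYPPAY"), c(1L, 5L))
  expect_equal(py_motif_scan("LPPYPPAY", n_terminal_window = 3), 1L)
  expect_equal(py_motif_scan("PPPYY"), c(1L, 2L))
})

test_that("poison/antidote segment comparison flags the parental mismatch", {
  A <- toy_gene(seed = 71)
  B <- toy_gene(seed = 72)
  B$gene_id <- "toyB"
  chi <- build_chimera(A, B, k = 5)
  rep_tab <- compare_poison_antidote(list(chimera = chi, A = A, B = B),
                                     k = 5)
  self <- rep_tab[rep_tab$self_match, ]
  expect_true(all(self$segment_identity == 1))
  # the chimera's swapped segment is B's, so it mismatches A's antidote
  chiA <- rep_tab[rep_tab$poison_of == "chimera" &
                    rep_tab$antidote_of == "A", ]
  expect_lt(chiA$segment_identity, 1)
  chiB <- rep_tab[rep_tab$poison_of == "chimera" &
                    rep_tab$antidote_of == "B", ]
  expect_equal(chiB$segment_identity, 1)
})
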