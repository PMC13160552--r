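#' Build an exon-swap chimera from two gene models
#'
#' The chimera carries exons `1..k` of parent A (with A's introns) and
#' exons `k+1..end` of parent B (with B's introns); the junction sits at
#' the exon/intron boundary after A's exon `k`, so the intron between the
#' swapped exons is B's. This mirrors the construct design in which the
#' last exon(s) of one driver are grafted onto another.
#'
#' @param parentA,parentB [gene_model()] objects with annotated exons.
#' @param k the last exon index taken from A; requires
#'   `1 <= k < n_exons(A)` and B to have at least `k + 1` exons.
#' @param gene_id identifier for the chimera.
#' @return a [gene_model()] with attribute `provenance` recording the
#'   parents and junction.
#' @export
build_chimera <- function(parentA, parentB, k,
                          gene_id = paste0(parentA$gene_id, "x",
                                           parentB$gene_id, "_k", k)) {
  stopifnot(inherits(parentA, "GeneModel"), inherits(parentB, "GeneModel"))
  nA <- nrow(parentA$exons); nB <- nrow(parentB$exons)
  k <- assert_count(k, "k")
  if (k >= nA)
    stop(sprintf("k = %d leaves no exons of parent A to swap out (A has %d exons)",
                 k, nA))
  if (nB < k + 1L)
    stop(sprintf("parent B has no exons %d..end", k + 1L))
  exA <- parentA$exons; exB <- parentB$exons
  # A part: gene start through the end of exon k
  partA <- substring(parentA$seq, 1L, exA$end[k])
  # B part: from the start of B's intron k (the intron preceding B's exon
  # k+1) through the end of B
  b_from <- exB$end[k] + 1L
  partB <- substring(parentB$seq, b_from, nchar(parentB$seq))
  seq <- paste0(partA, partB)
  offset <- exA$end[k] - (b_from - 1L)
  new_exons <- rbind(exA[seq_len(k), , drop = FALSE],
                     data.frame(start = exB$start[(k + 1L):nB] + offset,
                                end = exB$end[(k + 1L):nB] + offset))
  out <- gene_model(gene_id, seq, new_exons, strand = "+")
  attr(out, "provenance") <- list(parentA = parentA$gene_id,
                                  parentB = parentB$gene_id, k = k,
                                  junction = exA$end[k])
  out
}

#' Derive the antidote (long) and poison (short) isoform CDS of a gene
#'
#' The antidote CDS starts at the exon-1 ATG and is the full spliced CDS.
#' The poison CDS starts at the exon-2 ATG when present, otherwise at the
#' intron-1 ATG (in which case the retained intron tail up to exon 2 is
#' included, in frame); a gene with neither poison start is antidote-only
#' (suppressor-like) and gets an empty poison CDS.
#'
#' @param model a [gene_model()] with at least 2 exons.
#' @param window poison-start search window (see
#'   [detect_poison_starts()]).
#' @return list of class `IsoformPair`: `antidote_cds`, `poison_cds`,
#'   `start_used` (`"exon2_atg"`, `"intron1_atg"` or `"none"`).
#' @export
derive_isoforms <- function(model, window = 30L) {
  antidote <- spliced_seq(model)
  if (substr(antidote, 1L, 3L) != "ATG")
    stop("gene is not translatable: the spliced CDS lacks a start codon")
  ps <- detect_poison_starts(model, window = window)
  ex <- model$exons
  o1 <- ex$end[1L] - ex$start[1L] + 1L
  rest_from_exon2 <- function(from_local) {
    # spliced sequence from a position inside exon 2 to the gene end
    paste0(substring(model$seq, ex$start[2L] + from_local - 1L, ex$end[2L]),
           paste(substring(model$seq, ex$start[-(1:2)], ex$end[-(1:2)]),
                 collapse = ""))
  }
  if (ps$exon2_atg) {
    poison <- rest_from_exon2(ps$exon2_atg_pos)
    used <- "exon2_atg"
  } else if (ps$intron1_atg) {
    intr <- intron_seq(model, 1L)
    tail_part <- substring(intr, ps$intron1_atg_pos, nchar(intr))
    poison <- paste0(tail_part, rest_from_exon2(1L))
    used <- "intron1_atg"
  } else {
    poison <- ""
    used <- "none"
  }
  out <- list(antidote_cds = antidote, poison_cds = poison,
              start_used = used)
  class(out) <- "IsoformPair"
  out
}

#' Introduce a poison-start ATG right before the start of exon 2
#'
#' Inserts an ATG codon at the 5' end of exon 2, at the first codon
#' boundary of the gene's reading frame (0-2 nt of original exon 2 may
#' precede it so that the ATG is in frame). The spliced CDS grows by
#' exactly 3 nt and downstream coordinates shift by 3; splice boundaries
#' are untouched. Re-applying to a gene that already has a poison start
#' is an error unless `force = TRUE`.
#'
#' @param model a [gene_model()] with at least 2 exons.
#' @param force allow insertion even when a poison start already exists.
#' @return the modified [gene_model()] with attribute `poison_insertion`
#'   (the gene-local insertion position), usable by
#'   [remove_poison_start()] to restore the original.
#' @export
insert_poison_start <- function(model, force = FALSE) {
  if (nrow(model$exons) < 2L) stop("model must have at least 2 exons")
  ps <- detect_poison_starts(model)
  if ((ps$exon2_atg || ps$intron1_atg) && !force)
    stop("a poison start is already present; use force = TRUE to insert anyway")
  ex <- model$exons
  o1 <- ex$end[1L] - ex$start[1L] + 1L
  r <- (3L - o1 %% 3L) %% 3L  # exon-2 nt preceding the in-frame boundary
  if (ex$end[2L] - ex$start[2L] + 1L < r + 3L)
    stop("exon 2 is too short for an in-frame insertion without disrupting a splice boundary")
  ins_pos <- ex$start[2L] + r  # ATG occupies [ins_pos, ins_pos + 2]
  seq <- paste0(substring(model$seq, 1L, ins_pos - 1L), "ATG",
                substring(model$seq, ins_pos, nchar(model$seq)))
  new_ex <- ex
  new_ex$end[2L] <- new_ex$end[2L] + 3L
  if (nrow(ex) > 2L) {
    new_ex$start[3:nrow(ex)] <- new_ex$start[3:nrow(ex)] + 3L
    new_ex$end[3:nrow(ex)] <- new_ex$end[3:nrow(ex)] + 3L
  }
  out <- gene_model(model$gene_id, seq, new_ex, strain = model$strain,
                    contig = model$contig, start = model$start,
                    end = model$end, strand = model$strand,
                    status = model$status, locus_id = model$locus_id)
  attr(out, "poison_insertion") <- ins_pos
  out
}

#' Remove a previously inserted poison-start ATG
#'
#' Exact inverse of [insert_poison_start()]: deleting the recorded 3 nt
#' restores the original model byte-identically.
#'
#' @param model a model returned by [insert_poison_start()].
#' @return the restored [gene_model()].
#' @export
remove_poison_start <- function(model) {
  ins_pos <- attr(model, "poison_insertion")
  if (is.null(ins_pos))
    stop("model carries no recorded poison-start insertion")
  seq <- paste0(substring(model$seq, 1L, ins_pos - 1L),
                substring(model$seq, ins_pos + 3L, nchar(model$seq)))
  ex <- model$exons
  ex$end[2L] <- ex$end[2L] - 3L
  if (nrow(ex) > 2L) {
    ex$start[3:nrow(ex)] <- ex$start[3:nrow(ex)] - 3L
    ex$end[3:nrow(ex)] <- ex$end[3:nrow(ex)] - 3L
  }
  gene_model(model$gene_id, seq, ex, strain = model$strain,
             contig = model$contig, start = model$start, end = model$end,
             strand = model$strand, status = model$status,
             locus_id = model$locus_id)
}

#' Scan a protein for PY motifs
#'
#' Finds all matches of the Leu/Pro-Pro-X-Tyr pattern (`[LP]P.Y`) that
#' start within the first `n_terminal_window` residues (default: the
#' whole sequence). Overlapping matches are all reported.
#'
#' @param protein amino-acid character string.
#' @param n_terminal_window restrict matches to this N-terminal stretch.
#' @return integer vector of 1-based match start positions.
#' @export
py_motif_scan <- function(protein, n_terminal_window = NULL) {
  protein <- toupper(protein)
  hits <- gregexpr("(?=[LP]P.Y)", protein, perl = TRUE)[[1L]]
  pos <- as.integer(hits[hits > 0L])
  if (!is.null(n_terminal_window))
    pos <- pos[pos <= n_terminal_window]
  pos
}

#' Compare poison and antidote C-terminal segments across genes
#'
#' Sequence-level proxy for detoxification specificity: for every
#' poison/antidote pair among the supplied genes, the protein segments
#' encoded downstream of exon `k` (the swapped region of a chimera) are
#' compared. Identity 1 marks a self-match; a chimera's poison typically
#' mismatches both parental antidotes over the swapped segment. No
#' functional rescue is claimed; this reports sequence identity only.
#'
#' @param models named list of [gene_model()] objects (e.g. chimera plus
#'   parents).
#' @param k exon index: segments are the proteins encoded by exons
#'   `k+1..end`.
#' @return data frame: `poison_of`, `antidote_of`, `segment_identity`,
#'   `self_match`.
#' @export
compare_poison_antidote <- function(models, k) {
  stopifnot(is.list(models), !is.null(names(models)))
  seg_protein <- function(model) {
    ex <- model$exons
    if (nrow(ex) < k + 1L)
      stop(sprintf("gene '%s' has no exons beyond %d", model$gene_id, k))
    cds <- spliced_seq(model)
    off <- sum(ex$end[seq_len(k)] - ex$start[seq_len(k)] + 1L)
    # first complete codon at or after the segment start
    from <- ceiling(off / 3) * 3L + 1L
    translate_cds(substring(cds, from, nchar(cds)))
  }
  segs <- lapply(models, seg_protein)
  grid <- expand.grid(poison_of = names(models),
                      antidote_of = names(models),
                      stringsAsFactors = FALSE)
  grid$segment_identity <- mapply(function(p, a) {
    sp <- segs[[p]]; sa <- segs[[a]]
    if (!nchar(sp) || !nchar(sa)) return(NA_real_)
    if (nchar(sp) == nchar(sa)) {
      v1 <- strsplit(sp, "")[[1L]]; v2 <- strsplit(sa, "")[[1L]]
      mean(v1 == v2)
    } else {
      aa <- sort(unique(c(strsplit(paste0(sp, sa, "*X"), "")[[1L]])))
      sm <- matrix(-1, length(aa), length(aa), dimnames = list(aa, aa))
      diag(sm) <- 1
      pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(sp),
                                          Biostrings::AAString(sa),
                                          type = "overlap",
                                          substitutionMatrix = sm,
                                          gapOpening = 0, gapExtension = 2)
      s1 <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
      s2 <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
      sum(s1 == s2 & s1 != "-") / length(s1)
    }
  }, grid$poison_of, grid$antidote_of)
  grid$self_match <- grid$poison_of == grid$antidote_of
  grid
}
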