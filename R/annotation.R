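.wtfkit_env <- new.env(parent = emptyenv())

# Gumbel (Karlin-Altschul-style) E-value calibration for the seeded local
# search: lambda solves sum p_i p_j exp(lambda * s_ij) = 1 for the ungapped
# scheme, and K is fitted once per scoring scheme from the maxima of local
# alignment scores on random sequence pairs (E[Smax] ~ (ln(K m n) + gamma) /
# lambda).  Cached per scheme.
evalue_params <- function(match = 1, mismatch = -2, gap_open = 5,
                          gap_ext = 2) {
  key <- paste(match, mismatch, gap_open, gap_ext, sep = "/")
  cache <- .wtfkit_env$evalue_cache
  if (is.null(cache)) cache <- list()
  if (!is.null(cache[[key]])) return(cache[[key]])
  lambda <- uniroot(function(l) 0.25 * exp(l * match) +
                      0.75 * exp(l * mismatch) - 1,
                    interval = c(1e-6, 10))$root
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  n0 <- 400L
  scores <- with_private_seed(190642L, {
    vapply(seq_len(24L), function(i) {
      a <- Biostrings::DNAString(random_dna(n0))
      b <- Biostrings::DNAString(random_dna(n0))
      Biostrings::pairwiseAlignment(a, b, type = "local",
                                    substitutionMatrix = sm,
                                    gapOpening = gap_open,
                                    gapExtension = gap_ext,
                                    scoreOnly = TRUE)
    }, numeric(1L))
  })
  K <- exp(lambda * mean(scores) - 0.5772157) / (n0 * n0)
  out <- list(lambda = lambda, K = K, match = match, mismatch = mismatch,
              gap_open = gap_open, gap_ext = gap_ext)
  cache[[key]] <- out
  .wtfkit_env$evalue_cache <- cache
  out
}

# cluster seed hits that imply a similar gene placement and return candidate
# genome windows
seed_windows <- function(qseq, subject, seed_len, contig_len) {
  Lq <- nchar(qseq)
  kmers <- substring(qseq, seq_len(Lq - seed_len + 1L),
                     seq_len(Lq - seed_len + 1L) + seed_len - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  if (!any(ok)) return(NULL)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers[ok]))
  mp <- Biostrings::matchPDict(pd, subject)
  starts <- lapply(seq_along(mp), function(i) Biostrings::start(mp[[i]]))
  if (!sum(lengths(starts))) return(NULL)
  gpos <- unlist(starts, use.names = FALSE)
  qpos <- rep(which(ok), lengths(starts))
  s0 <- gpos - qpos + 1L  # implied gene start on the contig
  o <- order(s0)
  s0 <- s0[o]
  grp <- cumsum(c(TRUE, diff(s0) > 200L))
  lapply(split(s0, grp), function(v) {
    c(max(1L, min(v) - 30L), min(contig_len, max(v) + Lq - 1L + 30L))
  })
}

#' Find family members in a genome by seeded local alignment
#'
#' Exact-match k-mer seeding on both strands followed by gapped local
#' alignment of the query against each seeded window, scored with a
#' match/mismatch/gap scheme and an extreme-value E-value calibrated on
#' random sequence (see the methods vignette). Hits from different
#' queries whose intervals overlap by at least half the shorter one are
#' merged into a single candidate, keeping the best-scoring alignment.
#'
#' @param genome a [seq_record_set()] of contigs.
#' @param queries a [seq_record_set()] of family gene sequences.
#' @param e_max E-value cutoff (default `1e-5`).
#' @param seed_len exact-match seed length (default 11); queries shorter
#'   than this raise an error.
#' @param match,mismatch,gap_open,gap_ext local-alignment scoring.
#' @return data frame of candidate hits: `contig`, `start`, `end`
#'   (1-based inclusive on the forward strand), `strand`, `score`,
#'   `evalue`, `identity`, `query`.
#' @export
find_family_members <- function(genome, queries, e_max = 1e-5,
                                seed_len = 11L, match = 1, mismatch = -2,
                                gap_open = 5, gap_ext = 2) {
  stopifnot(inherits(genome, "SeqRecordSet"),
            inherits(queries, "SeqRecordSet"))
  if (!nrow(queries)) stop("'queries' must be non-empty")
  if (e_max <= 0) stop("'e_max' must be positive")
  if (any(nchar(queries$seq) < seed_len))
    stop("query shorter than the seed length")
  ev <- evalue_params(match, mismatch, gap_open, gap_ext)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  hits <- list()
  for (ci in seq_len(nrow(genome))) {
    contig <- genome$id[ci]
    cseq <- genome$seq[ci]
    clen <- nchar(cseq)
    subject <- Biostrings::DNAString(cseq)
    for (qi in seq_len(nrow(queries))) {
      for (strand in c("+", "-")) {
        qseq <- if (strand == "+") queries$seq[qi]
          else revcomp(queries$seq[qi])
        win <- seed_windows(qseq, subject, seed_len, clen)
        if (is.null(win)) next
        for (w in win) {
          region <- substring(cseq, w[1L], w[2L])
          pa <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(qseq), Biostrings::DNAString(region),
            type = "local", substitutionMatrix = sm,
            gapOpening = gap_open, gapExtension = gap_ext)
          S <- Biostrings::score(pa)
          E <- ev$K * clen * nchar(qseq) * exp(-ev$lambda * S)
          if (E > e_max) next
          s1 <- strsplit(as.character(Biostrings::alignedPattern(pa)),
                         "")[[1L]]
          s2 <- strsplit(as.character(Biostrings::alignedSubject(pa)),
                         "")[[1L]]
          idn <- sum(s1 == s2 & s1 != "-") / length(s1)
          sub <- Biostrings::subject(pa)
          hstart <- w[1L] + Biostrings::start(sub) - 1L
          hend <- w[1L] + Biostrings::end(sub) - 1L
          hits[[length(hits) + 1L]] <- data.frame(
            contig = contig, start = hstart, end = hend, strand = strand,
            score = S, evalue = E, identity = idn,
            query = queries$id[qi], stringsAsFactors = FALSE)
        }
      }
    }
  }
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), evalue = numeric(),
                      identity = numeric(), query = character(),
                      stringsAsFactors = FALSE)
  if (!length(hits)) return(empty)
  h <- do.call(rbind, hits)
  # merge overlapping candidates (same contig & strand, overlap >= 50% of
  # the shorter interval), keeping the best-scoring representative
  merged <- list()
  for (key in unique(paste(h$contig, h$strand))) {
    g <- h[paste(h$contig, h$strand) == key, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    cur <- g[1L, , drop = FALSE]
    cs <- cur$start; ce <- cur$end
    flush <- function(cur, cs, ce) {
      cur$start <- cs; cur$end <- ce
      merged[[length(merged) + 1L]] <<- cur
    }
    if (nrow(g) > 1L) for (r in 2L:nrow(g)) {
      row <- g[r, , drop = FALSE]
      ov <- min(ce, row$end) - max(cs, row$start) + 1L
      shorter <- min(ce - cs + 1L, row$end - row$start + 1L)
      if (ov >= 0.5 * shorter) {
        cs <- min(cs, row$start); ce <- max(ce, row$end)
        if (row$score > cur$score) cur <- row
      } else {
        flush(cur, cs, ce)
        cur <- row; cs <- row$start; ce <- row$end
      }
    }
    flush(cur, cs, ce)
  }
  out <- do.call(rbind, merged)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# position map pattern -> subject from an overlap alignment; NA where the
# pattern base sits opposite a gap
alignment_position_map <- function(a, b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                      Biostrings::DNAString(b),
                                      type = "overlap",
                                      substitutionMatrix = sm,
                                      gapOpening = 0, gapExtension = 2)
  s1 <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  s2 <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  p1 <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  p2 <- Biostrings::start(Biostrings::subject(pa)) - 1L
  map <- rep(NA_integer_, nchar(a))
  for (i in seq_along(s1)) {
    if (s1[i] != "-") {
      p1 <- p1 + 1L
      if (s2[i] != "-") { p2 <- p2 + 1L; map[p1] <- p2 }
    } else if (s2[i] != "-") p2 <- p2 + 1L
  }
  map
}

#' Transfer an exon structure from reference models onto a candidate
#'
#' Chooses the reference gene with the highest sequence identity to the
#' candidate interval (ties broken by reference order and flagged), aligns
#' the two, and maps the reference exon boundaries through the alignment.
#' Boundaries falling opposite a gap are nudged to the nearest aligned
#' position and flagged.
#'
#' @param candidate one row of a [find_family_members()] result (or any
#'   list with `contig`, `start`, `end`, `strand`).
#' @param genome the [seq_record_set()] the candidate lives in.
#' @param references list of reference [gene_model()] objects.
#' @param floor minimum identity to any reference for the candidate to be
#'   accepted as a family member (default 0.5); below it `NULL` is
#'   returned.
#' @param gene_id identifier for the new model.
#' @return a [gene_model()] with attributes `ref_identity`, `ref_used`,
#'   `tie` and `unmappable_exons`, or `NULL` if rejected.
#' @export
transfer_exon_structure <- function(candidate, genome, references,
                                    floor = 0.5,
                                    gene_id = paste0(candidate$contig, ":",
                                                     candidate$start)) {
  cseq <- substring(get_seq(genome, candidate$contig), candidate$start,
                    candidate$end)
  if (identical(candidate$strand, "-")) cseq <- revcomp(cseq)
  ids <- vapply(references, function(r) pairwise_identity(r$seq, cseq),
                numeric(1L))
  best <- which(ids == max(ids))
  tie <- length(best) > 1L
  best <- best[1L]
  if (ids[best] < floor) return(NULL)
  ref <- references[[best]]
  map <- alignment_position_map(ref$seq, cseq)
  nudge <- function(p, dir) {
    if (!is.na(map[p])) return(map[p])
    idx <- if (dir > 0) seq(p, length(map)) else seq(p, 1L)
    hit <- idx[which(!is.na(map[idx]))[1L]]
    if (is.na(hit)) NA_integer_ else map[hit]
  }
  ex <- ref$exons
  starts <- vapply(ex$start, nudge, integer(1L), dir = 1L)
  ends <- vapply(ex$end, nudge, integer(1L), dir = -1L)
  unmappable <- which(is.na(starts) | is.na(ends) | starts > ends)
  keep <- setdiff(seq_len(nrow(ex)), unmappable)
  if (!length(keep)) return(NULL)
  model <- gene_model(gene_id, cseq,
                      data.frame(start = starts[keep], end = ends[keep]),
                      strain = candidate$strain %||% NA_character_,
                      contig = candidate$contig,
                      start = candidate$start, end = candidate$end,
                      strand = candidate$strand)
  attr(model, "ref_identity") <- ids[best]
  attr(model, "ref_used") <- ref$gene_id
  attr(model, "tie") <- tie
  attr(model, "unmappable_exons") <- unmappable
  model
}

#' Call pseudogene status from a gene model
#'
#' A family member is called a pseudogene when its spliced CDS carries any
#' of: a premature in-frame stop before the final 10% of codons, a length
#' that is not a multiple of 3 (frameshift), or a missing ATG start.
#'
#' @param model a [gene_model()].
#' @return list with `status` (`"intact"` or `"pseudogene"`) and
#'   `disruptions` (data frame `type`, `codon`).
#' @export
call_pseudogene <- function(model) {
  cds <- spliced_seq(model)
  dis <- list()
  if (nchar(cds) %% 3L != 0L)
    dis[[length(dis) + 1L]] <- data.frame(type = "frameshift",
                                          codon = NA_integer_)
  if (substr(cds, 1L, 3L) != "ATG")
    dis[[length(dis) + 1L]] <- data.frame(type = "missing_start",
                                          codon = 1L)
  ncod <- nchar(cds) %/% 3L
  if (ncod >= 2L) {
    codons <- substring(cds, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
    stop_at <- which(codons %in% c("TAA", "TAG", "TGA"))
    premature <- stop_at[stop_at <= floor(0.9 * ncod) & stop_at < ncod]
    for (j in premature)
      dis[[length(dis) + 1L]] <- data.frame(type = "stop_gain", codon = j)
  }
  disruptions <- if (length(dis)) do.call(rbind, dis)
    else data.frame(type = character(), codon = integer())
  list(status = if (nrow(disruptions)) "pseudogene" else "intact",
       disruptions = disruptions)
}

#' Detect alternative poison-isoform start codons
#'
#' The short (poison) isoform of an autonomous driver starts either at an
#' in-frame ATG near the start of exon 2 (`exon2_atg`) or at an ATG in the
#' 3' tail of intron 1 whose reading frame runs continuously into exon 2
#' (`intron1_atg`). "Near" is a window of `window` nt (default 30).
#'
#' @param model a [gene_model()] with at least 2 exons (a single-exon
#'   model returns both flags `FALSE` with a warning).
#' @param window search window in nt.
#' @return list: `exon2_atg`, `intron1_atg` (logicals), and
#'   `exon2_atg_pos` / `intron1_atg_pos` (1-based position within exon 2 /
#'   intron 1, `NA` when absent).
#' @export
detect_poison_starts <- function(model, window = 30L) {
  if (nrow(model$exons) < 2L) {
    warning("single-exon model: poison start flags set to FALSE")
    return(list(exon2_atg = FALSE, intron1_atg = FALSE,
                exon2_atg_pos = NA_integer_, intron1_atg_pos = NA_integer_))
  }
  ex <- model$exons
  o1 <- ex$end[1L] - ex$start[1L] + 1L  # spliced offset of exon 2
  exon2 <- substring(model$seq, ex$start[2L], ex$end[2L])
  e2_pos <- NA_integer_
  lim <- min(window, nchar(exon2) - 2L)
  if (lim >= 1L) for (p in seq_len(lim)) {
    if (substr(exon2, p, p + 2L) == "ATG" && (o1 + p - 1L) %% 3L == 0L) {
      e2_pos <- p; break
    }
  }
  intr <- intron_seq(model, 1L)
  i1_pos <- NA_integer_
  Li <- nchar(intr)
  if (Li >= 3L) {
    lo <- max(1L, Li - window + 1L)
    for (q in seq(lo, Li - 2L)) {
      t <- Li - q + 1L  # retained-tail length from the ATG
      if (substr(intr, q, q + 2L) == "ATG" && t %% 3L == o1 %% 3L) {
        i1_pos <- q
        # keep scanning: the ATG closest to exon 2 is reported
      }
    }
  }
  list(exon2_atg = !is.na(e2_pos), intron1_atg = !is.na(i1_pos),
       exon2_atg_pos = e2_pos, intron1_atg_pos = i1_pos)
}

extract_flanks <- function(model, genome, flank_len, min_flank = 50L) {
  cseq <- get_seq(genome, model$contig)
  clen <- nchar(cseq)
  up <- substring(cseq, max(1L, model$start - flank_len), model$start - 1L)
  down <- substring(cseq, model$end + 1L, min(clen, model$end + flank_len))
  if (identical(model$strand, "-")) {
    f5 <- revcomp(down); f3 <- revcomp(up)
  } else {
    f5 <- up; f3 <- down
  }
  list(f5 = f5, f3 = f3,
       single = nchar(f5) < min_flank || nchar(f3) < min_flank)
}

#' Assign family members to loci by flanking-sequence identity
#'
#' The 1 kb of sequence flanking a family gene identifies its genomic
#' locus across strains (synteny by flank identity). Genes are nodes; an
#' edge joins two genes from different strains when both their 5' and 3'
#' flanks align at identity at least `flank_identity_min`. Connected
#' components are the loci. A gene within `min_flank` bp of a contig end
#' is compared in single-flank mode and flagged.
#'
#' @param models list of [gene_model()] objects with `strain`, `contig`
#'   and genomic coordinates set; `status` (from [call_pseudogene()]) is
#'   used for the pseudogene layer when present.
#' @param genomes named list (by strain) of [seq_record_set()] objects.
#' @param flank_len flank length in bp (default 1000).
#' @param flank_identity_min minimum flank identity (default 0.8).
#' @param min_flank shortest usable flank before single-flank mode.
#' @return list of class `PresenceMatrix`: `assignment` (data frame
#'   `gene_id`, `strain`, `locus`, `single_flank`), `presence` (loci x
#'   strains copy counts), `pseudogene` (loci x strains pseudogene
#'   counts).
#' @export
assign_loci <- function(models, genomes, flank_len = 1000L,
                        flank_identity_min = 0.8, min_flank = 50L) {
  stopifnot(length(models) >= 1L)
  n <- length(models)
  strains <- vapply(models, function(m) m$strain, "")
  ids <- vapply(models, function(m) m$gene_id, "")
  fl <- lapply(seq_len(n), function(i)
    extract_flanks(models[[i]], genomes[[strains[i]]], flank_len,
                   min_flank))
  edges <- matrix(integer(0), ncol = 2L)
  if (n >= 2L) {
    pairs <- utils::combn(n, 2L)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      if (strains[i] == strains[j]) next
      ok5 <- nchar(fl[[i]]$f5) >= min_flank && nchar(fl[[j]]$f5) >= min_flank
      ok3 <- nchar(fl[[i]]$f3) >= min_flank && nchar(fl[[j]]$f3) >= min_flank
      if (!ok5 && !ok3) next
      pass <- TRUE
      if (ok5)
        pass <- pairwise_identity(fl[[i]]$f5, fl[[j]]$f5) >=
          flank_identity_min
      if (pass && ok3)
        pass <- pairwise_identity(fl[[i]]$f3, fl[[j]]$f3) >=
          flank_identity_min
      if (pass) edges <- rbind(edges, c(i, j))
    }
  }
  ig <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L] %||% integer(0),
               to = edges[, 2L] %||% integer(0)),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(ig)$membership[as.character(seq_len(n))]
  # deterministic locus labels: number components by their smallest gene id
  first <- vapply(split(ids, comp), min, "")
  lab_for_comp <- setNames(rank(first, ties.method = "first"),
                           names(first))
  locus <- sprintf("locus_%02d", lab_for_comp[as.character(comp)])
  assignment <- data.frame(gene_id = ids, strain = strains, locus = locus,
                           single_flank = vapply(fl, function(f) f$single,
                                                 logical(1L)),
                           stringsAsFactors = FALSE)
  loci <- sort(unique(locus))
  strain_levels <- sort(unique(strains))
  presence <- table(factor(locus, levels = loci),
                    factor(strains, levels = strain_levels))
  status <- vapply(models, function(m)
    if (!is.na(m$status)) m$status else "intact", "")
  pseudo <- table(factor(locus[status == "pseudogene"], levels = loci),
                  factor(strains[status == "pseudogene"],
                         levels = strain_levels))
  out <- list(assignment = assignment,
              presence = unclass(as.matrix(presence)),
              pseudogene = unclass(as.matrix(pseudo)))
  class(out) <- "PresenceMatrix"
  out
}

#' Flag a gene as flanked by a solo-LTR
#'
#' `TRUE` when any sequence from the LTR library aligns within `window`
#' bp of either gene end at identity at least `identity_min` while
#' covering at least `coverage_min` of the LTR.
#'
#' @param model a placed [gene_model()].
#' @param genome the [seq_record_set()] containing the model's contig.
#' @param ltr_library a non-empty [seq_record_set()] of LTR sequences.
#' @param window distance from the gene ends searched (bp).
#' @param identity_min identity floor (default 0.7).
#' @param coverage_min minimum fraction of the LTR aligned.
#' @return logical flag.
#' @export
flag_solo_ltr <- function(model, genome, ltr_library, window = 500L,
                          identity_min = 0.7, coverage_min = 0.8) {
  if (!nrow(ltr_library)) stop("'ltr_library' must be non-empty")
  cseq <- get_seq(genome, model$contig)
  clen <- nchar(cseq)
  maxL <- max(nchar(ltr_library$seq))
  regions <- c(
    substring(cseq, max(1L, model$start - window - maxL), model$start - 1L),
    substring(cseq, model$end + 1L, min(clen, model$end + window + maxL)))
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  for (reg in regions) {
    if (nchar(reg) < 10L) next
    for (k in seq_len(nrow(ltr_library))) {
      ltr <- ltr_library$seq[k]
      for (ls in c(ltr, revcomp(ltr))) {
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(ls), Biostrings::DNAString(reg),
          type = "overlap", substitutionMatrix = sm,
          gapOpening = 0, gapExtension = 2)
        s1 <- strsplit(as.character(Biostrings::alignedPattern(pa)),
                       "")[[1L]]
        s2 <- strsplit(as.character(Biostrings::alignedSubject(pa)),
                       "")[[1L]]
        if (!length(s1)) next
        idn <- sum(s1 == s2 & s1 != "-") / length(s1)
        cov <- sum(s1 != "-") / nchar(ls)
        if (idn >= identity_min && cov >= coverage_min) return(TRUE)
      }
    }
  }
  FALSE
}
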