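#' Ancestor gene template for the family simulator
#'
#' Defines the exon/intron architecture of the ancestral family member.
#' The default mimics a six-exon spore-killer gene of roughly 1.3 kb with
#' a 1,020 bp coding sequence; exon lengths must sum to a multiple of 3.
#'
#' @param exon_lens integer vector of exon lengths (bp).
#' @param intron_lens integer vector of intron lengths (bp), one fewer
#'   than `exon_lens`.
#' @return a list of class `ancestor_model`.
#' @export
ancestor_model <- function(exon_lens = c(228, 105, 129, 120, 153, 285),
                           intron_lens = c(48, 57, 51, 60, 54)) {
  exon_lens <- as.integer(exon_lens)
  intron_lens <- as.integer(intron_lens)
  if (length(intron_lens) != length(exon_lens) - 1L)
    stop("need exactly one intron fewer than exons")
  if (any(exon_lens < 3L) || any(intron_lens < 1L))
    stop("exon lengths must be >= 3 and intron lengths >= 1")
  if (sum(exon_lens) %% 3L != 0L)
    stop("exon lengths must sum to a multiple of 3 (coding exons)")
  out <- list(exon_lens = exon_lens, intron_lens = intron_lens)
  class(out) <- "ancestor_model"
  out
}

#' Parameters for the gene-family simulator
#'
#' All rates are per gene (or per site) per generation. The defaults are
#' the package's reference conditions for a small multi-strain family:
#' 5 strains, 8 ancestral loci, 200 generations of divergence, point
#' mutation at `1e-4`/site/generation, and modest duplication, conversion
#' and pseudogenization channels.
#'
#' @param n_strains number of strains (tips of the strain genealogy).
#' @param n_loci number of ancestral loci (all start as identical copies
#'   of the ancestor gene, embedded in locus-specific random flanks).
#' @param generations depth of the strain genealogy in generations.
#' @param mu substitution probability per site per generation.
#' @param dup_rate per-gene per-generation probability of duplication to
#'   a brand-new locus.
#' @param conv_rate per-gene per-generation probability of receiving a
#'   gene-conversion tract from a random co-resident family member.
#' @param tract_len_mean mean conversion tract length (bp, geometric).
#' @param pseudo_rate per-gene per-generation probability of a
#'   pseudogenizing stop-gain.
#' @param anc ancestor gene template, see [ancestor_model()].
#' @param flank_len length of the locus-identifying flanks (bp).
#' @param infinite_sites if `TRUE`, no gene site is ever mutated twice
#'   within a locus, so clonal output is homoplasy-free.
#' @param seed integer seed; identical parameters and seed give identical
#'   output.
#' @return a list of class `FamilySimParams`.
#' @export
family_sim_params <- function(n_strains = 5L, n_loci = 8L,
                              generations = 200L, mu = 1e-4,
                              dup_rate = 5e-4, conv_rate = 1e-3,
                              tract_len_mean = 300, pseudo_rate = 5e-4,
                              anc = ancestor_model(), flank_len = 1000L,
                              infinite_sites = FALSE, seed = 1L) {
  p <- list(n_strains = assert_count(n_strains, "n_strains"),
            n_loci = assert_count(n_loci, "n_loci"),
            generations = assert_count(generations, "generations"),
            mu = assert_scalar_number(mu, "mu", 0, 1),
            dup_rate = assert_scalar_number(dup_rate, "dup_rate", 0, 1),
            conv_rate = assert_scalar_number(conv_rate, "conv_rate", 0, 1),
            tract_len_mean = assert_scalar_number(tract_len_mean,
                                                  "tract_len_mean", 1, Inf),
            pseudo_rate = assert_scalar_number(pseudo_rate, "pseudo_rate",
                                               0, 1),
            anc = anc,
            flank_len = assert_count(flank_len, "flank_len", min = 0L),
            infinite_sites = isTRUE(infinite_sites),
            seed = assert_count(seed, "seed"))
  stopifnot(inherits(anc, "ancestor_model"))
  class(p) <- "FamilySimParams"
  p
}

# unspliced-position of each spliced (CDS) position, plus exon table
anc_layout <- function(anc) {
  ne <- length(anc$exon_lens)
  starts <- integer(ne); ends <- integer(ne)
  pos <- 0L
  splice_map <- integer(sum(anc$exon_lens))
  k <- 0L
  for (i in seq_len(ne)) {
    starts[i] <- pos + 1L
    ends[i] <- pos + anc$exon_lens[i]
    splice_map[(k + 1L):(k + anc$exon_lens[i])] <- starts[i]:ends[i]
    k <- k + anc$exon_lens[i]
    pos <- ends[i]
    if (i < ne) pos <- pos + anc$intron_lens[i]
  }
  list(exons = data.frame(start = starts, end = ends),
       splice_map = splice_map, gene_len = pos,
       n_codons = sum(anc$exon_lens) %/% 3L)
}

# integer-coded ancestral gene: ATG + random non-stop codons + TAA in the
# exons, random introns
build_ancestor_gene <- function(anc, layout) {
  ncod <- layout$n_codons
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(ncod)
  codons[1L] <- "ATG"
  for (i in 2L:(ncod - 1L)) {
    repeat {
      cd <- random_dna(3L)
      if (!cd %in% stops) break
    }
    codons[i] <- cd
  }
  codons[ncod] <- "TAA"
  cds <- seq_to_int(paste(codons, collapse = ""))
  gene <- random_dna_int(layout$gene_len)
  gene[layout$splice_map] <- cds
  gene
}

# integer-generation strain genealogy: a coalescent-shaped random tree
# rescaled so the root-to-tip depth equals `generations`
strain_genealogy <- function(n_strains, generations) {
  if (n_strains == 1L) return(NULL)
  tr <- ape::rcoal(n_strains, tip.label = paste0("S", seq_len(n_strains)))
  depth <- ape::node.depth.edgelength(tr)
  times <- round(depth / max(depth) * generations)
  tr$edge.length <- times[tr$edge[, 2L]] - times[tr$edge[, 1L]]
  attr(tr, "node_gen") <- times
  tr
}

#' Simulate the evolution of a multi-locus gene family across strains
#'
#' Forward-time simulation: an ancestral genome carrying `n_loci`
#' identical copies of the ancestor gene (each flanked by locus-specific
#' random sequence) evolves along a random coalescent-shaped strain
#' genealogy. Every generation each gene independently draws point
#' mutations (per-site), duplication to a new locus (with fresh random
#' flanks), an incoming gene-conversion tract from a uniformly chosen
#' co-resident family member (geometric tract length, uniform placement,
#' truncated at the gene ends), and pseudogenizing stop-gains (a random
#' in-frame codon in the body of the CDS set to TAA). Genes are gap-free,
#' so the per-locus true alignments are simply the sequences stacked.
#' Flank sequences mutate at `mu` but their events are not logged.
#'
#' @param params a [family_sim_params()] object.
#' @return a list of class `FamilySim` with elements `genomes` (per-strain
#'   [seq_record_set()], one contig per strain), `models` (per-strain
#'   `FeatureTable`), `gene_models` (list of [gene_model()] objects),
#'   `alignments` (per-locus character matrices in true alignment
#'   coordinates), `truth` (the event log data frame), `tree` (strain
#'   genealogy: `phylo` object plus newick string, `NULL` for one
#'   strain), `ancestor` (the ancestral [gene_model()]) and `params`.
#' @export
simulate_family <- function(params) {
  stopifnot(inherits(params, "FamilySimParams"))
  set.seed(params$seed)
  layout <- anc_layout(params$anc)
  glen <- layout$gene_len
  flen <- params$flank_len

  tr <- strain_genealogy(params$n_strains, params$generations)
  total_branch_gens <- if (is.null(tr)) params$generations
    else sum(tr$edge.length)
  if (params$infinite_sites &&
      params$mu * glen * total_branch_gens * params$n_loci > glen)
    stop("infinite_sites: expected mutation count exceeds the gene length; ",
         "use a longer ancestor sequence or a lower mutation rate")

  anc_gene <- build_ancestor_gene(params$anc, layout)
  locus_ids <- sprintf("L%02d", seq_len(params$n_loci))
  root_state <- setNames(lapply(locus_ids, function(l) {
    list(gene = anc_gene,
         f5 = random_dna_int(flen), f3 = random_dna_int(flen))
  }), locus_ids)

  env <- new.env(parent = emptyenv())
  env$log <- vector("list", 256L); env$nlog <- 0L
  env$locus_counter <- params$n_loci
  # family-wide used-site mask: under infinite sites no gene column is ever
  # mutated twice anywhere in the family, so pooled paralog alignments are
  # homoplasy-free as well as the per-locus ones
  env$used <- logical(glen)

  add_event <- function(gen, node, kind, locus, donor = NA_character_,
                        pos1 = NA_integer_, pos2 = NA_integer_,
                        detail = NA_character_) {
    env$nlog <- env$nlog + 1L
    if (env$nlog > length(env$log))
      env$log <- c(env$log, vector("list", length(env$log)))
    env$log[[env$nlog]] <- data.frame(
      generation = gen, node = node, kind = kind, locus = locus,
      donor = donor, pos1 = pos1, pos2 = pos2, detail = detail,
      stringsAsFactors = FALSE)
  }

  mutate_sites <- function(gene, nm, locus, gen, node, log_events = TRUE) {
    if (nm == 0L) return(gene)
    if (params$infinite_sites) {
      avail <- which(!env$used)
      if (length(avail) < nm)
        stop("infinite_sites: the gene sequence is exhausted; ",
             "use a longer ancestor sequence")
      sites <- if (length(avail) == 1L) avail
        else sample(avail, nm)
      env$used[sites] <- TRUE
    } else {
      sites <- sample.int(glen, nm)
    }
    newb <- ((gene[sites] - 1L + sample.int(3L, nm, replace = TRUE)) %% 4L) + 1L
    if (log_events)
      for (i in seq_len(nm))
        add_event(gen, node, "mutation", locus, pos1 = sites[i],
                  detail = sprintf("%s>%s", DNA_BASES[gene[sites[i]]],
                                   DNA_BASES[newb[i]]))
    gene[sites] <- newb
    gene
  }

  pseudogenize <- function(gene, locus, gen, node) {
    ncod <- layout$n_codons
    hi <- max(2L, floor(0.9 * ncod) - 1L)
    cand <- 2L:hi
    if (params$infinite_sites) {
      free <- cand[vapply(cand, function(j) {
        !any(env$used[layout$splice_map[(3L * j - 2L):(3L * j)]])
      }, logical(1L))]
      if (!length(free)) return(gene)  # nowhere clean to disrupt
      j <- if (length(free) == 1L) free else sample(free, 1L)
      env$used[layout$splice_map[(3L * j - 2L):(3L * j)]] <- TRUE
    } else {
      j <- sample(cand, 1L)
    }
    sites <- layout$splice_map[(3L * j - 2L):(3L * j)]
    gene[sites] <- c(4L, 1L, 1L)  # TAA
    add_event(gen, node, "pseudogenization", locus, pos1 = j,
              detail = sprintf("stop_gain_codon_%d", j))
    gene
  }

  evolve <- function(state, gens, gen0, node) {
    if (gens <= 0L) return(state)
    for (g in seq_len(gens)) {
      gen <- gen0 + g
      for (locus in names(state)) {
        entry <- state[[locus]]
        nm <- rbinom(1L, glen, params$mu)
        if (nm > 0L)
          entry$gene <- mutate_sites(entry$gene, nm, locus, gen, node)
        if (flen > 0L) {
          n5 <- rbinom(1L, flen, params$mu)
          if (n5 > 0L) {
            s <- sample.int(flen, n5)
            entry$f5[s] <- ((entry$f5[s] - 1L +
                               sample.int(3L, n5, replace = TRUE)) %% 4L) + 1L
          }
          n3 <- rbinom(1L, flen, params$mu)
          if (n3 > 0L) {
            s <- sample.int(flen, n3)
            entry$f3[s] <- ((entry$f3[s] - 1L +
                               sample.int(3L, n3, replace = TRUE)) %% 4L) + 1L
          }
        }
        if (runif(1L) < params$dup_rate) {
          env$locus_counter <- env$locus_counter + 1L
          newloc <- sprintf("L%02d", env$locus_counter)
          state[[newloc]] <- list(gene = entry$gene,
                                  f5 = random_dna_int(flen),
                                  f3 = random_dna_int(flen))
          add_event(gen, node, "duplication", locus, donor = locus,
                    detail = sprintf("new_locus=%s", newloc))
        }
        if (params$conv_rate > 0 && length(state) >= 2L &&
            runif(1L) < params$conv_rate) {
          others <- setdiff(names(state), locus)
          donor <- if (length(others) == 1L) others else sample(others, 1L)
          tlen <- min(glen, rgeom(1L, 1 / params$tract_len_mean) + 1L)
          tstart <- sample.int(glen, 1L)
          tend <- min(glen, tstart + tlen - 1L)
          entry$gene[tstart:tend] <- state[[donor]]$gene[tstart:tend]
          add_event(gen, node, "conversion", locus, donor = donor,
                    pos1 = tstart, pos2 = tend)
        }
        if (runif(1L) < params$pseudo_rate)
          entry$gene <- pseudogenize(entry$gene, locus, gen, node)
        state[[locus]] <- entry
      }
    }
    state
  }

  leaves <- list()
  if (is.null(tr)) {
    leaves[["S1"]] <- evolve(root_state, params$generations, 0L, 1L)
  } else {
    node_gen <- attr(tr, "node_gen")
    root <- params$n_strains + 1L
    recurse <- function(node, state) {
      kids <- tr$edge[tr$edge[, 1L] == node, 2L]
      for (child in kids) {
        st <- evolve(state, node_gen[child] - node_gen[node],
                     node_gen[node], child)
        if (child <= params$n_strains)
          leaves[[tr$tip.label[child]]] <<- st
        else recurse(child, st)
      }
    }
    recurse(root, root_state)
  }

  truth <- if (env$nlog)
    do.call(rbind, env$log[seq_len(env$nlog)])
  else data.frame(generation = integer(), node = integer(),
                  kind = character(), locus = character(),
                  donor = character(), pos1 = integer(), pos2 = integer(),
                  detail = character(), stringsAsFactors = FALSE)

  strains <- paste0("S", seq_len(params$n_strains))
  all_loci <- sort(unique(unlist(lapply(leaves, names))))
  anc_model <- gene_model("ancestor", int_to_seq(anc_gene), layout$exons)

  genomes <- list(); models <- list(); gene_models <- list()
  for (s in strains) {
    st <- leaves[[s]]
    loci <- intersect(all_loci, names(st))
    contig <- paste0(s, "_chr")
    offset <- 0L
    blocks <- character(length(loci))
    feats <- list()
    for (i in seq_along(loci)) {
      l <- loci[[i]]
      e <- st[[l]]
      block <- paste0(int_to_seq(e$f5), int_to_seq(e$gene),
                      int_to_seq(e$f3))
      blocks[i] <- block
      gstart <- offset + flen + 1L
      gm <- gene_model(paste0(s, "_", l), int_to_seq(e$gene),
                       layout$exons, strain = s, contig = contig,
                       start = gstart, end = gstart + glen - 1L,
                       strand = "+", locus_id = l)
      gene_models[[gm$gene_id]] <- gm
      feats[[i]] <- gene_model_features(gm, source = "family_sim")
      offset <- offset + nchar(block)
    }
    genomes[[s]] <- seq_record_set(contig, paste(blocks, collapse = ""))
    ft <- do.call(rbind, feats)
    class(ft) <- c("FeatureTable", "data.frame")
    models[[s]] <- ft
  }

  alignments <- setNames(lapply(all_loci, function(l) {
    carriers <- strains[vapply(strains, function(s)
      l %in% names(leaves[[s]]), logical(1L))]
    m <- do.call(rbind, lapply(carriers, function(s)
      strsplit(int_to_seq(leaves[[s]][[l]]$gene), "")[[1L]]))
    rownames(m) <- paste0(carriers, "_", l)
    m
  }), all_loci)

  out <- list(genomes = genomes, models = models,
              gene_models = gene_models, alignments = alignments,
              truth = truth,
              tree = if (is.null(tr)) NULL
                else list(phylo = tr, newick = ape::write.tree(tr)),
              ancestor = anc_model, params = params)
  class(out) <- "FamilySim"
  out
}

#' Matched no-recombination control simulation
#'
#' Runs [simulate_family()] with the conversion channel switched off and
#' infinite-sites mutation forced on, guaranteeing zero homoplasy in the
#' per-locus true alignments: every column pattern maps onto the strain
#' genealogy with a single mutation, so four-gamete and PHI statistics are
#' exactly zero.
#'
#' @param params a [family_sim_params()] object; `conv_rate` and
#'   `infinite_sites` are overridden.
#' @return a `FamilySim` object, see [simulate_family()].
#' @export
make_clonal_null <- function(params) {
  stopifnot(inherits(params, "FamilySimParams"))
  params$conv_rate <- 0
  params$infinite_sites <- TRUE
  simulate_family(params)
}

#' True alignment of one locus as an AlignmentMatrix
#' @param sim a `FamilySim` object.
#' @param locus locus identifier, e.g. `"L01"`.
#' @export
locus_alignment <- function(sim, locus) {
  stopifnot(inherits(sim, "FamilySim"))
  m <- sim$alignments[[locus]]
  if (is.null(m)) stop(sprintf("no such locus: %s", locus))
  alignment_matrix(m)
}

#' Pooled paralog alignment across loci
#'
#' All family members share the ancestor's coordinate system (the
#' simulator is indel-free), so genes from different loci can be stacked
#' into one alignment. This mirrors the family-wide alignments on which
#' recombination tests are typically run: gene conversion between loci
#' then shows up as mosaic taxa.
#'
#' @param sim a `FamilySim` object.
#' @param loci loci to pool (default: all).
#' @return an [alignment_matrix()] with one row per gene
#'   (`<strain>_<locus>`).
#' @export
pooled_alignment <- function(sim, loci = NULL) {
  stopifnot(inherits(sim, "FamilySim"))
  loci <- loci %||% names(sim$alignments)
  m <- do.call(rbind, unname(sim$alignments[loci]))
  alignment_matrix(m)
}

#' Strains carrying the consequences of a truth-log event
#'
#' Maps an event's branch (the `node` column of the truth log) to the set
#' of leaf strains that inherit it.
#'
#' @param sim a `FamilySim` object.
#' @param node node id from the truth log.
#' @return character vector of strain labels.
#' @export
event_strains <- function(sim, node) {
  if (is.null(sim$tree)) return("S1")
  tr <- sim$tree$phylo
  ntip <- length(tr$tip.label)
  if (node <= ntip) return(tr$tip.label[node])
  desc <- ape::extract.clade(tr, node)$tip.label
  desc
}

#' Join two genes at a single crossover breakpoint
#'
#' Builds a chimeric sequence from two genes defined on the same true
#' alignment coordinate system: columns `1..breakpoint` from A and
#' `breakpoint+1..end` from B. `breakpoint = 0` returns B; a breakpoint at
#' the last column returns A.
#'
#' @param geneA,geneB character strings of equal length (aligned
#'   coordinates).
#' @param breakpoint column index in `0..nchar(geneA)`.
#' @return list with `seq` (the chimera) and `truth` (breakpoint record).
#' @export
inject_single_crossover <- function(geneA, geneB, breakpoint) {
  geneA <- toupper(geneA); geneB <- toupper(geneB)
  if (nchar(geneA) != nchar(geneB))
    stop("parents must be defined on the same alignment coordinates")
  L <- nchar(geneA)
  if (!is.numeric(breakpoint) || length(breakpoint) != 1L ||
      breakpoint != floor(breakpoint) || breakpoint < 0 || breakpoint > L)
    stop(sprintf("breakpoint must be an integer in [0, %d]", L))
  seq <- paste0(substr(geneA, 1L, breakpoint),
                substr(geneB, breakpoint + 1L, L))
  list(seq = seq,
       truth = list(kind = "single_crossover", breakpoint = breakpoint,
                    length = L))
}
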