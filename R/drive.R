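#' Poison/antidote specificity of one family member
#'
#' A gene is described by the poison it secretes (or `NULL` for an
#' antidote-only suppressor) and the set of poisons its antidote can
#' detoxify.
#'
#' @param poison poison label, or `NULL` for an antidote-only gene.
#' @param antidotes character vector of poison labels the gene's antidote
#'   neutralises.
#' @return list of class `Specificity`.
#' @export
specificity <- function(poison = NULL, antidotes = character()) {
  out <- list(poison_id = poison, antidote_ids = as.character(antidotes))
  class(out) <- "Specificity"
  out
}

genotype_poisons <- function(g) {
  unique(unlist(lapply(g, function(x) x$poison_id)))
}

genotype_antidotes <- function(g) {
  unique(unlist(lapply(g, function(x) x$antidote_ids)))
}

#' Survival probability of a spore under poison-antidote killing
#'
#' All four spores of a tetrad are exposed to every poison carried by
#' either haploid parent; a spore survives a given poison with
#' probability 1 when any of its own genes' antidotes covers it and with
#' probability `1 - c` otherwise. Survival is independent across distinct
#' poisons, so probabilities multiply.
#'
#' @param parents list of two genotypes; a genotype is a named list (one
#'   entry per locus) of [specificity()] objects, with `NULL` for an empty
#'   locus.
#' @param spore the spore genotype: a named list over the same loci; each
#'   allele must come from one of the parents.
#' @param c killing efficiency in `[0, 1]`.
#' @return survival probability in `[0, 1]`.
#' @export
spore_survival <- function(parents, spore, c) {
  assert_scalar_number(c, "c", 0, 1)
  stopifnot(is.list(parents), length(parents) == 2L)
  loci <- union(names(parents[[1L]]), names(parents[[2L]]))
  same_allele <- function(a, b) {
    (is.null(a) && is.null(b)) || (!is.null(a) && !is.null(b) &&
                                     identical(unclass(a), unclass(b)))
  }
  for (l in loci) {
    sp <- spore[[l]]
    if (!same_allele(sp, parents[[1L]][[l]]) &&
        !same_allele(sp, parents[[2L]][[l]]))
      stop(sprintf("spore allele at locus '%s' is not derivable from the parents", l))
  }
  poisons <- unique(c(genotype_poisons(parents[[1L]]),
                      genotype_poisons(parents[[2L]])))
  if (!length(poisons)) return(1)
  anti <- genotype_antidotes(spore)
  prod(ifelse(poisons %in% anti, 1, 1 - c))
}

#' Deterministic one-generation driver-frequency recursion
#'
#' Infinite-population recursion for a single autonomous poison-antidote
#' driver in a haploid, obligately outcrossing population: haploids pair
#' at random, each mating yields a tetrad of four spores, spores lacking
#' the driver in a driver-by-nondriver mating die with probability `c`,
#' and the next generation is drawn from the surviving spore pool. The
#' closed form is `p' = p / (1 - c p (1 - p))`; it reduces to identity at
#' `c = 0` and fixes `p = 0` and `p = 1`.
#'
#' @param p current driver frequency in `[0, 1]`.
#' @param c killing efficiency in `[0, 1]`.
#' @return next-generation driver frequency.
#' @export
next_gen_deterministic <- function(p, c) {
  assert_scalar_number(c, "c", 0, 1)
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]")
  p / (1 - c * p * (1 - p))
}

wf_update_map <- function(scenario, c) {
  switch(scenario,
         novel_driver = ,
         recombinant_novel_specificity = function(p)
           next_gen_deterministic(p, c),
         duplicate_same_specificity = function(p) p,
         stop(sprintf("unknown scenario '%s'", scenario)))
}

#' Wright-Fisher simulation of a drive scenario
#'
#' Finite-population counterpart of [next_gen_deterministic()]: each
#' generation, `N` haploids are binomially resampled from the post-killing
#' spore pool whose expected driver share is given by the scenario map.
#' Scenarios: `novel_driver` and `recombinant_novel_specificity` follow
#' the drive recursion (the poison is not detoxified by anything already
#' fixed); `duplicate_same_specificity` models a duplicate whose poison
#' the fixed ancestral antidote covers, so every spore survives and the
#' allele is exactly neutral.
#'
#' @param params list with `N` (haploid population size, >= 2), `c`
#'   (killing efficiency), `generations`, `p0` (initial driver
#'   frequency), `seed` (optional).
#' @param scenario one of `"novel_driver"`,
#'   `"duplicate_same_specificity"`, `"recombinant_novel_specificity"`.
#' @return list of class `DriveState`: `trajectory` (per-generation driver
#'   frequency, starting at `p0`), `scenario`, `params`.
#' @export
simulate_wf <- function(params, scenario = "novel_driver") {
  N <- assert_count(params$N, "N", min = 2L)
  cc <- assert_scalar_number(params$c, "c", 0, 1)
  gens <- assert_count(params$generations, "generations")
  p0 <- assert_scalar_number(params$p0, "p0", 0, 1)
  if (!is.null(params$seed)) set.seed(params$seed)
  fmap <- wf_update_map(scenario, cc)
  traj <- numeric(gens + 1L)
  traj[1L] <- p <- p0
  for (g in seq_len(gens)) {
    p <- rbinom(1L, N, fmap(p)) / N
    traj[g + 1L] <- p
  }
  out <- list(trajectory = traj, scenario = scenario,
              params = list(N = N, c = cc, generations = gens, p0 = p0))
  class(out) <- "DriveState"
  out
}

#' Monte-Carlo fixation probability of a drive allele
#'
#' Runs Wright-Fisher replicates until fixation or loss (with a generous
#' generation cap) and reports the fixation fraction with its binomial
#' standard error and a normal-approximation confidence interval.
#'
#' @param params as in [simulate_wf()] (the `generations` entry is used
#'   as a per-replicate cap; default `200 * N` if absent).
#' @param scenario see [simulate_wf()].
#' @param replicates number of Monte-Carlo replicates.
#' @param conf confidence level for the reported interval.
#' @return list: `estimate`, `se`, `ci` (length-2), `fixed`, `replicates`,
#'   `unresolved` (replicates hitting the cap; counted as not fixed).
#' @export
estimate_fixation_prob <- function(params, scenario = "novel_driver",
                                   replicates = 1000L, conf = 0.99) {
  replicates <- assert_count(replicates, "replicates")
  N <- assert_count(params$N, "N", min = 2L)
  cc <- assert_scalar_number(params$c, "c", 0, 1)
  p0 <- assert_scalar_number(params$p0, "p0", 0, 1)
  cap <- if (!is.null(params$generations)) params$generations else 200L * N
  if (!is.null(params$seed)) set.seed(params$seed)
  fmap <- wf_update_map(scenario, cc)
  fixed <- 0L; unresolved <- 0L
  for (r in seq_len(replicates)) {
    p <- p0
    g <- 0L
    while (p > 0 && p < 1 && g < cap) {
      p <- rbinom(1L, N, fmap(p)) / N
      g <- g + 1L
    }
    if (p >= 1) fixed <- fixed + 1L
    else if (p > 0) unresolved <- unresolved + 1L
  }
  est <- fixed / replicates
  se <- sqrt(est * (1 - est) / replicates)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(estimate = est, se = se,
       ci = c(max(0, est - z * se), min(1, est + z * se)),
       fixed = fixed, replicates = replicates, unresolved = unresolved)
}
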