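# Selfing-pedigree simulation: individuals are pairs of recombinant gametes,
# each gamete a piecewise-constant founder-origin function along a chromosome
# (breakpoints + origin labels, 0 = parent A, 1 = parent B).

#' Pedigree configuration
#'
#' @param final_generation generation of the bulked populations (F1 = 1).
#' @param select_het_through last generation at which the advanced individual
#'   is required to be heterozygous at the causal locus. The populations are
#'   founded by `n_sibling_populations` independently drawn heterozygotes of
#'   that generation, all offspring of the same individual of the previous
#'   generation.
#' @param bulk_size individuals per bulk.
#' @param n_sibling_populations number of sibling populations.
#' @param mean_crossovers mean crossovers per chromosome per meiosis
#'   (Poisson count, no interference).
#' @param crossover_density placement of crossovers along the chromosome:
#'   `"distal"` (default) concentrates crossovers near the chromosome ends,
#'   as observed in large cereal chromosomes whose pericentromeric bulk
#'   rarely recombines; `"uniform"` places them uniformly.
#' @param distal_frac,distal_window under `"distal"`, the fraction of
#'   crossovers falling in the two terminal windows, and the width of each
#'   window as a fraction of chromosome length.
#' @param max_tries bound on redraws when searching for an offspring of the
#'   required causal-locus genotype.
#' @return a list of configuration values for [simulate_pedigree()].
#' @export
pedigree_config <- function(final_generation = 5,
                            select_het_through = 4,
                            bulk_size = 10,
                            n_sibling_populations = 2,
                            mean_crossovers = 1.0,
                            crossover_density = c("distal", "uniform"),
                            distal_frac = 0.9,
                            distal_window = 0.1,
                            max_tries = 1000) {
  stopifnot(final_generation >= 2, bulk_size >= 1,
            select_het_through >= 2, select_het_through < final_generation + 1)
  list(final_generation = final_generation,
       select_het_through = select_het_through,
       bulk_size = bulk_size,
       n_sibling_populations = n_sibling_populations,
       mean_crossovers = mean_crossovers,
       crossover_density = match.arg(crossover_density),
       distal_frac = distal_frac,
       distal_window = distal_window,
       max_tries = max_tries)
}

# crossover position sampler; `xo` carries density parameters
sample_xo_positions <- function(n, L, xo) {
  if (n == 0) return(numeric(0))
  if (xo$density == "uniform") return(sort(stats::runif(n, 0, L)))
  w <- xo$distal_window * L
  distal <- stats::runif(n) < xo$distal_frac
  pos <- stats::runif(n, 0, L)
  nd <- sum(distal)
  if (nd) {
    right <- stats::runif(nd) < 0.5
    p <- stats::runif(nd, 0, w)
    pos[distal] <- ifelse(right, L - p, p)
  }
  sort(pos)
}

xo_model <- function(cfg) {
  list(mean = cfg$mean_crossovers,
       density = cfg$crossover_density %||% "distal",
       distal_frac = cfg$distal_frac %||% 0.9,
       distal_window = cfg$distal_window %||% 0.1)
}

# -- gamete primitives -------------------------------------------------------

new_gamete <- function(bp = numeric(0), org = 0L) list(bp = bp, org = as.integer(org))

gamete_origin <- function(g, pos) g$org[findInterval(pos, g$bp) + 1L]

compress_gamete <- function(bp, org) {
  keep <- c(diff(org) != 0L)
  new_gamete(bp[keep], c(org[c(keep, TRUE)]))
}

# one meiosis on one chromosome of an individual with gametes g1, g2
meiosis_chrom <- function(g1, g2, length, xo_cfg) {
  nxo <- stats::rpois(1, xo_cfg$mean)
  xo <- sample_xo_positions(nxo, length, xo_cfg)
  start <- sample.int(2L, 1L)
  bps <- sort(unique(c(xo, g1$bp, g2$bp)))
  mids <- (c(0, bps) + c(bps, length)) / 2
  active <- (start - 1L + findInterval(mids, xo)) %% 2L + 1L
  org <- ifelse(active == 1L, gamete_origin(g1, mids), gamete_origin(g2, mids))
  compress_gamete(bps, as.integer(org))
}

# an individual: list with one element per chromosome, each list(g1, g2)
f1_individual <- function(chromosomes) {
  lapply(seq_len(nrow(chromosomes)), function(i)
    list(g1 = new_gamete(org = 0L), g2 = new_gamete(org = 1L)))
}

self_individual <- function(ind, chromosomes, xo_cfg) {
  lapply(seq_along(ind), function(i) {
    L <- chromosomes$length[i]
    list(g1 = meiosis_chrom(ind[[i]]$g1, ind[[i]]$g2, L, xo_cfg),
         g2 = meiosis_chrom(ind[[i]]$g1, ind[[i]]$g2, L, xo_cfg))
  })
}

# donor (parent-B) allele dosage of an individual at positions on one chromosome
dose_at <- function(ind, chrom_idx, pos) {
  g <- ind[[chrom_idx]]
  gamete_origin(g$g1, pos) + gamete_origin(g$g2, pos)
}

# dosage across all sites of a genome model
dose_at_sites <- function(ind, genome) {
  s <- genome$sites
  out <- integer(nrow(s))
  for (i in seq_len(nrow(genome$chromosomes))) {
    sel <- s$chrom == genome$chromosomes$name[i]
    if (any(sel)) out[sel] <- dose_at(ind, i, s$pos[sel])
  }
  out
}

draw_offspring_with_dose <- function(parent, genome, chrom_idx, causal_pos,
                                     dose, xo_cfg, max_tries, what) {
  for (t in seq_len(max_tries)) {
    off <- self_individual(parent, genome$chromosomes, xo_cfg)
    if (dose_at(off, chrom_idx, causal_pos) == dose) return(off)
  }
  stop(sprintf("no %s offspring found at the causal locus after %d redraws",
               what, max_tries))
}

# -- user-facing operations --------------------------------------------------

#' Expected per-locus homozygosity under selfing
#'
#' Probability that a locus heterozygous in the F1 is homozygous in a
#' generation-`g` selfing descendant with no selection: `1 - (1/2)^(g - 1)`.
#' For an F4 individual this is 0.875, i.e. 87.5% of the genome is expected
#' to be fixed.
#'
#' @param generation integer generation number (F1 = 1).
#' @return homozygous fraction in `[0, 1)`.
#' @examples
#' expected_homozygosity(4)  # 0.875
#' @export
expected_homozygosity <- function(generation) {
  if (any(generation < 1)) stop("generation must be >= 1 (F1 = 1)")
  1 - (1 / 2)^(generation - 1)
}

#' Simulate the selfing pedigree and form contrasting bulks
#'
#' Advances an F1 heterozygote by single-seed descent with heterozygote
#' selection at the causal locus through `select_het_through`, founds
#' `n_sibling_populations` sibling populations from independently drawn
#' heterozygotes of that generation, selfs each founder to the final
#' generation, and draws one bulk of causal-allele homozygotes (carriers) and
#' one bulk of non-carriers per population.
#'
#' @param genome a `genome_model` from [simulate_parents()].
#' @param cfg a list from [pedigree_config()].
#' @param seed integer seed.
#' @return an object of class `sim_truth`: ground truth for every downstream
#'   stage, with components `bulks` (per-bulk metadata and member
#'   individuals), `true_freq` (site x bulk matrix of donor-allele
#'   frequencies), `membership` (causal-locus genotype of every bulked
#'   individual) and `genome`.
#' @export
simulate_pedigree <- function(genome, cfg = pedigree_config(), seed = 1) {
  set.seed(derive_seed(seed, "pedigree"))
  chrom_idx <- match(genome$causal$chrom, genome$chromosomes$name)
  if (is.na(chrom_idx)) stop("causal locus chromosome absent from genome model")
  cpos <- genome$causal$pos
  mx <- xo_model(cfg)

  cur <- f1_individual(genome$chromosomes)
  # single-seed descent with heterozygote selection up to the generation
  # preceding the population founders
  g <- 2
  while (g < cfg$select_het_through) {
    cur <- draw_offspring_with_dose(cur, genome, chrom_idx, cpos, 1L, mx,
                                    cfg$max_tries, "heterozygous")
    g <- g + 1
  }

  bulks <- list()
  for (p in seq_len(cfg$n_sibling_populations)) {
    founder <- draw_offspring_with_dose(cur, genome, chrom_idx, cpos, 1L, mx,
                                        cfg$max_tries, "heterozygous")
    pop_name <- paste0("SP", p)
    # self the founder down to the final generation, then sieve offspring
    # into the two contrasting bulks
    n_self <- cfg$final_generation - cfg$select_het_through
    carriers <- list(); noncarriers <- list()
    tries <- 0
    while ((length(carriers) < cfg$bulk_size ||
            length(noncarriers) < cfg$bulk_size) &&
           tries < cfg$max_tries * cfg$bulk_size) {
      tries <- tries + 1
      off <- founder
      for (k in seq_len(n_self)) off <- self_individual(off, genome$chromosomes, mx)
      d <- dose_at(off, chrom_idx, cpos)
      if (d == 2L && length(carriers) < cfg$bulk_size)
        carriers[[length(carriers) + 1L]] <- off
      else if (d == 0L && length(noncarriers) < cfg$bulk_size)
        noncarriers[[length(noncarriers) + 1L]] <- off
    }
    if (length(carriers) < cfg$bulk_size || length(noncarriers) < cfg$bulk_size)
      stop(sprintf(
        "population %s: could not fill bulks (carriers %d/%d, non-carriers %d/%d) within %d draws",
        pop_name, length(carriers), cfg$bulk_size,
        length(noncarriers), cfg$bulk_size, tries))
    bulks[[paste0("carrier-", pop_name)]] <-
      list(population = pop_name, bulk_type = "carrier", members = carriers)
    bulks[[paste0("noncarrier-", pop_name)]] <-
      list(population = pop_name, bulk_type = "noncarrier", members = noncarriers)
  }

  nsites <- nrow(genome$sites)
  true_freq <- matrix(NA_real_, nsites, length(bulks),
                      dimnames = list(site_key(genome$sites$chrom,
                                               genome$sites$pos),
                                      names(bulks)))
  membership <- do.call(rbind, lapply(names(bulks), function(bn) {
    b <- bulks[[bn]]
    doses <- vapply(b$members, dose_at_sites, integer(nsites), genome)
    if (nsites == 1L) doses <- matrix(doses, nrow = 1L)
    true_freq[, bn] <<- rowSums(doses) / (2 * length(b$members))
    data.frame(bulk = bn, population = b$population, bulk_type = b$bulk_type,
               member = seq_along(b$members),
               causal_dose = vapply(b$members, dose_at, integer(1),
                                    chrom_idx, cpos),
               stringsAsFactors = FALSE)
  }))

  structure(list(genome = genome, bulks = bulks, true_freq = true_freq,
                 membership = membership, cfg = cfg, seed = seed),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Bulk-segregant pedigree simulation\n")
  cat(sprintf("  %d bulk(s) of %d, final generation F%d\n",
              length(x$bulks), x$cfg$bulk_size, x$cfg$final_generation))
  ck <- site_key(x$genome$causal$chrom, x$genome$causal$pos)
  cat("  donor-allele frequency at the causal locus:\n")
  print(round(x$true_freq[ck, ], 3))
  invisible(x)
}

#' Simulate per-locus homozygosity under selfing without selection
#'
#' Monte-Carlo companion to [expected_homozygosity()]: selfs unlinked loci
#' independently from an F1 heterozygote and reports the homozygous fraction.
#'
#' @param generation target generation (F1 = 1).
#' @param n_loci number of independent loci.
#' @param seed integer seed.
#' @return list with `fraction` (observed homozygous fraction), `se`
#'   (binomial Monte-Carlo standard error) and `expected`.
#' @export
simulate_selfing_homozygosity <- function(generation, n_loci = 10000, seed = 1) {
  if (generation < 1) stop("generation must be >= 1")
  set.seed(derive_seed(seed, "selfing"))
  # an unlinked locus is Markov under selfing: Aa -> {AA, Aa, aa} w.p. 1/4,1/2,1/4
  state <- rep(1L, n_loci)  # 1 = heterozygous
  if (generation > 1) {
    for (g in 2:generation) {
      het <- state == 1L
      u <- stats::runif(sum(het))
      state[het][u < 0.25] <- 0L
      state[het][u >= 0.75] <- 2L
    }
  }
  frac <- mean(state != 1L)
  p <- expected_homozygosity(generation)
  list(fraction = frac, se = sqrt(p * (1 - p) / n_loci), expected = p)
}
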