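# Linkage validation on simulated material: genotyping, two-point
# recombination-fraction estimation (F2, EM) and map functions.

#' Simulate an F2 mapping population
#'
#' Selfs the F1 between the two founder parents once, `n` times
#' independently, under the Haldane crossover model.
#'
#' @param genome a `genome_model`.
#' @param n number of F2 individuals.
#' @param cfg a [pedigree_config()] supplying the crossover model.
#' @param seed integer seed.
#' @return object of class `sim_population` holding the individuals.
#' @export
simulate_f2 <- function(genome, n, cfg = pedigree_config(), seed = 1) {
  set.seed(derive_seed(seed, "f2"))
  xo <- xo_model(cfg)
  f1 <- f1_individual(genome$chromosomes)
  inds <- lapply(seq_len(n), function(i)
    self_individual(f1, genome$chromosomes, xo))
  structure(list(genome = genome, individuals = inds, design = "F2"),
            class = "sim_population")
}

#' Genotype simulated individuals at marker positions
#'
#' Reads codominant genotypes off the simulated chromosome mosaics at the
#' requested positions. Accepts either a `sim_population` (e.g. an F2 from
#' [simulate_f2()]) or a `sim_truth`, in which case the bulked individuals
#' are genotyped.
#'
#' @param population a `sim_population` or `sim_truth`.
#' @param marker_positions data frame with `chrom` and `pos` columns (and
#'   optionally `name`), or a named list of `chrom:pos` keys.
#' @param missing_rate probability that a genotype call is missing.
#' @param seed integer seed (used only when `missing_rate > 0`).
#' @return character matrix individuals x markers with codes `"AA"`, `"AB"`,
#'   `"BB"` (parent A / heterozygous / parent B i.e. donor homozygote) and
#'   `NA` for missing.
#' @export
genotype_population <- function(population, marker_positions,
                                missing_rate = 0, seed = 1) {
  if (is.character(marker_positions)) {
    sp <- strsplit(marker_positions, ":", fixed = TRUE)
    marker_positions <- data.frame(
      chrom = vapply(sp, `[`, character(1), 1),
      pos = as.numeric(vapply(sp, `[`, character(1), 2)),
      name = marker_positions, stringsAsFactors = FALSE)
  }
  if (is.null(marker_positions$name))
    marker_positions$name <- site_key(marker_positions$chrom,
                                      marker_positions$pos)
  if (inherits(population, "sim_truth")) {
    genome <- population$genome
    inds <- unlist(lapply(population$bulks, function(b) b$members),
                   recursive = FALSE)
  } else if (inherits(population, "sim_population")) {
    genome <- population$genome
    inds <- population$individuals
  } else stop("population must be a sim_population or sim_truth")

  ci <- match(marker_positions$chrom, genome$chromosomes$name)
  if (anyNA(ci))
    stop("marker chromosome(s) absent from the simulated genome: ",
         paste(unique(marker_positions$chrom[is.na(ci)]), collapse = ", "))
  off <- marker_positions$pos < 1 |
    marker_positions$pos > genome$chromosomes$length[ci]
  if (any(off))
    stop("marker position(s) off the chromosome: ",
         paste(marker_positions$name[off], collapse = ", "))

  codes <- c("AA", "AB", "BB")
  G <- matrix(NA_character_, length(inds), nrow(marker_positions),
              dimnames = list(NULL, marker_positions$name))
  for (j in seq_len(nrow(marker_positions))) {
    d <- vapply(inds, dose_at, integer(1), ci[j], marker_positions$pos[j])
    G[, j] <- codes[d + 1L]
  }
  if (missing_rate > 0) {
    set.seed(derive_seed(seed, "missing"))
    G[stats::runif(length(G)) < missing_rate] <- NA_character_
  }
  G
}

#' Two-point recombination fraction in an F2 (EM)
#'
#' Maximum-likelihood recombination fraction between two codominant loci in
#' an F2 design, by EM over the nine two-locus genotype classes (the
#' double-heterozygote class mixes parental and recombinant gamete pairs),
#' with a LOD score against independence (r = 0.5).
#'
#' @param geno genotype matrix from [genotype_population()] (codes
#'   `AA`/`AB`/`BB`), or `NULL` if `a` and `b` are given directly.
#' @param locus_a,locus_b column names or indices in `geno`.
#' @param a,b alternatively, two genotype code vectors.
#' @param tol EM convergence tolerance on r.
#' @param max_iter iteration cap.
#' @return list with `rf` (estimate in `[0, 0.5]`), `lod` and `n` (complete
#'   pairs used).
#' @export
two_point_rf <- function(geno = NULL, locus_a = 1, locus_b = 2,
                         a = NULL, b = NULL, tol = 1e-8, max_iter = 200) {
  if (!is.null(geno)) { a <- geno[, locus_a]; b <- geno[, locus_b] }
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  codes <- c("AA", "AB", "BB")
  if (!all(a %in% codes) || !all(b %in% codes))
    stop("genotype codes must be AA/AB/BB")
  da <- match(a, codes) - 1L   # donor-allele dose 0/1/2
  db <- match(b, codes) - 1L
  if (length(unique(da)) < 2 || length(unique(db)) < 2)
    stop("monomorphic locus: recombination fraction undefined")
  n <- length(da)
  counts <- table(factor(da, 0:2), factor(db, 0:2))

  class_probs <- function(r) {
    # gamete types by (allele at A, allele at B): ab, aB, Ab, AB
    gt <- c(ab = (1 - r) / 2, aB = r / 2, Ab = r / 2, AB = (1 - r) / 2)
    al <- expand.grid(g1 = names(gt), g2 = names(gt), stringsAsFactors = FALSE)
    pa <- gt[al$g1] * gt[al$g2]
    dosA <- (al$g1 %in% c("Ab", "AB")) + (al$g2 %in% c("Ab", "AB"))
    dosB <- (al$g1 %in% c("aB", "AB")) + (al$g2 %in% c("aB", "AB"))
    P <- matrix(0, 3, 3)
    for (i in seq_along(pa)) P[dosA[i] + 1, dosB[i] + 1] <-
        P[dosA[i] + 1, dosB[i] + 1] + pa[i]
    P
  }

  loglik <- function(r) {
    P <- class_probs(r)
    sum(counts[counts > 0] * log(P[counts > 0]))
  }

  # EM: expected recombinant gametes per individual class
  r <- 0.25
  for (it in seq_len(max_iter)) {
    # recombinant-gamete count by class; double het is the mixture
    recm <- matrix(c(0, 1, 2,
                     1, NA, 1,
                     2, 1, 0), 3, 3, byrow = TRUE)
    t_dh <- r^2 / (r^2 + (1 - r)^2)     # P(double het from two recombinants)
    recm[2, 2] <- 2 * t_dh
    r_new <- sum(counts * recm) / (2 * n)
    r_new <- min(max(r_new, 1e-9), 0.5)
    if (abs(r_new - r) < tol) { r <- r_new; break }
    r <- r_new
  }
  lod <- (loglik(r) - loglik(0.5)) / log(10)
  list(rf = r, lod = lod, n = n)
}

#' Map distance from a recombination fraction
#'
#' Haldane: `-50 ln(1 - 2r)`; Kosambi: `25 ln((1 + 2r) / (1 - 2r))`
#' (centimorgans).
#'
#' @param rf recombination fraction(s) in `[0, 0.5)`.
#' @param fun `"kosambi"` (default, conventional in wheat mapping) or
#'   `"haldane"`.
#' @return distance(s) in cM.
#' @examples
#' map_distance(0.1, "haldane")  # 11.157
#' @export
map_distance <- function(rf, fun = c("kosambi", "haldane")) {
  fun <- match.arg(fun)
  if (any(rf < 0 | rf >= 0.5)) stop("rf must be in [0, 0.5)")
  switch(fun,
         haldane = -50 * log(1 - 2 * rf),
         kosambi = 25 * log((1 + 2 * rf) / (1 - 2 * rf)))
}
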