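#' Default configuration for the synthetic D-genome model
#'
#' The synthetic genome stands in for a diploid D-genome reference carrying
#' biallelic sites that differ between two donor accessions (parents "A" and
#' "B"), overlaid by a fixed AABB homoeologous background. Four site types are
#' generated:
#'
#' * `"P"` — parent-divergent sites with no alignable homoeologous copy
#'   (true subgenome-specific allelic variants);
#' * `"H"` — sites monomorphic between the parents where the homoeolog
#'   carries a different base (true homoeologous polymorphisms);
#' * `"B"` — sites divergent both between parents and versus the homoeolog
#'   (the homoeolog base is constrained to the parent-B allele so each site
#'   stays biallelic against either reference);
#' * `"U"` — homoeolog-divergent sites whose homoeologous copy is not
#'   expressed in the tetraploid reference sample, so they carry
#'   contaminating reads in the bulks but leave no tetraploid evidence
#'   (true unclassifiable sites).
#'
#' @param n_chrom number of chromosomes (at most 7 in default layouts).
#' @param chrom_length chromosome length in bp (recycled across chromosomes);
#'   the default matches the physical scale of wheat D-genome chromosomes,
#'   which at one crossover per meiosis gives a realistically low cM/Mb rate.
#' @param sites_per_chrom background SNP sites per chromosome.
#' @param causal_chrom,causal_pos location of the selected (carrier) locus;
#'   the default places it subtelomerically, as for a short-arm
#'   hybrid-necrosis locus.
#' @param region candidate target interval (bp, closed) on the causal
#'   chromosome; mirrors the physically delimited target region of a
#'   fine-mapping experiment.
#' @param region_extra_sites additional sites planted uniformly inside
#'   `region` — target intervals identified by prior fine mapping are
#'   SNP-dense relative to a desk-scale uniform background.
#' @param type_probs probabilities of site types `P`, `H`, `B`, `U`.
#' @param rho_beta shape parameters of the Beta distribution from which the
#'   per-site homoeologous read contamination is drawn (homoeolog-covered
#'   sites only).
#' @param minus_strand_frac fraction of transcripts anchored on the minus
#'   strand.
#' @param flank flanking sequence length (bp) kept on each side of a site for
#'   marker design.
#' @return a list of configuration values for [simulate_parents()].
#' @export
genome_config <- function(n_chrom = 7,
                          chrom_length = 600e6,
                          sites_per_chrom = 4000,
                          causal_chrom = "2D",
                          causal_pos = 82550000,
                          region = c(81800000, 83300000),
                          region_extra_sites = 20,
                          type_probs = c(P = 0.25, H = 0.55, B = 0.10, U = 0.10),
                          rho_beta = c(2, 5),
                          minus_strand_frac = 0.1,
                          flank = 100) {
  stopifnot(n_chrom >= 1, n_chrom <= 7)
  chroms <- paste0(seq_len(n_chrom), "D")
  list(
    chromosomes = data.frame(name = chroms,
                             length = rep_len(chrom_length, n_chrom),
                             stringsAsFactors = FALSE),
    sites_per_chrom = rep_len(sites_per_chrom, n_chrom),
    causal_chrom = causal_chrom,
    causal_pos = causal_pos,
    region = region,
    region_extra_sites = region_extra_sites,
    type_probs = type_probs,
    rho_beta = rho_beta,
    minus_strand_frac = minus_strand_frac,
    flank = flank
  )
}

#' Simulate two divergent diploid parents over a homoeologous background
#'
#' Draws SNP site positions, parental alleles, per-site homoeolog bases and
#' homoeologous-contamination rates, and a transcript anchoring for every
#' site. The result is the ground-truth genome model every other simulation
#' stage consumes.
#'
#' @param config a list from [genome_config()].
#' @param seed integer seed; the same seed reproduces the model exactly.
#' @return an object of class `genome_model` with components `chromosomes`
#'   (data frame of name/length), `sites` (one row per SNP site), `causal`
#'   (list with `chrom` and `pos`) and `config`.
#' @examples
#' gm <- simulate_parents(genome_config(n_chrom = 2, sites_per_chrom = 50), seed = 1)
#' nrow(gm$sites)
#' @export
simulate_parents <- function(config = genome_config(), seed = 1) {
  set.seed(derive_seed(seed, "parents"))
  chroms <- config$chromosomes
  if (any(chroms$length <= 0)) stop("chromosome lengths must be positive")
  nsites <- config$sites_per_chrom
  if (nsites[match(config$causal_chrom, chroms$name)] <= 0)
    stop("the causal chromosome must carry at least one SNP site")
  if (!config$causal_chrom %in% chroms$name)
    stop("causal chromosome not in the chromosome set")

  rows <- vector("list", nrow(chroms))
  for (i in seq_len(nrow(chroms))) {
    cn <- chroms$name[i]
    n <- nsites[i]
    pos <- if (n > 0) sort(sample.int(chroms$length[i], n)) else integer(0)
    if (cn == config$causal_chrom) {
      extra <- sort(sample(seq.int(config$region[1], config$region[2]),
                           config$region_extra_sites))
      pos <- sort(unique(as.integer(c(pos, extra, config$causal_pos))))
    }
    if (length(pos))
      rows[[i]] <- data.frame(chrom = cn, pos = pos, stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(sites)) {
    sites <- data.frame(chrom = character(0), pos = integer(0))
  }
  n <- nrow(sites)

  tp <- config$type_probs
  sites$type <- sample(names(tp), n, replace = TRUE, prob = tp)
  # causal site itself is a subgenome-specific allelic variant
  ci <- which(sites$chrom == config$causal_chrom & sites$pos == config$causal_pos)
  sites$type[ci] <- "P"

  sites$a_allele <- sample(DNA_BASES, n, replace = TRUE)
  other <- function(b) vapply(b, function(x) sample(setdiff(DNA_BASES, x), 1),
                              character(1), USE.NAMES = FALSE)
  pdiv <- sites$type %in% c("P", "B")
  sites$b_allele <- sites$a_allele
  sites$b_allele[pdiv] <- other(sites$a_allele[pdiv])

  sites$hom_base <- NA_character_
  hdiv <- sites$type %in% c("H", "U")
  sites$hom_base[hdiv] <- other(sites$a_allele[hdiv])
  sites$hom_base[sites$type == "B"] <- sites$b_allele[sites$type == "B"]

  sites$rho <- 0
  hom_covered <- sites$type != "P"
  sites$rho[hom_covered] <- stats::rbeta(sum(hom_covered),
                                         config$rho_beta[1], config$rho_beta[2])
  sites$tetraploid_expressed <- sites$type %in% c("H", "B")

  sites$transcript_id <- sprintf("tx%06d", seq_len(n))
  sites$transcript_pos <- rep.int(config$flank + 1L, n)
  sites$strand <- ifelse(stats::runif(n) < config$minus_strand_frac, "-", "+")
  rownames(sites) <- NULL

  structure(list(chromosomes = chroms, sites = sites,
                 causal = list(chrom = config$causal_chrom,
                               pos = config$causal_pos),
                 config = config),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("Synthetic diploid genome over a homoeologous background\n")
  cat(sprintf("  %d chromosome(s), %d SNP site(s)\n",
              nrow(x$chromosomes), nrow(x$sites)))
  cat(sprintf("  causal locus: %s:%d\n", x$causal$chrom, x$causal$pos))
  tt <- table(factor(x$sites$type, levels = c("P", "H", "B", "U")))
  cat(sprintf("  site types: P=%d H=%d B=%d U=%d\n",
              tt["P"], tt["H"], tt["B"], tt["U"]))
  invisible(x)
}

#' Deterministic flanking sequences for marker design
#'
#' Generates, for each requested site, the genomic sequence around it with the
#' parent-A allele at the central position. Flanks are drawn deterministically
#' from the model's site keys so repeated calls agree.
#'
#' @param genome a `genome_model`.
#' @param keys optional character vector of `chrom:pos` keys (default: all).
#' @param flank flank length on each side (bp).
#' @param seed integer seed.
#' @return named character vector of sequences of length `2*flank + 1`; names
#'   are site keys. Attributes `alleles` carries the `a/b` allele pair.
#' @export
site_flanks <- function(genome, keys = NULL, flank = genome$config$flank, seed = 1) {
  s <- genome$sites
  k <- site_key(s$chrom, s$pos)
  if (!is.null(keys)) {
    idx <- match(keys, k)
    if (anyNA(idx)) stop("unknown site key(s): ", paste(keys[is.na(idx)], collapse = ", "))
    s <- s[idx, , drop = FALSE]
    k <- k[idx]
  }
  out <- character(nrow(s))
  for (i in seq_len(nrow(s))) {
    set.seed(derive_seed(seed, paste0("flank:", k[i])))
    sq <- random_dna(2 * flank + 1)
    substr(sq, flank + 1, flank + 1) <- s$a_allele[i]
    out[i] <- sq
  }
  names(out) <- k
  attr(out, "alleles") <- data.frame(key = k, a = s$a_allele, b = s$b_allele,
                                     stringsAsFactors = FALSE)
  out
}
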