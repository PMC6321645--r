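# Read-depth sampling of allele counts at SNP sites, with homoeologous
# contamination, for hexaploid bulks and for the tetraploid reference sample.

#' Sequencing depth model
#'
#' @param family `"nbinom"` (default) or `"poisson"`.
#' @param mean expected depth per site.
#' @param size negative-binomial dispersion (ignored for Poisson); smaller
#'   values give stronger overdispersion.
#' @return a list describing the depth distribution.
#' @export
depth_model <- function(family = c("nbinom", "poisson"), mean = 30, size = 5) {
  family <- match.arg(family)
  stopifnot(mean >= 0, size > 0)
  list(family = family, mean = mean, size = size)
}

# `runs` merged sequencing runs: the sum of iid per-run depths
draw_depth <- function(n, dm, runs = 1) {
  mu <- dm$mean * runs
  if (dm$family == "poisson") stats::rpois(n, mu)
  else stats::rnbinom(n, size = dm$size * runs, mu = mu)
}

# transcript-space ref/alt bases for a site row against a reference parent
ref_alt_bases <- function(sites, reference) {
  ref_g <- if (reference == "A") sites$a_allele else sites$b_allele
  alt_g <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    cand <- c(if (sites$a_allele[i] != ref_g[i]) sites$a_allele[i],
              if (sites$b_allele[i] != ref_g[i]) sites$b_allele[i],
              if (!is.na(sites$hom_base[i]) && sites$hom_base[i] != ref_g[i])
                sites$hom_base[i])
    cand <- unique(cand)
    # generator guarantees biallelism; fall back to an arbitrary other base
    alt_g[i] <- if (length(cand)) cand[1] else setdiff(DNA_BASES, ref_g[i])[1]
  }
  minus <- sites$strand == "-"
  ref_t <- ref_g; alt_t <- alt_g
  ref_t[minus] <- complement_base(ref_g[minus])
  alt_t[minus] <- complement_base(alt_g[minus])
  list(ref = ref_t, alt = alt_t)
}

#' Sample an allele-count table for one bulk against one reference
#'
#' Each read at a site is homoeologous with the site's contamination
#' probability `rho` (its base is the homoeolog base) and otherwise drawn from
#' the bulk chromosome pool at the bulk's true donor-allele frequency. Counts
#' are reported in transcript coordinates against the chosen parental
#' transcript reference; the alternate allele is the base differing from that
#' reference.
#'
#' @param truth a `sim_truth` from [simulate_pedigree()].
#' @param bulk bulk name (e.g. `"carrier-SP1"`) or index.
#' @param reference `"A"` or `"B"`: which parent's transcripts serve as the
#'   alignment reference.
#' @param dm a [depth_model()] describing per-run depth.
#' @param runs number of merged sequencing runs per bulk library (each bulk
#'   of the emulated design was sequenced twice and the alignments merged).
#' @param seed integer seed.
#' @return a count-table data frame (columns `chrom`, `pos`, `transcript_id`,
#'   `transcript_pos`, `ref_base`, `alt_base`, `depth`, `alt_depth`) with a
#'   `"pair"` attribute describing the alignment pair. The `chrom`/`pos`
#'   columns hold the placeholder `"."`/`0`: genome coordinates are assigned
#'   by anchoring, not by the simulator.
#' @export
sample_allele_counts <- function(truth, bulk, reference = c("A", "B"),
                                 dm = depth_model(), runs = 2, seed = 1) {
  reference <- match.arg(reference)
  if (is.numeric(bulk)) bulk <- names(truth$bulks)[bulk]
  if (!bulk %in% names(truth$bulks)) stop("unknown bulk: ", bulk)
  genome <- truth$genome
  s <- genome$sites
  n <- nrow(s)
  set.seed(derive_seed(seed, paste("counts", bulk, reference)))

  f <- truth$true_freq[, bulk]                # donor (parent-B) allele frequency
  D <- draw_depth(n, dm, runs)
  nh <- stats::rbinom(n, D, s$rho)            # homoeologous reads
  nd <- D - nh

  ref_g <- if (reference == "A") s$a_allele else s$b_allele
  hom_alt <- !is.na(s$hom_base) & s$hom_base != ref_g
  pdiv <- s$a_allele != s$b_allele
  p_alt_d <- ifelse(pdiv, if (reference == "A") f else 1 - f, 0)

  K <- ifelse(hom_alt, nh, 0L) + stats::rbinom(n, nd, p_alt_d)
  ba <- ref_alt_bases(s, reference)
  out <- data.frame(chrom = ".", pos = 0L,
                    transcript_id = s$transcript_id,
                    transcript_pos = s$transcript_pos,
                    ref_base = ba$ref, alt_base = ba$alt,
                    depth = as.integer(D), alt_depth = as.integer(K),
                    stringsAsFactors = FALSE)
  attr(out, "pair") <- list(sample = bulk,
                            population = truth$bulks[[bulk]]$population,
                            bulk_type = truth$bulks[[bulk]]$bulk_type,
                            reference = reference)
  out
}

#' Sample allele counts for the tetraploid reference sample
#'
#' The tetraploid (AABB) sample carries no D genome: all its reads aligning
#' to the D-genome transcript references are homoeologous. Sites whose
#' homoeologous copy is not expressed receive zero depth; at expressed sites
#' every read carries the homoeolog base, so the site yields alternate reads
#' exactly when that base differs from the reference transcript base.
#'
#' @param genome a `genome_model`.
#' @inheritParams sample_allele_counts
#' @return a count-table data frame with a `"pair"` attribute
#'   (`sample = "tetraploid"`). The tetraploid library is sequenced in a
#'   single run by default.
#' @export
simulate_tetraploid_counts <- function(genome, reference = c("A", "B"),
                                       dm = depth_model(), runs = 1, seed = 1) {
  reference <- match.arg(reference)
  s <- genome$sites
  n <- nrow(s)
  set.seed(derive_seed(seed, paste("tetraploid", reference)))
  D <- ifelse(s$tetraploid_expressed, draw_depth(n, dm, runs), 0L)
  ref_g <- if (reference == "A") s$a_allele else s$b_allele
  hom_alt <- !is.na(s$hom_base) & s$hom_base != ref_g
  K <- ifelse(hom_alt, D, 0L)
  ba <- ref_alt_bases(s, reference)
  out <- data.frame(chrom = ".", pos = 0L,
                    transcript_id = s$transcript_id,
                    transcript_pos = s$transcript_pos,
                    ref_base = ba$ref, alt_base = ba$alt,
                    depth = as.integer(D), alt_depth = as.integer(K),
                    stringsAsFactors = FALSE)
  attr(out, "pair") <- list(sample = "tetraploid", population = NA_character_,
                            bulk_type = NA_character_, reference = reference)
  out
}

#' Simulate the full set of bulk alignment-pair tables
#'
#' One table per bulk x transcript-reference combination (eight tables for the
#' default two populations).
#'
#' @inheritParams sample_allele_counts
#' @return named list of count tables; names are `<bulk>.ref<A|B>`.
#' @export
simulate_bulk_tables <- function(truth, dm = depth_model(), runs = 2, seed = 1) {
  out <- list()
  for (bulk in names(truth$bulks)) {
    for (ref in c("A", "B")) {
      nm <- paste0(bulk, ".ref", ref)
      out[[nm]] <- sample_allele_counts(truth, bulk, ref, dm, runs,
                                        seed = derive_seed(seed, nm))
    }
  }
  out
}
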