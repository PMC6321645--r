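# Shared fixtures and independent oracles. Expensive simulations are built
# once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# mid-size three-chromosome experiment used by several property tests
mid_fixture <- function() {
  cached("mid", {
    cfg <- genome_config(n_chrom = 3, sites_per_chrom = 800,
                         causal_chrom = "2D")
    gm <- simulate_parents(cfg, seed = 5)
    tr <- simulate_pedigree(gm, pedigree_config(), seed = 5)
    dir <- file.path(tempdir(), "mid_bundle")
    emit_fixture_bundle(tr, dir, seed = 5)
    list(cfg = cfg, genome = gm, truth = tr, dir = dir,
         bundle = read_fixture_bundle(dir))
  })
}

mid_scan <- function() {
  cached("mid_scan", bsa_scan(mid_fixture()$bundle))
}

# full default-condition experiment (used by the acceptance tests)
default_run <- function() {
  cached("default_run", run_bsa_pipeline(seed = 1, write_reports = FALSE))
}

# minimal hand-built truth object: one bulk pair, arbitrary site table
toy_truth <- function(sites, freq_carrier, freq_noncarrier,
                      chrom_length = 1e6) {
  chroms <- data.frame(name = unique(sites$chrom), length = chrom_length,
                       stringsAsFactors = FALSE)
  genome <- structure(list(
    chromosomes = chroms, sites = sites,
    causal = list(chrom = sites$chrom[1], pos = sites$pos[1]),
    config = list(flank = 100)), class = "genome_model")
  tf <- cbind(`carrier-SP1` = freq_carrier, `noncarrier-SP1` = freq_noncarrier)
  rownames(tf) <- paste(sites$chrom, sites$pos, sep = ":")
  structure(list(
    genome = genome,
    bulks = list(
      `carrier-SP1` = list(population = "SP1", bulk_type = "carrier",
                           members = list()),
      `noncarrier-SP1` = list(population = "SP1", bulk_type = "noncarrier",
                              members = list())),
    true_freq = tf, membership = NULL, seed = 0), class = "sim_truth")
}

toy_sites <- function(n, type = "P", rho = 0, hom_base = NA_character_,
                      a = "A", b = "G", strand = "+") {
  data.frame(chrom = "1D", pos = seq_len(n) * 1000L, type = type,
             a_allele = a, b_allele = b, hom_base = hom_base, rho = rho,
             tetraploid_expressed = type %in% c("H", "B"),
             transcript_id = sprintf("t%04d", seq_len(n)),
             transcript_pos = 101L, strand = strand,
             stringsAsFactors = FALSE)
}

# -- independent oracles -----------------------------------------------------

# exact permutation distribution of the pairwise rank-sum, from first
# principles (two-sided on |W - E[W]|)
perm_ranksum_p <- function(xi, xj) {
  m <- length(xi); n <- length(xj); N <- m + n
  r <- rank(c(xi, xj))
  E <- m * (N + 1) / 2
  obs <- abs(sum(r[seq_len(m)]) - E)
  sets <- utils::combn(N, m)
  dev <- abs(colSums(matrix(r[sets], nrow = m)) - E)
  mean(dev >= obs - 1e-9)
}

# quadratic brute-force IUPAC digestion: scan every substring on both strands
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

brute_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

brute_digest <- function(seq, site) {
  sq <- strsplit(toupper(seq), "")[[1]]
  L <- length(sq); k <- nchar(site)
  hits <- integer(0)
  for (pat in unique(c(site, brute_revcomp(site)))) {
    pb <- strsplit(pat, "")[[1]]
    for (i in seq_len(max(L - k + 1, 0))) {
      ok <- TRUE
      for (j in seq_len(k))
        if (!sq[i + j - 1] %in% IUPAC_SETS[[pb[j]]]) { ok <- FALSE; break }
      if (ok) hits <- c(hits, i)
    }
  }
  cuts <- sort(unique(hits - 1L))
  cuts <- cuts[cuts > 0 & cuts < L]
  diff(c(0L, cuts, L))
}

# brute-force de-duplication of site keys across sets
brute_union_size <- function(sets) {
  keys <- unlist(lapply(sets, function(s) paste(s$chrom, s$pos)))
  length(unique(keys))
}

random_flank <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
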