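# Synthetic-data generator: parents, pedigree, depth sampling, fixtures.

test_that("simulate_parents conserves site counts and is deterministic", {
  cfg <- genome_config(n_chrom = 7, sites_per_chrom = 500,
                       region_extra_sites = 0)
  gm1 <- simulate_parents(cfg, seed = 11)
  # positions are sampled without replacement, plus the causal site
  expect_gte(nrow(gm1$sites), 7 * 500)
  expect_lte(nrow(gm1$sites), 7 * 500 + 1)
  expect_identical(simulate_parents(cfg, seed = 11), gm1)
  expect_false(identical(simulate_parents(cfg, seed = 12)$sites$pos,
                         gm1$sites$pos))
  # positions strictly increasing within a chromosome
  by_chrom <- split(gm1$sites$pos, gm1$sites$chrom)
  for (p in by_chrom) expect_true(all(diff(p) > 0))
})

test_that("simulate_parents handles degenerate and invalid configurations", {
  cfg <- genome_config(n_chrom = 3, sites_per_chrom = c(50, 50, 0),
                       causal_chrom = "2D")
  gm <- simulate_parents(cfg, seed = 1)
  expect_equal(sum(gm$sites$chrom == "3D"), 0)
  cfg_bad <- genome_config(n_chrom = 3, sites_per_chrom = c(50, 0, 50),
                           causal_chrom = "2D")
  expect_error(simulate_parents(cfg_bad, seed = 1), "causal chromosome")
  cfg_len <- genome_config(n_chrom = 2, chrom_length = 0)
  expect_error(simulate_parents(cfg_len, seed = 1), "positive")
})

test_that("pedigree forms the expected bulks with fixation at the causal locus", {
  fx <- mid_fixture()
  tr <- fx$truth
  expect_length(tr$bulks, 4)
  for (b in tr$bulks) expect_length(b$members, 10)
  ck <- paste(fx$genome$causal$chrom, fx$genome$causal$pos, sep = ":")
  expect_equal(unname(tr$true_freq[ck, c("carrier-SP1", "carrier-SP2")]),
               c(1, 1))
  expect_equal(unname(tr$true_freq[ck, c("noncarrier-SP1", "noncarrier-SP2")]),
               c(0, 0))
  expect_true(all(tr$membership$causal_dose[tr$membership$bulk_type == "carrier"] == 2))
  expect_true(all(tr$membership$causal_dose[tr$membership$bulk_type == "noncarrier"] == 0))
})

test_that("unlinked loci segregate around one half across replicate pedigrees", {
  # Monte-Carlo over replicate pedigrees: mean donor-allele frequency at an
  # unlinked site in a large bulk is 1/2 with binomial spread
  cfg <- genome_config(n_chrom = 2, sites_per_chrom = c(2, 1),
                       causal_chrom = "2D", causal_pos = 500000,
                       region = c(400000, 600000), region_extra_sites = 0,
                       chrom_length = 1e6)
  freqs <- vapply(1:200, function(s) {
    gm <- simulate_parents(cfg, seed = 1000 + s)
    tr <- simulate_pedigree(gm, pedigree_config(bulk_size = 10), seed = s)
    k <- paste(gm$sites$chrom, gm$sites$pos, sep = ":")
    unlinked <- k[gm$sites$chrom == "1D"][1]
    mean(tr$true_freq[unlinked, ])
  }, numeric(1))
  se <- sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(mean(freqs) - 0.5), 3 * se + 0.02)
})

test_that("expected homozygosity follows the selfing closed form", {
  expect_identical(expected_homozygosity(4), 0.875)
  expect_identical(expected_homozygosity(1), 0)
  expect_equal(expected_homozygosity(5), 0.9375)
  expect_error(expected_homozygosity(0), "generation")
  sim <- simulate_selfing_homozygosity(4, n_loci = 10000, seed = 2)
  expect_lt(abs(sim$fraction - 0.875), 3 * sim$se)
})

test_that("allele-count sampling reproduces closed-form expectations", {
  # no contamination, fixed donor allele, non-donor reference: K/D = 1
  s <- toy_sites(200, type = "P", rho = 0)
  tr <- toy_truth(s, freq_carrier = rep(1, 200), freq_noncarrier = rep(0, 200))
  tab <- sample_allele_counts(tr, "carrier-SP1", "A", seed = 3)
  expect_true(all(tab$alt_depth == tab$depth))
  expect_true(all(tab$alt_depth <= tab$depth))
  # mirrored against the donor reference
  tab_b <- sample_allele_counts(tr, "carrier-SP1", "B", seed = 3)
  expect_true(all(tab_b$alt_depth == 0))
  # 50/50 homoeolog mixture, homoeolog matches the reference, fixed donor:
  # E[K/D] = (1 - rho) * 1 = 0.5
  s2 <- toy_sites(2000, type = "B", rho = 0.5, hom_base = "A")
  tr2 <- toy_truth(s2, rep(1, 2000), rep(0, 2000))
  t2 <- sample_allele_counts(tr2, "carrier-SP1", "A",
                             depth_model("nbinom", 50, 5), seed = 4)
  idx <- t2$alt_depth / t2$depth
  expect_lt(abs(mean(idx, na.rm = TRUE) - 0.5), 0.02)
})

test_that("tetraploid sample yields pure homoeologous counts", {
  s <- toy_sites(50, type = "H", rho = 0.3, hom_base = "C")
  s$tetraploid_expressed <- TRUE
  gm <- toy_truth(s, rep(0, 50), rep(0, 50))$genome
  # homoeolog base differs from both references: all reads alternate
  tt <- simulate_tetraploid_counts(gm, "A", seed = 1)
  expect_true(all(tt$alt_depth == tt$depth))
  # homoeolog base equal to the reference base: no alternate reads
  s$hom_base <- "A"
  gm2 <- toy_truth(s, rep(0, 50), rep(0, 50))$genome
  tt2 <- simulate_tetraploid_counts(gm2, "A", seed = 1)
  expect_true(all(tt2$alt_depth == 0))
  # unexpressed homoeolog: zero depth, record kept
  s$tetraploid_expressed <- FALSE
  gm3 <- toy_truth(s, rep(0, 50), rep(0, 50))$genome
  tt3 <- simulate_tetraploid_counts(gm3, "A", seed = 1)
  expect_equal(nrow(tt3), 50)
  expect_true(all(tt3$depth == 0))
})

test_that("fixture bundles are complete, seeded and deterministic", {
  fx <- mid_fixture()
  files <- unlist(fx$dir |> list.files(full.names = TRUE))
  expect_true(length(files) >= 14)  # 8 bulk + 2 tetraploid + 4 artifacts
  # byte-identical regeneration under the same seed
  d2 <- file.path(tempdir(), "mid_bundle_rep")
  emit_fixture_bundle(fx$truth, d2, seed = 5)
  for (f in list.files(fx$dir)) {
    expect_identical(unname(tools::md5sum(file.path(d2, f))),
                     unname(tools::md5sum(file.path(fx$dir, f))),
                     info = f)
  }
  # unanchored fraction
  anchors <- fx$bundle$anchors
  n_sites <- nrow(fx$genome$sites)
  expect_equal(n_sites - nrow(anchors), round(n_sites * 0.007))
  # count conservation everywhere
  for (tab in c(fx$bundle$bulk_tables, fx$bundle$tetraploid_tables))
    expect_true(all(tab$alt_depth <= tab$depth & tab$alt_depth >= 0))
})
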