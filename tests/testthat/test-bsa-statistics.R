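# SNP-index, polarization, delta averaging and the Steel-Dwass test.

test_that("snp_index computes fractions with a missing-data depth floor", {
  expect_equal(snp_index(c(20, 40, 8, 0), c(10, 40, 4, 0)),
               c(0.5, 1, NA, NA))
  expect_equal(snp_index(8, 4, min_depth = 5), 0.5)
  expect_error(snp_index(10, 11), "exceeds")
  expect_error(snp_index(-1, 0), "negative")
})

test_that("polarization re-expresses indices on the donor allele", {
  expect_equal(polarize_index(0.8, "A", donor_parent = "B"), 0.8)
  expect_equal(polarize_index(0.8, "B", donor_parent = "B"), 0.2)
  expect_equal(polarize_index(c(0, NA, 1), "B"), c(1, NA, 0))
  expect_error(polarize_index(0.5, "X"), "labels")
  expect_error(polarize_index(1.2, "A"), "outside")
})

test_that("delta averaging uses available pairs and records informativeness", {
  expect_equal(delta_snp_index(1, 0), 1)
  expect_equal(delta_snp_index(0.5, 0.5), 0)
  expect_true(is.na(delta_snp_index(NA, 0.5)))
  av <- average_delta(c(0.4, 0.6, 0.5, 0.5))
  expect_equal(av$avg_delta, 0.5)
  expect_equal(av$n_informative, 4)
  av2 <- average_delta(c(0.4, NA, 0.6, NA))
  expect_equal(av2$avg_delta, 0.5)
  expect_equal(av2$n_informative, 2)
  av3 <- average_delta(rep(NA_real_, 4))
  expect_true(is.na(av3$avg_delta))
  expect_equal(av3$n_informative, 0)
  m <- average_delta(rbind(c(0.4, NA, 0.6, NA), rep(NA_real_, 4)))
  expect_equal(m$avg_delta, c(0.5, NA))
  expect_equal(m$n_informative, c(2, 0))
})

test_that("polarized indices agree across references on an uncontaminated fixture", {
  n <- 60
  s <- toy_sites(n, type = "P", rho = 0)
  tr <- toy_truth(s, freq_carrier = rep(1, n), freq_noncarrier = rep(0, n))
  anchors <- data.frame(transcript_id = s$transcript_id,
                        transcript_pos = s$transcript_pos,
                        chrom = s$chrom, pos = s$pos, strand = s$strand,
                        stringsAsFactors = FALSE)
  tabs <- list()
  for (bulk in c("carrier-SP1", "noncarrier-SP1")) for (ref in c("A", "B"))
    tabs[[paste0(bulk, ".ref", ref)]] <-
      sample_allele_counts(tr, bulk, ref, seed = 7)
  sets <- lapply(tabs, function(t) anchor_sites(call_snps(t), anchors)$anchored)
  nr <- merge_nonredundant(sets)
  rec <- delta_index_records(tabs, nr, anchors)
  # fixed alleles, no contamination: both references give the same polarized
  # index at every site with depth, and the delta is exactly 1
  ia <- rec[["idx_carrier-SP1.refA"]]; ib <- rec[["idx_carrier-SP1.refB"]]
  ok <- !is.na(ia) & !is.na(ib)
  expect_true(any(ok))
  expect_equal(ia[ok], ib[ok])
  expect_true(all(rec$avg_delta[rec$n_informative > 0] == 1))
  expect_true(all(rec$avg_delta >= -1 & rec$avg_delta <= 1, na.rm = TRUE))
})

test_that("steel_dwass: symmetry, separation monotonicity, group handling", {
  same <- steel_dwass(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1, tolerance = 1e-6)
  far <- steel_dwass(list(a = 1:3, b = 101:103, c = 201:203))
  near <- steel_dwass(list(a = 1:3, b = 2:4, c = 3:5))
  expect_true(all(far$p_value < near$p_value))
  expect_warning(steel_dwass(list(a = 1:4, b = 2:5, c = 7)), "fewer than 2")
  expect_error(suppressWarnings(steel_dwass(list(a = 1:4, b = 3))),
               "at least 2")
  # vector + grouping factor interface
  g <- rep(c("x", "y"), each = 4)
  v <- c(1, 2, 3, 4, 10, 11, 12, 13)
  expect_equal(steel_dwass(v, g)$p_value,
               steel_dwass(split(v, g))$p_value)
})

test_that("steel_dwass exact mode matches independent permutation enumeration", {
  set.seed(21)
  for (rep in 1:6) {
    k <- sample(2:3, 1)
    x <- lapply(seq_len(k), function(i)
      round(rnorm(sample(4:6, 1), mean = i * runif(1)), 1))
    names(x) <- paste0("g", seq_len(k))
    ex <- steel_dwass(x, method = "exact")
    for (r in seq_len(nrow(ex))) {
      oracle <- perm_ranksum_p(x[[ex$group_i[r]]], x[[ex$group_j[r]]])
      expect_lt(abs(ex$p_value[r] - oracle), 0.02)
    }
  }
})

test_that("chromosome tracks are sorted, labelled and complete", {
  sc <- mid_scan()
  tr <- sc$tracks
  expect_true(all(tr$category %in% c("Aet", "Ldn", "Unknown")))
  expect_false(is.unsorted(order(tr$chrom, tr$pos)))
  o <- order(tr$chrom, tr$pos)
  expect_equal(o, seq_along(o))
  expect_equal(nrow(tr), sum(!is.na(sc$records$avg_delta)))
  expect_equal(nrow(chromosome_tracks(sc$records[0, ])), 0)
  # all averaged deltas bounded
  expect_true(all(tr$avg_delta >= -1 & tr$avg_delta <= 1))
})
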