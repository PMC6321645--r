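# Region filtering, candidate selection, in-silico digestion, dCAPS design.

rec_stub <- function(pos, delta, category = "D_SPECIFIC", chrom = "2D") {
  data.frame(chrom = chrom, pos = pos, avg_delta = delta, category = category,
             stringsAsFactors = FALSE)
}

test_that("region filter is closed, counted and idempotent", {
  rec <- rec_stub(c(50, 100, 150, 200, 250), c(0.5, 0.4, 0.3, 0.2, 0.1),
                  c("D_SPECIFIC", "HOMOEOLOGOUS", "D_SPECIFIC",
                    "UNCLASSIFIED", "D_SPECIFIC"))
  rg <- region_filter("2D", 100, 200)
  fr <- filter_region(rec, rg)
  expect_equal(fr$total, 3)                      # both boundaries included
  expect_equal(unname(fr$counts),
               c(1L, 1L, 1L))
  expect_equal(fr$delta_range, c(0.2, 0.4))
  # idempotence
  fr2 <- filter_region(fr$records, rg)
  expect_equal(fr2$records, fr$records)
  # counts equal a brute-force scan
  inside <- rec$pos >= 100 & rec$pos <= 200
  expect_equal(sum(fr$counts), sum(inside))
  # empty region is empty, not an error
  expect_equal(filter_region(rec, region_filter("2D", 900, 950))$total, 0)
  expect_error(region_filter("2D", 10, 5), "exceed")
})

test_that("candidate selection is strict, ranked and monotone", {
  rec <- rec_stub(1:4, c(0.54, 0.40, 0.38, 0.10))
  sel <- select_candidates(rec, min_delta = 0.38)
  expect_equal(nrow(sel), 2)                     # strict: 0.38 itself excluded
  expect_equal(sel$avg_delta, c(0.54, 0.40))
  expect_equal(nrow(select_candidates(rec, 0.38, strict = FALSE)), 3)
  expect_equal(nrow(select_candidates(rec[0, ])), 0)
  for (th in c(0, 0.2, 0.45, 0.6))
    expect_true(all(select_candidates(rec, th + 0.05)$pos %in%
                      select_candidates(rec, th)$pos))
  # non-eligible categories never selected
  rec2 <- rec_stub(1:2, c(0.9, 0.9), c("HOMOEOLOGOUS", "UNCLASSIFIED"))
  expect_equal(nrow(select_candidates(rec2)), 0)
})

test_that("in-silico digestion conserves length and matches the brute-force scan", {
  fr <- in_silico_digest("AAAGACTCAAA", "HinfI")  # one GANTC match
  expect_length(fr, 2)
  expect_equal(sum(fr), 11)
  expect_equal(in_silico_digest("AAAATTTT", "HpaII"), 8)  # no site
  set.seed(13)
  enzymes <- restriction_enzymes()
  for (i in 1:20) {
    seq <- random_flank(80, 1300 + i)
    e <- enzymes[sample.int(nrow(enzymes), 1), ]
    mine <- in_silico_digest(seq, e)
    oracle <- brute_digest(seq, e$site)
    expect_equal(mine, oracle, info = paste(e$name, seq))
    expect_equal(sum(mine), nchar(seq))
  }
  expect_error(in_silico_digest("ANNA", "HpaII"), "unambiguous")
})

test_that("enzyme table covers the standard dCAPS enzymes and validates input", {
  et <- restriction_enzymes()
  expect_true(all(c("StyI", "HpaII", "HinfI") %in% et$name))
  expect_equal(et$site[et$name == "StyI"], "CCWWGG")
  expect_equal(et$site[et$name == "HpaII"], "CCGG")
  expect_equal(et$site[et$name == "HinfI"], "GANTC")
  expect_error(in_silico_digest("ACGT", list(name = "bad", site = "CG")),
               "at least 4")
  expect_error(in_silico_digest("ACGT", list(name = "bad", site = "CXGG")),
               "IUPAC")
})

test_that("a SNP creating a natural restriction site yields a zero-mismatch CAPS assay", {
  flank <- paste0(strrep("AT", 20), "GATCCGGATTACA", strrep("GC", 20))
  # the third base of the embedded CCGG; G/A alleles toggle the HpaII site
  off <- 46
  cand <- design_dcaps(flank, off, "G", "A")
  expect_gt(nrow(cand), 0)
  hp <- cand[cand$enzyme == "HpaII", ]
  expect_true(any(hp$n_introduced_mismatches == 0))
  expect_true(all(hp$cut_allele == "G"))
})

test_that("every designed assay discriminates the alleles under digestion", {
  found <- 0
  for (i in 1:12) {
    flank <- random_flank(161, 2600 + i)
    ref <- substr(flank, 81, 81)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    cand <- design_dcaps(flank, 81, ref, alt)
    if (nrow(cand) == 0) next
    found <- found + nrow(cand)
    for (r in seq_len(nrow(cand))) {
      enz <- cand$enzyme[r]
      f_cut <- in_silico_digest(cand$amplicon_cut_allele[r], enz)
      f_oth <- in_silico_digest(cand$amplicon_other_allele[r], enz)
      expect_false(identical(sort(f_cut), sort(f_oth)))
      # reported fragments match a recomputed digest and sum to the amplicon
      expect_equal(paste(f_cut, collapse = ","), cand$fragments_cut_allele[r])
      expect_equal(sum(f_cut), cand$amplicon_length[r])
      expect_equal(sum(f_oth), cand$amplicon_length[r])
      # the primer never mutates the SNP: amplicons differ at exactly one base
      d <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                  cand$amplicon_cut_allele[r], cand$amplicon_other_allele[r])
      expect_equal(unname(d), 1)
    }
  }
  expect_gt(found, 0)
})

test_that("dCAPS design validates its inputs", {
  flank <- random_flank(101, 77)
  ref <- substr(flank, 51, 51)
  expect_error(design_dcaps(flank, 51, ref, ref), "differ")
  expect_error(design_dcaps(flank, 51, "N", "A"), "unambiguous")
  expect_error(design_dcaps("ACGTNACGT", 3, "G", "A"), "unambiguous")
  expect_error(design_dcaps(flank, 300, ref, "A"), "outside")
})
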