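# Evidence-set construction and site classification.

nr_stub <- function(n = 4) {
  data.frame(chrom = "1D", pos = seq_len(n), ref_base = "A", alt_base = "G",
             alts = "G", multi_allelic = FALSE, stringsAsFactors = FALSE)
}

test_that("classification follows the evidence flags and precedence", {
  nr <- nr_stub(4)
  pk <- c("1D:1", "1D:3")           # pairwise evidence at sites 1 and 3
  tk <- c("1D:2", "1D:3")           # tetraploid evidence at sites 2 and 3
  cl <- classify_sites(nr, pk, tk)
  expect_equal(as.character(cl$category),
               c("D_SPECIFIC", "HOMOEOLOGOUS", "HOMOEOLOGOUS", "UNCLASSIFIED"))
  expect_equal(cl$class_label, c("Aet", "Ldn", "Ldn", "Unknown"))
  expect_equal(cl$in_parental_pairwise, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(cl$in_tetraploid, c(FALSE, TRUE, TRUE, FALSE))
  # pairwise precedence flips only the double-evidence site
  cl2 <- classify_sites(nr, pk, tk, precedence = "pairwise")
  expect_equal(as.character(cl2$category)[3], "D_SPECIFIC")
  expect_equal(as.character(cl2$category)[-3], as.character(cl$category)[-3])
})

test_that("classification partitions the site set and ignores input order", {
  sc <- mid_scan()
  tt <- table(sc$nr$category)
  expect_equal(sum(tt), nrow(sc$nr))
  perm <- sample(nrow(sc$nr))
  cl_perm <- classify_sites(sc$nr[perm, 1:6], sc$evidence$pairwise_keys,
                            sc$evidence$tetraploid_keys)
  expect_equal(as.character(cl_perm$category),
               as.character(sc$nr$category[perm]))
})

test_that("empty evidence sets warn and default everything away from that class", {
  nr <- nr_stub(3)
  ev <- NULL
  w <- testthat::capture_warnings(
    ev <- build_evidence_sets(data.frame(chrom = character(0),
                                         pos = integer(0)),
                              list(), data.frame(transcript_id = character(0),
                                                 transcript_pos = integer(0),
                                                 chrom = character(0),
                                                 pos = integer(0),
                                                 strand = character(0))))
  expect_true(any(grepl("empty", w)))
  cl <- classify_sites(nr, ev$pairwise_keys, "1D:2")
  expect_equal(as.character(cl$category),
               c("UNCLASSIFIED", "HOMOEOLOGOUS", "UNCLASSIFIED"))
})

test_that("tetraploid evidence keys are the anchored union over references", {
  fx <- mid_fixture()
  ev <- build_evidence_sets(fx$bundle$pairwise, fx$bundle$tetraploid_tables,
                            fx$bundle$anchors)
  # brute-force recomputation
  keys <- character(0)
  for (tt in fx$bundle$tetraploid_tables) {
    called <- call_snps(tt)
    anc <- anchor_sites(called, fx$bundle$anchors)$anchored
    keys <- union(keys, paste(anc$chrom, anc$pos, sep = ":"))
  }
  expect_setequal(ev$tetraploid_keys, keys)
  expect_setequal(ev$pairwise_keys,
                  unique(paste(fx$bundle$pairwise$chrom,
                               fx$bundle$pairwise$pos, sep = ":")))
})

test_that("subgenome-specific calls recover the simulated truth", {
  fx <- mid_fixture()
  sc <- mid_scan()
  key <- paste(sc$nr$chrom, sc$nr$pos, sep = ":")
  gkey <- paste(fx$genome$sites$chrom, fx$genome$sites$pos, sep = ":")
  truth_type <- fx$genome$sites$type[match(key, gkey)]
  pred <- as.character(sc$nr$category) == "D_SPECIFIC"
  truth <- truth_type == "P"
  recall <- sum(pred & truth) / sum(truth)
  precision <- sum(pred & truth) / sum(pred)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("chromosome tabulation adds consistent margins", {
  cl <- data.frame(chrom = c("1D", "1D", "2D"),
                   category = c("D_SPECIFIC", "HOMOEOLOGOUS", "D_SPECIFIC"))
  tab <- tabulate_by_chromosome(cl)
  expect_equal(tab["Total", "Total"], 3)
  expect_equal(unname(tab["1D", c("D_SPECIFIC", "HOMOEOLOGOUS", "UNCLASSIFIED")]),
               c(1L, 1L, 0L))
  # margins equal brute-force sums on a larger random table
  set.seed(3)
  cl2 <- data.frame(chrom = sample(paste0(1:7, "D"), 500, replace = TRUE),
                    category = sample(c("D_SPECIFIC", "HOMOEOLOGOUS",
                                        "UNCLASSIFIED"), 500, replace = TRUE))
  t2 <- tabulate_by_chromosome(cl2)
  expect_equal(unname(t2["Total", "Total"]), 500L)
  expect_equal(unname(t2[-nrow(t2), "Total"]),
               unname(rowSums(t2[-nrow(t2), -ncol(t2)])))
  expect_equal(unname(t2["Total", -ncol(t2)]),
               unname(colSums(t2[-nrow(t2), -ncol(t2)])))
  # empty input
  t0 <- tabulate_by_chromosome(cl2[0, ])
  expect_equal(unname(t0["Total", "Total"]), 0L)
})
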