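# SNP calling thresholds, anchoring, and the non-redundant merge.

count_row <- function(tx, tpos, ref, alt, d, k) {
  data.frame(chrom = ".", pos = 0L, transcript_id = tx, transcript_pos = tpos,
             ref_base = ref, alt_base = alt, depth = d, alt_depth = k,
             stringsAsFactors = FALSE)
}

test_that("call_snps applies inclusive depth and frequency thresholds", {
  tab <- rbind(count_row("t1", 10L, "A", "G", 10L, 1L),   # boundary: called
               count_row("t2", 10L, "A", "G", 9L, 9L),    # shallow: not called
               count_row("t3", 10L, "A", "G", 0L, 0L),    # zero depth
               count_row("t4", 10L, "A", "G", 100L, 9L),  # 9% < 10%
               count_row("t5", 10L, "A", "G", 100L, 10L)) # 10%: called
  called <- call_snps(tab)
  expect_setequal(called$transcript_id, c("t1", "t5"))
  expect_error(call_snps(transform(tab, alt_depth = -1)), "negative")
  expect_error(call_snps(transform(tab, alt_depth = depth + 1)), "exceeds")
})

test_that("call_snps is monotone in both thresholds", {
  set.seed(42)
  d <- sample(0:60, 300, replace = TRUE)
  k <- rbinom(300, d, 0.2)
  tab <- count_row(sprintf("t%03d", 1:300), 1L, "A", "C", d, k)
  for (md in c(5, 10, 20)) for (mf in c(0.05, 0.1, 0.3)) {
    base <- call_snps(tab, mf, md)$transcript_id
    expect_true(all(call_snps(tab, mf, md + 5)$transcript_id %in% base))
    expect_true(all(call_snps(tab, mf + 0.05, md)$transcript_id %in% base))
  }
})

test_that("anchoring maps coordinates, reverse-complements minus strands, and partitions", {
  anchors <- data.frame(
    transcript_id = c("t1", "t2"), transcript_pos = c(100L, 50L),
    chrom = c("2D", "2D"), pos = c(81800099L, 123L), strand = c("+", "-"),
    stringsAsFactors = FALSE)
  sites <- rbind(count_row("t1", 100L, "A", "G", 20L, 10L),
                 count_row("t2", 50L, "C", "T", 20L, 10L),
                 count_row("t3", 7L, "A", "G", 20L, 10L))[,
    c("transcript_id", "transcript_pos", "ref_base", "alt_base")]
  res <- anchor_sites(sites, anchors)
  expect_equal(nrow(res$anchored) + nrow(res$unanchored), nrow(sites))
  expect_equal(res$anchored$pos[res$anchored$transcript_id == "t1"], 81800099L)
  # minus strand: C -> G, T -> A in genome orientation
  minus <- res$anchored[res$anchored$transcript_id == "t2", ]
  expect_equal(minus$ref_base, "G")
  expect_equal(minus$alt_base, "A")
  expect_equal(res$unanchored$transcript_id, "t3")
})

test_that("anchor conflicts at one genome coordinate are excluded and recorded", {
  anchors <- data.frame(
    transcript_id = c("t1", "t2"), transcript_pos = c(10L, 10L),
    chrom = "1D", pos = c(500L, 500L), strand = "+",
    stringsAsFactors = FALSE)
  sites <- data.frame(transcript_id = c("t1", "t2"), transcript_pos = 10L,
                      ref_base = c("A", "C"), alt_base = c("G", "T"),
                      stringsAsFactors = FALSE)
  res <- anchor_sites(sites, anchors)
  expect_equal(nrow(res$anchored), 0)
  expect_equal(nrow(res$conflicts), 2)
})

test_that("non-redundant merge is a keyed union with provenance and algebraic laws", {
  mk <- function(pos, ref = "A", alt = "G")
    data.frame(chrom = "1D", pos = pos, transcript_id = "t", transcript_pos = 1L,
               ref_base = ref, alt_base = alt, strand = "+",
               stringsAsFactors = FALSE)
  s1 <- mk(1:10); s2 <- mk(6:15)
  m <- merge_nonredundant(list(a = s1, b = s2))
  expect_equal(nrow(m), 15)
  expect_equal(sum(m$called_a & m$called_b), 5)
  # idempotence
  expect_equal(nrow(merge_nonredundant(list(a = s1, b = s1))), 10)
  # commutativity of the keyed union
  m2 <- merge_nonredundant(list(a = s2, b = s1))
  expect_setequal(paste(m$chrom, m$pos), paste(m2$chrom, m2$pos))
  # brute-force union size oracle on random sets
  set.seed(9)
  sets <- lapply(1:8, function(i) mk(sample.int(40, 20)))
  names(sets) <- paste0("p", 1:8)
  expect_equal(nrow(merge_nonredundant(sets)), brute_union_size(sets))
})

test_that("reference swaps across references are biallelic, extra alleles flag multi-allelic", {
  a <- data.frame(chrom = "1D", pos = 1L, transcript_id = "t", transcript_pos = 1L,
                  ref_base = "A", alt_base = "G", strand = "+",
                  stringsAsFactors = FALSE)
  b <- transform(a, ref_base = "G", alt_base = "A")   # same pair, swapped
  c <- transform(a, alt_base = "T")                   # third allele
  m_swap <- merge_nonredundant(list(x = a, y = b))
  expect_false(m_swap$multi_allelic)
  m_tri <- merge_nonredundant(list(x = a, y = c))
  expect_true(m_tri$multi_allelic)
  expect_setequal(strsplit(m_tri$alts, ",")[[1]], c("G", "T"))
})
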