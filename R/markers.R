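# Candidate-region filtering, candidate SNP selection, dCAPS/CAPS assay
# design and in-silico restriction digestion.

#' Built-in restriction enzyme table
#'
#' Recognition sites in IUPAC notation. The set covers the enzymes commonly
#' used for wheat dCAPS assays and is user-extensible: pass any data frame
#' with `name` and `site` columns to the design functions.
#'
#' @return data frame with columns `name` and `site`.
#' @export
restriction_enzymes <- function() {
  data.frame(name = c("StyI", "HpaII", "HinfI", "EcoRI", "DdeI", "RsaI"),
             site = c("CCWWGG", "CCGG", "GANTC", "GAATTC", "CTNAG", "GTAC"),
             stringsAsFactors = FALSE)
}

validate_enzyme <- function(enzyme) {
  if (is.character(enzyme) && length(enzyme) == 1) {
    et <- restriction_enzymes()
    i <- match(enzyme, et$name)
    if (is.na(i)) stop("unknown enzyme: ", enzyme)
    enzyme <- list(name = et$name[i], site = et$site[i])
  }
  if (is.data.frame(enzyme)) enzyme <- list(name = enzyme$name[1], site = enzyme$site[1])
  site <- toupper(enzyme$site)
  if (nchar(site) < 4) stop("recognition site must be at least 4 bases")
  b <- strsplit(site, "")[[1]]
  if (!all(b %in% names(IUPAC_EXPAND)))
    stop("recognition site contains non-IUPAC characters")
  list(name = enzyme$name, site = site)
}

#' Region filter
#'
#' @param chrom chromosome name.
#' @param start_bp,end_bp 1-based closed physical interval.
#' @return a `region_filter` list.
#' @export
region_filter <- function(chrom, start_bp, end_bp) {
  if (start_bp > end_bp) stop("region start must not exceed end")
  structure(list(chrom = chrom, start_bp = start_bp, end_bp = end_bp),
            class = "region_filter")
}

#' Filter classified delta-index records to a physical candidate region
#'
#' @param records classified `delta_records` (must carry `chrom`, `pos`,
#'   `category`, `avg_delta`).
#' @param region a [region_filter()].
#' @return list with `records` (the subset), `counts` (named per-category
#'   site counts), `total` and `delta_range` (min/max of the non-missing
#'   averaged delta-SNP-index in the subset).
#' @export
filter_region <- function(records, region) {
  stopifnot(inherits(region, "region_filter"))
  keep <- records$chrom == region$chrom &
    records$pos >= region$start_bp & records$pos <= region$end_bp
  sub <- records[keep, , drop = FALSE]
  rownames(sub) <- NULL
  counts <- table(factor(as.character(sub$category), levels = CATEGORY_LEVELS))
  dr <- if (any(!is.na(sub$avg_delta)))
    range(sub$avg_delta, na.rm = TRUE) else c(NA_real_, NA_real_)
  list(records = sub,
       counts = stats::setNames(as.integer(counts), names(counts)),
       total = nrow(sub), delta_range = dr)
}

#' Select candidate marker SNPs
#'
#' Subgenome-specific sites whose averaged delta-SNP-index exceeds
#' `min_delta` (strict inequality by default, matching a "higher than"
#' selection rule), ranked by decreasing delta.
#'
#' @param subset the `records` element of [filter_region()] (or any
#'   classified `delta_records`).
#' @param min_delta selection threshold on `avg_delta`.
#' @param category category eligible for marker conversion.
#' @param strict use strict inequality (`>`); `FALSE` uses `>=`.
#' @return the selected rows sorted by `avg_delta` descending.
#' @export
select_candidates <- function(subset, min_delta = 0.38,
                              category = "D_SPECIFIC", strict = TRUE) {
  if (is.list(subset) && !is.data.frame(subset) && !is.null(subset$records))
    subset <- subset$records
  ok <- !is.na(subset$avg_delta) & as.character(subset$category) %in% category &
    (if (strict) subset$avg_delta > min_delta else subset$avg_delta >= min_delta)
  out <- subset[ok, , drop = FALSE]
  out <- out[order(-out$avg_delta), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' In-silico restriction digestion
#'
#' Finds every match of the enzyme's IUPAC recognition site on either strand
#' of a plain sequence and cuts the fragment at the 5' start of each matched
#' site (one fixed cut-offset convention for all enzymes; fragment lengths,
#' not sticky-end chemistry, are what a dCAPS gel resolves).
#'
#' @param amplicon_seq unambiguous DNA sequence (character scalar).
#' @param enzyme enzyme name from [restriction_enzymes()], or a list/data
#'   frame with `name` and `site`.
#' @return integer vector of fragment lengths, in order along the sequence,
#'   summing to `nchar(amplicon_seq)`.
#' @examples
#' in_silico_digest("AAAGACTCAAA", "HinfI")  # GACTC matches GANTC
#' @export
in_silico_digest <- function(amplicon_seq, enzyme) {
  enz <- validate_enzyme(enzyme)
  seq <- toupper(amplicon_seq)
  if (!all(strsplit(seq, "")[[1]] %in% DNA_BASES))
    stop("amplicon must be plain unambiguous DNA")
  L <- nchar(seq)
  subj <- Biostrings::DNAString(seq)
  starts <- integer(0)
  for (pat in unique(c(enz$site, revcomp(enz$site)))) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj, fixed = FALSE)
    starts <- c(starts, Biostrings::start(m))
  }
  cuts <- sort(unique(starts - 1L))
  cuts <- cuts[cuts > 0 & cuts < L]
  diff(c(0L, cuts, L))
}

# concrete IUPAC-compatible base, preferring the template base
concretize <- function(template_base, code) {
  exp <- IUPAC_EXPAND[[code]]
  if (template_base %in% exp) template_base else exp[1]
}

#' Design dCAPS/CAPS assays for a SNP
#'
#' Searches both strands for primer placements where the SNP falls inside an
#' enzyme recognition window overlapping the primer's 3' end. Up to
#' `max_mismatches` bases of the primer are altered so that the recognition
#' site is completed by exactly one allele; mismatches are confined to the 3'
#' half of the primer, never at the 3'-terminal base, and the primer never
#' covers the SNP itself. Natural CAPS candidates (the SNP alone creates or
#' destroys a site inside the amplicon; zero introduced mismatches) are
#' reported first. Every returned candidate is validated by in-silico
#' digestion: the two allelic amplicons must yield different fragment
#' multisets.
#'
#' @param flank_seq genomic sequence around the SNP (plain DNA).
#' @param snp_offset 1-based position of the SNP within `flank_seq`.
#' @param ref_allele,alt_allele the two alleles (single bases; must differ).
#' @param enzymes data frame of candidate enzymes (default
#'   [restriction_enzymes()]).
#' @param max_mismatches maximum primer mismatches to introduce (dCAPS).
#' @param primer_len_range allowed primer lengths.
#' @param gc_bounds preferred primer GC-content interval; the length whose GC
#'   is closest to the interval midpoint is chosen.
#' @param amplicon_3p bases kept on the template side of the SNP (reverse
#'   primer 3' end), bounded by the available flank.
#' @return data frame of class `dcaps_candidates`, one row per validated
#'   assay: `enzyme`, `strand`, `cut_allele`, `n_introduced_mismatches`,
#'   `fwd_primer`, `rev_primer`, `amplicon_length` and the per-allele
#'   fragment lengths (comma-joined). Zero rows when no assay exists.
#' @export
design_dcaps <- function(flank_seq, snp_offset, ref_allele, alt_allele,
                         enzymes = restriction_enzymes(),
                         max_mismatches = 1, primer_len_range = c(18, 26),
                         gc_bounds = c(0.4, 0.6), amplicon_3p = 60) {
  flank_seq <- toupper(flank_seq)
  ref_allele <- toupper(ref_allele); alt_allele <- toupper(alt_allele)
  if (!all(strsplit(flank_seq, "")[[1]] %in% DNA_BASES))
    stop("flank_seq must be plain unambiguous DNA")
  if (!ref_allele %in% DNA_BASES || !alt_allele %in% DNA_BASES)
    stop("alleles must be single unambiguous bases")
  if (ref_allele == alt_allele) stop("alleles must differ")
  if (snp_offset < 1 || snp_offset > nchar(flank_seq))
    stop("snp_offset outside flank_seq")

  out <- list()
  for (strand in c("+", "-")) {
    if (strand == "+") {
      seqs <- flank_seq; off <- snp_offset
      a1 <- ref_allele; a2 <- alt_allele
    } else {
      seqs <- revcomp(flank_seq); off <- nchar(flank_seq) - snp_offset + 1
      a1 <- complement_base(ref_allele); a2 <- complement_base(alt_allele)
    }
    for (e in seq_len(nrow(enzymes))) {
      enz <- validate_enzyme(enzymes[e, ])
      cand <- dcaps_one_strand(seqs, off, a1, a2, enz, max_mismatches,
                               primer_len_range, gc_bounds, amplicon_3p)
      if (!is.null(cand)) {
        cand$strand <- strand
        # report the cut allele in the input (plus-strand) orientation
        if (strand == "-")
          cand$cut_allele <- complement_base(cand$cut_allele)
        out[[length(out) + 1L]] <- cand
      }
    }
  }
  if (!length(out)) {
    res <- data.frame(enzyme = character(0), strand = character(0),
                      cut_allele = character(0),
                      n_introduced_mismatches = integer(0),
                      fwd_primer = character(0), rev_primer = character(0),
                      amplicon_length = integer(0),
                      fragments_cut_allele = character(0),
                      fragments_other_allele = character(0),
                      amplicon_cut_allele = character(0),
                      amplicon_other_allele = character(0),
                      stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$n_introduced_mismatches,
                     -res$amplicon_length), , drop = FALSE]
    res <- res[!duplicated(res[, c("enzyme", "strand", "cut_allele",
                                   "n_introduced_mismatches")]), , drop = FALSE]
    res <- res[, c("enzyme", "strand", "cut_allele", "n_introduced_mismatches",
                   "fwd_primer", "rev_primer", "amplicon_length",
                   "fragments_cut_allele", "fragments_other_allele",
                   "amplicon_cut_allele", "amplicon_other_allele")]
    rownames(res) <- NULL
  }
  class(res) <- c("dcaps_candidates", "data.frame")
  res
}

# search one strand / one enzyme; returns at most the best placement rows
dcaps_one_strand <- function(seqs, off, a1, a2, enz, max_mismatches,
                             plen_range, gc_bounds, amplicon_3p) {
  L <- nchar(enz$site)
  site <- strsplit(enz$site, "")[[1]]
  tmpl <- strsplit(seqs, "")[[1]]
  n <- length(tmpl)
  rows <- list()

  right_end <- min(n, off + amplicon_3p)
  for (alleles in list(c(a1, a2), c(a2, a1))) {
    cut_a <- alleles[1]; other_a <- alleles[2]
    t_cut <- tmpl; t_cut[off] <- cut_a
    t_oth <- tmpl; t_oth[off] <- other_a
    for (w in seq(max(1L, off - L + 1L), off)) {
      if (w + L - 1L > n) next
      win <- w:(w + L - 1L)
      # the SNP must discriminate: with cut allele the window can complete the
      # site, with the other allele it must not
      if (iupac_matches(other_a, site[off - w + 1L])) next
      if (!iupac_matches(cut_a, site[off - w + 1L])) next
      if (off - 1L < w) next  # window cannot overlap a primer ending before the SNP
      # template positions right of the primer (incl. SNP) must match as-is
      for (e3 in w:(off - 1L)) {
        # primer 3' end at e3; window positions <= e3 are primer-forcible
        tpl_side <- win[win > e3]
        if (!all(iupac_matches(t_cut[tpl_side], site[tpl_side - w + 1L]))) next
        prim_side <- win[win <= e3]
        forced <- character(length(prim_side))
        mm <- 0L
        ok <- TRUE
        for (ii in seq_along(prim_side)) {
          p <- prim_side[ii]
          if (iupac_matches(tmpl[p], site[p - w + 1L])) {
            forced[ii] <- tmpl[p]
          } else {
            if (p == e3) { ok <- FALSE; break }  # no mismatch at the 3' base
            forced[ii] <- concretize(tmpl[p], site[p - w + 1L])
            mm <- mm + 1L
          }
        }
        if (!ok || mm > max_mismatches) next
        for (plen in plen_range[1]:plen_range[2]) {
          p5 <- e3 - plen + 1L
          if (p5 < 1L) next
          # mismatches must sit in the 3' half of the primer
          mism_pos <- prim_side[forced != tmpl[prim_side]]
          if (length(mism_pos) && any(mism_pos < e3 - floor(plen / 2) + 1L)) next
          if (length(prim_side) && any(prim_side < p5 & forced != tmpl[prim_side]))
            next  # forced base would fall outside the primer
          primer <- tmpl[p5:e3]
          inp <- prim_side >= p5
          primer[prim_side[inp] - p5 + 1L] <- forced[inp]
          fwd <- paste(primer, collapse = "")
          # amplicon: primer-substituted left part through the reverse primer
          amp_cut <- t_cut; amp_oth <- t_oth
          amp_cut[prim_side] <- forced; amp_oth[prim_side] <- forced
          rlen <- min(plen, right_end - off)
          if (rlen < plen_range[1]) next
          rp5 <- right_end - rlen + 1L
          rev_primer <- revcomp(paste(tmpl[rp5:right_end], collapse = ""))
          amp_c <- paste(amp_cut[p5:right_end], collapse = "")
          amp_o <- paste(amp_oth[p5:right_end], collapse = "")
          fc <- in_silico_digest(amp_c, enz)
          fo <- in_silico_digest(amp_o, enz)
          if (identical(sort(fc), sort(fo))) next  # not allele-discriminating
          gc <- gc_content(fwd)
          rows[[length(rows) + 1L]] <- data.frame(
            enzyme = enz$name, cut_allele = cut_a,
            n_introduced_mismatches = mm, fwd_primer = fwd,
            rev_primer = rev_primer, amplicon_length = nchar(amp_c),
            fragments_cut_allele = paste(fc, collapse = ","),
            fragments_other_allele = paste(fo, collapse = ","),
            amplicon_cut_allele = amp_c, amplicon_other_allele = amp_o,
            gc_ok = gc >= gc_bounds[1] && gc <= gc_bounds[2],
            gc_dist = abs(gc - mean(gc_bounds)),
            stringsAsFactors = FALSE)
          break  # one primer length per placement is enough
        }
      }
    }
  }
  if (!length(rows)) return(NULL)
  df <- do.call(rbind, rows)
  df <- df[order(df$n_introduced_mismatches, !df$gc_ok, df$gc_dist), ,
           drop = FALSE]
  df <- df[!duplicated(df[, c("enzyme", "cut_allele")]), , drop = FALSE]
  df$gc_ok <- df$gc_dist <- NULL
  df
}

#' Write a dCAPS candidate report
#'
#' Tab-separated report mirroring the usual marker-table layout: marker
#' name, primer sequences 5' to 3', restriction enzyme, fragment lengths.
#'
#' @param candidates a `dcaps_candidates` data frame (optionally with a
#'   `marker` column; otherwise names are generated).
#' @inheritParams write_count_table
#' @export
write_dcaps_report <- function(candidates, path) {
  con <- open_out(path)
  on.exit(close(con))
  y <- as.data.frame(candidates)
  if (is.null(y$marker) && nrow(y))
    y$marker <- sprintf("bsa%d", seq_len(nrow(y)))
  cols <- c("marker", "fwd_primer", "rev_primer", "enzyme", "cut_allele",
            "n_introduced_mismatches", "amplicon_length",
            "fragments_cut_allele", "fragments_other_allele")
  y <- y[, intersect(cols, names(y)), drop = FALSE]
  writeLines(paste(names(y), collapse = "\t"), con)
  if (nrow(y))
    writeLines(do.call(paste, c(lapply(y, as.character), sep = "\t")), con)
  invisible(path)
}
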