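# SNP calling thresholds, transcript-to-genome anchoring, and the
# non-redundant merge of the per-alignment-pair site sets.

#' Call SNP sites from an allele-count table
#'
#' A site is called when its depth reaches `min_depth` and its alternate
#' allele fraction reaches `min_alt_fraction` (both boundaries inclusive) —
#' the threshold behaviour of a depth/frequency variant filter.
#'
#' @param table a count-table data frame (see [read_count_table()]).
#' @param min_alt_fraction minimum alternate-allele read fraction.
#' @param min_depth minimum total depth.
#' @return the subset of rows passing both thresholds, in transcript
#'   coordinates (columns `transcript_id`, `transcript_pos`, `ref_base`,
#'   `alt_base`), preserving the `"pair"` attribute.
#' @examples
#' tab <- data.frame(chrom = ".", pos = 0L, transcript_id = "tx1",
#'                   transcript_pos = 101L, ref_base = "A", alt_base = "G",
#'                   depth = 10L, alt_depth = 1L)
#' nrow(call_snps(tab))  # 1: 1/10 = 0.1 is on the inclusive boundary
#' @export
call_snps <- function(table, min_alt_fraction = 0.1, min_depth = 10) {
  if (min_alt_fraction < 0 || min_alt_fraction > 1)
    stop("min_alt_fraction must be in [0, 1]")
  if (min_depth < 0) stop("min_depth must be non-negative")
  if (any(table$depth < 0 | table$alt_depth < 0))
    stop("negative counts in table")
  if (any(table$alt_depth > table$depth))
    stop("alt_depth exceeds depth")
  ok <- table$depth >= min_depth &
    table$depth > 0 & table$alt_depth / pmax(table$depth, 1L) >= min_alt_fraction
  out <- table[ok, c("transcript_id", "transcript_pos", "ref_base", "alt_base"),
               drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pair") <- attr(table, "pair")
  out
}

#' Anchor transcript-coordinate SNP sites to the genome
#'
#' Joins sites to the anchoring table by transcript position. Sites on the
#' minus strand have their bases reverse-complemented into genome
#' orientation. When two transcript positions anchor to the same genome
#' coordinate with conflicting reference bases the site is recorded as a
#' conflict and excluded from the anchored set.
#'
#' @param sites transcript-coordinate site data frame from [call_snps()].
#' @param anchors anchoring table (see [read_anchor_table()]).
#' @return list with `anchored` (genome-coordinate sites: `chrom`, `pos`,
#'   `transcript_id`, `transcript_pos`, `ref_base`, `alt_base`, `strand`),
#'   `unanchored` (input rows without an anchor) and `conflicts`.
#' @export
anchor_sites <- function(sites, anchors) {
  akey <- paste(anchors$transcript_id, anchors$transcript_pos)
  skey <- paste(sites$transcript_id, sites$transcript_pos)
  idx <- match(skey, akey)
  unanchored <- sites[is.na(idx), , drop = FALSE]
  rownames(unanchored) <- NULL
  hit <- !is.na(idx)
  a <- anchors[idx[hit], , drop = FALSE]
  s <- sites[hit, , drop = FALSE]
  minus <- a$strand == "-"
  ref <- s$ref_base; alt <- s$alt_base
  if (any(minus)) {
    ref[minus] <- complement_base(ref[minus])
    alt[minus] <- complement_base(alt[minus])
  }
  anc <- data.frame(chrom = a$chrom, pos = a$pos,
                    transcript_id = s$transcript_id,
                    transcript_pos = s$transcript_pos,
                    ref_base = ref, alt_base = alt, strand = a$strand,
                    stringsAsFactors = FALSE)
  # conflicting reference bases at one genome coordinate
  key <- site_key(anc$chrom, anc$pos)
  conflict_keys <- unique(key[ave(anc$ref_base, key,
                                  FUN = function(v) length(unique(v))) > 1])
  conflicts <- anc[key %in% conflict_keys, , drop = FALSE]
  anc <- anc[!key %in% conflict_keys, , drop = FALSE]
  rownames(anc) <- rownames(conflicts) <- NULL
  attr(anc, "pair") <- attr(sites, "pair")
  list(anchored = anc, unanchored = unanchored, conflicts = conflicts)
}

#' Merge anchored site sets into one non-redundant site set
#'
#' Takes the genome-anchored SNP sets of the alignment pairs and unions them
#' by genome coordinate, keeping a per-site provenance mask of which pairs
#' called the site. Sites reported with different alternate alleles across
#' pairs are retained and flagged multi-allelic.
#'
#' @param anchored_sets named list of anchored site data frames (the
#'   `anchored` component of [anchor_sites()]).
#' @return data frame keyed by (`chrom`, `pos`) with `ref_base`, `alt_base`
#'   (first seen), `alts` (comma-joined distinct alternates), `multi_allelic`
#'   and one logical `called_<name>` column per input set, sorted by
#'   chromosome and position.
#' @export
merge_nonredundant <- function(anchored_sets) {
  if (is.data.frame(anchored_sets)) anchored_sets <- list(anchored_sets)
  if (is.null(names(anchored_sets)) || any(!nzchar(names(anchored_sets))))
    names(anchored_sets) <- paste0("pair", seq_along(anchored_sets))
  all_rows <- do.call(rbind, lapply(names(anchored_sets), function(nm) {
    x <- anchored_sets[[nm]]
    if (nrow(x) == 0)
      return(data.frame(chrom = character(0), pos = integer(0),
                        ref_base = character(0), alt_base = character(0),
                        set = character(0), stringsAsFactors = FALSE))
    data.frame(chrom = x$chrom, pos = x$pos, ref_base = x$ref_base,
               alt_base = x$alt_base, set = nm, stringsAsFactors = FALSE)
  }))
  if (nrow(all_rows) == 0) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref_base = character(0), alt_base = character(0),
                      alts = character(0), multi_allelic = logical(0))
    for (nm in names(anchored_sets)) out[[paste0("called_", nm)]] <- logical(0)
    return(out)
  }
  key <- site_key(all_rows$chrom, all_rows$pos)
  first <- !duplicated(key)
  out <- data.frame(chrom = all_rows$chrom[first], pos = all_rows$pos[first],
                    ref_base = all_rows$ref_base[first],
                    alt_base = all_rows$alt_base[first],
                    stringsAsFactors = FALSE)
  ukey <- key[first]
  # the two transcript references swap ref/alt at parent-divergent sites, so
  # a site's identity is its unordered allele set: more than two distinct
  # bases across pairs makes it multi-allelic
  alleles <- vapply(split(paste(all_rows$ref_base, all_rows$alt_base),
                          key)[ukey],
                    function(v) {
                      b <- sort(unique(unlist(strsplit(v, " ", fixed = TRUE))))
                      paste(b, collapse = ",")
                    }, character(1))
  n_alleles <- nchar(alleles) %/% 2 + 1L
  out$alts <- vapply(seq_len(nrow(out)), function(i) {
    b <- strsplit(alleles[i], ",", fixed = TRUE)[[1]]
    paste(setdiff(b, out$ref_base[i]), collapse = ",")
  }, character(1))
  out$multi_allelic <- n_alleles > 2L
  for (nm in names(anchored_sets)) {
    called <- unique(key[all_rows$set == nm])
    out[[paste0("called_", nm)]] <- ukey %in% called
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a non-redundant site set in a minimal VCF dialect
#'
#' Writes `CHROM POS ID REF ALT QUAL FILTER INFO` records; INFO carries the
#' provenance mask (`PAIRS=`), the multi-allelic flag and, when present, the
#' classification category (`CLASS=`).
#'
#' @param nr a merged site data frame from [merge_nonredundant()] (optionally
#'   after [classify_sites()]).
#' @inheritParams write_count_table
#' @export
write_sites_vcf <- function(nr, path) {
  con <- open_out(path)
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=PAIRS,Number=1,Type=String,Description=\"Alignment pairs calling the site\">",
               "##INFO=<ID=MULTI,Number=0,Type=Flag,Description=\"Multiple alternate alleles observed\">",
               "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Site classification\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(nr) == 0) return(invisible(path))
  pcols <- grep("^called_", names(nr), value = TRUE)
  pairs <- apply(nr[, pcols, drop = FALSE], 1, function(v)
    paste(sub("^called_", "", pcols[as.logical(v)]), collapse = "|"))
  info <- paste0("PAIRS=", ifelse(nzchar(pairs), pairs, "."))
  info <- ifelse(nr$multi_allelic, paste0(info, ";MULTI"), info)
  if (!is.null(nr$category)) info <- paste0(info, ";CLASS=", nr$category)
  writeLines(paste(nr$chrom, nr$pos, ".", nr$ref_base, nr$alts, ".", "PASS",
                   info, sep = "\t"), con)
  invisible(path)
}
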