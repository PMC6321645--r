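# Classification of non-redundant sites into subgenome-specific allelic
# variation, homoeologous polymorphism, or unclassified.

CATEGORY_LEVELS <- c("D_SPECIFIC", "HOMOEOLOGOUS", "UNCLASSIFIED")
CATEGORY_LABELS <- c(D_SPECIFIC = "Aet", HOMOEOLOGOUS = "Ldn",
                     UNCLASSIFIED = "Unknown")

#' Build the two classification evidence sets
#'
#' The parental-pairwise evidence set is the anchored list of SNPs between
#' the two diploid donor accessions. The tetraploid evidence set is obtained
#' by calling SNPs from the tetraploid sample's count tables against each
#' transcript reference, anchoring them, and unioning the genome keys: the
#' tetraploid carries no D genome, so any SNP in its alignments is a
#' homoeologous polymorphism.
#'
#' @param pairwise_sites genome-coordinate site list (see [read_site_list()]).
#' @param tetraploid_tables list of tetraploid count tables (one per
#'   transcript reference).
#' @param anchors anchoring table.
#' @param min_alt_fraction,min_depth calling thresholds passed to
#'   [call_snps()].
#' @return list with character vectors `pairwise_keys` and `tetraploid_keys`
#'   (`chrom:pos` keys).
#' @export
build_evidence_sets <- function(pairwise_sites, tetraploid_tables, anchors,
                                min_alt_fraction = 0.1, min_depth = 10) {
  pairwise_keys <- unique(site_key(pairwise_sites$chrom, pairwise_sites$pos))
  tet <- character(0)
  for (tt in tetraploid_tables) {
    called <- call_snps(tt, min_alt_fraction, min_depth)
    anc <- anchor_sites(called, anchors)$anchored
    tet <- c(tet, site_key(anc$chrom, anc$pos))
  }
  tetraploid_keys <- unique(tet)
  if (length(pairwise_keys) == 0)
    warning("empty parental-pairwise evidence set: no site can be called subgenome-specific")
  if (length(tetraploid_keys) == 0)
    warning("empty tetraploid evidence set: no site can be called homoeologous")
  list(pairwise_keys = pairwise_keys, tetraploid_keys = tetraploid_keys)
}

#' Classify non-redundant sites by evidence membership
#'
#' A site found in the parental-pairwise set only is a subgenome-specific
#' allelic variant (`D_SPECIFIC`); a site found in the tetraploid set only is
#' a homoeologous polymorphism (`HOMOEOLOGOUS`); a site in neither is
#' `UNCLASSIFIED`. Sites in both sets are resolved by `precedence` (default
#' tetraploid: polymorphism in tetraploid reads cannot be separated from
#' homoeologous signal), with both evidence flags preserved.
#'
#' @param nr merged site set from [merge_nonredundant()].
#' @param pairwise_keys,tetraploid_keys evidence key vectors from
#'   [build_evidence_sets()].
#' @param precedence `"tetraploid"` or `"pairwise"`: which class wins when a
#'   site carries both kinds of evidence.
#' @return `nr` with added columns `in_parental_pairwise`, `in_tetraploid`,
#'   `category` (factor) and `class_label` (`Aet`/`Ldn`/`Unknown`).
#' @export
classify_sites <- function(nr, pairwise_keys, tetraploid_keys,
                           precedence = c("tetraploid", "pairwise")) {
  precedence <- match.arg(precedence)
  key <- site_key(nr$chrom, nr$pos)
  inp <- key %in% pairwise_keys
  int <- key %in% tetraploid_keys
  cat <- rep("UNCLASSIFIED", nrow(nr))
  cat[inp & !int] <- "D_SPECIFIC"
  cat[int & !inp] <- "HOMOEOLOGOUS"
  cat[inp & int] <- if (precedence == "tetraploid") "HOMOEOLOGOUS" else "D_SPECIFIC"
  nr$in_parental_pairwise <- inp
  nr$in_tetraploid <- int
  nr$category <- factor(cat, levels = CATEGORY_LEVELS)
  nr$class_label <- unname(CATEGORY_LABELS[cat])
  nr
}

#' Tabulate classified sites by chromosome and category
#'
#' @param classified data frame with `chrom` and `category` columns
#'   (from [classify_sites()]), or any data frame of classified sites.
#' @return integer matrix with one row per chromosome plus a `Total` row, and
#'   columns `D_SPECIFIC`, `HOMOEOLOGOUS`, `UNCLASSIFIED`, `Total`.
#' @export
tabulate_by_chromosome <- function(classified) {
  cat <- factor(as.character(classified$category), levels = CATEGORY_LEVELS)
  tab <- table(chrom = classified$chrom, category = cat)
  m <- matrix(as.integer(tab), nrow = nrow(tab), ncol = ncol(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m <- cbind(m, Total = rowSums(m))
  rbind(m, Total = colSums(m))
}

#' Write a classified-site table
#'
#' Tab-separated export of classified sites with the category given as the
#' display labels `Aet` / `Ldn` / `Unknown`.
#'
#' @param classified output of [classify_sites()].
#' @inheritParams write_count_table
#' @export
write_classified_table <- function(classified, path) {
  con <- open_out(path)
  on.exit(close(con))
  y <- data.frame(chrom = classified$chrom, pos_1based = classified$pos,
                  ref_base = classified$ref_base, alt_base = classified$alt_base,
                  category = classified$class_label,
                  in_parental_pairwise = classified$in_parental_pairwise,
                  in_tetraploid = classified$in_tetraploid,
                  stringsAsFactors = FALSE)
  writeLines(paste(names(y), collapse = "\t"), con)
  if (nrow(y))
    writeLines(do.call(paste, c(lapply(y, as.character), sep = "\t")), con)
  invisible(path)
}
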