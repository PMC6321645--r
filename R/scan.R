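# The central analysis: from allele-count tables to classified, averaged
# delta-SNP-index tracks with Steel-Dwass localization and candidate
# selection, wrapped in a classed result object.

#' Read a fixture bundle from disk
#'
#' Loads the artifacts written by [emit_fixture_bundle()] (or arranged in the
#' same layout) back into memory.
#'
#' @param dir bundle directory.
#' @return list with `bulk_tables`, `tetraploid_tables`, `anchors`,
#'   `pairwise`, `flanks` (if present) and `truth` (if present).
#' @export
read_fixture_bundle <- function(dir) {
  fs <- list.files(dir, full.names = TRUE)
  pick <- function(pat) fs[grepl(pat, basename(fs))]
  bulk_files <- pick("^counts_(carrier|noncarrier)")
  tet_files <- pick("^counts_tetraploid")
  if (!length(bulk_files)) stop("no bulk count tables found in ", dir)
  bulk_tables <- lapply(bulk_files, read_count_table)
  names(bulk_tables) <- sub("\\.tsv(\\.gz)?$", "",
                            sub("^counts_", "", basename(bulk_files)))
  tetraploid_tables <- lapply(tet_files, read_count_table)
  names(tetraploid_tables) <- sub("\\.tsv(\\.gz)?$", "",
                                  sub("^counts_", "", basename(tet_files)))
  anchors_f <- pick("^anchors\\.tsv")
  pairwise_f <- pick("^pairwise_snps\\.tsv")
  if (!length(anchors_f)) stop("anchoring table missing in ", dir)
  if (!length(pairwise_f)) stop("parental-pairwise SNP list missing in ", dir)
  flanks_f <- pick("^flanks\\.fa")
  truth_f <- pick("^truth\\.json")
  list(bulk_tables = bulk_tables,
       tetraploid_tables = tetraploid_tables,
       anchors = read_anchor_table(anchors_f[1]),
       pairwise = read_site_list(pairwise_f[1]),
       flanks = if (length(flanks_f)) read_flank_fasta(flanks_f[1]) else NULL,
       truth = if (length(truth_f)) read_sim_truth(truth_f[1]) else NULL)
}

#' Bulked-segregant scan of allele-count tables
#'
#' The full analysis chain: call SNPs in every bulk alignment pair, anchor
#' them to the genome, merge into the non-redundant site set, classify sites
#' by parental-pairwise and tetraploid evidence, compute polarized SNP-index
#' and the per-site average of the four delta-SNP-index values, run the
#' Steel-Dwass all-pairs comparison of subgenome-specific sites across
#' chromosomes, and (when a candidate region is given) filter the region and
#' select high-delta candidate SNPs.
#'
#' @param bundle either a bundle directory path or a list as returned by
#'   [read_fixture_bundle()].
#' @param min_alt_fraction,min_depth SNP-calling thresholds.
#' @param donor_parent donor (carrier-allele) parent label.
#' @param precedence evidence precedence for [classify_sites()].
#' @param region optional [region_filter()] for candidate selection.
#' @param min_delta candidate selection threshold (strict).
#' @return object of class `bsa_scan` with components `nr` (classified
#'   non-redundant sites), `records` (delta-index records), `tracks`,
#'   `steel_dwass` (all-pairs comparison of subgenome-specific sites across
#'   chromosomes, `NULL` when fewer than two chromosomes have enough sites),
#'   `region_summary`, `candidates`, `stage_counts` and `params`.
#' @export
bsa_scan <- function(bundle, min_alt_fraction = 0.1, min_depth = 10,
                     donor_parent = "B",
                     precedence = c("tetraploid", "pairwise"),
                     region = NULL, min_delta = 0.38) {
  precedence <- match.arg(precedence)
  if (is.character(bundle)) bundle <- read_fixture_bundle(bundle)
  stage <- list()

  anchored_sets <- list()
  for (nm in names(bundle$bulk_tables)) {
    called <- call_snps(bundle$bulk_tables[[nm]], min_alt_fraction, min_depth)
    anc <- anchor_sites(called, bundle$anchors)
    anchored_sets[[nm]] <- anc$anchored
    stage[[nm]] <- c(input = nrow(bundle$bulk_tables[[nm]]),
                     called = nrow(called), anchored = nrow(anc$anchored),
                     unanchored = nrow(anc$unanchored),
                     conflicts = nrow(anc$conflicts))
  }
  nr <- merge_nonredundant(anchored_sets)

  ev <- build_evidence_sets(bundle$pairwise, bundle$tetraploid_tables,
                            bundle$anchors, min_alt_fraction, min_depth)
  nr <- classify_sites(nr, ev$pairwise_keys, ev$tetraploid_keys, precedence)

  records <- delta_index_records(bundle$bulk_tables, nr, bundle$anchors,
                                 min_depth, donor_parent)
  tracks <- chromosome_tracks(records)

  dsp <- records[as.character(records$category) == "D_SPECIFIC" &
                   !is.na(records$avg_delta), ]
  groups <- split(dsp$avg_delta, dsp$chrom)
  groups <- groups[lengths(groups) >= 2]
  sd_res <- if (length(groups) >= 2) steel_dwass(groups) else NULL

  region_summary <- candidates <- NULL
  if (!is.null(region)) {
    region_summary <- filter_region(records, region)
    candidates <- select_candidates(region_summary$records, min_delta)
  }

  structure(list(nr = nr, records = records, tracks = tracks,
                 steel_dwass = sd_res, region_summary = region_summary,
                 candidates = candidates, evidence = ev,
                 stage_counts = do.call(rbind, stage),
                 params = list(min_alt_fraction = min_alt_fraction,
                               min_depth = min_depth,
                               donor_parent = donor_parent,
                               precedence = precedence, region = region,
                               min_delta = min_delta)),
            class = "bsa_scan")
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat("Bulked-segregant scan\n")
  cat(sprintf("  non-redundant SNP sites: %d\n", nrow(x$nr)))
  tt <- table(x$nr$category)
  cat(sprintf("  classified: %d subgenome-specific (Aet), %d homoeologous (Ldn), %d unclassified\n",
              tt["D_SPECIFIC"], tt["HOMOEOLOGOUS"], tt["UNCLASSIFIED"]))
  if (!is.null(x$region_summary)) {
    rs <- x$region_summary
    cat(sprintf("  candidate region %s:%d-%d: %d site(s), avg delta in [%.4f, %.4f]\n",
                x$params$region$chrom, x$params$region$start_bp,
                x$params$region$end_bp, rs$total,
                rs$delta_range[1], rs$delta_range[2]))
    cat(sprintf("  candidates with avg delta > %.2f: %d\n",
                x$params$min_delta, nrow(x$candidates)))
  }
  invisible(x)
}

#' @export
summary.bsa_scan <- function(object, ...) {
  out <- list(classification = tabulate_by_chromosome(object$nr),
              steel_dwass = object$steel_dwass,
              region = object$region_summary,
              candidates = object$candidates)
  class(out) <- "summary.bsa_scan"
  out
}

#' @export
print.summary.bsa_scan <- function(x, ...) {
  cat("Classification by chromosome:\n")
  print(x$classification)
  if (!is.null(x$steel_dwass)) {
    cat("\nSteel-Dwass comparison of subgenome-specific sites across chromosomes:\n")
    print(x$steel_dwass)
  }
  if (!is.null(x$region)) {
    cat("\nCandidate region counts:\n")
    print(x$region$counts)
  }
  invisible(x)
}

#' Plot a bulked-segregant scan
#'
#' `type = "tracks"` draws the averaged delta-SNP-index along each
#' chromosome, colour-coded by site class; `type = "groups"` draws the
#' per-chromosome distributions of subgenome-specific sites as box plots.
#'
#' @param x a `bsa_scan`.
#' @param type plot flavour.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.bsa_scan <- function(x, type = c("tracks", "groups"), ...) {
  type <- match.arg(type)
  tr <- x$tracks
  if (type == "tracks") {
    chroms <- unique(tr$chrom)
    op <- graphics::par(mfrow = c(ceiling(length(chroms) / 2), 2),
                        mar = c(3, 4, 2, 1))
    on.exit(graphics::par(op))
    cols <- c(Aet = "red3", Ldn = "grey40", Unknown = "steelblue")
    for (cn in chroms) {
      s <- tr[tr$chrom == cn, ]
      graphics::plot(s$pos / 1e6, s$avg_delta, col = cols[s$category],
                     pch = 16, cex = 0.5, ylim = c(-1, 1),
                     xlab = "position (Mb)", ylab = "avg delta-SNP-index",
                     main = cn, ...)
      graphics::abline(h = 0, lty = 3)
    }
  } else {
    dsp <- tr[tr$category == "Aet", ]
    graphics::boxplot(avg_delta ~ chrom, data = dsp,
                      ylab = "avg delta-SNP-index",
                      main = "subgenome-specific sites", ...)
  }
  invisible(x)
}
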