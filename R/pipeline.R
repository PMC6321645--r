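# End-to-end pipeline: simulate -> emit -> scan -> design markers ->
# validate by two-point linkage on a fresh mapping population.

#' Run the complete simulated experiment
#'
#' Simulates the parents, the selfing pedigree with bulk formation, writes a
#' fixture bundle, re-reads it through the standard readers, runs
#' [bsa_scan()], designs dCAPS assays for the selected candidate SNPs, and
#' validates the candidates by two-point linkage against the causal locus in
#' a freshly simulated F2 mapping population.
#'
#' @param seed one integer seed; every stage derives its own seed from it.
#' @param out_dir output directory for the bundle and reports (default: a
#'   temporary directory).
#' @param genome_cfg configuration from [genome_config()].
#' @param ped_cfg configuration from [pedigree_config()].
#' @param dm a [depth_model()].
#' @param region candidate region (defaults to the genome configuration's
#'   target interval on the causal chromosome).
#' @param min_alt_fraction,min_depth,min_delta analysis thresholds.
#' @param n_f2 size of the validation mapping population.
#' @param write_reports write track/classification/VCF/marker/map reports
#'   into `out_dir`.
#' @return list with `truth`, `scan` (a `bsa_scan`), `markers` (candidate
#'   sites with design success, recombination fraction, LOD and cM distance
#'   to the causal locus), `dcaps` (all validated assays) and `files`.
#' @export
run_bsa_pipeline <- function(seed = 1, out_dir = tempfile("bsa_run_"),
                             genome_cfg = genome_config(),
                             ped_cfg = pedigree_config(),
                             dm = depth_model(),
                             region = NULL,
                             min_alt_fraction = 0.1, min_depth = 10,
                             min_delta = 0.38, n_f2 = 788,
                             write_reports = TRUE) {
  genome <- simulate_parents(genome_cfg, seed = seed)
  truth <- simulate_pedigree(genome, ped_cfg, seed = seed)
  files <- emit_fixture_bundle(truth, out_dir, dm, seed = seed)
  bundle <- read_fixture_bundle(out_dir)

  if (is.null(region))
    region <- region_filter(genome_cfg$causal_chrom,
                            genome_cfg$region[1], genome_cfg$region[2])
  scan <- bsa_scan(bundle, min_alt_fraction, min_depth,
                   region = region, min_delta = min_delta)

  cand <- scan$candidates
  dcaps_all <- list()
  designed <- logical(nrow(cand))
  if (nrow(cand)) {
    keys <- site_key(cand$chrom, cand$pos)
    fl <- bundle$flanks
    al <- attr(fl, "alleles")
    for (i in seq_along(keys)) {
      k <- keys[i]
      if (is.null(fl) || !k %in% names(fl)) next
      ai <- match(k, al$key)
      des <- design_dcaps(fl[[k]], (nchar(fl[[k]]) + 1) %/% 2,
                          al$a[ai], al$b[ai])
      designed[i] <- nrow(des) > 0
      if (nrow(des)) {
        des$marker <- sprintf("bsa%d", i)
        dcaps_all[[k]] <- des
      }
    }
  }
  dcaps <- if (length(dcaps_all)) do.call(rbind, dcaps_all) else NULL

  markers <- NULL
  if (nrow(cand)) {
    f2 <- simulate_f2(genome, n_f2, ped_cfg,
                      seed = derive_seed(seed, "mapping"))
    loci <- data.frame(chrom = c(cand$chrom, genome$causal$chrom),
                       pos = c(cand$pos, genome$causal$pos),
                       name = c(site_key(cand$chrom, cand$pos), "causal"),
                       stringsAsFactors = FALSE)
    G <- genotype_population(f2, loci)
    markers <- data.frame(key = site_key(cand$chrom, cand$pos),
                          chrom = cand$chrom, pos = cand$pos,
                          avg_delta = cand$avg_delta, dcaps_designed = designed,
                          rf = NA_real_, lod = NA_real_, cM = NA_real_,
                          stringsAsFactors = FALSE)
    for (i in seq_len(nrow(markers))) {
      est <- tryCatch(two_point_rf(G, markers$key[i], "causal"),
                      error = function(e) NULL)
      if (!is.null(est)) {
        markers$rf[i] <- est$rf
        markers$lod[i] <- est$lod
        markers$cM[i] <- if (est$rf < 0.5) map_distance(est$rf) else NA_real_
      } else {
        # co-segregation so complete that a locus is monomorphic-in-pairs
        # cannot happen in an F2; a failure here means a degenerate draw
        markers$rf[i] <- 0; markers$lod[i] <- NA_real_; markers$cM[i] <- 0
      }
    }
  }

  if (write_reports) {
    write_track_table(scan$tracks, file.path(out_dir, "tracks.tsv"))
    write_classified_table(scan$nr, file.path(out_dir, "classified_sites.tsv"))
    write_sites_vcf(scan$nr, file.path(out_dir, "nr_sites.vcf"))
    if (!is.null(dcaps))
      write_dcaps_report(dcaps, file.path(out_dir, "dcaps_markers.tsv"))
    if (!is.null(markers))
      utils::write.table(markers, file.path(out_dir, "map_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(truth = truth, scan = scan, markers = markers, dcaps = dcaps,
       files = files, out_dir = out_dir, seed = seed)
}
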