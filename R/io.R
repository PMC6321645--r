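# Readers and writers for every artifact the pipeline touches: tab-separated
# count/anchor/site/track tables, 2-line FASTA flanks, JSON ground truth and
# a minimal VCF-dialect site export. All text readers/writers accept `.gz`
# paths transparently.

open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

COUNT_COLS <- c(chrom = "chrom", pos = "pos_1based",
                transcript_id = "transcript_id",
                transcript_pos = "transcript_pos_1based",
                ref_base = "ref_base", alt_base = "alt_base",
                depth = "depth", alt_depth = "alt_depth")

#' Write / read an allele-count table
#'
#' Tab-separated dialect with columns `chrom`, `pos_1based`, `transcript_id`,
#' `transcript_pos_1based`, `ref_base`, `alt_base`, `depth`, `alt_depth`.
#' The alignment-pair metadata (sample, population, bulk type, reference) is
#' carried in a `#pair` header line and restored on read.
#'
#' @param x a count-table data frame (see [sample_allele_counts()]).
#' @param path file path; a `.gz` suffix enables compression.
#' @return `write_count_table` returns `path` invisibly; `read_count_table`
#'   returns the data frame with its `"pair"` attribute.
#' @export
write_count_table <- function(x, path) {
  con <- open_out(path)
  on.exit(close(con))
  p <- attr(x, "pair")
  if (!is.null(p))
    writeLines(sprintf("#pair\tsample=%s\tpopulation=%s\tbulk_type=%s\treference=%s",
                       p$sample, p$population, p$bulk_type, p$reference), con)
  y <- x[, names(COUNT_COLS)]
  names(y) <- unname(COUNT_COLS)
  writeLines(paste(names(y), collapse = "\t"), con)
  if (nrow(y))
    writeLines(do.call(paste, c(lapply(y, as.character), sep = "\t")), con)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  first <- readLines(path, n = 1)
  pair <- NULL
  if (length(first) && startsWith(first, "#pair")) {
    kv <- strsplit(sub("^#pair\t", "", first), "\t")[[1]]
    pair <- as.list(sub("^[^=]+=", "", kv))
    names(pair) <- sub("=.*$", "", kv)
    pair <- lapply(pair, function(v) if (identical(v, "NA")) NA_character_ else v)
  }
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = c("character", "integer", "character",
                                        "integer", "character", "character",
                                        "integer", "integer"))
  bad <- !names(x) %in% COUNT_COLS
  if (any(bad))
    stop(path, ": unexpected column(s): ", paste(names(x)[bad], collapse = ", "))
  names(x) <- names(COUNT_COLS)[match(names(x), COUNT_COLS)]
  if (any(x$depth < 0 | x$alt_depth < 0))
    stop(path, ": negative counts at line(s) ",
         paste(utils::head(which(x$depth < 0 | x$alt_depth < 0), 5), collapse = ", "))
  if (any(x$alt_depth > x$depth))
    stop(path, ": alt_depth exceeds depth at line(s) ",
         paste(utils::head(which(x$alt_depth > x$depth), 5), collapse = ", "))
  attr(x, "pair") <- pair
  x
}

#' Write / read a transcript-to-genome anchoring table
#'
#' Tab-separated columns `transcript_id`, `transcript_pos_1based`, `chrom`,
#' `pos_1based`, `strand`.
#'
#' @param x data frame with columns `transcript_id`, `transcript_pos`,
#'   `chrom`, `pos`, `strand`.
#' @inheritParams write_count_table
#' @export
write_anchor_table <- function(x, path) {
  con <- open_out(path)
  on.exit(close(con))
  y <- x[, c("transcript_id", "transcript_pos", "chrom", "pos", "strand")]
  names(y) <- c("transcript_id", "transcript_pos_1based", "chrom",
                "pos_1based", "strand")
  writeLines(paste(names(y), collapse = "\t"), con)
  if (nrow(y))
    writeLines(do.call(paste, c(lapply(y, as.character), sep = "\t")), con)
  invisible(path)
}

#' @rdname write_anchor_table
#' @export
read_anchor_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "integer", "character",
                                        "integer", "character"))
  names(x) <- c("transcript_id", "transcript_pos", "chrom", "pos", "strand")
  if (!all(x$strand %in% c("+", "-")))
    stop(path, ": strand must be '+' or '-'")
  x
}

#' Write / read a genome-anchored SNP site list
#'
#' Tab-separated columns `chrom`, `pos_1based`, `ref_base`, `alt_base`; used
#' for the parental-pairwise SNP list.
#'
#' @param x data frame with columns `chrom`, `pos`, `ref_base`, `alt_base`.
#' @inheritParams write_count_table
#' @export
write_site_list <- function(x, path) {
  con <- open_out(path)
  on.exit(close(con))
  y <- x[, c("chrom", "pos", "ref_base", "alt_base")]
  names(y) <- c("chrom", "pos_1based", "ref_base", "alt_base")
  writeLines(paste(names(y), collapse = "\t"), con)
  if (nrow(y))
    writeLines(do.call(paste, c(lapply(y, as.character), sep = "\t")), con)
  invisible(path)
}

#' @rdname write_site_list
#' @export
read_site_list <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "integer", "character",
                                        "character"))
  names(x) <- c("chrom", "pos", "ref_base", "alt_base")
  x
}

#' Write / read flanking sequences as 2-line FASTA records
#'
#' @param flanks named character vector from [site_flanks()]; the optional
#'   `alleles` attribute is encoded in the description line.
#' @inheritParams write_count_table
#' @export
write_flank_fasta <- function(flanks, path) {
  al <- attr(flanks, "alleles")
  xs <- Biostrings::DNAStringSet(unname(flanks))
  nm <- names(flanks)
  if (!is.null(al)) nm <- paste0(nm, " alleles=", al$a, "/", al$b)
  names(xs) <- nm
  Biostrings::writeXStringSet(xs, path, width = max(nchar(flanks), 80L),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname write_flank_fasta
#' @export
read_flank_fasta <- function(path) {
  xs <- Biostrings::readDNAStringSet(path)
  out <- as.character(xs)
  full <- names(out)
  names(out) <- sub("\\s.*$", "", full)
  al <- regmatches(full, regexpr("alleles=[ACGT]/[ACGT]", full))
  if (length(al) == length(full)) {
    ab <- do.call(rbind, strsplit(sub("^alleles=", "", al), "/"))
    attr(out, "alleles") <- data.frame(key = names(out), a = ab[, 1], b = ab[, 2],
                                       stringsAsFactors = FALSE)
  }
  out
}

#' Write / read simulation ground truth as JSON
#'
#' Serializes the JSON-representable parts of a `sim_truth`: causal locus,
#' bulk membership, per-site true donor-allele frequencies and the seed.
#' (Member chromosome mosaics are an R-session object and are not part of the
#' on-disk truth file.)
#'
#' @param truth a `sim_truth` (or a list as returned by `read_sim_truth`).
#' @inheritParams write_count_table
#' @export
write_sim_truth <- function(truth, path) {
  obj <- list(causal = truth$genome$causal %||% truth$causal,
              membership = truth$membership,
              site_key = rownames(truth$true_freq),
              bulk = colnames(truth$true_freq),
              true_freq = unname(truth$true_freq),
              seed = truth$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tf <- as.matrix(obj$true_freq)
  dimnames(tf) <- list(obj$site_key, obj$bulk)
  list(causal = list(chrom = obj$causal$chrom, pos = obj$causal$pos),
       membership = as.data.frame(obj$membership),
       true_freq = tf, seed = obj$seed)
}

#' Emit a complete fixture bundle for the pipeline
#'
#' Writes the eight bulk alignment-pair count tables, the two tetraploid
#' count tables, the anchoring table (with a configurable fraction of sites
#' left unanchored), the parental-pairwise SNP list, flanking sequences for
#' marker design, and the ground-truth JSON. Every artifact round-trips
#' through the matching reader.
#'
#' @param truth a `sim_truth` from [simulate_pedigree()].
#' @param dir output directory (created if needed).
#' @param dm a [depth_model()] for count sampling.
#' @param unanchored_frac fraction of sites whose anchor row is withheld,
#'   emulating transcripts that fail to map to the genome.
#' @param seed integer seed.
#' @param gzip write `.gz`-compressed tables.
#' @return invisibly, a named list of file paths (`bulk_tables`,
#'   `tetraploid_tables`, `anchors`, `pairwise`, `flanks`, `truth`).
#' @export
emit_fixture_bundle <- function(truth, dir, dm = depth_model(),
                                unanchored_frac = 0.007, seed = 1,
                                gzip = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  genome <- truth$genome
  ext <- if (gzip) ".tsv.gz" else ".tsv"
  set.seed(derive_seed(seed, "bundle"))

  tabs <- simulate_bulk_tables(truth, dm, seed = seed)
  bulk_paths <- character(0)
  for (nm in names(tabs)) {
    p <- file.path(dir, paste0("counts_", gsub("[^A-Za-z0-9_.-]", "_", nm), ext))
    write_count_table(tabs[[nm]], p)
    bulk_paths[nm] <- p
  }
  tet_paths <- character(0)
  for (ref in c("A", "B")) {
    tt <- simulate_tetraploid_counts(genome, ref, dm,
                                     seed = derive_seed(seed, paste0("tet", ref)))
    p <- file.path(dir, paste0("counts_tetraploid_ref", ref, ext))
    write_count_table(tt, p)
    tet_paths[paste0("tetraploid.ref", ref)] <- p
  }

  s <- genome$sites
  anchors <- data.frame(transcript_id = s$transcript_id,
                        transcript_pos = s$transcript_pos,
                        chrom = s$chrom, pos = s$pos, strand = s$strand,
                        stringsAsFactors = FALSE)
  n_drop <- round(nrow(anchors) * unanchored_frac)
  if (n_drop > 0) anchors <- anchors[-sample.int(nrow(anchors), n_drop), ]
  anchors_path <- file.path(dir, paste0("anchors", ext))
  write_anchor_table(anchors, anchors_path)

  pdiv <- s$a_allele != s$b_allele
  pairwise <- data.frame(chrom = s$chrom[pdiv], pos = s$pos[pdiv],
                         ref_base = s$a_allele[pdiv],
                         alt_base = s$b_allele[pdiv],
                         stringsAsFactors = FALSE)
  pairwise_path <- file.path(dir, paste0("pairwise_snps", ext))
  write_site_list(pairwise, pairwise_path)

  flanks_path <- file.path(dir, "flanks.fa")
  write_flank_fasta(site_flanks(genome, seed = seed), flanks_path)

  truth_path <- file.path(dir, "truth.json")
  write_sim_truth(truth, truth_path)

  invisible(list(bulk_tables = bulk_paths, tetraploid_tables = tet_paths,
                 anchors = anchors_path, pairwise = pairwise_path,
                 flanks = flanks_path, truth = truth_path))
}
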