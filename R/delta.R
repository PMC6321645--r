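# SNP-index, polarization, delta-SNP-index and per-site averaging over the
# alignment pairs.

#' SNP-index: alternate-allele read fraction
#'
#' `alt_depth / depth`, reported as missing (`NA`, not 0) below the depth
#' floor — a shallow site carries no usable frequency estimate.
#'
#' @param depth,alt_depth integer vectors of total and alternate read counts.
#' @param min_depth depth floor below which the index is missing.
#' @return numeric vector in `[0, 1]` with `NA` at shallow sites.
#' @examples
#' snp_index(c(20, 40, 8), c(10, 40, 4))  # 0.5, 1, NA
#' @export
snp_index <- function(depth, alt_depth, min_depth = 10) {
  if (any(depth < 0 | alt_depth < 0, na.rm = TRUE)) stop("negative counts")
  if (any(alt_depth > depth, na.rm = TRUE)) stop("alt_depth exceeds depth")
  out <- ifelse(depth >= min_depth & depth > 0, alt_depth / depth, NA_real_)
  as.numeric(out)
}

#' Polarize a SNP-index to the donor-parent allele frequency
#'
#' SNP-indices computed against the two parental transcript references point
#' in opposite allelic directions at parent-divergent sites; averaging the
#' raw values across references would cancel the signal. Polarization re-
#' expresses every index as the frequency of the donor (carrier-parent)
#' allele: unchanged when the alignment reference is the non-donor parent,
#' `1 - index` when the reference is the donor parent itself.
#'
#' @param index numeric vector of SNP-index values in `[0, 1]`.
#' @param reference_parent parent used as alignment reference (`"A"`/`"B"`).
#' @param donor_parent parent carrying the selected (carrier) allele.
#' @return polarized index vector.
#' @export
polarize_index <- function(index, reference_parent, donor_parent = "B") {
  if (!reference_parent %in% c("A", "B") || !donor_parent %in% c("A", "B"))
    stop("parent labels must be \"A\" or \"B\"")
  if (any(index < 0 | index > 1, na.rm = TRUE)) stop("index outside [0, 1]")
  if (identical(reference_parent, donor_parent)) 1 - index else index
}

#' Delta-SNP-index of a contrasting bulk pair
#'
#' Carrier-bulk index minus non-carrier-bulk index (both polarized, same
#' reference); missing when either input is missing.
#'
#' @param carrier_index,noncarrier_index polarized SNP-index vectors.
#' @return numeric vector in `[-1, 1]`.
#' @export
delta_snp_index <- function(carrier_index, noncarrier_index) {
  carrier_index - noncarrier_index
}

#' Average the available delta-SNP-index values at a site
#'
#' @param deltas numeric vector or matrix (sites x pairs) of delta-SNP-index
#'   values, possibly containing missing values.
#' @return for a vector, a list with `avg_delta` and `n_informative`; for a
#'   matrix, a data frame with one row per site. The average is missing when
#'   no pair is informative.
#' @export
average_delta <- function(deltas) {
  if (is.matrix(deltas)) {
    n_inf <- rowSums(!is.na(deltas))
    avg <- ifelse(n_inf > 0, rowMeans(deltas, na.rm = TRUE), NA_real_)
    return(data.frame(avg_delta = as.numeric(avg), n_informative = n_inf))
  }
  n_inf <- sum(!is.na(deltas))
  list(avg_delta = if (n_inf > 0) mean(deltas, na.rm = TRUE) else NA_real_,
       n_informative = n_inf)
}

#' Per-site delta-SNP-index records over all alignment pairs
#'
#' Anchors every bulk count table to the genome, computes polarized
#' SNP-indices over the non-redundant site set, forms the four contrasting
#' delta-SNP-index values (two populations x two references) and their
#' per-site average over the available values.
#'
#' @param bulk_tables named list of the eight bulk count tables (each with a
#'   `"pair"` attribute; see [simulate_bulk_tables()] / [read_count_table()]).
#' @param nr non-redundant site set (from [merge_nonredundant()], optionally
#'   classified); multi-allelic sites are excluded from averaging unless
#'   `keep_multiallelic`.
#' @param anchors anchoring table.
#' @param min_depth depth floor for [snp_index()].
#' @param donor_parent donor (carrier) parent label.
#' @param keep_multiallelic keep multi-allelic sites in the output.
#' @return data frame of class `delta_records`: site key columns, one
#'   polarized-index column per pair (`idx_*`), the four delta columns
#'   (`delta_<population>_ref<R>`), `avg_delta` and `n_informative`.
#' @export
delta_index_records <- function(bulk_tables, nr, anchors, min_depth = 10,
                                donor_parent = "B", keep_multiallelic = FALSE) {
  if (!keep_multiallelic && !is.null(nr$multi_allelic))
    nr <- nr[!nr$multi_allelic, , drop = FALSE]
  out <- nr[, intersect(c("chrom", "pos", "ref_base", "alt_base", "category",
                          "class_label"), names(nr)), drop = FALSE]
  key <- site_key(nr$chrom, nr$pos)
  akey <- paste(anchors$transcript_id, anchors$transcript_pos)

  idx_cols <- list()
  meta <- list()
  for (nm in names(bulk_tables)) {
    tab <- bulk_tables[[nm]]
    pair <- attr(tab, "pair")
    if (is.null(pair)) stop("bulk table '", nm, "' lacks pair metadata")
    ai <- match(paste(tab$transcript_id, tab$transcript_pos), akey)
    gk <- ifelse(is.na(ai), NA_character_,
                 site_key(anchors$chrom[ai], anchors$pos[ai]))
    ridx <- match(key, gk)
    idx <- snp_index(tab$depth[ridx], tab$alt_depth[ridx], min_depth)
    idx_cols[[nm]] <- polarize_index(idx, pair$reference, donor_parent)
    meta[[nm]] <- pair
  }

  pops <- sort(unique(vapply(meta, function(p) p$population, character(1))))
  refs <- sort(unique(vapply(meta, function(p) p$reference, character(1))))
  deltas <- matrix(NA_real_, nrow(out), 0)
  for (p in pops) for (r in refs) {
    sel <- function(bt) {
      hit <- vapply(meta, function(m)
        identical(m$population, p) && identical(m$reference, r) &&
          identical(m$bulk_type, bt), logical(1))
      if (sum(hit) != 1)
        stop(sprintf("expected exactly one %s table for population %s, reference %s",
                     bt, p, r))
      idx_cols[[names(which(hit))]]
    }
    d <- delta_snp_index(sel("carrier"), sel("noncarrier"))
    deltas <- cbind(deltas, d)
    colnames(deltas)[ncol(deltas)] <- paste0("delta_", p, "_ref", r)
  }

  for (nm in names(idx_cols)) out[[paste0("idx_", nm)]] <- idx_cols[[nm]]
  out <- cbind(out, as.data.frame(deltas))
  av <- average_delta(deltas)
  out$avg_delta <- av$avg_delta
  out$n_informative <- av$n_informative
  class(out) <- c("delta_records", "data.frame")
  out
}

#' Plot-ready per-chromosome delta-SNP-index tracks
#'
#' @param records a `delta_records` data frame carrying a `class_label`
#'   column (i.e. built from a classified site set).
#' @return data frame with `chrom`, `pos`, `avg_delta`, `category`
#'   (`Aet`/`Ldn`/`Unknown`), rows with a non-missing average only, sorted by
#'   chromosome then position.
#' @export
chromosome_tracks <- function(records) {
  if (is.null(records$class_label))
    stop("records lack classification labels; run classify_sites() first")
  keep <- !is.na(records$avg_delta)
  out <- data.frame(chrom = records$chrom[keep], pos = records$pos[keep],
                    avg_delta = records$avg_delta[keep],
                    category = records$class_label[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a track table
#'
#' @param tracks output of [chromosome_tracks()].
#' @inheritParams write_count_table
#' @export
write_track_table <- function(tracks, path) {
  con <- open_out(path)
  on.exit(close(con))
  y <- tracks
  names(y)[names(y) == "pos"] <- "pos_1based"
  writeLines(paste(names(y), collapse = "\t"), con)
  if (nrow(y))
    writeLines(do.call(paste, c(lapply(y, as.character), sep = "\t")), con)
  invisible(path)
}
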