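# Density, motif-composition and positional statistics.
#
# TR density is base pairs of detected repeats per megabase of valid (A/C/G/T)
# sequence; relative density rescales so the whole-genome density is exactly
# 100. Positional profiles normalize each region to a 0-99 scale with ten
# equal intervals and report the percentage of TR occurrences per decile.

#' Per-class TR densities, relative densities and GC content
#'
#' Region intervals are unioned per class (so bases shared between mRNAs are
#' counted once), TR base pairs are the summed clipped overlaps with that
#' union, and the denominator counts valid nucleotides only. A `GENOME` row
#' covering the full sequences is always included and anchors the relative
#' density at exactly 100.
#'
#' @param trs a [tr_table()].
#' @param regions per-mRNA region data frame from [extract_all_regions()];
#'   may be `NULL` to get the genome row only.
#' @param seqs named character vector of sequences.
#' @return data frame with one row per region class: `region_class`,
#'   `total_valid_nt`, `tr_bp`, `density` (bp/Mbp), `relative_density`
#'   (genome = 100), `gc_percent`.
#' @export
compute_density <- function(trs, regions, seqs) {
  seqs <- .as_seqs(seqs)
  uni <- if (is.null(regions) || nrow(regions) == 0L) NULL else
    union_regions(regions)

  class_stats <- function(class, iv) {
    counts <- matrix(0L, nrow = 0, ncol = 4)
    for (sid in unique(iv$seq_id)) {
      sel <- iv$seq_id == sid
      counts <- rbind(counts, cpp_base_counts(seqs[[sid]],
                                              iv$start[sel], iv$end[sel]))
    }
    tot <- sum(counts)
    if (tot == 0L)
      stop("density undefined for region class '", class,
           "': no valid nucleotides", call. = FALSE)
    gc <- 100 * sum(counts[, c("C", "G")]) / tot
    asn <- assign_trs(trs, iv)
    data.frame(region_class = class, total_valid_nt = tot,
               tr_bp = sum(asn$overlap_bp),
               density = sum(asn$overlap_bp) / tot * 1e6,
               gc_percent = gc, stringsAsFactors = FALSE)
  }

  rows <- list(class_stats("GENOME", data.frame(
    seq_id = names(seqs), region_class = "GENOME", start = 0L,
    end = nchar(seqs), stringsAsFactors = FALSE)))
  if (!is.null(uni))
    for (cl in intersect(.REGION_CLASSES, unique(uni$region_class)))
      rows[[length(rows) + 1L]] <-
        class_stats(cl, uni[uni$region_class == cl, , drop = FALSE])
  out <- do.call(rbind, rows)
  gd <- out$density[out$region_class == "GENOME"]
  out$relative_density <- if (gd > 0) relative_density(out$density, gd) else
    NA_real_
  rownames(out) <- NULL
  out[, c("region_class", "total_valid_nt", "tr_bp", "density",
          "relative_density", "gc_percent")]
}

#' Relative TR density (whole genome = 100)
#'
#' @param region_density density of a region (bp/Mbp).
#' @param genome_density whole-genome density (bp/Mbp), must be > 0.
#' @return `100 * region_density / genome_density`.
#' @examples
#' relative_density(40000, 20000) # 200
#' @export
relative_density <- function(region_density, genome_density) {
  if (length(genome_density) != 1L || is.na(genome_density) ||
      genome_density <= 0)
    stop("relative density undefined: genome density must be > 0",
         call. = FALSE)
  100 * region_density / genome_density
}

#' Decile positional profiles of TRs within regions
#'
#' Each region (the spliced, strand-oriented union of one mRNA's intervals of
#' one class — e.g. an mRNA's CDS across exons, or a single intergenic
#' window) is normalized to a 0-99 scale with ten equal intervals. Each TR is
#' assigned one decile by its anchor position (midpoint by default, which is
#' invariant to repeat length; start-based assignment is available for
#' sensitivity analysis): `bin = floor(10 * offset / region_length)`, clamped
#' to 9, with `offset` measured 5' to 3' in the region's sense orientation.
#' Bins are reported as percentages of the TRs assigned to each class.
#'
#' @param trs a [tr_table()].
#' @param regions per-mRNA region data frame from [extract_all_regions()].
#' @param anchor `"midpoint"` (default) or `"start"` (sense-oriented start).
#' @return data frame: `region_class`, `n` (TRs assigned), and `bin0` ...
#'   `bin9` percentages (rows with `n = 0` are all-zero).
#' @export
profile_bins <- function(trs, regions, anchor = c("midpoint", "start")) {
  anchor <- match.arg(anchor)
  trs <- as.data.frame(trs)
  classes <- intersect(.REGION_CLASSES, unique(regions$region_class))
  counts <- matrix(0, nrow = length(classes), ncol = 10,
                   dimnames = list(classes, paste0("bin", 0:9)))
  if (nrow(trs) > 0L && nrow(regions) > 0L) {
    key <- if (is.null(regions$mrna_id))
      paste(seq_len(nrow(regions)), regions$region_class, sep = "\r")
    else paste(regions$mrna_id, regions$region_class, sep = "\r")
    for (g in unique(key)) {
      iv <- regions[key == g, , drop = FALSE]
      iv <- iv[order(iv$start), , drop = FALSE]
      cl <- iv$region_class[1]
      if (!cl %in% classes) next
      total <- sum(iv$end - iv$start)
      cum <- cumsum(c(0L, (iv$end - iv$start)[-nrow(iv)]))
      sel <- trs$seq_id == iv$seq_id[1]
      if (!any(sel)) next
      pos <- if (anchor == "midpoint") (trs$start[sel] + trs$end[sel]) %/% 2L
        else if (iv$strand[1] == "+") trs$start[sel] else trs$end[sel] - 1L
      for (k in seq_len(nrow(iv))) {
        inside <- pos >= iv$start[k] & pos < iv$end[k]
        if (!any(inside)) next
        off <- cum[k] + pos[inside] - iv$start[k]        # plus-orientation
        if (iv$strand[1] == "-") off <- total - 1L - off # sense flip
        bin <- pmin(9L, (10L * off) %/% total)
        for (b in bin) counts[cl, b + 1L] <- counts[cl, b + 1L] + 1
      }
    }
  }
  n <- rowSums(counts)
  pct <- counts
  pct[n > 0, ] <- 100 * counts[n > 0, , drop = FALSE] / n[n > 0]
  out <- data.frame(region_class = classes, n = as.integer(n),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(pct, row.names = seq_along(classes)))
}

#' Unit-size frequency table
#'
#' Percentage of TR occurrences by unit length 1-50, plus per-motif-class
#' counts.
#'
#' @param trs a [tr_table()].
#' @return list with `by_unit_length` (data frame `unit_len`, `count`,
#'   `percent`; percentages sum to 100) and `by_motif` (data frame
#'   `canonical_unit`, `count`).
#' @export
unit_size_frequency <- function(trs) {
  trs <- as.data.frame(trs)
  if (nrow(trs) == 0L)
    return(list(by_unit_length = data.frame(unit_len = integer(0),
                                            count = integer(0),
                                            percent = numeric(0)),
                by_motif = data.frame(canonical_unit = character(0),
                                      count = integer(0))))
  tab <- table(factor(trs$unit_len, levels = 1:50))
  keep <- tab > 0
  by_len <- data.frame(unit_len = as.integer(names(tab))[keep],
                       count = as.integer(tab)[keep],
                       percent = 100 * as.integer(tab)[keep] / nrow(trs))
  mt <- sort(table(trs$canonical_unit), decreasing = TRUE)
  list(by_unit_length = by_len,
       by_motif = data.frame(canonical_unit = names(mt),
                             count = as.integer(mt),
                             stringsAsFactors = FALSE))
}

#' Top repeat motifs
#'
#' Ranks canonical motif classes by occurrence count (ties broken
#' alphabetically). Each class is counted separately from its reverse
#' complement, but the display label reports the conventional joint
#' "AAG/CTT" form.
#'
#' @param trs a [tr_table()].
#' @param k number of motifs to report.
#' @return data frame `canonical_unit`, `display`, `count`, ranked.
#' @export
top_motifs <- function(trs, k = 5L) {
  trs <- as.data.frame(trs)
  if (nrow(trs) == 0L)
    return(data.frame(canonical_unit = character(0), display = character(0),
                      count = integer(0)))
  tab <- table(trs$canonical_unit)
  ord <- order(-as.integer(tab), names(tab))
  tab <- tab[ord][seq_len(min(k, length(tab)))]
  data.frame(canonical_unit = names(tab),
             display = motif_pair_label(names(tab)),
             count = as.integer(tab), stringsAsFactors = FALSE)
}

#' Fraction of mRNAs with at least one TR, per region class
#'
#' An mRNA counts once per class no matter how many TRs hit it. Assignments
#' must come from per-mRNA regions (so `mrna_id` is available); pass regions
#' extracted with `include_mrna_span = TRUE` to also get the whole-transcript
#' (`MRNA`) fraction.
#'
#' @param assignments output of [assign_trs()] on per-mRNA regions.
#' @param models the `gene_model_list` (denominator: all mRNAs).
#' @return data frame `region_class`, `n_mrna_with_tr`, `fraction`.
#' @export
tr_presence_frequency <- function(assignments, models) {
  n <- length(models)
  if (n == 0L) stop("no denominators: empty gene model list", call. = FALSE)
  if (is.null(assignments$mrna_id))
    stop("assignments lack mrna_id; use per-mRNA regions", call. = FALSE)
  classes <- intersect(c(.REGION_CLASSES, "MRNA"),
                       unique(assignments$region_class))
  cnt <- vapply(classes, function(cl) {
    length(unique(assignments$mrna_id[assignments$region_class == cl]))
  }, integer(1))
  data.frame(region_class = classes, n_mrna_with_tr = as.integer(cnt),
             fraction = cnt / n, row.names = NULL, stringsAsFactors = FALSE)
}
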