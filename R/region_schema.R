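# Gene-anchored region schema: the four intragenic classes (5'-UTR, CDS,
# intron, 3'-UTR) plus six intergenic windows tiled away from each transcript
# in transcription orientation:
#
#   UI200  = 1-200 nt upstream of the 5'-UTR (gene start when no UTR),
#   UI500  = 201-700 nt upstream,  UI1000 = 701-1700 nt upstream,
#   DI200/DI500/DI1000 = the mirrored windows downstream of the 3'-UTR.
#
# "Upstream" for a minus-strand gene is rightward in assembly coordinates.
# Windows are clipped at sequence ends only; overlap with neighboring genes
# is permitted (density denominators later use per-class interval unions).

.REGION_CLASSES <- c("UI1000", "UI500", "UI200", "FIVE_UTR", "CDS", "INTRON",
                     "THREE_UTR", "DI200", "DI500", "DI1000")

.region_row <- function(model, class, start, end, seq_len) {
  start <- max(0L, as.integer(start))
  end <- min(as.integer(seq_len), as.integer(end))
  if (end <= start) return(NULL)
  data.frame(seq_id = model$seq_id, region_class = class, start = start,
             end = end, strand = model$strand, gene_id = model$gene_id,
             mrna_id = model$mrna_id, stringsAsFactors = FALSE)
}

.empty_regions <- function() {
  data.frame(seq_id = character(0), region_class = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             gene_id = character(0), mrna_id = character(0),
             stringsAsFactors = FALSE)
}

#' Extract the analysis regions of one gene model
#'
#' Materializes, for one mRNA, the annotated 5'-UTR/CDS/3'-UTR intervals,
#' introns (gaps between consecutive exons), and the six intergenic windows
#' at offsets 1-200, 201-700 and 701-1700 from the transcript ends, oriented
#' by strand and clipped at sequence ends. When UTRs are unannotated the
#' windows anchor on the gene start/end and the UTR classes are skipped for
#' that mRNA.
#'
#' @param model a gene model from [read_gff3()].
#' @param seq_len length of the owning sequence (for clipping).
#' @param include_mrna_span also emit a `MRNA` region covering the gene span
#'   (useful for per-mRNA TR presence; off by default because it overlaps the
#'   other classes).
#' @return data frame with columns `seq_id`, `region_class`, `start`, `end`
#'   (0-based half-open), `strand`, `gene_id`, `mrna_id`.
#' @export
extract_regions <- function(model, seq_len, include_mrna_span = FALSE) {
  ex <- model$exons
  if (nrow(ex) > 1L) {
    if (is.unsorted(ex[, 1])) stop("annotation error: unsorted exons in '",
                                   model$mrna_id, "'", call. = FALSE)
    if (any(ex[-1, 1] < ex[-nrow(ex), 2]))
      stop("annotation error: overlapping exons in '", model$mrna_id, "'",
           call. = FALSE)
  }
  rows <- list()
  add <- function(class, s, e) rows[[length(rows) + 1L]] <<-
    .region_row(model, class, s, e, seq_len)
  for (k in seq_len(nrow(model$five_utr)))
    add("FIVE_UTR", model$five_utr[k, 1], model$five_utr[k, 2])
  for (k in seq_len(nrow(model$cds)))
    add("CDS", model$cds[k, 1], model$cds[k, 2])
  for (k in seq_len(nrow(model$three_utr)))
    add("THREE_UTR", model$three_utr[k, 1], model$three_utr[k, 2])
  if (nrow(ex) > 1L)
    for (k in seq_len(nrow(ex) - 1L))
      add("INTRON", ex[k, 2], ex[k + 1L, 1])

  # transcript 5'/3' anchors in assembly coordinates
  has5 <- nrow(model$five_utr) > 0L
  has3 <- nrow(model$three_utr) > 0L
  if (model$strand == "+") {
    a <- if (has5) min(model$five_utr[, 1]) else model$gene_span[1]
    b <- if (has3) max(model$three_utr[, 2]) else model$gene_span[2]
    add("UI200", a - 200L, a)
    add("UI500", a - 700L, a - 200L)
    add("UI1000", a - 1700L, a - 700L)
    add("DI200", b, b + 200L)
    add("DI500", b + 200L, b + 700L)
    add("DI1000", b + 700L, b + 1700L)
  } else {
    a <- if (has5) max(model$five_utr[, 2]) else model$gene_span[2]
    b <- if (has3) min(model$three_utr[, 1]) else model$gene_span[1]
    add("UI200", a, a + 200L)
    add("UI500", a + 200L, a + 700L)
    add("UI1000", a + 700L, a + 1700L)
    add("DI200", b - 200L, b)
    add("DI500", b - 700L, b - 200L)
    add("DI1000", b - 1700L, b - 700L)
  }
  if (include_mrna_span)
    add("MRNA", model$gene_span[1], model$gene_span[2])
  out <- do.call(rbind, rows)
  if (is.null(out)) .empty_regions() else out
}

#' Extract regions for all gene models
#'
#' @param models a `gene_model_list`.
#' @param seqs named character vector of sequences (for clipping lengths).
#' @inheritParams extract_regions
#' @return row-bound region data frame; see [extract_regions()].
#' @export
extract_all_regions <- function(models, seqs, include_mrna_span = FALSE) {
  lens <- setNames(nchar(seqs), names(seqs))
  out <- do.call(rbind, lapply(models, function(m) {
    if (!m$seq_id %in% names(lens))
      stop("gene model '", m$mrna_id, "' on unknown sequence '", m$seq_id,
           "'", call. = FALSE)
    extract_regions(m, lens[[m$seq_id]], include_mrna_span)
  }))
  if (is.null(out)) .empty_regions() else out
}

#' Union region intervals per class
#'
#' Merges the per-mRNA intervals of each region class (per sequence) into a
#' disjoint interval set so that shared bases (e.g. exons common to two
#' mRNAs, or overlapping windows of neighboring genes) are not counted twice
#' in density denominators.
#'
#' @param regions region data frame.
#' @return data frame with columns `seq_id`, `region_class`, `start`, `end`.
#' @export
union_regions <- function(regions) {
  if (nrow(regions) == 0L)
    return(regions[, c("seq_id", "region_class", "start", "end")])
  parts <- split(regions, list(regions$seq_id, regions$region_class),
                 drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(p) {
    red <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))
    data.frame(seq_id = p$seq_id[1], region_class = p$region_class[1],
               start = BiocGenerics::start(red) - 1L,
               end = BiocGenerics::end(red), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$seq_id, out$region_class, out$start), , drop = FALSE]
}

#' Assign TRs to regions by overlap
#'
#' Every (TR, region) pair overlapping by at least 1 bp, with the clipped
#' overlap length; a TR may hit several regions and contributes its clipped
#' base pairs to each.
#'
#' @param trs a [tr_table()].
#' @param regions region data frame ([extract_regions()] output or
#'   [union_regions()] output).
#' @return data frame with `tr_row`, `region_row`, `overlap_bp`, plus the
#'   TR span, `region_class` and (when present) `mrna_id`.
#' @export
assign_trs <- function(trs, regions) {
  trs <- as.data.frame(trs)
  empty <- data.frame(tr_row = integer(0), region_row = integer(0),
                      seq_id = character(0), start = integer(0),
                      end = integer(0), region_class = character(0),
                      overlap_bp = integer(0), stringsAsFactors = FALSE)
  if (!is.null(regions$mrna_id)) empty$mrna_id <- character(0)
  if (nrow(trs) == 0L || nrow(regions) == 0L) return(empty)
  out <- lapply(intersect(unique(trs$seq_id), unique(regions$seq_id)),
                function(sid) {
    ti <- which(trs$seq_id == sid)
    ri <- which(regions$seq_id == sid)
    tir <- IRanges::IRanges(trs$start[ti] + 1L, trs$end[ti])
    rir <- IRanges::IRanges(regions$start[ri] + 1L, regions$end[ri])
    hits <- IRanges::findOverlaps(tir, rir)
    if (length(hits) == 0L) return(NULL)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    res <- data.frame(
      tr_row = ti[qh], region_row = ri[sh], seq_id = sid,
      start = trs$start[ti[qh]], end = trs$end[ti[qh]],
      region_class = regions$region_class[ri[sh]],
      overlap_bp = IRanges::width(IRanges::pintersect(tir[qh], rir[sh])),
      stringsAsFactors = FALSE)
    if (!is.null(regions$mrna_id)) res$mrna_id <- regions$mrna_id[ri[sh]]
    res
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}
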