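# File formats: FASTA, GFF3, the pipeline's own TR table (TSV) and BED6.
#
# Internal convention: all coordinates are 0-based half-open. GFF3 is 1-based
# inclusive and converted at this boundary only; BED6 is natively 0-based
# half-open. Sequences are stored as plain uppercase character strings keyed
# by sequence id.

.IUPAC <- "ACGTNRYSWKMBDHV"

#' Read a FASTA file
#'
#' Sequences are uppercased on ingest (soft-masked lowercase is treated as
#' ordinary sequence) and validated against the IUPAC nucleotide alphabet.
#' Line wrapping is irrelevant. Errors identify the offending line for
#' malformed input and reject duplicate ids and empty files.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase sequences (names are the
#'   first whitespace-delimited token of each header).
#' @seealso [write_fasta()], [valid_length()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0L) stop("FASTA format error: empty file: ", path,
                                call. = FALSE)
  hdr <- startsWith(lines, ">")
  if (!hdr[1])
    stop("FASTA format error at line 1: expected '>' header", call. = FALSE)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  if (any(!nzchar(ids)))
    stop("FASTA format error at line ", which(hdr & lines == ">")[1],
         ": empty sequence id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("FASTA format error: duplicate sequence id '",
         ids[duplicated(ids)][1], "'", call. = FALSE)
  body <- toupper(lines)
  bad <- !hdr & grepl(sprintf("[^%s]", .IUPAC), body)
  if (any(bad))
    stop("FASTA format error at line ", which(bad)[1],
         ": non-IUPAC character", call. = FALSE)
  grp <- cumsum(hdr)
  seqs <- vapply(split(body[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  out <- character(length(ids))
  names(out) <- ids
  out[as.integer(names(seqs))] <- seqs
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Count valid (A/C/G/T) nucleotides
#'
#' N and other ambiguity codes do not count: every length denominator in the
#' density statistics uses this count, not the raw string length.
#'
#' @param seqs character vector of sequences.
#' @return integer vector of valid-nucleotide counts.
#' @export
valid_length <- function(seqs) {
  vapply(seqs, function(s) sum(cpp_base_counts(s, 0L, nchar(s))),
         integer(1), USE.NAMES = !is.null(names(seqs)))
}

# --- coordinate conversion (its own inverse composed the other way) ---------

#' Convert between GFF3 (1-based inclusive) and internal (0-based half-open)
#'
#' @param start,end feature coordinates.
#' @return two-column matrix `start`, `end` in the other convention.
#' @export
gff_to_zero_based <- function(start, end) {
  cbind(start = as.integer(start) - 1L, end = as.integer(end))
}

#' @rdname gff_to_zero_based
#' @export
zero_based_to_gff <- function(start, end) {
  cbind(start = as.integer(start) + 1L, end = as.integer(end))
}

# --- gene models -------------------------------------------------------------

.sort_iv <- function(m) {
  if (is.null(m) || nrow(m) == 0L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  m <- m[order(m[, 1]), , drop = FALSE]
  colnames(m) <- c("start", "end")
  m
}

#' Read gene models from GFF3
#'
#' Parses canonical GFF3 (via `rtracklayer`) and assembles one gene model per
#' mRNA: gene span, sorted exons, CDS, and the 5'/3'-UTR intervals when
#' annotated (models without UTR rows are valid; region extraction then
#' anchors on the gene ends). All coordinates are converted to 0-based
#' half-open.
#'
#' @param path path to a GFF3 file with gene/mRNA/exon/CDS and optional
#'   five_prime_UTR/three_prime_UTR features linked by `ID`/`Parent`.
#' @return a list of gene models (class `gene_model_list`); each element has
#'   fields `gene_id`, `mrna_id`, `seq_id`, `strand`, `gene_span`, `exons`,
#'   `cds`, `five_utr`, `three_utr` (interval fields are 2-column matrices).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(gr$type),
    id = if (is.null(gr$ID)) NA_character_ else as.character(gr$ID),
    stringsAsFactors = FALSE)
  par <- gr$Parent
  df$parent <- if (is.null(par)) NA_character_ else
    vapply(as.list(par), function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))

  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  if (nrow(mrnas) == 0L)
    stop("annotation error: no mRNA features in ", path, call. = FALSE)

  models <- vector("list", nrow(mrnas))
  for (i in seq_len(nrow(mrnas))) {
    m <- mrnas[i, ]
    if (is.na(m$id))
      stop("annotation error: mRNA without ID attribute", call. = FALSE)
    if (!m$strand %in% c("+", "-"))
      stop("annotation error: unknown strand for feature '", m$id, "'",
           call. = FALSE)
    kids <- df[!is.na(df$parent) & df$parent == m$id, , drop = FALSE]
    iv <- function(type) .sort_iv(as.matrix(
      kids[kids$type == type, c("start", "end"), drop = FALSE]))
    exons <- iv("exon")
    if (nrow(exons) == 0L)
      stop("annotation error: mRNA '", m$id, "' has no exons", call. = FALSE)
    if (nrow(exons) > 1L && any(exons[-1, 1] < exons[-nrow(exons), 2]))
      stop("annotation error: overlapping exons in mRNA '", m$id, "'",
           call. = FALSE)
    for (ch in list(exons, iv("CDS"), iv("five_prime_UTR"), iv("three_prime_UTR")))
      if (nrow(ch) && (min(ch[, 1]) < m$start || max(ch[, 2]) > m$end))
        stop("annotation error: child interval outside mRNA '", m$id, "'",
             call. = FALSE)
    g <- genes[!is.na(genes$id) & genes$id == ifelse(is.na(m$parent), "", m$parent), ,
               drop = FALSE]
    gene_span <- if (nrow(g)) c(g$start[1], g$end[1]) else c(m$start, m$end)
    gene_id <- if (nrow(g)) g$id[1] else m$id
    models[[i]] <- structure(list(
      gene_id = gene_id, mrna_id = m$id, seq_id = m$seq_id,
      strand = m$strand, gene_span = gene_span,
      exons = exons, cds = iv("CDS"),
      five_utr = iv("five_prime_UTR"), three_utr = iv("three_prime_UTR")),
      class = "gene_model")
  }
  structure(models, class = "gene_model_list")
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon, CDS and UTR rows with 1-based inclusive
#' coordinates and `ID`/`Parent` attributes; `read_gff3()` round-trips the
#' result.
#'
#' @param models a `gene_model_list` (or list of gene models).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  rows <- list("##gff-version 3")
  fmt <- function(seq_id, type, s, e, strand, attr)
    sprintf("%s\ttrscape\t%s\t%d\t%d\t.\t%s\t.\t%s",
            seq_id, type, s + 1L, e, strand, attr)
  for (m in models) {
    rows[[length(rows) + 1L]] <-
      fmt(m$seq_id, "gene", m$gene_span[1], m$gene_span[2], m$strand,
          paste0("ID=", m$gene_id))
    rows[[length(rows) + 1L]] <-
      fmt(m$seq_id, "mRNA", min(m$exons[, 1]), max(m$exons[, 2]), m$strand,
          paste0("ID=", m$mrna_id, ";Parent=", m$gene_id))
    emit <- function(ivs, type) {
      for (k in seq_len(nrow(ivs)))
        rows[[length(rows) + 1L]] <<-
          fmt(m$seq_id, type, ivs[k, 1], ivs[k, 2], m$strand,
              paste0("ID=", m$mrna_id, ".", type, k, ";Parent=", m$mrna_id))
    }
    emit(m$exons, "exon")
    emit(m$cds, "CDS")
    emit(m$five_utr, "five_prime_UTR")
    emit(m$three_utr, "three_prime_UTR")
  }
  writeLines(unlist(rows), path)
  invisible(path)
}

# --- TR tables ---------------------------------------------------------------

.TR_COLS <- c("seq_id", "start", "end", "unit", "canonical_unit", "unit_len",
              "copies", "score", "perfect")

#' Construct / validate a tandem-repeat table
#'
#' The pipeline's working container for detected repeats: one row per TR with
#' 0-based half-open `start`/`end`, the observed (consensus) `unit`, its
#' `canonical_unit` motif class, real-valued `copies`, integer alignment
#' `score`, and a `perfect` flag.
#'
#' @param df data frame with at least the nine TR columns.
#' @return the data frame, column-ordered, with class `tr_table`.
#' @export
tr_table <- function(df) {
  miss <- setdiff(.TR_COLS, names(df))
  if (length(miss))
    stop("TR table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[, union(.TR_COLS, names(df)), drop = FALSE]
  class(df) <- c("tr_table", "data.frame")
  df
}

.empty_tr_table <- function() {
  tr_table(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), unit = character(0),
                      canonical_unit = character(0), unit_len = integer(0),
                      copies = numeric(0), score = integer(0),
                      perfect = logical(0), stringsAsFactors = FALSE))
}

#' Write / read a TR table (TSV)
#'
#' Tab-separated with a header and the nine standard columns; coordinates
#' stay 0-based half-open. `read_tr_table(write_tr_table(x))` is lossless.
#'
#' @param trs a `tr_table`.
#' @param path file path.
#' @return `path` invisibly (write); a `tr_table` (read).
#' @export
write_tr_table <- function(trs, path) {
  trs <- tr_table(as.data.frame(trs))
  write.table(trs[, .TR_COLS, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tr_table
#' @export
read_tr_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(seq_id = "character", unit = "character",
                                  canonical_unit = "character"))
  df$perfect <- as.logical(df$perfect)
  tr_table(df)
}

#' Write TRs as BED6
#'
#' 0-based half-open; name = canonical unit, score = alignment score,
#' strand = "+" (detection is strand-agnostic).
#'
#' @inheritParams write_tr_table
#' @export
write_bed <- function(trs, path) {
  trs <- as.data.frame(trs)
  bed <- data.frame(trs$seq_id, trs$start, trs$end, trs$canonical_unit,
                    trs$score, rep("+", nrow(trs)))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write labeled genomic regions as BED6
#'
#' @param regions region data frame from [extract_regions()].
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(regions$seq_id, regions$start, regions$end,
                    regions$region_class, 0L, regions$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
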