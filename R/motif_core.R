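# Motif algebra: canonical rotations, primitive units, reverse complements,
# GC content. Motif classes keep a motif and its reverse complement separate
# (genes live on both strands); motif_pair_label() gives the joint
# "AAG/CTT"-style display form.

.check_motif <- function(unit, what = "motif") {
  if (length(unit) == 0L) return(invisible(unit))
  if (anyNA(unit) || any(!nzchar(unit)))
    stop(what, " must be a nonempty A/C/G/T string", call. = FALSE)
  if (any(grepl("[^ACGT]", unit)))
    stop(what, " contains characters outside A/C/G/T", call. = FALSE)
  invisible(unit)
}

.rotations <- function(x) {
  n <- nchar(x)
  if (n == 1L) return(x)
  xx <- paste0(x, x)
  vapply(seq_len(n), function(k) substr(xx, k, k + n - 1L), character(1))
}

#' Canonical rotation of a repeat motif
#'
#' Returns the lexicographically smallest cyclic rotation (ASCII order,
#' A < C < G < T), the representative used for motif classes: among
#' `AAG`, `AGA`, `GAA` the canonical form is `AAG`. Idempotent and invariant
#' under any rotation of the input. A motif and its reverse complement are
#' *not* merged; see [reverse_complement()] and [motif_pair_label()].
#'
#' @param unit character vector of A/C/G/T motif strings.
#' @return character vector of canonical rotations.
#' @examples
#' canonical_rotation(c("AGA", "GAA", "A"))
#' @export
canonical_rotation <- function(unit) {
  unit <- toupper(as.character(unit))
  .check_motif(unit)
  vapply(unit, function(x) min(.rotations(x)), character(1), USE.NAMES = FALSE)
}

#' Primitive (smallest-period) unit of a motif
#'
#' Reduces a motif to its smallest repeating period using the KMP border
#' function: `"ATAT"` reduces to `"AT"`, `"AAAAAA"` to `"A"`; a primitive
#' motif is returned unchanged. The result's smallest period equals its
#' length, and its length always divides the input length.
#'
#' @inheritParams canonical_rotation
#' @return character vector of primitive units.
#' @examples
#' primitive_unit(c("ATAT", "AAG", "AAAAAA"))
#' @export
primitive_unit <- function(unit) {
  unit <- toupper(as.character(unit))
  .check_motif(unit)
  vapply(unit, function(x) {
    n <- nchar(x)
    if (n == 1L) return(x)
    v <- strsplit(x, "", fixed = TRUE)[[1]]
    f <- integer(n + 1L)
    k <- 0L
    for (i in 2:n) {
      while (k > 0L && v[i] != v[k + 1L]) k <- f[k + 1L]
      if (v[i] == v[k + 1L]) k <- k + 1L
      f[i + 1L] <- k
    }
    p <- n - f[n + 1L]
    if (n %% p == 0L) substr(x, 1L, p) else x
  }, character(1), USE.NAMES = FALSE)
}

#' Reverse complement of a motif or sequence
#'
#' Watson-Crick reverse complement over A/C/G/T. An involution:
#' `reverse_complement(reverse_complement(x)) == x`.
#'
#' @inheritParams canonical_rotation
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("AAG") # "CTT"
#' @export
reverse_complement <- function(unit) {
  unit <- toupper(as.character(unit))
  .check_motif(unit, "sequence")
  comp <- chartr("ACGT", "TGCA", unit)
  vapply(comp, function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                 collapse = ""),
         character(1), USE.NAMES = FALSE)
}

#' GC content of a sequence
#'
#' 100 * (#G + #C) / (#A + #C + #G + #T). Only valid nucleotides enter the
#' denominator; N and other IUPAC ambiguity codes are ignored. Errors when a
#' sequence contains no valid nucleotide at all (the content is undefined).
#'
#' @param seq character vector of nucleotide strings (any IUPAC letters).
#' @return numeric vector of GC percentages.
#' @examples
#' gc_content("ATGCN") # 50
#' @export
gc_content <- function(seq) {
  seq <- toupper(as.character(seq))
  vapply(seq, function(x) {
    cnt <- cpp_base_counts(x, 0L, nchar(x))
    tot <- sum(cnt)
    if (tot == 0L)
      stop("GC content undefined: no valid (A/C/G/T) nucleotides", call. = FALSE)
    100 * (cnt[1, "G"] + cnt[1, "C"]) / tot
  }, numeric(1), USE.NAMES = FALSE)
}

#' Joint display label for a motif and its reverse complement
#'
#' Motif classes are counted separately by strand, but survey tables
#' conventionally display the pair jointly ("AAG/CTT"). Palindromic classes
#' (e.g. "AT") collapse to a single label.
#'
#' @inheritParams canonical_rotation
#' @return character vector of display labels.
#' @examples
#' motif_pair_label(c("AAG", "AT"))
#' @export
motif_pair_label <- function(unit) {
  unit <- canonical_rotation(unit)
  rc <- canonical_rotation(reverse_complement(unit))
  ifelse(rc == unit, unit, paste0(unit, "/", rc))
}
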