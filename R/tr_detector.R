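# Tandem-repeat detection: Phobos-style perfect + imperfect search with unit
# sizes 1-50 bp, minimum repeat length 12 nt and minimum alignment score 12.
#
# Perfect TRs are maximal primitive tandem runs. Imperfect detection is
# seed-and-extend: maximal perfect runs (>= 2 exact copies, relaxed length
# floor) are extended in both directions by wraparound dynamic programming
# under a score drop-off rule, the arg-max window is re-scored with free
# phases, and overlapping candidate calls are resolved by score.

#' Scoring scheme for repeat alignments
#'
#' The published thresholds fix only the minimum score (12); the alignment
#' scheme itself is configurable. The defaults (+1 match, -4 mismatch,
#' -4 indel) make a perfect repeat's score equal its length, so the 12-nt
#' length and score-12 thresholds coincide on perfect repeats.
#'
#' @param match positive per-base match reward.
#' @param mismatch,indel negative penalties.
#' @return list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -4L, indel = -4L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  indel <- as.integer(indel)
  if (match <= 0L) stop("match reward must be positive", call. = FALSE)
  if (mismatch >= 0L || indel >= 0L)
    stop("mismatch and indel penalties must be negative", call. = FALSE)
  structure(list(match = match, mismatch = mismatch, indel = indel),
            class = "scoring_scheme")
}

#' Detector configuration
#'
#' @param max_unit largest repeat unit size considered (1-50).
#' @param min_length minimum total repeat length in nt.
#' @param min_score minimum alignment score.
#' @param scheme a [scoring_scheme()].
#' @param dropoff score drop-off that terminates seed extension (default
#'   4x|mismatch|; generous enough that alignments with locally clustered
#'   mismatches near the score threshold are not truncated).
#' @param seed_floor minimum seed length in nt (seeds always also need two
#'   exact unit copies).
#' @return list of class `detect_config`.
#' @export
detect_config <- function(max_unit = 50L, min_length = 12L, min_score = 12L,
                          scheme = scoring_scheme(), dropoff = NULL,
                          seed_floor = 5L) {
  if (max_unit < 1L || max_unit > 50L)
    stop("max_unit must be in 1..50", call. = FALSE)
  if (min_length <= 0L || min_score <= 0L)
    stop("thresholds must be positive", call. = FALSE)
  if (is.null(dropoff)) dropoff <- 4L * abs(scheme$mismatch)
  structure(list(max_unit = as.integer(max_unit),
                 min_length = as.integer(min_length),
                 min_score = as.integer(min_score), scheme = scheme,
                 dropoff = as.integer(dropoff),
                 seed_floor = as.integer(seed_floor)),
            class = "detect_config")
}

.as_seqs <- function(seqs) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  toupper(seqs)
}

#' Detect perfect tandem repeats
#'
#' Enumerates every maximal run `u^k p` (u primitive, p a proper prefix of u)
#' with at least two full copies and total length >= `min_length`. Maximal
#' means not extendable by one base on either side; runs never span non-ACGT
#' residues. The score of a perfect run is its length times the match reward.
#'
#' @param seqs named character vector of sequences.
#' @param max_unit largest unit size (1-50).
#' @param min_length minimum repeat length (default 12).
#' @param match_reward per-base match reward used for the score.
#' @return a [tr_table()] sorted by sequence and start.
#' @examples
#' detect_perfect(c(s1 = "AAGAAGAAGAAG"))
#' @export
detect_perfect <- function(seqs, max_unit = 50L, min_length = 12L,
                           match_reward = 1L) {
  seqs <- .as_seqs(seqs)
  out <- lapply(seq_along(seqs), function(i) {
    d <- cpp_detect_perfect(seqs[[i]], as.integer(max_unit),
                            as.integer(min_length))
    if (nrow(d) == 0L) return(NULL)
    d$seq_id <- names(seqs)[i]
    d
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(.empty_tr_table())
  len <- out$end - out$start
  ul <- nchar(out$unit)
  trs <- data.frame(seq_id = out$seq_id, start = out$start, end = out$end,
                    unit = out$unit,
                    canonical_unit = canonical_rotation(out$unit),
                    unit_len = ul, copies = len / ul,
                    score = len * as.integer(match_reward),
                    perfect = TRUE, stringsAsFactors = FALSE)
  trs <- trs[order(trs$seq_id, trs$start, trs$unit_len), , drop = FALSE]
  rownames(trs) <- NULL
  tr_table(trs)
}

#' Align a window against indefinite repetitions of a unit
#'
#' Optimal global (in the window) wraparound alignment against `u^Inf` with
#' free start and end phase, computed by dynamic programming over
#' |window| x |unit| with column-wrap transitions. Returns the optimal score
#' and the match/mismatch/indel counts realizing it, plus the per-column
#' majority consensus of the aligned copies.
#'
#' @param window A/C/G/T string to score.
#' @param unit repeat unit (A/C/G/T).
#' @param scheme a [scoring_scheme()].
#' @return list with `score`, `n_match`, `n_mismatch`, `n_indel`,
#'   `consensus` (same length as `unit`) and `start_phase`.
#' @examples
#' align_against_perfect("AAGAAG", "AAG")$score # 6
#' @export
align_against_perfect <- function(window, unit, scheme = scoring_scheme()) {
  window <- toupper(window); unit <- toupper(unit)
  if (!nzchar(window)) stop("window must be nonempty", call. = FALSE)
  if (grepl("[^ACGT]", window))
    stop("window contains characters outside A/C/G/T", call. = FALSE)
  .check_motif(unit, "unit")
  cpp_align_repeat(window, unit, scheme$match, scheme$mismatch, scheme$indel)
}

#' Detect perfect and imperfect tandem repeats
#'
#' Seed-and-extend detection. Every reported TR satisfies all thresholds:
#' length >= `min_length`, score >= `min_score`, at least two copies, and a
#' primitive unit; `perfect` is `TRUE` iff the optimal alignment has no
#' mismatch and no indel. The reported `unit` is the majority consensus
#' across aligned copies, rotated to the phase observed at the repeat start;
#' `canonical_unit` is its canonical rotation. Overlapping candidate calls
#' (>= 50% of the shorter span) are resolved by score via
#' [resolve_overlaps()]. Repeats never span non-ACGT residues.
#'
#' @param seqs named character vector of sequences.
#' @param config a [detect_config()].
#' @return a [tr_table()] sorted by sequence and start.
#' @examples
#' detect(c(s = "AAGAAGAAGAAGTTTTTTTTTTTTTT"), detect_config(max_unit = 6))
#' @export
detect <- function(seqs, config = detect_config()) {
  seqs <- .as_seqs(seqs)
  sch <- config$scheme
  pieces <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    if (nchar(s) < config$min_length) return(NULL)
    d <- cpp_detect(s, config$max_unit, config$min_length, config$min_score,
                    sch$match, sch$mismatch, sch$indel, config$dropoff,
                    config$seed_floor)
    if (nrow(d) == 0L) return(NULL)
    d$seq_id <- names(seqs)[i]

    # consensus units are occasionally non-primitive; re-score against the
    # reduced unit so unit-size statistics stay well defined
    prim <- primitive_unit(d$unit)
    redo <- which(nchar(prim) < nchar(d$unit))
    for (k in redo) {
      a <- cpp_align_repeat(substr(s, d$start[k] + 1L, d$end[k]), prim[k],
                            sch$match, sch$mismatch, sch$indel)
      d$unit[k] <- paste0(substr(a$consensus, a$start_phase + 1L, nchar(prim[k])),
                          substr(a$consensus, 1L, a$start_phase))
      d$score[k] <- a$score
      d$n_match[k] <- a$n_match; d$n_mismatch[k] <- a$n_mismatch
      d$n_indel[k] <- a$n_indel
    }
    d
  })
  d <- do.call(rbind, pieces)
  if (is.null(d)) return(.empty_tr_table())

  len <- d$end - d$start
  ul <- nchar(d$unit)
  keep <- len >= config$min_length & d$score >= config$min_score &
    len >= 2L * ul
  d <- d[keep, , drop = FALSE]
  if (nrow(d) == 0L) return(.empty_tr_table())
  d <- d[!duplicated(d[, c("seq_id", "start", "end", "unit")]), , drop = FALSE]

  len <- d$end - d$start
  ul <- nchar(d$unit)
  trs <- tr_table(data.frame(
    seq_id = d$seq_id, start = d$start, end = d$end, unit = d$unit,
    canonical_unit = canonical_rotation(d$unit), unit_len = ul,
    copies = len / ul, score = d$score,
    perfect = d$n_mismatch == 0L & d$n_indel == 0L,
    n_match = d$n_match, n_mismatch = d$n_mismatch, n_indel = d$n_indel,
    stringsAsFactors = FALSE))
  resolve_overlaps(trs)
}

#' Resolve overlapping repeat calls
#'
#' Among candidates whose spans overlap at least 50% of the shorter span,
#' keeps the highest score; ties prefer the smaller unit, then the leftmost
#' start. The kept set is pairwise below the overlap threshold.
#'
#' @param trs a [tr_table()] of candidates.
#' @param threshold overlap fraction of the shorter span that triggers
#'   resolution (default 0.5).
#' @return filtered [tr_table()] sorted by sequence and start.
#' @export
resolve_overlaps <- function(trs, threshold = 0.5) {
  trs <- as.data.frame(trs)
  if (nrow(trs) <= 1L) {
    rownames(trs) <- NULL
    return(tr_table(trs))
  }
  keep <- logical(nrow(trs))
  for (sid in unique(trs$seq_id)) {
    idx <- which(trs$seq_id == sid)
    ir <- IRanges::IRanges(start = trs$start[idx] + 1L, end = trs$end[idx])
    hits <- IRanges::findOverlaps(ir, ir)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    off <- qh != sh
    qh <- qh[off]; sh <- sh[off]
    ov <- IRanges::width(IRanges::pintersect(ir[qh], ir[sh]))
    shorter <- pmin(IRanges::width(ir)[qh], IRanges::width(ir)[sh])
    conflict <- ov >= threshold * shorter
    adj <- split(sh[conflict], qh[conflict])
    pri <- order(-trs$score[idx], trs$unit_len[idx], trs$start[idx],
                 trs$end[idx])
    taken <- logical(length(idx))
    for (k in pri) {
      nb <- adj[[as.character(k)]]
      if (is.null(nb) || !any(taken[nb])) taken[k] <- TRUE
    }
    keep[idx[taken]] <- TRUE
  }
  out <- trs[keep, , drop = FALSE]
  out <- out[order(out$seq_id, out$start, out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  tr_table(out)
}
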