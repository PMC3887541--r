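# Independent oracles: everything here is deliberately written against the
# definitions, not against the package internals, so the two routes can
# disagree when one of them is wrong.

random_seq <- function(n, gc = 50) {
  g <- gc / 100
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)),
        collapse = "")
}

# Smallest-period check by direct divisor enumeration (no border function).
oracle_is_primitive <- function(unit) {
  n <- nchar(unit)
  if (n == 1L) return(TRUE)
  for (p in seq_len(n - 1L)) {
    if (n %% p == 0L && strrep(substr(unit, 1L, p), n / p) == unit)
      return(FALSE)
  }
  TRUE
}

# Brute-force enumeration of maximal primitive tandem runs: for each unit
# size u, positions where s[i] == s[i+u] (both valid) form runs via rle();
# a run of r matches is a span of length r + u, kept when it has >= 2 full
# copies (r >= u), length >= min_length, and a primitive leading unit.
oracle_detect_perfect <- function(seq, max_unit, min_length = 12L) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  valid <- v %in% c("A", "C", "G", "T")
  rows <- list()
  for (u in seq_len(min(max_unit, n %/% 2L))) {
    if (n - u < 1L) break
    m <- valid[1:(n - u)] & valid[(u + 1L):n] & v[1:(n - u)] == v[(u + 1L):n]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= u)) {
      len <- r$lengths[k] + u
      if (len < min_length) next
      unit <- substr(seq, starts[k], starts[k] + u - 1L)
      if (!oracle_is_primitive(unit)) next
      rows[[length(rows) + 1L]] <-
        data.frame(start = starts[k] - 1L, end = starts[k] - 1L + len,
                   unit = unit, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0), unit = character(0))
  out[order(out$start, nchar(out$unit), out$unit), , drop = FALSE]
}

# Exhaustive fitting DP of a window against a linearly replicated unit with
# free start/end position in the reference: the independent route to the
# wraparound alignment score.
oracle_align_score <- function(window, unit, match = 1, mismatch = -4,
                               indel = -4) {
  w <- strsplit(window, "", fixed = TRUE)[[1]]
  m <- length(w)
  reps <- ceiling(2 * m / nchar(unit)) + 2L
  ref <- strsplit(strrep(unit, reps), "", fixed = TRUE)[[1]]
  L <- length(ref)
  prev <- rep(0, L + 1L) # free start anywhere in the reference
  for (i in seq_len(m)) {
    sub <- ifelse(w[i] == ref, match, mismatch)
    tmp <- pmax(prev[1:L] + sub, prev[2:(L + 1L)] + indel)
    row <- numeric(L + 1L)
    row[1] <- prev[1] + indel
    for (j in 1:L) row[j + 1L] <- max(tmp[j], row[j] + indel)
    prev <- row
  }
  max(prev)
}

# Local variant (free start AND free end in the window as well): the best
# alignment score of any subwindow against any stretch of u^inf. Used to
# decide whether a mutated array still contains a reportable repeat.
oracle_best_local_score <- function(window, unit, match = 1, mismatch = -4,
                                    indel = -4) {
  w <- strsplit(window, "", fixed = TRUE)[[1]]
  m <- length(w)
  reps <- ceiling(2 * m / nchar(unit)) + 2L
  ref <- strsplit(strrep(unit, reps), "", fixed = TRUE)[[1]]
  L <- length(ref)
  prev <- rep(0, L + 1L)
  best <- 0
  for (i in seq_len(m)) {
    sub <- ifelse(w[i] == ref, match, mismatch)
    tmp <- pmax(prev[1:L] + sub, prev[2:(L + 1L)] + indel)
    tmp <- pmax(tmp, 0) # local: restart anywhere in the window
    row <- numeric(L + 1L)
    for (j in 1:L) row[j + 1L] <- max(tmp[j], row[j] + indel)
    prev <- row
    best <- max(best, max(row))
  }
  best
}

# Best reportable score within an array: maximum local score over every
# primitive unit (length <= max_u) occurring as a substring.
oracle_best_array_score <- function(array, max_u = 4L, ...) {
  n <- nchar(array)
  units <- unique(unlist(lapply(seq_len(min(max_u, n)), function(u)
    unique(substring(array, 1:(n - u + 1L), u:n)))))
  units <- units[vapply(units, oracle_is_primitive, logical(1))]
  max(vapply(units, function(u) oracle_best_local_score(array, u, ...),
             numeric(1)))
}

tr_key <- function(df) paste(df$seq_id, df$start, df$end, df$canonical_unit)
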