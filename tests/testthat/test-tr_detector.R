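test_that("detect_perfect finds maximal primitive runs above thresholds", {
  expect_equal(as.data.frame(detect_perfect(c(s1 = "AAGAAGAAGAAG"))),
               data.frame(seq_id = "s1", start = 0L, end = 12L, unit = "AAG",
                          canonical_unit = "AAG", unit_len = 3L, copies = 4,
                          score = 12L, perfect = TRUE,
                          stringsAsFactors = FALSE))
  # 11 nt is below the 12-nt minimum
  expect_equal(nrow(detect_perfect(c(s1 = "AAGAAGAAGAA"))), 0)
  # partial trailing copy counts toward length and copy number
  acgt <- detect_perfect(c(s1 = "ACGTACGTACGTAC"))
  expect_equal(acgt$start, 0)
  expect_equal(acgt$end, 14)
  expect_equal(acgt$unit, "ACGT")
  expect_equal(acgt$copies, 3.5)
  expect_equal(acgt$score, 14)
  # an N breaks a run
  expect_equal(nrow(detect_perfect(c(s = "AAAAAANAAAAAA"))), 0)
  expect_equal(nrow(detect_perfect(c(s = ""))), 0)
})

test_that("detect_perfect matches the brute-force oracle on random sequence", {
  set.seed(31)
  for (i in 1:40) {
    s <- random_seq(600)
    got <- as.data.frame(detect_perfect(c(x = s), max_unit = 6))
    want <- oracle_detect_perfect(s, max_unit = 6)
    got <- got[order(got$start, got$unit_len, got$unit),
               c("start", "end", "unit")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("align_against_perfect scores perfect and mutated windows", {
  a <- align_against_perfect("AAGAAG", "AAG")
  expect_equal(a[c("score", "n_match", "n_mismatch", "n_indel")],
               list(score = 6L, n_match = 6L, n_mismatch = 0L, n_indel = 0L))
  # 21-nt window, one substitution: 20 matches - 4
  a <- align_against_perfect("AAGAAGAAGTAGAAGAAGAAG", "AAG")
  expect_equal(a$score, 16)
  expect_equal(a$n_mismatch, 1)
  # one deletion: 8 matches + 1 indel under (+1,-4,-4); the exhaustive DP
  # oracle confirms 4 (all eight window bases align as matches)
  a <- align_against_perfect("AAGAGAAG", "AAG")
  expect_equal(a$score, oracle_align_score("AAGAGAAG", "AAG"))
  expect_equal(a$score, 4)
  expect_equal(a$n_indel, 1)
  expect_error(align_against_perfect("AANG", "A"), "A/C/G/T")
  expect_error(align_against_perfect("", "A"), "nonempty")
})

test_that("align_against_perfect equals the exhaustive DP oracle", {
  set.seed(32)
  schemes <- list(scoring_scheme(), scoring_scheme(2L, -3L, -5L))
  for (i in 1:150) {
    u <- paste(sample(c("A", "C", "G", "T"), sample(1:10, 1), replace = TRUE),
               collapse = "")
    w <- if (i %% 2 == 0) random_seq(sample(5:60, 1)) else
      substitute_bases(substr(strrep(u, 20), 1, sample(5:60, 1)),
                       sample(0:3, 1))
    sch <- schemes[[1 + i %% 2]]
    expect_identical(
      align_against_perfect(w, u, sch)$score,
      as.integer(oracle_align_score(w, u, sch$match, sch$mismatch,
                                    sch$indel)),
      label = paste("window", w, "unit", u))
    # reported counts realize the score
    a <- align_against_perfect(w, u, sch)
    expect_equal(a$score, a$n_match * sch$match + a$n_mismatch * sch$mismatch +
                   a$n_indel * sch$indel)
  }
})

test_that("detect recovers a planted imperfect array with the oracle score", {
  set.seed(33)
  arr <- strrep("AAG", 10)
  substr(arr, 14, 14) <- "T" # one substitution in copy 5
  bg <- random_seq(1000)
  # plant at a fixed offset and break the flanking period so the planted
  # span is the maximal repeat
  s <- paste0(substr(bg, 1, 400), "C", arr, "C", substr(bg, 433, 1000))
  trs <- detect(c(chr = s), detect_config(max_unit = 6))
  hit <- trs[trs$start <= 401 & trs$end >= 431, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 401)
  expect_equal(hit$end, 431)
  expect_false(hit$perfect)
  expect_equal(hit$score, 25) # 29 matches - 1 mismatch
  expect_equal(hit$score, as.integer(oracle_align_score(arr, "AAG")))
  expect_equal(hit$canonical_unit, "AAG")
})

test_that("detect handles degenerate inputs", {
  expect_equal(nrow(detect(c(s = strrep("N", 200)))), 0)
  expect_equal(nrow(detect(c(s = "ACGTACG"))), 0) # shorter than min_length
  homo <- detect(c(s = strrep("A", 100)))
  expect_equal(nrow(homo), 1)
  expect_equal(homo$unit, "A") # primitivity forces unit A, not AA
  expect_equal(homo$start, 0)
  expect_equal(homo$end, 100)
  expect_equal(homo$score, 100)
})

test_that("every reported TR satisfies the configured thresholds", {
  set.seed(34)
  for (i in 1:8) {
    s <- random_seq(3000, gc = sample(c(30, 50, 65), 1))
    cfg <- detect_config(max_unit = 25, min_length = sample(12:20, 1),
                         min_score = sample(12:16, 1))
    trs <- detect(c(x = s), cfg)
    if (nrow(trs) == 0) next
    expect_true(all(trs$end - trs$start >= cfg$min_length))
    expect_true(all(trs$score >= cfg$min_score))
    expect_true(all(trs$copies >= 2))
    expect_identical(primitive_unit(trs$unit), trs$unit)
    expect_identical(canonical_rotation(trs$unit), trs$canonical_unit)
    expect_true(all(!grepl("[^ACGT]",
                           substring(s, trs$start + 1, trs$end))))
  }
})

test_that("raising thresholds never adds a repeat", {
  set.seed(35)
  for (i in 1:6) {
    s <- c(x = random_seq(2000, gc = 40))
    loose <- detect(s, detect_config(max_unit = 10))
    strict1 <- detect(s, detect_config(max_unit = 10, min_score = 16))
    strict2 <- detect(s, detect_config(max_unit = 10, min_length = 16))
    expect_true(all(tr_key(strict1) %in% tr_key(loose)))
    expect_true(all(tr_key(strict2) %in% tr_key(loose)))
  }
})

test_that("detection is deterministic and strand-symmetric", {
  set.seed(36)
  arrays <- c(strrep("AAG", 8), strrep("ACGT", 5), strrep("A", 15),
              {a <- strrep("AGC", 9); substr(a, 13, 13) <- "T"; a})
  s <- paste(arrays, collapse = strrep("N", 20))
  n <- nchar(s)
  fwd <- detect(c(x = s))
  expect_identical(fwd, detect(c(x = s)))
  rev <- detect(c(x = chartr("ACGT", "TGCA",
                             paste(rev(strsplit(s, "")[[1]]), collapse = ""))))
  expect_equal(nrow(rev), nrow(fwd))
  mirrored <- data.frame(start = n - rev$end, end = n - rev$start,
                         cls = canonical_rotation(reverse_complement(rev$unit)))
  mirrored <- mirrored[order(mirrored$start), ]
  expect_equal(mirrored$start, fwd$start)
  expect_equal(mirrored$end, fwd$end)
  expect_equal(mirrored$cls, fwd$canonical_unit)
  # perfect detection is strand-symmetric on arbitrary random sequence
  for (i in 1:10) {
    r <- random_seq(800)
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(r, "")[[1]]),
                                       collapse = ""))
    f <- as.data.frame(detect_perfect(c(x = r), max_unit = 8))
    b <- as.data.frame(detect_perfect(c(x = rc), max_unit = 8))
    expect_equal(sort(800 - b$end), sort(f$start))
    expect_equal(sort(canonical_rotation(reverse_complement(b$unit))),
                 sort(f$canonical_unit))
  }
})

test_that("resolve_overlaps keeps the best call per overlapping cluster", {
  mk <- function(start, end, unit, score)
    data.frame(seq_id = "s", start = start, end = end, unit = unit,
               canonical_unit = canonical_rotation(unit),
               unit_len = nchar(unit), copies = (end - start) / nchar(unit),
               score = score, perfect = TRUE, stringsAsFactors = FALSE)
  # disjoint calls are all kept
  two <- tr_table(rbind(mk(0, 12, "A", 12), mk(50, 62, "AG", 12)))
  expect_equal(nrow(resolve_overlaps(two)), 2)
  # nested lower-scoring call inside a higher-scoring one is dropped
  nest <- tr_table(rbind(mk(10, 40, "ACG", 30), mk(15, 29, "AC", 14)))
  out <- resolve_overlaps(nest)
  expect_equal(nrow(out), 1)
  expect_equal(out$unit, "ACG")
  # tie on score prefers the smaller unit, then the leftmost start
  tie <- tr_table(rbind(mk(0, 12, "ACGT", 12), mk(0, 12, "AC", 12)))
  expect_equal(resolve_overlaps(tie)$unit, "AC")
  # below-threshold overlap (< 50% of the shorter) keeps both
  brush <- tr_table(rbind(mk(0, 20, "AC", 20), mk(16, 36, "AG", 20)))
  expect_equal(nrow(resolve_overlaps(brush)), 2)
  # pairwise-below-threshold postcondition on a crafted pile-up
  set.seed(37)
  pile <- tr_table(do.call(rbind, lapply(1:30, function(i) {
    s <- sample(0:150, 1)
    mk(s, s + sample(c(12, 16, 24), 1), sample(c("A", "AC", "ACG"), 1),
       sample(12:30, 1))
  })))
  out <- resolve_overlaps(pile)
  if (nrow(out) > 1) {
    for (i in 1:(nrow(out) - 1)) for (j in (i + 1):nrow(out)) {
      ov <- max(0, min(out$end[i], out$end[j]) - max(out$start[i], out$start[j]))
      shorter <- min(out$end[i] - out$start[i], out$end[j] - out$start[j])
      expect_lt(ov, 0.5 * shorter)
    }
  }
})
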