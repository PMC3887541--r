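small_spec <- function(...) {
  simulation_spec(sequence_length = 60000, genes_per_sequence = 6, ...)
}

test_that("simulation is a deterministic function of (spec, seed)", {
  spec <- small_spec(plan = list(FIVE_UTR = 20000, CDS = 5000))
  s1 <- simulate_genome(spec, seed = 5)
  s2 <- simulate_genome(spec, seed = 5)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$truth, s2$truth)
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in c("genome.fasta", "genes.gff3", "truth.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  s3 <- simulate_genome(spec, seed = 6)
  expect_false(identical(s1$sequences, s3$sequences))
})

test_that("truth table recounts exactly against the emitted sequence", {
  spec <- small_spec(plan = list(FIVE_UTR = 25000, UI200 = 20000),
                     imperfection_rate = 0.2)
  sim <- simulate_genome(spec, seed = 9)
  expect_gt(nrow(sim$truth), 0)
  regions <- extract_all_regions(sim$models, sim$sequences)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    planted <- substr(sim$sequences[[tr$seq_id]], tr$start + 1, tr$end)
    if (tr$perfect) {
      expect_identical(planted, strrep(tr$unit, tr$copies))
    } else {
      # replay the mutation log on the pristine array
      arr <- strsplit(strrep(tr$unit, tr$copies), "")[[1]]
      ev <- strsplit(strsplit(tr$mutations, ";")[[1]], ":")
      subs <- Filter(function(e) e[1] == "sub", ev)
      for (e in subs) arr[as.integer(e[2]) + 1] <- sub(".*>", "", e[3])
      idl <- Filter(function(e) e[1] != "sub", ev)
      ord <- order(-vapply(idl, function(e) as.integer(e[2]), numeric(1)))
      for (e in idl[ord]) {
        off <- as.integer(e[2])
        if (e[1] == "del") arr <- arr[-(off + 1)]
        else arr <- append(arr, sub(".*>", "", e[3]), after = off)
      }
      expect_identical(planted, paste(arr, collapse = ""))
    }
    # planted inside the targeted region class
    hit <- regions[regions$region_class == tr$region_class &
                     regions$seq_id == tr$seq_id &
                     regions$start <= tr$start & regions$end >= tr$end, ]
    expect_gt(nrow(hit), 0)
    # thresholds hold pre-mutation
    expect_gte(tr$copies, 2)
    expect_gte(tr$unit_len * tr$copies, 12)
  }
  # planted spans are pairwise disjoint
  tt <- sim$truth[order(sim$truth$seq_id, sim$truth$start), ]
  same <- tt$seq_id[-1] == tt$seq_id[-nrow(tt)]
  expect_true(all(tt$start[-1][same] >= tt$end[-nrow(tt)][same]))
})

test_that("mutate_array logs reconstruct the mutation and its score", {
  no <- mutate_array(strrep("AAG", 5), rate = 0)
  expect_identical(no$seq, strrep("AAG", 5))
  expect_equal(nrow(no$log), 0)
  # deterministic under a seed
  m1 <- mutate_array(strrep("ACG", 10), rate = 0.5, seed = 3)
  m2 <- mutate_array(strrep("ACG", 10), rate = 0.5, seed = 3)
  expect_identical(m1, m2)
  # a single logged substitution reproduces the oracle-scored outcome:
  # 30 nt with one substitution scores 29 - 4 = 25 under (+1,-4,-4)
  set.seed(54)
  repeat {
    m <- mutate_array(strrep("AAG", 10), rate = 0.1)
    if (nrow(m$log) == 1 && m$log$type == "sub") break
  }
  expect_equal(oracle_align_score(m$seq, "AAG"), 25)
  expect_equal(align_against_perfect(m$seq, "AAG")$score, 25)
  # indels are applied and logged consistently
  set.seed(55)
  m <- mutate_array(strrep("ACGT", 8), rate = 0, indel_rate = 0.4)
  delta <- sum(m$log$type == "ins") - sum(m$log$type == "del")
  expect_equal(nchar(m$seq), 32 + delta)
})

test_that("planting respects target densities and motif GC matching", {
  spec <- simulation_spec(sequence_length = 200000, genes_per_sequence = 0,
                          plan = list(GENOME = 12000))
  sim <- simulate_genome(spec, seed = 13)
  planted <- sum(sim$truth$end - sim$truth$start)
  target <- 12000 / 1e6 * 200000
  expect_gte(planted, target)
  expect_lte(planted, target + 50 * 3) # overshoot bounded by one array
  # GC-matched pools: high-GC background receives GC-rich motifs
  hi <- simulate_genome(simulation_spec(sequence_length = 50000,
                                        genes_per_sequence = 0,
                                        background_gc = 62,
                                        plan = list(GENOME = 10000)),
                        seed = 14)
  expect_gte(mean(vapply(hi$truth$unit, gc_content, numeric(1))), 55)
  lo <- simulate_genome(simulation_spec(sequence_length = 50000,
                                        genes_per_sequence = 0,
                                        background_gc = 35,
                                        plan = list(GENOME = 10000)),
                        seed = 14)
  expect_lte(mean(vapply(lo$truth$unit, gc_content, numeric(1))), 45)
})

test_that("gene models carry the specified UTR widths on both strands", {
  spec <- small_spec()
  sim <- simulate_genome(spec, seed = 17)
  strands <- vapply(sim$models, `[[`, character(1), "strand")
  expect_true(all(c("+", "-") %in% strands)) # both strands exercised
  for (m in sim$models) {
    expect_equal(unname(m$five_utr[, 2] - m$five_utr[, 1]),
                 spec$five_utr_length)
    expect_equal(unname(m$three_utr[, 2] - m$three_utr[, 1]),
                 spec$three_utr_length)
    # UTRs sit at the transcript ends in transcription orientation
    if (m$strand == "+") {
      expect_equal(unname(m$five_utr[1, 1]), m$gene_span[1])
      expect_equal(unname(m$three_utr[1, 2]), m$gene_span[2])
    } else {
      expect_equal(unname(m$five_utr[1, 2]), m$gene_span[2])
      expect_equal(unname(m$three_utr[1, 1]), m$gene_span[1])
    }
    # CDS + UTRs tile the exons exactly
    expect_equal(sum(m$exons[, 2] - m$exons[, 1]),
                 sum(m$cds[, 2] - m$cds[, 1]) + spec$five_utr_length +
                   spec$three_utr_length)
  }
})

test_that("infeasible plans raise capacity errors naming the class", {
  expect_error(
    simulate_genome(small_spec(plan = list(FIVE_UTR = 900000)), seed = 1),
    "capacity error.*FIVE_UTR")
  expect_error(
    simulate_genome(simulation_spec(sequence_length = 50000,
                                    genes_per_sequence = 0,
                                    plan = list(INTRON = 10000)), seed = 1),
    "capacity error.*INTRON")
})

test_that("high mutation loads produce detector-invisible negative controls", {
  # arrays mutated until the best local score is < 12 must not be detected
  set.seed(56)
  misses <- 0L
  for (i in 1:20) {
    m <- mutate_array(strrep("ACG", 6), rate = 0.9)
    score <- oracle_best_array_score(m$seq, max_u = 6)
    s <- paste0(strrep("N", 10), m$seq, strrep("N", 10))
    trs <- detect(c(x = s), detect_config(max_unit = 6))
    if (score < 12) {
      expect_equal(nrow(trs), 0)
      misses <- misses + 1L
    } else {
      expect_gt(nrow(trs), 0)
    }
  }
  expect_gt(misses, 0) # the negative control actually exercised the branch
})
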