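# Synthetic genomes with planted tandem repeats.
#
# The generator emits (i) iid background sequence at a stated GC content,
# (ii) non-overlapping gene models with UTR/CDS/intron structure written as
# standards-compliant GFF3, and (iii) TR arrays planted inside designated
# region classes until per-class target densities (or counts) are met, with
# optional per-copy mutations. Everything is deterministic given the seed and
# the ground truth is returned as a table that recounts exactly against the
# emitted sequence.

#' Simulation specification
#'
#' Defaults describe a compact plant-like chromosome: ~2.7 kb genes (4 exons,
#' 250 nt CDS per exon, 350 nt introns, 250/350 nt UTRs) spaced so that the
#' 1700 nt upstream/downstream window stacks of neighboring genes never
#' overlap, on an iid background at the stated GC.
#'
#' The planting `plan` is a named list keyed by region class (`FIVE_UTR`,
#' `UI200`, ..., or `GENOME` for anywhere); each entry is either a target
#' density in bp/Mbp (numeric) or a list with fields `density` or `n`
#' (array count), and optional per-class `motif_pool`, `copies_range`,
#' `imperfection_rate` overrides.
#'
#' @param n_sequences,sequence_length number and length of sequences.
#' @param background_gc background GC percentage.
#' @param genes_per_sequence gene models per sequence (0 for gene-free).
#' @param n_exons,exon_cds_length,intron_length exon/intron structure.
#' @param five_utr_length,three_utr_length UTR lengths.
#' @param utr_annotated when `FALSE`, genes carry no UTRs (the four
#'   UTR-less-species situation): UTR lengths are forced to 0 and intergenic
#'   windows anchor on gene ends.
#' @param plan planting plan (see above).
#' @param motif_pool default motif pool; `NULL` = all primitive canonical
#'   motifs of length 1-3, sampled with GC-matching weights (Gaussian in
#'   motif GC around `background_gc`, sd 12 percentage points).
#' @param copies_range integer range of copy numbers (low, high); copies are
#'   raised when needed so every planted array is >= 12 nt pre-mutation.
#' @param imperfection_rate per-copy substitution probability in [0, 1).
#' @param indel_rate per-copy indel probability in [0, 1).
#' @param plant_gap minimum background gap between planted arrays (keeps
#'   planted spans pairwise disjoint and un-bridgeable by seed extension).
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_sequences = 1L, sequence_length = 250000L,
                            background_gc = 40, genes_per_sequence = 25L,
                            n_exons = 4L, exon_cds_length = 250L,
                            intron_length = 350L, five_utr_length = 250L,
                            three_utr_length = 350L, utr_annotated = TRUE,
                            plan = list(), motif_pool = NULL,
                            copies_range = c(4L, 10L),
                            imperfection_rate = 0, indel_rate = 0,
                            plant_gap = 12L) {
  if (background_gc < 0 || background_gc > 100)
    stop("background_gc must be a percentage", call. = FALSE)
  if (imperfection_rate < 0 || imperfection_rate >= 1)
    stop("imperfection_rate must be in [0,1)", call. = FALSE)
  if (sequence_length <= 0 || n_sequences <= 0)
    stop("lengths must be positive", call. = FALSE)
  if (!utr_annotated) five_utr_length <- three_utr_length <- 0L
  structure(list(
    n_sequences = as.integer(n_sequences),
    sequence_length = as.integer(sequence_length),
    background_gc = background_gc,
    genes_per_sequence = as.integer(genes_per_sequence),
    n_exons = as.integer(n_exons),
    exon_cds_length = as.integer(exon_cds_length),
    intron_length = as.integer(intron_length),
    five_utr_length = as.integer(five_utr_length),
    three_utr_length = as.integer(three_utr_length),
    utr_annotated = utr_annotated, plan = plan, motif_pool = motif_pool,
    copies_range = as.integer(copies_range),
    imperfection_rate = imperfection_rate, indel_rate = indel_rate,
    plant_gap = as.integer(plant_gap)), class = "simulation_spec")
}

#' Default GC-matched motif pool
#'
#' All primitive canonical motifs of unit size 1-3, with sampling weights
#' Gaussian in motif GC fraction around the target GC (sd `sd_gc`). High-GC
#' backgrounds therefore receive GC-rich planted motifs and vice versa,
#' mirroring the empirical coupling between regional GC and top TR motifs.
#'
#' @param gc target GC percentage.
#' @param sd_gc weight bandwidth in GC percentage points.
#' @return data frame `motif`, `weight`.
#' @export
default_motif_pool <- function(gc, sd_gc = 12) {
  b <- c("A", "C", "G", "T")
  k2 <- as.vector(outer(b, b, paste0))
  k3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  pool <- unique(canonical_rotation(c(b, k2, k3)))
  pool <- pool[primitive_unit(pool) == pool]
  g <- vapply(pool, gc_content, numeric(1))
  data.frame(motif = pool,
             weight = exp(-((g - gc)^2) / (2 * sd_gc^2)),
             stringsAsFactors = FALSE)
}

#' Mutate a perfect repeat array
#'
#' Each full copy receives a substitution with probability `rate` (position
#' uniform within the copy, replacement uniform over the three other bases)
#' and, optionally, a single-base indel with probability `indel_rate`
#' (deletion or insertion with equal odds). The returned log is sufficient to
#' reconstruct the mutated string from the original.
#'
#' @param array perfect A/C/G/T repeat array (an exact number of unit copies).
#' @param rate per-copy substitution probability in [0, 1).
#' @param indel_rate per-copy indel probability in [0, 1).
#' @param seed optional integer seed (uses the current RNG stream when NULL).
#' @return list with `seq` (mutated string) and `log` (data frame `type`,
#'   `offset` — 0-based, relative to the original array — `from`, `to`).
#' @export
mutate_array <- function(array, rate, indel_rate = 0, seed = NULL) {
  if (rate < 0 || rate >= 1 || indel_rate < 0 || indel_rate >= 1)
    stop("rates must be in [0,1)", call. = FALSE)
  .check_motif(array, "array")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  u <- nchar(primitive_unit(array))
  n_copies <- nchar(array) %/% u
  v <- strsplit(array, "", fixed = TRUE)[[1]]
  log <- data.frame(type = character(0), offset = integer(0),
                    from = character(0), to = character(0),
                    stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  events <- list()
  for (cp in seq_len(n_copies)) {
    if (rate > 0 && runif(1) < rate) {
      off <- (cp - 1L) * u + sample.int(u, 1L) - 1L
      to <- sample(setdiff(bases, v[off + 1L]), 1L)
      events[[length(events) + 1L]] <-
        data.frame(type = "sub", offset = off, from = v[off + 1L], to = to,
                   stringsAsFactors = FALSE)
    }
    if (indel_rate > 0 && runif(1) < indel_rate) {
      off <- (cp - 1L) * u + sample.int(u, 1L) - 1L
      if (runif(1) < 0.5)
        events[[length(events) + 1L]] <-
          data.frame(type = "del", offset = off, from = v[off + 1L], to = "",
                     stringsAsFactors = FALSE)
      else
        events[[length(events) + 1L]] <-
          data.frame(type = "ins", offset = off, from = "",
                     to = sample(bases, 1L), stringsAsFactors = FALSE)
    }
  }
  if (length(events)) {
    log <- do.call(rbind, events)
    # apply substitutions first, then indels right-to-left so offsets
    # (relative to the original array) stay valid
    for (i in which(log$type == "sub")) v[log$offset[i] + 1L] <- log$to[i]
    idl <- which(log$type != "sub")
    for (i in idl[order(-log$offset[idl])]) {
      if (log$type[i] == "del") v <- v[-(log$offset[i] + 1L)]
      else v <- append(v, log$to[i], after = log$offset[i])
    }
  }
  list(seq = paste(v, collapse = ""), log = log)
}

.normalize_plan <- function(spec) {
  plan <- spec$plan
  if (length(plan) == 0L) return(list())
  if (is.null(names(plan)) || any(!nzchar(names(plan))))
    stop("plan entries must be named by region class", call. = FALSE)
  lapply(setNames(names(plan), names(plan)), function(cl) {
    e <- plan[[cl]]
    if (is.numeric(e)) e <- list(density = e)
    if (is.null(e$density) && is.null(e$n))
      stop("plan for '", cl, "' needs a density or an array count",
           call. = FALSE)
    if (!is.null(e$density) && e$density < 0)
      stop("densities must be >= 0", call. = FALSE)
    pool <- e$motif_pool
    if (is.null(pool)) pool <- spec$motif_pool
    if (is.null(pool)) pool <- default_motif_pool(spec$background_gc)
    if (is.character(pool))
      pool <- data.frame(motif = pool, weight = 1, stringsAsFactors = FALSE)
    list(density = e$density, n = e$n, pool = pool,
         copies_range = if (is.null(e$copies_range)) spec$copies_range else
           as.integer(e$copies_range),
         imperfection_rate = if (is.null(e$imperfection_rate))
           spec$imperfection_rate else e$imperfection_rate,
         indel_rate = if (is.null(e$indel_rate)) spec$indel_rate else
           e$indel_rate)
  })
}

.build_models <- function(spec) {
  if (spec$genes_per_sequence == 0L) return(structure(list(),
                                                      class = "gene_model_list"))
  n_ex <- spec$n_exons
  tl <- spec$five_utr_length + spec$three_utr_length +
    n_ex * spec$exon_cds_length + (n_ex - 1L) * spec$intron_length
  slot <- spec$sequence_length %/% spec$genes_per_sequence
  head_room <- slot - tl - 3400L
  if (head_room < 0L)
    stop("capacity error: genes (", tl, " nt + 2x1700 nt windows) do not fit",
         " in ", slot, " nt slots", call. = FALSE)
  models <- list()
  for (s in seq_len(spec$n_sequences)) {
    sid <- paste0("chr", s)
    for (g in seq_len(spec$genes_per_sequence)) {
      jit <- if (head_room > 0L) sample.int(head_room, 1L) - 1L else 0L
      gstart <- (g - 1L) * slot + 1700L + jit
      strand <- sample(c("+", "-"), 1L)
      lu <- if (strand == "+") spec$five_utr_length else spec$three_utr_length
      ru <- if (strand == "+") spec$three_utr_length else spec$five_utr_length
      exons <- matrix(integer(0), ncol = 2)
      pos <- gstart
      for (k in seq_len(n_ex)) {
        w <- spec$exon_cds_length + (if (k == 1L) lu else 0L) +
          (if (k == n_ex) ru else 0L)
        exons <- rbind(exons, c(pos, pos + w))
        pos <- pos + w + (if (k < n_ex) spec$intron_length else 0L)
      }
      gend <- exons[n_ex, 2]
      cds <- exons
      cds[1, 1] <- cds[1, 1] + lu
      cds[n_ex, 2] <- cds[n_ex, 2] - ru
      five <- three <- matrix(integer(0), ncol = 2)
      # the 5'-UTR occupies the transcript 5' end: the left exon extra (lu)
      # on the plus strand, the right exon extra (ru) on the minus strand
      if (spec$utr_annotated && spec$five_utr_length > 0L) {
        five <- if (strand == "+") matrix(c(gstart, gstart + lu), ncol = 2)
          else matrix(c(gend - ru, gend), ncol = 2)
      }
      if (spec$utr_annotated && spec$three_utr_length > 0L) {
        three <- if (strand == "+") matrix(c(gend - ru, gend), ncol = 2)
          else matrix(c(gstart, gstart + lu), ncol = 2)
      }
      gid <- sprintf("%s.g%02d", sid, g)
      models[[length(models) + 1L]] <- structure(list(
        gene_id = gid, mrna_id = paste0(gid, ".m1"), seq_id = sid,
        strand = strand, gene_span = c(gstart, gend),
        exons = .sort_iv(exons), cds = .sort_iv(cds),
        five_utr = .sort_iv(five), three_utr = .sort_iv(three)),
        class = "gene_model")
    }
  }
  structure(models, class = "gene_model_list")
}

.empty_truth <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             unit = character(0), canonical_unit = character(0),
             unit_len = integer(0), copies = numeric(0),
             region_class = character(0), n_mutations = integer(0),
             mutations = character(0), perfect = logical(0),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic genome with planted tandem repeats
#'
#' See [simulation_spec()] for the model. Planted arrays are pairwise
#' disjoint (separated by at least `plant_gap` background bases), never cross
#' region boundaries, and each satisfies the detector thresholds (at least
#' 12 nt and two full copies) before mutation. After writing an array the two
#' flanking background bases are adjusted, when needed, to break the repeat
#' period so the planted span is also the maximal detectable span.
#'
#' @param spec a [simulation_spec()].
#' @param seed integer seed; the output is a deterministic function of
#'   (spec, seed).
#' @return list of class `tr_simulation`: `sequences` (named character),
#'   `models` (`gene_model_list`), `truth` (planted-TR table with mutation
#'   logs), `spec`, `seed`.
#' @export
simulate_genome <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "simulation_spec"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  gcf <- spec$background_gc / 100
  bases <- c("A", "C", "G", "T")
  pr <- c((1 - gcf) / 2, gcf / 2, gcf / 2, (1 - gcf) / 2)
  chars <- lapply(seq_len(spec$n_sequences), function(i)
    sample(bases, spec$sequence_length, replace = TRUE, prob = pr))
  names(chars) <- paste0("chr", seq_len(spec$n_sequences))

  models <- .build_models(spec)
  lens <- setNames(rep(spec$sequence_length, spec$n_sequences), names(chars))
  regions <- if (length(models))
    extract_all_regions(models, setNames(strrep("N", lens), names(lens)))
  else .empty_regions()

  plan <- .normalize_plan(spec)
  truth <- list()
  reserved <- lapply(chars, function(x) matrix(integer(0), ncol = 2))
  gap <- spec$plant_gap

  for (cl in names(plan)) {
    p <- plan[[cl]]
    iv <- if (cl == "GENOME")
      data.frame(seq_id = names(chars), start = 0L,
                 end = as.integer(lens), stringsAsFactors = FALSE)
    else regions[regions$region_class == cl, c("seq_id", "start", "end"),
                 drop = FALSE]
    if (nrow(iv) == 0L)
      stop("capacity error: no '", cl, "' regions available to plant into",
           call. = FALSE)
    capacity <- sum(iv$end - iv$start)
    target_bp <- if (!is.null(p$density))
      p$density / 1e6 * capacity else Inf
    target_n <- if (!is.null(p$n)) p$n else Inf
    if (is.finite(target_bp) && target_bp > 0.6 * capacity)
      stop("capacity error: target density for '", cl,
           "' exceeds region capacity", call. = FALSE)
    w_iv <- iv$end - iv$start
    planted_bp <- 0
    planted_n <- 0L
    fails <- 0L
    while ((is.finite(target_bp) && planted_bp < target_bp) ||
           (is.finite(target_n) && planted_n < target_n)) {
      if (is.finite(target_n) && planted_n >= target_n) break
      if (is.finite(target_bp) && planted_bp >= target_bp) break
      motif <- sample(p$pool$motif, 1L, prob = p$pool$weight)
      u <- nchar(motif)
      lo <- max(p$copies_range[1], 2L, ceiling(12 / u))
      hi <- max(p$copies_range[2], lo)
      copies <- sample(lo:hi, 1L)
      arr <- strrep(motif, copies)
      mut <- if (p$imperfection_rate > 0 || p$indel_rate > 0)
        mutate_array(arr, p$imperfection_rate, p$indel_rate)
      else list(seq = arr, log = NULL)
      alen <- nchar(mut$seq)
      placed <- FALSE
      for (try in seq_len(200L)) {
        k <- sample.int(nrow(iv), 1L, prob = w_iv)
        room <- iv$end[k] - iv$start[k] - alen
        if (room < 0L) next
        s0 <- iv$start[k] + sample.int(room + 1L, 1L) - 1L
        e0 <- s0 + alen
        res <- reserved[[iv$seq_id[k]]]
        if (nrow(res) && any(pmax(res[, 1], s0 - gap) <
                             pmin(res[, 2], e0 + gap))) next
        sid <- iv$seq_id[k]
        chars[[sid]][(s0 + 1L):e0] <-
          strsplit(mut$seq, "", fixed = TRUE)[[1]]
        # break the repeat period at the flanks so the planted span is
        # exactly the maximal run
        if (s0 >= 1L) {
          inside <- chars[[sid]][s0 + u]
          if (chars[[sid]][s0] == inside)
            chars[[sid]][s0] <- sample(setdiff(bases, inside), 1L)
        }
        if (e0 < lens[[sid]]) {
          inside <- chars[[sid]][e0 + 1L - u]
          if (chars[[sid]][e0 + 1L] == inside)
            chars[[sid]][e0 + 1L] <- sample(setdiff(bases, inside), 1L)
        }
        reserved[[sid]] <- rbind(res, c(s0, e0))
        mlog <- mut$log
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = sid, start = s0, end = e0, unit = motif,
          canonical_unit = canonical_rotation(motif), unit_len = u,
          copies = copies, region_class = cl,
          n_mutations = if (is.null(mlog)) 0L else nrow(mlog),
          mutations = if (is.null(mlog) || nrow(mlog) == 0L) "" else
            paste(sprintf("%s:%d:%s>%s", mlog$type, mlog$offset, mlog$from,
                          mlog$to), collapse = ";"),
          perfect = is.null(mlog) || nrow(mlog) == 0L,
          stringsAsFactors = FALSE)
        planted_bp <- planted_bp + alen
        planted_n <- planted_n + 1L
        placed <- TRUE
        fails <- 0L
        break
      }
      if (!placed) {
        fails <- fails + 1L
        if (fails >= 20L)
          stop("capacity error: cannot place more arrays in '", cl, "'",
               call. = FALSE)
      }
    }
  }

  truth <- if (length(truth)) do.call(rbind, truth) else .empty_truth()
  truth <- truth[order(truth$seq_id, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  structure(list(
    sequences = vapply(chars, paste, character(1), collapse = ""),
    models = models, truth = truth, spec = spec, seed = seed),
    class = "tr_simulation")
}

#' Write a simulation to disk
#'
#' Emits `genome.fasta`, `genes.gff3` and `truth.tsv` under `dir`.
#'
#' @param sim a `tr_simulation` from [simulate_genome()].
#' @param dir output directory (created if missing).
#' @return named character vector of the three paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "tr_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fasta")
  gff <- file.path(dir, "genes.gff3")
  tsv <- file.path(dir, "truth.tsv")
  write_fasta(sim$sequences, fa)
  write_gff3(sim$models, gff)
  write.table(sim$truth, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, gff3 = gff, truth = tsv))
}
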