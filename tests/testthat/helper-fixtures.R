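# Handcrafted fixtures built in code at test time.

# Three-gene GFF3: a plus-strand gene with UTRs and one intron, a
# minus-strand gene with UTRs and one intron, and a plus-strand UTR-less
# gene near the end of a short sequence (exercises window clipping).
gff3_fixture_lines <- function() c(
  "##gff-version 3",
  "chr1\ttest\tgene\t2001\t4000\t.\t+\t.\tID=geneA",
  "chr1\ttest\tmRNA\t2001\t4000\t.\t+\t.\tID=mA;Parent=geneA",
  "chr1\ttest\texon\t2001\t2900\t.\t+\t.\tID=mA.e1;Parent=mA",
  "chr1\ttest\texon\t3101\t4000\t.\t+\t.\tID=mA.e2;Parent=mA",
  "chr1\ttest\tfive_prime_UTR\t2001\t2200\t.\t+\t.\tID=mA.u5;Parent=mA",
  "chr1\ttest\tCDS\t2201\t2900\t.\t+\t.\tID=mA.c1;Parent=mA",
  "chr1\ttest\tCDS\t3101\t3700\t.\t+\t.\tID=mA.c2;Parent=mA",
  "chr1\ttest\tthree_prime_UTR\t3701\t4000\t.\t+\t.\tID=mA.u3;Parent=mA",
  "chr1\ttest\tgene\t6001\t8000\t.\t-\t.\tID=geneB",
  "chr1\ttest\tmRNA\t6001\t8000\t.\t-\t.\tID=mB;Parent=geneB",
  "chr1\ttest\texon\t6001\t7000\t.\t-\t.\tID=mB.e1;Parent=mB",
  "chr1\ttest\texon\t7201\t8000\t.\t-\t.\tID=mB.e2;Parent=mB",
  "chr1\ttest\tthree_prime_UTR\t6001\t6500\t.\t-\t.\tID=mB.u3;Parent=mB",
  "chr1\ttest\tCDS\t6501\t7000\t.\t-\t.\tID=mB.c1;Parent=mB",
  "chr1\ttest\tCDS\t7201\t7800\t.\t-\t.\tID=mB.c2;Parent=mB",
  "chr1\ttest\tfive_prime_UTR\t7801\t8000\t.\t-\t.\tID=mB.u5;Parent=mB",
  "chr2\ttest\tgene\t1801\t2400\t.\t+\t.\tID=geneC",
  "chr2\ttest\tmRNA\t1801\t2400\t.\t+\t.\tID=mC;Parent=geneC",
  "chr2\ttest\texon\t1801\t2400\t.\t+\t.\tID=mC.e1;Parent=mC",
  "chr2\ttest\tCDS\t1801\t2400\t.\t+\t.\tID=mC.c1;Parent=mC")

write_gff3_fixture <- function(path = tempfile(fileext = ".gff3")) {
  writeLines(gff3_fixture_lines(), path)
  path
}

# Hand-computed expected regions for the fixture (0-based half-open).
expected_fixture_regions <- function() {
  rows <- function(mrna, class, start, end)
    data.frame(mrna_id = mrna, region_class = class, start = start, end = end,
               stringsAsFactors = FALSE)
  rbind(
    rows("mA", "FIVE_UTR", 2000, 2200),
    rows("mA", "CDS", c(2200, 3100), c(2900, 3700)),
    rows("mA", "INTRON", 2900, 3100),
    rows("mA", "THREE_UTR", 3700, 4000),
    rows("mA", "UI200", 1800, 2000),
    rows("mA", "UI500", 1300, 1800),
    rows("mA", "UI1000", 300, 1300),
    rows("mA", "DI200", 4000, 4200),
    rows("mA", "DI500", 4200, 4700),
    rows("mA", "DI1000", 4700, 5700),
    rows("mB", "FIVE_UTR", 7800, 8000),
    rows("mB", "CDS", c(6500, 7200), c(7000, 7800)),
    rows("mB", "INTRON", 7000, 7200),
    rows("mB", "THREE_UTR", 6000, 6500),
    rows("mB", "UI200", 8000, 8200),
    rows("mB", "UI500", 8200, 8700),
    rows("mB", "UI1000", 8700, 9700),
    rows("mB", "DI200", 5800, 6000),
    rows("mB", "DI500", 5300, 5800),
    rows("mB", "DI1000", 4300, 5300),
    rows("mC", "CDS", 1800, 2400),
    rows("mC", "UI200", 1600, 1800),
    rows("mC", "UI500", 1100, 1600),
    rows("mC", "UI1000", 100, 1100),
    rows("mC", "DI200", 2400, 2600),
    rows("mC", "DI500", 2600, 3000))
}

fixture_seqs <- function() {
  set.seed(424242)
  c(chr1 = random_seq(10000), chr2 = random_seq(3000))
}

# A random TR table for round-trip tests.
random_tr_table <- function(n = 25L) {
  units <- replicate(n, paste(sample(c("A", "C", "G", "T"),
                                     sample(1:6, 1), replace = TRUE),
                              collapse = ""))
  units <- primitive_unit(units)
  ul <- nchar(units)
  copies <- sample(2:10, n, replace = TRUE)
  start <- sample.int(5000L, n)
  len <- ul * copies
  tr_table(data.frame(
    seq_id = sample(c("s1", "s2"), n, replace = TRUE), start = start,
    end = start + len, unit = units,
    canonical_unit = canonical_rotation(units), unit_len = ul,
    copies = as.numeric(copies), score = as.integer(len),
    perfect = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE))
}

# Mutate a perfect array with an exact number of substitutions at distinct
# positions (test-controlled alternative to mutate_array()).
substitute_bases <- function(array, k) {
  if (k == 0L) return(array)
  v <- strsplit(array, "", fixed = TRUE)[[1]]
  pos <- sample(length(v), k)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  paste(v, collapse = "")
}
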