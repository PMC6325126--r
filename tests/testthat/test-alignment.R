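test_that("load_alignments converts SAM records to 0-based half-open spans", {
  sam <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(sam, c(
    sam_record("fwd", 0L, "chr1", 51L, 60L, "100M", strrep("A", 100)),
    sam_record("rev", 16L, "chr1", 201L, 60L, "100M", strrep("A", 100)),
    sam_record("lowq", 0L, "chr1", 1L, 0L, "50M", strrep("A", 50)),
    sam_record("clip", 0L, "chr1", 301L, 60L, "10S80M10S", strrep("A", 100)),
    sam_record("indel", 0L, "chr1", 401L, 60L, "40M5D40M2I18M",
               strrep("A", 100)),
    sam_record("unmapped", 4L, "*", 0L, 0L, "*", strrep("A", 10)),
    sam_record("secondary", 256L, "chr1", 11L, 60L, "50M", strrep("A", 50))
  ))
  reads <- load_alignments(sam, min_mapq = 1L)
  expect_equal(nrow(reads), 4L)
  expect_equal(attr(reads, "chrom_lengths"), c(chr1 = 1000L))
  fwd <- reads[reads$start == 50L, ]
  expect_equal(fwd$end, 150L)
  expect_equal(fwd$strand, "+")
  rev <- reads[reads$start == 200L, ]
  expect_equal(rev$strand, "-")
  # soft clips do not shift the counted ends; deletions consume reference
  expect_equal(reads$end[reads$start == 300] - 300, 80)
  expect_equal(reads$end[reads$start == 400] - 400, 40 + 5 + 40 + 18)
  # raising min_mapq drops everything below it
  expect_equal(nrow(load_alignments(sam, min_mapq = 61L)), 0L)
})

test_that("load_alignments error paths", {
  expect_error(load_alignments(tempfile()), "not found")
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines("@HD\tVN:1.6", sam)   # header without @SQ lengths
  expect_error(load_alignments(sam), "sequence lengths|malformed")
})

test_that("empty SAM yields empty stream and all-zero counts", {
  sam <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(sam, character(0))
  reads <- load_alignments(sam)
  expect_equal(nrow(reads), 0L)
  counts <- tally_positions(reads)
  expect_true(all(counts$counts$chr1$D == 0L))
  expect_true(all(counts$counts$chr1$F == 0L))
  expect_true(all(counts$counts$chr1$R == 0L))
})

test_that("tally_positions places D, F and R per the strand convention", {
  reads <- data.frame(
    chrom = "chr1",
    strand = c("+", "+", "+", "-"),
    start = c(50L, 50L, 50L, 200L),
    end = c(150L, 150L, 150L, 300L),
    mapq = 60L
  )
  counts <- tally_positions(reads, c(chr1 = 1000L))
  cc <- counts$counts$chr1
  at <- function(v, pos0) v[pos0 + 1L]
  expect_equal(at(cc$F, 50L), 3L)
  expect_true(all(at(cc$D, 50:149) == 3L))
  expect_equal(at(cc$D, 150L), 0L)
  # reverse 5' end recorded at the nick coordinate (half-open end)
  expect_equal(at(cc$R, 300L), 1L)
  expect_equal(sum(cc$R), 1L)
  expect_true(all(at(cc$D, 200:299) == 1L))
  # spec-literal alternative: rightmost covered base
  cb <- tally_positions(reads, c(chr1 = 1000L),
                        reverse_five_prime = "base")$counts$chr1
  expect_equal(at(cb$R, 299L), 1L)
  # conservation: F and R totals equal read counts by strand
  expect_equal(sum(cc$F), 3L)
  expect_equal(counts$n_forward, 3L)
  expect_equal(counts$n_reverse, 1L)
  expect_silent(endovseq:::validate_counts(counts))
})

test_that("tally_positions rejects out-of-bounds and unknown chromosomes", {
  r <- data.frame(chrom = "chr1", strand = "+", start = 990L, end = 1010L,
                  mapq = 60L)
  expect_error(tally_positions(r, c(chr1 = 1000L)), "beyond chromosome end")
  expect_error(tally_positions(r, c(chr2 = 1000L)), "undeclared")
})

test_that("counts survive the sidecar round trip", {
  set.seed(42)
  n <- 200L
  reads <- data.frame(
    chrom = "chr1", strand = sample(c("+", "-"), n, TRUE),
    start = sample.int(900L, n, TRUE) - 1L, mapq = 60L)
  reads$end <- reads$start + sample(20:100, n, TRUE)
  counts <- tally_positions(reads, c(chr1 = 1000L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(counts, path)
  back <- read_counts(path)
  expect_identical(back$counts, counts$counts)
  expect_identical(back$chrom_lengths, counts$chrom_lengths)
  expect_identical(back$reverse_five_prime, counts$reverse_five_prime)
})

test_that("tallying simulator SAM output reproduces in-memory counts", {
  g <- guide_rna("RNF2", "GTCATCTTAGTCATTACCTG")
  cfg <- sim_config(genome_length = 2e4, depth = 8, seed = 5)
  ref <- generate_reference(cfg)
  sam <- withr::local_tempfile(fileext = ".sam")
  sim <- plant_and_simulate(ref, g, config = cfg, sam = sam)
  from_mem <- tally_positions(sim$reads)
  from_sam <- tally_positions(load_alignments(sam))
  expect_identical(from_mem$counts, from_sam$counts)
})
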