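test_that("generate_reference is deterministic with controlled composition", {
  cfg <- sim_config(genome_length = 1e5, gc_content = 0.5, seed = 42)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(as.character(r1), as.character(r2))
  gc <- Biostrings::letterFrequency(r1[[1]], "GC", as.prob = TRUE)
  expect_gt(gc, 0.48)
  expect_lt(gc, 0.52)
  expect_error(generate_reference(sim_config(genome_length = 1e4 - 1)),
               "at least 10 kb")
  expect_error(sim_config(depth = 0), "depth")
  expect_error(sim_config(fragment_mean = 100, read_length = 150),
               "fragment mean")
})

test_that("planted nick geometry obeys the stagger invariants", {
  guides <- guides20()
  cfg <- sim_config(genome_length = 5e4, depth = 5, seed = 8)
  ref <- generate_reference(cfg)
  sim <- plant_and_simulate(ref, guides, n_offtargets_per_guide = 2,
                            config = cfg)
  reg <- sim$registry
  expect_equal(nrow(reg), 15L)
  L <- 20L
  fwd <- reg$strand == "+"
  # edited strand nick one residue 3' of the deaminated A; nCas9 between
  # protospacer positions 17 and 18
  expect_equal(reg$top_nick[fwd],
               reg$protospacer_start[fwd] + reg$edited_A_offset[fwd] + 1L)
  expect_equal(reg$bottom_nick[fwd], reg$protospacer_start[fwd] + L - 3L)
  expect_equal(reg$top_nick[!fwd],
               reg$protospacer_start[!fwd] + L - reg$edited_A_offset[!fwd] - 1L)
  expect_equal(reg$bottom_nick[!fwd], reg$protospacer_start[!fwd] + 3L)
  stagger <- abs(reg$bottom_nick - reg$top_nick)
  expect_true(all(stagger >= 9L & stagger <= 13L))
  # the edited A is inside the deamination window and is an A in the
  # planted sequence
  expect_true(all(reg$edited_A_offset >= 3L & reg$edited_A_offset <= 7L))
  expect_equal(
    substr(reg$planted_protospacer, reg$edited_A_offset + 1L,
           reg$edited_A_offset + 1L),
    rep("A", nrow(reg)))
  # planted sequences really sit in the returned reference
  for (i in seq_len(nrow(reg))) {
    got <- as.character(Biostrings::subseq(sim$reference[[1]],
                                           reg$protospacer_start[i] + 1L,
                                           reg$protospacer_start[i] + L))
    want <- if (reg$strand[i] == "+") reg$planted_protospacer[i] else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(reg$planted_protospacer[i])))
    expect_equal(got, want)
  }
})

test_that("cleavage produces the expected F/R pileups at the nicks", {
  g <- guide_rna("EMX1", "GAGTCCGAGCAGAAGAAGAA")
  cfg <- sim_config(genome_length = 5e4, depth = 35, seed = 21)
  ref <- generate_reference(cfg)
  sim <- plant_and_simulate(ref, g, config = cfg, cleavage_fraction = 1.0)
  cc <- tally_positions(sim$reads)$counts$chr1
  reg <- sim$registry
  lo <- min(reg$top_nick, reg$bottom_nick)
  hi <- max(reg$top_nick, reg$bottom_nick)
  # forward starts pile at the left nick, reverse ends at the right nick,
  # separated by exactly the stagger
  expect_gt(cc$F[lo + 1L], 10L)
  expect_gt(cc$R[hi + 1L], 10L)
  expect_equal(hi - lo, abs(reg$bottom_nick - reg$top_nick))
  # elsewhere no such pileups exist
  expect_lt(max(cc$F[-(lo + 1L)]), 5L)
})

test_that("uncleaved simulations look uniform and score empty", {
  g <- guide_rna("EMX1", "GAGTCCGAGCAGAAGAAGAA")
  cfg <- sim_config(genome_length = 2e5, depth = 35, seed = 13)
  ref <- generate_reference(cfg)
  sim <- plant_and_simulate(ref, g, n_offtargets_per_guide = 3,
                            config = cfg, cleavage_fraction = 0)
  track <- score_genome(tally_positions(sim$reads))
  expect_true(nrow(track) == 0L || max(track$score) <= 0.1)
  expect_lt(abs(mean_depth(sim$reads) - cfg$depth) / cfg$depth, 0.05)
})

test_that("simulation is deterministic, SAM output byte-identical", {
  g <- guide_rna("RNF2", "GTCATCTTAGTCATTACCTG")
  cfg <- sim_config(genome_length = 2e4, depth = 6, seed = 77)
  ref <- generate_reference(cfg)
  s1 <- withr::local_tempfile(fileext = ".sam")
  s2 <- withr::local_tempfile(fileext = ".sam")
  plant_and_simulate(ref, g, config = cfg, sam = s1)
  plant_and_simulate(ref, g, config = cfg, sam = s2)
  expect_identical(readLines(s1), readLines(s2))
})

test_that("mix_datasets subsamples the stated proportions", {
  mk <- function(n, tag) {
    r <- data.frame(chrom = "chr1", strand = "+",
                    start = seq_len(n), end = seq_len(n) + 100L,
                    mapq = 60L, origin = tag)
    attr(r, "chrom_lengths") <- c(chr1 = 10000L)
    r
  }
  treated <- mk(1000L, "t")
  untreated <- mk(2000L, "u")
  m1 <- mix_datasets(treated, untreated, 1, seed = 1)
  expect_equal(nrow(m1), 1000L)
  expect_true(all(m1$origin == "t"))
  m25 <- mix_datasets(treated, untreated, 2.5, seed = 1)
  expect_equal(nrow(m25), 1000L)
  expect_equal(sum(m25$origin == "t"), 400L)
  expect_error(mix_datasets(treated, mk(10L, "u"), 10), "too small")
  expect_error(mix_datasets(treated, untreated, 0.5), ">= 1")
})

test_that("annotation recovers planted mismatch counts and strands", {
  guides <- guides20()
  cfg <- sim_config(genome_length = 1e5, depth = 35, seed = 19)
  ref <- generate_reference(cfg)
  sim <- plant_and_simulate(ref, guides[1:3], n_offtargets_per_guide = 2,
                            config = cfg)
  sites <- call_sites(score_genome(tally_positions(sim$reads)), 2.5)
  reg <- sim$registry
  lo <- pmin(reg$top_nick, reg$bottom_nick)
  for (i in seq_len(nrow(reg))) {
    j <- which(abs(sites$pos - lo[i]) <= 25)
    expect_length(j, 1L)
    g <- Filter(function(g) g$name == reg$guide[i], guides)[[1]]
    ann <- annotate_site(sites[j, ], sim$reference, g)
    expect_equal(ann$mismatches, reg$mismatches[i])
    expect_equal(ann$matched_strand, reg$strand[i])
    expect_equal(ann$matched_protospacer, reg$planted_protospacer[i])
    expect_true(ann$has_window_A)
  }
})
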