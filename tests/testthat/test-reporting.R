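test_that("position_frequency_matrix tallies and normalises", {
  one <- position_frequency_matrix("ACGTA")
  expect_equal(one$n_sites, 1L)
  expect_true(all(apply(one$frequencies, 2, max) == 1))
  expect_equal(colSums(one$counts), rep(1L, 5), ignore_attr = TRUE)
  two <- position_frequency_matrix(c("ACGTA", "AGGTA"))
  expect_equal(two$frequencies["C", 2], 0.5, ignore_attr = TRUE)
  expect_equal(two$frequencies["G", 2], 0.5, ignore_attr = TRUE)
  expect_true(all(two$frequencies[, -2][two$frequencies[, -2] > 0] == 1))
  expect_true(all(abs(colSums(two$frequencies) - 1) < 1e-9))
  expect_error(position_frequency_matrix(character(0)), "no sequences")
  expect_error(position_frequency_matrix(c("ACGT", "ACGTA")),
               "mixed lengths")
})

test_that("PFM conserves unmutated positions across the pipeline", {
  g <- guide_rna("EMX1", "GAGTCCGAGCAGAAGAAGAA")
  cfg <- sim_config(genome_length = 1e5, depth = 35, seed = 29)
  ref <- generate_reference(cfg)
  sim <- plant_and_simulate(ref, g, n_offtargets_per_guide = 3,
                            mismatch_range = 1:2, config = cfg)
  sites <- call_sites(score_genome(tally_positions(sim$reads)), 2.5)
  ann <- annotate_sites(sites, sim$reference, g)
  pfm <- position_frequency_matrix(ann)
  expect_equal(pfm$n_sites, nrow(sim$registry))
  # positions never touched by the mismatch generator are fully conserved
  proto <- strsplit(g$protospacer, "")[[1]]
  mutated <- unique(unlist(lapply(sim$registry$planted_protospacer,
                                  function(s)
                                    which(strsplit(s, "")[[1]] != proto))))
  conserved <- setdiff(seq_along(proto), mutated)
  for (p in conserved)
    expect_equal(unname(pfm$frequencies[proto[p], p]), 1)
})

test_that("conversion_frequency counts A-to-G edits and respects coverage", {
  refseq <- "GGATCAACGTTAGCAATTGG"
  #          123456789012345678901   (A at 1-based 3, 6, 7, 13, 16, 17)
  reads <- c(
    sam_record("r1", 0L, "amp", 1L, 60L, "20M", refseq),
    sam_record("r2", 0L, "amp", 1L, 60L, "20M",
               sub("GGATCAAC", "GGATCGAC", refseq)),  # A>G at 1-based 6
    sam_record("r3", 0L, "amp", 1L, 60L, "10M",
               substr(refseq, 1, 10))
  )
  sam <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(sam, reads, c(amp = 20L))
  tab <- conversion_frequency(sam, c(amp = refseq))
  expect_equal(nrow(tab), 20L)
  # identical reads: conversion 0 at covered reference-A positions
  expect_equal(tab$conversion[tab$pos == 2L], 0)
  # one of three reads converted at 0-based position 5
  expect_equal(tab$conversion[tab$pos == 5L], 1 / 3)
  # depth drops after the short read; uncovered positions are NA
  expect_equal(tab$depth[tab$pos == 3L], 3L)
  expect_equal(tab$depth[tab$pos == 15L], 2L)
  uncovered <- conversion_frequency(
    withr::local_tempfile(fileext = ".sam") |>
      write_test_sam(sam_record("r", 0L, "amp", 1L, 60L, "5M",
                                substr(refseq, 1, 5)),
                     c(amp = 20L)),
    c(amp = refseq))
  expect_true(is.na(uncovered$conversion[uncovered$pos == 11L]))
  expect_error(conversion_frequency(sam, c(other = refseq)),
               "does not match")
})

test_that("pipeline driver produces a coherent run directory", {
  guides <- guides20()[1:2]
  outdir <- withr::local_tempdir()
  cfg <- sim_config(genome_length = 5e4, depth = 35, seed = 31)
  res <- run_pipeline(guides, cfg, n_offtargets_per_guide = 1,
                      outdir = outdir)
  expect_true(all(file.exists(file.path(outdir, c(
    "reference.fa", "reads.sam", "registry.tsv", "counts.tsv", "scores.tsv",
    "sites.bed", "sites.tsv", "allocation.tsv", "pfm.tsv",
    "manifest.json")))))
  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"))
  expect_equal(manifest$seed, cfg$seed)
  expect_equal(manifest$n_sites_called, nrow(res$sites))
  # every planted site was called and allocated to its generating guide
  expect_equal(nrow(res$sites), nrow(res$simulation$registry))
  al <- res$allocation
  expect_true(all(al$allocated_guide[!al$allocation_tie] %in%
                    vapply(guides, `[[`, character(1), "name")))
  bed <- utils::read.delim(file.path(outdir, "sites.bed"), header = FALSE)
  expect_equal(nrow(bed), nrow(res$sites))
  expect_equal(ncol(bed), 6L)
})

test_that("CLI subcommands chain over files", {
  outdir <- withr::local_tempdir()
  simdir <- file.path(outdir, "sim")
  guides_tsv <- file.path(outdir, "guides.tsv")
  writeLines(c("name\tprotospacer\tpam",
               "EMX1\tGAGTCCGAGCAGAAGAAGAA\tNGG"), guides_tsv)
  suppressMessages({
    endov_cli(c("simulate", "--genome-length", "30000", "--depth", "35",
                "--seed", "4", "--guides", guides_tsv,
                "--offtargets", "1", "--outdir", simdir))
    endov_cli(c("tally", "--sam", file.path(simdir, "reads.sam"),
                "--out", file.path(outdir, "counts.tsv")))
    endov_cli(c("score", "--counts", file.path(outdir, "counts.tsv"),
                "--out", file.path(outdir, "scores.tsv")))
    endov_cli(c("call", "--scores", file.path(outdir, "scores.tsv"),
                "--threshold", "2.5",
                "--out", file.path(outdir, "sites.tsv")))
    endov_cli(c("annotate", "--sites", file.path(outdir, "sites.tsv"),
                "--reference", file.path(simdir, "reference.fa"),
                "--guides", guides_tsv,
                "--out", file.path(outdir, "ann.tsv")))
    endov_cli(c("report", "--sites", file.path(outdir, "ann.tsv"),
                "--out", file.path(outdir, "pfm.tsv")))
    cmp <- endov_cli(c("compare", "--a", file.path(outdir, "sites.tsv"),
                       "--b", file.path(outdir, "sites.tsv")))
  })
  sites <- utils::read.delim(file.path(outdir, "sites.tsv"))
  reg <- utils::read.delim(file.path(simdir, "registry.tsv"))
  expect_equal(nrow(sites), nrow(reg))
  expect_equal(cmp$shared, nrow(sites))
  expect_equal(cmp$only_a, 0L)
  pfm <- utils::read.delim(file.path(outdir, "pfm.tsv"))
  expect_equal(nrow(pfm), 23L)
})
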