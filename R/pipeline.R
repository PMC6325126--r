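#' Run the full simulate-score-call-allocate pipeline
#'
#' End-to-end driver used by the command line interface and by validation:
#' simulate a genome with planted cleavage events, tally read ends, score
#' every position, call sites at a threshold, annotate them against the
#' guides, allocate them by edit distance, and summarise the captured-site
#' motif as a position frequency matrix.
#'
#' @param guides A `guide_rna` or list of them.
#' @param config A [sim_config()].
#' @param n_offtargets_per_guide,mismatch_range,cleavage_fraction Passed to
#'   [plant_and_simulate()].
#' @param threshold Score threshold for [call_sites()] (default 2.5).
#' @param params [scoring_params()].
#' @param outdir Optional output directory; when given, writes
#'   `reference.fa`, `reads.sam`, `registry.tsv`, `counts.tsv`,
#'   `scores.tsv`, `sites.bed`, `sites.tsv`, `allocation.tsv`, `pfm.tsv`
#'   and `manifest.json`.
#' @return List with `simulation`, `counts`, `track`, `sites`, `annotated`,
#'   `allocation` and `pfm`.
#' @export
run_pipeline <- function(guides, config = sim_config(),
                         n_offtargets_per_guide = 2L, mismatch_range = 1:3,
                         cleavage_fraction = 1.0, threshold = 2.5,
                         params = scoring_params(), outdir = NULL) {
  if (inherits(guides, "guide_rna")) guides <- list(guides)
  ref <- generate_reference(config)
  sim <- plant_and_simulate(ref, guides,
                            n_offtargets_per_guide = n_offtargets_per_guide,
                            mismatch_range = mismatch_range,
                            config = config,
                            cleavage_fraction = cleavage_fraction)
  counts <- tally_positions(sim$reads)
  track <- score_genome(counts, params)
  sites <- call_sites(track, threshold)
  annotated <- if (nrow(sites))
    annotate_sites(sites, sim$reference, guides) else sites
  allocation <- if (nrow(sites))
    allocate_sites(annotated, guides) else annotated
  pfm <- if (nrow(sites) && length(unique(nchar(annotated$matched_sequence))) == 1L)
    position_frequency_matrix(annotated) else NULL

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(sim$reference, file.path(outdir, "reference.fa"))
    write_sim_sam(sim$reads, sim$reference, file.path(outdir, "reads.sam"))
    utils::write.table(sim$registry, file.path(outdir, "registry.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_counts(counts, file.path(outdir, "counts.tsv"))
    write_score_track(track, file.path(outdir, "scores.tsv"))
    if (nrow(sites)) {
      write_sites_bed(annotated, file.path(outdir, "sites.bed"),
                      file.path(outdir, "sites.tsv"))
      utils::write.table(allocation, file.path(outdir, "allocation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(pfm)) write_pfm(pfm, file.path(outdir, "pfm.tsv"))
    manifest <- list(
      tool = "endovseq",
      version = as.character(utils::packageVersion("endovseq")),
      timestamp = format(Sys.time(), tz = "UTC"),
      seed = config$seed,
      config = unclass(config),
      scoring = unclass(params),
      threshold = threshold,
      n_offtargets_per_guide = n_offtargets_per_guide,
      cleavage_fraction = cleavage_fraction,
      guides = lapply(guides, unclass),
      n_reads = nrow(sim$reads),
      n_sites_called = nrow(sites)
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(simulation = sim, counts = counts, track = track, sites = sites,
       annotated = annotated, allocation = allocation, pfm = pfm)
}

#' Command line interface
#'
#' Subcommand dispatcher for use with `Rscript -e 'endovseq::endov_cli()'`.
#' Subcommands: `simulate`, `tally`, `score`, `call`, `annotate`,
#' `allocate`, `compare`, `report`, `pipeline`.  Run a subcommand with
#' `--help` for its flags.  Any flag may also be supplied through a JSON
#' config file (`--config`); explicit flags win.
#'
#' @param args Character vector of arguments (defaults to the command
#'   line).
#' @return Invisibly, the subcommand's result.
#' @export
endov_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: endov_cli <simulate|tally|score|call|annotate|",
                 "allocate|compare|report|pipeline> [flags]", sep = "")
  if (!length(args)) {
    message(usage)
    return(invisible(NULL))
  }
  sub <- args[1]
  rest <- args[-1]
  handler <- switch(sub,
                    simulate = cli_simulate, tally = cli_tally,
                    score = cli_score, call = cli_call,
                    annotate = cli_annotate, allocate = cli_allocate,
                    compare = cli_compare, report = cli_report,
                    pipeline = cli_pipeline,
                    stop("unknown subcommand '", sub, "'\n", usage,
                         call. = FALSE))
  invisible(handler(rest))
}

# internal: merge JSON config file values under explicit flags
cli_opts <- function(parser, args) {
  opt <- optparse::parse_args(parser, args = args)
  if (!is.null(opt$config) && nzchar(opt$config)) {
    cfg <- jsonlite::read_json(opt$config, simplifyVector = TRUE)
    supplied <- sub("^--?", "", grep("^--", args, value = TRUE))
    supplied <- sub("=.*$", "", supplied)
    for (nm in setdiff(names(cfg), supplied)) opt[[nm]] <- cfg[[nm]]
  }
  opt
}

cli_common_sim <- function() {
  list(
    optparse::make_option("--genome-length", type = "double", default = 1e6,
                          dest = "genome_length"),
    optparse::make_option("--gc-content", type = "double", default = 0.41,
                          dest = "gc_content"),
    optparse::make_option("--depth", type = "double", default = 35),
    optparse::make_option("--fragment-mean", type = "double", default = 450,
                          dest = "fragment_mean"),
    optparse::make_option("--fragment-sd", type = "double", default = 30,
                          dest = "fragment_sd"),
    optparse::make_option("--read-length", type = "integer", default = 150L,
                          dest = "read_length"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--config", type = "character", default = NULL)
  )
}

cli_guides <- function(opt) {
  if (!is.null(opt$guides) && nzchar(opt$guides)) read_guides(opt$guides)
  else multiplex_guides()
}

cli_simulate <- function(args) {
  parser <- optparse::OptionParser(option_list = c(cli_common_sim(), list(
    optparse::make_option("--guides", type = "character", default = NULL),
    optparse::make_option("--offtargets", type = "integer", default = 2L),
    optparse::make_option("--cleavage-fraction", type = "double",
                          default = 1.0, dest = "cleavage_fraction"),
    optparse::make_option("--outdir", type = "character", default = "endov_sim")
  )))
  opt <- cli_opts(parser, args)
  cfg <- sim_config(genome_length = opt$genome_length,
                    gc_content = opt$gc_content, depth = opt$depth,
                    fragment_mean = opt$fragment_mean,
                    fragment_sd = opt$fragment_sd,
                    read_length = opt$read_length, seed = opt$seed)
  dir.create(opt$outdir, recursive = TRUE, showWarnings = FALSE)
  ref <- generate_reference(cfg)
  sim <- plant_and_simulate(
    ref, cli_guides(opt), n_offtargets_per_guide = opt$offtargets,
    config = cfg, cleavage_fraction = opt$cleavage_fraction,
    sam = file.path(opt$outdir, "reads.sam"),
    registry_path = file.path(opt$outdir, "registry.tsv"))
  Biostrings::writeXStringSet(sim$reference,
                              file.path(opt$outdir, "reference.fa"))
  jsonlite::write_json(list(seed = cfg$seed, config = unclass(cfg)),
                       file.path(opt$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message("simulate: ", nrow(sim$reads), " reads, ",
          nrow(sim$registry), " planted sites -> ", opt$outdir)
  invisible(sim)
}

cli_tally <- function(args) {
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--sam", type = "character"),
    optparse::make_option("--min-mapq", type = "integer", default = 1L,
                          dest = "min_mapq"),
    optparse::make_option("--out", type = "character", default = "counts.tsv"),
    optparse::make_option("--config", type = "character", default = NULL)
  ))
  opt <- cli_opts(parser, args)
  counts <- tally_positions(load_alignments(opt$sam, opt$min_mapq))
  write_counts(counts, opt$out)
  message("tally: ", counts$n_forward + counts$n_reverse, " reads -> ",
          opt$out)
  invisible(counts)
}

cli_score <- function(args) {
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--counts", type = "character"),
    optparse::make_option("--min-start-reads", type = "integer", default = 2L,
                          dest = "min_start_reads"),
    optparse::make_option("--out", type = "character", default = "scores.tsv"),
    optparse::make_option("--bedgraph", type = "character", default = NULL),
    optparse::make_option("--config", type = "character", default = NULL)
  ))
  opt <- cli_opts(parser, args)
  track <- score_genome(read_counts(opt$counts),
                        scoring_params(min_start_reads = opt$min_start_reads))
  write_score_track(track, opt$out)
  if (!is.null(opt$bedgraph))
    write_score_track(track, opt$bedgraph, format = "bedgraph")
  message("score: ", nrow(track), " positive positions -> ", opt$out)
  invisible(track)
}

cli_call <- function(args) {
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--scores", type = "character"),
    optparse::make_option("--threshold", type = "double", default = 2.5),
    optparse::make_option("--merge-window", type = "integer", default = 20L,
                          dest = "merge_window"),
    optparse::make_option("--out", type = "character", default = "sites.tsv"),
    optparse::make_option("--config", type = "character", default = NULL)
  ))
  opt <- cli_opts(parser, args)
  track <- utils::read.delim(opt$scores)
  sites <- call_sites(track, opt$threshold, opt$merge_window)
  utils::write.table(sites, opt$out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message("call: ", nrow(sites), " sites at threshold ", opt$threshold,
          " -> ", opt$out)
  invisible(sites)
}

cli_annotate <- function(args) {
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--sites", type = "character"),
    optparse::make_option("--reference", type = "character"),
    optparse::make_option("--guides", type = "character", default = NULL),
    optparse::make_option("--search-radius", type = "integer", default = 25L,
                          dest = "search_radius"),
    optparse::make_option("--out", type = "character",
                          default = "sites_annotated.tsv"),
    optparse::make_option("--bed", type = "character", default = NULL),
    optparse::make_option("--config", type = "character", default = NULL)
  ))
  opt <- cli_opts(parser, args)
  sites <- utils::read.delim(opt$sites)
  ann <- annotate_sites(sites, opt$reference, cli_guides(opt),
                        opt$search_radius)
  utils::write.table(ann, opt$out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(opt$bed)) write_sites_bed(ann, opt$bed)
  n_nopam <- sum(!ann$pam_ok)
  if (n_nopam) warning(n_nopam, " site(s) without a PAM-bearing match",
                       call. = FALSE)
  message("annotate: ", nrow(ann), " sites -> ", opt$out)
  invisible(ann)
}

cli_allocate <- function(args) {
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--sites", type = "character"),
    optparse::make_option("--guides", type = "character", default = NULL),
    optparse::make_option("--include-pam", action = "store_true",
                          default = FALSE, dest = "include_pam"),
    optparse::make_option("--out", type = "character",
                          default = "allocation.tsv"),
    optparse::make_option("--matrix", type = "character", default = NULL),
    optparse::make_option("--config", type = "character", default = NULL)
  ))
  opt <- cli_opts(parser, args)
  guides <- cli_guides(opt)
  sites <- utils::read.delim(opt$sites)
  alloc <- allocate_sites(sites, guides, include_pam = opt$include_pam)
  utils::write.table(alloc, opt$out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(opt$matrix)) {
    m <- build_distance_matrix(guides, include_pam = opt$include_pam)
    utils::write.table(as.data.frame(unclass(m)), opt$matrix, sep = "\t",
                       quote = FALSE)
  }
  n_tie <- sum(alloc$allocation_tie)
  if (n_tie) warning(n_tie, " allocation tie(s)", call. = FALSE)
  message("allocate: ", nrow(alloc), " sites over ", length(guides),
          " guides -> ", opt$out)
  invisible(alloc)
}

cli_compare <- function(args) {
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--a", type = "character"),
    optparse::make_option("--b", type = "character"),
    optparse::make_option("--tolerance", type = "integer", default = 25L),
    optparse::make_option("--out", type = "character", default = NULL),
    optparse::make_option("--config", type = "character", default = NULL)
  ))
  opt <- cli_opts(parser, args)
  cmp <- compare_site_lists(utils::read.delim(opt$a),
                            utils::read.delim(opt$b), opt$tolerance)
  msg <- sprintf("compare: only_a=%d shared=%d only_b=%d",
                 cmp$only_a, cmp$shared, cmp$only_b)
  if (!is.null(opt$out))
    jsonlite::write_json(cmp[c("only_a", "only_b", "shared")], opt$out,
                         auto_unbox = TRUE)
  message(msg)
  invisible(cmp)
}

cli_report <- function(args) {
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--sites", type = "character"),
    optparse::make_option("--out", type = "character", default = "pfm.tsv"),
    optparse::make_option("--config", type = "character", default = NULL)
  ))
  opt <- cli_opts(parser, args)
  pfm <- position_frequency_matrix(utils::read.delim(opt$sites))
  write_pfm(pfm, opt$out)
  message("report: PFM over ", pfm$n_sites, " sites -> ", opt$out)
  invisible(pfm)
}

cli_pipeline <- function(args) {
  parser <- optparse::OptionParser(option_list = c(cli_common_sim(), list(
    optparse::make_option("--guides", type = "character", default = NULL),
    optparse::make_option("--offtargets", type = "integer", default = 2L),
    optparse::make_option("--cleavage-fraction", type = "double",
                          default = 1.0, dest = "cleavage_fraction"),
    optparse::make_option("--threshold", type = "double", default = 2.5),
    optparse::make_option("--outdir", type = "character",
                          default = "endov_run")
  )))
  opt <- cli_opts(parser, args)
  cfg <- sim_config(genome_length = opt$genome_length,
                    gc_content = opt$gc_content, depth = opt$depth,
                    fragment_mean = opt$fragment_mean,
                    fragment_sd = opt$fragment_sd,
                    read_length = opt$read_length, seed = opt$seed)
  res <- run_pipeline(cli_guides(opt), cfg,
                      n_offtargets_per_guide = opt$offtargets,
                      cleavage_fraction = opt$cleavage_fraction,
                      threshold = opt$threshold, outdir = opt$outdir)
  message("pipeline: ", nrow(res$sites), " sites called -> ", opt$outdir)
  invisible(res)
}
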