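#' Simulator configuration
#'
#' Emulates the wet protocol: genomic DNA fragmented to 400-500 bp, blunt
#' end repaired and sequenced at 30-40x depth, hence the defaults of 450/30
#' bp fragments, 35x depth and 150 bp reads.
#'
#' @param genome_length Reference length in bp (default 1e6; minimum 1e4).
#' @param gc_content GC fraction of the random reference (default 0.41,
#'   human-like).
#' @param depth Target mean read depth (default 35).
#' @param fragment_mean,fragment_sd Fragment length distribution in bp
#'   (defaults 450 and 30; lengths are truncated below at 50 bp).
#' @param read_length Read length in bp (default 150).
#' @param seed Integer seed driving every random choice of a run.
#' @return A `sim_config` object.
#' @export
sim_config <- function(genome_length = 1e6, gc_content = 0.41, depth = 35,
                       fragment_mean = 450, fragment_sd = 30,
                       read_length = 150L, seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              gc_content = gc_content, depth = depth,
              fragment_mean = fragment_mean, fragment_sd = fragment_sd,
              read_length = as.integer(read_length), seed = as.integer(seed))
  if (cfg$depth <= 0) stop("depth must be positive", call. = FALSE)
  if (cfg$fragment_mean <= cfg$read_length)
    stop("fragment mean must exceed the read length", call. = FALSE)
  if (cfg$gc_content < 0 || cfg$gc_content > 1)
    stop("gc_content must be in [0, 1]", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Generate a random reference sequence
#'
#' i.i.d. bases with the configured GC content; deterministic for a fixed
#' seed.
#'
#' @param config A [sim_config()].
#' @param chrom Chromosome name (default `"chr1"`).
#' @param fasta Optional path; when given the sequence is also written as
#'   FASTA.
#' @return A `DNAStringSet` with one sequence.
#' @export
generate_reference <- function(config = sim_config(), chrom = "chr1",
                               fasta = NULL) {
  if (config$genome_length < 1e4)
    stop("genome_length must be at least 10 kb", call. = FALSE)
  set.seed(config$seed)
  gc <- config$gc_content
  bases <- sample(c("A", "C", "G", "T"), config$genome_length,
                  replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  ref <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(ref) <- chrom
  if (!is.null(fasta)) Biostrings::writeXStringSet(ref, fasta)
  ref
}

# internal: pick mismatch positions with a PAM-distal bias (position 1 is
# PAM-distal) and mutate; the chosen edited-A position is protected
mutate_protospacer <- function(proto, k, protect) {
  n <- nchar(proto)
  if (k == 0L) return(proto)
  s <- strsplit(proto, "")[[1]]
  pool <- setdiff(seq_len(n), protect)
  wts <- (n - pool + 1)                 # linear bias toward the distal end
  pos <- sample(pool, k, prob = wts)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
  paste(s, collapse = "")
}

# internal: cut coordinates for a planted site.
# Forward-strand site with protospacer at [p, p+L): the deaminated A sits at
# 0-based protospacer offset a0 (within the deamination window); the EndoV
# nick on the edited strand is the inter-base coordinate p + a0 + 1 and the
# nCas9 nick on the opposite strand is p + L - 3 (between protospacer
# positions L-3 and L-2, i.e. 3 bp 5' of the PAM).  Geometry mirrors for
# reverse-strand sites.
site_nicks <- function(p, L, a0, strand) {
  if (strand == "+") {
    list(top = p + a0 + 1L, bottom = p + L - 3L)
  } else {
    list(top = p + L - a0 - 1L, bottom = p + 3L)
  }
}

#' Plant cleavage events and simulate WGS reads
#'
#' Writes one on-target and `n_offtargets_per_guide` mismatched off-target
#' protospacer+PAM copies per guide into the reference, then simulates
#' whole-genome sequencing: molecules with normal fragment lengths and
#' uniform starts; a fraction `cleavage_fraction` of the molecules spanning
#' a planted site is split there.  Each cleavage event nicks both strands
#' with the characteristic stagger (EndoV one residue 3' of the inosine on
#' the edited strand, nCas9 between protospacer positions 17 and 18 of the
#' other strand); after blunt-end repair the upstream fragment ends at the
#' downstream nick and the downstream fragment begins at the upstream nick
#' (5'-overhang fill-in), so both cut coordinates surface as read 5' ends.
#' Reads of `read_length` are taken from both ends of every fragment.
#'
#' @param reference `DNAStringSet` (single sequence) from
#'   [generate_reference()], or a FASTA path.
#' @param guides A `guide_rna` or list of them.
#' @param n_offtargets_per_guide Off-target sites planted per guide
#'   (default 0).
#' @param mismatch_range Integer range of off-target mismatch counts
#'   (default `1:3`).
#' @param config A [sim_config()]; its `seed` makes the run reproducible.
#' @param cleavage_fraction Probability that a molecule spanning a planted
#'   site is cut there (default 1: the in vitro digestion is near-complete).
#' @param sam Optional output SAM path.
#' @param registry_path Optional output TSV path for the ground-truth
#'   registry.
#' @return List with `reads` (data frame as in [load_alignments()], with
#'   `chrom_lengths` attached), `registry` (one row per planted site:
#'   `guide`, `chrom`, `protospacer_start`, `strand`, `mismatches`,
#'   `edited_A_offset` 0-based, `cleavage_fraction`, `top_nick`,
#'   `bottom_nick`, `planted_protospacer`), and `reference` (the mutated
#'   `DNAStringSet`).
#' @export
plant_and_simulate <- function(reference, guides,
                               n_offtargets_per_guide = 0L,
                               mismatch_range = 1:3,
                               config = sim_config(),
                               cleavage_fraction = 1.0,
                               sam = NULL, registry_path = NULL) {
  ref <- as_reference(reference)
  if (length(ref) != 1L)
    stop("the simulator plants on a single-sequence reference", call. = FALSE)
  if (inherits(guides, "guide_rna")) guides <- list(guides)
  if (any(cleavage_fraction < 0 | cleavage_fraction > 1))
    stop("cleavage_fraction must lie in [0, 1]", call. = FALSE)
  chrom <- names(ref)
  G <- length(ref[[1]])
  set.seed(config$seed + 1L)

  # --- plant sites -------------------------------------------------------
  n_sites <- length(guides) * (1L + n_offtargets_per_guide)
  margin <- 600L
  spacing <- 200L
  seqchr <- as.character(ref[[1]])
  registry <- NULL
  occupied <- integer(0)
  cf <- rep_len(cleavage_fraction, n_sites)
  site_idx <- 0L
  for (g in guides) {
    L <- nchar(g$protospacer)
    npam <- nchar(g$pam)
    for (k_mm in c(0L, sample(rep(mismatch_range, length.out =
                                    max(n_offtargets_per_guide, 1L)),
                              n_offtargets_per_guide))) {
      site_idx <- site_idx + 1L
      # choose a placement clear of other sites
      for (try in 1:1000) {
        p <- sample.int(G - 2L * margin, 1L) + margin
        if (!any(abs(p - occupied) < spacing)) break
        if (try == 1000)
          stop("could not place non-overlapping sites; genome too small",
               call. = FALSE)
      }
      occupied <- c(occupied, p)
      strand <- sample(c("+", "-"), 1L)
      # choose the edited A: an A of the window kept intact by the mutations
      wd <- g$deamination_window
      wpos <- wd[1]:wd[2]
      proto_chars <- strsplit(g$protospacer, "")[[1]]
      a_candidates <- wpos[proto_chars[wpos] == "A"]
      if (!length(a_candidates)) {
        # guide has no window A: force one so deamination is possible
        forced <- sample(wpos, 1L)
        proto_chars[forced] <- "A"
        a_candidates <- forced
      }
      edited_pos1 <- if (length(a_candidates) == 1L) a_candidates else
        sample(a_candidates, 1L)
      planted <- mutate_protospacer(paste(proto_chars, collapse = ""),
                                    k_mm, protect = edited_pos1)
      pam_concrete <- paste(vapply(strsplit(g$pam, "")[[1]], function(ch) {
        b <- iupac_bases(ch)
        if (length(b) == 1L) b else sample(b, 1L)
      }, character(1)), collapse = "")
      cassette <- paste0(planted, pam_concrete)
      if (strand == "+") {
        substr(seqchr, p + 1L, p + L + npam) <- cassette
        proto_start <- p
      } else {
        substr(seqchr, p + 1L, p + L + npam) <- revcomp(cassette)
        proto_start <- p + npam            # protospacer genome interval start
      }
      nicks <- site_nicks(proto_start, L, edited_pos1 - 1L, strand)
      mm_actual <- sum(strsplit(planted, "")[[1]] !=
                         strsplit(g$protospacer, "")[[1]])
      registry <- rbind(registry, data.frame(
        guide = g$name, chrom = chrom, protospacer_start = proto_start,
        strand = strand, mismatches = mm_actual,
        edited_A_offset = edited_pos1 - 1L,
        cleavage_fraction = cf[site_idx],
        top_nick = nicks$top, bottom_nick = nicks$bottom,
        planted_protospacer = planted, stringsAsFactors = FALSE))
    }
  }
  ref_out <- Biostrings::DNAStringSet(seqchr)
  names(ref_out) <- chrom

  # --- fragment and cut --------------------------------------------------
  rl <- config$read_length
  n_frag <- round(config$depth * G / (2 * rl))
  flen <- pmax(50L, as.integer(round(stats::rnorm(n_frag, config$fragment_mean,
                                                  config$fragment_sd))))
  fs <- as.integer(floor(stats::runif(n_frag) * (G - flen + 1L)))
  fe <- fs + flen

  cut_lo <- pmin(registry$top_nick, registry$bottom_nick)
  cut_hi <- pmax(registry$top_nick, registry$bottom_nick)
  ord <- order(cut_lo)
  cut_lo <- cut_lo[ord]
  cut_hi <- cut_hi[ord]
  cf_ord <- registry$cleavage_fraction[ord]

  frag_a <- fs
  frag_b <- fe
  for (s in seq_along(cut_lo)) {
    span <- which(frag_a < cut_lo[s] & frag_b > cut_hi[s])
    if (!length(span)) next
    cut <- span[stats::runif(length(span)) < cf_ord[s]]
    if (!length(cut)) next
    # upstream piece keeps [a, cut_hi); downstream piece becomes
    # [cut_lo, b) and is appended for possible further cuts downstream
    new_a <- rep(cut_lo[s], length(cut))
    new_b <- frag_b[cut]
    frag_b[cut] <- cut_hi[s]
    frag_a <- c(frag_a, new_a)
    frag_b <- c(frag_b, new_b)
  }

  # --- reads from fragment ends -----------------------------------------
  w <- pmin(rl, frag_b - frag_a)
  reads <- data.frame(
    chrom = chrom,
    strand = rep(c("+", "-"), each = length(frag_a)),
    start = c(frag_a, frag_b - w),
    end = c(frag_a + w, frag_b),
    mapq = 60L,
    stringsAsFactors = FALSE
  )
  attr(reads, "chrom_lengths") <- structure(G, names = chrom)

  if (!is.null(sam)) write_sim_sam(reads, ref_out, sam)
  if (!is.null(registry_path))
    utils::write.table(registry, registry_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(reads = reads, registry = registry, reference = ref_out)
}

#' Write simulated reads as SAM
#'
#' Emits a headered, unpaired SAM with sequences taken from the reference
#' (reverse-complemented for reverse reads) and uniform high base quality;
#' the score uses only coordinates, so no error model is applied.
#'
#' @param reads Read data frame from [plant_and_simulate()].
#' @param reference The (mutated) reference `DNAStringSet`.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sim_sam <- function(reads, reference, path) {
  ref <- as_reference(reference)
  cl <- attr(reads, "chrom_lengths")
  if (is.null(cl))
    cl <- structure(vapply(seq_along(ref), function(i) length(ref[[i]]),
                           integer(1)), names = names(ref))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(cl), cl), con)
  if (nrow(reads)) {
    o <- order(reads$chrom, reads$start)
    reads <- reads[o, ]
    w <- reads$end - reads$start
    seqs <- character(nrow(reads))
    for (ch in unique(reads$chrom)) {
      sel <- reads$chrom == ch
      v <- Biostrings::Views(ref[[ch]], start = reads$start[sel] + 1L,
                             end = reads$end[sel])
      s <- as.character(Biostrings::DNAStringSet(v))
      rev <- reads$strand[sel] == "-"
      if (any(rev)) s[rev] <- revcomp(s[rev])
      seqs[sel] <- s
    }
    writeLines(sprintf("read%06d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                       seq_len(nrow(reads)),
                       ifelse(reads$strand == "-", 16L, 0L),
                       reads$chrom, reads$start + 1L, reads$mapq, w,
                       seqs, strrep("I", w)), con)
  }
  invisible(path)
}

#' Mix treated and untreated read sets (dilution experiment)
#'
#' Emulates diluting editor-treated genomic DNA with untreated DNA before
#' sequencing: the output keeps the treated pool's total read count, with a
#' `1/dilution_factor` proportion subsampled (without replacement) from the
#' treated reads and the remainder from the untreated reads.
#'
#' @param treated,untreated Read data frames (same columns as
#'   [plant_and_simulate()] output).
#' @param dilution_factor Dilution factor >= 1 (1 returns the treated set).
#' @param seed Integer seed.
#' @return A read data frame with `chrom_lengths` attribute taken from
#'   `treated`.
#' @export
mix_datasets <- function(treated, untreated, dilution_factor, seed = 1L) {
  if (dilution_factor < 1) stop("dilution_factor must be >= 1", call. = FALSE)
  n <- nrow(treated)
  n_t <- round(n / dilution_factor)
  n_u <- n - n_t
  if (n_u > nrow(untreated))
    stop("untreated pool too small: need ", n_u, " reads, have ",
         nrow(untreated), call. = FALSE)
  set.seed(seed)
  out <- rbind(treated[sample.int(n, n_t), ],
               untreated[sample.int(nrow(untreated), n_u), ])
  rownames(out) <- NULL
  attr(out, "chrom_lengths") <- attr(treated, "chrom_lengths")
  out
}

#' Realised mean depth of a read set
#'
#' @param reads Read data frame.
#' @param chrom_lengths Chromosome lengths (defaults to the attached
#'   attribute).
#' @return Mean per-base depth across the genome.
#' @export
mean_depth <- function(reads, chrom_lengths = attr(reads, "chrom_lengths")) {
  sum(as.numeric(reads$end - reads$start)) / sum(as.numeric(chrom_lengths))
}
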