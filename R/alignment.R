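#' Load read alignments from SAM/BAM
#'
#' Parses a SAM or BAM file into the minimal read representation the scoring
#' pipeline needs: one row per primary, mapped alignment, with 0-based
#' half-open reference coordinates.  Unmapped, secondary and supplementary
#' records are skipped, as are records below `min_mapq`.  Soft-clipped bases
#' never shift the counted alignment ends: the span is the CIGAR
#' reference-consumed span.
#'
#' @param path Path to a SAM (`.sam`) or BAM file whose header declares
#'   sequence lengths.
#' @param min_mapq Minimum mapping quality kept (default 1, which drops
#'   MAPQ-0 multimappers whose coincident ends would fabricate signal).
#' @return A `data.frame` with columns `chrom`, `strand` (`"+"`/`"-"`),
#'   `start`, `end` (0-based half-open), `mapq`, carrying the header's
#'   chromosome lengths in `attr(, "chrom_lengths")`.
#' @export
load_alignments <- function(path, min_mapq = 1L) {
  if (!file.exists(path)) stop("alignment file not found: ", path,
                               call. = FALSE)
  bam <- as_bam(path)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  if (length(hdr$targets) == 0L)
    stop("SAM/BAM header of ", path, " declares no sequence lengths",
         call. = FALSE)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("rname", "strand", "pos", "cigar", "mapq"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(rec$pos) & !is.na(rec$mapq) & rec$mapq >= min_mapq
  width <- integer(0)
  if (any(keep))
    width <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar[keep])
  reads <- data.frame(
    chrom = as.character(rec$rname[keep]),
    strand = ifelse(as.character(rec$strand[keep]) == "-", "-", "+"),
    start = rec$pos[keep] - 1L,
    end = rec$pos[keep] - 1L + width,
    mapq = rec$mapq[keep],
    stringsAsFactors = FALSE
  )
  attr(reads, "chrom_lengths") <- hdr$targets
  reads
}

# internal: SAM text -> temporary BAM; BAM passed through
as_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    out <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("malformed SAM ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    out
  } else {
    path
  }
}

#' Tally per-position depth and read-start counts
#'
#' Reduces reads to the three per-position arrays the cleavage score
#' consumes: sequencing depth `D`, forward-strand 5' read starts `F`, and
#' reverse-strand 5' read ends `R`.  Coordinates are 0-based.  `F[i]` counts
#' forward reads whose leftmost aligned base is `i`.  For reverse reads the
#' 5' terminus is the rightmost aligned base; with the default
#' `reverse_five_prime = "nick"` convention its count is recorded at the
#' half-open end coordinate (the inter-base cut position just 3' of that
#' base), so that a blunt fragment boundary at cut coordinate `c` places
#' forward starts and reverse ends at the same `c`.  Set
#' `reverse_five_prime = "base"` to record it at the rightmost covered base
#' (`end - 1`) instead.
#'
#' @param reads Data frame as returned by [load_alignments()] or
#'   [plant_and_simulate()].
#' @param chrom_lengths Named integer vector of chromosome lengths; defaults
#'   to `attr(reads, "chrom_lengths")`.
#' @param reverse_five_prime Either `"nick"` (default) or `"base"`; see
#'   Details.
#' @return A `position_counts` object: per-chromosome integer vectors `D`,
#'   `F`, `R`, each of length `chrom_length + 1` so that the terminal nick
#'   coordinate is representable (index `j` holds 0-based position `j - 1`).
#' @export
tally_positions <- function(reads, chrom_lengths = attr(reads, "chrom_lengths"),
                            reverse_five_prime = c("nick", "base")) {
  reverse_five_prime <- match.arg(reverse_five_prime)
  if (is.null(chrom_lengths))
    stop("chrom_lengths missing and not attached to reads", call. = FALSE)
  chrom_lengths <- structure(as.integer(chrom_lengths),
                             names = names(chrom_lengths))
  bad_chrom <- setdiff(unique(reads$chrom), names(chrom_lengths))
  if (length(bad_chrom))
    stop("reads on undeclared chromosome(s): ",
         paste(bad_chrom, collapse = ", "), call. = FALSE)
  over <- reads$end > chrom_lengths[reads$chrom] | reads$start < 0L
  if (any(over)) {
    i <- which(over)[1]
    stop(sprintf("read beyond chromosome end: %s:[%d,%d) on %s of length %d",
                 reads$chrom[i], reads$start[i], reads$end[i], reads$chrom[i],
                 chrom_lengths[reads$chrom[i]]), call. = FALSE)
  }
  if (any(reads$start >= reads$end))
    stop("read with empty span (start >= end)", call. = FALSE)

  counts <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    n <- L + 1L                      # indices 1..L+1 <-> positions 0..L
    sel <- reads$chrom == ch
    s <- reads$start[sel]
    e <- reads$end[sel]
    fwd <- reads$strand[sel] == "+"
    # depth via difference array over covered bases [s, e)
    inc <- integer(n + 1L)
    if (any(sel)) {
      t1 <- tabulate(s + 1L, nbins = n + 1L)
      t2 <- tabulate(e + 1L, nbins = n + 1L)
      inc <- t1 - t2
    }
    D <- cumsum(inc)[seq_len(n)]
    F_ <- tabulate(s[fwd] + 1L, nbins = n)
    rpos <- if (reverse_five_prime == "nick") e[!fwd] else e[!fwd] - 1L
    R_ <- tabulate(rpos + 1L, nbins = n)
    list(D = as.integer(D), F = F_, R = R_)
  })
  names(counts) <- names(chrom_lengths)
  structure(
    list(chrom_lengths = chrom_lengths, counts = counts,
         n_forward = sum(reads$strand == "+"),
         n_reverse = sum(reads$strand == "-"),
         reverse_five_prime = reverse_five_prime),
    class = "position_counts"
  )
}

#' @export
print.position_counts <- function(x, ...) {
  cat(sprintf("<position_counts> %d chromosome(s), %d forward / %d reverse reads (reverse 5' at %s)\n",
              length(x$chrom_lengths), x$n_forward, x$n_reverse,
              x$reverse_five_prime))
  invisible(x)
}

#' Write / read the counts sidecar
#'
#' Serialises a `position_counts` object to a tab-separated table with
#' columns `chrom`, `pos` (0-based), `D`, `F`, `R`, one row per position
#' where any of the three counts is non-zero.  Chromosome lengths and the
#' reverse-read convention are stored in `#`-prefixed header lines so the
#' round-trip is lossless.
#'
#' @param counts A `position_counts` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#chrom_lengths\t%s",
                     paste(sprintf("%s:%d", names(counts$chrom_lengths),
                                   counts$chrom_lengths), collapse = ",")),
             con)
  writeLines(sprintf("#reverse_five_prime\t%s", counts$reverse_five_prime),
             con)
  writeLines("chrom\tpos\tD\tF\tR", con)
  for (ch in names(counts$counts)) {
    cc <- counts$counts[[ch]]
    j <- which(cc$D > 0L | cc$F > 0L | cc$R > 0L)
    if (!length(j)) next
    writeLines(sprintf("%s\t%d\t%d\t%d\t%d", ch, j - 1L,
                       cc$D[j], cc$F[j], cc$R[j]), con)
  }
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  cl_line <- sub("^#chrom_lengths\t", "", hdr[startsWith(hdr, "#chrom_lengths")])
  if (!length(cl_line)) stop("counts sidecar lacks #chrom_lengths header",
                             call. = FALSE)
  parts <- strsplit(strsplit(cl_line, ",")[[1]], ":")
  chrom_lengths <- structure(vapply(parts, function(p) as.integer(p[2]),
                                    integer(1)),
                             names = vapply(parts, `[`, character(1), 1))
  conv <- sub("^#reverse_five_prime\t", "",
              hdr[startsWith(hdr, "#reverse_five_prime")])
  if (!length(conv)) conv <- "nick"
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")])
  counts <- lapply(names(chrom_lengths), function(ch) {
    n <- chrom_lengths[[ch]] + 1L
    sel <- tab$chrom == ch
    mk <- function(col) {
      v <- integer(n)
      v[tab$pos[sel] + 1L] <- as.integer(col[sel])
      v
    }
    list(D = mk(tab$D), F = mk(tab$F), R = mk(tab$R))
  })
  names(counts) <- names(chrom_lengths)
  structure(
    list(chrom_lengths = chrom_lengths, counts = counts,
         n_forward = sum(tab$F), n_reverse = sum(tab$R),
         reverse_five_prime = conv),
    class = "position_counts"
  )
}

# internal: invariant checks used by tests and the simulator coupling
validate_counts <- function(counts) {
  for (ch in names(counts$counts)) {
    cc <- counts$counts[[ch]]
    stopifnot(all(cc$D >= 0L), all(cc$F >= 0L), all(cc$R >= 0L))
    stopifnot(all(cc$F <= cc$D))
    if (counts$reverse_five_prime == "nick") {
      # a read ending at nick coordinate c covers base c-1
      stopifnot(all(cc$R[-1] <= cc$D[-length(cc$D)]))
    } else {
      stopifnot(all(cc$R <= cc$D))
    }
  }
  invisible(TRUE)
}
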