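#' Position frequency matrix of captured sites
#'
#' Tallies per-position base composition over a set of equal-length matched
#' sequences (protospacer+PAM, guide orientation), the numeric form of a
#' sequence logo.
#'
#' @param sites Annotated site data frame (uses `matched_sequence`) or a
#'   character vector of equal-length DNA strings.
#' @return A `position_frequency_matrix`: list with integer `counts` (4 x L,
#'   rows A/C/G/T), numeric `frequencies` (columns sum to 1), and
#'   `n_sites`.
#' @export
position_frequency_matrix <- function(sites) {
  seqs <- if (is.character(sites)) sites else sites$matched_sequence
  if (is.null(seqs) || !length(seqs))
    stop("no sequences to tally", call. = FALSE)
  seqs <- toupper(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("matched sequences have mixed lengths: ",
         paste(sort(L), collapse = ", "), call. = FALSE)
  mat <- do.call(rbind, strsplit(seqs, ""))
  counts <- vapply(seq_len(L), function(j)
    c(A = sum(mat[, j] == "A"), C = sum(mat[, j] == "C"),
      G = sum(mat[, j] == "G"), T = sum(mat[, j] == "T")),
    integer(4))
  freqs <- sweep(counts, 2L, pmax(colSums(counts), 1L), "/")
  structure(list(counts = counts, frequencies = freqs,
                 n_sites = length(seqs), length = L),
            class = "position_frequency_matrix")
}

#' @export
print.position_frequency_matrix <- function(x, ...) {
  cat(sprintf("<position_frequency_matrix> %d sites x %d positions\n",
              x$n_sites, x$length))
  print(round(x$frequencies, 3))
  invisible(x)
}

#' Write a position frequency matrix
#'
#' Tab-separated position x base table of proportions (plus counts columns).
#'
#' @param pfm A [position_frequency_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path) {
  tab <- data.frame(pos = seq_len(pfm$length),
                    t(pfm$frequencies),
                    t(pfm$counts))
  names(tab) <- c("pos", "A", "C", "G", "T",
                  "count_A", "count_C", "count_G", "count_T")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-position base counts and A-to-G conversion frequency
#'
#' A minimal amplicon readout: piles up aligned read bases over a reference
#' amplicon and reports, at every reference-A position, the A-to-G
#' conversion frequency `G / (A + G)`.  Positions with zero coverage are
#' reported as `NA`, not 0 (no evidence is not evidence of absence).
#'
#' @param alignments SAM/BAM path with reads aligned to the amplicon.
#' @param reference The amplicon reference (`DNAStringSet`, FASTA path, or
#'   character string).
#' @return `data.frame(chrom, pos, ref, A, C, G, T, depth, conversion)` with
#'   0-based positions; `conversion` is non-`NA` only at covered
#'   reference-A positions.
#' @export
conversion_frequency <- function(alignments, reference) {
  ref <- as_reference(reference)
  bam <- as_bam(alignments)
  sorted <- tempfile()
  bam <- Rsamtools::sortBam(bam, sorted)
  Rsamtools::indexBam(bam)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  bad <- setdiff(names(hdr), names(ref))
  if (length(bad) || any(hdr[names(hdr)] !=
                         vapply(names(hdr), function(ch) length(ref[[ch]]),
                                integer(1))))
    stop("alignment header does not match the amplicon reference",
         call. = FALSE)
  pp <- Rsamtools::PileupParam(max_depth = 100000L, min_base_quality = 0L,
                               min_mapq = 0L, min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  p <- Rsamtools::pileup(bam, pileupParam = pp)
  out <- do.call(rbind, lapply(names(hdr), function(ch) {
    L <- hdr[[ch]]
    refchars <- strsplit(as.character(ref[[ch]]), "")[[1]]
    counts <- matrix(0L, nrow = L, ncol = 4,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
    sel <- p$seqnames == ch & p$nucleotide %in% c("A", "C", "G", "T")
    if (any(sel))
      counts[cbind(p$pos[sel],
                   match(as.character(p$nucleotide[sel]),
                         c("A", "C", "G", "T")))] <- p$count[sel]
    depth <- rowSums(counts)
    conv <- rep(NA_real_, L)
    isA <- refchars == "A" & (counts[, "A"] + counts[, "G"]) > 0
    conv[isA] <- counts[isA, "G"] / (counts[isA, "A"] + counts[isA, "G"])
    data.frame(chrom = ch, pos = seq_len(L) - 1L, ref = refchars,
               A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
               T = counts[, "T"], depth = depth, conversion = conv,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
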