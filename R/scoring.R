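#' Scoring parameters
#'
#' Parameters of the per-position cleavage score.  The score couples a
#' forward read-start pileup at position `i` with reverse read-end pileups at
#' `i + forward_pair_offset + alpha` (first summation), and a reverse pileup
#' at `i + reverse_anchor_offset` with forward pileups at
#' `i + forward_back_offset + alpha` (second summation), for `alpha` in
#' `alpha_min..alpha_max`.  The defaults (8, 11, -3, alpha 1..5) encode the
#' 9-13 bp stagger expected between the deaminase/EndoV nick on the edited
#' strand and the nCas9 nick on the opposite strand.
#'
#' @param alpha_min,alpha_max Inclusive alpha range (defaults 1 and 5).
#' @param forward_pair_offset Offset added to `i` before `alpha` for the
#'   paired reverse pileup of the first summation (default 8).
#' @param reverse_anchor_offset Offset of the anchoring reverse pileup of the
#'   second summation (default 11).
#' @param forward_back_offset Offset added to `i` before `alpha` for the
#'   paired forward pileups of the second summation (default -3).
#' @param clamp_negative When `TRUE` (default) an alpha-term is zeroed unless
#'   both of its start counts reach `min_start_reads`; this removes the
#'   negative "evidence" the raw algebra assigns to lone read ends.
#' @param min_start_reads Minimum read-start count for a pileup to count as
#'   evidence (default 2).
#' @param use_offset_depth The first summation divides both factors by `D_i`
#'   exactly as the score is defined; set `TRUE` to divide the reverse factor
#'   by the depth at the reverse pileup position instead.
#' @return A `scoring_params` object.
#' @export
scoring_params <- function(alpha_min = 1L, alpha_max = 5L,
                           forward_pair_offset = 8L,
                           reverse_anchor_offset = 11L,
                           forward_back_offset = -3L,
                           clamp_negative = TRUE,
                           min_start_reads = 2L,
                           use_offset_depth = FALSE) {
  p <- list(alpha_min = as.integer(alpha_min),
            alpha_max = as.integer(alpha_max),
            forward_pair_offset = as.integer(forward_pair_offset),
            reverse_anchor_offset = as.integer(reverse_anchor_offset),
            forward_back_offset = as.integer(forward_back_offset),
            clamp_negative = isTRUE(clamp_negative),
            min_start_reads = as.integer(min_start_reads),
            use_offset_depth = isTRUE(use_offset_depth))
  if (p$alpha_min > p$alpha_max)
    stop("alpha_min must not exceed alpha_max", call. = FALSE)
  if (p$min_start_reads < 1L)
    stop("min_start_reads must be >= 1", call. = FALSE)
  structure(p, class = "scoring_params")
}

# internal: fetch v at 0-based positions, zero outside the stored range
at0 <- function(v, pos0) {
  out <- numeric(length(pos0))
  ok <- pos0 >= 0L & pos0 < length(v)
  out[ok] <- v[pos0[ok] + 1L]
  out
}

# internal: vectorised score at 0-based positions i0 given one chromosome's
# count vectors
score_at <- function(cc, i0, params) {
  ms <- params$min_start_reads
  clamp <- params$clamp_negative
  total <- numeric(length(i0))

  Fi <- at0(cc$F, i0)
  Di <- at0(cc$D, i0)
  for (a in params$alpha_min:params$alpha_max) {
    jr <- i0 + params$forward_pair_offset + a
    Ra <- at0(cc$R, jr)
    Dden <- if (params$use_offset_depth) at0(cc$D, jr) else Di
    term <- (Fi - 1) / Di * (Ra - 1) / Dden * (Fi + Ra - 2)
    bad <- Di == 0 | Dden == 0
    if (clamp) bad <- bad | Fi < ms | Ra < ms
    term[bad] <- 0
    total <- total + term
  }

  ja <- i0 + params$reverse_anchor_offset
  R11 <- at0(cc$R, ja)
  D11 <- at0(cc$D, ja)
  for (a in params$alpha_min:params$alpha_max) {
    jf <- i0 + params$forward_back_offset + a
    Fa <- at0(cc$F, jf)
    Da <- at0(cc$D, jf)
    term <- (R11 - 1) / D11 * (Fa - 1) / Da * (R11 + Fa - 2)
    bad <- D11 == 0 | Da == 0
    if (clamp) bad <- bad | R11 < ms | Fa < ms
    term[bad] <- 0
    total <- total + term
  }
  if (clamp) total <- pmax(total, 0)
  total
}

#' Cleavage score at given positions
#'
#' Evaluates the cleavage score at 0-based position(s) `i` of one
#' chromosome.  Positions whose offset references fall outside the
#' chromosome are treated as having zero counts, and any alpha-term with a
#' zero denominator contributes 0 (an uncovered position carries no
#' evidence).
#'
#' @param counts A `position_counts` object from [tally_positions()].
#' @param chrom Chromosome name.
#' @param i Integer vector of 0-based positions.
#' @param params A [scoring_params()] object.
#' @return Numeric vector of scores, one per position.
#' @examples
#' # a single cut supported by 10 forward and 10 reverse read ends at the
#' # expected stagger scores (9/20)*(9/20)*18 = 3.645
#' @export
cleavage_score <- function(counts, chrom, i, params = scoring_params()) {
  if (!chrom %in% names(counts$counts))
    stop("unknown chromosome: ", chrom, call. = FALSE)
  score_at(counts$counts[[chrom]], as.integer(i), params)
}

#' Score the whole genome
#'
#' Computes the cleavage score at every position of every chromosome and
#' returns the sparse set of positions with positive score.  With the
#' default clamping, only positions where either the forward start count at
#' `i` or the reverse end count at `i + reverse_anchor_offset` reaches
#' `min_start_reads` can score above zero, so only those are evaluated; the
#' result is identical to a full scan.  Without clamping a full scan over
#' covered positions is performed.
#'
#' @inheritParams cleavage_score
#' @return A `score_track`: `data.frame(chrom, pos, score)` sorted by
#'   chromosome and position, with `chrom_lengths` and `params` attributes.
#' @export
score_genome <- function(counts, params = scoring_params()) {
  out <- lapply(names(counts$counts), function(ch) {
    cc <- counts$counts[[ch]]
    if (params$clamp_negative) {
      ms <- params$min_start_reads
      cand <- sort(unique(c(which(cc$F >= ms) - 1L,
                            which(cc$R >= ms) - 1L -
                              params$reverse_anchor_offset)))
      cand <- cand[cand >= 0L]
    } else {
      cand <- which(cc$D > 0L) - 1L
    }
    if (!length(cand))
      return(data.frame(chrom = character(0), pos = integer(0),
                        score = numeric(0)))
    sc <- score_at(cc, cand, params)
    keep <- sc > 0
    data.frame(chrom = rep(ch, sum(keep)), pos = cand[keep],
               score = sc[keep], stringsAsFactors = FALSE)
  })
  track <- do.call(rbind, out)
  rownames(track) <- NULL
  structure(track,
            chrom_lengths = counts$chrom_lengths,
            params = params,
            class = c("score_track", "data.frame"))
}

#' Write a score track
#'
#' @param track A `score_track` from [score_genome()].
#' @param path Output path for the tab-separated table (`chrom`, `pos`
#'   0-based, `score`).
#' @param format `"tsv"` (default) or `"bedgraph"`.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path, format = c("tsv", "bedgraph")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(track)[c("chrom", "pos", "score")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("track type=bedGraph name=cleavage_score", con)
    writeLines(sprintf("%s\t%d\t%d\t%g", track$chrom, track$pos,
                       track$pos + 1L, track$score), con)
  }
  invisible(path)
}
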