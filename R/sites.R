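#' Call candidate cleavage sites from a score track
#'
#' Positions scoring above `threshold` are clustered: consecutive
#' above-threshold positions at most `merge_window` bp apart are merged into
#' one site, whose representative position is its maximum-scoring position
#' (ties broken leftmost).  The default merge window of 20 bp is one
#' protospacer+PAM footprint, so the two score peaks produced by the paired
#' nicks of one cleavage event collapse into a single site.
#'
#' @param track A `score_track` from [score_genome()].
#' @param threshold Minimum score (exclusive), e.g. 2.5 for stringent calls
#'   or 0.1 for sensitive calls.
#' @param merge_window Maximum gap (bp) between above-threshold positions
#'   merged into one site (default 20).
#' @return `data.frame(chrom, pos, score, start, end)` sorted by chromosome
#'   then position; `[start, end)` is the merged above-threshold interval.
#' @export
call_sites <- function(track, threshold, merge_window = 20L) {
  stopifnot(threshold > 0, merge_window >= 1L)
  hits <- as.data.frame(track)[track$score > threshold, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(chrom = character(0), pos = integer(0),
                      score = numeric(0), start = integer(0),
                      end = integer(0)))
  hits <- hits[order(hits$chrom, hits$pos), ]
  out <- do.call(rbind, lapply(split(hits, hits$chrom), function(h) {
    gap <- c(Inf, diff(h$pos))
    grp <- cumsum(gap > merge_window)
    do.call(rbind, lapply(split(h, grp), function(g) {
      best <- which.max(g$score)        # which.max takes the first = leftmost
      data.frame(chrom = g$chrom[1], pos = g$pos[best],
                 score = g$score[best], start = min(g$pos),
                 end = max(g$pos) + 1L, stringsAsFactors = FALSE)
    }))
  }))
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

# internal: accept a DNAStringSet, a named character vector, or a FASTA path
as_reference <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) return(reference)
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference))
    return(Biostrings::readDNAStringSet(reference))
  if (is.character(reference)) {
    if (is.null(names(reference)))
      names(reference) <- paste0("chr", seq_along(reference))
    return(Biostrings::DNAStringSet(reference))
  }
  stop("reference must be a DNAStringSet, FASTA path, or character vector",
       call. = FALSE)
}

#' Annotate a called site with its best protospacer+PAM match
#'
#' Scans every protospacer+PAM-length window on both strands within
#' `search_radius` bp of the site's representative position.  Among windows
#' whose PAM-position substring matches the guide's IUPAC PAM, the window
#' minimising Hamming mismatches to the protospacer wins (ties: closest to
#' the site position, then forward strand).  If no PAM-bearing window
#' exists, the overall minimum-mismatch window is returned with
#' `pam_ok = FALSE`.
#'
#' @param site One row of the data frame from [call_sites()] (or any list
#'   with `chrom` and `pos`).
#' @param reference Reference genome: `DNAStringSet`, FASTA path, or named
#'   character vector.
#' @param guide A [guide_rna()].
#' @param search_radius Search radius in bp around `site$pos` (default 25,
#'   covering the 9-13 bp nick stagger plus merge slack).
#' @return A one-row `data.frame` with the site columns plus `guide`,
#'   `matched_strand`, `matched_sequence` (protospacer+PAM, guide
#'   orientation), `matched_protospacer`, `matched_pam`, `mismatches`,
#'   `pam_ok` and `has_window_A`.
#' @export
annotate_site <- function(site, reference, guide, search_radius = 25L) {
  ref <- as_reference(reference)
  chrom <- as.character(site$chrom)
  if (!chrom %in% names(ref))
    stop("reference lacks chromosome ", chrom, call. = FALSE)
  chromseq <- ref[[chrom]]
  L <- length(chromseq)
  np <- nchar(guide$protospacer)
  npam <- nchar(guide$pam)
  w <- np + npam
  pos <- as.integer(site$pos)

  starts <- seq.int(max(0L, pos - search_radius),
                    min(L - w, pos + search_radius))
  if (!length(starts))
    stop("site ", chrom, ":", pos, " leaves no full window within bounds",
         call. = FALSE)
  proto <- strsplit(guide$protospacer, "")[[1]]
  pam_sets <- lapply(strsplit(guide$pam, "")[[1]], iupac_bases)

  best <- NULL
  consider <- function(strand, start0, seq_chr) {
    s <- strsplit(seq_chr, "")[[1]]
    mm <- sum(s[seq_len(np)] != proto)
    pam_chr <- s[np + seq_len(npam)]
    ok <- all(vapply(seq_len(npam),
                     function(k) pam_chr[k] %in% pam_sets[[k]], logical(1)))
    dist <- abs(start0 + (w - 1) / 2 - pos)
    cand <- list(strand = strand, start0 = start0, seq = seq_chr, mm = mm,
                 pam_ok = ok, dist = dist)
    if (is.null(best)) { best <<- cand; return(invisible()) }
    better <-
      (cand$pam_ok && !best$pam_ok) ||
      (cand$pam_ok == best$pam_ok &&
         (cand$mm < best$mm ||
            (cand$mm == best$mm && cand$dist < best$dist)))
    if (better) best <<- cand
    invisible()
  }
  region <- as.character(Biostrings::subseq(chromseq, starts[1] + 1L,
                                            starts[length(starts)] + w))
  for (s0 in starts) {
    off <- s0 - starts[1]
    win <- substr(region, off + 1L, off + w)
    consider("+", s0, win)                       # PAM 3' on forward strand
    consider("-", s0, revcomp(win))              # PAM 3' on reverse strand
  }
  wd <- guide$deamination_window
  proto_part <- substr(best$seq, 1L, np)
  pam_part <- substr(best$seq, np + 1L, w)
  window_bases <- strsplit(substr(proto_part, wd[1], wd[2]), "")[[1]]
  out <- data.frame(
    chrom = chrom, pos = pos,
    score = if (!is.null(site$score)) site$score else NA_real_,
    start = if (!is.null(site$start)) site$start else pos,
    end = if (!is.null(site$end)) site$end else pos + 1L,
    guide = guide$name,
    matched_strand = best$strand,
    matched_sequence = best$seq,
    matched_protospacer = proto_part,
    matched_pam = pam_part,
    mismatches = best$mm,
    pam_ok = best$pam_ok,
    has_window_A = any(window_bases == "A"),
    stringsAsFactors = FALSE
  )
  out
}

#' Annotate sites against one or more guides
#'
#' Each site is annotated against every guide and keeps the annotation with
#' the fewest mismatches (PAM-bearing matches preferred; ties broken by
#' guide order).
#'
#' @param sites Data frame from [call_sites()].
#' @param reference See [annotate_site()].
#' @param guides A `guide_rna` or list of them.
#' @param search_radius See [annotate_site()].
#' @return Data frame of annotated sites, one row per input site.
#' @export
annotate_sites <- function(sites, reference, guides, search_radius = 25L) {
  if (inherits(guides, "guide_rna")) guides <- list(guides)
  ref <- as_reference(reference)
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    anns <- lapply(guides, function(g)
      annotate_site(sites[i, ], ref, g, search_radius))
    key <- vapply(anns, function(a) a$mismatches + ifelse(a$pam_ok, 0, 1000),
                  numeric(1))
    anns[[which.min(key)]]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare two site lists
#'
#' Two sites are shared when they lie on the same chromosome within
#' `tolerance` bp of each other; matching is greedy nearest-first and each
#' site is counted once, so `only_a + shared == nrow(a)` and
#' `only_b + shared == nrow(b)`.
#'
#' @param a,b Site data frames with `chrom` and `pos` columns.
#' @param tolerance Maximum position difference in bp (default 25).
#' @return A list with counts `only_a`, `only_b`, `shared`, and a data frame
#'   `pairs` of matched positions.
#' @export
compare_site_lists <- function(a, b, tolerance = 25L) {
  pairs <- data.frame(chrom = character(0), pos_a = integer(0),
                      pos_b = integer(0))
  used_a <- logical(nrow(a))
  used_b <- logical(nrow(b))
  if (nrow(a) && nrow(b)) {
    cand <- do.call(rbind, lapply(intersect(unique(a$chrom), unique(b$chrom)),
                                  function(ch) {
      ia <- which(a$chrom == ch)
      ib <- which(b$chrom == ch)
      g <- expand.grid(ia = ia, ib = ib)
      g$d <- abs(a$pos[g$ia] - b$pos[g$ib])
      g[g$d <= tolerance, , drop = FALSE]
    }))
    if (!is.null(cand) && nrow(cand)) {
      cand <- cand[order(cand$d), ]
      for (k in seq_len(nrow(cand))) {
        i <- cand$ia[k]; j <- cand$ib[k]
        if (!used_a[i] && !used_b[j]) {
          used_a[i] <- TRUE
          used_b[j] <- TRUE
          pairs <- rbind(pairs, data.frame(chrom = a$chrom[i],
                                           pos_a = a$pos[i],
                                           pos_b = b$pos[j]))
        }
      }
    }
  }
  list(only_a = sum(!used_a), only_b = sum(!used_b), shared = sum(used_a),
       pairs = pairs)
}

#' Write called sites as BED6 plus an annotation table
#'
#' @param sites Annotated site data frame from [annotate_sites()].
#' @param bed_path Output BED6 path (`chrom`, `start`, `end`, guide name,
#'   score, matched strand).
#' @param table_path Optional path for the full tab-separated annotation
#'   table.
#' @return `bed_path`, invisibly.
#' @export
write_sites_bed <- function(sites, bed_path, table_path = NULL) {
  bed <- data.frame(sites$chrom, sites$start, sites$end,
                    if (!is.null(sites$guide)) sites$guide else ".",
                    sites$score,
                    if (!is.null(sites$matched_strand))
                      sites$matched_strand else ".")
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(table_path))
    utils::write.table(sites, table_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(bed_path)
}
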