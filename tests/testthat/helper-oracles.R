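# Independent oracles and small fixture builders used across the suite.

# Naive loop transcription of the printed cleavage-score equation, with the
# same zero-denominator / min-start clamping conventions.  Deliberately
# scalar and offset-by-offset so it shares no code with score_at().
naive_score <- function(D, F_, R_, i0, min_start = 2L) {
  g <- function(v, p0) if (p0 >= 0 && p0 < length(v)) v[p0 + 1] else 0
  s <- 0
  for (a in 1:5) {
    Fi <- g(F_, i0); Di <- g(D, i0); Ra <- g(R_, i0 + 8 + a)
    if (Di > 0 && Fi >= min_start && Ra >= min_start)
      s <- s + (Fi - 1) / Di * (Ra - 1) / Di * (Fi + Ra - 2)
  }
  for (a in 1:5) {
    R11 <- g(R_, i0 + 11); D11 <- g(D, i0 + 11)
    Fa <- g(F_, i0 - 3 + a); Da <- g(D, i0 - 3 + a)
    if (D11 > 0 && Da > 0 && R11 >= min_start && Fa >= min_start)
      s <- s + (R11 - 1) / D11 * (Fa - 1) / Da * (R11 + Fa - 2)
  }
  s
}

# wrap raw vectors into a position_counts object (positions 0..L, vectors
# length L+1 as the package stores them)
make_counts <- function(D, F_, R_, chrom = "chr1") {
  L <- length(D) - 1L
  structure(list(chrom_lengths = structure(L, names = chrom),
                 counts = structure(list(list(D = as.integer(D),
                                              F = as.integer(F_),
                                              R = as.integer(R_))),
                                    names = chrom),
                 n_forward = sum(F_), n_reverse = sum(R_),
                 reverse_five_prime = "nick"),
            class = "position_counts")
}

# plain recursive Levenshtein with memoisation — an oracle independent of
# the package's row DP
lev_recursive <- function(a, b) {
  sa <- strsplit(toupper(a), "")[[1]]
  sb <- strsplit(toupper(b), "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    v <- min(rec(i - 1, j) + 1, rec(i, j - 1) + 1,
             rec(i - 1, j - 1) + (sa[i] != sb[j]))
    memo[[key]] <- v
    v
  }
  rec(length(sa), length(sb))
}

# random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# write a minimal single-read-friendly SAM file
write_test_sam <- function(path, records,
                           chrom_lengths = c(chr1 = 1000L)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                     chrom_lengths), con)
  if (length(records)) writeLines(records, con)
  invisible(path)
}

sam_record <- function(qname, flag, chrom, pos1, mapq, cigar, seq) {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
          qname, flag, chrom, pos1, mapq, cigar, seq,
          strrep("I", nchar(seq)))
}

# the five 20-nt guides of the bundled multiplex set (the 18-nt HBB-28
# guide's nick stagger falls partly outside the score's alpha-window)
guides20 <- function() {
  Filter(function(g) nchar(g$protospacer) == 20L, multiplex_guides())
}
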