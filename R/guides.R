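#' Define a guide RNA
#'
#' A guide RNA is described by its protospacer (the genomic strand matched by
#' the spacer, written 5'->3'), a PAM pattern in IUPAC code immediately 3' of
#' the protospacer, and the deamination window: the protospacer positions
#' (1-based, counted from the PAM-distal end) where the adenine deaminase is
#' active.
#'
#' @param name Guide identifier.
#' @param protospacer DNA string over ACGT, 16-24 nt, 5'->3'.
#' @param pam IUPAC pattern for the PAM (default `"NGG"`, SpCas9).
#' @param deamination_window Integer vector of length 2, inclusive 1-based
#'   protospacer positions of the editing window (default `c(4, 8)`).
#' @return A `guide_rna` object (a named list).
#' @examples
#' guide_rna("EMX1", "GAGTCCGAGCAGAAGAAGAA")
#' @export
guide_rna <- function(name, protospacer, pam = "NGG",
                      deamination_window = c(4L, 8L)) {
  protospacer <- toupper(protospacer)
  pam <- toupper(pam)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("guide name must be a non-empty string", call. = FALSE)
  if (!grepl("^[ACGT]+$", protospacer))
    stop("protospacer of ", name, " must be over the alphabet ACGT",
         call. = FALSE)
  n <- nchar(protospacer)
  if (n < 16L || n > 24L)
    stop("protospacer of ", name, " must be 16-24 nt, got ", n, call. = FALSE)
  iupac <- "^[ACGTRYSWKMBDHVN]+$"
  if (!grepl(iupac, pam))
    stop("PAM of ", name, " is not a valid IUPAC pattern: ", pam,
         call. = FALSE)
  deamination_window <- as.integer(deamination_window)
  if (length(deamination_window) != 2L ||
      deamination_window[1] < 1L || deamination_window[2] > n ||
      deamination_window[1] > deamination_window[2])
    stop("deamination window of ", name, " must lie within 1..", n,
         call. = FALSE)
  structure(
    list(name = name, protospacer = protospacer, pam = pam,
         deamination_window = deamination_window),
    class = "guide_rna"
  )
}

#' @export
print.guide_rna <- function(x, ...) {
  cat(sprintf("<guide_rna> %s: %s + %s (window %d-%d)\n",
              x$name, x$protospacer, x$pam,
              x$deamination_window[1], x$deamination_window[2]))
  invisible(x)
}

#' Read a guide table
#'
#' Reads a tab-separated table with columns `name`, `protospacer` and
#' optionally `pam` into a list of [guide_rna()] objects.
#'
#' @param path Path to a TSV file.
#' @return List of `guide_rna` objects.
#' @export
read_guides <- function(path) {
  if (!file.exists(path)) stop("guide table not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("name", "protospacer") %in% names(tab)))
    stop("guide table needs columns 'name' and 'protospacer'", call. = FALSE)
  if (anyDuplicated(tab$name))
    stop("duplicate guide names in ", path, call. = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    guide_rna(tab$name[i], tab$protospacer[i],
              pam = if ("pam" %in% names(tab)) tab$pam[i] else "NGG")
  })
}

#' The six multiplex guides
#'
#' Returns the guide set used for the six-guide multiplex digestion
#' (HEK293-2, EMX1, FANCF, HBB-28(T>C), RNF2, HBG).  The protospacer strings
#' shipped with the package are reconstructions of these well-characterised
#' targets from the primary literature (see
#' `inst/extdata/multiplex_guides_synthetic.tsv`); they are suitable for
#' exercising the allocator but are not an authoritative transcription of any
#' specific experiment.
#'
#' @return List of six `guide_rna` objects.
#' @export
multiplex_guides <- function() {
  read_guides(system.file("extdata", "multiplex_guides_synthetic.tsv",
                          package = "endovseq", mustWork = TRUE))
}

# internal: expand one IUPAC pattern character to its base set
iupac_bases <- function(ch) {
  switch(ch,
         A = "A", C = "C", G = "G", T = "T",
         R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
         W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
         B = c("C", "G", "T"), D = c("A", "G", "T"),
         H = c("A", "C", "T"), V = c("A", "C", "G"),
         N = c("A", "C", "G", "T"),
         stop("invalid IUPAC code: ", ch, call. = FALSE))
}

# internal: does `seq` (ACGT) match the IUPAC `pattern` of equal length?
iupac_match <- function(seq, pattern) {
  if (nchar(seq) != nchar(pattern)) return(FALSE)
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  all(vapply(seq_along(s), function(i) s[i] %in% iupac_bases(p[i]), logical(1)))
}

# internal: reverse complement for plain character strings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
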