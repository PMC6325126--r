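#' Levenshtein edit distance
#'
#' Minimum number of unit-cost insertions, deletions and substitutions
#' transforming `a` into `b`, by dynamic programming.  Comparison is
#' case-insensitive (DNA strings).
#'
#' @param a,b Character strings (vectors are recycled pairwise).
#' @return Integer vector of distances.
#' @examples
#' levenshtein("kitten", "sitting")  # 3
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(toupper(a), n)
  b <- rep_len(toupper(b), n)
  vapply(seq_len(n), function(k) lev1(a[k], b[k]), integer(1))
}

# internal: single-pair DP, row-vectorised
lev1 <- function(a, b) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  m <- length(sa)
  n <- length(sb)
  if (m == 0L) return(n)
  if (n == 0L) return(m)
  prev <- 0:n                                    # row i-1, indices 0..n
  jj <- seq_len(n)
  for (i in seq_len(m)) {
    # candidate costs without the intra-row insertion recurrence
    v <- pmin(prev[jj] + (sb != sa[i]),          # substitution / match
              prev[jj + 1L] + 1L)                # deletion from a
    # fold in insertions: cur[j] = min_{k<=j} (u[k] + j - k)
    u <- c(i, v - jj)
    cur <- cummin(u) + 0:n
    prev <- cur
  }
  as.integer(prev[n + 1L])
}

# internal: the string a guide contributes to edit-distance comparisons
guide_site_string <- function(guide, include_pam = FALSE) {
  if (include_pam) paste0(guide$protospacer, concrete_pam(guide$pam))
  else guide$protospacer
}

# internal: IUPAC PAM -> representative concrete string (N -> A is arbitrary
# but fixed; distances involving degenerate positions are approximate)
concrete_pam <- function(pam) {
  paste(vapply(strsplit(pam, "")[[1]],
               function(ch) iupac_bases(ch)[1], character(1)),
        collapse = "")
}

#' Pairwise edit-distance matrix over guide target sites
#'
#' @param guides List of [guide_rna()] objects (at least two, unique names).
#' @param include_pam Append the PAM to each site string before comparison
#'   (default `FALSE`: protospacers only).
#' @return An `edit_distance_matrix`: square integer matrix with guide names
#'   as dimnames.
#' @export
build_distance_matrix <- function(guides, include_pam = FALSE) {
  if (inherits(guides, "guide_rna")) guides <- list(guides)
  if (length(guides) < 2L) stop("need at least two guides", call. = FALSE)
  nms <- vapply(guides, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate guide names: ",
         paste(nms[duplicated(nms)], collapse = ", "), call. = FALSE)
  strs <- vapply(guides, guide_site_string, character(1),
                 include_pam = include_pam)
  k <- length(strs)
  m <- matrix(0L, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    m[i, j] <- m[j, i] <- lev1(strs[i], strs[j])
  }
  structure(m, class = c("edit_distance_matrix", "matrix", "array"))
}

#' Summarise an edit-distance matrix
#'
#' The mean is taken over distinct off-diagonal unordered pairs; the zero
#' diagonal (each site against itself) is reported separately by
#' construction.
#'
#' @param m An `edit_distance_matrix`.
#' @return List with `max`, `max_pair` (character vector of the two guide
#'   names attaining the maximum, first such pair in row order), and `mean`.
#' @export
edit_distance_summary <- function(m) {
  ut <- upper.tri(m)
  mx <- max(m[ut])
  idx <- which(m == mx & ut, arr.ind = TRUE)[1, ]
  list(max = mx,
       max_pair = c(rownames(m)[idx[1]], colnames(m)[idx[2]]),
       mean = mean(m[ut]))
}

#' Allocate captured sites to guides by edit distance
#'
#' Each site's matched protospacer is compared with every guide's site
#' string by Levenshtein distance and assigned to the nearest guide,
#' mirroring the multiplex deconvolution in which one digestion carries
#' several guides and captured sites are attributed afterwards.  Ties are
#' broken by guide order and flagged.
#'
#' @param sites Annotated site data frame (needs `matched_protospacer`, or
#'   `matched_sequence` when `include_pam = TRUE`).
#' @param guides List of [guide_rna()] objects.
#' @param include_pam Compare protospacer+PAM strings instead of
#'   protospacers alone (default `FALSE`).
#' @return The input data frame with columns `allocated_guide`,
#'   `allocation_distance` and `allocation_tie` appended.
#' @export
allocate_sites <- function(sites, guides, include_pam = FALSE) {
  if (inherits(guides, "guide_rna")) guides <- list(guides)
  if (!length(guides)) stop("empty guide list", call. = FALSE)
  nms <- vapply(guides, `[[`, character(1), "name")
  gstr <- vapply(guides, guide_site_string, character(1),
                 include_pam = include_pam)
  qry <- if (include_pam) sites$matched_sequence else sites$matched_protospacer
  if (is.null(qry))
    stop("sites lack matched sequences; annotate them first", call. = FALSE)
  d <- vapply(gstr, function(g) levenshtein(qry, g),
              integer(length(qry)))
  d <- matrix(d, nrow = length(qry))
  best <- apply(d, 1L, which.min)                  # first minimum = tie break
  mins <- d[cbind(seq_along(best), best)]
  tie <- rowSums(d == mins) >= 2L
  out <- sites
  out$allocated_guide <- nms[best]
  out$allocation_distance <- as.integer(mins)
  out$allocation_tie <- tie
  out
}
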