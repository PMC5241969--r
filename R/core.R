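# Disease-ID mapping, homology-template scoring and small shared helpers.

#' Map disease names to disease IDs through a lookup table
#'
#' A pluggable stand-in for a named-entity normaliser: names are lower-cased
#' and trimmed, then looked up; unmapped names are dropped and their count
#' reported, so only mutations whose disease names map are retained
#' downstream.
#'
#' @param names character vector of raw disease names.
#' @param table named character vector (normalised name -> ID), e.g. from
#'   [read_disease_table()].
#' @return character vector of mapped IDs (order preserved, unmapped
#'   dropped).
#' @export
map_disease_names <- function(names, table) {
  key <- tolower(trimws(names))
  ids <- unname(table[key])
  n_drop <- sum(is.na(ids))
  if (n_drop > 0) message(n_drop, " disease name(s) could not be mapped; dropped")
  ids[!is.na(ids)]
}

#' Do two disease-ID sets indicate the same disease?
#'
#' Two mutations "cause the same disease" iff their disease-ID sets
#' intersect; mutations may carry several phenotypes.
#'
#' @param a,b character vectors of disease IDs.
#' @return logical scalar; FALSE when either set is empty.
#' @export
same_disease <- function(a, b) length(intersect(a, b)) > 0

#' Homology-template match score
#'
#' m = SeqID1 * Cov1 + SeqID2 * Cov2 over the two target proteins; used to
#' rank candidate co-crystal templates. All four inputs are fractions in
#' \[0, 1\], so m lies in \[0, 2\].
#'
#' @param seqid1,cov1 sequence identity and coverage of the first target.
#' @param seqid2,cov2 sequence identity and coverage of the second target.
#' @return the match score.
#' @export
match_score <- function(seqid1, cov1, seqid2, cov2) {
  v <- c(seqid1, cov1, seqid2, cov2)
  if (any(v < 0) || any(v > 1)) stop("identities and coverages must lie in [0, 1]")
  seqid1 * cov1 + seqid2 * cov2
}

#' Is a template candidate admissible for homology modelling?
#'
#' Requires sequence identity and coverage above 40% for both target
#' proteins (all four quantities > 0.40).
#'
#' @inheritParams match_score
#' @param cutoff admissibility threshold on each quantity (default 0.40).
#' @return logical scalar.
#' @export
template_admissible <- function(seqid1, cov1, seqid2, cov2, cutoff = 0.40) {
  v <- c(seqid1, cov1, seqid2, cov2)
  if (any(v < 0) || any(v > 1)) stop("identities and coverages must lie in [0, 1]")
  all(v > cutoff)
}

# All unordered pairs of indices 1..n as a 2-column integer matrix,
# vectorised (no combn) so millions of pairs stay cheap.
pair_index <- function(n) {
  if (n < 2) return(matrix(integer(0), ncol = 2,
                           dimnames = list(NULL, c("i", "j"))))
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  cbind(i = i, j = j)
}

# Pairwise same-disease indicator for a mutation table given a pair index
# matrix. Fast path: when every mutation carries at most one disease ID the
# check collapses to vectorised equality.
pair_same_disease <- function(muts, idx) {
  if (nrow(idx) == 0) return(logical(0))
  ids <- muts$diseases
  lens <- lengths(ids)
  if (all(lens <= 1L)) {
    d <- vapply(ids, function(x) if (length(x)) x else NA_character_, "")
    out <- !is.na(d[idx[, 1]]) & !is.na(d[idx[, 2]]) &
      d[idx[, 1]] == d[idx[, 2]]
    out[is.na(out)] <- FALSE
    return(out)
  }
  vapply(seq_len(nrow(idx)),
         function(k) same_disease(ids[[idx[k, 1]]], ids[[idx[k, 2]]]),
         logical(1))
}
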